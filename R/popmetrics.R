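# Signal correlation, between-session similarity, trial reliability ----------

#' Pairwise signal-correlation matrix
#'
#' Signal correlation between two neurons is the Pearson correlation of
#' their stimulus-averaged response vectors (one mean per grating across
#' retained trials). Neurons with a constant mean vector have undefined
#' correlations and are dropped with a warning.
#'
#' @param session A `session_data` (after [filter_trials()]).
#' @param neurons Optional subset of neuron ids.
#' @return A `signal_corr` object: the correlation matrix with neuron ids as
#'   dimnames.
#' @export
signal_correlation <- function(session, neurons = NULL) {
  stopifnot(inherits(session, "session_data"))
  ids <- if (is.null(neurons)) session$neuron_ids else neurons
  if (length(ids) < 2L) stop("need >= 2 neurons", call. = FALSE)
  idx <- match(ids, session$neuron_ids)
  if (anyNA(idx)) stop("unknown neuron id", call. = FALSE)
  m <- apply(session$responses[idx, , , drop = FALSE], c(1, 2), mean,
             na.rm = TRUE)
  const <- apply(m, 1, function(v) stats::sd(v) == 0 || !is.finite(stats::sd(v)))
  if (any(const)) {
    warning(sprintf("dropping %d neuron(s) with constant mean vector",
                    sum(const)), call. = FALSE)
    m <- m[!const, , drop = FALSE]
    ids <- ids[!const]
  }
  if (nrow(m) < 2L)
    stop("fewer than 2 neurons with non-constant mean vectors",
         call. = FALSE)
  cm <- stats::cor(t(m))
  dimnames(cm) <- list(ids, ids)
  structure(cm, class = c("signal_corr", "matrix"))
}

#' Similarity of two signal-correlation matrices
#'
#' Pearson correlation over the vectorized strict upper triangles (the
#' diagonal of ones is excluded so that self-correlations cannot inflate the
#' agreement). Both matrices must cover the same neurons in the same order.
#'
#' @param m1,m2 `signal_corr` matrices.
#' @return Pearson correlation scalar.
#' @export
similarity <- function(m1, m2) {
  if (!identical(rownames(m1), rownames(m2)))
    stop("signal-correlation matrices cover different neuron sets",
         call. = FALSE)
  ut <- upper.tri(m1)
  stats::cor(m1[ut], m2[ut])
}

#' Trial-to-trial response reliability at the preferred stimulus
#'
#' Reliability of a neuron is the proportion of preferred-stimulus trials on
#' which the response is at least `n_sd` (default 2) standard deviations
#' above the gray-screen baseline mean. The preferred stimulus is the grid
#' point nearest the fitted (mu_theta, mu_sf).
#'
#' @param session A `session_data` with `baseline` samples.
#' @param fits Fit table ([fit_table()]) for the neurons of interest; only
#'   rows with `sig & converged` are scored.
#' @param n_sd Threshold multiplier (default 2).
#' @return data.frame with `neuron_id`, `reliability`, `threshold`,
#'   `baseline_mean`, `baseline_sd`, `pref_stim`.
#' @export
reliability <- function(session, fits, n_sd = 2) {
  stopifnot(inherits(session, "session_data"))
  if (is.null(session$baseline) || ncol(session$baseline) == 0L)
    stop_field("baseline", "session carries no baseline samples")
  tuned <- fits[fits$sig & fits$converged, , drop = FALSE]
  rows <- lapply(seq_len(nrow(tuned)), function(i) {
    nid <- tuned$neuron_id[i]
    ni <- match(nid, session$neuron_ids)
    base <- session$baseline[ni, ]
    bm <- mean(base)
    bs <- stats::sd(base)
    thr <- bm + n_sd * bs
    if (bs == 0 && bm == 0) thr <- 0  # degenerate: any positive response
    ps <- nearest_stimulus(session$grid, tuned$mu_theta[i], tuned$mu_sf[i])
    resp <- session$responses[ni, ps, ]
    resp <- resp[!is.na(resp)]
    rel <- if (thr == 0) mean(resp > 0) else mean(resp >= thr)
    data.frame(neuron_id = nid, reliability = rel, threshold = thr,
               baseline_mean = bm, baseline_sd = bs, pref_stim = ps,
               stringsAsFactors = FALSE)
  })
  if (length(rows) == 0L)
    return(data.frame(neuron_id = character(), reliability = numeric(),
                      threshold = numeric(), baseline_mean = numeric(),
                      baseline_sd = numeric(), pref_stim = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
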