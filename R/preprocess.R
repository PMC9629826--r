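# Preprocessing: event traces -> response tensor, trial QC, responsivity ----

#' Extract per-presentation responses from event traces
#'
#' For each stimulus presentation, the response is the mean event count over
#' the frames falling inside the response window (default 194--320 ms after
#' stimulus onset). A frame belongs to the window when its center time,
#' `(frame - onset + 0.5) / frame_rate`, lies in `[window[1], window[2])` ms.
#' At 15.5 Hz this selects the two frames spanning roughly 194--320 ms.
#' Presentations whose window extends past the end of the trace are marked
#' invalid (NA) with a warning.
#'
#' @param events Neurons x frames matrix of per-frame event counts (a vector
#'   is treated as one neuron).
#' @param onsets data.frame with columns `frame` (1-based onset frame) and
#'   `stim` (stimulus index).
#' @param frame_rate Acquisition rate, Hz (> 0).
#' @param grid A [stim_grid()]; defines the stimulus axis length.
#' @param window Response window in ms, `c(start, end)` with start < end.
#' @return Neurons x stimuli x trials array; trials are the per-stimulus
#'   presentation order. Stimuli with fewer presentations than the maximum
#'   are NA-padded.
#' @export
extract_responses <- function(events, onsets, frame_rate, grid,
                              window = c(194, 320)) {
  check_scalar(frame_rate, "frame_rate", 0, strict_lower = TRUE)
  if (window[1] >= window[2])
    stop_field("window", "start must be < end")
  if (is.vector(events)) events <- matrix(events, nrow = 1)
  n_frames <- ncol(events)
  if (any(onsets$frame < 1 | onsets$frame > n_frames))
    stop_field("onsets", "onset frames must lie within the trace")

  sel <- window_frames(frame_rate, window)
  n_stim <- grid$n_stim
  counts <- integer(n_stim)
  max_trials <- max(table(factor(onsets$stim, levels = seq_len(n_stim))))
  out <- array(NA_real_, dim = c(nrow(events), n_stim, max_trials))
  n_invalid <- 0L
  for (p in seq_len(nrow(onsets))) {
    s <- onsets$stim[p]
    counts[s] <- counts[s] + 1L
    frames <- onsets$frame[p] + sel
    if (max(frames) > n_frames) {
      n_invalid <- n_invalid + 1L
      next
    }
    out[, s, counts[s]] <- rowMeans(events[, frames, drop = FALSE])
  }
  if (n_invalid > 0L)
    warning(sprintf(
      "%d presentation(s) extend past the end of the trace; marked invalid",
      n_invalid), call. = FALSE)
  out
}

#' Frame offsets covered by a response window
#'
#' @param frame_rate Hz.
#' @param window `c(start, end)` in ms; a frame is included when its center
#'   time relative to onset lies in `[start, end)`.
#' @return Integer vector of onset-relative frame offsets (0 = onset frame).
#' @export
window_frames <- function(frame_rate, window = c(194, 320)) {
  frame_ms <- 1000 / frame_rate
  max_off <- ceiling(window[2] / frame_ms) + 1L
  off <- 0:max_off
  centers <- (off + 0.5) * frame_ms
  off[centers >= window[1] & centers < window[2]]
}

#' Remove locomotion- and blink-contaminated trials
#'
#' Any trial with a true flag is dropped for all neurons. Because the same
#' presentations are flagged for every neuron, the per-stimulus retained
#' trial counts are equal across neurons; stimuli with unequal retained
#' counts are NA-padded to the maximum. Errors if any stimulus loses all its
#' trials.
#'
#' @param session A `session_data` with `flags`.
#' @return The session with flagged trials removed and `flags` reset to all
#'   FALSE; the per-stimulus retained counts are attached as attribute
#'   `trial_counts`.
#' @export
filter_trials <- function(session) {
  stopifnot(inherits(session, "session_data"))
  if (is.null(session$flags) || length(session$flags) == 0L)
    stop_field("flags", "session carries no trial flags")
  flagged <- Reduce(`|`, session$flags)
  keep_counts <- rowSums(!flagged)
  if (any(keep_counts == 0L))
    stop(sprintf("all trials flagged for stimulus %s",
                 paste(which(keep_counts == 0L), collapse = ", ")),
         call. = FALSE)
  d <- dim(session$responses)
  n_keep <- max(keep_counts)
  out <- array(NA_real_, dim = c(d[1], d[2], n_keep),
               dimnames = list(dimnames(session$responses)[[1]], NULL, NULL))
  for (s in seq_len(d[2])) {
    keep <- which(!flagged[s, ])
    out[, s, seq_along(keep)] <- session$responses[, s, keep]
  }
  session$responses <- out
  session$flags <- lapply(session$flags, function(f)
    matrix(FALSE, d[2], n_keep))
  attr(session, "trial_counts") <- keep_counts
  session
}

#' Screen visually responsive neurons by one-way ANOVA
#'
#' For each neuron, a one-way ANOVA of single-trial responses with stimulus
#' as the factor; a neuron is responsive when p < alpha (default 0.01).
#' Degenerate data (zero variance everywhere with equal means) yield p = 1
#' by convention.
#'
#' @param session A `session_data` (after [filter_trials()]).
#' @param alpha Significance level (default 0.01).
#' @return data.frame with columns `neuron_id`, `p`, `responsive`.
#' @export
test_responsiveness <- function(session, alpha = 0.01) {
  stopifnot(inherits(session, "session_data"))
  check_scalar(alpha, "alpha", 0, 1)
  d <- dim(session$responses)
  stim_f <- factor(rep(seq_len(d[2]), times = d[3]))
  p <- vapply(seq_len(d[1]), function(i) {
    y <- as.numeric(session$responses[i, , ])
    ok <- !is.na(y)
    g <- stim_f[ok]
    y <- y[ok]
    if (min(table(g)) < 2L)
      stop("test_responsiveness requires >= 2 trials per stimulus",
           call. = FALSE)
    pv <- tryCatch(
      stats::oneway.test(y ~ g, var.equal = TRUE)$p.value,
      error = function(e) NaN)
    if (is.nan(pv)) 1 else pv  # degenerate: no variance anywhere
  }, numeric(1))
  data.frame(neuron_id = session$neuron_ids, p = p,
             responsive = p < alpha, stringsAsFactors = FALSE)
}

#' Deconvolve a fluorescence trace by greedy matching pursuit
#'
#' Generative model: `f = s * k + beta * p + b` with `s` a non-negative
#' event train, `k` a causal exponential kernel, `p` the neuropil trace and
#' `b` a constant baseline. Events are added greedily, one per iteration at
#' the (time, amplitude >= 0) giving the largest residual-sum-of-squares
#' reduction; `beta` and `b` are refit by least squares after each sweep of
#' additions; iteration stops when the residual variance falls to
#' `(1 + tol)` times the noise-variance estimate (from the median absolute
#' deviation of the first-differenced trace) or at the sweep cap (5 sweeps
#' per second of data).
#'
#' @param f Fluorescence trace.
#' @param p Neuropil trace, or NULL to omit the neuropil term.
#' @param kernel_tau Kernel decay constant, seconds.
#' @param frame_rate Hz.
#' @param tol Stopping tolerance on the residual variance (default 0).
#' @param events_per_sweep Events added between baseline refits.
#' @return A `deconv_model`: list with `s` (events per frame), `k`, `beta`,
#'   `b`, `fitted`, `residual`, `noise_sd`, `n_sweeps`, `converged`.
#' @export
deconvolve <- function(f, p = NULL, kernel_tau = 0.7, frame_rate = 15.5,
                       tol = 0, events_per_sweep = 10L) {
  if (any(!is.finite(f))) stop_field("f", "trace must be finite")
  n <- length(f)
  k <- exp_kernel(kernel_tau, frame_rate)
  kk <- sum(k^2)
  noise_sd <- stats::mad(diff(f)) / sqrt(2)
  target_var <- (1 + tol) * noise_sd^2
  max_sweeps <- max(2L, ceiling(5 * n / frame_rate))

  s <- numeric(n)
  beta <- 0
  b <- stats::median(f)
  refit_bg <- function(resid_of_events) {
    # least squares for beta, b on f - s*k
    if (is.null(p)) {
      beta <<- 0
      b <<- mean(resid_of_events)
    } else {
      co <- stats::coef(stats::lm(resid_of_events ~ p))
      b <<- co[[1]]
      beta <<- co[[2]]
    }
  }
  model_of <- function() {
    conv_causal(s, k) + (if (is.null(p)) 0 else beta * p) + b
  }

  converged <- FALSE
  n_sweeps <- 0L
  repeat {
    n_sweeps <- n_sweeps + 1L
    added <- 0L
    for (it in seq_len(events_per_sweep)) {
      r <- f - model_of()
      if (stats::var(r) <= target_var) break
      # cross-correlate residual with kernel; optimal amplitude at t is
      # <r, k_t>/||k||^2, RSS reduction a^2 ||k||^2 -> pick max correlation
      xc <- xcorr_kernel(r, k)
      t_best <- which.max(xc)
      a <- xc[t_best] / kk
      if (a <= 0) break
      s[t_best] <- s[t_best] + a
      added <- added + 1L
    }
    refit_bg(f - conv_causal(s, k))
    r <- f - model_of()
    if (stats::var(r) <= target_var) {
      converged <- TRUE
      break
    }
    if (added == 0L || n_sweeps >= max_sweeps) break
  }
  structure(
    list(s = s, k = k, beta = beta, b = unname(b), fitted = model_of(),
         residual = f - model_of(), noise_sd = noise_sd,
         n_sweeps = n_sweeps, converged = converged),
    class = "deconv_model")
}

# c_t = sum_j r[t + j] k[j+1]  (correlation of the residual with a kernel
# placed at onset t)
xcorr_kernel <- function(r, k) {
  n <- length(r)
  pad <- c(r, numeric(length(k)))
  out <- numeric(n)
  for (j in seq_along(k)) {
    out <- out + k[j] * pad[j:(j + n - 1L)]
  }
  out
}

#' @export
print.deconv_model <- function(x, ...) {
  cat(sprintf(
    "<deconv_model> %d events, beta=%.3f b=%.3f, %d sweeps, converged=%s\n",
    sum(x$s > 0), x$beta, x$b, x$n_sweeps, x$converged))
  invisible(x)
}
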