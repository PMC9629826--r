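# KNN stimulus decoding with set-based cross-validation ----------------------
#
# Population response vectors (one entry per neuron) are grouped into sets,
# each holding exactly one trial of every stimulus. Decoding is
# leave-one-set-out: a test vector's neighbors are all vectors outside its
# set, so every stimulus is equally represented among potential neighbors.
# Classification is by majority vote of the k = 4 nearest neighbors under
# Euclidean distance.

#' Partition a session into decoding sets
#'
#' Each set holds exactly one trial of every stimulus; the number of sets
#' equals the number of trials used. When more trials are available than the
#' target, trials are randomly subsampled (seeded).
#'
#' @param session A `session_data` (after [filter_trials()]).
#' @param n_sets Target number of sets; default is the minimum per-stimulus
#'   trial count.
#' @param seed Integer seed for subsampling/assignment.
#' @param neurons Optional subset of neuron ids.
#' @return A `decode_sets` object: list with `X` (vectors x neurons matrix),
#'   `stim` (true stimulus per vector), `set` (set index per vector),
#'   `n_sets`, `grid`, `neuron_ids`.
#' @export
make_sets <- function(session, n_sets = NULL, seed = 1L, neurons = NULL) {
  stopifnot(inherits(session, "session_data"))
  ids <- if (is.null(neurons)) session$neuron_ids else neurons
  idx <- match(ids, session$neuron_ids)
  resp <- session$responses[idx, , , drop = FALSE]
  n_stim <- dim(resp)[2]
  avail <- vapply(seq_len(n_stim),
                  function(s) sum(!is.na(resp[1, s, ])), integer(1))
  target <- if (is.null(n_sets)) min(avail) else as.integer(n_sets)
  if (target < 1L) stop("no trials available", call. = FALSE)
  if (any(avail < target))
    stop(sprintf("stimulus %s has fewer than %d trials",
                 paste(which(avail < target), collapse = ", "), target),
         call. = FALSE)
  set.seed(seed)
  X <- matrix(NA_real_, nrow = n_stim * target, ncol = length(ids))
  stim <- integer(n_stim * target)
  setid <- integer(n_stim * target)
  row <- 0L
  for (s in seq_len(n_stim)) {
    pool <- which(!is.na(resp[1, s, ]))
    chosen <- if (length(pool) == 1L) pool else
      sample(pool, target)
    for (g in seq_len(target)) {
      row <- row + 1L
      X[row, ] <- resp[, s, chosen[g]]
      stim[row] <- s
      setid[row] <- g
    }
  }
  structure(list(X = X, stim = stim, set = setid, n_sets = target,
                 grid = session$grid, neuron_ids = ids),
            class = "decode_sets")
}

#' KNN decoding with set-based cross-validation
#'
#' Each set is held out in turn; its vectors are classified by majority vote
#' of the k nearest (Euclidean) vectors among all other sets. Distance ties
#' resolve to the lower set index then the lower stimulus index; vote ties
#' resolve to the tied class whose nearest member is closest.
#'
#' @param x A `session_data` or a [make_sets()] result.
#' @param k Neighbor count (default 4).
#' @param seed Seed for set construction (and label shuffling, if any).
#' @param shuffle_labels If TRUE the stimulus labels of all vectors are
#'   permuted before decoding, a chance-level control.
#' @param ... Passed to [make_sets()] when `x` is a session.
#' @return A `decode_result`: list with `accuracy`, `confusion` (true x
#'   predicted counts, sf-major stimulus order), `per_sf` (accuracy per
#'   spatial frequency, averaged over orientations), `k`, `chance`,
#'   `n_sets`, `n_neurons`.
#' @export
knn_decode <- function(x, k = 4, seed = 1L, shuffle_labels = FALSE, ...) {
  sets <- if (inherits(x, "decode_sets")) x else
    make_sets(x, seed = seed, ...)
  if (sets$n_sets < 2L)
    stop("need >= 2 sets for cross-validation", call. = FALSE)
  if (k > sets$n_sets - 1L)
    stop("k exceeds the per-class neighbor pool (n_sets - 1)", call. = FALSE)
  stim <- sets$stim
  if (shuffle_labels) {
    set.seed(child_seed(seed, "shuffle"))
    stim <- stim[sample(length(stim))]
  }
  pred <- integer(length(stim))
  for (s in seq_len(sets$n_sets)) {
    test <- which(sets$set == s)
    train <- which(sets$set != s)
    pred[test] <- knn_predict(sets$X[test, , drop = FALSE],
                              sets$X[train, , drop = FALSE],
                              stim[train], sets$set[train], k)
  }
  summarize_decode(stim, pred, sets, k)
}

# classify rows of Xt against reference rows Xr with labels lab; tie-breaks:
# distance, then lower set index, then lower stimulus label
knn_predict <- function(Xt, Xr, lab, setid, k) {
  d2 <- outer(rowSums(Xt^2), rep(1, nrow(Xr))) +
    outer(rep(1, nrow(Xt)), rowSums(Xr^2)) - 2 * Xt %*% t(Xr)
  vapply(seq_len(nrow(Xt)), function(i) {
    ord <- order(d2[i, ], setid, lab)
    nb <- ord[seq_len(k)]
    votes <- table(lab[nb])
    top <- as.integer(names(votes)[votes == max(votes)])
    if (length(top) == 1L) return(top)
    # vote tie: tied class whose nearest member comes first in the ordering
    lab[nb][match(TRUE, lab[nb] %in% top)]
  }, integer(1))
}

summarize_decode <- function(stim, pred, sets, k) {
  n_stim <- sets$grid$n_stim
  conf <- matrix(0L, n_stim, n_stim)
  for (i in seq_along(stim)) conf[stim[i], pred[i]] <- conf[stim[i], pred[i]] + 1L
  acc <- mean(pred == stim)
  per_stim <- vapply(seq_len(n_stim), function(s) {
    idx <- stim == s
    if (!any(idx)) NA_real_ else mean(pred[idx] == s)
  }, numeric(1))
  n_ori <- length(sets$grid$orientations)
  per_sf <- vapply(seq_along(sets$grid$spatial_freqs), function(j) {
    mean(per_stim[((j - 1L) * n_ori + 1L):(j * n_ori)], na.rm = TRUE)
  }, numeric(1))
  names(per_sf) <- sets$grid$spatial_freqs
  structure(list(accuracy = acc, confusion = conf, per_sf = per_sf,
                 k = k, chance = 1 / n_stim, n_sets = sets$n_sets,
                 n_neurons = length(sets$neuron_ids)),
            class = "decode_result")
}

#' Decode low- and high-spatial-frequency stimuli separately
#'
#' The stimulus set is split at the boundary (inclusive on the low side) and
#' an independent decoder is run on each subset; chance is 1 over each
#' subset's size.
#'
#' @param session A `session_data`.
#' @param boundary Spatial-frequency split, cycles/degree (default 0.1).
#' @param k Neighbor count.
#' @param seed Integer seed.
#' @param ... Passed to [knn_decode()].
#' @return List with elements `low` and `high`, each a `decode_result`.
#' @export
sf_split_decode <- function(session, boundary = 0.1, k = 4, seed = 1L, ...) {
  stopifnot(inherits(session, "session_data"))
  g <- session$grid
  low_sf <- g$spatial_freqs[g$spatial_freqs <= boundary]
  high_sf <- g$spatial_freqs[g$spatial_freqs > boundary]
  if (length(low_sf) == 0L || length(high_sf) == 0L)
    stop("boundary does not split the grid", call. = FALSE)
  list(low = knn_decode(subset_sf(session, low_sf), k = k, seed = seed, ...),
       high = knn_decode(subset_sf(session, high_sf), k = k, seed = seed,
                         ...))
}

# restrict a session to a subset of spatial frequencies
subset_sf <- function(session, sfs) {
  g <- session$grid
  keep <- g$stimuli$sf %in% sfs
  session$responses <- session$responses[, keep, , drop = FALSE]
  session$flags <- lapply(session$flags, function(f)
    f[keep, , drop = FALSE])
  session$grid <- stim_grid(g$orientations, sfs)
  session
}

#' Match neuron and trial counts across sessions
#'
#' Restricts every session to the tracked neurons shared by all sessions
#' (optionally randomly subsampled to `n_neurons`, with the identical subset
#' used everywhere) and randomly subsamples trials so each stimulus has the
#' minimum per-stimulus trial count found across sessions (or `n_trials`).
#'
#' @param sessions List of `session_data` sharing tracked neuron ids.
#' @param seed Integer seed.
#' @param n_neurons,n_trials Optional explicit targets.
#' @return List of reduced sessions.
#' @export
subsample_match <- function(sessions, seed = 1L, n_neurons = NULL,
                            n_trials = NULL) {
  stopifnot(length(sessions) >= 2L)
  shared <- Reduce(intersect, lapply(sessions, `[[`, "neuron_ids"))
  if (length(shared) == 0L) stop("no shared neurons", call. = FALSE)
  set.seed(seed)
  if (!is.null(n_neurons) && n_neurons < length(shared))
    shared <- sort(sample(shared, n_neurons))
  min_trials <- min(vapply(sessions, function(se) {
    min(apply(!is.na(se$responses[1, , , drop = TRUE]), 1, sum))
  }, numeric(1)))
  target <- if (is.null(n_trials)) min_trials else min(n_trials, min_trials)
  lapply(sessions, function(se) {
    idx <- match(shared, se$neuron_ids)
    se$responses <- se$responses[idx, , , drop = FALSE]
    se$baseline <- se$baseline[idx, , drop = FALSE]
    se$neuron_ids <- shared
    n_stim <- dim(se$responses)[2]
    out <- array(NA_real_,
                 dim = c(length(shared), n_stim, target),
                 dimnames = list(shared, NULL, NULL))
    for (s in seq_len(n_stim)) {
      pool <- which(!is.na(se$responses[1, s, ]))
      chosen <- if (length(pool) == target) pool else sample(pool, target)
      out[, s, ] <- se$responses[, s, chosen]
    }
    se$responses <- out
    se$flags <- lapply(se$flags, function(f) matrix(FALSE, n_stim, target))
    if (!is.null(attr(se, "truth")))
      attr(se, "truth") <-
        attr(se, "truth")[match(shared, attr(se, "truth")$neuron_id), ]
    se
  })
}

#' Representational drift under a fixed classifier
#'
#' A KNN classifier is anchored to the training session: `acc_X1` is its
#' held-out (set-based cross-validated) accuracy within that session, and
#' `acc_X2` is its accuracy on every vector of a second session, with all
#' training-session vectors serving as neighbors. Only neurons tracked in
#' both sessions are used and trial counts are matched. Drift is
#' `acc_X2 - acc_X1`; a negative value means the second session is less
#' decodable by the first session's representation.
#'
#' If the test session is the training session itself, `acc_X2` is computed
#' with self-exclusion and equals `acc_X1` exactly.
#'
#' @param train,test `session_data` objects sharing tracked neuron ids.
#' @param k Neighbor count.
#' @param seed Integer seed (trial matching and set assignment).
#' @return A `drift_result`: list with `acc_X1`, `acc_X2`, `drift`, `k`,
#'   `n_neurons`, `n_trials`.
#' @export
fixed_classifier_drift <- function(train, test, k = 4, seed = 1L) {
  self_test <- identical(train$responses, test$responses) &&
    identical(train$neuron_ids, test$neuron_ids)
  matched <- subsample_match(list(train, test), seed = seed)
  train_m <- matched[[1]]
  test_m <- matched[[2]]
  tr_sets <- make_sets(train_m, seed = child_seed(seed, "train_sets"))
  cv <- knn_decode(tr_sets, k = k)
  acc1 <- cv$accuracy
  if (self_test) {
    acc2 <- acc1
  } else {
    te_sets <- make_sets(test_m, seed = child_seed(seed, "test_sets"))
    pred <- knn_predict(te_sets$X, tr_sets$X, tr_sets$stim, tr_sets$set, k)
    acc2 <- mean(pred == te_sets$stim)
  }
  structure(list(acc_X1 = acc1, acc_X2 = acc2, drift = acc2 - acc1, k = k,
                 n_neurons = length(train_m$neuron_ids),
                 n_trials = tr_sets$n_sets),
            class = "drift_result")
}

#' @export
print.decode_result <- function(x, ...) {
  cat(sprintf(
    "<decode_result> accuracy=%.4f (chance %.4f), k=%d, %d sets x %d neurons\n",
    x$accuracy, x$chance, x$k, x$n_sets, x$n_neurons))
  invisible(x)
}

#' @export
print.drift_result <- function(x, ...) {
  cat(sprintf(
    "<drift_result> acc_X1=%.4f acc_X2=%.4f drift=%+.4f (k=%d)\n",
    x$acc_X1, x$acc_X2, x$drift, x$k))
  invisible(x)
}
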