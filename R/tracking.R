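# Cross-session neuron identity from pre-aligned pixel masks -----------------

#' Match neurons across sessions by pixel-mask overlap
#'
#' Masks are sets of (row, col) pixel coordinates in a common, pre-aligned
#' field of view. Overlap between mask i of session A and mask j of session
#' B is intersection-over-union (the stricter, symmetric reading of
#' "percentage of overlapping pixels"); `method = "min"` divides by the
#' smaller mask instead. Pairs exceeding the threshold are accepted
#' greedily, by descending overlap, one-to-one.
#'
#' @param masks_a,masks_b Named lists of two-column matrices (row, col) of
#'   pixel coordinates; names are neuron ids.
#' @param threshold Acceptance threshold on overlap (default 0.75).
#' @param method `"iou"` (default) or `"min"` (intersection over smaller
#'   mask).
#' @return data.frame with columns `id_a`, `id_b`, `overlap`, sorted by
#'   descending overlap.
#' @export
match_neurons <- function(masks_a, masks_b, threshold = 0.75,
                          method = c("iou", "min")) {
  method <- match.arg(method)
  check_scalar(threshold, "threshold", 0, 1)
  keys_a <- lapply(masks_a, mask_keys)
  keys_b <- lapply(masks_b, mask_keys)

  cand <- expand.grid(a = seq_along(keys_a), b = seq_along(keys_b))
  cand$overlap <- mapply(function(i, j) {
    inter <- length(intersect(keys_a[[i]], keys_b[[j]]))
    if (inter == 0L) return(0)
    na <- length(keys_a[[i]])
    nb <- length(keys_b[[j]])
    denom <- if (method == "iou") na + nb - inter else min(na, nb)
    inter / denom
  }, cand$a, cand$b)
  cand <- cand[cand$overlap > threshold, , drop = FALSE]
  cand <- cand[order(-cand$overlap, cand$a, cand$b), , drop = FALSE]

  used_a <- logical(length(keys_a))
  used_b <- logical(length(keys_b))
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    i <- cand$a[r]; j <- cand$b[r]
    if (!used_a[i] && !used_b[j]) {
      keep[r] <- TRUE
      used_a[i] <- TRUE
      used_b[j] <- TRUE
    }
  }
  out <- cand[keep, , drop = FALSE]
  data.frame(
    id_a = mask_ids(masks_a)[out$a],
    id_b = mask_ids(masks_b)[out$b],
    overlap = out$overlap,
    stringsAsFactors = FALSE, row.names = NULL)
}

mask_ids <- function(masks) {
  if (!is.null(names(masks))) names(masks) else
    paste0("m", seq_along(masks))
}

mask_keys <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) == 0L) stop("empty neuron mask", call. = FALSE)
  paste(m[, 1], m[, 2], sep = ",")
}
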