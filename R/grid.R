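# Stimulus grid: the orientation x spatial-frequency lattice -----------------

#' Construct a stimulus grid
#'
#' The lattice of grating stimuli: every combination of an orientation
#' (degrees, axial with period 180) and a spatial frequency (cycles per
#' degree). Stimulus indices run spatial-frequency-major: all orientations at
#' the lowest spatial frequency first, then the next spatial frequency, and
#' so on. This is also the ordering of decoder confusion matrices.
#'
#' @param orientations Ascending unique orientations in [0, 180), degrees.
#' @param spatial_freqs Ascending unique positive spatial frequencies,
#'   cycles/degree.
#' @return An object of class `stim_grid` with elements `orientations`,
#'   `spatial_freqs`, `n_stim`, and a lookup table `stimuli` (data.frame with
#'   columns `stim`, `orientation`, `sf`).
#' @examples
#' g <- default_grid()
#' g$n_stim  # 180
#' @export
stim_grid <- function(orientations, spatial_freqs) {
  if (!is.numeric(orientations) || length(orientations) < 1L)
    stop_field("orientations", "must be a non-empty numeric vector")
  if (anyDuplicated(orientations) || is.unsorted(orientations, strictly = TRUE))
    stop_field("orientations", "must be strictly ascending and unique")
  if (any(orientations < 0 | orientations >= 180))
    stop_field("orientations", "must lie in [0, 180)")
  if (!is.numeric(spatial_freqs) || length(spatial_freqs) < 1L)
    stop_field("spatial_freqs", "must be a non-empty numeric vector")
  if (anyDuplicated(spatial_freqs) ||
      is.unsorted(spatial_freqs, strictly = TRUE))
    stop_field("spatial_freqs", "must be strictly ascending and unique")
  if (any(spatial_freqs <= 0))
    stop_field("spatial_freqs", "must be positive")

  n_ori <- length(orientations)
  n_sf <- length(spatial_freqs)
  stimuli <- data.frame(
    stim = seq_len(n_ori * n_sf),
    orientation = rep(orientations, times = n_sf),
    sf = rep(spatial_freqs, each = n_ori)
  )
  structure(
    list(orientations = orientations, spatial_freqs = spatial_freqs,
         n_stim = n_ori * n_sf, stimuli = stimuli),
    class = "stim_grid"
  )
}

#' The standard 12 x 15 grating grid
#'
#' Orientations 0 to 165 degrees in steps of 15; spatial frequencies 0.02 to
#' 0.30 cycles/degree in steps of 0.02. 180 stimuli in total.
#'
#' @return A [stim_grid()].
#' @export
default_grid <- function() {
  stim_grid(orientations = seq(0, 165, by = 15),
            spatial_freqs = seq(0.02, 0.30, by = 0.02))
}

#' Stimulus index of an (orientation, spatial frequency) pair
#'
#' @param grid A [stim_grid()].
#' @param orientation Orientation in degrees (must match a grid value after
#'   reduction modulo 180).
#' @param sf Spatial frequency in cycles/degree (must match a grid value).
#' @return Integer stimulus index in [1, n_stim].
#' @export
index_of <- function(grid, orientation, sf) {
  stopifnot(inherits(grid, "stim_grid"))
  io <- match_close(wrap_ori(orientation), grid$orientations)
  if (is.na(io)) stop_field("orientation", "not on the grid")
  is_ <- match_close(sf, grid$spatial_freqs)
  if (is.na(is_)) stop_field("sf", "not on the grid")
  (is_ - 1L) * length(grid$orientations) + io
}

# tolerant match for floating-point grid values
match_close <- function(x, table, tol = 1e-8) {
  i <- which(abs(table - x) < tol)
  if (length(i) == 1L) i else NA_integer_
}

#' Nearest grid stimulus to a fitted preference
#'
#' Orientation distance is taken on the axial circle; spatial-frequency
#' distance is linear. Ties go to the lower index (hence lower sf / lower
#' orientation).
#'
#' @param grid A [stim_grid()].
#' @param orientation,sf Fitted preferred orientation (deg) and spatial
#'   frequency (cycles/deg).
#' @return Integer stimulus index.
#' @export
nearest_stimulus <- function(grid, orientation, sf) {
  stopifnot(inherits(grid, "stim_grid"))
  io <- which.min(delta_ori(grid$orientations, orientation))
  is_ <- which.min(abs(grid$spatial_freqs - sf))
  (is_ - 1L) * length(grid$orientations) + io
}

#' @export
print.stim_grid <- function(x, ...) {
  cat(sprintf(
    "<stim_grid> %d orientations x %d spatial frequencies = %d stimuli\n",
    length(x$orientations), length(x$spatial_freqs), x$n_stim))
  cat(sprintf("  orientations: %s deg\n",
              paste(x$orientations, collapse = ", ")))
  cat(sprintf("  spatial freqs: %s cycles/deg\n",
              paste(x$spatial_freqs, collapse = ", ")))
  invisible(x)
}
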