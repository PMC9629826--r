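#' @keywords internal
"_PACKAGE"

# Orientation arithmetic on the 180-degree (axial) circle --------------------

#' Wrap an orientation difference into (-90, 90]
#'
#' Orientations of a sinusoidal grating are axial: 0 and 180 degrees are the
#' same stimulus. Residuals between orientations are therefore evaluated on
#' the 180-degree circle.
#'
#' @param d Numeric vector of orientation differences in degrees.
#' @return Differences wrapped into (-90, 90].
#' @export
wrap_ori_diff <- function(d) {
  w <- (d + 90) %% 180 - 90
  # map the -90 boundary to +90 so the range is (-90, 90]
  w[w == -90] <- 90
  w
}

#' Wrap an orientation into [0, 180)
#' @param theta Numeric vector of orientations in degrees.
#' @return Orientations reduced modulo 180.
#' @export
wrap_ori <- function(theta) theta %% 180

#' Absolute orientation-preference change on the axial circle
#'
#' The magnitude of a change in preferred orientation, taking the shorter arc
#' on the 180-degree circle; lies in [0, 90].
#'
#' @param a,b Orientations in degrees.
#' @return Absolute wrapped differences in degrees.
#' @export
delta_ori <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

# Seed fan-out ---------------------------------------------------------------

#' Derive a stage-specific child seed from a master seed
#'
#' Stable fan-out so that each pipeline stage is independently reproducible
#' from a single master seed. The stage name is hashed with a small
#' multiplicative mix; the result is kept in [1, 2^31 - 2].
#'
#' @param master Integer master seed.
#' @param stage Character scalar naming the stage.
#' @return An integer seed.
#' @export
child_seed <- function(master, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- as.double(master) %% 2147483647
  for (code in utf8ToInt(stage)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h %% 2147483646 + 1)
}

# Validation helpers ---------------------------------------------------------

stop_field <- function(field, msg) {
  stop(sprintf("invalid '%s': %s", field, msg), call. = FALSE)
}

check_scalar <- function(x, field, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_field(field, "must be a finite numeric scalar")
  if (strict_lower && x <= lower)
    stop_field(field, sprintf("must be > %g", lower))
  if (!strict_lower && x < lower)
    stop_field(field, sprintf("must be >= %g", lower))
  if (x > upper)
    stop_field(field, sprintf("must be <= %g", upper))
  invisible(x)
}
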