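# Synthetic session generator ------------------------------------------------
#
# Emulates the statistical structure of trial-based grating experiments in
# mouse V1: a population in which a fraction of neurons carries 2D Gaussian
# tuning over (orientation, spatial frequency), responses are event counts
# with Poisson (optionally overdispersed) trial noise, unreliable trials are
# Bernoulli-gated, and a fraction of trials is contaminated by locomotion or
# eye blinks.

#' Ground-truth tuning parameters for a synthetic population
#'
#' One row per neuron. Tuned neurons respond, on responsive trials, with mean
#' event count `B + G(theta, phi)` where `G` is the 2D Gaussian tuning
#' surface ([tuning_surface()]); untuned neurons and non-responsive trials
#' have mean `B`.
#'
#' @param is_tuned Logical vector, one per neuron.
#' @param A Amplitude parameter of the Gaussian surface (event units; the
#'   peak response above baseline is `A / (2 pi sigma_theta sigma_sf
#'   sqrt(1 - rho^2))`).
#' @param B Baseline event count per response window (>= 0).
#' @param mu_theta Preferred orientation, degrees in [0, 180).
#' @param mu_sf Preferred spatial frequency, cycles/degree; must lie within
#'   the grid's spatial-frequency range.
#' @param sigma_theta Orientation tuning width, degrees (>= 1).
#' @param sigma_sf Spatial-frequency tuning width, cycles/degree (>= 0.001).
#' @param rho Orientation/spatial-frequency correlation, |rho| < 1.
#' @param reliability Probability that a trial is responsive, in [0, 1].
#' @param grid A [stim_grid()] used to validate `mu_sf`.
#' @return A data.frame of class `ground_truth`.
#' @export
ground_truth <- function(is_tuned, A, B, mu_theta, mu_sf,
                         sigma_theta, sigma_sf, rho, reliability, grid) {
  stopifnot(inherits(grid, "stim_grid"))
  n <- length(is_tuned)
  df <- data.frame(
    neuron_id = paste0("n", seq_len(n)),
    is_tuned = as.logical(is_tuned),
    A = rep_len(A, n), B = rep_len(B, n),
    mu_theta = rep_len(mu_theta, n), mu_sf = rep_len(mu_sf, n),
    sigma_theta = rep_len(sigma_theta, n), sigma_sf = rep_len(sigma_sf, n),
    rho = rep_len(rho, n), reliability = rep_len(reliability, n),
    stringsAsFactors = FALSE
  )
  validate_truth(df, grid)
  class(df) <- c("ground_truth", "data.frame")
  attr(df, "grid") <- grid
  df
}

validate_truth <- function(df, grid) {
  if (any(df$A < 0)) stop_field("A", "must be >= 0")
  if (any(df$B < 0)) stop_field("B", "must be >= 0")
  if (any(df$sigma_theta < 1)) stop_field("sigma_theta", "must be >= 1 deg")
  if (any(df$sigma_sf < 0.001))
    stop_field("sigma_sf", "must be >= 0.001 cycles/deg")
  if (any(abs(df$rho) >= 1)) stop_field("rho", "must satisfy |rho| < 1")
  if (any(df$reliability < 0 | df$reliability > 1))
    stop_field("reliability", "must lie in [0, 1]")
  rng <- range(grid$spatial_freqs)
  if (any(df$mu_sf < rng[1] | df$mu_sf > rng[2]))
    stop_field("mu_sf", "must lie within the grid spatial-frequency range")
  if (any(df$mu_theta < 0 | df$mu_theta >= 180))
    stop_field("mu_theta", "must lie in [0, 180)")
  invisible(df)
}

#' Amplitude parameter giving a requested peak response
#'
#' @param peak Desired peak event count above baseline.
#' @param sigma_theta,sigma_sf,rho Width and correlation parameters.
#' @return The `A` value for [ground_truth()].
#' @export
amplitude_for_peak <- function(peak, sigma_theta, sigma_sf, rho = 0) {
  peak * 2 * pi * sigma_theta * sigma_sf * sqrt(1 - rho^2)
}

#' Draw a random synthetic population
#'
#' Convenience sampler for [ground_truth()]: a stated fraction of neurons is
#' tuned, with preferences uniform over the stimulus space and widths,
#' amplitudes and reliabilities drawn uniformly from plausible ranges for
#' deconvolved event responses in layer 2/3 of mouse V1.
#'
#' @param n_neurons Number of neurons.
#' @param grid A [stim_grid()].
#' @param tuned_fraction Fraction of tuned neurons (default 0.4, within the
#'   30--50% responsive range typical of these recordings).
#' @param peak_range Range of peak evoked event counts above baseline.
#' @param baseline_range Range of baseline event counts per window.
#' @param sigma_theta_range Orientation width range, degrees.
#' @param sigma_sf_range Spatial-frequency width range, cycles/degree.
#' @param rho_range Correlation range.
#' @param reliability_range Trial-reliability range.
#' @param seed Integer seed.
#' @return A [ground_truth()] data.frame.
#' @export
sample_population <- function(n_neurons, grid, tuned_fraction = 0.4,
                              peak_range = c(2, 6),
                              baseline_range = c(0.05, 0.3),
                              sigma_theta_range = c(12, 30),
                              sigma_sf_range = c(0.02, 0.08),
                              rho_range = c(-0.3, 0.3),
                              reliability_range = c(0.6, 0.9),
                              seed = 1L) {
  stopifnot(inherits(grid, "stim_grid"))
  check_scalar(tuned_fraction, "tuned_fraction", 0, 1)
  set.seed(seed)
  n_tuned <- round(n_neurons * tuned_fraction)
  is_tuned <- seq_len(n_neurons) <= n_tuned
  sfr <- range(grid$spatial_freqs)
  st <- stats::runif(n_neurons, sigma_theta_range[1], sigma_theta_range[2])
  ss <- stats::runif(n_neurons, sigma_sf_range[1], sigma_sf_range[2])
  rho <- stats::runif(n_neurons, rho_range[1], rho_range[2])
  peak <- stats::runif(n_neurons, peak_range[1], peak_range[2])
  ground_truth(
    is_tuned = is_tuned,
    A = amplitude_for_peak(peak, st, ss, rho),
    B = stats::runif(n_neurons, baseline_range[1], baseline_range[2]),
    mu_theta = stats::runif(n_neurons, 0, 180),
    mu_sf = stats::runif(n_neurons, sfr[1], sfr[2]),
    sigma_theta = st, sigma_sf = ss, rho = rho,
    reliability = stats::runif(n_neurons, reliability_range[1],
                               reliability_range[2]),
    grid = grid
  )
}

#' Expected response surface of a population on a grid
#'
#' The analytic per-stimulus mean response (including baseline and the
#' reliability gate's expectation if requested).
#'
#' @param truth A [ground_truth()].
#' @param grid A [stim_grid()].
#' @param include_reliability Multiply the tuned component by the reliability
#'   (the marginal mean over gated trials) rather than conditioning on a
#'   responsive trial.
#' @return Matrix neurons x stimuli of mean event counts.
#' @export
mean_surface <- function(truth, grid, include_reliability = FALSE) {
  th <- grid$stimuli$orientation
  ph <- grid$stimuli$sf
  out <- matrix(0, nrow = nrow(truth), ncol = grid$n_stim,
                dimnames = list(truth$neuron_id, NULL))
  for (i in seq_len(nrow(truth))) {
    g <- 0
    if (truth$is_tuned[i]) {
      g <- tuning_surface(th, ph,
                          A = truth$A[i], B = 0,
                          mu_theta = truth$mu_theta[i],
                          mu_sf = truth$mu_sf[i],
                          sigma_theta = truth$sigma_theta[i],
                          sigma_sf = truth$sigma_sf[i],
                          rho = truth$rho[i])
      if (include_reliability) g <- g * truth$reliability[i]
    }
    out[i, ] <- truth$B[i] + g
  }
  out
}

#' Generate one synthetic imaging session
#'
#' Tuned neurons respond on a fraction `reliability` of trials with mean
#' `B + G(theta, phi)` and otherwise with mean `B`; untuned neurons always
#' respond at `B`. Event counts are Poisson (or overdispersed via a
#' negative-binomial with the stated variance inflation). Gray-screen
#' baseline samples are drawn at rate `B`. A stated fraction of trials is
#' flagged as locomotion or eye-blink contaminated.
#'
#' @param grid A [stim_grid()].
#' @param truth A [ground_truth()].
#' @param n_trials Trials per stimulus (default 36, the typical number
#'   presented; exclusion then leaves roughly 25).
#' @param seed Integer seed; the session is fully reproducible from it.
#' @param flag_rates Named vector `c(locomotion=, blink=)` of per-trial
#'   contamination probabilities.
#' @param n_baseline Number of gray-screen baseline bins per neuron.
#' @param noise `"poisson"` (default) or `"none"` for the deterministic
#'   mean-surface limit.
#' @param dispersion Variance inflation factor (1 = Poisson; > 1 uses a
#'   negative binomial with variance `dispersion * mean`).
#' @return A `session_data` object: list with `responses` (neurons x stimuli
#'   x trials array), `baseline` (neurons x bins matrix), `flags` (list of
#'   stimulus x trial logical matrices), `neuron_ids`, `grid`. The generating
#'   `truth` is attached as an attribute.
#' @export
generate_session <- function(grid, truth, n_trials = 36, seed = 1L,
                             flag_rates = c(locomotion = 0.2, blink = 0.1),
                             n_baseline = 100,
                             noise = c("poisson", "none"),
                             dispersion = 1) {
  stopifnot(inherits(grid, "stim_grid"), inherits(truth, "ground_truth"))
  check_scalar(n_trials, "n_trials", 1)
  check_scalar(dispersion, "dispersion", 1)
  noise <- match.arg(noise)
  validate_truth(truth, grid)
  set.seed(seed)

  n_neuron <- nrow(truth)
  n_stim <- grid$n_stim
  surf <- mean_surface(truth, grid) - truth$B  # tuned component only

  # Bernoulli reliability gate per (neuron, stimulus, trial)
  gate <- array(
    stats::rbinom(n_neuron * n_stim * n_trials, 1L,
                  rep(truth$reliability, times = n_stim * n_trials)),
    dim = c(n_neuron, n_stim, n_trials))
  lambda <- array(rep(surf, times = n_trials),
                  dim = c(n_neuron, n_stim, n_trials)) * gate +
    truth$B
  responses <- draw_counts(lambda, noise, dispersion)
  dimnames(responses) <- list(truth$neuron_id, NULL, NULL)

  baseline <- draw_counts(matrix(truth$B, n_neuron, n_baseline),
                          noise, dispersion)
  rownames(baseline) <- truth$neuron_id

  flags <- lapply(flag_rates, function(p) {
    matrix(stats::rbinom(n_stim * n_trials, 1L, p) == 1L, n_stim, n_trials)
  })

  sess <- structure(
    list(responses = responses, baseline = baseline, flags = flags,
         neuron_ids = truth$neuron_id, grid = grid),
    class = "session_data")
  attr(sess, "truth") <- truth

  flagged <- Reduce(`|`, flags)
  if (any(rowSums(!flagged) == 0)) {
    bad <- which(rowSums(!flagged) == 0)
    stop(sprintf(
      "session rejected: stimulus %s has no unflagged trial",
      paste(bad, collapse = ", ")), call. = FALSE)
  }
  sess
}

draw_counts <- function(lambda, noise, dispersion) {
  out <- lambda
  if (noise == "none") return(out)
  v <- as.numeric(lambda)
  if (dispersion == 1) {
    x <- stats::rpois(length(v), v)
  } else {
    # NB with mean m and variance dispersion * m
    size <- v / (dispersion - 1)
    x <- ifelse(v > 0, stats::rnbinom(length(v), size = pmax(size, 1e-12),
                                      mu = v), 0)
  }
  out[] <- x
  out
}

#' Per-session condition specification for a longitudinal experiment
#'
#' @param name Session label (e.g. "B1", "B2", "pDE", "Rec").
#' @param theta_jitter SD (degrees) of the wrapped Gaussian jitter applied to
#'   each tuned neuron's preferred orientation relative to the previous
#'   session.
#' @param sf_jitter SD (cycles/degree) of the jitter on preferred spatial
#'   frequency (clamped to the grid range).
#' @param reliability_mult Multiplier applied to each neuron's base
#'   reliability for this session (clipped to [0, 1]).
#' @param reset If TRUE, tuning parameters rebound to their first-session
#'   values before this session's jitter is applied.
#' @return A list of class `session_spec`.
#' @export
session_spec <- function(name, theta_jitter = 0, sf_jitter = 0,
                         reliability_mult = 1, reset = FALSE) {
  check_scalar(theta_jitter, "theta_jitter", 0)
  check_scalar(sf_jitter, "sf_jitter", 0)
  check_scalar(reliability_mult, "reliability_mult", 0)
  structure(list(name = name, theta_jitter = theta_jitter,
                 sf_jitter = sf_jitter,
                 reliability_mult = reliability_mult, reset = reset),
            class = "session_spec")
}

#' Default four-session dark-exposure schedule
#'
#' Emulates the B1/B2/pDE/Rec design with planted effects: larger
#' orientation-preference drift across the control interval (B1 to B2) than
#' across dark exposure (B2 to pDE), reduced response reliability on the
#' post-dark-exposure session, and recovery after light reintroduction.
#'
#' @return List of four [session_spec()]s.
#' @export
default_schedule <- function() {
  list(
    session_spec("B1"),
    session_spec("B2", theta_jitter = 12, sf_jitter = 0.02),
    session_spec("pDE", theta_jitter = 4, sf_jitter = 0.01,
                 reliability_mult = 0.6),
    session_spec("Rec", theta_jitter = 8, sf_jitter = 0.02,
                 reliability_mult = 1)
  )
}

#' Generate a tracked multi-session experiment
#'
#' Sessions share neuron identities. Preferred orientations drift between
#' consecutive sessions by wrapped Gaussian jitter of the per-session scale;
#' reliability is scaled per-session relative to the base population; a
#' `reset = TRUE` session rebounds to the first session's parameters.
#'
#' @param grid A [stim_grid()].
#' @param truth Base-session [ground_truth()].
#' @param schedule List of [session_spec()]s (>= 2 sessions).
#' @param seed Integer seed.
#' @param ... Passed to [generate_session()] (`n_trials`, `flag_rates`, ...).
#' @return Named list of `session_data`, one per schedule entry; each carries
#'   its own per-session `truth` attribute.
#' @export
generate_experiment <- function(grid, truth, schedule, seed = 1L, ...) {
  stopifnot(inherits(grid, "stim_grid"), inherits(truth, "ground_truth"))
  if (!is.list(schedule) || length(schedule) < 2L)
    stop("schedule must list at least 2 sessions", call. = FALSE)
  set.seed(seed)
  n_sessions <- length(schedule)
  sess_seeds <- sample.int(2147483646L, n_sessions)
  sfr <- range(grid$spatial_freqs)

  current <- truth
  sessions <- vector("list", n_sessions)
  for (s in seq_len(n_sessions)) {
    sp <- schedule[[s]]
    stopifnot(inherits(sp, "session_spec"))
    if (isTRUE(sp$reset)) current <- truth
    if (s > 1L) {
      if (sp$theta_jitter > 0) {
        jit <- stats::rnorm(nrow(current), 0, sp$theta_jitter)
        current$mu_theta <- wrap_ori(current$mu_theta + jit)
      }
      if (sp$sf_jitter > 0) {
        jit <- stats::rnorm(nrow(current), 0, sp$sf_jitter)
        current$mu_sf <- pmin(pmax(current$mu_sf + jit, sfr[1]), sfr[2])
      }
    }
    sess_truth <- current
    sess_truth$reliability <-
      pmin(pmax(truth$reliability * sp$reliability_mult, 0), 1)
    sessions[[s]] <- generate_session(grid, sess_truth,
                                      seed = sess_seeds[s], ...)
  }
  names(sessions) <- vapply(schedule, `[[`, "", "name")
  sessions
}

#' Synthesize a calcium fluorescence trace from an event train
#'
#' The generative model for the indicator signal: events convolved with a
#' causal exponential kernel, plus scaled neuropil contamination, plus a
#' baseline, plus white Gaussian noise.
#'
#' @param events Per-frame event counts (numeric vector).
#' @param kernel_tau Indicator decay time constant, seconds (> 0).
#' @param frame_rate Acquisition rate, Hz (> 0).
#' @param neuropil_coef Neuropil scaling coefficient.
#' @param baseline Baseline fluorescence (a.u.).
#' @param noise_sd SD of additive Gaussian noise (>= 0).
#' @param neuropil Optional neuropil trace; if NULL a slow AR(1) drift is
#'   generated.
#' @param seed Integer seed.
#' @return List with `f` (fluorescence), `events`, `kernel`, `neuropil`,
#'   `neuropil_coef`, `baseline`, `noise_sd`, `frame_rate`, `kernel_tau`.
#' @export
generate_fluorescence <- function(events, kernel_tau = 0.7,
                                  frame_rate = 15.5, neuropil_coef = 0.7,
                                  baseline = 0, noise_sd = 0.05,
                                  neuropil = NULL, seed = 1L) {
  check_scalar(kernel_tau, "kernel_tau", 0, strict_lower = TRUE)
  check_scalar(frame_rate, "frame_rate", 0, strict_lower = TRUE)
  check_scalar(noise_sd, "noise_sd", 0)
  n <- length(events)
  set.seed(seed)
  k <- exp_kernel(kernel_tau, frame_rate)
  sig <- conv_causal(events, k)
  if (is.null(neuropil)) {
    neuropil <- as.numeric(stats::filter(stats::rnorm(n, 0, 0.1), 0.98,
                                         method = "recursive"))
  }
  f <- sig + neuropil_coef * neuropil + baseline +
    stats::rnorm(n, 0, noise_sd)
  list(f = f, events = events, kernel = k, neuropil = neuropil,
       neuropil_coef = neuropil_coef, baseline = baseline,
       noise_sd = noise_sd, frame_rate = frame_rate,
       kernel_tau = kernel_tau)
}

#' Causal exponential kernel sampled at the frame rate
#'
#' Unit amplitude at lag zero, truncated at five time constants.
#'
#' @param tau Decay constant, seconds.
#' @param frame_rate Hz.
#' @return Numeric vector of kernel weights.
#' @export
exp_kernel <- function(tau, frame_rate) {
  n_lag <- max(2L, ceiling(5 * tau * frame_rate))
  exp(-(0:(n_lag - 1L)) / (tau * frame_rate))
}

# causal convolution: y_t = sum_{j >= 0} k_{j+1} x_{t-j}
conv_causal <- function(x, k) {
  n <- length(x)
  y <- stats::convolve(x, rev(k), type = "open")
  y[seq_len(n)]
}

#' @export
print.session_data <- function(x, ...) {
  d <- dim(x$responses)
  cat(sprintf(
    "<session_data> %d neurons x %d stimuli x %d trials\n", d[1], d[2], d[3]))
  flagged <- Reduce(`|`, x$flags)
  cat(sprintf("  flagged trials: %.1f%%\n", 100 * mean(flagged)))
  invisible(x)
}
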