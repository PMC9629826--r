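test_that("identical seeds give bit-identical sessions", {
  g <- small_grid()
  truth <- sample_population(10, g, seed = 7)
  s1 <- generate_session(g, truth, n_trials = 12, seed = 99)
  s2 <- generate_session(g, truth, n_trials = 12, seed = 99)
  expect_identical(s1, s2)
  s3 <- generate_session(g, truth, n_trials = 12, seed = 100)
  expect_false(identical(s1$responses, s3$responses))
})

test_that("zero-amplitude populations are pure baseline draws", {
  g <- small_grid()
  truth <- ground_truth(is_tuned = rep(TRUE, 50), A = 0, B = 2,
                        mu_theta = 45, mu_sf = 0.15, sigma_theta = 20,
                        sigma_sf = 0.05, rho = 0, reliability = 1,
                        grid = g)
  sess <- generate_session(g, truth, n_trials = 30, seed = 4,
                           flag_rates = c(locomotion = 0, blink = 0))
  # per-neuron means concentrate around B = 2
  m <- apply(sess$responses, 1, mean)
  expect_true(all(abs(m - 2) < 5 * sqrt(2 / (12 * 30))))
})

test_that("noiseless reliable neurons peak at their true preferred stimulus", {
  g <- default_grid()
  truth <- sample_population(20, g, tuned_fraction = 1, seed = 3,
                             reliability_range = c(1, 1))
  # snap preferences onto grid points so index_of is defined
  truth$mu_theta <- g$orientations[
    apply(outer(truth$mu_theta, g$orientations, delta_ori), 1, which.min)]
  truth$mu_sf <- g$spatial_freqs[
    apply(abs(outer(truth$mu_sf, g$spatial_freqs, "-")), 1, which.min)]
  sess <- generate_session(g, truth, n_trials = 2, seed = 5,
                           noise = "none",
                           flag_rates = c(locomotion = 0, blink = 0))
  # oracle: direct evaluation of the generative mean surface
  surf <- mean_surface(truth, g)
  for (i in seq_len(20)) {
    expected <- index_of(g, truth$mu_theta[i], truth$mu_sf[i])
    expect_identical(which.max(surf[i, ]), as.integer(expected))
    expect_identical(which.max(sess$responses[i, , 1]), as.integer(expected))
  }
})

test_that("flagged-trial fraction matches the requested rate", {
  g <- small_grid()
  truth <- sample_population(5, g, seed = 1)
  sess <- generate_session(g, truth, n_trials = 200, seed = 11,
                           flag_rates = c(locomotion = 0.2, blink = 0.1))
  n <- length(sess$flags$locomotion)
  for (nm in c("locomotion", "blink")) {
    p <- c(locomotion = 0.2, blink = 0.1)[[nm]]
    phat <- mean(sess$flags[[nm]])
    # binomial 99% CI
    expect_lt(abs(phat - p), 2.58 * sqrt(p * (1 - p) / n))
  }
})

test_that("empirical per-stimulus means match the analytic surface", {
  g <- small_grid()
  truth <- one_neuron_truth(g, mu_theta = 45, mu_sf = 0.15,
                            reliability = 0.7)
  sess <- generate_session(g, truth, n_trials = 10000, seed = 21,
                           flag_rates = c(locomotion = 0, blink = 0))
  expected <- truth$B +
    (mean_surface(truth, g)[1, ] - truth$B) * truth$reliability
  emp <- apply(sess$responses[1, , ], 1, mean)
  # Poisson mixture variance per stimulus
  lam_on <- mean_surface(truth, g)[1, ]
  v <- truth$reliability * (lam_on + lam_on^2) +
    (1 - truth$reliability) * (truth$B + truth$B^2) - expected^2
  se <- sqrt(v / 10000)
  expect_true(all(abs(emp - expected) < 3.5 * se + 1e-9))
})

test_that("invalid ground-truth parameters name the offending field", {
  g <- small_grid()
  expect_error(ground_truth(TRUE, A = 1, B = 0.1, mu_theta = 45,
                            mu_sf = 0.15, sigma_theta = 0.5,
                            sigma_sf = 0.05, rho = 0, reliability = 1,
                            grid = g), "sigma_theta")
  expect_error(ground_truth(TRUE, A = 1, B = 0.1, mu_theta = 45,
                            mu_sf = 0.9, sigma_theta = 10, sigma_sf = 0.05,
                            rho = 0, reliability = 1, grid = g), "mu_sf")
  expect_error(ground_truth(TRUE, A = 1, B = 0.1, mu_theta = 45,
                            mu_sf = 0.15, sigma_theta = 10,
                            sigma_sf = 0.05, rho = 1.2, reliability = 1,
                            grid = g), "rho")
})

test_that("experiments with zero jitter keep preferences identical", {
  g <- small_grid()
  truth <- sample_population(12, g, seed = 2)
  sched <- list(session_spec("a"), session_spec("b"), session_spec("c"))
  sessions <- generate_experiment(g, truth, sched, seed = 5, n_trials = 6)
  expect_equal(length(sessions), 3L)
  t1 <- attr(sessions[[1]], "truth")
  t3 <- attr(sessions[[3]], "truth")
  expect_equal(t1$mu_theta, t3$mu_theta)
  expect_equal(t1$mu_sf, t3$mu_sf)
  expect_identical(sessions[[1]]$neuron_ids, sessions[[3]]$neuron_ids)
})

test_that("reliability multipliers propagate per session", {
  g <- small_grid()
  truth <- sample_population(12, g, seed = 2,
                             reliability_range = c(0.8, 0.8))
  sched <- list(session_spec("b1"), session_spec("b2"),
                session_spec("low", reliability_mult = 0.5),
                session_spec("back", reliability_mult = 1))
  sessions <- generate_experiment(g, truth, sched, seed = 5, n_trials = 6)
  rel <- sapply(sessions, function(s) median(attr(s, "truth")$reliability))
  expect_equal(unname(rel), 0.8 * c(1, 1, 0.5, 1))
})

test_that("orientation jitter matches the folded-normal scale per pair", {
  g <- small_grid()
  truth <- sample_population(400, g, tuned_fraction = 1, seed = 3)
  sched <- list(session_spec("s1"),
                session_spec("s2", theta_jitter = 10),
                session_spec("s3", theta_jitter = 0))
  sessions <- generate_experiment(g, truth, sched, seed = 9, n_trials = 2,
                                  flag_rates = c(locomotion = 0, blink = 0))
  mu <- lapply(sessions, function(s) attr(s, "truth")$mu_theta)
  d12 <- mean(delta_ori(mu[[1]], mu[[2]]))
  d23 <- mean(delta_ori(mu[[2]], mu[[3]]))
  # oracle: Monte-Carlo mean of |wrapped N(0, 10)| on the axial circle
  set.seed(42)
  draws <- abs(rnorm(2e5, 0, 10)) %% 180
  ref <- mean(pmin(draws, 180 - draws))
  expect_lt(abs(d12 - ref), 0.75)  # ~ 3 SE at n = 400
  expect_equal(d23, 0)
})

test_that("rebound sessions reset to first-session parameters", {
  g <- small_grid()
  truth <- sample_population(20, g, tuned_fraction = 1, seed = 3)
  sched <- list(session_spec("s1"),
                session_spec("s2", theta_jitter = 20),
                session_spec("s3", reset = TRUE))
  sessions <- generate_experiment(g, truth, sched, seed = 9, n_trials = 2,
                                  flag_rates = c(locomotion = 0, blink = 0))
  expect_equal(attr(sessions[[3]], "truth")$mu_theta,
               attr(sessions[[1]], "truth")$mu_theta)
})

test_that("fluorescence synthesis follows the convolutional model", {
  n <- 200
  # zero events, zero noise: trace is exactly beta * p + b
  p <- sin(seq_len(n) / 10)
  fl <- generate_fluorescence(numeric(n), neuropil_coef = 0.5,
                              baseline = 2, noise_sd = 0, neuropil = p,
                              seed = 1)
  expect_equal(fl$f, 0.5 * p + 2)
  # single impulse: trace equals the kernel shifted to the event frame
  ev <- numeric(n); ev[37] <- 1
  fl <- generate_fluorescence(ev, kernel_tau = 0.7, frame_rate = 15.5,
                              neuropil_coef = 0, baseline = 0,
                              noise_sd = 0, neuropil = numeric(n), seed = 1)
  k <- exp_kernel(0.7, 15.5)
  expected <- numeric(n)
  expected[37:min(n, 36 + length(k))] <- k[1:(min(n, 36 + length(k)) - 36)]
  expect_equal(fl$f, expected, tolerance = 1e-10)
  expect_error(generate_fluorescence(ev, noise_sd = -1), "noise_sd")
})
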