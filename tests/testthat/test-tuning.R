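test_that("circular-moment initialization recovers the preferred angle", {
  oris <- seq(0, 165, by = 15)
  # all response at 45 degrees
  r <- ifelse(oris == 45, 1, 0)
  expect_equal(init_orientation(r, oris)$preferred, 45)
  # uniform responses: zero moment, undefined preference
  expect_error(init_orientation(rep(1, 12), oris), "undefined")
  expect_error(init_orientation(rep(0, 12), oris), "undefined")
  # oracle: the first circular moment of 1 + cos(2(theta - 30)) sampled on a
  # uniform 12-point grid is exact (orthogonality of harmonics)
  r <- 1 + cos(2 * (oris - 30) * pi / 180)
  expect_equal(init_orientation(r, oris)$preferred, 30, tolerance = 1e-9)
})

test_that("spatial-frequency initialization picks the peak, ties go low", {
  g <- small_grid()
  truth <- one_neuron_truth(g, mu_theta = 45, mu_sf = 0.15)
  resp <- exact_responses(g, as.list(truth[1, ]), n_trials = 2)
  expect_equal(init_sf(resp, g, 45), 0.15)
  # exact two-way tie: lower sf wins
  r <- matrix(0, g$n_stim, 2)
  i1 <- index_of(g, 90, 0.05)
  i2 <- index_of(g, 90, 0.25)
  r[c(i1, i2), ] <- 3
  expect_equal(init_sf(r, g, 90), 0.05)
})

test_that("noiseless model data are recovered essentially exactly", {
  g <- default_grid()
  pars <- list(A = amplitude_for_peak(4, 18, 0.05, 0.3), B = 0.3,
               mu_theta = 67, mu_sf = 0.14, sigma_theta = 18,
               sigma_sf = 0.05, rho = 0.3)
  resp <- exact_responses(g, pars, n_trials = 2)
  ft <- fit_tuning(resp, g)
  expect_true(ft$converged)
  for (nm in names(pars)) {
    expect_lt(abs(ft[[nm]] - pars[[nm]]) / max(abs(pars[[nm]]), 1e-6),
              1e-3)
  }
  expect_equal(ft$r2, 1, tolerance = 1e-9)
})

test_that("orientation preference near the 0/180 boundary does not reflect", {
  g <- default_grid()
  set.seed(13)
  truth <- one_neuron_truth(g, mu_theta = 178, mu_sf = 0.12, peak = 6)
  sess <- generate_session(g, truth, n_trials = 25, seed = 14,
                           flag_rates = c(locomotion = 0, blink = 0))
  ft <- fit_tuning(sess$responses[1, , ], g)
  expect_lt(delta_ori(ft$mu_theta, 178), 5)
  expect_true(ft$mu_theta >= 0 && ft$mu_theta < 180)
})

test_that("fits are scale-equivariant", {
  g <- small_grid()
  set.seed(3)
  truth <- one_neuron_truth(g, mu_theta = 45, mu_sf = 0.15, peak = 5)
  sess <- generate_session(g, truth, n_trials = 15, seed = 5,
                           flag_rates = c(locomotion = 0, blink = 0))
  resp <- sess$responses[1, , ]
  f1 <- fit_tuning(resp, g)
  f2 <- fit_tuning(3 * resp, g)
  expect_equal(f2$A / f1$A, 3, tolerance = 1e-4)
  expect_equal(f2$B, 3 * f1$B, tolerance = 1e-4)
  expect_equal(f2$mu_theta, f1$mu_theta, tolerance = 1e-4)
  expect_equal(f2$mu_sf, f1$mu_sf, tolerance = 1e-6)
  expect_equal(f2$sigma_theta, f1$sigma_theta, tolerance = 1e-3)
  expect_equal(f2$r2, f1$r2, tolerance = 1e-8)
})

test_that("rotating all stimulus orientations rotates the fit", {
  g <- default_grid()
  pars <- list(A = amplitude_for_peak(4, 16, 0.05), B = 0.2, mu_theta = 40,
               mu_sf = 0.14, sigma_theta = 16, sigma_sf = 0.05, rho = 0)
  resp <- exact_responses(g, pars, n_trials = 2)
  f1 <- fit_tuning(resp, g)
  # shift responses by one orientation step (15 deg rotation of stimuli)
  n_ori <- 12L
  perm <- unlist(lapply(0:14, function(b) b * n_ori + c(n_ori, 1:(n_ori - 1))))
  f2 <- fit_tuning(resp[perm, ], g)
  expect_equal(delta_ori(f2$mu_theta, wrap_ori(f1$mu_theta + 15)), 0,
               tolerance = 1e-3)
  expect_equal(f2$r2, f1$r2, tolerance = 1e-6)
})

test_that("orientation recovery on Poisson-noise neurons is accurate", {
  g <- default_grid()
  n <- 60
  truth <- sample_population(n, g, tuned_fraction = 1, seed = 31,
                             peak_range = c(3, 6),
                             baseline_range = c(0.1, 0.2),
                             reliability_range = c(1, 1))
  sess <- generate_session(g, truth, n_trials = 25, seed = 32,
                           flag_rates = c(locomotion = 0, blink = 0))
  err <- vapply(seq_len(n), function(i) {
    ft <- fit_tuning(sess$responses[i, , ], g)
    delta_ori(ft$mu_theta, truth$mu_theta[i])
  }, numeric(1))
  expect_lt(median(err), 5)
})

test_that("permutation test separates tuned neurons from chance", {
  g <- small_grid()
  set.seed(7)
  truth <- one_neuron_truth(g, mu_theta = 90, mu_sf = 0.15, peak = 8)
  sess <- generate_session(g, truth, n_trials = 20, seed = 8,
                           flag_rates = c(locomotion = 0, blink = 0))
  resp <- sess$responses[1, , ]
  ft <- fit_tuning(resp, g)
  pt <- permutation_test(resp, g, ft, n_perm = 60, seed = 9)
  expect_true(pt$sig)
  expect_gt(ft$r2, pt$threshold)
  expect_lt(pt$p, 0.05)
  expect_error(permutation_test(resp, g, ft, n_perm = 10), "n_perm")
})

test_that("null R2 distribution is exchangeable with the observed on null data", {
  g <- small_grid()
  set.seed(17)
  resp <- matrix(rpois(g$n_stim * 8, 1.5), g$n_stim, 8)
  ft <- fit_tuning(resp, g)
  pt <- permutation_test(resp, g, ft, n_perm = 100, seed = 18)
  # observed R2 should sit inside the bulk of the null distribution
  expect_gt(mean(pt$null_r2 >= ft$r2 - 1e-12), 0.02)
  expect_gt(ft$r2, quantile(pt$null_r2, 0.01) - 0.05)
})

test_that("bandwidth formulas evaluate and scale linearly", {
  expect_equal(hwhm(1), 2 * log(2))
  expect_equal(hwhm(1), 1.3863, tolerance = 1e-4)
  expect_equal(hwhm(1, "hwhm-exact"), sqrt(2 * log(2)))
  expect_equal(hwhm(1, "hwhm-exact"), 1.1774, tolerance = 1e-4)
  expect_equal(hwhm(c(2, 7) * 3.5), 3.5 * hwhm(c(2, 7)))
  expect_error(hwhm(0), "sigma")
  expect_error(hwhm(-1), "sigma")
})

test_that("stability deltas wrap orientation and exclude untuned neurons", {
  mk <- function(id, mt, ms, bt, bs, sig = TRUE, conv = TRUE)
    data.frame(neuron_id = id, mu_theta = mt, mu_sf = ms, bw_theta = bt,
               bw_sf = bs, sig = sig, converged = conv,
               stringsAsFactors = FALSE)
  a <- mk(c("n1", "n2", "n3"), c(175, 30, 10), c(0.1, 0.2, 0.1),
          c(20, 25, 30), c(0.05, 0.06, 0.07))
  b <- mk(c("n1", "n2", "n3"), c(5, 30, 50), c(0.12, 0.2, 0.1),
          c(18, 25, 30), c(0.05, 0.06, 0.07),
          sig = c(TRUE, TRUE, FALSE))
  d <- stability_deltas(a, b)
  expect_equal(d$neuron_id, c("n1", "n2"))  # n3 untuned in b: excluded
  expect_equal(d$d_mu_theta, c(10, 0))      # 175 vs 5 wraps to 10
  expect_equal(d$d_bw_theta, c(2, 0))
  expect_equal(d$d_mu_sf, c(0.02, 0))
  # identical fits give all-zero deltas
  d0 <- stability_deltas(a, a)
  expect_true(all(d0$d_mu_theta == 0 & d0$d_bw_theta == 0 &
                    d0$d_mu_sf == 0 & d0$d_bw_sf == 0))
})

test_that("planted jitter differences are detectable by rank-sum", {
  g <- small_grid()
  truth <- sample_population(150, g, tuned_fraction = 1, seed = 41)
  sched_j <- list(session_spec("a"), session_spec("b", theta_jitter = 15))
  sched_0 <- list(session_spec("a"), session_spec("b", theta_jitter = 0.5))
  s_j <- generate_experiment(g, truth, sched_j, seed = 42, n_trials = 2,
                             flag_rates = c(locomotion = 0, blink = 0))
  s_0 <- generate_experiment(g, truth, sched_0, seed = 43, n_trials = 2,
                             flag_rates = c(locomotion = 0, blink = 0))
  d_j <- delta_ori(attr(s_j[[1]], "truth")$mu_theta,
                   attr(s_j[[2]], "truth")$mu_theta)
  d_0 <- delta_ori(attr(s_0[[1]], "truth")$mu_theta,
                   attr(s_0[[2]], "truth")$mu_theta)
  expect_lt(contrast(d_j, d_0, test = "rank-sum")$p, 0.05)
})
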