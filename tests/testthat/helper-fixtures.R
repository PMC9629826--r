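# Shared fixtures and independent oracles, built in code at test time.

# a compact 4 x 3 grid (12 stimuli) for fast simulations
small_grid <- function() {
  stim_grid(orientations = c(0, 45, 90, 135),
            spatial_freqs = c(0.05, 0.15, 0.25))
}

# a single-neuron tuned population on a grid
one_neuron_truth <- function(grid, mu_theta = 60, mu_sf = 0.15,
                             sigma_theta = 20, sigma_sf = 0.06,
                             peak = 5, B = 0.2, rho = 0,
                             reliability = 1) {
  ground_truth(is_tuned = TRUE,
               A = amplitude_for_peak(peak, sigma_theta, sigma_sf, rho),
               B = B, mu_theta = mu_theta, mu_sf = mu_sf,
               sigma_theta = sigma_theta, sigma_sf = sigma_sf, rho = rho,
               reliability = reliability, grid = grid)
}

# exact single-trial response matrix from the model (noiseless), replicated
exact_responses <- function(grid, pars, n_trials = 3) {
  mu <- tuning_surface(grid$stimuli$orientation, grid$stimuli$sf,
                       A = pars$A, B = pars$B, mu_theta = pars$mu_theta,
                       mu_sf = pars$mu_sf, sigma_theta = pars$sigma_theta,
                       sigma_sf = pars$sigma_sf, rho = pars$rho)
  matrix(rep(mu, n_trials), nrow = grid$n_stim)
}

# Independent brute-force KNN oracle: explicit loops, recomputes distances
# from scratch, resolves ties by (distance, set, label) and vote ties by the
# closest member of the tied classes.
brute_knn_cv <- function(X, stim, setid, k) {
  n <- nrow(X)
  pred <- integer(n)
  for (i in seq_len(n)) {
    cand <- which(setid != setid[i])
    d <- numeric(length(cand))
    for (jj in seq_along(cand))
      d[jj] <- sqrt(sum((X[i, ] - X[cand[jj], ])^2))
    ord <- cand[order(d, setid[cand], stim[cand])]
    nb <- ord[1:k]
    counts <- sapply(unique(stim[nb]), function(cl) sum(stim[nb] == cl))
    names(counts) <- unique(stim[nb])
    best <- as.integer(names(counts)[counts == max(counts)])
    if (length(best) == 1L) {
      pred[i] <- best
    } else {
      # nearest member among tied classes
      for (v in nb) {
        if (stim[v] %in% best) {
          pred[i] <- stim[v]
          break
        }
      }
    }
  }
  pred
}
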