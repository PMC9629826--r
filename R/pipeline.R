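# End-to-end synthetic dark-exposure experiment ------------------------------

#' Configuration for a synthetic dark-exposure experiment
#'
#' Bundles the stimulus grid, population, four-session schedule
#' (B1/B2/pDE/Rec) and analysis parameters. Any component can be overridden.
#'
#' @param grid A [stim_grid()] (default: the 12 x 15 grating grid).
#' @param n_neurons Population size.
#' @param tuned_fraction Fraction of tuned neurons.
#' @param schedule List of [session_spec()]s (default: [default_schedule()]).
#' @param n_trials Trials presented per stimulus per session.
#' @param flag_rates Per-trial contamination probabilities.
#' @param alpha ANOVA responsivity level.
#' @param n_perm Permutations for the tuning significance test.
#' @param k Decoder neighbor count.
#' @param n_sd Reliability threshold multiplier.
#' @param population_args Extra arguments to [sample_population()].
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(grid = default_grid(), n_neurons = 40,
                              tuned_fraction = 0.4,
                              schedule = default_schedule(),
                              n_trials = 36,
                              flag_rates = c(locomotion = 0.2, blink = 0.1),
                              alpha = 0.01, n_perm = 200, k = 4, n_sd = 2,
                              population_args = list()) {
  structure(list(grid = grid, n_neurons = n_neurons,
                 tuned_fraction = tuned_fraction, schedule = schedule,
                 n_trials = n_trials, flag_rates = flag_rates,
                 alpha = alpha, n_perm = n_perm, k = k, n_sd = n_sd,
                 population_args = population_args),
            class = "experiment_config")
}

#' Run the full synthetic experiment pipeline
#'
#' Simulates the four-session design, then runs every analysis stage:
#' trial filtering, ANOVA responsivity, per-neuron tuning fits with
#' permutation significance, stability deltas per condition (control =
#' B1 to B2, DE = B2 to pDE, LRx = pDE to Rec), signal-correlation
#' similarities, per-session reliability, per-session decoders (on
#' neuron/trial-matched data), fixed-classifier drift for the condition
#' pairs, and rank-sum condition contrasts with Benjamini-Hochberg
#' correction. Fully deterministic for a given config and master seed;
#' stage seeds are fanned out with [child_seed()].
#'
#' @param config An [experiment_config()].
#' @param seed Master integer seed.
#' @param out_dir Optional output directory; when given, writes `report.md`,
#'   `results.json` and `tables/*.csv`.
#' @return A list of stage results (invisibly when `out_dir` is given).
#' @export
run_experiment <- function(config = experiment_config(), seed = 1L,
                           out_dir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  stage <- function(name) child_seed(seed, name)

  truth <- do.call(sample_population, c(
    list(n_neurons = config$n_neurons, grid = config$grid,
         tuned_fraction = config$tuned_fraction,
         seed = stage("population")),
    config$population_args))

  sessions <- generate_experiment(
    config$grid, truth, config$schedule, seed = stage("sessions"),
    n_trials = config$n_trials, flag_rates = config$flag_rates)
  sess_names <- names(sessions)

  filtered <- lapply(sessions, filter_trials)
  responsivity <- lapply(filtered, test_responsiveness,
                         alpha = config$alpha)

  fits <- lapply(sess_names, function(nm) {
    resp_ids <- responsivity[[nm]]$neuron_id[responsivity[[nm]]$responsive]
    if (length(resp_ids) == 0L) return(NULL)
    fit_table(filtered[[nm]], neurons = resp_ids, n_perm = config$n_perm,
              seed = stage(paste0("fits_", nm)))
  })
  names(fits) <- sess_names

  conditions <- list(control = c(1L, 2L), DE = c(2L, 3L), LRx = c(3L, 4L))
  conditions <- conditions[vapply(conditions, max, 1L) <=
                             length(sessions)]

  deltas <- lapply(conditions, function(pr) {
    a <- fits[[pr[1]]]; b <- fits[[pr[2]]]
    if (is.null(a) || is.null(b)) return(NULL)
    stability_deltas(a, b)
  })

  similarities <- lapply(conditions, function(pr) {
    a <- fits[[pr[1]]]; b <- fits[[pr[2]]]
    if (is.null(a) || is.null(b)) return(NA_real_)
    ids <- intersect(a$neuron_id[a$sig], b$neuron_id[b$sig])
    if (length(ids) < 3L) return(NA_real_)
    tryCatch(
      similarity(signal_correlation(filtered[[pr[1]]], neurons = ids),
                 signal_correlation(filtered[[pr[2]]], neurons = ids)),
      error = function(e) NA_real_)
  })

  reliab <- lapply(sess_names, function(nm) {
    if (is.null(fits[[nm]])) return(NULL)
    reliability(filtered[[nm]], fits[[nm]], n_sd = config$n_sd)
  })
  names(reliab) <- sess_names

  # decoders on matched data (all tracked neurons, matched trials)
  matched <- subsample_match(filtered, seed = stage("match"))
  names(matched) <- sess_names
  decodes <- lapply(sess_names, function(nm)
    knn_decode(matched[[nm]], k = config$k,
               seed = stage(paste0("decode_", nm))))
  names(decodes) <- sess_names

  drift_pairs <- list(control = c(1L, 2L), DE = c(2L, 3L),
                      LRx = c(4L, 3L))  # Rec-trained classifier tested on pDE
  drift_pairs <- drift_pairs[vapply(drift_pairs, max, 1L) <=
                               length(sessions)]
  drifts <- lapply(drift_pairs, function(pr)
    fixed_classifier_drift(filtered[[pr[1]]], filtered[[pr[2]]],
                           k = config$k, seed = stage("drift")))

  contrasts <- run_contrasts(deltas, reliab)

  results <- list(
    seed = seed, truth = truth, responsivity = responsivity, fits = fits,
    deltas = deltas, similarities = similarities, reliability = reliab,
    decoding = decodes, drift = drifts, contrasts = contrasts)

  if (!is.null(out_dir)) {
    write_report(results, config, out_dir)
    return(invisible(results))
  }
  results
}

run_contrasts <- function(deltas, reliab) {
  rows <- list()
  if (!is.null(deltas$control) && !is.null(deltas$DE) &&
      nrow(deltas$control) > 1L && nrow(deltas$DE) > 1L) {
    rows$ori_stability <- contrast(deltas$control$d_mu_theta,
                                   deltas$DE$d_mu_theta,
                                   test = "rank-sum",
                                   label = "d_mu_theta control vs DE")
    rows$bw_stability <- contrast(deltas$control$d_bw_theta,
                                  deltas$DE$d_bw_theta,
                                  test = "rank-sum",
                                  label = "d_bw_theta control vs DE")
  }
  nm <- names(reliab)
  if (all(c("B2", "pDE") %in% nm) &&
      !is.null(reliab$B2) && !is.null(reliab$pDE) &&
      nrow(reliab$B2) > 1L && nrow(reliab$pDE) > 1L) {
    rows$reliability_de <- contrast(reliab$B2$reliability,
                                    reliab$pDE$reliability,
                                    test = "rank-sum",
                                    label = "reliability B2 vs pDE")
  }
  if (all(c("pDE", "Rec") %in% nm) &&
      !is.null(reliab$pDE) && !is.null(reliab$Rec) &&
      nrow(reliab$pDE) > 1L && nrow(reliab$Rec) > 1L) {
    rows$reliability_rec <- contrast(reliab$pDE$reliability,
                                     reliab$Rec$reliability,
                                     test = "rank-sum",
                                     label = "reliability pDE vs Rec")
  }
  if (length(rows) == 0L) return(NULL)
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  rownames(out) <- NULL
  out
}

write_report <- function(results, config, out_dir) {
  dir.create(file.path(out_dir, "tables"), recursive = TRUE,
             showWarnings = FALSE)
  tdir <- file.path(out_dir, "tables")
  for (nm in names(results$fits)) {
    if (!is.null(results$fits[[nm]]))
      utils::write.csv(results$fits[[nm]],
                       file.path(tdir, paste0("fits_", nm, ".csv")),
                       row.names = FALSE)
    if (!is.null(results$reliability[[nm]]))
      utils::write.csv(results$reliability[[nm]],
                       file.path(tdir, paste0("reliability_", nm, ".csv")),
                       row.names = FALSE)
  }
  for (nm in names(results$deltas)) {
    if (!is.null(results$deltas[[nm]]))
      utils::write.csv(results$deltas[[nm]],
                       file.path(tdir, paste0("deltas_", nm, ".csv")),
                       row.names = FALSE)
  }
  if (!is.null(results$contrasts))
    utils::write.csv(results$contrasts, file.path(tdir, "contrasts.csv"),
                     row.names = FALSE)

  summary <- list(
    seed = results$seed,
    responsive_fraction = vapply(results$responsivity,
                                 function(r) mean(r$responsive), numeric(1)),
    tuned_count = vapply(results$fits,
                         function(f) if (is.null(f)) 0L else sum(f$sig),
                         integer(1)),
    similarity = lapply(results$similarities, function(x) x),
    median_reliability = vapply(results$reliability, function(r)
      if (is.null(r) || nrow(r) == 0L) NA_real_
      else stats::median(r$reliability), numeric(1)),
    decoding_accuracy = vapply(results$decoding, `[[`, numeric(1),
                               "accuracy"),
    chance = results$decoding[[1]]$chance,
    drift = lapply(results$drift, function(d)
      d[c("acc_X1", "acc_X2", "drift")]),
    contrasts = results$contrasts)
  jsonlite::write_json(summary, file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")

  md <- c(
    "# Synthetic dark-exposure experiment report", "",
    sprintf("Master seed: %d", results$seed),
    sprintf("Sessions: %s", paste(names(results$fits), collapse = ", ")),
    "",
    "## Responsive fraction per session",
    sprintf("- %s: %.2f", names(results$responsivity),
            vapply(results$responsivity, function(r) mean(r$responsive),
                   numeric(1))),
    "",
    "## Decoding accuracy (chance = 1/n_stim)",
    sprintf("- %s: %.4f", names(results$decoding),
            vapply(results$decoding, `[[`, numeric(1), "accuracy")),
    "",
    "## Fixed-classifier drift",
    sprintf("- %s: acc_X1=%.4f acc_X2=%.4f drift=%+.4f",
            names(results$drift),
            vapply(results$drift, `[[`, numeric(1), "acc_X1"),
            vapply(results$drift, `[[`, numeric(1), "acc_X2"),
            vapply(results$drift, `[[`, numeric(1), "drift")),
    "")
  if (!is.null(results$contrasts)) {
    md <- c(md, "## Condition contrasts",
            sprintf("- %s (%s): stat=%.3f p=%.4g p_adj=%.4g",
                    results$contrasts$analysis, results$contrasts$test,
                    results$contrasts$statistic, results$contrasts$p,
                    results$contrasts$p_adj))
  }
  writeLines(md, file.path(out_dir, "report.md"))
  invisible(out_dir)
}
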