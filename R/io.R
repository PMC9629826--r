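# Plain-text session serialization -------------------------------------------
#
# A session is written as a directory of CSVs plus a JSON sidecar:
#   responses.csv  long format (neuron_id, orientation, sf, trial, events)
#   baseline.csv   (neuron_id, bin, events)
#   flags.csv      (stim, trial, locomotion, blink)
#   grid.json      orientations and spatial frequencies
#   truth.csv      generating parameters, when present

#' Write a session to a directory of CSV/JSON files
#'
#' @param session A `session_data`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "session_data"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(session$responses)
  long <- data.frame(
    neuron_id = rep(session$neuron_ids, times = d[2] * d[3]),
    orientation = rep(rep(session$grid$stimuli$orientation, each = d[1]),
                      times = d[3]),
    sf = rep(rep(session$grid$stimuli$sf, each = d[1]), times = d[3]),
    trial = rep(seq_len(d[3]), each = d[1] * d[2]),
    events = as.numeric(session$responses))
  long <- long[!is.na(long$events), ]
  utils::write.csv(long, file.path(dir, "responses.csv"), row.names = FALSE)

  nb <- ncol(session$baseline)
  utils::write.csv(
    data.frame(neuron_id = rep(session$neuron_ids, times = nb),
               bin = rep(seq_len(nb), each = d[1]),
               events = as.numeric(session$baseline)),
    file.path(dir, "baseline.csv"), row.names = FALSE)

  fl <- data.frame(stim = rep(seq_len(d[2]), times = d[3]),
                   trial = rep(seq_len(d[3]), each = d[2]))
  for (nm in names(session$flags))
    fl[[nm]] <- as.logical(session$flags[[nm]])
  utils::write.csv(fl, file.path(dir, "flags.csv"), row.names = FALSE)

  jsonlite::write_json(
    list(orientations = session$grid$orientations,
         spatial_freqs = session$grid$spatial_freqs),
    file.path(dir, "grid.json"), digits = NA)

  truth <- attr(session, "truth")
  if (!is.null(truth))
    utils::write.csv(as.data.frame(truth), file.path(dir, "truth.csv"),
                     row.names = FALSE)
  invisible(dir)
}

#' Read a session written by [write_session()]
#'
#' @param dir Directory path.
#' @return A `session_data`.
#' @export
read_session <- function(dir) {
  gj <- jsonlite::read_json(file.path(dir, "grid.json"),
                            simplifyVector = TRUE)
  grid <- stim_grid(gj$orientations, gj$spatial_freqs)
  long <- utils::read.csv(file.path(dir, "responses.csv"))
  ids <- unique(long$neuron_id)
  n_trial <- max(long$trial)
  resp <- array(NA_real_, dim = c(length(ids), grid$n_stim, n_trial),
                dimnames = list(ids, NULL, NULL))
  stim <- mapply(function(o, s) index_of(grid, o, s),
                 long$orientation, long$sf)
  resp[cbind(match(long$neuron_id, ids), stim, long$trial)] <- long$events

  bl <- utils::read.csv(file.path(dir, "baseline.csv"))
  baseline <- matrix(NA_real_, length(ids), max(bl$bin),
                     dimnames = list(ids, NULL))
  baseline[cbind(match(bl$neuron_id, ids), bl$bin)] <- bl$events

  fl <- utils::read.csv(file.path(dir, "flags.csv"))
  flag_names <- setdiff(names(fl), c("stim", "trial"))
  flags <- lapply(flag_names, function(nm) {
    m <- matrix(FALSE, grid$n_stim, n_trial)
    m[cbind(fl$stim, fl$trial)] <- fl[[nm]]
    m
  })
  names(flags) <- flag_names

  sess <- structure(
    list(responses = resp, baseline = baseline, flags = flags,
         neuron_ids = ids, grid = grid),
    class = "session_data")
  tf <- file.path(dir, "truth.csv")
  if (file.exists(tf)) {
    truth <- utils::read.csv(tf, stringsAsFactors = FALSE)
    class(truth) <- c("ground_truth", "data.frame")
    attr(sess, "truth") <- truth
  }
  sess
}
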