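#' Write and read trace batches as long-format CSV
#'
#' Traces are stored as `molecule_id, time_s, intensity` rows; a `# seed:`
#' comment line records the batch seed when supplied. An optional truth
#' sidecar stores the simulator's latent channel (rate, completion,
#' barrier presence) one row per molecule.
#'
#' @param traces List of `helicase_trace` objects.
#' @param path Output CSV path.
#' @param truth_path Optional sidecar CSV path for the truth channel.
#' @param seed Seed to record in the header comment.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path, truth_path = NULL, seed = NULL) {
  long <- do.call(rbind, lapply(traces, function(tr) {
    data.frame(molecule_id = tr$molecule_id, time_s = tr$times,
               intensity = tr$intensity)
  }))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(paste0("# seed: ", seed), con)
  utils::write.csv(long, con, row.names = FALSE)
  if (!is.null(truth_path)) {
    truth <- do.call(rbind, lapply(traces, function(tr) {
      data.frame(molecule_id = tr$molecule_id,
                 rate_bp_s = tr$truth$rate_bp_s,
                 completion_time_s = tr$truth$completion_time_s,
                 barrier_present = tr$truth$barrier_present,
                 arrested = tr$truth$arrested,
                 n_pauses = nrow(tr$truth$pauses))
    }))
    utils::write.csv(truth, truth_path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_traces
#' @return `read_traces()` returns a list of `helicase_trace` objects
#'   (without a truth channel).
#' @export
read_traces <- function(path) {
  long <- utils::read.csv(path, comment.char = "#")
  stopifnot(all(c("molecule_id", "time_s", "intensity") %in% names(long)))
  lapply(split(long, long$molecule_id), function(d) {
    d <- d[order(d$time_s), ]
    structure(
      list(molecule_id = as.character(d$molecule_id[1]),
           times = d$time_s, intensity = d$intensity,
           frame_interval_s = stats::median(diff(d$time_s)),
           truth = NULL),
      class = "helicase_trace"
    )
  })
}

#' Write and read ensemble curves as two-column CSV
#'
#' @param curve An [ensemble_curve()].
#' @param path CSV path.
#' @return `path` invisibly; `read_curve()` returns an [ensemble_curve()].
#' @export
write_curve <- function(curve, path) {
  utils::write.csv(data.frame(time_s = curve$time_s, signal = curve$signal),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_curve
#' @param normalized Whether the stored curve is normalized.
#' @export
read_curve <- function(path, normalized = FALSE) {
  d <- utils::read.csv(path, comment.char = "#")
  ensemble_curve(d$time_s, d$signal, normalized = normalized)
}
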