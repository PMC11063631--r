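## Plain-text session serialization: a directory of CSV tables plus a
## DCF header. Intended for modest sessions; everything is human-readable
## and round-trips exactly to printed precision.

#' Write a session to a directory of plain-text files
#'
#' Writes `meta.dcf` (scalars and run bounds), `dff.csv` (neuron x frame),
#' `events.csv`, `covariates.csv`, and `trials.csv`.
#'
#' @param session a `pm_session`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "pm_session"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  meta <- data.frame(frame_hz = session$frame_hz,
                     frames_per_bin = session$frames_per_bin,
                     microscope_id = session$microscope_id,
                     run_starts = paste(session$run_bounds[, "start"],
                                        collapse = ";"),
                     run_ends = paste(session$run_bounds[, "end"],
                                      collapse = ";"))
  write.dcf(meta, file.path(dir, "meta.dcf"))
  utils::write.csv(session$dff, file.path(dir, "dff.csv"),
                   row.names = FALSE)
  utils::write.csv(session$events, file.path(dir, "events.csv"),
                   row.names = FALSE)
  utils::write.csv(session$covariates, file.path(dir, "covariates.csv"),
                   row.names = FALSE)
  utils::write.csv(session$trials, file.path(dir, "trials.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a session written by [write_session()]
#'
#' @param dir directory containing the session files.
#' @return a `pm_session`.
#' @export
read_session <- function(dir) {
  meta <- as.data.frame(read.dcf(file.path(dir, "meta.dcf")),
                        stringsAsFactors = FALSE)
  num <- function(s) as.numeric(strsplit(as.character(s), ";")[[1]])
  structure(
    list(dff = as.matrix(utils::read.csv(file.path(dir, "dff.csv"))),
         frame_hz = as.numeric(meta$frame_hz),
         frames_per_bin = as.integer(meta$frames_per_bin),
         run_bounds = cbind(start = num(meta$run_starts),
                            end = num(meta$run_ends)),
         events = utils::read.csv(file.path(dir, "events.csv"),
                                  stringsAsFactors = FALSE),
         covariates = utils::read.csv(file.path(dir, "covariates.csv")),
         trials = utils::read.csv(file.path(dir, "trials.csv"),
                                  stringsAsFactors = FALSE),
         microscope_id = as.character(meta$microscope_id)),
    class = "pm_session")
}
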