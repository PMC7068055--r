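#' Read and write the pipeline's plain file dialects
#'
#' Event tables and pupil samples are tab-separated text; continuous or
#' epoched signal matrices are stored as little-endian float64 binaries with
#' a JSON sidecar describing shape, channel names, sampling rate and units;
#' ground-truth and decomposition metadata are JSON; configurations are
#' YAML.
#'
#' @param sequence a `trial_sequence`.
#' @param path file path (the sidecar uses `paste0(path, ".json")`).
#' @name io
NULL

#' @rdname io
#' @export
write_event_table <- function(sequence, path) {
  utils::write.table(as.data.frame(sequence), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_event_table <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(out) <- c("trial_sequence", "data.frame")
  out
}

#' @rdname io
#' @param pupil data frame with `time_ms`, `left_counts`, `right_counts`,
#'   `blink_flag_left`, `blink_flag_right`.
#' @export
write_pupil_samples <- function(pupil, path) {
  utils::write.table(pupil, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_pupil_samples <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname io
#' @param x channels x samples numeric matrix.
#' @param fs sampling rate, Hz.
#' @param units signal units (e.g. `"uV"`, `"mm"`).
#' @export
write_signal_matrix <- function(x, path, fs, units) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(t(x)), con, size = 8, endian = "little")
  sidecar <- list(channels = rownames(x) %||%
                    paste0("ch", seq_len(nrow(x))),
                  n_channels = nrow(x), n_samples = ncol(x),
                  fs = fs, units = units, dtype = "float64-le",
                  order = "channel-major")
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname io
#' @export
read_signal_matrix <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, "double", n = meta$n_channels * meta$n_samples,
               size = 8, endian = "little")
  x <- matrix(v, nrow = meta$n_channels, byrow = TRUE,
              dimnames = list(meta$channels, NULL))
  attr(x, "fs") <- meta$fs
  attr(x, "units") <- meta$units
  x
}

#' @rdname io
#' @param truth a `ground_truth` object.
#' @export
write_truth_manifest <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname io
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}
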