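#' Write an LFP trace as float32 binary with a JSON sidecar
#'
#' @param trace an [lfp_trace].
#' @param path output path for the binary (little-endian float32); the
#'   sidecar is written next to it as `<path>.json` with `fs_hz` and units.
#' @return `path`, invisibly.
#' @export
write_lfp <- function(trace, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(trace$samples), con, size = 4L, endian = "little")
  jsonlite::write_json(list(fs_hz = trace$fs_hz, units = "uV"),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read an LFP trace written by [write_lfp]
#'
#' @param path binary path; `<path>.json` must hold the sampling rate.
#' @return an [lfp_trace].
#' @export
read_lfp <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"))
  n <- file.info(path)$size / 4L
  con <- file(path, "rb")
  on.exit(close(con))
  x <- readBin(con, numeric(), n = n, size = 4L, endian = "little")
  lfp_trace(x, meta$fs_hz)
}

#' Write / read the pipeline's tabular artifacts
#'
#' Thin CSV wrappers so every stage's inputs and outputs round-trip through
#' plain text: trajectories (`t_s,x_cm,y_cm`), trial tables, event series
#' (`t_s,label,bird_id`), labeled windows and zone count tables.
#'
#' @param x data.frame to write.
#' @param path file path.
#' @return `path` (write) or the data.frame (read).
#' @export
write_table_csv <- function(x, path) {
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) read.csv(path, stringsAsFactors = FALSE)
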