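#' Write / read a recording as a directory container
#'
#' A recording is stored losslessly as a directory holding `meta.json`
#' (fs, t_start_s, dimensions, seed), `signal.bin` (little-endian
#' float64, channel-major), `events.tsv`, `channels.tsv` and
#' `ground_truth.tsv`. A container without a ground-truth table loads
#' with an empty ground truth and a warning; a malformed events table
#' raises a schema error naming the missing column.
#'
#' @param rec a `synthetic_recording`.
#' @param path directory path (created if absent).
#' @return `read_recording` returns the recording (without the
#'   originating `run_spec`, which is not serialized).
#' @export
write_recording <- function(rec, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(fs = rec$fs, t_start_s = rec$t_start_s,
               n_channels = nrow(rec$signal), n_samples = ncol(rec$signal),
               seed = rec$seed %||% NA)
  jsonlite::write_json(meta, file.path(path, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  con <- file(file.path(path, "signal.bin"), "wb")
  on.exit(close(con))
  writeBin(as.vector(t(rec$signal)), con, size = 8, endian = "little")
  write_events(rec$events, file.path(path, "events.tsv"))
  write.table(rec$layout, file.path(path, "channels.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(rec$ground_truth, file.path(path, "ground_truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  need <- function(f) {
    p <- file.path(path, f)
    if (!file.exists(p)) stop("recording container is missing '", f, "'")
    p
  }
  meta <- jsonlite::read_json(need("meta.json"), simplifyVector = TRUE)
  for (k in c("fs", "t_start_s", "n_channels", "n_samples")) {
    if (is.null(meta[[k]])) stop("meta.json is missing field '", k, "'")
  }
  con <- file(need("signal.bin"), "rb")
  on.exit(close(con))
  x <- readBin(con, "double", n = meta$n_channels * meta$n_samples,
               size = 8, endian = "little")
  if (length(x) != meta$n_channels * meta$n_samples) {
    stop("signal.bin is truncated")
  }
  signal <- matrix(x, nrow = meta$n_channels, byrow = TRUE)
  events <- read_events(need("events.tsv"))
  layout <- read.delim(need("channels.tsv"), stringsAsFactors = FALSE)
  missing_ch <- setdiff(c("name", "roi"), names(layout))
  if (length(missing_ch)) {
    stop("channels.tsv is missing column(s): ",
         paste(missing_ch, collapse = ", "))
  }
  gt_path <- file.path(path, "ground_truth.tsv")
  if (file.exists(gt_path)) {
    ground_truth <- read.delim(gt_path, stringsAsFactors = FALSE)
  } else {
    warning("container has no ground_truth.tsv; loading empty ground truth")
    ground_truth <- data.frame(trial_index = integer(0),
                               condition = character(0),
                               component = character(0),
                               amplitude = numeric(0),
                               center_s = numeric(0), start_s = numeric(0))
  }
  structure(list(signal = signal, fs = meta$fs, t_start_s = meta$t_start_s,
                 events = events, layout = layout,
                 ground_truth = ground_truth,
                 seed = if (is.null(meta$seed)) NA else meta$seed),
            class = "synthetic_recording")
}
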