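#' @include simulate.R
NULL

.findPython <- function() {
  for (cand in c("python", "python3")) {
    p <- Sys.which(cand)
    if (nzchar(p)) return(p)
  }
  stop("bulk fast5 I/O requires a 'python' interpreter with h5py on PATH")
}

.fast5Script <- function() {
  s <- system.file("python", "fast5io.py", package = "poretag")
  if (!nzchar(s)) stop("fast5io.py helper not found in the installed package")
  s
}

.runFast5Helper <- function(args) {
  out <- suppressWarnings(system2(.findPython(), c(.fast5Script(), args),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0)
    stop(paste(out, collapse = "\n"))
  invisible(out)
}

#' Read per-channel raw traces from a bulk fast5 file
#'
#' Reads the standard bulk-raw layout (`/Raw/Channel_<id>/Signal` datasets,
#' sampling rate from the channel `Meta` attributes). Integer DAC signals
#' are converted to pA when calibration attributes (`range`,
#' `digitisation`, `offset`) are present; otherwise values are taken as
#' already-scaled currents (detection is scale-equivariant, so this loses
#' nothing). HDF5 access is delegated to the bundled `h5py` helper script.
#'
#' @param path path to a bulk fast5 (HDF5) file.
#' @param channels optional integer vector of channel ids to read; `NULL`
#'   (default) reads all. An explicitly empty selection is an error.
#' @param voltageMv applied potential to record on the traces (not stored in
#'   all bulk files), default `NA`.
#' @return List of [NanoporeTrace-class], one per selected channel.
#' @seealso [writeBulkFast5()], [readCsvTrace()]
#' @export
readBulkFast5 <- function(path, channels = NULL, voltageMv = NA_real_) {
  if (!file.exists(path)) stop("I/O error: no such file: ", path)
  if (!is.null(channels) && length(channels) == 0L)
    stop("empty channel selection")
  tmp <- tempfile("fast5dump")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
  .runFast5Helper(c("dump", shQuote(path), shQuote(tmp),
                    if (!is.null(channels)) as.character(as.integer(channels))))
  meta <- utils::read.delim(file.path(tmp, "meta.tsv"))
  lapply(seq_len(nrow(meta)), function(i) {
    vals <- scan(file.path(tmp, sprintf("channel_%d.csv", meta$channel[i])),
                 what = numeric(), quiet = TRUE)
    nanoporeTrace(vals, channelId = meta$channel[i],
                  samplingRateHz = meta$sampling_rate[i],
                  voltageMv = voltageMv, source = path)
  })
}

#' Write traces to a bulk fast5 file
#'
#' Writes the standard bulk-raw layout used by [readBulkFast5()]: one
#' `/Raw/Channel_<id>/Signal` float dataset per trace (values in pA, no DAC
#' calibration) with the sampling rate on the channel's `Meta` group.
#'
#' @param traces list of [NanoporeTrace-class] (or a single trace).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeBulkFast5 <- function(traces, path) {
  if (is(traces, "NanoporeTrace")) traces <- list(traces)
  tmp <- tempfile("fast5pack")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
  meta <- data.frame(
    channel = vapply(traces, channelId, integer(1)),
    sampling_rate = vapply(traces, samplingRateHz, numeric(1))
  )
  if (anyDuplicated(meta$channel)) stop("duplicate channel ids")
  for (i in seq_along(traces)) {
    f <- file.path(tmp, sprintf("channel_%d.csv", meta$channel[i]))
    writeLines(format(samples(traces[[i]]), digits = 17, trim = TRUE,
                      scientific = FALSE), f)
  }
  utils::write.table(meta, file.path(tmp, "meta.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  .runFast5Helper(c("pack", shQuote(path), shQuote(tmp)))
  invisible(path)
}

#' Read a single-channel trace from a CSV/plain-text file
#'
#' Accepts one current value (pA) per row, or `index,current` rows (the
#' last comma-separated field is used); an optional non-numeric header line
#' is skipped.
#'
#' @param path input file.
#' @param samplingRateHz sampling rate to record, default 3012.
#' @param channelId channel id to record, default 1.
#' @param voltageMv applied potential to record, default `NA`.
#' @return A [NanoporeTrace-class] with samples in file order.
#' @export
readCsvTrace <- function(path, samplingRateHz = 3012, channelId = 1L,
                         voltageMv = NA_real_) {
  if (!file.exists(path)) stop("I/O error: no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("format error: empty trace file: ", path)
  fields <- vapply(strsplit(lines, ","), function(f) trimws(f[length(f)]),
                   character(1))
  vals <- suppressWarnings(as.numeric(fields))
  start <- 1L
  if (is.na(vals[1]) && length(vals) > 1L) start <- 2L  # header line
  if (anyNA(vals[start:length(vals)])) {
    bad <- which(is.na(vals))
    bad <- bad[bad >= start][1]
    stop(sprintf("parse error: non-numeric value at row %d: '%s'",
                 bad, lines[bad]))
  }
  if (start > length(vals)) stop("format error: no numeric rows in ", path)
  nanoporeTrace(vals[start:length(vals)], channelId = channelId,
                samplingRateHz = samplingRateHz, voltageMv = voltageMv,
                source = path)
}

#' Write a trace as a one-value-per-row CSV
#'
#' @param trace a [NanoporeTrace-class].
#' @param path output file.
#' @param header write a `current_pA` header line, default `TRUE`.
#' @return `path`, invisibly.
#' @export
writeCsvTrace <- function(trace, path, header = TRUE) {
  con <- file(path, "w")
  on.exit(close(con))
  if (header) writeLines("current_pA", con)
  writeLines(format(samples(trace), digits = 17, trim = TRUE,
                    scientific = FALSE), con)
  invisible(path)
}

.TSV_HEADER <- c("channel", "i_o", "i_r", "ratio", "start", "end", "tau",
                 "i_mean")

#' Write an event table as TSV
#'
#' One row per accepted event: channel id, the channel baseline `i_o` (pA,
#' repeated on every row of that channel), the in-event minimum `i_r` (pA),
#' the `i_r/i_o` ratio, the start and end of the event in data time points
#' (0-based half-open integers), the dwell time `tau = end - start`, and an
#' informational in-event mean current. An empty table writes a header-only
#' file.
#'
#' @param events an [EventTable-class] or a compatible data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @seealso [readEventsTsv()]
#' @export
writeEventsTsv <- function(events, path) {
  ev <- if (is(events, "EventTable")) events@events else as.data.frame(events)
  if (!all(c("channel", "i_o", "i_r", "ratio", "start", "end", "tau")
           %in% names(ev)))
    stop("events must carry channel, i_o, i_r, ratio, start, end, tau")
  if (is.null(ev$i_mean)) ev$i_mean <- NA_real_
  ev <- ev[, .TSV_HEADER, drop = FALSE]
  ev$start <- as.integer(ev$start)
  ev$end <- as.integer(ev$end)
  ev$tau <- as.integer(ev$tau)
  utils::write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an event TSV back into a data.frame
#'
#' @param path file written by [writeEventsTsv()].
#' @return data.frame with the event columns.
#' @export
readEventsTsv <- function(path) {
  if (!file.exists(path)) stop("I/O error: no such file: ", path)
  ev <- utils::read.delim(path)
  if (!all(c("channel", "i_o", "i_r", "ratio", "start", "end", "tau")
           %in% names(ev)))
    stop("format error: not an event TSV: ", path)
  ev$channel <- as.integer(ev$channel)
  ev$start <- as.integer(ev$start)
  ev$end <- as.integer(ev$end)
  ev$tau <- as.integer(ev$tau)
  ev
}
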