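#' @include AllClasses.R
NULL

# Minimal RIFF/WAVE reader and writer (mono PCM-16 and IEEE float-32).
# Chunk-walks the container so files with LIST/fact chunks still parse.

#' Read a mono WAV file into a Recording
#'
#' Accepts 16-bit integer PCM and 32-bit IEEE float, mono only. Integer
#' samples are rescaled to `[-1, 1]` (division by 32768); the sampling rate
#' is taken from the header. If a sidecar events file `<path>.events.csv`
#' exists its markers are attached.
#'
#' @param path WAV file path.
#' @param phase,participantId,units metadata attached to the returned
#'   [Recording-class]; units default to `"raw"` and are never guessed from
#'   the file.
#' @return A [Recording-class].
#' @seealso [writeWav()], [readEvents()]
#' @export
readWav <- function(path, phase = "isometric", participantId = NA_character_,
                    units = "raw") {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAVE file: ", path)
  readBin(con, "integer", 1, 4, endian = "little")  # container size
  if (!identical(readChar(con, 4, useBytes = TRUE), "WAVE"))
    stop("not a RIFF/WAVE file: ", path)

  fmt <- NULL; dat <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        audioFormat = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        channels = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        rate = readBin(con, "integer", 1, 4, endian = "little"),
        byteRate = readBin(con, "integer", 1, 4, endian = "little"),
        blockAlign = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        bits = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE))
      extra <- sz - 16L
      if (extra > 0) readBin(con, "raw", extra)
    } else if (identical(id, "data")) {
      dat <- readBin(con, "raw", sz)
      if (sz %% 2L == 1L) readBin(con, "raw", 1)
      break
    } else {
      readBin(con, "raw", sz + (sz %% 2L))
    }
  }
  if (is.null(fmt)) stop("WAV file has no 'fmt ' chunk: ", path)
  if (is.null(dat)) stop("WAV file has no 'data' chunk: ", path)
  if (fmt$channels != 1L)
    stop("only mono WAV is supported; file has ", fmt$channels, " channels")

  x <- if (fmt$audioFormat == 1L && fmt$bits == 16L) {
    readBin(dat, "integer", length(dat) / 2L, 2L, signed = TRUE,
            endian = "little") / 32768
  } else if (fmt$audioFormat == 3L && fmt$bits == 32L) {
    readBin(dat, "double", length(dat) / 4L, 4L, endian = "little")
  } else {
    stop("unsupported WAV encoding (format ", fmt$audioFormat, ", ",
         fmt$bits, " bits); expected PCM-16 or float-32")
  }
  if (length(x) == 0) stop("WAV file contains no samples: ", path)

  events <- NULL
  sidecar <- paste0(path, ".events.csv")
  if (file.exists(sidecar)) events <- readEvents(sidecar)
  Recording(x, rate = fmt$rate, phase = phase, events = events,
            participantId = participantId, units = units)
}

#' Write a Recording to a mono WAV file
#'
#' Float-32 by default (lossless for real-valued signals); `encoding =
#' "pcm16"` quantizes to 16-bit integers and requires samples within
#' `[-1, 1]`. Event markers, which WAV cannot carry portably, go to a sidecar
#' CSV `<path>.events.csv`.
#'
#' @param recording a [Recording-class].
#' @param path output file path.
#' @param encoding `"float32"` (default) or `"pcm16"`.
#' @return `path`, invisibly.
#' @export
writeWav <- function(recording, path, encoding = c("float32", "pcm16")) {
  encoding <- match.arg(encoding)
  x <- recording@samples
  if (length(x) == 0) stop("refusing to write an empty recording")
  rate <- as.integer(round(recording@rate))
  if (encoding == "pcm16") {
    if (max(abs(x)) > 1)
      stop("pcm16 encoding requires samples within [-1, 1]")
    pcm <- as.integer(pmax(pmin(round(x * 32768), 32767), -32768))
    bytesPer <- 2L; fmtCode <- 1L
    payload <- writeBin(pcm, raw(), 2L, endian = "little")
  } else {
    bytesPer <- 4L; fmtCode <- 3L
    payload <- writeBin(as.numeric(x), raw(), 4L, endian = "little")
  }
  dataSize <- length(payload)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + dataSize), con, 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4L, endian = "little")
  writeBin(fmtCode, con, 2L, endian = "little")
  writeBin(1L, con, 2L, endian = "little")                 # mono
  writeBin(rate, con, 4L, endian = "little")
  writeBin(rate * bytesPer, con, 4L, endian = "little")    # byte rate
  writeBin(bytesPer, con, 2L, endian = "little")           # block align
  writeBin(8L * bytesPer, con, 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(dataSize), con, 4L, endian = "little")
  writeBin(payload, con)
  if (nrow(recording@events))
    writeEvents(recording@events, paste0(path, ".events.csv"))
  invisible(path)
}

#' Read a two-column CSV signal
#'
#' The sampling rate is inferred as `1 / median(diff(time))`; spacing must be
#' uniform to within 1% of the median step or the file is rejected. Rows with
#' missing values are rejected with their row indices.
#'
#' @param path CSV path (header row, comma separator, `.` decimal).
#' @param time_column,value_column column names.
#' @param phase,participantId,units metadata for the returned
#'   [Recording-class].
#' @return A [Recording-class].
#' @export
readCsvSignal <- function(path, time_column = "time_s",
                          value_column = "amplitude",
                          phase = "isometric",
                          participantId = NA_character_, units = "raw") {
  df <- utils::read.csv(path, check.names = FALSE)
  missing_cols <- setdiff(c(time_column, value_column), names(df))
  if (length(missing_cols))
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  tt <- df[[time_column]]; vv <- df[[value_column]]
  bad <- which(!is.finite(tt) | !is.finite(vv))
  if (length(bad))
    stop("non-finite values in rows: ", paste(bad, collapse = ", "))
  if (length(tt) < 2) stop("need at least two samples to infer a rate")
  dt <- diff(tt)
  if (any(dt <= 0)) stop("time column must be strictly increasing")
  step <- stats::median(dt)
  if (max(abs(dt - step)) > 0.01 * step)
    stop("non-uniform sample spacing (beyond 1% of the median step ",
         signif(step, 6), " s)")
  Recording(vv, rate = 1 / step, phase = phase,
            participantId = participantId, units = units)
}

#' Write a Recording as a two-column CSV
#'
#' @param recording a [Recording-class].
#' @param path output path.
#' @param time_column,value_column column names to write.
#' @return `path`, invisibly.
#' @export
writeCsvSignal <- function(recording, path, time_column = "time_s",
                           value_column = "amplitude") {
  n <- length(recording@samples)
  if (n == 0) stop("refusing to write an empty recording")
  df <- data.frame(seq(0, by = 1 / recording@rate, length.out = n),
                   recording@samples)
  names(df) <- c(time_column, value_column)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read / write event-marker sidecar files
#'
#' Events (e.g. fatigue-button presses) live in a plain CSV with columns
#' `time_s` and `label`.
#'
#' @param events `data.frame` with columns `time_s`, `label`.
#' @param path CSV path.
#' @return `readEvents` returns the events `data.frame`; `writeEvents`
#'   returns `path` invisibly.
#' @export
readEvents <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "label") %in% names(df)))
    stop("events file must have columns time_s and label: ", path)
  data.frame(time_s = as.numeric(df$time_s), label = as.character(df$label))
}

#' @rdname readEvents
#' @export
writeEvents <- function(events, path) {
  utils::write.csv(events[, c("time_s", "label")], path, row.names = FALSE)
  invisible(path)
}

#' Write / read a feature table
#'
#' One row per analysis window: `window_start_s`, `rms_pct_mvc`, `mdf_hz`,
#' `mnf_hz`, `defined`. Rereading reproduces the original series.
#'
#' @param series a [FeatureSeries-class].
#' @param path CSV path.
#' @return `writeFeatures` returns `path` invisibly; `readFeatures` a
#'   [FeatureSeries-class].
#' @export
writeFeatures <- function(series, path) {
  if (length(series@windowStart) == 0)
    stop("refusing to write an empty feature series")
  df <- featureTable(series)
  df$kind <- series@kind
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatures
#' @export
readFeatures <- function(path) {
  df <- utils::read.csv(path)
  need <- c("window_start_s", "rms_pct_mvc", "mdf_hz", "mnf_hz")
  if (!all(need %in% names(df)))
    stop("feature file must have columns: ", paste(need, collapse = ", "))
  defined <- if ("defined" %in% names(df)) as.logical(df$defined)
             else !is.na(df$mdf_hz)
  kind <- if ("kind" %in% names(df)) as.character(df$kind[1]) else "isometric"
  new("FeatureSeries", windowStart = df$window_start_s, rms = df$rms_pct_mvc,
      mdf = df$mdf_hz, mnf = df$mnf_hz, defined = defined, kind = kind)
}
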