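# Minimal mono 16-bit PCM WAV I/O for persisting simulated recordings.
# Only the canonical 44-byte RIFF/fmt/data layout is supported.

#' Write a recording as a mono 16-bit PCM WAV file
#'
#' @param rec a `wb_recording` (or list with `samples` in \[-1, 1\] and
#'   `sample_rate`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(rec, path) {
  x <- rec$samples
  sr <- as.integer(rec$sample_rate)
  stopifnot(length(x) > 0, sr > 0)
  pcm <- as.integer(round(pmin(1, pmax(-1, x)) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + data_bytes, con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")  # PCM
  writeBin(1L, con, size = 2, endian = "little")  # mono
  writeBin(sr, con, size = 4, endian = "little")
  writeBin(sr * 2L, con, size = 4, endian = "little")  # byte rate
  writeBin(2L, con, size = 2, endian = "little")  # block align
  writeBin(16L, con, size = 2, endian = "little") # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a mono 16-bit PCM WAV file
#'
#' @param path file written by [write_wav()] (or any canonical mono
#'   16-bit PCM WAV).
#' @return list with `samples` (amplitudes in \[-1, 1\]) and
#'   `sample_rate`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file: ", path)
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file: ", path)
  sr <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk found in ", path)
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      if (fmt[1] != 1L || fmt[2] != 1L) stop("only mono PCM WAV is supported")
      sr <- readBin(con, integer(), size = 4, endian = "little")
      invisible(readBin(con, integer(), size = 4, endian = "little"))
      ba_bits <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      if (ba_bits[2] != 16L) stop("only 16-bit PCM WAV is supported")
      if (size > 16) invisible(readBin(con, raw(), n = size - 16))
    } else if (id == "data") {
      pcm <- readBin(con, integer(), n = size / 2, size = 2,
                     signed = TRUE, endian = "little")
      if (is.null(sr)) stop("data chunk precedes fmt chunk in ", path)
      return(list(samples = pcm / 32767, sample_rate = sr))
    } else {
      invisible(readBin(con, raw(), n = size))
    }
  }
}

#' Persist a recording set as WAV files plus a metadata CSV
#'
#' Writes one WAV per recording and a sidecar `metadata.csv` with
#' columns `file`, `label`, `timestamp` (ISO-8601), `temperature_C`,
#' `humidity_pct`, `validity`.
#'
#' @param recordings list of `wb_recording` objects.
#' @param dir output directory (created if needed).
#' @return path of the metadata CSV, invisibly.
#' @export
write_recording_set <- function(recordings, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("rec%05d.wav", seq_along(recordings))
  for (i in seq_along(recordings)) {
    write_wav(recordings[[i]], file.path(dir, files[i]))
  }
  meta <- data.frame(
    file = files,
    label = vapply(recordings, `[[`, "", "label"),
    timestamp = vapply(recordings, function(r) {
      format(r$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
    }, ""),
    temperature_C = vapply(recordings, `[[`, 0, "temperature"),
    humidity_pct = vapply(recordings, `[[`, 0, "humidity"),
    validity = vapply(recordings, `[[`, "", "validity")
  )
  path <- file.path(dir, "metadata.csv")
  utils::write.csv(meta, path, row.names = FALSE)
  invisible(path)
}
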