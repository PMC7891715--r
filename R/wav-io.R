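#' Read a mono PCM WAV file
#'
#' Minimal reader for the 16-bit mono PCM subset of the RIFF/WAVE format used
#' by fixed-duration recorder clips. Chunks other than `fmt ` and `data` are
#' skipped.
#'
#' @param path Path to a `.wav` file.
#' @return A list with `samples` (numeric, scaled to `[-1, 1]`) and
#'   `sample_rate` (Hz).
#' @seealso [write_wav()]
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", 1, size = 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  fmt <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", size)
      fmt <- list(
        format   = readBin(raw[1:2], "integer", 1, size = 2, endian = "little"),
        channels = readBin(raw[3:4], "integer", 1, size = 2, endian = "little"),
        rate     = readBin(raw[5:8], "integer", 1, size = 4, endian = "little"),
        bits     = readBin(raw[15:16], "integer", 1, size = 2, endian = "little")
      )
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("malformed WAV (data before fmt): ", path)
      samples <- readBin(con, "integer", size / 2, size = 2, signed = TRUE,
                         endian = "little")
      break
    } else {
      seek(con, size + size %% 2, origin = "current")
    }
  }
  if (is.null(fmt) || is.null(samples)) stop("malformed WAV file: ", path)
  if (fmt$format != 1L || fmt$bits != 16L)
    stop("only 16-bit PCM WAV is supported: ", path)
  if (fmt$channels != 1L)
    stop("only mono WAV is supported (", fmt$channels, " channels): ", path)
  list(samples = samples / 32767, sample_rate = fmt$rate)
}

#' Write a mono PCM WAV file
#'
#' Writes numeric samples as 16-bit mono PCM. Samples are clipped to
#' `[-1, 1]` and quantized; writing the same samples twice yields
#' byte-identical files.
#'
#' @param samples Numeric vector in `[-1, 1]`.
#' @param sample_rate Sampling rate in Hz.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, sample_rate, path) {
  x <- as.integer(round(pmax(pmin(samples, 1), -1) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  nbytes <- length(x) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + nbytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")                 # PCM
  writeBin(1L, con, size = 2, endian = "little")                 # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")                 # block align
  writeBin(16L, con, size = 2, endian = "little")                # bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(nbytes), con, size = 4, endian = "little")
  writeBin(x, con, size = 2, endian = "little")
  invisible(path)
}

#' Parse clip start times from timestamped filenames
#'
#' Filenames of the form `YYYYMMDD_HHMMSS.wav` (any directory prefix) are
#' parsed as UTC start times. Supply a different parser to [build_ltsa()] for
#' other naming dialects.
#'
#' @param files Character vector of file paths.
#' @return `POSIXct` vector of clip start times (UTC).
#' @export
parse_clip_time <- function(files) {
  base <- sub("\\.[Ww][Aa][Vv]$", "", basename(files))
  out <- as.POSIXct(strptime(base, "%Y%m%d_%H%M%S", tz = "UTC"))
  if (anyNA(out))
    stop("cannot parse timestamps from: ",
         paste(base[is.na(out)][1:min(3, sum(is.na(out)))], collapse = ", "))
  out
}
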