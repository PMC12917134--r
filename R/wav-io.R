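# Minimal RIFF/WAVE I/O for PCM 16-bit mono, the only encoding the pipeline
# accepts. Other encodings are rejected with a clear message rather than
# guessed at.

#' Construct a waveform object
#'
#' A `cogspeech_waveform` holds mono audio samples on the [-1, 1] scale with
#' their sample rate, plus optional participant/task labels used by the
#' feature tables.
#'
#' @param samples numeric vector of samples in [-1, 1] (values are clipped on
#'   write, not on construction).
#' @param sample_rate sampling rate in Hz, must be positive.
#' @param participant_id,task optional labels carried through feature tables.
#' @return an object of class `cogspeech_waveform`.
#' @export
waveform <- function(samples, sample_rate, participant_id = NA_character_,
                     task = NA_character_) {
  if (!is.numeric(samples) || any(!is.finite(samples))) {
    cs_stop("waveform samples must be finite numeric values", "cogspeech_validation_error")
  }
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0) {
    cs_stop("sample_rate must be a single positive number", "cogspeech_validation_error")
  }
  structure(
    list(samples = as.numeric(samples), sample_rate = as.numeric(sample_rate),
         participant_id = participant_id, task = task),
    class = "cogspeech_waveform"
  )
}

#' @export
print.cogspeech_waveform <- function(x, ...) {
  cat(sprintf("<cogspeech_waveform: %d samples @ %g Hz (%.2f s)>\n",
              length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate))
  invisible(x)
}

#' Duration of a waveform in seconds
#' @param w a `cogspeech_waveform`.
#' @return duration in seconds.
#' @export
wav_duration <- function(w) length(w$samples) / w$sample_rate

#' Write a waveform as a 16-bit PCM mono WAV file
#'
#' @param w a `cogspeech_waveform`; samples outside [-1, 1] are clipped.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(w, path) {
  stopifnot(inherits(w, "cogspeech_waveform"))
  x <- pmax(-1, pmin(1, w$samples))
  pcm <- as.integer(round(x * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  n_bytes <- length(pcm) * 2L
  sr <- as.integer(round(w$sample_rate))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")          # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")           # PCM
  writeBin(1L, con, size = 2, endian = "little")           # mono
  writeBin(sr, con, size = 4, endian = "little")
  writeBin(sr * 2L, con, size = 4, endian = "little")      # byte rate
  writeBin(2L, con, size = 2, endian = "little")           # block align
  writeBin(16L, con, size = 2, endian = "little")          # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM mono WAV file
#'
#' @param path path to a RIFF/WAVE file. Only uncompressed 16-bit mono PCM is
#'   supported; anything else is rejected.
#' @param participant_id,task optional labels to attach.
#' @return a `cogspeech_waveform`.
#' @export
read_wav <- function(path, participant_id = NA_character_, task = NA_character_) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  readBin(con, "integer", size = 4, endian = "little")
  wave <- readChar(con, 4)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE")) {
    cs_stop(sprintf("'%s' is not a RIFF/WAVE file", path), "cogspeech_format_error")
  }
  sample_rate <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0L || nchar(id) < 4L) {
      cs_stop("WAV file has no data chunk", "cogspeech_format_error")
    }
    size <- readBin(con, "integer", size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", n = 2, size = 2, endian = "little")
      sample_rate <- readBin(con, "integer", size = 4, endian = "little")
      readBin(con, "integer", size = 4, endian = "little")
      readBin(con, "integer", size = 2, endian = "little")
      bits <- readBin(con, "integer", size = 2, endian = "little")
      if (fmt[1] != 1L || fmt[2] != 1L || bits != 16L) {
        cs_stop("only PCM 16-bit mono WAV is supported", "cogspeech_format_error")
      }
      if (size > 16L) readBin(con, "raw", n = size - 16L)
    } else if (identical(id, "data")) {
      if (is.null(sample_rate)) {
        cs_stop("WAV data chunk precedes fmt chunk", "cogspeech_format_error")
      }
      pcm <- readBin(con, "integer", n = size %/% 2L, size = 2,
                     signed = TRUE, endian = "little")
      return(waveform(pcm / 32767, sample_rate, participant_id, task))
    } else {
      readBin(con, "raw", n = size + (size %% 2L))
    }
  }
}
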