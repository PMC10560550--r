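#' Multichannel recording container
#'
#' @param samples numeric matrix, time x channels, normalized to [-1, 1] full
#'   scale.
#' @param sample_rate Hz.
#' @param channel_map integer vector mapping channel column -> microphone row
#'   in the array geometry (default identity).
#' @param full_scale_pa sound pressure in Pa corresponding to full-scale
#'   amplitude 1.0 (from the absolute microphone calibration).
#' @return object of class `multichannel_recording`.
#' @export
multichannel_recording <- function(samples, sample_rate,
                                   channel_map = seq_len(ncol(samples)),
                                   full_scale_pa = 0.5) {
  samples <- as.matrix(samples)
  stopifnot(ncol(samples) >= 1, sample_rate > 0, full_scale_pa > 0,
            length(channel_map) == ncol(samples))
  structure(list(samples = samples, sample_rate = sample_rate,
                 channel_map = as.integer(channel_map),
                 full_scale_pa = full_scale_pa),
            class = "multichannel_recording")
}

#' @export
print.multichannel_recording <- function(x, ...) {
  cat(sprintf("Multichannel recording: %d channels, %.3f s at %g kHz (FS = %g Pa)\n",
              ncol(x$samples), nrow(x$samples) / x$sample_rate,
              x$sample_rate / 1e3, x$full_scale_pa))
  invisible(x)
}

#' Channel carrying the central microphone
#' @param rec a [multichannel_recording()].
#' @param geometry a [mic_array_geometry()].
#' @return integer column index.
#' @export
central_channel <- function(rec, geometry) {
  ch <- which(rec$channel_map == geometry$central_index)
  if (length(ch) != 1) stop("no unique channel mapped to the central microphone")
  ch
}

#' Write a recording as 16-bit PCM RIFF WAV
#'
#' Plain RIFF/PCM writer (multichannel, little-endian, 16-bit). Samples are
#' clipped to [-1, 1] and quantized round-to-nearest.
#'
#' @param rec a [multichannel_recording()].
#' @param path output file.
#' @export
write_wav <- function(rec, path) {
  stopifnot(inherits(rec, "multichannel_recording"))
  x <- rec$samples
  x[x > 1] <- 1; x[x < -1] <- -1
  q <- round(x * 32767)                     # keep matrix shape
  inter <- as.integer(t(q))                 # interleave channels
  n_ch <- ncol(x); fs <- as.integer(rec$sample_rate)
  block <- n_ch * 2L
  data_bytes <- length(inter) * 2L
  con <- file(path, "wb"); on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")             # PCM
  writeBin(n_ch, con, size = 2, endian = "little")
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(fs * block, con, size = 4, endian = "little")     # byte rate
  writeBin(block, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")            # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(inter, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM RIFF WAV
#'
#' @param path WAV file.
#' @param channel_map,full_scale_pa as in [multichannel_recording()].
#' @return a [multichannel_recording()] with samples in [-1, 1].
#' @export
read_wav <- function(path, channel_map = NULL, full_scale_pa = 0.5) {
  con <- file(path, "rb"); on.exit(close(con))
  if (readChar(con, 4, useBytes = TRUE) != "RIFF") stop("not a RIFF file")
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  if (readChar(con, 4, useBytes = TRUE) != "WAVE") stop("not a WAVE file")
  n_ch <- NULL; fs <- NULL; bits <- NULL; data <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id, type = "bytes") < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", 1, 2, endian = "little")
      if (fmt != 1) stop("only PCM WAV supported")
      n_ch <- readBin(con, "integer", 1, 2, endian = "little")
      fs <- readBin(con, "integer", 1, 4, endian = "little")
      invisible(readBin(con, "integer", 1, 4, endian = "little")) # byte rate
      invisible(readBin(con, "integer", 1, 2, endian = "little")) # block align
      bits <- readBin(con, "integer", 1, 2, endian = "little")
      if (size > 16) invisible(readBin(con, "raw", size - 16))
    } else if (id == "data") {
      if (is.null(bits)) stop("data chunk before fmt chunk")
      if (bits != 16) stop("only 16-bit WAV supported")
      data <- readBin(con, "integer", size / 2, 2, signed = TRUE,
                      endian = "little")
      break
    } else {
      invisible(readBin(con, "raw", size + size %% 2))
    }
  }
  if (is.null(data)) stop("no data chunk found")
  m <- matrix(data / 32767, ncol = n_ch, byrow = TRUE)
  if (is.null(channel_map)) channel_map <- seq_len(n_ch)
  multichannel_recording(m, fs, channel_map, full_scale_pa)
}
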