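#' Construct a mono audio clip
#'
#' The basic unit of audio handled by the package: a mono waveform with a
#' sample rate. Amplitudes are nominally in `[-1, 1]` but are not clipped;
#' all processing is floating point.
#'
#' @param samples Numeric vector of amplitude values.
#' @param sample_rate Sample rate in Hz (positive integer).
#' @return An object of class `audio_clip` with fields `samples` and
#'   `sample_rate`; `duration(clip)` gives the length in seconds.
#' @export
audio_clip <- function(samples, sample_rate) {
  if (!is.numeric(samples)) stop("samples must be numeric")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    stop("sample_rate must be a single positive number")
  structure(
    list(samples = as.numeric(samples), sample_rate = as.integer(sample_rate)),
    class = "audio_clip"
  )
}

#' @export
print.audio_clip <- function(x, ...) {
  cat(sprintf(
    "<audio_clip: %.3f s @ %d Hz, %d samples, peak %.3f>\n",
    clip_duration(x), x$sample_rate, length(x$samples),
    if (length(x$samples)) max(abs(x$samples)) else 0
  ))
  invisible(x)
}

#' Duration of a clip in seconds
#' @param clip An `audio_clip`.
#' @return Duration in seconds.
#' @export
clip_duration <- function(clip) length(clip$samples) / clip$sample_rate

#' Split a recording into fixed-length chunks
#'
#' Recordings are processed in contiguous, non-overlapping chunks (3 s by
#' default); a trailing remainder shorter than one chunk is zero-padded to
#' full length and kept, so late vocalisations are never dropped.
#'
#' @param recording An `audio_clip`.
#' @param chunk_seconds Chunk length in seconds (default 3).
#' @return List of `audio_clip` chunks, each exactly `chunk_seconds` long,
#'   in temporal order.
#' @export
chunk_recording <- function(recording, chunk_seconds = 3) {
  stopifnot(inherits(recording, "audio_clip"))
  if (length(recording$samples) == 0L) stop("cannot chunk an empty recording")
  if (chunk_seconds <= 0) stop("chunk_seconds must be positive")
  sr <- recording$sample_rate
  chunk_len <- round(chunk_seconds * sr)
  n <- length(recording$samples)
  n_chunks <- ceiling(n / chunk_len)
  padded <- c(recording$samples, rep(0, n_chunks * chunk_len - n))
  lapply(seq_len(n_chunks), function(i) {
    audio_clip(padded[((i - 1L) * chunk_len + 1L):(i * chunk_len)], sr)
  })
}

#' Resample a clip by band-limited (Fourier) interpolation
#'
#' Length is `round(n * target_rate / sample_rate)`; the spectrum is truncated
#' (downsampling) or zero-padded (upsampling) so content below the new Nyquist
#' frequency is preserved.
#'
#' @param clip An `audio_clip`.
#' @param target_rate Target sample rate in Hz.
#' @return Resampled `audio_clip`.
#' @export
resample <- function(clip, target_rate) {
  stopifnot(inherits(clip, "audio_clip"))
  if (!is.numeric(target_rate) || target_rate <= 0) stop("target_rate must be positive")
  target_rate <- as.integer(target_rate)
  if (target_rate == clip$sample_rate) return(clip)
  n <- length(clip$samples)
  m <- round(as.numeric(n) * target_rate / clip$sample_rate)
  if (n == 0L || m == 0L) return(audio_clip(numeric(m), target_rate))
  spec <- stats::fft(clip$samples)
  out_spec <- complex(m)
  half <- min(n, m) %/% 2L
  # keep DC..half-1 positive bins and the mirrored negative bins
  out_spec[1:(half + 1L)] <- spec[1:(half + 1L)]
  if (half > 0L) out_spec[(m - half + 1L):m] <- spec[(n - half + 1L):n]
  # Nyquist bin of an even-length truncation must stay conjugate-symmetric
  if (m < n && m %% 2L == 0L) out_spec[half + 1L] <- Re(spec[half + 1L])
  out <- Re(stats::fft(out_spec, inverse = TRUE)) / n
  audio_clip(out, target_rate)
}

#' Read a mono waveform from a 16-bit PCM WAV file
#'
#' Minimal RIFF/WAVE reader (PCM 16-bit only, the format this package writes).
#' Multi-channel files are converted to mono by channel averaging.
#'
#' @param path Path to a WAV file.
#' @return An `audio_clip` with samples scaled to `[-1, 1]`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  sample_rate <- NULL; n_channels <- NULL; bits <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      if (fmt[1] != 1L) stop("only PCM WAV is supported")
      n_channels <- fmt[2]
      sample_rate <- readBin(con, "integer", 1, size = 4, endian = "little")
      invisible(readBin(con, "integer", 1, size = 4, endian = "little")) # byte rate
      invisible(readBin(con, "integer", 1, size = 2, endian = "little")) # block align
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (size > 16L) invisible(readBin(con, "raw", size - 16L))
      if (bits != 16L) stop("only 16-bit PCM WAV is supported")
    } else if (identical(id, "data")) {
      samples <- readBin(con, "integer", size %/% 2L, size = 2, signed = TRUE,
                         endian = "little")
      if (size %% 2L == 1L) invisible(readBin(con, "raw", 1L))
    } else {
      invisible(readBin(con, "raw", size + size %% 2L))
    }
    if (!is.null(samples) && !is.null(sample_rate)) break
  }
  if (is.null(samples) || is.null(sample_rate)) stop("malformed WAV file: ", path)
  x <- samples / 32768
  if (n_channels > 1L) {
    x <- colMeans(matrix(x, nrow = n_channels))
  }
  audio_clip(x, sample_rate)
}

#' Write a clip to a 16-bit PCM WAV file
#'
#' Samples are clamped to `[-1, 1]` at write time (training itself never
#' clips; only serialisation does).
#'
#' @param clip An `audio_clip`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(clip, path) {
  stopifnot(inherits(clip, "audio_clip"))
  x <- pmin(pmax(clip$samples, -1), 1)
  pcm <- as.integer(round(x * 32767))
  data_size <- 2L * length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")              # PCM
  writeBin(1L, con, size = 2, endian = "little")              # mono
  writeBin(clip$sample_rate, con, size = 4, endian = "little")
  writeBin(clip$sample_rate * 2L, con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Root-mean-square amplitude of a clip
#' @param clip An `audio_clip`.
#' @return RMS value (0 for an empty clip).
#' @export
clip_rms <- function(clip) {
  if (length(clip$samples) == 0L) return(0)
  sqrt(mean(clip$samples^2))
}
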