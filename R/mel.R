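#' Mel front-end configuration
#'
#' Parameters of the STFT + mel filterbank + log compression pipeline.
#' Framing is left-aligned (no centre padding): a window is placed at every
#' `hop_length` samples starting at sample 1, and only full windows count.
#' This is the framing convention under which a 3 s input yields 298 frames
#' for both built-in presets.
#'
#' @param n_mels Number of mel bands.
#' @param sample_rate Expected sample rate in Hz.
#' @param win_length Analysis window length in samples.
#' @param hop_length Hop between consecutive windows in samples.
#' @param n_fft FFT size (the window is zero-padded from `win_length`).
#' @param log_floor Additive floor before log compression.
#' @param standardize If `TRUE` (default), per-spectrogram mean/sd
#'   standardisation is applied when spectrograms are fed to models.
#' @param spectrogram If `FALSE`, the front-end is a raw-waveform
#'   pass-through (no STFT); used by the 48 kHz raw preset.
#' @return A `mel_config` object.
#' @export
mel_config <- function(n_mels = 128L, sample_rate = 16000L, win_length = 400L,
                       hop_length = 160L, n_fft = 512L, log_floor = 1e-10,
                       standardize = TRUE, spectrogram = TRUE) {
  stopifnot(n_mels >= 1L, win_length <= n_fft, hop_length <= win_length,
            sample_rate > 0, log_floor > 0)
  structure(
    list(n_mels = as.integer(n_mels), sample_rate = as.integer(sample_rate),
         win_length = as.integer(win_length), hop_length = as.integer(hop_length),
         n_fft = as.integer(n_fft), log_floor = log_floor,
         standardize = isTRUE(standardize), spectrogram = isTRUE(spectrogram)),
    class = "mel_config"
  )
}

#' Named front-end presets
#'
#' Three presets are provided:
#' * `"passt"`: 128 mel bands, 16 kHz, window 400, hop 160, FFT 512.
#' * `"psla"`: 128 mel bands, 32 kHz, window 800, hop 320, FFT 1024.
#' * `"birdnet_raw"`: 48 kHz raw-waveform pass-through (no spectrogram).
#'
#' The two spectrogram presets both produce 298 frames from a 3 s input.
#'
#' @param name Preset name.
#' @return A `mel_config`.
#' @export
frontend_preset <- function(name = c("passt", "psla", "birdnet_raw")) {
  name <- match.arg(name)
  switch(name,
    passt = mel_config(128L, 16000L, 400L, 160L, 512L),
    psla  = mel_config(128L, 32000L, 800L, 320L, 1024L),
    birdnet_raw = mel_config(1L, 48000L, 1L, 1L, 1L, spectrogram = FALSE)
  )
}

#' Number of STFT frames for a given duration
#'
#' Left-aligned framing without centre padding:
#' `1 + floor((duration * sample_rate - win_length) / hop_length)`.
#'
#' @param config A `mel_config`.
#' @param duration Signal duration in seconds.
#' @return Integer frame count.
#' @export
frame_count <- function(config, duration) {
  stopifnot(inherits(config, "mel_config"))
  n <- round(duration * config$sample_rate)
  if (n < config$win_length)
    stop(sprintf("signal (%d samples) shorter than one window (%d samples)",
                 n, config$win_length))
  as.integer(1L + floor((n - config$win_length) / config$hop_length))
}

# Periodic Hann window, the STFT convention used throughout.
hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / n)

hz_to_mel <- function(f) {
  # Slaney mel scale: linear below 1 kHz, logarithmic above.
  ifelse(f < 1000, 3 * f / 200, 15 + 27 * log(f / 1000) / log(6.4))
}

mel_to_hz <- function(m) {
  ifelse(m < 15, 200 * m / 3, 1000 * exp((m - 15) * log(6.4) / 27))
}

#' Slaney-style mel filterbank matrix
#'
#' Triangular filters with area normalisation (each filter scaled by
#' `2 / (f_upper - f_lower)`), spanning `[0, sample_rate/2]`.
#'
#' @param config A `mel_config`.
#' @return Matrix `n_mels x (n_fft/2 + 1)`.
#' @export
mel_filterbank <- function(config) {
  n_bins <- config$n_fft %/% 2L + 1L
  fft_freqs <- (seq_len(n_bins) - 1L) * config$sample_rate / config$n_fft
  mel_pts <- seq(hz_to_mel(0), hz_to_mel(config$sample_rate / 2),
                 length.out = config$n_mels + 2L)
  hz_pts <- mel_to_hz(mel_pts)
  fb <- matrix(0, config$n_mels, n_bins)
  for (k in seq_len(config$n_mels)) {
    lo <- hz_pts[k]; mid <- hz_pts[k + 1L]; hi <- hz_pts[k + 2L]
    up <- (fft_freqs - lo) / (mid - lo)
    down <- (hi - fft_freqs) / (hi - mid)
    fb[k, ] <- pmax(0, pmin(up, down)) * 2 / (hi - lo)
  }
  fb
}

#' Compute a log-mel spectrogram
#'
#' STFT with a periodic Hann window and no centre padding, power spectrum,
#' Slaney mel projection, then `log(mel_power + log_floor)`. The clip's
#' sample rate must equal the config's; resample upstream — this operation
#' never resamples silently.
#'
#' @param clip An `audio_clip`.
#' @param config A `mel_config`.
#' @return A `mel_spectrogram`: list with `values` (matrix `n_mels x
#'   n_frames`) and `config`.
#' @export
compute_mel <- function(clip, config) {
  stopifnot(inherits(clip, "audio_clip"), inherits(config, "mel_config"))
  if (!config$spectrogram)
    stop("config is a raw-waveform pass-through preset; no spectrogram defined")
  if (clip$sample_rate != config$sample_rate)
    stop(sprintf("sample-rate mismatch: clip %d Hz vs config %d Hz (resample upstream)",
                 clip$sample_rate, config$sample_rate))
  n_frames <- frame_count(config, clip_duration(clip))
  win <- hann_window(config$win_length)
  # frame matrix: win_length x n_frames, zero-padded to n_fft
  idx <- outer(seq_len(config$win_length),
               (seq_len(n_frames) - 1L) * config$hop_length, "+")
  frames <- matrix(clip$samples[idx], nrow = config$win_length) * win
  padded <- rbind(frames, matrix(0, config$n_fft - config$win_length, n_frames))
  spec <- stats::mvfft(padded)[seq_len(config$n_fft %/% 2L + 1L), , drop = FALSE]
  power <- Re(spec)^2 + Im(spec)^2
  melp <- mel_filterbank(config) %*% power
  values <- log(melp + config$log_floor)
  structure(list(values = values, config = config), class = "mel_spectrogram")
}

#' @export
print.mel_spectrogram <- function(x, ...) {
  cat(sprintf("<mel_spectrogram: %d mels x %d frames, range [%.2f, %.2f]>\n",
              nrow(x$values), ncol(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' Per-spectrogram standardisation
#'
#' Subtract the global mean and divide by the global standard deviation of
#' the matrix. Guarded for (near-)silent input: if sd < 1e-8 the values are
#' only centred.
#'
#' @param values Numeric matrix of log-mel energies.
#' @return Standardised matrix.
#' @export
standardize_mel <- function(values) {
  mu <- mean(values)
  sdv <- stats::sd(as.vector(values))
  if (!is.finite(sdv) || sdv < 1e-8) return(values - mu)
  (values - mu) / sdv
}
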