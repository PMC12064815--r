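#' Waveform augmentation configuration
#'
#' MixUp is applied with probability 0.6 and background-noise addition,
#' independently, with probability 0.5; noise is scaled to a random SNR drawn
#' uniformly from 3-30 dB. Both operate on raw waveforms before spectrogram
#' conversion. The Beta shape of the MixUp ratio defaults to a symmetric 0.2.
#'
#' @param mixup_prob Probability of applying MixUp (default 0.6).
#' @param noise_prob Probability of adding background noise (default 0.5).
#' @param snr_range_db Closed SNR interval in dB (default `c(3, 30)`).
#' @param beta_alpha Symmetric Beta shape for the MixUp ratio (default 0.2).
#' @param rng_seed Integer seed of the trainer's single RNG stream.
#' @return An `augmentation_config`.
#' @export
augmentation_config <- function(mixup_prob = 0.6, noise_prob = 0.5,
                                snr_range_db = c(3, 30), beta_alpha = 0.2,
                                rng_seed = 1L) {
  stopifnot(mixup_prob >= 0, mixup_prob <= 1, noise_prob >= 0, noise_prob <= 1,
            length(snr_range_db) == 2L, snr_range_db[1] <= snr_range_db[2],
            beta_alpha > 0)
  structure(list(mixup_prob = mixup_prob, noise_prob = noise_prob,
                 snr_range_db = as.numeric(snr_range_db),
                 beta_alpha = beta_alpha, rng_seed = as.integer(rng_seed)),
            class = "augmentation_config")
}

#' MixUp of two clips and their targets
#'
#' Convex combination `lam * a + (1 - lam) * b` of the waveforms and the
#' same combination of the target vectors. No clipping is applied (floating
#' point). For multi-label targets, callers may clamp the combined target at
#' 1 (see [augment_for_training()]).
#'
#' @param clip_a,clip_b Same-length, same-rate `audio_clip`s.
#' @param target_a,target_b Same-length target vectors.
#' @param lam Mixing ratio in `[0, 1]`.
#' @return List with `clip` and `target`.
#' @export
mixup <- function(clip_a, clip_b, target_a, target_b, lam) {
  if (clip_a$sample_rate != clip_b$sample_rate)
    stop("mixup: sample-rate mismatch")
  if (length(clip_a$samples) != length(clip_b$samples))
    stop("mixup: length mismatch")
  if (length(target_a) != length(target_b))
    stop("mixup: target dimension mismatch")
  stopifnot(lam >= 0, lam <= 1)
  list(
    clip = audio_clip(lam * clip_a$samples + (1 - lam) * clip_b$samples,
                      clip_a$sample_rate),
    target = lam * target_a + (1 - lam) * target_b
  )
}

#' Add background noise at a controlled SNR
#'
#' The noise is gain-scaled so that
#' `10 * log10(rms(signal)^2 / rms(scaled noise)^2) = snr_db`, i.e.
#' `g = (rms_s / rms_n) * 10^(-snr_db / 20)`, then added to the signal.
#' Labels are unchanged by noise addition. If the noise clip is longer than
#' the signal a random window is cropped; if shorter it is tiled.
#'
#' @param clip Signal `audio_clip`.
#' @param noise Noise `audio_clip` at the same sample rate.
#' @param snr_db Requested signal-to-noise ratio in dB.
#' @return The noisy `audio_clip`; if the signal is silent the input is
#'   returned unchanged with a warning (SNR undefined).
#' @export
add_background_noise <- function(clip, noise, snr_db) {
  if (clip$sample_rate != noise$sample_rate)
    stop("add_background_noise: sample-rate mismatch")
  rms_s <- clip_rms(clip)
  if (rms_s == 0) {
    warning("silent signal: skipping noise augmentation (SNR undefined)")
    return(clip)
  }
  n <- length(clip$samples)
  nz <- noise$samples
  if (length(nz) == 0L || all(nz == 0)) stop("silent noise clip")
  if (length(nz) < n) nz <- rep_len(nz, n)
  if (length(nz) > n) {
    start <- sample.int(length(nz) - n + 1L, 1L)
    nz <- nz[start:(start + n - 1L)]
  }
  rms_n <- sqrt(mean(nz^2))
  if (rms_n == 0) stop("silent noise window")
  g <- (rms_s / rms_n) * 10^(-snr_db / 20)
  audio_clip(clip$samples + g * nz, clip$sample_rate)
}

#' On-the-fly training augmentation
#'
#' With probability `mixup_prob`, mixes the example with a partner drawn
#' uniformly from the batch (ratio `lam ~ Beta(alpha, alpha)`); independently,
#' with probability `noise_prob`, adds a noise-pool clip at an SNR drawn
#' uniformly from `snr_range_db`. MixUp is applied first. The returned
#' waveform is the single input shown to both teacher and student under
#' consistent teaching. Multi-label mixed targets are clamped at 1.
#'
#' @param clip The example's `audio_clip`.
#' @param target Its target vector.
#' @param batch_clips List of candidate MixUp partners (`audio_clip`s).
#' @param batch_targets Their target vectors.
#' @param cfg An `augmentation_config`.
#' @param noise_pool List of noise `audio_clip`s; must be non-empty when
#'   `noise_prob > 0` (validated at configuration time by the trainer).
#' @param single_label If `TRUE`, targets stay a convex combination (sum 1);
#'   if `FALSE` they are clamped elementwise at 1.
#' @return List with `clip`, `target`, and flags `mixed`, `noised`.
#' @export
augment_for_training <- function(clip, target, batch_clips, batch_targets,
                                 cfg, noise_pool = list(),
                                 single_label = TRUE) {
  stopifnot(inherits(cfg, "augmentation_config"))
  mixed <- FALSE; noised <- FALSE
  if (cfg$mixup_prob > 0 && stats::runif(1) < cfg$mixup_prob &&
      length(batch_clips) > 0) {
    j <- sample.int(length(batch_clips), 1L)
    lam <- stats::rbeta(1, cfg$beta_alpha, cfg$beta_alpha)
    mx <- mixup(clip, batch_clips[[j]], target, batch_targets[[j]], lam)
    clip <- mx$clip
    target <- if (single_label) mx$target else pmin(mx$target, 1)
    mixed <- TRUE
  }
  if (cfg$noise_prob > 0 && stats::runif(1) < cfg$noise_prob) {
    if (length(noise_pool) == 0L)
      stop("noise augmentation enabled but the noise pool is empty")
    k <- sample.int(length(noise_pool), 1L)
    snr <- stats::runif(1, cfg$snr_range_db[1], cfg$snr_range_db[2])
    clip <- suppressWarnings(add_background_noise(clip, noise_pool[[k]], snr))
    noised <- TRUE
  }
  list(clip = clip, target = target, mixed = mixed, noised = noised)
}
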