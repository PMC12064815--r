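#' Synthetic species vocalisation profile
#'
#' Calls are frequency-modulated tones: each species is characterised by a
#' base frequency inside the bird band (500-10,000 Hz), a chirp rate
#' (linear frequency sweep), a bandwidth for the sweep, and a call duration.
#' Profiles stand in for real vocalisations; the generator's purpose is
#' pipeline behaviour, not bioacoustic realism.
#'
#' @param species_id Species code string.
#' @param base_frequency Centre frequency in Hz (must lie in 500-10,000).
#' @param chirp_rate Sweep rate in Hz/s.
#' @param bandwidth Frequency excursion of the sweep in Hz.
#' @param call_duration Call length in seconds.
#' @return A `species_profile`.
#' @export
species_profile <- function(species_id, base_frequency, chirp_rate = 0,
                            bandwidth = 200, call_duration = 0.5) {
  stopifnot(base_frequency >= 500, base_frequency <= 10000, call_duration > 0)
  structure(list(species_id = as.character(species_id),
                 base_frequency = base_frequency, chirp_rate = chirp_rate,
                 bandwidth = bandwidth, call_duration = call_duration),
            class = "species_profile")
}

#' Deterministic bank of distinct species profiles
#'
#' Base frequencies are evenly spaced over `freq_range` so profiles are
#' pairwise distinct by at least the spacing margin; chirp rate, bandwidth
#' and duration vary cyclically so species differ in more than pitch.
#'
#' @param n Number of species.
#' @param freq_range Frequency interval to spread species over (Hz).
#' @param prefix Species-code prefix.
#' @return List of `species_profile`.
#' @export
make_species_profiles <- function(n, freq_range = c(1000, 7000), prefix = "sp") {
  stopifnot(n >= 1)
  freqs <- if (n == 1L) mean(freq_range) else
    seq(freq_range[1], freq_range[2], length.out = n)
  lapply(seq_len(n), function(k) {
    species_profile(sprintf("%s%02d", prefix, k), freqs[k],
                    chirp_rate = c(0, 400, -400, 800)[(k - 1L) %% 4L + 1L],
                    bandwidth = 100 + 50 * ((k - 1L) %% 3L),
                    call_duration = 0.3 + 0.1 * ((k - 1L) %% 4L))
  })
}

#' Synthesise one call of a species
#'
#' A linear-chirp sine centred on the profile's base frequency with a Hann
#' amplitude envelope, so the dominant spectral energy sits in the profile's
#' band.
#'
#' @param profile A `species_profile`.
#' @param sample_rate Sample rate in Hz.
#' @param amplitude Peak amplitude.
#' @return An `audio_clip` of length `call_duration`.
#' @export
synthesize_call <- function(profile, sample_rate = 16000L, amplitude = 0.25) {
  n <- round(profile$call_duration * sample_rate)
  t <- (seq_len(n) - 1L) / sample_rate
  f0 <- profile$base_frequency - profile$chirp_rate * profile$call_duration / 2
  phase <- 2 * pi * (f0 * t + 0.5 * profile$chirp_rate * t^2)
  env <- hann_window(n)
  audio_clip(amplitude * env * sin(phase), sample_rate)
}

#' Scene configuration for the synthetic corpus
#'
#' The stated world the generator emulates: focal recordings with one loud
#' target species and fainter background species, a long-tailed (Zipf-like)
#' recordings-per-species distribution covering all three data regimes,
#' incomplete secondary labels, polyphonic soundscapes, and noise-only clips.
#'
#' @param n_species Number of species (default 12).
#' @param zipf_exponent Exponent s of the count law
#'   `count_k = round(max_count * k^-s)` (default 1.2).
#' @param max_count Recordings of the most frequent species (default 250;
#'   with the defaults the corpus spans the low/medium/high regimes).
#' @param min_count Floor on recordings per species (default 5).
#' @param recording_seconds Focal recording length in seconds (default 3).
#' @param sample_rate Corpus sample rate (default 16000).
#' @param foreground_to_background_gain_db Salience gap between the primary
#'   and background species in focal recordings (default 15 dB).
#' @param secondary_label_completeness Probability that a background species
#'   present in a focal recording appears in the annotation (default 0.5).
#' @param n_secondary_range Integer range of background species per focal
#'   recording (default 0-2).
#' @param polyphony_probs Distribution over 1..6 concurrent species in
#'   soundscapes (default decaying, mirroring dawn-chorus polyphony).
#' @param noise_floor RMS-scale of the white-noise floor (default 0.01).
#' @param noise_fraction Noise-only clips as a fraction of the focal corpus
#'   (default 0.1).
#' @param test_fraction Held-out fraction per species (default 0.25).
#' @param seed Integer seed; recorded in the output manifest.
#' @return A `scene_config`.
#' @export
scene_config <- function(n_species = 12L, zipf_exponent = 1.2, max_count = 250L,
                         min_count = 5L, recording_seconds = 3,
                         sample_rate = 16000L,
                         foreground_to_background_gain_db = 15,
                         secondary_label_completeness = 0.5,
                         n_secondary_range = c(0L, 2L),
                         polyphony_probs = c(0.3, 0.25, 0.2, 0.12, 0.08, 0.05),
                         noise_floor = 0.01, noise_fraction = 0.1,
                         test_fraction = 0.25, seed = 1L) {
  stopifnot(n_species >= 1, zipf_exponent > 0, max_count >= min_count,
            secondary_label_completeness >= 0, secondary_label_completeness <= 1,
            abs(sum(polyphony_probs) - 1) < 1e-8, test_fraction >= 0,
            test_fraction < 1)
  structure(list(
    n_species = as.integer(n_species), zipf_exponent = zipf_exponent,
    max_count = as.integer(max_count), min_count = as.integer(min_count),
    recording_seconds = recording_seconds, sample_rate = as.integer(sample_rate),
    foreground_to_background_gain_db = foreground_to_background_gain_db,
    secondary_label_completeness = secondary_label_completeness,
    n_secondary_range = as.integer(n_secondary_range),
    polyphony_probs = polyphony_probs, noise_floor = noise_floor,
    noise_fraction = noise_fraction, test_fraction = test_fraction,
    seed = as.integer(seed)), class = "scene_config")
}

#' Deterministic recordings-per-species counts under the scene's Zipf law
#' @param scene A `scene_config`.
#' @return Integer vector of length `n_species` (rank-ordered).
#' @export
zipf_counts <- function(scene) {
  k <- seq_len(scene$n_species)
  pmax(scene$min_count, as.integer(round(scene$max_count * k^(-scene$zipf_exponent))))
}

# place a call at a uniform-random onset inside a buffer of n samples
.place_call <- function(buffer, call, sr) {
  n <- length(buffer)
  m <- length(call$samples)
  if (m >= n) return(buffer + call$samples[seq_len(n)])
  start <- sample.int(n - m + 1L, 1L)
  buffer[start:(start + m - 1L)] <- buffer[start:(start + m - 1L)] + call$samples
  buffer
}

#' Generate a noise-only clip ("no birds present")
#' @param scene A `scene_config`.
#' @param seconds Clip length (defaults to the scene's recording length).
#' @return An `audio_clip` of band-broad noise.
#' @export
generate_noise_clip <- function(scene, seconds = scene$recording_seconds) {
  n <- round(seconds * scene$sample_rate)
  # white noise with slow amplitude modulation, loosely wind/rain-like
  am <- 1 + 0.5 * sin(2 * pi * stats::runif(1, 0.2, 1) * (seq_len(n) - 1L) / scene$sample_rate)
  audio_clip(stats::rnorm(n, sd = 10 * scene$noise_floor) * am, scene$sample_rate)
}

#' Generate one focal recording with a weak annotation
#'
#' The primary species calls at full gain; each background species is
#' attenuated by the scene's foreground/background gap and enters the
#' annotation only with probability `secondary_label_completeness`
#' (modelling incomplete secondary labels). A noise floor is always present.
#'
#' @param scene A `scene_config`.
#' @param profiles Profile list for the full vocabulary.
#' @param primary Index (into `profiles`) of the primary species.
#' @param secondaries Integer indices of background species (may be empty).
#' @param recording_id Identifier for the annotation.
#' @return List with `clip` (`audio_clip`), `annotation`
#'   (`recording_annotation`, possibly missing some secondaries) and
#'   `present` (character vector of all species truly present).
#' @export
generate_focal_recording <- function(scene, profiles, primary,
                                     secondaries = integer(),
                                     recording_id = "rec") {
  sr <- scene$sample_rate
  n <- round(scene$recording_seconds * sr)
  buf <- stats::rnorm(n, sd = scene$noise_floor)
  n_calls <- sample(1:2, 1L)
  for (i in seq_len(n_calls))
    buf <- .place_call(buf, synthesize_call(profiles[[primary]], sr, 0.25), sr)
  bg_amp <- 0.25 * 10^(-scene$foreground_to_background_gain_db / 20)
  for (s in secondaries)
    buf <- .place_call(buf, synthesize_call(profiles[[s]], sr, bg_amp), sr)
  labelled <- secondaries[stats::runif(length(secondaries)) <
                            scene$secondary_label_completeness]
  ids <- vapply(profiles, `[[`, "", "species_id")
  ann <- recording_annotation(recording_id, ids[primary], ids[labelled],
                              source = "focal")
  list(clip = audio_clip(buf, sr), annotation = ann,
       present = ids[c(primary, secondaries)])
}

#' Generate one polyphonic soundscape clip
#'
#' All vocalising species call at comparable gains (no focal salience gap)
#' and all are annotated; the first drawn species is recorded as primary.
#'
#' @param scene A `scene_config`.
#' @param profiles Profile list.
#' @param recording_id Identifier.
#' @param seconds Clip length (defaults to the scene's recording length).
#' @return List with `clip`, `annotation`, `present` and `polyphony`.
#' @export
generate_soundscape <- function(scene, profiles, recording_id = "scape",
                                seconds = scene$recording_seconds) {
  sr <- scene$sample_rate
  n <- round(seconds * sr)
  k <- sample.int(length(scene$polyphony_probs), 1L, prob = scene$polyphony_probs)
  k <- min(k, length(profiles))
  who <- sample.int(length(profiles), k)
  buf <- stats::rnorm(n, sd = scene$noise_floor)
  for (s in who) {
    amp <- 0.25 * 10^(stats::runif(1, -6, 0) / 20)  # mild level variation
    for (i in seq_len(sample(1:2, 1L)))
      buf <- .place_call(buf, synthesize_call(profiles[[s]], sr, amp), sr)
  }
  ids <- vapply(profiles, `[[`, "", "species_id")
  ann <- recording_annotation(recording_id, ids[who[1L]],
                              if (k > 1L) ids[who[-1L]] else character(),
                              source = "soundscape")
  list(clip = audio_clip(buf, sr), annotation = ann, present = ids[who],
       polyphony = k)
}

#' Generate a full synthetic corpus
#'
#' Produces focal recordings per species following the scene's Zipf law,
#' noise-only clips labelled with the noise class, a stratified train/test
#' split, a per-species count table, and a manifest with the full scene
#' configuration and seed. Reproducible: the same scene (including seed)
#' yields an identical corpus. Test-split recordings are annotated with
#' complete secondary labels so held-out metrics are measured against full
#' truth; the configured incompleteness applies to the train split.
#'
#' @param scene A `scene_config`.
#' @param profiles Optional profile list (defaults to
#'   `make_species_profiles(scene$n_species)`).
#' @return A `synthetic_corpus`: list with `clips` (named list of
#'   `audio_clip`), `annotations` (named list of `recording_annotation`),
#'   `present` (named list, full truth), `split` (named character),
#'   `counts` (data.frame species/count/regime), `vocab`, `profiles`,
#'   `manifest`.
#' @export
generate_dataset <- function(scene, profiles = NULL) {
  stopifnot(inherits(scene, "scene_config"))
  if (is.null(profiles)) profiles <- make_species_profiles(scene$n_species)
  if (length(profiles) < scene$n_species)
    stop("more species requested than distinct profiles available")
  set.seed(scene$seed)
  ids <- vapply(profiles, `[[`, "", "species_id")
  vocab <- class_vocabulary(ids)
  counts <- zipf_counts(scene)
  clips <- list(); anns <- list(); present <- list(); split <- character()
  for (k in seq_len(scene$n_species)) {
    n_test <- if (counts[k] >= 4L) max(1L, round(scene$test_fraction * counts[k])) else 0L
    for (i in seq_len(counts[k])) {
      rid <- sprintf("%s_r%03d", ids[k], i)
      is_test <- i > counts[k] - n_test
      sec_choices <- scene$n_secondary_range[1]:scene$n_secondary_range[2]
      n_sec <- sec_choices[sample.int(length(sec_choices), 1L)]
      others <- setdiff(seq_len(scene$n_species), k)
      sec <- if (n_sec > 0L && length(others))
        others[sample.int(length(others), min(n_sec, length(others)))]
      else integer()
      sc <- scene
      if (is_test) sc$secondary_label_completeness <- 1
      rec <- generate_focal_recording(sc, profiles, k, sec, rid)
      clips[[rid]] <- rec$clip; anns[[rid]] <- rec$annotation
      present[[rid]] <- rec$present
      split[rid] <- if (is_test) "test" else "train"
    }
  }
  n_noise <- max(2L, round(scene$noise_fraction * sum(counts)))
  for (i in seq_len(n_noise)) {
    rid <- sprintf("noise_r%03d", i)
    clips[[rid]] <- generate_noise_clip(scene)
    anns[[rid]] <- recording_annotation(rid, vocab$noise_class, source = "noise")
    present[[rid]] <- character()
    split[rid] <- if (i %% 4L == 0L) "test" else "train"
  }
  count_df <- data.frame(species = ids, count = counts,
                         regime = data_regime(counts), stringsAsFactors = FALSE)
  manifest <- list(scene = unclass(scene), n_recordings = length(clips),
                   n_noise = n_noise, species = ids,
                   package_version = "0.1.0")
  structure(list(clips = clips, annotations = anns, present = present,
                 split = split, counts = count_df, vocab = vocab,
                 profiles = profiles, manifest = manifest),
            class = "synthetic_corpus")
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cat(sprintf("<synthetic_corpus: %d recordings (%d train / %d test), %d species + noise>\n",
              length(x$clips), sum(x$split == "train"), sum(x$split == "test"),
              length(x$vocab$species_ids)))
  invisible(x)
}

#' Write a synthetic corpus to disk
#'
#' WAV files, annotation CSV (weak-label dialect), species-count CSV,
#' vocabulary JSON and a manifest JSON with the full scene config and seed.
#'
#' @param corpus A `synthetic_corpus`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(file.path(dir, "audio"), recursive = TRUE, showWarnings = FALSE)
  for (rid in names(corpus$clips))
    write_wav(corpus$clips[[rid]], file.path(dir, "audio", paste0(rid, ".wav")))
  write_annotations(corpus$annotations, file.path(dir, "annotations.csv"),
                    split = corpus$split)
  utils::write.csv(corpus$counts, file.path(dir, "species_counts.csv"),
                   row.names = FALSE)
  write_vocabulary(corpus$vocab, file.path(dir, "vocabulary.json"))
  jsonlite::write_json(corpus$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
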