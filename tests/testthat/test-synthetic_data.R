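test_that("synthesize_call concentrates energy at the profile frequency", {
  prof <- species_profile("sp01", 3000, chirp_rate = 0, call_duration = 0.5)
  call <- synthesize_call(prof, 16000, 0.3)
  expect_equal(clip_duration(call), 0.5)
  # FFT peak within one bin of the base frequency
  pk <- oracle_peak_freq(call$samples, 16000)
  expect_lt(abs(pk - 3000), 16000 / length(call$samples) + 1e-9)
  # zero amplitude -> silence
  expect_true(all(synthesize_call(prof, 16000, 0)$samples == 0))
})

test_that("distinct profiles are separable by a nearest-band oracle", {
  profs <- make_species_profiles(5)
  sr <- 16000
  set.seed(77)
  correct <- 0; total <- 0
  for (rep_i in 1:40) for (k in seq_along(profs)) {
    call <- synthesize_call(profs[[k]], sr, 0.25)
    # oracle: pick the profile whose base frequency is nearest the FFT peak
    pk <- oracle_peak_freq(call$samples + rnorm(length(call$samples), sd = 0.005), sr)
    guess <- which.min(abs(vapply(profs, `[[`, 0, "base_frequency") - pk))
    correct <- correct + (guess == k); total <- total + 1
  }
  expect_gt(correct / total, 0.95)
})

test_that("focal recordings honour gain gap and label completeness", {
  profs <- make_species_profiles(4)
  scene <- scene_config(n_species = 4, seed = 3)

  # completeness 1: all present species annotated
  sc1 <- scene; sc1$secondary_label_completeness <- 1
  set.seed(1)
  rec1 <- generate_focal_recording(sc1, profs, 1, c(2, 3), "r1")
  expect_identical(sort(rec1$annotation$secondary_species),
                   sort(c("sp02", "sp03")))
  expect_identical(sort(rec1$present), sort(c("sp01", "sp02", "sp03")))

  # completeness 0: primary only
  sc0 <- scene; sc0$secondary_label_completeness <- 0
  set.seed(1)
  rec0 <- generate_focal_recording(sc0, profs, 1, c(2, 3), "r0")
  expect_identical(rec0$annotation$secondary_species, character(0))
  expect_identical(rec0$annotation$primary_species, "sp01")

  # the synthesized calls themselves are placed with the configured gap:
  # compare RMS of a primary-amplitude call vs a background-amplitude call
  bg_amp <- 0.25 * 10^(-scene$foreground_to_background_gain_db / 20)
  fg_call <- synthesize_call(profs[[1]], scene$sample_rate, 0.25)
  bg_call <- synthesize_call(profs[[1]], scene$sample_rate, bg_amp)
  gap_db <- 20 * log10(clip_rms(fg_call) / clip_rms(bg_call))
  expect_lt(abs(gap_db - scene$foreground_to_background_gain_db), 1)
})

test_that("generate_dataset is reproducible and follows its stated world", {
  scene <- scene_config(n_species = 5, max_count = 12, min_count = 5,
                        noise_fraction = 0.2, seed = 9)
  c1 <- generate_dataset(scene)
  c2 <- generate_dataset(scene)
  # byte-identical annotation CSVs on rerun
  f1 <- tempfile(); f2 <- tempfile()
  write_annotations(c1$annotations, f1, c1$split)
  write_annotations(c2$annotations, f2, c2$split)
  expect_identical(readLines(f1), readLines(f2))
  # waveforms identical too
  expect_identical(c1$clips[[1]]$samples, c2$clips[[1]]$samples)

  # counts follow the configured Zipf law exactly (deterministic law)
  k <- 1:5
  expected <- pmax(5L, as.integer(round(12 * k^(-1.2))))
  expect_identical(c1$counts$count, expected)
  expect_identical(unname(table(c1$split)["test"] > 0), TRUE)

  # noise clips labelled with the noise class
  noise_ids <- names(c1$annotations)[startsWith(names(c1$annotations), "noise_")]
  expect_gt(length(noise_ids), 0)
  for (rid in noise_ids)
    expect_identical(c1$annotations[[rid]]$primary_species, c1$vocab$noise_class)

  # infeasible configuration errors
  expect_error(generate_dataset(scene, profiles = make_species_profiles(3)),
               "more species")
})

test_that("default scene covers all three data regimes", {
  counts <- zipf_counts(scene_config())
  expect_setequal(unique(data_regime(counts)), c("low", "medium", "high"))
})

test_that("soundscape polyphony follows the configured distribution", {
  scene <- scene_config(n_species = 8, seed = 21)
  profs <- make_species_profiles(8)
  set.seed(21)
  n <- 400
  poly <- vapply(seq_len(n), function(i)
    generate_soundscape(scene, profs, paste0("s", i))$polyphony, 0L)
  # binomial 99.9% bounds per polyphony level
  for (k in 1:6) {
    p <- scene$polyphony_probs[k]
    obs <- mean(poly == k)
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(obs - p), 3.3 * se + 1e-9)
  }
  # all vocalising species are annotated in soundscapes
  set.seed(5)
  ss <- generate_soundscape(scene, profs, "s_chk")
  expect_setequal(c(ss$annotation$primary_species, ss$annotation$secondary_species),
                  ss$present)
})

test_that("test-split annotations carry complete secondary labels", {
  scene <- scene_config(n_species = 6, max_count = 10, min_count = 8,
                        secondary_label_completeness = 0, n_secondary_range = c(1L, 2L),
                        seed = 15)
  corpus <- generate_dataset(scene)
  test_ids <- names(corpus$split)[corpus$split == "test" &
                                    !startsWith(names(corpus$split), "noise_")]
  # with completeness 0 on train, secondaries only ever appear in test rows
  train_ids <- names(corpus$split)[corpus$split == "train" &
                                     !startsWith(names(corpus$split), "noise_")]
  n_sec_train <- vapply(corpus$annotations[train_ids],
                        function(a) length(a$secondary_species), 0L)
  expect_true(all(n_sec_train == 0))
  n_sec_test <- vapply(corpus$annotations[test_ids],
                       function(a) length(a$secondary_species), 0L)
  n_present_test <- vapply(corpus$present[test_ids], length, 0L)
  expect_identical(n_sec_test, n_present_test - 1L)
})

test_that("write_corpus emits the full file set", {
  corpus <- tiny_corpus()
  d <- tempfile()
  write_corpus(corpus, d)
  expect_true(file.exists(file.path(d, "annotations.csv")))
  expect_true(file.exists(file.path(d, "species_counts.csv")))
  expect_true(file.exists(file.path(d, "vocabulary.json")))
  expect_true(file.exists(file.path(d, "manifest.json")))
  wavs <- list.files(file.path(d, "audio"), pattern = "\\.wav$")
  expect_length(wavs, length(corpus$clips))
  # WAV round-trip is faithful to 16-bit quantisation
  rid <- names(corpus$clips)[1]
  back <- read_wav(file.path(d, "audio", paste0(rid, ".wav")))
  expect_identical(back$sample_rate, corpus$clips[[rid]]$sample_rate)
  expect_lt(max(abs(back$samples - pmin(pmax(corpus$clips[[rid]]$samples, -1), 1))),
            1 / 32768 + 1e-9)
  # manifest records the seed
  mf <- jsonlite::read_json(file.path(d, "manifest.json"))
  expect_identical(mf$scene$seed, 202L)
  unlink(d, recursive = TRUE)
})
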