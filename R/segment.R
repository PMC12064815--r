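#' Energy-based segment selection
#'
#' A band-ratio heuristic for discarding 3-second chunks likely devoid of
#' bird sound: each chunk's spectral energy inside the bird band (default
#' 500-10,000 Hz) is compared with the recording's mean chunk band-energy;
#' chunks with `ratio >= ratio_threshold` are kept. (The mean, not the
#' median, is the reference: with a median reference the median chunk always
#' scores exactly 1, so silence could never be discarded from
#' mostly-silent recordings.) The top-scoring chunk of
#' every recording is always kept so no recording becomes empty. Decisions
#' are invariant to global gain (ratios cancel).
#'
#' @param chunks List of `audio_clip` chunks from one recording.
#' @param band_hz Frequency band in Hz (default `c(500, 10000)`, clipped to
#'   Nyquist).
#' @param ratio_threshold Keep threshold on the energy ratio (default 1).
#' @return data.frame with `chunk_index`, `score` (energy ratio) and `keep`.
#' @export
energy_detector <- function(chunks, band_hz = c(500, 10000), ratio_threshold = 1) {
  if (length(chunks) == 0L) stop("no chunks supplied")
  energies <- vapply(chunks, function(ch) {
    n <- length(ch$samples)
    spec <- stats::fft(ch$samples)
    freqs <- (seq_len(n %/% 2L + 1L) - 1L) * ch$sample_rate / n
    p <- Mod(spec[seq_len(n %/% 2L + 1L)])^2
    hi <- min(band_hz[2], ch$sample_rate / 2)
    sum(p[freqs >= band_hz[1] & freqs <= hi])
  }, 0)
  ref <- mean(energies)
  score <- if (ref > 0) energies / ref else rep(1, length(energies))
  keep <- score >= ratio_threshold
  keep[which.max(score)] <- TRUE  # top-1 guarantee
  data.frame(chunk_index = seq_along(chunks), score = score, keep = keep)
}

#' Threshold filter on external detector scores
#'
#' The machine-learning segment-selection route: any detector satisfying the
#' contract (a per-chunk bird-presence score in `[0, 1]`) plugs in; chunks
#' whose score strictly exceeds the threshold (default 0.3) are kept.
#'
#' @param scores Numeric per-chunk scores in `[0, 1]`.
#' @param threshold Keep threshold (default 0.3); strict `>` comparison,
#'   configurable via `inclusive`.
#' @param inclusive If `TRUE`, use `>=` instead of `>`.
#' @return data.frame with `chunk_index`, `score`, `keep`.
#' @export
score_threshold_filter <- function(scores, threshold = 0.3, inclusive = FALSE) {
  if (any(scores < 0 | scores > 1)) stop("detector scores must be in [0, 1]")
  keep <- if (inclusive) scores >= threshold else scores > threshold
  data.frame(chunk_index = seq_along(scores), score = scores, keep = keep)
}

#' Segment-select every recording of a corpus
#'
#' Runs [chunk_recording()] plus [energy_detector()] over a set of
#' recordings; retained chunks inherit the recording's weak annotation
#' unchanged (label-preserving filtering).
#'
#' @param clips Named list of `audio_clip` recordings.
#' @param chunk_seconds Chunk length (default 3).
#' @param band_hz,ratio_threshold Passed to [energy_detector()].
#' @return data.frame with `recording_id`, `chunk_index`, `score`, `keep`.
#' @export
select_segments <- function(clips, chunk_seconds = 3, band_hz = c(500, 10000),
                            ratio_threshold = 1) {
  out <- lapply(names(clips), function(rid) {
    dec <- energy_detector(chunk_recording(clips[[rid]], chunk_seconds),
                           band_hz, ratio_threshold)
    cbind(recording_id = rid, dec, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
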