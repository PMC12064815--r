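# Independent brute-force oracles. These deliberately avoid the package's own
# code paths: AP by rank enumeration, AUROC by exhaustive pair counting, F1 by
# confusion-matrix enumeration, KL by the two-class closed form.

oracle_average_precision <- function(scores, truths) {
  # enumerate precision at each positive, processing tied scores as a block
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- truths[ord]
  P <- sum(y)
  if (P == 0) return(NA_real_)
  ap <- 0; i <- 1; tp <- 0; seen <- 0
  while (i <= length(s)) {
    j <- i
    while (j < length(s) && s[j + 1] == s[i]) j <- j + 1
    tp_block <- sum(y[i:j])
    tp <- tp + tp_block
    seen <- seen + (j - i + 1)
    if (tp_block > 0) ap <- ap + tp_block * tp / seen
    i <- j + 1
  }
  ap / P
}

oracle_auroc <- function(scores, truths) {
  pos <- scores[truths == 1]; neg <- scores[truths == 0]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  wins <- 0
  for (p in pos) wins <- wins + sum(p > neg) + 0.5 * sum(p == neg)
  wins / (length(pos) * length(neg))
}

oracle_macro_f1 <- function(pred_idx, truth_idx) {
  classes <- sort(unique(c(pred_idx, truth_idx)))
  f1s <- c()
  for (k in classes) {
    tp <- sum(pred_idx == k & truth_idx == k)
    fp <- sum(pred_idx == k & truth_idx != k)
    fn <- sum(pred_idx != k & truth_idx == k)
    if (2 * tp + fp + fn > 0) f1s <- c(f1s, 2 * tp / (2 * tp + fp + fn))
  }
  mean(f1s)
}

oracle_micro_pr <- function(pred_mat, truth_mat) {
  tp <- 0; fp <- 0; fn <- 0
  for (i in seq_len(nrow(pred_mat))) for (k in seq_len(ncol(pred_mat))) {
    if (pred_mat[i, k] && truth_mat[i, k] == 1) tp <- tp + 1
    if (pred_mat[i, k] && truth_mat[i, k] == 0) fp <- fp + 1
    if (!pred_mat[i, k] && truth_mat[i, k] == 1) fn <- fn + 1
  }
  c(precision = if (tp + fp > 0) tp / (tp + fp) else 0,
    recall = if (tp + fn > 0) tp / (tp + fn) else 0)
}

# two-class KL(softmax(t) || softmax(s)) in nats, closed form
oracle_kl2 <- function(teacher_logits, student_logits) {
  p <- 1 / (1 + exp(-(teacher_logits[1] - teacher_logits[2])))
  q <- 1 / (1 + exp(-(student_logits[1] - student_logits[2])))
  p * log(p / q) + (1 - p) * log((1 - p) / (1 - q))
}

# band-limited energy of a waveform via direct FFT binning
oracle_band_energy <- function(samples, sample_rate, lo, hi) {
  n <- length(samples)
  spec <- Mod(stats::fft(samples))[1:(n %/% 2 + 1)]^2
  freqs <- (0:(n %/% 2)) * sample_rate / n
  sum(spec[freqs >= lo & freqs <= min(hi, sample_rate / 2)])
}

# dominant frequency of a waveform by FFT peak
oracle_peak_freq <- function(samples, sample_rate) {
  n <- length(samples)
  spec <- Mod(stats::fft(samples))[1:(n %/% 2 + 1)]
  (which.max(spec) - 1) * sample_rate / n
}

make_tone <- function(freq, seconds = 3, sample_rate = 16000, amp = 0.5) {
  audio_clip(amp * sin(2 * pi * freq * (0:(round(seconds * sample_rate) - 1)) / sample_rate),
             sample_rate)
}
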