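#' Max-pool chunk scores into a recording-level prediction
#'
#' The recording's score for each class is the highest chunk score for that
#' class — the strongest evidence anywhere in the recording, matching the
#' weak (recording-level) ground truth.
#'
#' @param chunk_scores Matrix `chunks x classes` of post-activation scores.
#' @return Numeric vector of per-class maxima.
#' @export
max_pool_recording <- function(chunk_scores) {
  if (is.null(dim(chunk_scores))) chunk_scores <- matrix(chunk_scores, nrow = 1)
  if (nrow(chunk_scores) == 0L) stop("no chunks to pool")
  apply(chunk_scores, 2, max)
}

#' Chunk-wise inference with recording-level max pooling
#'
#' Splits the recording into 3 s chunks, scores each chunk with the model's
#' activation, and max-pools over chunks.
#'
#' @param model A `bird_classifier`.
#' @param recording An `audio_clip` (at the model's front-end sample rate).
#' @param chunk_seconds Chunk length (default 3).
#' @return Per-class recording scores in `[0, 1]`.
#' @export
predict_recording <- function(model, recording, chunk_seconds = 3) {
  chunks <- chunk_recording(recording, chunk_seconds)
  scores <- t(vapply(chunks, function(ch) predict_scores(model, ch),
                     numeric(n_classes(model$vocab))))
  max_pool_recording(scores)
}

#' Score every recording of a corpus split
#'
#' @param model A `bird_classifier`.
#' @param corpus A `synthetic_corpus` (or any list with `clips`, `split`).
#' @param split Which split to score (default `"test"`).
#' @return Matrix `recordings x classes` of pooled scores, with recording
#'   ids as row names.
#' @export
predict_corpus <- function(model, corpus, split = "test") {
  ids <- names(corpus$clips)[corpus$split == split]
  out <- t(vapply(ids, function(rid) predict_recording(model, corpus$clips[[rid]]),
                  numeric(n_classes(model$vocab))))
  rownames(out) <- ids
  colnames(out) <- model$vocab$classes
  out
}

#' Single-label F1 from pooled scores
#'
#' The predicted label of a recording is the argmax of its pooled scores
#' (ties broken towards the lowest class index). Macro F1 averages per-class
#' F1 over classes present in truth or predictions; micro F1 over
#' single-label data equals accuracy.
#'
#' @param scores Matrix `recordings x classes`.
#' @param truth_idx Integer vector of true class indices.
#' @param averaging `"macro"` or `"micro"`.
#' @return F1 in `[0, 1]`.
#' @export
single_label_f1 <- function(scores, truth_idx, averaging = c("macro", "micro")) {
  averaging <- match.arg(averaging)
  pred_idx <- apply(scores, 1, which.max)  # which.max: lowest index on ties
  if (averaging == "micro") return(mean(pred_idx == truth_idx))
  classes <- sort(unique(c(truth_idx, pred_idx)))
  f1s <- vapply(classes, function(k) {
    tp <- sum(pred_idx == k & truth_idx == k)
    fp <- sum(pred_idx == k & truth_idx != k)
    fn <- sum(pred_idx != k & truth_idx == k)
    if (2 * tp + fp + fn == 0) return(NA_real_)
    2 * tp / (2 * tp + fp + fn)
  }, 0)
  mean(f1s, na.rm = TRUE)
}

#' Average precision of one class
#'
#' Area under the precision-recall step curve computed from the ranking of
#' scores; tied scores are handled as one group (precision evaluated at the
#' end of the group, credited to the positives inside it).
#'
#' @param scores Numeric scores for one class over recordings.
#' @param truths Binary (0/1) truth vector.
#' @return AP in `[0, 1]`; `NA` if the class has no positives.
#' @export
average_precision <- function(scores, truths) {
  truths <- as.numeric(truths)
  P <- sum(truths)
  if (P == 0) return(NA_real_)
  groups <- sort(unique(scores), decreasing = TRUE)
  tp <- 0; n_seen <- 0; ap <- 0
  for (g in groups) {
    in_g <- scores == g
    tp_g <- sum(truths[in_g])
    tp <- tp + tp_g
    n_seen <- n_seen + sum(in_g)
    if (tp_g > 0) ap <- ap + tp_g * tp / n_seen
  }
  ap / P
}

#' Area under the ROC curve via the rank statistic
#'
#' Probability that a random positive outranks a random negative, ties
#' counted one half: `(sum of positive ranks - P(P+1)/2) / (P * N)`.
#'
#' @param scores Numeric scores.
#' @param truths Binary truth vector.
#' @return AUROC in `[0, 1]`; `NA` for degenerate classes.
#' @export
auroc <- function(scores, truths) {
  truths <- as.numeric(truths)
  P <- sum(truths); N <- sum(1 - truths)
  if (P == 0 || N == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[truths == 1]) - P * (P + 1) / 2) / (P * N)
}

#' Mean average precision and macro AUROC over classes
#'
#' Classes with no positives are excluded from mAP; classes without both a
#' positive and a negative are excluded from macro AUROC. Exclusions are
#' reported.
#'
#' @param scores Matrix `recordings x classes`.
#' @param truths Binary matrix of the same shape.
#' @return List with `mAP`, `macro_auroc`, `per_class_ap`, `excluded`.
#' @export
multilabel_metrics <- function(scores, truths) {
  K <- ncol(scores)
  ap <- vapply(seq_len(K), function(k) average_precision(scores[, k], truths[, k]), 0)
  au <- vapply(seq_len(K), function(k) auroc(scores[, k], truths[, k]), 0)
  names(ap) <- colnames(scores); names(au) <- colnames(scores)
  list(mAP = mean(ap, na.rm = TRUE), macro_auroc = mean(au, na.rm = TRUE),
       per_class_ap = ap, per_class_auroc = au,
       excluded = colnames(scores)[is.na(ap)])
}

#' Micro-averaged precision and recall at a decision threshold
#'
#' A class is predicted present in a recording iff its pooled score is
#' `>= threshold` (inclusive). Precision with zero predictions is reported
#' as 0 with a warning.
#'
#' @param scores Matrix `recordings x classes`.
#' @param truths Binary matrix of the same shape.
#' @param threshold Decision threshold (default 0.2).
#' @return List with `precision`, `recall`, `tp`, `fp`, `fn`.
#' @export
thresholded_pr <- function(scores, truths, threshold = 0.2) {
  stopifnot(threshold >= 0)
  pred <- scores >= threshold
  tp <- sum(pred & truths == 1)
  fp <- sum(pred & truths == 0)
  fn <- sum(!pred & truths == 1)
  precision <- if (tp + fp == 0) {
    warning("no predictions above threshold; precision reported as 0")
    0
  } else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  list(precision = precision, recall = recall, tp = tp, fp = fp, fn = fn)
}

#' Foreground vs background recall per species
#'
#' Restricted to recordings with exactly two labelled species, the contrast
#' measures how often a target species is recovered when it is the loud
#' primary ("foreground instances") vs the fainter secondary ("background
#' instances"). Species with no qualifying instances on a side are omitted.
#'
#' @param scores Matrix `recordings x classes` (rownames = recording ids).
#' @param annotations Named list of `recording_annotation`.
#' @param vocab A `class_vocabulary`.
#' @param target_species Species codes to report (default: all species).
#' @param threshold Detection threshold (default 0.2).
#' @return data.frame with `species`, `foreground_recall`,
#'   `background_recall`, `n_foreground`, `n_background`.
#' @export
foreground_background_recall <- function(scores, annotations, vocab,
                                         target_species = vocab$species_ids,
                                         threshold = 0.2) {
  anns <- annotations[rownames(scores)]
  two_labelled <- vapply(anns, function(a)
    length(a$secondary_species) == 1L && a$primary_species != vocab$noise_class,
    TRUE)
  rows <- lapply(target_species, function(sp) {
    k <- match(sp, vocab$classes)
    fg <- which(two_labelled & vapply(anns, function(a) a$primary_species == sp, TRUE))
    bg <- which(two_labelled & vapply(anns, function(a) sp %in% a$secondary_species, TRUE))
    if (length(fg) == 0L && length(bg) == 0L) return(NULL)
    data.frame(
      species = sp,
      foreground_recall = if (length(fg)) mean(scores[fg, k] >= threshold) else NA_real_,
      background_recall = if (length(bg)) mean(scores[bg, k] >= threshold) else NA_real_,
      n_foreground = length(fg), n_background = length(bg),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-class AP grouped by data-availability regime
#'
#' Groups per-class average precision by [data_regime()] of the training
#' count and summarises each group (n, median, quartiles). Empty groups are
#' reported with `n = 0`, not as errors.
#'
#' @param per_class_ap Named numeric vector of AP values (species codes).
#' @param per_class_counts Named counts of training recordings per species.
#' @return data.frame with `regime`, `n`, `median_ap`, `q1_ap`, `q3_ap`.
#' @export
stratified_ap <- function(per_class_ap, per_class_counts) {
  sp <- intersect(names(per_class_ap), names(per_class_counts))
  regime <- data_regime(per_class_counts[sp])
  out <- lapply(c("low", "medium", "high"), function(rg) {
    aps <- per_class_ap[sp][regime == rg]
    aps <- aps[!is.na(aps)]
    if (length(aps) == 0L)
      return(data.frame(regime = rg, n = 0L, median_ap = NA_real_,
                        q1_ap = NA_real_, q3_ap = NA_real_))
    q <- stats::quantile(aps, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(regime = rg, n = length(aps), median_ap = q[2],
               q1_ap = q[1], q3_ap = q[3])
  })
  do.call(rbind, out)
}

#' Full evaluation of a model on a corpus split
#'
#' Chunk-wise inference, max pooling, and the package's metric suite:
#' single-label F1 (macro and micro) against primary labels, mAP and macro
#' AUROC against full multi-label truth, micro precision/recall at the
#' threshold, and regime-stratified AP.
#'
#' @param model A `bird_classifier`.
#' @param corpus A `synthetic_corpus`.
#' @param split Split to evaluate (default `"test"`).
#' @param threshold Decision threshold for precision/recall (default 0.2).
#' @param use_secondary Evaluate against secondary labels too?
#' @return A `metrics_report` list.
#' @export
evaluate_model <- function(model, corpus, split = "test", threshold = 0.2,
                           use_secondary = TRUE) {
  scores <- predict_corpus(model, corpus, split)
  ids <- rownames(scores)
  vocab <- model$vocab
  truth <- t(vapply(ids, function(rid)
    build_target(corpus$annotations[[rid]], vocab,
                 use_secondary = use_secondary, mode = "multi"),
    numeric(n_classes(vocab))))
  truth_idx <- vapply(ids, function(rid)
    match(corpus$annotations[[rid]]$primary_species, vocab$classes), 0L)
  ml <- multilabel_metrics(scores, truth)
  pr <- thresholded_pr(scores, truth, threshold)
  train_counts <- stats::setNames(corpus$counts$count, corpus$counts$species)
  structure(list(
    f1_macro = single_label_f1(scores, truth_idx, "macro"),
    f1_micro = single_label_f1(scores, truth_idx, "micro"),
    mAP = ml$mAP, macro_auroc = ml$macro_auroc,
    per_class_ap = ml$per_class_ap,
    precision = pr$precision, recall = pr$recall, threshold = threshold,
    stratified = stratified_ap(ml$per_class_ap, train_counts),
    n_recordings = length(ids), split = split
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics_report (%s, n=%d): F1 macro %.3f / micro %.3f | mAP %.3f | AUROC %.3f | P %.3f R %.3f @ %.2f>\n",
    x$split, x$n_recordings, x$f1_macro, x$f1_micro, x$mAP, x$macro_auroc,
    x$precision, x$recall, x$threshold))
  invisible(x)
}

#' Write a metrics report as JSON (plus per-class CSV)
#' @param report A `metrics_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_metrics <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  flat <- report[c("f1_macro", "f1_micro", "mAP", "macro_auroc", "precision",
                   "recall", "threshold", "n_recordings", "split")]
  jsonlite::write_json(flat, file.path(dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(data.frame(species = names(report$per_class_ap),
                              ap = as.numeric(report$per_class_ap)),
                   file.path(dir, "per_class_ap.csv"), row.names = FALSE)
  utils::write.csv(report$stratified, file.path(dir, "stratified_ap.csv"),
                   row.names = FALSE)
  invisible(dir)
}
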