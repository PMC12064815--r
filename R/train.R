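#' Training configuration
#'
#' Plumbing hyperparameters: epoch budget, batch size, Adam learning rate,
#' and the seed of the single RNG stream used for shuffling, augmentation
#' draws and MixUp partners. Defaults follow common practice for head-only
#' (1e-3) vs full-network (1e-4) training; pass the rate explicitly to
#' override.
#'
#' @param epochs Number of epochs.
#' @param batch_size Batch size (default 16).
#' @param learning_rate Adam step size; if `NULL`, chosen per strategy
#'   (1e-3 head-only, 1e-4 full).
#' @param optimizer_kind Only `"adam"` is implemented.
#' @param seed Integer RNG seed.
#' @param augmentation An `augmentation_config`, or `NULL` to disable
#'   waveform augmentation.
#' @return A `train_config`.
#' @export
train_config <- function(epochs = 20L, batch_size = 16L, learning_rate = NULL,
                         optimizer_kind = "adam", seed = 1L,
                         augmentation = NULL) {
  stopifnot(epochs >= 1, batch_size >= 1, optimizer_kind == "adam")
  if (!is.null(learning_rate)) stopifnot(learning_rate >= 0)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, optimizer_kind = optimizer_kind,
                 seed = as.integer(seed), augmentation = augmentation),
            class = "train_config")
}

#' Assemble a training dataset from a synthetic corpus
#'
#' Builds (clip, target) pairs for one split, using [build_target()] in the
#' requested mode. Noise-only recordings become noise-class examples.
#'
#' @param corpus A `synthetic_corpus`.
#' @param split `"train"` or `"test"`.
#' @param mode `"single"` or `"multi"` label mode.
#' @param use_secondary Include secondary labels in multi-label targets?
#' @return List with `clips`, `targets`, `ids`, `vocab`, `mode`.
#' @export
corpus_dataset <- function(corpus, split = "train", mode = c("single", "multi"),
                           use_secondary = TRUE) {
  mode <- match.arg(mode)
  ids <- names(corpus$clips)[corpus$split == split]
  targets <- lapply(ids, function(rid)
    build_target(corpus$annotations[[rid]], corpus$vocab,
                 use_secondary = use_secondary, mode = mode))
  list(clips = corpus$clips[ids], targets = targets, ids = ids,
       vocab = corpus$vocab, mode = mode)
}

# Adam state helpers -------------------------------------------------------

.adam_init <- function(params, names) {
  st <- list(t = 0L, m = list(), v = list())
  for (nm in names) {
    st$m[[nm]] <- params[[nm]] * 0
    st$v[[nm]] <- params[[nm]] * 0
  }
  st
}

.adam_step <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  st$t <- st$t + 1L
  for (nm in names(st$m)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g^2
    mhat <- st$m[[nm]] / (1 - beta1^st$t)
    vhat <- st$v[[nm]] / (1 - beta2^st$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = st)
}

#' Train a classifier with one of the three transfer strategies
#'
#' * `"deep_finetune"`: all parameters train (scope `all`).
#' * `"shallow_finetune"`: the backbone is frozen; only the head trains
#'   (scope `head_only`).
#' * `"distill"`: requires a frozen `teacher` with an identical class
#'   vocabulary; minimises `lambda * L_g + (1 - lambda) * L_kd` where the
#'   teacher's logits are produced from the *identical* augmented input as
#'   the student's at every step (consistent teaching; the trainer records a
#'   checksum of each input fed to both networks).
#'
#' Waveform augmentation (MixUp, background noise) is applied on the fly
#' before spectrogram conversion when `train_cfg$augmentation` is set. When
#' augmentation is disabled, model inputs are precomputed once for speed.
#'
#' @param strategy `"deep_finetune"`, `"shallow_finetune"` or `"distill"`.
#' @param student A `bird_classifier` to train.
#' @param dataset A dataset from [corpus_dataset()] (fields `clips`,
#'   `targets`, `vocab`).
#' @param train_cfg A `train_config`.
#' @param teacher Frozen `bird_classifier` (distillation only).
#' @param distill_cfg A `distill_config` (distillation only).
#' @param noise_pool List of noise `audio_clip`s for noise augmentation.
#' @param verbose Print per-epoch losses?
#' @return List with `model` (trained), `log` (data.frame: epoch, loss,
#'   loss_g, loss_kd, backbone_checksum, teacher_checksum) and
#'   `consistent_teaching_ok` (all teacher/student input checksums matched).
#' @export
train <- function(strategy = c("deep_finetune", "shallow_finetune", "distill"),
                  student, dataset, train_cfg = train_config(),
                  teacher = NULL, distill_cfg = NULL,
                  noise_pool = list(), verbose = FALSE) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(student, "bird_classifier"), inherits(train_cfg, "train_config"))
  if (strategy == "distill") {
    if (is.null(teacher)) stop("distillation requires a teacher model")
    if (!identical(teacher$vocab$classes, student$vocab$classes))
      stop("teacher/student class vocabulary mismatch")
    if (is.null(distill_cfg)) distill_cfg <- distill_config()
    teacher <- set_trainable_scope(teacher, "frozen")
  }
  aug <- train_cfg$augmentation
  if (!is.null(aug) && aug$noise_prob > 0 && length(noise_pool) == 0L)
    stop("noise augmentation enabled but no noise pool supplied")
  student <- set_trainable_scope(student, switch(strategy,
    deep_finetune = "all", shallow_finetune = "head_only", distill = "all"))
  lr <- train_cfg$learning_rate
  if (is.null(lr)) lr <- if (strategy == "shallow_finetune") 1e-3 else 1e-4
  gt_kind <- if (student$activation_kind == "softmax")
    "cross_entropy" else "binary_cross_entropy"
  single_label <- student$activation_kind == "softmax"
  n <- length(dataset$clips)
  if (n == 0L) stop("empty dataset")
  set.seed(train_cfg$seed)
  trainable <- trainable_param_names(student)
  adam <- .adam_init(student$params, trainable)
  teacher_ck0 <- if (!is.null(teacher)) param_checksum(teacher, "all") else NA_character_
  # precompute model inputs when augmentation cannot change them
  static_inputs <- NULL
  if (is.null(aug) || (aug$mixup_prob == 0 && aug$noise_prob == 0)) {
    static_inputs <- lapply(dataset$clips, function(cl) model_input(student, cl))
  }
  log_rows <- vector("list", train_cfg$epochs)
  consistent_ok <- TRUE
  for (epoch in seq_len(train_cfg$epochs)) {
    order_idx <- sample.int(n)
    tot <- 0; tot_g <- 0; tot_kd <- 0
    for (start in seq(1L, n, by = train_cfg$batch_size)) {
      batch <- order_idx[start:min(start + train_cfg$batch_size - 1L, n)]
      grads_sum <- NULL
      for (i in batch) {
        if (!is.null(static_inputs)) {
          X <- static_inputs[[i]]
          tgt <- dataset$targets[[i]]
        } else {
          a <- augment_for_training(
            dataset$clips[[i]], dataset$targets[[i]],
            dataset$clips[batch], dataset$targets[batch],
            aug, noise_pool, single_label = single_label)
          X <- model_input(student, a$clip)
          tgt <- a$target
        }
        student_input_ck <- digest::digest(X)
        fw <- model_forward(student, X, keep_cache = TRUE)
        lg <- ground_truth_loss(fw$logits, tgt, gt_kind)
        if (strategy == "distill") {
          # consistent teaching: the teacher consumes the identical augmented
          # input object the student just saw, never a re-augmented one
          teacher_input_ck <- digest::digest(X)
          tlog <- model_forward(teacher, X)$logits
          consistent_ok <- consistent_ok &&
            identical(student_input_ck, teacher_input_ck)
          lkd <- distillation_loss(fw$logits, tlog, distill_cfg)
          loss <- distill_cfg$lam_weight * lg + (1 - distill_cfg$lam_weight) * lkd
          dlog <- distill_cfg$lam_weight *
            ground_truth_loss_grad(fw$logits, tgt, gt_kind) +
            (1 - distill_cfg$lam_weight) *
            distillation_loss_grad(fw$logits, tlog, distill_cfg)
          tot_kd <- tot_kd + lkd
        } else {
          loss <- lg
          dlog <- ground_truth_loss_grad(fw$logits, tgt, gt_kind)
        }
        tot <- tot + loss; tot_g <- tot_g + lg
        if (lr > 0 && length(trainable)) {
          g <- model_backward(student, fw$cache, dlog)
          if (is.null(grads_sum)) {
            grads_sum <- g[trainable]
          } else {
            for (nm in trainable) grads_sum[[nm]] <- grads_sum[[nm]] + g[[nm]]
          }
        }
      }
      if (lr > 0 && !is.null(grads_sum)) {
        for (nm in trainable) grads_sum[[nm]] <- grads_sum[[nm]] / length(batch)
        upd <- .adam_step(student$params, grads_sum, adam, lr)
        student$params <- upd$params
        adam <- upd$state
      }
    }
    log_rows[[epoch]] <- data.frame(
      epoch = epoch, loss = tot / n, loss_g = tot_g / n,
      loss_kd = if (strategy == "distill") tot_kd / n else NA_real_,
      backbone_checksum = param_checksum(student, "backbone"),
      teacher_checksum = if (!is.null(teacher)) param_checksum(teacher, "all")
                         else NA_character_,
      stringsAsFactors = FALSE)
    if (verbose)
      message(sprintf("epoch %d: loss %.4f", epoch, tot / n))
  }
  log_df <- do.call(rbind, log_rows)
  if (!is.null(teacher) && param_checksum(teacher, "all") != teacher_ck0)
    stop("frozen teacher changed during training")  # defensive; cannot happen
  list(model = student, log = log_df, consistent_teaching_ok = consistent_ok)
}

#' Write a training log and run manifest
#'
#' The CSV holds the per-epoch loss curve and scope checksums; the JSON
#' manifest captures the resolved configuration and seeds so the run is
#' reproducible from the manifest alone.
#'
#' @param result A result from [train()].
#' @param dir Output directory.
#' @param run_config Optional list of configuration to embed in the manifest.
#' @return `dir`, invisibly.
#' @export
write_training_log <- function(result, dir, run_config = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$log, file.path(dir, "training_log.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    c(run_config, list(final_loss = utils::tail(result$log$loss, 1),
                       consistent_teaching_ok = result$consistent_teaching_ok)),
    file.path(dir, "run_manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
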