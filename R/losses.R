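#' Numerically stable softmax
#' @param z Numeric vector of logits.
#' @return Probability vector summing to 1.
#' @export
softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

#' Elementwise logistic sigmoid
#' @param z Numeric vector of logits.
#' @return Values in (0, 1).
#' @export
sigmoid <- function(z) 1 / (1 + exp(-z))

.clamp_log <- function(p, floor = 1e-12) log(pmax(p, floor))

#' Distillation hyperparameters
#'
#' Houses the weighting `lam_weight` (lambda) between ground-truth and
#' distillation losses, the teacher temperature `tau`, and the loss kinds.
#' Single-label mode pairs cross-entropy + softmax + KL divergence;
#' multi-label mode pairs binary cross-entropy + sigmoid + BCE.
#'
#' @param lam_weight Lambda in `[0, 1]` (default 0.5).
#' @param temperature Tau > 0 applied to the teacher logits (default 1).
#' @param ground_truth_loss `"cross_entropy"` or `"binary_cross_entropy"`.
#' @param distillation_loss `"kl_divergence"` or `"binary_cross_entropy"`.
#' @return A `distill_config`.
#' @export
distill_config <- function(lam_weight = 0.5, temperature = 1.0,
                           ground_truth_loss = c("cross_entropy", "binary_cross_entropy"),
                           distillation_loss = c("kl_divergence", "binary_cross_entropy")) {
  ground_truth_loss <- match.arg(ground_truth_loss)
  distillation_loss <- match.arg(distillation_loss)
  if (lam_weight < 0 || lam_weight > 1) stop("lam_weight must be in [0, 1]")
  if (temperature <= 0) stop("temperature must be positive")
  structure(list(lam_weight = lam_weight, temperature = temperature,
                 ground_truth_loss = ground_truth_loss,
                 distillation_loss = distillation_loss),
            class = "distill_config")
}

#' Ground-truth loss
#'
#' Cross-entropy (`-sum(y * log softmax(z))`, single-label) or binary
#' cross-entropy (mean over classes, multi-label). Targets must lie in
#' `[0, 1]`; soft targets from MixUp are valid. Logs are clamped so the
#' loss is always finite.
#'
#' @param logits Numeric vector of unnormalised scores.
#' @param target Target vector of the same length, values in `[0, 1]`.
#' @param kind `"cross_entropy"` or `"binary_cross_entropy"`.
#' @return Scalar loss, >= 0.
#' @export
ground_truth_loss <- function(logits, target,
                              kind = c("cross_entropy", "binary_cross_entropy")) {
  kind <- match.arg(kind)
  if (length(logits) != length(target)) stop("logits/target dimension mismatch")
  if (any(target < 0 | target > 1)) stop("target values must be in [0, 1]")
  if (kind == "cross_entropy") {
    -sum(target * .clamp_log(softmax(logits)))
  } else {
    p <- sigmoid(logits)
    -mean(target * .clamp_log(p) + (1 - target) * .clamp_log(1 - p))
  }
}

# gradient of ground_truth_loss w.r.t. logits
ground_truth_loss_grad <- function(logits, target, kind) {
  if (kind == "cross_entropy") {
    softmax(logits) * sum(target) - target
  } else {
    (sigmoid(logits) - target) / length(logits)
  }
}

#' Distillation loss against a frozen teacher
#'
#' The temperature divides the teacher logits only. `"kl_divergence"`
#' computes `KL(softmax(teacher/tau) || softmax(student))` in nats
#' (single-label); `"binary_cross_entropy"` treats the teacher's sigmoid
#' outputs as soft targets (multi-label).
#'
#' @param student_logits,teacher_logits Same-length numeric vectors; under
#'   consistent teaching both come from the identical augmented input.
#' @param cfg A `distill_config`.
#' @return Scalar loss, >= 0 for KL.
#' @export
distillation_loss <- function(student_logits, teacher_logits, cfg) {
  stopifnot(inherits(cfg, "distill_config"))
  if (length(student_logits) != length(teacher_logits))
    stop("student/teacher logit dimension mismatch")
  if (cfg$distillation_loss == "kl_divergence") {
    pt <- softmax(teacher_logits / cfg$temperature)
    ps <- softmax(student_logits)
    sum(pt * (.clamp_log(pt) - .clamp_log(ps)))
  } else {
    pt <- sigmoid(teacher_logits / cfg$temperature)
    ps <- sigmoid(student_logits)
    -mean(pt * .clamp_log(ps) + (1 - pt) * .clamp_log(1 - ps))
  }
}

# gradient of distillation_loss w.r.t. student logits
distillation_loss_grad <- function(student_logits, teacher_logits, cfg) {
  if (cfg$distillation_loss == "kl_divergence") {
    pt <- softmax(teacher_logits / cfg$temperature)
    softmax(student_logits) - pt
  } else {
    pt <- sigmoid(teacher_logits / cfg$temperature)
    (sigmoid(student_logits) - pt) / length(student_logits)
  }
}

#' Total distillation objective
#'
#' `lambda * L_g + (1 - lambda) * L_kd`. With `lambda = 1` this reduces
#' bit-exactly to ground-truth training; with `lambda = 0` to pure
#' distillation.
#'
#' @inheritParams distillation_loss
#' @param target Ground-truth target vector.
#' @return Scalar loss.
#' @export
total_distill_loss <- function(student_logits, teacher_logits, target, cfg) {
  stopifnot(inherits(cfg, "distill_config"))
  lg <- ground_truth_loss(student_logits, target, cfg$ground_truth_loss)
  if (cfg$lam_weight == 1) return(lg)
  lkd <- distillation_loss(student_logits, teacher_logits, cfg)
  if (cfg$lam_weight == 0) return(lkd)
  cfg$lam_weight * lg + (1 - cfg$lam_weight) * lkd
}
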