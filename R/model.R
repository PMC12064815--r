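#' Tiny reference classifier architectures
#'
#' Three desk-scale architectures share one contract: a backbone `f1` mapping
#' the model input to an embedding, and a head `f2` mapping the embedding to
#' per-class logits. They are stand-ins for large pretrained audio networks,
#' small enough that full train/eval cycles on synthetic corpora run in
#' seconds-to-minutes on one CPU:
#'
#' * `"melband"`: per-band time-mean and time-max log-mel energies -> dense
#'   ReLU layer -> linear head. Fast; also the shape used for hand-constructed
#'   template teachers.
#' * `"cnn"`: average-pooled spectrogram -> one 3x3 convolution (ReLU) ->
#'   time pooling (frequency preserved) -> dense ReLU -> linear head.
#' * `"transformer"`: average-pooled spectrogram -> non-overlapping patches ->
#'   linear patch embedding + learned positional embedding -> one single-head
#'   self-attention block with residual FFN -> mean pooling -> dense ReLU ->
#'   linear head.
#'
#' @param arch `"melband"`, `"cnn"` or `"transformer"`.
#' @param vocab A `class_vocabulary`; its ordering defines logit indices.
#' @param frontend Front-end preset name (see [frontend_preset()]) or a
#'   `mel_config`. Must be a spectrogram front-end.
#' @param activation_kind `"softmax"` (single-label) or `"sigmoid"`
#'   (multi-label); applied by callers, never inside [model_forward()].
#' @param embedding_dim Embedding width (default 64).
#' @param n_filters Convolution filters for `"cnn"` (default 8).
#' @param attn_dim Token width for `"transformer"` (default 32).
#' @param seed Integer seed for weight initialisation.
#' @return A `bird_classifier`.
#' @export
build_model <- function(arch = c("melband", "cnn", "transformer"), vocab,
                        frontend = "passt",
                        activation_kind = c("softmax", "sigmoid"),
                        embedding_dim = 64L, n_filters = 8L, attn_dim = 32L,
                        seed = 1L) {
  arch <- match.arg(arch)
  activation_kind <- match.arg(activation_kind)
  stopifnot(inherits(vocab, "class_vocabulary"))
  frontend_name <- if (is.character(frontend)) frontend else "custom"
  mel_cfg <- if (is.character(frontend)) frontend_preset(frontend) else frontend
  if (!mel_cfg$spectrogram)
    stop("reference architectures require a spectrogram front-end; ",
         "the raw-waveform preset is a front-end-level pass-through only")
  K <- n_classes(vocab)
  n_frames3 <- frame_count(mel_cfg, 3)
  dims <- .arch_dims(arch, mel_cfg$n_mels, n_frames3, embedding_dim,
                     n_filters, attn_dim)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  params <- .init_params(arch, dims, K)
  head_names <- c("Wh", "bh")
  model <- structure(
    list(arch = arch, frontend_name = frontend_name, mel_cfg = mel_cfg,
         vocab = vocab, activation_kind = activation_kind,
         dims = dims, params = params,
         backbone_param_names = setdiff(names(params), head_names),
         head_param_names = head_names,
         trainable_scope = "all", version = "1"),
    class = "bird_classifier"
  )
  model
}

.arch_dims <- function(arch, n_mels, n_frames, emb, n_filters, attn_dim) {
  pf <- 4L; pt <- 8L
  Fp <- n_mels %/% pf; Tp <- n_frames %/% pt
  d <- list(arch = arch, n_mels = n_mels, n_frames = n_frames,
            pool_f = pf, pool_t = pt, Fp = Fp, Tp = Tp, emb = as.integer(emb))
  if (arch == "cnn") {
    d$C <- as.integer(n_filters)
    d$feat <- d$C * Fp
  } else if (arch == "transformer") {
    d$patch_f <- 8L; d$patch_t <- 6L; d$d <- as.integer(attn_dim)
    d$gf <- Fp %/% d$patch_f; d$gt <- Tp %/% d$patch_t
    if (d$gf < 1L || d$gt < 1L) stop("input too small for the patch grid")
    d$n_patch <- d$gf * d$gt
    d$patch_dim <- d$patch_f * d$patch_t
    d$ffn <- 2L * d$d
  } else {
    d$feat <- 2L * n_mels
  }
  d
}

.rmat <- function(nr, nc, scale) matrix(stats::rnorm(nr * nc, sd = scale), nr, nc)

.init_params <- function(arch, dims, K) {
  emb <- dims$emb
  p <- list()
  if (arch == "melband") {
    p$W1 <- .rmat(emb, dims$feat, sqrt(2 / dims$feat)); p$b1 <- numeric(emb)
  } else if (arch == "cnn") {
    p$Wc <- .rmat(dims$C, 9L, sqrt(2 / 9)); p$bc <- numeric(dims$C)
    p$W1 <- .rmat(emb, dims$feat, sqrt(2 / dims$feat)); p$b1 <- numeric(emb)
  } else {
    d <- dims$d
    p$We <- .rmat(d, dims$patch_dim, sqrt(2 / dims$patch_dim)); p$be <- numeric(d)
    p$Epos <- .rmat(d, dims$n_patch, 0.02)
    p$Wq <- .rmat(d, d, sqrt(1 / d)); p$Wk <- .rmat(d, d, sqrt(1 / d))
    p$Wv <- .rmat(d, d, sqrt(1 / d)); p$Wo <- .rmat(d, d, sqrt(1 / d))
    p$Wf1 <- .rmat(dims$ffn, d, sqrt(2 / d)); p$bf1 <- numeric(dims$ffn)
    p$Wf2 <- .rmat(d, dims$ffn, sqrt(2 / dims$ffn)); p$bf2 <- numeric(d)
    p$W1 <- .rmat(emb, d, sqrt(2 / d)); p$b1 <- numeric(emb)
  }
  p$Wh <- .rmat(K, emb, sqrt(1 / emb)); p$bh <- numeric(K)
  p
}

#' @export
print.bird_classifier <- function(x, ...) {
  n_par <- sum(vapply(x$params, length, 0L))
  cat(sprintf(
    "<bird_classifier: arch=%s frontend=%s classes=%d params=%d scope=%s activation=%s>\n",
    x$arch, x$frontend_name, n_classes(x$vocab), n_par, x$trainable_scope,
    x$activation_kind))
  invisible(x)
}

#' Prepare the model input matrix from a clip or spectrogram
#'
#' Computes the log-mel spectrogram if given a waveform (the clip must match
#' the front-end sample rate) and applies per-spectrogram standardisation
#' when the front-end config enables it.
#'
#' @param model A `bird_classifier`.
#' @param x An `audio_clip` or `mel_spectrogram`.
#' @return Numeric matrix `n_mels x n_frames`.
#' @export
model_input <- function(model, x) {
  if (inherits(x, "audio_clip")) x <- compute_mel(x, model$mel_cfg)
  stopifnot(inherits(x, "mel_spectrogram"))
  v <- x$values
  if (model$mel_cfg$standardize) v <- standardize_mel(v)
  v
}

# 2-D average pooling by integer factors, trimming any remainder.
.avg_pool2 <- function(X, pf, pt) {
  Fp <- nrow(X) %/% pf; Tp <- ncol(X) %/% pt
  X <- X[seq_len(Fp * pf), seq_len(Tp * pt), drop = FALSE]
  # pool rows then columns via block sums
  Xr <- matrix(colSums(matrix(X, nrow = pf)), nrow = Fp)       # Fp x (Tp*pt)
  Xc <- matrix(colSums(matrix(t(Xr), nrow = pt)), nrow = Tp)   # Tp x Fp
  t(Xc) / (pf * pt)
}

# 3x3 same-padding im2col: returns 9 x (Fp*Tp), column order (t-1)*Fp + f.
.im2col3 <- function(X) {
  Fp <- nrow(X); Tp <- ncol(X)
  Xp <- matrix(0, Fp + 2L, Tp + 2L)
  Xp[2:(Fp + 1L), 2:(Tp + 1L)] <- X
  out <- matrix(0, 9L, Fp * Tp)
  r <- 1L
  for (dj in 0:2) for (di in 0:2) {
    out[r, ] <- as.vector(Xp[di + seq_len(Fp), dj + seq_len(Tp)])
    r <- r + 1L
  }
  out
}

#' Forward pass: model input to logits
#'
#' Deterministic (evaluation-mode) forward pass. Raw logits are returned;
#' the activation (`softmax`/`sigmoid`) is applied by callers.
#'
#' @param model A `bird_classifier`.
#' @param input Matrix from [model_input()] (or an `audio_clip` /
#'   `mel_spectrogram`, converted internally).
#' @param keep_cache Keep intermediate activations for [model_backward()]?
#' @return List with `logits` (length `n_classes`) and, if requested, `cache`.
#' @export
model_forward <- function(model, input, keep_cache = FALSE) {
  if (!is.matrix(input)) input <- model_input(model, input)
  dims <- model$dims
  if (nrow(input) != dims$n_mels)
    stop(sprintf("input has %d rows; model front-end expects %d mel bands",
                 nrow(input), dims$n_mels))
  p <- model$params
  cache <- list(input = input)
  if (model$arch == "melband") {
    feats <- c(rowMeans(input), apply(input, 1, max))
    h_pre <- as.vector(p$W1 %*% feats) + p$b1
    h <- pmax(h_pre, 0)
    cache$feats <- feats; cache$h <- h
  } else if (model$arch == "cnn") {
    X <- .avg_pool2(input, dims$pool_f, dims$pool_t)
    P <- .im2col3(X)
    A_pre <- p$Wc %*% P + p$bc            # C x (Fp*Tp)
    A <- pmax(A_pre, 0)
    Tp <- ncol(X)
    M <- matrix(0, dims$C, nrow(X))       # time-mean, frequency kept
    for (f in seq_len(nrow(X)))
      M[, f] <- rowMeans(A[, (seq_len(Tp) - 1L) * nrow(X) + f, drop = FALSE])
    feats <- as.vector(M)
    h_pre <- as.vector(p$W1 %*% feats) + p$b1
    h <- pmax(h_pre, 0)
    cache$P <- P; cache$A <- A; cache$Fp <- nrow(X); cache$Tp <- Tp
    cache$feats <- feats; cache$h <- h
  } else {
    X <- .avg_pool2(input, dims$pool_f, dims$pool_t)
    # patches: column = flattened patch_f x patch_t block, frequency-major grid
    Pm <- matrix(0, dims$patch_dim, dims$n_patch)
    k <- 1L
    for (jt in seq_len(dims$gt)) for (jf in seq_len(dims$gf)) {
      blk <- X[((jf - 1L) * dims$patch_f + 1L):(jf * dims$patch_f),
               ((jt - 1L) * dims$patch_t + 1L):(jt * dims$patch_t)]
      Pm[, k] <- as.vector(blk); k <- k + 1L
    }
    Z0 <- p$We %*% Pm + p$be + p$Epos
    Q <- p$Wq %*% Z0; Km <- p$Wk %*% Z0; V <- p$Wv %*% Z0
    S <- crossprod(Km, Q) / sqrt(dims$d)          # N x N, columns = queries
    A <- apply(S, 2, softmax)
    O <- V %*% A
    Z1 <- Z0 + p$Wo %*% O
    Hf_pre <- p$Wf1 %*% Z1 + p$bf1
    Hf <- pmax(Hf_pre, 0)
    Z2 <- Z1 + p$Wf2 %*% Hf + p$bf2
    u <- rowMeans(Z2)
    h_pre <- as.vector(p$W1 %*% u) + p$b1
    h <- pmax(h_pre, 0)
    cache <- c(cache, list(Pm = Pm, Z0 = Z0, Q = Q, Km = Km, V = V, A = A,
                           O = O, Z1 = Z1, Hf = Hf, Z2 = Z2, u = u, h = h))
  }
  logits <- as.vector(p$Wh %*% cache$h) + p$bh
  if (!all(is.finite(logits))) stop("non-finite logits")
  list(logits = logits, cache = if (keep_cache) cache else NULL)
}

# Backward pass: gradient of a scalar loss w.r.t. every parameter, given
# d loss / d logits. Returns a named list congruent with model$params.
model_backward <- function(model, cache, dlogits) {
  p <- model$params
  dims <- model$dims
  g <- list()
  g$Wh <- outer(dlogits, cache$h)
  g$bh <- dlogits
  dh <- as.vector(crossprod(p$Wh, dlogits)) * (cache$h > 0)
  if (model$arch == "melband") {
    g$W1 <- outer(dh, cache$feats); g$b1 <- dh
  } else if (model$arch == "cnn") {
    g$W1 <- outer(dh, cache$feats); g$b1 <- dh
    dM <- matrix(as.vector(crossprod(p$W1, dh)), dims$C, cache$Fp)
    dA <- matrix(0, dims$C, cache$Fp * cache$Tp)
    for (f in seq_len(cache$Fp))
      dA[, (seq_len(cache$Tp) - 1L) * cache$Fp + f] <- dM[, f] / cache$Tp
    dA <- dA * (cache$A > 0)
    g$Wc <- dA %*% t(cache$P)
    g$bc <- rowSums(dA)
  } else {
    g$W1 <- outer(dh, cache$u); g$b1 <- dh
    N <- dims$n_patch
    dZ2 <- matrix(as.vector(crossprod(p$W1, dh)) / N, dims$d, N)
    g$Wf2 <- dZ2 %*% t(cache$Hf); g$bf2 <- rowSums(dZ2)
    dHf <- crossprod(p$Wf2, dZ2) * (cache$Hf > 0)
    g$Wf1 <- dHf %*% t(cache$Z1); g$bf1 <- rowSums(dHf)
    dZ1 <- dZ2 + crossprod(p$Wf1, dHf)
    g$Wo <- dZ1 %*% t(cache$O)
    dO <- crossprod(p$Wo, dZ1)
    dV <- dO %*% t(cache$A)
    dAm <- crossprod(cache$V, dO)
    dS <- cache$A * sweep(dAm, 2, colSums(cache$A * dAm))
    dQ <- (cache$Km %*% dS) / sqrt(dims$d)
    dK <- (cache$Q %*% t(dS)) / sqrt(dims$d)
    g$Wq <- dQ %*% t(cache$Z0); g$Wk <- dK %*% t(cache$Z0); g$Wv <- dV %*% t(cache$Z0)
    dZ0 <- dZ1 + crossprod(p$Wq, dQ) + crossprod(p$Wk, dK) + crossprod(p$Wv, dV)
    g$We <- dZ0 %*% t(cache$Pm); g$be <- rowSums(dZ0)
    g$Epos <- dZ0
  }
  g
}

#' Set which parameters training may update
#'
#' `"head_only"` freezes every backbone parameter (shallow finetuning),
#' `"frozen"` freezes all (a distillation teacher), `"all"` unfreezes all
#' (deep finetuning). Frozen parameters are bit-identical before and after
#' any number of training steps.
#'
#' @param model A `bird_classifier`.
#' @param scope `"all"`, `"head_only"` or `"frozen"`.
#' @return The model with the scope recorded.
#' @export
set_trainable_scope <- function(model, scope = c("all", "head_only", "frozen")) {
  model$trainable_scope <- match.arg(scope)
  model
}

# Names of parameters the current scope allows to change.
trainable_param_names <- function(model) {
  switch(model$trainable_scope,
         all = names(model$params),
         head_only = model$head_param_names,
         frozen = character())
}

#' Checksum of model parameters
#'
#' SHA-1 digest of the selected parameter group, used to assert freeze
#' contracts (backbone unchanged under shallow finetuning, teacher unchanged
#' under distillation).
#'
#' @param model A `bird_classifier`.
#' @param which `"all"`, `"backbone"` or `"head"`.
#' @return Character checksum.
#' @export
param_checksum <- function(model, which = c("all", "backbone", "head")) {
  which <- match.arg(which)
  nm <- switch(which, all = names(model$params),
               backbone = model$backbone_param_names,
               head = model$head_param_names)
  digest::digest(model$params[nm])
}

#' Class scores for one clip
#'
#' Forward pass plus the model's activation: softmax probabilities
#' (single-label) or per-class sigmoid scores (multi-label).
#'
#' @param model A `bird_classifier`.
#' @param x Clip, spectrogram or input matrix.
#' @return Numeric vector of per-class scores in `[0, 1]`.
#' @export
predict_scores <- function(model, x) {
  z <- model_forward(model, x)$logits
  if (model$activation_kind == "softmax") softmax(z) else sigmoid(z)
}

#' Save a model checkpoint as a single JSON file
#'
#' The checkpoint stores a version field, the architecture and front-end
#' configuration, the class vocabulary (ordering included), and all weights
#' at full precision.
#'
#' @param model A `bird_classifier`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  obj <- list(
    version = model$version,
    arch = model$arch,
    frontend_name = model$frontend_name,
    mel_cfg = unclass(model$mel_cfg),
    activation_kind = model$activation_kind,
    trainable_scope = model$trainable_scope,
    vocab = list(species_ids = model$vocab$species_ids,
                 noise_class = model$vocab$noise_class),
    dims = model$dims,
    params = lapply(model$params, function(x) {
      if (is.matrix(x)) list(dim = dim(x), values = as.vector(x))
      else list(dim = NULL, values = as.vector(x))
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_checkpoint
#' @param strict Error if the checkpoint lacks a version field.
#' @export
load_checkpoint <- function(path, strict = TRUE) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (strict && is.null(obj$version)) stop("checkpoint has no version field")
  vocab <- class_vocabulary(obj$vocab$species_ids, obj$vocab$noise_class)
  mel_cfg <- do.call(mel_config, obj$mel_cfg[c("n_mels", "sample_rate", "win_length",
                                               "hop_length", "n_fft", "log_floor",
                                               "standardize", "spectrogram")])
  params <- lapply(obj$params, function(x) {
    if (!is.null(x$dim) && length(x$dim)) matrix(x$values, x$dim[1], x$dim[2])
    else as.numeric(x$values)
  })
  dims <- obj$dims
  int_fields <- setdiff(names(dims), "arch")
  dims[int_fields] <- lapply(dims[int_fields], as.integer)
  structure(
    list(arch = obj$arch, frontend_name = obj$frontend_name, mel_cfg = mel_cfg,
         vocab = vocab, activation_kind = obj$activation_kind, dims = dims,
         params = params,
         backbone_param_names = setdiff(names(params), c("Wh", "bh")),
         head_param_names = c("Wh", "bh"),
         trainable_scope = obj$trainable_scope, version = obj$version),
    class = "bird_classifier"
  )
}

#' Hand-constructed band-template teacher
#'
#' Builds a `melband` model whose weights are set analytically from the
#' synthetic species profiles rather than trained: hidden unit k reads the
#' time-max log-mel energy in a 3-band window centred on species k's base
#' frequency, thresholded by `margin`; the head scales that evidence, and
#' the noise class receives a constant bias that wins when no species band
#' is active. On well-separated synthetic species this classifier is close
#' to Bayes-optimal for the generator, which makes it a reference teacher
#' for distillation tests.
#'
#' @param vocab A `class_vocabulary` (species order must match `profiles`).
#' @param profiles List of `species_profile` (one per species in `vocab`).
#' @param frontend Front-end preset name or `mel_config`.
#' @param margin Activation threshold on standardised band maxima.
#' @param scale Head gain applied to thresholded evidence.
#' @param noise_bias Head bias of the noise class.
#' @return A frozen `bird_classifier` with softmax activation.
#' @export
template_teacher <- function(vocab, profiles, frontend = "passt",
                             margin = 1.5, scale = 8, noise_bias = 2) {
  stopifnot(length(profiles) == length(vocab$species_ids))
  mel_cfg <- if (is.character(frontend)) frontend_preset(frontend) else frontend
  K <- n_classes(vocab)
  emb <- max(64L, K + 1L)
  model <- build_model("melband", vocab, frontend = frontend,
                       activation_kind = "softmax", embedding_dim = emb, seed = 0L)
  n_mels <- mel_cfg$n_mels
  centers <- mel_to_hz(seq(hz_to_mel(0), hz_to_mel(mel_cfg$sample_rate / 2),
                           length.out = n_mels + 2L))[2:(n_mels + 1L)]
  W1 <- matrix(0, emb, 2L * n_mels); b1 <- numeric(emb)
  Wh <- matrix(0, K, emb); bh <- numeric(K)
  for (k in seq_along(profiles)) {
    band <- which.min(abs(centers - profiles[[k]]$base_frequency))
    win <- unique(pmax(1L, pmin(n_mels, (band - 1L):(band + 1L))))
    # relative evidence: band-window time-max minus across-band mean of the
    # time-maxima, so broadband noise (flat maxima) produces no evidence
    W1[k, n_mels + seq_len(n_mels)] <- -1 / n_mels
    W1[k, n_mels + win] <- W1[k, n_mels + win] + 1 / length(win)
    b1[k] <- -margin
    Wh[k, k] <- scale
  }
  bh[vocab$noise_class_index] <- noise_bias
  model$params <- list(W1 = W1, b1 = b1, Wh = Wh, bh = bh)
  set_trainable_scope(model, "frozen")
}
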