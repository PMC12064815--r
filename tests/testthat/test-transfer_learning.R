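test_that("ground-truth loss matches closed-form oracles", {
  # uniform softmax: CE = log K
  expect_equal(ground_truth_loss(rep(0.7, 5), c(0, 1, 0, 0, 0), "cross_entropy"),
               log(5), tolerance = 1e-12)
  # overwhelming correct logit: CE -> 0
  expect_lt(ground_truth_loss(c(50, 0, 0), c(1, 0, 0), "cross_entropy"), 1e-12)
  # frozen scalar example: softmax oracle for logits (1, 0, -1), target class 1
  expect_equal(ground_truth_loss(c(1, 0, -1), c(1, 0, 0), "cross_entropy"),
               0.40760596444438, tolerance = 1e-10)
  # BCE equals its elementwise formula
  z <- c(0.3, -1.2, 2); t <- c(1, 0, 1)
  p <- 1 / (1 + exp(-z))
  expect_equal(ground_truth_loss(z, t, "binary_cross_entropy"),
               -mean(t * log(p) + (1 - t) * log(1 - p)), tolerance = 1e-12)
  expect_error(ground_truth_loss(c(0, 0), c(1.2, 0), "cross_entropy"), "\\[0, 1\\]")
  expect_error(ground_truth_loss(c(0, 0), c(1, 0, 0), "cross_entropy"), "mismatch")
})

test_that("distillation loss matches its definition and limits", {
  cfg <- distill_config()
  # identical logits, tau 1 -> KL = 0
  expect_equal(distillation_loss(c(1, 2, 3), c(1, 2, 3), cfg), 0, tolerance = 1e-12)
  # teacher (2,0), student (0,0): independent two-class closed form
  expect_equal(distillation_loss(c(0, 0), c(2, 0), cfg),
               oracle_kl2(c(2, 0), c(0, 0)), tolerance = 1e-12)
  expect_equal(distillation_loss(c(0, 0), c(2, 0), cfg), 0.327813325472738,
               tolerance = 1e-10)
  # huge tau: teacher -> uniform, KL -> KL(uniform || student)
  hot <- distill_config(temperature = 1e8)
  s <- c(1, -1, 0.5)
  ps <- softmax(s)
  expect_equal(distillation_loss(s, c(5, 1, -2), hot),
               sum(rep(1 / 3, 3) * log((1 / 3) / ps)), tolerance = 1e-6)
  # temperature divides the teacher logits only
  cold <- distill_config(temperature = 2)
  expect_equal(distillation_loss(c(0, 0), c(2, 0), cold),
               oracle_kl2(c(1, 0), c(0, 0)), tolerance = 1e-12)
  # BCE variant uses teacher sigmoids as soft targets
  bcfg <- distill_config(ground_truth_loss = "binary_cross_entropy",
                         distillation_loss = "binary_cross_entropy")
  tz <- c(2, -1); sz <- c(0.5, 0.5)
  pt <- sigmoid(tz); psg <- sigmoid(sz)
  expect_equal(distillation_loss(sz, tz, bcfg),
               -mean(pt * log(psg) + (1 - pt) * log(1 - psg)), tolerance = 1e-12)
  expect_error(distillation_loss(c(0, 0), c(0, 0, 0), cfg), "mismatch")
})

test_that("KL distillation loss is non-negative over random logit pairs", {
  set.seed(123)
  cfg <- distill_config()
  for (i in 1:1000) {
    k <- sample(2:8, 1)
    l <- distillation_loss(rnorm(k, sd = 3), rnorm(k, sd = 3), cfg)
    expect_gte(l, 0)
  }
})

test_that("total loss reduces bit-exactly at lambda 0 and 1", {
  set.seed(5)
  s <- rnorm(4); t <- rnorm(4); y <- c(0, 0, 1, 0)
  lam1 <- distill_config(lam_weight = 1)
  expect_identical(total_distill_loss(s, t, y, lam1),
                   ground_truth_loss(s, y, "cross_entropy"))
  lam0 <- distill_config(lam_weight = 0)
  expect_identical(total_distill_loss(s, t, y, lam0),
                   distillation_loss(s, t, lam0))
  expect_equal(total_distill_loss(s, s, y, lam0), 0, tolerance = 1e-12)
  # lambda = 0.5 arithmetic: 0.5 * L_g + 0.5 * L_kd
  half <- distill_config(lam_weight = 0.5)
  expect_equal(total_distill_loss(s, t, y, half),
               0.5 * ground_truth_loss(s, y, "cross_entropy") +
                 0.5 * distillation_loss(s, t, half), tolerance = 1e-15)
  expect_error(distill_config(lam_weight = 1.5), "lam_weight")
})

test_that("shallow finetuning solves a separable task the logistic oracle solves", {
  corpus <- small_corpus()
  ds <- corpus_dataset(corpus, "train", mode = "single")
  m <- build_model("melband", corpus$vocab, seed = 31)
  res <- train("shallow_finetune", m, ds,
               train_config(epochs = 50, learning_rate = 1e-2, seed = 31))
  # training accuracy >= 0.95
  acc <- mean(vapply(seq_along(ds$clips), function(i) {
    which.max(predict_scores(res$model, ds$clips[[i]])) ==
      which.max(ds$targets[[i]])
  }, TRUE))
  expect_gte(acc, 0.95)
  # oracle: one-vs-rest ridge discriminant on the frozen embeddings confirms
  # the task is (near-)linearly separable independent of our trainer
  emb <- t(vapply(ds$clips, function(cl) {
    fw <- model_forward(m, model_input(m, cl), keep_cache = TRUE)
    fw$cache$h
  }, numeric(m$dims$emb)))
  y <- vapply(ds$targets, which.max, 0L)
  X <- cbind(1, emb)
  gram <- crossprod(X) + 1e-6 * diag(ncol(X))
  oracle_pred <- vapply(sort(unique(y)), function(k)
    as.vector(X %*% solve(gram, crossprod(X, as.numeric(y == k)))),
    numeric(nrow(X)))
  expect_gte(mean(sort(unique(y))[apply(oracle_pred, 1, which.max)] == y), 0.95)
})

test_that("zero learning rate leaves parameters untouched with a flat loss", {
  corpus <- tiny_corpus()
  ds <- corpus_dataset(corpus, "train", mode = "single")
  m <- build_model("melband", corpus$vocab, seed = 3)
  ck <- param_checksum(m, "all")
  res <- train("deep_finetune", m, ds,
               train_config(epochs = 3, learning_rate = 0, seed = 1))
  expect_identical(param_checksum(res$model, "all"), ck)
  expect_lt(diff(range(res$log$loss)), 1e-12)
})

test_that("distillation validates teacher presence and vocabulary", {
  corpus <- tiny_corpus()
  ds <- corpus_dataset(corpus, "train", mode = "single")
  m <- build_model("melband", corpus$vocab, seed = 1)
  expect_error(train("distill", m, ds, train_config(epochs = 1)), "teacher")
  other <- build_model("melband", class_vocabulary(c("zz1", "zz2")), seed = 1)
  expect_error(train("distill", m, ds, train_config(epochs = 1), teacher = other),
               "vocabulary mismatch")
})

test_that("cross-architecture distillation runs symmetrically and reduces loss", {
  corpus <- tiny_corpus()
  ds <- corpus_dataset(corpus, "train", mode = "single")
  cnn <- build_model("cnn", corpus$vocab, seed = 6)
  tfm <- build_model("transformer", corpus$vocab, seed = 7)
  tc <- train_config(epochs = 3, learning_rate = 3e-3, seed = 6)
  for (pair in list(list(t = cnn, s = tfm), list(t = tfm, s = cnn))) {
    teacher <- set_trainable_scope(pair$t, "frozen")
    ck <- param_checksum(teacher, "all")
    res <- train("distill", pair$s, ds, tc, teacher = teacher,
                 distill_cfg = distill_config())
    expect_lt(tail(res$log$loss, 1), res$log$loss[1])
    expect_true(res$consistent_teaching_ok)
    expect_identical(tail(res$log$teacher_checksum, 1), ck)
  }
})

test_that("pure distillation from a perfect teacher transfers its argmax", {
  corpus <- small_corpus()
  teacher <- template_teacher(corpus$vocab, corpus$profiles)
  ds <- corpus_dataset(corpus, "train", mode = "single")
  student <- build_model("melband", corpus$vocab, seed = 13)
  res <- train("distill", student, ds,
               train_config(epochs = 30, learning_rate = 3e-3, seed = 13),
               teacher = teacher, distill_cfg = distill_config(lam_weight = 0))
  test_ids <- names(corpus$clips)[corpus$split == "test"]
  agree <- mean(vapply(test_ids, function(rid) {
    x <- model_input(student, corpus$clips[[rid]])
    which.max(model_forward(res$model, x)$logits) ==
      which.max(model_forward(teacher, x)$logits)
  }, TRUE))
  expect_gte(agree, 0.9)
})
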