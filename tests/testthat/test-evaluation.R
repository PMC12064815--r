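test_that("max pooling takes per-class maxima and dominates added chunks", {
  expect_identical(max_pool_recording(matrix(c(0.1, 0.9, 0.3), ncol = 1)), 0.9)
  one <- matrix(c(0.2, 0.7, 0.1), nrow = 1)
  expect_identical(max_pool_recording(one), as.vector(one))
  set.seed(2)
  m <- matrix(runif(15), 5, 3)
  brute <- vapply(1:3, function(k) { mx <- -Inf; for (i in 1:5) mx <- max(mx, m[i, k]); mx }, 0)
  expect_identical(max_pool_recording(m), brute)
  # dominance: adding a chunk never decreases any score
  for (i in 1:20) {
    extra <- rbind(m, runif(3))
    expect_true(all(max_pool_recording(extra) >= max_pool_recording(m)))
    m <- extra
  }
  expect_error(max_pool_recording(matrix(0, 0, 3)), "no chunks")
})

test_that("single-label F1 matches confusion-matrix oracles", {
  # perfect predictions
  sc <- diag(3); truth <- 1:3
  expect_equal(single_label_f1(sc, truth, "macro"), 1)
  # every prediction lands on class 1, truth balanced over two classes;
  # hand-counted: class1 tp=2 fp=2 fn=0 -> F1 = 2/3; class2 tp=0 fn=2 -> 0
  sc2 <- matrix(c(rep(0.9, 4), rep(0.1, 4)), ncol = 2)
  truth2 <- c(1, 1, 2, 2)
  expect_equal(single_label_f1(sc2, truth2, "macro"), mean(c(2/3, 0)),
               tolerance = 1e-12)
  # micro F1 equals accuracy for single-label top-1
  set.seed(3)
  sc3 <- matrix(runif(60), 20, 3)
  truth3 <- sample(1:3, 20, replace = TRUE)
  pred3 <- apply(sc3, 1, which.max)
  expect_equal(single_label_f1(sc3, truth3, "micro"), mean(pred3 == truth3))
  # macro agrees with the independent confusion-matrix oracle
  expect_equal(single_label_f1(sc3, truth3, "macro"),
               oracle_macro_f1(pred3, truth3), tolerance = 1e-12)
})

test_that("average precision matches rank-enumeration oracles", {
  expect_equal(average_precision(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(average_precision(c(0.9, 0.8, 0.7), c(1, 0, 1)), 5 / 6,
               tolerance = 1e-12)
  expect_true(is.na(average_precision(c(0.5, 0.2), c(0, 0))))
  set.seed(9)
  for (i in 1:50) {
    n <- sample(5:60, 1)
    s <- round(runif(n), sample(c(1, 2, 6), 1))  # induce ties sometimes
    y <- rbinom(n, 1, 0.3)
    if (sum(y) == 0) y[1] <- 1
    expect_equal(average_precision(s, y), oracle_average_precision(s, y),
                 tolerance = 1e-12)
  }
})

test_that("AUROC equals exhaustive pairwise counting with half-ties", {
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auroc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  expect_true(is.na(auroc(c(0.1, 0.9), c(1, 1))))
  set.seed(10)
  for (i in 1:50) {
    n <- sample(5:80, 1)
    s <- round(runif(n), sample(c(1, 6), 1))
    y <- rbinom(n, 1, 0.4)
    if (sum(y) == 0) y[1] <- 1
    if (sum(y) == n) y[1] <- 0
    expect_equal(auroc(s, y), oracle_auroc(s, y), tolerance = 1e-12)
  }
})

test_that("AP and AUROC are invariant under strictly monotone transforms", {
  set.seed(12)
  s <- runif(100); y <- rbinom(100, 1, 0.3); y[1] <- 1; y[2] <- 0
  for (f in list(function(x) 2 * x + 1, function(x) x^3, plogis, exp)) {
    expect_equal(average_precision(f(s), y), average_precision(s, y),
                 tolerance = 1e-12)
    expect_equal(auroc(f(s), y), auroc(s, y), tolerance = 1e-12)
  }
})

test_that("thresholded precision/recall matches brute-force confusion counts", {
  # threshold 0 -> every class predicted, recall 1
  sc <- matrix(runif(12), 4, 3); tr <- matrix(rbinom(12, 1, 0.5), 4, 3)
  if (sum(tr) == 0) tr[1, 1] <- 1
  pr0 <- thresholded_pr(sc, tr, 0)
  expect_equal(pr0$recall, 1)
  # impossible threshold -> zero predictions, precision 0 with warning
  expect_warning(pr_hi <- thresholded_pr(sc, tr, 1 + 1e-9), "precision")
  expect_identical(pr_hi$precision, 0)
  # hand-built 3x3 case against enumeration
  sc3 <- matrix(c(0.9, 0.1, 0.4,
                  0.3, 0.8, 0.05,
                  0.25, 0.15, 0.6), 3, 3, byrow = TRUE)
  tr3 <- matrix(c(1, 0, 1,
                  0, 1, 0,
                  1, 0, 1), 3, 3, byrow = TRUE)
  pr <- thresholded_pr(sc3, tr3, 0.2)
  o <- oracle_micro_pr(sc3 >= 0.2, tr3)
  expect_equal(pr$precision, unname(o["precision"]), tolerance = 1e-12)
  expect_equal(pr$recall, unname(o["recall"]), tolerance = 1e-12)
})

test_that("foreground/background recall restricts to two-species recordings", {
  vocab <- class_vocabulary(c("A", "B", "C"))
  anns <- list(
    r1 = recording_annotation("r1", "A", "B"),    # qualifies: A fg, B bg
    r2 = recording_annotation("r2", "B", "A"),    # qualifies: B fg, A bg
    r3 = recording_annotation("r3", "A"),         # one label: excluded
    r4 = recording_annotation("r4", "A", c("B", "C")),  # three labels: excluded
    r5 = recording_annotation("r5", "C", "A"),    # qualifies
    r6 = recording_annotation("r6", "noise")      # noise: excluded
  )
  sc <- matrix(0, 6, 4, dimnames = list(names(anns), vocab$classes))
  sc["r1", "A"] <- 0.9; sc["r1", "B"] <- 0.1
  sc["r2", "B"] <- 0.8; sc["r2", "A"] <- 0.5
  sc["r5", "C"] <- 0.7; sc["r5", "A"] <- 0.05
  out <- foreground_background_recall(sc, anns, vocab, threshold = 0.2)
  # brute-force: qualifying set is exactly the recordings with two labels
  qual <- names(anns)[vapply(anns, function(a) length(a$secondary_species) == 1 &&
                               a$primary_species != "noise", TRUE)]
  expect_identical(sort(qual), c("r1", "r2", "r5"))
  a_row <- out[out$species == "A", ]
  expect_equal(a_row$foreground_recall, 1)         # r1 detected
  expect_equal(a_row$background_recall, 0.5)       # r2 yes, r5 no
  expect_identical(a_row$n_background, 2L)
  # species with detections in all foreground instances -> recall 1
  expect_equal(out[out$species == "B", ]$foreground_recall, 1)
})

test_that("stratified AP groups by regime and matches a brute-force groupby", {
  ap <- c(a = 0.2, b = 0.5, c = 0.9)
  counts <- c(a = 10, b = 100, c = 300)
  out <- stratified_ap(ap, counts)
  expect_identical(out$n, c(1L, 1L, 1L))
  expect_equal(out$median_ap, c(0.2, 0.5, 0.9))
  # all in one regime
  out1 <- stratified_ap(c(x = 0.3, y = 0.6), c(x = 5, y = 7))
  expect_identical(out1$n, c(2L, 0L, 0L))
  expect_equal(out1[out1$regime == "low", "median_ap"], 0.45)
  # random case vs tapply
  set.seed(33)
  ap2 <- setNames(runif(20), paste0("s", 1:20))
  ct2 <- setNames(sample(c(5, 60, 500), 20, replace = TRUE), names(ap2))
  out2 <- stratified_ap(ap2, ct2)
  brute <- tapply(ap2, data_regime(ct2), median)
  for (rg in names(brute))
    expect_equal(out2[out2$regime == rg, "median_ap"], unname(brute[rg]))
})

test_that("evaluate_model produces a coherent report on the tiny corpus", {
  corpus <- tiny_corpus()
  teacher <- template_teacher(corpus$vocab, corpus$profiles)
  rep <- evaluate_model(teacher, corpus, split = "test")
  expect_s3_class(rep, "metrics_report")
  for (f in c("f1_macro", "f1_micro", "mAP", "macro_auroc", "precision", "recall"))
    expect_true(rep[[f]] >= 0 && rep[[f]] <= 1)
  expect_identical(nrow(rep$stratified), 3L)
  d <- tempfile()
  write_metrics(rep, d)
  expect_true(file.exists(file.path(d, "metrics.json")))
  js <- jsonlite::read_json(file.path(d, "metrics.json"))
  expect_true(all(c("f1_macro", "mAP", "macro_auroc", "precision", "recall")
                  %in% names(js)))
})
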