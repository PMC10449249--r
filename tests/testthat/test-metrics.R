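test_that("AUC matches hand cases and the complement property", {
  expect_equal(metric_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(metric_auc(c(0.9, 0.8, 0.1), c(1, 0, 1)), 0.5)
  expect_error(metric_auc(c(0.3, 0.4), c(1, 1)), "both classes")
  set.seed(3)
  for (i in 1:20) {
    s <- runif(8); l <- c(rbinom(6, 1, 0.5), 0, 1)
    a <- metric_auc(s, l)
    expect_equal(metric_auc(s, 1 - l), 1 - a)
    # invariance under a strictly monotone transform
    expect_equal(metric_auc(exp(3 * s), l), a)
  }
})

test_that("F1 handles perfect, empty and hand-computed cases", {
  truth <- matrix(c(1, 0, 0, 1), 2, 2)
  expect_equal(metric_f1(truth, truth), 1)
  expect_equal(metric_f1(truth, truth, "micro"), 1)
  expect_equal(metric_f1(matrix(0, 2, 2), truth), 0)
  # TP=1 FP=1 FN=1 => F1 = 0.5
  pred <- matrix(c(1, 1, 0, 0), 2, 2)
  tr <- matrix(c(1, 0, 1, 0), 2, 2)
  expect_equal(metric_f1(pred, tr, "micro"), 0.5)
})

test_that("hamming distance is the mismatch fraction", {
  a <- matrix(c(1, 0, 1, 0, 1, 1), 2, 3)
  expect_equal(hamming_distance(a, a), 0)
  expect_equal(hamming_distance(a, 1 - a), 1)
  b <- a; b[1, 1] <- 0; b[2, 3] <- 0
  expect_equal(hamming_distance(b, a), 2 / 6)
})

test_that("one-error, ranking loss and coverage match their definitions", {
  s <- matrix(c(0.9, 0.5, 0.1), 1, 3)
  expect_equal(one_error(s, matrix(c(1, 0, 0), 1, 3)), 0)
  expect_equal(one_error(s, matrix(c(0, 1, 1), 1, 3)), 1)
  expect_equal(ranking_loss(s, matrix(c(1, 0, 0), 1, 3)), 0)
  expect_equal(coverage(s, matrix(c(0, 0, 1), 1, 3)), 2)  # worst rank 3 - 1
  expect_equal(coverage(s, matrix(c(0, 0, 1), 1, 3), normalized = TRUE),
               2 / 3)
  expect_warning(one_error(rbind(s, s),
                           matrix(c(1, 0, 0, 0, 0, 0), 2, 3, byrow = TRUE)),
                 "excluded")
})

test_that("all ranking metrics match brute-force enumeration", {
  set.seed(12)
  for (i in 1:60) {
    inst <- random_label_instance()
    s <- inst$scores; tr <- inst$truth
    expect_equal(one_error(s, tr), oracle_one_error(s, tr),
                 tolerance = 1e-12)
    expect_equal(ranking_loss(s, tr), oracle_ranking_loss(s, tr),
                 tolerance = 1e-12)
    expect_equal(coverage(s, tr), oracle_coverage(s, tr),
                 tolerance = 1e-12)
    pred <- matrix(rbinom(length(tr), 1, 0.5), nrow(tr), ncol(tr))
    expect_equal(metric_f1(pred, tr), oracle_f1_macro(pred, tr),
                 tolerance = 1e-12)
    expect_equal(hamming_distance(pred, tr), mean(pred != tr),
                 tolerance = 1e-12)
    j <- sample(ncol(tr), 1)
    if (any(tr[, j] == 1) && any(tr[, j] == 0))
      expect_equal(metric_auc(s[, j], tr[, j]), oracle_auc(s[, j], tr[, j]),
                   tolerance = 1e-12)
    # ranges
    expect_true(one_error(s, tr) >= 0 && one_error(s, tr) <= 1)
    expect_true(ranking_loss(s, tr) >= 0 && ranking_loss(s, tr) <= 1)
    expect_true(coverage(s, tr) >= 0 && coverage(s, tr) <= ncol(tr) - 1)
  }
})

test_that("binary panel computes the three ratios with NA guards", {
  p <- binary_panel(c(TRUE, TRUE, TRUE, FALSE, rep(FALSE, 5), TRUE),
                    c(TRUE, TRUE, TRUE, TRUE, rep(FALSE, 5), FALSE))
  expect_equal(p$sensitivity, 0.75)
  expect_equal(p$specificity, 5 / 6)
  expect_equal(p$precision, 0.75)
  perfect <- binary_panel(c(TRUE, FALSE), c(TRUE, FALSE))
  expect_equal(unlist(perfect), c(sensitivity = 1, specificity = 1,
                                  precision = 1))
  allpos <- binary_panel(rep(TRUE, 4), c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(allpos$specificity, 0)
  nopos <- binary_panel(rep(FALSE, 3), rep(FALSE, 3))
  expect_true(is.na(nopos$sensitivity))
  expect_true(is.na(nopos$precision))
})

test_that("metric_report assembles the index panel", {
  set.seed(5)
  inst <- random_label_instance()
  pred <- (inst$scores > 0.5) * 1
  rep <- metric_report(inst$scores, pred, inst$truth)
  expect_named(rep, c("auc", "hd", "rl", "cov", "oe", "f1"))
  expect_equal(rep$hd, hamming_distance(pred, inst$truth))
})
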