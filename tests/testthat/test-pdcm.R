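test_that("fuse concatenates in the contracted order", {
  hd <- rnorm(768); hs <- rnorm(768); swm <- runif(6)
  f <- fuse(hd, hs, swm, dropout_rate = 0.5, training = FALSE)
  expect_identical(f$h_dropouted, f$h_concatenated)   # inference: no dropout
  expect_equal(length(f$h_swm), 1542L)                # 6 + 2*768
  expect_equal(f$h_swm[1:6], swm)
  expect_equal(f$h_concatenated, c(hd, hs))
  expect_error(fuse(hd[1:10], hs, swm), "768")
  expect_error(fuse(hd, hs, swm[1:3]), "length 6")
})

test_that("classify is a softmax affine map", {
  zero <- list(W = matrix(0, 1542, 6), b = numeric(6))
  s <- classify(rnorm(1542), zero)
  expect_equal(unname(s), rep(1 / 6, 6))
  p <- list(W = matrix(rnorm(1542 * 6, sd = 0.1), 1542, 6), b = rnorm(6))
  x <- rnorm(1542)
  s1 <- classify(x, p)
  expect_equal(sum(s1), 1, tolerance = 1e-6)
  # argmax invariant to a constant shift of all logits
  p2 <- p; p2$b <- p$b + 5
  expect_equal(which.max(classify(x, p2)), which.max(s1))
  sg <- classify(x, p, head = "sigmoid")
  expect_true(all(sg > 0 & sg < 1))
})

test_that("focal loss reduces to cross-entropy and matches hand arithmetic", {
  s <- c(1, 0, 0, 0, 0, 0)
  expect_equal(focal_loss(s, 1, gamma = 2), 0, tolerance = 1e-6)
  s2 <- c(0.9, 0.02, 0.02, 0.02, 0.02, 0.02)
  expect_equal(focal_loss(s2, 1, gamma = 0, alpha = 1), -log(0.9))
  expect_equal(focal_loss(s2, 1, gamma = 2, alpha = 1),
               0.1^2 * -log(0.9), tolerance = 1e-12)
  expect_equal(0.1^2 * -log(0.9), 1.054e-3, tolerance = 1e-3)
  set.seed(2)
  for (i in 1:20) {   # non-negative, equals CE at gamma=0
    z <- runif(6); s <- z / sum(z); y <- sample(6, 1)
    expect_gte(focal_loss(s, y, gamma = runif(1, 0, 4)), 0)
    expect_equal(focal_loss(s, y, gamma = 0, alpha = 1), -log(s[y]),
                 tolerance = 1e-9)
  }
})

test_that("amplify_negatives relabels a seeded 10% sample", {
  units <- training_units(sprintf("dx %d", 1:120),
                          replicate(120, c("s1"), simplify = FALSE),
                          rep(c(1:5, 6), each = 20))
  expect_identical(amplify_negatives(units, fraction = 0), units)
  out <- amplify_negatives(units, 0.10, seed = 5)
  expect_equal(nrow(out), 130L)             # floor(0.1 * 100 padua units)
  extra <- out[121:130, ]
  expect_true(all(extra$label == 6L))
  expect_true(all(grepl("\\?$|undecided$", extra$diagnosis)))
  expect_identical(amplify_negatives(units, 0.10, seed = 5), out)
  expect_false(identical(amplify_negatives(units, 0.10, seed = 6), out))
  expect_error(amplify_negatives(units, 1.5), "<= 1")
})

test_that("training follows the early-stopping and checkpoint contract", {
  w <- tiny_world()
  m <- w$model
  h <- m$history
  expect_lte(nrow(h), 15L)
  expect_gte(m$best_val_f1, max(h$val_f1) - 1e-12)
  expect_lte(m$best_epoch, nrow(h))
  # determinism: identical config => identical history
  m2 <- train_pdcm(w$units, w$bundle$corpora,
                   train_config(seed = 11L, max_epochs = 15L,
                                patience = 15L))
  expect_identical(m$history, m2$history)
  expect_identical(m$head$W, m2$head$W)
  # patience semantics on a short run
  m3 <- train_pdcm(w$units, w$bundle$corpora,
                   train_config(seed = 11L, max_epochs = 15L,
                                patience = 2L))
  stall_run <- nrow(m3$history)
  expect_lte(stall_run, 15L)

  expect_error(train_pdcm(w$units[w$units$label == 1, ], w$bundle$corpora,
                          train_config(seed = 1)),
               "two represented categories")
})

test_that("diagnose_only predictions ignore the symptom input", {
  w <- tiny_world()
  m <- train_pdcm(w$units, w$bundle$corpora,
                  train_config(seed = 11L, max_epochs = 3L, patience = 3L,
                               mode = "diagnose_only"))
  p1 <- predict_patient(m, "dx1x01 dx1x02", c("sym1x01"))
  p2 <- predict_patient(m, "dx1x01 dx1x02", c("sym4x07", "sym5x02"))
  expect_identical(p1$scores, p2$scores)
  expect_identical(p1$flags, p2$flags)
})

test_that("patient-level aggregation is a union over unit argmaxes", {
  w <- tiny_world()
  m <- w$model
  p0 <- predict_patient(m, character(), c("sym1x01"))
  expect_false(any(p0$flags))
  expect_equal(unname(p0$scores), rep(0, 6))

  d1 <- w$units$diagnosis[w$units$label == 1][1]
  d2 <- w$units$diagnosis[w$units$label == 2][1]
  p1 <- predict_patient(m, d1, character())
  p12 <- predict_patient(m, c(d1, d2), character())
  # adding a unit never un-sets a flag
  expect_true(all(p12$flags[p1$flags]))
  expect_equal(length(p12$unit_categories), 2L)
})

test_that("a saved artifact reloads and predicts bit-identically", {
  w <- tiny_world()
  dir <- withr::local_tempdir()
  save_pdcm(w$model, dir)
  back <- load_pdcm(dir)
  expect_identical(back$head$W, w$model$head$W)
  units <- w$units[seq(1, 60, by = 7), ]
  expect_identical(predict_units(w$model, units), predict_units(back, units))
})
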