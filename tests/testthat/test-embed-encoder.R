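test_that("vectorize respects the fixed embedding geometry", {
  emb <- hash_embedder()
  expect_equal(dim(vectorize("", "diagnosis", emb)), c(20L, 768L))
  expect_true(all(vectorize("", "diagnosis", emb) == 0))
  expect_equal(dim(vectorize("any diagnosis string", "diagnosis", emb)),
               c(20L, 768L))
  expect_equal(dim(vectorize(c("fever", "cough"), "symptom", emb)),
               c(50L, 768L))

  # 60 terms truncate at the tail: rows are the first 50 terms
  terms <- sprintf("term%02d", 1:60)
  m <- vectorize(terms, "symptom", emb)
  expect_equal(dim(m), c(50L, 768L))
  expect_equal(m[50, ], vectorize(terms[1:50], "symptom", emb)[50, ])
  expect_false(all(m[50, ] == 0))

  # short input pads with zero rows
  m2 <- vectorize(c("fever", "cough"), "symptom", emb)
  expect_true(all(m2[3:50, ] == 0))
})

test_that("the hashing embedder is deterministic and token-sensitive", {
  e1 <- hash_embedder(); e2 <- hash_embedder()
  expect_identical(vectorize("fever cough", "diagnosis", e1),
                   vectorize("fever cough", "diagnosis", e2))
  expect_false(identical(e1$embed_one("fever"), e1$embed_one("cough")))
  v <- e1$embed_one("fever")
  expect_equal(length(v), 768L)
  expect_lt(abs(mean(v)), 0.15)   # zero-mean-ish uniform stream
})

test_that("encode has the contracted geometry and zero fixed point", {
  pz <- encoder_params(1, init = "zero")
  expect_equal(encode(matrix(0, 20, 768), pz), rep(0, 768))

  p <- encoder_params(7)
  emb <- hash_embedder()
  for (role in c("diagnosis", "symptom")) {
    h <- encode(vectorize("alpha beta", role, emb), p)
    expect_equal(length(h), 768L)
    expect_true(all(is.finite(h)))
  }
  expect_error(encode_batch(array(0, c(1, 20, 100)), p), "width")
})

test_that("masking makes padding-row placement irrelevant", {
  p <- encoder_params(7)
  emb <- hash_embedder()
  m <- vectorize(c("alpha", "beta", "gamma"), "symptom", emb)
  base <- encode(m, p, mask = TRUE)
  shuffled <- m[c(1:3, 50, 4:49), ]   # move a padding row between tokens?
  # padding rows are all-zero; moving them among themselves is free, and
  # with masking even interleaving them between real tokens is free
  interleaved <- rbind(m[1, ], matrix(0, 2, 768), m[2:3, ],
                       matrix(0, 45, 768))
  expect_equal(encode(interleaved, p, mask = TRUE), base, tolerance = 1e-12)
  expect_equal(encode(shuffled, p, mask = TRUE), base, tolerance = 1e-12)
})

test_that("encoder parameters regenerate bit-identically from the seed", {
  a <- encoder_params(123); b <- encoder_params(123)
  expect_identical(a$l1$fw$W, b$l1$fw$W)
  expect_identical(a$l2$bw$U, b$l2$bw$U)
  expect_false(identical(encoder_params(124)$l1$fw$W, a$l1$fw$W))
  # batch and single paths agree
  emb <- hash_embedder()
  X <- vectorize_batch(list("one two", "three"), "diagnosis", emb)
  H <- encode_batch(X, a)
  expect_equal(H[1, ], encode(X[1, , ], a))
  expect_equal(H[2, ], encode(X[2, , ], a))
})
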