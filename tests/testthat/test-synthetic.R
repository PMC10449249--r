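test_that("generation is deterministic under the seed", {
  spec <- generator_spec(seed = 5, n_records = 20)
  b1 <- gen_corpora(spec); b2 <- gen_corpora(spec)
  expect_identical(b1, b2)
  u1 <- gen_training_units(spec, b1); u2 <- gen_training_units(spec, b2)
  expect_identical(u1, u2)
  r1 <- gen_emr(spec, b1); r2 <- gen_emr(spec, b1)
  expect_identical(r1, r2)
  # the vocabularies are fixed catalogs; the seeded draws live in the
  # units and records
  u3 <- gen_training_units(generator_spec(seed = 6, n_records = 20), b1)
  expect_false(identical(u3, u1))
})

test_that("corpora honor sizes and the overlap switch", {
  spec <- generator_spec(seed = 1, symptom_vocab_size = 15,
                         diag_vocab_size = 8)
  b <- gen_corpora(spec)
  expect_true(all(vapply(b$corpora, length, integer(1)) == 15L))
  expect_true(all(lengths(b$diag_vocab) == 8L))
  # overlap 0 => disjoint vocabularies
  terms <- lapply(b$corpora, names)
  for (i in 1:5) for (j in (i + 1):6)
    expect_length(intersect(terms[[i]], terms[[j]]), 0)
  # positive overlap shares terms
  bo <- gen_corpora(generator_spec(seed = 1, symptom_overlap = 0.4))
  shared <- intersect(names(bo$corpora[[1]]), names(bo$corpora[[2]]))
  expect_gt(length(shared), 0)
})

test_that("training units follow label counts and the noise contract", {
  spec <- generator_spec(seed = 2, n_units_per_category = 30)
  b <- gen_corpora(spec)
  u <- gen_training_units(spec, b)
  expect_equal(nrow(u), 180L)
  expect_equal(as.integer(table(u$label)), rep(30L, 6))
  # noise 0: every unit's symptoms live in its category corpus
  for (i in seq_len(nrow(u)))
    expect_true(all(u$symptoms[[i]] %in% names(b$corpora[[u$label[i]]])))
  # with noise, some symptoms leave the category corpus
  spec_n <- generator_spec(seed = 2, n_units_per_category = 30,
                           symptom_noise_rate = 0.5)
  un <- gen_training_units(spec_n, b)
  out_of_cat <- vapply(seq_len(nrow(un)), function(i)
    any(!un$symptoms[[i]] %in% names(b$corpora[[un$label[i]]])),
    logical(1))
  expect_gt(mean(out_of_cat), 0.3)
})

test_that("EMR records plant exactly the gold evidence", {
  prev0 <- stats::setNames(rep(0, 11), padua_item_ids())
  spec0 <- generator_spec(seed = 3, n_records = 15,
                          item_prevalences = prev0)
  b <- gen_corpora(spec0)
  recs <- gen_emr(spec0, b)
  for (r in recs) {
    expect_false(any(r$gold_flags$flags))
    expect_equal(total_score(r$gold_flags), 0)
  }

  # force a planted in-window surgery and check the date lands inside
  prev_s <- prev0; prev_s[["recent_surgery_trauma"]] <- 1
  spec_s <- generator_spec(seed = 4, n_records = 10,
                           item_prevalences = prev_s)
  recs_s <- gen_emr(spec_s, gen_corpora(spec_s))
  for (r in recs_s) {
    expect_true(r$gold_flags$flags[["recent_surgery_trauma"]])
    m <- extract_record_matches(r, gen_corpora(spec_s)$lexicons)
    flag <- recent_surgery_flag(m, 30, r$record_date)
    expect_true(as.logical(flag))
  }
})

test_that("empirical prevalence stays within 3-sigma binomial bounds", {
  spec <- generator_spec(seed = 9, n_records = 1000)
  recs <- gen_emr(spec, gen_corpora(spec))
  gold <- t(vapply(recs, function(r) r$gold_flags$flags, logical(11)))
  prev <- spec$item_prevalences[padua_item_ids()]
  for (id in padua_item_ids()) {
    p <- prev[[id]]
    sd3 <- 3 * sqrt(p * (1 - p) / 1000)
    expect_lte(abs(mean(gold[, id]) - p), max(sd3, 1e-9))
  }
})

test_that("branch B reproduces planted gold flags exactly", {
  # rule/numeric items only; negated and out-of-window distractors active
  prev <- default_item_prevalences()
  prev[padua_disease_ids()] <- 0
  spec <- generator_spec(seed = 13, n_records = 150,
                         item_prevalences = prev)
  b <- gen_corpora(spec)
  recs <- gen_emr(spec, b)
  rep <- evaluate_batch(recs, NULL, b$lexicons)
  bb <- c("elderly", "obesity", "hormonal", "thrombophilic",
          "reduced_mobility", "recent_surgery_trauma")
  expect_identical(rep$pred_flags[, bb], rep$gold_flags[, bb])
})
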