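two_cat_corpora <- function() {
  symptom_corpora(list(c(fever = 2, cough = 1), c(cough = 1)))
}

test_that("tf, iwf and ti match hand arithmetic", {
  corp <- two_cat_corpora()
  expect_equal(tf("fever", corp[[1]]), 2 / 3)
  expect_equal(tf("cough", corp[[2]]), 1)
  expect_equal(tf("absent", corp[[1]]), 0)
  expect_error(tf("fever", numeric()), "empty corpus")

  glob <- global_corpus(corp)
  expect_equal(iwf("cough", glob), log(2))   # W_c=4, W_{c,t}=2
  expect_equal(iwf("fever", glob), log(2))
  expect_error(iwf("absent", glob), "absent")
  big <- stats::setNames(c(1, 99), c("rare", "common"))
  expect_equal(iwf("rare", big), log(100))

  expect_equal(ti("cough", 1, corp), (1 / 3) * log(2))
  expect_equal(ti("cough", 2, corp), log(2))
  expect_equal(ti("fever", 2, corp), 0)   # absent from category 2
})

test_that("build_swm reproduces the worked two-category example", {
  corp <- two_cat_corpora()
  expect_equal(unname(build_swm("cough", corp)), c(0.5, 1, 0, 0, 0, 0),
               tolerance = 1e-12)
  expect_equal(unname(build_swm(character(), corp)), rep(0, 6))
  expect_equal(unname(build_swm("unknown_term", corp)), rep(0, 6))
})

test_that("build_swm matches the brute-force oracle on random corpora", {
  set.seed(20)
  for (i in 1:40) {
    corp <- random_toy_corpora()
    syms <- sample(paste0("t", 1:20), sample(0:8, 1))
    expect_equal(unname(build_swm(syms, corp)), oracle_swm(syms, corp),
                 tolerance = 1e-12)
  }
})

test_that("SWM properties: monotone, bounded per symptom, TF scale-free", {
  set.seed(21)
  for (i in 1:15) {
    corp <- random_toy_corpora()
    syms <- sample(paste0("t", 1:20), sample(1:6, 1))
    base <- build_swm(syms, corp)
    extra <- build_swm(c(syms, sample(paste0("t", 1:20), 1)), corp)
    expect_true(all(extra >= base - 1e-12))
    # each symptom's contribution per category is in [0, 1]
    one <- build_swm(syms[1], corp, dedupe = FALSE)
    expect_true(all(one >= 0 & one <= 1 + 1e-12))
  }
  # scaling one category's counts leaves its TF (hence its TI ratios) alone
  corp <- two_cat_corpora()
  scaled <- symptom_corpora(list(c(fever = 2, cough = 1) * 7, c(cough = 1)))
  expect_equal(tf("fever", corp[[1]]), tf("fever", scaled[[1]]))
  expect_equal(tf("cough", corp[[1]]), tf("cough", scaled[[1]]))
})

test_that("duplicate symptoms follow the dedupe switch", {
  corp <- two_cat_corpora()
  once <- build_swm("cough", corp)
  expect_equal(build_swm(c("cough", "cough"), corp), once)  # dedupe default
  expect_equal(build_swm(c("cough", "cough"), corp, dedupe = FALSE),
               2 * once)
})

test_that("zero-TI categories contribute zero instead of dividing by zero", {
  # category 2's only term spans the whole pool => IWF = 0 => max TI = 0
  corp <- symptom_corpora(list(c(only = 3), c(only = 1)))
  expect_equal(unname(build_swm("only", corp))[2], 0)
})

test_that("corpora TSV round-trips", {
  corp <- two_cat_corpora()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_corpora_tsv(corp, path)
  back <- read_corpora_tsv(path)
  expect_equal(lapply(back, as.list), lapply(corp, as.list))
})
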