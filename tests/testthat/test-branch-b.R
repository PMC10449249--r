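lex <- toy_lexicons()

test_that("segment produces TIME/TERM/NEG/OTHER tokens with clean spans", {
  expect_equal(nrow(segment("", lex)), 0L)

  s <- paste0("On April 16, 2021, he was hospitalized Hospital for ",
              "artificial joint replacement")
  tk <- segment(s, lex)
  expect_equal(tk$surface[tk$pos == "TIME"], "On April 16, 2021")
  expect_equal(tk$surface[tk$pos == "TERM"], "artificial joint replacement")
  # spans 0-based half-open, ordered, non-overlapping, faithful to source
  expect_true(all(diff(tk$start) > 0))
  expect_true(all(tk$end > tk$start))
  expect_true(all(tk$end[-nrow(tk)] <= tk$start[-1]))
  for (i in seq_len(nrow(tk)))
    expect_equal(substr(s, tk$start[i] + 1, tk$end[i]), tk$surface[i])

  tk2 <- segment("no hormone use", lex)
  expect_equal(tk2$pos, c("NEG", "TERM", "OTHER"))
  expect_equal(tk2$surface, c("no", "hormone", "use"))
})

test_that("lexicon matching needs word boundaries for ASCII terms", {
  tk <- segment("normal findings with no hormone", lex)
  # "no" must not fire inside "normal"
  neg <- tk[tk$pos == "NEG", ]
  expect_equal(nrow(neg), 1L)
  expect_equal(neg$start, 21L)
})

test_that("match_corpus keeps per-sentence indexes", {
  tk <- segment("fever and cough", lex)
  m <- match_corpus(tk, lex$symptom, sentence_index = 1L)
  expect_equal(m$term, c("fever", "cough"))
  expect_false(any(m$negated))
  m2 <- rbind(m, match_corpus(segment("fever again", lex), lex$symptom, 2L))
  expect_equal(m2$sentence_index[m2$term == "fever"], c(1L, 2L))
  expect_equal(nrow(match_corpus(segment("nothing here", lex), lex$symptom)),
               0L)
})

test_that("negation cues flag matches in the same clause only", {
  tk <- segment("patient is not using hormone", lex)
  m <- filter_negated(match_corpus(tk, lex$hormone), tk)
  expect_true(all(m$negated))

  tk <- segment("no abnormalities seen", lex)
  m <- filter_negated(match_corpus(tk, lex$symptom), tk)
  expect_true(all(m$negated))

  tk <- segment("fever and cough persist", lex)
  m <- filter_negated(match_corpus(tk, lex$symptom), tk)
  expect_false(any(m$negated))

  # cue in a different comma-delimited clause does not negate
  tk <- segment("no edema, cough persists", lex)
  m <- filter_negated(match_corpus(tk, lex$symptom), tk)
  expect_true(m$negated[m$term == "edema"])
  expect_false(m$negated[m$term == "cough"])

  # a finite token window restricts the scope
  tk <- segment("no history of note today fever", lex)
  m_all <- filter_negated(match_corpus(tk, lex$symptom), tk)
  m_w1 <- filter_negated(match_corpus(tk, lex$symptom), tk, window = 1)
  expect_true(m_all$negated[1])
  expect_false(m_w1$negated[1])
})

test_that("parse_time resolves absolute and relative expressions", {
  expect_equal(parse_time("On April 16, 2021"), as.Date("2021-04-16"))
  expect_equal(parse_time("April 16, 2021"), as.Date("2021-04-16"))
  expect_equal(parse_time("2021-04-16"), as.Date("2021-04-16"))
  expect_equal(parse_time("3 days ago", as.Date("2021-05-01")),
               as.Date("2021-04-28"))
  expect_equal(parse_time("2 weeks ago", as.Date("2021-05-01")),
               as.Date("2021-04-17"))
  expect_equal(parse_time("1 month ago", as.Date("2021-03-31")),
               as.Date("2021-02-28"))   # clamped to month length
  expect_true(is.na(parse_time("complete garbage")))
})

test_that("recent_surgery_flag honors the window boundary and negation", {
  mk <- function(date_str, negated = FALSE) {
    data.frame(term = "appendectomy", lexicon_name = "surgery_trauma",
               sentence_index = 1L, negated = negated,
               anchored_date = as.Date(date_str), token_row = 1L,
               stringsAsFactors = FALSE)
  }
  ref <- as.Date("2021-04-30")
  expect_true(as.logical(recent_surgery_flag(mk("2021-04-16"), 30, ref)))
  expect_false(as.logical(recent_surgery_flag(mk("2021-04-16"), 30,
                                              as.Date("2021-12-01"))))
  # boundary: exactly window_days fires, window_days + 1 does not
  expect_true(as.logical(recent_surgery_flag(mk(ref - 30), 30, ref)))
  expect_false(as.logical(recent_surgery_flag(mk(ref - 31), 30, ref)))
  expect_false(as.logical(recent_surgery_flag(mk(ref + 1), 30, ref)))
  expect_false(as.logical(recent_surgery_flag(mk("2021-04-16", TRUE), 30, ref)))
  expect_false(as.logical(recent_surgery_flag(mk(NA), 30, ref)))
})

test_that("lexicon rule flags need one non-negated match", {
  tk <- segment("patient in deep coma", lex)
  m <- filter_negated(match_corpus(tk, lex$reduced_mobility), tk)
  expect_true(as.logical(reduced_mobility_flag(m)))
  tk2 <- segment("not bedridden", lex)
  m2 <- filter_negated(match_corpus(tk2, lex$reduced_mobility), tk2)
  expect_false(as.logical(reduced_mobility_flag(m2)))
  expect_false(as.logical(hormone_flag(m2[0, ])))
})

test_that("numeric rules: age, BMI and thrombophilia labs", {
  expect_true(as.logical(elderly_flag(70)))
  expect_false(as.logical(elderly_flag(69.5)))
  expect_false(as.logical(elderly_flag(NA)))
  expect_match(attr(elderly_flag(NA), "evidence"), "missing data")

  expect_true(as.logical(obesity_flag(1.70, 88)))    # BMI 30.45
  expect_false(as.logical(obesity_flag(1.70, 60)))   # BMI 20.76
  expect_error(obesity_flag(0, 60), "positive")
  # agreement with direct BMI arithmetic at the threshold
  set.seed(9)
  for (i in 1:30) {
    h <- runif(1, 1.4, 2.0); w <- runif(1, 40, 130)
    expect_identical(as.logical(obesity_flag(h, w)), w / h^2 >= 30)
  }

  expect_false(as.logical(thrombophilia_flag(lab_panel())))
  expect_true(as.logical(thrombophilia_flag(lab_panel(protein_c = 50))))
  expect_true(as.logical(thrombophilia_flag(lab_panel(d_dimer = 1.2))))
  ok <- lab_panel(protein_c = 95, protein_s = 80, antithrombin_iii = 100,
                  d_dimer = 0.3)
  expect_false(as.logical(thrombophilia_flag(ok)))
})

test_that("extract_symptoms is deduplicated, ordered, negation-aware", {
  rec <- emr_record("r1", "2021-04-30",
                    sections = list(
                      complaints = "fever and cough. fever again. no edema",
                      examination = "chest pain noted"))
  syms <- extract_symptoms(rec, lex)
  expect_equal(syms, c("fever", "cough", "chest pain"))
  rec2 <- emr_record("r2", "2021-04-30",
                     sections = list(complaints = "no fever"))
  expect_equal(extract_symptoms(rec2, lex), character())
})

test_that("extraction is deterministic", {
  rec <- emr_record("r3", "2021-04-30",
                    diagnoses = "something",
                    sections = list(
                      past_history = "appendectomy on 2021-04-20",
                      complaints = "fever, no cough"))
  a <- extract_record_matches(rec, lex)
  b <- extract_record_matches(rec, lex)
  expect_identical(a, b)
  expect_true(as.logical(recent_surgery_flag(a, 30, rec$record_date)))
})
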