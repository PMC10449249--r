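# Shared fixtures and independent brute-force oracles.  The oracles are
# deliberately naive (nested loops, pair enumeration) and never call the
# implementation they check.

toy_lexicons <- function() {
  lexicon_set(
    surgery_trauma = c("artificial joint replacement", "hip fracture repair",
                       "appendectomy"),
    hormone = c("hormone", "estrogen therapy", "tamoxifen"),
    reduced_mobility = c("deep coma", "bedridden", "paraplegia"),
    symptom = c("fever", "cough", "chest pain", "abnormalities", "edema")
  )
}

# brute-force TF / IWF / TI / SWM, straight from the formulas
oracle_tf <- function(term, corpus) {
  n <- if (term %in% names(corpus)) corpus[[term]] else 0
  n / sum(corpus)
}

oracle_iwf <- function(term, corpora) {
  wc <- 0; wct <- 0
  for (k in seq_along(corpora)) {
    for (t in names(corpora[[k]])) {
      wc <- wc + corpora[[k]][[t]]
      if (t == term) wct <- wct + corpora[[k]][[t]]
    }
  }
  log(wc / wct)
}

oracle_ti <- function(term, k, corpora) {
  if (!(term %in% names(corpora[[k]])) || corpora[[k]][[term]] == 0) return(0)
  oracle_tf(term, corpora[[k]]) * oracle_iwf(term, corpora)
}

oracle_swm <- function(symptoms, corpora, dedupe = TRUE) {
  if (dedupe) symptoms <- unique(symptoms)
  swm <- numeric(6)
  for (t in symptoms) {
    for (k in 1:6) {
      corpus <- corpora[[k]]
      corpus <- corpus[corpus > 0]
      if (!length(corpus) || !(t %in% names(corpus))) next
      ti_max <- max(vapply(names(corpus), oracle_ti, numeric(1),
                           k = k, corpora = corpora))
      if (ti_max > 0)
        swm[k] <- swm[k] + oracle_ti(t, k, corpora) / ti_max
    }
  }
  swm
}

random_toy_corpora <- function() {
  n_cat <- sample(2:6, 1)
  counts <- lapply(seq_len(6), function(k) {
    if (k > n_cat) return(numeric())
    n_terms <- sample(1:20, 1)
    terms <- sample(paste0("t", 1:20), n_terms)
    stats::setNames(sample(1:9, n_terms, replace = TRUE), terms)
  })
  symptom_corpora(counts)
}

# brute-force multi-label metric oracles
oracle_auc <- function(scores, labels) {
  pos <- which(labels == 1); neg <- which(labels == 0)
  s <- 0
  for (i in pos) for (j in neg)
    s <- s + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  s / (length(pos) * length(neg))
}

oracle_f1_macro <- function(pred, truth) {
  f1s <- c()
  for (j in seq_len(ncol(pred))) {
    tp <- sum(pred[, j] == 1 & truth[, j] == 1)
    fp <- sum(pred[, j] == 1 & truth[, j] == 0)
    fn <- sum(pred[, j] == 0 & truth[, j] == 1)
    if (2 * tp + fp + fn == 0) next
    f1s <- c(f1s, 2 * tp / (2 * tp + fp + fn))
  }
  if (!length(f1s)) 1 else mean(f1s)
}

oracle_one_error <- function(scores, truth) {
  miss <- c()
  for (i in seq_len(nrow(scores))) {
    if (sum(truth[i, ]) == 0) next
    miss <- c(miss, truth[i, which.max(scores[i, ])] == 0)
  }
  mean(miss)
}

oracle_ranking_loss <- function(scores, truth) {
  per <- c()
  for (i in seq_len(nrow(scores))) {
    rel <- which(truth[i, ] == 1); irr <- which(truth[i, ] == 0)
    if (!length(rel) || !length(irr)) next
    s <- 0
    for (a in rel) for (b in irr)
      s <- s + (scores[i, a] < scores[i, b]) +
        0.5 * (scores[i, a] == scores[i, b])
    per <- c(per, s / (length(rel) * length(irr)))
  }
  mean(per)
}

oracle_coverage <- function(scores, truth) {
  per <- c()
  for (i in seq_len(nrow(scores))) {
    rel <- which(truth[i, ] == 1)
    if (!length(rel)) next
    worst <- min(scores[i, rel])
    per <- c(per, sum(scores[i, ] >= worst) - 1)
  }
  mean(per)
}

random_label_instance <- function() {
  n <- sample(2:6, 1); L <- sample(2:6, 1)
  scores <- matrix(round(stats::runif(n * L), 2), n, L)  # rounded => ties
  truth <- matrix(stats::rbinom(n * L, 1, 0.4), n, L)
  for (i in seq_len(n)) {           # ensure >=1 relevant and >=1 irrelevant
    if (sum(truth[i, ]) == 0) truth[i, sample(L, 1)] <- 1
    if (sum(truth[i, ]) == L) truth[i, sample(L, 1)] <- 0
  }
  list(scores = scores, truth = truth)
}

# small trained model shared by expensive tests (built once per session)
tiny_world <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    spec <- generator_spec(seed = 11L, n_units_per_category = 12L,
                           diag_vocab_size = 10L, symptom_vocab_size = 12L)
    bundle <- gen_corpora(spec)
    units <- gen_training_units(spec, bundle)
    model <- train_pdcm(units, bundle$corpora,
                        train_config(seed = 11L, max_epochs = 15L,
                                     patience = 15L))
    cache <<- list(spec = spec, bundle = bundle, units = units,
                   model = model)
    cache
  }
})
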