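# TF-IWF term weighting and the symptom weight matrix (SWM).
#
# Each of the six disease categories (the five Padua disease items plus
# "others") carries a symptom corpus: a bag of symptom terms with
# occurrence counts.  TF measures how frequent a symptom is within one
# category's corpus; IWF down-weights symptoms that are common across the
# pooled corpus; their product TI scores how characteristic a symptom is
# of a category.  The SWM of a symptom list is the length-6 vector of
# max-normalized TI contributions summed over the list.

N_CATEGORIES <- 6L

#' Category labels used by the classifier branch
#'
#' Categories 1..5 are the Padua disease items; category 6 is the
#' catch-all negative class `"others"`.
#' @return Character vector of length 6.
#' @export
category_ids <- function() c(padua_disease_ids(), "others")

#' Construct a set of category symptom corpora
#'
#' @param counts A list of up to 6 named numeric vectors, one per
#'   category in [category_ids()] order: names are symptom terms, values
#'   are non-negative occurrence counts.  Missing/NULL entries are empty
#'   corpora.
#' @return A `symptom_corpora` object (list of 6 named numeric vectors).
#' @export
symptom_corpora <- function(counts) {
  stopifnot(is.list(counts), length(counts) <= N_CATEGORIES)
  out <- vector("list", N_CATEGORIES)
  for (k in seq_len(N_CATEGORIES)) {
    v <- if (k <= length(counts) && !is.null(counts[[k]])) counts[[k]] else numeric()
    if (length(v)) {
      if (is.null(names(v)) || any(!nzchar(names(v))))
        stop("corpus ", k, ": term counts must be named")
      if (any(v < 0)) stop("corpus ", k, ": counts must be non-negative")
      v <- tapply(as.numeric(v), names(v), sum)  # merge duplicate terms
      v <- stats::setNames(as.numeric(v), names(v))
    }
    out[[k]] <- v
  }
  names(out) <- category_ids()
  structure(out, class = "symptom_corpora")
}

#' Pool category corpora into the global symptom corpus
#' @param corpora A [symptom_corpora()] object.
#' @return Named numeric vector of pooled term counts.
#' @export
global_corpus <- function(corpora) {
  all_terms <- unlist(lapply(corpora, names), use.names = FALSE)
  all_counts <- unlist(lapply(corpora, unname), use.names = FALSE)
  if (!length(all_terms)) return(numeric())
  v <- tapply(all_counts, all_terms, sum)
  stats::setNames(as.numeric(v), names(v))
}

#' Term frequency of a symptom within one category corpus
#'
#' `TF = N[k,t] / count(N[k])`: the occurrence count of term `t` in the
#' category's corpus over the corpus's total count.  Absent terms have
#' TF 0.
#'
#' @param term Symptom term (single string).
#' @param corpus Named numeric vector of term counts for one category.
#' @return TF in `[0, 1]`.
#' @export
tf <- function(term, corpus) {
  total <- sum(corpus)
  if (!length(corpus) || total <= 0) stop("empty corpus: TF undefined")
  n <- unname(corpus[term])
  if (is.na(n)) n <- 0
  as.numeric(n) / total
}

#' Inverse word frequency of a symptom over the pooled corpus
#'
#' `IWF = log(W_c / W[c,t])`: log of the pooled total count over the
#' term's pooled count.  Defined only for terms present in the pool.
#'
#' @param term Symptom term.
#' @param global Named numeric vector of pooled counts (see
#'   [global_corpus()]).
#' @param base Logarithm base; natural log by default.  The choice
#'   cancels in the max-normalized SWM.
#' @return Non-negative real.
#' @export
iwf <- function(term, global, base = exp(1)) {
  w_ct <- if (length(global)) unname(global[term]) else NA_real_
  if (is.na(w_ct) || w_ct <= 0)
    stop("term absent from the global corpus: IWF undefined for '", term, "'")
  log(sum(global) / w_ct, base = base)
}

#' TF-IWF score of a symptom for one category
#'
#' `TI = TF x IWF`; 0 when the term is absent from the category corpus.
#'
#' @param term Symptom term.
#' @param category Category index 1..6 or id from [category_ids()].
#' @param corpora A [symptom_corpora()] object.
#' @inheritParams iwf
#' @return Non-negative real.
#' @export
ti <- function(term, category, corpora, base = exp(1)) {
  k <- resolve_category(category)
  corpus <- corpora[[k]]
  if (!length(corpus) || !(term %in% names(corpus)) || corpus[[term]] == 0)
    return(0)
  tf(term, corpus) * iwf(term, global_corpus(corpora), base = base)
}

resolve_category <- function(category) {
  if (is.character(category)) {
    k <- match(category, category_ids())
    if (is.na(k)) stop("unknown category id: ", category)
    return(k)
  }
  k <- as.integer(category)
  if (is.na(k) || k < 1L || k > N_CATEGORIES) stop("category out of range")
  k
}

#' Precompute SWM statistics for a corpus set
#'
#' Tabulates every category's TI scores and per-category TI maximum so
#' that SWM construction is a lookup.  This is the object serialized with
#' a trained model.
#'
#' @inheritParams ti
#' @return An `swm_stats` object: list with `ti` (list of 6 named numeric
#'   vectors) and `ti_max` (numeric length 6).
#' @export
swm_stats <- function(corpora, base = exp(1)) {
  if (!inherits(corpora, "symptom_corpora")) corpora <- symptom_corpora(corpora)
  global <- global_corpus(corpora)
  w_c <- sum(global)
  ti_tab <- vector("list", N_CATEGORIES)
  ti_max <- numeric(N_CATEGORIES)
  for (k in seq_len(N_CATEGORIES)) {
    corpus <- corpora[[k]]
    corpus <- corpus[corpus > 0]
    if (!length(corpus)) { ti_tab[[k]] <- numeric(); next }
    tf_k <- corpus / sum(corpus)
    iwf_k <- log(w_c / global[names(corpus)], base = base)
    ti_tab[[k]] <- tf_k * iwf_k
    ti_max[k] <- max(ti_tab[[k]])
  }
  names(ti_tab) <- category_ids()
  structure(list(ti = ti_tab, ti_max = ti_max), class = "swm_stats")
}

#' Build the symptom weight vector for a symptom list
#'
#' Starting from six zeros, each symptom adds, to every category whose
#' corpus contains it, its TI score normalized by that category's maximum
#' TI.  Unknown symptoms contribute nothing; a category whose maximum TI
#' is 0 contributes 0 (the 0/0 guard).
#'
#' @param symptoms Character vector of symptom terms (may be empty).
#' @param corpora A [symptom_corpora()] object, or a precomputed
#'   [swm_stats()] object.
#' @param dedupe Drop duplicate symptoms first?  Defaults to `TRUE` for
#'   patient-level use, where extracted symptom sets are deduplicated.
#' @inheritParams iwf
#' @return Numeric vector of length 6 (named by [category_ids()]).
#' @examples
#' corp <- symptom_corpora(list(c(fever = 2, cough = 1), c(cough = 1)))
#' build_swm("cough", corp)  # c(0.5, 1, 0, 0, 0, 0)
#' @export
build_swm <- function(symptoms, corpora, dedupe = TRUE, base = exp(1)) {
  stats_obj <- if (inherits(corpora, "swm_stats")) corpora
               else swm_stats(corpora, base = base)
  symptoms <- as.character(symptoms)
  if (dedupe) symptoms <- unique(symptoms)
  swm <- stats::setNames(numeric(N_CATEGORIES), category_ids())
  if (!length(symptoms)) return(swm)
  for (k in seq_len(N_CATEGORIES)) {
    tab <- stats_obj$ti[[k]]
    mx <- stats_obj$ti_max[k]
    if (!length(tab) || mx <= 0) next
    hit <- symptoms[symptoms %in% names(tab)]
    if (length(hit)) swm[k] <- sum(tab[hit] / mx)
  }
  swm
}

#' Read category symptom corpora from a TSV file
#'
#' Format: `term <TAB> category-index <TAB> count`, category indices
#' 1..6, `#` comment lines ignored.
#'
#' @param path TSV path (UTF-8).
#' @return A [symptom_corpora()] object.
#' @export
read_corpora_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                          comment.char = "#", fileEncoding = "UTF-8",
                          col.names = c("term", "category", "count"),
                          stringsAsFactors = FALSE)
  counts <- lapply(seq_len(N_CATEGORIES), function(k) {
    sub <- df[df$category == k, , drop = FALSE]
    if (!nrow(sub)) return(numeric())
    stats::setNames(as.numeric(sub$count), sub$term)
  })
  symptom_corpora(counts)
}

#' @rdname read_corpora_tsv
#' @param corpora A [symptom_corpora()] object to write.
#' @export
write_corpora_tsv <- function(corpora, path) {
  rows <- do.call(rbind, lapply(seq_len(N_CATEGORIES), function(k) {
    v <- corpora[[k]]
    if (!length(v)) return(NULL)
    data.frame(term = names(v), category = k, count = as.numeric(v))
  }))
  utils::write.table(rows, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
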