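# End-to-end orchestration: EMR record in, Branch B extraction, Branch A
# prediction, 11 item flags with provenance, Padua total and risk level;
# batch evaluation against gold labels.

#' Assessment options
#'
#' @param window_days Surgery look-back window (30).
#' @param calendar_month Calendar-month window mode (see
#'   [recent_surgery_flag()]).
#' @param negation_window Token window for negation scope (`Inf` =
#'   whole clause).
#' @param lab_thresholds See [default_lab_thresholds()].
#' @param cutoff,three_level See [stratify()].
#' @param scale Scale definition ([default_scale()]).
#' @return An options list.
#' @export
assess_options <- function(window_days = 30L, calendar_month = FALSE,
                           negation_window = Inf,
                           lab_thresholds = default_lab_thresholds(),
                           cutoff = 3L, three_level = FALSE,
                           scale = default_scale()) {
  list(window_days = as.integer(window_days),
       calendar_month = calendar_month,
       negation_window = negation_window,
       lab_thresholds = lab_thresholds, cutoff = as.integer(cutoff),
       three_level = three_level, scale = scale)
}

#' Assess one EMR record
#'
#' Branch B extracts the patient's symptoms, the three lexicon-rule flags
#' (recent surgery with its time window, reduced mobility, hormonal
#' treatment) and the three numeric flags (elderly, obesity,
#' thrombophilia); Branch A classifies each diagnosis with the extracted
#' symptoms into the five disease items.  The eleven flags are scored
#' and stratified.
#'
#' @param record An [emr_record()].
#' @param model A trained `pdcm_model` (or `NULL` to run Branch B only).
#' @param lexicons A [lexicon_set()].
#' @param opts An [assess_options()] list.
#' @return A `risk_assessment` with attributes `category_scores` (the 6
#'   per-category maxima from Branch A) and `symptoms` (the extracted
#'   symptom list).
#' @export
assess <- function(record, model, lexicons, opts = assess_options()) {
  stopifnot(inherits(record, "emr_record"))
  matches <- extract_record_matches(record, lexicons,
                                    negation_window = opts$negation_window)
  symptoms <- unique(matches$term[matches$lexicon_name == "symptom" &
                                  !matches$negated])

  fl <- logical(); prov <- list()
  put <- function(id, flag) {
    fl[[id]] <<- as.logical(flag)
    if (isTRUE(as.logical(flag))) prov[[id]] <<- attr(flag, "evidence")
  }
  put("recent_surgery_trauma",
      recent_surgery_flag(matches, opts$window_days, record$record_date,
                          opts$calendar_month))
  put("reduced_mobility", reduced_mobility_flag(matches))
  put("hormonal", hormone_flag(matches))
  put("elderly", elderly_flag(record$age_years))
  put("obesity", obesity_flag(record$height_m, record$weight_kg))
  put("thrombophilic", thrombophilia_flag(record$labs, opts$lab_thresholds))

  scores <- stats::setNames(numeric(6L), category_ids())
  if (!is.null(model)) {
    pr <- predict_patient(model, record$diagnoses, symptoms)
    scores <- pr$scores
    for (id in padua_disease_ids()) {
      flag <- pr$flags[[id]]
      if (flag) {
        hit <- which(pr$unit_categories == id)
        attr(flag, "evidence") <-
          sprintf("diagnosis '%s' classified as %s",
                  record$diagnoses[hit], id)
      }
      put(id, flag)
    }
  }

  out <- risk_assessment(item_flags(fl, prov), scale = opts$scale,
                         cutoff = opts$cutoff,
                         three_level = opts$three_level)
  attr(out, "category_scores") <- scores
  attr(out, "symptoms") <- symptoms
  attr(out, "record_id") <- record$record_id
  out
}

#' Assess a batch of records and evaluate against gold flags
#'
#' Every record must carry `gold_flags`.  Records failing schema
#' validation are rejected with a message and the batch continues.
#'
#' @param records List of [emr_record()]s with gold flags.
#' @param model,lexicons,opts As in [assess()].
#' @return An `assessment_report`: list with `assessments`,
#'   `item_table` (per-item predicted/gold counts and AUC where both
#'   outcomes occur), `risk` (sensitivity/specificity/precision of the
#'   high-risk call plus the total-score AUC), and `errors`.
#' @export
evaluate_batch <- function(records, model, lexicons,
                           opts = assess_options()) {
  if (!length(records)) stop("no records")
  has_gold <- vapply(records, function(r) !is.null(r$gold_flags), logical(1))
  if (!all(has_gold)) stop("every record needs gold_flags for evaluation")

  assessments <- list(); errors <- character()
  for (r in records) {
    a <- tryCatch(assess(r, model, lexicons, opts),
                  error = function(e) e)
    if (inherits(a, "error")) {
      errors <- c(errors, paste0(r$record_id, ": ", conditionMessage(a)))
    } else assessments[[length(assessments) + 1L]] <- a
  }
  kept <- vapply(assessments, function(a) attr(a, "record_id"), character(1))
  gold <- records[match(kept, vapply(records, `[[`, character(1),
                                     "record_id"))]

  ids <- padua_item_ids()
  pred_m <- t(vapply(assessments, function(a) a$flags$flags, logical(11L)))
  gold_m <- t(vapply(gold, function(r) r$gold_flags$flags, logical(11L)))
  colnames(pred_m) <- colnames(gold_m) <- ids
  score_m <- t(vapply(assessments, function(a) {
    cs <- attr(a, "category_scores")
    c(cs[1:5], as.numeric(a$flags$flags[6:11]))
  }, numeric(11L)))
  colnames(score_m) <- ids

  item_table <- do.call(rbind, lapply(ids, function(id) {
    g <- gold_m[, id]; p <- pred_m[, id]
    auc <- if (any(g) && !all(g)) metric_auc(score_m[, id], g) else NA_real_
    data.frame(item = id, n_gold = sum(g), n_pred = sum(p),
               agreement = mean(p == g), auc = auc,
               stringsAsFactors = FALSE)
  }))

  pred_total <- vapply(assessments, `[[`, numeric(1), "total")
  gold_total <- vapply(gold, function(r)
    total_score(r$gold_flags, opts$scale), numeric(1))
  pred_high <- pred_total >= opts$cutoff
  gold_high <- gold_total >= opts$cutoff
  risk <- binary_panel(pred_high, gold_high)
  risk$auc <- if (any(gold_high) && !all(gold_high))
    metric_auc(pred_total, gold_high) else NA_real_
  risk$level_accuracy <- mean(
    vapply(pred_total, stratify, character(1), cutoff = opts$cutoff,
           three_level = TRUE) ==
    vapply(gold_total, stratify, character(1), cutoff = opts$cutoff,
           three_level = TRUE))

  structure(list(assessments = assessments, item_table = item_table,
                 risk = risk, errors = errors,
                 pred_flags = pred_m, gold_flags = gold_m),
            class = "assessment_report")
}

#' @export
print.assessment_report <- function(x, ...) {
  cat("Batch assessment over", length(x$assessments), "records",
      if (length(x$errors)) paste0("(", length(x$errors), " rejected)"),
      "\n")
  print(x$item_table, row.names = FALSE)
  cat(sprintf("risk (high vs low): sens %.3f  spec %.3f  prec %.3f  AUC %s\n",
              x$risk$sensitivity, x$risk$specificity, x$risk$precision,
              ifelse(is.na(x$risk$auc), "NA",
                     sprintf("%.3f", x$risk$auc))))
  invisible(x)
}
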