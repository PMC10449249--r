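# Branch B: clinical-factor extraction from EMR records — lexicon matches
# with negation filtering, the 30-day surgery window, and numeric rules.

SECTION_NAMES <- c("past_history", "complaints", "examination",
                   "treatment_plan")

#' Construct a laboratory panel for the thrombophilia rule
#'
#' @param protein_c,protein_s,antithrombin_iii Activity percentages
#'   (optional).
#' @param d_dimer Concentration in mg/L (optional).
#' @return A `lab_panel` object (list; absent values are `NA`).
#' @export
lab_panel <- function(protein_c = NA_real_, protein_s = NA_real_,
                      antithrombin_iii = NA_real_, d_dimer = NA_real_) {
  vals <- list(protein_c = protein_c, protein_s = protein_s,
               antithrombin_iii = antithrombin_iii, d_dimer = d_dimer)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.na(v) && v < 0) stop("lab value must be non-negative: ", nm)
  }
  structure(lapply(vals, as.numeric), class = "lab_panel")
}

#' Construct an EMR record
#'
#' One patient's document: a structured diagnosis list, narrative
#' sections, structured numerics and the record date.  At least one of
#' `diagnoses`/`sections` must be non-empty.
#'
#' @param record_id Identifier string.
#' @param record_date `Date` (or ISO-8601 string) the record was written;
#'   the reference for relative time expressions and the surgery window.
#' @param diagnoses Character vector of diagnosis strings.
#' @param sections Named list of narrative texts; recognised names are
#'   `past_history`, `complaints`, `examination`, `treatment_plan`.
#' @param age_years,height_m,weight_kg Optional numerics.
#' @param labs A [lab_panel()].
#' @param gold_flags Optional [item_flags()] gold standard.
#' @return An `emr_record` object.
#' @export
emr_record <- function(record_id, record_date, diagnoses = character(),
                       sections = list(), age_years = NA_real_,
                       height_m = NA_real_, weight_kg = NA_real_,
                       labs = lab_panel(), gold_flags = NULL) {
  record_date <- as.Date(record_date)
  if (is.na(record_date)) stop("record_date is required")
  sections <- sections[vapply(sections, function(s)
    !is.null(s) && nzchar(s), logical(1))]
  if (!length(diagnoses) && !length(sections))
    stop("record needs at least one diagnosis or narrative section")
  if (length(sections) && (is.null(names(sections)) ||
                           !all(names(sections) %in% SECTION_NAMES)))
    stop("section names must be among: ",
         paste(SECTION_NAMES, collapse = ", "))
  if (!is.na(height_m) && height_m <= 0)
    stop("height must be positive")
  structure(list(record_id = as.character(record_id),
                 record_date = record_date,
                 diagnoses = as.character(diagnoses),
                 sections = lapply(sections, as.character),
                 age_years = as.numeric(age_years),
                 height_m = as.numeric(height_m),
                 weight_kg = as.numeric(weight_kg),
                 labs = if (inherits(labs, "lab_panel")) labs
                        else do.call(lab_panel, as.list(labs)),
                 gold_flags = gold_flags),
            class = "emr_record")
}

#' Run segmentation + matching + negation + date anchoring over a record
#'
#' Every narrative section is sentence-split; each sentence is segmented
#' against the lexicon set; matches from the four matching lexicons are
#' negation-filtered and date-anchored against the record date.
#'
#' @param record An [emr_record()].
#' @param lexicons A [lexicon_set()].
#' @param negation_window Token window for [filter_negated()].
#' @return A `data.frame` of matches across all sections with extra
#'   columns `section` and `sentence` (the matched sentence text).
#' @export
extract_record_matches <- function(record, lexicons, negation_window = Inf) {
  stopifnot(inherits(record, "emr_record"), inherits(lexicons, "lexicon_set"))
  match_lex <- lexicons[c("surgery_trauma", "hormone", "reduced_mobility",
                          "symptom")]
  out <- list()
  sent_counter <- 0L
  for (sec in names(record$sections)) {
    for (sentence in split_sentences(record$sections[[sec]])) {
      sent_counter <- sent_counter + 1L
      tokens <- segment(sentence, lexicons)
      for (lex in match_lex) {
        m <- match_corpus(tokens, lex, sentence_index = sent_counter)
        if (!nrow(m)) next
        m <- filter_negated(m, tokens, window = negation_window)
        m <- anchor_dates(m, tokens, reference_date = record$record_date)
        m$section <- sec
        m$sentence <- sentence
        out[[length(out) + 1L]] <- m
      }
    }
  }
  if (!length(out))
    return(cbind(match_corpus(empty_tokens(), lexicons$symptom),
                 data.frame(section = character(), sentence = character())))
  do.call(rbind, out)
}

#' Recent (<= 1 month) trauma/surgery flag
#'
#' Fires when a non-negated surgery/trauma match carries an anchored date
#' within `window_days` before the reference date (inclusive on both
#' ends).  Undated mentions never fire the flag.
#'
#' @param matches Surgery/trauma matches (negation-filtered,
#'   date-anchored).
#' @param window_days Window length; 30 by default ("one month").
#' @param reference_date The record date.
#' @param calendar_month Use calendar-month arithmetic (date on/after the
#'   same day-of-month one month earlier) instead of a fixed day count.
#' @return Logical flag with attribute `"evidence"`.
#' @export
recent_surgery_flag <- function(matches, window_days = 30L,
                                reference_date, calendar_month = FALSE) {
  matches <- matches[matches$lexicon_name == "surgery_trauma" &
                     !matches$negated & !is.na(matches$anchored_date), ,
                     drop = FALSE]
  if (!nrow(matches)) return(flag_with_evidence(FALSE, character()))
  ref <- as.Date(reference_date)
  lower <- if (calendar_month) subtract_months(ref, 1L) else ref - window_days
  hit <- matches$anchored_date >= lower & matches$anchored_date <= ref
  ev <- sprintf("%s on %s", matches$term[hit],
                format(matches$anchored_date[hit]))
  flag_with_evidence(any(hit), ev)
}

flag_with_evidence <- function(flag, evidence) {
  structure(flag, evidence = as.character(evidence))
}

any_match_flag <- function(matches, lex_name) {
  m <- matches[matches$lexicon_name == lex_name & !matches$negated, ,
               drop = FALSE]
  flag_with_evidence(nrow(m) > 0L, unique(m$term))
}

#' Reduced-mobility and hormonal-treatment flags
#'
#' True iff at least one non-negated match from the respective lexicon.
#'
#' @param matches Negation-filtered matches from
#'   [extract_record_matches()].
#' @return Logical flag with attribute `"evidence"`.
#' @export
reduced_mobility_flag <- function(matches) {
  any_match_flag(matches, "reduced_mobility")
}

#' @rdname reduced_mobility_flag
#' @export
hormone_flag <- function(matches) any_match_flag(matches, "hormone")

#' Numeric rules: elderly age and obesity
#'
#' Elderly: age >= 70 years.  Obesity: BMI = weight / height^2 >= 30
#' kg/m^2.  Missing inputs yield `FALSE` with a "missing data" note.
#'
#' @param age_years Age in years (may be `NA`).
#' @param threshold Rule threshold (70 years / 30 kg/m^2).
#' @return Logical flag with attribute `"evidence"`.
#' @export
elderly_flag <- function(age_years, threshold = 70) {
  if (is.null(age_years) || is.na(age_years))
    return(flag_with_evidence(FALSE, "missing data: age"))
  flag_with_evidence(age_years >= threshold,
                     sprintf("age %.0f years", age_years))
}

#' @rdname elderly_flag
#' @param height_m Height in meters (must be positive when present).
#' @param weight_kg Weight in kilograms.
#' @export
obesity_flag <- function(height_m, weight_kg, threshold = 30) {
  if (is.null(height_m) || is.null(weight_kg) ||
      is.na(height_m) || is.na(weight_kg))
    return(flag_with_evidence(FALSE, "missing data: height/weight"))
  if (height_m <= 0) stop("height must be positive")
  bmi <- weight_kg / height_m^2
  flag_with_evidence(bmi >= threshold, sprintf("BMI %.2f kg/m2", bmi))
}

#' Default thrombophilia lab thresholds
#'
#' Reference bounds for the laboratory rule.  These are configurable
#' package defaults (activity below the bound for protein C, protein S
#' and antithrombin III; d-dimer above the bound), not published
#' constants.
#'
#' @return Named list: `protein_c` 70, `protein_s` 60,
#'   `antithrombin_iii` 80 (activity %), `d_dimer` 0.5 (mg/L).
#' @export
default_lab_thresholds <- function() {
  list(protein_c = 70, protein_s = 60, antithrombin_iii = 80, d_dimer = 0.5)
}

#' Thrombophilia flag from the laboratory panel
#'
#' True iff any present lab crosses its pathological bound: protein C,
#' protein S or antithrombin III activity below their lower bounds, or
#' d-dimer above its upper bound.  An all-absent panel is `FALSE`.
#'
#' @param labs A [lab_panel()].
#' @param thresholds See [default_lab_thresholds()].
#' @return Logical flag with attribute `"evidence"`.
#' @export
thrombophilia_flag <- function(labs, thresholds = default_lab_thresholds()) {
  ev <- character()
  low <- c("protein_c", "protein_s", "antithrombin_iii")
  for (nm in low) {
    v <- labs[[nm]]
    if (!is.na(v) && v < thresholds[[nm]])
      ev <- c(ev, sprintf("%s %.1f%% < %.1f%%", nm, v, thresholds[[nm]]))
  }
  v <- labs$d_dimer
  if (!is.na(v) && v > thresholds$d_dimer)
    ev <- c(ev, sprintf("d_dimer %.2f mg/L > %.2f mg/L", v,
                        thresholds$d_dimer))
  flag_with_evidence(length(ev) > 0L, ev)
}

#' Extract the patient's symptom list for the classifier branch
#'
#' Deduplicated, non-negated symptom-lexicon matches across all narrative
#' sections, in first-occurrence order.
#'
#' @param record An [emr_record()].
#' @param lexicons A [lexicon_set()] (its `symptom` and `negation`
#'   members are used).
#' @param negation_window Token window for [filter_negated()].
#' @return Character vector of symptom terms.
#' @export
extract_symptoms <- function(record, lexicons, negation_window = Inf) {
  m <- extract_record_matches(record, lexicons,
                              negation_window = negation_window)
  unique(m$term[m$lexicon_name == "symptom" & !m$negated])
}
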