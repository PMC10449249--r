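# Padua scale: item definitions, scoring, risk stratification.

#' Padua item identifiers
#'
#' The eleven canonical item ids of the Padua prediction score, in display
#' order.  Five items are disease categories decided by the classifier
#' branch; the remainder come from lexicon rules or numeric rules.
#'
#' @return Character vector of length 11.
#' @export
padua_item_ids <- function() {
  c("prior_vte", "active_cancer", "heart_resp_failure", "mi_stroke",
    "infection_rheum", "elderly", "obesity", "hormonal", "thrombophilic",
    "reduced_mobility", "recent_surgery_trauma")
}

#' The five disease-category item ids handled by Branch A
#' @return Character vector of length 5.
#' @export
padua_disease_ids <- function() {
  c("prior_vte", "active_cancer", "heart_resp_failure", "mi_stroke",
    "infection_rheum")
}

#' Default Padua scale definition
#'
#' Returns the standard 11-item Padua scale with its published integer
#' weights: prior VTE 3, active cancer 3, heart/respiratory failure 1,
#' acute MI/ischemic stroke 1, acute infection or rheumatologic disorder 1,
#' elderly age (>= 70 years) 1, BMI >= 30 kg/m^2 1, ongoing hormonal
#' treatment 1, thrombophilic condition 3, reduced mobility 3, recent
#' (<= 1 month) trauma and/or surgery 2.  The weights sum to 20.
#'
#' @return A `data.frame` with columns `id`, `label`, `points`, `source`
#'   (one of `"branch_a"`, `"branch_b_rules"`, `"branch_b_numeric"`).
#' @examples
#' sc <- default_scale()
#' sum(sc$points)  # 20
#' @export
default_scale <- function() {
  df <- data.frame(
    id = padua_item_ids(),
    label = c("Prior VTE", "Active cancer", "Heart/respiratory failure",
              "Acute MI/ischemic stroke",
              "Acute infection/rheumatologic disorder",
              "Elderly age (>=70 years)", "BMI >=30 kg/m2",
              "Ongoing hormonal treatment", "Thrombophilic",
              "Reduced mobility", "Recent (<=1 month of) trauma and/or surgery"),
    points = c(3L, 3L, 1L, 1L, 1L, 1L, 1L, 1L, 3L, 3L, 2L),
    source = c(rep("branch_a", 5L), "branch_b_numeric", "branch_b_numeric",
               "branch_b_rules", "branch_b_numeric", "branch_b_rules",
               "branch_b_rules"),
    stringsAsFactors = FALSE
  )
  class(df) <- c("padua_scale", "data.frame")
  df
}

validate_scale <- function(scale) {
  stopifnot(is.data.frame(scale),
            all(c("id", "label", "points") %in% names(scale)))
  if (!setequal(scale$id, padua_item_ids()) || anyDuplicated(scale$id))
    stop("scale must contain each of the 11 Padua item ids exactly once")
  if (!all(scale$points %in% 1:3))
    stop("item points must be integers in {1,2,3}")
  invisible(scale)
}

#' Construct an item-flag set
#'
#' @param flags Named logical vector (names are item ids); missing items
#'   default to `FALSE`.
#' @param provenance Named list of character vectors of evidence strings;
#'   every `TRUE` flag must carry at least one evidence string.
#' @return An `item_flags` object: list with elements `flags` (named
#'   logical, all 11 ids) and `provenance`.
#' @export
item_flags <- function(flags = NULL, provenance = list()) {
  ids <- padua_item_ids()
  out <- stats::setNames(rep(FALSE, length(ids)), ids)
  if (!is.null(flags) && length(flags)) {
    if (is.null(names(flags)) || !all(names(flags) %in% ids))
      stop("flags must be named with Padua item ids")
    out[names(flags)] <- as.logical(flags)
  }
  prov <- stats::setNames(vector("list", length(ids)), ids)
  for (id in names(provenance)) {
    if (!id %in% ids) stop("unknown item id in provenance: ", id)
    prov[[id]] <- as.character(provenance[[id]])
  }
  for (id in ids[out]) {
    if (length(prov[[id]]) == 0L)
      prov[[id]] <- "flag set without explicit evidence"
  }
  structure(list(flags = out, provenance = prov), class = "item_flags")
}

as_item_flags <- function(x) {
  if (inherits(x, "item_flags")) return(x)
  if (is.logical(x)) return(item_flags(x))
  stop("cannot coerce to item_flags")
}

#' Total Padua score
#'
#' Sum of the weights of all items flagged present.
#'
#' @param flags An [item_flags()] object or named logical vector covering
#'   all 11 item ids.
#' @param scale Scale definition, default [default_scale()].
#' @return Integer total in `[0, 20]` for the default scale.
#' @export
total_score <- function(flags, scale = default_scale()) {
  validate_scale(scale)
  fl <- if (inherits(flags, "item_flags")) flags$flags else flags
  if (is.null(names(fl)) || !setequal(names(fl), scale$id))
    stop("flags must cover all 11 Padua item ids")
  sum(scale$points[match(names(fl)[fl], scale$id)])
}

#' Stratify a Padua total score into a risk level
#'
#' Scores at or above the cutoff are high risk; below it, low risk.  A
#' total equal to the cutoff is treated as high risk (the conservative
#' clinical reading); lower the cutoff or raise it to obtain the strict
#' `> cutoff` reading.  In three-level mode a total of exactly 0 is
#' reported as its own stratum, `"score_zero"`.
#'
#' @param total Non-negative integer score.
#' @param cutoff Risk threshold, default 3.
#' @param three_level Report `"score_zero"` for totals of 0?
#' @return One of `"score_zero"`, `"low"`, `"high"`.
#' @export
stratify <- function(total, cutoff = 3L, three_level = FALSE) {
  if (length(total) != 1L || is.na(total) || total < 0)
    stop("total must be a single non-negative number")
  if (three_level && total == 0) return("score_zero")
  if (total >= cutoff) "high" else "low"
}

#' Assemble a risk assessment from item flags
#'
#' @inheritParams total_score
#' @inheritParams stratify
#' @return A `risk_assessment` object: list with `flags`, `total`, `level`.
#' @export
risk_assessment <- function(flags, scale = default_scale(), cutoff = 3L,
                            three_level = FALSE) {
  flags <- as_item_flags(flags)
  total <- total_score(flags, scale)
  structure(list(flags = flags, total = total,
                 level = stratify(total, cutoff, three_level)),
            class = "risk_assessment")
}

#' @export
print.risk_assessment <- function(x, ...) {
  cat("Padua risk assessment: total =", x$total, "| level =", x$level, "\n")
  on <- names(x$flags$flags)[x$flags$flags]
  if (length(on)) {
    for (id in on)
      cat("  +", id, ":", paste(x$flags$provenance[[id]], collapse = "; "),
          "\n")
  } else cat("  (no items present)\n")
  invisible(x)
}

#' Export / import a scale definition as JSON
#'
#' The JSON document is a list of `{id, label, points, source}` objects so
#' localized labels can be swapped without code changes.
#'
#' @param scale A scale `data.frame` as from [default_scale()].
#' @param path File path.
#' @return `read_scale_json` returns the validated scale `data.frame`.
#' @export
write_scale_json <- function(scale, path) {
  validate_scale(scale)
  jsonlite::write_json(as.data.frame(scale), path, auto_unbox = FALSE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_scale_json
#' @export
read_scale_json <- function(path) {
  df <- jsonlite::read_json(path, simplifyVector = TRUE)
  df$points <- as.integer(df$points)
  df <- df[match(padua_item_ids(), df$id), , drop = FALSE]
  rownames(df) <- NULL
  validate_scale(df)
  class(df) <- c("padua_scale", "data.frame")
  df
}
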