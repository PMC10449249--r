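# Lexicon-intervened segmentation, corpus matching, negation filtering and
# temporal anchoring for Branch B.
#
# The default segmenter is a self-contained greedy longest-match scanner
# over the union of the loaded lexicons plus date/time patterns, so the
# package runs with no model downloads.  An external lexical analyzer can
# replace it behind the same token contract (surface, pos, span).

TIME_PATTERNS <- c(
  # "On April 16, 2021" / "April 16, 2021"
  paste0("(?:[Oo]n )?(?:January|February|March|April|May|June|July|August|",
         "September|October|November|December) \\d{1,2}, \\d{4}"),
  "\\d{4}-\\d{1,2}-\\d{1,2}",                 # ISO-8601
  "\\d{4}\u5e74\\d{1,2}\u6708\\d{1,2}\u65e5", # CJK year-month-day
  "\\d+ (?:day|week|month|year)s? ago"
)

CLAUSE_DELIMS <- c(",", ";", "\uff0c", "\uff1b", "\u3001")
SENTENCE_SPLIT_RE <-
  "[\u3002\uff0e!?\uff01\uff1f;\uff1b\n]|\\.(?!\\d)"

empty_tokens <- function(sentence = "") {
  structure(data.frame(surface = character(), pos = character(),
                       start = integer(), end = integer(),
                       stringsAsFactors = FALSE),
            sentence = sentence)
}

# TRUE when position i (1-based, 0 = outside) borders an ASCII alnum char,
# used to require word boundaries for alphabetic lexicon entries.
is_alnum_at <- function(chars, i) {
  if (i < 1L || i > length(chars)) return(FALSE)
  grepl("[A-Za-z0-9]", chars[i])
}

#' Segment a sentence with intervening lexicons
#'
#' Greedy longest-match segmentation: date/time expressions become `TIME`
#' tokens; entries of the matching lexicons become `TERM` tokens; entries
#' of the negation lexicon become `NEG` tokens; the remaining spans are
#' whitespace-split into `OTHER` tokens.  At a given start position the
#' longest candidate wins, with `TIME` breaking length ties.  Entries
#' edged by ASCII letters/digits match only at word boundaries, so "no"
#' never fires inside "normal".
#'
#' @param sentence A single string (may be empty).
#' @param lexicons A [lexicon_set()], or a list of `lexicon` objects; the
#'   one named `"negation"` provides the negation cues.
#' @return A `data.frame` with columns `surface`, `pos` (one of `TERM`,
#'   `TIME`, `NEG`, `OTHER`), `start`, `end` (0-based, half-open character
#'   spans), ordered and non-overlapping; the raw sentence is attached as
#'   attribute `"sentence"`.
#' @export
segment <- function(sentence, lexicons) {
  stopifnot(is.character(sentence), length(sentence) == 1L)
  if (is.na(sentence) || !nzchar(sentence)) return(empty_tokens(sentence))
  if (inherits(lexicons, "lexicon")) lexicons <- list(lexicons)
  chars <- strsplit(sentence, "", fixed = TRUE)[[1]]
  n <- length(chars)

  starts <- integer(); lens <- integer(); poss <- character(); prio <- integer()
  add <- function(s, l, p, pr) {
    starts <<- c(starts, s); lens <<- c(lens, l)
    poss <<- c(poss, rep(p, length(s))); prio <<- c(prio, rep(pr, length(s)))
  }
  for (pat in TIME_PATTERNS) {
    m <- gregexpr(pat, sentence, perl = TRUE)[[1]]
    if (m[1] != -1L) add(as.integer(m), attr(m, "match.length"), "TIME", 1L)
  }
  for (lex in lexicons) {
    if (!inherits(lex, "lexicon")) next
    p <- if (lex$name == "negation") "NEG" else "TERM"
    for (entry in lex$entries) {
      m <- gregexpr(entry, sentence, fixed = TRUE)[[1]]
      if (m[1] == -1L) next
      s <- as.integer(m); l <- attr(m, "match.length")
      keep <- vapply(seq_along(s), function(i) {
        first <- substr(entry, 1L, 1L); last <- substr(entry, nchar(entry), nchar(entry))
        ok <- TRUE
        if (grepl("[A-Za-z0-9]", first)) ok <- ok && !is_alnum_at(chars, s[i] - 1L)
        if (grepl("[A-Za-z0-9]", last))  ok <- ok && !is_alnum_at(chars, s[i] + l[i])
        ok
      }, logical(1))
      if (any(keep)) add(s[keep], l[keep], p, 2L)
    }
  }

  acc_s <- integer(); acc_e <- integer(); acc_p <- character()
  if (length(starts)) {
    ord <- order(starts, prio, -lens)
    cursor <- 1L
    i <- 1L
    while (i <= length(ord)) {
      j <- ord[i]
      if (starts[j] >= cursor) {
        # among candidates at this exact start not yet passed, ord already
        # puts the preferred one first
        acc_s <- c(acc_s, starts[j]); acc_e <- c(acc_e, starts[j] + lens[j])
        acc_p <- c(acc_p, poss[j])
        cursor <- starts[j] + lens[j]
      }
      i <- i + 1L
    }
  }

  # fill gaps with whitespace-split OTHER tokens
  out_s <- integer(); out_e <- integer(); out_p <- character()
  bounds <- c(1L, acc_e); ends <- c(acc_s, n + 1L)
  emit_other <- function(from, to) {
    if (to < from) return()
    txt <- paste(chars[from:to], collapse = "")
    m <- gregexpr("\\S+", txt, perl = TRUE)[[1]]
    if (m[1] == -1L) return()
    s <- as.integer(m) + from - 1L; l <- attr(m, "match.length")
    out_s <<- c(out_s, s); out_e <<- c(out_e, s + l)
    out_p <<- c(out_p, rep("OTHER", length(s)))
  }
  for (g in seq_along(bounds)) emit_other(bounds[g], ends[g] - 1L)

  all_s <- c(acc_s, out_s); all_e <- c(acc_e, out_e); all_p <- c(acc_p, out_p)
  ord <- order(all_s)
  surf <- vapply(ord, function(i)
    paste(chars[all_s[i]:(all_e[i] - 1L)], collapse = ""), character(1))
  structure(data.frame(surface = surf, pos = all_p[ord],
                       start = all_s[ord] - 1L, end = all_e[ord] - 1L,
                       stringsAsFactors = FALSE),
            sentence = sentence)
}

#' Split narrative text into sentences
#'
#' Splits on CJK/ASCII sentence punctuation, semicolons and newlines; an
#' ASCII period between digits (decimal point) does not split.
#'
#' @param text A single string.
#' @return Character vector of trimmed, non-empty sentences.
#' @export
split_sentences <- function(text) {
  if (is.null(text) || is.na(text) || !nzchar(text)) return(character())
  parts <- strsplit(text, SENTENCE_SPLIT_RE, perl = TRUE)[[1]]
  parts <- trimws(parts)
  parts[nzchar(parts)]
}

#' Match segmented tokens against a lexicon
#'
#' @param tokens Token `data.frame` from [segment()].
#' @param lex The `lexicon` to match (`TERM` tokens only).
#' @param sentence_index Integer tag recorded on each match.
#' @return A `data.frame` of matches: `term`, `lexicon_name`,
#'   `sentence_index`, `negated` (all `FALSE` initially), `anchored_date`
#'   (`Date`, `NA` initially), `token_row` (row in `tokens`).
#' @export
match_corpus <- function(tokens, lex, sentence_index = 1L) {
  stopifnot(inherits(lex, "lexicon"))
  rows <- which(tokens$pos == "TERM" & tokens$surface %in% lex$entries)
  data.frame(term = tokens$surface[rows],
             lexicon_name = rep(lex$name, length(rows)),
             sentence_index = rep(as.integer(sentence_index), length(rows)),
             negated = rep(FALSE, length(rows)),
             anchored_date = rep(as.Date(NA), length(rows)),
             token_row = rows,
             stringsAsFactors = FALSE)
}

clause_index <- function(tokens) {
  sentence <- attr(tokens, "sentence") %||% ""
  chars <- strsplit(sentence, "", fixed = TRUE)[[1]]
  delim_pos <- which(chars %in% CLAUSE_DELIMS)
  vapply(tokens$start, function(s) sum(delim_pos <= s), integer(1))
}

#' Flag matches negated by a cue in the same clause
#'
#' A match is negated when a `NEG` token occurs in the same
#' comma/semicolon-delimited clause, within `window` tokens before or
#' after it (default: anywhere in the clause).  Negated matches are kept
#' in the result (for provenance) but excluded from downstream flags.
#'
#' @param matches Match `data.frame` from [match_corpus()].
#' @param tokens The token `data.frame` the matches came from.
#' @param window Maximum token distance between cue and match; `Inf`
#'   means the whole clause.
#' @return `matches` with its `negated` column updated.
#' @export
filter_negated <- function(matches, tokens, window = Inf) {
  if (!nrow(matches)) return(matches)
  cl <- clause_index(tokens)
  neg_rows <- which(tokens$pos == "NEG")
  if (!length(neg_rows)) return(matches)
  for (i in seq_len(nrow(matches))) {
    r <- matches$token_row[i]
    same <- neg_rows[cl[neg_rows] == cl[r]]
    if (length(same) && any(abs(same - r) <= window))
      matches$negated[i] <- TRUE
  }
  matches
}

MONTH_NAMES <- c("January", "February", "March", "April", "May", "June",
                 "July", "August", "September", "October", "November",
                 "December")

subtract_months <- function(date, n) {
  lt <- as.POSIXlt(date)
  day <- lt$mday
  lt$mday <- 1L
  lt$mon <- lt$mon - n
  first <- as.Date(lt)
  # clamp day to the target month's length
  nxt <- seq(first, by = "1 month", length.out = 2L)[2L]
  as.Date(first) + min(day, as.integer(nxt - first)) - 1L
}

#' Resolve a time expression to a calendar date
#'
#' Handles absolute forms ("On April 16, 2021", "2021-04-16",
#' "2021\u5e744\u670816\u65e5") and simple relative phrases
#' ("3 days/weeks/months/years ago") resolved against `reference_date`.
#' Unparseable input yields `NA` rather than an error.
#'
#' @param x A `TIME` token surface string (or a token `data.frame` row).
#' @param reference_date `Date` used for relative phrases.
#' @return A `Date`, or `NA` if unresolvable.
#' @export
parse_time <- function(x, reference_date = Sys.Date()) {
  if (is.data.frame(x)) x <- x$surface[1]
  if (is.null(x) || is.na(x) || !nzchar(x)) return(as.Date(NA))
  x <- trimws(sub("^[Oo]n ", "", x))
  m <- regmatches(x, regexec(
    paste0("^(", paste(MONTH_NAMES, collapse = "|"),
           ") (\\d{1,2}), (\\d{4})$"), x))[[1]]
  if (length(m) == 4L) {
    d <- suppressWarnings(as.Date(sprintf("%s-%02d-%02d", m[4],
                                          match(m[2], MONTH_NAMES),
                                          as.integer(m[3]))))
    return(d)
  }
  if (grepl("^\\d{4}-\\d{1,2}-\\d{1,2}$", x))
    return(suppressWarnings(as.Date(x)))
  m <- regmatches(x, regexec(
    "^(\\d{4})\u5e74(\\d{1,2})\u6708(\\d{1,2})\u65e5$", x))[[1]]
  if (length(m) == 4L)
    return(suppressWarnings(as.Date(sprintf("%s-%02d-%02d", m[2],
                                            as.integer(m[3]),
                                            as.integer(m[4])))))
  m <- regmatches(x, regexec("^(\\d+) (day|week|month|year)s? ago$", x))[[1]]
  if (length(m) == 3L) {
    n <- as.integer(m[2])
    ref <- as.Date(reference_date)
    return(switch(m[3],
                  day = ref - n,
                  week = ref - 7L * n,
                  month = subtract_months(ref, n),
                  year = subtract_months(ref, 12L * n)))
  }
  as.Date(NA)
}

#' Anchor matches to the nearest parseable date in their sentence
#'
#' @param matches Match `data.frame` (one sentence's matches).
#' @param tokens The sentence's token `data.frame`.
#' @param reference_date `Date` for relative phrases.
#' @return `matches` with `anchored_date` filled where a `TIME` token in
#'   the sentence parsed; the nearest (by token distance) wins.
#' @export
anchor_dates <- function(matches, tokens, reference_date = Sys.Date()) {
  if (!nrow(matches)) return(matches)
  time_rows <- which(tokens$pos == "TIME")
  if (!length(time_rows)) return(matches)
  dates <- as.Date(vapply(time_rows, function(r)
    as.character(parse_time(tokens$surface[r], reference_date)), character(1)))
  ok <- !is.na(dates)
  time_rows <- time_rows[ok]; dates <- dates[ok]
  if (!length(time_rows)) return(matches)
  for (i in seq_len(nrow(matches))) {
    j <- which.min(abs(time_rows - matches$token_row[i]))
    matches$anchored_date[i] <- dates[j]
  }
  matches
}
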