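# Lexicons: term lists driving Branch B matching and negation filtering.

LEXICON_NAMES <- c("surgery_trauma", "hormone", "reduced_mobility",
                   "symptom", "negation")

#' Construct a lexicon
#'
#' @param name One of `"surgery_trauma"`, `"hormone"`,
#'   `"reduced_mobility"`, `"symptom"`, `"negation"`.
#' @param entries Character vector of terms; whitespace-trimmed, unique,
#'   non-empty.
#' @return A `lexicon` object.
#' @export
lexicon <- function(name, entries) {
  name <- match.arg(name, LEXICON_NAMES)
  entries <- trimws(as.character(entries))
  entries <- unique(entries[nzchar(entries)])
  if (!length(entries)) stop("lexicon '", name, "' has no entries")
  structure(list(name = name, entries = entries), class = "lexicon")
}

#' Default negation lexicon
#'
#' Seeded from common clinical negation cues ("no", "not", "none",
#' "not used", "not seen", "not found", "denies", "without", plus their
#' common Chinese counterparts); extensible via [read_lexicon()].
#'
#' @return A `lexicon` object named `"negation"`.
#' @export
default_negation_lexicon <- function() {
  lexicon("negation",
          c("no", "not", "none", "never", "denies", "denied", "without",
            "not used", "not using", "not seen", "not found", "negative for",
            "\u65e0", "\u672a\u89c1", "\u672a\u89c1\u660e\u663e",
            "\u5426\u8ba4", "\u672a"))
}

#' Read a lexicon from a text file
#'
#' UTF-8, one term per line; `#` starts a comment line; blank lines and
#' duplicates are dropped (duplicates with a warning).  Terms may contain
#' internal spaces, preserved verbatim.
#'
#' @param path File path.
#' @param name Lexicon name (see [lexicon()]); defaults to the file's
#'   base name without extension if it is a known name.
#' @return A `lexicon` object.
#' @export
read_lexicon <- function(path, name = NULL) {
  if (!file.exists(path)) stop("lexicon file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("\r$", "", lines)               # tolerate CRLF
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (anyDuplicated(lines))
    warning("duplicate lexicon entries dropped in ", path)
  if (is.null(name)) {
    stem <- sub("\\.[^.]*$", "", basename(path))
    if (!stem %in% LEXICON_NAMES)
      stop("cannot infer lexicon name from file name: ", path)
    name <- stem
  }
  lexicon(name, lines)
}

#' @rdname read_lexicon
#' @param lex A `lexicon` object to write.
#' @export
write_lexicon <- function(lex, path) {
  stopifnot(inherits(lex, "lexicon"))
  writeLines(c(paste0("# lexicon: ", lex$name), lex$entries), path,
             useBytes = FALSE)
  invisible(path)
}

#' Bundle the Branch-B lexicons
#'
#' @param surgery_trauma,hormone,reduced_mobility,symptom `lexicon`
#'   objects (or bare character vectors) for the four matching corpora.
#' @param negation Negation-cue lexicon; defaults to
#'   [default_negation_lexicon()].
#' @return A named list of `lexicon` objects, class `lexicon_set`.
#' @export
lexicon_set <- function(surgery_trauma, hormone, reduced_mobility, symptom,
                        negation = default_negation_lexicon()) {
  coerce <- function(x, nm) if (inherits(x, "lexicon")) x else lexicon(nm, x)
  structure(list(
    surgery_trauma = coerce(surgery_trauma, "surgery_trauma"),
    hormone = coerce(hormone, "hormone"),
    reduced_mobility = coerce(reduced_mobility, "reduced_mobility"),
    symptom = coerce(symptom, "symptom"),
    negation = coerce(negation, "negation")
  ), class = "lexicon_set")
}
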