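# Readers/writers: EMR JSON Lines, reports, pipeline configuration and
# the model artifact.  All text is UTF-8, all dates ISO-8601; reports
# are written atomically (temp file + rename).

record_to_list <- function(r) {
  out <- list(record_id = r$record_id,
              record_date = format(r$record_date),
              diagnoses = as.list(r$diagnoses),
              sections = r$sections)
  for (nm in c("age_years", "height_m", "weight_kg"))
    if (!is.na(r[[nm]])) out[[nm]] <- r[[nm]]
  labs <- Filter(function(v) !is.na(v), r$labs)
  if (length(labs)) out$labs <- labs
  if (!is.null(r$gold_flags))
    out$gold_flags <- as.list(r$gold_flags$flags)
  out
}

list_to_record <- function(x) {
  labs <- do.call(lab_panel, lapply(x$labs %||% list(), as.numeric))
  gold <- NULL
  if (!is.null(x$gold_flags))
    gold <- item_flags(unlist(x$gold_flags))
  emr_record(record_id = x$record_id,
             record_date = x$record_date,
             diagnoses = unlist(x$diagnoses) %||% character(),
             sections = lapply(x$sections %||% list(), paste,
                               collapse = "\n"),
             age_years = as.numeric(x$age_years %||% NA_real_),
             height_m = as.numeric(x$height_m %||% NA_real_),
             weight_kg = as.numeric(x$weight_kg %||% NA_real_),
             labs = labs, gold_flags = gold)
}

#' Read EMR records from a JSON Lines file
#'
#' One JSON object per line, schema mirroring [emr_record()].  Malformed
#' lines are collected (attribute `"errors"`), valid lines kept; under
#' `strict = TRUE` records missing any of age/height/weight/labs are
#' dropped as well, mirroring a missing-values removal step.
#'
#' @param path File path (UTF-8).
#' @param strict Drop records with missing numeric fields?
#' @return List of `emr_record`s with attribute `"errors"` (character).
#' @export
read_emr_jsonl <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop("cannot read EMR file: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  records <- list(); errors <- character()
  for (i in seq_along(lines)) {
    r <- tryCatch(list_to_record(jsonlite::fromJSON(lines[i],
                                                    simplifyVector = FALSE)),
                  error = function(e) e)
    if (inherits(r, "error")) {
      errors <- c(errors, sprintf("line %d: %s", i, conditionMessage(r)))
      next
    }
    if (strict && (is.na(r$age_years) || is.na(r$height_m) ||
                   is.na(r$weight_kg)))
      next
    records[[length(records) + 1L]] <- r
  }
  structure(records, errors = errors)
}

#' @rdname read_emr_jsonl
#' @param records List of `emr_record`s to write.
#' @export
write_emr_jsonl <- function(records, path) {
  lines <- vapply(records, function(r)
    as.character(jsonlite::toJSON(record_to_list(r), auto_unbox = TRUE,
                                  digits = NA)), character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write a JSON report atomically
#'
#' @param report Any jsonlite-serializable object.
#' @param path Destination; written via a temp file then renamed.
#' @export
write_report <- function(report, path) {
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(report, tmp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE, na = "null")
  file.rename(tmp, path)
  invisible(path)
}

#' Read and validate a pipeline configuration JSON
#'
#' Known keys: `lexicon_dir`, `scale_json`, `train`, `window_days`,
#' `negation_window`, `lab_thresholds`, `cutoff`, `three_level`,
#' `cov_normalized`, `seed`.  Unknown keys are rejected; referenced
#' files must exist.
#'
#' @param path JSON file.
#' @return Named list of options.
#' @export
read_pipeline_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("lexicon_dir", "scale_json", "train", "window_days",
             "negation_window", "lab_thresholds", "cutoff", "three_level",
             "cov_normalized", "seed")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  for (key in c("lexicon_dir", "scale_json")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]]))
      stop("config path does not exist: ", cfg[[key]])
  }
  cfg
}

# ---- model artifact ------------------------------------------------------
# A directory of plain-text files.  Doubles are printed with %.17g so a
# reload reproduces predictions bit-exactly; the encoder is regenerated
# from its stored seed rather than serialized.

write_num_matrix <- function(m, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(m), ncol(m)), con)
  for (i in seq_len(nrow(m)))
    writeLines(paste(sprintf("%.17g", m[i, ]), collapse = " "), con)
  invisible(path)
}

read_num_matrix <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  dims <- as.integer(strsplit(lines[1], " ")[[1]])
  vals <- lapply(lines[-1], function(l) as.numeric(strsplit(l, " ")[[1]]))
  matrix(unlist(vals), nrow = dims[1], ncol = dims[2], byrow = TRUE)
}

#' Save / load a trained classifier artifact
#'
#' The artifact is a directory of text files: `config.json` (training
#' configuration, encoder seed, embedder spec), `head_w.txt` /
#' `head_b.txt` (full-precision head parameters) and `swm.tsv` (the
#' per-category TI tables).  Reloading reproduces predictions
#' bit-exactly.
#'
#' @param model A `pdcm_model`.
#' @param dir Artifact directory (created if absent).
#' @return `load_pdcm` returns the restored `pdcm_model`.
#' @export
save_pdcm <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(config = model$config, encoder_seed = model$encoder_seed,
               embedder_spec = model$embedder_spec,
               best_epoch = model$best_epoch,
               best_val_f1 = model$best_val_f1)
  jsonlite::write_json(meta, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  write_num_matrix(model$head$W, file.path(dir, "head_w.txt"))
  write_num_matrix(matrix(model$head$b, nrow = 1L),
                   file.path(dir, "head_b.txt"))
  rows <- do.call(rbind, lapply(seq_len(6L), function(k) {
    tab <- model$stats$ti[[k]]
    if (!length(tab)) return(NULL)
    data.frame(category = k, term = names(tab),
               ti = sprintf("%.17g", tab),
               ti_max = sprintf("%.17g", model$stats$ti_max[k]),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, file.path(dir, "swm.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(dir)
}

#' @rdname save_pdcm
#' @export
load_pdcm <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "config.json"),
                              simplifyVector = TRUE)
  W <- read_num_matrix(file.path(dir, "head_w.txt"))
  b <- as.numeric(read_num_matrix(file.path(dir, "head_b.txt")))
  tab <- utils::read.table(file.path(dir, "swm.tsv"), sep = "\t",
                           header = TRUE, quote = "",
                           fileEncoding = "UTF-8",
                           stringsAsFactors = FALSE)
  ti <- lapply(seq_len(6L), function(k) {
    sub <- tab[tab$category == k, , drop = FALSE]
    stats::setNames(as.numeric(sub$ti), sub$term)
  })
  names(ti) <- category_ids()
  ti_max <- vapply(seq_len(6L), function(k) {
    sub <- tab[tab$category == k, , drop = FALSE]
    if (!nrow(sub)) 0 else as.numeric(sub$ti_max[1])
  }, numeric(1))
  cfg <- meta$config
  cfg$focal_alpha <- cfg$focal_alpha %||% NULL
  config <- do.call(train_config, cfg[!vapply(cfg, is.null, logical(1))])
  structure(list(head = list(W = W, b = b),
                 stats = structure(list(ti = ti, ti_max = ti_max),
                                   class = "swm_stats"),
                 config = config,
                 history = NULL,
                 best_epoch = meta$best_epoch,
                 best_val_f1 = meta$best_val_f1,
                 encoder_seed = meta$encoder_seed,
                 embedder_spec = meta$embedder_spec),
            class = "pdcm_model")
}
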