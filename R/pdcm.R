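# Branch A: the disease-category classifier.
#
# Each (diagnosis text, symptom list) pair is one classification unit.
# The diagnosis embeds to 20 x 768 and the symptom list to 50 x 768; two
# fixed seeded BiLSTM stacks encode them to h_diagnosis and h_symptoms
# (768 each); h_concatenated = [h_diagnosis, h_symptoms] passes through
# dropout and is prepended with the unit's length-6 symptom weight vector
# to give the 1542-wide fused feature; a linear layer + softmax scores
# the six categories and focal loss drives gradient training of that
# head.  Ablation modes zero the symptom branch and/or the weight vector.

PDCM_MODES <- c("pdcm", "diagnose_only", "diagnose_symptom",
                "pdcm_without_amplification")

#' Training configuration
#'
#' Defaults follow the published training protocol where stated (100
#' epoch cap, early stopping after 10 epochs without validation-F1
#' improvement, 7:3 train/validation split, 10% negative-sample
#' amplification with uncertainty markers) and documented package
#' defaults elsewhere (dropout 0.5, focal gamma 2, inverse-frequency
#' alpha, Adam-style optimizer, learning rate 1e-3, batch 32).
#'
#' @param max_epochs Epoch cap (100).
#' @param patience Early-stopping patience in epochs (10).
#' @param train_fraction Training share of the stratified split (0.7).
#' @param dropout_rate Dropout on the concatenated encoder features.
#' @param focal_gamma Focal-loss focusing exponent.
#' @param focal_alpha Per-class weights; `NULL` means inverse-frequency
#'   weights computed from the training labels.
#' @param seed Master seed for every stochastic step.
#' @param mode One of `"pdcm"`, `"diagnose_only"`, `"diagnose_symptom"`,
#'   `"pdcm_without_amplification"`.
#' @param amplify_fraction Fraction of disease-category units duplicated
#'   as uncertainty-marked negatives (0.10).
#' @param uncertainty_markers Marker strings appended to amplified
#'   diagnoses.
#' @param lr,batch_size Optimizer settings.
#' @param f1_average Checkpoint-selection F1 averaging, `"macro"` or
#'   `"micro"`.
#' @return A `train_config` list.
#' @export
train_config <- function(max_epochs = 100L, patience = 10L,
                         train_fraction = 0.7, dropout_rate = 0.5,
                         focal_gamma = 2, focal_alpha = NULL, seed = 1L,
                         mode = "pdcm", amplify_fraction = 0.10,
                         uncertainty_markers = c("?", "undecided"),
                         lr = 1e-3, batch_size = 32L,
                         f1_average = c("macro", "micro")) {
  mode <- match.arg(mode, PDCM_MODES)
  stopifnot(train_fraction > 0, train_fraction < 1,
            patience <= max_epochs,
            amplify_fraction >= 0, amplify_fraction <= 1)
  list(max_epochs = as.integer(max_epochs), patience = as.integer(patience),
       train_fraction = train_fraction, dropout_rate = dropout_rate,
       focal_gamma = focal_gamma, focal_alpha = focal_alpha,
       seed = as.integer(seed), mode = mode,
       amplify_fraction = amplify_fraction,
       uncertainty_markers = uncertainty_markers,
       lr = lr, batch_size = as.integer(batch_size),
       f1_average = match.arg(f1_average))
}

#' Construct training units
#'
#' @param diagnosis Character vector of diagnosis texts.
#' @param symptoms List of character vectors (one symptom list per unit).
#' @param label Integer category labels, 1..6 in [category_ids()] order
#'   (6 = "others"), or category id strings.
#' @return A `data.frame` with a list column `symptoms`.
#' @export
training_units <- function(diagnosis, symptoms, label) {
  if (is.character(label)) label <- match(label, category_ids())
  label <- as.integer(label)
  stopifnot(length(diagnosis) == length(symptoms),
            length(diagnosis) == length(label),
            all(nzchar(diagnosis)), all(label >= 1L & label <= 6L))
  out <- data.frame(diagnosis = as.character(diagnosis), label = label,
                    stringsAsFactors = FALSE)
  out$symptoms <- lapply(symptoms, as.character)
  out
}

#' Fuse encoder outputs with the symptom weight vector
#'
#' `h_concatenated = [h_diagnosis, h_symptoms]` (1536); dropout applies
#' only during training (inverted dropout, so inference needs no
#' rescaling); `h_swm = [swm, h_dropouted]` (1542).
#'
#' @param h_diag,h_symp Length-768 feature vectors.
#' @param swm Length-6 symptom weight vector.
#' @param dropout_rate Dropout probability.
#' @param training Apply dropout?
#' @return List with `h_concatenated`, `h_dropouted`, `h_swm`.
#' @export
fuse <- function(h_diag, h_symp, swm, dropout_rate = 0.5, training = FALSE) {
  if (length(h_diag) != FEATURE_DIM || length(h_symp) != FEATURE_DIM)
    stop("encoder features must have length 768")
  if (length(swm) != 6L) stop("symptom weight vector must have length 6")
  h_concat <- c(h_diag, h_symp)
  h_drop <- if (training && dropout_rate > 0) {
    keep <- stats::rbinom(length(h_concat), 1L, 1 - dropout_rate)
    h_concat * keep / (1 - dropout_rate)
  } else h_concat
  list(h_concatenated = h_concat, h_dropouted = h_drop,
       h_swm = c(as.numeric(swm), h_drop))
}

#' Linear classification head
#'
#' Affine map of the fused feature to 6 logits, then softmax (default)
#' or element-wise sigmoid for the optional multi-label head.
#'
#' @param fused Fused feature vector (1542) or matrix (n x 1542), or the
#'   list returned by [fuse()] (its `h_swm` is used).
#' @param parameters List with `W` (1542 x 6) and `b` (length 6).
#' @param head `"softmax"` or `"sigmoid"`.
#' @return Numeric vector/matrix of 6 category scores per input.
#' @export
classify <- function(fused, parameters, head = c("softmax", "sigmoid")) {
  head <- match.arg(head)
  if (is.list(fused) && !is.null(fused$h_swm)) fused <- fused$h_swm
  single <- !is.matrix(fused)
  Z <- (if (single) matrix(fused, nrow = 1L) else fused) %*% parameters$W
  Z <- sweep(Z, 2L, parameters$b, "+")
  S <- if (head == "softmax") softmax_rows(Z) else sigmoid(Z)
  colnames(S) <- category_ids()
  if (single) S[1, ] else S
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

#' Focal loss
#'
#' `-alpha[y] * (1 - p_y)^gamma * log(p_y)`, averaged over the batch.
#' At `gamma = 0`, `alpha = 1` this is the standard cross-entropy.
#'
#' @param scores Matrix `n x 6` of class probabilities (or a length-6
#'   vector for one sample).
#' @param label Integer labels 1..6.
#' @param gamma Focusing exponent (>= 0).
#' @param alpha Per-class weights (recycled scalar allowed).
#' @param eps Probability clamp guarding `log(0)`.
#' @return Mean loss (non-negative scalar).
#' @export
focal_loss <- function(scores, label, gamma = 2, alpha = 1, eps = 1e-7) {
  if (!is.matrix(scores)) scores <- matrix(scores, nrow = 1L)
  label <- as.integer(label)
  stopifnot(nrow(scores) == length(label), all(label >= 1L & label <= ncol(scores)))
  alpha <- rep_len(alpha, ncol(scores))
  p <- pmin(pmax(scores[cbind(seq_len(nrow(scores)), label)], eps), 1)
  mean(-alpha[label] * (1 - p)^gamma * log(p))
}

#' Amplify uncertainty-marked negative samples
#'
#' Samples `floor(fraction * n)` of the disease-category units (labels
#' 1..5) without replacement, appends a random uncertainty marker to each
#' sampled diagnosis text, relabels the copy as the negative class
#' ("others") and returns the originals plus the amplified copies.
#'
#' @param units Units from [training_units()].
#' @param fraction Amplification fraction (0.10 by default).
#' @param markers Uncertainty marker strings.
#' @param seed Integer seed.
#' @return Augmented units `data.frame`.
#' @export
amplify_negatives <- function(units, fraction = 0.10,
                              markers = c("?", "undecided"), seed = 1L) {
  stopifnot(nrow(units) > 0, length(markers) > 0)
  if (fraction > 1) stop("amplify fraction must be <= 1")
  padua_rows <- which(units$label %in% 1:5)
  k <- floor(fraction * length(padua_rows))
  if (k == 0L) return(units)
  with_seed(seed, {
    pick <- padua_rows[sample.int(length(padua_rows), k)]
    mk <- sample(markers, k, replace = TRUE)
    extra <- units[pick, , drop = FALSE]
    extra$diagnosis <- paste(extra$diagnosis, mk)
    extra$label <- 6L
    out <- rbind(units, extra)
    rownames(out) <- NULL
    out
  })
}

# Precompute per-unit features: the SWM block and both encoder outputs.
# Shared across ablation modes (the mode wiring zeroes blocks later), so
# ablation studies encode each dataset once.

#' Precompute classifier features for a unit set
#'
#' @param units Units from [training_units()].
#' @param stats An [swm_stats()] object (or corpora coercible to one).
#' @param encoder_seed Seed for the fixed encoder parameters.
#' @param embedder A [hash_embedder()].
#' @param chunk_size Passed to [encode_batch()].
#' @return A `pdcm_features` list: `swm` (n x 6), `h_diag`, `h_symp`
#'   (n x 768 each), plus the seeds/specs needed to reproduce them.
#' @export
pdcm_features <- function(units, stats, encoder_seed = 20L,
                          embedder = default_embedder(), chunk_size = 256L) {
  if (!inherits(stats, "swm_stats")) stats <- swm_stats(stats)
  n <- nrow(units)
  swm <- t(vapply(units$symptoms, build_swm, numeric(6L), corpora = stats))
  enc_d <- encoder_params_cached(encoder_seed)
  enc_s <- encoder_params_cached(encoder_seed + 1L)
  h_diag <- encode_batch(vectorize_batch(units$diagnosis, "diagnosis",
                                         embedder),
                         enc_d, chunk_size = chunk_size)
  h_symp <- encode_batch(vectorize_batch(units$symptoms, "symptom",
                                         embedder),
                         enc_s, chunk_size = chunk_size)
  structure(list(swm = swm, h_diag = h_diag, h_symp = h_symp,
                 encoder_seed = as.integer(encoder_seed),
                 embedder_spec = embedder$spec),
            class = "pdcm_features")
}

mode_design <- function(feats, mode) {
  swm <- feats$swm; h_symp <- feats$h_symp
  if (mode == "diagnose_only") { swm[] <- 0; h_symp[] <- 0 }
  if (mode == "diagnose_symptom") swm[] <- 0
  cbind(swm, feats$h_diag, h_symp)
}

macro_f1_int <- function(pred, truth, n_classes = 6L, average = "macro") {
  P <- matrix(0L, length(pred), n_classes); P[cbind(seq_along(pred), pred)] <- 1L
  T_ <- matrix(0L, length(truth), n_classes); T_[cbind(seq_along(truth), truth)] <- 1L
  metric_f1(P, T_, average = average)
}

#' Train the disease-category classifier
#'
#' Stratified seeded 7:3 split; negative-sample amplification (unless the
#' mode disables it); per-epoch Adam updates of the classification head
#' under focal loss with dropout on the concatenated encoder features;
#' per-epoch validation F1; stops at the epoch cap or after `patience`
#' epochs without improvement and returns the best-F1 checkpoint.
#'
#' @param units Units from [training_units()] (>= 2 categories).
#' @param corpora [symptom_corpora()] or [swm_stats()] for the SWM block.
#' @param config A [train_config()].
#' @param features Optional precomputed [pdcm_features()] for `units`
#'   *after amplification*; when supplied, amplification is skipped and
#'   the features are used as-is (used by ablation studies to share one
#'   encoding across modes).
#' @return A `pdcm_model` object with elements `head` (W, b), `stats`,
#'   `config`, `history` (per-epoch data.frame), `best_epoch`,
#'   `best_val_f1`, `encoder_seed`, `embedder_spec`.
#' @export
train_pdcm <- function(units, corpora, config = train_config(),
                       features = NULL) {
  if (length(unique(units$label)) < 2L)
    stop("training needs at least two represented categories")
  stats <- if (inherits(corpora, "swm_stats")) corpora else swm_stats(corpora)

  if (is.null(features)) {
    if (config$mode != "pdcm_without_amplification" &&
        config$amplify_fraction > 0)
      units <- amplify_negatives(units, config$amplify_fraction,
                                 config$uncertainty_markers,
                                 seed = config$seed + 1L)
    features <- pdcm_features(units, stats,
                              encoder_seed = config$seed + 1000L)
  }
  X <- mode_design(features, config$mode)
  y <- units$label
  n <- nrow(X)

  with_seed(config$seed, {
    # stratified split
    tr_idx <- integer()
    for (k in sort(unique(y))) {
      rows <- which(y == k)
      n_tr <- max(1L, round(config$train_fraction * length(rows)))
      tr_idx <- c(tr_idx, rows[sample.int(length(rows), n_tr)])
    }
    tr_idx <- sort(tr_idx)
    va_idx <- setdiff(seq_len(n), tr_idx)
    if (!length(va_idx)) stop("validation split is empty; need more units")

    alpha <- config$focal_alpha
    if (is.null(alpha)) {
      freq <- tabulate(y[tr_idx], nbins = 6L)
      inv <- ifelse(freq > 0, 1 / freq, 0)
      alpha <- inv / mean(inv[freq > 0])
    }

    d <- ncol(X)
    W <- matrix(stats::rnorm(d * 6L, sd = 0.01), d, 6L)
    b <- numeric(6L)
    mW <- vW <- matrix(0, d, 6L); mb <- vb <- numeric(6L)
    beta1 <- 0.9; beta2 <- 0.999; eps_adam <- 1e-8; step <- 0L
    drop_cols <- 6L + seq_len(2L * FEATURE_DIM)  # dropout spares the SWM block

    history <- data.frame(epoch = integer(), train_loss = numeric(),
                          val_loss = numeric(), val_f1 = numeric())
    best <- list(f1 = -Inf, loss = Inf, W = W, b = b, epoch = 0L)
    stall <- 0L
    for (epoch in seq_len(config$max_epochs)) {
      ord <- tr_idx[sample.int(length(tr_idx))]
      loss_sum <- 0; loss_n <- 0L
      for (lo in seq(1L, length(ord), by = config$batch_size)) {
        rows <- ord[lo:min(lo + config$batch_size - 1L, length(ord))]
        Xb <- X[rows, , drop = FALSE]
        if (config$dropout_rate > 0) {
          keep <- matrix(stats::rbinom(length(rows) * length(drop_cols), 1L,
                                       1 - config$dropout_rate),
                         length(rows), length(drop_cols))
          Xb[, drop_cols] <- Xb[, drop_cols] * keep / (1 - config$dropout_rate)
        }
        yb <- y[rows]
        Z <- sweep(Xb %*% W, 2L, b, "+")
        P <- softmax_rows(Z)
        p_y <- pmin(pmax(P[cbind(seq_along(yb), yb)], 1e-7), 1 - 1e-12)
        loss_sum <- loss_sum +
          sum(-alpha[yb] * (1 - p_y)^config$focal_gamma * log(p_y))
        loss_n <- loss_n + length(yb)
        # d(loss)/d(logit): focal chain rule through p_y = softmax_y
        g <- config$focal_gamma
        dL_du <- alpha[yb] * (g * (1 - p_y)^(ifelse(g > 0, g - 1, 0)) *
                                ifelse(g > 0, log(p_y), 0) -
                              (1 - p_y)^g / p_y)
        onehot <- matrix(0, length(yb), 6L)
        onehot[cbind(seq_along(yb), yb)] <- 1
        dZ <- (dL_du * p_y) * (onehot - P) / length(yb)
        gW <- crossprod(Xb, dZ); gb <- colSums(dZ)
        step <- step + 1L
        mW <- beta1 * mW + (1 - beta1) * gW; vW <- beta2 * vW + (1 - beta2) * gW^2
        mb <- beta1 * mb + (1 - beta1) * gb; vb <- beta2 * vb + (1 - beta2) * gb^2
        cW <- (mW / (1 - beta1^step)) / (sqrt(vW / (1 - beta2^step)) + eps_adam)
        cb <- (mb / (1 - beta1^step)) / (sqrt(vb / (1 - beta2^step)) + eps_adam)
        W <- W - config$lr * cW; b <- b - config$lr * cb
      }
      Pv <- softmax_rows(sweep(X[va_idx, , drop = FALSE] %*% W, 2L, b, "+"))
      pred_v <- max.col(Pv, ties.method = "first")
      f1_v <- macro_f1_int(pred_v, y[va_idx], average = config$f1_average)
      loss_v <- focal_loss(Pv, y[va_idx], gamma = config$focal_gamma,
                           alpha = alpha)
      history <- rbind(history, data.frame(epoch = epoch,
                                           train_loss = loss_sum / loss_n,
                                           val_loss = loss_v,
                                           val_f1 = f1_v))
      # early stopping counts epochs without F1 improvement; among F1
      # ties the checkpoint with the lower validation loss is kept
      if (f1_v > best$f1 + 1e-12) {
        best <- list(f1 = f1_v, loss = loss_v, W = W, b = b, epoch = epoch)
        stall <- 0L
      } else {
        if (f1_v >= best$f1 - 1e-12 && loss_v < best$loss)
          best <- list(f1 = best$f1, loss = loss_v, W = W, b = b,
                       epoch = epoch)
        stall <- stall + 1L
      }
      if (stall >= config$patience) break
    }

    structure(list(head = list(W = unname(best$W), b = unname(best$b)),
                   stats = stats, config = config, history = history,
                   best_epoch = best$epoch, best_val_f1 = best$f1,
                   encoder_seed = features$encoder_seed,
                   embedder_spec = features$embedder_spec,
                   val_idx = va_idx),
              class = "pdcm_model")
  })
}

#' @export
print.pdcm_model <- function(x, ...) {
  cat("PDCM classifier head (mode:", x$config$mode, ")\n")
  cat("  epochs run:", nrow(x$history), "| best epoch:", x$best_epoch,
      "| best val F1:", round(x$best_val_f1, 4), "\n")
  invisible(x)
}

#' Score units with a trained model
#'
#' @param model A `pdcm_model`.
#' @param units Units from [training_units()] (labels ignored).
#' @return Matrix `n x 6` of softmax category scores.
#' @export
predict_units <- function(model, units) {
  spec <- model$embedder_spec
  emb <- if (identical(as.integer(spec$dim), EMBED_DIM) && spec$scale == 1)
    default_embedder()
  else hash_embedder(dim = spec$dim, scale = spec$scale)
  feats <- pdcm_features(units, model$stats,
                         encoder_seed = model$encoder_seed,
                         embedder = emb)
  X <- mode_design(feats, model$config$mode)
  S <- softmax_rows(sweep(X %*% model$head$W, 2L, model$head$b, "+"))
  colnames(S) <- category_ids()
  S
}

#' Patient-level disease-item prediction
#'
#' Each diagnosis string forms one unit with the patient's extracted
#' symptoms; a Padua disease item is flagged iff some unit's argmax
#' category is that item; the per-category patient score is the maximum
#' unit score (used by the ranking metrics).
#'
#' @param model A trained `pdcm_model`.
#' @param diagnoses Character vector (may be empty).
#' @param symptoms Character vector of extracted symptom terms.
#' @return List with `flags` (named logical, the 5 disease items),
#'   `scores` (named numeric, 6 per-category maxima; zeros when there
#'   are no diagnoses) and `unit_categories` (the argmax category id per
#'   diagnosis, for provenance).
#' @export
predict_patient <- function(model, diagnoses, symptoms = character()) {
  ids <- padua_disease_ids()
  if (!length(diagnoses))
    return(list(flags = stats::setNames(rep(FALSE, 5L), ids),
                scores = stats::setNames(numeric(6L), category_ids()),
                unit_categories = character()))
  units <- training_units(diagnoses,
                          rep(list(as.character(symptoms)), length(diagnoses)),
                          rep(6L, length(diagnoses)))
  S <- predict_units(model, units)
  am <- max.col(S, ties.method = "first")
  flags <- vapply(seq_len(5L), function(k) any(am == k), logical(1))
  list(flags = stats::setNames(flags, ids),
       scores = stats::setNames(apply(S, 2L, max), category_ids()),
       unit_categories = category_ids()[am])
}
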