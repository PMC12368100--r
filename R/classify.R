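# Charging and pairwise amino-acid classifiers.
#
# The classifier contract is the probability interface: a model maps a
# signal chunk to P(positive class). The default architecture is a
# ridge-regularized logistic model on per-position window metrics
# (trimmed-mean normalized current at offsets -3..+6, log dwell at offsets
# -3..+10); a variant ("chunk_bins") operates on binned raw-sample vectors.
# Training is deterministic given the seed and runs in seconds on one CPU.
#
# Per-read probabilities are mapped to integer modification-likelihood (ML)
# scores on the 0-255 scale, round(255 x p); scores >= 200 (i.e. score >
# cutoff 199) call a read charged.

#' Stratified train/test split of labelled chunks
#'
#' Splits by read (each chunk belongs to one read), stratified within class,
#' and attaches class-balancing sampling weights (each class contributes
#' equal total weight regardless of imbalance).
#'
#' @param positive_chunks,negative_chunks Chunk lists (from
#'   [extract_chunks()]); positives are the charged class (or amino acid i
#'   of an ordered pair).
#' @param split Training fraction (default 0.8).
#' @param seed Integer seed; the split is deterministic given the seed.
#' @return List with elements `train` and `test`, each a list of `chunks`,
#'   `labels` (1 = positive) and `weights` (train only; mean 1).
#' @export
make_training_dataset <- function(positive_chunks, negative_chunks,
                                  split = 0.8, seed = 1) {
  if (length(positive_chunks) < 10 || length(negative_chunks) < 10) {
    stopf("each class needs at least 10 reads (got %d and %d)",
          length(positive_chunks), length(negative_chunks))
  }
  pick <- function(chunks, sub_seed) {
    n <- length(chunks)
    n_train <- floor(n * split)
    idx <- with_local_seed(sub_seed, sample.int(n, n_train))
    list(train = chunks[idx], test = chunks[-idx])
  }
  p <- pick(positive_chunks, derive_seed(seed, 1))
  n <- pick(negative_chunks, derive_seed(seed, 2))
  train_chunks <- c(p$train, n$train)
  train_labels <- rep(c(1L, 0L), c(length(p$train), length(n$train)))
  w <- ifelse(train_labels == 1L, 1 / length(p$train), 1 / length(n$train))
  list(
    train = list(chunks = train_chunks, labels = train_labels,
                 weights = w / mean(w)),
    test = list(chunks = c(p$test, n$test),
                labels = rep(c(1L, 0L), c(length(p$test), length(n$test)))))
}

#' Classifier architecture configuration
#'
#' @param features `"window"` (per-position window metrics, default) or
#'   `"chunk_bins"` (binned raw-sample vector; requires chunks with
#'   retained samples).
#' @param lambda Ridge penalty of the logistic model.
#' @param n_bins Number of sample bins for `"chunk_bins"`.
#' @return A list of class `classifier_config`.
#' @export
classifier_config <- function(features = c("window", "chunk_bins"),
                              lambda = 0.01, n_bins = 40) {
  features <- match.arg(features)
  structure(list(features = features, lambda = lambda, n_bins = n_bins),
            class = "classifier_config")
}

chunk_feature_matrix <- function(chunks, config) {
  if (config$features == "window") {
    x <- t(vapply(chunks, `[[`, chunks[[1]]$features, "features"))
  } else {
    if (is.null(chunks[[1]]$samples)) {
      stopf("chunk_bins features require chunks with retained samples")
    }
    nb <- config$n_bins
    x <- t(vapply(chunks, function(ch) {
      s <- ch$samples
      grp <- cut(seq_along(s), nb, labels = FALSE)
      vapply(split(s, grp), mean, 0, USE.NAMES = FALSE)
    }, numeric(nb)))
    colnames(x) <- paste0("bin_", seq_len(nb))
  }
  if (!all(is.finite(x))) stopf("non-finite feature values in training data")
  x
}

#' Train the charging classifier
#'
#' Fits a ridge-penalized logistic model (via glmnet) on the training
#' features with class-balancing weights. Training is deterministic given
#' the seed (the seed only governs any upstream split).
#'
#' @param train The `train` element of [make_training_dataset()].
#' @param config A [classifier_config()].
#' @param seed Integer seed recorded in the model.
#' @return A list of class `charging_classifier` with the fitted
#'   coefficients, feature names, config and seed.
#' @export
train_charging_model <- function(train, config = classifier_config(),
                                 seed = 1) {
  x <- chunk_feature_matrix(train$chunks, config)
  y <- train$labels
  if (length(unique(y)) != 2) stopf("training set must contain both classes")
  fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                        weights = train$weights,
                        lambda = c(10 * config$lambda, config$lambda),
                        standardize = TRUE)
  beta <- as.numeric(stats::coef(fit, s = config$lambda))
  if (!all(is.finite(beta))) {
    stopf("training diverged: non-finite coefficients (lambda=%g)", config$lambda)
  }
  structure(list(intercept = beta[1],
                 coef = stats::setNames(beta[-1], colnames(x)),
                 config = config, seed = as.integer(seed),
                 n_train = length(y)),
            class = "charging_classifier")
}

#' Predict charging probabilities for chunks
#'
#' @param object A `charging_classifier`.
#' @param chunks List of chunks.
#' @param ... Unused.
#' @return Numeric vector of probabilities in \[0,1\].
#' @export
predict.charging_classifier <- function(object, chunks, ...) {
  if (length(chunks) == 0) return(numeric(0))
  x <- chunk_feature_matrix(chunks, object$config)
  x <- x[, names(object$coef), drop = FALSE]
  as.numeric(stats::plogis(object$intercept + x %*% object$coef))
}

#' Score reads on the 0-255 modification-likelihood scale
#'
#' @param model A `charging_classifier`.
#' @param chunks List of chunks.
#' @return `data.frame` with `read_id`, `prob` and integer `score`
#'   (`round(255 * prob)`).
#' @export
score_reads <- function(model, chunks) {
  prob <- predict(model, chunks)
  data.frame(read_id = vapply(chunks, `[[`, "", "read_id"),
             prob = prob,
             score = as.integer(round(255 * prob)),
             stringsAsFactors = FALSE)
}

#' Call charging state from ML scores
#'
#' A read is called charged when its score exceeds the cutoff, i.e. with the
#' default cutoff of 199: score >= 200 is charged, score <= 199 uncharged.
#'
#' @param scores `data.frame` from [score_reads()] (columns `read_id`,
#'   `score`).
#' @param cutoff Integer cutoff (default 199).
#' @return `data.frame` with `read_id`, `score`, `charged` (logical).
#' @export
classify_charging <- function(scores, cutoff = 199) {
  if (nrow(scores) == 0) {
    return(data.frame(read_id = character(0), score = integer(0),
                      charged = logical(0), stringsAsFactors = FALSE))
  }
  data.frame(read_id = scores$read_id, score = scores$score,
             charged = scores$score > cutoff, stringsAsFactors = FALSE)
}

#' Evaluate per-read calls against truth
#'
#' Charged is the positive class; F1 = 2TP / (2TP + FP + FN).
#'
#' @param calls `data.frame` with `read_id` and logical `charged`.
#' @param truth `data.frame` with `read_id` and logical `charged`, same
#'   read set.
#' @return A list of class `eval_report`: `TP`, `FP`, `FN`, `TN`, `n`,
#'   `precision`, `recall`, `F1`.
#' @export
evaluate_classifier <- function(calls, truth) {
  if (!setequal(calls$read_id, truth$read_id) ||
      nrow(calls) != nrow(truth)) {
    stopf("calls and truth must cover the same read ids")
  }
  m <- match(calls$read_id, truth$read_id)
  pred <- calls$charged
  obs <- truth$charged[m]
  TP <- sum(pred & obs); FP <- sum(pred & !obs)
  FN <- sum(!pred & obs); TN <- sum(!pred & !obs)
  structure(list(TP = TP, FP = FP, FN = FN, TN = TN, n = length(pred),
                 precision = if (TP + FP > 0) TP / (TP + FP) else NA_real_,
                 recall = if (TP + FN > 0) TP / (TP + FN) else NA_real_,
                 F1 = f1_score(TP, FP, FN)),
            class = "eval_report")
}

#' F1 score from confusion counts
#'
#' @param TP,FP,FN Confusion counts.
#' @return `2TP / (2TP + FP + FN)`; `NA` when the denominator is zero.
#' @export
f1_score <- function(TP, FP, FN) {
  den <- 2 * TP + FP + FN
  if (den == 0) return(NA_real_)
  2 * TP / den
}

#' Save / load a classifier checkpoint
#'
#' Self-describing single-file JSON format embedding coefficients, config
#' and seed.
#'
#' @param model A `charging_classifier`.
#' @param path File path.
#' @return `save_model`: `path`, invisibly. `load_model`: the model.
#' @export
save_model <- function(model, path) {
  payload <- list(format = "trnacharge_classifier", version = 1L,
                  intercept = model$intercept,
                  coef = as.list(model$coef),
                  config = unclass(model$config),
                  seed = model$seed, n_train = model$n_train)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "trnacharge_classifier")) {
    stopf("'%s' is not a classifier checkpoint", path)
  }
  cfg <- payload$config
  structure(list(intercept = payload$intercept,
                 coef = unlist(payload$coef),
                 config = structure(list(features = cfg$features,
                                         lambda = cfg$lambda,
                                         n_bins = cfg$n_bins),
                                    class = "classifier_config"),
                 seed = as.integer(payload$seed),
                 n_train = payload$n_train),
            class = "charging_classifier")
}

#' Train all ordered pairwise amino-acid models
#'
#' For every ordered pair (i, j) of the supplied amino-acid chunk sets, a
#' model is trained with i as the positive class and evaluated on the
#' held-out split at the 0.5 probability threshold; the unordered matrix
#' reports the mean F1 of the two ordered models per pair. n amino acids
#' yield n(n-1) ordered models (380 for the full 20-amino-acid panel).
#'
#' @param chunk_sets Named list (by amino-acid code) of chunk lists from
#'   pairwise (inserted-T) references.
#' @param seed Integer seed.
#' @param split Training fraction per amino acid.
#' @param config A [classifier_config()].
#' @return List with `ordered` (full asymmetric F1 matrix), `unordered`
#'   (symmetric mean-F1 matrix), `n_models`.
#' @export
train_pairwise_models <- function(chunk_sets, seed = 1, split = 0.8,
                                  config = classifier_config()) {
  codes <- names(chunk_sets)
  if (length(codes) < 2) stopf("at least two amino-acid chunk sets required")
  n <- length(codes)
  ordered <- matrix(NA_real_, n, n, dimnames = list(codes, codes))
  n_models <- 0L
  # Split each amino-acid library once so both orders of a pair reuse it.
  splits <- lapply(seq_along(codes), function(i) {
    chunks <- chunk_sets[[i]]
    if (length(chunks) < 10) {
      warnf("amino acid '%s' has < 10 reads; its pairs are skipped", codes[i])
      return(NULL)
    }
    n_train <- floor(length(chunks) * split)
    idx <- with_local_seed(derive_seed(seed, i), sample.int(length(chunks), n_train))
    list(train = chunks[idx], test = chunks[-idx])
  })
  names(splits) <- codes
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j || is.null(splits[[i]]) || is.null(splits[[j]])) next
      tr <- list(chunks = c(splits[[i]]$train, splits[[j]]$train),
                 labels = rep(c(1L, 0L), c(length(splits[[i]]$train),
                                           length(splits[[j]]$train))))
      tr$weights <- {
        w <- ifelse(tr$labels == 1L, 1 / sum(tr$labels == 1L),
                    1 / sum(tr$labels == 0L))
        w / mean(w)
      }
      fit <- train_charging_model(tr, config, seed = derive_seed(seed, i * n + j))
      test_chunks <- c(splits[[i]]$test, splits[[j]]$test)
      obs <- rep(c(TRUE, FALSE), c(length(splits[[i]]$test),
                                   length(splits[[j]]$test)))
      pred <- predict(fit, test_chunks) >= 0.5
      ordered[i, j] <- f1_score(sum(pred & obs), sum(pred & !obs),
                                sum(!pred & obs))
      n_models <- n_models + 1L
    }
  }
  unordered <- (ordered + t(ordered)) / 2
  list(ordered = ordered, unordered = unordered, n_models = n_models)
}

#' Alignment-based charging baseline
#'
#' Calls each read by the minimum edit distance between the 3'-terminal
#' region of its basecall and the two unique 3' adapters; ties are
#' `"unassigned"` and count as misclassifications of the true class during
#' evaluation (an unassigned truly-charged read is a false negative, an
#' unassigned truly-uncharged read a false positive).
#'
#' @param basecalls `data.frame` with `read_id` and `basecall`.
#' @param adapters An `adapter_set`.
#' @param truth Optional truth `data.frame` (`read_id`, logical `charged`)
#'   for evaluation.
#' @param slack Extra 3'-terminal characters retained beyond the adapter
#'   length (absorbs indels).
#' @return List with `calls` (`read_id`, `call` in
#'   charged/uncharged/unassigned) and, when truth is given, `report`
#'   (an `eval_report`).
#' @export
alignment_baseline <- function(basecalls, adapters, truth = NULL, slack = 6) {
  n3 <- max(nchar(adapters$charged_3p), nchar(adapters$uncharged_3p)) + slack
  region <- substr(basecalls$basecall,
                   pmax(1, nchar(basecalls$basecall) - n3 + 1),
                   nchar(basecalls$basecall))
  d_ch <- as.numeric(utils::adist(region, adapters$charged_3p))
  d_un <- as.numeric(utils::adist(region, adapters$uncharged_3p))
  call <- ifelse(d_ch < d_un, "charged",
                 ifelse(d_un < d_ch, "uncharged", "unassigned"))
  calls <- data.frame(read_id = basecalls$read_id, call = call,
                      stringsAsFactors = FALSE)
  out <- list(calls = calls)
  if (!is.null(truth)) {
    m <- match(calls$read_id, truth$read_id)
    obs <- truth$charged[m]
    # unassigned -> the wrong class for evaluation purposes
    pred <- ifelse(call == "charged", TRUE,
                   ifelse(call == "uncharged", FALSE, !obs))
    out$report <- evaluate_classifier(
      data.frame(read_id = calls$read_id, charged = pred),
      truth[m, c("read_id", "charged")])
  }
  out
}
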