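# Multinomial Naive Bayes with additive smoothing, the precision / recall /
# F-score / accuracy metrics, the positional token-agreement score,
# stratified cross-validation and ROC curves.

#' Train a multinomial Naive Bayes model
#'
#' Fits class log priors and additively smoothed (Laplace, `alpha`) token
#' log likelihoods in log space from a non-negative feature matrix. The
#' first factor level of `labels` is the tie-break ("negative") class used
#' by [predict_nb()].
#'
#' @param x numeric matrix or `dgCMatrix` (documents x vocabulary), entries
#'   >= 0. Column names are the vocabulary.
#' @param labels class labels (coerced to factor); at least one example per
#'   class, at least two classes.
#' @param alpha smoothing constant, > 0.
#' @return an object of class `fm_nb`.
#' @export
train_nb <- function(x, labels, alpha = 1) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0) {
    stop_fm("alpha must be a positive number")
  }
  labels <- factor(labels)
  labels <- droplevels(labels)
  if (nlevels(labels) < 2) {
    stop_fm("training data must contain at least two classes")
  }
  x <- methods::as(x, "matrix")
  if (nrow(x) != length(labels)) stop_fm("nrow(x) must equal length(labels)")
  if (any(x < 0)) stop_fm("feature values must be non-negative")
  V <- ncol(x)
  classes <- levels(labels)
  log_prior <- log(table(labels) / length(labels))
  log_lik <- matrix(NA_real_, nrow = length(classes), ncol = V,
                    dimnames = list(classes, colnames(x)))
  for (cl in classes) {
    counts <- colSums(x[labels == cl, , drop = FALSE])
    log_lik[cl, ] <- log(counts + alpha) - log(sum(counts) + alpha * V)
  }
  structure(list(classes = classes,
                 log_prior = setNames(as.numeric(log_prior), classes),
                 log_lik = log_lik, alpha = alpha,
                 vocabulary = colnames(x)),
            class = "fm_nb")
}

#' @export
print.fm_nb <- function(x, ...) {
  cat(sprintf("<fm_nb> classes: %s; vocabulary: %d grams; alpha = %g\n",
              paste(x$classes, collapse = ", "), length(x$vocabulary),
              x$alpha))
  invisible(x)
}

check_vocabulary <- function(model, x) {
  nm <- if (is.matrix(x) || inherits(x, "Matrix")) colnames(x) else names(x)
  len <- if (is.matrix(x) || inherits(x, "Matrix")) ncol(x) else length(x)
  if (len != length(model$vocabulary)) {
    stop_fm("feature vector has %d entries but the model vocabulary has %d",
            len, length(model$vocabulary))
  }
  if (!is.null(nm) && !is.null(model$vocabulary) &&
      !identical(unname(nm), unname(model$vocabulary))) {
    stop_fm("feature vocabulary does not match the model vocabulary")
  }
  invisible(TRUE)
}

#' Predict with a Naive Bayes model
#'
#' Scores each class as `log prior + sum(count * log likelihood)` and
#' normalizes to posteriors. Ties are resolved deterministically to the
#' first (negative) class.
#'
#' @param model an `fm_nb`.
#' @param x a feature vector over the model vocabulary, or a matrix of them
#'   (documents in rows).
#' @return for a single vector, a list with `label` and `posterior` (named,
#'   sums to 1); for a matrix, a list with `label` (character vector) and
#'   `posterior` (matrix documents x classes).
#' @export
predict_nb <- function(model, x) {
  stopifnot(inherits(model, "fm_nb"))
  single <- !(is.matrix(x) || inherits(x, "Matrix"))
  check_vocabulary(model, x)
  xm <- if (single) matrix(as.numeric(x), nrow = 1) else methods::as(x, "matrix")
  scores <- xm %*% t(model$log_lik)
  scores <- sweep(scores, 2, model$log_prior, `+`)
  # log-sum-exp normalization
  mx <- apply(scores, 1, max)
  post <- exp(scores - mx)
  post <- post / rowSums(post)
  colnames(post) <- model$classes
  idx <- apply(scores, 1, which.max)  # first max wins: negative class on ties
  label <- model$classes[idx]
  if (single) list(label = label, posterior = post[1, ]) else
    list(label = label, posterior = post)
}

#' Precision, recall, F-score and accuracy from label sequences
#'
#' `P = TP/(TP+FP)`, `R = TP/(TP+FN)`, `F = 2PR/(P+R)`,
#' `accuracy = (TP+TN)/total`. Zero-denominator cases are reported as
#' `NA` (undefined), never coerced to 0 or 1.
#'
#' @param true_labels vector of gold labels.
#' @param predicted_labels vector of predicted labels, same length.
#' @param positive_label the label counted as positive.
#' @return an object of class `fm_eval` with fields tp, fp, fn, tn,
#'   precision, recall, f_score, accuracy.
#' @export
evaluate_predictions <- function(true_labels, predicted_labels,
                                 positive_label) {
  if (length(true_labels) != length(predicted_labels)) {
    stop_fm("label sequences have different lengths (%d vs %d)",
            length(true_labels), length(predicted_labels))
  }
  truth <- as.character(true_labels) == as.character(positive_label)
  pred <- as.character(predicted_labels) == as.character(positive_label)
  tp <- sum(truth & pred); fp <- sum(!truth & pred)
  fn <- sum(truth & !pred); tn <- sum(!truth & !pred)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f_score <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  total <- tp + fp + fn + tn
  accuracy <- if (total > 0) (tp + tn) / total else NA_real_
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 precision = precision, recall = recall,
                 f_score = f_score, accuracy = accuracy,
                 positive_label = as.character(positive_label)),
            class = "fm_eval")
}

#' @export
print.fm_eval <- function(x, ...) {
  fmt <- function(v) ifelse(is.na(v), "undefined", sprintf("%.4f", v))
  cat(sprintf("<fm_eval> TP=%d FP=%d FN=%d TN=%d | P=%s R=%s F=%s acc=%s\n",
              x$tp, x$fp, x$fn, x$tn, fmt(x$precision), fmt(x$recall),
              fmt(x$f_score), fmt(x$accuracy)))
  invisible(x)
}

#' Positional token-agreement score
#'
#' The fraction of positions at which the predicted token labels agree with
#' the gold labels; labels are drawn from `n` (no token instance), `y`
#' (token instance) and `a` (noise). For gold `(n,y,n,a)` against predicted
#' `(n,n,n,a)` the score is 0.75.
#'
#' @param gold_tokens gold label sequence.
#' @param predicted_tokens predicted label sequence, same length.
#' @return agreement fraction in \[0, 1\].
#' @export
token_agreement_score <- function(gold_tokens, predicted_tokens) {
  if (length(gold_tokens) != length(predicted_tokens)) {
    stop_fm("label sequences have different lengths (%d vs %d)",
            length(gold_tokens), length(predicted_tokens))
  }
  ok <- c("n", "y", "a")
  if (!all(gold_tokens %in% ok) || !all(predicted_tokens %in% ok)) {
    stop_fm("labels must be drawn from {n, y, a}")
  }
  mean(gold_tokens == predicted_tokens)
}

#' ROC curve and AUC from positive-class posteriors
#'
#' Sweeps the decision threshold over all distinct posterior values; the
#' curve starts at (0,0), ends at (1,1), and both coordinates are
#' non-decreasing. The area under the curve is computed by the trapezoid
#' rule.
#'
#' @param true_labels gold labels (both classes must be present).
#' @param positive_posteriors posterior probability of the positive class,
#'   in \[0, 1\].
#' @param positive_label which label is positive.
#' @return data frame of class `fm_roc` with columns `fpr`, `tpr`,
#'   `threshold`; the AUC is in `attr(x, "auc")`.
#' @export
roc_curve <- function(true_labels, positive_posteriors, positive_label) {
  if (length(true_labels) != length(positive_posteriors)) {
    stop_fm("labels and posteriors have different lengths")
  }
  if (any(positive_posteriors < 0 | positive_posteriors > 1)) {
    stop_fm("posteriors must be in [0, 1]")
  }
  truth <- as.character(true_labels) == as.character(positive_label)
  P <- sum(truth); N <- sum(!truth)
  if (P == 0 || N == 0) {
    stop_fm("ROC needs both classes present in the truth labels")
  }
  ord <- order(positive_posteriors, decreasing = TRUE)
  post <- positive_posteriors[ord]
  truth <- truth[ord]
  # cumulative counts at each distinct threshold
  distinct <- c(which(diff(post) != 0), length(post))
  tpr <- cumsum(truth)[distinct] / P
  fpr <- cumsum(!truth)[distinct] / N
  out <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr),
                    threshold = c(Inf, post[distinct]))
  if (out$fpr[nrow(out)] != 1 || out$tpr[nrow(out)] != 1) {
    out <- rbind(out, data.frame(fpr = 1, tpr = 1, threshold = -Inf))
  }
  auc <- sum(diff(out$fpr) * (utils::head(out$tpr, -1) + utils::tail(out$tpr, -1)) / 2)
  structure(out, auc = auc, class = c("fm_roc", "data.frame"))
}

make_stratified_folds <- function(labels, k, seed) {
  labels <- factor(labels)
  fold <- integer(length(labels))
  with_local_seed(seed, {
    offset <- 0L
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      # cycle fold numbers continuously across classes so that every fold is
      # used even when a class has fewer than k members
      fold[idx] <- ((offset + seq_along(idx) - 1L) %% k) + 1L
      offset <- offset + length(idx)
    }
  })
  fold
}

#' Stratified k-fold cross-validation of the Naive Bayes classifier
#'
#' Partitions the data into `k` stratified folds (the partition is fixed by
#' `seed`); each example is tested exactly once. Reports per-fold and pooled
#' metrics plus a pooled ROC curve. A fold whose training part lacks a class
#' is skipped with a warning.
#'
#' @param x feature matrix (documents x vocabulary).
#' @param labels class labels (factor; first level = negative class).
#' @param k number of folds (>= 2; default 10).
#' @param seed integer seed fixing the fold assignment.
#' @param alpha Naive Bayes smoothing constant.
#' @param positive_label label treated as positive (default: last factor
#'   level).
#' @return an object of class `fm_cv`: `pooled` (fm_eval), `folds` (list of
#'   fm_eval), `fold_assignment`, `roc` (fm_roc or NULL), `auc`,
#'   `predicted`, `posterior`.
#' @export
cross_validate <- function(x, labels, k = 10, seed = 1, alpha = 1,
                           positive_label = NULL) {
  labels <- factor(labels)
  n <- length(labels)
  if (k < 2) stop_fm("k must be >= 2")
  if (n < k) stop_fm("need at least k examples")
  if (is.null(positive_label)) positive_label <- levels(labels)[nlevels(labels)]
  fold <- make_stratified_folds(labels, k, seed)
  predicted <- rep(NA_character_, n)
  posterior <- rep(NA_real_, n)
  fold_reports <- vector("list", k)
  for (f in seq_len(k)) {
    test_idx <- which(fold == f)
    train_idx <- which(fold != f)
    if (length(test_idx) == 0) next
    if (nlevels(droplevels(labels[train_idx])) < 2) {
      warn_fm("fold %d skipped: a class is absent from its training part", f)
      next
    }
    model <- train_nb(x[train_idx, , drop = FALSE], labels[train_idx], alpha)
    pr <- predict_nb(model, x[test_idx, , drop = FALSE])
    predicted[test_idx] <- pr$label
    posterior[test_idx] <- pr$posterior[, as.character(positive_label)]
    fold_reports[[f]] <- evaluate_predictions(labels[test_idx], pr$label,
                                              positive_label)
  }
  tested <- !is.na(predicted)
  pooled <- evaluate_predictions(labels[tested], predicted[tested],
                                 positive_label)
  roc <- NULL; auc <- NA_real_
  if (nlevels(droplevels(labels[tested])) == 2) {
    roc <- roc_curve(labels[tested], posterior[tested], positive_label)
    auc <- attr(roc, "auc")
  }
  structure(list(pooled = pooled, folds = fold_reports,
                 fold_assignment = fold, roc = roc, auc = auc,
                 predicted = predicted, posterior = posterior,
                 positive_label = positive_label),
            class = "fm_cv")
}

#' @export
print.fm_cv <- function(x, ...) {
  cat(sprintf("<fm_cv> %d folds; pooled:\n", length(x$folds)))
  print(x$pooled)
  if (!is.na(x$auc)) cat(sprintf("  pooled AUC = %.4f\n", x$auc))
  invisible(x)
}

#' Single stratified train/test split evaluation
#'
#' Implements the split-style evaluation modes: `train_frac = 0.4` trains on
#' 40% and tests on 60%; `train_frac = 0.5` is the five-of-ten-halves mode.
#'
#' @inheritParams cross_validate
#' @param train_frac fraction of each class used for training.
#' @return list with `report` (fm_eval), `model` (fm_nb), `test_idx`, `roc`,
#'   `auc`.
#' @export
split_validate <- function(x, labels, train_frac = 0.4, seed = 1, alpha = 1,
                           positive_label = NULL) {
  stopifnot(train_frac > 0, train_frac < 1)
  labels <- factor(labels)
  if (is.null(positive_label)) positive_label <- levels(labels)[nlevels(labels)]
  train_idx <- integer(0)
  with_local_seed(seed, {
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      n_train <- max(1L, round(train_frac * length(idx)))
      train_idx <- c(train_idx, idx[sample.int(length(idx), n_train)])
    }
  })
  test_idx <- setdiff(seq_along(labels), train_idx)
  model <- train_nb(x[train_idx, , drop = FALSE], labels[train_idx], alpha)
  pr <- predict_nb(model, x[test_idx, , drop = FALSE])
  report <- evaluate_predictions(labels[test_idx], pr$label, positive_label)
  roc <- NULL; auc <- NA_real_
  if (nlevels(droplevels(labels[test_idx])) == 2) {
    roc <- roc_curve(labels[test_idx],
                     pr$posterior[, as.character(positive_label)],
                     positive_label)
    auc <- attr(roc, "auc")
  }
  list(report = report, model = model, test_idx = test_idx, roc = roc,
       auc = auc)
}

#' Serialize a Naive Bayes model to versioned JSON
#'
#' @param model an `fm_nb`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_nb_model <- function(model, path) {
  stopifnot(inherits(model, "fm_nb"))
  payload <- list(
    format = jsonlite::unbox("fusemine-nb"),
    version = jsonlite::unbox(1L),
    classes = model$classes,
    alpha = jsonlite::unbox(model$alpha),
    vocabulary = model$vocabulary,
    log_prior = as.numeric(model$log_prior),
    log_lik = lapply(model$classes, function(cl) as.numeric(model$log_lik[cl, ]))
  )
  json <- jsonlite::toJSON(payload, digits = NA, pretty = TRUE)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(enc2utf8(as.character(json)), con, useBytes = TRUE)
  invisible(path)
}

#' Read a Naive Bayes model written by [write_nb_model()]
#'
#' @param path path to the JSON file.
#' @return an `fm_nb`.
#' @export
read_nb_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$format, "fusemine-nb")) {
    stop_fm("'%s' is not a fusemine model file", path)
  }
  log_lik <- x$log_lik
  if (is.list(log_lik)) log_lik <- do.call(rbind, log_lik)
  if (is.null(dim(log_lik))) {
    log_lik <- matrix(log_lik, nrow = length(x$classes), byrow = TRUE)
  }
  dimnames(log_lik) <- list(x$classes, x$vocabulary)
  structure(list(classes = x$classes,
                 log_prior = setNames(x$log_prior, x$classes),
                 log_lik = log_lik, alpha = x$alpha,
                 vocabulary = x$vocabulary),
            class = "fm_nb")
}
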