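#' Linear SVM classification with leakage-free cross-validation
#'
#' Feature normalization statistics (per-feature mean and SD) are always
#' computed on training data only and applied unchanged to test data; the
#' classifier is a linear-kernel soft-margin SVM. Evaluation is stratified
#' 5-fold cross-validation; an online-replay mode trains once on a
#' calibration session and streams per-epoch decisions for a second
#' session.
#'
#' @name classify
NULL

CLASS_LEVELS <- c("relax", "nback")

#' Fit per-feature z-score normalization statistics on a training set
#'
#' @param train a `feature_matrix` or numeric matrix (training rows only).
#' @return A `normalization_stats`: list with `mean` and `sd` (n-1
#'   denominator) per feature.
#' @export
fit_normalizer <- function(train) {
  x <- if (inherits(train, "feature_matrix")) train$x else train
  if (nrow(x) < 2L) abort_ns("need at least 2 training rows to estimate SDs")
  mu <- colMeans(x)
  sd <- apply(x, 2L, stats::sd)
  zero <- which(sd == 0)
  if (length(zero) > 0) {
    abort_ns(sprintf(
      "zero-variance feature column(s): %s",
      paste(colnames(x)[zero], collapse = ", ")
    ))
  }
  structure(list(mean = mu, sd = sd), class = "normalization_stats")
}

#' Apply training-set normalization statistics to a matrix
#'
#' @param stats a `normalization_stats` from [fit_normalizer()].
#' @param x a `feature_matrix` or numeric matrix.
#' @return The z-scored numeric matrix.
#' @export
apply_normalizer <- function(stats, x) {
  if (inherits(x, "feature_matrix")) x <- x$x
  if (ncol(x) != length(stats$mean)) {
    abort_ns("feature-column mismatch between data and normalizer")
  }
  sweep(sweep(x, 2L, stats$mean, "-"), 2L, stats$sd, "/")
}

#' Train a linear SVM on normalized features
#'
#' Maximum-margin linear decision rule (soft margin, cost `C`) over
#' z-scored features; deterministic given data and `C`. Prediction
#' tie-break: a decision value of exactly zero maps to `"relax"`.
#'
#' @param train a `feature_matrix` with both classes present.
#' @param stats a `normalization_stats` fitted on `train` (fitted here if
#'   `NULL`).
#' @param C soft-margin cost (default 1).
#' @return A `state_classifier`: list with the fitted `e1071::svm` model,
#'   the normalizer, `w` and `b` of the decision function
#'   `f(x) = x . w + b`, and the class level mapped to positive scores.
#' @export
train_classifier <- function(train, stats = NULL, C = 1) {
  stopifnot(inherits(train, "feature_matrix"))
  y <- factor(train$labels, levels = CLASS_LEVELS)
  if (anyNA(y)) abort_ns("labels must be 'relax' or 'nback'")
  if (length(unique(y)) < 2L) abort_ns("training set contains a single class")
  stats <- stats %||% fit_normalizer(train)
  xz <- apply_normalizer(stats, train)
  model <- e1071::svm(xz, y,
    kernel = "linear", cost = C, scale = FALSE,
    type = "C-classification"
  )
  # recover the explicit linear rule; libsvm orients decision values by
  # order of class appearance in the training data, so canonicalize to
  # score > 0 <=> "nback"
  w <- drop(t(model$coefs) %*% model$SV)
  b <- -model$rho
  dv <- attr(
    predict(model, xz[1, , drop = FALSE], decision.values = TRUE),
    "decision.values"
  )
  libsvm_positive <- strsplit(colnames(dv), "/", fixed = TRUE)[[1]][1]
  if (libsvm_positive != "nback") {
    w <- -w
    b <- -b
  }
  structure(
    list(
      model = model, stats = stats, C = C,
      w = w, b = b, positive_class = "nback",
      feature_names = colnames(train$x)
    ),
    class = "state_classifier"
  )
}

#' Predict epoch labels with a trained classifier
#'
#' @param object a `state_classifier`.
#' @param newdata a `feature_matrix` or numeric matrix (raw, un-normalized
#'   features; the classifier's own training normalizer is applied).
#' @param ... unused.
#' @return A data.frame with `score` (signed decision value) and `label`.
#' @export
predict.state_classifier <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "feature_matrix")) newdata$x else newdata
  if (ncol(x) != length(object$w)) {
    abort_ns("feature-column mismatch between sessions")
  }
  xz <- apply_normalizer(object$stats, x)
  score <- drop(xz %*% object$w) + object$b
  # score > 0 -> "nback"; an exact boundary tie deterministically maps to
  # "relax"
  label <- ifelse(score > 0, "nback", "relax")
  data.frame(score = score, label = label, stringsAsFactors = FALSE)
}

# seed-reproducible stratified fold assignment: class proportions preserved
stratified_folds <- function(labels, k, seed) {
  if (k > length(labels)) abort_ns("more folds than epochs")
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      if (length(idx) < k) {
        abort_ns(sprintf(
          "class '%s' has %d epoch(s); need at least %d for %d-fold CV",
          cl, length(idx), k, k
        ))
      }
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  fold
}

#' Stratified k-fold cross-validation of the linear SVM
#'
#' Normalization statistics and the decision rule are fitted inside each
#' training fold only, so no test information leaks into training. The
#' headline accuracy is the mean over fold accuracies, in percent; the
#' pooled per-epoch accuracy is also reported.
#'
#' @param features a `feature_matrix`.
#' @param k number of folds (default 5).
#' @param C SVM cost (default 1).
#' @param seed integer controlling the fold assignment.
#' @return A `cv_result`: list with `fold_accuracies` (fractions),
#'   `mean_accuracy` (%), `pooled_accuracy` (%), `predictions` (data.frame
#'   `epoch`, `fold`, `truth`, `predicted`, `score`), `confusion`,
#'   `fold_assignment`.
#' @export
crossvalidate <- function(features, k = 5, C = 1, seed = 1) {
  stopifnot(inherits(features, "feature_matrix"))
  labels <- features$labels
  fold <- stratified_folds(labels, k, seed)
  preds <- data.frame(
    epoch = seq_along(labels), fold = fold, truth = labels,
    predicted = NA_character_, score = NA_real_, stringsAsFactors = FALSE
  )
  acc <- numeric(k)
  for (f in seq_len(k)) {
    tr_idx <- which(fold != f)
    te_idx <- which(fold == f)
    train_fm <- structure(
      list(x = features$x[tr_idx, , drop = FALSE], labels = labels[tr_idx]),
      class = "feature_matrix"
    )
    clf <- train_classifier(train_fm, C = C)
    p <- predict(clf, features$x[te_idx, , drop = FALSE])
    preds$predicted[te_idx] <- p$label
    preds$score[te_idx] <- p$score
    acc[f] <- mean(p$label == labels[te_idx])
  }
  confusion <- table(truth = preds$truth, predicted = preds$predicted)
  structure(
    list(
      fold_accuracies = acc,
      mean_accuracy = 100 * mean(acc),
      pooled_accuracy = 100 * mean(preds$predicted == preds$truth),
      predictions = preds,
      confusion = confusion,
      fold_assignment = fold,
      k = k, C = C, seed = seed
    ),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "<cv_result> %d-fold CV: mean accuracy %.2f%% (folds: %s), pooled %.2f%%\n",
    x$k, x$mean_accuracy,
    paste(sprintf("%.2f", x$fold_accuracies), collapse = ", "),
    x$pooled_accuracy
  ))
  invisible(x)
}

#' Replay an online session against a calibration-trained classifier
#'
#' Trains once on all calibration epochs (with the calibration-fitted
#' normalizer), then applies the fixed decision rule to the online epochs
#' in temporal order -- the simulated feedback stream of the closed-loop
#' session.
#'
#' @param calibration a `feature_matrix` (both classes present).
#' @param online a `feature_matrix` with the same feature columns.
#' @param C SVM cost.
#' @return An `online_replay`: list with `predictions` (per-epoch decision
#'   stream: `epoch`, `truth`, `predicted`, `score`), `accuracy` (%),
#'   `classifier`.
#' @export
replay_online <- function(calibration, online, C = 1) {
  stopifnot(inherits(calibration, "feature_matrix"), inherits(online, "feature_matrix"))
  if (!identical(colnames(calibration$x), colnames(online$x))) {
    abort_ns("feature-column mismatch between calibration and online sessions")
  }
  clf <- train_classifier(calibration, C = C)
  p <- predict(clf, online)
  structure(
    list(
      predictions = data.frame(
        epoch = seq_along(online$labels), truth = online$labels,
        predicted = p$label, score = p$score, stringsAsFactors = FALSE
      ),
      accuracy = 100 * mean(p$label == online$labels),
      classifier = clf
    ),
    class = "online_replay"
  )
}
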