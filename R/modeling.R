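#' Classifier specification
#'
#' @param kind one of "knn", "rf", "svm-l", "svm-r", "svm-p", "bnn".
#' @param k neighbours for KNN (Euclidean distance; default 1).
#' @param trees trees for the random forest (default 500; bootstrap
#'   resamples of training-set size, sqrt(p) features per split).
#' @param gamma RBF kernel width parameter for "svm-r" (NULL = e1071
#'   default 1/p); for the polynomial kernel it is the inner-product
#'   scale.
#' @param degree polynomial degree for "svm-p" (degree 1 degenerates to
#'   the linear kernel).
#' @param cost SVM cost parameter.
#' @param bnn list of [trainBNN()] arguments for kind "bnn".
#' @return list of class `ClassifierSpec`.
#' @export
classifierSpec <- function(kind = c("knn", "rf", "svm-l", "svm-r",
                                    "svm-p", "bnn"),
                           k = 1, trees = 500, gamma = NULL, degree = 3,
                           cost = 1, bnn = list()) {
  kind <- match.arg(kind)
  if (k < 1 || trees < 1 || degree < 1) stop("invalid hyperparameter")
  structure(list(kind = kind, k = k, trees = trees, gamma = gamma,
                 degree = degree, cost = cost, bnn = bnn),
            class = "ClassifierSpec")
}

# One-vs-rest multi-class SVM on top of e1071's binary machines:
# one binary SVM per class, prediction by the largest decision value.
svmOneVsRest <- function(xtr, ytr, xte, kernel, gamma, degree, cost) {
  classes <- levels(ytr)
  scores <- matrix(NA_real_, nrow = nrow(xte), ncol = length(classes),
                   dimnames = list(NULL, classes))
  args <- list(kernel = kernel, cost = cost, scale = FALSE)
  if (!is.null(gamma)) args$gamma <- gamma
  if (kernel == "polynomial") args$degree <- degree
  for (cl in classes) {
    yy <- factor(ifelse(ytr == cl, "pos", "neg"), levels = c("pos", "neg"))
    fit <- do.call(e1071::svm, c(list(x = xtr, y = yy), args))
    dv <- attr(stats::predict(fit, xte, decision.values = TRUE),
               "decision.values")
    # orient so that larger = more "pos"
    s <- dv[, 1]
    if (grepl("^neg", colnames(dv)[1])) s <- -s
    scores[, cl] <- s
  }
  factor(classes[max.col(scores)], levels = classes)
}

# Fit spec on (xtr, ytr), predict labels for xte.
fitPredict <- function(spec, xtr, ytr, xte, seed = 1L) {
  ytr <- factor(ytr)
  switch(spec$kind,
    "knn" = withSeed(seed, class::knn(xtr, xte, ytr, k = spec$k)),
    "rf" = withSeed(seed, {
      fit <- randomForest::randomForest(x = xtr, y = ytr,
                                        ntree = spec$trees)
      stats::predict(fit, xte)
    }),
    "svm-l" = svmOneVsRest(xtr, ytr, xte, "linear", spec$gamma,
                           spec$degree, spec$cost),
    "svm-r" = svmOneVsRest(xtr, ytr, xte, "radial", spec$gamma,
                           spec$degree, spec$cost),
    "svm-p" = svmOneVsRest(xtr, ytr, xte, "polynomial", spec$gamma,
                           spec$degree, spec$cost),
    "bnn" = withSeed(seed, {
      fit <- do.call(trainBNN, c(list(x = xtr, y = ytr), spec$bnn))
      predictBNN(fit, xte)$class
    }),
    stop("unknown classifier kind: ", spec$kind))
}

#' Classification metrics with macro-averaged one-vs-rest components
#'
#' Multi-class accuracy plus per-class one-vs-rest precision, recall and
#' F1, macro-averaged with equal class weight. Zero-denominator
#' per-class ratios are returned as 0 and flagged. The default F1 is the
#' standard harmonic mean of precision and recall; an accuracy-based
#' variant 2*accuracy*recall/(accuracy+recall) is available behind
#' `f1 = "accuracy"`.
#'
#' @param predictions predicted labels.
#' @param labels true labels (same length).
#' @param f1 "standard" or "accuracy".
#' @return object of class `MetricsReport`: list with `accuracy`,
#'   `precision`, `recall`, `f1` (macro), `perClass` (data.frame with
#'   TP/FP/FN/TN and per-class metrics) and `undefinedRatios` flag.
#' @export
computeMetrics <- function(predictions, labels,
                           f1 = c("standard", "accuracy")) {
  f1 <- match.arg(f1)
  if (length(predictions) == 0 || length(predictions) != length(labels))
    stop("predictions and labels must be non-empty and equal length")
  classes <- sort(union(as.character(labels), as.character(predictions)))
  pred <- factor(as.character(predictions), levels = classes)
  truth <- factor(as.character(labels), levels = classes)
  acc <- mean(pred == truth)
  n <- length(truth)
  pc <- data.frame(class = classes, TP = NA_real_, FP = NA_real_,
                   FN = NA_real_, TN = NA_real_, precision = NA_real_,
                   recall = NA_real_, f1 = NA_real_,
                   stringsAsFactors = FALSE)
  undef <- FALSE
  for (i in seq_along(classes)) {
    tp <- sum(pred == classes[i] & truth == classes[i])
    fp <- sum(pred == classes[i] & truth != classes[i])
    fn <- sum(pred != classes[i] & truth == classes[i])
    tn <- n - tp - fp - fn
    prec <- if (tp + fp > 0) tp / (tp + fp) else {undef <- TRUE; 0}
    rec <- if (tp + fn > 0) tp / (tp + fn) else {undef <- TRUE; 0}
    base <- if (f1 == "standard") prec else acc
    f1i <- if (base + rec > 0) 2 * base * rec / (base + rec)
           else {undef <- TRUE; 0}
    pc[i, 2:8] <- c(tp, fp, fn, tn, prec, rec, f1i)
  }
  structure(list(accuracy = acc, precision = mean(pc$precision),
                 recall = mean(pc$recall), f1 = mean(pc$f1),
                 perClass = pc, undefinedRatios = undef,
                 f1Variant = f1),
            class = "MetricsReport")
}

#' @export
print.MetricsReport <- function(x, ...) {
  cat(sprintf(
    "accuracy %.4f | macro precision %.4f | recall %.4f | F1 %.4f\n",
    x$accuracy, x$precision, x$recall, x$f1))
  invisible(x)
}

#' Stratified fold assignment
#'
#' @param labels class labels.
#' @param folds number of folds.
#' @param seed RNG seed; identical inputs give identical folds.
#' @return integer fold id per sample.
#' @export
stratifiedFolds <- function(labels, folds, seed = 1L) {
  labels <- factor(labels)
  if (folds < 2) stop("need at least 2 folds")
  if (any(table(labels) < folds))
    stop("each class needs at least `folds` samples for stratified folds")
  id <- integer(length(labels))
  withSeed(seed, {
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })
  id
}

#' Cross-validated training and evaluation
#'
#' Stratified k-fold cross-validation: per fold, features are z-scored
#' with statistics fitted on the training rows only (or once globally
#' when `globalStandardize = TRUE`), the classifier is fitted and the held-out
#' fold evaluated; metrics are aggregated as mean and standard deviation
#' over folds.
#'
#' @param features feature table (matrix epochs x features or
#'   `SummarizedExperiment`).
#' @param labels class labels; defaults to the table's MWL labels.
#' @param spec a [classifierSpec()].
#' @param folds number of folds (default 10).
#' @param seed RNG seed controlling fold assignment and any stochastic
#'   fitting.
#' @param globalStandardize if TRUE, standardize globally before splitting.
#' @param f1 F1 variant, see [computeMetrics()].
#' @return object of class `CVReport`: list with `mean`, `sd` (named
#'   accuracy/precision/recall/f1), `folds` (per-fold data.frame),
#'   `reports` (per-fold `MetricsReport`s), `spec`, `seed`.
#' @export
crossValidate <- function(features, labels = NULL, spec = classifierSpec(),
                          folds = 10, seed = 1L, globalStandardize = FALSE,
                          f1 = "standard") {
  m <- asFeatureMatrix(features)
  if (is.null(labels) && is(features, "SummarizedExperiment"))
    labels <- mwlLabels(features)
  labels <- factor(labels)
  if (!all(is.finite(m))) stop("non-finite feature values")
  foldId <- stratifiedFolds(labels, folds, seed)
  if (globalStandardize) m <- zscoreFeatures(m)
  perFold <- vector("list", folds)
  for (f in seq_len(folds)) {
    te <- foldId == f
    xtr <- m[!te, , drop = FALSE]
    xte <- m[te, , drop = FALSE]
    if (!globalStandardize) {
      z <- zscoreFeatures(rbind(xtr, xte), fitRows = seq_len(nrow(xtr)))
      xtr <- z[seq_len(nrow(xtr)), , drop = FALSE]
      xte <- z[nrow(xtr) + seq_len(sum(te)), , drop = FALSE]
    }
    if (nlevels(droplevels(labels[!te])) < nlevels(labels))
      stop("a class is absent from the training split of fold ", f)
    pred <- fitPredict(spec, xtr, labels[!te], xte,
                       seed = seed + 7919L * f)
    perFold[[f]] <- computeMetrics(pred, labels[te], f1 = f1)
  }
  tab <- data.frame(fold = seq_len(folds),
                    accuracy = vapply(perFold, `[[`, 0, "accuracy"),
                    precision = vapply(perFold, `[[`, 0, "precision"),
                    recall = vapply(perFold, `[[`, 0, "recall"),
                    f1 = vapply(perFold, `[[`, 0, "f1"))
  structure(list(mean = colMeans(tab[, -1]),
                 sd = apply(tab[, -1], 2, stats::sd),
                 folds = tab, reports = perFold, spec = spec,
                 seed = seed, globalStandardize = globalStandardize),
            class = "CVReport")
}

#' @export
print.CVReport <- function(x, ...) {
  cat(sprintf("%d-fold CV (%s): ", nrow(x$folds), x$spec$kind))
  cat(sprintf("accuracy %.4f +/- %.4f | precision %.4f | recall %.4f | F1 %.4f\n",
              x$mean["accuracy"], x$sd["accuracy"], x$mean["precision"],
              x$mean["recall"], x$mean["f1"]))
  invisible(x)
}
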