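#' Sequential forward floating selection (SFFS)
#'
#' Wrapper feature selection around a cross-validated classifier
#' (default KNN with k = 1, 10-fold stratified CV, accuracy criterion).
#' Plain forward selection greedily adds the accuracy-maximizing
#' feature; the floating variant follows every inclusion with
#' conditional exclusion steps that remove a feature again whenever the
#' removal strictly improves the best criterion known at the smaller
#' subset size. A state-history check skips exclusions that would
#' revisit a previously seen subset (cycle protection). Ties are broken
#' toward the lowest column index, making the search deterministic.
#'
#' @param features feature table (matrix epochs x features or
#'   `SummarizedExperiment`).
#' @param labels class labels; defaults to the table's MWL labels.
#' @param spec wrapped estimator, a [classifierSpec()] (default KNN k=1).
#' @param folds CV folds for the criterion (default 10).
#' @param maxD largest subset size to grow to (default: all features).
#' @param seed RNG seed fixing the fold assignment for every criterion
#'   evaluation.
#' @param globalStandardize passed to [crossValidate()].
#' @return object of class `SFFSTrace`: list with `bestBySize`
#'   (data.frame size, criterion, features), `best` (overall best subset
#'   and criterion), `steps` (log of inclusion/exclusion/skip events),
#'   and `evaluations` (criterion calls made).
#' @export
sffs <- function(features, labels = NULL, spec = classifierSpec(),
                 folds = 10, maxD = NULL, seed = 1L, globalStandardize = FALSE) {
  m <- asFeatureMatrix(features)
  if (is.null(labels) && is(features, "SummarizedExperiment"))
    labels <- mwlLabels(features)
  labels <- factor(labels)
  if (!all(is.finite(m))) stop("non-finite feature values")
  p <- ncol(m)
  if (is.null(maxD)) maxD <- p
  if (maxD > p) stop("maxD exceeds the number of features")
  cn <- colnames(m)
  if (is.null(cn)) cn <- colnames(m) <- paste0("f", seq_len(p))

  nEval <- 0L
  crit <- function(cols) {
    nEval <<- nEval + 1L
    cv <- crossValidate(m[, cols, drop = FALSE], labels, spec = spec,
                        folds = folds, seed = seed, globalStandardize = globalStandardize)
    unname(cv$mean["accuracy"])
  }

  bestCrit <- rep(-Inf, maxD)          # best criterion known per size
  bestSet <- vector("list", maxD)
  note <- function(cols, value) {
    d <- length(cols)
    if (d >= 1 && d <= maxD && value > bestCrit[d]) {
      bestCrit[d] <<- value
      bestSet[[d]] <<- sort(cols)
    }
  }
  keyOf <- function(cols) paste(sort(cols), collapse = ",")
  visited <- new.env(hash = TRUE)
  steps <- list()
  log1 <- function(action, feature, size, value) {
    steps[[length(steps) + 1L]] <<- data.frame(
      action = action, feature = feature, size = size,
      criterion = value, stringsAsFactors = FALSE)
  }

  current <- integer(0)
  currentCrit <- -Inf
  while (length(current) < maxD) {
    # forward inclusion: best single addition
    cand <- setdiff(seq_len(p), current)
    vals <- vapply(cand, function(j) crit(c(current, j)), numeric(1))
    j <- cand[which.max(vals)]
    current <- c(current, j)
    currentCrit <- max(vals)
    note(current, currentCrit)
    assign(keyOf(current), TRUE, envir = visited)
    log1("include", cn[j], length(current), currentCrit)

    # conditional exclusion (floating): drop a feature while doing so
    # strictly improves the best-known criterion at the smaller size
    while (length(current) > 2) {
      vals <- vapply(current, function(j)
        crit(setdiff(current, j)), numeric(1))
      i <- which.max(vals)
      smaller <- setdiff(current, current[i])
      if (vals[i] <= bestCrit[length(smaller)] + 1e-12) break
      if (exists(keyOf(smaller), envir = visited)) {
        log1("skip-cycle", cn[current[i]], length(smaller), vals[i])
        break
      }
      dropped <- current[i]
      current <- smaller
      currentCrit <- vals[i]
      note(current, currentCrit)
      assign(keyOf(current), TRUE, envir = visited)
      log1("exclude", cn[dropped], length(current), currentCrit)
    }
  }

  sizes <- which(is.finite(bestCrit))
  bestBySize <- data.frame(
    size = sizes, criterion = bestCrit[sizes],
    features = vapply(bestSet[sizes],
                      function(s) paste(cn[s], collapse = ","), ""),
    stringsAsFactors = FALSE)
  bi <- sizes[which.max(bestCrit[sizes])]
  structure(list(bestBySize = bestBySize,
                 best = list(size = bi, criterion = bestCrit[bi],
                             features = cn[bestSet[[bi]]],
                             columns = bestSet[[bi]]),
                 steps = do.call(rbind, steps),
                 evaluations = nEval, spec = spec, folds = folds,
                 seed = seed),
            class = "SFFSTrace")
}

#' @export
print.SFFSTrace <- function(x, ...) {
  cat("SFFS trace:", nrow(x$bestBySize), "subset sizes,",
      x$evaluations, "criterion evaluations\n")
  cat(sprintf("best: %d feature(s), criterion %.4f\n  %s\n",
              x$best$size, x$best$criterion,
              paste(x$best$features, collapse = ", ")))
  invisible(x)
}

#' Plain sequential forward selection (no floating step)
#'
#' Reference forward search used for comparison with [sffs()]; by
#' construction the floating search never reports a worse criterion at
#' any subset size it reaches.
#'
#' @inheritParams sffs
#' @return data.frame `size`, `criterion`, `features`.
#' @export
sfs <- function(features, labels = NULL, spec = classifierSpec(),
                folds = 10, maxD = NULL, seed = 1L, globalStandardize = FALSE) {
  m <- asFeatureMatrix(features)
  if (is.null(labels) && is(features, "SummarizedExperiment"))
    labels <- mwlLabels(features)
  labels <- factor(labels)
  p <- ncol(m)
  if (is.null(maxD)) maxD <- p
  cn <- colnames(m)
  if (is.null(cn)) cn <- paste0("f", seq_len(p))
  crit <- function(cols) {
    cv <- crossValidate(m[, cols, drop = FALSE], labels, spec = spec,
                        folds = folds, seed = seed, globalStandardize = globalStandardize)
    unname(cv$mean["accuracy"])
  }
  current <- integer(0)
  out <- data.frame(size = integer(), criterion = numeric(),
                    features = character(), stringsAsFactors = FALSE)
  while (length(current) < maxD) {
    cand <- setdiff(seq_len(p), current)
    vals <- vapply(cand, function(j) crit(c(current, j)), numeric(1))
    j <- cand[which.max(vals)]
    current <- c(current, j)
    out <- rbind(out, data.frame(
      size = length(current), criterion = max(vals),
      features = paste(cn[sort(current)], collapse = ","),
      stringsAsFactors = FALSE))
  }
  out
}
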