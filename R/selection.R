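#' @importFrom stats shapiro.test kruskal.test sd var
NULL

# Accept either a SummarizedExperiment feature table or a plain
# epochs x features matrix.
asFeatureMatrix <- function(x, domain = NULL) {
  if (is(x, "SummarizedExperiment")) featureMatrix(x, domain)
  else as.matrix(x)
}

#' Per-feature normality screen
#'
#' Shapiro-Wilk test of each feature column. Features whose values are
#' (numerically) constant cannot be tested; they are flagged degenerate
#' and treated as non-normal by convention, so the rank-based path is
#' taken downstream either way.
#'
#' @param features feature table (matrix epochs x features, or a
#'   `SummarizedExperiment` from [extractFeatures()]).
#' @param alpha significance level for the normal/non-normal call.
#' @return data.frame with `feature`, `p`, `normal`, `degenerate`.
#' @export
normalityScreen <- function(features, alpha = 0.05) {
  m <- asFeatureMatrix(features)
  if (nrow(m) < 3) stop("need at least 3 samples per feature")
  res <- data.frame(feature = colnames(m), p = NA_real_,
                    normal = NA, degenerate = FALSE,
                    stringsAsFactors = FALSE)
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    if (stats::var(x) < .Machine$double.eps) {
      res$degenerate[j] <- TRUE
      res$p[j] <- 0
    } else {
      if (length(x) > 5000) x <- x[seq(1, length(x), length.out = 5000)]
      res$p[j] <- stats::shapiro.test(x)$p.value
    }
  }
  res$normal <- res$p >= alpha & !res$degenerate
  res
}

#' Kruskal-Wallis feature screen across workload classes
#'
#' Tie-corrected Kruskal-Wallis H per feature over the three MWL
#' classes, with chi-squared (df = classes - 1) p-values, and the
#' selected feature sets at both conventional significance levels. The
#' stricter set is always a subset of the looser one.
#'
#' @param features feature table (matrix or `SummarizedExperiment`).
#' @param labels class labels (factor or character), one per epoch; if
#'   omitted and `features` carries MWL labels, those are used.
#' @param alphas significance levels for the selected sets.
#' @return object of class `ScreenResult`: list with `table`
#'   (feature, H, p), `selected` (named list of feature-name vectors per
#'   alpha), and `alphas`.
#' @export
kwScreen <- function(features, labels = NULL, alphas = c(0.05, 0.01)) {
  m <- asFeatureMatrix(features)
  if (is.null(labels) && is(features, "SummarizedExperiment"))
    labels <- mwlLabels(features)
  labels <- factor(labels)
  if (nlevels(labels) < 3) stop("need at least 3 classes for the screen")
  if (any(table(labels) < 2)) stop("each class needs at least 2 samples")
  tab <- data.frame(feature = colnames(m), H = NA_real_, p = NA_real_,
                    stringsAsFactors = FALSE)
  for (j in seq_len(ncol(m))) {
    if (stats::var(m[, j]) < .Machine$double.eps) {
      # constant feature: all mean ranks equal, H = 0 by definition
      tab$H[j] <- 0
      tab$p[j] <- 1
    } else {
      kt <- stats::kruskal.test(m[, j], labels)
      tab$H[j] <- unname(kt$statistic)
      tab$p[j] <- kt$p.value
    }
  }
  selected <- lapply(alphas, function(a) tab$feature[tab$p < a])
  names(selected) <- paste0("alpha", alphas)
  structure(list(table = tab, selected = selected, alphas = alphas),
            class = "ScreenResult")
}

#' @export
print.ScreenResult <- function(x, ...) {
  cat("Kruskal-Wallis screen over", nrow(x$table), "features\n")
  for (i in seq_along(x$alphas))
    cat(sprintf("  selected at alpha = %.2g: %d features\n",
                x$alphas[i], length(x$selected[[i]])))
  invisible(x)
}

#' Z-score standardization with an explicit fitting subset
#'
#' Standardizes every feature column to zero mean and unit variance
#' using statistics estimated on `fitRows` only (leakage-safe when fit
#' on training rows), then applied to all rows. Zero-variance features
#' are mapped to 0 and flagged.
#'
#' @param features feature table (matrix or `SummarizedExperiment`).
#' @param fitRows integer or logical row subset to estimate mean/sd on
#'   (default: all rows, the global standardization used when the whole
#'   table is screened at once).
#' @return standardized matrix with attributes `center`, `scale`,
#'   `degenerate` (names of zero-variance features).
#' @export
zscoreFeatures <- function(features, fitRows = NULL) {
  m <- asFeatureMatrix(features)
  if (is.null(fitRows)) fitRows <- seq_len(nrow(m))
  fit <- m[fitRows, , drop = FALSE]
  ctr <- colMeans(fit)
  scl <- apply(fit, 2, stats::sd)
  degenerate <- colnames(m)[scl < .Machine$double.eps]
  scl[scl < .Machine$double.eps] <- 1
  out <- sweep(sweep(m, 2, ctr), 2, scl, "/")
  out[, degenerate] <- 0
  attr(out, "center") <- ctr
  attr(out, "scale") <- scl
  attr(out, "degenerate") <- degenerate
  out
}
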