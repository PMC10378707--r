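#' Test workload differences between flight phases
#'
#' Runs a one-way ANOVA of the NASA-TLX weighted scores across the three
#' phases, plus all pairwise Welch t-tests judged against a
#' Bonferroni-corrected threshold (family alpha divided by the number of
#' comparisons, reported to three decimals: 0.05/3 -> 0.017), and ranks
#' the phases by mean score to obtain the low/middle/high label map.
#'
#' @param scores data.frame with columns `phase` and `weighted_score`
#'   (e.g. from [simulateTLX()] or [simulateTLXScores()]).
#' @param alpha family-wise significance level (default 0.05).
#' @return an object of class `MWLLabeling`: list with `map` (named
#'   character phase -> low/middle/high), `phaseMeans`, `anova`
#'   (F, p, degenerate flag), `pairwise` (data.frame of Welch p-values),
#'   and `alphaCorrected`.
#' @export
testPhaseDifferences <- function(scores, alpha = 0.05) {
  stopifnot(all(c("phase", "weighted_score") %in% names(scores)))
  phases <- unique(scores$phase)
  if (length(phases) < 2) stop("need at least two phases")
  counts <- table(scores$phase)
  if (any(counts < 2))
    stop("each phase needs at least 2 records; short: ",
         paste(names(counts)[counts < 2], collapse = ", "))
  nComp <- choose(length(phases), 2)
  alphaCorr <- round(alpha / nComp, 3)

  phaseMeans <- tapply(scores$weighted_score, scores$phase, mean)
  degenerate <- all(tapply(scores$weighted_score, scores$phase,
                           stats::var) < .Machine$double.eps)
  if (degenerate) {
    anovaRes <- list(F = NA_real_, p = NA_real_, degenerate = TRUE)
  } else {
    fit <- stats::aov(weighted_score ~ factor(phase), data = scores)
    s <- summary(fit)[[1]]
    anovaRes <- list(F = s$`F value`[1], p = s$`Pr(>F)`[1],
                     degenerate = FALSE)
  }

  pairs <- utils::combn(sort(phases), 2)
  pw <- data.frame(phase1 = pairs[1, ], phase2 = pairs[2, ],
                   p = NA_real_, significant = NA,
                   stringsAsFactors = FALSE)
  for (i in seq_len(ncol(pairs))) {
    x <- scores$weighted_score[scores$phase == pairs[1, i]]
    y <- scores$weighted_score[scores$phase == pairs[2, i]]
    if (stats::var(x) + stats::var(y) < .Machine$double.eps) {
      pw$p[i] <- NA_real_
    } else {
      pw$p[i] <- stats::t.test(x, y)$p.value
    }
  }
  pw$significant <- !is.na(pw$p) & pw$p < alphaCorr

  rk <- rank(phaseMeans, ties.method = "min")
  if (anyDuplicated(rk))
    stop("tie in phase mean scores; supply an explicit label map")
  lv <- c("low", "middle", "high")[rank(phaseMeans)]
  names(lv) <- names(phaseMeans)

  structure(list(map = lv, phaseMeans = phaseMeans, anova = anovaRes,
                 pairwise = pw, alphaCorrected = alphaCorr),
            class = "MWLLabeling")
}

#' @export
print.MWLLabeling <- function(x, ...) {
  cat("MWL labeling by phase mean weighted score:\n")
  for (p in names(x$map))
    cat(sprintf("  %-10s mean %8.2f -> %s\n", p, x$phaseMeans[[p]],
                x$map[[p]]))
  if (!isTRUE(x$anova$degenerate))
    cat(sprintf("one-way ANOVA: F = %.2f, p = %.3g\n",
                x$anova$F, x$anova$p))
  else cat("one-way ANOVA: degenerate (zero within-phase variance)\n")
  cat(sprintf("pairwise Welch t-tests at corrected alpha %.3f:\n",
              x$alphaCorrected))
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}

#' Attach MWL labels to a feature table
#'
#' Maps each epoch's phase to its workload label (low/middle/high, from
#' the phase ranking in an `MWLLabeling`) and stores it in the feature
#' table's column metadata.
#'
#' @param labeling an `MWLLabeling` from [testPhaseDifferences()], or a
#'   named character vector phase -> label.
#' @param features a [SummarizedExperiment::SummarizedExperiment] from
#'   [extractFeatures()] (epoch phase in `colData(features)$phase`).
#' @return the feature table with `colData(features)$mwl` added.
#' @export
assignLabels <- function(labeling, features) {
  map <- if (inherits(labeling, "MWLLabeling")) labeling$map else labeling
  phases <- SummarizedExperiment::colData(features)$phase
  if (is.null(phases)) stop("features must carry colData column 'phase'")
  miss <- setdiff(unique(phases), names(map))
  if (length(miss))
    stop("no label for phase(s): ", paste(miss, collapse = ", "))
  SummarizedExperiment::colData(features)$mwl <-
    factor(unname(map[phases]), levels = c("low", "middle", "high"))
  features
}
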