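#' Region-by-band classification comparison harness
#'
#' For every combination of brain region (frontal, temporal, occipital,
#' or all channels) and frequency band (the six bands, or "mix" for all
#' six together), selects the matching band-power columns (e.g.
#' temporal x delta -> T7-delta, T8-delta) and runs cross-validated
#' classification on just those columns, producing one metrics row per
#' cell.
#'
#' @param features a labelled feature table from [extractFeatures()] +
#'   [assignLabels()] (or a matrix plus explicit `labels`).
#' @param labels class labels; defaults to the table's MWL labels.
#' @param regions named list region -> channel vector; defaults to the
#'   montage's frontal/temporal/occipital map plus "all".
#' @param bands band names to test; "mix" is always added.
#' @param spec classifier (default KNN k = 1, the comparison estimator).
#' @param folds CV folds (default 10).
#' @param seed RNG seed for fold assignment.
#' @return object of class `RegionBandTable`: data.frame with region,
#'   band, nFeatures, and mean/sd of accuracy, precision, recall, F1;
#'   per-cell `CVReport`s attached as attribute `"reports"`.
#' @export
regionBandHarness <- function(features, labels = NULL, regions = NULL,
                              bands = defaultBands()$name,
                              spec = classifierSpec("knn", k = 1),
                              folds = 10, seed = 1L) {
  if (is.null(labels) && is(features, "SummarizedExperiment"))
    labels <- mwlLabels(features)
  m <- asFeatureMatrix(features)
  if (is.null(regions)) {
    rmap <- defaultChannelRegions()
    chans <- unique(sub("-.*$", "", colnames(m)))
    rmap <- rmap[names(rmap) %in% chans]
    regions <- split(names(rmap), unname(rmap))
    regions$all <- names(rmap)
  }
  cells <- expand.grid(region = names(regions),
                       band = c(bands, "mix"),
                       stringsAsFactors = FALSE)
  out <- data.frame(cells, nFeatures = NA_integer_,
                    accuracy = NA_real_, accuracy_sd = NA_real_,
                    precision = NA_real_, recall = NA_real_,
                    f1 = NA_real_)
  reports <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    chs <- regions[[cells$region[i]]]
    bds <- if (cells$band[i] == "mix") bands else cells$band[i]
    cols <- as.vector(outer(chs, bds, paste, sep = "-"))
    cols <- intersect(cols, colnames(m))
    if (!length(cols))
      stop("no feature columns for ", cells$region[i], " x ",
           cells$band[i])
    cv <- crossValidate(m[, cols, drop = FALSE], labels, spec = spec,
                        folds = folds, seed = seed)
    out$nFeatures[i] <- length(cols)
    out$accuracy[i] <- cv$mean["accuracy"]
    out$accuracy_sd[i] <- cv$sd["accuracy"]
    out$precision[i] <- cv$mean["precision"]
    out$recall[i] <- cv$mean["recall"]
    out$f1[i] <- cv$mean["f1"]
    reports[[i]] <- cv
  }
  attr(out, "reports") <- reports
  class(out) <- c("RegionBandTable", "data.frame")
  out
}
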