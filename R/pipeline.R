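#' Default end-to-end run configuration
#'
#' All tunable parameters of the pipeline in one serializable list:
#' simulation, filtering, windowing, rejection, feature, labeling,
#' selection and classification settings plus a single global seed that
#' fans out deterministically to every stage (stage seed =
#' seed * 1000 + stage offset + participant index).
#'
#' @param seed global integer seed.
#' @param nParticipants virtual participants to simulate.
#' @param out optional output directory; `NULL` keeps everything in
#'   memory.
#' @return list of class `RunConfig`.
#' @export
runConfig <- function(seed = 1L, nParticipants = 10, out = NULL) {
  structure(list(
    seed = as.integer(seed),
    nParticipants = nParticipants,
    out = out,
    sim = list(phaseDurations = c("take-off" = 60, "cruise" = 60,
                                  "landing" = 60),
               noiseAmp = 10, noiseExponent = 1,
               artifactRate = 4, artifactAmp = 150, fs = 128),
    filter = list(highCutHz = 40, lowCutHz = NULL),
    channels = list(flatVarUV2 = 1e-3, clipUV = 500),
    window = list(windowS = 2, overlap = 0.5),
    reject = list(ptpUV = 150),
    features = list(m = 2, rFraction = 0.2, taper = "rectangular"),
    tlx = list(n = 21),
    selection = list(method = "none", alpha = 0.01, pool = "psd"),
    classifier = list(kind = "knn", k = 1, folds = 10),
    globalStandardize = FALSE), class = "RunConfig")
}

#' Validate a run configuration
#'
#' Checks every cross-field invariant and returns all violations at
#' once rather than failing on the first.
#'
#' @param config a `RunConfig`.
#' @return character vector of error messages (empty when valid), with
#'   attribute `warnings` for non-fatal inconsistencies (e.g. a band
#'   edge above the filter cut).
#' @export
validateConfig <- function(config) {
  errs <- character()
  warns <- character()
  chk <- function(ok, msg) if (!isTRUE(ok)) errs <<- c(errs, msg)
  chk(is.numeric(config$seed) && length(config$seed) == 1, "seed")
  chk(config$nParticipants >= 1, "nParticipants: must be >= 1")
  chk(all(config$sim$phaseDurations >= config$window$windowS),
      "sim.phaseDurations: each phase must fit one window")
  chk(config$sim$noiseAmp >= 0, "sim.noiseAmp: must be >= 0")
  chk(config$filter$highCutHz < config$sim$fs / 2,
      "filter.highCutHz: must be below Nyquist")
  chk(config$window$overlap >= 0 && config$window$overlap < 1,
      "window.overlap: must lie in [0, 1)")
  chk(config$window$windowS > 0, "window.windowS: must be positive")
  chk(config$reject$ptpUV > 0, "reject.ptpUV: must be positive")
  chk(config$features$m >= 1, "features.m: must be >= 1")
  chk(config$features$rFraction > 0, "features.rFraction: must be > 0")
  chk(config$selection$method %in% c("none", "kw", "sffs"),
      "selection.method: one of none/kw/sffs")
  chk(config$classifier$folds >= 2, "classifier.folds: must be >= 2")
  bands <- defaultBands()
  if (any(bands$high_hz > config$filter$highCutHz))
    warns <- c(warns, sprintf(
      "band '%s' extends above the %g Hz low-pass cut",
      bands$name[which(bands$high_hz > config$filter$highCutHz)[1]],
      config$filter$highCutHz))
  known <- names(runConfig())
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    errs <- c(errs, paste("unknown config key(s):",
                          paste(unknown, collapse = ", ")))
  attr(errs, "warnings") <- warns
  errs
}

#' Read a run configuration from YAML
#'
#' @param path YAML file with (a subset of) the [runConfig()] keys;
#'   unknown keys are rejected by [validateConfig()].
#' @return a `RunConfig` with the file's values over the defaults.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- runConfig()
  for (k in names(y)) {
    if (is.list(cfg[[k]]) && is.list(y[[k]]))
      for (k2 in names(y[[k]])) cfg[[k]][[k2]] <- y[[k]][[k2]]
    else cfg[[k]] <- y[[k]]
  }
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' Run the full workload-detection pipeline
#'
#' Simulate -> preprocess -> extract features -> label from the TLX
#' survey -> (optionally) select features -> cross-validated
#' classification, with per-stage counts collected in a manifest.
#' Deterministic under the config seed.
#'
#' @param config a `RunConfig` from [runConfig()] or [readRunConfig()].
#' @return list of class `RunManifest`: `counts` (epochs and features
#'   per stage), `labeling` (the `MWLLabeling`), `selection` (screen or
#'   SFFS result, if requested), `cv` (the final `CVReport`), `config`,
#'   and `features` (the labelled feature table).
#' @export
runPipeline <- function(config = runConfig()) {
  errs <- validateConfig(config)
  if (length(errs))
    stop("invalid RunConfig: ", paste(errs, collapse = "; "))
  for (w in attr(errs, "warnings")) warning(w)

  seed <- config$seed
  featList <- vector("list", config$nParticipants)
  counts <- list(epochsSegmented = 0L, epochsRetained = 0L)
  for (i in seq_len(config$nParticipants)) {
    sc <- simConfig(fs = config$sim$fs,
                    phaseDurations = config$sim$phaseDurations,
                    noiseAmp = config$sim$noiseAmp,
                    noiseExponent = config$sim$noiseExponent,
                    artifactRate = config$sim$artifactRate,
                    artifactAmp = config$sim$artifactAmp,
                    seed = seed * 1000L + i)
    rec <- simulateRecording(sc)
    rec <- lowpassFilter(rec, config$filter$highCutHz,
                         config$filter$lowCutHz)
    rec <- dropBadChannels(rec, config$channels$flatVarUV2,
                           config$channels$clipUV)
    ep <- segmentEpochs(rec, config$window$windowS,
                        config$window$overlap)
    counts$epochsSegmented <- counts$epochsSegmented + nEpochs(ep)
    ep <- rejectEpochs(ep, config$reject$ptpUV)
    counts$epochsRetained <- counts$epochsRetained + nEpochs(ep)
    fe <- extractFeatures(ep, m = config$features$m,
                          r = config$features$rFraction,
                          taper = config$features$taper)
    SummarizedExperiment::colData(fe)$participant <- i
    colnames(fe) <- paste0("p", i, "_",
                           SummarizedExperiment::colData(fe)$epoch_id)
    featList[[i]] <- fe
  }
  features <- do.call(SummarizedExperiment::cbind, featList)

  tlx <- simulateTLX(tlxConfig(seed = seed * 1000L + 900L),
                     config$tlx$n)
  labeling <- testPhaseDifferences(tlx)
  features <- assignLabels(labeling, features)

  selection <- NULL
  useCols <- NULL
  if (config$selection$method == "kw") {
    pool <- featureMatrix(features, config$selection$pool)
    selection <- kwScreen(pool, mwlLabels(features))
    useCols <- selection$selected[[paste0("alpha",
                                          config$selection$alpha)]]
  } else if (config$selection$method == "sffs") {
    pool <- featureMatrix(features, config$selection$pool)
    selection <- sffs(pool, mwlLabels(features),
                      folds = config$classifier$folds,
                      seed = seed * 1000L + 910L,
                      globalStandardize = config$globalStandardize)
    useCols <- selection$best$features
  }

  m <- featureMatrix(features)
  if (!is.null(useCols)) m <- m[, useCols, drop = FALSE]
  spec <- classifierSpec(config$classifier$kind,
                         k = config$classifier$k)
  cv <- crossValidate(m, mwlLabels(features), spec = spec,
                      folds = config$classifier$folds,
                      seed = seed * 1000L + 920L,
                      globalStandardize = config$globalStandardize)

  counts$featureColumns <- ncol(featureMatrix(features))
  counts$featureColumnsUsed <- ncol(m)
  counts$featureRows <- nrow(featureMatrix(features))

  manifest <- structure(list(counts = counts, labeling = labeling,
                             selection = selection, cv = cv,
                             config = config, features = features),
                        class = "RunManifest")
  if (!is.null(config$out)) writeManifest(manifest, config$out)
  manifest
}

writeManifest <- function(manifest, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeFeatureCSV(manifest$features, file.path(dir, "features.csv"))
  jsonlite::write_json(
    list(counts = manifest$counts,
         labelMap = as.list(manifest$labeling$map),
         alphaCorrected = manifest$labeling$alphaCorrected,
         cvMean = as.list(manifest$cv$mean),
         cvSd = as.list(manifest$cv$sd),
         seed = manifest$config$seed),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.RunManifest <- function(x, ...) {
  cat("MWL pipeline run (seed ", x$config$seed, ")\n", sep = "")
  cat("  epochs: ", x$counts$epochsSegmented, " segmented, ",
      x$counts$epochsRetained, " retained\n", sep = "")
  cat("  features: ", x$counts$featureRows, " epochs x ",
      x$counts$featureColumns, " columns (",
      x$counts$featureColumnsUsed, " used)\n", sep = "")
  print(x$cv)
  invisible(x)
}
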