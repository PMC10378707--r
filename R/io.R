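#' @importFrom utils read.csv write.csv
NULL

#' Write a recording to long-format CSV
#'
#' Signal rows are `time_s, channel, value_uV`; annotations go to a
#' companion CSV `phase, start_s, end_s`.
#'
#' @param recording an [EEGRecording-class].
#' @param signalPath path for the signal CSV.
#' @param annotationsPath path for the annotations CSV (default:
#'   signalPath with `_annotations` inserted).
#' @return invisibly, the two paths.
#' @export
writeRecordingCSV <- function(recording, signalPath,
                              annotationsPath = NULL) {
  stopifnot(is(recording, "EEGRecording"))
  if (is.null(annotationsPath))
    annotationsPath <- sub("(\\.csv)?$", "_annotations.csv", signalPath)
  x <- recording@samples
  nT <- ncol(x)
  df <- data.frame(
    time_s = rep((seq_len(nT) - 1) / recording@fs,
                 times = nrow(x)),
    channel = rep(recording@channelNames, each = nT),
    value_uV = as.vector(t(x)))
  utils::write.csv(df, signalPath, row.names = FALSE)
  utils::write.csv(recording@annotations, annotationsPath,
                   row.names = FALSE)
  invisible(c(signal = signalPath, annotations = annotationsPath))
}

#' Read a recording from long-format CSV
#'
#' @param signalPath CSV with columns `time_s, channel, value_uV`.
#' @param annotationsPath CSV with columns `phase, start_s, end_s`.
#' @param fs sampling rate; inferred from the time stamps if omitted.
#' @return an [EEGRecording-class].
#' @export
readRecordingCSV <- function(signalPath, annotationsPath, fs = NULL) {
  df <- utils::read.csv(signalPath, stringsAsFactors = FALSE)
  need <- c("time_s", "channel", "value_uV")
  if (!all(need %in% names(df)))
    stop("signal CSV needs columns ", paste(need, collapse = ", "))
  chans <- unique(df$channel)
  times <- sort(unique(df$time_s))
  if (is.null(fs)) fs <- round(1 / stats::median(diff(times)))
  x <- matrix(NA_real_, nrow = length(chans), ncol = length(times),
              dimnames = list(chans, NULL))
  for (ch in chans) {
    sub <- df[df$channel == ch, ]
    x[ch, ] <- sub$value_uV[order(sub$time_s)]
  }
  ann <- utils::read.csv(annotationsPath, stringsAsFactors = FALSE)
  new("EEGRecording", samples = x, fs = fs, channelNames = chans,
      annotations = ann, provenance = list(source = signalPath))
}

#' Write a feature table to CSV with a JSON metadata sidecar
#'
#' The CSV holds one row per epoch: epoch metadata (id, phase, start
#' time, MWL label when present) followed by the feature columns in
#' their fixed documented order. The sidecar records band edges, entropy
#' parameters and PSD convention.
#'
#' @param features a feature table from [extractFeatures()].
#' @param path CSV path; the sidecar is written to `<path>.meta.json`.
#' @return invisibly, the CSV path.
#' @export
writeFeatureCSV <- function(features, path) {
  cd <- as.data.frame(SummarizedExperiment::colData(features))
  m <- featureMatrix(features)
  utils::write.csv(cbind(cd, as.data.frame(m)), path, row.names = FALSE)
  meta <- S4Vectors::metadata(features)
  jsonlite::write_json(
    list(bands = meta$bands, m = meta$m, rFraction = meta$rFraction,
         taper = meta$taper, fs = meta$fs,
         psdConvention = "one-sided periodogram, |fft|^2/(fs*N)"),
    paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write TLX records to CSV
#'
#' Long format `participant, phase, subscale, rating` plus a weights
#' table `subscale, weight`.
#'
#' @param tlx data.frame from [simulateTLX()].
#' @param path ratings CSV path; weights go to `<path>.weights.csv`.
#' @return invisibly, the ratings path.
#' @export
writeTLXCSV <- function(tlx, path) {
  long <- stats::reshape(
    tlx[, c("participant", "phase", tlxSubscales)],
    direction = "long", varying = tlxSubscales, v.names = "rating",
    timevar = "subscale", times = tlxSubscales,
    idvar = c("participant", "phase"))
  rownames(long) <- NULL
  utils::write.csv(long[order(long$participant, long$phase), ],
                   path, row.names = FALSE)
  w <- attr(tlx, "weights")
  if (!is.null(w))
    utils::write.csv(data.frame(subscale = names(w), weight = unname(w)),
                     paste0(path, ".weights.csv"), row.names = FALSE)
  invisible(path)
}
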