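#' Canonical EEG frequency bands
#'
#' The six bands used throughout: delta 1-3, theta 4-7, alpha 8-11,
#' beta1 12-20, beta2 21-29, gamma 30-40 Hz. Edges are closed intervals
#' on the printed integer boundaries; spectral bins falling in the gaps
#' between bands (e.g. 3.5 Hz) belong to no band.
#'
#' @return data.frame with columns `name`, `low_hz`, `high_hz`.
#' @export
defaultBands <- function() {
  data.frame(name = c("delta", "theta", "alpha", "beta1", "beta2", "gamma"),
             low_hz = c(1, 4, 8, 12, 21, 30),
             high_hz = c(3, 7, 11, 20, 29, 40),
             stringsAsFactors = FALSE)
}

#' Discrete Fourier spectrum of one epoch channel
#'
#' Plain DFT of the (optionally Hann-tapered) sample vector, with the
#' per-bin frequencies attached. Bin spacing is fs/N (0.5 Hz for the
#' default 2-s window at 128 Hz).
#'
#' @param x numeric sample vector (length >= 2, finite).
#' @param fs sampling rate, Hz.
#' @param taper "rectangular" (default; the raw windowed samples go into
#'   the DFT) or "hann".
#' @return list of class `Spectrum`: `coefficients` (complex, length N),
#'   `freqs` (Hz per bin), `N`, `fs`, `taper`.
#' @export
fftSpectrum <- function(x, fs, taper = c("rectangular", "hann")) {
  taper <- match.arg(taper)
  if (length(x) < 2) stop("need at least 2 samples")
  if (!all(is.finite(x))) stop("non-finite samples in input")
  if (taper == "hann") {
    n <- length(x)
    w <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
    # preserve power on stationary signals
    x <- x * w / sqrt(mean(w^2))
  }
  n <- length(x)
  structure(list(coefficients = stats::fft(x),
                 freqs = (seq_len(n) - 1) * fs / n,
                 N = n, fs = fs, taper = taper),
            class = "Spectrum")
}

#' Band powers from a spectrum
#'
#' One-sided periodogram band powers: PSD per bin is |f_k|^2 / (fs * N)
#' (doubled off DC/Nyquist), summed times the bin width over all bins
#' whose frequency lies in the closed band interval. Summing every bin
#' this way recovers the signal's mean square exactly (Parseval).
#'
#' @param spectrum a `Spectrum` from [fftSpectrum()].
#' @param bands data.frame as [defaultBands()].
#' @return named numeric vector of band powers (uV^2).
#' @export
bandPowers <- function(spectrum, bands = defaultBands()) {
  stopifnot(inherits(spectrum, "Spectrum"))
  fs <- spectrum$fs
  if (any(bands$high_hz >= fs / 2))
    stop("band edges must lie below the Nyquist frequency")
  psd <- periodogramPSD(spectrum)
  freqs <- psd$freqs
  df <- fs / spectrum$N
  out <- numeric(nrow(bands))
  names(out) <- bands$name
  for (b in seq_len(nrow(bands))) {
    sel <- freqs >= bands$low_hz[b] & freqs <= bands$high_hz[b]
    if (!any(sel))
      stop("band '", bands$name[b], "' contains no spectral bin at ",
           df, " Hz resolution")
    out[b] <- sum(psd$psd[sel]) * df
  }
  out
}

# One-sided periodogram: freqs 0..Nyquist, psd in uV^2/Hz.
periodogramPSD <- function(spectrum) {
  n <- spectrum$N
  fs <- spectrum$fs
  half <- floor(n / 2) + 1L
  p <- Mod(spectrum$coefficients[seq_len(half)])^2 / (fs * n)
  mult <- rep(2, half)
  mult[1] <- 1
  if (n %% 2 == 0) mult[half] <- 1
  list(freqs = spectrum$freqs[seq_len(half)], psd = p * mult)
}

#' Time-domain features of one epoch channel
#'
#' The ten descriptive statistics used per channel: mean, variance,
#' standard deviation, peak-to-peak amplitude, skewness, kurtosis
#' (excess), RMS, zero crossings (strict sign changes; exact zeros
#' inherit the previous sign), Hjorth mobility sqrt(var(dx)/var(x)) and
#' Hjorth complexity mobility(dx)/mobility(x). For a zero-variance
#' input the scale-free statistics are returned as 0 and the result is
#' flagged degenerate.
#'
#' @param x numeric sample vector (length >= 3).
#' @return named numeric vector (mean, vari, std, ptp, skewness,
#'   kurtosis, rms, zc, hm, hc) with attribute `degenerate`.
#' @export
timeDomainFeatures <- function(x) {
  if (length(x) < 3) stop("need at least 3 samples")
  if (!all(is.finite(x))) stop("non-finite samples in input")
  v <- stats::var(x)
  degenerate <- v < .Machine$double.eps
  out <- c(mean = mean(x), vari = v, std = sqrt(v),
           ptp = max(x) - min(x),
           skewness = 0, kurtosis = 0,
           rms = sqrt(mean(x^2)), zc = 0, hm = 0, hc = 0)
  if (!degenerate) {
    out["skewness"] <- e1071::skewness(x, type = 1)
    out["kurtosis"] <- e1071::kurtosis(x, type = 1)
    out["zc"] <- zeroCrossings(x)
    d1 <- diff(x)
    vd1 <- stats::var(d1)
    hm <- sqrt(vd1 / v)
    out["hm"] <- hm
    if (vd1 >= .Machine$double.eps) {
      d2 <- diff(d1)
      out["hc"] <- sqrt(stats::var(d2) / vd1) / hm
    }
  }
  attr(out, "degenerate") <- degenerate
  out
}

# Strict sign changes between consecutive samples; exact zeros carry the
# previous sign forward.
zeroCrossings <- function(x) {
  s <- sign(x)
  nz <- s != 0
  if (!any(nz)) return(0L)
  # forward-fill zeros with the previous non-zero sign
  idx <- cumsum(nz)
  filled <- s[nz][pmax(idx, 1L)]
  filled[idx == 0] <- filled[which(idx > 0)[1]]  # leading zeros: first sign
  sum(filled[-1] != filled[-length(filled)])
}

#' Extract the full feature table from an epoch set
#'
#' Computes, for every passing epoch and channel, the six band powers
#' plus the ten time-domain statistics plus sample/approximate entropy
#' (18 features per channel; 90 for the five-channel montage). Features
#' are named `<channel>-<feature>` and returned as a
#' `SummarizedExperiment` with features as rows and epochs as columns.
#'
#' @param epochs an [EpochSet-class].
#' @param bands band table as [defaultBands()].
#' @param m embedding dimension for the entropies (default 2).
#' @param r entropy tolerance as a fraction of the epoch-channel
#'   standard deviation (default 0.2).
#' @param taper passed to [fftSpectrum()].
#' @return a [SummarizedExperiment::SummarizedExperiment]; `rowData`
#'   holds channel, feature, domain ("psd"/"time"/"entropy") and band
#'   edges; `colData` holds epoch id, phase and start time; `metadata`
#'   records the extraction parameters and any degenerate epochs.
#' @export
extractFeatures <- function(epochs, bands = defaultBands(), m = 2,
                            r = 0.2, taper = c("rectangular", "hann")) {
  stopifnot(is(epochs, "EpochSet"))
  taper <- match.arg(taper)
  keep <- epochs@info$quality == "pass"
  if (!any(keep)) stop("no pass-quality epochs to extract features from")
  arr <- epochs@samples[, , keep, drop = FALSE]
  info <- epochs@info[keep, , drop = FALSE]
  chans <- epochs@channelNames
  fs <- epochs@fs

  tdNames <- c("mean", "vari", "std", "ptp", "skewness", "kurtosis",
               "rms", "zc", "hm", "hc")
  featNames <- c(bands$name, tdNames, "se", "ae")
  rowNames <- as.vector(t(outer(chans, featNames, paste, sep = "-")))
  nEp <- dim(arr)[3]
  mat <- matrix(NA_real_, nrow = length(rowNames), ncol = nEp,
                dimnames = list(rowNames, info$epoch_id))
  degenerateEpochs <- integer()

  for (e in seq_len(nEp)) {
    col <- numeric(0)
    flagged <- FALSE
    for (ci in seq_along(chans)) {
      x <- arr[ci, , e]
      bp <- bandPowers(fftSpectrum(x, fs, taper), bands)
      td <- timeDomainFeatures(x)
      if (isTRUE(attr(td, "degenerate"))) flagged <- TRUE
      en <- entropyFeatures(x, m = m, r = r * stats::sd(x))
      col <- c(col, bp, td, en)
    }
    mat[, e] <- col
    if (flagged) degenerateEpochs <- c(degenerateEpochs, info$epoch_id[e])
  }

  rd <- S4Vectors::DataFrame(
    channel = rep(chans, each = length(featNames)),
    feature = rep(featNames, times = length(chans)),
    domain = rep(c(rep("psd", nrow(bands)), rep("time", length(tdNames)),
                   rep("entropy", 2)), times = length(chans)),
    row.names = rowNames)
  cd <- S4Vectors::DataFrame(epoch_id = info$epoch_id,
                             phase = info$phase,
                             start_s = info$start_s,
                             row.names = as.character(info$epoch_id))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(features = mat), rowData = rd, colData = cd,
    metadata = list(bands = bands, m = m, rFraction = r, taper = taper,
                    fs = fs, degenerateEpochs = degenerateEpochs,
                    channelRegions =
                      defaultChannelRegions()[intersect(
                        names(defaultChannelRegions()), chans)]))
}

#' Feature matrix in epochs-by-features orientation
#'
#' @param features a feature table from [extractFeatures()].
#' @param domain optional filter: "psd" for the 30 band-power columns,
#'   "calculative" for the 60 time-domain + entropy columns, or NULL for
#'   all.
#' @return numeric matrix, epochs x features.
#' @export
featureMatrix <- function(features, domain = NULL) {
  m <- t(SummarizedExperiment::assay(features, "features"))
  if (!is.null(domain)) {
    dom <- SummarizedExperiment::rowData(features)$domain
    sel <- if (domain == "psd") dom == "psd"
           else if (domain == "calculative") dom != "psd"
           else stop("domain must be 'psd', 'calculative' or NULL")
    m <- m[, sel, drop = FALSE]
  }
  m
}

#' MWL labels of a feature table
#'
#' @param features a labelled feature table (see [assignLabels()]).
#' @return factor of low/middle/high labels, one per epoch.
#' @export
mwlLabels <- function(features) {
  l <- SummarizedExperiment::colData(features)$mwl
  if (is.null(l)) stop("feature table has no MWL labels; run assignLabels()")
  l
}
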