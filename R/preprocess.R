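#' Zero-phase low-pass filter
#'
#' Removes content above the cut frequency with a zero-phase FIR filter
#' (Hamming-window design, 129 taps, -6 dB point 4 Hz above the cut,
#' applied forward and backward), so epoch alignment is preserved. The
#' realized response leaves the passband up to cut-2 Hz essentially
#' untouched (< 1 dB) and attenuates cut+10 Hz and above by far more
#' than 20 dB. An optional high-pass (same design, reflected) is exposed
#' for slow-drift removal.
#'
#' @param recording an [EEGRecording-class].
#' @param highCutHz upper passband edge, Hz; must be below Nyquist.
#' @param lowCutHz optional lower edge for drift removal (e.g. 0.5 Hz);
#'   `NULL` (default) disables it.
#' @return a filtered copy of the recording.
#' @export
lowpassFilter <- function(recording, highCutHz = 40, lowCutHz = NULL) {
  stopifnot(is(recording, "EEGRecording"))
  fs <- recording@fs
  if (highCutHz >= fs / 2)
    stop("highCutHz must be below the Nyquist frequency (", fs / 2, " Hz)")
  ntaps <- 128
  w <- min((highCutHz + 4) / (fs / 2), 0.99)
  b <- as.numeric(signal::fir1(ntaps, w, type = "low"))
  x <- recording@samples
  for (i in seq_len(nrow(x)))
    x[i, ] <- filtfiltPadded(b, x[i, ])
  if (!is.null(lowCutHz)) {
    if (lowCutHz <= 0 || lowCutHz >= highCutHz)
      stop("lowCutHz must lie in (0, highCutHz)")
    nt <- max(64, 2 * ceiling(1.65 * fs / lowCutHz / 2))
    bh <- as.numeric(signal::fir1(nt, lowCutHz / (fs / 2), type = "high"))
    for (i in seq_len(nrow(x)))
      x[i, ] <- filtfiltPadded(bh, x[i, ])
  }
  out <- recording
  out@samples <- x
  out@provenance <- c(recording@provenance,
                      list(lowpass = list(highCutHz = highCutHz,
                                          lowCutHz = lowCutHz,
                                          taps = ntaps + 1,
                                          zeroPhase = TRUE)))
  out
}

# Zero-phase filtering with reflected end padding, so boundary
# transients do not leak into the signal proper.
filtfiltPadded <- function(b, x) {
  np <- min(3 * length(b), length(x) - 1)
  pre <- 2 * x[1] - x[(np + 1):2]
  post <- 2 * x[length(x)] - x[(length(x) - 1):(length(x) - np)]
  y <- signal::filtfilt(b, 1, c(pre, x, post))
  y[(np + 1):(np + length(x))]
}

#' Remove flat or clipped channels
#'
#' Drops channels whose variance falls below a flat-line threshold or
#' that contain any sample beyond a clipping bound (electrode fault /
#' poor scalp contact). Removals are logged in the provenance.
#'
#' @param recording an [EEGRecording-class].
#' @param flatVarUV2 variance floor, uV^2.
#' @param clipUV absolute amplitude ceiling, uV.
#' @return the recording without the offending channels.
#' @export
dropBadChannels <- function(recording, flatVarUV2 = 1e-3, clipUV = 500) {
  stopifnot(is(recording, "EEGRecording"))
  if (flatVarUV2 <= 0 || clipUV <= 0) stop("thresholds must be positive")
  x <- recording@samples
  v <- apply(x, 1, stats::var)
  mx <- apply(abs(x), 1, max)
  bad <- v < flatVarUV2 | mx > clipUV
  if (all(bad))
    stop("all channels removed as bad: ",
         paste(recording@channelNames, collapse = ", "))
  out <- recording
  out@samples <- x[!bad, , drop = FALSE]
  out@channelNames <- recording@channelNames[!bad]
  out@provenance <- c(recording@provenance, list(droppedChannels = list(
    channels = recording@channelNames[bad],
    reason = ifelse(v[bad] < flatVarUV2, "flat", "clipped"),
    flatVarUV2 = flatVarUV2, clipUV = clipUV)))
  out
}

#' Cut a recording into fixed-length overlapping epochs
#'
#' Within each annotated phase, windows start at the phase onset and
#' advance by `window_s * (1 - overlap)` seconds; a window is kept only
#' if it lies entirely inside its phase (trailing partials are
#' discarded, and no window ever crosses a phase boundary). With the
#' defaults (2 s, 50% overlap) a phase of integer length n seconds
#' yields n - 1 epochs.
#'
#' @param recording an annotated [EEGRecording-class].
#' @param windowS window length in seconds (default 2).
#' @param overlap fractional overlap in `[0, 1)` (default 0.5).
#' @return an [EpochSet-class]; phases shorter than one window
#'   contribute no epochs (with a warning).
#' @export
segmentEpochs <- function(recording, windowS = 2, overlap = 0.5) {
  stopifnot(is(recording, "EEGRecording"))
  if (overlap < 0 || overlap >= 1) stop("overlap must lie in [0, 1)")
  if (windowS <= 0) stop("windowS must be positive")
  fs <- recording@fs
  ann <- recording@annotations
  if (nrow(ann) == 0) stop("recording has no phase annotations")
  wlen <- round(windowS * fs)
  step <- round(windowS * (1 - overlap) * fs)
  if (step < 1) stop("overlap too close to 1 for this window length")
  x <- recording@samples
  epochs <- list()
  info <- list()
  for (p in seq_len(nrow(ann))) {
    s0 <- round(ann$start_s[p] * fs)       # 0-based sample offset
    s1 <- round(ann$end_s[p] * fs)
    if (s1 - s0 < wlen) {
      warning("phase '", ann$phase[p], "' shorter than one window; ",
              "no epochs produced")
      next
    }
    starts <- seq(s0, s1 - wlen, by = step)
    for (st in starts) {
      epochs[[length(epochs) + 1L]] <- x[, (st + 1):(st + wlen),
                                         drop = FALSE]
      info[[length(info) + 1L]] <- data.frame(
        phase = ann$phase[p], start_s = st / fs,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(epochs)) stop("no epochs produced from any phase")
  info <- do.call(rbind, info)
  info <- data.frame(epoch_id = seq_len(nrow(info)), info,
                     quality = "pass", reason = "",
                     stringsAsFactors = FALSE)
  arr <- array(unlist(epochs),
               dim = c(nrow(x), wlen, length(epochs)),
               dimnames = list(recording@channelNames, NULL, NULL))
  new("EpochSet", samples = arr, fs = fs,
      channelNames = recording@channelNames, info = info,
      provenance = c(recording@provenance,
                     list(segmentation = list(windowS = windowS,
                                              overlap = overlap,
                                              windowSamples = wlen))))
}

#' Reject epochs with excessive peak-to-peak amplitude
#'
#' Flags and removes epochs whose peak-to-peak amplitude on any channel
#' exceeds the threshold (ocular and movement artifacts); the retained
#' set and the rejection count are logged.
#'
#' @param epochs an [EpochSet-class].
#' @param ptpUV peak-to-peak threshold in uV (default 150). `Inf`
#'   disables rejection.
#' @return the epoch set restricted to passing epochs.
#' @export
rejectEpochs <- function(epochs, ptpUV = 150) {
  stopifnot(is(epochs, "EpochSet"))
  if (ptpUV <= 0) stop("ptpUV must be positive")
  arr <- epochs@samples
  n <- dim(arr)[3]
  ptp <- vapply(seq_len(n), function(i) {
    m <- arr[, , i, drop = FALSE]
    max(apply(matrix(m, nrow = dim(arr)[1]), 1,
              function(ch) max(ch) - min(ch)))
  }, numeric(1))
  bad <- ptp > ptpUV
  if (all(bad)) stop("all ", n, " epochs exceed the ", ptpUV,
                     " uV peak-to-peak threshold")
  out <- epochs
  out@samples <- arr[, , !bad, drop = FALSE]
  info <- epochs@info[!bad, , drop = FALSE]
  rownames(info) <- NULL
  out@info <- info
  out@provenance <- c(epochs@provenance, list(rejection = list(
    ptpUV = ptpUV, rejected = sum(bad), retained = sum(!bad))))
  out
}
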