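#' @import methods
NULL

#' EEGRecording: a multichannel EEG recording with phase annotations
#'
#' Container for a continuous multichannel EEG signal in microvolts,
#' its sampling rate, channel labels and a set of non-overlapping phase
#' annotations (e.g. take-off / cruise / landing).
#'
#' @slot samples numeric matrix, channels x time points, in uV.
#' @slot fs sampling rate in Hz.
#' @slot channelNames character vector, one label per row of `samples`.
#' @slot annotations data.frame with columns `phase`, `start_s`, `end_s`;
#'   intervals are half-open `[start_s, end_s)`, non-overlapping and
#'   contained in the recording duration.
#' @slot provenance list of processing notes (filter settings, removed
#'   channels, ...), appended to by the preprocessing steps.
#'
#' @seealso [simulateRecording()], [lowpassFilter()], [segmentEpochs()]
#' @export
setClass("EEGRecording",
  representation(
    samples = "matrix",
    fs = "numeric",
    channelNames = "character",
    annotations = "data.frame",
    provenance = "list"
  ),
  prototype(provenance = list())
)

setValidity("EEGRecording", function(object) {
  msg <- character()
  if (!is.numeric(object@samples))
    msg <- c(msg, "samples must be a numeric matrix")
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (nrow(object@samples) != length(object@channelNames))
    msg <- c(msg, "channelNames length must equal number of sample rows")
  ann <- object@annotations
  if (nrow(ann) > 0) {
    need <- c("phase", "start_s", "end_s")
    if (!all(need %in% names(ann))) {
      msg <- c(msg, "annotations needs columns phase, start_s, end_s")
    } else {
      dur <- ncol(object@samples) / object@fs
      if (any(ann$start_s < 0) || any(ann$end_s > dur + 1e-9))
        msg <- c(msg, "annotations must lie within the recording duration")
      if (any(ann$end_s <= ann$start_s))
        msg <- c(msg, "annotation end_s must exceed start_s")
      o <- order(ann$start_s)
      if (nrow(ann) > 1 &&
          any(ann$start_s[o][-1] < ann$end_s[o][-nrow(ann)] - 1e-9))
        msg <- c(msg, "annotations must not overlap")
    }
  }
  if (length(msg)) msg else TRUE
})

#' EpochSet: fixed-length EEG analysis windows with labels and quality flags
#'
#' Holds the windows cut from an [EEGRecording-class] (default 2 s with 50%
#' overlap), each carrying the phase it was cut from, its offset, and a
#' pass/fail quality flag set by [rejectEpochs()].
#'
#' @slot samples numeric array, channels x window length x epochs, uV.
#' @slot fs sampling rate in Hz.
#' @slot channelNames character vector of channel labels.
#' @slot info data.frame, one row per epoch: `epoch_id`, `phase`,
#'   `start_s`, `quality` ("pass"/"fail"), `reason`.
#' @slot provenance list of processing notes (window length, overlap,
#'   rejection threshold and counts).
#'
#' @seealso [segmentEpochs()], [rejectEpochs()], [extractFeatures()]
#' @export
setClass("EpochSet",
  representation(
    samples = "array",
    fs = "numeric",
    channelNames = "character",
    info = "data.frame",
    provenance = "list"
  ),
  prototype(provenance = list())
)

setValidity("EpochSet", function(object) {
  msg <- character()
  d <- dim(object@samples)
  if (length(d) != 3L)
    msg <- c(msg, "samples must be a 3-d array (channels x time x epochs)")
  else {
    if (d[1] != length(object@channelNames))
      msg <- c(msg, "channelNames length must equal first array dimension")
    if (d[3] != nrow(object@info))
      msg <- c(msg, "info must have one row per epoch")
  }
  need <- c("epoch_id", "phase", "start_s", "quality")
  if (!all(need %in% names(object@info)))
    msg <- c(msg, "info needs columns epoch_id, phase, start_s, quality")
  else if (nrow(object@info) > 1 && is.unsorted(object@info$start_s))
    msg <- c(msg, "epochs must be sorted by start_s")
  if (length(msg)) msg else TRUE
})
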