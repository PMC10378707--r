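#' @name mwldetect-accessors
#' @title Accessors for EEGRecording and EpochSet objects
#' @description Slot accessors; user code should use these rather than `@`.
#' @param object an [EEGRecording-class] or [EpochSet-class].
NULL

#' @rdname mwldetect-accessors
#' @export
setGeneric("eegSamples", function(object) standardGeneric("eegSamples"))

#' @rdname mwldetect-accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))

#' @rdname mwldetect-accessors
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))

#' @rdname mwldetect-accessors
#' @export
setGeneric("phaseAnnotations",
           function(object) standardGeneric("phaseAnnotations"))

#' @rdname mwldetect-accessors
#' @export
setGeneric("epochArray", function(object) standardGeneric("epochArray"))

#' @rdname mwldetect-accessors
#' @export
setGeneric("epochInfo", function(object) standardGeneric("epochInfo"))

#' @rdname mwldetect-accessors
#' @export
setGeneric("nEpochs", function(object) standardGeneric("nEpochs"))

#' @rdname mwldetect-accessors
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))

#' @rdname mwldetect-accessors
setMethod("eegSamples", "EEGRecording", function(object) object@samples)

#' @rdname mwldetect-accessors
setMethod("samplingRate", "EEGRecording", function(object) object@fs)

#' @rdname mwldetect-accessors
setMethod("channelNames", "EEGRecording",
          function(object) object@channelNames)

#' @rdname mwldetect-accessors
setMethod("phaseAnnotations", "EEGRecording",
          function(object) object@annotations)

#' @rdname mwldetect-accessors
setMethod("provenance", "EEGRecording", function(object) object@provenance)

#' @rdname mwldetect-accessors
setMethod("samplingRate", "EpochSet", function(object) object@fs)

#' @rdname mwldetect-accessors
setMethod("channelNames", "EpochSet", function(object) object@channelNames)

#' @rdname mwldetect-accessors
setMethod("epochArray", "EpochSet", function(object) object@samples)

#' @rdname mwldetect-accessors
setMethod("epochInfo", "EpochSet", function(object) object@info)

#' @rdname mwldetect-accessors
setMethod("nEpochs", "EpochSet", function(object) dim(object@samples)[3])

#' @rdname mwldetect-accessors
setMethod("provenance", "EpochSet", function(object) object@provenance)

setMethod("show", "EEGRecording", function(object) {
  dur <- ncol(object@samples) / object@fs
  cat("EEGRecording:", nrow(object@samples), "channel(s) x",
      sprintf("%.1f s", dur), "at", object@fs, "Hz\n")
  cat("  channels:", paste(object@channelNames, collapse = ", "), "\n")
  ann <- object@annotations
  if (nrow(ann)) {
    cat("  phases:\n")
    for (i in seq_len(nrow(ann)))
      cat(sprintf("    %-10s %7.1f - %7.1f s\n",
                  ann$phase[i], ann$start_s[i], ann$end_s[i]))
  }
  invisible(object)
})

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@samples)
  cat("EpochSet:", d[3], "epoch(s) of", d[2], "samples (",
      sprintf("%.1f s", d[2] / object@fs), ") x", d[1], "channel(s)\n")
  tab <- table(object@info$phase, object@info$quality)
  print(tab)
  invisible(object)
})
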