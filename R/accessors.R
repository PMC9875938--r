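#' Accessors for Epochs and related objects
#'
#' Small generic accessors so downstream code never touches slots directly.
#'
#' @param x an [Epochs-class], [Montage-class] or other package object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))
#' @rdname accessors
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))
#' @rdname accessors
#' @export
setGeneric("times", function(x) standardGeneric("times"))
#' @rdname accessors
#' @export
setGeneric("srate", function(x) standardGeneric("srate"))
#' @rdname accessors
#' @export
setGeneric("trialData", function(x) standardGeneric("trialData"))
#' @rdname accessors
#' @export
setGeneric("epochData", function(x) standardGeneric("epochData"))
#' @rdname accessors
#' @export
setGeneric("montage", function(x) standardGeneric("montage"))
#' @rdname accessors
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))
#' @rdname accessors
#' @export
setGeneric("channelPositions", function(x) standardGeneric("channelPositions"))
#' @rdname accessors
#' @export
setGeneric("mixing", function(x) standardGeneric("mixing"))
#' @rdname accessors
#' @export
setGeneric("unmixing", function(x) standardGeneric("unmixing"))
#' @rdname accessors
#' @export
setGeneric("gain", function(x) standardGeneric("gain"))
#' @rdname accessors
#' @export
setGeneric("sWaveform", function(x) standardGeneric("sWaveform"))
#' @rdname accessors
#' @export
setGeneric("cWaveform", function(x) standardGeneric("cWaveform"))
#' @rdname accessors
#' @export
setGeneric("cLatencies", function(x) standardGeneric("cLatencies"))

setMethod("nTrials", "Epochs", function(x) dim(x@data)[1])
setMethod("nChannels", "Epochs", function(x) dim(x@data)[2])
setMethod("times", "Epochs", function(x) x@times)
setMethod("srate", "Epochs", function(x) x@srate)
setMethod("trialData", "Epochs", function(x) x@trials)
setMethod("epochData", "Epochs", function(x) x@data)
setMethod("montage", "Epochs", function(x) x@montage)
setMethod("channelLabels", "Epochs", function(x) x@montage@labels)
setMethod("channelLabels", "Montage", function(x) x@labels)
setMethod("channelPositions", "Epochs", function(x) x@montage@positions)
setMethod("channelPositions", "Montage", function(x) x@positions)
setMethod("nChannels", "Montage", function(x) length(x@labels))
setMethod("mixing", "GroupICAModel", function(x) x@mixing)
setMethod("unmixing", "GroupICAModel", function(x) x@unmixing)
setMethod("gain", "LeadField", function(x) x@gain)
setMethod("sWaveform", "RideResult", function(x) x@sWaveform)
setMethod("cWaveform", "RideResult", function(x) x@cWaveform)
setMethod("cLatencies", "RideResult", function(x) x@cLatencySamples)
setMethod("times", "RideResult", function(x) x@times)

#' Construct an Epochs object
#'
#' @param data trials x channels x time numeric array.
#' @param srate sampling rate in Hz.
#' @param tminMs time of the first sample in ms (stimulus onset = 0).
#' @param montage a [Montage-class].
#' @param trials data.frame of per-trial metadata.
#' @param unitLabel amplitude unit label.
#' @return an [Epochs-class] object.
#' @export
newEpochs <- function(data, srate, tminMs, montage, trials,
                      unitLabel = "uV") {
  tms <- tminMs + (seq_len(dim(data)[3]) - 1L) * 1000 / srate
  new("Epochs", data = data, srate = srate, times = tms, montage = montage,
      trials = trials, unitLabel = unitLabel, history = character(0))
}

#' Subset epochs by trial
#'
#' @param x an [Epochs-class].
#' @param keep integer or logical index over trials.
#' @return the subsetted [Epochs-class].
#' @export
subsetTrials <- function(x, keep) {
  stopifnot(is(x, "Epochs"))
  new("Epochs", data = x@data[keep, , , drop = FALSE], srate = x@srate,
      times = x@times, montage = x@montage,
      trials = x@trials[keep, , drop = FALSE], unitLabel = x@unitLabel,
      history = x@history)
}
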