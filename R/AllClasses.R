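#' @import methods
#' @importFrom stats median sd cor rnorm runif rbinom rlnorm qnorm pnorm pt
#'   quantile approx t.test prcomp
#' @importFrom Rcpp sourceCpp
#' @useDynLib simonEEG, .registration = TRUE
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))
setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Montage: electrode labels and unit-sphere positions
#'
#' A `Montage` holds the channel labels and the 3-D positions of the
#' electrodes on a unit sphere (head-centred coordinates: +x right,
#' +y anterior, +z superior).
#'
#' @slot labels character vector of unique channel labels.
#' @slot positions numeric matrix, channels x 3, each row unit-norm.
#'
#' @seealso [makeMontage()]
#' @export
setClass("Montage",
  representation(labels = "character", positions = "matrix"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@positions) != length(object@labels))
      msg <- c(msg, "number of positions must match number of labels")
    if (ncol(object@positions) != 3L)
      msg <- c(msg, "positions must be a channels x 3 matrix")
    if (anyDuplicated(object@labels))
      msg <- c(msg, "channel labels must be unique")
    nrm <- sqrt(rowSums(object@positions^2))
    if (length(nrm) && any(abs(nrm - 1) > 1e-6))
      msg <- c(msg, "electrode positions must lie on the unit sphere")
    if (length(msg)) msg else TRUE
  }
)

#' Epochs: single-trial multi-channel EEG segments
#'
#' The central data container: a trials x channels x time tensor with a
#' uniform time axis, the electrode montage, and one metadata row per trial.
#' Sample k of a trial sits at time `times(x)[1] + k / srate(x)`; the epoch
#' window is half-open, so the nominal end time is not itself a sample.
#'
#' @slot data numeric array, trials x channels x time. Amplitudes are in
#'   microvolts until [csdTransform()] converts them to current source
#'   density units.
#' @slot srate sampling rate in Hz.
#' @slot times time axis in ms, strictly increasing, uniform at 1000/srate.
#' @slot montage a [Montage-class] object.
#' @slot trials data.frame with one row per trial (see [generateTrialTable()]).
#' @slot unitLabel amplitude unit label, `"uV"` or `"CSD (uV/m^2)"`.
#'
#' @seealso [simulateEpochs()], [nTrials()], [nChannels()], [times()]
#' @export
setClass("Epochs",
  representation(data = "array", srate = "numeric", times = "numeric",
                 montage = "Montage", trials = "data.frame",
                 unitLabel = "character", history = "character"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@data)
    if (length(d) != 3L)
      msg <- c(msg, "data must be a trials x channels x time array")
    else {
      if (d[2] != length(object@montage@labels))
        msg <- c(msg, "channel dimension must match montage size")
      if (d[3] != length(object@times))
        msg <- c(msg, "time dimension must match times vector")
      if (nrow(object@trials) != d[1])
        msg <- c(msg, "trial metadata rows must match trial count")
    }
    if (length(object@times) > 1L) {
      dt <- diff(object@times)
      if (any(dt <= 0)) msg <- c(msg, "times must be strictly increasing")
      if (max(abs(dt - 1000 / object@srate)) > 1e-6)
        msg <- c(msg, "times must be uniform at 1000/srate ms")
    }
    if (length(msg)) msg else TRUE
  }
)

#' Ground truth of a simulated session
#'
#' Everything needed to score recovery of the generating model from a
#' simulated [Epochs-class] object: the two source topographies, the fixed
#' stimulus-locked latency, the per-trial latency of the variable source,
#' per-condition amplitudes and the noise parameters.
#'
#' @slot sTopography,cTopography unit-norm channel loading vectors.
#' @slot sLatencyMs fixed latency of the stimulus-locked source (ms).
#' @slot cLatencyMs per-trial latency of the latency-variable source (ms).
#' @slot amplitudeByCondition data.frame: condition, sAmp, cAmp.
#' @slot noiseParams named numeric: pinkSd, whiteSd.
#' @slot seed integer seed the session was generated with.
#' @export
setClass("SimTruth",
  representation(sTopography = "numeric", cTopography = "numeric",
                 sLatencyMs = "numeric", cLatencyMs = "numeric",
                 amplitudeByCondition = "data.frame",
                 noiseParams = "numeric", seed = "integer"))

#' Result of a RIDE decomposition
#'
#' @slot sWaveform,cWaveform channels x time cluster waveforms (same time
#'   axis as the decomposed epochs); the C waveform lives at the median
#'   single-trial latency.
#' @slot cLatencySamples per-trial latency of the C cluster, as sample
#'   indices into the epoch time axis.
#' @slot sLatencySample sample index of the stimulus-locked reference (time 0).
#' @slot nIterations iterations run.
#' @slot converged logical convergence flag.
#' @slot latencyHistory list of per-iteration latency vectors.
#' @slot times time axis in ms.
#' @slot config the `RideConfig` list used.
#' @export
setClass("RideResult",
  representation(sWaveform = "matrix", cWaveform = "matrix",
                 cLatencySamples = "numeric", sLatencySample = "numeric",
                 nIterations = "integer", converged = "logical",
                 latencyHistory = "list", times = "numeric", config = "list"))

#' Group spatial ICA model
#'
#' Fitted by [fitGroupICA()] on channel-space concatenated subject data.
#' Topographies (`mixing` columns) are stored unit-norm with the sign fixed
#' so that the channel of maximal absolute loading is positive; `unmixing`
#' rows carry the compensating scale so that `unmixing %*% mixing` is the
#' identity on the retained subspace.
#'
#' @slot mixing channels x components topography matrix.
#' @slot unmixing components x channels spatial filter matrix.
#' @slot pcaBasis channels x components whitening basis (PCA eigenvectors).
#' @slot channelMeans channel means removed before fitting.
#' @slot nComponents number of retained components.
#' @slot explainedVarianceFraction group variance fraction retained by the PCA.
#' @slot seed integer seed.
#' @slot clusterTag,conditionTag optional bookkeeping tags ("S"/"C",
#'   "congruent"/"incongruent").
#' @export
setClass("GroupICAModel",
  representation(mixing = "matrix", unmixing = "matrix", pcaBasis = "matrix",
                 channelMeans = "numeric", nComponents = "integer",
                 explainedVarianceFraction = "numeric", seed = "integer",
                 clusterTag = "character", conditionTag = "character"),
  validity = function(object) {
    P <- object@unmixing %*% object@mixing
    if (max(abs(P - diag(nrow(P)))) > 1e-6)
      return("unmixing %*% mixing must be the identity on the retained subspace")
    TRUE
  }
)

#' Single-subject decoding result
#'
#' Per-time AUC of a binary condition classifier and, optionally, the full
#' temporal-generalization matrix (train time x test time).
#'
#' @slot subjectAuc numeric vector, AUC per (train = test) time point.
#' @slot subjectTg train x test AUC matrix, or NULL if generalization was
#'   not requested.
#' @slot times decoded time points in ms.
#' @slot nTrialsPerClass trial count per class after balancing.
#' @export
setClass("DecodingResult",
  representation(subjectAuc = "numeric", subjectTg = "matrixOrNULL",
                 times = "numeric", nTrialsPerClass = "integer"),
  validity = function(object) {
    if (any(object@subjectAuc < 0 | object@subjectAuc > 1))
      return("AUC values must lie in [0, 1]")
    TRUE
  }
)

#' Simulated lead field
#'
#' @slot gain channels x sources gain matrix, average-referenced
#'   (column means zero).
#' @slot sourcePositions sources x 3 coordinates inside the unit sphere.
#' @slot montage the [Montage-class] the gain refers to.
#' @export
setClass("LeadField",
  representation(gain = "matrix", sourcePositions = "matrix",
                 montage = "Montage"),
  validity = function(object) {
    msg <- character()
    if (!all(is.finite(object@gain))) msg <- c(msg, "gain must be finite")
    if (any(colSums(object@gain^2) == 0)) msg <- c(msg, "gain columns must be non-zero")
    if (max(abs(colMeans(object@gain))) > 1e-8)
      msg <- c(msg, "gain must be average-referenced (column means zero)")
    if (length(msg)) msg else TRUE
  }
)

setMethod("show", "Montage", function(object) {
  cat("Montage with", length(object@labels), "channels:",
      paste(utils::head(object@labels, 6), collapse = ", "),
      if (length(object@labels) > 6) "..." else "", "\n")
})

setMethod("show", "Epochs", function(object) {
  d <- dim(object@data)
  cat(sprintf("Epochs: %d trials x %d channels x %d samples @ %g Hz [%s]\n",
              d[1], d[2], d[3], object@srate, object@unitLabel))
  cat(sprintf("  time %g .. %g ms\n", object@times[1],
              object@times[length(object@times)]))
  if ("trial_type" %in% names(object@trials))
    print(table(object@trials$trial_type, object@trials$congruency))
})

setMethod("show", "RideResult", function(object) {
  cat(sprintf("RideResult: %d trials, %d iterations, converged = %s\n",
              length(object@cLatencySamples), object@nIterations,
              object@converged))
})

setMethod("show", "GroupICAModel", function(object) {
  cat(sprintf("GroupICAModel: %d components on %d channels (%.1f%% variance retained)\n",
              object@nComponents, nrow(object@mixing),
              100 * object@explainedVarianceFraction))
})

setMethod("show", "LeadField", function(object) {
  cat(sprintf("LeadField: %d channels x %d sources\n",
              nrow(object@gain), ncol(object@gain)))
})

setMethod("show", "DecodingResult", function(object) {
  cat(sprintf("DecodingResult: %d time points, peak AUC %.3f at %g ms%s\n",
              length(object@times), max(object@subjectAuc),
              object@times[which.max(object@subjectAuc)],
              if (is.null(object@subjectTg)) "" else " (+ TG matrix)"))
})
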