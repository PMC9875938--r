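# Residue iteration decomposition (RIDE) into a stimulus-locked S cluster
# and a latency-variable C cluster. No response-locked (R) cluster is
# estimated: in a Go/Nogo design the withheld-response trials carry no
# response marker, so only S and C are separable.
#
# Alternating scheme, one latency per trial shared across channels:
#   S = median over trials of (trial - C shifted to that trial's latency),
#       in stimulus-locked frame, tapered to the S window;
#   C = median over trials of (trial - S) after aligning each residual to
#       its current latency, tapered to the C window (kept at the median
#       latency position);
#   latencies re-estimated by maximising the channel-summed cross-covariance
#   of the C template with each residual inside the search window.

#' RIDE configuration
#'
#' @param sWindowMs S-cluster window of interest (default -200..600 ms).
#' @param cWindowMs C-cluster window (default 150..800 ms).
#' @param cSearchWindowMs latency search window; defaults to `cWindowMs`.
#' @param maxIter maximum number of decompose/re-estimate iterations.
#' @param latencyTolSamples convergence tolerance on the median absolute
#'   latency change, in samples.
#' @param maxStepMs trust region: maximal latency move per iteration, in ms
#'   (stabilises single-trial estimates against distant spurious score
#'   peaks).
#' @return list of class `RideConfig`.
#' @export
rideConfig <- function(sWindowMs = c(-200, 600), cWindowMs = c(150, 800),
                       cSearchWindowMs = cWindowMs, maxIter = 20,
                       latencyTolSamples = 1, maxStepMs = 100) {
  stopifnot(maxIter >= 1, sWindowMs[1] < sWindowMs[2],
            cWindowMs[1] < cWindowMs[2],
            cSearchWindowMs[1] < cSearchWindowMs[2])
  structure(list(sWindowMs = sWindowMs, cWindowMs = cWindowMs,
                 cSearchWindowMs = cSearchWindowMs,
                 maxIter = as.integer(maxIter),
                 latencyTolSamples = latencyTolSamples,
                 maxStepMs = maxStepMs),
            class = "RideConfig")
}

# trials x (channels*time) view of the data tensor
.flattenTrials <- function(d) {
  n <- dim(d)[1]
  matrix(d, n, dim(d)[2] * dim(d)[3])
}

# median over trials of a trials x channels x time tensor -> channels x time
.medianWave <- function(d) {
  .medianOverTrials(d)
}

#' Per-trial latency estimation by template matching
#'
#' For each trial, finds the integer shift of the template that maximises
#' the cross-covariance with the residual, summed over channels. Shifts are
#' relative to the template's current position; ties are broken toward the
#' smallest absolute shift (then toward the earlier one).
#'
#' @param residuals trials x channels x time array.
#' @param template channels x time matrix (nonzero).
#' @param searchShifts integer vector of candidate shifts in samples.
#' @param center optional per-trial current shift; with `maxStep`, restricts
#'   each trial's candidates to a trust region `center +/- maxStep` (used to
#'   damp noise-driven jumps between distant score peaks across iterations).
#' @param maxStep maximal per-trial move in samples (default unrestricted).
#' @return integer vector of shifts, one per trial.
#' @export
estimateLatencies <- function(residuals, template, searchShifts,
                              center = NULL, maxStep = Inf) {
  if (!length(searchShifts)) stop("empty search window")
  if (all(template == 0)) stop("all-zero template")
  R <- .flattenTrials(residuals)
  scores <- vapply(searchShifts, function(s) {
    as.numeric(R %*% as.numeric(.shiftMat(template, s)))
  }, numeric(nrow(R)))
  if (nrow(R) == 1L) scores <- matrix(scores, 1L)
  if (!is.null(center) && is.finite(maxStep)) {
    for (i in seq_len(nrow(scores))) {
      far <- abs(searchShifts - center[i]) > maxStep
      if (!all(far)) scores[i, far] <- -Inf
    }
  }
  # tie-break: order candidates by |shift| then shift, pick first maximum
  ord <- order(abs(searchShifts), searchShifts)
  sc <- scores[, ord, drop = FALSE]
  best <- apply(sc, 1, function(v) ord[which.max(v)])
  searchShifts[best]
}

# initial latency: Woody-style template matching against the grand average
# tapered to the C window. Matching runs on average-removed residuals so
# that the stimulus-locked part, identical across trials, cancels exactly
# and cannot capture the alignment; the template anchor is the peak of its
# channel-RMS envelope.
.initLatencies <- function(d, avg, cTaper, searchIdx) {
  template <- avg * rep(cTaper, each = nrow(avg))
  env <- sqrt(colMeans(template^2))
  anchor <- which.max(env)
  shifts <- (min(searchIdx) - anchor):(max(searchIdx) - anchor)
  if (all(template == 0) || !length(shifts))
    return(rep(searchIdx[ceiling(length(searchIdx) / 2)], dim(d)[1]))
  # matching on (trial - avg + template): subtracting the average cancels
  # the stimulus-locked part exactly, and adding the template back removes
  # the self-subtraction dip the average's own C share would imprint on
  # every trial's score function
  resid <- d
  for (tr in seq_len(dim(d)[1]))
    resid[tr, , ] <- d[tr, , ] - avg + template
  anchor + estimateLatencies(resid, template, shifts)
}

#' RIDE decomposition of epoched data
#'
#' Decomposes single-trial epochs into a stimulus-locked S cluster and a
#' latency-variable C cluster by alternating median-based waveform
#' extraction and template-matching latency re-estimation, iterated until
#' the median absolute latency change is within tolerance.
#'
#' @param epochs an [Epochs-class] with at least 10 trials.
#' @param config a [rideConfig()].
#' @return a [RideResult-class]. `cLatencySamples` are indices into
#'   `times(epochs)` marking each trial's C-cluster position.
#' @examples
#' tt <- simulateBehaviour(generateTrialTable(taskDesign(48, 0.5, 0.5, 2)))
#' sim <- simulateEpochs(tt, montage = makeMontage(16, "fibonacci-sphere"),
#'                       srateHz = 64, seed = 3)
#' rideDecompose(sim$epochs)
#' @export
rideDecompose <- function(epochs, config = rideConfig()) {
  stopifnot(inherits(config, "RideConfig"))
  d <- epochData(epochs)
  if (dim(d)[1] < 10) stop("RIDE needs at least 10 trials")
  tms <- times(epochs)
  nT <- length(tms)
  fs <- srate(epochs)

  sTaper <- .tukeyWindowOnAxis(tms, config$sWindowMs)
  cTaper <- .tukeyWindowOnAxis(tms, config$cWindowMs)
  searchIdx <- which(tms >= config$cSearchWindowMs[1] &
                     tms <= config$cSearchWindowMs[2])
  if (!length(searchIdx)) stop("C search window contains no samples")

  avg <- apply(d, c(2, 3), mean)
  lat <- .initLatencies(d, avg, cTaper, searchIdx)
  latRef <- round(median(lat))                 # C template anchored here
  history <- list(lat)

  n <- dim(d)[1]
  sWave <- matrix(0, dim(d)[2], nT)
  cWave <- matrix(0, dim(d)[2], nT)
  converged <- FALSE
  iter <- 0L
  degenerate <- FALSE

  for (iter in seq_len(config$maxIter)) {
    # inner alternation: decompose S and C to self-consistency for the
    # current latencies, so neither waveform retains the other's share;
    # trials sharing a latency shift are processed as one block
    shiftBy <- lat - latRef
    groups <- split(seq_len(n), shiftBy)
    shiftVals <- as.integer(names(groups))
    nCh <- dim(d)[2]
    for (pass in seq_len(30L)) {
      resS <- d
      if (any(cWave != 0)) {
        for (gi in seq_along(groups)) {
          trs <- groups[[gi]]
          csh <- .shiftMat(cWave, shiftVals[gi])
          resS[trs, , ] <- d[trs, , , drop = FALSE] -
            rep(csh, each = length(trs))
        }
      }
      sNew <- .medianWave(resS)
      sNew <- sNew * rep(sTaper, each = nCh)

      resC <- array(0, dim(d))
      for (gi in seq_along(groups)) {
        trs <- groups[[gi]]
        sh <- -shiftVals[gi]
        if (sh >= 0) { dest <- (1 + sh):nT; src <- 1:(nT - sh) }
        else { dest <- 1:(nT + sh); src <- (1 - sh):nT }
        resC[trs, , dest] <- d[trs, , src, drop = FALSE] -
          rep(sNew[, src], each = length(trs))
      }
      cNew <- .medianWave(resC)
      cNew <- cNew * rep(cTaper, each = nCh)

      dS <- sum((sNew - sWave)^2)
      dC <- sum((cNew - cWave)^2)
      sWave <- sNew
      cWave <- cNew
      ref <- max(sum(sWave^2) + sum(cWave^2), 1e-12)
      if ((dS + dC) / ref < 1e-5) break
    }

    if (all(cWave == 0) || sum(cWave^2) < 1e-12 * max(1, sum(sWave^2))) {
      degenerate <- TRUE
      converged <- TRUE
      break
    }

    # latency re-estimation by template matching. Matching runs on
    # (trial - average + expected smeared C): subtracting the average
    # cancels the stimulus-locked content exactly (no reliance on the S
    # estimate), and adding back the latency-distribution-smeared template
    # removes the self-subtraction bias the average's C share would
    # otherwise imprint identically on every trial's score function.
    shifts <- (min(searchIdx) - latRef):(max(searchIdx) - latRef)
    cbarExp <- matrix(0, nCh, nT)
    for (gi in seq_along(groups))
      cbarExp <- cbarExp +
        length(groups[[gi]]) / n * .shiftMat(cWave, shiftVals[gi])
    resid <- d
    for (tr in seq_len(n)) resid[tr, , ] <- d[tr, , ] - avg + cbarExp
    maxStep <- round(config$maxStepMs * fs / 1000)
    newLat <- latRef + estimateLatencies(resid, cWave, shifts,
                                         center = lat - latRef,
                                         maxStep = maxStep)
    delta <- abs(newLat - lat)
    lat <- newLat
    history[[length(history) + 1L]] <- lat
    # during early iterations single-trial estimates can sit frozen on the
    # same noise optimum while the template still improves, so convergence
    # requires the mean change small as well, and at least 3 iterations
    if (iter >= 3L && median(delta) <= config$latencyTolSamples &&
        mean(delta) <= max(1, config$latencyTolSamples)) {
      converged <- TRUE
      break
    }
  }

  new("RideResult", sWaveform = sWave,
      cWaveform = if (degenerate) matrix(0, dim(d)[2], nT) else cWave,
      cLatencySamples = as.numeric(lat),
      sLatencySample = as.numeric(which.min(abs(tms))),
      nIterations = iter, converged = converged,
      latencyHistory = history, times = tms,
      config = unclass(config))
}

#' Single-trial S and C cluster reconstructions
#'
#' Splits each trial into its stimulus-locked and latency-variable parts:
#' the S-trial is the trial minus the C waveform shifted to that trial's
#' latency; the C-trial is the trial minus the S waveform. Latencies whose
#' shift pushes the C window outside the epoch are zero-padded and flagged.
#'
#' @param epochs the [Epochs-class] the decomposition was fitted on.
#' @param result the corresponding [RideResult-class].
#' @return list with 3-D arrays `S` and `C` (same shape as the data) and a
#'   logical `truncated` flag per trial.
#' @export
singleTrialClusters <- function(epochs, result) {
  d <- epochData(epochs)
  if (dim(d)[1] != length(result@cLatencySamples))
    stop("result does not match the epochs (trial count differs)")
  nT <- dim(d)[3]
  latRef <- round(median(result@cLatencySamples))
  S <- d
  C <- d
  truncated <- logical(dim(d)[1])
  cw <- result@cWaveform
  support <- range(which(colSums(cw^2) > 0), na.rm = TRUE)
  for (tr in seq_len(dim(d)[1])) {
    sh <- result@cLatencySamples[tr] - latRef
    S[tr, , ] <- d[tr, , ] - .shiftMat(cw, sh)
    C[tr, , ] <- d[tr, , ] - result@sWaveform
    if (is.finite(support[1]) &&
        (support[1] + sh < 1 || support[2] + sh > nT))
      truncated[tr] <- TRUE
  }
  list(S = S, C = C, truncated = truncated)
}
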