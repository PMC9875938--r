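# Simon Go/Nogo task simulation.
#
# The task: a letter ("A" or "B") appears left or right of fixation. Go
# trials require a left-hand response to "A" and a right-hand response to
# "B" regardless of stimulus side; a trial is congruent when the stimulus
# side matches the responding hand. On Nogo trials the response must be
# withheld; left-side "A" and right-side "B" count as congruent.

#' Task design parameters
#'
#' Defaults reproduce the standard design: 720 trials, 70% Go / 30% Nogo,
#' 50/50 congruency, 6 blocks of 120 trials, 200 ms stimuli, 1700 ms
#' response deadline, inter-trial interval jittered in 1300-1700 ms.
#'
#' @param nTrials total number of trials.
#' @param goProportion fraction of Go trials.
#' @param congruentProportion fraction of congruent trials.
#' @param nBlocks number of blocks; must divide `nTrials`.
#' @param stimDurationMs stimulus duration.
#' @param responseDeadlineMs response deadline after stimulus onset.
#' @param itiRangeMs length-2 inter-trial-interval range.
#' @return a list of class `TaskDesign`.
#' @export
taskDesign <- function(nTrials = 720, goProportion = 0.70,
                       congruentProportion = 0.50, nBlocks = 6,
                       stimDurationMs = 200, responseDeadlineMs = 1700,
                       itiRangeMs = c(1300, 1700)) {
  stopifnot(nTrials >= 1, nBlocks >= 1,
            goProportion >= 0, goProportion <= 1,
            congruentProportion >= 0, congruentProportion <= 1,
            length(itiRangeMs) == 2, itiRangeMs[1] <= itiRangeMs[2])
  if (nTrials %% nBlocks != 0)
    stop("nTrials must be divisible by nBlocks")
  structure(list(nTrials = as.integer(nTrials), goProportion = goProportion,
                 congruentProportion = congruentProportion,
                 nBlocks = as.integer(nBlocks),
                 stimDurationMs = stimDurationMs,
                 responseDeadlineMs = responseDeadlineMs,
                 itiRangeMs = itiRangeMs),
            class = "TaskDesign")
}

.cellCounts <- function(design) {
  perBlock <- design$nTrials / design$nBlocks
  n <- perBlock * c(
    go_congruent = design$goProportion * design$congruentProportion,
    go_incongruent = design$goProportion * (1 - design$congruentProportion),
    nogo_congruent = (1 - design$goProportion) * design$congruentProportion,
    nogo_incongruent = (1 - design$goProportion) * (1 - design$congruentProportion))
  if (max(abs(n - round(n))) > 1e-9)
    stop("per-block cell counts implied by the proportions are not whole ",
         "numbers; choose nTrials/proportions that balance across blocks")
  as.integer(round(n))
}

#' Generate a balanced, randomised trial table
#'
#' Each block contains exactly the same number of trials of each of the four
#' type x congruency cells, in randomised order. Letter identity is drawn
#' uniformly per trial; stimulus side then follows from the congruency cell
#' ("A" maps to the left hand, "B" to the right).
#'
#' @param design a [taskDesign()] list.
#' @param seed integer seed.
#' @return data.frame with columns block, trial_type (`go`/`nogo`),
#'   congruency (`congruent`/`incongruent`), letter, side, rt_ms (NA until
#'   [simulateBehaviour()]), outcome (NA likewise).
#' @examples
#' tt <- generateTrialTable(taskDesign(), seed = 1)
#' table(tt$trial_type)
#' @export
generateTrialTable <- function(design = taskDesign(), seed = 1L) {
  stopifnot(inherits(design, "TaskDesign"))
  counts <- .cellCounts(design)
  rng <- .makeRng(seed)
  cells <- data.frame(
    trial_type = rep(c("go", "go", "nogo", "nogo"), counts),
    congruency = rep(c("congruent", "incongruent",
                       "congruent", "incongruent"), counts))
  blocks <- lapply(seq_len(design$nBlocks), function(b) {
    idx <- rng$sampleInt(nrow(cells), nrow(cells))
    out <- cells[idx, , drop = FALSE]
    out$block <- b
    out
  })
  tt <- do.call(rbind, blocks)
  rownames(tt) <- NULL
  tt$letter <- c("A", "B")[1L + (rng$unif(nrow(tt)) < 0.5)]
  # responding hand: A -> left, B -> right; congruent = stimulus on that side
  hand <- ifelse(tt$letter == "A", "left", "right")
  tt$side <- ifelse(tt$congruency == "congruent", hand,
                    ifelse(hand == "left", "right", "left"))
  tt$rt_ms <- NA_real_
  tt$outcome <- NA_character_
  tt[, c("block", "trial_type", "congruency", "letter", "side",
         "rt_ms", "outcome")]
}

#' Behavioural parameter set
#'
#' Defaults follow typical conflict-task performance: congruent Go responses
#' faster than incongruent (539 vs 550 ms on average), log-normal RT
#' dispersion of about 110 ms, a small Go commission-error rate, and Nogo
#' false-alarm rates of 6.1% (congruent) vs 4.7% (incongruent) so that
#' congruent Nogo trials, where the prepotent response is stronger, fail
#' inhibition more often.
#'
#' @param rtMeanMs named c(congruent=, incongruent=) mean correct-Go RT.
#' @param rtSdMs trial-level RT standard deviation.
#' @param goErrorRate probability of a wrong-hand Go response.
#' @param nogoFalseAlarmRate named per-congruency false-alarm probabilities.
#' @return list of class `BehaviourParams`.
#' @export
behaviourParams <- function(rtMeanMs = c(congruent = 539, incongruent = 550),
                            rtSdMs = 110,
                            goErrorRate = 0.022,
                            nogoFalseAlarmRate = c(congruent = 0.061,
                                                   incongruent = 0.047)) {
  stopifnot(all(rtMeanMs > 0), rtSdMs >= 0,
            goErrorRate >= 0, goErrorRate <= 1,
            all(nogoFalseAlarmRate >= 0), all(nogoFalseAlarmRate <= 1))
  structure(list(rtMeanMs = rtMeanMs, rtSdMs = rtSdMs,
                 goErrorRate = goErrorRate,
                 nogoFalseAlarmRate = nogoFalseAlarmRate),
            class = "BehaviourParams")
}

# log-normal meanlog/sdlog for a target arithmetic mean and sd
.lnormPars <- function(m, s) {
  if (s <= 0) return(c(meanlog = log(m), sdlog = 0))
  v <- log(1 + (s / m)^2)
  c(meanlog = log(m) - v / 2, sdlog = sqrt(v))
}

#' Simulate behavioural outcomes on a trial table
#'
#' Go RTs are drawn log-normal per congruency; draws beyond the deadline
#' become misses (no RT). A small fraction of responded Go trials are
#' wrong-hand errors. Nogo outcomes are Bernoulli false alarms with the
#' configured per-congruency rates; false alarms receive an RT from the same
#' log-normal family, truncated at the deadline.
#'
#' @param trials a trial table from [generateTrialTable()].
#' @param behav a [behaviourParams()] list.
#' @param seed integer seed.
#' @param deadlineMs response deadline in ms.
#' @return the trial table with `rt_ms` and `outcome` filled
#'   (`correct`/`error`/`miss` for Go; `false_alarm`/`correct_omission` for
#'   Nogo).
#' @export
simulateBehaviour <- function(trials, behav = behaviourParams(), seed = 1L,
                              deadlineMs = 1700) {
  stopifnot(inherits(behav, "BehaviourParams"))
  rng <- .makeRng(seed)
  n <- nrow(trials)
  out <- trials
  for (cg in c("congruent", "incongruent")) {
    p <- .lnormPars(behav$rtMeanMs[[cg]], behav$rtSdMs)
    isGo <- trials$trial_type == "go" & trials$congruency == cg
    if (any(isGo)) {
      rt <- rng$lnorm(sum(isGo), p[["meanlog"]], p[["sdlog"]])
      miss <- rt > deadlineMs
      err <- !miss & rng$unif(sum(isGo)) < behav$goErrorRate
      out$rt_ms[isGo] <- ifelse(miss, NA_real_, rt)
      out$outcome[isGo] <- ifelse(miss, "miss", ifelse(err, "error", "correct"))
    }
    isNogo <- trials$trial_type == "nogo" & trials$congruency == cg
    if (any(isNogo)) {
      fa <- rng$unif(sum(isNogo)) < behav$nogoFalseAlarmRate[[cg]]
      rt <- rng$lnorm(sum(isNogo), p[["meanlog"]], p[["sdlog"]])
      rt <- pmin(rt, deadlineMs)         # a false alarm is by definition pre-deadline
      out$rt_ms[isNogo] <- ifelse(fa, rt, NA_real_)
      out$outcome[isNogo] <- ifelse(fa, "false_alarm", "correct_omission")
    }
  }
  out
}

#' Ground-truth signal parameters for epoch simulation
#'
#' The generating model per trial is
#' `sAmp * sTopo (x) sWave(t - sLat) + cAmp * cTopo (x) cWave(t - cLat_i) + noise`,
#' with a stimulus-locked source S at a fixed latency and a latency-variable
#' source C whose per-trial latency is coupled to RT. For trials without an
#' RT (correct Nogo), a surrogate RT from the same log-normal family drives
#' the C latency, so Nogo latencies share the Go latency distribution.
#'
#' @param sLatencyMs fixed S peak latency.
#' @param sWidthMs Gaussian envelope SD of the S waveform.
#' @param cLatencyMeanMs mean C peak latency.
#' @param cLatencySdMs across-trial SD of the C latency (jitter).
#' @param rtCoupling target Pearson correlation between C latency and RT.
#' @param sAmp named per-condition S amplitude (uV at the peak channel).
#' @param cAmp named per-condition C amplitude.
#' @param freqHz oscillatory frequency of the Gabor-like waveforms.
#' @param pinkSd spatially smooth 1/f background noise SD (uV).
#' @param whiteSd white sensor noise SD (uV).
#' @return list of class `TruthParams`.
#' @export
truthParams <- function(sLatencyMs = 180, sWidthMs = 60,
                        cLatencyMeanMs = 450, cLatencySdMs = 50,
                        rtCoupling = 0.8,
                        sAmp = c(congruent = 32, incongruent = 32),
                        cAmp = c(congruent = 22, incongruent = 26),
                        freqHz = 4, pinkSd = 4, whiteSd = 2) {
  structure(list(sLatencyMs = sLatencyMs, sWidthMs = sWidthMs,
                 cLatencyMeanMs = cLatencyMeanMs, cLatencySdMs = cLatencySdMs,
                 rtCoupling = rtCoupling, sAmp = sAmp, cAmp = cAmp,
                 freqHz = freqHz, pinkSd = pinkSd, whiteSd = whiteSd),
            class = "TruthParams")
}

# Gabor-ish biphasic waveform: Gaussian envelope times a sine half-cycle pair
.gaborWave <- function(tMs, centerMs, widthMs, freqHz) {
  exp(-0.5 * ((tMs - centerMs) / widthMs)^2) *
    sin(2 * pi * freqHz * (tMs - centerMs) / 1000 + pi / 2)
}

# smooth unit-norm topography: Gaussian on the sphere around a focus
.smoothTopo <- function(positions, focus, fwhm = 1.0) {
  d2 <- rowSums((positions - matrix(focus, nrow(positions), 3,
                                    byrow = TRUE))^2)
  v <- exp(-d2 / (2 * (fwhm / 2.355)^2))
  v <- v - mean(v) * 0.5            # keep some spatial structure, non-constant
  v / sqrt(sum(v^2))
}

# spatially smooth pink-ish noise: AR(1) in time per spatial basis function
.backgroundNoise <- function(rng, nTrial, nCh, nT, positions, pinkSd, whiteSd) {
  noise <- array(0, c(nTrial, nCh, nT))
  if (pinkSd > 0) {
    nb <- 8L                                  # spatial smoothness basis size
    basis <- vapply(seq_len(nb), function(k) {
      u <- c(cos(2.4 * k), sin(1.7 * k + 1), cos(0.9 * k + 2))
      .smoothTopo(positions, u / sqrt(sum(u^2)), fwhm = 1.4)
    }, numeric(nCh))
    a <- 0.97                                  # AR(1) pole -> 1/f-like spectrum
    sc <- pinkSd * sqrt(1 - a^2)
    for (tr in seq_len(nTrial)) {
      e <- matrix(rng$norm(nb * nT), nb, nT)
      x <- matrix(0, nb, nT)
      x[, 1] <- e[, 1] * pinkSd
      for (t in 2:nT) x[, t] <- a * x[, t - 1] + sc * e[, t]
      noise[tr, , ] <- basis %*% x
    }
  }
  if (whiteSd > 0)
    noise <- noise + array(rng$norm(nTrial * nCh * nT) * whiteSd,
                           c(nTrial, nCh, nT))
  noise
}

#' Simulate ground-truth EEG epochs for a trial table
#'
#' @param trials trial table with behavioural outcomes filled in.
#' @param truth a [truthParams()] list.
#' @param montage a [Montage-class]; topographies are generated on it.
#' @param seed integer seed.
#' @param srateHz sampling rate of the simulated epochs.
#' @param windowMs length-2 epoch window (half-open) around stimulus onset.
#' @return list with elements `epochs` ([Epochs-class]) and `truth`
#'   ([SimTruth-class]).
#' @examples
#' tt <- simulateBehaviour(generateTrialTable(taskDesign(120, 0.5, 0.5, 2)))
#' sim <- simulateEpochs(tt, seed = 2, srateHz = 128)
#' sim$epochs
#' @export
simulateEpochs <- function(trials, truth = truthParams(),
                           montage = makeMontage(60), seed = 1L,
                           srateHz = 256, windowMs = c(-500, 1500)) {
  stopifnot(inherits(truth, "TruthParams"))
  rng <- .makeRng(seed)
  nT <- round((windowMs[2] - windowMs[1]) * srateHz / 1000)
  tms <- windowMs[1] + (seq_len(nT) - 1L) * 1000 / srateHz
  pos <- channelPositions(montage)
  nCh <- nrow(pos)
  n <- nrow(trials)

  if (truth$sLatencyMs + 3 * truth$sWidthMs > windowMs[2] ||
      truth$sLatencyMs - 3 * truth$sWidthMs < windowMs[1])
    stop("S latency window extends beyond the epoch")

  sTopo <- .smoothTopo(pos, c(0.0, 0.55, 0.84), fwhm = 1.2)   # fronto-central
  cTopo <- .smoothTopo(pos, c(0.0, -0.45, 0.89), fwhm = 1.2)  # centro-parietal

  # C latency: linear in RT at the target coupling, same family for Nogo
  rt <- trials$rt_ms
  rtMean <- if (all(is.na(rt))) truth$cLatencyMeanMs else mean(rt, na.rm = TRUE)
  rtSd <- if (sum(!is.na(rt)) > 1) sd(rt, na.rm = TRUE) else 0
  surrogate <- is.na(rt)
  if (any(surrogate)) {
    p <- .lnormPars(max(rtMean, 1), max(rtSd, 1))
    rt[surrogate] <- rng$lnorm(sum(surrogate), p[["meanlog"]], p[["sdlog"]])
  }
  rho <- min(max(truth$rtCoupling, 0), 0.999)
  zRt <- if (rtSd > 0) (rt - rtMean) / rtSd else rep(0, n)
  cLat <- truth$cLatencyMeanMs + truth$cLatencySdMs *
    (rho * zRt + sqrt(1 - rho^2) * rng$norm(n))
  cLat <- pmin(pmax(cLat, tms[1] + 3 * truth$sWidthMs),
               tms[nT] - 3 * truth$sWidthMs)

  sAmpTr <- truth$sAmp[trials$congruency]
  cAmpTr <- truth$cAmp[trials$congruency]

  data <- .backgroundNoise(rng, n, nCh, nT, pos, truth$pinkSd, truth$whiteSd)
  sWave <- .gaborWave(tms, truth$sLatencyMs, truth$sWidthMs, truth$freqHz)
  for (tr in seq_len(n)) {
    cWave <- .gaborWave(tms, cLat[tr], truth$sWidthMs, truth$freqHz)
    data[tr, , ] <- data[tr, , ] +
      outer(sTopo, sAmpTr[tr] * sWave) + outer(cTopo, cAmpTr[tr] * cWave)
  }

  epochs <- newEpochs(data, srateHz, windowMs[1], montage, trials)
  truthObj <- new("SimTruth", sTopography = sTopo, cTopography = cTopo,
                  sLatencyMs = truth$sLatencyMs, cLatencyMs = cLat,
                  amplitudeByCondition = data.frame(
                    condition = names(truth$sAmp),
                    sAmp = unname(truth$sAmp),
                    cAmp = unname(truth$cAmp[names(truth$sAmp)])),
                  noiseParams = c(pinkSd = truth$pinkSd,
                                  whiteSd = truth$whiteSd),
                  seed = as.integer(seed))
  list(epochs = epochs, truth = truthObj)
}

#' Write / read a trial table as TSV
#'
#' @param trials trial table data.frame.
#' @param path file path.
#' @return `readTrialTable` returns the data.frame.
#' @export
writeTrialTable <- function(trials, path) {
  utils::write.table(trials, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeTrialTable
#' @export
readTrialTable <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
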