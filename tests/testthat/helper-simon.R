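# Shared fixtures, built in code.

# small Go/Nogo session with behaviour filled in
smallSession <- function(nTrials = 80, seed = 1L, behav = behaviourParams()) {
  tt <- generateTrialTable(taskDesign(nTrials, 0.5, 0.5, 2), seed = seed)
  simulateBehaviour(tt, behav, seed = seed + 1000L)
}

# wrap a mixing matrix into a GroupICAModel with the package's sign/scale
# conventions (for corrmap tests that need hand-made topographies)
mkIcaModel <- function(M) {
  M <- apply(M, 2, function(v) {
    v <- v / sqrt(sum(v^2))
    s <- sign(v[which.max(abs(v))])
    if (s == 0) s <- 1
    v * s
  })
  W <- MASS::ginv(M)
  new("GroupICAModel", mixing = M, unmixing = W, pcaBasis = M,
      channelMeans = rep(0, nrow(M)), nComponents = ncol(M),
      explainedVarianceFraction = 1, seed = 1L,
      clusterTag = NA_character_, conditionTag = NA_character_)
}

# vector with exact Pearson correlation r to v
plantCorrelated <- function(v, r) {
  zt <- as.numeric(scale(v))
  w <- stats::rnorm(length(v))
  w <- w - mean(w)
  w <- w - sum(w * zt) / sum(zt * zt) * zt
  zw <- w / stats::sd(w)
  r * zt + sqrt(1 - r^2) * zw
}

# two-source noiseless/noisy epochs with known truth on a small montage
smallTwoSourceSim <- function(nTrials = 80, nCh = 20, srate = 128,
                              seed = 5L, truth = truthParams()) {
  tt <- smallSession(nTrials, seed = seed)
  simulateEpochs(tt, truth, makeMontage(nCh, "fibonacci-sphere"),
                 seed = seed + 1L, srateHz = srate,
                 windowMs = c(-500, 1500))
}

# the generating S waveform of the simulator on a time axis
truthSWave <- function(truth, tms, tp = truthParams()) {
  truth@sTopography %o%
    (tp$sAmp[[1]] * exp(-0.5 * ((tms - tp$sLatencyMs) / tp$sWidthMs)^2) *
       sin(2 * pi * tp$freqHz * (tms - tp$sLatencyMs) / 1000 + pi / 2))
}
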