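test_that("latency estimation finds exact shifts and breaks ties toward
          zero", {
  set.seed(1)
  tmpl <- matrix(0, 4, 120)
  tmpl[, 50:62] <- matrix(rnorm(52), 4)
  res <- array(0, c(3, 4, 120))
  true <- c(-9, 0, 12)
  for (i in 1:3) res[i, , ] <- simonEEG:::.shiftMat(tmpl, true[i])
  expect_equal(estimateLatencies(res, tmpl, -30:30), true)

  # orthogonal residual: all scores equal(ly zero) -> smallest |shift| wins
  resO <- array(0, c(1, 4, 120))
  expect_equal(estimateLatencies(resO, tmpl, -30:30), 0)
  expect_error(estimateLatencies(res, tmpl * 0, -30:30), "template")
  expect_error(estimateLatencies(res, tmpl, integer(0)), "search")
})

test_that("noisy shifted copies are recovered with small mean error", {
  set.seed(2)
  nT <- 160
  tmpl <- matrix(0, 6, nT)
  tms <- seq_len(nT)
  tmpl[, ] <- rep(exp(-0.5 * ((tms - 80) / 8)^2) * sin(tms / 4), each = 6) *
    rnorm(6)
  jitterSd <- 10
  n <- 300
  shifts <- round(rnorm(n, 0, jitterSd))
  shifts <- pmin(pmax(shifts, -30), 30)
  res <- array(rnorm(n * 6 * nT, sd = sqrt(mean(tmpl^2))), c(n, 6, nT))
  for (i in seq_len(n))
    res[i, , ] <- res[i, , ] + simonEEG:::.shiftMat(tmpl, shifts[i])
  est <- estimateLatencies(res, tmpl, -40:40)
  expect_lt(mean(abs(est - shifts)), jitterSd / 2)
})

test_that("pure stimulus-locked data yield S = average and a flagged zero
          C waveform", {
  tt <- smallSession(24, seed = 3)
  tp <- truthParams(cAmp = c(congruent = 0, incongruent = 0),
                    pinkSd = 0, whiteSd = 0)
  sim <- simulateEpochs(tt, tp, makeMontage(16, "fibonacci-sphere"),
                        seed = 4, srateHz = 128)
  rr <- rideDecompose(sim$epochs)
  expect_true(rr@converged)
  expect_lt(max(abs(cWaveform(rr))), 1e-9)
  avg <- apply(epochData(sim$epochs), c(2, 3), mean)
  tms <- times(sim$epochs)
  win <- tms >= -200 + 80 & tms <= 600 - 80     # inside the taper plateau
  expect_lt(max(abs(sWaveform(rr)[, win] - avg[, win])), 1e-6)
})

test_that("zero latency jitter gives constant recovered latencies and an
          additive S + C reconstruction", {
  tt <- smallSession(24, seed = 5, behav = behaviourParams(rtSdMs = 0))
  tp <- truthParams(cLatencySdMs = 0, rtCoupling = 0, pinkSd = 0,
                    whiteSd = 0)
  sim <- simulateEpochs(tt, tp, makeMontage(16, "fibonacci-sphere"),
                        seed = 6, srateHz = 128)
  rr <- rideDecompose(sim$epochs)
  expect_lte(diff(range(cLatencies(rr))), 1)
  avg <- apply(epochData(sim$epochs), c(2, 3), mean)
  rec <- sWaveform(rr) + cWaveform(rr)   # all latencies at the reference
  tms <- times(sim$epochs)
  win <- tms >= 250 & tms <= 650
  relErr <- sqrt(sum((rec[, win] - avg[, win])^2) / sum(avg[, win]^2))
  expect_lt(relErr, 0.15)
})

test_that("two-source recovery succeeds on a compact problem", {
  sim <- smallTwoSourceSim(96, nCh = 24, srate = 128, seed = 7)
  rr <- rideDecompose(sim$epochs)
  tms <- times(sim$epochs)
  expect_gte(cor(tms[cLatencies(rr)], sim$truth@cLatencyMs), 0.8)
  trueS <- truthSWave(sim$truth, tms)
  chS <- which.max(abs(sim$truth@sTopography))
  expect_gte(cor(sWaveform(rr)[chS, ], trueS[chS, ]), 0.9)
})

test_that("decomposition is self-consistent on data resynthesized from its
          own result", {
  sim <- smallTwoSourceSim(64, nCh = 16, srate = 128, seed = 8)
  rr <- rideDecompose(sim$epochs)
  latRef <- round(median(cLatencies(rr)))
  d <- array(0, dim(epochData(sim$epochs)))
  for (i in seq_len(dim(d)[1]))
    d[i, , ] <- sWaveform(rr) +
      simonEEG:::.shiftMat(cWaveform(rr), cLatencies(rr)[i] - latRef)
  ep2 <- newEpochs(d, srate(sim$epochs), times(sim$epochs)[1],
                   montage(sim$epochs), trialData(sim$epochs))
  rr2 <- rideDecompose(ep2)
  expect_gte(cor(cLatencies(rr2), cLatencies(rr)), 0.95)
  chS <- which.max(rowSums(sWaveform(rr)^2))
  # the S/C split is only identifiable up to the window overlap, so the
  # individual waveforms agree approximately ...
  expect_gte(cor(sWaveform(rr2)[chS, ], sWaveform(rr)[chS, ]), 0.9)
  # ... while the reconstructed single-trial model agrees almost exactly
  latRef2 <- round(median(cLatencies(rr2)))
  for (i in c(1, 10)) {
    rec1 <- d[i, , ]                         # the generating model itself
    rec2 <- sWaveform(rr2) +
      simonEEG:::.shiftMat(cWaveform(rr2), cLatencies(rr2)[i] - latRef2)
    expect_gte(cor(as.numeric(rec1), as.numeric(rec2)), 0.95)
  }
})

test_that("median waveform extraction resists amplitude outliers better
          than a mean", {
  sim <- smallTwoSourceSim(64, nCh = 16, srate = 128, seed = 9)
  d <- epochData(sim$epochs)
  clean <- rideDecompose(sim$epochs)
  dOut <- d
  out <- seq_len(6)                         # 10% contaminated
  dOut[out, , ] <- dOut[out, , ] + 200
  epOut <- newEpochs(dOut, srate(sim$epochs), times(sim$epochs)[1],
                     montage(sim$epochs), trialData(sim$epochs))
  dirty <- rideDecompose(epOut)
  medShift <- sqrt(mean((sWaveform(dirty) - sWaveform(clean))^2))
  meanClean <- apply(d, c(2, 3), mean)
  meanDirty <- apply(dOut, c(2, 3), mean)
  meanShift <- sqrt(mean((meanDirty - meanClean)^2))
  expect_lt(medShift, meanShift)
})

test_that("latency changes settle: final iteration moves less than the
          first, across runs", {
  ok <- 0L
  for (sd in 1:4) {
    sim <- smallTwoSourceSim(64, nCh = 16, srate = 128, seed = 20 + sd)
    rr <- rideDecompose(sim$epochs)
    h <- rr@latencyHistory
    if (length(h) >= 3) {
      first <- mean(abs(h[[2]] - h[[1]]))
      last <- mean(abs(h[[length(h)]] - h[[length(h) - 1]]))
      if (last <= first) ok <- ok + 1L
    } else ok <- ok + 1L
  }
  expect_gte(ok, 3L)
})

test_that("single-trial clusters cancel exactly in the noiseless case and
          satisfy the bookkeeping identity", {
  tt <- smallSession(24, seed = 10)
  tp <- truthParams(pinkSd = 0, whiteSd = 0)
  sim <- simulateEpochs(tt, tp, makeMontage(16, "fibonacci-sphere"),
                        seed = 11, srateHz = 128)
  rr <- rideDecompose(sim$epochs)
  st <- singleTrialClusters(sim$epochs, rr)
  d <- epochData(sim$epochs)
  latRef <- round(median(cLatencies(rr)))
  for (i in c(1, 5)) {
    csh <- simonEEG:::.shiftMat(cWaveform(rr), cLatencies(rr)[i] - latRef)
    # definitional identities, computed independently of the function
    expect_lt(max(abs(st$S[i, , ] - (d[i, , ] - csh))), 1e-9)
    expect_lt(max(abs(st$C[i, , ] - (d[i, , ] - sWaveform(rr)))), 1e-9)
    # bookkeeping: S-trial + C-trial - trial = trial - (S + C at latency)
    lhs <- st$S[i, , ] + st$C[i, , ] - d[i, , ]
    expect_lt(max(abs(lhs - (d[i, , ] - sWaveform(rr) - csh))), 1e-9)
  }
  expect_error(singleTrialClusters(subsetTrials(sim$epochs, 1:3), rr),
               "trial count")
})

test_that("zero-amplitude C leaves C-trials as pure residual noise", {
  tt <- smallSession(24, seed = 12)
  tp <- truthParams(cAmp = c(congruent = 0, incongruent = 0),
                    pinkSd = 0, whiteSd = 1)
  sim <- simulateEpochs(tt, tp, makeMontage(16, "fibonacci-sphere"),
                        seed = 13, srateHz = 128)
  rr <- rideDecompose(sim$epochs)
  st <- singleTrialClusters(sim$epochs, rr)
  resid <- epochData(sim$epochs) -
    rep(sWaveform(rr), each = nTrials(sim$epochs))
  expect_lt(max(abs(st$C - resid)), 1e-9)
})
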