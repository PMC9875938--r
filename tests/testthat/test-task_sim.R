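test_that("default design yields the printed trial counts, balanced per block", {
  tt <- generateTrialTable(taskDesign(), seed = 1)
  expect_equal(sum(tt$trial_type == "go"), 504)
  expect_equal(sum(tt$trial_type == "nogo"), 216)
  expect_equal(as.integer(table(tt$block)), rep(120L, 6))
  # per-block cell counts equal across blocks, for several seeds
  for (sd in 1:4) {
    tt <- generateTrialTable(taskDesign(), seed = sd)
    tab <- table(tt$block, tt$trial_type, tt$congruency)
    expect_true(all(tab[, "go", "congruent"] == 42))
    expect_true(all(tab[, "go", "incongruent"] == 42))
    expect_true(all(tab[, "nogo", "congruent"] == 18))
    expect_true(all(tab[, "nogo", "incongruent"] == 18))
  }
})

test_that("a 4-trial balanced design gives one trial per cell, and

          non-integral cell counts are rejected", {
  tt <- generateTrialTable(taskDesign(4, 0.5, 0.5, 1), seed = 2)
  expect_equal(nrow(unique(tt[, c("trial_type", "congruency")])), 4L)
  expect_error(generateTrialTable(taskDesign(10, 0.7, 0.5, 1)),
               "not whole")
  expect_error(taskDesign(10, 0.7, 0.5, 3), "divisible")
})

test_that("congruency is consistent with the letter/side response mapping", {
  tt <- generateTrialTable(taskDesign(240, 0.5, 0.5, 2), seed = 3)
  hand <- ifelse(tt$letter == "A", "left", "right")
  expect_true(all((tt$side == hand) == (tt$congruency == "congruent")))
})

test_that("behavioural simulation honours degenerate parameter settings", {
  tt <- generateTrialTable(taskDesign(240, 0.5, 0.5, 2), seed = 1)
  noFa <- simulateBehaviour(tt, behaviourParams(
    nogoFalseAlarmRate = c(congruent = 0, incongruent = 0)), seed = 2)
  expect_true(all(noFa$outcome[noFa$trial_type == "nogo"] ==
                    "correct_omission"))
  fixed <- simulateBehaviour(tt, behaviourParams(
    rtMeanMs = c(congruent = 539, incongruent = 550), rtSdMs = 0,
    goErrorRate = 0), seed = 3)
  rtC <- fixed$rt_ms[fixed$trial_type == "go" &
                       fixed$congruency == "congruent"]
  expect_true(all(abs(rtC - 539) < 1e-9))
})

test_that("default false-alarm rates reproduce the target Nogo accuracies in
          expectation", {
  tt <- generateTrialTable(taskDesign(), seed = 1)
  nogo <- tt[tt$trial_type == "nogo", ]
  accC <- accI <- numeric(400)
  for (i in seq_len(400)) {
    b <- simulateBehaviour(nogo, seed = i)
    s <- summarizeBehaviour(b)
    accC[i] <- s$nogo_accuracy_pct[s$congruency == "congruent"]
    accI[i] <- s$nogo_accuracy_pct[s$congruency == "incongruent"]
  }
  expect_lt(abs(mean(accC) - 93.9), 0.3)
  expect_lt(abs(mean(accI) - 95.3), 0.3)
})

test_that("noiseless single-source epochs are identical across trials and
          rank one in channel space", {
  tt <- smallSession(40, seed = 4)
  tp <- truthParams(cAmp = c(congruent = 0, incongruent = 0),
                    sAmp = c(congruent = 10, incongruent = 10),
                    pinkSd = 0, whiteSd = 0)
  sim <- simulateEpochs(tt, tp, makeMontage(16, "fibonacci-sphere"),
                        seed = 5, srateHz = 128)
  d <- epochData(sim$epochs)
  expect_lt(max(abs(sweep(d, c(2, 3), d[1, , ]))), 1e-9)
  expect_equal(qr(d[1, , ])$rank, 1L)
})

test_that("zero condition deltas and zero noise give identical condition
          averages", {
  tt <- smallSession(40, seed = 6, behav = behaviourParams(
    rtMeanMs = c(congruent = 545, incongruent = 545)))
  tp <- truthParams(cAmp = c(congruent = 20, incongruent = 20),
                    cLatencySdMs = 0, rtCoupling = 0,
                    pinkSd = 0, whiteSd = 0)
  sim <- simulateEpochs(tt, tp, makeMontage(16, "fibonacci-sphere"),
                        seed = 7, srateHz = 128)
  d <- epochData(sim$epochs)
  cg <- trialData(sim$epochs)$congruency == "congruent"
  avgC <- apply(d[cg, , , drop = FALSE], c(2, 3), mean)
  avgI <- apply(d[!cg, , , drop = FALSE], c(2, 3), mean)
  expect_lt(max(abs(avgC - avgI)), 1e-9)
})

test_that("simulated C latencies track RT at the configured coupling", {
  tt <- simulateBehaviour(generateTrialTable(taskDesign(), seed = 8),
                          seed = 9)
  go <- tt[tt$trial_type == "go" & !is.na(tt$rt_ms), ]
  sim <- simulateEpochs(go, truthParams(rtCoupling = 0.8),
                        makeMontage(16, "fibonacci-sphere"),
                        seed = 10, srateHz = 64)
  r <- cor(sim$truth@cLatencyMs, go$rt_ms)
  expect_gte(r, 0.8 - 0.05)
})

test_that("montages are deterministic, unit-norm and well labelled", {
  m1 <- makeMontage(60, "fibonacci-sphere")
  m2 <- makeMontage(60, "fibonacci-sphere")
  expect_identical(channelPositions(m1), channelPositions(m2))
  expect_equal(max(abs(sqrt(rowSums(channelPositions(m1)^2)) - 1)), 0,
               tolerance = 1e-9)
  expect_equal(nrow(unique(channelPositions(m1))), 60L)
  mt <- makeMontage(60, "ten-ten-subset")
  expect_true(all(grepl("^(Fp|AF|F|FT|FC|T|C|TP|CP|P|PO|O)[z0-9]+$",
                        channelLabels(mt))))
  expect_false(anyDuplicated(channelLabels(mt)) > 0)
  expect_error(makeMontage(8), "16")
  expect_error(makeMontage(60, "bogus"))
})

test_that("trial tables round-trip through TSV", {
  tt <- simulateBehaviour(generateTrialTable(taskDesign(24, 0.5, 0.5, 1),
                                             seed = 1), seed = 2)
  f <- tempfile(fileext = ".tsv")
  writeTrialTable(tt, f)
  back <- readTrialTable(f)
  expect_equal(back$trial_type, tt$trial_type)
  expect_equal(back$rt_ms, tt$rt_ms, tolerance = 1e-8)
})
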