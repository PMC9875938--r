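# small epochs wrapper around a single-channel signal matrix
signalEpochs <- function(x, srate, tmin = 0, nCh = 1) {
  n <- if (is.matrix(x)) nrow(x) else 1L
  xm <- if (is.matrix(x)) x else matrix(x, 1)
  d <- array(0, c(n, nCh, ncol(xm)))
  for (ch in seq_len(nCh)) d[, ch, ] <- xm
  newEpochs(d, srate, tmin, makeMontage(max(nCh, 16), "fibonacci-sphere"),
            data.frame(trial = seq_len(n)))
}

test_that("band-pass keeps the passband and strongly attenuates beyond it", {
  fs <- 256
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  ep10 <- signalEpochs(sin(2 * pi * 10 * t), fs, nCh = 16)
  f10 <- bandpassFilter(ep10, 0.5, 40, 4)
  mid <- 200:800
  amp <- max(abs(epochData(f10)[1, 1, mid]))
  expect_gt(amp, 0.99)          # < 1% passband loss after edge trimming

  ep80 <- signalEpochs(sin(2 * pi * 80 * t), fs, nCh = 16)
  f80 <- bandpassFilter(ep80, 0.5, 40, 4)
  amp80 <- max(abs(epochData(f80)[1, 1, mid]))
  expect_lt(20 * log10(amp80), -20)   # >= 20 dB down at 80 Hz

  dc <- signalEpochs(rep(5, length(t)), fs, nCh = 16)
  fdc <- bandpassFilter(dc, 0.5, 40, 4)
  expect_lt(abs(mean(epochData(fdc)[1, 1, mid])), 0.25)  # 5% of the offset

  expect_error(bandpassFilter(ep10, 0.5, 200, 4), "srate/2")
})

test_that("resampling follows the half-open window convention and preserves
          band-limited content", {
  fs <- 500
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)    # 2000 samples = 4000 ms
  ep <- signalEpochs(sin(2 * pi * 5 * t), fs, tmin = -2000, nCh = 16)
  rs <- resampleEpochs(ep, 256)
  expect_equal(dim(epochData(rs))[3], 1024L)   # 4 s x 256 Hz
  expect_equal(srate(rs), 256)
  tNew <- (times(rs) + 2000) / 1000
  mid <- 100:900
  r <- cor(epochData(rs)[1, 1, mid], sin(2 * pi * 5 * tNew[mid]))
  expect_gt(r, 0.999)

  cst <- resampleEpochs(signalEpochs(rep(3, length(t)), fs, nCh = 16), 100)
  expect_lt(max(abs(epochData(cst)[1, 1, 50:350] - 3)), 0.01)
  expect_error(resampleEpochs(ep, 0), "positive")
  expect_error(resampleEpochs(ep, 600), "below")
})

test_that("artifact rejection drops spikes and flatlines and keeps clean
          simulated trials", {
  sim <- smallTwoSourceSim(40, seed = 11)
  ep <- sim$epochs
  d <- epochData(ep)
  d[3, 2, 50] <- 150                      # amplitude artifact
  d[7, , ] <- 0                           # flat trial
  ep@data <- d
  r <- rejectArtifacts(ep, 100, 0.5, 100)
  expect_equal(r$log$reason[3], "amplitude_exceeds")
  expect_equal(r$log$reason[7], "flatline")
  expect_false(any(r$log$kept[c(3, 7)]))
  expect_true(all(r$log$kept[-c(3, 7)]))  # ongoing noise keeps the rest
  expect_equal(nTrials(r$epochs), 38L)
  expect_error(rejectArtifacts(ep, 100, 0.5, 10000), "longer")
})

test_that("CSD output is reference-free and zero for spatially constant maps", {
  m <- makeMontage(32, "fibonacci-sphere")
  d <- array(7, c(2, 32, 5))
  ep <- newEpochs(d, 100, 0, m, data.frame(trial = 1:2))
  out <- csdTransform(ep)
  expect_lt(max(abs(epochData(out))), 1e-8)
  expect_match(out@unitLabel, "CSD")

  set.seed(1)
  d2 <- array(rnorm(2 * 32 * 5), c(2, 32, 5))
  epA <- newEpochs(d2, 100, 0, m, data.frame(trial = 1:2))
  epB <- newEpochs(d2 + 25, 100, 0, m, data.frame(trial = 1:2))
  expect_equal(epochData(csdTransform(epA)), epochData(csdTransform(epB)),
               tolerance = 1e-6)
})

test_that("CSD of a low-order spherical harmonic reproduces its sign
          pattern", {
  m <- makeMontage(60, "fibonacci-sphere")
  pos <- channelPositions(m)
  harm <- pos[, 3]                         # degree-1 harmonic (z)
  d <- array(harm, c(1, 60, 1))
  ep <- newEpochs(d, 100, 0, m, data.frame(trial = 1))
  out <- epochData(csdTransform(ep))[1, , 1]
  # eigenfunction of the surface Laplacian: same spatial pattern
  expect_gt(abs(cor(out, harm)), 0.99)
})

test_that("CSD rejects duplicate electrode positions", {
  m <- makeMontage(16, "fibonacci-sphere")
  p <- channelPositions(m)
  p[2, ] <- p[1, ]
  mDup <- new("Montage", labels = channelLabels(m), positions = p)
  ep <- newEpochs(array(rnorm(16 * 3), c(1, 16, 3)), 100, 0, mDup,
                  data.frame(trial = 1))
  expect_error(csdTransform(ep), "singular|duplicate")
})

test_that("baseline correction subtracts the window mean exactly", {
  fs <- 100
  nT <- 100
  tmin <- -500
  ramp <- seq_len(nT)
  ep <- signalEpochs(rbind(ramp, rep(5, nT)), fs, tmin = tmin, nCh = 16)
  out <- baselineCorrect(ep, c(-300, 0))
  tms <- times(out)
  sel <- tms >= -300 & tms < 0
  expect_lt(max(abs(apply(epochData(out)[, 1, sel], 1, mean))), 1e-10)
  expect_equal(epochData(out)[1, 1, ], ramp - mean(ramp[sel]),
               tolerance = 1e-10)
  expect_lt(max(abs(epochData(out)[2, 1, ])), 1e-10)
  expect_error(baselineCorrect(ep, c(900, 1000)), "no samples")
})

test_that("the chain refuses silent reordering of its stages", {
  sim <- smallTwoSourceSim(16, nCh = 16, seed = 12)
  ep <- baselineCorrect(sim$epochs, c(-300, 0))
  expect_error(bandpassFilter(ep), "chain order")
  ep2 <- csdTransform(sim$epochs)
  expect_error(resampleEpochs(ep2, 64), "chain order")
  # canonical order passes end to end and is reproducible
  r1 <- preprocessChain(sim$epochs, targetHz = 64)
  r2 <- preprocessChain(sim$epochs, targetHz = 64)
  expect_identical(epochData(r1$epochs), epochData(r2$epochs))
  expect_identical(r1$log$kept, r2$log$kept)
})
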