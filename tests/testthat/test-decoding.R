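nullData <- function(nTr, nCh, nT, seed) {
  set.seed(seed)
  array(rnorm(nTr * nCh * nT), c(nTr, nCh, nT))
}

test_that("undersampling balances classes deterministically", {
  labels <- c(rep("a", 108), rep("b", 108))
  expect_equal(undersample(labels, 1), seq_along(labels))
  labels2 <- c(rep("a", 120), rep("b", 96))
  keep <- undersample(labels2, 2)
  expect_equal(sum(labels2[keep] == "a"), 96L)
  expect_equal(sum(labels2[keep] == "b"), 96L)
  expect_identical(undersample(labels2, 7), undersample(labels2, 7))
  expect_false(identical(undersample(labels2, 7), undersample(labels2, 8)))
  expect_error(undersample(rep("a", 10), 1), "two classes")
})

test_that("decoding statistically identical classes stays at chance", {
  tms <- seq(0, 1000, by = 40)
  aucs <- numeric(6)
  for (i in seq_len(6)) {
    dr <- decodePair(nullData(40, 12, length(tms), i),
                     nullData(40, 12, length(tms), i + 100), tms,
                     cv = cvConfig(seed = i), generalize = FALSE)
    aucs[i] <- mean(dr@subjectAuc)
  }
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("a window-limited separable effect is decoded inside, and only
          inside, its window", {
  tms <- seq(0, 1000, by = 40)
  win <- tms >= 300 & tms <= 600
  dA <- nullData(50, 12, length(tms), 1)
  dB <- nullData(50, 12, length(tms), 2)
  dA[, 1:4, win] <- dA[, 1:4, win] + 1.5
  dr <- decodePair(dA, dB, tms, cv = cvConfig(seed = 3), generalize = TRUE)
  expect_gt(mean(dr@subjectAuc[win]), 0.9)
  expect_lt(abs(mean(dr@subjectAuc[!win]) - 0.5), 0.08)
  # sustained effect generalizes across the whole block
  expect_gt(mean(dr@subjectTg[win, win]), 0.8)
  expect_lt(abs(mean(dr@subjectTg[!win, !win]) - 0.5), 0.08)
  # diagonal of the TG matrix is the AUC time course
  expect_equal(diag(dr@subjectTg), dr@subjectAuc)
})

test_that("the linear SVM separates its own training data perfectly when
          classes are separable", {
  set.seed(4)
  x <- rbind(matrix(rnorm(30 * 5, 3), 30), matrix(rnorm(30 * 5, -3), 30))
  y <- factor(rep(c("A", "B"), each = 30))
  clf <- simonEEG:::.svmDecision(x, y, "A")
  s <- clf$score(x)
  expect_equal(simonEEG:::.rankAuc(s[y == "A"], s[y == "B"]), 1.0)
})

test_that("the group cluster test returns nothing when every subject sits
          at chance", {
  scores <- matrix(0.5, 12, 30)
  ct <- groupClusterTest(scores, nPerm = 200, seed = 1)
  expect_equal(nrow(ct$clusters), 0L)
  expect_false(any(ct$significantMask))
})

test_that("a strong confined effect yields exactly one significant cluster
          covering its span", {
  set.seed(5)
  scores <- matrix(0.5 + rnorm(16 * 40, sd = 0.01), 16, 40)
  scores[, 18:25] <- 0.8
  ct <- groupClusterTest(scores, nPerm = 500, seed = 2)
  sig <- ct$clusters[ct$clusters$p_value < 0.05, ]
  expect_equal(nrow(sig), 1L)
  expect_true(all(ct$significantMask[18:25]))
  expect_true(sum(ct$significantMask) <= 12)
})

test_that("1-D and 2-D cluster statistics agree on the diagonal
          pointwise z", {
  set.seed(6)
  nS <- 10; T <- 12
  tg <- array(0.5 + rnorm(nS * T * T, sd = 0.05), c(nS, T, T))
  for (s in seq_len(nS)) diag(tg[s, , ]) <- 0.5 + abs(rnorm(T, 0.1, 0.02))
  ct2 <- groupClusterTest(tg, nPerm = 200, seed = 3)
  diagScores <- t(vapply(seq_len(nS), function(s) diag(tg[s, , ]),
                         numeric(T)))
  ct1 <- groupClusterTest(diagScores, nPerm = 200, seed = 3)
  expect_equal(diag(ct2$pointZ), ct1$pointZ, tolerance = 1e-12)
  expect_equal(dim(ct2$significantMask), c(T, T))
})

test_that("2-D clusters are 4-connected", {
  mask <- matrix(FALSE, 5, 5)
  mask[1, 1] <- TRUE
  mask[2, 1] <- TRUE        # connected to [1,1]
  mask[4, 4] <- TRUE        # diagonal-only: separate cluster
  mask[5, 5] <- TRUE
  lab <- simonEEG:::.label4(mask)
  expect_equal(lab[1, 1], lab[2, 1])
  expect_true(lab[4, 4] != lab[5, 5])
  expect_equal(max(lab), 3L)
})

test_that("the point-wise signed-rank z matches the reference
          implementation", {
  set.seed(7)
  for (i in 1:5) {
    x <- rnorm(25, 0.05)
    mom <- simonEEG:::.signedRankMoments(abs(x))
    W <- sum(mom$ranks[x > 0])
    z <- (W - mom$mu) / mom$sigma
    ref <- suppressWarnings(
      stats::wilcox.test(x, alternative = "greater", exact = FALSE,
                         correct = FALSE))
    zRef <- stats::qnorm(1 - ref$p.value)
    expect_equal(z, zRef, tolerance = 1e-6)
  }
})

test_that("permutation counts below 100 warn but proceed", {
  scores <- matrix(0.5 + rnorm(8 * 10, sd = 0.02), 8, 10)
  expect_warning(ct <- groupClusterTest(scores, nPerm = 50, seed = 4),
                 "coarse")
  expect_true(ct$lowPermWarning)
  expect_error(groupClusterTest(scores[1:3, ], nPerm = 200), "5 subjects")
})
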