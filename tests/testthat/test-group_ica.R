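mixSources <- function(nCh, k, N, seed) {
  set.seed(seed)
  A <- matrix(rnorm(nCh * k), nCh, k)
  S <- matrix(rnorm(k * N)^3, k, N)        # super-Gaussian sources
  X <- A %*% S
  list(A = A, S = S,
       data = aperm(array(X, c(nCh, N, 1)), c(3, 1, 2)))
}

test_that("noiseless super-Gaussian mixtures are unmixed almost exactly", {
  mx <- mixSources(60, 3, 4000, seed = 1)
  m <- fitGroupICA(list(mx$data), nComponents = 3, varThreshold = 0.5,
                   seed = 1)
  rmat <- abs(cor(mixing(m), mx$A))
  expect_true(all(apply(rmat, 2, max) >= 0.99))
  expect_lt(amariDistance(unmixing(m), mx$A), 0.05)
})

test_that("amari distance stays small for up to 5 sources", {
  for (k in c(4, 5)) {
    mx <- mixSources(40, k, 4000, seed = k)
    m <- fitGroupICA(list(mx$data), nComponents = k, varThreshold = 0.5,
                     seed = 2)
    expect_lt(amariDistance(unmixing(m), mx$A), 0.05)
  }
})

test_that("rank-1 data with one component return the generating topography
          up to sign", {
  set.seed(3)
  a <- rnorm(30)
  act <- rnorm(500)^3
  d <- aperm(array(outer(a, act), c(30, 500, 1)), c(3, 1, 2))
  m <- fitGroupICA(list(d), nComponents = 1, varThreshold = 0.5, seed = 1)
  expect_gte(abs(cor(mixing(m)[, 1], a)), 1 - 1e-6)
  # stored sign convention: dominant channel positive
  expect_gt(mixing(m)[which.max(abs(mixing(m)[, 1])), 1], 0)
})

test_that("fitting is deterministic under a fixed seed, including on
          Gaussian data", {
  set.seed(4)
  d <- array(rnorm(4 * 20 * 300), c(4, 20, 300))
  m1 <- fitGroupICA(list(d), nComponents = 5, varThreshold = 0.1, seed = 9)
  m2 <- fitGroupICA(list(d), nComponents = 5, varThreshold = 0.1, seed = 9)
  expect_identical(mixing(m1), mixing(m2))
  expect_identical(unmixing(m1), unmixing(m2))
})

test_that("a subject poorly represented in the group subspace triggers the
          variance check", {
  mx <- mixSources(20, 2, 800, seed = 5)
  set.seed(6)
  odd <- array(rnorm(1 * 20 * 800), c(1, 20, 800))  # white, full-rank
  expect_error(
    fitGroupICA(list(mx$data, odd), nComponents = 2, varThreshold = 0.98,
                seed = 1),
    "retains only")
  expect_error(fitGroupICA(list(mx$data), nComponents = 25), "components")
})

test_that("back-reconstruction inverts the mixing and is linear", {
  mx <- mixSources(24, 3, 600, seed = 7)
  m <- fitGroupICA(list(mx$data), nComponents = 3, varThreshold = 0.5,
                   seed = 1)
  act <- backReconstruct(m, mx$data)
  # recovered activations match the generating sources after matching
  rmat <- abs(cor(t(act[1, , ]), t(mx$S)))
  expect_true(all(apply(rmat, 2, max) >= 0.99))
  expect_equal(backReconstruct(m, mx$data * 0),
               array(0, dim(act)), tolerance = 1e-12)
  set.seed(8)
  d2 <- array(rnorm(length(mx$data)), dim(mx$data))
  lhs <- backReconstruct(m, mx$data + d2)
  rhs <- backReconstruct(m, mx$data) + backReconstruct(m, d2)
  expect_equal(lhs, rhs, tolerance = 1e-8)
})

test_that("back-projection is rank one and sums to the subspace
          projection", {
  mx <- mixSources(24, 3, 600, seed = 9)
  m <- fitGroupICA(list(mx$data), nComponents = 3, varThreshold = 0.5,
                   seed = 1)
  bp1 <- backprojectIC(m, mx$data, 1)
  expect_equal(qr(bp1[1, , ])$rank, 1L)
  cv <- cov(t(bp1[1, , ]))
  expect_equal(qr(cv)$rank, 1L)
  tot <- bp1
  for (ic in 2:3) tot <- tot + backprojectIC(m, mx$data, ic)
  X <- matrix(mx$data[1, , ], 24)
  proj <- m@pcaBasis %*% crossprod(m@pcaBasis, X)
  expect_equal(tot[1, , ], proj, tolerance = 1e-8)
  expect_error(backprojectIC(m, mx$data, 9), "index")
})

test_that("single-source data back-project onto themselves", {
  set.seed(10)
  a <- rnorm(18)
  act <- rnorm(400)^3
  X <- outer(a, act)
  d <- aperm(array(X, c(18, 400, 1)), c(3, 1, 2))
  m <- fitGroupICA(list(d), nComponents = 1, varThreshold = 0.5, seed = 1)
  bp <- backprojectIC(m, d, 1)
  expect_lt(max(abs(bp[1, , ] - X)), 1e-5 * max(abs(X)))
})

test_that("the common pair projector confines both classes to one
          subspace", {
  mx <- mixSources(24, 3, 300, seed = 11)
  m1 <- fitGroupICA(list(mx$data), nComponents = 3, varThreshold = 0.5,
                    seed = 1)
  m2 <- fitGroupICA(list(mx$data), nComponents = 3, varThreshold = 0.5,
                    seed = 2)
  pr <- projectPair(m1, 1, m2, 2, mx$data)
  basis <- cbind(mixing(m1)[, 1], mixing(m2)[, 2])
  # residual orthogonal to the basis must vanish
  Q <- qr.Q(qr(basis))
  resid <- pr[1, , ] - Q %*% crossprod(Q, pr[1, , ])
  expect_lt(max(abs(resid)), 1e-8)
})
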