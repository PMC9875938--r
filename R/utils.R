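# Internal helpers.

# A self-contained seeded RNG stream. Each returned closure swaps its own
# RNG state in and out of the session, so package randomness neither
# disturbs nor depends on the caller's global stream.
.makeRng <- function(seed) {
  seed <- as.integer(seed)
  state <- local({
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    s
  })
  draw <- function(f) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", state, envir = globalenv())
    x <- f()
    state <<- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    x
  }
  list(
    unif = function(n, min = 0, max = 1)
      draw(function() stats::runif(n, min, max)),
    norm = function(n, mean = 0, sd = 1)
      draw(function() stats::rnorm(n, mean, sd)),
    lnorm = function(n, meanlog, sdlog)
      draw(function() stats::rlnorm(n, meanlog, sdlog)),
    sampleInt = function(n, size, replace = FALSE)
      draw(function() sample.int(n, size, replace = replace))
  )
}

# AUC by the rank (Mann-Whitney) formula: scores for the positive class
# should be large.
.rankAuc <- function(scoresPos, scoresNeg) {
  nP <- length(scoresPos); nN <- length(scoresNeg)
  r <- rank(c(scoresPos, scoresNeg))
  (sum(r[seq_len(nP)]) - nP * (nP + 1) / 2) / (nP * nN)
}

#' Amari distance between an unmixing matrix and a mixing matrix
#'
#' Permutation- and scale-invariant discrepancy of an estimated unmixing
#' `W` from the truth implied by a mixing matrix `A`: zero iff `W %*% A`
#' is a scaled permutation. Normalised to `[0, 1]`.
#'
#' @param W estimated unmixing (k x channels, possibly via a subspace).
#' @param A true mixing (channels x k).
#' @return scalar in `[0, 1]`.
#' @export
amariDistance <- function(W, A) {
  P <- abs(W %*% A)
  k <- nrow(P)
  rowTerm <- sum(rowSums(P / apply(P, 1, max)) - 1)
  colTerm <- sum(colSums(t(t(P) / apply(P, 2, max))) - 1)
  (rowTerm + colTerm) / (2 * k * (k - 1))
}

# cosine-edged (Tukey) taper restricted to [a, b] on a time axis; `frac`
# of the window length is ramped at each edge, zero outside.
.tukeyWindowOnAxis <- function(timesMs, windowMs, frac = 0.1) {
  a <- windowMs[1]; b <- windowMs[2]
  L <- b - a
  ramp <- frac * L
  w <- numeric(length(timesMs))
  inside <- timesMs >= a & timesMs <= b
  w[inside] <- 1
  lo <- inside & timesMs < a + ramp
  hi <- inside & timesMs > b - ramp
  w[lo] <- 0.5 * (1 - cos(pi * (timesMs[lo] - a) / ramp))
  w[hi] <- 0.5 * (1 - cos(pi * (b - timesMs[hi]) / ramp))
  w
}

# integer-shift a channels x time matrix along time, zero-padding
.shiftMat <- function(m, shift) {
  nT <- ncol(m)
  out <- matrix(0, nrow(m), nT)
  if (shift >= 0) {
    if (shift < nT) out[, (1 + shift):nT] <- m[, 1:(nT - shift)]
  } else {
    s <- -shift
    if (s < nT) out[, 1:(nT - s)] <- m[, (1 + s):nT]
  }
  out
}
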