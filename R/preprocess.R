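# Pre-processing chain for epoched data. The canonical order is fixed:
#   filter -> resample -> reject -> csd -> baseline
# Each step records itself in the Epochs history and refuses to run after a
# later step, so the chain cannot be silently reordered.

.stageOrder <- c("filter", "resample", "reject", "csd", "baseline")

.checkStage <- function(epochs, stage) {
  later <- .stageOrder[seq_along(.stageOrder) > match(stage, .stageOrder)]
  bad <- intersect(later, epochs@history)
  if (length(bad))
    stop(sprintf("cannot apply '%s' after '%s': the chain order is %s",
                 stage, bad[1], paste(.stageOrder, collapse = " -> ")))
}

.withStage <- function(epochs, stage) {
  epochs@history <- c(epochs@history, stage)
  epochs
}

#' Zero-phase band-pass filter
#'
#' Forward-backward (zero-phase) Butterworth IIR filter applied per trial
#' and channel. Defaults to the 0.5-40 Hz band at order 4 (effective order 8
#' after the two passes).
#'
#' @param epochs an [Epochs-class].
#' @param lowHz,highHz band edges in Hz; `0 < lowHz < highHz < srate/2`.
#' @param order Butterworth order of each pass.
#' @return the filtered [Epochs-class].
#' @export
bandpassFilter <- function(epochs, lowHz = 0.5, highHz = 40, order = 4) {
  .checkStage(epochs, "filter")
  fs <- srate(epochs)
  if (!(lowHz > 0 && lowHz < highHz && highHz < fs / 2))
    stop("band edges must satisfy 0 < low < high < srate/2")
  bf <- signal::butter(order, c(lowHz, highHz) / (fs / 2), type = "pass")
  d <- epochs@data
  for (tr in seq_len(dim(d)[1]))
    for (ch in seq_len(dim(d)[2]))
      d[tr, ch, ] <- signal::filtfilt(bf, d[tr, ch, ])
  epochs@data <- d
  .withStage(epochs, "filter")
}

# Fourier-domain resampling of one finite segment: spectrum truncation is
# an ideal anti-aliasing low-pass, exact for band-limited content and for
# constants (DC bin preserved).
.fftResample <- function(x, nNew) {
  nOld <- length(x)
  X <- stats::fft(x)
  Y <- complex(real = numeric(nNew), imaginary = numeric(nNew))
  half <- (min(nOld, nNew) - 1) %/% 2          # positive bins excl. DC
  Y[1] <- X[1]
  if (half >= 1) {
    Y[2:(half + 1)] <- X[2:(half + 1)]
    Y[(nNew - half + 1):nNew] <- X[(nOld - half + 1):nOld]
  }
  Re(stats::fft(Y, inverse = TRUE)) / nOld
}

#' Anti-aliased resampling
#'
#' Fourier-domain resampling of every trial and channel: the spectrum is
#' truncated at the new Nyquist frequency (an ideal anti-aliasing low-pass
#' on the finite segment) and inverted on the new grid. The output length
#' follows the half-open window convention: `round(duration_s * targetHz)`
#' samples, with the time axis rescaled to start at the same first-sample
#' time.
#'
#' @param epochs an [Epochs-class].
#' @param targetHz new sampling rate, below the current one.
#' @return the resampled [Epochs-class].
#' @export
resampleEpochs <- function(epochs, targetHz) {
  .checkStage(epochs, "resample")
  fs <- srate(epochs)
  if (targetHz <= 0) stop("target rate must be positive")
  if (targetHz >= fs) stop("target rate must be below the current rate")
  d <- epochs@data
  nOld <- dim(d)[3]
  nNew <- round(nOld * targetHz / fs)
  out <- array(0, c(dim(d)[1], dim(d)[2], nNew))
  for (tr in seq_len(dim(d)[1]))
    for (ch in seq_len(dim(d)[2]))
      out[tr, ch, ] <- .fftResample(d[tr, ch, ], nNew)
  e <- newEpochs(out, targetHz, epochs@times[1], epochs@montage,
                 epochs@trials, epochs@unitLabel)
  e@history <- epochs@history
  .withStage(e, "resample")
}

#' Automated artifact rejection
#'
#' Drops trials on two criteria: any sample on any channel beyond
#' `+/- ampLimit`, or peak-to-peak activity below `flatLimit` on any channel
#' within any sliding window of `flatWindowMs` (a flatline / disconnected
#' electrode detector). Deterministic given the thresholds.
#'
#' @param epochs an [Epochs-class].
#' @param ampLimit absolute amplitude limit (default 100 uV).
#' @param flatLimit minimum peak-to-peak activity (default 0.5 uV).
#' @param flatWindowMs sliding window length for the flatline check.
#' @return list with `epochs` (kept trials) and `log`, a data.frame with one
#'   row per input trial: trial, kept, reason
#'   (`amplitude_exceeds`/`flatline`/`none`), offending_channel.
#' @export
rejectArtifacts <- function(epochs, ampLimit = 100, flatLimit = 0.5,
                            flatWindowMs = 100) {
  .checkStage(epochs, "reject")
  if (ampLimit <= 0 || flatLimit <= 0) stop("limits must be positive")
  d <- epochs@data
  nT <- dim(d)[3]
  w <- round(flatWindowMs * srate(epochs) / 1000)
  if (w > nT) stop("flatline window longer than the epoch")
  w <- max(w, 2L)
  labs <- channelLabels(epochs)
  n <- dim(d)[1]
  reason <- rep("none", n)
  offending <- rep(NA_character_, n)
  for (tr in seq_len(n)) {
    m <- d[tr, , ]                       # channels x time
    over <- which(abs(m) > ampLimit, arr.ind = TRUE)
    if (nrow(over)) {
      reason[tr] <- "amplitude_exceeds"
      offending[tr] <- labs[over[1, 1]]
      next
    }
    # rolling peak-to-peak per channel via shifted pmax/pmin
    nW <- nT - w + 1L
    rmax <- m[, seq_len(nW)]
    rmin <- rmax
    for (k in seq_len(w - 1L)) {
      sl <- m[, (1L + k):(nW + k), drop = FALSE]
      rmax <- pmax(rmax, sl)
      rmin <- pmin(rmin, sl)
    }
    flat <- which(rmax - rmin < flatLimit, arr.ind = TRUE)
    if (nrow(flat)) {
      reason[tr] <- "flatline"
      offending[tr] <- labs[flat[1, 1]]
    }
  }
  kept <- reason == "none"
  log <- data.frame(trial = seq_len(n), kept = kept, reason = reason,
                    offending_channel = offending,
                    stringsAsFactors = FALSE)
  e <- subsetTrials(epochs, kept)
  e <- .withStage(e, "reject")
  list(epochs = e, log = log)
}

#' Write a rejection log as TSV
#' @param log the log data.frame from [rejectArtifacts()].
#' @param path file path.
#' @export
writeRejectionLog <- function(log, path) {
  utils::write.table(log, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Legendre polynomial series sums for the spherical-spline Laplacian:
# g(x) = sum (2n+1) P_n(x) / (n(n+1))^m / 4pi        (potential spline)
# h(x) = sum (2n+1) P_n(x) / (n(n+1))^(m-1) / 4pi    (its surface Laplacian)
.legendreSums <- function(x, m, nTerms) {
  pPrev <- rep(1, length(x))      # P_0
  pCur <- x                       # P_1
  gs <- numeric(length(x))
  hs <- numeric(length(x))
  for (n in seq_len(nTerms)) {
    if (n > 1) {
      pNew <- ((2 * n - 1) * x * pCur - (n - 1) * pPrev) / n
      pPrev <- pCur
      pCur <- pNew
    }
    gs <- gs + (2 * n + 1) * pCur / (n * (n + 1))^m
    hs <- hs + (2 * n + 1) * pCur / (n * (n + 1))^(m - 1)
  }
  list(g = gs / (4 * pi), h = hs / (4 * pi))
}

# linear operator of the spherical-spline surface Laplacian (CSD) for a
# montage; applied per time sample as a channels x channels matrix
.csdOperator <- function(positions, m = 4, lambda = 1e-5, nLegendre = 50) {
  n <- nrow(positions)
  cosang <- tcrossprod(positions)
  cosang[cosang > 1] <- 1
  cosang[cosang < -1] <- -1
  if (any(cosang[upper.tri(cosang)] > 1 - 1e-10))
    stop("duplicate electrode positions make the spline system singular")
  sums <- .legendreSums(cosang, m, nLegendre)
  G <- matrix(sums$g, n, n)
  H <- matrix(sums$h, n, n)
  A <- rbind(cbind(G + lambda * diag(n), rep(1, n)), c(rep(1, n), 0))
  Ainv <- solve(A)
  H %*% Ainv[seq_len(n), seq_len(n)]
}

#' Current source density (surface Laplacian) transform
#'
#' Spherical-spline surface Laplacian per time sample. The result is
#' reference-free: adding any constant to all channels leaves the output
#' unchanged, and a spatially constant map transforms to zero.
#'
#' @param epochs an [Epochs-class] with unit-sphere electrode positions.
#' @param m spline stiffness order (default 4).
#' @param lambda smoothing regularisation (default 1e-5).
#' @param nLegendre number of Legendre series terms (default 50).
#' @return the transformed [Epochs-class], unit label updated.
#' @export
csdTransform <- function(epochs, m = 4, lambda = 1e-5, nLegendre = 50) {
  .checkStage(epochs, "csd")
  L <- .csdOperator(channelPositions(epochs), m, lambda, nLegendre)
  d <- epochs@data
  for (tr in seq_len(dim(d)[1]))
    d[tr, , ] <- L %*% d[tr, , ]
  epochs@data <- d
  epochs@unitLabel <- "CSD (uV/m^2)"
  .withStage(epochs, "csd")
}

#' Baseline correction
#'
#' Subtracts, per trial and channel, the mean amplitude over the baseline
#' window (default -300 to 0 ms).
#'
#' @param epochs an [Epochs-class].
#' @param windowMs length-2 baseline window in ms, inside the epoch.
#' @return the corrected [Epochs-class].
#' @export
baselineCorrect <- function(epochs, windowMs = c(-300, 0)) {
  .checkStage(epochs, "baseline")
  tms <- times(epochs)
  sel <- tms >= windowMs[1] & tms < windowMs[2]
  if (!any(sel)) stop("baseline window contains no samples")
  d <- epochs@data
  bl <- apply(d[, , sel, drop = FALSE], c(1, 2), mean)
  epochs@data <- d - array(bl, dim(d))   # recycles over time (3rd dim last)
  .withStage(epochs, "baseline")
}

#' Run the full pre-processing chain in canonical order
#'
#' filter -> resample -> reject -> CSD -> baseline. Stages can be switched
#' off individually; the order itself is fixed.
#'
#' @param epochs raw [Epochs-class].
#' @param band band-pass edges in Hz, or NULL to skip.
#' @param filterOrder Butterworth order.
#' @param targetHz resampling target, or NULL to skip.
#' @param ampLimit,flatLimit,flatWindowMs rejection thresholds
#'   (see [rejectArtifacts()]); `ampLimit = NULL` skips rejection.
#' @param csd logical, apply the CSD transform.
#' @param baselineMs baseline window, or NULL to skip.
#' @return list with `epochs` and `log` (NULL when rejection skipped).
#' @export
preprocessChain <- function(epochs, band = c(0.5, 40), filterOrder = 4,
                            targetHz = NULL, ampLimit = 100, flatLimit = 0.5,
                            flatWindowMs = 100, csd = TRUE,
                            baselineMs = c(-300, 0)) {
  log <- NULL
  if (!is.null(band))
    epochs <- bandpassFilter(epochs, band[1], band[2], filterOrder)
  if (!is.null(targetHz))
    epochs <- resampleEpochs(epochs, targetHz)
  if (!is.null(ampLimit)) {
    r <- rejectArtifacts(epochs, ampLimit, flatLimit, flatWindowMs)
    epochs <- r$epochs
    log <- r$log
  }
  if (isTRUE(csd))
    epochs <- csdTransform(epochs)
  if (!is.null(baselineMs))
    epochs <- baselineCorrect(epochs, baselineMs)
  list(epochs = epochs, log = log)
}
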