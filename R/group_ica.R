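# Group spatial ICA. Subjects share a montage, so their samples (all trials
# and time points) are concatenated in channel space, reduced by one group
# PCA, and unmixed with FastICA. Back-reconstruction applies the group
# spatial filters to a subject's own data; back-projection returns the
# rank-1 channel-space data of a single component.

# FastICA on whitened data Z (k x N): tanh contrast, deflation first,
# symmetric decorrelation fallback. Returns the k x k rotation W with
# orthonormal rows such that W %*% Z are the independent sources.
.fastICACore <- function(Z, rng, maxIter = 200, tol = 1e-4, restarts = 5) {
  k <- nrow(Z)
  N <- ncol(Z)
  deflate <- function(Winit) {
    W <- matrix(0, k, k)
    for (i in seq_len(k)) {
      w <- Winit[i, ]
      w <- w / sqrt(sum(w^2))
      for (it in seq_len(maxIter)) {
        wx <- drop(w %*% Z)
        g <- tanh(wx)
        gp <- 1 - g^2
        wNew <- Z %*% g / N - mean(gp) * w
        if (i > 1) {
          proj <- W[seq_len(i - 1), , drop = FALSE]
          wNew <- wNew - t(proj) %*% (proj %*% wNew)
        }
        nrm <- sqrt(sum(wNew^2))
        if (nrm < 1e-12) return(NULL)
        wNew <- wNew / nrm
        conv <- abs(abs(sum(wNew * w)) - 1) < tol
        w <- drop(wNew)
        if (conv) break
        if (it == maxIter) return(NULL)
      }
      W[i, ] <- w
    }
    W
  }
  # symmetric decorrelation update; near-Gaussian dimensions may never meet
  # the tolerance, in which case the final (orthonormal, deterministic)
  # estimate is returned with converged = FALSE
  symmetric <- function(Winit) {
    sym <- function(M) {
      s <- svd(M)
      s$u %*% t(s$v)
    }
    W <- sym(Winit)
    for (it in seq_len(maxIter)) {
      WX <- W %*% Z
      G <- tanh(WX)
      GP <- 1 - G^2
      WNew <- G %*% t(Z) / N - diag(rowMeans(GP)) %*% W
      if (!all(is.finite(WNew))) return(NULL)
      WNew <- sym(WNew)
      d <- max(abs(abs(diag(WNew %*% t(W))) - 1))
      W <- WNew
      if (d < tol) return(structure(W, converged = TRUE))
    }
    structure(W, converged = FALSE)
  }
  seeds <- integer(0)
  firstInit <- NULL
  for (r in seq_len(restarts)) {
    Winit <- matrix(rng$norm(k * k), k, k)
    if (is.null(firstInit)) firstInit <- Winit
    seeds <- c(seeds, r)
    W <- deflate(Winit)
    if (!is.null(W)) return(structure(W, converged = TRUE))
    W <- symmetric(Winit)
    if (!is.null(W) && isTRUE(attr(W, "converged"))) return(W)
  }
  # accept the symmetric estimate from the first initialisation even when
  # the tolerance was not met (arbitrary but deterministic rotation of the
  # near-Gaussian subspace)
  W <- symmetric(firstInit)
  if (is.null(W))
    stop("FastICA failed (non-finite update) after ", restarts,
         " restarts; restart trail: ", paste(seeds, collapse = ", "))
  W
}

# stack a list of trials x channels x time arrays into channels x samples
.stackChannels <- function(subjectData) {
  mats <- lapply(subjectData, function(d) {
    if (length(dim(d)) != 3) stop("each subject must be a 3-D array")
    m <- aperm(d, c(2, 1, 3))
    dim(m) <- c(dim(d)[2], dim(d)[1] * dim(d)[3])
    m
  })
  do.call(cbind, mats)
}

#' Fit a group spatial ICA model
#'
#' Concatenates all subjects' samples in channel space, whitens with a
#' single group PCA to `nComponents` dimensions, and unmixes with FastICA
#' (tanh contrast; deflation with a symmetric-decorrelation fallback; up to
#' 5 restarts). Each subject's data must individually be well represented
#' in the retained subspace: if the retained variance fraction of any
#' subject falls below `varThreshold`, fitting stops with an error.
#'
#' Component topographies (columns of `mixing`) are stored unit-norm with
#' the maximal-|loading| channel positive; `unmixing` rows carry the
#' compensating scale and sign.
#'
#' @param subjectData list of trials x channels x time arrays (shared montage).
#' @param nComponents retained dimensionality (default 20).
#' @param varThreshold minimum per-subject retained variance fraction
#'   (default 0.98).
#' @param seed integer seed for the FastICA initialisation.
#' @param clusterTag,conditionTag optional bookkeeping tags.
#' @return a [GroupICAModel-class].
#' @export
fitGroupICA <- function(subjectData, nComponents = 20, varThreshold = 0.98,
                        seed = 1L, clusterTag = NA_character_,
                        conditionTag = NA_character_) {
  if (!length(subjectData)) stop("no subjects")
  X <- .stackChannels(subjectData)
  nCh <- nrow(X)
  if (nComponents > nCh) stop("more components than channels")
  mu <- rowMeans(X)
  X <- X - mu
  eg <- eigen(tcrossprod(X) / ncol(X), symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  if (ev[nComponents] <= 1e-12 * ev[1])
    stop("data rank below the requested number of components")
  keep <- seq_len(nComponents)
  E <- eg$vectors[, keep, drop = FALSE]
  evf <- sum(ev[keep]) / sum(ev)

  # every subject must be individually representable in the group subspace
  for (i in seq_along(subjectData)) {
    Xi <- .stackChannels(subjectData[i]) - mu
    tot <- sum(Xi^2)
    ret <- sum((crossprod(E, Xi))^2)
    if (tot > 0 && ret / tot < varThreshold)
      stop(sprintf(paste0("subject %d retains only %.1f%% of its variance ",
                          "in the %d-dimensional group subspace ",
                          "(threshold %.1f%%)"),
                   i, 100 * ret / tot, nComponents, 100 * varThreshold))
  }

  D <- sqrt(ev[keep])
  K <- diag(1 / D, nComponents) %*% t(E)      # whitening, comps x channels
  Z <- K %*% X
  rng <- .makeRng(seed)
  W0 <- .fastICACore(Z, rng)

  unmix <- W0 %*% K                            # comps x channels
  mix <- E %*% diag(D, nComponents) %*% t(W0)  # channels x comps

  # fix scale and sign: unit-norm topography, dominant channel positive
  for (j in seq_len(nComponents)) {
    s <- sqrt(sum(mix[, j]^2))
    sgn <- sign(mix[which.max(abs(mix[, j])), j])
    if (sgn == 0) sgn <- 1
    mix[, j] <- mix[, j] / (s * sgn)
    unmix[j, ] <- unmix[j, ] * s * sgn
  }

  new("GroupICAModel", mixing = mix, unmixing = unmix, pcaBasis = E,
      channelMeans = mu, nComponents = as.integer(nComponents),
      explainedVarianceFraction = evf, seed = as.integer(seed),
      clusterTag = clusterTag, conditionTag = conditionTag)
}

#' Back-reconstruct subject component activations
#'
#' Applies the group spatial filters to one subject's channel data,
#' yielding per-trial component activation time courses. The map is
#' purely linear (no re-centering), so zero data give zero activations
#' and activations of summed inputs add.
#'
#' @param model a [GroupICAModel-class].
#' @param subjectData trials x channels x time array on the same montage.
#' @return trials x components x time array.
#' @export
backReconstruct <- function(model, subjectData) {
  d <- subjectData
  if (dim(d)[2] != ncol(model@unmixing))
    stop("channel count does not match the model montage")
  n <- dim(d)[1]; nT <- dim(d)[3]
  out <- array(0, c(n, model@nComponents, nT))
  for (tr in seq_len(n))
    out[tr, , ] <- model@unmixing %*% d[tr, , ]
  out
}

#' Joint channel-space projection onto a matched component pair
#'
#' Projects trials onto the 2-D channel subspace spanned by the two
#' topographies of a matched component pair (one per condition model).
#' Using one common projector for both trial classes keeps a downstream
#' classifier honest: with per-condition rank-1 back-projections the two
#' classes lie on two different lines in channel space and are linearly
#' separable by construction, independent of any condition effect.
#'
#' @param modelA,modelB [GroupICAModel-class] objects on the same montage.
#' @param icA,icB the matched component index in each model.
#' @param subjectData trials x channels x time array.
#' @return trials x channels x time array confined to the pair subspace.
#' @export
projectPair <- function(modelA, icA, modelB, icB, subjectData) {
  basis <- cbind(modelA@mixing[, icA], modelB@mixing[, icB])
  Q <- qr.Q(qr(basis))
  if (qr(basis)$rank < 2) Q <- Q[, 1, drop = FALSE]
  P <- tcrossprod(Q)
  out <- subjectData
  for (tr in seq_len(dim(subjectData)[1]))
    out[tr, , ] <- P %*% subjectData[tr, , ]
  out
}

#' Rank-1 back-projection of a single component
#'
#' Returns the channel-space data carried by one component: topography
#' times activation, per trial. Summed over all components this equals the
#' projection of the (centred) input onto the retained PCA subspace.
#'
#' @param model a [GroupICAModel-class].
#' @param subjectData trials x channels x time array.
#' @param ic component index.
#' @return trials x channels x time array of rank-1 channel data.
#' @export
backprojectIC <- function(model, subjectData, ic) {
  if (ic < 1 || ic > model@nComponents) stop("invalid component index")
  act <- backReconstruct(model, subjectData)
  d <- subjectData
  out <- array(0, dim(d))
  topo <- model@mixing[, ic]
  for (tr in seq_len(dim(d)[1]))
    out[tr, , ] <- outer(topo, act[tr, ic, ])
  out
}
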