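# Time-resolved MVPA on back-projected component data: binary
# congruent-vs-incongruent classification per time point (linear SVM on the
# channel amplitudes, 60 features on the standard montage), optional
# temporal generalization (train at t, test at all t'), AUC scoring from
# decision values, and group-level Wilcoxon-vs-chance statistics with
# cluster-based sign-flip permutation correction.

#' Cross-validation configuration for decoding
#'
#' @param nFolds number of folds (default 5).
#' @param nRepeats number of repeated CV partitions (default 2).
#' @param classifier only `"linear-svm"` (cost 1, features z-scored per
#'   fold with training statistics).
#' @param decodeWindowMs time window submitted to the classifier
#'   (default 0-1000 ms post-stimulus).
#' @param seed integer seed for fold assignment and undersampling.
#' @return list of class `CVConfig`.
#' @export
cvConfig <- function(nFolds = 5, nRepeats = 2, classifier = "linear-svm",
                     decodeWindowMs = c(0, 1000), seed = 1L) {
  stopifnot(nFolds >= 2, nRepeats >= 1)
  classifier <- match.arg(classifier, "linear-svm")
  structure(list(nFolds = as.integer(nFolds), nRepeats = as.integer(nRepeats),
                 classifier = classifier, decodeWindowMs = decodeWindowMs,
                 seed = as.integer(seed)),
            class = "CVConfig")
}

#' Undersample the majority class
#'
#' Randomly subsamples the majority class down to the minority count so
#' both classes are balanced; deterministic under the seed.
#'
#' @param labels vector with exactly two distinct values.
#' @param seed integer seed.
#' @return sorted integer indices of the kept observations.
#' @export
undersample <- function(labels, seed = 1L) {
  lv <- unique(labels)
  if (length(lv) != 2) stop("undersampling needs exactly two classes")
  rng <- .makeRng(seed)
  n1 <- sum(labels == lv[1])
  n2 <- sum(labels == lv[2])
  nKeep <- min(n1, n2)
  keep <- c()
  for (v in lv) {
    idx <- which(labels == v)
    if (length(idx) > nKeep)
      idx <- idx[rng$sampleInt(length(idx), nKeep)]
    keep <- c(keep, idx)
  }
  sort(keep)
}

# linear-SVM decision values, orientation fixed so that larger values mean
# class `posLevel`
.svmDecision <- function(xTrain, yTrain, posLevel) {
  fit <- e1071::svm(xTrain, yTrain, kernel = "linear", cost = 1,
                    scale = FALSE)
  w <- crossprod(fit$coefs, fit$SV)          # 1 x features
  dv <- function(x) drop(x %*% t(w)) - fit$rho
  dvTrain <- dv(xTrain)
  flip <- mean(dvTrain[yTrain == posLevel]) <
          mean(dvTrain[yTrain != posLevel])
  list(score = function(x) if (flip) -dv(x) else dv(x))
}

#' Single-subject time-resolved decoding of two trial classes
#'
#' Balances the classes by undersampling, then runs repeated stratified
#' k-fold cross-validation: at each training time point a linear SVM is fit
#' on the channel amplitudes (z-scored with training-fold statistics) and
#' scored by AUC from its decision values on the held-out trials, at the
#' same time point and, if `generalize`, at every other one.
#'
#' @param dataA,dataB trials x channels x time arrays for the two classes.
#' @param timesMs the shared time axis in ms.
#' @param cv a [cvConfig()].
#' @param generalize compute the full temporal-generalization matrix.
#' @param stepMs optional decoding grid step; time points are subsampled to
#'   this resolution to bound the number of classifier fits.
#' @return a [DecodingResult-class].
#' @export
decodePair <- function(dataA, dataB, timesMs, cv = cvConfig(),
                       generalize = TRUE, stepMs = NULL) {
  stopifnot(inherits(cv, "CVConfig"))
  sel <- which(timesMs >= cv$decodeWindowMs[1] &
               timesMs <= cv$decodeWindowMs[2])
  if (!is.null(stepMs)) {
    keepEvery <- max(1L, round(stepMs / diff(timesMs[1:2])))
    sel <- sel[seq(1, length(sel), by = keepEvery)]
  }
  if (!length(sel)) stop("decoding window contains no samples")
  tms <- timesMs[sel]

  labels <- c(rep("A", dim(dataA)[1]), rep("B", dim(dataB)[1]))
  X <- array(0, c(length(labels), dim(dataA)[2], length(sel)))
  X[labels == "A", , ] <- dataA[, , sel, drop = FALSE]
  X[labels == "B", , ] <- dataB[, , sel, drop = FALSE]
  keep <- undersample(labels, seed = cv$seed)
  X <- X[keep, , , drop = FALSE]
  y <- factor(labels[keep])
  n <- length(y)
  nPerClass <- n / 2L
  if (nPerClass < cv$nFolds) stop("fewer trials per class than folds")

  rng <- .makeRng(cv$seed + 1L)
  T <- length(sel)
  aucSum <- if (generalize) matrix(0, T, T) else numeric(T)
  nCv <- 0L

  for (rep in seq_len(cv$nRepeats)) {
    # stratified fold assignment
    fold <- integer(n)
    for (lv in levels(y)) {
      idx <- which(y == lv)
      fold[idx] <- rep_len(seq_len(cv$nFolds),
                           length(idx))[rng$sampleInt(length(idx),
                                                      length(idx))]
    }
    for (f in seq_len(cv$nFolds)) {
      isTest <- fold == f
      if (length(unique(y[!isTest])) < 2 || !any(isTest)) next
      yTr <- y[!isTest]; yTe <- y[isTest]
      # per-time z-scoring with training statistics
      Xs <- X
      for (t in seq_len(T)) {
        mu <- colMeans(X[!isTest, , t, drop = FALSE][, , 1])
        sg <- apply(X[!isTest, , t, drop = FALSE][, , 1], 2, sd)
        sg[sg == 0] <- 1
        Xs[, , t] <- sweep(sweep(X[, , t], 2, mu), 2, sg, "/")
      }
      for (t in seq_len(T)) {
        clf <- .svmDecision(Xs[!isTest, , t], yTr, posLevel = "A")
        if (generalize) {
          for (t2 in seq_len(T)) {
            s <- clf$score(Xs[isTest, , t2, drop = FALSE][, , 1, drop = TRUE])
            aucSum[t, t2] <- aucSum[t, t2] +
              .rankAuc(s[yTe == "A"], s[yTe == "B"])
          }
        } else {
          s <- clf$score(Xs[isTest, , t, drop = FALSE][, , 1, drop = TRUE])
          aucSum[t] <- aucSum[t] + .rankAuc(s[yTe == "A"], s[yTe == "B"])
        }
      }
      nCv <- nCv + 1L
    }
  }
  if (generalize) {
    tg <- aucSum / nCv
    new("DecodingResult", subjectAuc = diag(tg), subjectTg = tg,
        times = tms, nTrialsPerClass = as.integer(nPerClass))
  } else {
    new("DecodingResult", subjectAuc = aucSum / nCv, subjectTg = NULL,
        times = tms, nTrialsPerClass = as.integer(nPerClass))
  }
}

# ---- Wilcoxon signed-rank machinery (shared with the behaviour module) ----

# tie-corrected signed-rank moments for |d| ranks of the nonzero entries
.signedRankMoments <- function(absd) {
  m <- length(absd)
  r <- rank(absd)
  mu <- m * (m + 1) / 4
  ties <- table(r)
  tieTerm <- sum(ties^3 - ties)
  s2 <- m * (m + 1) * (2 * m + 1) / 24 - tieTerm / 48
  list(ranks = r, mu = mu, sigma = sqrt(max(s2, 0)))
}

# exact upper tail P(W >= w) for signed ranks `r` under random signs
.signedRankExactTail <- function(r, w) {
  r2 <- round(2 * r)                # half-ranks from ties become integers
  maxW <- sum(r2)
  dist <- numeric(maxW + 1)         # index = W2 + 1
  dist[1] <- 1
  for (x in r2) {
    shifted <- c(numeric(x), dist[seq_len(maxW + 1 - x)])
    dist <- (dist + shifted) / 2
  }
  sum(dist[seq(floor(2 * w) + 1, maxW + 1)])
}

# per-point critical W for one-sided (greater) forming threshold
.signedRankCritical <- function(absd, alpha, exactMax = 11) {
  mom <- .signedRankMoments(absd)
  m <- length(absd)
  if (m == 0) return(list(crit = Inf, mom = mom))
  if (m <= exactMax) {
    ws <- seq(0, sum(mom$ranks), by = 0.5)
    tails <- vapply(ws, function(w) .signedRankExactTail(mom$ranks, w),
                    numeric(1))
    ok <- ws[tails < alpha]
    crit <- if (length(ok)) min(ok) else Inf
  } else {
    crit <- mom$mu + qnorm(1 - alpha) * mom$sigma
    if (mom$sigma == 0) crit <- Inf
  }
  list(crit = crit, mom = mom)
}

# 4-connected labelling of a logical matrix; returns integer labels
.label4 <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (lab[start] > 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    nr <- nrow(mask)
    while (length(queue)) {
      p <- queue[[1]]
      queue <- queue[-1]
      i <- (p - 1L) %% nr + 1L
      j <- (p - 1L) %/% nr + 1L
      for (q in c(if (i > 1) p - 1L, if (i < nr) p + 1L,
                  if (j > 1) p - nr, if (j < ncol(mask)) p + nr)) {
        if (mask[q] && lab[q] == 0L) {
          lab[q] <- cur
          queue <- c(queue, q)
        }
      }
    }
  }
  lab
}

# cluster masses (sum of z) for a supra-threshold mask; dims NULL -> 1-D
.clusterMasses <- function(supra, z, dims2 = NULL) {
  if (is.null(dims2)) {
    r <- rle(supra)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    if (!length(keep)) return(list(masses = numeric(0), members = list()))
    members <- lapply(keep, function(k) starts[k]:ends[k])
  } else {
    lab <- .label4(matrix(supra, dims2[1], dims2[2]))
    ks <- seq_len(max(lab))
    if (!length(ks) || max(lab) == 0)
      return(list(masses = numeric(0), members = list()))
    members <- lapply(ks, function(k) which(lab == k))
  }
  list(masses = vapply(members, function(mm) sum(z[mm]), numeric(1)),
       members = members)
}

#' Group-level cluster-based permutation test against chance
#'
#' Point-wise Wilcoxon signed-rank tests of subject scores against the
#' chance level (one-sided, above chance), cluster formation at point-wise
#' p < `clusterAlpha` (contiguity in 1-D, 4-connectivity in 2-D), cluster
#' mass = sum of signed-rank z within the cluster, and a max-cluster-mass
#' null from random per-subject sign flips of (score - chance).
#'
#' @param subjectScores subjects x time matrix, or subjects x time x time
#'   array for temporal-generalization input.
#' @param chance chance level (default 0.5 for AUC).
#' @param nPerm number of sign-flip permutations (default 1000; below 100 a
#'   warning is attached and the test proceeds).
#' @param alpha significance level for corrected cluster p-values.
#' @param clusterAlpha point-wise cluster-forming threshold.
#' @param seed integer seed.
#' @return list of class `ClusterStatsResult`: `clusters` (data.frame with
#'   cluster_id, mass, p_value, n_points), `members` (list of point index
#'   vectors), `significantMask` (logical, over time or time x time),
#'   `pointZ`, `nPermutations`, `lowPermWarning`.
#' @export
groupClusterTest <- function(subjectScores, chance = 0.5, nPerm = 1000,
                             alpha = 0.05, clusterAlpha = 0.05, seed = 1L) {
  dims <- dim(subjectScores)
  is2d <- length(dims) == 3
  nSub <- dims[1]
  if (nSub < 5) stop("cluster test needs at least 5 subjects")
  lowPerm <- nPerm < 100
  if (lowPerm)
    warning("fewer than 100 permutations; p-values will be coarse")
  D <- matrix(subjectScores - chance, nSub)
  P <- ncol(D)
  dims2 <- if (is2d) dims[2:3] else NULL

  ranks <- matrix(0, nSub, P)
  crit <- numeric(P)
  mu <- numeric(P)
  sigma <- numeric(P)
  for (p in seq_len(P)) {
    nz <- D[, p] != 0
    if (!any(nz)) { crit[p] <- Inf; sigma[p] <- 1; next }
    cw <- .signedRankCritical(abs(D[nz, p]), clusterAlpha)
    ranks[nz, p] <- cw$mom$ranks
    crit[p] <- cw$crit
    mu[p] <- cw$mom$mu
    sigma[p] <- if (cw$mom$sigma > 0) cw$mom$sigma else 1
  }
  A <- ranks * (D > 0)
  B <- ranks * (D < 0)
  wObs <- colSums(A)
  zObs <- (wObs - mu) / sigma
  supraObs <- wObs >= crit
  obs <- .clusterMasses(supraObs, zObs, dims2)

  rng <- .makeRng(seed)
  signs <- matrix(rng$unif(nPerm * nSub) < 0.5, nPerm, nSub)
  Sp <- signs * 1          # keep original sign
  Sm <- (!signs) * 1       # flipped
  Wp <- Sp %*% A + Sm %*% B
  nullMax <- numeric(nPerm)
  for (b in seq_len(nPerm)) {
    zb <- (Wp[b, ] - mu) / sigma
    sb <- Wp[b, ] >= crit
    cm <- .clusterMasses(sb, zb, dims2)
    nullMax[b] <- if (length(cm$masses)) max(cm$masses) else 0
  }

  pvals <- vapply(obs$masses, function(m0) (1 + sum(nullMax >= m0)) /
                    (1 + nPerm), numeric(1))
  sig <- logical(P)
  for (k in seq_along(obs$masses))
    if (pvals[k] < alpha) sig[obs$members[[k]]] <- TRUE
  clusters <- data.frame(cluster_id = seq_along(obs$masses),
                         mass = obs$masses, p_value = pvals,
                         n_points = lengths(obs$members))
  structure(list(clusters = clusters, members = obs$members,
                 significantMask = if (is2d) matrix(sig, dims2[1], dims2[2])
                                   else sig,
                 pointZ = if (is2d) matrix(zObs, dims2[1], dims2[2]) else zObs,
                 nPermutations = nPerm, lowPermWarning = lowPerm),
            class = "ClusterStatsResult")
}
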