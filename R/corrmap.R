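# Matching of independent components across two decompositions (e.g., the
# congruent and incongruent condition models) by correlating their channel
# topographies, in the style of template-based topography clustering.
# ICA polarity is arbitrary, so |Pearson r| across channels is the
# similarity; every component of either model serves once as a template
# seed, clusters above the threshold are capped per condition, and the
# reported pairs are deduplicated reciprocal best matches.

#' Match components of two ICA models by topography correlation
#'
#' For each component of each model used as a template seed, components of
#' the other model whose topographies correlate above `threshold` (in
#' absolute Pearson r across channels) form a cluster, keeping at most
#' `maxPerGroup` members per condition. Reported pairs are reciprocal best
#' matches; a component appears in at most one pair (largest |r| wins, then
#' the lowest index).
#'
#' @param modelA,modelB [GroupICAModel-class] objects on the same montage.
#' @param threshold absolute-correlation threshold in (0, 1] (default 0.85).
#' @param maxPerGroup cluster cap per condition (default 3).
#' @return data.frame with columns pair_id, ic_a, ic_b,
#'   topography_correlation (signed), abs_correlation, template_seed_ic,
#'   cluster_id; zero rows when nothing matches.
#' @export
matchComponents <- function(modelA, modelB, threshold = 0.85,
                            maxPerGroup = 3) {
  if (!modelA@nComponents || !modelB@nComponents) stop("empty model")
  if (nrow(modelA@mixing) != nrow(modelB@mixing))
    stop("models must share a montage")
  stopifnot(threshold > 0, threshold <= 1)
  A <- modelA@mixing
  B <- modelB@mixing
  R <- stats::cor(A, B)             # nA x nB, channels are observations
  aR <- abs(R)
  nA <- ncol(A); nB <- ncol(B)

  # template-seeded clusters: seed k from either model collects the top
  # maxPerGroup components of each model above threshold
  candidates <- NULL
  seedId <- 0L
  for (side in c("A", "B")) {
    n <- if (side == "A") nA else nB
    for (k in seq_len(n)) {
      seedId <- seedId + 1L
      simA <- if (side == "A") {
        v <- abs(stats::cor(A, A[, k])); v
      } else abs(stats::cor(A, B[, k]))
      simB <- if (side == "A") abs(stats::cor(B, A[, k]))
              else { v <- abs(stats::cor(B, B[, k])); v }
      memA <- which(simA >= threshold - 1e-12)
      memB <- which(simB >= threshold - 1e-12)
      memA <- memA[order(-simA[memA])][seq_len(min(maxPerGroup, length(memA)))]
      memB <- memB[order(-simB[memB])][seq_len(min(maxPerGroup, length(memB)))]
      if (!length(memA) || !length(memB)) next
      # reciprocal best pairs within the cluster
      for (i in memA) {
        j <- memB[which.max(aR[i, memB])]
        if (aR[i, j] < threshold) next
        iBack <- memA[which.max(aR[memA, j])]
        if (iBack == i)
          candidates <- rbind(candidates,
                             data.frame(ic_a = i, ic_b = j,
                                        topography_correlation = R[i, j],
                                        abs_correlation = aR[i, j],
                                        template_seed_ic = seedId,
                                        cluster_id = seedId))
      }
    }
  }
  empty <- data.frame(pair_id = integer(0), ic_a = integer(0),
                      ic_b = integer(0),
                      topography_correlation = numeric(0),
                      abs_correlation = numeric(0),
                      template_seed_ic = integer(0),
                      cluster_id = integer(0))
  if (is.null(candidates)) return(empty)

  # global reciprocal-best requirement across the full models
  keepGlobal <- with(candidates, vapply(seq_len(nrow(candidates)), function(r) {
    i <- ic_a[r]; j <- ic_b[r]
    which.max(aR[i, ]) == j && which.max(aR[, j]) == i
  }, logical(1)))
  candidates <- candidates[keepGlobal, , drop = FALSE]
  if (!nrow(candidates)) return(empty)

  # deduplicate: best |r| first, then lowest indices; each IC used once
  ord <- order(-candidates$abs_correlation, candidates$ic_a, candidates$ic_b)
  candidates <- candidates[ord, , drop = FALSE]
  usedA <- logical(nA); usedB <- logical(nB)
  keep <- logical(nrow(candidates))
  for (r in seq_len(nrow(candidates))) {
    i <- candidates$ic_a[r]; j <- candidates$ic_b[r]
    if (!usedA[i] && !usedB[j]) {
      keep[r] <- TRUE
      usedA[i] <- TRUE
      usedB[j] <- TRUE
    }
  }
  out <- candidates[keep, , drop = FALSE]
  out <- out[order(-out$abs_correlation, out$ic_a), , drop = FALSE]
  out <- cbind(pair_id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Write component matches as TSV
#' @param matches data.frame from [matchComponents()].
#' @param path file path.
#' @export
writeMatches <- function(matches, path) {
  utils::write.table(matches, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
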