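# Behavioural aggregation and inference: per-condition RT and accuracy
# summaries, paired t with the dz effect size (mean difference over SD of
# differences, so dz = t / sqrt(n)), and a Wilcoxon signed-rank fallback
# for non-normal accuracy variables.

#' Per-condition behavioural summary
#'
#' Mean correct-Go RT with its standard error, Go accuracy (correct
#' responses among responded-or-erred trials, misses excluded from the
#' denominator's correct count but reported separately), and Nogo accuracy
#' (correct omissions) with the false-alarm percentage, split by congruency.
#'
#' @param trials trial table with outcomes (see [simulateBehaviour()]).
#' @return data.frame with one row per congruency: n_go, mean_rt_ms,
#'   se_rt_ms, go_accuracy_pct, miss_pct, n_nogo, nogo_accuracy_pct,
#'   false_alarm_pct. Empty cells yield NA, not an error.
#' @export
summarizeBehaviour <- function(trials) {
  if (!nrow(trials) || all(is.na(trials$outcome)))
    stop("trial outcomes are not populated")
  rows <- lapply(c("congruent", "incongruent"), function(cg) {
    go <- trials[trials$trial_type == "go" & trials$congruency == cg, ]
    nogo <- trials[trials$trial_type == "nogo" & trials$congruency == cg, ]
    rt <- go$rt_ms[go$outcome == "correct"]
    nGo <- nrow(go)
    data.frame(
      congruency = cg,
      n_go = nGo,
      mean_rt_ms = if (length(rt)) mean(rt) else NA_real_,
      se_rt_ms = if (length(rt) > 1) sd(rt) / sqrt(length(rt))
                 else if (length(rt) == 1) 0 else NA_real_,
      go_accuracy_pct = if (nGo) 100 * mean(go$outcome == "correct")
                        else NA_real_,
      miss_pct = if (nGo) 100 * mean(go$outcome == "miss") else NA_real_,
      n_nogo = nrow(nogo),
      nogo_accuracy_pct = if (nrow(nogo))
        100 * mean(nogo$outcome == "correct_omission") else NA_real_,
      false_alarm_pct = if (nrow(nogo))
        100 * mean(nogo$outcome == "false_alarm") else NA_real_)
  })
  do.call(rbind, rows)
}

#' Paired t-test with the dz effect size
#'
#' Two-sided paired t-test via [stats::t.test()], augmented with
#' `dz = mean(d) / sd(d) = t / sqrt(n)`, the within-subject effect-size
#' convention consistent with reporting paired designs by (t, n, d)
#' triplets.
#'
#' @param x,y paired numeric vectors.
#' @return list of class `StatRecord`: statistic, df, p_value,
#'   effect_size_dz, test_name, n.
#' @export
pairedT <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  if (sd(d) == 0) stop("zero variance of the paired differences")
  tt <- stats::t.test(x, y, paired = TRUE)
  n <- length(d)
  structure(list(statistic = unname(tt$statistic),
                 df = unname(tt$parameter),
                 p_value = tt$p.value,
                 effect_size_dz = unname(tt$statistic) / sqrt(n),
                 test_name = "paired t", n = n),
            class = "StatRecord")
}

#' Wilcoxon signed-rank test for paired data
#'
#' Zero differences are dropped before ranking. For 12 or fewer nonzero
#' differences the null distribution of the rank sum is enumerated exactly;
#' otherwise the tie-corrected normal approximation provides the z value.
#'
#' @param x,y paired numeric vectors.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`
#'   (of x relative to y).
#' @return list of class `StatRecord` with the z statistic (normal
#'   approximation, reported for either mode), p_value, n (nonzero
#'   differences), exact flag.
#' @export
wilcoxonSignedRank <- function(x, y,
                               alternative = c("two.sided", "greater",
                                               "less")) {
  alternative <- match.arg(alternative)
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[d != 0]
  if (!length(d)) stop("all paired differences are zero")
  mom <- .signedRankMoments(abs(d))
  W <- sum(mom$ranks[d > 0])
  z <- if (mom$sigma > 0) (W - mom$mu) / mom$sigma else 0
  m <- length(d)
  if (m <= 12) {
    pGreater <- .signedRankExactTail(mom$ranks, W)
    pLess <- 1 - .signedRankExactTail(mom$ranks, W + 0.5)
    p <- switch(alternative,
                greater = pGreater, less = pLess,
                two.sided = min(1, 2 * min(pGreater, pLess)))
    exact <- TRUE
  } else {
    p <- switch(alternative,
                greater = 1 - pnorm(z),
                less = pnorm(z),
                two.sided = 2 * (1 - pnorm(abs(z))))
    exact <- FALSE
  }
  structure(list(statistic = z, df = NULL, p_value = p,
                 effect_size_dz = NULL,
                 test_name = "Wilcoxon signed-rank", n = m, exact = exact),
            class = "StatRecord")
}

#' @export
print.StatRecord <- function(x, ...) {
  cat(sprintf("%s: statistic = %.3f%s, p = %.4g, n = %d%s\n",
              x$test_name, x$statistic,
              if (!is.null(x$df)) sprintf(" (df = %g)", x$df) else "",
              x$p_value, x$n,
              if (!is.null(x$effect_size_dz))
                sprintf(", dz = %.2f", x$effect_size_dz) else ""))
  invisible(x)
}
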