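# End-to-end orchestration: simulate a cohort, preprocess, decompose with
# RIDE per condition, fit group ICA per cluster x condition, match
# components across conditions, decode each matched pair with MVPA +
# cluster statistics, contrast standardized source maps over the
# significant decoding window, and summarise behaviour. Fully reproducible:
# every stage seed is derived from the one config seed.

#' Pipeline configuration
#'
#' @param nSubjects number of simulated subjects.
#' @param arm which trial group feeds the EEG chain: `"nogo"` (primary) or
#'   `"go"`.
#' @param design a [taskDesign()].
#' @param behav a [behaviourParams()].
#' @param truth a [truthParams()]; set equal per-condition amplitudes for a
#'   null run.
#' @param montage a [Montage-class].
#' @param srateHz,windowMs simulation grid.
#' @param band,targetHz,ampLimit,flatLimit,flatWindowMs,csd,baselineMs
#'   pre-processing settings (see [preprocessChain()]).
#' @param ride a [rideConfig()].
#' @param nComponents,icaVarThreshold group-ICA settings.
#' @param matchThreshold,maxPerGroup component-matching settings.
#' @param cv a [cvConfig()]; its seed is re-derived per subject.
#' @param decodeStepMs decoding grid step in ms.
#' @param nPermCluster,clusterAlpha,alpha group cluster-test settings.
#' @param nSources,leadfieldGeometry,nPermSource source-stage settings.
#' @param seed master seed.
#' @return list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(nSubjects = 12, arm = c("nogo", "go"),
                           design = taskDesign(240, 0.5, 0.5, 4),
                           behav = behaviourParams(),
                           truth = truthParams(),
                           montage = makeMontage(60),
                           srateHz = 128, windowMs = c(-500, 1500),
                           band = c(0.5, 40), targetHz = NULL,
                           ampLimit = 100, flatLimit = 0.5,
                           flatWindowMs = 100, csd = TRUE,
                           baselineMs = c(-300, 0),
                           ride = rideConfig(),
                           nComponents = 20, icaVarThreshold = 0.8,
                           matchThreshold = 0.85, maxPerGroup = 3,
                           cv = cvConfig(), decodeStepMs = 40,
                           nPermCluster = 1000, clusterAlpha = 0.05,
                           alpha = 0.05,
                           nSources = 100,
                           leadfieldGeometry = "three-sphere-approx",
                           nPermSource = 1000, seed = 1L) {
  arm <- match.arg(arm)
  structure(as.list(environment()), class = "PipelineConfig")
}

.stageSeed <- function(seed, stage, k = 0L) {
  (seed * 1009L + match(stage, c("sim", "ica", "decode", "cluster",
                                 "source", "behaviour")) * 7919L +
     k * 104729L) %% 2147483399L + 1L
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> preprocess -> RIDE (per condition) -> group ICA
#' (per cluster x condition) -> component matching -> per-pair MVPA with
#' group cluster statistics -> source contrast over the significant
#' decoding window -> behavioural summary, and returns a structured,
#' seed-reproducible report.
#'
#' @param config a [pipelineConfig()].
#' @param verbose print stage progress.
#' @return list of class `PipelineReport`; see the elements `behaviour`,
#'   `matches`, `decoding`, `sourceContrast`, `trialCounts`, `parameters`.
#' @export
runPipeline <- function(config = pipelineConfig(), verbose = FALSE) {
  stopifnot(inherits(config, "PipelineConfig"))
  say <- function(...) if (verbose) message(sprintf(...))
  arm <- config$arm
  conds <- c("congruent", "incongruent")

  # --- simulate + preprocess per subject ------------------------------
  say("stage sim/preprocess: %d subjects", config$nSubjects)
  subjects <- vector("list", config$nSubjects)
  for (s in seq_len(config$nSubjects)) {
    sd <- .stageSeed(config$seed, "sim", s)
    tt <- generateTrialTable(config$design, seed = sd)
    tt <- simulateBehaviour(tt, config$behav, seed = sd + 1L,
                            deadlineMs = config$design$responseDeadlineMs)
    sim <- simulateEpochs(tt, config$truth, config$montage, seed = sd + 2L,
                          srateHz = config$srateHz,
                          windowMs = config$windowMs)
    pp <- tryCatch(
      preprocessChain(sim$epochs, band = config$band,
                      targetHz = config$targetHz,
                      ampLimit = config$ampLimit,
                      flatLimit = config$flatLimit,
                      flatWindowMs = config$flatWindowMs, csd = config$csd,
                      baselineMs = config$baselineMs),
      error = function(e) stop("stage preprocess failed for subject ", s,
                               ": ", conditionMessage(e)))
    subjects[[s]] <- list(epochs = pp$epochs, log = pp$log, trials = tt,
                          truth = sim$truth)
  }

  # --- RIDE per subject on the pooled arm trials ----------------------
  # One decomposition per subject (latencies stay per-trial); the S/C split
  # is then shared between congruencies. Fitting each congruency separately
  # would give each class its own waveform split, and that class-constant
  # offset reads as a condition effect downstream even under a null
  # generator.
  say("stage ride")
  clusters <- list(congruent = vector("list", config$nSubjects),
                   incongruent = vector("list", config$nSubjects))
  rideFits <- vector("list", config$nSubjects)
  for (s in seq_len(config$nSubjects)) {
    ep <- subjects[[s]]$epochs
    epc <- subsetTrials(ep, trialData(ep)$trial_type == arm)
    rr <- tryCatch(rideDecompose(epc, config$ride),
                   error = function(e) stop("stage ride failed (subject ",
                                            s, "): ", conditionMessage(e)))
    st <- singleTrialClusters(epc, rr)
    rideFits[[s]] <- rr
    for (cond in conds) {
      sel <- which(trialData(epc)$congruency == cond)
      # split-half: odd trials fit the group models (and matching), even
      # trials are decoded. Estimating the spatial model on the same trials
      # it later projects lets condition-specific fits chase their own
      # condition's sample noise, which every subject shares with the group
      # model — a double-dipping artifact that shows up as above-chance
      # decoding under a null generator.
      selModel <- sel[seq_along(sel) %% 2L == 1L]
      selDecode <- sel[seq_along(sel) %% 2L == 0L]
      clusters[[cond]][[s]] <- list(
        S = st$S[selModel, , , drop = FALSE],
        C = st$C[selModel, , , drop = FALSE],
        Sdecode = st$S[selDecode, , , drop = FALSE],
        Cdecode = st$C[selDecode, , , drop = FALSE],
        times = times(epc))
    }
  }
  timesMs <- clusters[[1]][[1]]$times

  # --- group ICA per cluster x condition ------------------------------
  say("stage ica")
  models <- list()
  for (cl in c("S", "C")) {
    for (cond in conds) {
      dat <- lapply(clusters[[cond]], `[[`, cl)
      models[[paste(cl, cond, sep = ".")]] <-
        fitGroupICA(dat, nComponents = config$nComponents,
                    varThreshold = config$icaVarThreshold,
                    seed = .stageSeed(config$seed, "ica",
                                      match(cl, c("S", "C")) * 2L +
                                        match(cond, conds)),
                    clusterTag = cl, conditionTag = cond)
    }
  }

  # --- match components across conditions -----------------------------
  say("stage match")
  matches <- list(
    S = matchComponents(models[["S.congruent"]], models[["S.incongruent"]],
                        config$matchThreshold, config$maxPerGroup),
    C = matchComponents(models[["C.congruent"]], models[["C.incongruent"]],
                        config$matchThreshold, config$maxPerGroup))

  # --- MVPA per matched pair ------------------------------------------
  say("stage decode")
  decoding <- list()
  for (cl in c("S", "C")) {
    mt <- matches[[cl]]
    if (!nrow(mt)) next
    for (p in seq_len(nrow(mt))) {
      aucMat <- NULL
      tgArr <- NULL
      dtimes <- NULL
      mA <- models[[paste(cl, "congruent", sep = ".")]]
      mB <- models[[paste(cl, "incongruent", sep = ".")]]
      for (s in seq_len(config$nSubjects)) {
        # one common pair projector for both classes, applied to the
        # held-out (decode) trial half; see projectPair()
        bpA <- projectPair(mA, mt$ic_a[p], mB, mt$ic_b[p],
                           clusters[["congruent"]][[s]][[paste0(cl, "decode")]])
        bpB <- projectPair(mA, mt$ic_a[p], mB, mt$ic_b[p],
                           clusters[["incongruent"]][[s]][[paste0(cl, "decode")]])
        cvS <- config$cv
        cvS$seed <- .stageSeed(config$seed, "decode",
                               s * 100L + p * 10L +
                                 match(cl, c("S", "C")))
        dr <- decodePair(bpA, bpB, timesMs, cv = cvS, generalize = TRUE,
                         stepMs = config$decodeStepMs)
        if (is.null(aucMat)) {
          dtimes <- dr@times
          aucMat <- matrix(0, config$nSubjects, length(dtimes))
          tgArr <- array(0, c(config$nSubjects, length(dtimes),
                              length(dtimes)))
        }
        aucMat[s, ] <- dr@subjectAuc
        tgArr[s, , ] <- dr@subjectTg
      }
      ct <- groupClusterTest(aucMat, chance = 0.5,
                             nPerm = config$nPermCluster,
                             alpha = config$alpha,
                             clusterAlpha = config$clusterAlpha,
                             seed = .stageSeed(config$seed, "cluster",
                                               p * 2L +
                                                 match(cl, c("S", "C"))))
      decoding[[paste0(cl, ".pair", p)]] <-
        list(cluster = cl, pair = p, times = dtimes,
             groupAuc = colMeans(aucMat), subjectAuc = aucMat,
             meanTg = apply(tgArr, c(2, 3), mean),
             clusterStats = ct)
    }
  }

  # --- source contrast over the significant decoding window -----------
  say("stage source")
  sourceContrast <- NULL
  sigWindows <- lapply(decoding, function(d)
    d$times[d$clusterStats$significantMask])
  sigTimes <- sort(unique(unlist(sigWindows)))
  if (length(sigTimes)) {
    lf <- makeLeadfield(config$montage, config$nSources,
                        config$leadfieldGeometry,
                        seed = .stageSeed(config$seed, "source"))
    tSel <- which(timesMs >= min(sigTimes) & timesMs <= max(sigTimes))
    mkMaps <- function(cond) {
      t(vapply(seq_len(config$nSubjects), function(s) {
        d <- clusters[[cond]][[s]]$Cdecode
        chanMap <- apply(d[, , tSel, drop = FALSE], 2, mean)
        sloretaLocalize(lf, chanMap)$power
      }, numeric(config$nSources)))
    }
    sourceContrast <- snpmContrast(mkMaps("congruent"), mkMaps("incongruent"),
                                   nPerm = config$nPermSource,
                                   alpha = config$alpha,
                                   seed = .stageSeed(config$seed, "source",
                                                     1L))
    sourceContrast$windowMs <- range(sigTimes)
  }

  # --- behaviour -------------------------------------------------------
  say("stage behaviour")
  perSubject <- lapply(subjects, function(su) summarizeBehaviour(su$trials))
  rtCong <- vapply(perSubject, function(b) b$mean_rt_ms[1], numeric(1))
  rtIncong <- vapply(perSubject, function(b) b$mean_rt_ms[2], numeric(1))
  accCong <- vapply(perSubject, function(b) b$nogo_accuracy_pct[1],
                    numeric(1))
  accIncong <- vapply(perSubject, function(b) b$nogo_accuracy_pct[2],
                      numeric(1))
  behaviour <- list(
    summary = do.call(rbind, lapply(seq_along(perSubject), function(i)
      cbind(subject = i, perSubject[[i]]))),
    rtTest = pairedT(rtCong, rtIncong),
    nogoAccTest = pairedT(accCong, accIncong),
    nogoAccWilcoxon = tryCatch(wilcoxonSignedRank(accCong, accIncong),
                               error = function(e) NULL))

  structure(list(
    behaviour = behaviour,
    matches = matches,
    decoding = decoding,
    sourceContrast = sourceContrast,
    trialCounts = table(subjects[[1]]$trials$trial_type,
                        subjects[[1]]$trials$congruency),
    rejection = lapply(subjects, function(su)
      if (is.null(su$log)) NULL else sum(!su$log$kept)),
    rideConvergence = data.frame(
      subject = seq_len(config$nSubjects),
      converged = vapply(rideFits, function(r) r@converged, logical(1)),
      iterations = vapply(rideFits, function(r) r@nIterations, integer(1))),
    parameters = config),
    class = "PipelineReport")
}

#' Write a pipeline report to a directory
#'
#' Serialises the report as JSON (scalar results, cluster tables, matches)
#' plus TSV tables; deterministic given the report, no timestamps.
#'
#' @param report a `PipelineReport`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeMatches(report$matches$S, file.path(dir, "matches_S.tsv"))
  writeMatches(report$matches$C, file.path(dir, "matches_C.tsv"))
  utils::write.table(report$behaviour$summary,
                     file.path(dir, "behaviour.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  dec <- lapply(report$decoding, function(d)
    list(cluster = d$cluster, pair = d$pair, times = d$times,
         groupAuc = d$groupAuc,
         clusters = d$clusterStats$clusters,
         significant = d$clusterStats$significantMask))
  payload <- list(
    decoding = dec,
    behaviour = list(
      rt = unclass(report$behaviour$rtTest),
      nogoAccuracy = unclass(report$behaviour$nogoAccTest)),
    sourceContrast = if (!is.null(report$sourceContrast))
      list(window_ms = report$sourceContrast$windowMs,
           n_significant = sum(report$sourceContrast$significantMask)))
  jsonlite::write_json(payload, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(dir)
}
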