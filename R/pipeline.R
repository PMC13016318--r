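#' Default pipeline configuration
#'
#' Nested configuration for [runStage()]: every analysis parameter of the
#' pipeline is reachable by key, with defaults equal to the analysis
#' settings documented in the methods vignette (gamma band and flanks,
#' smoothing frame, baseline and responsiveness windows, FDR levels,
#' surface thresholds and iteration count, decoding folds and windows,
#' PDC windowing and order, bootstrap count) and desk-scale synthetic
#' cohort sizes otherwise.
#'
#' @param nPatients,nPerClass cohort scale overrides.
#' @return nested named list.
#' @export
defaultConfig <- function(nPatients = 4, nPerClass = 30) {
  list(
    seed = 1,
    cohort = list(nPatients = nPatients, nPerClass = nPerClass,
                  electrodesPerRoi = 2, nOther = 2, sfreq = 500),
    preprocess = list(band = c(70, 150), flankHalfwidth = 1.5,
                      lineHz = 60, nHarmonics = 3, notchHalfwidth = 2,
                      sgOrder = 3, sgFrameMs = 201,
                      window = c(-0.7, 1.5), baseline = c(-0.5, -0.1),
                      respWindow = c(0.3, 0.7), respThreshold = 10),
    lme = list(binWidth = 0.01, bins = seq(-0.2, 1.0, by = 0.02),
               roiRadius = 10, fdrQ = 0.01),
    surface = list(subdiv = 2, lambda = 3, cutoff = 10,
                   window = c(0.3, 0.7), preset = "strict",
                   nIter = 200, alpha = 0.01, snapThreshold = 50),
    decoding = list(bins = seq(-0.2, 1.0, by = 0.05), binWidth = 0.05,
                    nFolds = 10, nShuffles = 100, cost = 1,
                    svrWindow = c(0.5, 0.8), gateShuffles = 200),
    pdc = list(windows = list(early = c(0.2, 0.5), late = c(0.5, 0.8)),
               lengthMs = 100, shiftMs = 50, order = 3, nFreqs = 64,
               fdrQ = 0.05, nBoot = 500),
    stim = list(nSessions = 8, trialsPerSession = 100, betaStim = -0.81,
                intercept = 2.0, sessionSd = 0.3))
}

# small FNV-1a hash of the serialized config, for provenance lines
configHash <- function(config) {
  s <- utf8ToInt(yaml::as.yaml(config))
  h <- 84696351
  for (b in s) h <- (bitwXor(h, b) * 16777619) %% 268435456
  sprintf("%07x", h)
}

stageLog <- function(outDir, stage, seed, config, msg = "done") {
  line <- sprintf("%s\tstage=%s\tseed=%s\tconfig=%s\t%s",
                  format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), stage,
                  seed, configHash(config), msg)
  cat(line, "\n", file = file.path(outDir, "pipeline.log"), append = TRUE)
}

needArtifact <- function(path, producer) {
  ok <- if (grepl("\\*", path)) length(Sys.glob(path)) > 0
        else file.exists(path)
  if (!ok)
    stop("missing upstream artifact ", basename(path),
         "; run stage '", producer, "' first")
}

loadBgaCohort <- function(outDir) {
  files <- Sys.glob(file.path(outDir, "bga", "*_bga.json"))
  ids <- sub("_bga\\.json$", "", basename(files))
  cohort <- lapply(ids, function(pid)
    readEpochs(file.path(outDir, "bga", paste0(pid, "_bga"))))
  names(cohort) <- ids
  cohort
}

loadResponsive <- function(outDir) {
  d <- readTsv(file.path(outDir, "bga", "responsive.tsv"))
  setNames(as.logical(d$responsive), d$name)
}

#' Run one pipeline stage (or all of them)
#'
#' Stage-wise driver over the package's analysis functions, operating on
#' a directory of artifacts. Every stage is deterministic given
#' `(config, seed)`; each writes a provenance line (stage, seed, config
#' hash) to `pipeline.log` and fails with an actionable message naming
#' the producing stage when an upstream artifact is missing.
#'
#' @param stage one of `"simulate"`, `"preprocess"`, `"lme"`,
#'   `"surface"`, `"decode"`, `"connectivity"`, `"behavior"`, `"stim"`,
#'   `"all"`.
#' @param outDir artifact directory.
#' @param config configuration list, see [defaultConfig()].
#' @param seed master seed (overrides `config$seed`).
#' @param verbose print progress.
#' @return invisibly, the stage's main result object.
#' @export
runStage <- function(stage = c("all", "simulate", "preprocess", "lme",
                               "surface", "decode", "connectivity",
                               "behavior", "stim"),
                     outDir, config = defaultConfig(), seed = NULL,
                     verbose = FALSE) {
  stage <- match.arg(stage)
  if (is.null(seed)) seed <- config$seed
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message("[", stage, "] ", ...)

  if (stage == "all") {
    for (s in c("simulate", "preprocess", "lme", "surface", "decode",
                "connectivity", "behavior", "stim"))
      runStage(s, outDir, config, seed, verbose)
    return(invisible(outDir))
  }

  rawDir <- file.path(outDir, "raw")
  res <- switch(stage,
    simulate = {
      cc <- config$cohort
      cfg <- defaultCohortConfig(nPatients = cc$nPatients,
                                 electrodesPerRoi = cc$electrodesPerRoi,
                                 nOther = cc$nOther, sfreq = cc$sfreq)
      say("simulating ", cc$nPatients, " patients")
      simulateCohort(cfg, seed = seed, nPerClass = cc$nPerClass,
                     outDir = rawDir)
    },
    preprocess = {
      needArtifact(file.path(rawDir, "*_ieeg.json"), "simulate")
      pp <- config$preprocess
      raw <- readCohort(rawDir)
      dir.create(file.path(outDir, "bga"), showWarnings = FALSE)
      masks <- list()
      for (pid in names(raw$patients)) {
        say("preprocessing ", pid)
        p <- raw$patients[[pid]]
        out <- preprocessRecording(p$recording, p$events, p$electrodes,
          band = pp$band, lineHz = pp$lineHz, nHarmonics = pp$nHarmonics,
          notchHalfwidth = pp$notchHalfwidth, window = pp$window,
          baseline = pp$baseline, respWindow = pp$respWindow,
          respThreshold = pp$respThreshold)
        writeEpochs(out$epochs, file.path(outDir, "bga",
                                          paste0(pid, "_bga")))
        masks[[pid]] <- data.frame(patient = pid,
                                   name = names(out$responsive),
                                   responsive = unname(out$responsive))
      }
      writeTsv(do.call(rbind, masks),
               file.path(outDir, "bga", "responsive.tsv"))
      masks
    },
    lme = {
      needArtifact(file.path(outDir, "bga", "responsive.tsv"),
                   "preprocess")
      cohort <- loadBgaCohort(outDir)
      resp <- loadResponsive(outDir)
      lc <- config$lme
      rc <- roiContrast(cohort, radius = lc$roiRadius,
                        responsive = resp, bins = lc$bins,
                        binWidth = lc$binWidth, fdrQ = lc$fdrQ)
      eff <- do.call(rbind, lapply(names(rc), function(r)
        cbind(roi = r, rc[[r]]$effects)))
      tr <- do.call(rbind, lapply(names(rc), function(r)
        cbind(roi = r, rc[[r]]$trace)))
      writeTsv(eff, file.path(outDir, "roi_effects.tsv"))
      writeTsv(tr, file.path(outDir, "roi_traces.tsv"))
      rc
    },
    surface = {
      needArtifact(file.path(outDir, "bga", "responsive.tsv"),
                   "preprocess")
      cohort <- loadBgaCohort(outDir)
      sc <- config$surface
      allXyz <- do.call(rbind, lapply(cohort, function(ep)
        as.matrix(ep@electrodes[, c("x", "y", "z")])))
      mesh <- icosphereMesh(sc$subdiv,
                            radius = median(sqrt(rowSums(allXyz^2))))
      preset <- surfaceThresholdPreset(sc$preset)
      map <- vertexLme(cohort, mesh, window = sc$window,
                       minPatients = preset$minPatients,
                       lambda = sc$lambda, cutoff = sc$cutoff,
                       snapThreshold = sc$snapThreshold)
      cs <- clusterFwe(map, mesh, tThresh = preset$tThresh,
                       nIter = sc$nIter, alpha = sc$alpha,
                       seed = childSeed(seed, 41))
      writeTsv(data.frame(vertex = seq_along(map@tstat),
                          beta = map@beta, tstat = map@tstat,
                          coverage = map@coverage),
               file.path(outDir, "vertex_map.tsv"))
      jsonlite::write_json(
        list(alpha = cs@alpha, tThresh = cs@tThresh,
             clusters = lapply(cs@clusters, function(cl)
               cl[c("extent", "peakT", "p")])),
        file.path(outDir, "clusters.json"), auto_unbox = TRUE,
        digits = NA, pretty = TRUE)
      list(map = map, clusters = cs)
    },
    decode = {
      needArtifact(file.path(outDir, "bga", "responsive.tsv"),
                   "preprocess")
      cohort <- loadBgaCohort(outDir)
      resp <- loadResponsive(outDir)
      dc <- config$decoding
      say("sliding decoder")
      sa <- slidingAuc(cohort, bins = dc$bins, binWidth = dc$binWidth,
                       nFolds = dc$nFolds, cost = dc$cost,
                       responsive = resp, seed = childSeed(seed, 51))
      say("permutation null (", dc$nShuffles, " shuffles)")
      pn <- permutationNull(cohort, nShuffles = dc$nShuffles,
                            bins = dc$bins, binWidth = dc$binWidth,
                            nFolds = dc$nFolds, cost = dc$cost,
                            responsive = resp,
                            seed = childSeed(seed, 52))
      ms <- svrMidscaleComparison(cohort, window = dc$svrWindow,
                                  nFolds = dc$nFolds, cost = dc$cost,
                                  gateShuffles = dc$gateShuffles,
                                  responsive = resp,
                                  seed = childSeed(seed, 53))
      auc <- do.call(rbind, lapply(rownames(sa$auc), function(p)
        data.frame(patient = p, time = sa$times, auc = sa$auc[p, ],
                   nullThresh = pn$threshold)))
      writeTsv(auc, file.path(outDir, "decoding_auc.tsv"))
      writeTsv(ms$perPatient, file.path(outDir, "midscale_mse.tsv"))
      list(auc = sa, null = pn, midscale = ms)
    },
    connectivity = {
      needArtifact(file.path(outDir, "bga", "responsive.tsv"),
                   "preprocess")
      cohort <- loadBgaCohort(outDir)
      pc <- config$pdc
      tabs <- lapply(pc$windows, function(w)
        roiPairPdc(cohort, timeWindow = w, lengthMs = pc$lengthMs,
                   shiftMs = pc$shiftMs, order = pc$order,
                   nFreqs = pc$nFreqs))
      tab <- do.call(rbind, tabs)
      writeTsv(tab, file.path(outDir, "pdc_edges.tsv"))
      nets <- lapply(tabs, edgeLme, fdrQ = pc$fdrQ)
      boot <- centralityBootstrap(tabs[[length(tabs)]], nBoot = pc$nBoot,
                                  seed = childSeed(seed, 61))
      jsonlite::write_json(
        list(networks = lapply(nets, function(n) n["edges"]),
             centralityBootstrap = boot),
        file.path(outDir, "network.json"), auto_unbox = TRUE,
        digits = NA, pretty = TRUE, force = TRUE)
      list(table = tab, networks = nets, bootstrap = boot)
    },
    behavior = {
      needArtifact(file.path(rawDir, "*_events.tsv"), "simulate")
      evFiles <- Sys.glob(file.path(rawDir, "*_events.tsv"))
      ev <- do.call(rbind, lapply(evFiles, function(f) {
        d <- readEvents(f)
        d$patient <- sub("_events\\.tsv$", "", basename(f))
        d
      }))
      bs <- summarizeBehavior(ev)
      writeTsv(bs$perPatient, file.path(outDir, "behavior_summary.tsv"))
      bs
    },
    stim = {
      st <- config$stim
      trials <- simulateStimTrials(nSessions = st$nSessions,
                                   trialsPerSession = st$trialsPerSession,
                                   betaStim = st$betaStim,
                                   intercept = st$intercept,
                                   sessionSd = st$sessionSd,
                                   seed = childSeed(seed, 71))
      writeTsv(trials, file.path(outDir, "stim_trials.tsv"))
      fit <- fitStimulationGlmm(trials)
      jsonlite::write_json(fit, file.path(outDir, "stim_glmm.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           force = TRUE)
      fit
    })
  stageLog(outDir, stage, seed, config)
  invisible(res)
}
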