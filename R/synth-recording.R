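#' Standardized ROI centers for the concreteness network
#'
#' Seven left-hemisphere regions of interest in standardized (Talairach)
#' mm coordinates: mid-fusiform (mFus), parahippocampal gyrus (PHG),
#' temporoparietal junction (TPJ), posterior and anterior inferior frontal
#' gyrus (pIFG, aIFG), frontal operculum (FO) and orbitofrontal cortex
#' (OFC).
#'
#' @return data.frame with columns `roi`, `x`, `y`, `z`.
#' @export
defaultRoiCenters <- function() {
  data.frame(
    roi = c("mFus", "PHG", "TPJ", "pIFG", "aIFG", "FO", "OFC"),
    x = c(-32, -25, -49, -42, -39, -38, -34),
    y = c(-35, -16, -52, 15, 33, 17, 26),
    z = c(-17, -22, 25, 30, 18, 9, -8),
    stringsAsFactors = FALSE)
}

#' Default synthetic cohort configuration
#'
#' Desk-scale defaults for [simulateCohort()]: a handful of patients, two
#' electrodes per ROI plus off-network contacts, 500 Hz sampling (2 kHz
#' available by setting `sfreq`), condition-specific multiplicative gamma
#' gains with concrete > abstract in the ventrotemporal/frontal network,
#' ROI-specific response latencies, optional directed ROI envelope
#' coupling, and behavioral parameters (sensitivity, response bias,
#' lognormal RTs, midscale abstractness bias).
#'
#' @param nPatients number of patients.
#' @param electrodesPerRoi electrodes per ROI.
#' @param nOther off-network (null-gain) electrodes per patient.
#' @param sfreq sampling rate in Hz (> 300 so the 150 Hz band edge stays
#'   below Nyquist).
#' @param coupling optional directed ROI coupling (array or per-condition
#'   list as in [simulateConnectivityCohort()]).
#' @return nested configuration list.
#' @export
defaultCohortConfig <- function(nPatients = 6, electrodesPerRoi = 2,
                                nOther = 4, sfreq = 500, coupling = NULL) {
  rois <- defaultRoiCenters()
  gain <- rbind(
    mFus = c(1.30, 1.10, 1.20), PHG = c(1.25, 1.10, 1.175),
    TPJ  = c(1.20, 1.08, 1.14), pIFG = c(1.22, 1.10, 1.16),
    aIFG = c(1.22, 1.10, 1.16), FO  = c(1.20, 1.08, 1.14),
    OFC  = c(1.25, 1.10, 1.175), other = c(1, 1, 1))
  colnames(gain) <- c("concrete", "abstract", "midscale")
  list(
    nPatients = nPatients,
    electrodesPerRoi = electrodesPerRoi,
    nOther = nOther,
    roiCenters = rois,
    sfreq = sfreq,
    gammaGain = gain,
    latency = c(mFus = 0.25, PHG = 0.25, TPJ = 0.45, pIFG = 0.45,
                aIFG = 0.40, FO = 0.40, OFC = 0.35, other = 0.30),
    normWindow = c(0.3, 0.7),
    wordDur = 1.0, fixationDur = 1.5, lead = 2.0, tailPad = 2.0,
    backgroundSd = 20, carrierSd = 15, lineAmp = 5, lineHz = 60,
    coupling = coupling, couplingSigma = 0.25,
    electrodeJitterSd = 3,
    behavior = list(lnDor = 2.2, bias = -0.25, respondP = 0.98,
                    abstractBiasMid = 0.65,
                    rtMeanlog = c(concrete = log(0.932),
                                  abstract = log(0.986),
                                  midscale = log(0.989)),
                    rtSdlog = 0.2))
}

validateCohortConfig <- function(cfg) {
  if (cfg$sfreq <= 300)
    stop("sfreq must exceed 300 Hz so the 150 Hz band edge is below Nyquist")
  if (!is.null(cfg$coupling)) {
    cc <- cfg$coupling
    if (!is.list(cc)) cc <- list(cc)
    for (a in cc) if (varSpectralRadius(a) >= 1)
      stop("unstable VAR coupling in config rejected")
  }
  invisible(cfg)
}

# trial response profile: gamma-density bump (shape 3) starting at the ROI
# latency, normalized so its mean over the canonical responsiveness
# window (300-700 ms) is 1 -- which makes a planted multiplicative gain g
# read out as window-mean BGA of 100(g - 1) in that window, for any ROI
# latency.
responseProfile <- function(t, latency, normWindow = c(0.3, 0.7),
                            shape = 3, scl = 0.08) {
  prof <- dgamma(t - latency, shape = shape, scale = scl)
  tt <- seq(normWindow[1], normWindow[2], by = 0.001)
  prof / mean(dgamma(tt - latency, shape = shape, scale = scl))
}

# 1/f^2-shaped background noise, unit-sd white carrier shaping via FFT
colouredNoise <- function(n, sfreq, exponent = 2) {
  w <- rnorm(n)
  W <- fft(w)
  f <- seq(0, sfreq, length.out = n + 1)[seq_len(n)]
  f[f > sfreq / 2] <- sfreq - f[f > sfreq / 2]  # fold to physical freq
  amp <- ifelse(f < 1, 1, f^(-exponent / 2))
  x <- Re(fft(W * amp, inverse = TRUE)) / n
  x / sd(x)
}

bandpassNoise <- function(n, sfreq, band) {
  w <- rnorm(n)
  env <- hilbertBandEnvelope(matrix(w, 1), sfreq, band = band,
                             flankHalfwidth = 1.5, analytic = TRUE)
  x <- Re(env[1, ])
  x / sd(x)
}

#' Simulate one patient's continuous recording, events and ground truth
#'
#' The signal model per electrode is additive: a 1/f^2 background, a line
#' component at `lineHz`, and a 70-150 Hz band-limited Gaussian carrier
#' whose envelope is multiplied, per trial, by a smooth gamma-density
#' response profile scaled by the configured (ROI, class) gamma gain --
#' so a planted gain is analytically recoverable as percent-change BGA.
#' If directed ROI coupling is configured, all electrodes of an ROI share
#' a per-trial VAR envelope modulation at the 20 Hz window rate.
#' The trial schedule is 1,000 ms word presentation plus 1,500 ms
#' fixation.
#'
#' @param cfg configuration list from [defaultCohortConfig()].
#' @param lexicon stimulus lexicon from [generateLexicon()].
#' @param patient patient index (used for naming).
#' @param seed integer seed.
#' @return list with elements `recording` ([ContinuousRecording-class]),
#'   `events` (data.frame: onset_s, word, class, response, rt_s, correct,
#'   length, zipf, artifact), `electrodes` (name, patient, x, y, z, roi)
#'   and `groundTruth` (planted per-trial gains, coupling, behavioral
#'   truth).
#' @export
simulateRecording <- function(cfg, lexicon, patient = 1, seed = NULL) {
  validateCohortConfig(cfg)
  withSeed(seed, {
    pid <- sprintf("sub-%02d", patient)
    sfreq <- cfg$sfreq
    ntr <- nrow(lexicon)
    soa <- cfg$wordDur + cfg$fixationDur
    onsets <- cfg$lead + (seq_len(ntr) - 1) * soa
    dur <- cfg$lead + ntr * soa + cfg$tailPad
    n <- round(dur * sfreq)
    tax <- (seq_len(n) - 1) / sfreq

    # electrode table
    rois <- cfg$roiCenters
    el <- do.call(rbind, lapply(seq_len(nrow(rois)), function(i) {
      data.frame(name = sprintf("%s%d", rois$roi[i],
                                seq_len(cfg$electrodesPerRoi)),
                 patient = pid,
                 x = rois$x[i] + rnorm(cfg$electrodesPerRoi, 0,
                                       cfg$electrodeJitterSd),
                 y = rois$y[i] + rnorm(cfg$electrodesPerRoi, 0,
                                       cfg$electrodeJitterSd),
                 z = rois$z[i] + rnorm(cfg$electrodesPerRoi, 0,
                                       cfg$electrodeJitterSd),
                 roi = rois$roi[i], stringsAsFactors = FALSE)
    }))
    if (cfg$nOther > 0)
      el <- rbind(el, data.frame(
        name = sprintf("oth%d", seq_len(cfg$nOther)), patient = pid,
        x = rnorm(cfg$nOther, 40, 10), y = rnorm(cfg$nOther, 0, 30),
        z = rnorm(cfg$nOther, 30, 15), roi = "other",
        stringsAsFactors = FALSE))
    nel <- nrow(el)

    # trial order and behavior
    ord <- sample.int(ntr)
    lex <- lexicon[ord, , drop = FALSE]
    beh <- simulateBehavior(lex, trueLnDor = cfg$behavior$lnDor,
                            bias = cfg$behavior$bias,
                            rtParams = list(meanlog = cfg$behavior$rtMeanlog,
                                            sdlog = cfg$behavior$rtSdlog),
                            abstractBiasMid = cfg$behavior$abstractBiasMid,
                            respondP = cfg$behavior$respondP)
    events <- data.frame(onset_s = onsets, word = lex$word, class = lex$class,
                         response = beh$response, rt_s = beh$rt_s,
                         correct = beh$correct, length = lex$length,
                         zipf = lex$zipf, artifact = FALSE,
                         stringsAsFactors = FALSE)

    # optional per-trial coupled ROI envelope modulation (20 Hz rate)
    zmod <- NULL
    if (!is.null(cfg$coupling)) {
      coup <- cfg$coupling
      if (!is.list(coup))
        coup <- list(concrete = coup, abstract = coup, midscale = coup)
      if (is.null(coup$midscale)) coup$midscale <- coup$concrete
      nWin <- length(seq(0, 1.2, by = 0.05))
      zmod <- lapply(seq_len(ntr), function(tr)
        simulateCoupledEnvelopes(coup[[events$class[tr]]], nWin,
                                 noiseSd = 1, burnin = 50))
    }

    gains <- matrix(1, ntr, nel, dimnames = list(NULL, el$name))
    linePhase <- runif(1, 0, 2 * pi)
    data <- matrix(0, nel, n)
    for (e in seq_len(nel)) {
      roi <- el$roi[e]
      lat <- cfg$latency[[roi]]
      g <- cfg$gammaGain[roi, ]
      m <- rep(1, n)
      for (tr in seq_len(ntr)) {
        i0 <- round(onsets[tr] * sfreq) + 1L
        span <- i0:min(n, i0 + round(1.3 * sfreq))
        rel <- tax[span] - onsets[tr]
        gtr <- g[[events$class[tr]]]
        gains[tr, e] <- gtr
        m[span] <- m[span] *
          (1 + (gtr - 1) * responseProfile(rel, lat, cfg$normWindow))
        if (!is.null(zmod)) {
          ridx <- match(roi, rois$roi)
          if (!is.na(ridx)) {
            zi <- approx(seq(0, 1.2, by = 0.05), zmod[[tr]][ridx, ],
                         xout = pmin(rel, 1.2), rule = 2)$y
            m[span] <- m[span] * exp(cfg$couplingSigma * zi)
          }
        }
      }
      carrier <- bandpassNoise(n, sfreq, c(70, 150)) * cfg$carrierSd
      data[e, ] <- colouredNoise(n, sfreq) * cfg$backgroundSd +
        cfg$lineAmp * sin(2 * pi * cfg$lineHz * tax + linePhase) +
        carrier * m
    }
    rec <- ContinuousRecording(data, sfreq, chNames = el$name)
    gt <- list(patient = pid, gains = gains,
               coupling = cfg$coupling,
               behavior = list(lnDor = cfg$behavior$lnDor,
                               abstractBiasMid = cfg$behavior$abstractBiasMid))
    list(recording = rec, events = events, electrodes = el, groundTruth = gt)
  })
}

#' Simulate a full synthetic cohort
#'
#' Generates the shared lexicon and one recording + events + electrode
#' table + ground truth per patient; optionally writes everything to
#' `outDir` in the package's on-disk layout (see [writeRecording()]).
#'
#' @param cfg configuration from [defaultCohortConfig()].
#' @param seed master integer seed; per-patient seeds are derived from it.
#' @param nPerClass words per class for the lexicon (default 80).
#' @param outDir optional output directory.
#' @return list with `lexicon` and `patients` (list of
#'   [simulateRecording()] results).
#' @export
simulateCohort <- function(cfg = defaultCohortConfig(), seed = 1,
                           nPerClass = 80, outDir = NULL) {
  validateCohortConfig(cfg)
  lex <- generateLexicon(nPerClass, seed = childSeed(seed, 1))
  patients <- lapply(seq_len(cfg$nPatients), function(p)
    simulateRecording(cfg, lex, patient = p, seed = childSeed(seed, 1 + p)))
  names(patients) <- vapply(patients, function(p) p$groundTruth$patient, "")
  out <- list(lexicon = lex, patients = patients)
  if (!is.null(outDir)) writeCohort(out, outDir)
  out
}
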