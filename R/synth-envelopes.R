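#' Spectral radius of the companion matrix of a VAR coefficient array
#'
#' @param A nodes x nodes x order coefficient array (a plain matrix is
#'   treated as order 1).
#' @return largest modulus eigenvalue of the companion matrix.
#' @export
varSpectralRadius <- function(A) {
  if (is.matrix(A)) A <- array(A, c(nrow(A), ncol(A), 1L))
  n <- dim(A)[1]; p <- dim(A)[3]
  comp <- matrix(0, n * p, n * p)
  for (r in seq_len(p)) comp[seq_len(n), (r - 1) * n + seq_len(n)] <- A[, , r]
  if (p > 1)
    comp[(n + 1):(n * p), seq_len(n * (p - 1))] <- diag(n * (p - 1))
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

#' Simulate a stationary VAR realization of coupled envelope series
#'
#' Generates node x sample series from a vector-autoregressive process,
#' the generative counterpart of the MVAR model fitted for partial
#' directed coherence. Unstable coefficient sets (companion spectral
#' radius >= 1) are rejected before any data is produced.
#'
#' @param coupling nodes x nodes x order coefficient array; `A[i, j, r]`
#'   couples node j at lag r into node i. A plain matrix is order 1.
#' @param nSamples samples to return (after burn-in).
#' @param noiseSd innovation SD per node (scalar recycled).
#' @param seed integer seed.
#' @param burnin samples discarded at the start (default 100).
#' @return nodes x nSamples numeric matrix.
#' @examples
#' A <- matrix(c(0.5, 0.4, 0, 0.5), 2, 2)  # node 1 drives node 2
#' z <- simulateCoupledEnvelopes(A, 500, seed = 1)
#' @export
simulateCoupledEnvelopes <- function(coupling, nSamples, noiseSd = 1,
                                     seed = NULL, burnin = 100) {
  if (is.matrix(coupling))
    coupling <- array(coupling, c(nrow(coupling), ncol(coupling), 1L))
  n <- dim(coupling)[1]; p <- dim(coupling)[3]
  if (dim(coupling)[2] != n) stop("coupling matrices must be square")
  sr <- varSpectralRadius(coupling)
  if (sr >= 1)
    stop("unstable VAR coefficients (spectral radius ", round(sr, 3),
         " >= 1); refusing to generate")
  stopifneg(nSamples, "nSamples")
  noiseSd <- rep_len(noiseSd, n)
  withSeed(seed, {
    total <- nSamples + burnin
    z <- matrix(0, n, total + p)
    eps <- matrix(rnorm(n * total, 0, noiseSd), n, total)
    for (t in seq_len(total)) {
      acc <- eps[, t]
      for (r in seq_len(p)) acc <- acc + coupling[, , r] %*% z[, t + p - r]
      z[, t + p] <- acc
    }
    z[, p + burnin + seq_len(nSamples), drop = FALSE]
  })
}

#' Simulate a cohort of envelope epochs with planted mixed-effects structure
#'
#' Epoch-level generator used to validate the mixed-effects and decoding
#' stages directly: per-trial, per-electrode percent-change BGA traces are
#' drawn from the hierarchical model the analysis assumes (patient and
#' electrode-within-patient random intercepts, trial noise), with a
#' concreteness effect confined to `effectWindow` and optional word-length
#' and frequency effects. Concreteness is coded +1 (concrete) / -1
#' (abstract); a planted `betaConc` of b yields a concrete-abstract BGA
#' difference of 2b inside the window.
#'
#' @param nPatients,nElectrodes,nTrialsPerClass cohort dimensions.
#' @param times epoch time axis in seconds (default 10 ms bins over
#'   \eqn{[-0.2, 1.0]} s).
#' @param betaConc concreteness effect, percent BGA per contrast unit.
#' @param effectWindow window (s) in which the effect is active.
#' @param betaLength,betaZipf covariate effects (percent per centered unit).
#' @param responseMean baseline task-evoked response (percent) added to all
#'   trials inside the effect window.
#' @param sdPatient,sdElectrode,sdNoise random-intercept and trial noise
#'   SDs (percent BGA).
#' @param classes trial classes to generate.
#' @param midscaleRegime for midscale trials: `"invariant"` plants the
#'   class-mean response midway between concrete and abstract regardless
#'   of the simulated rating; `"response-driven"` makes the neural signal
#'   follow the rating itself.
#' @param abstractBiasMid probability a midscale trial is rated abstract.
#' @param seed integer seed.
#' @return named list of [EnvelopeEpochs-class], one per patient.
#' @export
simulateEffectEpochs <- function(nPatients = 8, nElectrodes = 20,
                                 nTrialsPerClass = 75,
                                 times = seq(-0.2, 1.0, by = 0.01),
                                 betaConc = 15, effectWindow = c(0.4, 0.7),
                                 betaLength = 0, betaZipf = 0,
                                 responseMean = 30,
                                 sdPatient = 5, sdElectrode = 5, sdNoise = 25,
                                 classes = c("concrete", "abstract"),
                                 midscaleRegime = c("invariant",
                                                    "response-driven"),
                                 abstractBiasMid = 0.65,
                                 seed = NULL) {
  midscaleRegime <- match.arg(midscaleRegime)
  withSeed(seed, {
    nt <- length(times)
    inWin <- times >= effectWindow[1] & times <= effectWindow[2]
    cohort <- list()
    for (pat in seq_len(nPatients)) {
      pid <- sprintf("sub-%02d", pat)
      uPat <- rnorm(1, 0, sdPatient)
      uEl <- rnorm(nElectrodes, 0, sdElectrode)
      ntr <- nTrialsPerClass * length(classes)
      cls <- rep(classes, each = nTrialsPerClass)
      resp <- ifelse(cls == "concrete", "concrete",
              ifelse(cls == "abstract", "abstract",
                     ifelse(runif(ntr) < abstractBiasMid,
                            "abstract", "concrete")))
      x <- ifelse(cls == "concrete", 1, ifelse(cls == "abstract", -1, 0))
      if (any(cls == "midscale") && midscaleRegime == "response-driven") {
        mid <- cls == "midscale"
        x[mid] <- ifelse(resp[mid] == "concrete", 1, -1)
      }
      len <- pmax(3, round(rnorm(ntr, 7.6, 1.9)))
      zipf <- rnorm(ntr, 3.5, 0.65)
      fixed <- responseMean + betaConc * x +
        betaLength * (len - mean(len)) + betaZipf * (zipf - mean(zipf))
      arr <- array(rnorm(ntr * nElectrodes * nt, 0, sdNoise),
                   c(ntr, nElectrodes, nt))
      bump <- matrix(rep(as.numeric(inWin), each = ntr), ntr, nt)
      for (e in seq_len(nElectrodes))
        arr[, e, ] <- arr[, e, ] + (uPat + uEl[e] + fixed) * bump
      trials <- data.frame(word = sprintf("w%03d", seq_len(ntr)),
                           class = cls, response = resp,
                           rt_s = rlnorm(ntr, log(0.95), 0.2),
                           correct = resp == cls | cls == "midscale",
                           length = len, zipf = zipf,
                           stringsAsFactors = FALSE)
      electrodes <- data.frame(
        name = sprintf("e%02d", seq_len(nElectrodes)),
        patient = pid, x = 0, y = 0, z = 0, roi = "sim",
        stringsAsFactors = FALSE)
      cohort[[pid]] <- EnvelopeEpochs(arr, times, trials, electrodes)
    }
    cohort
  })
}

#' Simulate a cohort of coupled ROI envelope epochs
#'
#' Generator for the connectivity stage: per trial, ROI-level envelope
#' series follow a condition-specific stable VAR at the analysis window
#' rate (20 Hz, i.e. one value per 50 ms shift), and each electrode of an
#' ROI records that ROI's series plus independent measurement noise.
#'
#' @param coupling either a single nodes x nodes x order array used for
#'   both conditions or a named list with `concrete` and `abstract`
#'   arrays; node order defines the ROI order.
#' @param rois ROI names, one per node.
#' @param nPatients patients to simulate.
#' @param electrodesPerRoi electrodes recording each ROI.
#' @param nTrialsPerClass trials per condition (default 80).
#' @param times epoch time axis at the 20 Hz window rate.
#' @param noiseSd VAR innovation SD.
#' @param measurementSd per-electrode additive noise SD.
#' @param seed integer seed.
#' @return named list of [EnvelopeEpochs-class], one per patient.
#' @export
simulateConnectivityCohort <- function(coupling, rois,
                                       nPatients = 6,
                                       electrodesPerRoi = 2,
                                       nTrialsPerClass = 80,
                                       times = seq(0, 1.0, by = 0.05),
                                       noiseSd = 1, measurementSd = 0.3,
                                       seed = NULL) {
  if (!is.list(coupling))
    coupling <- list(concrete = coupling, abstract = coupling)
  norm1 <- function(a) if (is.matrix(a)) array(a, c(nrow(a), ncol(a), 1)) else a
  coupling <- lapply(coupling, norm1)
  n <- dim(coupling[[1]])[1]
  if (length(rois) != n) stop("`rois` must name one ROI per node")
  for (a in coupling)
    if (varSpectralRadius(a) >= 1) stop("unstable VAR coupling rejected")
  withSeed(seed, {
    nt <- length(times)
    nel <- n * electrodesPerRoi
    cohort <- list()
    for (pat in seq_len(nPatients)) {
      pid <- sprintf("sub-%02d", pat)
      ntr <- 2 * nTrialsPerClass
      cls <- rep(c("concrete", "abstract"), each = nTrialsPerClass)
      arr <- array(NA_real_, c(ntr, nel, nt))
      for (tr in seq_len(ntr)) {
        z <- simulateCoupledEnvelopes(coupling[[cls[tr]]], nt,
                                      noiseSd = noiseSd, burnin = 50)
        for (r in seq_len(n)) for (e in seq_len(electrodesPerRoi))
          arr[tr, (r - 1) * electrodesPerRoi + e, ] <-
            z[r, ] + rnorm(nt, 0, measurementSd)
      }
      electrodes <- data.frame(
        name = sprintf("%s_e%d", rep(rois, each = electrodesPerRoi),
                       rep(seq_len(electrodesPerRoi), n)),
        patient = pid, x = 0, y = 0, z = 0,
        roi = rep(rois, each = electrodesPerRoi),
        stringsAsFactors = FALSE)
      trials <- data.frame(word = sprintf("w%03d", seq_len(ntr)),
                           class = cls, response = cls,
                           rt_s = rlnorm(ntr, log(0.95), 0.2),
                           correct = TRUE,
                           length = pmax(3, round(rnorm(ntr, 7.6, 1.9))),
                           zipf = rnorm(ntr, 3.5, 0.65),
                           stringsAsFactors = FALSE)
      cohort[[pid]] <- EnvelopeEpochs(arr, times, trials, electrodes)
    }
    cohort
  })
}
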