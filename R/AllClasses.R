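#' Continuous multichannel intracranial recording
#'
#' Voltage traces for one patient: a channels x samples matrix in microvolts
#' with a sampling rate and per-channel metadata. Channels flagged as
#' excluded (e.g. seizure-onset or noisy contacts) are carried through the
#' pipeline untouched and ignored by referencing and epoching.
#'
#' @slot data numeric matrix, channels x samples (microvolts).
#' @slot sfreq sampling frequency in Hz.
#' @slot chNames character vector of channel names.
#' @slot excluded logical vector, one flag per channel.
#'
#' @exportClass ContinuousRecording
setClass("ContinuousRecording",
  representation(data = "matrix", sfreq = "numeric",
                 chNames = "character", excluded = "logical"))

setValidity("ContinuousRecording", function(object) {
  msg <- character()
  if (!is.numeric(object@data)) msg <- c(msg, "data must be numeric")
  if (anyNA(object@data) || any(!is.finite(object@data)))
    msg <- c(msg, "data must be finite")
  if (length(object@sfreq) != 1L || object@sfreq <= 0)
    msg <- c(msg, "sfreq must be a single positive number")
  if (length(object@chNames) != nrow(object@data))
    msg <- c(msg, "chNames length must equal number of channels")
  if (length(object@excluded) != nrow(object@data))
    msg <- c(msg, "excluded length must equal number of channels")
  if (length(msg)) msg else TRUE
})

#' Construct a ContinuousRecording
#'
#' @param data channels x samples numeric matrix (microvolts).
#' @param sfreq sampling frequency (Hz).
#' @param chNames channel names; defaults to `ch01`, `ch02`, ...
#' @param excluded logical exclusion flags per channel.
#' @return A [ContinuousRecording-class] object.
#' @export
ContinuousRecording <- function(data, sfreq, chNames = NULL, excluded = NULL) {
  data <- as.matrix(data)
  if (is.null(chNames))
    chNames <- sprintf("ch%02d", seq_len(nrow(data)))
  if (is.null(excluded)) excluded <- rep(FALSE, nrow(data))
  new("ContinuousRecording", data = data, sfreq = sfreq,
      chNames = as.character(chNames), excluded = as.logical(excluded))
}

#' Baseline-normalized broadband-gamma epochs
#'
#' Percent-change broadband gamma activity (BGA) for one patient:
#' a trials x electrodes x time array with the time axis in seconds
#' relative to word onset, per-trial covariates and an electrode table.
#'
#' @slot bga numeric array, trials x electrodes x time (percent change).
#' @slot times numeric time axis (s, relative to word onset).
#' @slot trials data.frame of per-trial covariates (word, class, response,
#'   rt_s, correct, length, zipf, ...).
#' @slot electrodes data.frame with one row per electrode (name, patient,
#'   x, y, z, roi).
#' @slot baseline the baseline window (s) the epochs were normalized to.
#'
#' @exportClass EnvelopeEpochs
setClass("EnvelopeEpochs",
  representation(bga = "array", times = "numeric", trials = "data.frame",
                 electrodes = "data.frame", baseline = "numeric"))

setValidity("EnvelopeEpochs", function(object) {
  msg <- character()
  d <- dim(object@bga)
  if (length(d) != 3L) msg <- c(msg, "bga must be a 3-d array")
  else {
    if (d[1] != nrow(object@trials))
      msg <- c(msg, "trials table must have one row per trial")
    if (d[2] != nrow(object@electrodes))
      msg <- c(msg, "electrodes table must have one row per electrode")
    if (d[3] != length(object@times))
      msg <- c(msg, "times length must equal third array dimension")
  }
  if (!all(c("name", "patient", "roi") %in% names(object@electrodes)))
    msg <- c(msg, "electrodes needs columns name, patient, roi")
  if (!"class" %in% names(object@trials))
    msg <- c(msg, "trials needs a class column")
  if (length(msg)) msg else TRUE
})

#' Construct an EnvelopeEpochs object
#'
#' @param bga trials x electrodes x time array of percent-change BGA.
#' @param times time axis in seconds relative to word onset.
#' @param trials per-trial covariate data.frame.
#' @param electrodes electrode table (name, patient, x, y, z, roi).
#' @param baseline baseline window (s) used for normalization.
#' @return An [EnvelopeEpochs-class] object.
#' @export
EnvelopeEpochs <- function(bga, times, trials, electrodes,
                           baseline = c(-0.5, -0.1)) {
  new("EnvelopeEpochs", bga = bga, times = as.numeric(times),
      trials = as.data.frame(trials), electrodes = as.data.frame(electrodes),
      baseline = as.numeric(baseline))
}

#' Triangle surface mesh
#'
#' A triangulated surface (vertices in mm, faces as 1-based vertex index
#' triples) together with its edge graph, used as the substrate for
#' geodesic recording zones and cluster statistics.
#'
#' @slot vertices N x 3 numeric matrix (mm).
#' @slot faces M x 3 integer matrix of vertex indices.
#' @slot graph igraph edge graph with Euclidean edge lengths (weight
#'   attribute).
#'
#' @exportClass SurfaceMesh
setClass("SurfaceMesh",
  representation(vertices = "matrix", faces = "matrix", graph = "ANY"))

setValidity("SurfaceMesh", function(object) {
  msg <- character()
  if (ncol(object@vertices) != 3L) msg <- c(msg, "vertices must be N x 3")
  if (ncol(object@faces) != 3L) msg <- c(msg, "faces must be M x 3")
  if (nrow(object@faces)) {
    if (max(object@faces) > nrow(object@vertices) || min(object@faces) < 1L)
      msg <- c(msg, "face indices out of range")
    # manifold-ish: each undirected face edge shared by at most 2 faces
    e <- rbind(object@faces[, c(1, 2)], object@faces[, c(2, 3)],
               object@faces[, c(3, 1)])
    key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    if (any(table(key) > 2L))
      msg <- c(msg, "non-manifold edge (shared by > 2 faces)")
    len <- sqrt(rowSums((object@vertices[e[, 1], , drop = FALSE] -
                         object@vertices[e[, 2], , drop = FALSE])^2))
    if (any(len <= 0)) msg <- c(msg, "degenerate zero-length edge")
  }
  if (length(msg)) msg else TRUE
})

#' Multivariate autoregressive model fit
#'
#' Least-squares MVAR fit of windowed envelope series: one node x node
#' coefficient matrix per lag, the residual noise covariance, and a
#' stability flag (companion-matrix spectral radius < 1).
#'
#' @slot A numeric array, nodes x nodes x order; `A[i, j, r]` is the
#'   influence of node j at lag r on node i.
#' @slot sigma residual covariance matrix.
#' @slot nobs number of regression observations.
#' @slot stable logical, spectral radius of the companion matrix < 1.
#'
#' @exportClass MVARModel
setClass("MVARModel",
  representation(A = "array", sigma = "matrix", nobs = "numeric",
                 stable = "logical"))

#' Partial directed coherence spectrum
#'
#' Directed coherence from node j to node i over normalized frequencies
#' in (0, 0.5], column-normalized per source so that
#' `sum_i pi[i, j, f]^2 == 1` at every frequency.
#'
#' @slot pi numeric array nodes x nodes x frequencies; `pi[i, j, f]` is
#'   the influence j -> i at frequency f.
#' @slot freqs normalized frequency grid in (0, 0.5].
#' @slot bandMean nodes x nodes matrix of frequency-averaged PDC.
#'
#' @exportClass PDCSpectrum
setClass("PDCSpectrum",
  representation(pi = "array", freqs = "numeric", bandMean = "matrix"))

#' Per-vertex statistic map from the surface-based LME
#'
#' @slot beta per-vertex concreteness effect (percent BGA per contrast unit).
#' @slot tstat per-vertex t statistic.
#' @slot coverage number of contributing patients per vertex.
#' @slot minPatients coverage threshold used; vertices below it are NA.
#'
#' @exportClass VertexStatMap
setClass("VertexStatMap",
  representation(beta = "numeric", tstat = "numeric", coverage = "numeric",
                 minPatients = "numeric"))

#' Suprathreshold cluster set with Monte Carlo FWE correction
#'
#' @slot clusters list of clusters, each `list(vertices, extent, peakT, p)`.
#' @slot nullMaxExtent null distribution of maximum cluster extents.
#' @slot alpha corrected alpha level.
#' @slot tThresh the vertex-level t threshold used.
#'
#' @exportClass ClusterSet
setClass("ClusterSet",
  representation(clusters = "list", nullMaxExtent = "numeric",
                 alpha = "numeric", tThresh = "numeric"))
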