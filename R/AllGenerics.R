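#' @rdname ContinuousRecording-class
#' @param object,x a `ContinuousRecording`
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))

#' @rdname ContinuousRecording-class
#' @export
setMethod("samplingRate", "ContinuousRecording", function(object) object@sfreq)

#' @rdname ContinuousRecording-class
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))

#' @rdname ContinuousRecording-class
#' @export
setMethod("channelNames", "ContinuousRecording",
          function(object) object@chNames)

#' @rdname ContinuousRecording-class
#' @export
setGeneric("voltages", function(object) standardGeneric("voltages"))

#' @rdname ContinuousRecording-class
#' @export
setMethod("voltages", "ContinuousRecording", function(object) object@data)

#' @rdname ContinuousRecording-class
#' @export
setGeneric("excludedChannels",
           function(object) standardGeneric("excludedChannels"))

#' @rdname ContinuousRecording-class
#' @export
setMethod("excludedChannels", "ContinuousRecording",
          function(object) object@excluded)

setMethod("show", "ContinuousRecording", function(object) {
  cat("ContinuousRecording:", nrow(object@data), "channels x",
      ncol(object@data), "samples @", object@sfreq, "Hz\n")
  cat("  duration:", round(ncol(object@data) / object@sfreq, 2), "s;",
      sum(object@excluded), "channel(s) excluded\n")
})

#' @rdname EnvelopeEpochs-class
#' @param object,x an `EnvelopeEpochs`
#' @export
setGeneric("bga", function(object) standardGeneric("bga"))

#' @rdname EnvelopeEpochs-class
#' @export
setMethod("bga", "EnvelopeEpochs", function(object) object@bga)

#' @rdname EnvelopeEpochs-class
#' @export
setGeneric("epochTimes", function(object) standardGeneric("epochTimes"))

#' @rdname EnvelopeEpochs-class
#' @export
setMethod("epochTimes", "EnvelopeEpochs", function(object) object@times)

#' @rdname EnvelopeEpochs-class
#' @export
setGeneric("trialInfo", function(object) standardGeneric("trialInfo"))

#' @rdname EnvelopeEpochs-class
#' @export
setMethod("trialInfo", "EnvelopeEpochs", function(object) object@trials)

#' @rdname EnvelopeEpochs-class
#' @export
setGeneric("electrodeInfo", function(object) standardGeneric("electrodeInfo"))

#' @rdname EnvelopeEpochs-class
#' @export
setMethod("electrodeInfo", "EnvelopeEpochs",
          function(object) object@electrodes)

setMethod("show", "EnvelopeEpochs", function(object) {
  d <- dim(object@bga)
  cat("EnvelopeEpochs:", d[1], "trials x", d[2], "electrodes x", d[3],
      "time points\n")
  cat("  time axis: [", min(object@times), ",", max(object@times),
      "] s; baseline [", object@baseline[1], ",", object@baseline[2], "] s\n")
  cat("  patients:", paste(unique(object@electrodes$patient), collapse = ", "),
      "\n")
})

#' @rdname SurfaceMesh-class
#' @param object,x a `SurfaceMesh`
#' @export
setGeneric("meshVertices", function(object) standardGeneric("meshVertices"))

#' @rdname SurfaceMesh-class
#' @export
setMethod("meshVertices", "SurfaceMesh", function(object) object@vertices)

#' @rdname SurfaceMesh-class
#' @export
setGeneric("meshFaces", function(object) standardGeneric("meshFaces"))

#' @rdname SurfaceMesh-class
#' @export
setMethod("meshFaces", "SurfaceMesh", function(object) object@faces)

setMethod("show", "SurfaceMesh", function(object) {
  cat("SurfaceMesh:", nrow(object@vertices), "vertices,",
      nrow(object@faces), "faces\n")
})

#' @rdname MVARModel-class
#' @param object an `MVARModel`
#' @export
setGeneric("mvarCoefficients",
           function(object) standardGeneric("mvarCoefficients"))

#' @rdname MVARModel-class
#' @export
setMethod("mvarCoefficients", "MVARModel", function(object) object@A)

#' @rdname MVARModel-class
#' @export
setGeneric("isStable", function(object) standardGeneric("isStable"))

#' @rdname MVARModel-class
#' @export
setMethod("isStable", "MVARModel", function(object) object@stable)

setMethod("show", "MVARModel", function(object) {
  d <- dim(object@A)
  cat("MVARModel:", d[1], "nodes, order", d[3], ";", object@nobs,
      "observations;", if (object@stable) "stable" else "UNSTABLE", "\n")
})

#' @rdname PDCSpectrum-class
#' @param object a `PDCSpectrum`
#' @export
setGeneric("pdcBandMean", function(object) standardGeneric("pdcBandMean"))

#' @rdname PDCSpectrum-class
#' @export
setMethod("pdcBandMean", "PDCSpectrum", function(object) object@bandMean)

setMethod("show", "PDCSpectrum", function(object) {
  d <- dim(object@pi)
  cat("PDCSpectrum:", d[1], "nodes x", d[3], "frequencies in (0, 0.5]\n")
})

setMethod("show", "VertexStatMap", function(object) {
  ok <- !is.na(object@tstat)
  cat("VertexStatMap:", length(object@tstat), "vertices,", sum(ok),
      "with coverage >=", object@minPatients, "patients\n")
  if (any(ok))
    cat("  t range: [", round(min(object@tstat[ok]), 2), ",",
        round(max(object@tstat[ok]), 2), "]\n")
})

setMethod("show", "ClusterSet", function(object) {
  cat("ClusterSet:", length(object@clusters), "cluster(s), |t| >",
      object@tThresh, ", alpha =", object@alpha, "\n")
  for (cl in object@clusters)
    cat("  extent", cl$extent, " peak t", round(cl$peakT, 2),
        " corrected p", signif(cl$p, 3),
        if (cl$p <= object@alpha) " *" else "", "\n")
})
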