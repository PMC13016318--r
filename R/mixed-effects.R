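#' Subset an EnvelopeEpochs object by electrode
#'
#' @param ep an [EnvelopeEpochs-class].
#' @param which integer, logical or character (electrode name) index.
#' @return an [EnvelopeEpochs-class] restricted to those electrodes.
#' @export
selectElectrodes <- function(ep, which) {
  stopifnot(is(ep, "EnvelopeEpochs"))
  if (is.character(which)) which <- match(which, ep@electrodes$name)
  EnvelopeEpochs(ep@bga[, which, , drop = FALSE], ep@times,
                 ep@trials, ep@electrodes[which, , drop = FALSE],
                 ep@baseline)
}

asCohort <- function(x) {
  if (is(x, "EnvelopeEpochs")) list(x) else x
}

# concreteness contrast code: concrete = +1, abstract = -1.
# codeBy = "response" implements the rated-class analysis (midscale trials
# coded by the participant's judgement); trials without a usable code are
# dropped.
concCode <- function(trials, codeBy) {
  src <- trials[[codeBy]]
  ifelse(src == "concrete", 1, ifelse(src == "abstract", -1, NA))
}

# long design table at one time bin: one row per retained trial x electrode
binTable <- function(cohort, idx, codeBy) {
  out <- lapply(cohort, function(ep) {
    y <- apply(ep@bga[, , idx, drop = FALSE], c(1, 2), mean)
    tr <- ep@trials
    conc <- concCode(tr, codeBy)
    keep <- !is.na(conc)
    nel <- nrow(ep@electrodes)
    data.frame(
      bga = as.vector(y[keep, , drop = FALSE]),
      conc = rep(conc[keep], nel),
      length = rep(tr$length[keep], nel),
      zipf = rep(tr$zipf[keep], nel),
      patient = ep@electrodes$patient[1],
      electrode = rep(ep@electrodes$name, each = sum(keep)),
      stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, out)
  d$length <- d$length - mean(d$length)
  d$zipf <- d$zipf - mean(d$zipf)
  d
}

#' Timepoint-wise hierarchical mixed-effects contrast of BGA
#'
#' At each time bin, fits (REML)
#' `BGA ~ Concreteness + WordLength + WordFrequency + (1|Patient) +
#' (1|Patient:Electrode)` on the pooled trial x electrode observations
#' and returns the concreteness effect series. Concreteness is coded
#' concrete = +1 / abstract = -1, so positive beta means concrete >
#' abstract. P-values are Wald (normal approximation on the t statistic);
#' q-values are Benjamini-Hochberg across bins. Bins whose fit fails are
#' flagged and carried with p = 1 rather than halting the sweep.
#'
#' @param cohort an [EnvelopeEpochs-class] or list of them (one per
#'   patient).
#' @param bins time-bin centers in seconds (default: 10 ms bins spanning
#'   the epoch from -0.2 s).
#' @param binWidth bin width in seconds.
#' @param codeBy `"class"` for the stimulus class contrast or
#'   `"response"` for the rated-class (midscale) analysis.
#' @param fdrQ FDR level used for the significance mask (default 0.01).
#' @return data.frame (effect series) with columns `time`, `beta`, `se`,
#'   `tstat`, `p`, `q`, `nObs`, `singular`, `significant`.
#' @export
fitPointwiseLme <- function(cohort, bins = NULL, binWidth = 0.01,
                            codeBy = c("class", "response"),
                            fdrQ = 0.01) {
  codeBy <- match.arg(codeBy)
  cohort <- asCohort(cohort)
  pats <- unique(vapply(cohort, function(e) e@electrodes$patient[1], ""))
  if (length(pats) < 2L)
    stop("pointwise LME needs at least 2 patients")
  times <- cohort[[1]]@times
  if (is.null(bins))
    bins <- times[times >= -0.2]
  fit0 <- NULL
  res <- lapply(bins, function(b) {
    idx <- which(times >= b - binWidth / 2 - 1e-9 &
                 times <= b + binWidth / 2 + 1e-9)
    if (!length(idx)) stop("bin at ", b, " s is outside the epoch")
    d <- binTable(cohort, idx, codeBy)
    fit <- tryCatch(suppressMessages(suppressWarnings({
      if (is.null(fit0)) {
        fit0 <<- lme4::lmer(
          bga ~ conc + length + zipf + (1 | patient) +
            (1 | patient:electrode),
          data = d, REML = TRUE,
          control = lme4::lmerControl(calc.derivs = FALSE))
        fit0
      } else lme4::refit(fit0, newresp = d$bga)
    })), error = function(e) NULL)
    if (is.null(fit))
      return(data.frame(time = b, beta = NA_real_, se = NA_real_,
                        tstat = NA_real_, p = 1, nObs = nrow(d),
                        singular = TRUE))
    co <- summary(fit)$coefficients
    data.frame(time = b, beta = co["conc", "Estimate"],
               se = co["conc", "Std. Error"],
               tstat = co["conc", "t value"],
               p = 2 * pnorm(-abs(co["conc", "t value"])),
               nObs = nrow(d), singular = lme4::isSingular(fit))
  })
  out <- do.call(rbind, res)
  fdr <- bhFdr(out$p, fdrQ)
  out$q <- fdr$q
  out$significant <- fdr$reject
  out
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Standard step-up procedure: returns monotone adjusted q-values and the
#' rejection mask at level `q`.
#'
#' @param p vector of p-values in \eqn{[0, 1]}.
#' @param q FDR level.
#' @return list with `q` (adjusted values) and `reject` (logical mask).
#' @export
bhFdr <- function(p, q = 0.05) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  adj <- p.adjust(p, method = "BH")
  list(q = adj, reject = adj <= q)
}

#' Assign electrodes to regions of interest
#'
#' Membership by distance from the electrode to each ROI center in
#' standardized coordinates: Euclidean by default, or geodesic along a
#' mesh when one is supplied (electrode and center snapped to their
#' nearest vertices).
#'
#' @param electrodes electrode table with `x`, `y`, `z`.
#' @param centers ROI centers (data.frame `roi`, `x`, `y`, `z`).
#' @param radius inclusion radius in mm (default 10).
#' @param mesh optional [SurfaceMesh-class] for geodesic assignment.
#' @return character vector of ROI labels (NA when unassigned); ties go
#'   to the nearest center.
#' @export
assignRoi <- function(electrodes, centers = defaultRoiCenters(),
                      radius = 10, mesh = NULL) {
  exyz <- as.matrix(electrodes[, c("x", "y", "z")])
  cxyz <- as.matrix(centers[, c("x", "y", "z")])
  if (is.null(mesh)) {
    d <- sqrt(outer(rowSums(exyz^2), rep(1, nrow(cxyz))) +
              outer(rep(1, nrow(exyz)), rowSums(cxyz^2)) -
              2 * exyz %*% t(cxyz))
  } else {
    ev <- nearestVertex(mesh, exyz)
    cv <- nearestVertex(mesh, cxyz)
    d <- matrix(NA_real_, nrow(exyz), nrow(cxyz))
    for (j in seq_len(nrow(cxyz))) {
      dist <- geodesicDistances(mesh, cv[j])
      d[, j] <- dist[ev]
    }
  }
  best <- apply(d, 1, which.min)
  bestD <- d[cbind(seq_len(nrow(d)), best)]
  ifelse(bestD <= radius, centers$roi[best], NA_character_)
}

#' Per-ROI grouped traces and effect series
#'
#' For each ROI covered by at least two patients: class-mean BGA traces
#' (electrodes averaged within patient first, then across patients, with
#' between-patient SE) and the pointwise LME effect series restricted to
#' that ROI's electrodes.
#'
#' @param cohort an [EnvelopeEpochs-class] or list of them.
#' @param centers ROI centers.
#' @param radius assignment radius (mm).
#' @param mesh optional mesh for geodesic assignment.
#' @param responsive optional named logical vector (or list per patient)
#'   restricting electrodes to responsive ones.
#' @param bins,binWidth,codeBy,fdrQ passed to [fitPointwiseLme()].
#' @return named list per ROI with `trace` (time, class, mean, se),
#'   `effects` (effect series), `nElectrodes`, `nPatients`.
#' @export
roiContrast <- function(cohort, centers = defaultRoiCenters(), radius = 10,
                        mesh = NULL, responsive = NULL, bins = NULL,
                        binWidth = 0.01, codeBy = "class", fdrQ = 0.01) {
  cohort <- asCohort(cohort)
  labeled <- lapply(cohort, function(ep) {
    lab <- assignRoi(ep@electrodes, centers, radius, mesh)
    if (!is.null(responsive)) {
      r <- if (is.list(responsive)) responsive[[ep@electrodes$patient[1]]]
           else responsive[ep@electrodes$name]
      lab[!r] <- NA
    }
    lab
  })
  out <- list()
  for (roi in centers$roi) {
    sub <- list()
    for (i in seq_along(cohort)) {
      w <- which(!is.na(labeled[[i]]) & labeled[[i]] == roi)
      if (length(w)) sub[[length(sub) + 1]] <- selectElectrodes(cohort[[i]], w)
    }
    pats <- unique(vapply(sub, function(e) e@electrodes$patient[1], ""))
    if (length(pats) < 2L) {
      warning("ROI ", roi, " covered by < 2 patients; excluded")
      next
    }
    times <- sub[[1]]@times
    classes <- sort(unique(unlist(lapply(sub,
                                         function(e) e@trials$class))))
    trace <- do.call(rbind, lapply(classes, function(cl) {
      perPat <- vapply(sub, function(ep) {
        sel <- ep@trials$class == cl
        colMeans(apply(ep@bga[sel, , , drop = FALSE], c(1, 3), mean))
      }, numeric(length(times)))
      data.frame(time = times, class = cl, mean = rowMeans(perPat),
                 se = apply(perPat, 1, sd) / sqrt(ncol(perPat)))
    }))
    eff <- fitPointwiseLme(sub, bins = bins, binWidth = binWidth,
                           codeBy = codeBy, fdrQ = fdrQ)
    out[[roi]] <- list(trace = trace, effects = eff,
                       nElectrodes = sum(vapply(sub, function(e)
                         nrow(e@electrodes), 0L)),
                       nPatients = length(pats))
  }
  out
}
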