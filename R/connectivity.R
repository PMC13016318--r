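#' Divide a multichannel envelope segment into overlapping windows
#'
#' One value per node per window: the mean envelope inside each 100 ms
#' window, shifted by 50 ms (defaults). With segment duration T ms,
#' `nWindows = floor((T - length) / shift) + 1`.
#'
#' @param x nodes x samples numeric matrix (a single-trial envelope
#'   segment).
#' @param sfreq sampling rate of the segment (Hz).
#' @param lengthMs window length in ms (default 100).
#' @param shiftMs window shift in ms (default 50).
#' @return list with `values` (nodes x windows matrix) and `centers`
#'   (window centers in s relative to segment start).
#' @export
windowSeries <- function(x, sfreq, lengthMs = 100, shiftMs = 50) {
  if (is.null(dim(x))) x <- matrix(x, 1)
  dtMs <- 1000 / sfreq
  totalMs <- ncol(x) * dtMs
  if (totalMs < lengthMs)
    stop("segment of ", totalMs, " ms is shorter than one ", lengthMs,
         " ms window")
  nw <- floor((totalMs - lengthMs) / shiftMs) + 1
  startsMs <- (seq_len(nw) - 1) * shiftMs
  vals <- vapply(startsMs, function(s0) {
    idx <- which((seq_len(ncol(x)) - 1) * dtMs >= s0 - 1e-9 &
                 (seq_len(ncol(x)) - 1) * dtMs < s0 + lengthMs - 1e-9)
    rowMeans(x[, idx, drop = FALSE])
  }, numeric(nrow(x)))
  vals <- matrix(vals, nrow = nrow(x))
  list(values = vals, centers = (startsMs + lengthMs / 2) / 1000)
}

#' Least-squares MVAR fit of windowed envelope series
#'
#' Fits `z_t = c + A_1 z_{t-1} + ... + A_p z_{t-p} + e_t` by ordinary
#' least squares, pooling observations across trials with trial
#' boundaries respected (no lag ever crosses a trial).
#'
#' @param series a nodes x windows matrix, or a list of such matrices
#'   (one per trial).
#' @param order model order p (default 3, spanning 300 ms at the default
#'   100/50 ms windowing).
#' @return an [MVARModel-class]; unstable fits are flagged (not
#'   rejected).
#' @export
fitMvar <- function(series, order = 3) {
  if (!is.list(series)) series <- list(series)
  n <- nrow(series[[1]])
  Xs <- list(); Ys <- list()
  for (tr in series) {
    w <- ncol(tr)
    if (w <= order) next
    for (t in (order + 1):w) {
      Ys[[length(Ys) + 1]] <- tr[, t]
      Xs[[length(Xs) + 1]] <- c(1, as.vector(
        vapply(seq_len(order), function(r) tr[, t - r], numeric(n))))
    }
  }
  if (!length(Ys))
    stop("no usable observations: every trial is shorter than order + 1")
  Y <- do.call(rbind, Ys)
  X <- do.call(rbind, Xs)
  if (nrow(X) < ncol(X)) stop("rank-deficient MVAR design (too few windows)")
  if (nrow(X) < 10 * order * n)
    warning("fewer than 10 x order x nodes effective samples (",
            nrow(X), ")")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("rank-deficient MVAR design")
  B <- qr.coef(qrX, Y)                      # (1 + n*p) x n
  resid <- Y - X %*% B
  sigma <- crossprod(resid) / (nrow(X) - ncol(X))
  A <- array(NA_real_, c(n, n, order))
  for (r in seq_len(order))
    A[, , r] <- t(B[1 + (r - 1) * n + seq_len(n), , drop = FALSE])
  stable <- varSpectralRadius(A) < 1
  if (!stable) warning("fitted MVAR model is unstable")
  new("MVARModel", A = A, sigma = as.matrix(sigma), nobs = nrow(X),
      stable = stable)
}

#' Partial directed coherence of an MVAR model
#'
#' With `Abar(f) = I - sum_r A_r exp(-i 2 pi f r)`, the PDC from node j
#' to node i is `|Abar[i, j](f)| / sqrt(sum_k |Abar[k, j](f)|^2)`,
#' evaluated on `nFreqs` normalized frequencies in (0, 0.5]. The column
#' normalization `sum_i pi[i, j](f)^2 = 1` holds at every frequency.
#'
#' @param model an [MVARModel-class].
#' @param nFreqs number of frequency points (default 64).
#' @return a [PDCSpectrum-class].
#' @export
pdc <- function(model, nFreqs = 64) {
  A <- model@A
  if (any(!is.finite(A))) stop("model coefficients must be finite")
  n <- dim(A)[1]; p <- dim(A)[3]
  freqs <- seq_len(nFreqs) / (2 * nFreqs)
  piArr <- array(NA_real_, c(n, n, nFreqs))
  for (k in seq_len(nFreqs)) {
    Abar <- diag(n) + 0i
    for (r in seq_len(p))
      Abar <- Abar - A[, , r] * exp(-2i * pi * freqs[k] * r)
    cn <- sqrt(colSums(Mod(Abar)^2))
    if (any(cn == 0)) stop("degenerate model: all-zero column in Abar")
    piArr[, , k] <- sweep(Mod(Abar), 2, cn, "/")
  }
  new("PDCSpectrum", pi = piArr, freqs = freqs,
      bandMean = apply(piArr, c(1, 2), mean))
}

epochSfreq <- function(ep) 1 / median(diff(ep@times))

#' Pairwise cross-ROI PDC table
#'
#' For every pair of electrodes spanning two different ROIs within a
#' patient, fits a bivariate MVAR to the windowed gamma envelopes of the
#' chosen post-onset window (pooling trials of one condition) and records
#' the band-mean PDC in both directions.
#'
#' @param cohort an [EnvelopeEpochs-class] or list of them.
#' @param rois ROI labels to include (default: all non-"other" ROIs
#'   present).
#' @param timeWindow analysis window in seconds, half-open
#'   (early \eqn{[0.2, 0.5)} or late \eqn{[0.5, 0.8)}).
#' @param lengthMs,shiftMs windowing of the envelope (100 / 50 ms).
#' @param order MVAR order (default 3).
#' @param nFreqs PDC frequency grid size.
#' @param conditions trial classes contrasted (default concrete,
#'   abstract).
#' @return data.frame with columns `patient`, `epair`, `src`, `dst`,
#'   `condition`, `window`, `pdc`, `stable`.
#' @export
roiPairPdc <- function(cohort, rois = NULL, timeWindow = c(0.5, 0.8),
                       lengthMs = 100, shiftMs = 50, order = 3,
                       nFreqs = 64,
                       conditions = c("concrete", "abstract")) {
  cohort <- asCohort(cohort)
  sfreq <- epochSfreq(cohort[[1]])
  rows <- list()
  for (ep in cohort) {
    pid <- ep@electrodes$patient[1]
    el <- ep@electrodes
    myRois <- if (is.null(rois)) setdiff(unique(el$roi), "other") else rois
    idx <- which(ep@times >= timeWindow[1] - 1e-9 &
                 ep@times < timeWindow[2] - 1e-9)
    if (length(idx) * 1000 / sfreq < lengthMs)
      stop("time window shorter than one PDC window for patient ", pid)
    winLabel <- paste0(timeWindow[1] * 1000, "-", timeWindow[2] * 1000,
                       "ms")
    pairsRoi <- utils::combn(myRois, 2, simplify = FALSE)
    for (pr in pairsRoi) {
      e1s <- which(el$roi == pr[1]); e2s <- which(el$roi == pr[2])
      if (!length(e1s) || !length(e2s)) next
      for (e1 in e1s) for (e2 in e2s) {
        epair <- paste0(pid, ":", el$name[e1], "-", el$name[e2])
        for (cond in conditions) {
          tr <- which(ep@trials$class == cond)
          if (!length(tr)) next
          segs <- lapply(tr, function(t)
            windowSeries(ep@bga[t, c(e1, e2), idx, drop = TRUE],
                         sfreq, lengthMs, shiftMs)$values)
          fit <- suppressWarnings(fitMvar(segs, order))
          bm <- pdcBandMean(pdc(fit, nFreqs))
          rows[[length(rows) + 1]] <- data.frame(
            patient = pid, epair = epair,
            src = c(pr[1], pr[2]), dst = c(pr[2], pr[1]),
            condition = cond, window = winLabel,
            pdc = c(bm[2, 1], bm[1, 2]), stable = fit@stable,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, rows)
}

fitOrNull <- function(expr) tryCatch(suppressMessages(suppressWarnings(expr)),
                                     error = function(e) NULL)

#' Edge-level mixed-effects network from a pairwise PDC table
#'
#' For every ordered ROI pair covered by at least two patients, fits an
#' LME of band-mean PDC with a fixed effect of concreteness (+1 concrete,
#' -1 abstract) and random intercepts for patient and electrode pair
#' within patient. Two networks are returned: the overall (intercept)
#' network, whose edge significance is assessed as net directed flow
#' (forward minus reverse PDC within electrode pair, against zero --
#' raw PDC has a positive estimation floor, so presence is only
#' interpretable as directional asymmetry), and the concreteness-contrast
#' network (the concreteness beta). Both are BH-corrected across ordered
#' pairs.
#'
#' @param pdcTable output of [roiPairPdc()].
#' @param fdrQ FDR level (default 0.05).
#' @return list with `edges` (data.frame: src, dst, nPatients, meanPdc,
#'   netFlow, pNet, qNet, netPresent, betaConc, pConc, qConc, sigConc)
#'   and `centrality` (node in/out degree of the mean-PDC network).
#' @export
edgeLme <- function(pdcTable, fdrQ = 0.05) {
  tab <- pdcTable
  key <- paste(tab$src, tab$dst, sep = "->")
  out <- list()
  for (k in unique(key)) {
    d <- tab[key == k, , drop = FALSE]
    if (length(unique(d$patient)) < 2) {
      warning("edge ", k, " covered by < 2 patients; dropped")
      next
    }
    d$conc <- ifelse(d$condition == "concrete", 1, -1)
    # reverse direction rows for the same electrode pairs
    rev <- tab[tab$src == d$dst[1] & tab$dst == d$src[1], , drop = FALSE]
    m <- merge(d, rev[, c("epair", "condition", "pdc")],
               by = c("epair", "condition"), suffixes = c("", ".rev"))
    m$asym <- m$pdc - m$pdc.rev
    fitC <- fitOrNull(lme4::lmer(pdc ~ conc + (1 | patient) +
                                   (1 | patient:epair), data = d,
                                 REML = TRUE,
                                 control = lme4::lmerControl(
                                   calc.derivs = FALSE)))
    if (is.null(fitC)) {
      lmC <- stats::lm(pdc ~ conc, data = d)
      coC <- summary(lmC)$coefficients
    } else coC <- summary(fitC)$coefficients
    fitN <- fitOrNull(lme4::lmer(asym ~ 1 + (1 | patient), data = m,
                                 REML = TRUE,
                                 control = lme4::lmerControl(
                                   calc.derivs = FALSE)))
    if (is.null(fitN)) {
      coN <- summary(stats::lm(asym ~ 1, data = m))$coefficients
    } else coN <- summary(fitN)$coefficients
    out[[k]] <- data.frame(
      src = d$src[1], dst = d$dst[1],
      nPatients = length(unique(d$patient)),
      meanPdc = coC["(Intercept)", "Estimate"],
      netFlow = coN["(Intercept)", "Estimate"],
      pNet = 2 * pnorm(-abs(coN["(Intercept)", "t value"])),
      betaConc = coC["conc", "Estimate"],
      pConc = 2 * pnorm(-abs(coC["conc", "t value"])),
      stringsAsFactors = FALSE)
  }
  edges <- do.call(rbind, out)
  rownames(edges) <- NULL
  fdrN <- bhFdr(edges$pNet, fdrQ)
  fdrC <- bhFdr(edges$pConc, fdrQ)
  edges$qNet <- fdrN$q
  edges$netPresent <- fdrN$reject & edges$netFlow > 0
  edges$qConc <- fdrC$q
  edges$sigConc <- fdrC$reject
  list(edges = edges, centrality = networkCentrality(edges, "meanPdc"))
}

#' Weighted in/out-degree centrality of a directed ROI network
#'
#' @param edges data.frame with `src`, `dst` and a weight column.
#' @param weight name of the weight column (default `"meanPdc"`).
#' @return data.frame with `node`, `outdegree`, `indegree`.
#' @export
networkCentrality <- function(edges, weight = "meanPdc") {
  nodes <- sort(unique(c(edges$src, edges$dst)))
  w <- edges[[weight]]
  data.frame(
    node = nodes,
    outdegree = vapply(nodes, function(n) sum(w[edges$src == n]), 0),
    indegree = vapply(nodes, function(n) sum(w[edges$dst == n]), 0),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Bootstrap confidence intervals for network centrality
#'
#' Resamples observations with replacement within each inter-ROI
#' connection, rebuilds the edge-mean network, and recomputes weighted
#' in/out degrees; returns percentile CIs.
#'
#' @param pdcTable output of [roiPairPdc()].
#' @param nBoot bootstrap networks (default 500, minimum 50).
#' @param level CI level (default 0.95).
#' @param seed integer seed.
#' @return data.frame with `node`, `outdegree`, `outLo`, `outHi`,
#'   `indegree`, `inLo`, `inHi`.
#' @export
centralityBootstrap <- function(pdcTable, nBoot = 500, level = 0.95,
                                seed = NULL) {
  if (nBoot < 50) stop("nBoot must be at least 50")
  key <- paste(pdcTable$src, pdcTable$dst, sep = "->")
  if (any(table(key) < 2)) stop("every edge needs at least 2 observations")
  edgeMean <- function(tab) {
    agg <- aggregate(pdc ~ src + dst, data = tab, FUN = mean)
    names(agg)[3] <- "meanPdc"
    agg
  }
  obsEdges <- edgeMean(pdcTable)
  obs <- networkCentrality(obsEdges)
  withSeed(seed, {
    boots <- lapply(seq_len(nBoot), function(b) {
      res <- do.call(rbind, lapply(split(pdcTable, key), function(d)
        d[sample.int(nrow(d), replace = TRUE), , drop = FALSE]))
      networkCentrality(edgeMean(res))
    })
    a <- (1 - level) / 2
    outM <- vapply(boots, function(b)
      b$outdegree[match(obs$node, b$node)], numeric(nrow(obs)))
    inM <- vapply(boots, function(b)
      b$indegree[match(obs$node, b$node)], numeric(nrow(obs)))
    outM <- matrix(outM, nrow = nrow(obs))
    inM <- matrix(inM, nrow = nrow(obs))
    data.frame(node = obs$node,
               outdegree = obs$outdegree,
               outLo = apply(outM, 1, quantile, a),
               outHi = apply(outM, 1, quantile, 1 - a),
               indegree = obs$indegree,
               inLo = apply(inM, 1, quantile, a),
               inHi = apply(inM, 1, quantile, 1 - a),
               row.names = NULL, stringsAsFactors = FALSE)
  })
}
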