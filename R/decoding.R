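# stratified fold assignment: balanced class proportions per fold
stratifiedFolds <- function(y, nFolds) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(nFolds), length(idx))
  }
  fold
}

# linear SVM decision values on held-out rows; positive favors "concrete".
# Standardization statistics come from the training rows only.
svmDecisionValues <- function(Xtr, ytr, Xte, cost = 1) {
  mu <- colMeans(Xtr)
  sdv <- apply(Xtr, 2, sd)
  sdv[sdv == 0] <- 1
  Ztr <- sweep(sweep(Xtr, 2, mu), 2, sdv, "/")
  Zte <- sweep(sweep(Xte, 2, mu), 2, sdv, "/")
  yf <- factor(ytr, levels = c("concrete", "abstract"))
  fit <- e1071::svm(Ztr, yf, kernel = "linear", cost = cost,
                    scale = FALSE)
  dv <- attr(predict(fit, Zte, decision.values = TRUE),
             "decision.values")
  v <- as.numeric(dv[, 1])
  if (colnames(dv)[1] == "abstract/concrete") v <- -v
  v
}

# cross-validated AUC for one feature matrix
cvAuc <- function(X, y, nFolds = 10, cost = 1) {
  fold <- stratifiedFolds(y, nFolds)
  dv <- numeric(length(y))
  for (k in seq_len(nFolds)) {
    te <- fold == k
    dv[te] <- svmDecisionValues(X[!te, , drop = FALSE], y[!te],
                                X[te, , drop = FALSE], cost)
  }
  rankAuc(dv, y == "concrete")
}

# per-patient feature tensor: trials x electrodes at each requested bin
decodingFeatures <- function(ep, bins, binWidth, responsive = NULL) {
  keepEl <- if (is.null(responsive)) seq_len(nrow(ep@electrodes))
            else which(responsive[ep@electrodes$name])
  lapply(bins, function(b) {
    idx <- which(ep@times >= b - binWidth / 2 - 1e-9 &
                 ep@times <= b + binWidth / 2 + 1e-9)
    apply(ep@bga[, keepEl, idx, drop = FALSE], c(1, 2), mean)
  })
}

#' Sliding-window single-trial decoding of concreteness
#'
#' Trains a linear maximum-margin classifier (SVM, cost 1) per time bin
#' within each patient, with stratified k-fold cross-validation and
#' within-training-fold standardization, and scores held-out decision
#' values as the area under the ROC curve. Only concrete/abstract trials
#' are used.
#'
#' @param cohort an [EnvelopeEpochs-class] or list of them (per patient).
#' @param bins time-bin centers in seconds (default: every 20 ms from
#'   -0.2 to 1.0 s).
#' @param binWidth bin width (s).
#' @param nFolds cross-validation folds (default 10).
#' @param cost SVM regularization constant.
#' @param responsive optional named logical electrode mask.
#' @param labels trial column giving the class (default `"class"`).
#' @param seed integer seed (fold assignment).
#' @return list with `times`, `auc` (patients x bins matrix), `mean`
#'   (group-mean AUC per bin).
#' @export
slidingAuc <- function(cohort, bins = seq(-0.2, 1.0, by = 0.02),
                       binWidth = 0.02, nFolds = 10, cost = 1,
                       responsive = NULL, labels = "class", seed = NULL) {
  cohort <- asCohort(cohort)
  withSeed(seed, {
    aucs <- t(vapply(cohort, function(ep) {
      y <- ep@trials[[labels]]
      keep <- y %in% c("concrete", "abstract")
      y <- y[keep]
      if (min(table(y)) < nFolds)
        stop("each class needs at least nFolds (", nFolds, ") trials")
      feats <- decodingFeatures(selectTrials(ep, keep), bins, binWidth,
                                responsive)
      vapply(feats, cvAuc, 0, y = y, nFolds = nFolds, cost = cost)
    }, numeric(length(bins))))
    rownames(aucs) <- vapply(cohort, function(e) e@electrodes$patient[1], "")
    list(times = bins, auc = aucs, mean = colMeans(aucs))
  })
}

selectTrials <- function(ep, which) {
  EnvelopeEpochs(ep@bga[which, , , drop = FALSE], ep@times,
                 ep@trials[which, , drop = FALSE], ep@electrodes,
                 ep@baseline)
}

#' Permutation null for the sliding decoder
#'
#' Re-runs the sliding decoder with condition labels randomly shuffled
#' within each patient and returns the null AUC distribution per time bin
#' with its pointwise two-sided threshold (97.5th percentile by default).
#'
#' @param cohort as in [slidingAuc()].
#' @param nShuffles number of label shuffles (default 1000, minimum 100).
#' @param bins,binWidth,nFolds,cost,responsive,labels as in
#'   [slidingAuc()].
#' @param probs threshold percentile (default 0.975).
#' @param seed integer seed.
#' @return list with `times`, `null` (shuffles x bins matrix of
#'   group-mean AUC), `threshold` per bin, `mean`.
#' @export
permutationNull <- function(cohort, nShuffles = 1000,
                            bins = seq(-0.2, 1.0, by = 0.02),
                            binWidth = 0.02, nFolds = 10, cost = 1,
                            responsive = NULL, labels = "class",
                            probs = 0.975, seed = NULL) {
  if (nShuffles < 100) stop("nShuffles must be at least 100")
  cohort <- asCohort(cohort)
  withSeed(seed, {
    nullMat <- t(vapply(seq_len(nShuffles), function(s) {
      curves <- vapply(cohort, function(ep) {
        y <- ep@trials[[labels]]
        keep <- y %in% c("concrete", "abstract")
        y <- sample(y[keep])  # shuffle within patient
        feats <- decodingFeatures(selectTrials(ep, keep), bins, binWidth,
                                  responsive)
        vapply(feats, cvAuc, 0, y = y, nFolds = nFolds, cost = cost)
      }, numeric(length(bins)))
      rowMeans(matrix(curves, nrow = length(bins)))
    }, numeric(length(bins))))
    list(times = bins, null = nullMat,
         threshold = apply(nullMat, 2, quantile, probs = probs),
         mean = mean(nullMat))
  })
}

# single-window decoder with its own shuffle null: the patient gate for
# the midscale analysis
windowDecoderGate <- function(X, y, nFolds = 10, cost = 1,
                              nShuffles = 200, alpha = 0.05) {
  obs <- cvAuc(X, y, nFolds, cost)
  null <- vapply(seq_len(nShuffles), function(s)
    cvAuc(X, sample(y), nFolds, cost), 0)
  p <- (1 + sum(null >= obs)) / (1 + nShuffles)
  list(auc = obs, p = p, pass = p < alpha)
}

#' Support-vector-regression model comparison on midscale words
#'
#' Within each patient passing the decodability gate (window decoder
#' beating its shuffle null at p < `gateAlpha`), trains a linear SVR on
#' window-mean features of the concrete (target 5) and abstract
#' (target 1) trials, predicts the midscale trials, and scores the
#' predictions against two competing label sets: the response-based
#' model (5 if the patient rated the word concrete, 1 if abstract) and
#' the midscale model (constant 3). The paired MSEs are compared at the
#' group level with a Wilcoxon signed-rank test.
#'
#' @param cohort an [EnvelopeEpochs-class] or list of them.
#' @param window feature window in seconds (default 0.5-0.8 s).
#' @param nFolds,cost decoder settings.
#' @param gateShuffles,gateAlpha decodability-gate settings.
#' @param responsive optional electrode mask.
#' @param seed integer seed.
#' @return list with `perPatient` (data.frame: patient, gateAuc, gateP,
#'   mseResponse, mseMidscale, winner), `p` (group signed-rank),
#'   `direction`, and `lnBf10` (approximate default-prior paired Bayes
#'   factor, NA when fewer than 3 patients pass the gate).
#' @export
svrMidscaleComparison <- function(cohort, window = c(0.5, 0.8),
                                  nFolds = 10, cost = 1,
                                  gateShuffles = 200, gateAlpha = 0.05,
                                  responsive = NULL, seed = NULL) {
  cohort <- asCohort(cohort)
  withSeed(seed, {
    rows <- list()
    for (ep in cohort) {
      pid <- ep@electrodes$patient[1]
      idx <- windowIndex(ep@times, window)
      keepEl <- if (is.null(responsive)) seq_len(nrow(ep@electrodes))
                else which(responsive[ep@electrodes$name])
      X <- apply(ep@bga[, keepEl, idx, drop = FALSE], c(1, 2), mean)
      cls <- ep@trials$class
      isMid <- cls == "midscale"
      if (!any(isMid)) stop("no midscale trials for patient ", pid)
      train <- cls %in% c("concrete", "abstract")
      gate <- windowDecoderGate(X[train, , drop = FALSE], cls[train],
                                nFolds, cost, gateShuffles, gateAlpha)
      row <- data.frame(patient = pid, gateAuc = gate$auc,
                        gateP = gate$p, mseResponse = NA_real_,
                        mseMidscale = NA_real_, winner = NA_character_,
                        stringsAsFactors = FALSE)
      if (gate$pass) {
        mu <- colMeans(X[train, , drop = FALSE])
        sdv <- apply(X[train, , drop = FALSE], 2, sd)
        sdv[sdv == 0] <- 1
        Ztr <- sweep(sweep(X[train, , drop = FALSE], 2, mu), 2, sdv, "/")
        Zmid <- sweep(sweep(X[isMid, , drop = FALSE], 2, mu), 2, sdv, "/")
        target <- ifelse(cls[train] == "concrete", 5, 1)
        fit <- e1071::svm(Ztr, target, type = "eps-regression",
                          kernel = "linear", cost = cost, scale = FALSE)
        pred <- as.numeric(predict(fit, Zmid))
        if (sd(pred) < 1e-10)
          warning("degenerate constant SVR predictions for patient ", pid)
        rated <- ifelse(ep@trials$response[isMid] == "concrete", 5, 1)
        row$mseResponse <- mean((pred - rated)^2)
        row$mseMidscale <- mean((pred - 3)^2)
        row$winner <- ifelse(row$mseMidscale < row$mseResponse,
                             "midscale", "response")
      }
      rows[[pid]] <- row
    }
    perPatient <- do.call(rbind, rows)
    passed <- perPatient[!is.na(perPatient$mseResponse), , drop = FALSE]
    grp <- if (nrow(passed) >= 5)
      groupSignrank(passed$mseMidscale, passed$mseResponse)
    else list(p = NA_real_, direction = NA_character_)
    lnBf <- if (nrow(passed) >= 3)
      pairedLnBf10(passed$mseMidscale - passed$mseResponse)
    else NA_real_
    list(perPatient = perPatient, p = grp$p, direction = grp$direction,
         lnBf10 = lnBf)
  })
}

#' Group-level Wilcoxon signed-rank test on paired values
#'
#' Exact two-sided signed-rank p for small samples without ties; a
#' tie-corrected normal approximation (no continuity correction)
#' otherwise. All-zero differences give p = 1.
#'
#' @param x,y paired per-patient values (at least 5 pairs).
#' @return list with `p`, `direction` (`"x<y"`, `"x>y"` or `"none"`),
#'   `statistic` (V) and `n` (non-zero pairs).
#' @export
groupSignrank <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired")
  if (length(x) < 5) stop("signed-rank test needs at least 5 pairs")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    return(list(p = 1, direction = "none", statistic = NA_real_, n = 0L))
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  hasTies <- any(duplicated(abs(d)))
  if (!hasTies && n <= 50) {
    p <- suppressWarnings(
      wilcox.test(d, exact = TRUE)$p.value)
  } else {
    mu <- n * (n + 1) / 4
    tie <- table(r)
    sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24 -
                  sum(tie^3 - tie) / 48)
    p <- if (sigma == 0) 1 else min(1, 2 * pnorm(-abs(V - mu) / sigma))
  }
  dir <- if (mean(d) < 0) "x<y" else if (mean(d) > 0) "x>y" else "none"
  list(p = p, direction = dir, statistic = V, n = n)
}

#' Approximate default-prior paired Bayes factor (ln BF10)
#'
#' Jeffreys-Zellner-Siow Bayes factor for a paired comparison (Cauchy
#' prior on the standardized effect, scale r = sqrt(2)/2), computed by
#' numerical integration from the paired t statistic. Provided as an
#' approximate companion to the signed-rank test, not as a Bayesian
#' analysis of the ranks themselves.
#'
#' @param d vector of paired differences.
#' @param rscale Cauchy prior scale (default sqrt(2)/2).
#' @return natural log of BF10.
#' @export
pairedLnBf10 <- function(d, rscale = sqrt(2) / 2) {
  n <- length(d)
  if (n < 2 || sd(d) == 0) return(NA_real_)
  t <- mean(d) / (sd(d) / sqrt(n))
  nu <- n - 1
  h0 <- (1 + t^2 / nu)^(-(nu + 1) / 2)
  integrand <- function(g) {
    (1 + n * g * rscale^2)^(-1 / 2) *
      (1 + t^2 / ((1 + n * g * rscale^2) * nu))^(-(nu + 1) / 2) *
      (2 * pi)^(-1 / 2) * g^(-3 / 2) * exp(-1 / (2 * g))
  }
  h1 <- integrate(integrand, 0, Inf, rel.tol = 1e-8)$value
  log(h1 / h0)
}
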