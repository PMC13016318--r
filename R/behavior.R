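#' Confusion table of concreteness judgements
#'
#' Counts scored concrete/abstract trials: `tp` concrete judged concrete,
#' `fn` concrete judged abstract, `fp` abstract judged concrete, `tn`
#' abstract judged abstract. Midscale and unanswered trials are excluded
#' (midscale words have no correct answer).
#'
#' @param trials data.frame with `class` and `response`.
#' @return named numeric vector `c(tp, fn, fp, tn)`.
#' @export
confusionTable <- function(trials) {
  t0 <- trials[trials$class %in% c("concrete", "abstract") &
                 !is.na(trials$response), , drop = FALSE]
  c(tp = sum(t0$class == "concrete" & t0$response == "concrete"),
    fn = sum(t0$class == "concrete" & t0$response == "abstract"),
    fp = sum(t0$class == "abstract" & t0$response == "concrete"),
    tn = sum(t0$class == "abstract" & t0$response == "abstract"))
}

#' Log diagnostic odds ratio with Wald confidence interval
#'
#' `ln((tp * tn) / (fp * fn))` with the Haldane correction (0.5 added to
#' every cell) applied if and only if any cell is zero. The Wald SE is
#' `sqrt(1/a + 1/b + 1/c + 1/d)` on the (possibly corrected) cells; the
#' judgement is called significantly above chance when the 95% CI
#' excludes 0.
#'
#' @param table confusion table: named vector or list with `tp`, `fn`,
#'   `fp`, `tn` (or a data.frame of trials, which is tabulated first).
#' @return list with `lnDor`, `se`, `ci95`, `significant`, `corrected`.
#' @export
lnDor <- function(table) {
  if (is.data.frame(table)) table <- confusionTable(table)
  cells <- as.numeric(table[c("tp", "fn", "fp", "tn")])
  if (any(is.na(cells) | cells < 0))
    stop("confusion table needs non-negative tp, fn, fp, tn")
  if (all(cells == 0)) stop("all-zero confusion table")
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  est <- log((cells[1] * cells[4]) / (cells[3] * cells[2]))
  se <- sqrt(sum(1 / cells))
  ci <- est + c(-1, 1) * qnorm(0.975) * se
  list(lnDor = est, se = se, ci95 = ci,
       significant = ci[1] > 0 | ci[2] < 0, corrected = corrected)
}

#' Behavioral summary per patient and cohort
#'
#' Accuracy per class (over responded trials), mean RT per class,
#' response rate, the fraction of midscale words rated abstract, and the
#' per-patient ln(DOR), with cohort mean and SD of each.
#'
#' @param trials data.frame with `patient`, `class`, `response`, `rt_s`
#'   (`correct` is derived from class and response).
#' @return list with `perPatient` (data.frame) and `cohort` (mean and SD
#'   of each summary).
#' @export
summarizeBehavior <- function(trials) {
  if (!"patient" %in% names(trials)) trials$patient <- "sub-01"
  per <- lapply(split(trials, trials$patient), function(d) {
    resp <- !is.na(d$response)
    acc <- function(cl) {
      sel <- d$class == cl & resp
      if (!any(sel)) return(NA_real_)
      100 * mean(d$response[sel] == cl)
    }
    rt <- function(cl) {
      sel <- d$class == cl & resp
      if (!any(sel)) return(NA_real_)
      1000 * mean(d$rt_s[sel])
    }
    midSel <- d$class == "midscale" & resp
    ld <- tryCatch(lnDor(d)$lnDor, error = function(e) NA_real_)
    data.frame(patient = d$patient[1],
               accConcrete = acc("concrete"), accAbstract = acc("abstract"),
               rtConcrete = rt("concrete"), rtAbstract = rt("abstract"),
               rtMidscale = rt("midscale"),
               responseRate = 100 * mean(resp),
               midscaleAbstract = if (any(midSel))
                 100 * mean(d$response[midSel] == "abstract") else NA_real_,
               lnDor = ld, stringsAsFactors = FALSE)
  })
  perPatient <- do.call(rbind, per)
  rownames(perPatient) <- NULL
  num <- perPatient[, -1, drop = FALSE]
  cohort <- data.frame(measure = names(num),
                       mean = vapply(num, mean, 0, na.rm = TRUE),
                       sd = vapply(num, sd, 0, na.rm = TRUE),
                       row.names = NULL, stringsAsFactors = FALSE)
  list(perPatient = perPatient, cohort = cohort)
}

#' Binomial GLMM for stimulation-session accuracy
#'
#' Logistic mixed model of judgement correctness on stimulation state,
#' word class and their interaction, with a random intercept per session
#' (sessions nested in patients): `correct ~ stim * class +
#' (1 | session)`. Class is coded concrete = +1/2 / abstract = -1/2 and
#' stimulation on = 1 / off = 0. Coefficients are reported on the logit
#' scale with Wald z statistics and 95% CIs (beta +/- 1.96 se).
#'
#' @param trials data.frame with `patient`, `session`, `class`, `stim`,
#'   `correct`.
#' @return list with `coefficients` (data.frame: term, beta, se, z, p,
#'   ciLo, ciHi), `nObs`, `df` (residual), and `separation` flag.
#' @export
fitStimulationGlmm <- function(trials) {
  if (!all(c("session", "class", "stim", "correct") %in% names(trials)))
    stop("trials must have columns session, class, stim, correct")
  if (length(unique(trials$stim)) < 2)
    stop("both stimulation states must be present")
  if (all(trials$correct) || !any(trials$correct))
    stop("complete separation: all trials ",
         if (all(trials$correct)) "correct" else "incorrect",
         "; no estimate possible")
  d <- trials
  d$conc <- ifelse(d$class == "concrete", 0.5, -0.5)
  d$sessionId <- paste0(d$patient, ":", d$session)
  nSessions <- length(unique(d$sessionId))
  if (nSessions >= 2) {
    fit <- fitOrNull(lme4::glmer(correct ~ stim * conc + (1 | sessionId),
                                 data = d, family = stats::binomial))
  } else fit <- NULL
  if (is.null(fit)) {
    if (nSessions >= 2)
      warning("GLMM failed; falling back to plain logistic regression")
    else
      warning("single session: plain logistic regression without ",
              "random effects")
    fit <- stats::glm(correct ~ stim * conc, data = d,
                      family = stats::binomial)
    co <- summary(fit)$coefficients
    zcol <- "z value"
  } else {
    co <- summary(fit)$coefficients
    zcol <- "z value"
  }
  terms <- rownames(co)
  res <- data.frame(term = terms, beta = co[, "Estimate"],
                    se = co[, "Std. Error"], z = co[, zcol],
                    p = co[, ncol(co)],
                    ciLo = co[, "Estimate"] - 1.96 * co[, "Std. Error"],
                    ciHi = co[, "Estimate"] + 1.96 * co[, "Std. Error"],
                    row.names = NULL, stringsAsFactors = FALSE)
  sep <- any(abs(res$beta) > 10)
  if (sep) warning("coefficients suggest quasi-separation")
  list(coefficients = res, nObs = nrow(d),
       df = nrow(d) - nrow(res), separation = sep)
}
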