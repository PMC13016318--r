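#' Simulate concreteness-judgement responses and reaction times
#'
#' Concrete and abstract trials are judged with a sensitivity fixed by the
#' true log diagnostic odds ratio: responses are drawn with
#' `logit(P(judge concrete | concrete)) = bias + lnDor/2` and
#' `logit(P(judge concrete | abstract)) = bias - lnDor/2`, so the expected
#' ln(DOR) of the resulting confusion table equals `trueLnDor` and `bias`
#' shifts both rates without changing sensitivity. Midscale trials are
#' judged abstract with probability `abstractBiasMid`. Reaction times are
#' lognormal with class-specific location. A fraction `1 - respondP` of
#' trials receive no response (NA).
#'
#' @param lexicon data.frame with at least `class` (one row per trial).
#' @param trueLnDor true log diagnostic odds ratio (finite).
#' @param bias response bias on the logit scale (0 = symmetric).
#' @param rtParams list with `meanlog` (named per class, seconds) and
#'   `sdlog`.
#' @param abstractBiasMid probability a midscale word is rated abstract.
#' @param respondP probability a trial receives any response.
#' @param seed integer seed.
#' @return data.frame with `class`, `response`, `rt_s`, `correct`
#'   (NA for midscale and non-responses).
#' @export
simulateBehavior <- function(lexicon, trueLnDor = 2.2, bias = -0.25,
                             rtParams = list(
                               meanlog = c(concrete = log(0.932),
                                           abstract = log(0.986),
                                           midscale = log(0.989)),
                               sdlog = 0.2),
                             abstractBiasMid = 0.65, respondP = 0.98,
                             seed = NULL) {
  if (!is.finite(trueLnDor)) stop("`trueLnDor` must be finite")
  if (abstractBiasMid < 0 || abstractBiasMid > 1)
    stop("`abstractBiasMid` must be a probability in [0, 1]")
  if (respondP < 0 || respondP > 1)
    stop("`respondP` must be a probability in [0, 1]")
  withSeed(seed, {
    n <- nrow(lexicon)
    cls <- lexicon$class
    pConc <- ifelse(cls == "concrete", plogis(bias + trueLnDor / 2),
             ifelse(cls == "abstract", plogis(bias - trueLnDor / 2),
                    1 - abstractBiasMid))
    response <- ifelse(runif(n) < pConc, "concrete", "abstract")
    rt <- rlnorm(n, rtParams$meanlog[cls], rtParams$sdlog)
    noResp <- runif(n) >= respondP
    response[noResp] <- NA_character_
    rt[noResp] <- NA_real_
    correct <- ifelse(cls == "midscale" | is.na(response), NA,
                      response == cls)
    data.frame(class = cls, response = response, rt_s = rt,
               correct = correct, stringsAsFactors = FALSE)
  })
}

#' Simulate a stimulation-mapping trial table
#'
#' Generates per-session concreteness-judgement accuracy data under
#' chronometric stimulation: previously-correct concrete/abstract words,
#' each trial stimulated with probability 1/2, with correctness drawn from
#' a logistic model with a session random intercept:
#' `logit(P(correct)) = intercept + betaStim*stim + betaClass*conc +
#' betaInteraction*stim*conc + u_session`.
#' Class is coded concrete = +1/2, abstract = -1/2 and stimulation
#' on = 1 / off = 0, matching the GLMM fitted by
#' [fitStimulationGlmm()].
#'
#' @param nSessions number of stimulation sessions (sites).
#' @param trialsPerSession trials per session.
#' @param betaStim stimulation main effect on the log-odds of a correct
#'   judgement (negative = disruption).
#' @param betaClass,betaInteraction class main effect and
#'   stimulation-by-class interaction (log-odds).
#' @param intercept baseline log-odds of correct (stimulation off).
#' @param sessionSd SD of the session random intercept.
#' @param nPatients sessions are split round-robin over this many patients.
#' @param seed integer seed.
#' @return data.frame with `patient`, `session`, `site`, `class`, `stim`,
#'   `correct`.
#' @export
simulateStimTrials <- function(nSessions = 8, trialsPerSession = 100,
                               betaStim = -0.81, betaClass = 0,
                               betaInteraction = 0, intercept = 2.0,
                               sessionSd = 0.3, nPatients = 4,
                               seed = NULL) {
  withSeed(seed, {
    out <- lapply(seq_len(nSessions), function(s) {
      u <- rnorm(1, 0, sessionSd)
      n <- trialsPerSession
      cls <- sample(rep(c("concrete", "abstract"), length.out = n))
      conc <- ifelse(cls == "concrete", 0.5, -0.5)
      stim <- as.integer(runif(n) < 0.5)
      eta <- intercept + betaStim * stim + betaClass * conc +
        betaInteraction * stim * conc + u
      data.frame(patient = sprintf("sub-%02d", (s - 1) %% nPatients + 1),
                 session = sprintf("ses-%02d", s),
                 site = sprintf("site-%02d", s),
                 class = cls, stim = stim,
                 correct = runif(n) < plogis(eta),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}
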