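#' Default class-conditional lexicon calibration
#'
#' Class-wise moments of the word-stimulus covariates used to calibrate
#' [generateLexicon()]: mean and inter-rater SD of the 1-5 Likert
#' concreteness rating per class, plus pooled (class-matched) moments for
#' word length in letters, Zipf frequency and syllable count.
#'
#' @return Nested list with one entry per class (`concrete`, `abstract`,
#'   `midscale`), each holding `concreteness = c(mean, sd)` and
#'   `concretenessSd = c(mean, sd)`, plus `covariates` with pooled
#'   `length`, `zipf` and `syllables` moments.
#' @export
defaultLexiconCalibration <- function() {
  list(
    concrete = list(concreteness = c(mean = 4.55, sd = 0.17),
                    concretenessSd = c(mean = 0.81, sd = 0.12)),
    abstract = list(concreteness = c(mean = 1.61, sd = 0.15),
                    concretenessSd = c(mean = 0.85, sd = 0.11)),
    midscale = list(concreteness = c(mean = 3.02, sd = 0.26),
                    concretenessSd = c(mean = 1.51, sd = 0.77)),
    covariates = list(length = c(mean = 7.6, sd = 1.9),
                      zipf = c(mean = 3.5, sd = 0.65),
                      syllables = c(mean = 2.5, sd = 0.87)))
}

rtrunc <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  x <- rnorm(n, mean, sd)
  while (any(bad <- (x < lo | x > hi)))
    x[bad] <- rnorm(sum(bad), mean, sd)
  x
}

#' Generate a synthetic stimulus lexicon
#'
#' Draws a word list with the class structure of a concreteness-judgement
#' stimulus set: three classes (concrete, abstract, midscale) whose
#' concreteness ratings follow the calibrated class moments -- concrete
#' high on the 1-5 scale, abstract low, midscale in between with a
#' markedly larger inter-rater SD -- while word length, Zipf frequency and
#' syllable count are drawn from pooled distributions independent of
#' class (i.e. matched covariates).
#'
#' @param nPerClass words per class (default 80).
#' @param calib calibration list as returned by
#'   [defaultLexiconCalibration()].
#' @param seed integer seed; the lexicon is a pure function of
#'   `(nPerClass, calib, seed)`.
#' @return data.frame with columns `word`, `class`, `concreteness_mean`,
#'   `concreteness_sd`, `length`, `zipf`, `syllables`.
#' @examples
#' lex <- generateLexicon(10, seed = 1)
#' table(lex$class)
#' @export
generateLexicon <- function(nPerClass = 80,
                            calib = defaultLexiconCalibration(),
                            seed = NULL) {
  if (!is.numeric(nPerClass) || nPerClass < 1)
    stop("`nPerClass` must be a positive count")
  nPerClass <- as.integer(nPerClass)
  classes <- c("concrete", "abstract", "midscale")
  if (!all(classes %in% names(calib)))
    stop("`calib` must supply entries for: ",
         paste(setdiff(classes, names(calib)), collapse = ", "))
  cov <- calib$covariates
  withSeed(seed, {
    out <- lapply(classes, function(cl) {
      cc <- calib[[cl]]
      len <- pmax(3L, as.integer(round(rtrunc(nPerClass, cov$length["mean"],
                                              cov$length["sd"], lo = 2.5))))
      data.frame(
        word = vapply(len, function(k)
          paste(sample(letters, k, replace = TRUE), collapse = ""), ""),
        class = cl,
        concreteness_mean = rtrunc(nPerClass, cc$concreteness["mean"],
                                   cc$concreteness["sd"], lo = 1, hi = 5),
        concreteness_sd = rtrunc(nPerClass, cc$concretenessSd["mean"],
                                 cc$concretenessSd["sd"], lo = 0.05),
        length = len,
        zipf = rtrunc(nPerClass, cov$zipf["mean"], cov$zipf["sd"], lo = 1),
        syllables = pmax(1L, as.integer(round(
          rtrunc(nPerClass, cov$syllables["mean"], cov$syllables["sd"],
                 lo = 0.5)))),
        stringsAsFactors = FALSE)
    })
    lex <- do.call(rbind, out)
    # disambiguate the rare duplicate letter string
    dup <- duplicated(lex$word)
    if (any(dup)) lex$word[dup] <- paste0(lex$word[dup], seq_len(sum(dup)))
    rownames(lex) <- NULL
    validateLexicon(lex)
    lex
  })
}

# class ordering and midscale-disagreement invariants
validateLexicon <- function(lex) {
  m <- tapply(lex$concreteness_mean, lex$class, mean)
  s <- tapply(lex$concreteness_sd, lex$class, mean)
  if (!(m["concrete"] > m["midscale"] && m["midscale"] > m["abstract"]))
    stop("lexicon violates class-mean ordering concrete > midscale > abstract")
  if (!(s["midscale"] > s["concrete"] && s["midscale"] > s["abstract"]))
    stop("lexicon violates midscale inter-rater disagreement invariant")
  invisible(lex)
}
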