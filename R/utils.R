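#' @import methods
#' @importFrom stats rnorm runif rbinom rlnorm qnorm pnorm sd var cor
#'   quantile median complete.cases setNames aggregate dnorm plogis qlogis
#'   fft p.adjust wilcox.test coef predict dgamma integrate
#' @importFrom utils head tail
NULL

# Evaluate expr with a locally seeded RNG, restoring the caller's RNG state.
# Every generator in the package routes its randomness through this so that
# (config, seed) fully determines the output.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
      stop("`seed` must be a single finite number")
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed) %% .Machine$integer.max)
  }
  force(expr)
}

# Derive a stream-specific child seed so independent generators fed from one
# master seed do not share RNG streams. Kept below 2^31.
childSeed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  (as.double(seed) * 48271 + stream * 10007) %% 2147483647
}

stopifneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop("`", name, "` must be a single positive number")
}

# mean over a closed time window of a [time] vector given a time axis
windowIndex <- function(times, window) {
  idx <- which(times >= window[1] & times <= window[2])
  if (length(idx) == 0L) stop("window [", window[1], ", ", window[2],
                              "] contains no samples")
  idx
}

# Rank-based AUC: probability that a positive-class score exceeds a
# negative-class score (ties counted half).
rankAuc <- function(scores, positive) {
  stopifnot(length(scores) == length(positive))
  np <- sum(positive); nn <- sum(!positive)
  if (np == 0L || nn == 0L) stop("need both classes to compute AUC")
  r <- rank(scores)
  (sum(r[positive]) - np * (np + 1) / 2) / (np * nn)
}
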