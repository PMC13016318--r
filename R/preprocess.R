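#' Remove line noise with zero-phase Butterworth band-stop filters
#'
#' Applies a forward-backward (zero-phase) 2nd-order Butterworth band-stop
#' at the line frequency and its harmonics to every channel.
#'
#' @param rec a [ContinuousRecording-class].
#' @param baseHz line frequency (Hz), 60 by default.
#' @param nHarmonics number of harmonics to notch (including the
#'   fundamental).
#' @param halfwidth stop-band half width (Hz).
#' @return filtered [ContinuousRecording-class].
#' @export
notchLineNoise <- function(rec, baseHz = 60, nHarmonics = 3,
                           halfwidth = 2) {
  stopifnot(is(rec, "ContinuousRecording"))
  nyq <- rec@sfreq / 2
  data <- rec@data
  for (h in seq_len(nHarmonics)) {
    f0 <- h * baseHz
    if (f0 + halfwidth >= nyq)
      stop("stop band around ", f0, " Hz reaches Nyquist (", nyq, " Hz)")
    bf <- signal::butter(2, c(f0 - halfwidth, f0 + halfwidth) / nyq,
                         type = "stop")
    for (ch in seq_len(nrow(data)))
      data[ch, ] <- signal::filtfilt(bf, data[ch, ])
  }
  ContinuousRecording(data, rec@sfreq, rec@chNames, rec@excluded)
}

#' Re-reference to the common average of included channels
#'
#' Subtracts, at every sample, the mean over all non-excluded channels
#' from each non-excluded channel. Excluded channels are untouched.
#'
#' @param rec a [ContinuousRecording-class].
#' @return re-referenced [ContinuousRecording-class].
#' @export
commonAverageReference <- function(rec) {
  stopifnot(is(rec, "ContinuousRecording"))
  keep <- !rec@excluded
  if (sum(keep) < 2L)
    stop("common average reference needs at least 2 included channels")
  avg <- colMeans(rec@data[keep, , drop = FALSE])
  data <- rec@data
  data[keep, ] <- sweep(data[keep, , drop = FALSE], 2, avg)
  ContinuousRecording(data, rec@sfreq, rec@chNames, rec@excluded)
}

# band mask with paired logistic flanks: value 0.5 at each band edge,
# 10-90% transition width = 2 * flankHalfwidth
bandMask <- function(f, band, flankHalfwidth = 1.5) {
  s <- flankHalfwidth / log(9)
  plogis((f - band[1]) / s) * plogis((band[2] - f) / s)
}

#' Frequency-domain bandpass Hilbert transform
#'
#' Computes the band-limited analytic amplitude of each channel: FFT,
#' zeroing of non-positive frequencies (doubling positive ones),
#' multiplication by a band mask equal to 1 inside the band and 0 far
#' outside with paired logistic flanks of the given half-width centred on
#' the band edges (mask value 0.5 exactly at each edge), inverse FFT, and
#' the magnitude of the result.
#'
#' @param x a [ContinuousRecording-class] or a channels x samples matrix.
#' @param sfreq sampling rate (required when `x` is a matrix).
#' @param band two-element band in Hz, default \eqn{[70, 150]} (broadband
#'   gamma).
#' @param flankHalfwidth sigmoid flank half-width in Hz (default 1.5).
#' @param analytic return the complex analytic signal instead of its
#'   magnitude.
#' @return channels x samples numeric (or complex) matrix.
#' @export
hilbertBandEnvelope <- function(x, sfreq = NULL, band = c(70, 150),
                                flankHalfwidth = 1.5, analytic = FALSE) {
  if (is(x, "ContinuousRecording")) {
    sfreq <- x@sfreq
    x <- x@data
  }
  if (is.null(sfreq)) stop("`sfreq` required for matrix input")
  if (band[2] >= sfreq / 2)
    stop("band edge ", band[2], " Hz is not below Nyquist (", sfreq / 2,
         " Hz)")
  n <- ncol(x)
  f <- (seq_len(n) - 1) * sfreq / n
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[2:(n / 2)] <- 2
    h[n / 2 + 1] <- 1  # Nyquist bin
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  mask <- h * bandMask(f, band, flankHalfwidth)
  out <- matrix(if (analytic) complex(real = 0) else 0, nrow(x), n)
  for (ch in seq_len(nrow(x))) {
    z <- fft(fft(x[ch, ]) * mask, inverse = TRUE) / n
    out[ch, ] <- if (analytic) z else Mod(z)
  }
  out
}

#' Savitzky-Golay smoothing of envelope series
#'
#' Polynomial-preserving FIR smoothing along time (3rd order, 201 ms
#' frame by default). The frame length in samples is the nearest odd
#' integer to `frameMs * sfreq / 1000`.
#'
#' @param env channels x samples envelope matrix.
#' @param sfreq sampling rate (Hz).
#' @param order polynomial order (default 3).
#' @param frameMs frame length in milliseconds (default 201).
#' @return smoothed matrix of the same shape.
#' @export
smoothEnvelope <- function(env, sfreq, order = 3, frameMs = 201) {
  frame <- round(frameMs * sfreq / 1000)
  if (frame %% 2 == 0) frame <- frame + 1
  if (frame < order + 2)
    stop("frame of ", frame, " samples is too short for order ", order)
  out <- env
  for (ch in seq_len(nrow(env)))
    out[ch, ] <- signal::sgolayfilt(env[ch, ], p = order, n = frame)
  out
}

#' Epoch an envelope and express it as percent change from baseline
#'
#' Cuts per-trial epochs around word onsets and normalizes each
#' trial x electrode trace to percent change from its own pre-stimulus
#' baseline mean: `bga(t) = 100 * (env(t) - m) / m` with `m` the mean
#' envelope inside the baseline window of that trial.
#'
#' @param env channels x samples envelope matrix (smoothed analytic
#'   amplitude).
#' @param sfreq sampling rate (Hz).
#' @param events data.frame with `onset_s` plus trial covariates (class,
#'   word, response, rt_s, correct, length, zipf, artifact).
#' @param electrodes electrode table (name, patient, x, y, z, roi)
#'   matching the channel order of `env`.
#' @param window epoch window in seconds relative to onset.
#' @param baseline baseline window in seconds.
#' @param dropArtifacts drop trials flagged in an `artifact` column.
#' @param dropIncorrect drop trials with `correct == FALSE` (midscale
#'   trials, whose correctness is NA, are always retained).
#' @return an [EnvelopeEpochs-class].
#' @export
epochAndBaseline <- function(env, sfreq, events, electrodes,
                             window = c(-0.7, 1.5),
                             baseline = c(-0.5, -0.1),
                             dropArtifacts = TRUE, dropIncorrect = FALSE) {
  stopifnot(baseline[1] >= window[1], baseline[2] <= window[2])
  ev <- events
  if (dropArtifacts && "artifact" %in% names(ev))
    ev <- ev[!isTRUE0(ev$artifact), , drop = FALSE]
  if (dropIncorrect && "correct" %in% names(ev))
    ev <- ev[is.na(ev$correct) | ev$correct, , drop = FALSE]
  n <- ncol(env)
  rel <- seq(round(window[1] * sfreq), round(window[2] * sfreq))
  times <- rel / sfreq
  onsetIdx <- round(ev$onset_s * sfreq) + 1L
  lo <- onsetIdx + rel[1]; hi <- onsetIdx + rel[length(rel)]
  bad <- which(lo < 1L | hi > n)
  if (length(bad))
    stop("epoch overruns recording for trial(s): ",
         paste(bad, collapse = ", "))
  bidx <- which(times >= baseline[1] & times <= baseline[2])
  ntr <- nrow(ev); nel <- nrow(env)
  arr <- array(NA_real_, c(ntr, nel, length(rel)))
  for (tr in seq_len(ntr)) {
    seg <- env[, onsetIdx[tr] + rel, drop = FALSE]
    m <- rowMeans(seg[, bidx, drop = FALSE])
    if (any(m <= 0))
      stop("non-positive baseline mean for trial ", tr,
           " (degenerate envelope)")
    arr[tr, , ] <- 100 * sweep(sweep(seg, 1, m), 1, m, "/")
  }
  ev$onset_s <- NULL
  EnvelopeEpochs(arr, times, ev, electrodes, baseline = baseline)
}

isTRUE0 <- function(x) !is.na(x) & x

#' Responsiveness filter
#'
#' An electrode is considered responsive if its trial-mean BGA over the
#' post-onset window strictly exceeds the threshold (mean BGA > 10% in
#' 300-700 ms by default).
#'
#' @param ep an [EnvelopeEpochs-class].
#' @param window test window in seconds.
#' @param threshold percent-change threshold (strict `>`).
#' @return named logical vector, one entry per electrode.
#' @export
responsiveMask <- function(ep, window = c(0.3, 0.7), threshold = 10) {
  stopifnot(is(ep, "EnvelopeEpochs"))
  idx <- windowIndex(ep@times, window)
  m <- apply(ep@bga[, , idx, drop = FALSE], 2, mean)
  setNames(m > threshold, ep@electrodes$name)
}

#' Full preprocessing chain for one patient
#'
#' notch -> common average reference -> frequency-domain Hilbert band
#' envelope -> Savitzky-Golay smoothing -> epoching with percent-change
#' baselining -> responsiveness mask.
#'
#' @param rec a [ContinuousRecording-class].
#' @param events,electrodes event and electrode tables (see
#'   [epochAndBaseline()]).
#' @param band gamma band (Hz).
#' @param lineHz,nHarmonics,notchHalfwidth notch settings.
#' @param window,baseline epoch and baseline windows (s).
#' @param respWindow,respThreshold responsiveness settings.
#' @param dropIncorrect drop incorrect-response trials (the default for
#'   neural contrasts).
#' @return list with `epochs` ([EnvelopeEpochs-class]) and `responsive`
#'   (named logical vector).
#' @export
preprocessRecording <- function(rec, events, electrodes,
                                band = c(70, 150), lineHz = 60,
                                nHarmonics = 3, notchHalfwidth = 2,
                                window = c(-0.7, 1.5),
                                baseline = c(-0.5, -0.1),
                                respWindow = c(0.3, 0.7),
                                respThreshold = 10,
                                dropIncorrect = TRUE) {
  rec <- notchLineNoise(rec, lineHz, nHarmonics, notchHalfwidth)
  rec <- commonAverageReference(rec)
  env <- hilbertBandEnvelope(rec, band = band)
  env <- smoothEnvelope(env, rec@sfreq)
  ep <- epochAndBaseline(env, rec@sfreq, events, electrodes,
                         window = window, baseline = baseline,
                         dropIncorrect = dropIncorrect)
  list(epochs = ep, responsive = responsiveMask(ep, respWindow,
                                                respThreshold))
}
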