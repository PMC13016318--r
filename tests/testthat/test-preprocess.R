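recFromMatrix <- function(x, fs) ContinuousRecording(x, fs)

test_that("line-noise notch removes the line and spares the passband", {
  fs <- 500
  t <- (0:(fs * 4 - 1)) / fs
  tone60 <- sin(2 * pi * 60 * t)
  tone100 <- sin(2 * pi * 100 * t)
  rec <- recFromMatrix(rbind(tone60, tone100, 0 * t), fs)
  out <- voltages(notchLineNoise(rec, 60, nHarmonics = 3, halfwidth = 2))
  mid <- (fs):(3 * fs)  # away from filter edges
  expect_lt(sqrt(mean(out[1, mid]^2)) / sqrt(mean(tone60[mid]^2)), 0.01)
  expect_lt(abs(sqrt(mean(out[2, mid]^2)) / sqrt(mean(tone100[mid]^2)) - 1),
            0.02)
  expect_equal(out[3, ], 0 * t)  # linearity: zero in, zero out
  expect_error(notchLineNoise(rec, 60, nHarmonics = 5), "Nyquist")
})

test_that("common average referencing zeroes the included-channel mean and is idempotent", {
  set.seed(1)
  x <- matrix(rnorm(5 * 100), 5, 100)
  rec <- recFromMatrix(x, 100)
  out <- commonAverageReference(rec)
  expect_lt(max(abs(colMeans(voltages(out)))), 1e-12)
  expect_equal(voltages(commonAverageReference(out)), voltages(out))

  # two channels that already sum to zero are unchanged
  rec2 <- recFromMatrix(rbind(rep(1, 50), rep(-1, 50)), 100)
  expect_equal(voltages(commonAverageReference(rec2)), voltages(rec2))

  rec1 <- ContinuousRecording(x, 100, excluded = c(FALSE, TRUE, TRUE,
                                                   TRUE, TRUE))
  expect_error(commonAverageReference(rec1), "2 included")

  # excluded channels pass through untouched
  rec3 <- ContinuousRecording(x, 100, excluded = c(FALSE, FALSE, FALSE,
                                                   FALSE, TRUE))
  expect_equal(voltages(commonAverageReference(rec3))[5, ], x[5, ])
})

test_that("Hilbert band envelope follows the logistic flank mask", {
  fs <- 500
  t <- (0:(fs * 4 - 1)) / fs
  x <- rbind(sin(2 * pi * 100 * t), sin(2 * pi * 30 * t),
             sin(2 * pi * 70 * t))
  env <- hilbertBandEnvelope(x, fs)
  mid <- (fs):(3 * fs)
  # in-band tone: unit envelope
  expect_lt(max(abs(env[1, mid] - 1)), 0.02)
  # 30 Hz: mask value from the flank formula is plogis(-40 log 9 / 1.5) ~ 0
  expect_lt(max(env[2, mid]), 0.01)
  # tone at the band edge: mask value 0.5 by the flank-center convention
  expect_lt(max(abs(env[3, mid] - 0.5)), 0.02)
  expect_error(hilbertBandEnvelope(x, fs, band = c(70, 260)), "Nyquist")
})

test_that("Savitzky-Golay smoothing preserves cubics and kills high frequency", {
  fs <- 500
  n <- 1000
  const <- matrix(5, 1, n)
  expect_equal(smoothEnvelope(const, fs), const)

  tt <- seq_len(n) / n
  cubic <- matrix(1 + 2 * tt - 3 * tt^2 + 0.5 * tt^3, 1, n)
  sm <- smoothEnvelope(cubic, fs)
  interior <- 150:850
  expect_lt(max(abs(sm[1, interior] - cubic[1, interior])), 1e-8)

  alt <- matrix(rep(c(1, -1), n / 2), 1, n)
  expect_lt(var(smoothEnvelope(alt, fs)[1, interior]), 0.1 * var(alt[1, ]))

  expect_error(smoothEnvelope(const, 10, frameMs = 201), "too short")
})

test_that("epoching normalizes to percent change from the per-trial baseline", {
  fs <- 100
  n <- 2000
  env <- matrix(2, 2, n)   # constant envelope: BGA identically 0
  ev <- data.frame(onset_s = c(5, 10), word = c("a", "b"),
                   class = c("concrete", "abstract"),
                   response = c("concrete", "abstract"), rt_s = 1,
                   correct = TRUE, length = 5, zipf = 3)
  el <- data.frame(name = c("e1", "e2"), patient = "sub-01", x = 0, y = 0,
                   z = 0, roi = "sim")
  ep <- epochAndBaseline(env, fs, ev, el)
  expect_equal(max(abs(bga(ep))), 0)
  expect_true(all(epochTimes(ep) >= -0.7 & epochTimes(ep) <= 1.5))

  # envelope stepping to 1.1 x baseline reads out as +10%
  env2 <- matrix(2, 1, n)
  on <- round(10 * fs):(round(10 * fs) + 200)
  env2[1, on] <- 2.2
  ep2 <- epochAndBaseline(env2, fs, ev[2, , drop = FALSE],
                          el[1, , drop = FALSE])
  idx <- which(epochTimes(ep2) >= 0.2 & epochTimes(ep2) <= 1.0)
  expect_equal(unique(round(bga(ep2)[1, 1, idx], 10)), 10)

  # epochs that overrun the recording are reported with trial numbers
  ev3 <- ev; ev3$onset_s[2] <- 19.6
  expect_error(epochAndBaseline(env, fs, ev3, el), "trial\\(s\\): 2")
  expect_error(epochAndBaseline(env * 0, fs, ev, el), "baseline")
})

test_that("responsiveness threshold is strict at 10%", {
  arr <- array(0, c(4, 3, 200))
  arr[, 1, ] <- 15
  arr[, 2, ] <- 10     # exactly at threshold: excluded
  ep <- makeEpochs(arr, times = seq(-0.5, 1.49, by = 0.01))
  mask <- responsiveMask(ep)
  expect_identical(unname(mask), c(TRUE, FALSE, FALSE))
  expect_false(any(responsiveMask(makeEpochs(array(0, c(4, 3, 200)),
                                  times = seq(-0.5, 1.49, by = 0.01)))))
})

test_that("baseline-window BGA is zero-mean and results are rate-invariant", {
  lex <- generateLexicon(15, seed = 20)
  cfg <- defaultCohortConfig(nPatients = 1, electrodesPerRoi = 2,
                             nOther = 2, sfreq = 2000)
  cfg$latency[] <- 0.3
  sim <- simulateRecording(cfg, lex, seed = 21)
  pp2k <- preprocessRecording(sim$recording, sim$events, sim$electrodes,
                              dropIncorrect = FALSE)
  ep <- pp2k$epochs
  bidx <- which(epochTimes(ep) >= -0.5 & epochTimes(ep) <= -0.1)
  expect_lt(max(abs(apply(bga(ep)[, , bidx], c(1, 2), mean))), 0.5)

  # decimate the same physical signal to 500 Hz and compare window means
  dec <- ContinuousRecording(voltages(sim$recording)[, seq(1, ncol(
    voltages(sim$recording)), by = 4)], 500,
    channelNames(sim$recording))
  pp500 <- preprocessRecording(dec, sim$events, sim$electrodes,
                               dropIncorrect = FALSE)
  win <- function(pp) {
    idx <- which(epochTimes(pp$epochs) >= 0.3 &
                 epochTimes(pp$epochs) <= 0.7)
    apply(bga(pp$epochs)[, , idx], 2, mean)
  }
  expect_lt(max(abs(win(pp2k) - win(pp500))), 2)
})
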