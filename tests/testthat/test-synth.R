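test_that("lexicon generation matches its calibration and is deterministic", {
  lex <- generateLexicon(80, seed = 1)
  expect_equal(nrow(lex), 240)
  expect_equal(as.vector(table(lex$class)), c(80, 80, 80))
  expect_identical(lex, generateLexicon(80, seed = 1))
  expect_false(identical(lex, generateLexicon(80, seed = 2)))

  # class-conditional moments converge to the calibration at large n
  big <- generateLexicon(1000, seed = 3)
  conc <- big$concreteness_mean[big$class == "concrete"]
  sem <- 0.17 / sqrt(1000)
  expect_lt(abs(mean(conc) - 4.55), 2 * sem + 0.02)  # truncation allowance
  m <- tapply(big$concreteness_mean, big$class, mean)
  expect_true(m["concrete"] > m["midscale"] &&
              m["midscale"] > m["abstract"])
  s <- tapply(big$concreteness_sd, big$class, mean)
  expect_true(s["midscale"] > max(s["concrete"], s["abstract"]))

  # covariates are matched (class-independent): pooled draws
  lens <- tapply(big$length, big$class, mean)
  expect_lt(diff(range(lens)), 0.5)

  expect_error(generateLexicon(0), "positive")
  expect_error(generateLexicon(5, calib = list(concrete = 1)), "abstract")
})

test_that("coupled envelope generator is a stationary VAR with planted structure", {
  # degenerate VAR: white noise, no lag-1 autocorrelation
  z0 <- simulateCoupledEnvelopes(matrix(0, 2, 2), 5000, seed = 1)
  r1 <- cor(z0[1, -1], z0[1, -5000])
  expect_lt(abs(r1), 0.05)

  # parameter recovery against the least-squares fit
  A <- matrix(c(0.5, 0.4, 0, 0.5), 2, 2)
  z <- simulateCoupledEnvelopes(A, 5000, seed = 2)
  fit <- fitMvar(z, order = 1)
  expect_lt(max(abs(fit@A[, , 1] - A)), 0.05)

  # determinism and stability enforcement
  expect_identical(simulateCoupledEnvelopes(A, 100, seed = 7),
                   simulateCoupledEnvelopes(A, 100, seed = 7))
  expect_error(simulateCoupledEnvelopes(diag(2) * 1.01, 100, seed = 1),
               "unstable")
})

test_that("behavioral generator hits its planted sensitivity", {
  lex <- generateLexicon(400, seed = 4)
  # chance performer: hit rate equals false-alarm rate in expectation
  b0 <- simulateBehavior(lex, trueLnDor = 0, bias = 0, respondP = 1,
                         seed = 5)
  ct <- confusionTable(b0)
  hit <- ct["tp"] / (ct["tp"] + ct["fn"])
  fa <- ct["fp"] / (ct["fp"] + ct["tn"])
  expect_lt(abs(hit - fa), 0.1)

  # planted ln(DOR) recovered
  b <- simulateBehavior(lex, trueLnDor = 2.2, respondP = 1, seed = 6)
  expect_lt(abs(lnDor(b)$lnDor - 2.2), 0.5)

  # boundary: all midscale trials rated abstract
  b1 <- simulateBehavior(lex, trueLnDor = 2, abstractBiasMid = 1,
                         respondP = 1, seed = 7)
  mid <- b1$class == "midscale"
  expect_true(all(b1$response[mid] == "abstract"))

  expect_error(simulateBehavior(lex, 2, abstractBiasMid = 1.5), "probab")
  expect_error(simulateBehavior(lex, Inf), "finite")
})

test_that("simulated recordings are deterministic and null gains give null BGA", {
  lex <- generateLexicon(10, seed = 8)
  cfg <- defaultCohortConfig(nPatients = 1, electrodesPerRoi = 1,
                             nOther = 1)
  a <- simulateRecording(cfg, lex, seed = 9)
  b <- simulateRecording(cfg, lex, seed = 9)
  expect_identical(voltages(a$recording), voltages(b$recording))
  expect_identical(a$events, b$events)

  # byte-identical container on disk
  d <- withr::local_tempdir()
  writeRecording(a$recording, file.path(d, "a"))
  writeRecording(b$recording, file.path(d, "b"))
  expect_identical(unname(tools::md5sum(file.path(d, "a.bin"))),
                   unname(tools::md5sum(file.path(d, "b.bin"))))

  # gamma gain identically 1: downstream mean percent change ~ 0
  lex2 <- generateLexicon(20, seed = 10)
  cfg0 <- defaultCohortConfig(nPatients = 1, electrodesPerRoi = 2,
                              nOther = 2)
  cfg0$gammaGain[, ] <- 1
  sim <- simulateRecording(cfg0, lex2, seed = 11)
  pp <- preprocessRecording(sim$recording, sim$events, sim$electrodes,
                            dropIncorrect = FALSE)
  idx <- which(epochTimes(pp$epochs) >= 0.3 & epochTimes(pp$epochs) <= 0.7)
  wm <- mean(bga(pp$epochs)[, , idx])
  expect_lt(abs(wm), 3)

  # unstable coupling rejected before any data is produced
  cfgBad <- defaultCohortConfig(nPatients = 1)
  cfgBad$coupling <- diag(7) * 1.05
  expect_error(simulateRecording(cfgBad, lex, seed = 1), "unstable")
})

test_that("a planted mFus gain survives the full chain as an mFus-specific effect", {
  lex <- generateLexicon(25, seed = 12)
  cfg <- defaultCohortConfig(nPatients = 3, electrodesPerRoi = 2,
                             nOther = 2)
  cfg$gammaGain[, ] <- 1.1                       # task response everywhere
  cfg$gammaGain["mFus", "concrete"] <- 1.3       # concreteness only in mFus
  cohort <- lapply(1:3, function(p) {
    sim <- simulateRecording(cfg, lex, patient = p, seed = 100 + p)
    preprocessRecording(sim$recording, sim$events, sim$electrodes,
                        dropIncorrect = FALSE)$epochs
  })
  isM <- function(ep) electrodeInfo(ep)$roi == "mFus"
  effM <- fitPointwiseLme(lapply(cohort, function(e)
    selectElectrodes(e, which(isM(e)))), bins = 0.5, binWidth = 0.4)
  effO <- fitPointwiseLme(lapply(cohort, function(e)
    selectElectrodes(e, which(!isM(e)))), bins = 0.5, binWidth = 0.4)
  expect_gt(effM$beta, 4)        # planted ~ +10 %/unit
  expect_lt(effM$q, 0.01)
  expect_gt(effO$q, 0.01)
})
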