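test_that("BH step-up matches its closed-form thresholds", {
  r <- bhFdr(c(0.01, 0.02, 0.03, 0.04, 0.05), 0.05)
  expect_true(all(r$reject))            # p_i <= i * 0.05 / 5 for all i
  r2 <- bhFdr(c(0.2, 0.5, 0.9), 0.05)
  expect_false(any(r2$reject))
  r3 <- bhFdr(0.04, 0.05)
  expect_true(r3$reject)
  expect_equal(r3$q, 0.04)              # m = 1 identity
  expect_true(all(bhFdr(runif(20))$q >= c(runif(0), 0)))
  expect_error(bhFdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("empirical FDP stays at or below q on null simulations", {
  set.seed(42)
  fdp <- replicate(500, {
    p <- runif(100)
    mean(bhFdr(p, 0.05)$reject)  # all rejections are false here
  })
  expect_lte(mean(fdp), 0.05 + 0.01)
})

test_that("pointwise LME recovers a planted beta and removes confounds", {
  co <- simulateEffectEpochs(nPatients = 4, nElectrodes = 8,
                             nTrialsPerClass = 50, betaConc = 12,
                             effectWindow = c(0.4, 0.7), seed = 1)
  eff <- fitPointwiseLme(co, bins = c(0.5, 0.6), binWidth = 0.02)
  expect_lt(max(abs(eff$beta - 12)), 4)
  expect_true(all(eff$q < 0.01))

  # planted length/frequency effects with a null concreteness effect:
  # the concreteness beta stays at zero
  coC <- simulateEffectEpochs(nPatients = 4, nElectrodes = 8,
                              nTrialsPerClass = 50, betaConc = 0,
                              betaLength = 5, betaZipf = -8,
                              effectWindow = c(0.4, 0.7), seed = 2)
  effC <- fitPointwiseLme(coC, bins = c(0.5, 0.6), binWidth = 0.02)
  expect_lt(max(abs(effC$beta)), 4)
  expect_error(fitPointwiseLme(co[1]), "2 patients")
})

test_that("positive beta means concrete > abstract", {
  co <- simulateEffectEpochs(nPatients = 3, nElectrodes = 6,
                             nTrialsPerClass = 40, betaConc = 10,
                             seed = 3)
  eff <- fitPointwiseLme(co, bins = 0.55, binWidth = 0.1)
  expect_gt(eff$beta, 0)
  # and the raw class means agree with the sign
  ep <- co[[1]]
  idx <- which(epochTimes(ep) >= 0.5 & epochTimes(ep) <= 0.6)
  mc <- mean(bga(ep)[trialInfo(ep)$class == "concrete", , idx])
  ma <- mean(bga(ep)[trialInfo(ep)$class == "abstract", , idx])
  expect_gt(mc, ma)
})

test_that("ROI assignment respects the radius", {
  centers <- defaultRoiCenters()
  el <- data.frame(name = c("a", "b"), patient = "p",
                   x = c(centers$x[1], centers$x[1] + 25),
                   y = c(centers$y[1], centers$y[1]),
                   z = c(centers$z[1], centers$z[1]), roi = "?")
  lab <- assignRoi(el, centers, radius = 10)
  expect_equal(lab[1], centers$roi[1])   # exactly at a center
  expect_true(is.na(lab[2]))             # > 2x radius from every center
})

test_that("grouped traces equal the patient-weighted electrode average", {
  co <- simulateEffectEpochs(nPatients = 3, nElectrodes = 4,
                             nTrialsPerClass = 20, betaConc = 8, seed = 4)
  # give patients different electrode counts
  co[[2]] <- selectElectrodes(co[[2]], 1:2)
  centers <- data.frame(roi = "sim", x = 0, y = 0, z = 0)
  rc <- suppressWarnings(roiContrast(co, centers, radius = 5,
                                     bins = 0.5, binWidth = 0.1))
  tr <- rc$sim$trace
  # oracle: weighted electrode average, weight 1 / n_electrodes(patient)
  cl <- "concrete"
  t1 <- epochTimes(co[[1]])[1]
  oracle <- mean(vapply(co, function(ep) {
    sel <- trialInfo(ep)$class == cl
    mean(bga(ep)[sel, , 1])
  }, 0))
  expect_equal(tr$mean[tr$class == cl & tr$time == t1], oracle,
               tolerance = 1e-10)
})

test_that("ROIs covered by fewer than two patients are excluded with a warning", {
  co <- simulateEffectEpochs(nPatients = 2, nElectrodes = 2,
                             nTrialsPerClass = 15, seed = 5)
  el <- electrodeInfo(co[[2]])
  el$x <- 100  # move patient 2 away from the ROI
  co[[2]] <- EnvelopeEpochs(bga(co[[2]]), epochTimes(co[[2]]),
                            trialInfo(co[[2]]), el)
  centers <- data.frame(roi = "sim", x = 0, y = 0, z = 0)
  expect_warning(rc <- roiContrast(co, centers, radius = 5, bins = 0.5,
                                   binWidth = 0.1), "< 2 patients")
  expect_length(rc, 0)
})
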