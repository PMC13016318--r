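test_that("decoder is at chance on shuffled labels and robust to feature scaling", {
  co <- simulateEffectEpochs(nPatients = 2, nElectrodes = 10,
                             nTrialsPerClass = 75, betaConc = 20,
                             sdNoise = 25, effectWindow = c(0.3, 1.0),
                             responseMean = 0, seed = 1)
  # shuffle labels before the whole pipeline: chance AUC
  coShuf <- lapply(co, function(ep) {
    tr <- trialInfo(ep)
    set.seed(9)
    tr$class <- sample(tr$class)
    EnvelopeEpochs(bga(ep), epochTimes(ep), tr, electrodeInfo(ep))
  })
  sa0 <- slidingAuc(coShuf, bins = seq(0.3, 0.9, by = 0.1),
                    binWidth = 0.1, seed = 2)
  expect_gt(mean(sa0$mean), 0.45)
  expect_lt(mean(sa0$mean), 0.55)

  # real labels decode late but not early
  sa <- slidingAuc(co, bins = c(-0.1, 0.6), binWidth = 0.1, seed = 3)
  expect_lt(sa$mean[1], 0.6)
  expect_gt(sa$mean[2], 0.9)

  # duplicated feature columns leave the AUC unchanged (standardization)
  ep <- co[[1]]
  dup <- EnvelopeEpochs(bga(ep)[, c(1:10, 1:10), ], epochTimes(ep),
                        trialInfo(ep),
                        rbind(electrodeInfo(ep),
                              transform(electrodeInfo(ep),
                                        name = paste0(name, "b"))))
  a1 <- slidingAuc(list(ep), bins = 0.6, binWidth = 0.1, seed = 4)
  a2 <- slidingAuc(list(dup), bins = 0.6, binWidth = 0.1, seed = 4)
  expect_equal(a1$mean, a2$mean, tolerance = 0.03)

  # monotone per-electrode rescaling leaves the AUC unchanged
  sc <- EnvelopeEpochs(sweep(bga(ep), 2, seq(0.1, 5, length.out = 10),
                             "*"),
                       epochTimes(ep), trialInfo(ep), electrodeInfo(ep))
  a3 <- slidingAuc(list(sc), bins = 0.6, binWidth = 0.1, seed = 4)
  expect_equal(a1$mean, a3$mean, tolerance = 0.03)

  expect_error(slidingAuc(co, bins = 0.5, binWidth = 0.1, nFolds = 100),
               "nFolds")
})

test_that("rank AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(5)
  scores <- rnorm(60)
  pos <- rbinom(60, 1, 0.5) == 1
  ours <- concretecascade:::rankAuc(scores, pos)
  ref <- as.numeric(pROC::auc(pROC::roc(pos, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("permutation null is centred at one half and deterministic", {
  co <- simulateEffectEpochs(nPatients = 2, nElectrodes = 8,
                             nTrialsPerClass = 60, betaConc = 0,
                             responseMean = 0, seed = 6)
  pn <- permutationNull(co, nShuffles = 100, bins = c(0.3, 0.5),
                        binWidth = 0.1, seed = 7)
  expect_lt(abs(pn$mean - 0.5), 0.015)
  pn2 <- permutationNull(co, nShuffles = 100, bins = c(0.3, 0.5),
                         binWidth = 0.1, seed = 7)
  expect_identical(pn$null, pn2$null)
  expect_error(permutationNull(co, nShuffles = 50), "at least 100")
})

test_that("SVR midscale comparison dissociates the generating regimes", {
  for (reg in c("invariant", "response-driven")) {
    co <- simulateEffectEpochs(nPatients = 6, nElectrodes = 10,
                               nTrialsPerClass = 30, betaConc = 20,
                               sdNoise = 25, effectWindow = c(0.4, 0.9),
                               responseMean = 20,
                               classes = c("concrete", "abstract",
                                           "midscale"),
                               midscaleRegime = reg, seed = 8)
    ms <- svrMidscaleComparison(co, gateShuffles = 100, seed = 9)
    ok <- ms$perPatient[!is.na(ms$perPatient$winner), ]
    expect_gt(nrow(ok), 3)
    if (reg == "invariant")
      expect_gte(mean(ok$winner == "midscale"), 0.8)
    else
      expect_gte(mean(ok$winner == "response"), 0.6)
    expect_true(all(ok$mseResponse >= 0 & ok$mseMidscale >= 0))
  }
})

test_that("signed-rank test matches exhaustive enumeration and symmetry", {
  expect_equal(groupSignrank(rep(1, 6), rep(1, 6))$p, 1)
  # n = 6 one-directional: exact two-sided p = 2 / 2^6
  r <- groupSignrank(rep(1, 6), 2:7)
  expect_equal(r$p, 0.03125)
  expect_equal(r$direction, "x<y")
  # antisymmetric differences: p = 1 by symmetry
  expect_equal(groupSignrank(c(1, -1, 2, -2, 3, -3), rep(0, 6))$p, 1)
  expect_error(groupSignrank(1:3, 3:1), "at least 5")
})

test_that("paired Bayes factor points the same way as the evidence", {
  set.seed(10)
  strong <- rnorm(10, 2, 0.5)
  expect_gt(pairedLnBf10(strong), 2)
  weak <- rnorm(10, 0, 1)
  expect_lt(pairedLnBf10(weak), 1)
})
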