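test_that("windowing arithmetic matches the overlap formula", {
  # 1,000 ms at 200 Hz: floor((1000 - 100) / 50) + 1 = 19 windows
  x <- matrix(rnorm(2 * 200), 2, 200)
  w <- windowSeries(x, 200)
  expect_equal(ncol(w$values), 19)
  # exactly one window length
  w1 <- windowSeries(x[, 1:20, drop = FALSE], 200)
  expect_equal(ncol(w1$values), 1)
  # constant envelope: every window equals the constant
  wc <- windowSeries(matrix(3, 1, 100), 200)
  expect_true(all(wc$values == 3))
  expect_error(windowSeries(x[, 1:10, drop = FALSE], 200), "shorter")
})

test_that("MVAR least squares recovers planted coefficients and nulls", {
  set.seed(1)
  # white noise: all coefficients near zero
  z0 <- matrix(rnorm(2 * 5000), 2, 5000)
  f0 <- fitMvar(z0, order = 1)
  expect_lt(max(abs(f0@A)), 0.05)

  # order-3 fit of an order-1 process: lags 2 and 3 vanish
  A <- matrix(c(0.5, 0.4, 0, 0.5), 2, 2)
  z <- simulateCoupledEnvelopes(A, 5000, seed = 2)
  f3 <- fitMvar(z, order = 3)
  expect_lt(max(abs(f3@A[, , 1] - A)), 0.06)
  expect_lt(max(abs(f3@A[, , 2:3])), 0.05)
  expect_true(isStable(f3))

  # trial boundaries are respected: permuting trial order leaves the
  # pooled fit unchanged
  trials <- lapply(1:20, function(i)
    simulateCoupledEnvelopes(A, 30, seed = 100 + i))
  fA <- fitMvar(trials, order = 2)
  fB <- fitMvar(trials[sample(20)], order = 2)
  expect_equal(fA@A, fB@A, tolerance = 1e-10)

  expect_error(fitMvar(matrix(rnorm(4), 2, 2), order = 3), "shorter")
})

test_that("PDC matches its closed form and column normalization", {
  # unidirectional VAR(1), 1 -> 2 with coefficient 0.4
  A <- array(0, c(2, 2, 1)); A[2, 1, 1] <- 0.4
  m <- new("MVARModel", A = A, sigma = diag(2), nobs = 1000,
           stable = TRUE)
  s <- pdc(m, 64)
  expect_equal(max(abs(s@pi[2, 1, ] - 0.4 / sqrt(1.16))), 0, tolerance = 1e-6)
  expect_true(all(s@pi[1, 2, ] == 0))

  # random stable models: sum_i pi_ij^2 = 1 at every frequency
  set.seed(3)
  for (rep in 1:5) {
    B <- array(rnorm(3 * 3 * 2, 0, 0.2), c(3, 3, 2))
    while (varSpectralRadius(B) >= 1) B <- B * 0.8
    sp <- pdc(new("MVARModel", A = B, sigma = diag(3), nobs = 500,
                  stable = TRUE), 32)
    expect_lt(max(abs(apply(sp@pi^2, c(2, 3), sum) - 1)), 1e-10)
  }

  # diagonal-only model: no cross-coupling
  D <- array(0, c(3, 3, 1)); for (i in 1:3) D[i, i, 1] <- 0.5
  sd0 <- pdc(new("MVARModel", A = D, sigma = diag(3), nobs = 500,
                 stable = TRUE), 16)
  off <- sd0@pi; for (i in 1:3) off[i, i, ] <- 0
  expect_equal(max(off), 0)
})

test_that("pairwise PDC recovers planted directionality and nulls reciprocity", {
  rois <- c("A", "B", "C")
  M <- matrix(0, 3, 3); M[2, 1] <- 0.5; diag(M) <- 0.3
  co <- simulateConnectivityCohort(M, rois, nPatients = 4,
                                   electrodesPerRoi = 1,
                                   nTrialsPerClass = 60, seed = 4)
  tab <- roiPairPdc(co, timeWindow = c(0.2, 0.8))
  # 500-800 ms at 100/50 ms windowing pools 5 windows per trial
  tabLate <- roiPairPdc(co, timeWindow = c(0.5, 0.8))
  expect_true(all(c("patient", "epair", "src", "dst", "condition",
                    "pdc") %in% names(tabLate)))
  fwd <- tab$pdc[tab$src == "A" & tab$dst == "B"]
  rev <- tab$pdc[tab$src == "B" & tab$dst == "A"]
  expect_gt(mean(fwd - rev), 0.1)

  # symmetric coupling: net flow centred at zero
  S <- matrix(0, 3, 3); S[2, 1] <- S[1, 2] <- 0.3; diag(S) <- 0.2
  coS <- simulateConnectivityCohort(S, rois, nPatients = 4,
                                    electrodesPerRoi = 1,
                                    nTrialsPerClass = 60, seed = 5)
  tS <- roiPairPdc(coS, timeWindow = c(0.2, 0.8))
  fwdS <- tS$pdc[tS$src == "A" & tS$dst == "B"]
  revS <- tS$pdc[tS$src == "B" & tS$dst == "A"]
  expect_lt(abs(mean(fwdS - revS)), 0.05)

  net <- edgeLme(tab)
  e <- net$edges
  expect_true(e$netPresent[e$src == "A" & e$dst == "B"])
  expect_false(e$netPresent[e$src == "B" & e$dst == "A"])
})

test_that("centrality bookkeeping conserves edge weight and bootstraps cover", {
  edges <- data.frame(src = c("A", "B"), dst = c("B", "C"),
                      meanPdc = c(0.4, 0.2))
  cen <- networkCentrality(edges)
  expect_equal(cen$outdegree[cen$node == "A"], 0.4)
  expect_equal(cen$indegree[cen$node == "B"], 0.4)
  expect_equal(cen$indegree[cen$node == "A"], 0)
  expect_equal(sum(cen$outdegree), sum(cen$indegree))
  expect_equal(sum(cen$outdegree), sum(edges$meanPdc))

  set.seed(6)
  tab <- data.frame(
    patient = rep(c("p1", "p2"), each = 8),
    epair = rep(sprintf("e%d", 1:4), 4),
    src = rep(c("A", "B"), 8), dst = rep(c("B", "A"), 8),
    condition = "concrete", window = "w",
    pdc = c(rnorm(16, 0.3, 0.05)))
  cb <- centralityBootstrap(tab, nBoot = 100, seed = 7)
  expect_true(all(cb$outLo <= cb$outdegree & cb$outdegree <= cb$outHi))
  expect_error(centralityBootstrap(tab, nBoot = 10), "at least 50")
})
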