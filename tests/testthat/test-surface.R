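test_that("mesh geodesics match a brute-force shortest-path oracle", {
  m <- pathMesh()
  d <- geodesicDistances(m, 1)
  expect_equal(d[1], 0)
  expect_equal(d[3], 2)  # via vertex 2, no shortcut
  expect_error(geodesicDistances(m, 99), "out of range")

  ico <- icosphereMesh(1, radius = 10)   # 42 vertices
  D <- floydWarshall(ico)
  for (s in c(1, 7, 25, 42))
    expect_equal(geodesicDistances(ico, s), D[s, ], tolerance = 1e-10)

  # truncation
  d2 <- geodesicDistances(ico, 1, maxDist = 8)
  expect_true(all(is.infinite(d2[D[1, ] > 8])))
})

test_that("recording zones decay exponentially and truncate at the cutoff", {
  ico <- icosphereMesh(2, radius = 50)
  v <- meshVertices(ico)[5, ]
  z <- recordingZone(ico, v, lambda = 3, cutoff = 10)
  expect_equal(z$weights[z$vertices == z$vertex], 1)
  d <- geodesicDistances(ico, z$vertex)
  expect_equal(z$weights, exp(-d[z$vertices] / 3))
  expect_true(all(d[z$vertices] <= 10))
  expect_true(all(d[setdiff(seq_len(nrow(meshVertices(ico))),
                            z$vertices)] > 10))
  # weight at d = lambda is exp(-1)
  wfun <- exp(-d[z$vertices] / 3)
  expect_equal(unname(wfun[which.min(abs(d[z$vertices] - 3))]),
               exp(-d[z$vertices][which.min(abs(d[z$vertices] - 3))] / 3))
  expect_error(recordingZone(ico, c(500, 0, 0)), "snap threshold")
})

test_that("vertex LME masks low coverage and localizes a planted effect", {
  mesh <- icosphereMesh(2, radius = 50)
  V <- meshVertices(mesh)
  pole <- which.max(V[, 3])
  far <- which.min(V[, 3])
  co <- simulateEffectEpochs(nPatients = 4, nElectrodes = 6,
                             nTrialsPerClass = 30, betaConc = 15,
                             sdNoise = 25, seed = 1)
  co <- lapply(co, function(ep) {
    el <- electrodeInfo(ep)
    for (e in 1:6) {
      base <- if (e <= 3) V[pole, ] else V[far, ]
      el[e, c("x", "y", "z")] <- base + rnorm(3, 0, 2)
    }
    b <- bga(ep)
    b[, 4:6, ] <- rnorm(length(b[, 4:6, ]), 0, 25)  # no effect far away
    EnvelopeEpochs(b, epochTimes(ep), trialInfo(ep), el)
  })
  map <- vertexLme(co, mesh, minPatients = 3)
  ok <- which(!is.na(map@tstat))
  expect_true(length(ok) >= 1)
  dpole <- geodesicDistances(mesh, pole)
  supra <- which(!is.na(map@tstat) & map@tstat > 2.5)
  expect_true(all(dpole[supra] <= 10))          # within the zone cutoff
  expect_true(any(dpole[supra] <= 10))          # and the effect is found
  farT <- map@tstat[ok[dpole[ok] > 20]]
  if (length(farT)) expect_true(all(abs(farT) < 2.5))

  # coverage below the threshold is masked
  map2 <- vertexLme(co[1:2], mesh, minPatients = 3)
  expect_true(all(is.na(map2@tstat)))
  expect_true(any(map2@coverage == 2))
})

test_that("cluster decomposition partitions the suprathreshold mask", {
  mesh <- icosphereMesh(2, radius = 50)
  nv <- nrow(meshVertices(mesh))
  set.seed(3)
  sm <- concretecascade:::meshSmoothOperator(mesh, rep(TRUE, nv))
  z <- rnorm(nv); for (i in 1:2) z <- sm(z); z <- z / sd(z)
  map <- new("VertexStatMap", beta = z, tstat = z, coverage = rep(3, nv),
             minPatients = 3)
  cs <- clusterFwe(map, mesh, tThresh = 1.5, nIter = 100, seed = 4)
  verts <- unlist(lapply(cs@clusters, `[[`, "vertices"))
  expect_false(any(duplicated(verts)))                   # disjoint
  expect_setequal(verts, which(abs(z) > 1.5))            # union = mask

  # all-zero map: empty cluster set
  map0 <- new("VertexStatMap", beta = rep(0, nv), tstat = rep(0, nv),
              coverage = rep(3, nv), minPatients = 3)
  expect_length(clusterFwe(map0, mesh, nIter = 100, seed = 1)@clusters, 0)

  # single suprathreshold vertex: one cluster of extent 1
  t1 <- rep(0, nv); t1[10] <- 3
  map1 <- new("VertexStatMap", beta = t1, tstat = t1,
              coverage = rep(3, nv), minPatients = 3)
  cs1 <- clusterFwe(map1, mesh, tThresh = 2.5, nIter = 100, seed = 2)
  expect_length(cs1@clusters, 1)
  expect_equal(cs1@clusters[[1]]$extent, 1)

  expect_error(clusterFwe(map1, mesh, nIter = 50), "unstable")
})

test_that("smoothing the null increases maximum cluster extents", {
  mesh <- icosphereMesh(2, radius = 50)
  nv <- nrow(meshVertices(mesh))
  t1 <- rep(0, nv); t1[10] <- 3
  map1 <- new("VertexStatMap", beta = t1, tstat = t1,
              coverage = rep(3, nv), minPatients = 3)
  m0 <- mean(clusterFwe(map1, mesh, nIter = 150, smoothPasses = 0,
                        seed = 5)@nullMaxExtent)
  m3 <- mean(clusterFwe(map1, mesh, nIter = 150, smoothPasses = 3,
                        seed = 5)@nullMaxExtent)
  m6 <- mean(clusterFwe(map1, mesh, nIter = 150, smoothPasses = 6,
                        seed = 5)@nullMaxExtent)
  expect_lt(m0, m3)
  expect_lt(m3, m6)
})
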