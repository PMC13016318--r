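#' Construct a SurfaceMesh
#'
#' @param vertices N x 3 matrix of coordinates (mm).
#' @param faces M x 3 matrix of 1-based vertex indices.
#' @return a [SurfaceMesh-class] with its Euclidean-weighted edge graph.
#' @export
SurfaceMesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- unique(e)
  w <- sqrt(rowSums((vertices[e[, 1], , drop = FALSE] -
                     vertices[e[, 2], , drop = FALSE])^2))
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  g <- igraph::set_edge_attr(g, "weight", value = w)
  if (igraph::vcount(g) < nrow(vertices))
    g <- igraph::add_vertices(g, nrow(vertices) - igraph::vcount(g))
  new("SurfaceMesh", vertices = vertices, faces = faces, graph = g)
}

#' Generate an icosphere test mesh
#'
#' Subdivided icosahedron projected onto a sphere: subdivision level k
#' gives 20 * 4^k faces (k = 3 gives 1,280 faces / 642 vertices).
#'
#' @param subdiv subdivision level.
#' @param radius sphere radius in mm.
#' @return a [SurfaceMesh-class].
#' @export
icosphereMesh <- function(subdiv = 3, radius = 50) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (k in seq_len(subdiv)) {
    mid <- new.env()
    key <- function(a, b) paste(min(a, b), max(a, b))
    midpoint <- function(a, b) {
      kk <- key(a, b)
      if (!is.null(mid[[kk]])) return(mid[[kk]])
      v <<- rbind(v, (v[a, ] + v[b, ]) / 2)
      mid[[kk]] <- nrow(v)
      nrow(v)
    }
    nf <- matrix(0L, 0, 3)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; cc <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(cc, ca, bc),
                  c(ab, bc, ca))
    }
    f <- nf
  }
  v <- v / sqrt(rowSums(v^2)) * radius
  SurfaceMesh(v, f)
}

#' Nearest mesh vertex for a set of points
#'
#' @param mesh a [SurfaceMesh-class].
#' @param xyz points as an n x 3 matrix (or length-3 vector).
#' @return integer vertex indices.
#' @export
nearestVertex <- function(mesh, xyz) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, 1)
  V <- mesh@vertices
  apply(xyz, 1, function(p)
    which.min(rowSums(sweep(V, 2, p)^2)))
}

#' Geodesic distances along mesh edges
#'
#' Shortest-path distance from a source vertex to every vertex along the
#' Euclidean-weighted edge graph, truncated at `maxDist` (Inf beyond).
#'
#' @param mesh a [SurfaceMesh-class].
#' @param source source vertex index.
#' @param maxDist truncation distance in mm (default Inf).
#' @return numeric vector of distances (mm), one per vertex.
#' @export
geodesicDistances <- function(mesh, source, maxDist = Inf) {
  if (source < 1 || source > nrow(mesh@vertices))
    stop("source vertex out of range")
  d <- as.numeric(igraph::distances(mesh@graph, v = source))
  d[d > maxDist] <- Inf
  d
}

#' Exponentially decaying geodesic recording zone of an electrode
#'
#' Snaps the electrode to its nearest vertex and weights surrounding
#' vertices by `exp(-d / lambda)` for geodesic distance `d <= cutoff`
#' (weight 1 at the snapped vertex, 0 beyond the cutoff).
#'
#' @param mesh a [SurfaceMesh-class].
#' @param electrodeXyz electrode position (mm).
#' @param lambda decay constant (mm, default 3).
#' @param cutoff truncation radius (mm, default 10).
#' @param snapThreshold maximum electrode-to-mesh distance (mm).
#' @return list with `vertex` (snapped vertex), `vertices` (indices with
#'   non-zero weight) and `weights`.
#' @export
recordingZone <- function(mesh, electrodeXyz, lambda = 3, cutoff = 10,
                          snapThreshold = 15) {
  vi <- nearestVertex(mesh, electrodeXyz)
  snapD <- sqrt(sum((mesh@vertices[vi, ] - as.numeric(electrodeXyz))^2))
  if (snapD > snapThreshold)
    stop("electrode is ", round(snapD, 1),
         " mm from the mesh (snap threshold ", snapThreshold, " mm)")
  d <- geodesicDistances(mesh, vi, maxDist = cutoff)
  idx <- which(is.finite(d))
  list(vertex = vi, vertices = idx, weights = exp(-d[idx] / lambda))
}

#' Vertex-wise weighted linear mixed-effects map
#'
#' Maps window-mean BGA onto the mesh through each electrode's recording
#' zone and fits, at every vertex covered by at least `minPatients`
#' patients, the concreteness LME (same design as [fitPointwiseLme()])
#' with zone weights as observation weights. Vertices below the coverage
#' threshold, or whose fit fails, are NA.
#'
#' @param cohort an [EnvelopeEpochs-class] or list of them.
#' @param mesh a [SurfaceMesh-class].
#' @param window analysis window in seconds (default 0.3-0.7 s).
#' @param minPatients patient-coverage threshold (default 3; see
#'   [surfaceThresholdPreset()]).
#' @param lambda,cutoff recording-zone parameters (mm).
#' @param snapThreshold maximum electrode-to-mesh snap distance (mm).
#' @param codeBy contrast source, as in [fitPointwiseLme()].
#' @return a [VertexStatMap-class].
#' @export
vertexLme <- function(cohort, mesh, window = c(0.3, 0.7), minPatients = 3,
                      lambda = 3, cutoff = 10, snapThreshold = 15,
                      codeBy = "class") {
  cohort <- asCohort(cohort)
  nv <- nrow(mesh@vertices)
  # per-electrode window-mean observations and zones
  obs <- list(); zoneOf <- list()
  eid <- 0L
  times <- cohort[[1]]@times
  idx <- windowIndex(times, window)
  for (ep in cohort) {
    y <- apply(ep@bga[, , idx, drop = FALSE], c(1, 2), mean)
    conc <- concCode(ep@trials, codeBy)
    keep <- !is.na(conc)
    for (e in seq_len(nrow(ep@electrodes))) {
      eid <- eid + 1L
      obs[[eid]] <- data.frame(
        bga = y[keep, e], conc = conc[keep],
        length = ep@trials$length[keep], zipf = ep@trials$zipf[keep],
        patient = ep@electrodes$patient[e],
        electrode = paste0(ep@electrodes$patient[e], ":",
                           ep@electrodes$name[e]),
        stringsAsFactors = FALSE)
      zoneOf[[eid]] <- recordingZone(
        mesh, as.numeric(ep@electrodes[e, c("x", "y", "z")]),
        lambda = lambda, cutoff = cutoff, snapThreshold = snapThreshold)
    }
  }
  # invert: electrodes (and weights) touching each vertex
  touch <- vector("list", nv)
  for (e in seq_along(zoneOf)) {
    z <- zoneOf[[e]]
    for (k in seq_along(z$vertices)) {
      vi <- z$vertices[k]
      touch[[vi]] <- rbind(touch[[vi]], c(e, z$weights[k]))
    }
  }
  beta <- tstat <- rep(NA_real_, nv)
  coverage <- rep(0, nv)
  for (vi in seq_len(nv)) {
    tv <- touch[[vi]]
    if (is.null(tv)) next
    d <- do.call(rbind, lapply(seq_len(nrow(tv)), function(r) {
      o <- obs[[tv[r, 1]]]
      o$w <- tv[r, 2]
      o
    }))
    coverage[vi] <- length(unique(d$patient))
    if (coverage[vi] < minPatients) next
    d$length <- d$length - mean(d$length)
    d$zipf <- d$zipf - mean(d$zipf)
    fit <- tryCatch(suppressMessages(suppressWarnings(
      lme4::lmer(bga ~ conc + length + zipf + (1 | patient) +
                   (1 | electrode),
                 data = d, weights = d$w, REML = TRUE,
                 control = lme4::lmerControl(calc.derivs = FALSE)))),
      error = function(e) NULL)
    if (is.null(fit)) next
    co <- summary(fit)$coefficients
    beta[vi] <- co["conc", "Estimate"]
    tstat[vi] <- co["conc", "t value"]
  }
  new("VertexStatMap", beta = beta, tstat = tstat, coverage = coverage,
      minPatients = minPatients)
}

#' Threshold presets for the surface analysis
#'
#' `"strict"` uses t > 2.5 with coverage from at least 3 patients;
#' `"methods"` lowers the vertex threshold to t > 2 at the same
#' coverage; `"lenient"` drops the t threshold to 1 for exploratory
#' maps.
#'
#' @param preset one of `"strict"`, `"methods"`, `"lenient"`.
#' @return list with `tThresh` and `minPatients`.
#' @export
surfaceThresholdPreset <- function(preset = c("strict", "methods",
                                              "lenient")) {
  switch(match.arg(preset),
         strict = list(tThresh = 2.5, minPatients = 3),
         methods = list(tThresh = 2, minPatients = 3),
         lenient = list(tThresh = 1, minPatients = 3))
}

# mean neighbor correlation of a vertex field over the mesh edges
# (restricted to vertices in `domain`)
meshNeighborCorrelation <- function(mesh, x, domain = NULL) {
  e <- igraph::as_edgelist(mesh@graph)
  if (!is.null(domain)) {
    keep <- domain[e[, 1]] & domain[e[, 2]]
    e <- e[keep, , drop = FALSE]
  }
  if (nrow(e) == 0) return(0)
  a <- x[e[, 1]]; b <- x[e[, 2]]
  if (sd(c(a, b)) == 0) return(0)
  cor(c(a, b), c(b, a))
}

# one pass of neighbor averaging: x <- (x + neighbor mean)/2 on the domain
meshSmoothOperator <- function(mesh, domain) {
  nv <- nrow(mesh@vertices)
  e <- igraph::as_edgelist(mesh@graph)
  keep <- domain[e[, 1]] & domain[e[, 2]]
  e <- e[keep, , drop = FALSE]
  A <- Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                            x = 1, dims = c(nv, nv))
  deg <- Matrix::rowSums(A)
  deg[deg == 0] <- 1
  function(x) as.numeric(0.5 * x + 0.5 * (A %*% x) / deg)
}

#' Cluster-extent family-wise error correction on a mesh
#'
#' Finds connected suprathreshold clusters (|t| > `tThresh` among
#' covered vertices) and corrects their extent (vertex count) against a
#' Monte Carlo null of vertex white noise smoothed on the mesh until its
#' neighbor correlation matches the observed map's smoothness (within
#' 0.02), standardized, and thresholded identically. Corrected p =
#' (1 + number of null max extents >= observed) / (1 + nIter).
#'
#' @param map a [VertexStatMap-class].
#' @param mesh the [SurfaceMesh-class] the map lives on.
#' @param tThresh vertex-level |t| threshold (default 2.5).
#' @param nIter Monte Carlo iterations (default 1000, minimum 100).
#' @param alpha corrected alpha level (default 0.01).
#' @param smoothPasses fixed number of smoothing passes for the null;
#'   estimated from the map when NULL.
#' @param seed integer seed for the Monte Carlo draws.
#' @return a [ClusterSet-class].
#' @export
clusterFwe <- function(map, mesh, tThresh = 2.5, nIter = 1000,
                       alpha = 0.01, smoothPasses = NULL, seed = NULL) {
  if (nIter < 100) stop("nIter < 100 gives unstable null quantiles")
  nv <- nrow(mesh@vertices)
  if (length(map@tstat) != nv) stop("map and mesh are not aligned")
  domain <- !is.na(map@tstat)
  if (sum(domain) < 2)
    return(new("ClusterSet", clusters = list(),
               nullMaxExtent = rep(0, nIter), alpha = alpha,
               tThresh = tThresh))
  supra <- domain & abs(map@tstat) > tThresh
  comps <- maskComponents(mesh, supra)
  smoother <- meshSmoothOperator(mesh, domain)
  if (is.null(smoothPasses))
    smoothPasses <- matchSmoothness(mesh, map@tstat, domain, smoother,
                                    seed = childSeed(seed, 99))
  nullMax <- withSeed(childSeed(seed, 1), {
    vapply(seq_len(nIter), function(i) {
      z <- numeric(nv)
      z[domain] <- rnorm(sum(domain))
      for (k in seq_len(smoothPasses)) z <- smoother(z)
      z[domain] <- z[domain] / sd(z[domain])
      m <- domain & abs(z) > tThresh
      if (!any(m)) return(0)
      max(vapply(maskComponents(mesh, m), length, 0L))
    }, 0)
  })
  clusters <- lapply(comps, function(vs) {
    ext <- length(vs)
    list(vertices = vs, extent = ext,
         peakT = max(abs(map@tstat[vs])),
         p = (1 + sum(nullMax >= ext)) / (1 + nIter))
  })
  new("ClusterSet", clusters = clusters, nullMaxExtent = nullMax,
      alpha = alpha, tThresh = tThresh)
}

# connected components of a vertex mask in mesh topology
maskComponents <- function(mesh, mask) {
  vs <- which(mask)
  if (!length(vs)) return(list())
  sub <- igraph::induced_subgraph(mesh@graph, vs)
  comp <- igraph::components(sub)
  lapply(seq_len(comp$no), function(k) vs[comp$membership == k])
}

# pick the number of neighbor-averaging passes whose white-noise neighbor
# correlation matches the observed field's (tolerance 0.02, a few draws
# per candidate)
matchSmoothness <- function(mesh, x, domain, smoother, maxPasses = 30,
                            tol = 0.02, nProbe = 3, seed = NULL) {
  target <- meshNeighborCorrelation(mesh, x, domain)
  if (!is.finite(target) || target <= 0) return(0L)
  nv <- nrow(mesh@vertices)
  withSeed(seed, {
    probes <- lapply(seq_len(nProbe), function(i) {
      z <- numeric(nv); z[domain] <- rnorm(sum(domain)); z
    })
    best <- 0L; bestGap <- Inf
    for (k in 0:maxPasses) {
      r <- mean(vapply(probes, function(z)
        meshNeighborCorrelation(mesh, z, domain), 0))
      gap <- abs(r - target)
      if (gap < bestGap) { bestGap <- gap; best <- k }
      if (gap <= tol || r > target) break
      probes <- lapply(probes, smoother)
    }
    best
  })
}
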