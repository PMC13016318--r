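# Shared in-code fixtures: everything is generated at test time.

# minimal single-patient epochs object with a hand-set BGA array
makeEpochs <- function(bgaArr, times = NULL, classes = NULL,
                       patient = "sub-01") {
  d <- dim(bgaArr)
  if (is.null(times)) times <- seq(-0.5, by = 0.01, length.out = d[3])
  if (is.null(classes))
    classes <- rep_len(c("concrete", "abstract"), d[1])
  trials <- data.frame(word = sprintf("w%03d", seq_len(d[1])),
                       class = classes, response = classes,
                       rt_s = 0.9, correct = TRUE,
                       length = rep_len(c(5, 7, 9), d[1]),
                       zipf = rep_len(c(3, 3.5, 4), d[1]),
                       stringsAsFactors = FALSE)
  electrodes <- data.frame(name = sprintf("e%02d", seq_len(d[2])),
                           patient = patient, x = 0, y = 0, z = 0,
                           roi = "sim", stringsAsFactors = FALSE)
  EnvelopeEpochs(bgaArr, times, trials, electrodes)
}

# a 4-vertex, 2-face mesh where vertex 3 is two unit edges away from
# vertex 1 with no shortcut
pathMesh <- function() {
  SurfaceMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(1, 1, 0)),
              rbind(c(1, 2, 4), c(2, 3, 4)))
}

# brute-force all-pairs shortest paths (Floyd-Warshall) as an
# independent oracle for the mesh geodesics
floydWarshall <- function(mesh) {
  V <- meshVertices(mesh)
  n <- nrow(V)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  f <- meshFaces(mesh)
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  for (r in seq_len(nrow(e))) {
    w <- sqrt(sum((V[e[r, 1], ] - V[e[r, 2], ])^2))
    D[e[r, 1], e[r, 2]] <- D[e[r, 2], e[r, 1]] <- w
  }
  for (k in seq_len(n)) for (i in seq_len(n)) {
    upd <- D[i, k] + D[k, ]
    better <- upd < D[i, ]
    D[i, better] <- upd[better]
  }
  D
}
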