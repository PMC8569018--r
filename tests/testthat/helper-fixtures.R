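# shared fixture builders: digitized solids and small phantoms, all
# generated in code at test time

voxelGrid <- function(d) {
  list(z = slice.index(array(0L, d), 1L),
       y = slice.index(array(0L, d), 2L),
       x = slice.index(array(0L, d), 3L))
}

digitizedBall <- function(d = c(40L, 40L, 40L), center = c(20, 20, 20),
                          radius = 15) {
  g <- voxelGrid(d)
  (g$z - center[1L])^2 + (g$y - center[2L])^2 + (g$x - center[3L])^2 <=
    radius^2
}

digitizedEllipsoid <- function(d, center, semi) {
  g <- voxelGrid(d)
  (g$z - center[1L])^2 / semi[1L]^2 + (g$y - center[2L])^2 / semi[2L]^2 +
    (g$x - center[3L])^2 / semi[3L]^2 <= 1
}

digitizedCylinderVolume <- function(d = c(48L, 96L, 96L), radius = 20,
                                    zSpan = c(10L, 38L), value = 100) {
  g <- voxelGrid(d)
  cy <- (d[2L] + 1) / 2
  cx <- (d[3L] + 1) / 2
  arr <- array(0, d)
  arr[(g$y - cy)^2 + (g$x - cx)^2 <= radius^2 &
        g$z >= zSpan[1L] & g$z <= zSpan[2L]] <- value
  arr
}

# small standard phantom reused across tests
smallPhantom <- function(tort = 1.15, seed = 9L, ...) {
  makeEmbryoPhantom(phantomSpec(targetTortuosity = tort, seed = seed, ...))
}

truthMaskOf <- function(ph, vs = 6.5) EmbryoMask(maskArray(ph$truth),
                                                 voxelSize = vs)
truthLandmarksOf <- function(ph) Landmarks(ph$truth@anteriorPoint,
                                           ph$truth@posteriorPoint)

# independent moment formulas (population central moments)
momentOracle <- function(x) {
  m <- mean(x)
  m2 <- mean((x - m)^2)
  c(mean = m, variation = sd(x) / m,
    skewness = mean((x - m)^3) / m2^1.5,
    kurtosis = mean((x - m)^4) / m2^2 - 3)
}

# independent geodesic distances on a voxel mask via igraph
geodesicOracle <- function(mask, seed) {
  co <- which(mask, arr.ind = TRUE)
  n <- nrow(co)
  edges <- NULL
  w <- NULL
  for (i in seq_len(n - 1L)) {
    dd <- sweep(co[(i + 1L):n, , drop = FALSE], 2L, co[i, ])
    nb <- which(apply(abs(dd), 1L, max) <= 1)
    if (length(nb)) {
      edges <- rbind(edges, cbind(i, i + nb))
      w <- c(w, sqrt(rowSums(dd[nb, , drop = FALSE]^2)))
    }
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  seedIdx <- which(apply(co, 1L, function(r) all(r == seed)))
  as.numeric(igraph::distances(g, v = seedIdx, weights = w))
}
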