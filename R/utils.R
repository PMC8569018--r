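#' Separable 3D Gaussian smoothing
#'
#' Smooths a 3D array with an isotropic Gaussian of standard deviation
#' \code{sigma} voxels, applied separably along each axis. The kernel is
#' truncated at 4 sigma and renormalized at the array edges (normalized
#' convolution), so a constant array is reproduced exactly.
#'
#' @param x 3D numeric array (z, y, x)
#' @param sigma standard deviation in voxels; 0 returns \code{x} unchanged
#' @return smoothed array of the same dimensions
#' @examples
#' a <- array(rnorm(4^3), c(4, 4, 4))
#' s <- gaussianSmooth3d(a, 1)
#' @export
gaussianSmooth3d <- function(x, sigma) {
  stopifnot(length(dim(x)) == 3L)
  if (sigma <= 0) return(x)
  d <- dim(x)
  for (ax in 1:3) {
    n <- d[ax]
    K <- .gaussLineKernel(n, sigma)
    x <- .applyAlongAxis(x, ax, K)
  }
  x
}

# n x n smoothing matrix with truncated, edge-renormalized Gaussian rows
.gaussLineKernel <- function(n, sigma) {
  r <- min(n - 1L, max(1L, ceiling(4 * sigma)))
  w <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- (i - r):(i + r)
    keep <- j >= 1L & j <= n
    K[i, j[keep]] <- w[keep]
  }
  K / rowSums(K)
}

# multiply axis `ax` of a 3D array by matrix K (K %*% line)
.applyAlongAxis <- function(x, ax, K) {
  d <- dim(x)
  if (ax == 1L) {
    y <- K %*% matrix(x, d[1L], d[2L] * d[3L])
    array(y, d)
  } else if (ax == 2L) {
    xp <- aperm(x, c(2L, 1L, 3L))
    y <- K %*% matrix(xp, d[2L], d[1L] * d[3L])
    aperm(array(y, d[c(2L, 1L, 3L)]), c(2L, 1L, 3L))
  } else {
    xp <- aperm(x, c(3L, 1L, 2L))
    y <- K %*% matrix(xp, d[3L], d[1L] * d[2L])
    aperm(array(y, d[c(3L, 1L, 2L)]), c(2L, 3L, 1L))
  }
}

#' Distribution statistics used by the descriptor array
#'
#' Mean, variation (sample SD over mean), moment skewness
#' (m3 / m2^(3/2)) and excess kurtosis (m4 / m2^2 - 3) of a value set.
#' A constant set has undefined variation/skewness/kurtosis, reported as NA.
#'
#' @param x numeric vector
#' @return named numeric: mean, variation, skewness, kurtosis
#' @export
sampleMoments <- function(x) {
  x <- as.numeric(x)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= 0) {
    return(c(mean = m, variation = if (m == 0) NA_real_ else 0,
             skewness = NA_real_, kurtosis = NA_real_))
  }
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  c(mean = m,
    variation = if (m == 0) NA_real_ else sd(x) / m,
    skewness = m3 / m2^1.5,
    kurtosis = m4 / m2^2 - 3)
}

# Otsu threshold on raw intensities (maximizes between-class variance)
.otsuThreshold <- function(x, nbins = 256L) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1L])
  h <- tabulate(pmin(nbins, 1L + floor((x - rng[1L]) / diff(rng) * nbins)),
                nbins)
  p <- h / sum(h)
  mids <- rng[1L] + (seq_len(nbins) - 0.5) / nbins * diff(rng)
  w1 <- cumsum(p)
  mu1 <- cumsum(p * mids)
  muT <- mu1[nbins]
  sb <- (muT * w1 - mu1)^2 / (w1 * (1 - w1))
  sb[!is.finite(sb)] <- -Inf
  mids[which.max(sb)]
}

# voxel coordinates (z,y,x, 1-based) of TRUE entries of a 3D logical array
.maskCoords <- function(mask) {
  which(mask, arr.ind = TRUE)
}

# 0-based linear index of a (z,y,x) 1-based voxel coordinate
.linearIndex0 <- function(coord, dims) {
  (coord[1L] - 1L) + dims[1L] * ((coord[2L] - 1L) +
    dims[2L] * (coord[3L] - 1L))
}

# TRUE where the 6-neighbor at offset `by` along `ax` is background;
# out-of-bounds neighbors count as background
.neighborBg <- function(bg, ax, by) {
  d <- dim(bg)
  n <- d[ax]
  out <- array(TRUE, d)
  if (n == 1L) return(out)
  lo <- 1:(n - 1L)
  hi <- 2:n
  if (ax == 1L) {
    if (by > 0) out[lo, , ] <- bg[hi, , ] else out[hi, , ] <- bg[lo, , ]
  } else if (ax == 2L) {
    if (by > 0) out[, lo, ] <- bg[, hi, ] else out[, hi, ] <- bg[, lo, ]
  } else {
    if (by > 0) out[, , lo] <- bg[, , hi] else out[, , hi] <- bg[, , lo]
  }
  out
}

# surface voxels: mask voxels 6-adjacent to background (array edges count
# as background)
.surfaceVoxels <- function(mask) {
  bg <- !mask
  any6 <- array(FALSE, dim(mask))
  for (ax in 1:3)
    for (by in c(-1L, 1L))
      any6 <- any6 | .neighborBg(bg, ax, by)
  mask & any6
}

# count of exposed voxel faces (mask faces adjacent to background or edge)
.exposedFaceCount <- function(mask) {
  d <- dim(mask)
  total <- 0L
  for (ax in 1:3) {
    m <- aperm(mask, c(ax, setdiff(1:3, ax)))
    dm <- dim(m)
    flat <- matrix(m, dm[1L], dm[2L] * dm[3L])
    padded <- rbind(FALSE, flat, FALSE)
    total <- total + sum(padded[-1L, , drop = FALSE] !=
                           padded[-nrow(padded), , drop = FALSE])
  }
  total
}

# crop the central `dims` region of a 3D array (for comparing FBP output,
# reconstructed on the detector-sized grid, with the source volume)
.cropCenter <- function(x, dims) {
  d <- dim(x)
  stopifnot(all(dims <= d))
  idx <- lapply(1:3, function(ax) {
    off <- floor((d[ax] - dims[ax]) / 2)
    seq_len(dims[ax]) + off
  })
  x[idx[[1L]], idx[[2L]], idx[[3L]], drop = FALSE]
}

# trilinear resampling of a 3D array by an integer-agnostic zoom factor
# (factor > 1 upsamples); target grid preserves the field of view center
.resampleLinear <- function(x, factor) {
  if (abs(factor - 1) < 1e-12) return(x)
  d <- dim(x)
  interpAxis <- function(arr, ax, nNew) {
    n <- dim(arr)[ax]
    # sample positions in source coordinates, center-aligned
    pos <- (seq_len(nNew) - (nNew + 1) / 2) / factor + (n + 1) / 2
    pos <- pmin(pmax(pos, 1), n)
    i0 <- pmin(floor(pos), n - 1L)
    f <- pos - i0
    W <- matrix(0, nNew, n)
    W[cbind(seq_len(nNew), i0)] <- 1 - f
    W[cbind(seq_len(nNew), i0 + 1L)] <- f
    .applyAlongAxis2(arr, ax, W)
  }
  for (ax in 1:3) {
    nNew <- max(2L, round(d[ax] * factor))
    x <- interpAxis(x, ax, nNew)
  }
  x
}

# like .applyAlongAxis but allowing non-square matrices
.applyAlongAxis2 <- function(x, ax, W) {
  d <- dim(x)
  perm <- c(ax, setdiff(1:3, ax))
  xp <- aperm(x, perm)
  y <- W %*% matrix(xp, d[ax], prod(d[-ax]))
  newd <- c(nrow(W), d[-ax])
  aperm(array(y, newd), order(perm))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
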