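#' Axis-correction parameters
#'
#' Controls the opposite-projection registration used to estimate the
#' rotation-axis offset: \code{nPairs} opposite-side projection pairs are
#' registered on their Gaussian gradient modulus images.
#'
#' @param nPairs number of opposite-projection pairs (default 16)
#' @param gradientSigma Gaussian smoothing sigma in micrometers before the
#'   gradient modulus (default 30, about 3 px at typical OPT sampling)
#' @param searchRange maximum |lag| considered, in pixels (NULL = half the
#'   detector width)
#' @param subPixel apply 3-point parabolic refinement of the correlation
#'   argmax (default TRUE)
#' @return an AxisCorrectionParams list
#' @export
axisCorrectionParams <- function(nPairs = 16L, gradientSigma = 30,
                                 searchRange = NULL, subPixel = TRUE) {
  if (nPairs < 1L) stop("nPairs must be >= 1")
  if (gradientSigma <= 0) stop("gradientSigma must be positive")
  structure(list(nPairs = as.integer(nPairs), gradientSigma = gradientSigma,
                 searchRange = searchRange, subPixel = isTRUE(subPixel)),
            class = "AxisCorrectionParams")
}

# 2D Gaussian gradient modulus (separable smoothing + central differences)
.gradientModulus2d <- function(img, sigmaPx) {
  d <- dim(img)
  if (sigmaPx > 0) {
    Kr <- .gaussLineKernel(d[1L], sigmaPx)
    Kc <- .gaussLineKernel(d[2L], sigmaPx)
    img <- Kr %*% img %*% t(Kc)
  }
  gr <- img * 0
  gc <- img * 0
  gr[2:(d[1L] - 1L), ] <- (img[3:d[1L], ] - img[1:(d[1L] - 2L), ]) / 2
  gc[, 2:(d[2L] - 1L)] <- (img[, 3:d[2L]] - img[, 1:(d[2L] - 2L)]) / 2
  sqrt(gr^2 + gc^2)
}

# full 2D cross-correlation via FFT; returns the (rowLag, colLag) argmax
# with optional parabolic sub-pixel refinement of the column lag
.xcorrPeak <- function(a, b, maxColLag, subPixel) {
  d <- dim(a)
  nr <- 2L * d[1L]
  nc <- 2L * d[2L]
  pa <- matrix(0, nr, nc)
  pb <- matrix(0, nr, nc)
  pa[seq_len(d[1L]), seq_len(d[2L])] <- a - mean(a)
  pb[seq_len(d[1L]), seq_len(d[2L])] <- b - mean(b)
  cc <- Re(fft(fft(pa) * Conj(fft(pb)), inverse = TRUE)) / (nr * nc)
  # circular lag grids: lag k stored at index k+1 (mod n)
  colLag <- c(0:(nc / 2 - 1L), -(nc / 2):-1L)
  keep <- abs(colLag) <= maxColLag
  cck <- cc[, keep, drop = FALSE]
  peak <- arrayInd(which.max(cck), dim(cck))
  lag <- colLag[keep][peak[2L]]
  if (subPixel) {
    r <- peak[1L]
    idxOf <- function(l) which(colLag == l)
    lm <- idxOf(lag - 1L)
    lp <- idxOf(lag + 1L)
    if (length(lm) && length(lp)) {
      y0 <- cc[r, idxOf(lag)]
      ym <- cc[r, lm]
      yp <- cc[r, lp]
      den <- ym - 2 * y0 + yp
      if (is.finite(den) && den < 0) {
        off <- 0.5 * (ym - yp) / den
        if (abs(off) <= 0.5) lag <- lag + off
      }
    }
  }
  lag
}

#' Estimate the rotation-axis offset of an OPT projection series
#'
#' Registers \code{nPairs} opposite-side projection pairs (theta,
#' theta + 180 deg): the second member is mirrored left-right, both are
#' transformed to their Gaussian gradient modulus, and the horizontal
#' displacement at the cross-correlation argmax is recorded. Because the
#' mirrored opposite projection is displaced by twice the axis offset, the
#' estimate is the median per-pair displacement divided by two. Positive
#' shift = rotation axis right of the detector center column.
#'
#' @param projections a \linkS4class{ProjectionSet}
#' @param params \code{\link{axisCorrectionParams}}
#' @return list with \code{shift} (px), \code{pairShifts} (per-pair
#'   displacements / 2) and \code{pairs} (angle indices used)
#' @export
estimateAxisShift <- function(projections, params = axisCorrectionParams()) {
  stopifnot(is(projections, "ProjectionSet"))
  img <- projections@images
  n <- dim(img)[3L]
  if (n < 2L) stop("need at least 2 projections")
  if (n %% 2L != 0L)
    stop("opposite-pair registration needs an even number of angles")
  if (params$nPairs > n / 2L)
    stop("nPairs cannot exceed n_angles / 2")
  sigmaPx <- params$gradientSigma / projections@pixelSize
  width <- dim(img)[2L]
  maxLag <- params$searchRange %||% floor(width / 2)

  idx <- unique(round(seq(1L, n / 2L, length.out = params$nPairs)))
  shifts <- vapply(idx, function(i) {
    a <- img[, , i]
    b <- img[, rev(seq_len(width)), i + n / 2L]   # mirrored opposite view
    ga <- .gradientModulus2d(a, sigmaPx)
    gb <- .gradientModulus2d(b, sigmaPx)
    tol <- 1e-10 * (max(abs(a)) + max(abs(b)) + 1e-300)
    if (max(ga) <= tol || max(gb) <= tol)
      stop("no structure for registration")
    .xcorrPeak(ga, gb, maxLag, params$subPixel) / 2
  }, numeric(1L))
  list(shift = median(shifts), pairShifts = shifts,
       pairs = cbind(idx, idx + n / 2L))
}

#' Apply a rotation-axis correction to a projection series
#'
#' Translates every projection horizontally by \code{-shift} pixels
#' (linear interpolation for fractional shifts), filling out-of-frame
#' columns with the edge value. The applied shift is recorded in the
#' returned object.
#'
#' @param projections a \linkS4class{ProjectionSet}
#' @param shift axis offset in pixels, as returned by
#'   \code{\link{estimateAxisShift}}
#' @return corrected \linkS4class{ProjectionSet}
#' @export
applyAxisCorrection <- function(projections, shift) {
  stopifnot(is(projections, "ProjectionSet"))
  width <- dim(projections@images)[2L]
  if (abs(shift) >= width / 4)
    stop("shift exceeds a quarter of the image width")
  out <- projections
  if (abs(shift) > 0)
    out@images <- .shiftColumns(projections@images, -shift)
  out@appliedShift <- projections@appliedShift + shift
  out
}

# frequency response of the discrete ramp (Ram-Lak) filter of length n
# (Kak & Slaney band-limited impulse response)
.rampFilterFreq <- function(n) {
  h <- numeric(n)
  h[1L] <- 0.25
  k <- seq_len(n - 1L)
  kc <- pmin(k, n - k)                  # circular distance from 0
  odd <- kc %% 2L == 1L
  h[1L + k[odd]] <- -1 / (pi * kc[odd])^2
  Re(fft(h))
}

#' Filtered back-projection reconstruction
#'
#' Slice-by-slice FBP of each detector row: projections are ramp-filtered
#' (Ram-Lak, FFT implementation) along the detector columns and
#' back-projected with linear interpolation over the full 360-degree
#' angular range. The output grid is detector-sized in y and x; negative
#' ringing values are retained. If \code{voxelSize} differs from the
#' detector pixel size the volume is resampled trilinearly.
#'
#' @param projections a (corrected) \linkS4class{ProjectionSet}
#' @param voxelSize requested isotropic output voxel size in micrometers
#'   (must be >= the detector pixel size; default = pixel size)
#' @return an \linkS4class{EmbryoVolume}
#' @export
reconstructFBP <- function(projections, voxelSize = NULL) {
  stopifnot(is(projections, "ProjectionSet"))
  voxelSize <- voxelSize %||% projections@pixelSize
  if (voxelSize < projections@pixelSize - 1e-9)
    stop("voxelSize must be >= the detector pixel size")
  img <- projections@images
  d <- dim(img)
  ang <- projections@angles
  if (length(ang) >= 2L) {
    sp <- diff(ang)
    if (any(abs(sp - sp[1L]) > 1e-6)) stop("angles must be uniformly spaced")
  }
  nz <- d[1L]; ndet <- d[2L]; na <- d[3L]

  # ramp filtering along detector columns, all rows/angles at once
  npad <- 2L^ceiling(log2(2L * ndet))
  H <- .rampFilterFreq(npad)
  lines <- matrix(0, npad, nz * na)
  lines[seq_len(ndet), ] <- matrix(aperm(img, c(2L, 1L, 3L)), ndet, nz * na)
  fl <- Re(mvfft(mvfft(lines) * H, inverse = TRUE)) / npad
  filtered <- aperm(array(fl[seq_len(ndet), ], c(ndet, nz, na)),
                    c(2L, 1L, 3L))

  rec <- .backproject_cpp(filtered, dim(filtered), ang * pi / 180,
                          as.integer(ndet), as.integer(ndet))
  rec <- rec * pi / na
  zoom <- projections@pixelSize / voxelSize
  if (abs(zoom - 1) > 1e-12) rec <- .resampleLinear(rec, zoom)
  EmbryoVolume(rec, voxelSize = voxelSize,
               channelLabels = projections@channelLabel)
}
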