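# Internal numerics shared across modules.

#' @useDynLib synapseQuant, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Evaluate expr with a fixed RNG state, restoring the caller's stream.
withSeed <- function(seed, expr) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE))
    get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE))
        rm(".Random.seed", envir = genv)
    } else assign(".Random.seed", old, envir = genv)
  })
  set.seed(seed)
  expr
}

#' Otsu intensity threshold
#'
#' Between-class-variance-maximizing threshold on an arbitrary-range image,
#' delegated to \code{EBImage::otsu} on the image's own intensity range.
#'
#' @param x numeric array of intensities.
#' @param levels histogram resolution.
#' @return scalar threshold on the intensity scale of \code{x}.
#' @export
otsuThreshold <- function(x, levels = 256L) {
  r <- range(x, finite = TRUE)
  if (diff(r) <= 0) return(r[1])
  EBImage::otsu(EBImage::Image(as.numeric(x), dim = c(length(x), 1L)),
                range = r, levels = levels)
}

#' Lower level of a nested Otsu split
#'
#' For trimodal intensity histograms (dark background, diffuse cytosol,
#' bright cortex) the standard Otsu threshold merges cytosol with
#' background. The nested rule first splits off the bright class with a
#' plain Otsu pass, then re-runs Otsu on the remaining (background +
#' cytosol) pixels; the second threshold separates background from
#' everything cellular. Falls back to \code{\link{otsuThreshold}} when
#' the nested split is degenerate.
#'
#' @param x numeric array of intensities.
#' @return scalar threshold on the intensity scale of \code{x}.
#' @export
otsu3Lower <- function(x) {
  tHi <- otsuThreshold(x)
  lowPart <- x[x <= tHi]
  if (length(lowPart) < 2 || diff(range(lowPart)) <= 0) return(tHi)
  tLo <- otsuThreshold(lowPart)
  if (!any(x > tLo)) return(tHi)
  tLo
}

# 6-connected component labeling for 2D/3D logical masks.
label3d <- function(mask) {
  d <- dim(mask)
  if (is.null(d)) d <- length(mask)
  if (length(d) == 2L) d <- c(d, 1L)
  label3d_cpp(as.logical(mask), as.integer(d))
}

# Largest connected TRUE component of a logical mask; empty mask -> NULL.
largestComponent <- function(mask) {
  lab <- label3d(mask)
  if (max(lab) == 0L) return(NULL)
  tab <- tabulate(lab[lab > 0L])
  out <- array(lab == which.max(tab), dim = dim(lab))
  out
}

# Separable anisotropic Gaussian blur of a 3D array; sigma in voxel units.
# Exact dense convolution matrices per axis (grids are small); edge
# renormalization keeps total intensity locally preserved.
gaussBlur3d <- function(a, sigmaVox) {
  kmat <- function(n, s) {
    if (s <= 0 || n == 1L) return(NULL)
    i <- seq_len(n)
    K <- exp(-outer(i, i, "-")^2 / (2 * s^2))
    K[abs(outer(i, i, "-")) > ceiling(4 * s)] <- 0
    K / rowSums(K)
  }
  d <- dim(a)
  K1 <- kmat(d[1], sigmaVox[1])
  K2 <- kmat(d[2], sigmaVox[2])
  K3 <- kmat(d[3], sigmaVox[3])
  if (!is.null(K1)) a <- array(K1 %*% matrix(a, d[1]), d)
  if (!is.null(K2)) {
    a <- aperm(a, c(2, 1, 3))
    a <- array(K2 %*% matrix(a, d[2]), d[c(2, 1, 3)])
    a <- aperm(a, c(2, 1, 3))
  }
  if (!is.null(K3)) {
    a <- aperm(a, c(3, 1, 2))
    a <- array(K3 %*% matrix(a, d[3]), d[c(3, 1, 2)])
    a <- aperm(a, c(2, 3, 1))
  }
  a
}

# Even-odd rasterization of a polygon (vertices in 0-based pixel coords)
# onto an nx x ny pixel grid; pixel centres at integer coordinates.
polygonMask <- function(poly, nx, ny) {
  px <- rep(seq_len(nx) - 1, times = ny)
  py <- rep(seq_len(ny) - 1, each = nx)
  inside <- rep(FALSE, nx * ny)
  n <- nrow(poly)
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  matrix(inside, nx, ny)
}

# Physical coordinates (um) of voxel centres along each axis:
# coordinate = 0-based index * spacing.
axisCoords <- function(n, spacing) (seq_len(n) - 1) * spacing

# Centroid (um) of a logical 3D mask under the package coordinate convention.
maskCentroid <- function(mask, voxelSize) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty mask")
  if (ncol(idx) == 2L) idx <- cbind(idx, 1L)
  colMeans((idx - 1) %*% diag(voxelSize))
}

# Jaccard index of two logical masks.
jaccard <- function(a, b) {
  u <- sum(a | b)
  if (u == 0) return(NA_real_)
  sum(a & b) / u
}

stopIfNot3 <- function(x, what) {
  if (length(x) != 3L || any(!is.finite(x)))
    stop(what, " must be a finite (x, y, z) triple")
  as.numeric(x)
}
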