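# Internal numerical helpers shared across modules.
# All physical coordinates are (z, y, x) in micrometres; voxel indices are
# converted through voxel_size with the origin at the corner voxel centre.

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Physical coordinates (um) of voxel centres along one axis
#' @keywords internal
axis_coords <- function(n, step) (seq_len(n) - 1) * step

#' Unit-normalize a vector
#' @keywords internal
unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stopf("cannot normalize a zero vector")
  v / n
}

#' Rotation matrix about an arbitrary axis (Rodrigues), (z,y,x) component order
#' @keywords internal
rotation_about_axis <- function(axis, angle_rad) {
  a <- unit(axis)
  K <- matrix(c(0, -a[3], a[2],
                a[3], 0, -a[1],
                -a[2], a[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle_rad) * K + (1 - cos(angle_rad)) * (K %*% K)
}

#' Random rotation: uniform axis, given angle (radians)
#' @keywords internal
random_rotation <- function(max_angle_rad) {
  ax <- stats::rnorm(3)
  ang <- stats::runif(1, 0, max_angle_rad)
  rotation_about_axis(ax, ang)
}

#' Check a 3x3 matrix is a proper rotation
#' @keywords internal
is_rotation_matrix <- function(R, tol = 1e-8) {
  is.matrix(R) && all(dim(R) == c(3, 3)) &&
    max(abs(R %*% t(R) - diag(3))) < tol &&
    abs(det(R) - 1) < tol
}

#' Separable Gaussian blur of a 3-D array via FFT, sigma in voxels per axis
#'
#' Circular convolution; callers pad the volume so wrap-around is negligible.
#' A sigma of 0 on an axis leaves that axis untouched.
#' @keywords internal
gaussian_blur3d <- function(vol, sigma_vox) {
  d <- dim(vol)
  if (all(sigma_vox <= 0)) return(vol)
  kern1 <- function(n, s) {
    if (s <= 0) return(c(1, rep(0, n - 1)))
    # circular distance from index 1
    x <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
    k <- exp(-x^2 / (2 * s^2))
    k / sum(k)
  }
  kz <- kern1(d[1], sigma_vox[1])
  ky <- kern1(d[2], sigma_vox[2])
  kx <- kern1(d[3], sigma_vox[3])
  K <- outer(outer(kz, ky), kx)
  dim(K) <- d
  out <- Re(stats::fft(stats::fft(vol) * stats::fft(K), inverse = TRUE)) / prod(d)
  out
}

#' Linear voxel indices whose centres lie within a sphere
#'
#' @param dims stack dims (z,y,x) in voxels
#' @param voxel_size (z,y,x) um
#' @param center (z,y,x) um
#' @param radius um
#' @return integer vector of linear indices into an array of dim `dims`
#' @keywords internal
sphere_voxels <- function(dims, voxel_size, center, radius) {
  lo <- pmax(1L, floor((center - radius) / voxel_size) + 1L)
  hi <- pmin(dims, ceiling((center + radius) / voxel_size) + 1L)
  if (any(lo > hi)) return(integer(0))
  zi <- lo[1]:hi[1]; yi <- lo[2]:hi[2]; xi <- lo[3]:hi[3]
  dz <- (zi - 1) * voxel_size[1] - center[1]
  dy <- (yi - 1) * voxel_size[2] - center[2]
  dx <- (xi - 1) * voxel_size[3] - center[3]
  inside <- outer(outer(dz^2, dy^2, `+`), dx^2, `+`) <= radius^2
  if (!any(inside)) return(integer(0))
  g <- which(inside, arr.ind = TRUE)
  (zi[g[, 1]]) + (yi[g[, 2]] - 1L) * dims[1] + (xi[g[, 3]] - 1L) * dims[1] * dims[2]
}

#' Does a sphere extend beyond the stack bounds?
#' @keywords internal
sphere_clipped <- function(dims, voxel_size, center, radius) {
  extent <- (dims - 1) * voxel_size
  any(center - radius < 0) || any(center + radius > extent)
}
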