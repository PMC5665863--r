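#' Canonical orientation of germarium-like samples
#'
#' Reproduces the two-step manual rotation used for sagittally mounted
#' samples: a least-squares mid-sagittal plane is fitted through the
#' nuclear centres and rotated flat (normal onto the stack Z axis), then
#' the sample is turned so the anterior direction points left (-x). The
#' anterior-posterior (AP) coordinate of each cell is its x position after
#' this transform, zeroed at the anterior-most cell.
#'
#' @name axis_geometry
NULL

#' Construct a rigid frame (rotation + translation)
#' @param rotation 3x3 proper orthonormal matrix, (z,y,x) component order
#' @param translation length-3 (z,y,x) um applied after rotation
#' @param anterior_direction pre-rotation unit vector pointing anterior
#' @return a `rigid_frame` object
#' @export
rigid_frame <- function(rotation, translation = c(0, 0, 0),
                        anterior_direction = NULL) {
  if (!is_rotation_matrix(rotation))
    stopf("rotation must be a proper orthonormal 3x3 matrix")
  structure(list(rotation = rotation, translation = as.numeric(translation),
                 anterior_direction = anterior_direction),
            class = "rigid_frame")
}

#' Apply a rigid frame to centres
#' @param frame a [rigid_frame]
#' @param centers n x 3 matrix (z,y,x um)
#' @return transformed n x 3 matrix
#' @export
apply_frame <- function(frame, centers) {
  stopifnot(inherits(frame, "rigid_frame"))
  sweep(as.matrix(centers) %*% t(frame$rotation), 2, frame$translation, `+`)
}

#' Least-squares mid-sagittal plane through nuclear centres
#'
#' The plane passes through the centroid with normal along the smallest
#' principal component of the centred covariance; the normal sign is
#' chosen toward +z (then +y, then +x when degenerate).
#'
#' @param centers n x 3 matrix or data.frame (z,y,x um), n >= 4
#' @return list: `point` (on the plane), `normal` (unit vector)
#' @export
fit_sagittal_plane <- function(centers) {
  X <- as.matrix(centers)
  if (nrow(X) < 4) stopf("need at least 4 points to fit the sagittal plane")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  e <- eigen(crossprod(Xc) / nrow(X), symmetric = TRUE)
  if (e$values[2] < 1e-10 * max(e$values[1], 1))
    stopf("degenerate point cloud (collinear): cannot fit a plane")
  n <- e$vectors[, 3]
  flip_to <- which(abs(n) > 1e-9)[1]
  if (length(flip_to) && n[flip_to] < 0) n <- -n
  list(point = as.numeric(ctr), normal = as.numeric(n))
}

#' Rotate a sample into the canonical frame
#'
#' Maps the sagittal-plane normal onto the stack Z axis and the in-plane
#' component of the anterior hint onto -x ("anterior to the left"), then
#' translates so the minimum x is 0.
#'
#' @param centers n x 3 matrix (z,y,x um)
#' @param plane list from [fit_sagittal_plane()]
#' @param anterior_hint (z,y,x) vector pointing anterior (pre-rotation);
#'   must not be parallel to the plane normal
#' @return list: `frame` (a [rigid_frame]), `centers` (transformed)
#' @export
rotate_to_canonical <- function(centers, plane, anterior_hint) {
  X <- as.matrix(centers)
  n <- unit(plane$normal)
  h <- unit(anterior_hint)
  h_in <- h - sum(h * n) * n
  if (sqrt(sum(h_in^2)) < 1e-8)
    stopf("anterior hint is parallel to the plane normal")
  a <- unit(h_in)
  r1 <- n              # -> +z
  r3 <- -a             # anterior -> -x, so row x = -anterior
  r2 <- c(r3[2] * r1[3] - r3[3] * r1[2],
          r3[3] * r1[1] - r3[1] * r1[3],
          r3[1] * r1[2] - r3[2] * r1[1])
  Q <- rbind(r1, unit(r2), r3)
  if (det(Q) < 0) Q[2, ] <- -Q[2, ]
  dimnames(Q) <- NULL
  Xr <- X %*% t(Q)
  tr <- c(0, 0, -min(Xr[, 3]))
  Xr[, 3] <- Xr[, 3] + tr[3]
  list(frame = rigid_frame(Q, tr, anterior_direction = h), centers = Xr)
}

#' Anterior-posterior coordinate from canonical centres
#'
#' In the canonical frame the AP coordinate is the x position, zeroed at
#' the anterior-most cell (which gets `ap_um = 0`).
#'
#' @param centers n x 3 matrix in the canonical frame
#' @return numeric `ap_um` per cell
#' @export
assign_ap_coordinate <- function(centers) {
  x <- as.matrix(centers)[, 3]
  x - min(x)
}

#' Map AP coordinates to germarium region labels
#'
#' `k` strictly increasing boundaries (um) split the axis into `k + 1`
#' half-open intervals `[b_i, b_{i+1})` labelled in order with
#' `R1, R2a, R2b_A, R2b_P, R3_S1, S2plus`; any interval beyond the sixth
#' label maps to `S2plus`. An empty boundary vector labels every cell
#' `unassigned`.
#'
#' @param ap_um AP coordinates (um)
#' @param boundaries strictly increasing boundary positions (um)
#' @return character vector of region labels
#' @export
label_regions <- function(ap_um,
                          boundaries = c(10, 15, 20, 25, 30)) {
  levels_all <- c("R1", "R2a", "R2b_A", "R2b_P", "R3_S1", "S2plus")
  if (length(boundaries) == 0) return(rep("unassigned", length(ap_um)))
  if (is.unsorted(boundaries, strictly = TRUE))
    stopf("region boundaries must be strictly increasing")
  idx <- findInterval(ap_um, boundaries) + 1L  # interval number, 1-based
  labs <- c(levels_all, rep("S2plus", max(0, length(boundaries) + 1 - length(levels_all))))
  labs[pmin(idx, length(boundaries) + 1L)]
}

#' Default germarium region boundaries (um along the AP axis)
#'
#' R1 [0,10), R2a [10,15), R2b_A [15,20), R2b_P [20,25), R3_S1 [25,30),
#' S2plus beyond. These are the reference conditions of the synthetic
#' phantom; for real samples they are user-supplied landmarks.
#' @return numeric vector of 5 boundaries
#' @export
default_region_boundaries <- function() c(10, 15, 20, 25, 30)
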