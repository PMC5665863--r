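#' Two-pass nuclear spot detection
#'
#' Mirrors the standard confocal workflow for epithelial nuclei: a coarse
#' automatic pass at the nominal nucleus diameter (2.5 um in the
#' germarium) marks whole nuclei, then each coarse spot is shrunk to a
#' small core (1.75 um) re-centred on the masked intensity centroid so
#' that only the bright, even centre of each nucleus is quantified.
#'
#' @name nucleus_detection
NULL

new_spot_set <- function(df, pass, channel, diameter) {
  rownames(df) <- NULL
  structure(df, pass_label = pass, source_channel = channel,
            spot_diameter = diameter, class = c("spot_set", "data.frame"))
}

#' @export
print.spot_set <- function(x, ...) {
  cat(sprintf("<spot_set> %d %s spot(s), %.3g um, channel '%s'\n",
              nrow(x), attr(x, "pass_label"), attr(x, "spot_diameter"),
              attr(x, "source_channel")))
  if (nrow(x)) print.data.frame(utils::head(x, 6))
  invisible(x)
}

#' Scale-matched blob detection of nuclei
#'
#' Computes a scale-normalized Laplacian-of-Gaussian response in physical
#' units (Gaussian sigma `diameter / (2*sqrt(3))` um, converted per axis to
#' voxels so anisotropy is handled correctly), finds local maxima of the
#' negated response, keeps those above `sensitivity * max(response)`, and
#' greedily suppresses maxima closer than `0.7 * diameter` to an accepted
#' spot (ties broken by larger raw intensity, then lexicographic (z,y,x)).
#' Accepted centres are refined to the raw-intensity centroid within the
#' spot radius, so localization is sub-voxel.
#'
#' @param stack a [voxel_stack]
#' @param channel channel to detect in (name or index)
#' @param diameter spot diameter in um; must span >= 2 voxels on every axis
#' @param sensitivity response threshold as a fraction of the maximum
#'   response, in (0, 1)
#' @return a `spot_set` data.frame: `id, z_um, y_um, x_um, diameter_um, score`
#' @export
detect_spots <- function(stack, channel, diameter = 2.5, sensitivity = 0.3) {
  stopifnot(inherits(stack, "voxel_stack"))
  vs <- stack$voxel_size
  if (any(diameter / vs < 2))
    stopf("diameter %.3g um is under-resolved by voxel size (%.2g, %.2g, %.2g) um",
          diameter, vs[1], vs[2], vs[3])
  vol <- stack_channel(stack, channel)
  dims <- dim(vol)
  empty <- new_spot_set(
    data.frame(id = integer(0), z_um = numeric(0), y_um = numeric(0),
               x_um = numeric(0), diameter_um = numeric(0), score = numeric(0)),
    "coarse", if (is.character(channel)) channel else stack$channels[channel],
    diameter)
  if (all(vol == 0)) return(empty)
  sigma_um <- diameter / (2 * sqrt(3))
  sm <- gaussian_blur3d(vol, sigma_um / vs)
  # physical-space Laplacian by central differences, negated and
  # scale-normalized so the response peaks at blob centres
  resp <- array(0, dims)
  for (ax in 1:3) {
    h2 <- vs[ax]^2
    d2 <- array(0, dims)
    idx_mid <- function(shift) {
      i <- vector("list", 3)
      for (a in 1:3) i[[a]] <- seq_len(dims[a])
      i[[ax]] <- pmin(pmax(i[[ax]] + shift, 1L), dims[ax])
      i
    }
    up <- idx_mid(1L); dn <- idx_mid(-1L)
    d2 <- (sm[up[[1]], up[[2]], up[[3]]] + sm[dn[[1]], dn[[2]], dn[[3]]] - 2 * sm) / h2
    resp <- resp + d2
  }
  resp <- -sigma_um^2 * resp
  rmax <- max(resp)
  if (rmax <= 0) return(empty)
  thr <- sensitivity * rmax
  cand <- which(local_maxima3d(resp) & resp >= thr)
  if (!length(cand)) return(empty)
  ai <- arrayInd(cand, dims)
  ord <- order(-resp[cand], -vol[cand], ai[, 1], ai[, 2], ai[, 3])
  cand <- cand[ord]; ai <- ai[ord, , drop = FALSE]
  pos <- sweep(ai - 1, 2, vs, `*`)
  min_sep <- 0.7 * diameter
  keep <- logical(length(cand))
  acc <- matrix(0, 0, 3)
  for (i in seq_along(cand)) {
    if (nrow(acc) == 0 ||
        min(sqrt(colSums((t(acc) - pos[i, ])^2))) >= min_sep) {
      keep[i] <- TRUE
      acc <- rbind(acc, pos[i, ])
    }
  }
  pos <- pos[keep, , drop = FALSE]
  score <- resp[cand[keep]]
  # sub-voxel refinement: raw-intensity centroid within the spot radius
  for (i in seq_len(nrow(pos))) {
    vox <- sphere_voxels(dims, vs, pos[i, ], diameter / 2)
    if (length(vox) > 0 && sum(vol[vox]) > 0) {
      w <- vol[vox]
      co <- sweep(arrayInd(vox, dims) - 1, 2, vs, `*`)
      pos[i, ] <- colSums(co * w) / sum(w)
    }
  }
  df <- data.frame(id = seq_len(nrow(pos)), z_um = pos[, 1], y_um = pos[, 2],
                   x_um = pos[, 3], diameter_um = diameter, score = score)
  new_spot_set(df, "coarse",
               if (is.character(channel)) channel else stack$channels[channel],
               diameter)
}

#' 3-D local maxima (26-connectivity)
#' @keywords internal
local_maxima3d <- function(a) {
  d <- dim(a)
  out <- array(TRUE, d)
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dz == 0 && dy == 0 && dx == 0) next
    sh <- a[pmin(pmax(seq_len(d[1]) + dz, 1L), d[1]),
            pmin(pmax(seq_len(d[2]) + dy, 1L), d[2]),
            pmin(pmax(seq_len(d[3]) + dx, 1L), d[3])]
    out <- out & (a >= sh)
  }
  # plateau handling: a flat region would be all-TRUE; strictness comes from
  # the greedy suppression ordering afterwards
  out
}

#' Refine coarse spots to small quantification cores
#'
#' For each coarse spot the detection channel is masked to that spot's
#' sphere and one core of `core_diameter` is placed at the masked
#' intensity centroid. A masked sphere with zero total intensity keeps the
#' coarse centre and is flagged `low_signal`. Exactly one core per coarse
#' spot; cores never leave their coarse sphere.
#'
#' @param stack a [voxel_stack]
#' @param coarse a coarse `spot_set`
#' @param core_diameter core diameter in um, <= the coarse diameter
#' @return a core `spot_set` with columns of `coarse` plus `low_signal`
#' @export
refine_cores <- function(stack, coarse, core_diameter = 1.75) {
  stopifnot(inherits(stack, "voxel_stack"), inherits(coarse, "spot_set"))
  if (!identical(attr(coarse, "pass_label"), "coarse"))
    stopf("refine_cores needs a coarse-pass spot_set")
  coarse_d <- attr(coarse, "spot_diameter")
  if (core_diameter > coarse_d)
    stopf("core diameter (%.3g) must be <= coarse diameter (%.3g)",
          core_diameter, coarse_d)
  vol <- stack_channel(stack, attr(coarse, "source_channel"))
  dims <- dim(vol); vs <- stack$voxel_size
  out <- as.data.frame(coarse)
  out$diameter_um <- core_diameter
  out$low_signal <- FALSE
  for (i in seq_len(nrow(out))) {
    ctr <- c(out$z_um[i], out$y_um[i], out$x_um[i])
    vox <- sphere_voxels(dims, vs, ctr, coarse_d / 2)
    if (length(vox) == 0 || sum(vol[vox]) <= 0) {
      out$low_signal[i] <- TRUE
      next
    }
    w <- vol[vox]
    co <- sweep(arrayInd(vox, dims) - 1, 2, vs, `*`)
    cen <- colSums(co * w) / sum(w)
    out$z_um[i] <- cen[1]; out$y_um[i] <- cen[2]; out$x_um[i] <- cen[3]
  }
  new_spot_set(out, "core", attr(coarse, "source_channel"), core_diameter)
}

#' Flag dividing / dying / damaged nuclei
#'
#' Damaged or mitotic nuclei show condensed or diffuse nuclear stain. The
#' flag is a robust outlier test on each core's nuclear-stain statistics:
#' cells whose core mean intensity or core coefficient of variation has a
#' robust z-score (median/MAD) beyond `z_cut` are flagged. Flags are
#' advisory; flagged cells stay in the table.
#'
#' @param stack a [voxel_stack]
#' @param cores a core `spot_set`
#' @param nuclear_channel channel name of the nuclear stain
#' @param z_cut robust z cutoff (default 3.5)
#' @return logical vector, one flag per core (all `FALSE` with a warning
#'   when fewer than 5 cells)
#' @export
flag_excluded <- function(stack, cores, nuclear_channel = "nuclear",
                          z_cut = 3.5) {
  stopifnot(inherits(cores, "spot_set"))
  n <- nrow(cores)
  if (n < 5) {
    warnf("only %d cells: exclusion flags not evaluated", n)
    return(rep(FALSE, n))
  }
  vol <- stack_channel(stack, nuclear_channel)
  dims <- dim(vol); vs <- stack$voxel_size
  r <- attr(cores, "spot_diameter") / 2
  m <- cv <- numeric(n)
  for (i in seq_len(n)) {
    vox <- sphere_voxels(dims, vs, c(cores$z_um[i], cores$y_um[i], cores$x_um[i]), r)
    v <- vol[vox]
    m[i] <- mean(v)
    cv[i] <- if (m[i] > 0) stats::sd(v) / m[i] else 0
  }
  rz <- function(x) {
    md <- stats::median(x)
    s <- stats::mad(x)
    if (s == 0) return(rep(0, length(x)))
    (x - md) / s
  }
  abs(rz(m)) > z_cut | abs(rz(cv)) > z_cut
}

#' Match detected spots to ground-truth nuclei
#'
#' One-to-one greedy matching by increasing distance up to `radius`.
#' With zero predictions, precision is reported as 1.0 by convention (no
#' false positives were made) and `n_pred = 0` records the situation.
#'
#' @param spots a `spot_set` (or data.frame with `z_um,y_um,x_um`)
#' @param truth data.frame with true centres `z_um,y_um,x_um`
#' @param radius matching radius in um (> 0)
#' @return list: `recall`, `precision`, `mean_error_um` (NA when no
#'   matches), `n_matched`, `n_pred`, `n_true`
#' @export
match_to_truth <- function(spots, truth, radius = 1.25) {
  if (radius <= 0) stopf("matching radius must be > 0")
  P <- as.matrix(as.data.frame(spots)[, c("z_um", "y_um", "x_um"), drop = FALSE])
  Tm <- as.matrix(truth[, c("z_um", "y_um", "x_um"), drop = FALSE])
  np <- nrow(P); nt <- nrow(Tm)
  if (np == 0) {
    return(list(recall = 0, precision = 1.0, mean_error_um = NA_real_,
                n_matched = 0L, n_pred = 0L, n_true = nt))
  }
  D <- outer(rowSums(P^2), rowSums(Tm^2), `+`) - 2 * P %*% t(Tm)
  D <- sqrt(pmax(D, 0))
  pairs <- which(D <= radius, arr.ind = TRUE)
  err <- numeric(0)
  used_p <- logical(np); used_t <- logical(nt)
  if (nrow(pairs)) {
    ord <- order(D[pairs])
    for (k in ord) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      if (!used_p[i] && !used_t[j]) {
        used_p[i] <- used_t[j] <- TRUE
        err <- c(err, D[i, j])
      }
    }
  }
  nm <- sum(used_t)
  list(recall = nm / nt, precision = nm / np,
       mean_error_um = if (nm) mean(err) else NA_real_,
       n_matched = as.integer(nm), n_pred = as.integer(np),
       n_true = as.integer(nt))
}
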