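#' Per-cell marker quantification and normalization
#'
#' Raw per-channel core means, background estimation from small spheres
#' placed away from nuclei, floored background subtraction, a laser-ramp
#' depth-bias QC, and the three normalization modes used for mosaic-clone
#' analysis: per-sample maximum, internal-control mean, and the
#' one-phase-decay gradient prediction.
#'
#' @name marker_quant
NULL

#' Mean intensity of each core sphere, per channel
#'
#' The mean is taken over voxels whose centres lie inside the core sphere
#' (centre-in-sphere test in um). Cores at the stack edge are averaged
#' over the in-bounds voxel subset and flagged `edge`.
#'
#' @param stack a [voxel_stack]
#' @param cores a core `spot_set`
#' @return data.frame: `cell_id`, `<channel>_raw` per channel, `edge` flag
#' @export
measure_intensities <- function(stack, cores) {
  stopifnot(inherits(stack, "voxel_stack"), inherits(cores, "spot_set"))
  if (!identical(attr(cores, "pass_label"), "core"))
    stopf("measure_intensities needs core-pass spots")
  dims <- dim(stack$data)[1:3]; vs <- stack$voxel_size
  n <- nrow(cores)
  out <- data.frame(cell_id = cores$id)
  mat <- matrix(NA_real_, n, length(stack$channels))
  edge <- logical(n)
  for (i in seq_len(n)) {
    ctr <- c(cores$z_um[i], cores$y_um[i], cores$x_um[i])
    r <- cores$diameter_um[i] / 2
    vox <- sphere_voxels(dims, vs, ctr, r)
    if (length(vox) == 0)
      stopf("core %s contains no voxel centres: diameter under-resolved",
            cores$id[i])
    edge[i] <- sphere_clipped(dims, vs, ctr, r)
    for (ci in seq_along(stack$channels))
      mat[i, ci] <- mean(stack$data[, , , ci][vox])
  }
  for (ci in seq_along(stack$channels))
    out[[paste0(stack$channels[ci], "_raw")]] <- mat[, ci]
  out$edge <- edge
  out
}

#' Background estimate from small spheres in cell-free tissue
#'
#' Places `n_spots` non-overlapping spheres of `core_diameter` across
#' exactly two z planes, either at caller-supplied centres or sampled from
#' low-nuclear-signal voxels inside the tissue bounding box, all disjoint
#' from the detected nuclei. Records the per-channel mean and sd of the
#' spot means.
#'
#' @param stack a [voxel_stack]
#' @param nuclei a `spot_set` of detected nuclei (exclusion zone uses the
#'   coarse diameter)
#' @param centers optional n x 3 matrix of manual spot centres (z,y,x um);
#'   overlap with a nucleus is an error
#' @param n_spots number of spots (default 10; the conventional range is
#'   8-12)
#' @param core_diameter spot diameter (um)
#' @param nuclear_channel channel used to find signal-free voxels
#' @param seed RNG seed for automatic placement
#' @return a `background_estimate`: list with `mean` and `sd` named per
#'   channel, `n_spots`, `centers`, `z_planes`
#' @export
estimate_background <- function(stack, nuclei, centers = NULL, n_spots = 10,
                                core_diameter = 1.75,
                                nuclear_channel = "nuclear", seed = 1) {
  stopifnot(inherits(stack, "voxel_stack"))
  dims <- dim(stack$data)[1:3]; vs <- stack$voxel_size
  excl_r <- (attr(nuclei, "spot_diameter") %||% 2.5) / 2 + core_diameter / 2
  nuc <- as.matrix(as.data.frame(nuclei)[, c("z_um", "y_um", "x_um"), drop = FALSE])
  clear_of_nuclei <- function(p) {
    nrow(nuc) == 0 || min(sqrt(colSums((t(nuc) - p)^2))) >= excl_r
  }
  if (!is.null(centers)) {
    centers <- as.matrix(centers)
    if (nrow(centers) < 2) stopf("need at least 2 manual background spots")
    for (i in seq_len(nrow(centers)))
      if (!clear_of_nuclei(centers[i, ]))
        stopf("manual background spot %d overlaps a detected nucleus", i)
    n_spots <- nrow(centers)
  } else {
    set.seed(seed)
    vol <- stack_channel(stack, nuclear_channel)
    # two z planes spread through the imaged depth
    zi <- unique(round(stats::quantile(seq_len(dims[1]), c(1/3, 2/3))))
    if (length(zi) < 2) zi <- unique(c(1L, dims[1]))
    if (length(zi) < 2) stopf("stack too thin for two background z planes")
    thr <- stats::quantile(vol, 0.25)
    picked <- matrix(NA_real_, 0, 3)
    tries <- 0
    while (nrow(picked) < n_spots) {
      tries <- tries + 1
      if (tries > 2e4)
        stopf("background region too small for %d non-overlapping spots", n_spots)
      zp <- zi[(nrow(picked) %% 2) + 1]
      yj <- sample.int(dims[2], 1); xj <- sample.int(dims[3], 1)
      if (vol[zp, yj, xj] > thr) next
      p <- c((zp - 1) * vs[1], (yj - 1) * vs[2], (xj - 1) * vs[3])
      if (!clear_of_nuclei(p)) next
      if (nrow(picked) > 0 &&
          min(sqrt(colSums((t(picked) - p)^2))) < core_diameter) next
      if (sphere_clipped(dims, vs, p, core_diameter / 2)) next
      picked <- rbind(picked, p)
    }
    centers <- picked
  }
  spot_means <- matrix(NA_real_, nrow(centers), length(stack$channels))
  for (i in seq_len(nrow(centers))) {
    vox <- sphere_voxels(dims, vs, centers[i, ], core_diameter / 2)
    if (length(vox) == 0) stopf("background spot %d contains no voxels", i)
    for (ci in seq_along(stack$channels))
      spot_means[i, ci] <- mean(stack$data[, , , ci][vox])
  }
  structure(list(
    mean = stats::setNames(colMeans(spot_means), stack$channels),
    sd = stats::setNames(apply(spot_means, 2, stats::sd), stack$channels),
    n_spots = nrow(centers), centers = centers,
    z_planes = sort(unique(round(centers[, 1] / vs[1]) + 1))),
    class = "background_estimate")
}

#' Floored background subtraction
#'
#' `bg_sub = max(raw - background mean, 0)` per channel. Negative results
#' are floored at 0 (a cell cannot have negative marker signal).
#'
#' @param raw data.frame from [measure_intensities()] with `<ch>_raw` columns
#' @param bg a `background_estimate`
#' @return `raw` with added `<ch>_bgsub` columns
#' @export
subtract_background <- function(raw, bg) {
  stopifnot(inherits(bg, "background_estimate"))
  for (ch in names(bg$mean)) {
    rc <- paste0(ch, "_raw")
    if (!rc %in% names(raw)) stopf("raw table lacks column %s", rc)
    raw[[paste0(ch, "_bgsub")]] <- pmax(raw[[rc]] - bg$mean[[ch]], 0)
  }
  raw
}

#' Depth-bias QC: was the laser-power correction adequate?
#'
#' Splits control cells into top/middle/bottom bands by z terciles and
#' compares band mean intensities; the sample passes if the maximum
#' pairwise band ratio is at most `1 + tolerance`. Residual depth
#' attenuation (an imperfect laser ramp) inflates this ratio.
#'
#' @param z_um cell z positions (um)
#' @param values cell intensities (one channel, background-subtracted)
#' @param control logical; which cells are internal controls
#' @param tolerance allowed fractional band imbalance (default 0.15)
#' @return list: `band_means` (top/middle/bottom), `max_ratio`, `pass`,
#'   `evaluable`
#' @export
depth_bias_qc <- function(z_um, values, control = NULL, tolerance = 0.15) {
  if (is.null(control)) control <- rep(TRUE, length(z_um))
  z <- z_um[control]; v <- values[control]
  if (length(z) < 9) {
    warnf("fewer than 3 control cells per depth band: depth QC not evaluable")
    return(list(band_means = c(top = NA, middle = NA, bottom = NA),
                max_ratio = NA_real_, pass = NA, evaluable = FALSE))
  }
  br <- stats::quantile(z, c(1/3, 2/3))
  band <- cut(z, c(-Inf, br, Inf), labels = c("top", "middle", "bottom"))
  if (min(table(band)) < 3) {
    warnf("fewer than 3 control cells in a depth band: depth QC not evaluable")
    return(list(band_means = c(top = NA, middle = NA, bottom = NA),
                max_ratio = NA_real_, pass = NA, evaluable = FALSE))
  }
  bm <- tapply(v, band, mean)
  ratio <- max(bm) / min(bm)
  list(band_means = bm, max_ratio = ratio, pass = ratio <= 1 + tolerance,
       evaluable = TRUE)
}

#' Normalize to the per-sample maximum
#'
#' `value / max(value)` over the non-excluded cells of each sample, so
#' results lie in \[0, 1\] and the brightest included cell is exactly 1.
#' Excluded cells are still scaled but never set the maximum.
#'
#' @param values background-subtracted intensities
#' @param sample_id sample grouping (default: one sample)
#' @param exclude logical; cells that must not set the maximum
#' @return normalized values
#' @export
normalize_max <- function(values, sample_id = NULL, exclude = NULL) {
  n <- length(values)
  if (is.null(sample_id)) sample_id <- rep(1L, n)
  if (is.null(exclude)) exclude <- rep(FALSE, n)
  out <- numeric(n)
  for (s in unique(sample_id)) {
    i <- sample_id == s
    mx <- suppressWarnings(max(values[i & !exclude]))
    if (!is.finite(mx) || mx <= 0) {
      warnf("sample %s: all-zero channel, normalized values set to 0", s)
      out[i] <- 0
    } else {
      out[i] <- values[i] / mx
    }
  }
  out
}

#' Normalize to the internal-control mean
#'
#' `value / mean(value over in-scope control cells)`, the mosaic-clone
#' convention: internal control cells of the same sample and region map to
#' 1 on average, and a clone cell's value is its fold change versus those
#' controls.
#'
#' @param values background-subtracted intensities
#' @param control logical; internal-control cells
#' @param in_scope logical; which cells define the control scope (e.g. one
#'   region); default all
#' @return normalized values
#' @export
normalize_to_control_mean <- function(values, control, in_scope = NULL) {
  if (is.null(in_scope)) in_scope <- rep(TRUE, length(values))
  ctrl <- control & in_scope
  if (sum(ctrl) < 3) stopf("need at least 3 in-scope control cells")
  m <- mean(values[ctrl])
  if (m <= 0) stopf("control mean is zero: cannot normalize")
  values / m
}
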