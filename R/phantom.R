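#' Expression profile along the anterior-posterior axis
#'
#' Defines the deterministic mean expression of one channel as a function of
#' AP position (um from the anterior tip), plus multiplicative lognormal
#' cell-to-cell variability. Supported shapes:
#' \describe{
#'   \item{one_phase_decay}{`plateau + (y0 - plateau) * exp(-K * x)`; the
#'     anterior-high Wnt-reporter gradient. `K >= 0` in 1/um.}
#'   \item{logistic_rise}{`floor + (ceiling - floor) / (1 + exp(-steepness *
#'     (x - midpoint)))`; a steep rise such as Eya within region 2b_A.}
#'   \item{linear_rise}{`max(intercept + slope * x, floor)`; a gradual rise
#'     such as Cas across region 2b.}
#'   \item{constant}{a flat level, e.g. the nuclear stain.}
#' }
#'
#' @param kind one of `"one_phase_decay"`, `"logistic_rise"`,
#'   `"linear_rise"`, `"constant"`
#' @param ... kind-specific parameters: decay `plateau, y0, K`; logistic
#'   `midpoint, steepness, floor, ceiling`; linear `slope, intercept`
#'   (optional `floor`, default 0); constant `value`
#' @param cell_sd sd of the multiplicative lognormal cell noise (>= 0); the
#'   noise factor has mean 1
#' @return a `profile_spec` object
#' @export
profile_spec <- function(kind, ..., cell_sd = 0) {
  pars <- list(...)
  kinds <- c("one_phase_decay", "logistic_rise", "linear_rise", "constant")
  if (!kind %in% kinds)
    stopf("unknown profile kind '%s' (must be one of: %s)", kind,
          paste(kinds, collapse = ", "))
  need <- switch(kind,
    one_phase_decay = c("plateau", "y0", "K"),
    logistic_rise   = c("midpoint", "steepness", "floor", "ceiling"),
    linear_rise     = c("slope", "intercept"),
    constant        = "value")
  missing <- setdiff(need, names(pars))
  if (length(missing)) stopf("profile '%s' needs parameters: %s", kind,
                             paste(missing, collapse = ", "))
  if (kind == "one_phase_decay" && pars$K < 0) stopf("decay rate K must be >= 0")
  if (kind == "logistic_rise" && pars$ceiling < pars$floor)
    stopf("logistic ceiling must be >= floor")
  if (cell_sd < 0) stopf("cell_sd must be >= 0")
  structure(list(kind = kind, parameters = pars, cell_sd = cell_sd),
            class = "profile_spec")
}

#' Deterministic mean of a profile at given AP positions
#' @param spec a [profile_spec]
#' @param ap_um AP positions in um (>= 0)
#' @return mean intensities (a.u.)
#' @export
profile_mean <- function(spec, ap_um) {
  stopifnot(inherits(spec, "profile_spec"))
  p <- spec$parameters
  switch(spec$kind,
    one_phase_decay = p$plateau + (p$y0 - p$plateau) * exp(-p$K * ap_um),
    logistic_rise = p$floor + (p$ceiling - p$floor) /
      (1 + exp(-p$steepness * (ap_um - p$midpoint))),
    linear_rise = pmax(p$intercept + p$slope * ap_um, p$floor %||% 0),
    constant = rep(p$value, length(ap_um)))
}

#' Draw per-cell expression at AP positions
#'
#' Profile mean times one mean-1 lognormal draw per cell (`meanlog =
#' -cell_sd^2/2`, `sdlog = cell_sd`). With `cell_sd = 0` the mean is
#' returned exactly. Uses the current RNG stream.
#'
#' @inheritParams profile_mean
#' @return intensities (a.u.), same length as `ap_um`
#' @export
sample_expression <- function(ap_um, spec) {
  if (any(ap_um < 0)) stopf("ap_um must be >= 0")
  m <- profile_mean(spec, ap_um)
  if (spec$cell_sd == 0) return(m)
  m * stats::rlnorm(length(ap_um), meanlog = -spec$cell_sd^2 / 2,
                    sdlog = spec$cell_sd)
}

#' Default channel profiles emulating the germarium expression landscape
#'
#' Nuclear stain flat; Eya rising steeply within region 2b_A (logistic
#' midpoint 16 um); Cas rising gradually across 2b (linear); a Wnt-reporter
#' one-phase decay (plateau 0.1, y0 1, K 0.08 per um).
#' @param cell_sd marker cell-to-cell lognormal sd (nuclear stain uses 0.1)
#' @return named list of [profile_spec]
#' @export
default_profiles <- function(cell_sd = 0.25) {
  list(
    nuclear = profile_spec("constant", value = 1, cell_sd = 0.1),
    eya = profile_spec("logistic_rise", midpoint = 16, steepness = 1,
                       floor = 0.05, ceiling = 1, cell_sd = cell_sd),
    cas = profile_spec("linear_rise", slope = 0.035, intercept = -0.25,
                       floor = 0.05, cell_sd = cell_sd),
    wnt_reporter = profile_spec("one_phase_decay", plateau = 0.1, y0 = 1,
                                K = 0.08, cell_sd = cell_sd)
  )
}

#' Parameters of the synthetic germarium phantom
#'
#' The defaults are the package's reference study conditions: a sagittally
#' mounted half-germarium imaged as a curved epithelial monolayer slab.
#' Nuclei (2.5 um) sit on an ellipsoidal shell (semi-axes x=16, y=9,
#' z=2.5 um, thickness 1 um); acquisition uses 0.43 um z steps and 0.14 um
#' xy pixels. Intensity is rendered at `gain` counts per unit expression
#' with additive background and Gaussian read noise of `gain / snr` counts
#' (so `snr` is blob peak over noise sd at unit expression); optional
#' Poisson shot noise. Depth attenuation is either pre-corrected at
#' acquisition (`laser_corrected = TRUE`, emulating a calibrated laser
#' ramp) or left as a residual `exp(-attenuation_per_um * depth)` bias for
#' the depth QC to catch.
#'
#' @param n_cells number of follicle nuclei (>= 1)
#' @param shell list: `semi_axes` (z,y,x um) and `thickness` (um)
#' @param nucleus_diameter_mean,nucleus_diameter_sd nucleus diameter (um)
#' @param voxel_size (z,y,x) um
#' @param marker_profiles named list of [profile_spec], one per channel;
#'   must contain `nuclear`
#' @param clone_fraction fraction of cells in the mutant clone, in \[0,1\]
#' @param clone_mode `"fraction"` (independent draws, exact count) or
#'   `"patch"` (one contiguous patch)
#' @param clone_effects named multipliers (> 0) applied to the true
#'   expression of clone cells, e.g. `c(eya = 1.83)`
#' @param clone_polarity `"positive"` (clone marker labels clone cells,
#'   MARCM-style) or `"negative"` (marker lost in the clone)
#' @param attenuation_per_um depth attenuation rate (>= 0, 1/um)
#' @param laser_corrected if `TRUE` the acquisition ramp exactly cancels
#'   attenuation (no net signal bias); if `FALSE` the residual bias is
#'   rendered
#' @param psf_sigma isotropic Gaussian PSF sigma (um)
#' @param noise list: `gaussian_sd` (counts; default `gain / snr`) and
#'   `poisson_scale` (0 disables shot noise)
#' @param background_level additive background (counts, >= 0)
#' @param gain counts per unit true expression
#' @param snr blob peak / Gaussian noise sd at unit expression
#' @param ap_length AP extent of the tissue (um); defaults to 2 * x semi-axis
#' @param tilt_deg maximum random mounting tilt applied to the rendered
#'   sample (degrees; the drawn rotation is recorded in the truth)
#' @param pad_um empty margin around the tissue (um)
#' @param max_voxels refuse to render stacks larger than this
#' @param seed RNG seed for the phantom
#' @return a `phantom_params` object
#' @export
phantom_params <- function(n_cells = 50,
                           shell = list(semi_axes = c(z = 2.5, y = 9, x = 16),
                                        thickness = 1),
                           nucleus_diameter_mean = 2.5,
                           nucleus_diameter_sd = 0.15,
                           voxel_size = c(z = 0.43, y = 0.14, x = 0.14),
                           marker_profiles = default_profiles(),
                           clone_fraction = 0.2,
                           clone_mode = c("fraction", "patch"),
                           clone_effects = c(eya = 1),
                           clone_polarity = c("positive", "negative"),
                           attenuation_per_um = 0.015,
                           laser_corrected = TRUE,
                           psf_sigma = 0.3,
                           noise = list(gaussian_sd = NULL, poisson_scale = 0),
                           background_level = 50,
                           gain = 1000,
                           snr = 10,
                           ap_length = NULL,
                           tilt_deg = 10,
                           pad_um = 2.5,
                           max_voxels = 5e7,
                           seed = 1) {
  clone_mode <- match.arg(clone_mode)
  clone_polarity <- match.arg(clone_polarity)
  if (n_cells < 1) stopf("n_cells must be >= 1")
  if (any(voxel_size <= 0)) stopf("voxel sizes must be > 0")
  if (clone_fraction < 0 || clone_fraction > 1)
    stopf("clone_fraction must be in [0, 1]")
  if (any(clone_effects <= 0)) stopf("clone effect multipliers must be > 0")
  if (attenuation_per_um < 0) stopf("attenuation_per_um must be >= 0")
  if (background_level < 0) stopf("background_level must be >= 0")
  if (!"nuclear" %in% names(marker_profiles))
    stopf("marker_profiles must contain a 'nuclear' channel")
  if (!all(c("z", "y", "x") %in% names(shell$semi_axes)))
    stopf("shell$semi_axes must be named (z, y, x)")
  if (any(shell$semi_axes <= 0) || shell$thickness < 0)
    stopf("shell semi-axes must be > 0 and thickness >= 0")
  if (is.null(noise$gaussian_sd)) noise$gaussian_sd <- gain / snr
  if (is.null(noise$poisson_scale)) noise$poisson_scale <- 0
  if (is.null(ap_length)) ap_length <- 2 * shell$semi_axes[["x"]]
  structure(list(
    n_cells = as.integer(n_cells), shell = shell,
    nucleus_diameter_mean = nucleus_diameter_mean,
    nucleus_diameter_sd = nucleus_diameter_sd,
    voxel_size = as.numeric(
      if (!is.null(names(voxel_size)) && all(c("z", "y", "x") %in% names(voxel_size)))
        voxel_size[c("z", "y", "x")] else voxel_size),
    marker_profiles = marker_profiles,
    clone_fraction = clone_fraction, clone_mode = clone_mode,
    clone_effects = clone_effects, clone_polarity = clone_polarity,
    attenuation_per_um = attenuation_per_um,
    laser_corrected = laser_corrected,
    psf_sigma = psf_sigma, noise = noise,
    background_level = background_level, gain = gain, snr = snr,
    ap_length = ap_length, tilt_deg = tilt_deg, pad_um = pad_um,
    max_voxels = max_voxels, seed = as.integer(seed)),
    class = "phantom_params")
}

#' Place nuclei on the ellipsoidal shell
#'
#' Rejection-samples positions approximately uniform on the shell surface
#' with radial jitter within the shell thickness, enforcing a minimum
#' centre separation of `0.8 * nucleus_diameter_mean`. Clone flags are
#' assigned either as exactly `round(clone_fraction * n_cells)` random
#' cells (`"fraction"` mode) or as one spatially contiguous patch of that
#' size (`"patch"` mode). Deterministic for a fixed `params$seed`.
#'
#' @param params a [phantom_params]
#' @return data.frame: `id`, centre `z_um,y_um,x_um` (tissue frame, origin
#'   at ellipsoid centre), `ap_um` (um from the anterior tip), `diameter_um`,
#'   `clone` (logical)
#' @export
place_nuclei <- function(params) {
  stopifnot(inherits(params, "phantom_params"))
  set.seed(params$seed)
  semi <- params$shell$semi_axes[c("z", "y", "x")]
  thick <- params$shell$thickness
  min_sep <- 0.8 * params$nucleus_diameter_mean
  n <- params$n_cells
  centers <- matrix(NA_real_, n, 3)
  placed <- 0L
  rejections <- 0L
  while (placed < n) {
    u <- unit(stats::rnorm(3))
    r <- 1 + stats::runif(1, -thick / 2, thick / 2) / min(semi)
    p <- semi * u * r
    ok <- placed == 0L ||
      min(sqrt(colSums((t(centers[seq_len(placed), , drop = FALSE]) - p)^2))) >= min_sep
    if (ok) {
      placed <- placed + 1L
      centers[placed, ] <- p
    } else {
      rejections <- rejections + 1L
      if (rejections > 1e5)
        stopf("shell too crowded: could not place %d nuclei at %.2f um separation",
              n, min_sep)
    }
  }
  diam <- pmax(stats::rnorm(n, params$nucleus_diameter_mean,
                            params$nucleus_diameter_sd), 0.5)
  k <- round(params$clone_fraction * n)
  clone <- rep(FALSE, n)
  if (k > 0) {
    if (params$clone_mode == "fraction") {
      clone[sample.int(n, k)] <- TRUE
    } else {
      seed_cell <- sample.int(n, 1)
      d <- sqrt(colSums((t(centers) - centers[seed_cell, ])^2))
      clone[order(d)[seq_len(k)]] <- TRUE
    }
  }
  # anterior tip at x = -a; cells in the outer shell half can sit slightly
  # beyond it, so the AP coordinate is floored at 0
  ap <- pmax(centers[, 3] + semi[["x"]], 0)
  data.frame(id = seq_len(n), z_um = centers[, 1], y_um = centers[, 2],
             x_um = centers[, 3], ap_um = ap, diameter_um = diam,
             clone = clone)
}

#' Generate a full phantom: ground truth plus rendered stack
#'
#' Places nuclei, draws per-channel true expression from the AP profiles
#' (clone multipliers applied), draws a random mounting tilt, and renders
#' the stack. The returned truth records everything downstream stages
#' estimate: stack-frame centres, true AP positions, clone flags, true
#' expressions, and the applied rotation.
#'
#' @param params a [phantom_params]
#' @param render if `FALSE`, skip rendering and return only the truth
#' @return list with `truth` (data.frame + attributes `rotation`,
#'   `translation`, `anterior_stack` unit vector, `profiles`, `params`) and
#'   `stack` (a [voxel_stack], or `NULL`)
#' @export
generate_phantom <- function(params, render = TRUE) {
  nuclei <- place_nuclei(params)  # seeds the RNG stream
  profs <- params$marker_profiles
  truth <- nuclei
  for (ch in names(profs)) {
    expr <- sample_expression(nuclei$ap_um, profs[[ch]])
    eff <- params$clone_effects[ch]
    if (!is.na(eff) && eff != 1) expr[nuclei$clone] <- expr[nuclei$clone] * eff
    truth[[paste0(ch, "_true")]] <- expr
  }
  # mounting tilt: recorded rotation from tissue frame to stack frame
  R <- if (params$tilt_deg > 0)
    random_rotation(params$tilt_deg * pi / 180) else diag(3)
  centers <- as.matrix(truth[, c("z_um", "y_um", "x_um")]) %*% t(R)
  rad <- truth$diameter_um / 2
  pad <- params$pad_um
  shift <- -apply(centers - rad, 2, min) + pad
  centers <- sweep(centers, 2, shift, `+`)
  truth$z_um <- centers[, 1]; truth$y_um <- centers[, 2]; truth$x_um <- centers[, 3]
  anterior_stack <- as.numeric(R %*% c(0, 0, -1))  # anterior = -x in tissue frame
  attr(truth, "rotation") <- R
  attr(truth, "translation") <- shift
  attr(truth, "anterior_stack") <- anterior_stack
  attr(truth, "profiles") <- profs
  attr(truth, "params") <- params
  stack <- if (render) render_stack(truth, params) else NULL
  list(truth = truth, stack = stack)
}

#' Render a truth table into a noisy multi-channel stack
#'
#' Each nucleus becomes a spherical Gaussian blob (sigma = diameter/4)
#' whose peak is `gain * true expression` counts. The clone-marker channel
#' (`clone`) is rendered only for clone cells (positive polarity) or only
#' for non-clone cells (negative). Depth attenuation multiplies signal by
#' `exp(-attenuation_per_um * z)` unless `laser_corrected` (the ramp
#' cancels it exactly); then isotropic PSF blur, background, Gaussian and
#' optional Poisson noise are applied, and counts are quantized to 16-bit
#' integers. Deterministic for a fixed `params$seed`.
#'
#' @param truth data.frame with `z_um,y_um,x_um,diameter_um,clone` and
#'   `<channel>_true` columns (as from [generate_phantom()] or hand-built)
#' @param params a [phantom_params]
#' @return a [voxel_stack] with channels `names(marker_profiles)` plus
#'   `clone`
#' @export
render_stack <- function(truth, params) {
  stopifnot(inherits(params, "phantom_params"))
  set.seed(params$seed + 1L)
  vs <- params$voxel_size
  centers <- as.matrix(truth[, c("z_um", "y_um", "x_um")])
  rad <- truth$diameter_um / 2
  extent <- apply(centers + rad, 2, max) + params$pad_um
  dims <- unname(pmax(ceiling(extent / vs) + 1L, 8L))
  if (prod(dims) * (length(params$marker_profiles) + 1) > params$max_voxels)
    stopf("stack of %d x %d x %d voxels exceeds the voxel budget",
          dims[1], dims[2], dims[3])
  channels <- c(names(params$marker_profiles), "clone")
  arr <- array(0, c(dims, length(channels)))
  att <- params$attenuation_per_um
  zc <- axis_coords(dims[1], vs[1])
  for (ci in seq_along(channels)) {
    ch <- channels[ci]
    vol <- array(0, dims)
    for (i in seq_len(nrow(truth))) {
      if (ch == "clone") {
        on <- if (params$clone_polarity == "positive") truth$clone[i] else !truth$clone[i]
        if (!on) next
        amp <- params$gain
      } else {
        amp <- params$gain * truth[[paste0(ch, "_true")]][i]
      }
      if (amp <= 0) next
      sig <- truth$diameter_um[i] / 4
      ctr <- centers[i, ]
      lo <- pmax(1L, floor((ctr - 3 * sig) / vs) + 1L)
      hi <- pmin(dims, ceiling((ctr + 3 * sig) / vs) + 1L)
      zi <- lo[1]:hi[1]; yi <- lo[2]:hi[2]; xi <- lo[3]:hi[3]
      gz <- exp(-((zi - 1) * vs[1] - ctr[1])^2 / (2 * sig^2))
      gy <- exp(-((yi - 1) * vs[2] - ctr[2])^2 / (2 * sig^2))
      gx <- exp(-((xi - 1) * vs[3] - ctr[3])^2 / (2 * sig^2))
      blob <- amp * outer(outer(gz, gy), gx)
      vol[zi, yi, xi] <- vol[zi, yi, xi] + blob
    }
    if (att > 0 && !params$laser_corrected)
      vol <- vol * exp(-att * zc)  # recycles along z (first dim)
    if (params$psf_sigma > 0)
      vol <- gaussian_blur3d(vol, params$psf_sigma / vs)
    vol <- vol + params$background_level
    if (params$noise$poisson_scale > 0) {
      s <- params$noise$poisson_scale
      vol[] <- stats::rpois(length(vol), pmax(vol, 0) * s) / s
    }
    if (params$noise$gaussian_sd > 0)
      vol <- vol + stats::rnorm(length(vol), 0, params$noise$gaussian_sd)
    arr[, , , ci] <- pmin(pmax(round(vol), 0), 65535)
  }
  voxel_stack(arr, vs, channels)
}

#' Write a phantom to disk (stack TIFF + truth CSV)
#'
#' @param phantom list from [generate_phantom()]
#' @param out_prefix path prefix; writes `<prefix>.tif`, `<prefix>.tif.meta.yaml`
#'   and `<prefix>_truth.csv`
#' @return invisible named character vector of written paths
#' @export
write_phantom <- function(phantom, out_prefix) {
  stack_path <- paste0(out_prefix, ".tif")
  truth_path <- paste0(out_prefix, "_truth.csv")
  write_stack(phantom$stack, stack_path)
  utils::write.csv(phantom$truth, truth_path, row.names = FALSE)
  invisible(c(stack = stack_path, truth = truth_path))
}
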