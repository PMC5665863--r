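#' Pipeline run configuration
#'
#' Collects every tunable the staged pipeline needs. `channel_roles` maps
#' roles onto stack channel names; markers are quantified and normalized,
#' the clone channel assigns clone/control labels with the stated
#' polarity. Region `boundaries` are AP positions in um (user landmarks),
#' or the phantom defaults. `normalization` selects the mode applied to
#' marker channels: `"max"` (per-sample maximum), `"control_mean"`
#' (internal-control mean), or `"decay"` (one-phase-decay prediction
#' fitted on control cells, for reporter gradients).
#'
#' @param nuclear_stain,clone_marker channel names
#' @param markers character vector of marker/reporter channel names
#' @param clone_polarity `"positive"` (marker present in clone cells) or
#'   `"negative"` (marker lost in clone cells)
#' @param coarse_diameter,core_diameter detection diameters (um);
#'   `coarse >= core > 0`
#' @param sensitivity blob-detection sensitivity in (0, 1)
#' @param n_background_spots background spot count (conventionally 8-12)
#' @param normalization one of `"max"`, `"control_mean"`, `"decay"`
#' @param boundaries region boundaries (um) or `"from-truth"` to take the
#'   phantom defaults
#' @param anterior_hint (z,y,x) anterior direction, or `"from-truth"`
#' @param alpha significance level for downstream tests
#' @param depth_tolerance depth-bias QC tolerance
#' @param seed RNG seed for stochastic stages (background placement)
#' @return a `run_config` object
#' @export
run_config <- function(nuclear_stain = "nuclear",
                       markers = c("eya", "cas", "wnt_reporter"),
                       clone_marker = "clone",
                       clone_polarity = c("positive", "negative"),
                       coarse_diameter = 2.5,
                       core_diameter = 1.75,
                       sensitivity = 0.3,
                       n_background_spots = 10,
                       normalization = "max",
                       boundaries = "from-truth",
                       anterior_hint = "from-truth",
                       alpha = 0.05,
                       depth_tolerance = 0.15,
                       seed = 1) {
  clone_polarity <- match.arg(clone_polarity)
  if (!normalization %in% c("max", "control_mean", "decay"))
    stopf("unknown normalization mode '%s'", normalization)
  if (!(coarse_diameter >= core_diameter && core_diameter > 0))
    stopf("need coarse_diameter >= core_diameter > 0")
  if (alpha <= 0 || alpha >= 1) stopf("alpha must be in (0, 1)")
  structure(list(nuclear_stain = nuclear_stain, markers = markers,
                 clone_marker = clone_marker, clone_polarity = clone_polarity,
                 coarse_diameter = coarse_diameter,
                 core_diameter = core_diameter, sensitivity = sensitivity,
                 n_background_spots = n_background_spots,
                 normalization = normalization, boundaries = boundaries,
                 anterior_hint = anterior_hint, alpha = alpha,
                 depth_tolerance = depth_tolerance, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full quantification pipeline on one stack
#'
#' Stage order is fixed: detect (coarse then core), QC-flag, measure,
#' background-subtract, orient (sagittal plane, canonical rotation, AP
#' coordinate, regions), clone-label, depth QC, normalize. Each stage is
#' logged with its parameters. Deterministic given `config$seed`.
#'
#' @param stack a [voxel_stack] (or a TIFF path readable by [read_stack()])
#' @param config a [run_config]
#' @param truth optional phantom truth (enables `"from-truth"` hints and
#'   adds matched `<ch>_true` columns for validation)
#' @param sample_id sample label stored in the table
#' @return list: `cells` (the cell table), `frame` (the recovered
#'   [rigid_frame]), `background`, `depth_qc`, `decay_fits` (when
#'   normalization = "decay"), `log` (per-stage records)
#' @export
run_pipeline <- function(stack, config = run_config(), truth = NULL,
                         sample_id = "sample1") {
  stopifnot(inherits(config, "run_config"))
  if (is.character(stack)) stack <- read_stack(stack)
  log <- list()
  stage <- function(name, ...) {
    log[[length(log) + 1]] <<- c(list(stage = name), list(...))
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  coarse <- run_stage("detect", detect_spots(stack, config$nuclear_stain,
                                             config$coarse_diameter,
                                             config$sensitivity))
  stage("detect", diameter = config$coarse_diameter,
        sensitivity = config$sensitivity, n_spots = nrow(coarse))
  if (nrow(coarse) == 0) stopf("pipeline stage 'detect' found no nuclei")
  cores <- run_stage("refine", refine_cores(stack, coarse, config$core_diameter))
  stage("refine", core_diameter = config$core_diameter)
  qc_flag <- run_stage("qc_flags",
                       suppressWarnings(flag_excluded(stack, cores,
                                                      config$nuclear_stain)))
  stage("qc_flags", n_flagged = sum(qc_flag))

  raw <- run_stage("measure", measure_intensities(stack, cores))
  stage("measure", n_cells = nrow(raw))
  bg <- run_stage("background",
                  estimate_background(stack, coarse,
                                      n_spots = config$n_background_spots,
                                      core_diameter = config$core_diameter,
                                      nuclear_channel = config$nuclear_stain,
                                      seed = config$seed))
  raw <- subtract_background(raw, bg)
  stage("background", n_spots = bg$n_spots,
        bg_nuclear = unname(bg$mean[config$nuclear_stain]))

  centers <- as.matrix(as.data.frame(cores)[, c("z_um", "y_um", "x_um")])
  hint <- config$anterior_hint
  if (identical(hint, "from-truth")) {
    if (is.null(truth)) stopf("anterior_hint 'from-truth' needs a truth table")
    hint <- attr(truth, "anterior_stack")
  }
  plane <- run_stage("orient", fit_sagittal_plane(centers))
  canon <- run_stage("orient", rotate_to_canonical(centers, plane, hint))
  ap <- assign_ap_coordinate(canon$centers)
  boundaries <- config$boundaries
  if (identical(boundaries, "from-truth")) boundaries <- default_region_boundaries()
  region <- label_regions(ap, boundaries)
  stage("orient", boundaries = boundaries)

  cells <- data.frame(cell_id = cores$id, sample_id = sample_id,
                      z_um = cores$z_um, y_um = cores$y_um, x_um = cores$x_um,
                      core_radius_um = cores$diameter_um / 2,
                      ap_um = ap, region = region)
  for (ch in c(config$nuclear_stain, config$markers, config$clone_marker)) {
    for (suffix in c("_raw", "_bgsub")) {
      cl <- paste0(ch, suffix)
      if (cl %in% names(raw)) cells[[cl]] <- raw[[cl]]
    }
  }
  cells$qc <- ifelse(qc_flag, "excluded_division_death", "")
  cells$qc <- ifelse(cores$low_signal,
                     trimws(paste(cells$qc, "low_signal")), cells$qc)
  cells$qc <- ifelse(raw$edge, trimws(paste(cells$qc, "edge")), cells$qc)
  excl <- qc_flag

  # clone labels from the clone-marker channel (bimodal: on/off)
  cl_col <- paste0(config$clone_marker, "_bgsub")
  if (cl_col %in% names(cells)) {
    v <- cells[[cl_col]]
    thr <- max(v) / 2
    marker_on <- if (max(v) > 0) v >= thr else rep(FALSE, length(v))
    is_clone <- if (config$clone_polarity == "positive") marker_on else !marker_on
    cells$clone <- ifelse(is_clone, "mutant", "control")
  } else {
    cells$clone <- "unassigned"
  }
  stage("clone_labels", n_mutant = sum(cells$clone == "mutant"))

  zb <- stats::quantile(cells$z_um, c(1/3, 2/3))
  cells$depth_band <- as.character(cut(cells$z_um, c(-Inf, zb, Inf),
                                       labels = c("top", "middle", "bottom")))
  dqc <- suppressWarnings(
    depth_bias_qc(cells$z_um, cells[[paste0(config$nuclear_stain, "_bgsub")]],
                  control = cells$clone != "mutant",
                  tolerance = config$depth_tolerance))
  stage("depth_qc", max_ratio = dqc$max_ratio, pass = dqc$pass)

  decay_fits <- NULL
  for (ch in config$markers) {
    v <- cells[[paste0(ch, "_bgsub")]]
    norm <- switch(config$normalization,
      max = normalize_max(v, cells$sample_id, exclude = excl),
      control_mean = normalize_to_control_mean(v, cells$clone == "control",
                                               in_scope = !excl),
      decay = {
        ctrl <- cells$clone == "control" & !excl
        fit <- fit_one_phase_decay(cells$ap_um[ctrl], v[ctrl])
        decay_fits[[ch]] <- fit
        normalize_to_decay_prediction(v, cells$ap_um, fit)$normalized
      })
    cells[[paste0(ch, "_norm")]] <- norm
  }
  stage("normalize", mode = config$normalization)

  if (!is.null(truth)) {
    # nearest-truth match gives each detected cell its ground-truth record
    Tm <- as.matrix(truth[, c("z_um", "y_um", "x_um")])
    D <- outer(rowSums(centers^2), rowSums(Tm^2), `+`) - 2 * centers %*% t(Tm)
    nn <- apply(D, 1, which.min)
    for (cl in grep("_true$", names(truth), value = TRUE))
      cells[[cl]] <- truth[[cl]][nn]
    cells$true_ap_um <- truth$ap_um[nn]
    cells$true_clone <- truth$clone[nn]
    cells$truth_id <- truth$id[nn]
  }

  list(cells = cells, frame = canon$frame, background = bg, depth_qc = dqc,
       decay_fits = decay_fits, log = log)
}
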