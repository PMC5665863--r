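# Shared fixtures: everything is generated in code, no files on disk.

# Small, fast phantom used by most unit tests (sub-second render).
tiny_params <- function(seed = 1, n_cells = 12, ...) {
  phantom_params(
    n_cells = n_cells,
    shell = list(semi_axes = c(z = 2, y = 5, x = 8), thickness = 0.8),
    tilt_deg = 8,
    seed = seed,
    ...
  )
}

# Noise-free imaging: no attenuation bias, no PSF, no background, no noise.
clean_imaging <- function(params) {
  params$psf_sigma <- 0
  params$background_level <- 0
  params$noise <- list(gaussian_sd = 0, poisson_scale = 0)
  params$attenuation_per_um <- 0
  params
}

# Hand-built spot_set for tests that bypass detection.
make_spots <- function(centers, diameter, pass = "core", channel = "nuclear") {
  df <- data.frame(id = seq_len(nrow(centers)),
                   z_um = centers[, 1], y_um = centers[, 2],
                   x_um = centers[, 3], diameter_um = diameter,
                   score = 1, low_signal = FALSE)
  germaquant:::new_spot_set(df, pass, channel, diameter)
}

# Brute-force masked intensity centroid (oracle for core refinement).
centroid_oracle <- function(vol, voxel_size, center, radius) {
  dims <- dim(vol)
  co <- expand.grid(z = (seq_len(dims[1]) - 1) * voxel_size[1],
                    y = (seq_len(dims[2]) - 1) * voxel_size[2],
                    x = (seq_len(dims[3]) - 1) * voxel_size[3])
  # expand.grid varies the first factor fastest = R column-major order
  d2 <- (co$z - center[1])^2 + (co$y - center[2])^2 + (co$x - center[3])^2
  keep <- d2 <= radius^2
  w <- as.vector(vol)[keep]
  c(sum(co$z[keep] * w), sum(co$y[keep] * w), sum(co$x[keep] * w)) / sum(w)
}

# Angle (degrees) between two direction vectors, sign-agnostic.
axis_angle_deg <- function(u, v) {
  acos(min(1, abs(sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
}
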