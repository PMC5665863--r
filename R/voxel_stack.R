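#' Multi-channel 3D intensity stack with physical voxel sizes
#'
#' A `voxel_stack` wraps a 4-D numeric array indexed `[z, y, x, channel]`
#' together with per-axis voxel sizes in micrometres and unique channel
#' names. All downstream geometry is done in physical um through
#' `voxel_size`; voxel `[1,1,1]` has its centre at the coordinate origin.
#'
#' @param data 4-D non-negative numeric array, dims (z, y, x, channel). A 3-D
#'   array is accepted as a single channel.
#' @param voxel_size numeric length-3, (z, y, x) voxel edge in um, all > 0.
#' @param channels character vector of unique channel names, one per channel.
#' @return An object of class `voxel_stack`.
#' @export
voxel_stack <- function(data, voxel_size, channels = NULL) {
  if (length(dim(data)) == 3) dim(data) <- c(dim(data), 1L)
  if (length(dim(data)) != 4) stopf("data must be a 3-D or 4-D array")
  if (any(data < 0)) stopf("intensities must be non-negative")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3 || any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stopf("voxel_size must be three positive values (z, y, x) in um")
  nc <- dim(data)[4]
  if (is.null(channels)) channels <- paste0("ch", seq_len(nc))
  if (length(channels) != nc)
    stopf("channel names (%d) do not match channel axis length (%d)",
          length(channels), nc)
  if (anyDuplicated(channels)) stopf("channel names must be unique")
  dimnames(data) <- list(NULL, NULL, NULL, channels)
  structure(list(data = data, voxel_size = voxel_size, channels = channels),
            class = "voxel_stack")
}

#' @export
print.voxel_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_stack> %d x %d x %d voxels (z,y,x), %d channel(s)\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  voxel size (um): z=%.3g y=%.3g x=%.3g\n",
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  cat("  channels:", paste(x$channels, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.voxel_stack <- function(x) dim(x$data)

#' Extract one channel as a 3-D array
#' @param stack a [voxel_stack]
#' @param channel channel name or index
#' @return 3-D numeric array (z, y, x)
#' @export
stack_channel <- function(stack, channel) {
  stopifnot(inherits(stack, "voxel_stack"))
  if (is.character(channel)) {
    if (!channel %in% stack$channels)
      stopf("unknown channel '%s' (have: %s)", channel,
            paste(stack$channels, collapse = ", "))
  }
  stack$data[, , , channel, drop = TRUE]
}

#' Write a stack as multi-page 16-bit TIFF with a YAML metadata sidecar
#'
#' Pages are ordered channel-major (all z planes of channel 1, then channel
#' 2, ...). Intensities must be integers in \[0, 65535\] (the renderer's
#' count scale); they round-trip bitwise through [read_stack()]. Voxel
#' sizes and channel names go to `<path>.meta.yaml` because baseline TIFF
#' carries no 3-D voxel metadata.
#'
#' @param stack a [voxel_stack] with integer-valued data in \[0, 65535\]
#' @param path output TIFF path
#' @return `path`, invisibly
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "voxel_stack"))
  d <- dim(stack$data)
  if (max(stack$data) > 65535 || any(stack$data != round(stack$data)))
    stopf("write_stack stores 16-bit counts: data must be integers in [0, 65535]")
  pages <- vector("list", d[1] * d[4])
  k <- 1L
  for (ci in seq_len(d[4])) {
    for (zi in seq_len(d[1])) {
      pages[[k]] <- stack$data[zi, , , ci] / 65535
      k <- k + 1L
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "LZW")
  meta <- list(voxel_size_um = as.list(stats::setNames(stack$voxel_size, c("z", "y", "x"))),
               channels = as.list(stack$channels),
               n_z = d[1], n_y = d[2], n_x = d[3],
               page_order = "channel_major", scale = 65535)
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  invisible(path)
}

#' Read a multi-page TIFF stack written by [write_stack()] (or a plain TIFF)
#'
#' Voxel size and channel names come from the YAML sidecar when present;
#' otherwise they must be supplied. A plain 3-D TIFF with no sidecar and
#' `channels` of length 1 is read as a single-channel stack.
#'
#' @param path TIFF path
#' @param voxel_size optional (z,y,x) um override
#' @param channels optional channel-name override; its length must match the
#'   channel count implied by the metadata (or 1 for a plain stack)
#' @return a [voxel_stack]
#' @export
read_stack <- function(path, voxel_size = NULL, channels = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta_path <- paste0(path, ".meta.yaml")
  meta <- if (file.exists(meta_path)) yaml::read_yaml(meta_path) else NULL
  if (is.null(voxel_size)) {
    if (is.null(meta))
      stopf("no voxel size: %s has no metadata sidecar and none was supplied", path)
    voxel_size <- unlist(meta$voxel_size_um)[c("z", "y", "x")]
  }
  scale <- if (!is.null(meta)) meta$scale else 65535
  if (is.null(channels)) {
    channels <- if (!is.null(meta)) unlist(meta$channels) else "ch1"
  } else if (!is.null(meta) && length(channels) != length(meta$channels)) {
    stopf("config names %d channels but file has %d",
          length(channels), length(meta$channels))
  }
  nc <- length(channels)
  nz_total <- length(pages)
  if (nz_total %% nc != 0)
    stopf("page count %d is not divisible by %d channels", nz_total, nc)
  nz <- nz_total %/% nc
  d2 <- dim(pages[[1]])
  arr <- array(0, c(nz, d2[1], d2[2], nc))
  k <- 1L
  for (ci in seq_len(nc)) {
    for (zi in seq_len(nz)) {
      arr[zi, , , ci] <- round(pages[[k]] * scale)
      k <- k + 1L
    }
  }
  voxel_stack(arr, voxel_size, channels)
}
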