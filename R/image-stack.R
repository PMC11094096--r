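#' Multi-channel fluorescence image stack
#'
#' Container for confocal-style voxel data: one 3D array per channel
#' (x, y, z), a common lateral pixel size and axial step.
#'
#' @param channels named list of 3D numeric arrays with identical dimensions
#'   (intensities in \[0, 1\]); 2D matrices are promoted to single-plane
#'   stacks.
#' @param pixel_size_xy lateral pixel size in um/px.
#' @param z_step axial plane spacing in um.
#' @param bit_depth nominal camera bit depth (metadata only).
#' @return An object of class `"image_stack"`.
#' @export
image_stack <- function(channels, pixel_size_xy, z_step = 0.25,
                        bit_depth = 12L) {
  if (is.null(names(channels)) || any(names(channels) == ""))
    stop("'channels' must be a named list")
  channels <- lapply(channels, function(a) {
    if (length(dim(a)) == 2L) dim(a) <- c(dim(a), 1L)
    a
  })
  dims <- lapply(channels, dim)
  if (length(unique(lapply(dims, identity))) != 1L)
    stop("all channels must have identical dimensions")
  if (pixel_size_xy <= 0 || z_step <= 0)
    stop("pixel sizes must be positive")
  structure(list(channels = channels, pixel_size_xy = pixel_size_xy,
                 z_step = z_step, bit_depth = bit_depth),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<image_stack> %dx%dx%d, %d channel(s) [%s], %g um/px, dz %g um\n",
              d[1], d[2], d[3], length(x$channels),
              paste(names(x$channels), collapse = ", "),
              x$pixel_size_xy, x$z_step))
  invisible(x)
}

.get_channel <- function(stack, channel) {
  if (!channel %in% names(stack$channels))
    stop(sprintf("unknown channel '%s' (have: %s)", channel,
                 paste(names(stack$channels), collapse = ", ")))
  stack$channels[[channel]]
}
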