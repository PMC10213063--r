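#' Multi-channel 3D image stack
#'
#' Container for a confocal stack with physical voxel dimensions. Voxel data
#' are stored as a 4-dimensional array indexed `[z, x, y, channel]` so that a
#' single x-z plane (the unit of analysis throughout the package) is a
#' contiguous `nz x nx` matrix. Pixel coordinates are 0-based everywhere in
#' the public interface: the array element `[r, c, , ]` holds the voxel at
#' `z = r - 1`, `x = c - 1`.
#'
#' @param data numeric array, either 3D (`z, x, y`, single channel) or 4D
#'   (`z, x, y, channel`). Intensities are conventionally in `[0, 1]` but
#'   this is not enforced (additive noise may leave the range slightly).
#' @param voxel_size_um numeric length-3, physical size of a voxel in
#'   micrometers as `c(dx, dy, dz)`.
#' @param channels character vector naming the channels, length equal to the
#'   4th extent of `data`.
#' @return an object of class `ImageStack` with elements `data`,
#'   `voxel_size_um` and `channels`.
#' @export
image_stack <- function(data, voxel_size_um = c(0.21, 0.21, 0.45),
                        channels = NULL) {
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data), 1L)
  stopifnot(length(dim(data)) == 4L, length(voxel_size_um) == 3L,
            all(voxel_size_um > 0))
  if (is.null(channels)) channels <- paste0("ch", seq_len(dim(data)[4]))
  stopifnot(length(channels) == dim(data)[4])
  structure(
    list(data = data,
         voxel_size_um = as.numeric(voxel_size_um),
         channels = as.character(channels)),
    class = "ImageStack")
}

#' @export
print.ImageStack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("ImageStack: %d x %d x %d voxels (x, y, z), %d channel(s)\n",
              d[2], d[3], d[1], d[4]))
  cat(sprintf("  voxel size: %.3g x %.3g x %.3g um (dx, dy, dz)\n",
              x$voxel_size_um[1], x$voxel_size_um[2], x$voxel_size_um[3]))
  cat("  channels:", paste(x$channels, collapse = ", "), "\n")
  invisible(x)
}

#' Extract one x-z plane from a stack
#'
#' @param stack an [image_stack()].
#' @param y 0-based y index of the plane.
#' @param channel channel name or 1-based channel index.
#' @return `nz x nx` numeric matrix; rows are z (0-based coordinate
#'   `row - 1`), columns are x.
#' @export
xz_plane <- function(stack, y, channel) {
  stopifnot(inherits(stack, "ImageStack"))
  ch <- if (is.character(channel)) match(channel, stack$channels) else channel
  if (is.na(ch) || ch < 1 || ch > dim(stack$data)[4])
    stop("unknown channel: ", channel)
  yy <- as.integer(y) + 1L
  if (yy < 1L || yy > dim(stack$data)[3]) stop("y index out of range: ", y)
  stack$data[, , yy, ch]
}

#' @rdname xz_plane
#' @export
n_planes <- function(stack) dim(stack$data)[3]
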