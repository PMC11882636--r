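#' Calibrated 3D intensity volume
#'
#' A `voxel_grid` wraps a 3D numeric array in axis order (z, y, x) together
#' with its physical voxel spacing in micrometres.  All volume measurements
#' in the package are derived from `spacing`, so a grid cannot be built
#' without it.
#'
#' @param data 3D numeric array, axis order (z, y, x).
#' @param spacing Numeric length-3, voxel spacing `(dz, dy, dx)` in um;
#'   all entries must be positive.
#' @param channel Optional channel name.
#' @return An object of class `voxel_grid` with elements `data`, `spacing`
#'   and `channel`.
#' @examples
#' g <- voxel_grid(array(0, c(4, 8, 8)), spacing = c(0.3, 0.1, 0.1))
#' voxel_volume(g)
#' @export
voxel_grid <- function(data, spacing, channel = "") {
  if (length(dim(data)) != 3L) abort("`data` must be a 3D array (z, y, x).")
  if (any(dim(data) < 1L)) abort("all dimensions must be >= 1.")
  if (length(spacing) != 3L || !is.numeric(spacing) || any(!is.finite(spacing)) ||
      any(spacing <= 0)) {
    abort("`spacing` must be three positive finite numbers (dz, dy, dx) in um.")
  }
  if (any(!is.finite(data))) abort("intensities must be finite.")
  structure(list(data = data, spacing = as.numeric(spacing),
                 channel = as.character(channel)[1]),
            class = "voxel_grid")
}

#' @rdname voxel_grid
#' @param x A `voxel_grid`.
#' @export
voxel_volume <- function(x) {
  sp <- if (inherits(x, "voxel_grid")) x$spacing else x
  prod(sp)
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_grid> %d x %d x %d (z,y,x), spacing %.4g x %.4g x %.4g um%s\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              if (nzchar(x$channel)) paste0(", channel '", x$channel, "'") else ""))
  invisible(x)
}

#' Calibrated 2D intensity image
#'
#' A `plane_image` wraps a 2D numeric matrix in axis order (y, x), with an
#' optional isotropic pixel size in micrometres per pixel.  When
#' `pixel_size` is absent, areas and distances are reported in pixel units.
#'
#' @param data 2D numeric matrix, axis order (y, x).
#' @param pixel_size Pixel size in um/px, or `NULL` for uncalibrated images.
#' @param channel Optional channel name.
#' @return An object of class `plane_image`.
#' @examples
#' img <- plane_image(matrix(0, 16, 16), pixel_size = 0.325)
#' @export
plane_image <- function(data, pixel_size = NULL, channel = "") {
  if (is.null(dim(data)) || length(dim(data)) != 2L) {
    abort("`data` must be a 2D matrix (y, x).")
  }
  if (!is.null(pixel_size)) {
    if (!is.numeric(pixel_size) || length(pixel_size) != 1L ||
        !is.finite(pixel_size) || pixel_size <= 0) {
      abort("`pixel_size` must be a single positive number (um/px).")
    }
    pixel_size <- as.numeric(pixel_size)
  }
  if (any(!is.finite(data))) abort("intensities must be finite.")
  structure(list(data = data, pixel_size = pixel_size,
                 channel = as.character(channel)[1]),
            class = "plane_image")
}

#' @export
print.plane_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<plane_image> %d x %d (y,x)%s%s\n", d[1], d[2],
              if (!is.null(x$pixel_size)) sprintf(", %.4g um/px", x$pixel_size) else "",
              if (nzchar(x$channel)) paste0(", channel '", x$channel, "'") else ""))
  invisible(x)
}

# coerce raw matrices/arrays where a container is expected
as_plane_image <- function(x) {
  if (inherits(x, "plane_image")) return(x)
  plane_image(x)
}

as_voxel_grid <- function(x, spacing = NULL) {
  if (inherits(x, "voxel_grid")) return(x)
  if (is.null(spacing)) abort("spacing required to build a voxel_grid from an array.")
  voxel_grid(x, spacing)
}
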