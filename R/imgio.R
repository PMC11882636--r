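#' Read a multi-page TIFF stack as a calibrated volume
#'
#' Pages are interpreted as ascending z slices.  Voxel spacing is taken
#' from a JSON sidecar (keys `dz_um`, `dy_um`, `dx_um`) or passed
#' explicitly; without spacing, physical volumes would be meaningless, so
#' the read fails.
#'
#' Integer-typed TIFF data (8/16-bit) are restored to their original
#' integer intensity values exactly; 32-bit float pages are read as-is.
#'
#' @param path Path to a grayscale multi-page TIFF.
#' @param sidecar_path Path to the spacing sidecar JSON.  Defaults to
#'   `<path>.json` when that file exists.
#' @param spacing Optional `(dz, dy, dx)` in um, overriding the sidecar.
#' @param channel Channel name to record on the grid.
#' @return A [voxel_grid].
#' @seealso [write_stack()]
#' @export
read_stack <- function(path, sidecar_path = NULL, spacing = NULL, channel = "") {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  if (is.null(sidecar_path)) {
    guess <- paste0(path, ".json")
    if (file.exists(guess)) sidecar_path <- guess
  }
  scale <- 1
  if (!is.null(sidecar_path) && file.exists(sidecar_path)) {
    meta <- read_spacing_sidecar(sidecar_path)
    if (is.null(spacing)) spacing <- meta$spacing
    scale <- meta$intensity_scale
  }
  if (is.null(spacing)) {
    abort("voxel spacing missing: supply `spacing` or a sidecar JSON with dz_um/dy_um/dx_um.")
  }
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  dims <- vapply(pages, function(p) dim(p)[1:2], integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    abort("ragged TIFF: pages have differing dimensions.")
  }
  bits <- attr(pages[[1]], "bits.per.sample")
  nz <- length(pages)
  arr <- array(0, c(nz, dims[1, 1], dims[2, 1]))
  for (z in seq_len(nz)) arr[z, , ] <- pages[[z]]
  if (!is.null(bits) && bits %in% c(8L, 16L)) {
    arr <- round(arr * (2^bits - 1))  # restore exact integer intensities
  } else {
    arr <- arr * scale                # 32-bit float pages carry data/scale
  }
  voxel_grid(arr, spacing, channel = channel)
}

#' Write a calibrated volume as a multi-page TIFF plus spacing sidecar
#'
#' Slices are written as TIFF pages in ascending z.  Non-negative integer
#' data up to 65535 are stored as 16-bit (8-bit when they fit) and round
#' trip exactly; anything else is stored as 32-bit float.
#'
#' @param grid A [voxel_grid] (or 3D array with `spacing` given).
#' @param path Output TIFF path.
#' @param sidecar_path Output JSON sidecar path; default `<path>.json`.
#' @param spacing Spacing when `grid` is a plain array.
#' @return `path`, invisibly.
#' @export
write_stack <- function(grid, path, sidecar_path = paste0(path, ".json"),
                        spacing = NULL) {
  grid <- as_voxel_grid(grid, spacing)
  a <- grid$data
  nz <- dim(a)[1]
  if (any(a < 0)) abort("intensities must be non-negative for TIFF export.")
  pages <- lapply(seq_len(nz), function(z) a[z, , , drop = TRUE])
  is_int <- all(a == round(a)) && max(a) <= 65535
  scale <- 1
  if (is_int) {
    bits <- if (max(a) <= 255) 8L else 16L
    denom <- 2^bits - 1
    pages <- lapply(pages, function(p) matrix(p / denom, nrow(p), ncol(p)))
    tiff::writeTIFF(pages, path, bits.per.sample = bits)
  } else {
    # 32-bit float pages must lie in [0, 1]; the scale is restored on read
    scale <- max(max(a), 1)
    pages <- lapply(pages, function(p) matrix(as.numeric(p) / scale,
                                              nrow(p), ncol(p)))
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  }
  write_spacing_sidecar(grid$spacing, sidecar_path, intensity_scale = scale)
  invisible(path)
}

read_spacing_sidecar <- function(path) {
  meta <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("dz_um", "dy_um", "dx_um")
  if (!all(need %in% names(meta))) {
    abort("sidecar must contain dz_um, dy_um and dx_um.")
  }
  sp <- as.numeric(c(meta$dz_um, meta$dy_um, meta$dx_um))
  if (any(!is.finite(sp)) || any(sp <= 0)) abort("sidecar spacing must be positive.")
  list(spacing = sp,
       intensity_scale = if (is.null(meta$intensity_scale)) 1
                         else as.numeric(meta$intensity_scale))
}

write_spacing_sidecar <- function(spacing, path, intensity_scale = 1) {
  jsonlite::write_json(
    list(dz_um = spacing[1], dy_um = spacing[2], dx_um = spacing[3],
         axes = "zyx", index_base = 0, intensity_scale = intensity_scale),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read / write a single 2D grayscale TIFF
#'
#' Integer data (8/16-bit) round trip exactly; other data are stored as
#' 32-bit float scaled into `[0, 1]`, with the scale and any pixel size
#' recorded in a JSON sidecar (`<path>.json`) and restored on read.
#'
#' @param path TIFF path.
#' @param pixel_size Optional um/px calibration; on read this overrides a
#'   sidecar value.
#' @param channel Channel name.
#' @return [read_plane()] returns a [plane_image]; [write_plane()] returns
#'   `path` invisibly.
#' @export
read_plane <- function(path, pixel_size = NULL, channel = "") {
  m <- tiff::readTIFF(path, info = TRUE)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  bits <- attr(m, "bits.per.sample")
  m <- matrix(as.numeric(m), nrow(m), ncol(m))
  scale <- 1
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$intensity_scale)) scale <- as.numeric(meta$intensity_scale)
    if (is.null(pixel_size) && !is.null(meta$pixel_size_um)) {
      pixel_size <- as.numeric(meta$pixel_size_um)
    }
  }
  m <- if (!is.null(bits) && bits %in% c(8L, 16L)) round(m * (2^bits - 1))
       else m * scale
  plane_image(m, pixel_size = pixel_size, channel = channel)
}

#' @rdname read_plane
#' @param img A [plane_image] or matrix.
#' @export
write_plane <- function(img, path) {
  img <- as_plane_image(img)
  m <- img$data
  if (any(m < 0)) abort("intensities must be non-negative for TIFF export.")
  is_int <- all(m == round(m)) && max(m) <= 65535
  scale <- 1
  if (is_int) {
    bits <- if (max(m) <= 255) 8L else 16L
    tiff::writeTIFF(m / (2^bits - 1), path, bits.per.sample = bits)
  } else {
    scale <- max(max(m), 1)
    tiff::writeTIFF(matrix(as.numeric(m) / scale, nrow(m), ncol(m)), path,
                    bits.per.sample = 32L)
  }
  meta <- list(intensity_scale = scale)
  if (!is.null(img$pixel_size)) meta$pixel_size_um <- img$pixel_size
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write tabular records as deterministic CSV
#'
#' Columns are written in their existing order, numeric fields at full
#' precision (up to 15 significant digits), UTF-8, with a header row.
#' Two runs on the same input produce byte-identical files.
#'
#' @param records A data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  records <- as.data.frame(records)
  num <- vapply(records, is.numeric, logical(1))
  for (j in which(num)) {
    records[[j]] <- vapply(records[[j]], function(v) {
      if (is.na(v)) "" else format(v, digits = 15, scientific = FALSE, trim = TRUE)
    }, character(1))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(records), collapse = ","), con, useBytes = TRUE)
  if (nrow(records) > 0) {
    rows <- do.call(paste, c(unname(as.list(records)), sep = ","))
    writeLines(rows, con, useBytes = TRUE)
  }
  invisible(path)
}

#' Read a pipeline configuration file
#'
#' Thin wrapper over YAML parsing so configuration handling is uniform
#' across the command-line scripts.
#'
#' @param path YAML file path.
#' @return A named list.
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}
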