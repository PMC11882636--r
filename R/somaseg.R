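#' Interpolate sparse per-slice traces into a dense 3D soma mask
#'
#' Implements shape-based interpolation: each untraced slice strictly
#' between two consecutive traced slices `z0 < z1` is the zero-superlevel
#' set of the linear blend `(1 - w) * D0 + w * D1` of the signed Euclidean
#' distance transforms of the bounding traced slices, with
#' `w = (z - z0) / (z1 - z0)`.  Signed distance is positive inside the
#' traced region (pixel units on each 2D slice, with the zero level at
#' the half-pixel boundary between foreground and background pixel
#' centers); pixels exactly at the zero level count as inside.  Traced
#' slices pass through unchanged and
#' slices outside `[min traced z, max traced z]` stay empty, so the
#' result agrees voxelwise with the input at every traced slice.
#'
#' Manual post-correction of a poorly interpolated slice is expressed by
#' adding that slice to the trace set and re-interpolating.
#'
#' @param traces A [sparse_traces()] object with at least one traced slice.
#' @return A `soma_mask`: a list with the dense logical `mask` (z, y, x)
#'   and `traced`, the 0-based indices of the traced slices.
#' @examples
#' disk <- function(r, n = 32) {
#'   d <- outer((1:n) - n / 2, (1:n) - n / 2, function(y, x) sqrt(y^2 + x^2))
#'   d <= r
#' }
#' tr <- sparse_traces(list(`0` = disk(10), `2` = disk(20)), z_extent = 3)
#' m <- interpolate_traces(tr)
#' sum(m$mask[2, , ])  # intermediate slice is a disk of radius ~15
#' @export
interpolate_traces <- function(traces) {
  if (!inherits(traces, "sparse_traces")) abort("`traces` must be a sparse_traces object.")
  if (length(traces$traces) == 0L) abort("at least one traced slice is required.")
  idx <- as.integer(names(traces$traces))
  shp <- traces$shape_yx
  nz <- traces$z_extent
  mask <- array(FALSE, c(nz, shp[1], shp[2]))
  for (i in seq_along(idx)) mask[idx[i] + 1L, , ] <- traces$traces[[i]]
  if (length(idx) > 1L) {
    sdts <- lapply(traces$traces, signed_distance)
    for (i in seq_len(length(idx) - 1L)) {
      z0 <- idx[i]; z1 <- idx[i + 1L]
      if (z1 - z0 < 2L) next
      d0 <- sdts[[i]]; d1 <- sdts[[i + 1L]]
      for (z in (z0 + 1L):(z1 - 1L)) {
        w <- (z - z0) / (z1 - z0)
        mask[z + 1L, , ] <- (1 - w) * d0 + w * d1 >= 0
      }
    }
  }
  soma_mask(mask, traced = idx)
}

# signed Euclidean distance in pixel units, positive inside the mask.
# Pixel-to-pixel distances are offset by half a pixel so the zero level
# sits on the region boundary (midway between the innermost background
# and outermost foreground pixel centers) instead of half a pixel out.
# Degenerate slices (all background / all foreground) get a constant
# pseudo-distance of -+(diagonal) so that blending toward them shrinks or
# grows shapes progressively instead of failing.
signed_distance <- function(m) {
  m <- m != 0
  big <- sqrt(nrow(m)^2 + ncol(m)^2)
  if (!any(m)) return(matrix(-big, nrow(m), ncol(m)))
  if (all(m)) return(matrix(big, nrow(m), ncol(m)))
  inside <- edt2d_cpp(m)     # distance of inside pixels to nearest outside
  outside <- edt2d_cpp(!m)   # distance of outside pixels to nearest inside
  ifelse(m, inside - 0.5, -(outside - 0.5))
}

#' Construct a soma mask
#'
#' @param mask Logical 3D array (z, y, x).
#' @param traced Integer vector of 0-based traced slice indices
#'   (provenance).
#' @return A `soma_mask` object.
#' @export
soma_mask <- function(mask, traced = integer(0)) {
  if (length(dim(mask)) != 3L) abort("`mask` must be a 3D array.")
  structure(list(mask = mask != 0, traced = sort(as.integer(traced))),
            class = "soma_mask")
}

#' @export
print.soma_mask <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf("<soma_mask> %d x %d x %d, %d voxels set, traced slices: %s\n",
              d[1], d[2], d[3], sum(x$mask),
              if (length(x$traced)) paste(x$traced, collapse = ", ") else "none"))
  invisible(x)
}

#' Voxelwise union of soma masks
#'
#' Combines the masks of several cell bodies segmented within the same
#' stack into one region, by logical OR.  Provenance is the union of the
#' traced slice indices.
#'
#' @param masks List of `soma_mask` objects (or logical arrays) with
#'   identical shapes.
#' @return A `soma_mask`.
#' @export
union_masks <- function(masks) {
  if (length(masks) == 0L) abort("`masks` must contain at least one mask.")
  get_arr <- function(m) if (inherits(m, "soma_mask")) m$mask else (m != 0)
  get_tr <- function(m) if (inherits(m, "soma_mask")) m$traced else integer(0)
  out <- get_arr(masks[[1]])
  traced <- get_tr(masks[[1]])
  for (m in masks[-1]) {
    a <- get_arr(m)
    if (!identical(dim(a), dim(out))) abort("all masks must share the same shape.")
    out <- out | a
    traced <- union(traced, get_tr(m))
  }
  soma_mask(out, traced = traced)
}

#' Read traces from a JSON polygon file
#'
#' The file holds a list of slices, each with a 0-based `z` index and one
#' or more closed `(y, x)` vertex rings; rings are rasterized by the
#' even-odd rule at pixel centers (pixel `(i, j)` has its center at
#' `(i + 0.5, j + 0.5)` in 0-based coordinates).
#'
#' @param path JSON file path.
#' @param shape Slice shape `(ny, nx)`.
#' @param z_extent Total slice count of the target stack.
#' @return A [sparse_traces()] object.
#' @export
read_traces_json <- function(path, shape, z_extent) {
  spec <- jsonlite::read_json(path, simplifyVector = FALSE)
  traces <- list()
  for (slice in spec) {
    m <- matrix(FALSE, shape[1], shape[2])
    for (ring in slice$rings) {
      v <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
      m <- xor(m, rasterize_ring(v, shape))
    }
    traces[[as.character(slice$z)]] <- m
  }
  sparse_traces(traces, z_extent = z_extent)
}

# even-odd scanline point-in-polygon test at pixel centers
rasterize_ring <- function(vertices, shape) {
  ny <- shape[1]; nx <- shape[2]
  py <- vertices[, 1]; px <- vertices[, 2]
  n <- length(py)
  m <- matrix(FALSE, ny, nx)
  cx <- (seq_len(nx)) - 0.5
  for (i in seq_len(ny)) {
    cy <- i - 0.5
    inside <- rep(FALSE, nx)
    j <- n
    for (k in seq_len(n)) {
      if ((py[k] > cy) != (py[j] > cy)) {
        xint <- px[k] + (cy - py[k]) / (py[j] - py[k]) * (px[j] - px[k])
        inside <- xor(inside, cx < xint)
      }
      j <- k
    }
    m[i, ] <- inside
  }
  m
}

#' Write a soma mask (or label volume) as a label TIFF with sidecar
#'
#' @param mask A `soma_mask` or integer 3D array.
#' @param path Output TIFF path.
#' @param spacing `(dz, dy, dx)` in um for the sidecar.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path, spacing) {
  arr <- if (inherits(mask, "soma_mask")) mask$mask * 1L else mask
  storage.mode(arr) <- "integer"
  write_stack(voxel_grid(arr, spacing, channel = "labels"), path)
}
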