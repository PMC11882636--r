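#' Threshold a volume at a fixed intensity
#'
#' A voxel is foreground iff its intensity is greater than or equal to
#' `t`.  Thresholds are assigned per image in this workflow because
#' illumination varies between captured regions of interest; see
#' [yen_threshold()] for an automatic alternative on 2D projections.
#'
#' @param grid A [voxel_grid] or 3D array.
#' @param t Finite threshold intensity.
#' @return A logical 3D array.
#' @export
threshold_volume <- function(grid, t) {
  if (!is.finite(t)) abort("`t` must be finite.")
  a <- if (inherits(grid, "voxel_grid")) grid$data else grid
  a >= t
}

#' Label connected components of a 3D binary volume
#'
#' Maximal connected sets of foreground voxels under the chosen
#' connectivity share a label; labels are `1..K`, assigned in raster-scan
#' order of each component's first voxel (array storage order: z fastest,
#' then y, then x).
#'
#' @param binary Logical 3D array (z, y, x).
#' @param connectivity One of 6 (faces), 18 (faces + edges) or
#'   26 (faces + edges + corners).  26 is the default for bright blob
#'   detection.
#' @return An integer 3D array of labels (0 = background).
#' @export
label_components <- function(binary, connectivity = 26L) {
  if (!connectivity %in% c(6L, 18L, 26L)) abort("connectivity must be 6, 18 or 26.")
  if (length(dim(binary)) != 3L) abort("`binary` must be a 3D array.")
  lab <- label3d_cpp(as.logical(binary), dim(binary), as.integer(connectivity))
  dim(lab) <- dim(binary)
  lab
}

#' Measure labeled 3D components with an inside/outside soma partition
#'
#' Computes, for every component, the calibrated volume
#' (`voxel_count * dz * dy * dx`), the equivalent spherical diameter
#' `(6 V / pi)^(1/3)`, and the split of that volume into the part lying
#' inside the soma mask and the remainder.  Components straddling the
#' soma boundary are split voxelwise, so `inside + outside = volume`
#' holds exactly for every record.
#'
#' @param labels Integer 3D label array from [label_components()].
#' @param spacing `(dz, dy, dx)` voxel spacing in um.
#' @param soma Optional `soma_mask` (or logical array) of the same shape;
#'   when absent all volume is reported as outside.
#' @return A tibble with columns `label`, `voxel_count`, `volume`,
#'   `equivalent_diameter`, `inside_volume`, `outside_volume`, sorted by
#'   label.  Classed `aggregate_records`.
#' @export
measure_components <- function(labels, spacing, soma = NULL) {
  if (length(spacing) != 3L || any(spacing <= 0)) abort("spacing must be 3 positive numbers.")
  smask <- NULL
  if (!is.null(soma)) {
    smask <- if (inherits(soma, "soma_mask")) soma$mask else (soma != 0)
    if (!identical(dim(smask), dim(labels))) abort("labels and soma must share the same shape.")
  }
  k <- max(labels, 0L)
  vox <- prod(spacing)
  if (k == 0L) {
    return(new_aggregate_records(tibble(
      label = integer(), voxel_count = integer(), volume = numeric(),
      equivalent_diameter = numeric(), inside_volume = numeric(),
      outside_volume = numeric())))
  }
  counts <- tabulate(labels, nbins = k)
  inside <- if (is.null(smask)) integer(k) else tabulate(labels[smask], nbins = k)
  vol <- counts * vox
  rec <- tibble(
    label = seq_len(k),
    voxel_count = as.integer(counts),
    volume = vol,
    equivalent_diameter = (6 * vol / pi)^(1 / 3),
    inside_volume = inside * vox,
    outside_volume = (counts - inside) * vox)
  new_aggregate_records(rec[rec$voxel_count > 0L, ])
}

new_aggregate_records <- function(x) {
  class(x) <- c("aggregate_records", setdiff(class(x), "aggregate_records"))
  x
}

#' Retain components within an equivalent-diameter window
#'
#' A reporting filter, off by default in the pipeline: retains records
#' with `d_min <= equivalent_diameter <= d_max`.  Filtering is idempotent.
#'
#' @param records An `aggregate_records` tibble.
#' @param d_min,d_max Diameter window in um, `0 <= d_min <= d_max`.
#' @return The filtered records.
#' @export
filter_by_diameter <- function(records, d_min = 0, d_max = Inf) {
  if (d_min < 0 || d_min > d_max) abort("need 0 <= d_min <= d_max.")
  new_aggregate_records(
    records[records$equivalent_diameter >= d_min &
              records$equivalent_diameter <= d_max, ])
}

#' Summarize aggregate burden for one stack
#'
#' Expresses the total aggregate volume as a percentage of the analyzed
#' tissue volume, and splits it into the inside-soma and outside-soma
#' compartments.  With zero components the mean component volume is
#' reported as `NA` (absent), not 0.
#'
#' @param records An `aggregate_records` tibble.
#' @param analyzed_volume Volume of the analyzed subvolume in um^3 (> 0).
#' @return A one-row tibble (class `stack_summary`) with columns
#'   `analyzed_volume`, `total_aggregate_volume`, `percent_volume`,
#'   `n_components`, `mean_component_volume`, `inside_total`,
#'   `outside_total`, `inside_percent`, `outside_percent`.
#' @export
summarize_stack <- function(records, analyzed_volume) {
  if (!is.numeric(analyzed_volume) || analyzed_volume <= 0) {
    abort("`analyzed_volume` must be > 0.")
  }
  n <- nrow(records)
  total <- sum(records$volume)
  inside <- sum(records$inside_volume)
  out <- tibble(
    analyzed_volume = analyzed_volume,
    total_aggregate_volume = total,
    percent_volume = 100 * total / analyzed_volume,
    n_components = n,
    mean_component_volume = if (n > 0) total / n else NA_real_,
    inside_total = inside,
    outside_total = total - inside,
    inside_percent = if (total > 0) 100 * inside / total else NA_real_,
    outside_percent = if (total > 0) 100 * (total - inside) / total else NA_real_)
  class(out) <- c("stack_summary", class(out))
  out
}

#' Quantify aggregate burden in a stack, end to end
#'
#' Runs the full 3D quantification chain: optional subvolume extraction,
#' fixed-intensity thresholding of the aggregate channel, 3D
#' connected-component labeling, calibrated per-component measurement
#' with an inside/outside soma partition, optional equivalent-diameter
#' filter, and a per-stack summary.
#'
#' @param grid Aggregate-channel [voxel_grid].
#' @param threshold Intensity threshold for this image.
#' @param soma Optional `soma_mask` aligned with `grid`.
#' @param connectivity 3D connectivity (6, 18 or 26).
#' @param subvolume Optional half-open 0-based bounds
#'   `list(z = c(z0, z1), y = c(y0, y1), x = c(x0, x1))`; the analyzed
#'   volume is the extracted extent times the voxel volume.
#' @param diameter_range Optional `(d_min, d_max)` um filter; `NULL`
#'   (default) retains every component.
#' @param denoise_sigma_um Optional per-axis Gaussian smoothing
#'   `(z, y, x)` in um applied before thresholding; 0 (default) is off.
#'   Light smoothing (about half a voxel) suppresses single-voxel noise
#'   components in unattended runs on noisy stacks.
#' @return A list of class `stack_quant` with `records`
#'   (per-component tibble), `summary` (one-row tibble) and `labels`
#'   (the retained-component label volume).
#' @examples
#' stk <- generate_aggregate_stack(
#'   aggregate_stack_config(shape = c(16, 64, 64),
#'                          soma_semiaxes_um = c(2, 2.5, 2.5),
#'                          n_aggregates = 5, diameter_range_um = c(0.4, 1)),
#'   seed = 1)
#' q <- quantify_stack(stk$aggregate, threshold = 60, soma = stk$truth$soma_mask)
#' q$summary$percent_volume
#' @export
quantify_stack <- function(grid, threshold, soma = NULL, connectivity = 26L,
                           subvolume = NULL, diameter_range = NULL,
                           denoise_sigma_um = c(0, 0, 0)) {
  grid <- if (inherits(grid, "voxel_grid")) grid else abort("`grid` must be a voxel_grid.")
  a <- grid$data
  if (any(denoise_sigma_um > 0)) {
    a <- blur3d(a, denoise_sigma_um / grid$spacing)
  }
  smask <- if (is.null(soma)) NULL else if (inherits(soma, "soma_mask")) soma$mask else (soma != 0)
  if (!is.null(subvolume)) {
    ix <- function(b, n) (b[1] + 1L):min(b[2], n)  # half-open, 0-based
    zi <- ix(subvolume$z, dim(a)[1]); yi <- ix(subvolume$y, dim(a)[2])
    xi <- ix(subvolume$x, dim(a)[3])
    a <- a[zi, yi, xi, drop = FALSE]
    if (!is.null(smask)) smask <- smask[zi, yi, xi, drop = FALSE]
  }
  bin <- a >= threshold
  labels <- label_components(bin, connectivity)
  rec <- measure_components(labels, grid$spacing, smask)
  if (!is.null(diameter_range)) {
    rec <- filter_by_diameter(rec, diameter_range[1], diameter_range[2])
    drop <- setdiff(seq_len(max(labels, 0L)), rec$label)
    if (length(drop)) labels[labels %in% drop] <- 0L
  }
  summary <- summarize_stack(rec, analyzed_volume = prod(dim(a)) * voxel_volume(grid))
  structure(list(records = rec, summary = summary, labels = labels),
            class = "stack_quant")
}

#' Gaussian smoothing of a calibrated volume
#'
#' Separable Gaussian filter with per-axis sigma in physical units,
#' converted to voxels through the grid's spacing; reflecting boundary.
#'
#' @param grid A [voxel_grid].
#' @param sigma_um Per-axis sigma `(z, y, x)` in um; axes with 0 are
#'   skipped.
#' @return The smoothed [voxel_grid].
#' @export
smooth_volume <- function(grid, sigma_um) {
  if (!inherits(grid, "voxel_grid")) abort("`grid` must be a voxel_grid.")
  voxel_grid(blur3d(grid$data, sigma_um / grid$spacing), grid$spacing,
             grid$channel)
}

#' @export
print.stack_quant <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("<stack_quant> %d component(s); aggregate volume %.4g um^3 ",
                     "(%.3g%% of %.4g um^3 analyzed); inside soma: %.3g%%\n"),
              s$n_components, s$total_aggregate_volume, s$percent_volume,
              s$analyzed_volume,
              if (is.na(s$inside_percent)) NA else s$inside_percent))
  invisible(x)
}

#' @rdname quantify_stack
#' @param x A `stack_quant` object.
#' @param ... Unused.
#' @export
tidy.stack_quant <- function(x, ...) as_tibble(x$records)

#' @rdname quantify_stack
#' @export
glance.stack_quant <- function(x, ...) as_tibble(x$summary)
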