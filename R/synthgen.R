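#' Configuration for synthetic aggregate stacks
#'
#' Builds the parameter list consumed by [generate_aggregate_stack()].
#' Defaults emulate the imaging conditions of high-magnification confocal
#' stacks of midbrain tissue: anisotropic voxels with a 0.3 um z-step,
#' punctate aggregates 0.3-3 um in equivalent diameter scattered around an
#' ellipsoidal neuron cell body.  The lateral pixel size of such stacks is
#' instrument-dependent and is therefore an explicit parameter rather than
#' a fixed constant.
#'
#' @param shape Stack dimensions `(nz, ny, nx)` in voxels.
#' @param spacing Voxel spacing `(dz, dy, dx)` in um.
#' @param n_somata Number of ellipsoidal cell bodies (>= 0).
#' @param soma_semiaxes_um Soma semi-axes `(z, y, x)` in um.
#' @param n_aggregates Number of spherical aggregates.
#' @param diameter_range_um Aggregate equivalent-diameter range
#'   `(d_min, d_max)` in um.
#' @param inside_fraction Fraction of aggregates placed entirely inside
#'   the soma; the remainder are placed entirely outside.
#' @param background,aggregate_intensity Background and object intensity
#'   of the aggregate channel (arbitrary units).
#' @param soma_background,soma_intensity Same for the soma-marker channel.
#' @param blur_sigma_um Per-axis Gaussian blur `(z, y, x)` in um; 0 = off.
#' @param gaussian_sd Additive Gaussian noise standard deviation; 0 = off.
#' @param poisson_noise Apply Poisson shot noise before Gaussian noise.
#' @return A named list of class `aggregate_stack_config`.
#' @export
aggregate_stack_config <- function(shape = c(32L, 192L, 192L),
                                   spacing = c(0.3, 0.1, 0.1),
                                   n_somata = 1L,
                                   soma_semiaxes_um = c(4, 7, 7),
                                   n_aggregates = 20L,
                                   diameter_range_um = c(0.3, 3),
                                   inside_fraction = 0.5,
                                   background = 10,
                                   aggregate_intensity = 110,
                                   soma_background = 10,
                                   soma_intensity = 90,
                                   blur_sigma_um = c(0, 0, 0),
                                   gaussian_sd = 0,
                                   poisson_noise = FALSE) {
  cfg <- list(shape = as.integer(shape), spacing = as.numeric(spacing),
              n_somata = as.integer(n_somata),
              soma_semiaxes_um = as.numeric(soma_semiaxes_um),
              n_aggregates = as.integer(n_aggregates),
              diameter_range_um = as.numeric(diameter_range_um),
              inside_fraction = inside_fraction,
              background = background,
              aggregate_intensity = aggregate_intensity,
              soma_background = soma_background,
              soma_intensity = soma_intensity,
              blur_sigma_um = as.numeric(blur_sigma_um),
              gaussian_sd = gaussian_sd,
              poisson_noise = isTRUE(poisson_noise))
  if (any(cfg$spacing <= 0)) abort("spacing must be positive.")
  if (cfg$n_somata < 0L) abort("n_somata must be >= 0.")
  if (cfg$n_aggregates < 0L) abort("n_aggregates must be >= 0.")
  if (cfg$diameter_range_um[1] > cfg$diameter_range_um[2] ||
      cfg$diameter_range_um[1] < 0) {
    abort("diameter_range_um must satisfy 0 <= d_min <= d_max.")
  }
  if (cfg$inside_fraction < 0 || cfg$inside_fraction > 1) {
    abort("inside_fraction must be in [0, 1].")
  }
  structure(cfg, class = c("aggregate_stack_config", "list"))
}

# center-of-voxel rasterization of an ellipsoid; center/semiaxes in um,
# voxel i covers [i, i+1) * spacing with its center at (i + 0.5) * spacing
rasterize_ellipsoid <- function(center, semi, shape, spacing) {
  lo <- pmax(0L, floor((center - semi) / spacing) - 1L)
  hi <- pmin(shape - 1L, ceiling((center + semi) / spacing) + 1L)
  out <- array(FALSE, shape)
  if (any(lo > hi)) return(out)
  iz <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; ix <- lo[3]:hi[3]
  cz <- (iz + 0.5) * spacing[1]; cy <- (iy + 0.5) * spacing[2]
  cx <- (ix + 0.5) * spacing[3]
  dz2 <- ((cz - center[1]) / semi[1])^2
  dy2 <- ((cy - center[2]) / semi[2])^2
  dx2 <- ((cx - center[3]) / semi[3])^2
  sub <- outer(outer(dz2, dy2, `+`), dx2, `+`) <= 1
  out[iz + 1L, iy + 1L, ix + 1L] <- sub
  out
}

#' Generate a synthetic two-channel confocal stack with exact ground truth
#'
#' Rasterizes an ellipsoidal cell-body ("soma") channel and a punctate
#' aggregate channel on an anisotropic voxel grid by center-of-voxel
#' inclusion, so that every object's true voxel volume is exactly
#' countable.  Aggregates are placed without mutual overlap, either fully
#' inside or fully outside the soma according to `inside_fraction`, and
#' the per-object inside volume is computed from the noise-free soma mask.
#' Optional Gaussian blur and Poisson/Gaussian noise are applied to the
#' intensity channels only; the returned truth always refers to the
#' noise-free rasterization.
#'
#' @param config An [aggregate_stack_config()].
#' @param seed Integer seed; identical `(config, seed)` pairs give
#'   bit-identical outputs.
#' @return A list with elements
#'   * `aggregate`, `soma`: [voxel_grid]s of the two channels;
#'   * `truth`: a `stack_truth` object holding `soma_mask`,
#'     `aggregate_labels`, a `per_object` tibble
#'     (`label`, `volume_um3`, `inside_um3`, `diameter_um`),
#'     `volume_fraction` (total aggregate volume over stack volume) and
#'     `spacing`.
#' @examples
#' cfg <- aggregate_stack_config(shape = c(16, 64, 64),
#'                               soma_semiaxes_um = c(2, 2.5, 2.5),
#'                               n_aggregates = 4,
#'                               diameter_range_um = c(0.4, 1))
#' stk <- generate_aggregate_stack(cfg, seed = 1)
#' stk$truth$per_object
#' @export
generate_aggregate_stack <- function(config = aggregate_stack_config(), seed) {
  cfg <- config
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  shape <- cfg$shape; sp <- cfg$spacing
  vox <- prod(sp)
  extent <- shape * sp
  tissue_vol <- prod(extent)

  n <- cfg$n_aggregates
  diam <- if (n > 0) runif(n, cfg$diameter_range_um[1], cfg$diameter_range_um[2]) else numeric(0)
  if (n > 0 && any(diam < sp[1] | diam < sp[2] | diam < sp[3])) {
    abort("aggregate diameter smaller than one voxel in at least one axis; increase d_min or refine spacing.")
  }
  if (sum(pi / 6 * diam^3) > tissue_vol) {
    abort("total requested aggregate volume exceeds the tissue volume.")
  }

  # soma mask
  soma_mask <- array(FALSE, shape)
  soma_centers <- list()
  if (cfg$n_somata > 0L) {
    for (s in seq_len(cfg$n_somata)) {
      frac <- if (cfg$n_somata == 1L) 0.5 else s / (cfg$n_somata + 1)
      ctr <- c(extent[1] / 2, extent[2] * frac, extent[3] / 2)
      soma_centers[[s]] <- ctr
      soma_mask <- soma_mask | rasterize_ellipsoid(ctr, cfg$soma_semiaxes_um, shape, sp)
    }
  }

  labels <- array(0L, shape)
  n_inside <- round(cfg$inside_fraction * n)
  placement <- c(rep(TRUE, n_inside), rep(FALSE, n - n_inside))
  per <- vector("list", n)
  semi_min <- min(cfg$soma_semiaxes_um)
  for (i in seq_len(n)) {
    r <- diam[i] / 2
    placed <- FALSE
    for (try in seq_len(400L)) {
      if (placement[i] && cfg$n_somata > 0L) {
        ctr0 <- soma_centers[[1L + (i %% max(1L, length(soma_centers)))]]
        # uniform direction, radius keeping the whole sphere inside
        u <- rnorm(3); u <- u / sqrt(sum(u^2))
        rad <- runif(1)^(1 / 3) * max(0, 1 - r / semi_min)
        ctr <- ctr0 + u * rad * cfg$soma_semiaxes_um
      } else {
        ctr <- c(runif(1, r, extent[1] - r), runif(1, r, extent[2] - r),
                 runif(1, r, extent[3] - r))
        if (cfg$n_somata > 0L) {
          dmin <- min(vapply(soma_centers, function(sc)
            sqrt(sum(((ctr - sc) / cfg$soma_semiaxes_um)^2)), numeric(1)))
          if (dmin < 1 + r / semi_min) next
        }
      }
      if (any(ctr < r) || any(ctr > extent - r)) next
      obj <- rasterize_ellipsoid(ctr, rep(r, 3), shape, sp)
      nv <- sum(obj)
      if (nv == 0L) next
      # collision test on a footprint padded by > 1 voxel so that distinct
      # objects are never 26-adjacent and component counts match the truth
      pad <- rasterize_ellipsoid(ctr, rep(r, 3) + 1.75 * sp, shape, sp)
      if (any(labels[pad] != 0L)) next
      labels[obj] <- i
      per[[i]] <- tibble(label = i, volume_um3 = nv * vox,
                         inside_um3 = sum(obj & soma_mask) * vox,
                         diameter_um = (6 * nv * vox / pi)^(1 / 3))
      placed <- TRUE
      break
    }
    if (!placed) abort("could not place aggregates without overlap; reduce n_aggregates or enlarge the stack.")
  }
  per_object <- if (n > 0) dplyr::bind_rows(per) else
    tibble(label = integer(), volume_um3 = numeric(),
           inside_um3 = numeric(), diameter_um = numeric())

  agg_img <- cfg$background + (cfg$aggregate_intensity - cfg$background) * (labels > 0)
  soma_img <- cfg$soma_background + (cfg$soma_intensity - cfg$soma_background) * soma_mask
  storage.mode(agg_img) <- "double"
  storage.mode(soma_img) <- "double"

  sig_vox <- cfg$blur_sigma_um / sp
  agg_img <- blur3d(agg_img, sig_vox)
  soma_img <- blur3d(soma_img, sig_vox)
  if (cfg$poisson_noise) {
    agg_img <- array(rpois(length(agg_img), pmax(agg_img, 0)), shape)
    soma_img <- array(rpois(length(soma_img), pmax(soma_img, 0)), shape)
    storage.mode(agg_img) <- "double"
    storage.mode(soma_img) <- "double"
  }
  if (cfg$gaussian_sd > 0) {
    agg_img <- pmax(0, agg_img + rnorm(length(agg_img), sd = cfg$gaussian_sd))
    soma_img <- pmax(0, soma_img + rnorm(length(soma_img), sd = cfg$gaussian_sd))
    dim(agg_img) <- shape; dim(soma_img) <- shape
  }

  truth <- structure(
    list(soma_mask = soma_mask, aggregate_labels = labels,
         per_object = per_object,
         volume_fraction = sum(per_object$volume_um3) / tissue_vol,
         spacing = sp),
    class = "stack_truth")
  list(aggregate = voxel_grid(agg_img, sp, channel = "aggregate"),
       soma = voxel_grid(soma_img, sp, channel = "soma"),
       truth = truth)
}

# separable Gaussian blur with per-axis sigma in voxels (0 = skip axis)
blur3d <- function(arr, sigma_vox) {
  shape <- dim(arr)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    half <- max(1L, ceiling(3 * s))
    k <- dnorm(seq(-half, half), sd = s)
    k <- k / sum(k)
    arr <- conv_axis_cpp(as.numeric(arr), shape, ax - 1L, k)
    dim(arr) <- shape
  }
  arr
}

#' Configuration for synthetic two-channel spinal cord images
#'
#' Parameters for [generate_spinal_image()], which emulates 2D projected
#' images of ventral-horn motor neurons: one channel of nucleus-marker
#' particles and a second channel in which a known fraction of nuclei are
#' surrounded by a cytoplasmic halo above a flat background.
#'
#' @param shape Image dimensions `(ny, nx)` in pixels.
#' @param n_nuclei Number of non-overlapping nuclei.
#' @param nucleus_radius_px Nucleus disk radius in px (>= 2).
#' @param halo_width_px Width of the halo annulus in px.
#' @param double_positive_fraction Fraction of nuclei with a halo.
#' @param pixel_size_um Pixel size in um/px.
#' @param background,nucleus_intensity,halo_intensity Channel levels (a.u.).
#' @param gaussian_sd Additive Gaussian noise sd on both channels; 0 = off.
#' @return A named list of class `spinal_image_config`.
#' @export
spinal_image_config <- function(shape = c(256L, 256L),
                                n_nuclei = 20L,
                                nucleus_radius_px = 6,
                                halo_width_px = 5,
                                double_positive_fraction = 0.6,
                                pixel_size_um = 0.325,
                                background = 10,
                                nucleus_intensity = 150,
                                halo_intensity = 80,
                                gaussian_sd = 0) {
  if (nucleus_radius_px < 2) abort("nucleus_radius_px must be >= 2 px.")
  if (double_positive_fraction < 0 || double_positive_fraction > 1) {
    abort("double_positive_fraction must be in [0, 1].")
  }
  structure(list(shape = as.integer(shape), n_nuclei = as.integer(n_nuclei),
                 nucleus_radius_px = nucleus_radius_px,
                 halo_width_px = halo_width_px,
                 double_positive_fraction = double_positive_fraction,
                 pixel_size_um = pixel_size_um,
                 background = background,
                 nucleus_intensity = nucleus_intensity,
                 halo_intensity = halo_intensity,
                 gaussian_sd = gaussian_sd),
            class = c("spinal_image_config", "list"))
}

#' Generate a synthetic two-channel motor-neuron image with known counts
#'
#' Places `n_nuclei` non-overlapping nucleus disks in the first channel
#' and draws a surrounding halo in the second channel around exactly
#' `round(double_positive_fraction * n_nuclei)` of them, giving an image
#' pair with an exactly known double-positive count.
#'
#' @param config A [spinal_image_config()].
#' @param seed Integer seed; identical `(config, seed)` pairs give
#'   bit-identical outputs.
#' @return A list with [plane_image]s `isl1` (nucleus channel) and `chat`
#'   (halo channel), and `truth`: a `spinal_truth` object with
#'   `nucleus_centers` (tibble of y/x in px, 0-based),
#'   `double_positive_flags`, `true_positive_count` and `pixel_size`.
#' @examples
#' img <- generate_spinal_image(spinal_image_config(n_nuclei = 10), seed = 2)
#' img$truth$true_positive_count
#' @export
generate_spinal_image <- function(config = spinal_image_config(), seed) {
  cfg <- config
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  ny <- cfg$shape[1]; nx <- cfg$shape[2]
  r <- cfg$nucleus_radius_px
  rh <- r + cfg$halo_width_px
  margin <- rh + 2
  min_sep <- 2 * rh + 3
  if (2 * margin >= ny || 2 * margin >= nx) {
    abort("image too small for the requested nucleus and halo radii.")
  }
  centers <- matrix(numeric(0), 0, 2)
  tries <- 0L
  while (nrow(centers) < cfg$n_nuclei) {
    tries <- tries + 1L
    if (tries > 4000L) {
      abort("could not place the requested number of nuclei without overlap.")
    }
    cand <- c(runif(1, margin, ny - margin), runif(1, margin, nx - margin))
    if (nrow(centers) > 0) {
      d2 <- (centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2
      if (any(d2 < min_sep^2)) next
    }
    centers <- rbind(centers, cand)
  }
  k <- as.integer(round(cfg$double_positive_fraction * cfg$n_nuclei))
  flags <- rep(FALSE, cfg$n_nuclei)
  if (k > 0) flags[sample(cfg$n_nuclei, k)] <- TRUE

  yy <- matrix(seq_len(ny) - 0.5, ny, nx)
  xx <- matrix(rep(seq_len(nx) - 0.5, each = ny), ny, nx)
  isl <- matrix(cfg$background, ny, nx)
  chat <- matrix(cfg$background, ny, nx)
  for (i in seq_len(nrow(centers))) {
    d2 <- (yy - centers[i, 1])^2 + (xx - centers[i, 2])^2
    isl[d2 <= r^2] <- cfg$nucleus_intensity
    if (flags[i]) chat[d2 > r^2 & d2 <= rh^2] <- cfg$halo_intensity
  }
  if (cfg$gaussian_sd > 0) {
    isl <- pmax(0, isl + rnorm(length(isl), sd = cfg$gaussian_sd))
    chat <- pmax(0, chat + rnorm(length(chat), sd = cfg$gaussian_sd))
    dim(isl) <- c(ny, nx); dim(chat) <- c(ny, nx)
  }
  truth <- structure(
    list(nucleus_centers = tibble(y = centers[, 1] - 0.5, x = centers[, 2] - 0.5),
         double_positive_flags = flags,
         true_positive_count = sum(flags),
         pixel_size = cfg$pixel_size_um),
    class = "spinal_truth")
  list(isl1 = plane_image(isl, cfg$pixel_size_um, channel = "isl1"),
       chat = plane_image(chat, cfg$pixel_size_um, channel = "chat"),
       truth = truth)
}

#' Reduce a dense 3D mask to sparse per-slice traces
#'
#' Keeps the mask's 2D slices at 0-based indices `0, step, 2*step, ...`,
#' mimicking manual tracing of a region of interest on every `step`-th
#' slice; the remaining slices are dropped and must be recovered by
#' [interpolate_traces()].
#'
#' @param dense_mask A logical 3D array (z, y, x) or a `soma_mask`.
#' @param step Positive integer slice stride; `step = 1` keeps every slice.
#' @return A `sparse_traces` object: a list of 2D masks keyed by 0-based
#'   slice index, plus `z_extent` and the slice shape.
#' @export
sparsify_traces <- function(dense_mask, step) {
  if (inherits(dense_mask, "soma_mask")) dense_mask <- dense_mask$mask
  if (length(dim(dense_mask)) != 3L) abort("`dense_mask` must be a 3D array.")
  step <- as.integer(step)
  if (is.na(step) || step < 1L) abort("`step` must be an integer >= 1.")
  nz <- dim(dense_mask)[1]
  idx <- seq.int(0L, nz - 1L, by = step)
  traces <- lapply(idx, function(z) dense_mask[z + 1L, , , drop = TRUE] != 0)
  names(traces) <- as.character(idx)
  sparse_traces(traces, z_extent = nz)
}

#' Construct a sparse trace set
#'
#' @param traces Named list of 2D logical masks; names are 0-based slice
#'   indices.
#' @param z_extent Total number of slices in the stack.
#' @return A `sparse_traces` object.
#' @export
sparse_traces <- function(traces, z_extent) {
  if (length(traces) > 0) {
    idx <- as.integer(names(traces))
    if (any(is.na(idx))) abort("trace names must be 0-based slice indices.")
    if (any(idx < 0L) || any(idx >= z_extent)) {
      abort("traced slice index out of range [0, z_extent).")
    }
    shp <- dim(as.matrix(traces[[1]]))
    for (t in traces) {
      if (!identical(dim(as.matrix(t))[1:2], shp)) {
        abort("all traced slices must share the same (y, x) shape.")
      }
    }
    traces <- traces[order(idx)]
    shape_yx <- shp
  } else {
    shape_yx <- NULL
  }
  structure(list(traces = lapply(traces, function(t) as.matrix(t) != 0),
                 z_extent = as.integer(z_extent), shape_yx = shape_yx),
            class = "sparse_traces")
}

#' @export
print.sparse_traces <- function(x, ...) {
  cat(sprintf("<sparse_traces> %d traced slice(s) of %d (z-extent)\n",
              length(x$traces), x$z_extent))
  invisible(x)
}
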