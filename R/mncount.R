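#' Contrast enhancement with saturation clipping
#'
#' Clips the intensity distribution at its `saturated_fraction / 2` and
#' `1 - saturated_fraction / 2` quantiles (order statistics of the sorted
#' pixels, so an equal pixel count saturates at each end) and, when
#' `normalize` is true, linearly rescales the clipped values to the full
#' representable range `[0, 1]`.  A constant image is returned unchanged
#' since no rescale is possible.
#'
#' @param img A [plane_image] or matrix.
#' @param saturated_fraction Fraction of pixels allowed to saturate
#'   (default 0.002, i.e. 0.2 percent), `0 <= f < 1`.
#' @param normalize Rescale to `[0, 1]` after clipping.
#' @return A [plane_image] with the same calibration.
#' @export
enhance_contrast <- function(img, saturated_fraction = 0.002, normalize = TRUE) {
  img <- as_plane_image(img)
  if (saturated_fraction < 0 || saturated_fraction >= 1) {
    abort("`saturated_fraction` must be in [0, 1).")
  }
  x <- img$data
  if (max(x) == min(x)) return(img)
  n <- length(x)
  k <- floor(n * saturated_fraction / 2)
  s <- sort(as.numeric(x))
  lo <- s[k + 1]
  hi <- s[n - k]
  if (hi <= lo) return(img)
  y <- pmin(pmax(x, lo), hi)
  if (normalize) y <- (y - lo) / (hi - lo)
  dim(y) <- dim(x)
  plane_image(y, img$pixel_size, img$channel)
}

#' Rolling-ball background subtraction
#'
#' Estimates the smooth background as the grayscale opening of the image
#' by a non-flat hemispherical ("ball") structuring element of the given
#' radius -- the surface traced by a ball of that radius rolling under
#' the intensity landscape -- and subtracts it.  The opening never
#' exceeds the image, so the output is non-negative; it is additionally
#' clipped at 0 against floating-point round-off.
#'
#' For radii above 32 px the image is shrunk by block-minimum
#' downsampling before rolling (as is standard for this filter), the ball
#' radius reduced proportionally, and the background restored to full
#' resolution by bilinear interpolation; `shrink = 1` forces the exact
#' computation.  A radius larger than both image dimensions degenerates
#' to a flat background at the global minimum.
#'
#' @param img A [plane_image] or matrix.
#' @param radius Ball radius in pixels (>= 1).
#' @param shrink `"auto"` or a positive integer downsampling factor.
#' @return A background-subtracted [plane_image].
#' @export
rolling_ball <- function(img, radius = 100, shrink = "auto") {
  img <- as_plane_image(img)
  if (radius < 1) abort("`radius` must be >= 1 px.")
  x <- img$data
  nr <- nrow(x); nc <- ncol(x)
  if (radius > nr && radius > nc) {
    bg <- matrix(min(x), nr, nc)
    return(plane_image(pmax(x - bg, 0), img$pixel_size, img$channel))
  }
  if (identical(shrink, "auto")) {
    shrink <- if (radius <= 32) 1L else if (radius <= 64) 2L
      else if (radius <= 128) 4L else 8L
  }
  shrink <- as.integer(shrink)
  if (shrink <= 1L) {
    bg <- ball_morph_cpp(ball_morph_cpp(x, radius, TRUE), radius, FALSE)
  } else {
    small <- block_min(x, shrink)
    op <- ball_morph_cpp(ball_morph_cpp(small, radius / shrink, TRUE),
                         radius / shrink, FALSE)
    bg <- bilinear_enlarge(op, shrink, nr, nc)
    bg <- pmin(bg, x)
  }
  plane_image(pmax(x - bg, 0), img$pixel_size, img$channel)
}

block_min <- function(x, s) {
  nr <- nrow(x); nc <- ncol(x)
  br <- ceiling(nr / s); bc <- ceiling(nc / s)
  out <- matrix(Inf, br, bc)
  ri <- pmin((seq_len(nr) - 1L) %/% s + 1L, br)
  ci <- pmin((seq_len(nc) - 1L) %/% s + 1L, bc)
  for (j in seq_len(nc)) {
    cj <- ci[j]
    col <- x[, j]
    mins <- tapply(col, ri, min)
    out[, cj] <- pmin(out[, cj], as.numeric(mins))
  }
  out
}

bilinear_enlarge <- function(small, s, nr, nc) {
  # block (i, j) of the small image sits at full-resolution center
  # ((i - 0.5) * s, (j - 0.5) * s)
  br <- nrow(small); bc <- ncol(small)
  gy <- pmin(pmax(((seq_len(nr) - 0.5) / s) + 0.5, 1), br)
  gx <- pmin(pmax(((seq_len(nc) - 0.5) / s) + 0.5, 1), bc)
  y0 <- pmin(floor(gy), br - 1L); y0[br == 1] <- 1
  x0 <- pmin(floor(gx), bc - 1L); x0[bc == 1] <- 1
  wy <- gy - y0; wx <- gx - x0
  y1 <- pmin(y0 + 1, br); x1 <- pmin(x0 + 1, bc)
  a <- small[y0, x0, drop = FALSE]; b <- small[y0, x1, drop = FALSE]
  c_ <- small[y1, x0, drop = FALSE]; d <- small[y1, x1, drop = FALSE]
  WY <- matrix(wy, nr, nc); WX <- matrix(wx, nr, nc, byrow = TRUE)
  a * (1 - WY) * (1 - WX) + b * (1 - WY) * WX + c_ * WY * (1 - WX) + d * WY * WX
}

#' Automatic threshold by Yen's entropic criterion
#'
#' Builds an `n_bins` histogram over the intensity range and returns the
#' bin-edge threshold maximizing Yen's criterion
#' `TC(t) = -ln[ (sum_{i<=t} p_i^2)(sum_{i>t} p_i^2) / (P(t)^2 (1-P(t))^2) ]`
#' over the normalized histogram `p`, with ties broken toward the lower
#' threshold.  The criterion is invariant to scaling all counts by a
#' positive constant.
#'
#' @param img A [plane_image] or matrix with at least two distinct values.
#' @param n_bins Number of histogram bins (default 256).
#' @return The threshold intensity (a bin edge); foreground is intensity
#'   strictly above it.
#' @export
yen_threshold <- function(img, n_bins = 256L) {
  x <- if (inherits(img, "plane_image")) img$data else img
  rng <- range(x)
  if (rng[1] == rng[2]) abort("constant image: no threshold exists.")
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bin <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(bin, nbins = n_bins)
  t <- yen_cut(counts)
  breaks[t + 1]
}

# index t (1..n-1) of the cut after bin t maximizing the Yen criterion;
# cuts with an empty side are undefined and skipped; ties -> lowest t
yen_cut <- function(counts) {
  p <- counts / sum(counts)
  n <- length(p)
  P1 <- cumsum(p)[-n]
  S1 <- cumsum(p^2)[-n]
  S2 <- sum(p^2) - S1
  crit <- rep(-Inf, n - 1L)
  ok <- P1 > 0 & P1 < 1 & S1 > 0 & S2 > 0
  crit[ok] <- -log(S1[ok]) - log(S2[ok]) + 2 * log(P1[ok]) + 2 * log(1 - P1[ok])
  if (!any(is.finite(crit))) abort("degenerate histogram: no valid cut.")
  which.max(crit)  # which.max returns the first (lowest) maximum
}

#' Fill holes and erode a binary mask
#'
#' Background components (4-connected) not touching the image border are
#' filled, then the mask is eroded once by a 3 x 3 square structuring
#' element (pixels outside the image count as background, so
#' border-touching foreground is eroded too).
#'
#' @param mask Logical 2D matrix.
#' @return The cleaned logical matrix.
#' @export
binary_cleanup <- function(mask) {
  mask <- mask != 0
  filled <- fill_holes(mask)
  erode3x3(filled)
}

fill_holes <- function(mask) {
  ny <- nrow(mask); nx <- ncol(mask)
  bg <- !mask
  lab <- label3d_cpp(as.logical(array(bg, c(1L, ny, nx))), c(1L, ny, nx), 6L)
  dim(lab) <- c(ny, nx)
  border_labels <- unique(c(lab[1, ], lab[ny, ], lab[, 1], lab[, nx]))
  border_labels <- border_labels[border_labels > 0L]
  mask | (bg & !(lab %in% border_labels))
}

erode3x3 <- function(mask) {
  ny <- nrow(mask); nx <- ncol(mask)
  p <- matrix(FALSE, ny + 2L, nx + 2L)
  p[2:(ny + 1L), 2:(nx + 1L)] <- mask
  out <- p[2:(ny + 1L), 2:(nx + 1L)]
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    out <- out & p[(2:(ny + 1L)) + dy, (2:(nx + 1L)) + dx]
  }
  out
}

# corner points (pixel units) of a set of 0-based pixel indices: each
# pixel (y, x) covers the unit square [y, y+1] x [x, x+1]
pixel_corners <- function(pix) {
  y <- pix[, 1]; x <- pix[, 2]
  cbind(c(y, y + 1, y, y + 1), c(x, x, x + 1, x + 1))
}

hull_perimeter_px <- function(pix) {
  pc <- unique(pixel_corners(pix))
  h <- grDevices::chull(pc[, 2], pc[, 1])
  hp <- pc[h, , drop = FALSE]
  nh <- nrow(hp)
  if (nh < 2) return(0)
  d <- sqrt(rowSums((hp - hp[c(2:nh, 1), , drop = FALSE])^2))
  sum(d)
}

#' Maximum caliper (Feret) diameter of a pixel set
#'
#' The maximum pairwise Euclidean distance between the corner points of
#' the component's pixels (each pixel treated as a unit square), scaled
#' by the pixel size when given.  Computed exactly via the convex hull of
#' the corner points.
#'
#' @param pixels Two-column matrix of 0-based `(y, x)` pixel indices.
#' @param pixel_size Optional um/px; when `NULL` the result is in px.
#' @return The Feret diameter (um, or px when uncalibrated).
#' @examples
#' feret_diameter(rbind(c(0, 0), c(3, 4)))  # sqrt(4^2 + 5^2)
#' @export
feret_diameter <- function(pixels, pixel_size = NULL) {
  pixels <- as.matrix(pixels)
  if (nrow(pixels) < 1) abort("`pixels` must contain at least one pixel.")
  pc <- unique(pixel_corners(pixels))
  h <- grDevices::chull(pc[, 2], pc[, 1])
  hp <- pc[h, , drop = FALSE]
  d2 <- outer(hp[, 1], hp[, 1], `-`)^2 + outer(hp[, 2], hp[, 2], `-`)^2
  f <- sqrt(max(d2))
  if (!is.null(pixel_size)) f * pixel_size else f
}

#' Segment and measure 2D particles
#'
#' Labels 8-connected components of a binary mask and measures each:
#' area (`n * pixel_size^2`), perimeter, circularity
#' `min(1, 4 pi area / perimeter^2)`, Feret diameter and centroid.
#' The perimeter is estimated as the length of the convex hull of the
#' component's pixel-corner points (a Cauchy mean-width estimator), which
#' avoids the systematic overestimation of raw pixel-edge counting that
#' would distort the circularity gate.  Components are retained iff their
#' area is at least `min_size` and their circularity lies in
#' `circ_range`.  Areas and lengths are calibrated (um) when
#' `pixel_size` is given, otherwise in pixel units.
#'
#' @param mask Logical 2D matrix.
#' @param pixel_size Optional um/px.
#' @param min_size Minimum area (um^2 when calibrated, else px^2).
#' @param circ_range Circularity window within `[0, 1]`.
#' @return A tibble (class `particles`) with columns `particle`, `area`,
#'   `perimeter`, `circularity`, `feret`, `centroid_y`, `centroid_x`,
#'   `n_pixels`.  The full label matrix (including rejected components)
#'   is attached as attribute `labels`; `particle` indexes into it.
#' @export
analyze_particles <- function(mask, pixel_size = NULL, min_size = 0.5,
                              circ_range = c(0.1, 1)) {
  if (min_size < 0) abort("`min_size` must be >= 0.")
  if (circ_range[1] < 0 || circ_range[2] > 1 || circ_range[1] > circ_range[2]) {
    abort("`circ_range` must lie within [0, 1].")
  }
  mask <- mask != 0
  ny <- nrow(mask); nx <- ncol(mask)
  lab <- label3d_cpp(as.logical(array(mask, c(1L, ny, nx))), c(1L, ny, nx), 26L)
  dim(lab) <- c(ny, nx)
  k <- max(lab, 0L)
  scale <- if (is.null(pixel_size)) 1 else pixel_size
  rows <- vector("list", k)
  for (id in seq_len(k)) {
    w <- which(lab == id, arr.ind = TRUE)
    pix <- cbind(w[, 1] - 1L, w[, 2] - 1L)  # 0-based (y, x)
    n <- nrow(pix)
    per_px <- hull_perimeter_px(pix)
    circ <- if (per_px > 0) min(1, 4 * pi * n / per_px^2) else 1
    rows[[id]] <- tibble(
      particle = id,
      area = n * scale^2,
      perimeter = per_px * scale,
      circularity = circ,
      feret = feret_diameter(pix, pixel_size = if (is.null(pixel_size)) NULL else pixel_size),
      centroid_y = mean(pix[, 1]) + 0.5,
      centroid_x = mean(pix[, 2]) + 0.5,
      n_pixels = n)
  }
  out <- if (k > 0) dplyr::bind_rows(rows) else
    tibble(particle = integer(), area = numeric(), perimeter = numeric(),
           circularity = numeric(), feret = numeric(), centroid_y = numeric(),
           centroid_x = numeric(), n_pixels = integer())
  out <- out[out$area >= min_size & out$circularity >= circ_range[1] &
               out$circularity <= circ_range[2], ]
  attr(out, "labels") <- lab
  attr(out, "pixel_size") <- pixel_size
  class(out) <- c("particles", class(out))
  out
}

#' Expand a particle by a fraction of its Feret diameter
#'
#' Morphological dilation of the particle by a Euclidean disk of radius
#' `round(factor * feret_px)` pixels; the zone always includes the
#' original particle.  This creates a perinuclear zone whose extent
#' scales with the particle's own size.
#'
#' @param particle_mask Logical 2D matrix of the particle.
#' @param feret_px Feret diameter in pixels (e.g. `feret / pixel_size`).
#' @param factor Expansion factor (>= 0); default 0.25.
#' @return A logical matrix of the expanded zone.
#' @export
expand_by_feret <- function(particle_mask, feret_px, factor = 0.25) {
  if (factor < 0) abort("`factor` must be >= 0.")
  particle_mask <- particle_mask != 0
  r <- round(factor * feret_px)
  if (r <= 0) return(particle_mask)
  d <- edt2d_cpp(!particle_mask)  # distance of every pixel to the particle
  particle_mask | (d <= r)
}

#' Estimate the background level from low-intensity boxes
#'
#' On a seeded random subset of `ceiling(subset_fraction * n)` images,
#' slides a `box x box` window over a half-box-stride grid, takes the
#' window with minimal mean intensity in each image (automating the
#' by-eye choice of a background area) and returns the mean of those
#' per-image means.  A box larger than an image dimension shrinks to fit,
#' with a warning.
#'
#' @param images List of [plane_image]s or matrices.
#' @param box Box side in px (default 500).
#' @param subset_fraction Fraction of images to sample (default 0.3).
#' @param seed Integer seed for the image subset.
#' @return A list with `level` (mean over images of the minimal-box
#'   means), `pixel_sd` (mean over images of the pixel standard deviation
#'   within the chosen box, usable as the background sd for a `k`-sigma
#'   call margin) and `n_images`.
#' @export
estimate_background <- function(images, box = 500L, subset_fraction = 0.3,
                                seed = 1L) {
  if (length(images) == 0L) abort("`images` must contain at least one image.")
  if (subset_fraction <= 0 || subset_fraction > 1) {
    abort("`subset_fraction` must be in (0, 1].")
  }
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  n_use <- ceiling(subset_fraction * length(images))
  pick <- sort(sample(length(images), n_use))
  stats <- vapply(images[pick], function(im) {
    x <- if (inherits(im, "plane_image")) im$data else im
    b <- min(box, nrow(x), ncol(x))
    if (b < box) warn(sprintf("background box shrunk from %d to %d px to fit the image.", box, b))
    min_box_stats(x, b)
  }, numeric(2))
  list(level = mean(stats[1, ]), pixel_sd = mean(stats[2, ]),
       n_images = n_use)
}

# mean and pixel sd of the minimal-mean box x box window on a half-box
# stride grid
min_box_stats <- function(x, b) {
  nr <- nrow(x); nc <- ncol(x)
  stride <- max(1L, floor(b / 2))
  ys <- unique(c(seq(0L, nr - b, by = stride), nr - b))
  xs <- unique(c(seq(0L, nc - b, by = stride), nc - b))
  sat <- rbind(0, cbind(0, apply(apply(x, 2, cumsum), 1, cumsum)))  # transposed SAT
  # sat[j+1, i+1] = sum x[1:i, 1:j]
  best <- Inf; by0 <- 0L; bx0 <- 0L
  for (y0 in ys) for (x0 in xs) {
    s <- sat[x0 + b + 1, y0 + b + 1] - sat[x0 + 1, y0 + b + 1] -
      sat[x0 + b + 1, y0 + 1] + sat[x0 + 1, y0 + 1]
    m <- s / (b * b)
    if (m < best) { best <- m; by0 <- y0; bx0 <- x0 }
  }
  px <- x[(by0 + 1):(by0 + b), (bx0 + 1):(bx0 + b)]
  c(best, sd(as.numeric(px)))
}

#' Call double-positive neurons from segmented nuclei and a second channel
#'
#' For each retained particle, measures the mean second-channel intensity
#' over its Feret-expanded zone and calls the particle positive iff that
#' mean is strictly greater than `background + k * background_sd`
#' (default `k = 0`: strictly above background).
#'
#' @param particles A `particles` tibble from [analyze_particles()].
#' @param chat_img The second-channel [plane_image] or matrix (same shape
#'   as the segmented image).
#' @param background Background intensity level (a.u.).
#' @param expand_factor Feret-expansion factor (default 0.25).
#' @param nucleus_img Optional nucleus-channel image for reporting the
#'   mean nucleus intensity of each particle.
#' @param k Margin in background standard deviations (default 0).
#' @param background_sd Background standard deviation used with `k`.
#' @return A tibble (class `neuron_calls`) with the particle columns plus
#'   `mean_nucleus_intensity`, `mean_chat_intensity`, `zone_area_px`,
#'   `background_level` and `positive`.
#' @export
call_positives <- function(particles, chat_img, background,
                           expand_factor = 0.25, nucleus_img = NULL,
                           k = 0, background_sd = 0) {
  chat <- if (inherits(chat_img, "plane_image")) chat_img$data else chat_img
  lab <- attr(particles, "labels")
  if (is.null(lab)) abort("`particles` must carry its label matrix (from analyze_particles).")
  if (!identical(dim(lab), dim(chat))) abort("channel images must share the segmentation's shape.")
  nuc <- if (is.null(nucleus_img)) NULL else
    if (inherits(nucleus_img, "plane_image")) nucleus_img$data else nucleus_img
  px <- attr(particles, "pixel_size")
  cutoff <- background + k * background_sd
  ny <- nrow(lab); nx <- ncol(lab)
  res <- particles
  res$mean_nucleus_intensity <- NA_real_
  res$mean_chat_intensity <- NA_real_
  res$zone_area_px <- NA_integer_
  for (i in seq_len(nrow(particles))) {
    id <- particles$particle[i]
    feret_px <- if (is.null(px)) particles$feret[i] else particles$feret[i] / px
    r <- ceiling(expand_factor * feret_px) + 1L
    w <- which(lab == id, arr.ind = TRUE)
    y0 <- max(1L, min(w[, 1]) - r); y1 <- min(ny, max(w[, 1]) + r)
    x0 <- max(1L, min(w[, 2]) - r); x1 <- min(nx, max(w[, 2]) + r)
    sub <- lab[y0:y1, x0:x1] == id
    zone <- expand_by_feret(sub, feret_px, expand_factor)
    chat_sub <- chat[y0:y1, x0:x1]
    res$mean_chat_intensity[i] <- mean(chat_sub[zone])
    res$zone_area_px[i] <- sum(zone)
    if (!is.null(nuc)) res$mean_nucleus_intensity[i] <- mean(nuc[y0:y1, x0:x1][sub])
  }
  res$background_level <- background
  res$positive <- res$mean_chat_intensity > cutoff
  class(res) <- c("neuron_calls", setdiff(class(res), "neuron_calls"))
  res
}

#' Section series geometry
#'
#' Describes a series of tissue sections by count and thickness; the
#' combined length is `n_sections * thickness_um / 1000` mm (for example
#' 50 sections of 30 um span 1.5 mm of cord).
#'
#' @param n_sections Number of sections (>= 1).
#' @param thickness_um Section thickness in um (> 0).
#' @return A list of class `section_series` with `n_sections`,
#'   `thickness_um` and `length_mm`.
#' @export
section_series <- function(n_sections, thickness_um) {
  if (n_sections < 1) abort("`n_sections` must be >= 1.")
  if (thickness_um <= 0) abort("`thickness_um` must be > 0.")
  structure(list(n_sections = as.integer(n_sections),
                 thickness_um = thickness_um,
                 length_mm = n_sections * thickness_um / 1000),
            class = "section_series")
}

#' Normalize a neuron count to a 1 mm length of spinal cord
#'
#' Divides the count by the combined length of cord spanned by the
#' counted sections.
#'
#' @param count Neuron count (>= 0).
#' @param series A [section_series()].
#' @return Neurons per mm.
#' @examples
#' normalize_per_mm(30, section_series(50, 30))  # 30 / 1.5 mm = 20 per mm
#' @export
normalize_per_mm <- function(count, series) {
  if (!inherits(series, "section_series")) abort("`series` must be a section_series.")
  if (series$length_mm <= 0) abort("zero combined section length.")
  count / series$length_mm
}

#' Count double-positive motor neurons in a two-channel image
#'
#' Runs the full automated chain on one image pair: contrast enhancement
#' and rolling-ball background subtraction of the nucleus channel, Yen
#' thresholding, hole filling and erosion, particle analysis with size
#' and circularity gates, Feret-proportional expansion of each nucleus,
#' and a strictly-above-background call on the mean second-channel
#' intensity in each expanded zone.  Optionally normalizes the count per
#' mm of cord when a [section_series()] is given.
#'
#' @param isl1 Nucleus-channel [plane_image].
#' @param chat Second-channel [plane_image] (same shape).
#' @param background Background level of the second channel; when `NULL`
#'   it is estimated from `chat` itself via [estimate_background()].
#' @param pixel_size um/px; taken from `isl1` when `NULL`.
#' @param saturated_fraction,rolling_ball_radius,min_size,circ_range,expand_factor,k
#'   Stage parameters, see the stage functions.
#' @param chat_display_range Optional `c(lo, hi)` clip-and-rescale applied
#'   to the second channel before intensity measurement; off by default.
#' @param background_box Box side for background estimation.
#' @param series Optional [section_series()] for per-mm normalization.
#' @param background_seed Seed for the background-image subset.
#' @return A list of class `mn_count` with `calls` (per-particle tibble),
#'   `count`, `per_mm` (or `NA`), `background`, `threshold` and the
#'   nucleus label matrix `labels`.
#' @examples
#' syn <- generate_spinal_image(spinal_image_config(n_nuclei = 12), seed = 3)
#' res <- count_motor_neurons(syn$isl1, syn$chat, background_box = 64)
#' res$count == syn$truth$true_positive_count
#' @export
count_motor_neurons <- function(isl1, chat, background = NULL,
                                pixel_size = NULL,
                                saturated_fraction = 0.002,
                                rolling_ball_radius = 100,
                                min_size = 0.5, circ_range = c(0.1, 1),
                                expand_factor = 0.25, k = 0,
                                chat_display_range = NULL,
                                background_box = 500L,
                                series = NULL,
                                background_seed = 1L) {
  isl1 <- as_plane_image(isl1)
  chat <- as_plane_image(chat)
  if (!identical(dim(isl1$data), dim(chat$data))) {
    abort("channel images must have the same shape.")
  }
  if (is.null(pixel_size)) pixel_size <- isl1$pixel_size
  if (!is.null(chat_display_range)) {
    lo <- chat_display_range[1]; hi <- chat_display_range[2]
    chat <- plane_image((pmin(pmax(chat$data, lo), hi) - lo) / (hi - lo),
                        chat$pixel_size, chat$channel)
  }
  pre <- enhance_contrast(isl1, saturated_fraction = saturated_fraction)
  pre <- rolling_ball(pre, radius = rolling_ball_radius)
  thr <- yen_threshold(pre)
  mask <- binary_cleanup(pre$data > thr)
  parts <- analyze_particles(mask, pixel_size = pixel_size,
                             min_size = min_size, circ_range = circ_range)
  bg_sd <- 0
  if (is.null(background)) {
    est <- estimate_background(list(chat), box = background_box,
                               subset_fraction = 1, seed = background_seed)
    background <- est$level
    bg_sd <- est$pixel_sd
  }
  calls <- call_positives(parts, chat, background = background,
                          expand_factor = expand_factor,
                          nucleus_img = isl1, k = k, background_sd = bg_sd)
  count <- sum(calls$positive)
  structure(list(calls = calls, count = count,
                 per_mm = if (is.null(series)) NA_real_ else
                   normalize_per_mm(count, series),
                 background = background, threshold = thr,
                 labels = attr(parts, "labels")),
            class = "mn_count")
}

#' @export
print.mn_count <- function(x, ...) {
  cat(sprintf("<mn_count> %d double-positive neuron(s) of %d particle(s); background %.4g%s\n",
              x$count, nrow(x$calls), x$background,
              if (!is.na(x$per_mm)) sprintf("; %.4g per mm", x$per_mm) else ""))
  invisible(x)
}

#' @rdname count_motor_neurons
#' @param x An `mn_count` object.
#' @param ... Unused.
#' @export
tidy.mn_count <- function(x, ...) {
  out <- x$calls
  attr(out, "labels") <- NULL
  class(out) <- class(tibble())
  out
}

#' @rdname count_motor_neurons
#' @export
glance.mn_count <- function(x, ...) {
  tibble(n_particles = nrow(x$calls), count = x$count, per_mm = x$per_mm,
         background = x$background, threshold = x$threshold)
}
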