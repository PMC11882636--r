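test_that("contrast enhancement matches the sorted-pixel quantile oracle", {
  ramp <- matrix(0:999, 20, 50)
  out <- enhance_contrast(ramp, saturated_fraction = 0.002)$data
  # oracle: clip bounds from the sorted pixel vector, then linear rescale
  s <- sort(as.numeric(ramp))
  k <- floor(length(s) * 0.001)
  lo <- s[k + 1]; hi <- s[length(s) - k]
  ref <- (pmin(pmax(ramp, lo), hi) - lo) / (hi - lo)
  expect_equal(out, ref)

  # zero saturation on a full-range [0, 1] image is the identity
  full <- matrix(seq(0, 1, length.out = 64), 8, 8)
  expect_equal(enhance_contrast(full, 0)$data, full)

  # constant image unchanged
  const <- matrix(5, 4, 4)
  expect_identical(enhance_contrast(const)$data, const)
})

test_that("rolling ball equals the brute-force grayscale opening", {
  set.seed(7)
  img <- matrix(runif(64 * 64, 0, 50), 64, 64)
  img[20:26, 30:36] <- img[20:26, 30:36] + 80
  for (r in c(4, 8.5)) {
    mine <- rolling_ball(img, radius = r, shrink = 1)$data
    ref <- img - oracle_ball_opening(img, r)
    expect_equal(mine, pmax(ref, 0), tolerance = 1e-12)
  }
})

test_that("rolling ball removes flat background and preserves a sharp peak", {
  img <- matrix(10, 64, 64)
  img[31:33, 31:33] <- 110
  out <- rolling_ball(img, radius = 20, shrink = 1)$data
  expect_lt(abs(out[32, 32] - 100), 1)
  expect_true(all(out[1:10, 1:10] == 0))
  # constant image maps to zero; output bounded by [0, input]
  expect_true(all(rolling_ball(matrix(7, 32, 32), 10)$data == 0))
  set.seed(8)
  x <- matrix(runif(32 * 32, 0, 99), 32, 32)
  out2 <- rolling_ball(x, 6, shrink = 1)$data
  expect_true(all(out2 >= 0) && all(out2 <= x + 1e-9))
})

test_that("radius exceeding both image dimensions degrades to the minimum surface", {
  x <- matrix(c(3, 5, 9, 4), 2, 2)
  expect_equal(rolling_ball(x, 100)$data, x - 3)
})

test_that("Yen threshold separates a two-level image and matches the exhaustive scan", {
  img <- matrix(rep(c(10, 200), each = 50), 10, 10)
  t <- yen_threshold(img)
  expect_gt(t, 10); expect_lt(t, 200)

  set.seed(19)
  for (rep in 1:30) {
    nb <- sample(8:256, 1)
    counts <- rpois(nb, lambda = sample(c(2, 20, 200), nb, replace = TRUE))
    if (sum(counts) == 0 || sum(counts > 0) < 2) next
    mine <- punctaquant:::yen_cut(counts)
    ref <- oracle_yen_cut(counts)
    if (mine != ref) {
      expect_lt(abs(oracle_yen_crit(counts, mine) - oracle_yen_crit(counts, ref)),
                1e-9)
    } else {
      expect_equal(mine, ref)
    }
  }
  # invariance under scaling all counts
  counts <- c(5, 0, 2, 9, 1, 7, 3, 4)
  expect_equal(punctaquant:::yen_cut(counts), punctaquant:::yen_cut(7 * counts))
  expect_error(yen_threshold(matrix(3, 4, 4)), "constant")
})

test_that("binary cleanup fills interior holes then erodes one layer", {
  n <- 32
  annulus <- disk_mask(10, n) & !disk_mask(4, n)
  out <- binary_cleanup(annulus)
  # oracle: brute-force fill (all background not reachable from border) + erode
  ref_fill <- disk_mask(10, n)
  ref <- ref_fill
  for (i in 1:n) for (j in 1:n) {
    if (!ref_fill[i, j]) next
    nb <- ref_fill[max(1, i - 1):min(n, i + 1), max(1, j - 1):min(n, j + 1)]
    if (sum(nb) < 9 || i == 1 || i == n || j == 1 || j == n) ref[i, j] <- FALSE
  }
  expect_identical(out, ref)
  expect_identical(binary_cleanup(matrix(FALSE, 5, 5)), matrix(FALSE, 5, 5))
  solid <- disk_mask(8, 24)
  expect_lt(sum(binary_cleanup(solid)), sum(solid))
})

test_that("particle analysis gates round nuclei in and thin debris out", {
  n <- 40
  disk <- disk_mask(10, n)
  p <- analyze_particles(disk, pixel_size = 1)
  expect_equal(nrow(p), 1L)
  expect_gte(p$circularity, 0.8); expect_lte(p$circularity, 1)
  expect_equal(p$perimeter, oracle_hull_perimeter(which(disk, arr.ind = TRUE) - 1L),
               tolerance = 1e-3)

  line <- matrix(FALSE, 10, 40); line[5, 5:34] <- TRUE
  pl <- analyze_particles(line, pixel_size = 1)
  expect_equal(nrow(pl), 0L)  # circularity below 0.1
  pl_all <- analyze_particles(line, pixel_size = 1, circ_range = c(0, 1))
  expect_lt(pl_all$circularity, 0.1)

  tiny <- matrix(FALSE, 8, 8); tiny[4, 4] <- TRUE
  expect_equal(nrow(analyze_particles(tiny, pixel_size = 0.6, min_size = 0.5)), 0L)
  expect_equal(nrow(analyze_particles(tiny, pixel_size = 0.8, min_size = 0.5,
                                      circ_range = c(0, 1))), 1L)
})

test_that("Feret diameter equals brute-force max corner distance", {
  expect_equal(feret_diameter(rbind(c(0, 0), c(3, 4))), sqrt(4^2 + 5^2))
  expect_equal(feret_diameter(rbind(c(0, 0))), sqrt(2))
  expect_equal(feret_diameter(rbind(c(0, 0), c(3, 4)), pixel_size = 2),
               2 * sqrt(41))
  set.seed(23)
  for (rep in 1:10) {
    npx <- sample(1:50, 1)
    pix <- unique(cbind(sample(0:20, npx, replace = TRUE),
                        sample(0:20, npx, replace = TRUE)))
    expect_equal(feret_diameter(pix), oracle_feret(pix))
  }
})

test_that("Feret expansion dilates by the stated disk radius", {
  n <- 40
  disk <- disk_mask(10, n)
  expect_identical(expand_by_feret(disk, feret_px = 20, factor = 0), disk)
  z1 <- expand_by_feret(disk, 20, 0.25)
  ref <- oracle_dilate(disk, 5)
  expect_identical(z1, ref)
  r_eq <- sqrt(sum(z1) / pi)
  expect_lt(abs(r_eq - 15), 1)
  # zone area grows with the factor
  areas <- vapply(c(0, 0.1, 0.25, 0.4), function(f) sum(expand_by_feret(disk, 20, f)),
                  numeric(1))
  expect_true(all(diff(areas) > 0))
})

test_that("background estimation finds low boxes and avoids bright blobs", {
  const <- matrix(42, 80, 80)
  expect_equal(estimate_background(list(const), box = 40, subset_fraction = 1)$level,
               42)
  blob <- matrix(10, 100, 100)
  blob[1:40, 1:40] <- 200
  est <- estimate_background(list(blob), box = 30, subset_fraction = 1)
  expect_equal(est$level, 10)
  expect_error(estimate_background(list()), "at least one")
  expect_warning(estimate_background(list(matrix(1, 20, 20)), box = 50,
                                     subset_fraction = 1), "shrunk")
})

test_that("positivity calls are strict and recover the generated truth", {
  syn <- generate_spinal_image(spinal_image_config(n_nuclei = 15L), seed = 4)
  res <- count_motor_neurons(syn$isl1, syn$chat, background_box = 64)
  expect_equal(res$count, syn$truth$true_positive_count)
  # boundary: a zone mean exactly at background is negative
  m <- matrix(FALSE, 9, 9); m[4:6, 4:6] <- TRUE
  p <- analyze_particles(m, circ_range = c(0, 1), min_size = 0)
  flat <- matrix(10, 9, 9)
  calls <- call_positives(p, flat, background = 10, expand_factor = 0)
  expect_false(any(calls$positive))
  bright <- matrix(100, 9, 9)
  expect_true(all(call_positives(p, bright, background = 10)$positive))
})

test_that("per-mm normalization follows the section geometry", {
  s <- section_series(50, 30)
  expect_equal(s$length_mm, 1.5)
  expect_equal(normalize_per_mm(30, s), 20)
  expect_equal(normalize_per_mm(0, s), 0)
  # linear in count
  expect_equal(normalize_per_mm(60, s), 2 * normalize_per_mm(30, s))
  expect_error(section_series(0, 30), ">= 1")
  expect_error(section_series(50, 0), "> 0")
})
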