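small_cfg <- function(...) {
  args <- utils::modifyList(
    list(shape = c(20L, 96L, 96L), soma_semiaxes_um = c(2, 3, 3),
         n_aggregates = 6L, diameter_range_um = c(0.4, 1.2)),
    list(...))
  do.call(aggregate_stack_config, args)
}

test_that("empty aggregate config gives a flat background and zero volume fraction", {
  stk <- generate_aggregate_stack(small_cfg(n_aggregates = 0L), seed = 1)
  expect_equal(stk$truth$volume_fraction, 0)
  expect_true(all(stk$aggregate$data == 10))
  expect_equal(nrow(stk$truth$per_object), 0L)
})

test_that("a unit-diameter sphere has volume ~pi/6 and its diameter identity holds", {
  cfg <- aggregate_stack_config(shape = c(24L, 48L, 48L), spacing = c(0.1, 0.1, 0.1),
                                n_somata = 0L, n_aggregates = 1L,
                                diameter_range_um = c(1, 1), inside_fraction = 0)
  stk <- generate_aggregate_stack(cfg, seed = 7)
  v <- stk$truth$per_object$volume_um3
  expect_lt(abs(v - pi / 6), 20 * prod(cfg$spacing))  # rasterization error, well under one layer of voxels
  expect_equal(stk$truth$per_object$diameter_um, (6 * v / pi)^(1 / 3))
})

test_that("rasterized voxels equal the label volume when blur and noise are off", {
  stk <- generate_aggregate_stack(small_cfg(), seed = 3)
  expect_identical(stk$aggregate$data > 10, stk$truth$aggregate_labels > 0)
})

test_that("identical config and seed give bit-identical stacks", {
  a <- generate_aggregate_stack(small_cfg(gaussian_sd = 5, poisson_noise = TRUE,
                                          blur_sigma_um = c(0.1, 0.1, 0.1)), seed = 11)
  b <- generate_aggregate_stack(small_cfg(gaussian_sd = 5, poisson_noise = TRUE,
                                          blur_sigma_um = c(0.1, 0.1, 0.1)), seed = 11)
  expect_identical(a$aggregate$data, b$aggregate$data)
  expect_identical(a$soma$data, b$soma$data)
  expect_identical(a$truth$per_object, b$truth$per_object)
})

test_that("per-object truth respects the inside <= total and diameter-range invariants", {
  for (seed in 1:3) {
    stk <- generate_aggregate_stack(small_cfg(), seed = seed)
    po <- stk$truth$per_object
    expect_true(all(po$inside_um3 <= po$volume_um3 + 1e-12))
    vox_diag <- sqrt(sum(stk$truth$spacing^2))
    expect_true(all(po$diameter_um >= 0.4 - vox_diag))
    expect_true(all(po$diameter_um <= 1.2 + vox_diag))
    expect_equal(sum(po$volume_um3) / prod(dim(stk$aggregate$data) * stk$aggregate$spacing),
                 stk$truth$volume_fraction)
  }
})

test_that("sub-voxel aggregate diameters are rejected with a sizing error", {
  cfg <- small_cfg(diameter_range_um = c(0.15, 0.25))  # below the 0.3 um z spacing
  expect_error(generate_aggregate_stack(cfg, seed = 1), "smaller than one voxel")
})

test_that("aggregate volume exceeding the tissue volume is rejected", {
  cfg <- aggregate_stack_config(shape = c(4L, 16L, 16L), spacing = c(0.3, 0.1, 0.1),
                                n_somata = 0L, n_aggregates = 50L,
                                diameter_range_um = c(1, 1.2))
  expect_error(generate_aggregate_stack(cfg, seed = 1), "exceeds the tissue volume")
})

test_that("spinal truth count equals the rounded double-positive fraction", {
  syn <- generate_spinal_image(spinal_image_config(n_nuclei = 10L,
                                                   double_positive_fraction = 0.6),
                               seed = 5)
  expect_equal(syn$truth$true_positive_count, 6L)
  expect_equal(sum(syn$truth$double_positive_flags), 6L)
  expect_equal(nrow(syn$truth$nucleus_centers), 10L)
})

test_that("zero double-positive fraction leaves the second channel flat", {
  syn <- generate_spinal_image(spinal_image_config(double_positive_fraction = 0),
                               seed = 2)
  expect_true(all(syn$chat$data == 10))
  expect_equal(syn$truth$true_positive_count, 0L)
})

test_that("exactly the flagged nuclei carry a halo above background", {
  syn <- generate_spinal_image(spinal_image_config(n_nuclei = 15L), seed = 9)
  cfg <- spinal_image_config(n_nuclei = 15L)
  for (i in seq_len(15)) {
    ctr <- unlist(syn$truth$nucleus_centers[i, ]) + 0.5
    y <- round(ctr[1]); x <- round(ctr[2])
    ring <- syn$chat$data[y + cfg$nucleus_radius_px + 2, x]
    expect_equal(ring > cfg$background, syn$truth$double_positive_flags[i])
  }
})

test_that("spinal images are reproducible and infeasible packings error", {
  a <- generate_spinal_image(spinal_image_config(gaussian_sd = 4), seed = 13)
  b <- generate_spinal_image(spinal_image_config(gaussian_sd = 4), seed = 13)
  expect_identical(a$isl1$data, b$isl1$data)
  expect_identical(a$chat$data, b$chat$data)
  expect_error(
    generate_spinal_image(spinal_image_config(shape = c(64L, 64L), n_nuclei = 200L),
                          seed = 1),
    "without overlap")
})

test_that("sparsify_traces keeps exactly the strided slices", {
  mask <- array(FALSE, c(5, 8, 8))
  for (z in 1:5) mask[z, 2:(2 + z), 3:6] <- TRUE
  tr1 <- sparsify_traces(mask, step = 1)
  expect_equal(as.integer(names(tr1$traces)), 0:4)
  for (z in 0:4) expect_identical(tr1$traces[[as.character(z)]],
                                  mask[z + 1, , ] != 0)
  tr2 <- sparsify_traces(mask, step = 2)
  expect_equal(as.integer(names(tr2$traces)), c(0L, 2L, 4L))
  expect_error(sparsify_traces(mask, step = 0), ">= 1")
})
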