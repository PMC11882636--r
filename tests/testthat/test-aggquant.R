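test_that("thresholding respects boundaries and is monotone", {
  set.seed(3)
  a <- array(runif(4 * 4 * 4, 0, 100), c(4, 4, 4))
  expect_true(all(threshold_volume(a, min(a))))
  expect_false(any(threshold_volume(a, max(a) + 1)))
  m1 <- threshold_volume(a, 30); m2 <- threshold_volume(a, 60)
  expect_true(all(m1[m2]))  # mask(t2) subset of mask(t1)
})

test_that("corner-touching voxels merge at 26- but not 6-connectivity", {
  v <- array(FALSE, c(3, 3, 3))
  v[1, 1, 1] <- TRUE; v[2, 2, 2] <- TRUE
  expect_equal(max(label_components(v, 26)), 1L)
  expect_equal(max(label_components(v, 18)), 2L)
  expect_equal(max(label_components(v, 6)), 2L)
  expect_equal(max(label_components(array(FALSE, c(2, 2, 2)), 26)), 0L)
})

test_that("labeling matches a brute-force flood fill on random volumes", {
  set.seed(11)
  for (rep in 1:25) {
    v <- array(runif(1000) < 0.25, c(10, 10, 10))
    for (conn in c(6L, 26L)) {
      mine <- label_components(v, conn)
      ref <- oracle_label3d(v, conn)
      expect_equal(max(mine), max(ref))
      expect_true(same_partition(mine, ref))
    }
  }
})

test_that("labels are assigned in raster-scan order of first voxels", {
  v <- array(FALSE, c(2, 3, 3))
  v[1, 1, 1] <- TRUE            # linear index 1
  v[2, 3, 2] <- TRUE            # later in storage order
  lab <- label_components(v, 6)
  expect_equal(lab[1, 1, 1], 1L)
  expect_equal(lab[2, 3, 2], 2L)
})

test_that("component measurements follow the calibrated arithmetic", {
  lab <- array(0L, c(4, 5, 5))
  lab[1, 1:5, 1] <- 1L; lab[2, 1:5, 1] <- 1L  # 10 voxels
  rec <- measure_components(lab, c(0.3, 0.1, 0.1))
  expect_equal(rec$volume, 0.03)
  expect_equal(rec$voxel_count, 10L)
  expect_equal(rec$equivalent_diameter, (6 * 0.03 / pi)^(1 / 3))
  # a component whose volume is pi/6 um^3 has equivalent diameter 1 um
  rec2 <- tibble::tibble(volume = pi / 6)
  expect_equal((6 * rec2$volume / pi)^(1 / 3), 1)
})

test_that("a sphere straddling a planar soma boundary splits about 50/50", {
  shape <- c(30L, 40L, 40L)
  sp <- c(0.1, 0.1, 0.1)
  obj <- punctaquant:::rasterize_ellipsoid(c(1.5, 2, 2), rep(0.8, 3), shape, sp)
  lab <- array(0L, shape); lab[obj] <- 1L
  soma <- array(FALSE, shape)
  soma[1:15, , ] <- TRUE  # half-space boundary through the sphere center
  rec <- measure_components(lab, sp, soma)
  frac <- rec$inside_volume / rec$volume
  expect_lt(abs(frac - 0.5), 0.07)  # one voxel layer across the equator
  expect_equal(rec$inside_volume + rec$outside_volume, rec$volume)
})

test_that("volumes are conserved between mask, records and summary", {
  set.seed(21)
  v <- array(runif(8 * 16 * 16) < 0.2, c(8, 16, 16))
  sp <- c(0.3, 0.1, 0.1)
  lab <- label_components(v, 26)
  soma <- array(runif(length(v)) < 0.5, dim(v))
  rec <- measure_components(lab, sp, soma)
  expect_equal(sum(rec$volume), sum(v) * prod(sp))
  expect_equal(rec$inside_volume + rec$outside_volume, rec$volume)
  s <- summarize_stack(rec, analyzed_volume = prod(dim(v)) * prod(sp))
  expect_equal(s$total_aggregate_volume, sum(rec$volume))
  expect_equal(s$inside_total + s$outside_total, s$total_aggregate_volume)
  expect_equal(s$inside_percent + s$outside_percent, 100)
  expect_gte(s$percent_volume, 0); expect_lte(s$percent_volume, 100)
})

test_that("diameter filtering is a window, identity at full range, idempotent", {
  rec <- measure_components(array(rep(c(0L, 1L), c(7, 1)), c(2, 2, 2)), c(1, 1, 1))
  rec$equivalent_diameter <- 3.5
  expect_equal(nrow(filter_by_diameter(rec, 0, Inf)), 1L)
  expect_equal(nrow(filter_by_diameter(rec, 0.3, 3)), 0L)
  f1 <- filter_by_diameter(rec, 0.3, 4)
  expect_identical(filter_by_diameter(f1, 0.3, 4), f1)
  expect_error(filter_by_diameter(rec, 5, 3), "d_min")
})

test_that("stack summaries follow the percent arithmetic and empty contract", {
  rec <- tibble::tibble(label = 1:2, voxel_count = c(1L, 1L), volume = c(1.5, 0.5),
                        equivalent_diameter = 1, inside_volume = c(1.5, 0),
                        outside_volume = c(0, 0.5))
  s <- summarize_stack(rec, analyzed_volume = 100)
  expect_equal(s$percent_volume, 2.0)
  expect_equal(s$mean_component_volume, 1.0)
  expect_equal(s$inside_percent, 75)
  empty <- rec[0, ]
  s0 <- summarize_stack(empty, analyzed_volume = 100)
  expect_equal(s0$percent_volume, 0)
  expect_true(is.na(s0$mean_component_volume))
  expect_error(summarize_stack(rec, analyzed_volume = 0), "> 0")
})

test_that("summaries are invariant to the ordering of records", {
  set.seed(5)
  v <- array(runif(6 * 12 * 12) < 0.2, c(6, 12, 12))
  rec <- measure_components(label_components(v, 26), c(0.3, 0.1, 0.1))
  shuffled <- rec[sample(nrow(rec)), ]
  s1 <- summarize_stack(rec, 100)
  s2 <- summarize_stack(shuffled, 100)
  expect_equal(as.list(s1), as.list(s2))
})

test_that("quantify_stack composes the stages and honors subvolumes", {
  stk <- generate_aggregate_stack(
    aggregate_stack_config(shape = c(20L, 96L, 96L), soma_semiaxes_um = c(2, 3, 3),
                           n_aggregates = 6L, diameter_range_um = c(0.4, 1.2)),
    seed = 2)
  q <- quantify_stack(stk$aggregate, threshold = 60, soma = stk$truth$soma_mask)
  expect_equal(q$summary$total_aggregate_volume,
               sum(stk$truth$per_object$volume_um3))
  expect_equal(q$summary$n_components, nrow(stk$truth$per_object))
  sub <- list(z = c(0L, 10L), y = c(0L, 48L), x = c(0L, 48L))
  qs <- quantify_stack(stk$aggregate, threshold = 60, subvolume = sub)
  expect_equal(qs$summary$analyzed_volume, 10 * 48 * 48 * 0.003)
  expect_s3_class(tidy(q), "tbl_df")
  expect_equal(glance(q)$n_components, q$summary$n_components)
})
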