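test_that("extract_mpr permutes axes consistently", {
  set.seed(2)
  v <- volume_grid(array(rnorm(4 * 5 * 6), c(4, 5, 6)), c(1, 2, 3), c(0, 0, 0))
  ax <- extract_mpr(v, "axial")
  co <- extract_mpr(v, "coronal")
  sa <- extract_mpr(v, "sagittal")
  expect_length(ax$planes, 6)
  expect_length(co$planes, 5)
  expect_length(sa$planes, 4)
  expect_identical(ax$spacing_mm, c(1, 2))
  expect_identical(co$spacing_mm, c(1, 3))
  expect_identical(sa$spacing_mm, c(2, 3))
  # voxel (i, j, k) appears at the permuted position in every stack
  expect_identical(ax$planes[[4]][2, 3], v$voxels[2, 3, 4])
  expect_identical(co$planes[[3]][2, 4], v$voxels[2, 3, 4])
  expect_identical(sa$planes[[2]][3, 4], v$voxels[2, 3, 4])
  expect_error(extract_mpr(v, "oblique"))
})

test_that("centre sagittal plane of a sphere shows the full-diameter disc", {
  ph <- quiet_phantom("solid", 20, 20, n = 61, spacing = 0.5)
  sa <- extract_mpr(ph$volume, "sagittal")
  centre <- sa$planes[[31]]
  mask <- centre >= -300
  ys <- which(rowSums(mask) > 0)
  extent <- (max(ys) - min(ys)) * sa$spacing_mm[1] + sa$spacing_mm[1]
  expect_lt(abs(extent - 20), 0.5 + 1e-9)
})

test_that("measure_size recovers sphere diameters and the GGN zero", {
  ph <- quiet_phantom("solid", 20, 20, n = 61, spacing = 0.5)
  m <- measure_size(ph$volume)
  expect_lt(abs(m$solid_mm - 20), 0.5 + 1e-9)
  expect_identical(m$thresholds_hu[["solid"]], -300)

  ggn <- quiet_phantom("pure_ggn", 16, 0, n = 61, spacing = 0.5)
  mg <- measure_size(ggn$volume)
  expect_identical(mg$solid_mm, 0)
  expect_lt(abs(mg$total_mm - 16), 1.0)

  expect_error(measure_size(ph$volume, solid_threshold_hu = -800,
                            total_threshold_hu = -300), "ordered")
})

test_that("measurement is invariant under axis permutation", {
  ph <- quiet_phantom("part_solid", 16, 9, n = 45, spacing = 0.5)
  m0 <- measure_size(ph$volume)$solid_mm
  perm <- volume_grid(aperm(ph$volume$voxels, c(3, 1, 2)),
                      ph$volume$spacing_mm[c(3, 1, 2)],
                      ph$volume$origin_mm[c(3, 1, 2)])
  expect_equal(measure_size(perm)$solid_mm, m0, tolerance = 1e-9)
})

test_that("raising the solid threshold never increases the measured size", {
  ph <- quiet_phantom("part_solid", 18, 10, n = 45, spacing = 0.5)
  th <- c(-400, -300, -200, -100)
  sizes <- vapply(th, function(t)
    measure_size(ph$volume, solid_threshold_hu = t)$solid_mm, numeric(1))
  expect_true(all(diff(sizes) <= 1e-9))
})

test_that("resolution change moves sphere measurements by less than 1 mm", {
  for (dmm in c(8, 14)) {
    fine <- quiet_phantom("solid", dmm, dmm, n = 51, spacing = 0.5)
    coarse <- quiet_phantom("solid", dmm, dmm, n = 27, spacing = 1.0)
    expect_lt(abs(measure_size(fine$volume)$solid_mm -
                    measure_size(coarse$volume)$solid_mm), 1.0 + 1e-9)
  }
})

test_that("largest component selection ignores detached small blobs", {
  v <- array(-850, c(30, 30, 30))
  v[5:20, 5:20, 5:20] <- -50     # big block
  v[26:27, 26:27, 26:27] <- -50  # detached small block
  vol <- volume_grid(v, c(1, 1, 1), c(0, 0, 0))
  m <- measure_size(vol)
  # diagonal of the 16-voxel cube dominates: ~ sqrt(3) * 15 + gain
  expect_gt(m$solid_mm, 15)
  expect_lt(m$solid_mm, 16 * sqrt(2) + 2)
})

test_that("conventional degradation under-reads the thin-section median", {
  # seeded part-solid cohort; 5 mm axial reads vs 1 mm source reads
  set.seed(77)
  diffs <- vapply(1:12, function(i) {
    d <- runif(1, 8, 16)
    ph <- quiet_phantom("part_solid", d + 6, d, n = 33, spacing = 1.0,
                        seed = i, center = c(0, 0, runif(1, -2.5, 2.5)))
    conv <- degrade(ph$volume, slice_condition(5, 5, 1))
    measure_size(conv, orientations = "axial")$solid_mm -
      measure_size(ph$volume)$solid_mm
  }, numeric(1))
  expect_lte(median(diffs), 0)
})

test_that("simulate_observer has the stated noise model", {
  truth <- structure(list(solid_mm = 10, total_mm = 15, solid_plane = "axial",
                          thresholds_hu = c(solid = -300, total = -700),
                          source = "real_tsct"),
                     class = "size_measurement")
  id <- simulate_observer(truth, observer_model(0, 0, seed = 1))
  expect_identical(id$solid_mm, 10)
  expect_identical(id$total_mm, 15)

  om <- observer_model(1, 0, seed = 5)
  reads <- vapply(1:4000, function(i)
    simulate_observer(truth, om, case_id = i)$solid_mm, numeric(1))
  expect_lt(abs(sd(reads) - 1), 0.05)
  expect_lt(abs(mean(reads) - 10), 0.05)

  # rounding, flooring, clamping
  rr <- simulate_observer(truth, observer_model(0, 2.5, seed = 1))
  expect_identical(rr$solid_mm, 10)
  expect_true(rr$solid_mm <= rr$total_mm)
  same <- simulate_observer(truth, om, case_id = 3)
  again <- simulate_observer(truth, om, case_id = 3)
  expect_identical(same$solid_mm, again$solid_mm)
})

test_that("two noisy observers reach the closed-form ICC", {
  # truth sd 9.6, observer sd 1: ICC ~ 92.16/93.16
  set.seed(88)
  truth_sizes <- pmax(rnorm(3000, 11.3, 9.6), 0)
  om_a <- observer_model(1, 0, seed = 31)
  om_b <- observer_model(1, 0, seed = 32)
  reads <- vapply(seq_along(truth_sizes), function(i) {
    t <- structure(list(solid_mm = truth_sizes[i], total_mm = truth_sizes[i] + 5,
                        solid_plane = "axial",
                        thresholds_hu = c(solid = -300, total = -700),
                        source = "real_tsct"), class = "size_measurement")
    c(simulate_observer(t, om_a, i)$solid_mm,
      simulate_observer(t, om_b, i)$solid_mm)
  }, numeric(2))
  r <- icc_agreement(reads[1, ], reads[2, ])
  # truncation at 0 perturbs the variance slightly; Monte-Carlo tolerance
  expect_lt(abs(r$icc - 92.16 / 93.16), 0.01)
})
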