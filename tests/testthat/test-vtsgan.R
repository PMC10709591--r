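# the model tests run at deliberately tiny scale; the 20-phantom training
# regime lives in test-acceptance.R

toy_cfg <- function(...) vts_model_config(patch_vox = c(8, 8, 12),
                                          base_channels = 4, depth = 1, ...)

test_that("make_training_pairs respects counts, ranges and seeding", {
  vols <- toy_training_volumes(2)
  pairs <- make_training_pairs(vols, 4, seed = 3, patch_vox = c(8, 8, 12))
  expect_length(pairs, 8)
  for (p in pairs) {
    expect_true(p$cond$thickness_mm >= 3 && p$cond$thickness_mm <= 8)
    expect_true(p$cond$interval_mm >= 3 && p$cond$interval_mm <= 8)
    expect_identical(dim(p$thin$voxels), c(8L, 8L, 12L))
    expect_identical(p$thick$spacing_mm[3], p$cond$interval_mm)
  }
  expect_length(make_training_pairs(vols, 0, seed = 3), 0)
  again <- make_training_pairs(vols, 4, seed = 3, patch_vox = c(8, 8, 12))
  expect_identical(pairs, again)
  expect_error(make_training_pairs(vols, 1, seed = 1,
                                   patch_vox = c(64, 64, 64)), "larger")
})

test_that("adversarial smoke training keeps finite, improving losses", {
  vols <- toy_training_volumes(2)
  pairs <- make_training_pairs(vols, 4, seed = 3, patch_vox = c(8, 8, 12))
  m <- vts_train(pairs, toy_cfg(), vts_train_config(epochs = 2, batch_size = 4),
                 seed = 1)
  h <- m$history
  expect_identical(nrow(h), 2L)
  expect_true(all(is.finite(unlist(h))))
  expect_lte(h$rec_l1[2], h$rec_l1[1])
  expect_false(is.null(m$discriminator))
  expect_error(vts_train(list(), toy_cfg()), "no training pairs")
})

test_that("pure regression training beats the linear baseline in-sample", {
  vols <- toy_training_volumes(4)
  pairs <- make_training_pairs(vols, 5, seed = 8, patch_vox = c(8, 8, 16))
  cfg <- vts_model_config(patch_vox = c(8, 8, 16), base_channels = 6,
                          depth = 2, kernel_vox = c(1, 1, 9), lambda_adv = 0)
  base_l1 <- mean(vapply(pairs, function(p) {
    pp <- vtsct:::prepare_pair(p, cfg)
    mean(abs(pp$A[, 1] - pp$y))
  }, numeric(1)))
  m <- vts_train(pairs, cfg, vts_train_config(epochs = 25, batch_size = 10,
                                              lr = 3e-3), seed = 2)
  expect_lte(m$history$rec_l1[25], base_l1)
})

test_that("training is deterministic under a fixed seed", {
  vols <- toy_training_volumes(2)
  pairs <- make_training_pairs(vols, 3, seed = 3, patch_vox = c(8, 8, 12))
  tc <- vts_train_config(epochs = 2, batch_size = 3)
  m1 <- vts_train(pairs, toy_cfg(), tc, seed = 11)
  m2 <- vts_train(pairs, toy_cfg(), tc, seed = 11)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$generator, m2$generator)
})

test_that("untrained generator equals the linear baseline (residual identity)", {
  vols <- toy_training_volumes(1)
  pairs <- make_training_pairs(vols, 1, seed = 4, patch_vox = c(8, 8, 12))
  # epochs = 1 with lr ~ 0 leaves the zero-initialised last layer untouched
  m <- vts_train(pairs, toy_cfg(lambda_adv = 0),
                 vts_train_config(epochs = 1, batch_size = 1, lr = 1e-300),
                 seed = 1)
  thin <- vols[[1]]
  cond <- slice_condition(5, 5, thin$spacing_mm[3])
  thick <- degrade(thin, cond)
  v <- vts_infer(m, thick, cond, 1.0)
  b <- baseline_interp(thick, cond, 1.0, "linear")
  expect_equal(v$voxels, b$voxels, tolerance = 1e-12)
  expect_identical(v$spacing_mm[3], 1)
  expect_identical(dim(v$voxels)[1:2], dim(thick$voxels)[1:2])
})

test_that("inference is bitwise deterministic and respects the clip range", {
  vols <- toy_training_volumes(1)
  pairs <- make_training_pairs(vols, 2, seed = 4, patch_vox = c(8, 8, 12))
  m <- vts_train(pairs, toy_cfg(), vts_train_config(epochs = 2, batch_size = 2),
                 seed = 5)
  cond <- slice_condition(5, 5, 1)
  thick <- degrade(vols[[1]], cond)
  a <- vts_infer(m, thick, cond, 1.0)
  b <- vts_infer(m, thick, cond, 1.0)
  expect_identical(a$voxels, b$voxels)
  expect_true(all(a$voxels >= -1024 & a$voxels <= 600))
  # chunked and whole-volume inference agree exactly
  ch <- vts_infer(m, thick, cond, 1.0, chunk_vox = 8 * 8 * 14)
  expect_equal(ch$voxels, a$voxels, tolerance = 1e-12)
  expect_error(vts_infer(m, thick, slice_condition(5, 4.5, 1), 1.0), "interval")
  expect_error(vts_infer(m, thick, cond, 2.0), "target_thin_mm")
})

test_that("baseline_interp reproduces constants, ramps and input slices", {
  cond <- slice_condition(5, 5, 1)
  const <- volume_grid(array(-400, c(3, 3, 5)), c(1, 1, 5), c(0, 0, 0))
  for (meth in c("nearest", "linear", "cubic")) {
    out <- baseline_interp(const, cond, 1, meth)
    expect_equal(as.vector(out$voxels), rep(-400, length(out$voxels)),
                 tolerance = 1e-12)
  }
  ramp <- volume_grid(array(rep(seq(-800, -400, length.out = 5),
                                each = 9), c(3, 3, 5)), c(1, 1, 5), c(0, 0, 0))
  lin <- baseline_interp(ramp, cond, 1, "linear")
  prof <- lin$voxels[1, 1, ]
  expect_equal(diff(prof), rep(100 / 5, length(prof) - 1), tolerance = 1e-9)

  nn <- baseline_interp(ramp, cond, 1, "nearest")
  expect_true(all(nn$voxels %in% ramp$voxels))
  expect_error(baseline_interp(ramp, cond, 1, "sinc"))
})

test_that("model checkpoints round-trip to bit-identical inference", {
  vols <- toy_training_volumes(1)
  pairs <- make_training_pairs(vols, 2, seed = 4, patch_vox = c(8, 8, 12))
  m <- vts_train(pairs, toy_cfg(), vts_train_config(epochs = 1, batch_size = 2),
                 seed = 6)
  cond <- slice_condition(5, 5, 1)
  thick <- degrade(vols[[1]], cond)
  before <- vts_infer(m, thick, cond, 1.0)
  f <- tempfile(fileext = ".rds")
  save_model(m, f)
  m2 <- load_model(f)
  after <- vts_infer(m2, thick, cond, 1.0)
  expect_identical(before$voxels, after$voxels)
  hf <- tempfile(fileext = ".csv")
  write_loss_history(m, hf)
  expect_identical(nrow(read.csv(hf)), 1L)
})
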