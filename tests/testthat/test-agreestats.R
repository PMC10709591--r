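test_that("icc_agreement handles the degenerate and perfect cases", {
  x <- c(1, 5, 9, 13, 2.5)
  r <- icc_agreement(x, x)
  expect_identical(r$icc, 1)
  expect_identical(r$p, 0)
  expect_error(icc_agreement(1:5, 1:4), "equal length")
  expect_error(icc_agreement(c(1, 2), c(1, 2)), "at least 3")
  expect_warning(icc_agreement(rep(2, 5), rep(2, 5)), "no variance")
})

test_that("icc_agreement matches the variance-components closed form", {
  # truth sd 9.6, two observers with independent N(0, 1) noise:
  # ICC = 9.6^2 / (9.6^2 + 1) = 92.16 / 93.16
  set.seed(401)
  truth <- rnorm(5000, 11.3, 9.6)
  r <- icc_agreement(truth + rnorm(5000), truth + rnorm(5000))
  expect_lt(abs(r$icc - 92.16 / 93.16), 0.005)
  expect_true(r$ci[1] <= r$icc && r$icc <= r$ci[2])
  expect_lt(r$p, 1e-10)
})

test_that("absolute-agreement ICC penalises a constant offset", {
  set.seed(7)
  x <- rnorm(200, 10, 5)
  y <- x + 8
  r <- icc_agreement(x, y)
  expect_lt(r$icc, cor(x, y) - 0.2)  # consistency correlation is ~1
})

test_that("ICC estimator bias vanishes as n grows", {
  target <- 92.16 / 93.16
  err <- vapply(c(50, 500, 5000), function(n) {
    set.seed(n)
    reps <- if (n == 50) 40 else if (n == 500) 10 else 2
    mean(vapply(seq_len(reps), function(i) {
      truth <- rnorm(n, 0, 9.6)
      icc_agreement(truth + rnorm(n), truth + rnorm(n))$icc
    }, numeric(1))) - target
  }, numeric(1))
  expect_true(abs(err[3]) < abs(err[1]) + 0.01)
  expect_lt(abs(err[3]), 0.003)
})

test_that("compare_dependent_r has the stated symmetries", {
  r0 <- compare_dependent_r(0.8, 0.8, 0.5, 93)
  expect_identical(r0$statistic, 0)
  expect_identical(r0$p, 1)
  a <- compare_dependent_r(0.9, 0.7, 0.5, 93)
  b <- compare_dependent_r(0.7, 0.9, 0.5, 93)
  expect_equal(a$statistic, -b$statistic, tolerance = 1e-12)
  expect_equal(a$p, b$p, tolerance = 1e-12)
  expect_error(compare_dependent_r(1, 0.5, 0.2, 93), "< 1")
  expect_error(compare_dependent_r(0.5, 0.4, 0.2, 3), "n >= 4")
})

test_that("compare_dependent_r approaches the Fisher z-test as r_ac -> 0", {
  w <- compare_dependent_r(0.6, 0.4, 1e-9, 200)$statistic
  f <- compare_dependent_r(0.6, 0.4, 0, 200, method = "fisher")$statistic
  expect_lt(abs(w - f) / abs(f), 0.15)  # same scale and sign, similar size
  expect_identical(sign(w), sign(f))
})

test_that("the reported significance direction is attainable at n = 93", {
  # paper-shaped configuration: r(virtual, real) = 0.95 vs
  # r(conventional, real) = 0.88 on 93 cases; r_ac estimated from a seeded
  # synthetic cohort sharing the latent size
  set.seed(12)
  truth <- rnorm(93, 11.3, 9.6)
  conv <- truth + rnorm(93, 0, 4.5)
  virt <- truth + rnorm(93, 0, 3)
  r_ac <- cor(conv, virt)
  res <- compare_dependent_r(0.95, 0.88, r_ac, 93)
  expect_lt(res$p, 0.05)
})

test_that("cohen_kappa matches hand computation and edge cases", {
  # 2x2 table [[45, 5], [5, 45]]: po = 0.9, pe = 0.5, kappa = 0.8
  a <- rep(c("x", "x", "y", "y"), c(45, 5, 5, 45))
  b <- rep(c("x", "y", "x", "y"), c(45, 5, 5, 45))
  k <- cohen_kappa(a, b)
  expect_equal(k$po, 0.9, tolerance = 1e-12)
  expect_equal(k$pe, 0.5, tolerance = 1e-12)
  expect_equal(k$kappa, 0.8, tolerance = 1e-12)
  expect_lt(k$p, 1e-10)

  ident <- cohen_kappa(c("a", "b", "a", "c"), c("a", "b", "a", "c"))
  expect_identical(ident$kappa, 1)

  # chance-level agreement by construction: po == pe exactly
  a2 <- rep(c("p", "q"), each = 50)
  b2 <- rep(rep(c("p", "q"), 2), c(25, 25, 25, 25))
  expect_equal(cohen_kappa(a2, b2)$kappa, 0, tolerance = 1e-12)

  expect_error(cohen_kappa(character(), character()), "empty")
  expect_warning(cohen_kappa(rep("a", 5), rep("a", 5)), "undefined")
})

test_that("kappa is invariant under category relabelling and bounded", {
  set.seed(31)
  cats <- c("I", "II", "III", "IV")
  a <- sample(cats, 200, replace = TRUE)
  b <- ifelse(runif(200) < 0.6, a, sample(cats, 200, replace = TRUE))
  k1 <- cohen_kappa(a, b, cats)
  perm <- c(I = "W", II = "X", III = "Y", IV = "Z")
  k2 <- cohen_kappa(perm[a], perm[b], unname(perm))
  expect_equal(k1$kappa, k2$kappa, tolerance = 1e-12)
  expect_true(k1$kappa >= -1 && k1$kappa <= 1)
})

test_that("kappa CI coverage is near nominal", {
  # seeded simulation: true kappa known for a symmetric 2-category process
  set.seed(99)
  p_true <- 0.85         # agreement probability; pe = 0.5 -> kappa = 0.7
  kap_true <- (p_true - 0.5) / 0.5
  n <- 150
  hits <- vapply(1:500, function(i) {
    a <- sample(c("u", "v"), n, replace = TRUE)
    agree <- runif(n) < p_true
    b <- ifelse(agree, a, ifelse(a == "u", "v", "u"))
    k <- cohen_kappa(a, b)
    k$ci[1] <= kap_true && kap_true <= k$ci[2]
  }, logical(1))
  expect_lt(abs(mean(hits) - 0.95), 0.03)
})

test_that("interpret_kappa maps values to the stated bands", {
  expect_identical(interpret_kappa(0.882), "almost perfect")
  expect_identical(interpret_kappa(0.757), "good")
  expect_identical(interpret_kappa(0.591), "moderate")
  expect_identical(interpret_kappa(c(0.1, 0.2, 0.3, 0.45, 0.65, 0.85, -0.5)),
                   c("poor", "poor", "fair", "moderate", "good",
                     "almost perfect", "poor"))
  expect_error(interpret_kappa(1.2), "\\[-1, 1\\]")
})

test_that("ancova_modality_observer behaves on constructed designs", {
  set.seed(55)
  n <- 93
  truth <- abs(rnorm(n, 11, 9))
  # observer B duplicates observer A exactly: observer F = 0, p = 1
  conv_read <- truth + rnorm(n, -1, 1)
  virt_read <- truth + rnorm(n, 0, 1)
  d1 <- rbind(
    data.frame(size = conv_read, observer = "A", modality = "conv", real_size = truth),
    data.frame(size = conv_read, observer = "B", modality = "conv", real_size = truth),
    data.frame(size = virt_read, observer = "A", modality = "virt", real_size = truth),
    data.frame(size = virt_read, observer = "B", modality = "virt", real_size = truth))
  r1 <- ancova_modality_observer(d1)
  expect_lt(r1$observer["F"], 1e-12)
  expect_gt(r1$observer["p"], 0.999)

  # -4 mm offset on one modality, noise sd 1: modality p < 0.001
  d2 <- do.call(rbind, lapply(c("A", "B"), function(o) rbind(
    data.frame(size = truth + rnorm(n), observer = o, modality = "conv",
               real_size = truth),
    data.frame(size = truth - 4 + rnorm(n), observer = o, modality = "virt",
               real_size = truth))))
  r2 <- ancova_modality_observer(d2)
  expect_lt(r2$modality["p"], 0.001)
  # covariate coefficient ~ 1 for truth + noise measurements
  expect_lt(abs(coef(r2$model)["real_size"] - 1), 0.05)

  expect_error(ancova_modality_observer(d2[, -1]), "columns")
})
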