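#' Specification of a synthetic lung-nodule phantom
#'
#' Describes an idealised nodule as up to two concentric spheres: a solid core
#' (high attenuation) inside a ground-glass (GGO) shell, embedded in lung
#' background. The three attenuation levels are chosen so that a single HU
#' threshold cleanly separates each pair of components; all are configurable.
#'
#' @param nodule_type one of "solid", "part_solid", "pure_ggn".
#' @param total_diameter_mm outer (GGO) diameter in mm, > 0.
#' @param solid_diameter_mm solid-core diameter in mm; 0 for pure GGN, equal
#'   to `total_diameter_mm` for solid nodules.
#' @param center_mm world position of the nodule centre (mm).
#' @param solid_hu,ggo_hu,lung_hu component attenuations; must satisfy
#'   `solid_hu > ggo_hu > lung_hu`.
#' @param noise_sd_hu standard deviation of additive Gaussian HU noise.
#' @return A `nodule_spec` object.
#' @export
nodule_spec <- function(nodule_type = c("part_solid", "solid", "pure_ggn"),
                        total_diameter_mm, solid_diameter_mm,
                        center_mm = c(0, 0, 0),
                        solid_hu = -50, ggo_hu = -450, lung_hu = -850,
                        noise_sd_hu = 20) {
  nodule_type <- match.arg(nodule_type)
  if (!is.finite(total_diameter_mm) || total_diameter_mm <= 0)
    stop("total_diameter_mm must be positive")
  if (!is.finite(solid_diameter_mm) || solid_diameter_mm < 0)
    stop("solid_diameter_mm must be non-negative")
  if (solid_diameter_mm > total_diameter_mm + 1e-9)
    stop("solid_diameter_mm must not exceed total_diameter_mm")
  if (noise_sd_hu < 0) stop("noise_sd_hu must be non-negative")
  if (!(solid_hu > ggo_hu && ggo_hu > lung_hu))
    stop("attenuations must be ordered solid_hu > ggo_hu > lung_hu")
  if ((nodule_type == "pure_ggn") != (solid_diameter_mm == 0))
    stop("pure_ggn nodules (and only those) must have solid_diameter_mm == 0")
  if ((nodule_type == "solid") != (solid_diameter_mm == total_diameter_mm))
    stop("solid nodules (and only those) must have solid == total diameter")
  structure(list(nodule_type = nodule_type,
                 total_diameter_mm = total_diameter_mm,
                 solid_diameter_mm = solid_diameter_mm,
                 center_mm = as.numeric(center_mm),
                 solid_hu = solid_hu, ggo_hu = ggo_hu, lung_hu = lung_hu,
                 noise_sd_hu = noise_sd_hu),
            class = "nodule_spec")
}

# sphere volume fraction per voxel at 2x supersampling along each axis:
# each voxel is split into 8 sub-voxels and the fraction of sub-voxel
# centres inside the sphere is the mixing weight.
sphere_fraction <- function(template, center, radius) {
  d <- template$dim_vox; s <- template$spacing_mm; o <- template$origin_mm
  sub <- function(ax) {
    cc <- axis_coords(d[ax], s[ax], o[ax])
    as.vector(rbind(cc - s[ax] / 4, cc + s[ax] / 4))
  }
  dx2 <- (sub(1) - center[1])^2
  dy2 <- (sub(2) - center[2])^2
  dz2 <- (sub(3) - center[3])^2
  n1 <- 2L * d[1]; n2 <- 2L * d[2]; n3 <- 2L * d[3]
  inside <- array(outer(outer(dx2, dy2, "+"), dz2, "+") <= radius^2,
                  dim = c(n1, n2, n3))
  pair_sum <- function(a, ax) {
    idx1 <- seq(1L, dim(a)[ax], by = 2L)
    idx2 <- idx1 + 1L
    switch(ax,
           a[idx1, , , drop = FALSE] + a[idx2, , , drop = FALSE],
           a[, idx1, , drop = FALSE] + a[, idx2, , drop = FALSE],
           a[, , idx1, drop = FALSE] + a[, , idx2, drop = FALSE])
  }
  f <- pair_sum(pair_sum(pair_sum(inside + 0, 1L), 2L), 3L) / 8
  array(f, dim = d)
}

#' Rasterise a nodule phantom onto a grid
#'
#' Voxels are filled by sub-voxel volume-fraction mixing (2x supersampling
#' per axis) of the three attenuation levels, so the sphere boundary carries
#' partial-volume values and sub-voxel size recovery is meaningful. Zero-mean
#' Gaussian noise of `spec$noise_sd_hu` is then added under the given seed;
#' the same spec, template and seed always yield a bitwise-identical volume.
#'
#' @param spec a [nodule_spec()].
#' @param template a [volume_template()]; z spacing must lie in [0.5, 1.0] mm
#'   (the thin-section regime) and in-plane spacing must be isotropic.
#' @param seed integer seed for the noise field and the invasive-size proxy.
#' @param invasive_size_mm optional pathological invasive size; when `NULL` it
#'   is drawn from the proxy model `true_solid + N(bias, sd^2)` floored at 0.
#' @param invasive_bias_mm,invasive_sd_mm proxy-model parameters (mm).
#' @return A list with elements `volume` (a `volume_grid`) and `truth`
#'   (a `nodule_truth`).
#' @export
generate_phantom <- function(spec, template, seed,
                             invasive_size_mm = NULL,
                             invasive_bias_mm = 2.4, invasive_sd_mm = 3) {
  stopifnot(inherits(spec, "nodule_spec"), inherits(template, "volume_template"))
  s <- template$spacing_mm
  if (abs(s[1] - s[2]) > 1e-9) stop("template must have isotropic in-plane spacing")
  if (s[3] < 0.5 - 1e-9 || s[3] > 1.0 + 1e-9)
    stop("template z-spacing must be within [0.5, 1.0] mm (thin-section regime)")
  lo <- template$origin_mm - s / 2
  hi <- template$origin_mm + (template$dim_vox - 1) * s + s / 2
  r_t <- spec$total_diameter_mm / 2
  if (any(spec$center_mm - r_t - 2 < lo) || any(spec$center_mm + r_t + 2 > hi))
    stop("nodule does not fit inside the grid with a 2 mm margin")

  f_total <- sphere_fraction(template, spec$center_mm, r_t)
  f_solid <- if (spec$solid_diameter_mm > 0)
    sphere_fraction(template, spec$center_mm, spec$solid_diameter_mm / 2)
  else array(0, dim = template$dim_vox)

  vox <- spec$lung_hu +
    (spec$ggo_hu - spec$lung_hu) * f_total +
    (spec$solid_hu - spec$ggo_hu) * f_solid

  draws <- with_seed(seed, {
    noise <- if (spec$noise_sd_hu > 0) rnorm(length(vox), 0, spec$noise_sd_hu) else 0
    inv <- if (is.null(invasive_size_mm))
      max(0, spec$solid_diameter_mm + rnorm(1, invasive_bias_mm, invasive_sd_mm))
    else invasive_size_mm
    list(noise = noise, inv = inv)
  })
  vox <- vox + draws$noise

  truth <- structure(list(spec = spec,
                          true_total_mm = spec$total_diameter_mm,
                          true_solid_mm = spec$solid_diameter_mm,
                          invasive_size_mm = draws$inv),
                     class = "nodule_truth")
  list(volume = volume_grid(vox, s, template$origin_mm), truth = truth)
}

# truncated-normal sampler by quantile inversion
rtruncnorm <- function(n, mean, sd, lower, upper) {
  pl <- pnorm(lower, mean, sd); pu <- pnorm(upper, mean, sd)
  qnorm(pl + runif(n) * (pu - pl), mean, sd)
}

#' Cohort distribution settings
#'
#' Defaults emulate the validation population: 27 solid / 55 part-solid /
#' 11 pure GGN out of 93 nodules, solid size truncated-normal
#' (11.3, 9.6) on [0, 36] mm, total size truncated-normal (19.6, 9.1) on
#' [5, 45] mm, and a pathological invasive-size proxy
#' `solid + N(2.4, 3^2)` floored at 0 mm.
#'
#' @param proportions named numeric, sampling weights for the three nodule
#'   types (need not sum to 1; must be non-negative, positive sum).
#' @param solid_mean,solid_sd,solid_bounds solid-size distribution (mm).
#' @param total_mean,total_sd,total_bounds total-size distribution (mm).
#' @param invasive_bias_mm,invasive_sd_mm invasive-size proxy (mm).
#' @param noise_sd_hu phantom HU noise level.
#' @return A list of validated settings.
#' @export
cohort_params <- function(proportions = c(solid = 27, part_solid = 55, pure_ggn = 11),
                          solid_mean = 11.3, solid_sd = 9.6, solid_bounds = c(0, 36),
                          total_mean = 19.6, total_sd = 9.1, total_bounds = c(5, 45),
                          invasive_bias_mm = 2.4, invasive_sd_mm = 3,
                          noise_sd_hu = 20) {
  if (length(proportions) != 3L || any(proportions < 0) || sum(proportions) <= 0)
    stop("proportions must be 3 non-negative weights with positive sum")
  if (!all(c("solid", "part_solid", "pure_ggn") %in% names(proportions)))
    stop("proportions must be named solid, part_solid, pure_ggn")
  if (solid_bounds[1] >= solid_bounds[2] || total_bounds[1] >= total_bounds[2])
    stop("distribution bounds must be increasing")
  if (solid_sd <= 0 || total_sd <= 0) stop("size sds must be positive")
  list(proportions = proportions / sum(proportions),
       solid_mean = solid_mean, solid_sd = solid_sd, solid_bounds = solid_bounds,
       total_mean = total_mean, total_sd = total_sd, total_bounds = total_bounds,
       invasive_bias_mm = invasive_bias_mm, invasive_sd_mm = invasive_sd_mm,
       noise_sd_hu = noise_sd_hu)
}

#' Draw a seeded nodule cohort
#'
#' Nodule types are drawn multinomially; a latent solid size is drawn from the
#' truncated normal for every case and is used directly for part-solid
#' nodules, forced to 0 for pure GGNs, and sets both diameters for solid
#' nodules (floored at the total-size lower bound). Total size is drawn
#' independently and clamped to exceed the solid size. The invasive size is
#' the pathology proxy `solid + N(bias, sd^2)` floored at 0.
#'
#' @param n number of nodules (>= 0).
#' @param params a [cohort_params()] list.
#' @param seed integer seed; identical seeds give identical cohorts.
#' @return A list with `specs` (list of [nodule_spec()]) and `truth`, a
#'   data.frame with columns id, nodule_type, total_mm, solid_mm, invasive_mm,
#'   seed.
#' @export
generate_cohort <- function(n, params = cohort_params(), seed) {
  n <- as.integer(n)
  if (is.na(n) || n < 0L) stop("n must be a non-negative integer")
  empty <- data.frame(id = integer(), nodule_type = character(),
                      total_mm = numeric(), solid_mm = numeric(),
                      invasive_mm = numeric(), seed = numeric())
  if (n == 0L) return(list(specs = list(), truth = empty))
  types <- c("solid", "part_solid", "pure_ggn")
  draws <- with_seed(seed, {
    ty <- sample(types, n, replace = TRUE,
                 prob = params$proportions[types])
    s_lat <- rtruncnorm(n, params$solid_mean, params$solid_sd,
                        params$solid_bounds[1], params$solid_bounds[2])
    t_lat <- rtruncnorm(n, params$total_mean, params$total_sd,
                        params$total_bounds[1], params$total_bounds[2])
    inv_noise <- rnorm(n, params$invasive_bias_mm, params$invasive_sd_mm)
    list(ty = ty, s = s_lat, t = t_lat, inv = inv_noise)
  })
  solid <- numeric(n); total <- numeric(n)
  for (i in seq_len(n)) {
    switch(draws$ty[i],
           pure_ggn = { solid[i] <- 0; total[i] <- draws$t[i] },
           part_solid = {
             solid[i] <- draws$s[i]
             total[i] <- max(draws$t[i], solid[i] + 1)
           },
           solid = {
             solid[i] <- max(draws$s[i], params$total_bounds[1])
             total[i] <- solid[i]
           })
  }
  invasive <- pmax(0, solid + draws$inv)
  specs <- vector("list", n)
  for (i in seq_len(n))
    specs[[i]] <- nodule_spec(draws$ty[i], total[i], solid[i],
                              noise_sd_hu = params$noise_sd_hu)
  truth <- data.frame(id = seq_len(n), nodule_type = draws$ty,
                      total_mm = total, solid_mm = solid,
                      invasive_mm = invasive, seed = as.numeric(seed))
  list(specs = specs, truth = truth)
}

#' Write cohort ground truth as a delimited table
#'
#' @param cohort result of [generate_cohort()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(cohort, path) {
  utils::write.csv(cohort$truth, path, row.names = FALSE)
  invisible(path)
}
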