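#' Extract an axis-aligned multiplanar reconstruction
#'
#' Returns the ordered stack of planes perpendicular to the chosen axis.
#' Axial planes are perpendicular to z (matrix axes x, y), coronal to y
#' (axes x, z) and sagittal to x (axes y, z). Planes are plain index
#' permutations of the volume -- no resampling -- with the correct per-plane
#' pixel spacings attached.
#'
#' @param volume a `volume_grid`.
#' @param orientation "axial", "coronal" or "sagittal".
#' @return A list with `planes` (list of matrices), `spacing_mm` (length-2)
#'   and `orientation`.
#' @export
extract_mpr <- function(volume, orientation = c("axial", "coronal", "sagittal")) {
  orientation <- match.arg(orientation)
  v <- volume$voxels; s <- volume$spacing_mm
  d <- dim(v)
  res <- switch(orientation,
    axial = list(planes = lapply(seq_len(d[3]), function(k) v[, , k]),
                 spacing_mm = s[c(1, 2)]),
    coronal = list(planes = lapply(seq_len(d[2]), function(j) v[, j, ]),
                   spacing_mm = s[c(1, 3)]),
    sagittal = list(planes = lapply(seq_len(d[1]), function(i) v[i, , ]),
                    spacing_mm = s[c(2, 3)]))
  res$orientation <- orientation
  res
}

# largest 26-connected foreground component of a logical 3D mask.
# Returns linear indices of its voxels (integer(0) if mask empty).
# Ties on size are broken by the lowest lexicographic centroid.
largest_component <- function(mask) {
  fg <- which(mask)
  if (length(fg) == 0L) return(integer(0))
  d <- dim(mask)
  id <- integer(prod(d))
  id[fg] <- seq_along(fg)
  co <- arrayInd(fg, d)
  edges <- vector("list", 13L)
  e <- 0L
  for (c in 0:1) for (b in -1:1) for (a in -1:1) {
    if (c == 0 && (b < 0 || (b == 0 && a <= 0))) next  # forward offsets only
    e <- e + 1L
    ii <- co[, 1] + a; jj <- co[, 2] + b; kk <- co[, 3] + c
    ok <- ii >= 1L & ii <= d[1] & jj >= 1L & jj <= d[2] & kk >= 1L & kk <= d[3]
    nl <- ii[ok] + (jj[ok] - 1L) * d[1] + (kk[ok] - 1L) * d[1] * d[2]
    nid <- id[nl]
    keep <- nid > 0L
    edges[[e]] <- rbind(id[fg[ok]][keep], nid[keep])
  }
  em <- do.call(cbind, edges)
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (length(em) > 0) g <- igraph::add_edges(g, as.vector(em))
  memb <- igraph::components(g)$membership
  sizes <- tabulate(memb)
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    cent <- t(vapply(best, function(m) colMeans(co[memb == m, , drop = FALSE]),
                     numeric(3)))
    best <- best[order(cent[, 1], cent[, 2], cent[, 3])][1]
  } else best <- best[1]
  fg[memb == best]
}

# maximum Feret (caliper) diameter in mm of a set of pixel centres. Pixel
# extent is honoured by adding half a pixel width projected onto the
# measurement direction: the two boundary pixels are on average about half
# covered by the object, so centre-to-centre distance alone under-reads by
# roughly a pixel while a full-pixel gain over-reads; the half-pixel
# convention keeps sphere recovery within half the in-plane spacing.
feret_max <- function(pts, spacing) {
  n <- nrow(pts)
  if (n == 0L) return(0)
  if (n == 1L) return(mean(spacing))
  h <- unique(grDevices::chull(pts))
  hp <- pts[h, , drop = FALSE]
  m <- nrow(hp)
  if (m == 1L) return(mean(spacing))
  dx <- outer(hp[, 1], hp[, 1], "-")
  dy <- outer(hp[, 2], hp[, 2], "-")
  d2 <- dx^2 + dy^2
  up <- d2 > 0
  val <- sqrt(d2[up]) +
    (dx[up]^2 * spacing[1] + dy[up]^2 * spacing[2]) / (2 * d2[up])
  max(val)
}

# max over planes of one orientation of the in-plane Feret diameter of the
# component given by linear voxel indices
orientation_feret <- function(idx3, d, spacing, orientation) {
  if (length(idx3) == 0L) return(0)
  co <- arrayInd(idx3, d)
  ax <- switch(orientation, axial = c(1L, 2L, 3L), coronal = c(1L, 3L, 2L),
               sagittal = c(2L, 3L, 1L))
  sp <- spacing[ax[1:2]]
  best <- 0
  for (p in unique(co[, ax[3]])) {
    sel <- co[, ax[3]] == p
    pts <- cbind(co[sel, ax[1]] * spacing[ax[1]],
                 co[sel, ax[2]] * spacing[ax[2]])
    best <- max(best, feret_max(pts, sp))
  }
  best
}

#' Measure maximal solid and total nodule size on MPR planes
#'
#' The volume is binarised at the solid (default -300 HU) and total (default
#' -700 HU) thresholds; for each, the largest 26-connected component is kept
#' and, for each of the three orthogonal orientations, the maximum over
#' planes of the in-plane maximum Feret diameter of the component's
#' cross-section is computed. The reported size is the maximum over the three
#' orientations; the arg-max orientation of the solid measurement is
#' reported as `solid_plane`. An empty mask yields 0. The default thresholds
#' sit between the phantom attenuation levels (-50 solid / -450 GGO / -850
#' lung), so each binarisation isolates one component boundary.
#'
#' @param volume a `volume_grid`.
#' @param solid_threshold_hu,total_threshold_hu HU thresholds; must satisfy
#'   `solid_threshold_hu > total_threshold_hu`.
#' @param source provenance label: "conventional", "virtual_tsct" or
#'   "real_tsct".
#' @param orientations which plane stacks to search; thin-section volumes
#'   use all three MPR orientations (the default), while conventional 5 mm
#'   axial CT is conventionally read on its axial planes only -- coronal and
#'   sagittal reformats of 5 mm slices are not diagnostic.
#' @param feret_3d if `TRUE`, additionally report the 3D maximum Feret
#'   diameter of the solid component (field `solid_3d_mm`); the per-plane
#'   maximum remains the headline value.
#' @return A `size_measurement` object with fields `solid_mm`, `total_mm`,
#'   `solid_plane`, `thresholds_hu`, `source`.
#' @export
measure_size <- function(volume, solid_threshold_hu = -300,
                         total_threshold_hu = -700,
                         source = c("real_tsct", "conventional", "virtual_tsct"),
                         orientations = c("axial", "coronal", "sagittal"),
                         feret_3d = FALSE) {
  source <- match.arg(source)
  orientations <- match.arg(orientations, several.ok = TRUE)
  if (!(solid_threshold_hu > total_threshold_hu))
    stop("thresholds must be ordered solid_threshold_hu > total_threshold_hu")
  v <- volume$voxels
  if (any(!is.finite(v))) stop("volume contains non-finite HU")
  d <- dim(v); sp <- volume$spacing_mm

  measure_one <- function(thr) {
    comp <- largest_component(v >= thr)
    per <- vapply(orientations, function(o) orientation_feret(comp, d, sp, o),
                  numeric(1))
    list(mm = max(per, 0), plane = if (all(per == 0)) NA_character_
         else orientations[which.max(per)], comp = comp)
  }
  sol <- measure_one(solid_threshold_hu)
  tot <- measure_one(total_threshold_hu)
  out <- structure(list(solid_mm = sol$mm,
                        total_mm = max(tot$mm, sol$mm),
                        solid_plane = sol$plane,
                        thresholds_hu = c(solid = solid_threshold_hu,
                                          total = total_threshold_hu),
                        source = source),
                   class = "size_measurement")
  if (feret_3d) out$solid_3d_mm <- feret3d_max(sol$comp, d, sp)
  out
}

# 3D maximum caliper over component boundary voxels (+ voxel-box extent)
feret3d_max <- function(idx3, d, spacing) {
  if (length(idx3) == 0L) return(0)
  co <- arrayInd(idx3, d)
  mask <- array(FALSE, d); mask[idx3] <- TRUE
  on_boundary <- rep(FALSE, nrow(co))
  for (ax in 1:3) for (s in c(-1L, 1L)) {
    nb <- co; nb[, ax] <- nb[, ax] + s
    inb <- nb[, ax] >= 1L & nb[, ax] <= d[ax]
    nl <- nb[, 1] + (nb[, 2] - 1L) * d[1] + (nb[, 3] - 1L) * d[1] * d[2]
    on_boundary <- on_boundary | !inb | (inb & !mask[pmin(pmax(nl, 1L), prod(d))])
  }
  bp <- co[on_boundary, , drop = FALSE]
  if (nrow(bp) == 1L) return(mean(spacing))
  pm <- sweep(bp, 2L, spacing, "*")
  best <- 0
  for (i in seq_len(nrow(pm) - 1L)) {
    dxyz <- sweep(pm[(i + 1L):nrow(pm), , drop = FALSE], 2L, pm[i, ], "-")
    d2 <- rowSums(dxyz^2)
    gain <- (dxyz^2 %*% spacing) / (2 * pmax(d2, 1e-12))
    best <- max(best, max(sqrt(d2) + gain))
  }
  best
}

#' @export
print.size_measurement <- function(x, ...) {
  cat(sprintf("<size_measurement> solid %.1f mm (%s), total %.1f mm [%s]\n",
              x$solid_mm, ifelse(is.na(x$solid_plane), "-", x$solid_plane),
              x$total_mm, x$source))
  invisible(x)
}

#' Simulated human observer
#'
#' Models a reader as additive Gaussian measurement noise followed by
#' rounding to the reporting precision (callipers are read to 1 mm by
#' default), flooring at 0 and clamping solid <= total.
#'
#' @param additive_sd_mm noise standard deviation in mm (>= 0).
#' @param rounding_mm reporting precision in mm (> 0), or 0 to disable.
#' @param seed integer observer seed; draws for case `i` are derived from it
#'   so per-case reads are reproducible in any order.
#' @return An `observer_model` object.
#' @export
observer_model <- function(additive_sd_mm = 1, rounding_mm = 1, seed = 1) {
  if (additive_sd_mm < 0) stop("additive_sd_mm must be >= 0")
  if (rounding_mm < 0) stop("rounding_mm must be >= 0")
  structure(list(additive_sd_mm = additive_sd_mm, rounding_mm = rounding_mm,
                 seed = as.integer(seed)),
            class = "observer_model")
}

#' Apply a simulated observer to a size measurement
#'
#' @param truth a `size_measurement` (the automated/ground-truth read).
#' @param model an [observer_model()].
#' @param case_id integer stream index; same (model, case_id) always gives
#'   the same read.
#' @return A perturbed `size_measurement`.
#' @export
simulate_observer <- function(truth, model, case_id = 1L) {
  stopifnot(inherits(truth, "size_measurement"), inherits(model, "observer_model"))
  noise <- with_seed(derive_seed(model$seed, case_id),
                     rnorm(2, 0, max(model$additive_sd_mm, 1e-12)))
  if (model$additive_sd_mm == 0) noise <- c(0, 0)
  s <- truth$solid_mm + noise[1]
  t <- truth$total_mm + noise[2]
  if (model$rounding_mm > 0) {
    s <- round(s / model$rounding_mm) * model$rounding_mm
    t <- round(t / model$rounding_mm) * model$rounding_mm
  }
  s <- max(s, 0); t <- max(t, 0)
  s <- min(s, t)
  out <- truth
  out$solid_mm <- s; out$total_mm <- t
  out
}
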