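#' 3D CT volume container
#'
#' A `volume_grid` carries a 3D voxel array of Hounsfield units together with
#' its geometry. The array axes are fixed project-wide: dimension 1 is x
#' (left-right), dimension 2 is y (antero-posterior), dimension 3 is z
#' (craniocaudal); axial slices are planes perpendicular to z. Voxel indices
#' are 1-based in R; the world position of voxel (i, j, k) is
#' `origin_mm + (c(i, j, k) - 1) * spacing_mm`, i.e. `origin_mm` is the centre
#' of the first voxel. All distances are millimetres.
#'
#' @param voxels 3D numeric array of HU values.
#' @param spacing_mm numeric length-3, per-axis voxel spacing in mm (all > 0).
#' @param origin_mm numeric length-3, world position of voxel (1,1,1) centre.
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(voxels, spacing_mm, origin_mm = c(0, 0, 0)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("voxels must be a 3D array")
  spacing_mm <- as.numeric(spacing_mm)
  origin_mm <- as.numeric(origin_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("spacing_mm must be 3 positive finite numbers")
  if (length(origin_mm) != 3L || any(!is.finite(origin_mm)))
    stop("origin_mm must be 3 finite numbers")
  if (any(!is.finite(voxels)))
    stop("voxels must be finite HU values")
  structure(list(voxels = voxels, spacing_mm = spacing_mm, origin_mm = origin_mm),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<volume_grid> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing_mm[1], x$spacing_mm[2], x$spacing_mm[3]))
  cat(sprintf("  origin (%.2f, %.2f, %.2f) mm, HU range [%.1f, %.1f]\n",
              x$origin_mm[1], x$origin_mm[2], x$origin_mm[3],
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Geometry-only template for a volume grid
#'
#' Describes the grid on which a phantom will be rasterised without holding
#' voxel data.
#'
#' @param dim_vox integer length-3, voxels per axis.
#' @param spacing_mm numeric length-3, voxel spacing in mm.
#' @param origin_mm numeric length-3, centre of the first voxel.
#' @return A `volume_template` object.
#' @export
volume_template <- function(dim_vox, spacing_mm, origin_mm = c(0, 0, 0)) {
  dim_vox <- as.integer(dim_vox)
  if (length(dim_vox) != 3L || any(dim_vox < 1L)) stop("dim_vox must be 3 positive integers")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0)) stop("spacing_mm must be positive")
  structure(list(dim_vox = dim_vox, spacing_mm = spacing_mm,
                 origin_mm = as.numeric(origin_mm)),
            class = "volume_template")
}

# world-coordinate voxel-centre positions along one axis
axis_coords <- function(n, spacing, origin) origin + (seq_len(n) - 1) * spacing

# z-extent (physical, slice edge to slice edge) of a volume in mm
z_extent_mm <- function(vol) dim(vol$voxels)[3] * vol$spacing_mm[3]

#' Resample a volume along z onto a new slice spacing
#'
#' In-plane grid is untouched; z columns are interpolated onto new slice
#' positions starting at the input's first slice centre. Positions outside the
#' input range are clamped to the nearest slice (constant extrapolation).
#'
#' @param vol a `volume_grid`.
#' @param new_dz_mm target z spacing in mm.
#' @param method one of "nearest", "linear", "cubic" (Catmull-Rom).
#' @param n_out number of output slices; default covers the input z span.
#' @param z_out optional explicit world z positions (uniformly spaced by
#'   `new_dz_mm`); overrides `n_out`.
#' @return A `volume_grid` with z spacing `new_dz_mm`.
#' @export
resample_z <- function(vol, new_dz_mm, method = c("linear", "nearest", "cubic"),
                       n_out = NULL, z_out = NULL) {
  method <- match.arg(method)
  if (!is.finite(new_dz_mm) || new_dz_mm <= 0) stop("new_dz_mm must be > 0")
  d <- dim(vol$voxels)
  z_in <- axis_coords(d[3], vol$spacing_mm[3], vol$origin_mm[3])
  if (is.null(z_out)) {
    if (is.null(n_out)) {
      span <- (d[3] - 1) * vol$spacing_mm[3]
      n_out <- max(1L, floor(span / new_dz_mm + 1e-9) + 1L)
    }
    z_out <- vol$origin_mm[3] + (seq_len(n_out) - 1) * new_dz_mm
  } else n_out <- length(z_out)
  W <- z_interp_matrix(z_in, z_out, method)
  m <- matrix(aperm(vol$voxels, c(3, 1, 2)), nrow = d[3])
  out <- W %*% m
  vox <- aperm(array(out, dim = c(n_out, d[1], d[2])), c(2, 3, 1))
  volume_grid(vox, c(vol$spacing_mm[1:2], new_dz_mm),
              c(vol$origin_mm[1:2], z_out[1]))
}

# Interpolation weight matrix mapping samples at z_in to positions z_out.
# Out-of-range targets clamp to the boundary sample. Cubic uses the
# Catmull-Rom kernel with edge replication, which reproduces affine ramps.
z_interp_matrix <- function(z_in, z_out, method) {
  n_in <- length(z_in); n_out <- length(z_out)
  W <- matrix(0, n_out, n_in)
  if (n_in == 1L) { W[, 1] <- 1; return(W) }
  dz <- z_in[2] - z_in[1]
  for (o in seq_len(n_out)) {
    t <- (z_out[o] - z_in[1]) / dz          # fractional index, 0-based
    if (t <= 0) { W[o, 1] <- 1; next }
    if (t >= n_in - 1) { W[o, n_in] <- 1; next }
    i0 <- floor(t); f <- t - i0; i0 <- as.integer(i0) + 1L  # left sample, 1-based
    if (method == "nearest") {
      W[o, if (f < 0.5) i0 else i0 + 1L] <- 1
    } else if (method == "linear") {
      W[o, i0] <- 1 - f
      W[o, i0 + 1L] <- f
    } else {  # cubic Catmull-Rom on samples i0-1 .. i0+2, edges replicated
      idx <- pmin(pmax(i0 + (-1L:2L), 1L), n_in)
      w <- c(-0.5 * f^3 + f^2 - 0.5 * f,
             1.5 * f^3 - 2.5 * f^2 + 1,
             -1.5 * f^3 + 2 * f^2 + 0.5 * f,
             0.5 * f^3 - 0.5 * f^2)
      for (q in 1:4) W[o, idx[q]] <- W[o, idx[q]] + w[q]
    }
  }
  W
}

# Evaluate a function of the RNG under a local, restored seed.
with_seed <- function(seed, expr) {
  seed <- as.integer(seed)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a child seed from a base seed and a stream index, staying < 2^31.
derive_seed <- function(seed, stream) {
  (as.numeric(seed) * 48271 + 7919 * as.numeric(stream)) %% 2147483629
}
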