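#' Slice condition of a thick-slice volume
#'
#' The conditioning label attached to a simulated thick-slice volume: its
#' slab thickness and reconstruction interval, and the slice spacing of the
#' thin source it was derived from. Training draws both from [3, 8] mm; the
#' validation regime uses 5.0 / 5.0 mm.
#'
#' @param thickness_mm slab thickness in mm.
#' @param interval_mm reconstruction interval (centre-to-centre) in mm, > 0.
#' @param source_thin_mm slice spacing of the thin source, <= thickness_mm.
#' @return A `slice_condition` object.
#' @export
slice_condition <- function(thickness_mm, interval_mm = thickness_mm,
                            source_thin_mm = 1.0) {
  if (!is.finite(thickness_mm) || thickness_mm <= 0) stop("thickness_mm must be > 0")
  if (!is.finite(interval_mm) || interval_mm <= 0) stop("interval_mm must be > 0")
  if (thickness_mm < source_thin_mm - 1e-9)
    stop("thickness_mm must be >= source_thin_mm")
  structure(list(thickness_mm = thickness_mm, interval_mm = interval_mm,
                 source_thin_mm = source_thin_mm),
            class = "slice_condition")
}

#' Simulate thick-slice CT by slab averaging
#'
#' Models a thick slice as the overlap-weighted mean of the thin slices its
#' slab spans (a box filter along z). Thin slice j occupies the half-open
#' z-range `[edge + (j-1) dz, edge + j dz)` where `edge` is the volume's lower
#' z face; slab k spans `[edge + (k-1) i, edge + (k-1) i + t)` for interval i
#' and thickness t, so the first slab sits flush with the volume's lower face
#' and its centre lies half a thickness above it. Partial overlaps are
#' weighted by overlap fraction; the in-plane grid is unchanged and the
#' output z spacing equals the interval. Only slabs fully inside the volume
#' are produced: the output has `floor((extent - t)/i) + 1` slices.
#'
#' @param thin a `volume_grid` with z spacing <= `cond$thickness_mm`.
#' @param cond a [slice_condition()].
#' @param kernel "box" (overlap-fraction slab average, the physically
#'   standard thick-slice model and the default) or "gaussian" (weights
#'   from a Gaussian whose FWHM equals the slab thickness, truncated to the
#'   slab; an alternative reconstruction-profile model).
#' @param phase_mm z offset of the first slab relative to the volume's lower
#'   face (default 0, deterministic alignment so exact oracles hold); draw
#'   it seeded, e.g. `runif(1, 0, cond$interval_mm)`, for random phase.
#' @return A `volume_grid` of thick slices.
#' @export
degrade <- function(thin, cond, kernel = c("box", "gaussian"), phase_mm = 0) {
  stopifnot(inherits(thin, "volume_grid"), inherits(cond, "slice_condition"))
  kernel <- match.arg(kernel)
  d <- dim(thin$voxels)
  dz <- thin$spacing_mm[3]
  t <- cond$thickness_mm; iv <- cond$interval_mm
  if (dz > t + 1e-9) stop("slab thinner than the source slice spacing")
  if (phase_mm < 0) stop("phase_mm must be >= 0")
  extent <- d[3] * dz
  n_out <- floor((extent - phase_mm - t) / iv + 1e-9) + 1
  if (n_out < 1) stop("volume z-extent shorter than one slab: no output slices")
  edge <- thin$origin_mm[3] - dz / 2 + phase_mm
  # weight matrix: W[k, j] = overlap([slab k), [slice j)) / thickness
  W <- matrix(0, n_out, d[3])
  slice_lo <- (thin$origin_mm[3] - dz / 2) + (seq_len(d[3]) - 1) * dz
  for (k in seq_len(n_out)) {
    a <- edge + (k - 1) * iv
    b <- a + t
    ov <- pmax(pmin(b, slice_lo + dz) - pmax(a, slice_lo), 0)
    if (kernel == "gaussian") {
      sigma <- t / (2 * sqrt(2 * log(2)))      # FWHM = thickness
      ov <- ov * exp(-((slice_lo + dz / 2 - (a + t / 2))^2) / (2 * sigma^2))
    }
    W[k, ] <- ov
  }
  W <- W / rowSums(W)
  m <- matrix(aperm(thin$voxels, c(3, 1, 2)), nrow = d[3])
  out <- W %*% m
  vox <- aperm(array(out, dim = c(n_out, d[1], d[2])), c(2, 3, 1))
  volume_grid(vox, c(thin$spacing_mm[1:2], iv),
              c(thin$origin_mm[1:2], edge + t / 2))
}

#' Draw random slice conditions
#'
#' Thickness and interval are drawn independently and uniformly on
#' `[lo, hi]` mm; thickness is rounded to `round_step` mm steps (set
#' `round_step = 0` to disable). Uses the current RNG state: seed with
#' `set.seed()` for reproducible draws.
#'
#' @param n number of conditions to draw.
#' @param lo,hi range in mm, `lo <= hi`.
#' @param round_step thickness rounding step in mm.
#' @param source_thin_mm thin source spacing recorded in each condition.
#' @return A list of [slice_condition()] objects (a single object if n == 1).
#' @export
sample_condition <- function(n = 1, lo = 3.0, hi = 8.0, round_step = 0.5,
                             source_thin_mm = 1.0) {
  if (lo > hi) stop("lo must be <= hi")
  if (lo <= 0) stop("lo must be positive")
  out <- vector("list", n)
  for (i in seq_len(n)) {
    t <- runif(1, lo, hi)
    if (round_step > 0) t <- min(hi, max(lo, round(t / round_step) * round_step))
    iv <- runif(1, lo, hi)
    out[[i]] <- slice_condition(t, iv, source_thin_mm)
  }
  if (n == 1) out[[1]] else out
}

#' Slice-count ratio between thin and thick reconstructions
#'
#' For contiguous non-overlapping slices covering a fixed z extent, the data
#' volume scales inversely with the interval: 0.5 mm vs 5 mm sections give a
#' 10-fold increase, 1.0 mm vs 5 mm a 5-fold increase.
#'
#' @param thin_interval_mm,thick_interval_mm slice intervals in mm, > 0.
#' @param z_extent_mm covered z extent in mm, > 0.
#' @return The ratio of thin to thick slice counts.
#' @export
slice_count_ratio <- function(thin_interval_mm, thick_interval_mm, z_extent_mm) {
  vals <- c(thin_interval_mm, thick_interval_mm, z_extent_mm)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all arguments must be positive")
  (z_extent_mm / thin_interval_mm) / (z_extent_mm / thick_interval_mm)
}
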