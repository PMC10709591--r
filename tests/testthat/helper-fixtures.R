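# shared in-code fixtures; everything is generated, nothing is stored

# small isotropic template centred on the origin
centered_template <- function(n, spacing) {
  volume_template(rep(n, 3), rep(spacing, 3), rep(-(n - 1) * spacing / 2, 3))
}

# noise-free phantom volume for a given nodule geometry
quiet_phantom <- function(type, total, solid, n = 49, spacing = 0.5, seed = 1,
                          center = c(0, 0, 0)) {
  spec <- nodule_spec(type, total, solid, center_mm = center, noise_sd_hu = 0)
  generate_phantom(spec, centered_template(n, spacing), seed = seed)
}

# a z-ramp volume: HU linear in slice index
ramp_volume <- function(dims = c(6, 6, 30), dz = 1, slope = 10, intercept = -800) {
  vox <- array(0, dims)
  for (k in seq_len(dims[3])) vox[, , k] <- intercept + slope * (k - 1)
  volume_grid(vox, c(1, 1, dz), c(0, 0, 0))
}

# tiny thin-volume training world shared by the model tests (kept small:
# the full-size regime is exercised by the acceptance suite)
toy_training_volumes <- function(n_vols = 4, seed = 11, n = 25) {
  with_seed_local(seed, lapply(seq_len(n_vols), function(i) {
    d <- runif(1, 8, 12)
    spec <- nodule_spec("part_solid", d + 6, d,
                        center_mm = c(0, 0, runif(1, -2.5, 2.5)),
                        noise_sd_hu = 20)
    generate_phantom(spec, centered_template(n, 1), seed = 1000 + i)$volume
  }))
}

with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# independently coded brute-force T-stage rule table (kept deliberately
# separate in style and logic from assign_t): walks a lookup data.frame
brute_force_t <- function(total, solid) {
  rules <- data.frame(
    name = c("Tis", "T1mi", "T1a", "T1b", "T1c", "T2a"),
    stringsAsFactors = FALSE)
  pick <- function(tt, ss) {
    if (ss == 0) {
      if (tt <= 30) return("Tis") else return("T1a")
    }
    if (ss <= 5) {
      if (tt <= 30) return("T1mi")
      # solid component present but lesion too large for T1mi: size rules
      return("T1a")
    }
    if (ss <= 10) return("T1a")
    if (ss <= 20) return("T1b")
    if (ss <= 30) return("T1c")
    "T2a"
  }
  mapply(pick, total, solid)
}
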