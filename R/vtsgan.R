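#' Model configuration for the slice-interpolation network
#'
#' The generator is a residual 3D convolutional network: the thick-slice
#' input is first resampled to the target thin grid by linear interpolation,
#' two constant condition channels (thickness and interval, scaled by
#' `cond_scale`) are appended, and the network predicts a correction that is
#' added to the linear upsampling. A network with zero weights in its last
#' layer is therefore exactly the linear baseline. The discriminator is a 3D
#' patch critic scoring every voxel of (candidate thin volume + condition
#' channels); training uses the least-squares adversarial loss plus an L1
#' reconstruction term with weights `lambda_adv` and `lambda_rec`.
#'
#' @param patch_vox integer length-3, training patch shape in voxels.
#' @param base_channels hidden channel width of both networks.
#' @param depth number of hidden conv layers (ReLU) in each network.
#' @param kernel_vox integer length-3 conv kernel extent per axis (odd).
#'   The default 3x3x3 is the generic 3D choice; a z-oriented kernel such as
#'   c(1, 1, 9) specialises the network to through-plane interpolation with
#'   a long z receptive field at a fraction of the cost.
#' @param lambda_rec,lambda_adv non-negative loss weights (defaults 100 / 1).
#' @param hu_clip HU clipping range for normalisation (maps to [-1, 1]).
#' @param cond_scale multiplier applied to the mm condition values before
#'   broadcasting them as constant channels.
#' @return A `vts_model_config` object.
#' @export
vts_model_config <- function(patch_vox = c(16, 16, 16), base_channels = 8,
                             depth = 2, kernel_vox = c(3, 3, 3),
                             lambda_rec = 100, lambda_adv = 1,
                             hu_clip = c(-1024, 600), cond_scale = 0.1) {
  if (lambda_rec < 0 || lambda_adv < 0) stop("loss weights must be non-negative")
  if (depth < 1 || base_channels < 1) stop("depth and base_channels must be >= 1")
  kernel_vox <- as.integer(kernel_vox)
  if (length(kernel_vox) != 3L || any(kernel_vox < 1L) || any(kernel_vox %% 2L == 0L))
    stop("kernel_vox must be three odd positive integers")
  if (hu_clip[1] >= hu_clip[2]) stop("hu_clip must be increasing")
  structure(list(patch_vox = as.integer(patch_vox), base_channels = base_channels,
                 depth = depth, kernel_vox = kernel_vox,
                 lambda_rec = lambda_rec, lambda_adv = lambda_adv,
                 hu_clip = as.numeric(hu_clip), cond_scale = cond_scale),
            class = "vts_model_config")
}

#' Training configuration
#'
#' @param epochs passes over the pair set.
#' @param batch_size pairs per optimisation step.
#' @param lr,beta1,beta2 Adam settings (conditional-GAN conventions).
#' @param lr_decay multiplicative learning-rate decay per epoch (1 = none).
#' @return A list of validated settings.
#' @export
vts_train_config <- function(epochs = 20, batch_size = 4, lr = 2e-3,
                             beta1 = 0.5, beta2 = 0.999, lr_decay = 1) {
  if (epochs < 1 || batch_size < 1 || lr <= 0) stop("invalid training config")
  if (lr_decay <= 0 || lr_decay > 1) stop("lr_decay must be in (0, 1]")
  list(epochs = epochs, batch_size = batch_size, lr = lr,
       beta1 = beta1, beta2 = beta2, lr_decay = lr_decay)
}

hu_normalize <- function(v, clip) {
  v <- pmin(pmax(v, clip[1]), clip[2])
  (v - clip[1]) / (clip[2] - clip[1]) * 2 - 1
}

# ---- minimal conv-net machinery (im2col over a 3x3x3 neighbourhood) -------

# neighbour index table with replicate padding: row = voxel, col = offset.
# kernel gives the (x, y, z) kernel extents (odd integers).
conv_index <- function(dims, kernel = c(3L, 3L, 3L)) {
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  r <- (as.integer(kernel) - 1L) %/% 2L
  ix <- rep.int(seq_len(nx), ny * nz)
  jy <- rep.int(rep(seq_len(ny), each = nx), nz)
  kz <- rep(seq_len(nz), each = nx * ny)
  n_off <- prod(2L * r + 1L)
  idx <- matrix(0L, nx * ny * nz, n_off)
  o <- 0L
  for (c in -r[3]:r[3]) for (b in -r[2]:r[2]) for (a in -r[1]:r[1]) {
    o <- o + 1L
    ii <- pmin.int(pmax.int(ix + a, 1L), nx)
    jj <- pmin.int(pmax.int(jy + b, 1L), ny)
    kk <- pmin.int(pmax.int(kz + c, 1L), nz)
    idx[, o] <- ii + (jj - 1L) * nx + (kk - 1L) * nx * ny
  }
  idx
}

im2col <- function(A, idx) {
  cin <- ncol(A)
  n_off <- ncol(idx)
  X <- matrix(0, nrow(A), n_off * cin)
  for (o in seq_len(n_off))
    X[, ((o - 1L) * cin + 1L):(o * cin)] <- A[idx[, o], , drop = FALSE]
  X
}

# network = list of layers: list(W [27*cin, cout], b [cout], act)
init_net <- function(cin, hidden, depth, cout, n_off = 27L, zero_last = FALSE) {
  widths <- c(cin, rep(hidden, depth), cout)
  layers <- vector("list", depth + 1L)
  for (l in seq_len(depth + 1L)) {
    fan_in <- n_off * widths[l]
    sd <- sqrt(2 / fan_in)
    W <- matrix(rnorm(fan_in * widths[l + 1L], 0, sd), fan_in, widths[l + 1L])
    if (zero_last && l == depth + 1L) W[] <- 0
    layers[[l]] <- list(W = W, b = numeric(widths[l + 1L]),
                        act = if (l <= depth) "relu" else "linear")
  }
  layers
}

net_forward <- function(net, A, idx, keep_cache = FALSE) {
  caches <- if (keep_cache) vector("list", length(net)) else NULL
  for (l in seq_along(net)) {
    X <- im2col(A, idx)
    Z <- X %*% net[[l]]$W
    Z <- sweep(Z, 2L, net[[l]]$b, "+")
    A_out <- if (net[[l]]$act == "relu") pmax(Z, 0) else Z
    if (keep_cache) caches[[l]] <- list(X = X, Z = Z)
    A <- A_out
  }
  list(out = A, caches = caches)
}

net_backward <- function(net, caches, idx, dOut, n_vox) {
  grads <- vector("list", length(net))
  dA <- dOut
  for (l in rev(seq_along(net))) {
    if (net[[l]]$act == "relu") dA <- dA * (caches[[l]]$Z > 0)
    grads[[l]] <- list(dW = crossprod(caches[[l]]$X, dA), db = colSums(dA))
    if (l > 1L) {
      dX <- dA %*% t(net[[l]]$W)
      cin <- length(net[[l - 1L]]$b)  # channels of the previous activation
      dPrev <- matrix(0, n_vox, cin)
      for (o in seq_len(ncol(idx))) {
        blk <- dX[, ((o - 1L) * cin + 1L):(o * cin), drop = FALSE]
        agg <- rowsum(blk, group = idx[, o])
        rows <- as.integer(rownames(agg))
        dPrev[rows, ] <- dPrev[rows, , drop = FALSE] + agg
      }
      dA <- dPrev
    }
  }
  grads
}

adam_init <- function(net) {
  lapply(net, function(l) list(mW = l$W * 0, vW = l$W * 0,
                               mb = l$b * 0, vb = l$b * 0))
}

adam_step <- function(net, grads, state, t, cfg) {
  b1 <- cfg$beta1; b2 <- cfg$beta2; lr <- cfg$lr; eps <- 1e-8
  corr1 <- 1 - b1^t; corr2 <- 1 - b2^t
  for (l in seq_along(net)) {
    g <- grads[[l]]
    state[[l]]$mW <- b1 * state[[l]]$mW + (1 - b1) * g$dW
    state[[l]]$vW <- b2 * state[[l]]$vW + (1 - b2) * g$dW^2
    state[[l]]$mb <- b1 * state[[l]]$mb + (1 - b1) * g$db
    state[[l]]$vb <- b2 * state[[l]]$vb + (1 - b2) * g$db^2
    net[[l]]$W <- net[[l]]$W - lr * (state[[l]]$mW / corr1) /
      (sqrt(state[[l]]$vW / corr2) + eps)
    net[[l]]$b <- net[[l]]$b - lr * (state[[l]]$mb / corr1) /
      (sqrt(state[[l]]$vb / corr2) + eps)
  }
  list(net = net, state = state)
}

sum_grads <- function(a, b) {
  if (is.null(a)) return(b)
  for (l in seq_along(a)) {
    a[[l]]$dW <- a[[l]]$dW + b[[l]]$dW
    a[[l]]$db <- a[[l]]$db + b[[l]]$db
  }
  a
}

scale_grads <- function(g, s) {
  for (l in seq_along(g)) { g[[l]]$dW <- g[[l]]$dW * s; g[[l]]$db <- g[[l]]$db * s }
  g
}

# ---- training pairs --------------------------------------------------------

#' Extract random labelled training pairs from thin volumes
#'
#' Random patches are cut from each thin volume; each patch is degraded with
#' an independently sampled slice condition, and the (thick patch, thin
#' patch, condition) triple is retained. Conditions are drawn uniformly on
#' `[lo, hi]` mm, capped so a slab always fits inside the patch.
#'
#' @param thin_volumes list of `volume_grid` thin volumes.
#' @param per_volume patches per volume (>= 0).
#' @param seed integer seed.
#' @param patch_vox patch shape in voxels.
#' @param lo,hi condition range in mm.
#' @return List of `list(thick, thin, cond)` triples.
#' @export
make_training_pairs <- function(thin_volumes, per_volume, seed,
                                patch_vox = c(16, 16, 16), lo = 3, hi = 8) {
  per_volume <- as.integer(per_volume)
  if (per_volume < 0L) stop("per_volume must be >= 0")
  if (per_volume == 0L || length(thin_volumes) == 0L) return(list())
  patch_vox <- as.integer(patch_vox)
  with_seed(seed, {
    pairs <- list()
    for (v in thin_volumes) {
      d <- dim(v$voxels)
      if (any(patch_vox > d)) stop("patch larger than volume")
      dz <- v$spacing_mm[3]
      hi_eff <- min(hi, patch_vox[3] * dz)
      if (hi_eff < lo) stop("patch z-extent shorter than the minimum slab")
      for (p in seq_len(per_volume)) {
        org <- vapply(1:3, function(ax) sample.int(d[ax] - patch_vox[ax] + 1L, 1L),
                      integer(1))
        sub <- v$voxels[org[1]:(org[1] + patch_vox[1] - 1L),
                        org[2]:(org[2] + patch_vox[2] - 1L),
                        org[3]:(org[3] + patch_vox[3] - 1L), drop = FALSE]
        thin_patch <- volume_grid(sub, v$spacing_mm,
                                  v$origin_mm + (org - 1) * v$spacing_mm)
        cond <- sample_condition(1, lo, hi_eff, source_thin_mm = dz)
        pairs[[length(pairs) + 1L]] <-
          list(thick = degrade(thin_patch, cond), thin = thin_patch, cond = cond)
      }
    }
    pairs
  })
}

# normalized (input-with-conditions, target) matrices for one pair
prepare_pair <- function(pair, config) {
  thin <- pair$thin
  d <- dim(thin$voxels)
  z_thin <- axis_coords(d[3], thin$spacing_mm[3], thin$origin_mm[3])
  up <- resample_z(pair$thick, thin$spacing_mm[3], "linear", z_out = z_thin)
  x_lin <- hu_normalize(as.vector(up$voxels), config$hu_clip)
  n <- length(x_lin)
  A <- cbind(x_lin,
             rep(pair$cond$thickness_mm * config$cond_scale, n),
             rep(pair$cond$interval_mm * config$cond_scale, n))
  y <- hu_normalize(as.vector(thin$voxels), config$hu_clip)
  list(A = A, y = y, dims = d)
}

# ---- training --------------------------------------------------------------

#' Train the conditional adversarial slice-interpolation model
#'
#' Alternates discriminator and generator updates. The generator minimises
#' `lambda_rec * L1(virtual, thin) + lambda_adv * (D(virtual) - 1)^2`; the
#' discriminator minimises the least-squares real/fake objective. Both
#' networks see the condition channels. With `lambda_adv = 0` the model is a
#' pure regression and the discriminator is skipped. Fully deterministic
#' under a fixed seed (single-threaded R arithmetic).
#'
#' @param pairs training pairs from [make_training_pairs()].
#' @param model_config a [vts_model_config()].
#' @param train_config a [vts_train_config()].
#' @param seed integer seed for weight init and shuffling.
#' @return A `vts_model` with weights, config and per-epoch loss history
#'   (columns epoch, rec_l1, g_adv, d_loss; `rec_l1` is mean absolute error
#'   in normalised units).
#' @export
vts_train <- function(pairs, model_config = vts_model_config(),
                      train_config = vts_train_config(), seed = 1) {
  if (length(pairs) == 0L) stop("no training pairs")
  prep <- lapply(pairs, prepare_pair, config = model_config)
  dims0 <- prep[[1]]$dims
  for (p in prep) if (any(p$dims != dims0)) stop("inconsistent patch shapes")
  idx <- conv_index(dims0, model_config$kernel_vox)
  n_off <- prod(model_config$kernel_vox)
  n_vox <- prod(dims0)
  C <- model_config$base_channels
  adv <- model_config$lambda_adv > 0

  with_seed(seed, {
    g_net <- init_net(3L, C, model_config$depth, 1L, n_off, zero_last = TRUE)
    d_net <- if (adv) init_net(3L, C, model_config$depth, 1L, n_off) else NULL
    g_state <- adam_init(g_net)
    d_state <- if (adv) adam_init(d_net) else NULL
    g_t <- 0L; d_t <- 0L
    hist <- data.frame(epoch = integer(), rec_l1 = numeric(),
                       g_adv = numeric(), d_loss = numeric())
    for (ep in seq_len(train_config$epochs)) {
      ep_cfg <- train_config
      ep_cfg$lr <- train_config$lr * train_config$lr_decay^(ep - 1)
      ord <- sample.int(length(prep))
      ep_rec <- 0; ep_adv <- 0; ep_d <- 0; n_seen <- 0
      for (start in seq(1L, length(ord), by = train_config$batch_size)) {
        batch <- ord[start:min(start + train_config$batch_size - 1L, length(ord))]
        gG <- NULL; gD <- NULL
        b_rec <- 0; b_adv <- 0; b_d <- 0
        for (s in batch) {
          A <- prep[[s]]$A; y <- prep[[s]]$y
          fw <- net_forward(g_net, A, idx, keep_cache = TRUE)
          fake <- A[, 1] + fw$out[, 1]
          resid <- fake - y
          b_rec <- b_rec + mean(abs(resid))
          d_fake_in <- cbind(fake, A[, 2], A[, 3])
          if (adv) {
            # discriminator update on this sample
            real_in <- cbind(y, A[, 2], A[, 3])
            fr <- net_forward(d_net, real_in, idx, keep_cache = TRUE)
            ff <- net_forward(d_net, d_fake_in, idx, keep_cache = TRUE)
            b_d <- b_d + 0.5 * (mean((fr$out - 1)^2) + mean(ff$out^2))
            gDr <- net_backward(d_net, fr$caches, idx, (fr$out - 1) / n_vox, n_vox)
            gDf <- net_backward(d_net, ff$caches, idx, ff$out / n_vox, n_vox)
            gD <- sum_grads(gD, sum_grads(gDr, gDf))
            # adversarial gradient w.r.t. fake (D weights not yet updated,
            # so the fake forward pass can be reused)
            b_adv <- b_adv + mean((ff$out - 1)^2)
            dAdv_in <- d_adv_input_grad(d_net, ff$caches, idx,
                                        2 * (ff$out - 1) / n_vox, n_vox)
            d_fake <- model_config$lambda_adv * dAdv_in[, 1]
          } else d_fake <- 0
          d_fake <- d_fake + model_config$lambda_rec * sign(resid) / n_vox
          gG <- sum_grads(gG, net_backward(g_net, fw$caches, idx,
                                           matrix(d_fake, ncol = 1L), n_vox))
        }
        nb <- length(batch)
        if (adv) {
          d_t <- d_t + 1L
          upd <- adam_step(d_net, scale_grads(gD, 1 / nb), d_state, d_t, ep_cfg)
          d_net <- upd$net; d_state <- upd$state
        }
        g_t <- g_t + 1L
        upd <- adam_step(g_net, scale_grads(gG, 1 / nb), g_state, g_t, ep_cfg)
        g_net <- upd$net; g_state <- upd$state
        ep_rec <- ep_rec + b_rec; ep_adv <- ep_adv + b_adv; ep_d <- ep_d + b_d
        n_seen <- n_seen + nb
      }
      row <- data.frame(epoch = ep, rec_l1 = ep_rec / n_seen,
                        g_adv = ep_adv / n_seen, d_loss = ep_d / n_seen)
      if (any(!is.finite(unlist(row))))
        stop(sprintf("non-finite loss at epoch %d: rec=%g adv=%g d=%g",
                     ep, row$rec_l1, row$g_adv, row$d_loss))
      hist <- rbind(hist, row)
    }
    structure(list(generator = g_net, discriminator = d_net,
                   config = model_config, history = hist, seed = seed),
              class = "vts_model")
  })
}

# gradient of the adversarial loss w.r.t. the discriminator INPUT
d_adv_input_grad <- function(net, caches, idx, dOut, n_vox) {
  dA <- dOut
  for (l in rev(seq_along(net))) {
    if (net[[l]]$act == "relu") dA <- dA * (caches[[l]]$Z > 0)
    dX <- dA %*% t(net[[l]]$W)
    cin <- nrow(net[[l]]$W) / ncol(idx)
    dPrev <- matrix(0, n_vox, cin)
    for (o in seq_len(ncol(idx))) {
      blk <- dX[, ((o - 1L) * cin + 1L):(o * cin), drop = FALSE]
      agg <- rowsum(blk, group = idx[, o])
      rows <- as.integer(rownames(agg))
      dPrev[rows, ] <- dPrev[rows, , drop = FALSE] + agg
    }
    dA <- dPrev
  }
  dA
}

#' @export
print.vts_model <- function(x, ...) {
  h <- x$history
  cat(sprintf("<vts_model> %d hidden ch, depth %d, %d epochs trained\n",
              x$config$base_channels, x$config$depth, nrow(h)))
  if (nrow(h) > 0)
    cat(sprintf("  final losses: rec_l1=%.4g g_adv=%.4g d=%.4g\n",
                h$rec_l1[nrow(h)], h$g_adv[nrow(h)], h$d_loss[nrow(h)]))
  invisible(x)
}

# ---- inference -------------------------------------------------------------

#' Reconstruct a virtual thin-section volume
#'
#' The thick volume is linearly resampled in z onto the target thin grid,
#' condition channels are appended, and the generator's residual is added.
#' Large volumes are processed in z chunks with a halo equal to the network
#' receptive-field radius, so chunked and whole-volume outputs are identical;
#' inference has no randomness and repeated calls are bitwise-identical.
#'
#' @param model a trained `vts_model` (or untrained: zero residual = linear).
#' @param thick a `volume_grid` of thick slices.
#' @param cond the [slice_condition()] of `thick`; its interval must match
#'   the volume's z spacing.
#' @param target_thin_mm target slice spacing, in [0.5, 1.0] mm.
#' @param chunk_vox max voxels per chunk before z-chunking kicks in.
#' @return A `volume_grid` with z spacing `target_thin_mm`, HU clipped to the
#'   model's `hu_clip` range.
#' @export
vts_infer <- function(model, thick, cond, target_thin_mm,
                      chunk_vox = 2e6) {
  stopifnot(inherits(model, "vts_model"), inherits(thick, "volume_grid"),
            inherits(cond, "slice_condition"))
  if (abs(cond$interval_mm - thick$spacing_mm[3]) > 1e-6)
    stop("condition interval does not match the volume's z spacing")
  if (target_thin_mm < 0.5 - 1e-9 || target_thin_mm > 1.0 + 1e-9)
    stop("target_thin_mm must be within [0.5, 1.0] mm")
  cfg <- model$config
  lin <- resample_z(thick, target_thin_mm, "linear")
  d <- dim(lin$voxels)
  halo <- (cfg$depth + 1L) * (cfg$kernel_vox[3] %/% 2L)  # z context per layer
  n_chunk_z <- max(2L * halo + 1L, floor(chunk_vox / (d[1] * d[2])))
  x_norm <- hu_normalize(as.vector(lin$voxels), cfg$hu_clip)
  scale <- (cfg$hu_clip[2] - cfg$hu_clip[1]) / 2
  resid <- numeric(prod(d))
  nxy <- d[1] * d[2]
  z0 <- 1L
  while (z0 <= d[3]) {
    z1 <- min(d[3], z0 + n_chunk_z - 1L)
    a <- max(1L, z0 - halo); b <- min(d[3], z1 + halo)
    rng <- ((a - 1L) * nxy + 1L):(b * nxy)       # z is the slowest axis
    sub_dims <- c(d[1], d[2], b - a + 1L)
    A <- cbind(x_norm[rng],
               rep(cond$thickness_mm * cfg$cond_scale, length(rng)),
               rep(cond$interval_mm * cfg$cond_scale, length(rng)))
    out <- net_forward(model$generator, A,
                       conv_index(sub_dims, cfg$kernel_vox))$out[, 1]
    keep <- ((z0 - a) * nxy + 1L):((z1 - a + 1L) * nxy)
    resid[((z0 - 1L) * nxy + 1L):(z1 * nxy)] <- out[keep]
    z0 <- z1 + 1L
  }
  vox <- as.vector(lin$voxels) + resid * scale
  vox <- pmin(pmax(vox, cfg$hu_clip[1]), cfg$hu_clip[2])
  volume_grid(array(vox, dim = d), lin$spacing_mm, lin$origin_mm)
}

#' Classical z-interpolation baselines
#'
#' Pure z-axis resampling of the thick volume onto the target thin grid; no
#' learning. The linear method reproduces affine z-profiles exactly.
#'
#' @param thick a `volume_grid`.
#' @param cond the matching [slice_condition()] (checked against z spacing).
#' @param target_thin_mm target slice spacing in mm.
#' @param method "nearest", "linear" or "cubic".
#' @return A `volume_grid`.
#' @export
baseline_interp <- function(thick, cond, target_thin_mm,
                            method = c("linear", "nearest", "cubic")) {
  method <- match.arg(method)
  if (abs(cond$interval_mm - thick$spacing_mm[3]) > 1e-6)
    stop("condition interval does not match the volume's z spacing")
  resample_z(thick, target_thin_mm, method)
}

#' Save / load a model checkpoint
#'
#' Single-file archive holding the weights, the config (also embedded as a
#' JSON string for external tools) and the loss history. A load-save
#' round trip reproduces inference bitwise.
#'
#' @param model a `vts_model`.
#' @param path checkpoint path.
#' @return `path` (save) or the restored `vts_model` (load).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "vts_model"))
  payload <- list(model = unclass(model),
                  config_json = jsonlite::toJSON(unclass(model$config),
                                                 auto_unbox = TRUE))
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  payload <- readRDS(path)
  m <- payload$model
  class(m$config) <- "vts_model_config"
  structure(m, class = "vts_model")
}

#' Export the training loss history as a delimited table
#'
#' @param model a trained `vts_model`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_loss_history <- function(model, path) {
  utils::write.csv(model$history, path, row.names = FALSE)
  invisible(path)
}
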