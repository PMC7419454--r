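## Mask-conditioned GAN with a speckle bank in the generator.
##
## Generator: 128-dim Gaussian seed -> linear -> 4x4 grid -> [nearest x2
## upsample + SPADE residual block] until the image size is reached (the
## penultimate block leaves 8 feature maps at full resolution) -> speckle
## bank (8 -> 32 maps, 4 learnable speckle sizes, channel attention) ->
## final SPADE residual block -> 3x3 conv -> sigmoid.  Discriminator:
## image/mask concatenation -> stride-2 spectral-normalized residual blocks
## -> global sum pooling -> linear -> sigmoid.

#' GAN configuration
#'
#' @param image_size output image side (pixels); must be a power of two
#'   times 4
#' @param z_dim latent dimension (128)
#' @param g_channels per-block generator channels from the 4x4 grid up;
#'   the last entry must be 8 (the speckle bank input width); `NULL` picks
#'   a doubling schedule capped at 256
#' @param g_final_channels channels of the block after the speckle bank
#' @param d_channels per-block discriminator channels; `NULL` picks a
#'   doubling schedule capped at 256
#' @param spade_hidden output channels of the first convolution in every
#'   SPADE layer (64 in the reference architecture; smaller for smoke runs)
#' @param n_speckle_sizes number of window sizes in the speckle bank
#' @param d_init initial window edge lengths (pixels), in (0, image_size]
#' @param softness soft-window steepness (> 0 keeps d learnable)
#' @param use_speckle `FALSE` replaces the speckle bank with an identity
#'   (the no-speckle baseline)
#' @param polar_in_network apply the bank's polar warping inside the
#'   generator
#' @param lr_init,lr_final,lr_milestones step-decay learning-rate schedule:
#'   `lr_init` until the first milestone epoch, the geometric midpoint until
#'   the second, then `lr_final`
#' @param d_lr_scale multiplier on the discriminator learning rate; values
#'   below 1 slow the discriminator down (two-timescale balancing)
#' @param d_warmup_steps discriminator-only warmup updates (at the full
#'   learning rate) before alternating training begins, so the adversarial
#'   game starts from a discriminator that already rejects untrained fakes
#' @param beta1,beta2,adam_eps Adam parameters
#' @param batch_size,epochs training extent
#' @param fid_every validate by FID every this many epochs
#' @param n_fid_images images generated per FID evaluation (capped at the
#'   dataset size)
#' @param seed master seed for weights, batches, phases and augmentation
#' @return validated config object of class `gan_config`
#' @export
gan_config <- function(image_size = 256L, z_dim = 128L,
                       g_channels = NULL, g_final_channels = 16L,
                       d_channels = NULL, spade_hidden = 64L,
                       n_speckle_sizes = 4L,
                       d_init = seq(28, 48, length.out = n_speckle_sizes),
                       softness = 0.5,
                       use_speckle = TRUE, polar_in_network = FALSE,
                       lr_init = 3e-4, lr_final = 1e-4,
                       lr_milestones = c(200L, 400L), d_lr_scale = 1,
                       d_warmup_steps = 0L,
                       beta1 = 0.5, beta2 = 0.999, adam_eps = 1e-8,
                       batch_size = 10L, epochs = 2L,
                       fid_every = 1L, n_fid_images = 16L, seed = 0L) {
  n_up <- log2(image_size / 4)
  if (n_up != round(n_up) || n_up < 1)
    stop("image_size must be 4 * 2^k for integer k >= 1")
  n_up <- as.integer(n_up)
  if (is.null(g_channels)) g_channels <- pmin(8L * 2L^((n_up - 1):0), 256L)
  if (length(g_channels) != n_up)
    stop("g_channels must have one entry per upsampling block (", n_up, ")")
  if (g_channels[length(g_channels)] != 8L)
    stop("the penultimate generator block must output 8 channels")
  if (is.null(d_channels)) d_channels <- pmin(16L * 2L^(0:(n_up - 1)), 256L)
  if (any(d_init <= 0) || any(d_init > image_size))
    stop("d_init must lie in (0, image_size]")
  if (lr_init <= 0 || lr_final <= 0) stop("learning rates must be positive")
  if (is.unsorted(lr_milestones, strictly = TRUE))
    stop("lr_milestones must be increasing")
  structure(list(image_size = as.integer(image_size), z_dim = as.integer(z_dim),
                 g_channels = as.integer(g_channels),
                 g_final_channels = as.integer(g_final_channels),
                 d_channels = as.integer(d_channels),
                 spade_hidden = as.integer(spade_hidden),
                 n_speckle_sizes = as.integer(n_speckle_sizes),
                 d_init = as.numeric(d_init), softness = softness,
                 use_speckle = isTRUE(use_speckle),
                 polar_in_network = isTRUE(polar_in_network),
                 lr_init = lr_init, lr_final = lr_final,
                 lr_milestones = as.integer(lr_milestones),
                 d_lr_scale = d_lr_scale,
                 d_warmup_steps = as.integer(d_warmup_steps),
                 beta1 = beta1, beta2 = beta2, adam_eps = adam_eps,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 fid_every = as.integer(fid_every),
                 n_fid_images = as.integer(n_fid_images),
                 seed = as.integer(seed)),
            class = "gan_config")
}

#' Scaled-down GAN configuration for CPU smoke runs
#'
#' 64 px images, slimmed channel schedule and SPADE width, batch size 4.
#' With 8 training pairs this gives 2 optimizer steps per epoch, so
#' `epochs = 100` is a 200-step run.  Training dynamics, not image
#' fidelity, are what a run at this scale can demonstrate.
#'
#' @param seed master seed
#' @param epochs training epochs
#' @param ... further overrides passed to [gan_config()]
#' @return a [gan_config()]
#' @export
smoke_gan_config <- function(seed = 0L, epochs = 100L, ...) {
  args <- list(image_size = 64L, g_channels = c(32L, 16L, 8L, 8L),
               g_final_channels = 8L, d_channels = c(8L, 16L, 32L, 32L),
               spade_hidden = 8L, batch_size = 4L, epochs = epochs,
               lr_init = 5e-4, d_lr_scale = 0.05, d_warmup_steps = 10L,
               fid_every = 25L, n_fid_images = 8L, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(gan_config, args)
}

lr_at_epoch <- function(cfg, epoch) {
  mid <- sqrt(cfg$lr_init * cfg$lr_final)
  if (epoch < cfg$lr_milestones[1]) cfg$lr_init
  else if (epoch < cfg$lr_milestones[2]) mid
  else cfg$lr_final
}

## ---- residual blocks -------------------------------------------------------

gen_resblock <- function(cin, cout, spade_hidden) {
  m <- new_module("gen_resblock")
  m$conv1 <- nn_conv(cin, cout, 3L, spectral = TRUE)
  m$spade1 <- spade_params(cout, hidden = spade_hidden)
  m$relu <- nn_relu()
  m$conv2 <- nn_conv(cout, cout, 3L, spectral = TRUE)
  m$spade2 <- spade_params(cout, hidden = spade_hidden)
  m$skip <- if (cin != cout) nn_conv(cin, cout, 1L, pad = 0L, spectral = TRUE)
  m$children <- Filter(Negate(is.null),
                       list(m$conv1, m$spade1, m$conv2, m$spade2, m$skip))
  m$fwd <- function(x, mask_oh) {
    h <- m$conv1$fwd(x)
    h <- m$spade1$fwd(h, mask_oh)
    h <- m$relu$fwd(h)
    h <- m$conv2$fwd(h)
    h <- m$spade2$fwd(h, mask_oh)
    h + if (is.null(m$skip)) x else m$skip$fwd(x)
  }
  m$bwd <- function(gy) {
    gh <- m$spade2$bwd(gy)
    gh <- m$conv2$bwd(gh)
    gh <- m$relu$bwd(gh)
    gh <- m$spade1$bwd(gh)
    gx <- m$conv1$bwd(gh)
    gx + if (is.null(m$skip)) gy else m$skip$bwd(gy)
  }
  m
}

disc_resblock <- function(cin, cout, stride = 2L) {
  m <- new_module("disc_resblock")
  m$conv1 <- nn_conv(cin, cout, 3L, stride = stride, spectral = TRUE)
  m$bn1 <- nn_batchnorm(cout)
  m$relu1 <- nn_relu()
  m$conv2 <- nn_conv(cout, cout, 3L, spectral = TRUE)
  m$bn2 <- nn_batchnorm(cout)
  m$skip <- nn_conv(cin, cout, 1L, stride = stride, pad = 0L, spectral = TRUE)
  m$relu2 <- nn_relu()
  m$children <- list(m$conv1, m$bn1, m$conv2, m$bn2, m$skip)
  m$fwd <- function(x) {
    h <- m$bn1$fwd(m$conv1$fwd(x))
    h <- m$relu1$fwd(h)
    h <- m$bn2$fwd(m$conv2$fwd(h))
    m$relu2$fwd(h + m$skip$fwd(x))
  }
  m$bwd <- function(gy) {
    g <- m$relu2$bwd(gy)
    gh <- m$bn2$bwd(g)
    gh <- m$conv2$bwd(gh)
    gh <- m$relu1$bwd(gh)
    gh <- m$bn1$bwd(gh)
    m$conv1$bwd(gh) + m$skip$bwd(g)
  }
  m
}

## ---- generator -------------------------------------------------------------

#' Build the generator network
#'
#' @param cfg a [gan_config()]
#' @return generator module with `fwd(z, mask_pyramid, speckle_seed)` and
#'   `bwd(gy)` closures
#' @export
build_generator <- function(cfg) {
  m <- new_module("generator")
  m$cfg <- cfg
  c0 <- cfg$g_channels[1]
  m$lin <- nn_linear(cfg$z_dim, 4L * 4L * c0, spectral = TRUE)
  chans <- c(c0, cfg$g_channels)
  m$blocks <- lapply(seq_along(cfg$g_channels), function(i)
    gen_resblock(chans[i], chans[i + 1], cfg$spade_hidden))
  if (cfg$use_speckle) {
    m$bank <- speckle_bank(n_in = 8L, d_init = cfg$d_init,
                           softness = cfg$softness,
                           polar = cfg$polar_in_network)
    bank_out <- m$bank$n_out
  } else {
    m$bank <- NULL
    bank_out <- 8L
  }
  m$final <- gen_resblock(bank_out, cfg$g_final_channels, cfg$spade_hidden)
  m$conv_out <- nn_conv(cfg$g_final_channels, 1L, 3L, spectral = TRUE)
  m$sig <- nn_sigmoid()
  m$children <- Filter(Negate(is.null),
                       c(list(m$lin), m$blocks,
                         list(m$bank, m$final, m$conv_out)))
  m$fwd <- function(z, mask_pyramid, speckle_seed = NULL) {
    N <- nrow(z)
    x <- array(t(m$lin$fwd(z)), dim = c(4L, 4L, c0, N))
    for (b in m$blocks) {
      x <- upsample2_fwd(x)
      x <- b$fwd(x, mask_pyramid[[as.character(nrow(x))]])
    }
    if (!is.null(m$bank)) x <- m$bank$fwd(x, seed = speckle_seed)
    x <- m$final$fwd(x, mask_pyramid[[as.character(nrow(x))]])
    m$sig$fwd(m$conv_out$fwd(x))
  }
  m$bwd <- function(gy) {
    g <- m$conv_out$bwd(m$sig$bwd(gy))
    g <- m$final$bwd(g)
    if (!is.null(m$bank)) g <- m$bank$bwd(g)
    for (b in rev(m$blocks)) {
      g <- b$bwd(g)
      g <- upsample2_bwd(g)
    }
    N <- dim(g)[4]
    m$lin$bwd(t(matrix(g, ncol = N)))
  }
  m
}

#' Build the discriminator network
#'
#' @param cfg a [gan_config()]
#' @return discriminator module mapping (image, one-hot mask) to a
#'   per-sample probability in (0, 1)
#' @export
build_discriminator <- function(cfg) {
  m <- new_module("discriminator")
  m$cfg <- cfg
  m$stem <- nn_conv(1L + 3L, cfg$d_channels[1], 3L, spectral = TRUE)
  m$stem_relu <- nn_relu()
  chans <- c(cfg$d_channels[1], cfg$d_channels)
  m$blocks <- lapply(seq_along(cfg$d_channels), function(i)
    disc_resblock(chans[i], chans[i + 1]))
  m$head <- nn_linear(chans[length(chans)], 1L, spectral = TRUE)
  m$sig <- nn_sigmoid()
  m$children <- c(list(m$stem), m$blocks, list(m$head))
  m$fwd <- function(img, mask_oh) {
    d <- tdim(img)
    x <- array(0, dim = c(d[1], d[2], 4L, d[4]))
    x[, , 1, ] <- img
    x[, , 2:4, ] <- mask_oh
    x <- m$stem_relu$fwd(m$stem$fwd(x))
    for (b in m$blocks) x <- b$fwd(x)
    dd <- tdim(x)
    m$pool_dims <- dd
    pooled <- t(matrix(colMeans(matrix(x, dd[1] * dd[2], dd[3] * dd[4])),
                       dd[3], dd[4]))
    m$sig$fwd(m$head$fwd(pooled))
  }
  m$bwd <- function(gp) {
    gpooled <- m$head$bwd(m$sig$bwd(gp))           # N x C
    dd <- m$pool_dims
    g <- array(0, dim = dd)
    for (ci in seq_len(dd[3]))
      g[, , ci, ] <- rep(gpooled[, ci] / (dd[1] * dd[2]),
                         each = dd[1] * dd[2])
    for (b in rev(m$blocks)) g <- b$bwd(g)
    gx <- m$stem$bwd(m$stem_relu$bwd(g))
    gx[, , 1, , drop = FALSE]                      # gradient w.r.t. the image
  }
  m
}

## ---- losses ----------------------------------------------------------------

clamp01 <- function(p, eps = 1e-7) pmin(pmax(p, eps), 1 - eps)

#' Non-saturating discriminator loss
#'
#' `-mean(log D(real)) - mean(log(1 - D(fake)))`, probabilities clamped to
#' `[1e-7, 1 - 1e-7]` before the logarithm.
#'
#' @param d_real,d_fake discriminator probabilities for real/generated
#'   samples
#' @return non-negative scalar loss
#' @export
loss_discriminator <- function(d_real, d_fake) {
  -mean(log(clamp01(d_real))) - mean(log(1 - clamp01(d_fake)))
}

#' Non-saturating generator loss
#'
#' `-mean(log D(fake))`, clamped as in [loss_discriminator()].
#'
#' @param d_fake discriminator probabilities for generated samples
#' @return non-negative scalar loss
#' @export
loss_generator <- function(d_fake) {
  -mean(log(clamp01(d_fake)))
}

# gradients of the losses w.r.t. the probabilities (zero in the clamp zone)
grad_loss_d_real <- function(p, eps = 1e-7) {
  g <- -1 / (length(p) * p)
  g[p < eps | p > 1 - eps] <- 0
  g
}
grad_loss_d_fake <- function(p, eps = 1e-7) {
  g <- 1 / (length(p) * (1 - p))
  g[p < eps | p > 1 - eps] <- 0
  g
}
grad_loss_g <- function(p, eps = 1e-7) {
  g <- -1 / (length(p) * p)
  g[p < eps | p > 1 - eps] <- 0
  g
}

## ---- data plumbing ---------------------------------------------------------

#' Jointly augment an image/mask pair
#'
#' Applies one random rotation plus independent horizontal and vertical
#' flips, identically to both image and mask.  The image is resampled
#' bilinearly, the mask with nearest neighbour so labels are preserved;
#' regions rotated in from outside the frame get label 2 (background).
#'
#' @param image intensity matrix in `[0, 1]`
#' @param mask integer label matrix over `{0, 1, 2}`
#' @param seed integer seed, or `NULL` to consume the current RNG stream
#' @return list with rotated/flipped `image` and `mask`
#' @export
augment_pair <- function(image, mask, seed = NULL) {
  same_shape(image, mask, "image vs mask")
  draws <- with_seed(seed, list(angle = runif(1, 0, 360),
                                hflip = runif(1) < 0.5,
                                vflip = runif(1) < 0.5))
  img <- rotate_image(image, draws$angle, "bilinear", fill = 0)
  msk <- rotate_image(mask, draws$angle, "nearest", fill = 2)
  if (draws$hflip) { img <- img[, ncol(img):1]; msk <- msk[, ncol(msk):1] }
  if (draws$vflip) { img <- img[nrow(img):1, ]; msk <- msk[nrow(msk):1, ] }
  list(image = img, mask = msk)
}

# one-hot mask tensors at every spatial size the generator's SPADE layers use
make_mask_pyramid <- function(masks, image_size) {
  sizes <- 4L * 2L^seq_len(as.integer(log2(image_size / 4)))
  N <- length(masks)
  pyr <- list()
  for (s in sizes) {
    t4 <- array(0, dim = c(s, s, 1L, N))
    for (i in seq_len(N)) t4[, , 1, i] <- resize_mask_nearest(masks[[i]], s, s)
    pyr[[as.character(s)]] <- one_hot_mask(t4)
  }
  pyr
}

load_dataset_dir <- function(dir) {
  imgs <- sort(list.files(dir, pattern = "^phantom.*\\.png$", full.names = TRUE))
  msks <- sort(list.files(dir, pattern = "^mask.*\\.png$", full.names = TRUE))
  if (length(imgs) == 0 || length(imgs) != length(msks))
    stop("dataset directory must contain matching phantom_*.png / mask_*.png pairs")
  lapply(seq_along(imgs), function(i)
    list(image = read_image(imgs[i]), mask = read_mask(msks[i])))
}

## ---- training --------------------------------------------------------------

#' Train the GAN on a directory (or list) of image/mask pairs
#'
#' Alternating Adam updates with the non-saturating losses; FID between
#' generated and training images (desk embedder) is logged every
#' `cfg$fid_every` epochs and the best-FID generator checkpoint is kept.
#' Fully deterministic given `cfg$seed`.
#'
#' @param data directory containing `phantom_*.png` / `mask_*.png` pairs, or
#'   a list of `list(image =, mask =)` pairs
#' @param cfg a [gan_config()]
#' @param out_dir output directory for `metrics.csv`,
#'   `checkpoint_best.rds` and `run_config.json`
#' @param verbose print a line per epoch
#' @return (invisibly) list with the loss log data frame, the best FID and
#'   the trained generator/discriminator modules
#' @export
train_gan <- function(data, cfg, out_dir, verbose = FALSE) {
  pairs <- if (is.character(data)) load_dataset_dir(data) else data
  if (length(pairs) < 2) stop("need at least 2 image/mask pairs")
  H <- nrow(pairs[[1]]$image)
  for (p in pairs) {
    same_shape(p$image, p$mask, "image vs mask")
    if (nrow(p$image) != cfg$image_size || ncol(p$image) != cfg$image_size)
      stop("dataset images are ", nrow(p$image), "x", ncol(p$image),
           " but cfg$image_size is ", cfg$image_size)
    bad <- setdiff(unique(as.vector(p$mask)), 0:2)
    if (length(bad)) stop("mask contains invalid label(s): ",
                          paste(bad, collapse = ", "))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(cfg$seed)
  G <- build_generator(cfg)
  D <- build_discriminator(cfg)
  adam_init(G); adam_init(D)
  set_training(G, TRUE); set_training(D, TRUE)
  B <- min(cfg$batch_size, length(pairs))
  steps_per_epoch <- max(1L, length(pairs) %/% B)
  embedder <- desk_embedder()
  real_images <- lapply(pairs, `[[`, "image")
  real_feats <- embed_images(real_images, embedder)
  real_stats <- gaussian_stats(real_feats)

  log_rows <- list()
  best_fid <- Inf
  ckpt_path <- file.path(out_dir, "checkpoint_best.rds")
  step_global <- 0L

  ## discriminator warmup: D-only updates against untrained fakes
  for (ws in seq_len(cfg$d_warmup_steps)) {
    idx <- sample(length(pairs), B, replace = B > length(pairs))
    aug <- lapply(pairs[idx], function(p) augment_pair(p$image, p$mask))
    real <- stack_images(lapply(aug, `[[`, "image"))
    pyr <- make_mask_pyramid(lapply(aug, `[[`, "mask"), cfg$image_size)
    mask_oh <- pyr[[as.character(cfg$image_size)]]
    z <- matrix(rnorm(B * cfg$z_dim), B, cfg$z_dim)
    fake <- G$fwd(z, pyr)
    zero_grads(D)
    p_real <- drop(D$fwd(real, mask_oh))
    D$bwd(matrix(grad_loss_d_real(p_real), ncol = 1))
    p_fake <- drop(D$fwd(fake, mask_oh))
    D$bwd(matrix(grad_loss_d_fake(p_fake), ncol = 1))
    adam_step(D, cfg$lr_init, cfg$beta1, cfg$beta2, cfg$adam_eps, ws)
  }
  for (epoch in seq_len(cfg$epochs)) {
    lr <- lr_at_epoch(cfg, epoch - 1L)
    order_idx <- sample(length(pairs))
    for (step in seq_len(steps_per_epoch)) {
      step_global <- step_global + 1L
      idx <- order_idx[((step - 1L) * B + seq_len(B) - 1L) %% length(pairs) + 1L]
      aug <- lapply(pairs[idx], function(p) augment_pair(p$image, p$mask))
      real <- stack_images(lapply(aug, `[[`, "image"))
      masks <- lapply(aug, `[[`, "mask")
      pyr <- make_mask_pyramid(masks, cfg$image_size)
      mask_oh <- pyr[[as.character(cfg$image_size)]]
      z <- matrix(rnorm(B * cfg$z_dim), B, cfg$z_dim)
      fake <- G$fwd(z, pyr)

      ## discriminator update
      zero_grads(D)
      p_real <- drop(D$fwd(real, mask_oh))
      D$bwd(matrix(grad_loss_d_real(p_real), ncol = 1))
      p_fake <- drop(D$fwd(fake, mask_oh))
      D$bwd(matrix(grad_loss_d_fake(p_fake), ncol = 1))
      loss_d <- loss_discriminator(p_real, p_fake)
      adam_step(D, lr * cfg$d_lr_scale, cfg$beta1, cfg$beta2, cfg$adam_eps,
                step_global)

      ## generator update (re-run D on the fake batch for fresh caches)
      zero_grads(G); zero_grads(D)
      p_fake2 <- drop(D$fwd(fake, mask_oh))
      g_img <- D$bwd(matrix(grad_loss_g(p_fake2), ncol = 1))
      G$bwd(g_img)
      loss_g <- loss_generator(p_fake2)
      adam_step(G, lr, cfg$beta1, cfg$beta2, cfg$adam_eps, step_global)
      if (!is.null(G$bank)) {
        G$bank$params$d <- pmin(pmax(G$bank$params$d, 1), cfg$image_size)
      }

      log_rows[[length(log_rows) + 1L]] <-
        data.frame(epoch = epoch, step = step_global, loss_d = loss_d,
                   loss_g = loss_g, d_real = mean(p_real),
                   d_fake = mean(p_fake), fid = NA_real_, lr = lr)
    }
    if (epoch %% cfg$fid_every == 0L || epoch == cfg$epochs) {
      nf <- min(cfg$n_fid_images, length(pairs))
      gen_masks <- lapply(pairs[seq_len(nf)], `[[`, "mask")
      gpyr <- make_mask_pyramid(gen_masks, cfg$image_size)
      zf <- matrix(rnorm(nf * cfg$z_dim), nf, cfg$z_dim)
      gen <- G$fwd(zf, gpyr)
      gen_list <- lapply(seq_len(nf), function(i) gen[, , 1, i])
      fid_val <- fid(gaussian_stats(embed_images(gen_list, embedder)),
                     real_stats)
      log_rows[[length(log_rows)]]$fid <- fid_val
      if (fid_val < best_fid) {
        best_fid <- fid_val
        saveRDS(list(cfg = cfg, epoch = epoch, fid = fid_val,
                     g_state = module_state(G), d_state = module_state(D)),
                ckpt_path)
      }
      if (verbose)
        message(sprintf("epoch %d  loss_D %.4f  loss_G %.4f  FID %.2f",
                        epoch, loss_d, loss_g, fid_val))
    }
  }
  set_training(G, FALSE); set_training(D, FALSE)
  log <- do.call(rbind, log_rows)
  write.csv(log, file.path(out_dir, "metrics.csv"), row.names = FALSE)
  jsonlite::write_json(list(config = unclass(cfg), best_fid = best_fid),
                       file.path(out_dir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(log = log, best_fid = best_fid, checkpoint = ckpt_path,
                 generator = G, discriminator = D))
}

#' Load a generator from a training checkpoint
#'
#' @param path `checkpoint_best.rds` written by [train_gan()]
#' @return list with the rebuilt `generator` and its `cfg`
#' @export
load_generator <- function(path) {
  ck <- readRDS(path)
  G <- build_generator(ck$cfg)
  set_module_state(G, ck$g_state)
  list(generator = G, cfg = ck$cfg)
}

#' Generate images from a (trained or fresh) generator
#'
#' @param G generator module from [build_generator()] or [load_generator()]
#' @param masks list of label-mask matrices to condition on
#' @param seed seed controlling both the latent draws and the speckle phases
#' @param z optional fixed latent matrix (`length(masks) x z_dim`)
#' @return list of generated intensity matrices in `[0, 1]`
#' @export
generate_images <- function(G, masks, seed = 0L, z = NULL) {
  cfg <- G$cfg
  n <- length(masks)
  pyr <- make_mask_pyramid(masks, cfg$image_size)
  out <- with_seed(seed, {
    if (is.null(z)) z <- matrix(rnorm(n * cfg$z_dim), n, cfg$z_dim)
    G$fwd(z, pyr)
  })
  lapply(seq_len(n), function(i) out[, , 1, i])
}
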