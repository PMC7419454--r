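## Synthetic artery masks and speckle phantoms.  Masks are built from
## randomly rotated, radially disturbed ellipses imitating the artery lumen
## and the intima/media band; phantoms render per-class base intensities,
## speckle them in the polar domain with per-class window sizes, warp back
## to Cartesian coordinates and add sensor noise.  Everything is
## deterministic per seed, so the whole package is testable without any
## real ultrasound data.

#' Specification for synthetic artery masks
#'
#' The lumen boundary is an ellipse with a low-order Fourier radial
#' perturbation `r(theta) = r_e(theta) * (1 + sum_k a_k cos(k theta + phi_k))`,
#' randomly rotated; the intima/media band is a second, larger disturbed
#' ellipse kept strictly outside the lumen; everything else is class 2.
#' Default geometry scales with the image size.
#'
#' @param image_size mask side length in pixels
#' @param lumen_radius_range range of the lumen reference radius (pixels)
#' @param wall_thickness_range range of the intima/media band thickness
#' @param center_jitter maximal displacement of the artery centre from the
#'   image centre (pixels)
#' @param eccentricity_range ellipse eccentricity range, within `[0, 1)`
#' @param n_harmonics number of Fourier harmonics in the disturbance
#' @param perturb_amp maximal total relative radial disturbance (< 1)
#' @param seed integer seed
#' @return object of class `artery_mask_spec`
#' @export
artery_mask_spec <- function(image_size = 256L,
                             lumen_radius_range = image_size * c(0.10, 0.21),
                             wall_thickness_range = image_size * c(0.05, 0.12),
                             center_jitter = 0.05 * image_size,
                             eccentricity_range = c(0, 0.45),
                             n_harmonics = 4L, perturb_amp = 0.15,
                             seed = 0L) {
  if (perturb_amp >= 1) stop("perturb_amp must be < 1")
  if (eccentricity_range[2] >= 1) stop("eccentricity must stay below 1")
  worst <- lumen_radius_range[2] * (1 + perturb_amp) +
    wall_thickness_range[2] * (1 + perturb_amp) + center_jitter
  if (worst >= image_size / 2)
    stop("geometry can exceed the frame: lumen radius + wall thickness + ",
         "jitter must stay below image_size / 2")
  structure(list(image_size = as.integer(image_size),
                 lumen_radius_range = lumen_radius_range,
                 wall_thickness_range = wall_thickness_range,
                 center_jitter = center_jitter,
                 eccentricity_range = eccentricity_range,
                 n_harmonics = as.integer(n_harmonics),
                 perturb_amp = perturb_amp, seed = as.integer(seed)),
            class = "artery_mask_spec")
}

# radius of a rotated ellipse plus Fourier disturbance, evaluated at angles th
disturbed_radius <- function(th, r0, ecc, rot, amps, phis) {
  b <- r0 * sqrt(1 - ecc^2)
  tr <- th - rot
  re <- r0 * b / sqrt((b * cos(tr))^2 + (r0 * sin(tr))^2)
  pert <- rep(0, length(th))
  for (k in seq_along(amps)) pert <- pert + amps[k] * cos(k * th + phis[k])
  re * (1 + pert)
}

#' Sample a synthetic artery segmentation mask
#'
#' @param spec an [artery_mask_spec()]
#' @return `image_size x image_size` integer matrix over `{0, 1, 2}`
#'   (0 lumen, 1 intima/media, 2 adventitia/background); the lumen is a
#'   single connected region entirely enclosed by class 1
#' @export
sample_artery_mask <- function(spec) {
  n <- spec$image_size
  draw_once <- function() {
    cr <- (n - 1) / 2 + runif(1, -1, 1) * spec$center_jitter
    cc <- (n - 1) / 2 + runif(1, -1, 1) * spec$center_jitter
    r0 <- runif(1, spec$lumen_radius_range[1], spec$lumen_radius_range[2])
    thick <- runif(1, spec$wall_thickness_range[1], spec$wall_thickness_range[2])
    ecc_l <- runif(1, spec$eccentricity_range[1], spec$eccentricity_range[2])
    ecc_w <- runif(1, spec$eccentricity_range[1], spec$eccentricity_range[2])
    rot <- runif(1, 0, 2 * pi)
    draw_harmonics <- function() {
      a <- runif(spec$n_harmonics, -1, 1)
      scale <- spec$perturb_amp * runif(1, 0.3, 1)
      if (sum(abs(a)) > 0) a * scale / sum(abs(a)) else a
    }
    al <- draw_harmonics(); pl <- runif(spec$n_harmonics, 0, 2 * pi)
    aw <- draw_harmonics(); pw <- runif(spec$n_harmonics, 0, 2 * pi)
    i <- rep(0:(n - 1), times = n); j <- rep(0:(n - 1), each = n)
    dy <- cr - i; dx <- j - cc
    r <- sqrt(dy^2 + dx^2)
    th <- atan2(dy, dx)
    rl <- disturbed_radius(th, r0, ecc_l, rot, al, pl)
    rw_raw <- disturbed_radius(th, r0 + thick, ecc_w, rot, aw, pw)
    rw <- pmax(rw_raw, rl + 2)      # wall stays strictly outside the lumen
    # reject contours leaving the frame
    max_r <- max(rw)
    margin <- min(cr, cc, n - 1 - cr, n - 1 - cc)
    if (max_r >= margin) return(NULL)
    lab <- rep(2L, n * n)
    lab[r <= rw] <- 1L
    lab[r <= rl] <- 0L
    matrix(lab, n, n)
  }
  with_seed(spec$seed, {
    for (try in 1:20) {
      m <- draw_once()
      if (!is.null(m)) return(m)
    }
    stop("could not sample an in-frame artery mask in 20 attempts; ",
         "shrink the geometry ranges")
  })
}

#' Texture specification for phantom rendering
#'
#' @param base_intensity per-class mean intensity (lumen, intima/media,
#'   adventitia), each in `[0, 1]`; lumen darkest, adventitia brightest
#' @param speckle_d per-class spectral window edge length (larger d =
#'   finer speckle); blood speckle is finest, adventitia coarsest
#' @param noise_sd additive Gaussian sensor noise level
#' @param softness window softness used during rendering
#' @param seed integer seed
#' @return object of class `phantom_texture_spec`
#' @export
phantom_texture_spec <- function(base_intensity = c(0.10, 0.55, 0.75),
                                 speckle_d = c(44, 28, 16),
                                 noise_sd = 0.02, softness = 0,
                                 seed = 0L) {
  if (any(base_intensity < 0 | base_intensity > 1))
    stop("base intensities must lie in [0, 1]")
  if (length(base_intensity) != 3L || length(speckle_d) != 3L)
    stop("need one base intensity and one window size per class")
  structure(list(base_intensity = base_intensity, speckle_d = speckle_d,
                 noise_sd = noise_sd, softness = softness,
                 seed = as.integer(seed)),
            class = "phantom_texture_spec")
}

#' Render a speckle phantom from a segmentation mask
#'
#' For each class, a constant image at the class base intensity is
#' speckled in the polar domain at the class window size and warped
#' polar -> Cartesian (so grains curve around the catheter centre, the
#' centric-view pipeline); the class regions are then composited,
#' Gaussian sensor noise added, and the result clipped at 0 and rescaled
#' to `[0, 1]`.
#'
#' @param mask integer label matrix over `{0, 1, 2}`
#' @param tex a [phantom_texture_spec()]
#' @return intensity matrix in `[0, 1]`, same shape as `mask`
#' @export
render_phantom <- function(mask, tex = phantom_texture_spec()) {
  H <- nrow(mask); W <- ncol(mask)
  spec <- default_polar_spec(H, W)
  with_seed(tex$seed, {
    out <- matrix(0, H, W)
    for (cls in 0:2) {
      w <- make_spectral_window(tex$speckle_d[cls + 1L], H, W, tex$softness)
      ph <- sample_phase_field(H, W)
      sp_polar <- apply_speckle(matrix(tex$base_intensity[cls + 1L], H, W),
                                w, ph)
      # the window keeps only a d^2/N^2 fraction of spectral power, so the
      # raw magnitude scales with d; renormalize the class texture back to
      # its stated mean intensity
      if (mean(sp_polar) > 0)
        sp_polar <- sp_polar * tex$base_intensity[cls + 1L] / mean(sp_polar)
      sp <- polar_to_cartesian(sp_polar, spec, H, W)
      sel <- mask == cls
      out[sel] <- sp[sel]
    }
    out <- out + matrix(rnorm(H * W, sd = tex$noise_sd), H, W)
    out <- pmax(out, 0)
    if (max(out) > 0) out <- out / max(out)
    out
  })
}

#' Generate a phantom dataset on disk
#'
#' Writes `n` (phantom, mask) PNG pairs plus a CSV manifest.  Pair `i` uses
#' seed `seed + i`, so regeneration with the same master seed is
#' byte-identical.
#'
#' @param n number of pairs
#' @param mask_spec an [artery_mask_spec()] (its seed field is overridden
#'   per pair)
#' @param tex_spec a [phantom_texture_spec()] (seed likewise per pair)
#' @param out_dir output directory (created if needed)
#' @param seed master seed
#' @return (invisibly) the manifest data frame
#' @export
generate_dataset <- function(n, mask_spec = artery_mask_spec(),
                             tex_spec = phantom_texture_spec(),
                             out_dir, seed = 0L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    si <- seed + i
    ms <- mask_spec; ms$seed <- si
    ts <- tex_spec; ts$seed <- si
    mask <- sample_artery_mask(ms)
    img <- render_phantom(mask, ts)
    fi <- sprintf("phantom_%04d.png", i)
    fm <- sprintf("mask_%04d.png", i)
    write_image(img, file.path(out_dir, fi))
    write_mask(mask, file.path(out_dir, fm))
    rows[[i]] <- data.frame(image = fi, mask = fm, seed = si,
                            image_size = ms$image_size)
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
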