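## Polar <-> Cartesian warping for centric (catheter-eye) ultrasound views.
## Resampling is bilinear and linear in the image, so each warp is realized
## as a sparse matrix; its transpose is the exact backward operator, which
## lets gradients flow through in-network warping.

#' Polar grid specification
#'
#' @param center_row,center_col disc centre in 0-based pixel coordinates
#' @param n_radii,n_angles polar grid size (rows = radii, cols = angles)
#' @param max_radius outer radius in pixels
#' @return object of class `polar_grid_spec`
#' @export
polar_grid_spec <- function(center_row, center_col, n_radii, n_angles,
                            max_radius) {
  stopifnot_scalar_number(max_radius, "max_radius", positive = TRUE)
  if (n_radii < 2 || n_angles < 2)
    stop("polar grid needs at least 2 radii and 2 angles")
  structure(list(center_row = center_row, center_col = center_col,
                 n_radii = as.integer(n_radii),
                 n_angles = as.integer(n_angles),
                 max_radius = max_radius),
            class = "polar_grid_spec")
}

#' Default polar grid for an H x W image
#'
#' Centre `((H-1)/2, (W-1)/2)`, `n_radii = H`, `n_angles = W`,
#' `max_radius = min(H, W) / 2`.
#'
#' @param height,width Cartesian image dimensions
#' @return a [polar_grid_spec()]
#' @export
default_polar_spec <- function(height, width) {
  polar_grid_spec((height - 1) / 2, (width - 1) / 2,
                  n_radii = height, n_angles = width,
                  max_radius = min(height, width) / 2)
}

check_polar_spec <- function(spec, height, width) {
  if (!inherits(spec, "polar_grid_spec")) stop("`spec` must be a polar_grid_spec")
  if (spec$max_radius > min(height, width) / 2 + 1e-9)
    stop("max_radius ", spec$max_radius, " exceeds image bounds (min side ",
         min(height, width), ")")
  invisible(spec)
}

# Sparse bilinear sampling operator: row p of the result picks the source
# image (H x W, column-major vec) at 0-based real coordinates (rr[p], cc[p]).
# Out-of-bounds contributions are dropped (sample to 0).  `wrap_col` wraps
# the column axis (used for the periodic angle axis of polar images).
bilinear_sample_matrix <- function(rr, cc, H, W, wrap_col = FALSE) {
  P <- length(rr)
  r0 <- floor(rr); c0 <- floor(cc)
  fr <- rr - r0;   fc <- cc - c0
  parts <- list(
    list(r = r0,     c = c0,     w = (1 - fr) * (1 - fc)),
    list(r = r0 + 1, c = c0,     w = fr * (1 - fc)),
    list(r = r0,     c = c0 + 1, w = (1 - fr) * fc),
    list(r = r0 + 1, c = c0 + 1, w = fr * fc))
  ii <- jj <- ww <- vector("list", 4L)
  for (k in seq_along(parts)) {
    p <- parts[[k]]
    cidx <- if (wrap_col) p$c %% W else p$c
    ok <- p$r >= 0 & p$r <= H - 1 & cidx >= 0 & cidx <= W - 1 & p$w > 0
    ii[[k]] <- which(ok)
    jj[[k]] <- p$r[ok] + 1L + H * cidx[ok]
    ww[[k]] <- p$w[ok]
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(ww),
                       dims = c(P, H * W))
}

polar_sample_coords <- function(spec) {
  radii <- seq(0, spec$max_radius, length.out = spec$n_radii)
  theta <- (seq_len(spec$n_angles) - 1) * 2 * pi / spec$n_angles
  # row index varies fastest in the output (radius axis)
  r <- rep(radii, times = spec$n_angles)
  th <- rep(theta, each = spec$n_radii)
  # angles counterclockwise from the positive column axis; rows grow downward
  list(rr = spec$center_row - r * sin(th),
       cc = spec$center_col + r * cos(th))
}

#' Warp a Cartesian image to a polar (radius x angle) grid
#'
#' Output row r, column a samples the Cartesian image at
#' `center + radius(r) * (cos(theta(a)), sin(theta(a)))` with bilinear
#' interpolation; samples outside the image are 0.
#'
#' @param image Cartesian image matrix
#' @param spec a [polar_grid_spec()]; default [default_polar_spec()]
#' @return `n_radii x n_angles` polar image
#' @export
cartesian_to_polar <- function(image, spec = NULL) {
  image <- as_image(image)
  H <- nrow(image); W <- ncol(image)
  if (is.null(spec)) spec <- default_polar_spec(H, W)
  check_polar_spec(spec, H, W)
  co <- polar_sample_coords(spec)
  M <- bilinear_sample_matrix(co$rr, co$cc, H, W)
  matrix(as.numeric(M %*% as.vector(image)), spec$n_radii, spec$n_angles)
}

cartesian_from_polar_coords <- function(spec, out_height, out_width) {
  i <- rep(0:(out_height - 1), times = out_width)
  j <- rep(0:(out_width - 1), each = out_height)
  dy <- spec$center_row - i
  dx <- j - spec$center_col
  r <- sqrt(dy^2 + dx^2)
  th <- atan2(dy, dx) %% (2 * pi)
  rr <- r / spec$max_radius * (spec$n_radii - 1)
  cc <- th / (2 * pi) * spec$n_angles
  list(rr = rr, cc = cc, inside = r <= spec$max_radius)
}

# Sparse operator taking vec(polar image) to vec(Cartesian image);
# reused (and transposed for gradients) by the in-network polar pipeline.
polar_to_cartesian_matrix <- function(spec, out_height, out_width) {
  co <- cartesian_from_polar_coords(spec, out_height, out_width)
  M <- bilinear_sample_matrix(co$rr, co$cc, spec$n_radii, spec$n_angles,
                              wrap_col = TRUE)
  M[!co$inside, ] <- 0   # outside the disc -> 0
  M
}

#' Warp a polar (radius x angle) image back to Cartesian coordinates
#'
#' Inverse resampling of [cartesian_to_polar()]: each Cartesian pixel reads
#' the polar image at its (radius, angle) with bilinear interpolation, the
#' angle axis wrapping periodically.  Pixels beyond `max_radius` are 0.
#'
#' @param image polar image (`n_radii x n_angles`)
#' @param spec a [polar_grid_spec()]
#' @param out_height,out_width Cartesian output size
#' @return `out_height x out_width` Cartesian image
#' @export
polar_to_cartesian <- function(image, spec, out_height, out_width) {
  image <- as_image(image)
  if (nrow(image) != spec$n_radii || ncol(image) != spec$n_angles)
    stop("polar image shape does not match the grid spec")
  check_polar_spec(spec, out_height, out_width)
  M <- polar_to_cartesian_matrix(spec, out_height, out_width)
  matrix(as.numeric(M %*% as.vector(image)), out_height, out_width)
}

#' Rotate an image about its centre
#'
#' @param image matrix to rotate
#' @param angle_deg rotation angle, degrees counterclockwise
#' @param interp `"bilinear"` for intensity images, `"nearest"` for label
#'   masks (labels preserved exactly)
#' @param fill value for samples falling outside the source image
#' @return rotated matrix of the same shape
#' @export
rotate_image <- function(image, angle_deg, interp = c("bilinear", "nearest"),
                         fill = 0) {
  interp <- match.arg(interp)
  image <- as_image(image)
  H <- nrow(image); W <- ncol(image)
  cr <- (H - 1) / 2; cc <- (W - 1) / 2
  a <- angle_deg * pi / 180
  i <- rep(0:(H - 1), times = W); j <- rep(0:(W - 1), each = H)
  # y measured upward so that positive angles match the package-wide
  # counterclockwise-from-column-axis convention
  yup <- cr - i; x <- j - cc
  xs <- cos(a) * x + sin(a) * yup
  ysup <- -sin(a) * x + cos(a) * yup
  rs <- cr - ysup
  cs <- cc + xs
  if (interp == "nearest") {
    ri <- round(rs); ci <- round(cs)
    ok <- ri >= 0 & ri <= H - 1 & ci >= 0 & ci <= W - 1
    out <- rep(fill, H * W)
    out[ok] <- image[cbind(ri[ok] + 1, ci[ok] + 1)]
    out <- matrix(out, H, W)
    if (is.integer(image)) storage.mode(out) <- "integer"
    out
  } else {
    M <- bilinear_sample_matrix(rs, cs, H, W)
    out <- matrix(as.numeric(M %*% as.vector(image)), H, W)
    cover <- matrix(as.numeric(M %*% rep(1, H * W)), H, W)
    out + fill * (1 - cover)
  }
}
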