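#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state so seeded operations are pure.
#' With `seed = NULL` the expression simply consumes the current RNG stream.
#'
#' @param seed integer seed or `NULL`
#' @param expr expression to evaluate
#' @return value of `expr`
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop("`", name, "` must be a single finite number", call. = FALSE)
  if (positive && x <= 0)
    stop("`", name, "` must be positive", call. = FALSE)
  invisible(x)
}

#' Coerce to an image matrix and validate
#' @param x numeric matrix
#' @param name label used in error messages
#' @return the validated matrix
#' @keywords internal
as_image <- function(x, name = "image") {
  if (!is.matrix(x) || !is.numeric(x))
    stop("`", name, "` must be a numeric matrix", call. = FALSE)
  if (!all(is.finite(x)))
    stop("`", name, "` contains non-finite values", call. = FALSE)
  x
}

same_shape <- function(a, b, what) {
  if (!identical(dim(a), dim(b)))
    stop("shape mismatch: ", what, " (", paste(dim(a), collapse = "x"),
         " vs ", paste(dim(b), collapse = "x"), ")", call. = FALSE)
  invisible(TRUE)
}

## --- 4-D tensor helpers; layout (H, W, C, N), column-major ----------------

tensor4 <- function(H, W, C, N, data = 0) {
  array(data, dim = c(H, W, C, N))
}

tdim <- function(x) {
  d <- dim(x)
  if (length(d) != 4L) stop("expected a 4-D (H, W, C, N) tensor")
  d
}

# per-channel mean over (H, W, N)
channel_mean <- function(x) {
  d <- tdim(x)
  cm <- colMeans(matrix(x, d[1] * d[2], d[3] * d[4]))
  rowMeans(matrix(cm, d[3], d[4]))
}

# per-channel sum over (H, W, N)
channel_sum <- function(x) {
  d <- tdim(x)
  cs <- colSums(matrix(x, d[1] * d[2], d[3] * d[4]))
  rowSums(matrix(cs, d[3], d[4]))
}

# broadcast a length-C vector over a (H, W, C, N) tensor
channel_expand <- function(v, d) {
  array(rep(rep(v, each = d[1] * d[2]), times = d[4]), dim = d)
}

# stack a list of H x W matrices into (H, W, 1, N)
stack_images <- function(images) {
  H <- nrow(images[[1]]); W <- ncol(images[[1]])
  x <- array(0, dim = c(H, W, 1, length(images)))
  for (i in seq_along(images)) {
    same_shape(images[[i]], images[[1]], "stacked images")
    x[, , 1, i] <- images[[i]]
  }
  x
}
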