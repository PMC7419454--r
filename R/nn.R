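## Minimal neural-network layer framework with hand-written backpropagation.
## Tensors are R arrays with dim (H, W, C, N); layers are environments with
## reference semantics holding $params, $grads, step caches and fwd/bwd
## closures.  Only what the generator/discriminator pair needs is provided.

new_module <- function(type) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e$children <- list()
  e$params <- list()
  e$grads <- list()
  class(e) <- c(paste0("es_", type), "es_module")
  e
}

# depth-first walk over a module tree, visiting every parameterized leaf
walk_modules <- function(mod, fn) {
  if (length(mod$params)) fn(mod)
  for (ch in mod$children) walk_modules(ch, fn)
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

zero_grads <- function(mod) {
  walk_modules(mod, function(m) {
    m$grads <- lapply(m$params, function(p) p * 0)
  })
}

accumulate_grad <- function(mod, name, g) {
  mod$grads[[name]] <- mod$grads[[name]] + g
}

n_parameters <- function(mod) {
  total <- 0
  walk_modules(mod, function(m) total <<- total + sum(lengths(m$params)))
  total
}

# training mode: spectral-norm power-iteration state is persisted/updated;
# in eval mode sigma is estimated from a deterministic start (or the frozen
# state) without side effects, so repeated forwards are identical
set_training <- function(mod, flag) {
  walk_modules(mod, function(m) m$training <- isTRUE(flag))
  invisible(mod)
}

# sigma and normalized weight for a layer, honouring train/eval mode
sn_apply <- function(m, wmat) {
  if (isTRUE(m$training)) {
    sn <- spectral_normalize(wmat, m$sn_state %||%
                               list(u = NULL, n_power_iterations = 1L))
    m$sn_state <- sn$state
  } else {
    st <- m$sn_state %||%
      list(u = rep(1 / sqrt(nrow(wmat)), nrow(wmat)),
           n_power_iterations = 8L)
    sn <- spectral_normalize(wmat, st)
  }
  sn
}

## ---- spectral normalization ----------------------------------------------

#' Spectrally normalize a weight matrix
#'
#' Divides a 2-D weight matrix by its largest singular value as estimated by
#' power iteration with a persistent left singular-vector estimate `u`
#' (the standard one-iteration-per-step scheme when used inside training).
#'
#' @param weight real matrix
#' @param state list with `u` (unit vector, `nrow(weight)` long; initialized
#'   randomly when `NULL`) and `n_power_iterations`
#' @return list with `weight` (normalized), `sigma` (the estimate) and the
#'   updated `state`
#' @export
spectral_normalize <- function(weight, state = NULL) {
  if (!is.matrix(weight)) stop("`weight` must be a 2-D matrix")
  if (is.null(state)) state <- list(u = NULL, n_power_iterations = 1L)
  u <- state$u
  if (is.null(u)) {
    u <- rnorm(nrow(weight))
    u <- u / sqrt(sum(u^2))
  }
  niter <- max(1L, state$n_power_iterations %||% 1L)
  v <- NULL
  for (k in seq_len(niter)) {
    v <- drop(crossprod(weight, u))
    v <- v / sqrt(sum(v^2) + 1e-12)
    u <- drop(weight %*% v)
    u <- u / sqrt(sum(u^2) + 1e-12)
  }
  sigma <- drop(crossprod(u, weight %*% v))
  state$u <- u
  list(weight = weight / sigma, sigma = sigma, state = state)
}

## ---- convolution ----------------------------------------------------------

nn_conv <- function(cin, cout, k = 3L, stride = 1L, pad = (k - 1L) %/% 2L,
                    spectral = FALSE, gain = sqrt(2), bias_init = 0) {
  m <- new_module("conv")
  sd <- gain / sqrt(k * k * cin)
  m$params$w <- array(rnorm(k * k * cin * cout, sd = sd),
                      dim = c(k, k, cin, cout))
  m$params$b <- rep(bias_init, cout)
  m$stride <- as.integer(stride); m$pad <- as.integer(pad)
  m$spectral <- spectral
  m$sn_state <- NULL
  m$fwd <- function(x) {
    w <- m$params$w
    if (m$spectral) {
      wm <- matrix(w, ncol = dim(w)[4])          # (k*k*cin) x cout
      sn <- sn_apply(m, t(wm))
      m$sigma <- sn$sigma
      w <- array(t(sn$weight), dim = dim(w))
    } else m$sigma <- 1
    m$w_used <- w
    m$x <- x
    .conv2d_fwd(x, w, m$params$b, m$stride, m$pad)
  }
  m$bwd <- function(gy) {
    r <- .conv2d_bwd(m$x, m$w_used, gy, m$stride, m$pad)
    accumulate_grad(m, "w", r$gw / m$sigma)   # sigma treated as a constant
    accumulate_grad(m, "b", r$gb)
    r$gx
  }
  m
}

## ---- linear ----------------------------------------------------------------

nn_linear <- function(fin, fout, spectral = FALSE, gain = 1) {
  m <- new_module("linear")
  m$params$w <- matrix(rnorm(fin * fout, sd = gain / sqrt(fin)), fin, fout)
  m$params$b <- numeric(fout)
  m$spectral <- spectral
  m$sn_state <- NULL
  m$fwd <- function(x) {                         # x: N x fin
    w <- m$params$w
    if (m$spectral) {
      sn <- sn_apply(m, w)
      m$sigma <- sn$sigma
      w <- sn$weight
    } else m$sigma <- 1
    m$w_used <- w
    m$x <- x
    sweep(x %*% w, 2, m$params$b, "+")
  }
  m$bwd <- function(gy) {
    accumulate_grad(m, "w", crossprod(m$x, gy) / m$sigma)
    accumulate_grad(m, "b", colSums(gy))
    gy %*% t(m$w_used)
  }
  m
}

## ---- batch normalization ---------------------------------------------------

nn_batchnorm <- function(C, affine = TRUE, eps = 1e-5) {
  m <- new_module("batchnorm")
  if (affine) {
    m$params$gamma <- rep(1, C)
    m$params$beta <- rep(0, C)
  }
  m$affine <- affine
  m$eps <- eps
  m$fwd <- function(x) {
    d <- tdim(x)
    mu <- channel_mean(x)
    v <- channel_mean(x * x) - mu^2
    istd <- 1 / sqrt(v + m$eps)
    xhat <- (x - channel_expand(mu, d)) * channel_expand(istd, d)
    m$xhat <- xhat; m$istd <- istd; m$d <- d
    if (m$affine)
      channel_expand(m$params$gamma, d) * xhat + channel_expand(m$params$beta, d)
    else xhat
  }
  m$bwd <- function(gy) {
    d <- m$d
    cnt <- d[1] * d[2] * d[4]
    ghat <- if (m$affine) gy * channel_expand(m$params$gamma, d) else gy
    if (m$affine) {
      accumulate_grad(m, "gamma", channel_sum(gy * m$xhat))
      accumulate_grad(m, "beta", channel_sum(gy))
    }
    s1 <- channel_sum(ghat) / cnt
    s2 <- channel_sum(ghat * m$xhat) / cnt
    (ghat - channel_expand(s1, d) - m$xhat * channel_expand(s2, d)) *
      channel_expand(m$istd, d)
  }
  m
}

## ---- activations and resampling -------------------------------------------

nn_relu <- function() {
  m <- new_module("relu")
  m$fwd <- function(x) { m$mask <- x > 0; x * m$mask }
  m$bwd <- function(gy) gy * m$mask
  m
}

nn_sigmoid <- function() {
  m <- new_module("sigmoid")
  m$fwd <- function(x) { m$y <- plogis(x); m$y }
  m$bwd <- function(gy) gy * m$y * (1 - m$y)
  m
}

upsample2_fwd <- function(x) {
  d <- tdim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , , drop = FALSE]
}

upsample2_bwd <- function(gy) {
  d <- tdim(gy)
  o1 <- seq(1, d[1], by = 2); o2 <- seq(2, d[1], by = 2)
  p1 <- seq(1, d[2], by = 2); p2 <- seq(2, d[2], by = 2)
  gy[o1, p1, , , drop = FALSE] + gy[o2, p1, , , drop = FALSE] +
    gy[o1, p2, , , drop = FALSE] + gy[o2, p2, , , drop = FALSE]
}

nn_upsample2 <- function() {
  m <- new_module("upsample2")
  m$fwd <- function(x) upsample2_fwd(x)
  m$bwd <- function(gy) upsample2_bwd(gy)
  m
}

## ---- Adam ------------------------------------------------------------------

adam_init <- function(mod) {
  walk_modules(mod, function(m) {
    m$adam <- lapply(m$params, function(p) list(mt = p * 0, vt = p * 0))
  })
  invisible(mod)
}

adam_step <- function(mod, lr, beta1 = 0.5, beta2 = 0.999, eps = 1e-8,
                      t = 1L) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  walk_modules(mod, function(m) {
    for (nm in names(m$params)) {
      g <- m$grads[[nm]]
      st <- m$adam[[nm]]
      st$mt <- beta1 * st$mt + (1 - beta1) * g
      st$vt <- beta2 * st$vt + (1 - beta2) * g * g
      m$adam[[nm]] <- st
      m$params[[nm]] <- m$params[[nm]] -
        lr * (st$mt / bc1) / (sqrt(st$vt / bc2) + eps)
    }
  })
  invisible(mod)
}

## ---- (de)serialization of module parameters -------------------------------

module_state <- function(mod) {
  st <- list(params = mod$params, sn_state = mod$sn_state)
  st$children <- lapply(mod$children, module_state)
  st
}

set_module_state <- function(mod, st) {
  if (length(st$params)) mod$params <- st$params
  if (!is.null(st$sn_state)) mod$sn_state <- st$sn_state
  for (i in seq_along(mod$children))
    set_module_state(mod$children[[i]], st$children[[i]])
  invisible(mod)
}
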