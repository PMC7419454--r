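# Shared fixtures, all built in code at test time.

# deterministic random image in [0, 1]
rand_image <- function(h, w, seed = 1) {
  echosynth:::with_seed(seed, matrix(runif(h * w), h, w))
}

# tiny concentric-disc mask: class 0 inside r0, class 1 inside r1, else 2
disc_mask <- function(n, r0 = n / 6, r1 = n / 3) {
  c0 <- (n - 1) / 2
  r <- sqrt(outer(((0:(n - 1)) - c0)^2, ((0:(n - 1)) - c0)^2, "+"))
  m <- matrix(2L, n, n)
  m[r <= r1] <- 1L
  m[r <= r0] <- 0L
  m
}

# flood fill from the border over non-wall pixels; TRUE where reachable
border_flood <- function(open) {
  H <- nrow(open); W <- ncol(open)
  reach <- matrix(FALSE, H, W)
  queue <- which(open & (row(open) %in% c(1, H) | col(open) %in% c(1, W)))
  reach[queue] <- TRUE
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    r <- (i - 1) %% H + 1; cc <- (i - 1) %/% H + 1
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      rr <- r + d[1]; c2 <- cc + d[2]
      if (rr >= 1 && rr <= H && c2 >= 1 && c2 <= W) {
        j <- rr + (c2 - 1) * H
        if (open[j] && !reach[j]) { reach[j] <- TRUE; queue <- c(queue, j) }
      }
    }
  }
  reach
}

# enclosure check: no lumen (class 0) pixel is reachable from the border
# without crossing the intima/media band (class 1)
lumen_enclosed <- function(mask) {
  reach <- border_flood(mask != 1L)
  !any(reach & mask == 0L)
}

smoke_dataset_dir <- local({
  dir <- NULL
  function() {
    if (is.null(dir)) {
      dir <<- file.path(tempdir(), "echosynth-smoke-data")
      if (!file.exists(file.path(dir, "manifest.csv")))
        generate_dataset(8, artery_mask_spec(image_size = 64),
                         phantom_texture_spec(), dir, seed = 1)
    }
    dir
  }
})
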