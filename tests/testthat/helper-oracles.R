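# Independent brute-force oracles, deliberately written as plain loops so
# they share no code path with the package implementations they check.

oracle_nui <- function(block_means) {
  mx <- block_means[1]; mn <- block_means[1]
  for (v in block_means) {
    if (v > mx) mx <- v
    if (v < mn) mn <- v
  }
  (mx - mn) / ((mx + mn) / 2)
}

oracle_cnr <- function(image, mask) {
  s <- c(); b <- c()
  for (i in seq_len(nrow(image))) {
    for (j in seq_len(ncol(image))) {
      if (mask[i, j]) s <- c(s, image[i, j]) else b <- c(b, image[i, j])
    }
  }
  mb <- sum(b) / length(b)
  ssq <- 0
  for (v in b) ssq <- ssq + (v - mb)^2
  (sum(s) / length(s) - mb) / sqrt(ssq / (length(b) - 1))
}

oracle_iqf_inv <- function(thick_um, dmin_mm) {
  acc <- 0
  for (i in seq_along(thick_um)) acc <- acc + thick_um[i] * dmin_mm[i]
  100 / acc
}

# a 2-D NPS object built directly from a generating function of (fx, fy),
# on the even-N shifted frequency grid the package uses
synthetic_nps <- function(fun, n, delta) {
  f <- (seq_len(n) - 1 - n / 2) / (n * delta)
  fxg <- matrix(f, n, n, byrow = TRUE)
  fyg <- matrix(f, n, n)
  structure(
    list(values = fun(fxg, fyg) + 0 * fxg, fx = f, fy = f,
         spacing_mm = c(delta, delta), n_noise_images = 1L),
    class = "nps_2d"
  )
}
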