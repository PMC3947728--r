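# Shared fixtures and independent brute-force oracles for the tests.

rand_image <- function(n, m = n, seed = 1) {
  set.seed(seed)
  matrix(runif(n * m), n, m)
}

smooth_rand_image <- function(n, seed = 1, sigma = 2) {
  gaussian_smooth(rand_image(n, n, seed), sigma = sigma, radius = 4L)
}

pad_rep <- function(x, r) {
  ri <- c(rep(1L, r), seq_len(nrow(x)), rep(nrow(x), r))
  ci <- c(rep(1L, r), seq_len(ncol(x)), rep(ncol(x), r))
  x[ri, ci, drop = FALSE]
}

# explicit per-window guided filter: loops over every window, replicate
# padding for both the window statistics and the coefficient averaging
guided_filter_bruteforce <- function(guide, input, radius, eps) {
  n <- nrow(guide); m <- ncol(guide); r <- radius
  gp <- pad_rep(guide, r); pp <- pad_rep(input, r)
  amat <- matrix(0, n, m); bmat <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    wi <- i:(i + 2 * r); wj <- j:(j + 2 * r)
    gw <- gp[wi, wj]; pw <- pp[wi, wj]
    mg <- mean(gw); mp <- mean(pw)
    a <- (mean(gw * pw) - mg * mp) / (mean(gw * gw) - mg^2 + eps + 1e-12)
    amat[i, j] <- a
    bmat[i, j] <- mp - a * mg
  }
  ap <- pad_rep(amat, r); bp <- pad_rep(bmat, r)
  out <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    wi <- i:(i + 2 * r); wj <- j:(j + 2 * r)
    out[i, j] <- mean(ap[wi, wj]) * guide[i, j] + mean(bp[wi, wj])
  }
  out
}

# direct neighborhood-summation box mean (replicate padding)
box_mean_bruteforce <- function(x, size) {
  r <- (size - 1L) %/% 2L
  p <- pad_rep(x, r)
  out <- matrix(0, nrow(x), ncol(x))
  for (i in seq_len(nrow(x))) for (j in seq_len(ncol(x)))
    out[i, j] <- mean(p[i:(i + 2 * r), j:(j + 2 * r)])
  out
}

total_variation <- function(x) {
  sum(abs(diff(x))) + sum(abs(t(diff(t(x)))))
}
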