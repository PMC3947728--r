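# Phase congruency via log-Gabor filters (frequency domain), with the
# maximum/minimum moment maps of the per-orientation congruency. Follows
# the standard monogenic/log-Gabor construction: 4 scales x 6
# orientations, noise threshold from the smallest-scale amplitude
# (Rayleigh model), sigmoid frequency-spread weighting.

pc_filter_bank <- function(n, m, nscale = 4L, norient = 6L,
                           min_wavelength = 3, mult = 2.1,
                           sigma_onf = 0.55) {
  fx <- ifelse(seq_len(m) - 1L <= m %/% 2L, seq_len(m) - 1L,
               seq_len(m) - 1L - m) / m
  fy <- ifelse(seq_len(n) - 1L <= n %/% 2L, seq_len(n) - 1L,
               seq_len(n) - 1L - n) / n
  u <- matrix(fx, n, m, byrow = TRUE)
  v <- matrix(fy, n, m)
  radius <- sqrt(u^2 + v^2)
  radius[1, 1] <- 1  # avoid log(0); DC is zeroed in each filter
  theta <- atan2(-v, u)
  lowpass <- 1 / (1 + (radius / 0.45)^30)
  radial <- vector("list", nscale)
  for (s in seq_len(nscale)) {
    fo <- 1 / (min_wavelength * mult^(s - 1L))
    lg <- exp(-(log(radius / fo))^2 / (2 * log(sigma_onf)^2)) * lowpass
    lg[1, 1] <- 0
    radial[[s]] <- lg
  }
  theta_sigma <- pi / norient / 1.5
  spread <- vector("list", norient)
  angles <- (seq_len(norient) - 1L) * pi / norient
  st <- sin(theta); ct <- cos(theta)
  for (o in seq_len(norient)) {
    ds <- st * cos(angles[o]) - ct * sin(angles[o])
    dc <- ct * cos(angles[o]) + st * sin(angles[o])
    dtheta <- abs(atan2(ds, dc))
    spread[[o]] <- exp(-dtheta^2 / (2 * theta_sigma^2))
  }
  list(radial = radial, spread = spread, angles = angles,
       nscale = nscale, norient = norient, mult = mult)
}

# Phase congruency map plus maximum/minimum moment maps for one image.
pc_features <- function(img, bank, k_noise = 2) {
  n <- nrow(img); m <- ncol(img)
  imf <- stats::fft(img)
  eps <- 1e-4
  pc_o <- vector("list", bank$norient)
  total_energy <- matrix(0, n, m)
  total_sum_an <- matrix(0, n, m)
  for (o in seq_len(bank$norient)) {
    sum_e <- matrix(0, n, m); sum_o <- matrix(0, n, m)
    sum_an <- matrix(0, n, m); max_an <- matrix(0, n, m)
    e_list <- vector("list", bank$nscale)
    o_list <- vector("list", bank$nscale)
    tau <- 0
    for (s in seq_len(bank$nscale)) {
      filt <- bank$radial[[s]] * bank$spread[[o]]
      eo <- stats::fft(imf * filt, inverse = TRUE) / (n * m)
      e <- Re(eo); od <- Im(eo)
      an <- sqrt(e^2 + od^2)
      e_list[[s]] <- e; o_list[[s]] <- od
      sum_e <- sum_e + e; sum_o <- sum_o + od
      sum_an <- sum_an + an
      max_an <- pmax(max_an, an)
      if (s == 1L) tau <- stats::median(an) / sqrt(log(4))
    }
    x_energy <- sqrt(sum_e^2 + sum_o^2) + eps
    mean_e <- sum_e / x_energy; mean_o <- sum_o / x_energy
    energy <- matrix(0, n, m)
    for (s in seq_len(bank$nscale)) {
      energy <- energy + e_list[[s]] * mean_e + o_list[[s]] * mean_o -
        abs(e_list[[s]] * mean_o - o_list[[s]] * mean_e)
    }
    # Rayleigh noise model on the total amplitude over scales
    total_tau <- tau * (1 - (1 / bank$mult)^bank$nscale) /
      (1 - 1 / bank$mult)
    noise_mean <- total_tau * sqrt(pi / 2)
    noise_sd <- total_tau * sqrt((4 - pi) / 2)
    t_thr <- noise_mean + k_noise * noise_sd
    energy <- pmax(energy - t_thr, 0)
    width <- (sum_an / (max_an + eps) - 1) / (bank$nscale - 1)
    weight <- 1 / (1 + exp(10 * (0.5 - width)))
    pc_o[[o]] <- weight * energy / (sum_an + eps)
    total_energy <- total_energy + weight * energy
    total_sum_an <- total_sum_an + sum_an
  }
  pc <- total_energy / (total_sum_an + eps)
  # second-moment matrix of the oriented congruency responses
  a <- matrix(0, n, m); bq <- matrix(0, n, m); cq <- matrix(0, n, m)
  for (o in seq_len(bank$norient)) {
    pcc <- pc_o[[o]] * cos(bank$angles[o])
    pcs <- pc_o[[o]] * sin(bank$angles[o])
    a <- a + pcc^2
    bq <- bq + pcc * pcs
    cq <- cq + pcs^2
  }
  bq <- 2 * bq
  disc <- sqrt(bq^2 + (a - cq)^2)
  list(pc = pc, moment_max = (cq + a + disc) / 2,
       moment_min = (cq + a - disc) / 2)
}

# Pearson correlation with the degenerate rule for constant maps.
corr_feature <- function(x, y) {
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx < EPS_NUM || sy < EPS_NUM) {
    if (sx < EPS_NUM && sy < EPS_NUM && max(abs(x - y)) < 1e-9) return(1)
    return(0)
  }
  max(stats::cor(as.vector(x), as.vector(y)), 0)
}

#' Phase-congruency fusion measure
#'
#' Feature-based score built on phase congruency, a contrast-invariant
#' measure of local phase alignment across log-Gabor scales. For each
#' image the phase-congruency map and the maximum and minimum moment maps
#' of its oriented components are computed (4 scales x 6 orientations).
#' For each of the three feature types, the component score is the
#' largest correlation between the fused image's map and the maps of
#' source A, source B, and the pixelwise maximum of the two source maps;
#' negative correlations are clamped at 0. The score is the product of
#' the three components, in [0,1], with constant feature maps scoring 1
#' only when identically equal.
#'
#' @inheritParams mi_measure
#' @return scalar score in [0,1].
#' @export
zhao_pc_measure <- function(a, b, f) {
  assert_same_shape(a, f, "images"); assert_same_shape(b, f, "images")
  bank <- pc_filter_bank(nrow(a), ncol(a))
  fa <- pc_features(a, bank)
  fb <- pc_features(b, bank)
  ff <- pc_features(f, bank)
  comp <- function(feat) {
    mx <- pmax(fa[[feat]], fb[[feat]])
    max(corr_feature(fa[[feat]], ff[[feat]]),
        corr_feature(fb[[feat]], ff[[feat]]),
        corr_feature(mx, ff[[feat]]))
  }
  comp("pc") * comp("moment_max") * comp("moment_min")
}
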