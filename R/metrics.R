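# entropy (bits) of a probability vector; 0 log 0 := 0
entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

bin_index <- function(x, bins) {
  rng <- range(x)
  if (rng[2] - rng[1] < EPS_NUM) return(rep(1L, length(x)))
  pmin(as.integer(floor((x - rng[1]) / (rng[2] - rng[1]) * bins)) + 1L,
       bins)
}

# MI(X,Y) and marginal entropies from a bins x bins joint histogram
mi_pair <- function(x, y, bins) {
  ix <- bin_index(x, bins); iy <- bin_index(y, bins)
  joint <- tabulate((iy - 1L) * bins + ix, nbins = bins * bins) /
    length(x)
  jm <- matrix(joint, bins, bins)
  px <- rowSums(jm); py <- colSums(jm)
  hx <- entropy_bits(px); hy <- entropy_bits(py)
  hxy <- entropy_bits(joint)
  list(mi = hx + hy - hxy, hx = hx, hy = hy)
}

#' Normalized mutual-information fusion measure
#'
#' Sums the mutual information each source shares with the fused image,
#' each normalized by the corresponding entropy sum:
#' \deqn{\zeta_{MI} = 2[ MI(A,F)/(H_A+H_F) + MI(B,F)/(H_B+H_F) ]}
#' Histograms use \code{bins} equal-width bins and base-2 logarithms. The
#' score lies in [0,2]; it equals 2 when F carries all and only the
#' information of each source (e.g. F = A = B). When an entropy sum is
#' zero (both images constant) the affected ratio is 0.5 — the
#' identical-image limit of MI/(H+H) — if the images are identical, and
#' 0 otherwise.
#'
#' @param a,b source images; \code{f} fused image (same shape).
#' @param f fused image.
#' @param bins number of histogram bins (>= 2), default 64.
#' @return scalar score in [0,2].
#' @export
mi_measure <- function(a, b, f, bins = 64L) {
  assert_same_shape(a, f, "images"); assert_same_shape(b, f, "images")
  if (bins < 2) stop("'bins' must be >= 2", call. = FALSE)
  ratio <- function(x) {
    p <- mi_pair(x, f, as.integer(bins))
    den <- p$hx + p$hy
    # degenerate zero-entropy pair: identical images score the
    # identical-image limit of MI/(H_X + H_F) = 1/2, keeping the total
    # within [0,2]; different images share no information
    if (den < EPS_NUM)
      return(if (max(abs(x - f)) < EPS_NUM) 0.5 else 0)
    p$mi / den
  }
  2 * (ratio(a) + ratio(b))
}

# windowed first/second moments (population) on a valid-window grid
win_stats <- function(x, size, stride) {
  mu <- win_mean_valid(x, size, stride)
  m2 <- win_mean_valid(x * x, size, stride)
  list(mu = mu, var = pmax(m2 - mu * mu, 0))
}

win_cov <- function(x, y, size, stride, mux, muy) {
  win_mean_valid(x * y, size, stride) - mux * muy
}

#' Structural-similarity fusion measure
#'
#' Sliding-window fusion SSIM. In each window the SSIM between each
#' source and the fused image is blended by the relative source variance
#' \eqn{\lambda_w = \sigma^2_{A,w}/(\sigma^2_{A,w}+\sigma^2_{B,w})} when
#' the sources agree (SSIM(A,B) >= 0.75 in the window), and the larger of
#' the two is taken when they disagree. The score is the mean over all
#' windows. Window SSIM uses uniform moments over the window and the
#' standard constants K1 = 0.01, K2 = 0.03 on unit dynamic range.
#'
#' @inheritParams mi_measure
#' @param size odd window side (default 8 following the fusion-SSIM
#'   convention; any size >= 2 and <= image size is accepted).
#' @param stride window step in pixels.
#' @return scalar score, typically in [0,1].
#' @export
ssim_fusion_measure <- function(a, b, f, size = 8L, stride = 1L) {
  assert_same_shape(a, f, "images"); assert_same_shape(b, f, "images")
  if (size > nrow(f) || size > ncol(f))
    stop("window larger than image", call. = FALSE)
  c1 <- 0.01^2; c2 <- 0.03^2
  sa <- win_stats(a, size, stride)
  sb <- win_stats(b, size, stride)
  sf <- win_stats(f, size, stride)
  ssim_w <- function(sx, sy, cxy)
    ((2 * sx$mu * sy$mu + c1) * (2 * cxy + c2)) /
      ((sx$mu^2 + sy$mu^2 + c1) * (sx$var + sy$var + c2))
  s_ab <- ssim_w(sa, sb, win_cov(a, b, size, stride, sa$mu, sb$mu))
  s_af <- ssim_w(sa, sf, win_cov(a, f, size, stride, sa$mu, sf$mu))
  s_bf <- ssim_w(sb, sf, win_cov(b, f, size, stride, sb$mu, sf$mu))
  den <- sa$var + sb$var
  lam <- ifelse(den < EPS_NUM, 0.5, sa$var / pmax(den, EPS_NUM))
  blend <- lam * s_af + (1 - lam) * s_bf
  mean(ifelse(s_ab >= 0.75, blend, pmax(s_af, s_bf)))
}

sobel_gradients <- function(x) {
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3L, 3L)  # d/dcol
  gx <- conv2_replicate(x, kx)
  gy <- conv2_replicate(x, t(kx))
  list(g = sqrt(gx^2 + gy^2), alpha = atan2(gy, gx))
}

#' Edge-preservation fusion measure (Xydeas-Petrovic)
#'
#' Measures how much Sobel edge strength and orientation each source
#' transfers into the fused image. Relative strength and orientation
#' agreement are mapped through sigmoids (constants Gamma_g = 0.9994,
#' kappa_g = -15, sigma_g = 0.5; Gamma_a = 0.9879, kappa_a = -22,
#' sigma_a = 0.8), their product normalized so that perfect preservation
#' scores 1, and the per-pixel preservation values are averaged with
#' weights \eqn{g^{1.5}} (the edge strength of each source). If neither
#' source contains any edge there is nothing to preserve and the score is
#' defined as 1.
#'
#' @inheritParams mi_measure
#' @return scalar score in [0,1].
#' @export
xydeas_petrovic_measure <- function(a, b, f) {
  assert_same_shape(a, f, "images"); assert_same_shape(b, f, "images")
  gam_g <- 0.9994; kap_g <- -15; sig_g <- 0.5
  gam_a <- 0.9879; kap_a <- -22; sig_a <- 0.8
  l_exp <- 1.5
  ga <- sobel_gradients(a); gb <- sobel_gradients(b)
  gf <- sobel_gradients(f)
  q_xf <- function(gs) {
    hi <- pmax(gs$g, gf$g)
    rel <- ifelse(hi < EPS_NUM, 1, pmin(gs$g, gf$g) / pmax(hi, EPS_NUM))
    # orientation difference folded to [0, pi/2]: gradient sign flips do
    # not count as edge misalignment
    d <- abs(gs$alpha - gf$alpha)
    d <- pmin(d, 2 * pi - d)
    d <- pmin(d, pi - d)
    ang <- 1 - d / (pi / 2)
    qg <- gam_g / (1 + exp(kap_g * (rel - sig_g)))
    qa <- gam_a / (1 + exp(kap_a * (ang - sig_a)))
    qg * qa
  }
  qmax <- (gam_g / (1 + exp(kap_g * (1 - sig_g)))) *
    (gam_a / (1 + exp(kap_a * (1 - sig_a))))
  wa <- ga$g^l_exp; wb <- gb$g^l_exp
  den <- sum(wa) + sum(wb)
  if (den < EPS_NUM) return(1)
  s <- (sum(q_xf(ga) * wa) + sum(q_xf(gb) * wb)) / den / qmax
  min(max(s, 0), 1)
}

# universal quality index per window with degenerate-window rule
uqi_windows <- function(x, y, size, stride) {
  sx <- win_stats(x, size, stride)
  sy <- win_stats(y, size, stride)
  cxy <- win_cov(x, y, size, stride, sx$mu, sy$mu)
  den <- (sx$mu^2 + sy$mu^2) * (sx$var + sy$var)
  q <- ifelse(den < EPS_NUM, 0, 4 * cxy * sx$mu * sy$mu / pmax(den, EPS_NUM))
  # degenerate windows: defined as 1 when the two windows are identical
  mse <- win_mean_valid((x - y)^2, size, stride)
  ifelse(den < EPS_NUM & mse < 1e-20, 1, q)
}

#' Piella-Heijmans fusion quality indices
#'
#' Two sliding-window scores built on the universal quality index
#' \eqn{Q_o}. The first averages the variance-blended window qualities
#' uniformly; the second weights each window by its saliency
#' \eqn{c(w) = \max(\sigma^2_{A,w}, \sigma^2_{B,w})} normalized over all
#' windows, emphasizing high-contrast regions. Both scores are clamped to
#' [0,1]. Degenerate zero-variance windows score 1 when the compared
#' windows are identical and 0 otherwise.
#'
#' @inheritParams ssim_fusion_measure
#' @return named numeric vector \code{c(p1 = ..., p2 = ...)}.
#' @export
piella_measures <- function(a, b, f, size = 8L, stride = 1L) {
  assert_same_shape(a, f, "images"); assert_same_shape(b, f, "images")
  if (size > nrow(f) || size > ncol(f))
    stop("window larger than image", call. = FALSE)
  sa <- win_stats(a, size, stride)
  sb <- win_stats(b, size, stride)
  q_af <- uqi_windows(a, f, size, stride)
  q_bf <- uqi_windows(b, f, size, stride)
  den <- sa$var + sb$var
  lam <- ifelse(den < EPS_NUM, 0.5, sa$var / pmax(den, EPS_NUM))
  blend <- lam * q_af + (1 - lam) * q_bf
  p1 <- mean(blend)
  cw <- pmax(sa$var, sb$var)
  tot <- sum(cw)
  p2 <- if (tot < EPS_NUM) p1 else sum(cw / tot * blend)
  c(p1 = min(max(p1, 0), 1), p2 = min(max(p2, 0), 1))
}

#' Evaluate all fusion quality metrics
#'
#' Computes the full seven-score report for a fusion triple: normalized
#' mutual information, fusion SSIM, Xydeas-Petrovic edge preservation,
#' phase-congruency score, the two Piella-Heijmans indices and the
#' visual-information-fidelity fusion score.
#'
#' @inheritParams mi_measure
#' @param bins histogram bins for the mutual-information score.
#' @param window sliding-window side for the SSIM and Piella scores.
#' @return object of class \code{"metric_report"}: named list with
#'   elements \code{zeta_mi}, \code{zeta_ssim}, \code{zeta_xp},
#'   \code{zeta_z}, \code{zeta_p1}, \code{zeta_p2}, \code{zeta_viff}.
#' @export
evaluate_all <- function(a, b, f, bins = 64L, window = 8L) {
  p <- piella_measures(a, b, f, size = window)
  rep <- list(zeta_mi = mi_measure(a, b, f, bins = bins),
              zeta_ssim = ssim_fusion_measure(a, b, f, size = window),
              zeta_xp = xydeas_petrovic_measure(a, b, f),
              zeta_z = zhao_pc_measure(a, b, f),
              zeta_p1 = unname(p["p1"]), zeta_p2 = unname(p["p2"]),
              zeta_viff = viff_measure(a, b, f))
  class(rep) <- "metric_report"
  rep
}

#' @export
print.metric_report <- function(x, ...) {
  cat("Fusion quality metrics\n")
  lab <- c(zeta_mi = "MI", zeta_ssim = "SSIM", zeta_xp = "XP",
           zeta_z = "Z", zeta_p1 = "P1", zeta_p2 = "P2",
           zeta_viff = "VIFF")
  for (k in names(lab))
    cat(sprintf("  zeta_%-5s %8.4f\n", lab[[k]], x[[k]]))
  invisible(x)
}

#' Write a metric report table
#'
#' Plain tab-separated table with columns metric, scheme, value; one row
#' per metric. Multiple reports (e.g. baseline and improved) may be
#' combined by naming the list elements by scheme.
#'
#' @param reports a single \code{metric_report} or a named list of them.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_metric_report <- function(reports, path) {
  if (inherits(reports, "metric_report"))
    reports <- list(result = reports)
  rows <- do.call(rbind, lapply(names(reports), function(sc) {
    r <- reports[[sc]]
    data.frame(metric = names(unclass(r)), scheme = sc,
               value = unlist(unclass(r), use.names = FALSE))
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
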