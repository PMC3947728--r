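#' Average (box) filter
#'
#' Replaces each pixel by the arithmetic mean of its \code{size} x
#' \code{size} neighborhood under replicate (edge-clamp) padding. This is
#' the smoother used to split an image into base and detail layers.
#'
#' @param img numeric matrix of intensities.
#' @param size odd window side length in pixels.
#' @return matrix of the same shape as \code{img}.
#' @examples
#' x <- matrix(0, 5, 5); x[3, 3] <- 1
#' average_filter(x, 3)
#' @export
average_filter <- function(img, size = 31L) {
  assert_gray(img)
  if (length(size) != 1L || !is.finite(size) || size < 1 || size %% 2 != 1)
    stop("'size' must be a positive odd integer", call. = FALSE)
  box_mean(img, as.integer((size - 1L) %/% 2L))
}

gaussian_kernel_1d <- function(sigma, radius) {
  k <- exp(-(seq.int(-radius, radius))^2 / (2 * sigma^2))
  k / sum(k)
}

#' Gaussian smoothing
#'
#' Convolution with a normalized, truncated 2-D Gaussian kernel (weights sum
#' to one), replicate padding. Separable implementation.
#'
#' @param img numeric matrix.
#' @param sigma Gaussian standard deviation in pixels (> 0).
#' @param radius kernel half-width in pixels; the kernel is
#'   \code{(2*radius+1)} square.
#' @return smoothed matrix, same shape.
#' @export
gaussian_smooth <- function(img, sigma = 5, radius = 5L) {
  assert_gray(img)
  if (length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
    stop("'sigma' must be a positive number", call. = FALSE)
  if (length(radius) != 1L || radius < 1)
    stop("'radius' must be >= 1", call. = FALSE)
  conv_sep_replicate(img, gaussian_kernel_1d(sigma, as.integer(radius)))
}

#' Laplacian response magnitude
#'
#' Absolute response of the 3x3 4-neighbor Laplacian kernel
#' \code{rbind(c(0,1,0), c(1,-4,1), c(0,1,0))} under replicate padding.
#' Used as the raw per-pixel saliency (local detail) measure.
#'
#' @param img numeric matrix.
#' @return non-negative matrix, same shape.
#' @export
laplacian_magnitude <- function(img) {
  assert_gray(img)
  k <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3L, 3L)
  abs(conv2_replicate(img, k))
}

# L2 norm of the Laplacian kernel; propagates a noise std through the
# Laplacian stage (sqrt(1+1+16+1+1)).
LAPLACIAN_L2 <- sqrt(20)

#' Guided filter
#'
#' Edge-preserving smoothing of \code{input} steered by \code{guide},
#' assuming the output is locally a linear transform of the guide within
#' each window. Per window k of half-width \code{radius}:
#' \code{a_k = cov(guide, input) / (var(guide) + eps)},
#' \code{b_k = mean(input) - a_k * mean(guide)}; the output pixel is the
#' mean over all covering windows of \code{a * guide + b}. All window
#' statistics use box filters with replicate padding, so the cost is
#' independent of \code{radius}.
#'
#' @param guide guidance image (numeric matrix).
#' @param input image to filter, same shape as \code{guide}.
#' @param radius window half-width in pixels (>= 1).
#' @param eps regularization added to the window variance (>= 0); larger
#'   values smooth more aggressively.
#' @return filtered matrix, same shape.
#' @export
guided_filter <- function(guide, input, radius = 45L, eps = 0.3) {
  assert_gray(guide, "guide"); assert_gray(input, "input")
  assert_same_shape(guide, input, "'guide' and 'input'")
  if (length(radius) != 1L || radius < 1)
    stop("'radius' must be >= 1", call. = FALSE)
  if (length(eps) != 1L || !is.finite(eps) || eps < 0)
    stop("'eps' must be >= 0", call. = FALSE)
  r <- as.integer(radius)
  mu_i <- box_mean(guide, r)
  mu_p <- box_mean(input, r)
  cov_ip <- box_mean(guide * input, r) - mu_i * mu_p
  var_i <- box_mean(guide * guide, r) - mu_i * mu_i
  a <- cov_ip / (var_i + eps + EPS_NUM)
  b <- mu_p - a * mu_i
  box_mean(a, r) * guide + box_mean(b, r)
}

#' LMMSE estimator for Rician-corrupted magnitude images
#'
#' Closed-form linear minimum mean-square-error estimate of the underlying
#' signal of a magnitude image corrupted by Rician noise, from local 2nd
#' and 4th moments. With M the observed image, \code{<.>} the box mean over
#' the window and \code{s2 = sigma_n^2}, the squared-signal estimate is
#' \deqn{\hat{x}^2 = \max(0, <M^2> - 2 s^2 + K (M^2 - <M^2>))}
#' with adaptive gain
#' \deqn{K = \mathrm{clamp}(1 - 4 s^2 (<M^2> - s^2) /
#'   \max(<M^4> - <M^2>^2, \epsilon), 0, 1)}
#' and the output is \eqn{\sqrt{\hat{x}^2}}. In homogeneous windows K
#' shrinks toward 0 (heavy smoothing plus bias removal); near structure the
#' 4th-moment spread drives K toward 1, preserving detail. With
#' \code{sigma_n = 0} the filter is the identity.
#'
#' @param img non-negative numeric matrix (magnitude data).
#' @param window odd local-moment window side length (>= 3).
#' @param sigma_n Rician noise standard deviation in intensity units, or
#'   the string \code{"estimate"} to infer it with
#'   \code{\link{estimate_noise_sigma}}.
#' @return non-negative matrix, same shape.
#' @export
lmmse_rician_filter <- function(img, window = 7L, sigma_n = "estimate") {
  assert_gray(img)
  if (any(img < 0))
    stop("'img' must be non-negative magnitude data", call. = FALSE)
  if (length(window) != 1L || window < 3 || window %% 2 != 1)
    stop("'window' must be an odd integer >= 3", call. = FALSE)
  if (is.character(sigma_n)) {
    if (!identical(sigma_n, "estimate"))
      stop("'sigma_n' must be a number >= 0 or \"estimate\"", call. = FALSE)
    sigma_n <- estimate_noise_sigma(img, window = window)
  }
  if (length(sigma_n) != 1L || !is.finite(sigma_n) || sigma_n < 0)
    stop("'sigma_n' must be >= 0", call. = FALSE)
  if (sigma_n == 0) return(img)  # noise-free limit: K = 1, exact identity
  r <- as.integer((window - 1L) %/% 2L)
  s2 <- sigma_n^2
  m2 <- img * img
  em2 <- box_mean(m2, r)
  em4 <- box_mean(m2 * m2, r)
  k <- 1 - 4 * s2 * (em2 - s2) / pmax(em4 - em2 * em2, EPS_NUM)
  k <- pmin(pmax(k, 0), 1)
  x2 <- pmax(em2 - 2 * s2 + k * (m2 - em2), 0)
  sqrt(x2)
}

#' Estimate the Rician noise standard deviation
#'
#' Robust estimate of the noise level of a magnitude image from
#' background-dominated regions, where Rician noise reduces to a Rayleigh
#' law with \eqn{E[M^2] = 2\sigma^2}. The local second moment
#' \eqn{\sqrt{<M^2>/2}} is computed over every window; the estimate is the
#' histogram mode of that statistic over the 10\% of windows with lowest
#' local mean.
#'
#' @param img non-negative numeric matrix.
#' @param window odd moment window side (default 7).
#' @param nbins histogram bins used for the mode (default 100).
#' @return estimated sigma (>= 0).
#' @export
estimate_noise_sigma <- function(img, window = 7L, nbins = 100L) {
  assert_gray(img)
  if (any(img < 0)) stop("'img' must be non-negative", call. = FALSE)
  if (nrow(img) < window || ncol(img) < window)
    stop("image smaller than the moment window", call. = FALSE)
  r <- as.integer((window - 1L) %/% 2L)
  mu <- box_mean(img, r)
  m2 <- box_mean(img * img, r)
  thr <- stats::quantile(mu, 0.10, names = FALSE)
  sel <- mu <= thr
  v <- sqrt(pmax(m2[sel], 0) / 2)  # SAT round-off can dip below 0
  if (length(v) == 0L) return(0)
  rng <- range(v)
  if (rng[2] - rng[1] < EPS_NUM) return(v[1])
  # histogram mode over range-scaled bins keeps the estimate homogeneous
  # of degree 1 in the image intensities
  breaks <- seq(rng[1], rng[2], length.out = nbins + 1L)
  h <- findInterval(v, breaks, rightmost.closed = TRUE)
  counts <- tabulate(h, nbins = nbins)
  i <- which.max(counts)
  (breaks[i] + breaks[i + 1L]) / 2
}
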