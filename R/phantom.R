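#' Simulate Rician noise on a magnitude image
#'
#' Corrupts the real and imaginary channels of a complex signal whose
#' magnitude is \code{img} with independent zero-mean Gaussian noise of
#' standard deviation \code{sigma} and returns the noisy magnitude
#' \eqn{\sqrt{(img+\eta_1)^2 + \eta_2^2}}. The resulting noise is
#' Rician: Rayleigh-like in low-intensity regions, Gaussian-like at high
#' intensity, and with a positive mean bias. \code{sigma = 0} returns the
#' input unchanged.
#'
#' @param img numeric matrix in [0,1].
#' @param sigma noise standard deviation in intensity units (>= 0).
#' @param seed integer seed; the caller's RNG state is preserved.
#' @param clip clip the noisy magnitude back to [0,1] (the pipeline
#'   convention). Use \code{FALSE} to study the raw noise law.
#' @return noisy magnitude matrix, same shape.
#' @export
add_rician_noise <- function(img, sigma, seed = 1L, clip = TRUE) {
  assert_gray(img)
  if (length(sigma) != 1L || !is.finite(sigma) || sigma < 0)
    stop("'sigma' must be >= 0", call. = FALSE)
  if (sigma == 0) return(img)
  n <- length(img)
  out <- with_seed(seed, {
    e1 <- matrix(stats::rnorm(n, sd = sigma), nrow(img))
    e2 <- matrix(stats::rnorm(n, sd = sigma), nrow(img))
    sqrt((img + e1)^2 + e2^2)
  })
  if (clip) out <- pmin(out, 1)
  out
}

# smooth raised-cosine taper from 1 (t <= lo) to 0 (t >= hi)
taper <- function(t, lo, hi) {
  u <- pmin(pmax((t - lo) / (hi - lo), 0), 1)
  (1 + cos(pi * u)) / 2
}

gauss_blob <- function(xx, yy, cx, cy, sd) {
  exp(-((xx - cx)^2 + (yy - cy)^2) / (2 * sd^2))
}

#' Generate a co-registered CT-like / MR-like phantom pair
#'
#' Builds a deterministic, seeded pair of complementary 2-D head-like
#' phantoms: the CT channel carries a bright elliptical "skull" ring,
#' sharp dense-structure blobs and only faint soft tissue; the MR channel
#' carries no skull signal (smooth taper at the skull boundary, emulating
#' its lower effective resolution there) but rich interior soft-tissue
#' contrast (seeded blobs, dark ventricles and smooth texture). The MR
#' channel is additionally corrupted with Rician noise of standard
#' deviation \code{sigma}. The pixelwise structure union
#' \code{pmax(ct, mr_clean)} serves as an ideal fusion reference.
#'
#' @param size image side in pixels (>= 64).
#' @param seed integer seed controlling blob layout, texture and noise.
#' @param sigma Rician noise std applied to the MR channel.
#' @param n_blobs number of soft-tissue blobs in the MR interior.
#' @return object of class \code{"phantom_pair"}: list with \code{ct},
#'   \code{mr_clean}, \code{mr_noisy}, \code{ideal_composite},
#'   \code{sigma}, \code{seed}.
#' @examples
#' ph <- generate_phantom_pair(size = 64, seed = 7, sigma = 0.1)
#' range(ph$ct); range(ph$mr_noisy)
#' @export
generate_phantom_pair <- function(size = 256L, seed = 1L, sigma = 0.1,
                                  n_blobs = 5L) {
  if (length(size) != 1L || size < 64)
    stop("'size' must be >= 64", call. = FALSE)
  size <- as.integer(size)
  cx <- seq(-1, 1, length.out = size)
  xx <- matrix(cx, size, size, byrow = TRUE)
  yy <- matrix(cx, size, size)
  # elliptical skull: outer and inner boundaries
  e_out <- (xx / 0.80)^2 + (yy / 0.92)^2
  e_in <- (xx / 0.68)^2 + (yy / 0.80)^2
  ring <- e_out <= 1 & e_in > 1
  interior <- e_in <= 1

  structures <- with_seed(seed, {
    blobs <- matrix(0, size, size)
    for (i in seq_len(n_blobs)) {
      r <- sqrt(stats::runif(1, 0, 0.45))
      th <- stats::runif(1, 0, 2 * pi)
      amp <- stats::runif(1, 0.15, 0.35) * sample(c(-1, 1), 1)
      blobs <- blobs + amp * gauss_blob(xx, yy, r * cos(th) * 0.6,
                                        r * sin(th) * 0.7,
                                        stats::runif(1, 0.05, 0.14))
    }
    tex <- matrix(0, size, size)
    for (i in 1:3) {
      fx <- stats::runif(1, 3, 8); fy <- stats::runif(1, 3, 8)
      tex <- tex + 0.03 * sin(pi * fx * xx + stats::runif(1, 0, 2 * pi)) *
        sin(pi * fy * yy + stats::runif(1, 0, 2 * pi))
    }
    # two sharp dense (calcification-like) structures for the CT channel
    calc <- matrix(0, size, size)
    for (i in 1:2) {
      r <- sqrt(stats::runif(1, 0, 0.3))
      th <- stats::runif(1, 0, 2 * pi)
      d2 <- (xx - r * cos(th) * 0.5)^2 + (yy - r * sin(th) * 0.6)^2
      calc <- calc + (d2 < 0.035^2) * 0.8
    }
    list(blobs = blobs, tex = tex, calc = calc)
  })

  # CT: bright skull ring, sharp dense blobs, faint interior
  ct <- matrix(0, size, size)
  ct[ring] <- 0.95
  ct <- ct + interior * (0.12 + 0.04 * (1 - e_in)) + structures$calc *
    interior
  ct <- clamp01(ct)

  # MR: no skull signal; soft-tissue interior with ventricles, blobs
  # and texture; smooth taper at the skull boundary
  vent <- (((xx - 0.12) / 0.10)^2 + (yy / 0.28)^2 <= 1) |
    (((xx + 0.12) / 0.10)^2 + (yy / 0.28)^2 <= 1)
  mr <- 0.45 + structures$blobs + structures$tex - 0.30 * vent
  mr <- mr * taper(e_in, 0.80, 1.0)
  mr <- clamp01(mr)

  out <- list(ct = ct, mr_clean = mr,
              mr_noisy = add_rician_noise(mr, sigma, seed = seed),
              ideal_composite = pmax(ct, mr),
              sigma = sigma, seed = as.integer(seed))
  class(out) <- "phantom_pair"
  out
}

#' @export
print.phantom_pair <- function(x, ...) {
  cat("Phantom pair: ", nrow(x$ct), " x ", ncol(x$ct),
      " pixels, sigma = ", x$sigma, ", seed = ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Write a phantom pair to disk
#'
#' Writes the four phantom images as 16-bit grayscale TIFF files plus a
#' sidecar text file recording seed, sigma and size.
#'
#' @param pair a \code{phantom_pair}.
#' @param dir output directory (created if missing).
#' @return the directory path, invisibly.
#' @export
write_phantom_pair <- function(pair, dir) {
  if (!inherits(pair, "phantom_pair"))
    stop("'pair' must be a phantom_pair", call. = FALSE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in c("ct", "mr_clean", "mr_noisy", "ideal_composite"))
    write_gray_image(pair[[nm]], file.path(dir, paste0(nm, ".tif")),
                     bits = 16L)
  writeLines(c(paste("seed:", pair$seed),
               paste("sigma:", pair$sigma),
               paste("size:", nrow(pair$ct))),
             file.path(dir, "phantom_metadata.txt"))
  invisible(dir)
}
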