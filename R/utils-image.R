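#' @keywords internal
"_PACKAGE"

# numerical guard used in every denominator
EPS_NUM <- 1e-12

#' Validate a grayscale image matrix
#'
#' Images are plain numeric matrices. Intensities are nominally in [0,1] but
#' intermediate carriers (saliency maps, weight maps before normalization)
#' may hold any finite real value.
#'
#' @param img object to validate.
#' @param arg name used in error messages.
#' @return the validated matrix, invisibly.
#' @keywords internal
assert_gray <- function(img, arg = "img") {
  if (!is.matrix(img) || !is.numeric(img))
    stop(sprintf("'%s' must be a numeric matrix", arg), call. = FALSE)
  if (nrow(img) < 1L || ncol(img) < 1L)
    stop(sprintf("'%s' must have at least one row and one column", arg),
         call. = FALSE)
  if (!all(is.finite(img)))
    stop(sprintf("'%s' contains non-finite values", arg), call. = FALSE)
  invisible(img)
}

assert_same_shape <- function(a, b, what = "images") {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("%s must have identical dimensions (%dx%d vs %dx%d)",
                 what, nrow(a), ncol(a), nrow(b), ncol(b)), call. = FALSE)
  invisible(NULL)
}

# Replicate (edge-clamp) padding by r pixels on every side.
pad_replicate <- function(x, r) {
  if (r == 0L) return(x)
  ri <- c(rep(1L, r), seq_len(nrow(x)), rep(nrow(x), r))
  ci <- c(rep(1L, r), seq_len(ncol(x)), rep(ncol(x), r))
  x[ri, ci, drop = FALSE]
}

# Summed-area table with a leading zero row/column, so that the sum over
# rows a..b, cols c..d of x is S[b+1,d+1] - S[a,d+1] - S[b+1,c] + S[a,c].
sat <- function(x) {
  s <- apply(x, 2L, cumsum)
  if (is.null(dim(s))) s <- matrix(s, nrow = nrow(x))
  s <- t(apply(s, 1L, cumsum))
  if (is.null(dim(s))) s <- matrix(s, ncol = ncol(x))
  rbind(0, cbind(0, s))
}

# Box mean with replicate padding; window is (2r+1) x (2r+1).
# O(N) in the number of pixels, independent of r.
box_mean <- function(x, r) {
  if (r == 0L) return(x)
  n <- nrow(x); m <- ncol(x)
  s <- sat(pad_replicate(x, r))
  hi_r <- (2L * r + 2L):(n + 2L * r + 1L); lo_r <- 1:n
  hi_c <- (2L * r + 2L):(m + 2L * r + 1L); lo_c <- 1:m
  (s[hi_r, hi_c, drop = FALSE] - s[lo_r, hi_c, drop = FALSE] -
     s[hi_r, lo_c, drop = FALSE] + s[lo_r, lo_c, drop = FALSE]) /
    (2 * r + 1)^2
}

# Valid-window (no padding) means of all size x size windows, then strided.
# Returns a (n-size+1)/stride x (m-size+1)/stride grid of window means.
win_mean_valid <- function(x, size, stride = 1L) {
  n <- nrow(x); m <- ncol(x)
  if (size > n || size > m)
    stop("window larger than image", call. = FALSE)
  s <- sat(x)
  ri <- seq.int(1L, n - size + 1L, by = stride)
  ci <- seq.int(1L, m - size + 1L, by = stride)
  (s[ri + size, ci + size, drop = FALSE] - s[ri, ci + size, drop = FALSE] -
     s[ri + size, ci, drop = FALSE] + s[ri, ci, drop = FALSE]) / size^2
}

# Separable convolution with replicate padding. k is a 1-D kernel applied
# along rows then columns (outer-product 2-D kernel).
conv_sep_replicate <- function(x, k) {
  r <- (length(k) - 1L) %/% 2L
  p <- pad_replicate(x, r)
  n <- nrow(x); m <- ncol(x)
  # rows direction (vertical)
  tmp <- matrix(0, n, m + 2L * r)
  for (i in seq_along(k))
    tmp <- tmp + k[i] * p[(i - 1L) + seq_len(n), , drop = FALSE]
  out <- matrix(0, n, m)
  for (j in seq_along(k))
    out <- out + k[j] * tmp[, (j - 1L) + seq_len(m), drop = FALSE]
  out
}

# Full (non-separable) 2-D convolution with replicate padding; kernel must
# be odd-sized in both dimensions. Used for small fixed kernels only.
conv2_replicate <- function(x, kernel) {
  kr <- (nrow(kernel) - 1L) %/% 2L
  kc <- (ncol(kernel) - 1L) %/% 2L
  stopifnot(kr * 2L + 1L == nrow(kernel), kc * 2L + 1L == ncol(kernel))
  r <- max(kr, kc)
  p <- pad_replicate(x, r)
  n <- nrow(x); m <- ncol(x)
  out <- matrix(0, n, m)
  for (i in seq_len(nrow(kernel))) {
    di <- i - 1L + (r - kr)
    for (j in seq_len(ncol(kernel))) {
      if (kernel[i, j] == 0) next
      dj <- j - 1L + (r - kc)
      out <- out + kernel[i, j] * p[di + seq_len(n), dj + seq_len(m),
                                    drop = FALSE]
    }
  }
  out
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Run code with a private RNG stream, restoring the caller's state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(),
                       inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}
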