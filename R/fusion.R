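#' Default multi-level weight table
#'
#' Graded weight levels assigned from the normalized saliency difference
#' at pixels where one source dominates: differences of at least 0.30 give
#' full weight 1, then 0.8, 0.7 and 0.6 at thresholds 0.25, 0.20 and 0.15,
#' and 0 otherwise. Thresholds must be strictly decreasing and levels
#' non-increasing within [0,1].
#'
#' @param thresholds decreasing saliency-difference thresholds.
#' @param levels weights assigned at each threshold.
#' @param default level used when no threshold is reached.
#' @return object of class \code{"weight_level_table"}.
#' @export
weight_level_table <- function(thresholds = c(0.30, 0.25, 0.20, 0.15),
                               levels = c(1, 0.8, 0.7, 0.6),
                               default = 0) {
  if (length(thresholds) != length(levels) || length(thresholds) < 1L)
    stop("'thresholds' and 'levels' must be non-empty and equal length",
         call. = FALSE)
  if (any(diff(thresholds) >= 0))
    stop("'thresholds' must be strictly decreasing", call. = FALSE)
  if (any(diff(levels) > 0))
    stop("'levels' must be non-increasing", call. = FALSE)
  if (any(levels < 0 | levels > 1) || default < 0 || default > 1)
    stop("levels must lie in [0,1]", call. = FALSE)
  structure(list(thresholds = as.numeric(thresholds),
                 levels = as.numeric(levels),
                 default = as.numeric(default)),
            class = "weight_level_table")
}

#' Fusion pipeline configuration
#'
#' Collects every tunable parameter of the two fusion pipelines. The
#' defaults follow the guided-filter fusion lineage: a 31x31 average
#' filter for the two-scale split, an 11x11 Gaussian (sigma 5) for the
#' baseline saliency smoother, a 7x7 LMMSE moment window, and guided
#' filter parameters (r1 = 45, eps1 = 0.3) for base-layer weights and
#' (r2 = 7, eps2 = 1e-6) for detail-layer weights.
#'
#' @param scheme \code{"improved"} (LMMSE saliency + multi-level weights)
#'   or \code{"gff"} (Gaussian saliency + binary weights).
#' @param avg_size odd side of the average filter for base/detail split.
#' @param gaussian_sigma,gaussian_radius baseline saliency smoother.
#' @param lmmse_window odd LMMSE moment window side.
#' @param lmmse_sigma noise std of the MR input in intensity units, or
#'   \code{"estimate"}.
#' @param guided_base,guided_detail lists with \code{radius} and
#'   \code{eps} for the two guided-filter passes.
#' @param weight_levels a \code{\link{weight_level_table}}.
#' @param tie_policy tie handling when saliencies are equal; the first
#'   image wins.
#' @param normalize_saliency jointly rescale the saliency pair to [0,1]
#'   before weight assignment so the level thresholds have a fixed scale.
#' @return object of class \code{"fusion_config"}.
#' @export
fusion_config <- function(scheme = c("improved", "gff"),
                          avg_size = 31L,
                          gaussian_sigma = 5,
                          gaussian_radius = 5L,
                          lmmse_window = 7L,
                          lmmse_sigma = "estimate",
                          guided_base = list(radius = 45L, eps = 0.3),
                          guided_detail = list(radius = 7L, eps = 1e-6),
                          weight_levels = weight_level_table(),
                          tie_policy = "first_image",
                          normalize_saliency = TRUE) {
  scheme <- match.arg(scheme)
  tie_policy <- match.arg(tie_policy, "first_image")
  if (!inherits(weight_levels, "weight_level_table"))
    weight_levels <- do.call(weight_level_table, as.list(weight_levels))
  cfg <- list(scheme = scheme, avg_size = as.integer(avg_size),
              gaussian_sigma = gaussian_sigma,
              gaussian_radius = as.integer(gaussian_radius),
              lmmse_window = as.integer(lmmse_window),
              lmmse_sigma = lmmse_sigma,
              guided_base = guided_base, guided_detail = guided_detail,
              weight_levels = weight_levels, tie_policy = tie_policy,
              normalize_saliency = isTRUE(normalize_saliency))
  class(cfg) <- "fusion_config"
  cfg
}

#' @export
print.fusion_config <- function(x, ...) {
  cat("Fusion configuration (", x$scheme, " scheme)\n", sep = "")
  cat("  average filter:", x$avg_size, "x", x$avg_size, "\n")
  cat("  gaussian: sigma", x$gaussian_sigma, ", radius",
      x$gaussian_radius, "\n")
  cat("  lmmse: window", x$lmmse_window, ", sigma_n",
      format(x$lmmse_sigma), "\n")
  cat("  guided base: r =", x$guided_base$radius, ", eps =",
      x$guided_base$eps, "\n")
  cat("  guided detail: r =", x$guided_detail$radius, ", eps =",
      x$guided_detail$eps, "\n")
  wl <- x$weight_levels
  cat("  weight levels:",
      paste(sprintf("(%.2f -> %.2f)", wl$thresholds, wl$levels),
            collapse = " "),
      "otherwise", wl$default, "\n")
  invisible(x)
}

#' Two-scale base/detail decomposition
#'
#' Splits an image into a low-frequency base layer (average-filtered) and
#' a residual detail layer. The layers sum back to the input exactly.
#'
#' @param img numeric matrix.
#' @param cfg a \code{\link{fusion_config}} (only \code{avg_size} is used).
#' @return list with components \code{base} and \code{detail}.
#' @export
two_scale_decompose <- function(img, cfg = fusion_config()) {
  base <- average_filter(img, cfg$avg_size)
  list(base = base, detail = img - base)
}

#' Baseline saliency map
#'
#' Gaussian-smoothed magnitude of the Laplacian response: the detail
#' measure of the baseline guided-filter fusion scheme.
#'
#' @inheritParams two_scale_decompose
#' @return non-negative matrix.
#' @export
saliency_gff <- function(img, cfg = fusion_config()) {
  gaussian_smooth(laplacian_magnitude(img),
                  sigma = cfg$gaussian_sigma, radius = cfg$gaussian_radius)
}

#' Noise-robust saliency map
#'
#' Applies the Rician LMMSE estimator to the Laplacian-magnitude map
#' instead of a Gaussian smoother, suppressing noise-driven saliency in
#' homogeneous regions while retaining structural detail. The configured
#' noise sigma is given in image-intensity units; it is scaled by the L2
#' norm of the Laplacian kernel (sqrt(20)) to match the noise level in the
#' Laplacian-magnitude domain. \code{sigma_n} overrides the configured
#' value when supplied.
#'
#' @inheritParams two_scale_decompose
#' @param sigma_n optional noise std override (image-intensity units), or
#'   \code{"estimate"}.
#' @return non-negative matrix.
#' @export
saliency_lmmse <- function(img, cfg = fusion_config(), sigma_n = NULL) {
  if (is.null(sigma_n)) sigma_n <- cfg$lmmse_sigma
  if (is.character(sigma_n)) sigma_n <- estimate_noise_sigma(img)
  lmmse_rician_filter(laplacian_magnitude(img),
                      window = cfg$lmmse_window,
                      sigma_n = sigma_n * LAPLACIAN_L2)
}

#' Jointly normalize a saliency pair to [0,1]
#'
#' Divides both maps by their joint maximum so the graded weight-level
#' thresholds act on a fixed scale. All-zero pairs pass through unchanged.
#'
#' @param s1,s2 non-negative saliency maps, same shape.
#' @return list with components \code{s1} and \code{s2}.
#' @export
normalize_saliency_pair <- function(s1, s2) {
  assert_gray(s1, "s1"); assert_gray(s2, "s2")
  assert_same_shape(s1, s2, "saliency maps")
  m <- max(max(s1), max(s2))
  if (m < EPS_NUM) return(list(s1 = s1 * 0, s2 = s2 * 0))
  list(s1 = s1 / m, s2 = s2 / m)
}

#' Binary (winner-take-all) weight maps
#'
#' The baseline rule: weight 1 where a source's saliency is at least the
#' other's, 0 elsewhere. Ties are awarded to the first image so the two
#' maps sum to one everywhere.
#'
#' @param s1,s2 saliency maps, same shape.
#' @param tie_policy only \code{"first_image"} is supported.
#' @return list with components \code{p1} and \code{p2}.
#' @export
binary_weight_maps <- function(s1, s2, tie_policy = "first_image") {
  assert_same_shape(s1, s2, "saliency maps")
  match.arg(tie_policy, "first_image")
  p1 <- (s1 >= s2) * 1
  list(p1 = p1, p2 = 1 - p1)
}

# vectorized level lookup: largest table threshold <= delta wins
weight_level_lookup <- function(delta, table) {
  asc <- rev(table$thresholds)               # ascending for findInterval
  lev <- c(table$default, rev(table$levels)) # index 0 -> default
  idx <- findInterval(delta, asc)            # thresholds are inclusive
  matrix(lev[idx + 1L], nrow(delta), ncol(delta))
}

#' Graded multi-level weight maps
#'
#' Where the first source dominates (\code{s1 >= s2}) its weight is the
#' table level matched by the saliency margin \code{s1 - s2} and the other
#' weight is 0, and symmetrically where the second dominates. Margins
#' below every threshold leave both weights at the table default (0),
#' deferring the decision to the post-refinement renormalization.
#'
#' @param s1,s2 saliency maps on the normalized [0,1] scale.
#' @param table a \code{\link{weight_level_table}}.
#' @return list with components \code{p1} and \code{p2}.
#' @export
multilevel_weight_maps <- function(s1, s2, table = weight_level_table()) {
  assert_same_shape(s1, s2, "saliency maps")
  if (!inherits(table, "weight_level_table"))
    stop("'table' must be a weight_level_table", call. = FALSE)
  d <- s1 - s2
  first <- d >= 0
  lev_ab <- weight_level_lookup(pmax(d, 0), table)
  lev_ba <- weight_level_lookup(pmax(-d, 0), table)
  p1 <- ifelse(first, lev_ab, 0)
  p2 <- ifelse(first, 0, lev_ba)
  list(p1 = p1, p2 = p2)
}

#' Normalize a refined weight-map set
#'
#' Clamps each map to [0,1], then renormalizes the base pair and the
#' detail pair to sum to one pixelwise. Pixels where a pair sums to
#' (numerically) zero fall back to an even 0.5/0.5 split.
#'
#' @param w list with \code{base_A}, \code{base_B}, \code{detail_A},
#'   \code{detail_B} matrices.
#' @return list of the same shape with normalized maps.
#' @export
normalize_weight_set <- function(w) {
  pair_norm <- function(a, b) {
    a <- clamp01(a); b <- clamp01(b)
    s <- a + b
    dead <- s < EPS_NUM
    s[dead] <- 1
    a <- a / s; b <- b / s
    a[dead] <- 0.5; b[dead] <- 0.5
    list(a = a, b = b)
  }
  bs <- pair_norm(w$base_A, w$base_B)
  dt <- pair_norm(w$detail_A, w$detail_B)
  list(base_A = bs$a, base_B = bs$b, detail_A = dt$a, detail_B = dt$b)
}

#' Guided refinement of weight maps
#'
#' Each raw weight map is filtered twice with the source image as guide:
#' once with the large/strong base-layer parameters and once with the
#' small/weak detail-layer parameters, aligning weight transitions with
#' image edges. The result is renormalized with
#' \code{\link{normalize_weight_set}}.
#'
#' @param p1,p2 raw weight maps for sources A and B.
#' @param a,b source images (guides), same shape.
#' @param cfg a \code{\link{fusion_config}}.
#' @return normalized weight-map set (list of four matrices).
#' @export
refine_weights <- function(p1, p2, a, b, cfg = fusion_config()) {
  assert_same_shape(p1, a, "weight map and source")
  assert_same_shape(p2, b, "weight map and source")
  assert_same_shape(a, b, "sources")
  gb <- cfg$guided_base; gd <- cfg$guided_detail
  raw <- list(
    base_A = guided_filter(a, p1, gb$radius, gb$eps),
    base_B = guided_filter(b, p2, gb$radius, gb$eps),
    detail_A = guided_filter(a, p1, gd$radius, gd$eps),
    detail_B = guided_filter(b, p2, gd$radius, gd$eps))
  normalize_weight_set(raw)
}

#' Weighted reconstruction of the fused image
#'
#' Weighted sum of the base and detail layers of both sources under a
#' normalized weight-map set, clipped to [0,1].
#'
#' @param w normalized weight-map set.
#' @param decomp_a,decomp_b two-scale decompositions of the sources.
#' @return fused image matrix in [0,1].
#' @export
reconstruct <- function(w, decomp_a, decomp_b) {
  assert_same_shape(decomp_a$base, decomp_b$base, "decompositions")
  f <- w$base_A * decomp_a$base + w$base_B * decomp_b$base +
    w$detail_A * decomp_a$detail + w$detail_B * decomp_b$detail
  clamp01(f)
}

#' Fuse two co-registered grayscale images
#'
#' Runs one of the two fusion pipelines on a pair of same-size grayscale
#' images in [0,1]. By convention the first input \code{a} is the (noisy)
#' MR image and the second input \code{b} is the CT image.
#'
#' The \code{"gff"} scheme is the baseline: average-filter two-scale
#' split, Gaussian-smoothed Laplacian saliency, binary winner-take-all
#' weight maps, guided refinement and weighted reconstruction. The
#' \code{"improved"} scheme replaces the Gaussian saliency smoother with
#' the Rician LMMSE estimator (applied with the configured noise sigma on
#' the MR input and sigma = 0 on the CT input, which is treated as
#' noise-free) and the binary maps with graded multi-level maps on the
#' jointly normalized saliency pair.
#'
#' @param a first source image (MR), numeric matrix in [0,1].
#' @param b second source image (CT), same shape.
#' @param cfg a \code{\link{fusion_config}}.
#' @return object of class \code{"fused_image"}: a list with the fused
#'   image \code{fused}, the saliency maps, raw and refined weight maps,
#'   decompositions, and the configuration used.
#' @examples
#' ph <- generate_phantom_pair(size = 64, seed = 1, sigma = 0.1)
#' fz <- fuse_images(ph$mr_noisy, ph$ct, fusion_config("improved",
#'   avg_size = 15, guided_base = list(radius = 11, eps = 0.3),
#'   guided_detail = list(radius = 3, eps = 1e-6)))
#' fz
#' @export
fuse_images <- function(a, b, cfg = fusion_config()) {
  assert_gray(a, "a"); assert_gray(b, "b")
  assert_same_shape(a, b, "source images")
  if (!inherits(cfg, "fusion_config"))
    stop("'cfg' must be a fusion_config", call. = FALSE)
  da <- two_scale_decompose(a, cfg)
  db <- two_scale_decompose(b, cfg)
  if (cfg$scheme == "gff") {
    s1 <- saliency_gff(a, cfg)
    s2 <- saliency_gff(b, cfg)
    if (cfg$normalize_saliency) {
      ns <- normalize_saliency_pair(s1, s2); s1 <- ns$s1; s2 <- ns$s2
    }
    p <- binary_weight_maps(s1, s2, cfg$tie_policy)
  } else {
    sig <- cfg$lmmse_sigma
    if (is.character(sig)) sig <- estimate_noise_sigma(a)
    s1 <- saliency_lmmse(a, cfg, sigma_n = sig)
    s2 <- saliency_lmmse(b, cfg, sigma_n = 0)
    if (cfg$normalize_saliency) {
      ns <- normalize_saliency_pair(s1, s2); s1 <- ns$s1; s2 <- ns$s2
    }
    p <- multilevel_weight_maps(s1, s2, cfg$weight_levels)
  }
  w <- refine_weights(p$p1, p$p2, a, b, cfg)
  f <- reconstruct(w, da, db)
  structure(list(fused = f, saliency = list(s1 = s1, s2 = s2),
                 raw_weights = p, weights = w,
                 decomp_a = da, decomp_b = db, config = cfg),
            class = "fused_image")
}

#' @export
print.fused_image <- function(x, ...) {
  cat("Fused image (", x$config$scheme, " scheme), ",
      nrow(x$fused), " x ", ncol(x$fused), " pixels\n", sep = "")
  cat("  intensity range: [",
      format(min(x$fused), digits = 4), ", ",
      format(max(x$fused), digits = 4), "]\n", sep = "")
  invisible(x)
}

#' @export
summary.fused_image <- function(object, ...) {
  f <- object$fused
  cat("Fused image summary (", object$config$scheme, " scheme)\n",
      sep = "")
  cat("  size:", nrow(f), "x", ncol(f), "\n")
  cat("  mean intensity:", format(mean(f), digits = 4), "\n")
  cat("  mean base weight on A:",
      format(mean(object$weights$base_A), digits = 4), "\n")
  cat("  mean detail weight on A:",
      format(mean(object$weights$detail_A), digits = 4), "\n")
  invisible(object)
}

#' @export
plot.fused_image <- function(x, ...) {
  op <- graphics::par(mar = c(0.5, 0.5, 2, 0.5))
  on.exit(graphics::par(op))
  graphics::image(t(x$fused[nrow(x$fused):1, , drop = FALSE]),
                  col = grDevices::gray.colors(256, 0, 1), axes = FALSE,
                  main = paste0("fused (", x$config$scheme, ")"), ...)
  invisible(x)
}
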