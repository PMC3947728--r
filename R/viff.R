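# Visual-information-fidelity fusion score: 4-level difference-of-
# Gaussians subbands, non-overlapping blocks, scalar Gaussian-scale-
# mixture / additive-noise information model per block, per-block source
# selection by reference information, subband-weighted combination.

dog_subbands <- function(img, nlevels = 4L) {
  prev <- img
  out <- vector("list", nlevels)
  for (k in seq_len(nlevels)) {
    sig <- 2^(k - 1L)
    blurred <- gaussian_smooth(img, sigma = sig,
                               radius = as.integer(ceiling(2.5 * sig)))
    out[[k]] <- prev - blurred
    prev <- blurred
  }
  out
}

# per-block VIF information terms for one source band C against the
# fused band D; returns matrices of distorted (vid) and reference (vind)
# information per block
vif_block_info <- function(cband, dband, block, sigma_nsq) {
  sc <- win_stats(cband, block, block)
  sd_ <- win_stats(dband, block, block)
  cov_cd <- win_cov(cband, dband, block, block, sc$mu, sd_$mu)
  g <- cov_cd / (sc$var + EPS_NUM)
  g <- pmax(g, 0)
  sv <- pmax(sd_$var - g * cov_cd, EPS_NUM)
  list(vid = log2(1 + g^2 * sc$var / (sv + sigma_nsq)),
       vind = log2(1 + sc$var / sigma_nsq))
}

#' Visual-information-fidelity fusion measure
#'
#' Multi-resolution information-theoretic fusion score. Source and fused
#' images are decomposed into four difference-of-Gaussians subbands
#' (Gaussian scales 1, 2, 4, 8 pixels) and partitioned into 8x8 blocks.
#' In each block the visual information of the fused band about the
#' better source band (the one with larger reference information) is
#' computed under a Gaussian-scale-mixture signal / additive-noise
#' observation model with noise variance \code{sigma_nsq}. Each subband
#' score is the ratio of summed fused-image information to summed
#' reference information, and the overall score combines the subbands
#' with weights \code{weights} (summing to 1). The score is clamped to
#' [0,1]; identical source and fused images score 1.
#'
#' @inheritParams mi_measure
#' @param sigma_nsq visual-noise variance of the information model.
#' @param weights subband weights, finest to coarsest, summing to 1.
#' @param block block side in pixels.
#' @return scalar score in [0,1].
#' @export
viff_measure <- function(a, b, f, sigma_nsq = 0.005,
                         weights = c(0.50, 0.25, 0.15, 0.10),
                         block = 8L) {
  assert_same_shape(a, f, "images"); assert_same_shape(b, f, "images")
  if (nrow(f) < 32L || ncol(f) < 32L)
    stop("images must be at least 32x32 for the subband decomposition",
         call. = FALSE)
  if (abs(sum(weights) - 1) > 1e-9)
    stop("'weights' must sum to 1", call. = FALSE)
  nlev <- length(weights)
  sa <- dog_subbands(a, nlev)
  sb <- dog_subbands(b, nlev)
  sf <- dog_subbands(f, nlev)
  score <- 0
  for (k in seq_len(nlev)) {
    ia <- vif_block_info(sa[[k]], sf[[k]], block, sigma_nsq)
    ib <- vif_block_info(sb[[k]], sf[[k]], block, sigma_nsq)
    use_a <- ia$vind >= ib$vind
    vid <- ifelse(use_a, ia$vid, ib$vid)
    vind <- ifelse(use_a, ia$vind, ib$vind)
    tot <- sum(vind)
    ratio <- if (tot < EPS_NUM) {
      # no information in any block: score by exact band agreement
      ref <- ifelse(use_a, sa[[k]], sb[[k]])
      if (max(abs(ref - sf[[k]])) < 1e-9) 1 else 0
    } else sum(vid) / tot
    score <- score + weights[k] * ratio
  }
  min(max(score, 0), 1)
}
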