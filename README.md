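# guidedfusion

Pixel-level fusion of co-registered CT and MR images in R, for anyone who
needs a single image combining the bone detail of CT with the soft-tissue
contrast of (possibly noisy) MR: medical-imaging researchers, method
developers benchmarking fusion algorithms, and teaching settings.

## The method

Each source image `X` is split at two scales by an average filter `f`:

    base_X   = X * f
    detail_X = X − base_X

Per-pixel saliency maps `S = smooth(|X * h|)` (Laplacian kernel `h`)
decide, pixel by pixel, which source should dominate. Raw weight maps are
refined with a guided filter `G_{r,ε}(P, X)` — an edge-preserving
smoother that keeps weight transitions aligned with image edges — then
renormalized pairwise, and the fused image is

    F = W_base_A · base_A + W_base_B · base_B
      + W_detail_A · detail_A + W_detail_B · detail_B

Two schemes are provided:

* **`gff`** — the classic guided-filter fusion baseline: Gaussian
  saliency smoothing, binary (winner-take-all) weight maps.
* **`improved`** — designed for Rician-noisy MR input: the Gaussian
  smoother is replaced by a local LMMSE estimator for Rician magnitude
  data (which removes the `2σ²` noise-energy bias in flat regions while
  keeping detail), and the binary maps are replaced by graded levels of
  the normalized saliency margin Δ: weight 1 for Δ ≥ 0.30, then 0.8,
  0.7, 0.6 at 0.25, 0.20, 0.15, and an even blend below that.

A suite of seven objective fusion metrics (ζ_MI, ζ_SSIM, ζ_XP, ζ_Z,
ζ_P1, ζ_P2, ζ_VIFF), a seeded CT/MR phantom generator with a Rician
noise simulator, PNG/TIFF I/O and a CLI round out the package. See the
methods vignette (`vignettes/guided-fusion-methods.Rmd`) for the full
model description and design rationale.

## Worked example

```r
library(guidedfusion)

ph <- generate_phantom_pair(size = 256, seed = 3, sigma = 0.1)
f_imp <- fuse_images(ph$mr_noisy, ph$ct, fusion_config("improved"))
f_imp
#> Fused image (improved scheme), 256 x 256 pixels
#>   intensity range: [0, 0.9982]

f_gff <- fuse_images(ph$mr_noisy, ph$ct, fusion_config("gff"))
evaluate_all(ph$mr_noisy, ph$ct, f_gff$fused)
#> Fusion quality metrics
#>   zeta_MI      0.7429
#>   zeta_SSIM    0.9095
#>   zeta_XP      0.4671
#>   zeta_Z       0.2913
#>   zeta_P1      0.8395
#>   zeta_P2      0.4265
#>   zeta_VIFF    0.4592
evaluate_all(ph$mr_noisy, ph$ct, f_imp$fused)
#> Fusion quality metrics
#>   zeta_MI      0.7294
#>   zeta_SSIM    0.8385
#>   zeta_XP      0.8998
#>   zeta_Z       0.7458
#>   zeta_P1      0.7906
#>   zeta_P2      0.8953
#>   zeta_VIFF    0.8062
```

The phantom pairs a CT channel (bright skull ring, dense blobs, faint
interior) with a Rician-noisy MR channel (rich soft-tissue interior, no
skull). Higher is better for every metric: on this noisy pair the
improved scheme transfers substantially more edge information (ζ_XP),
phase structure (ζ_Z), saliency-weighted quality (ζ_P2) and visual
information (ζ_VIFF) than the baseline, whose binary weights chase noise
in the MR channel.

## Command line

```sh
Rscript inst/cli/guidedfuse.R demo --seed 1 --outdir out/
Rscript inst/cli/guidedfuse.R fuse --mr mr.png --ct ct.png \
    --scheme improved --out fused.png --report metrics.tsv
Rscript inst/cli/guidedfuse.R evaluate --mr mr.png --ct ct.png \
    --fused fused.png --report metrics.tsv
Rscript inst/cli/guidedfuse.R phantom --size 256 --sigma 0.1 --seed 7 \
    --outdir phantom/
```

(After installation the script is also available under
`system.file("cli", "guidedfuse.R", package = "guidedfusion")`.)

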