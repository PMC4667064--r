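# amfuse

Spatial-domain, pixel-level fusion of co-registered grayscale image pairs —
the CT + MRI situation, where two modalities of the same anatomy carry
complementary information and a clinician wants one image with the locally
most informative content of each. `amfuse` is for image-analysis
practitioners who need a fast, deterministic fusion rule with auditable
intermediates (filter response, saliency maps, decision map) plus the two
standard objective fusion metrics to score results.

## Method

For each source image `I` (normalized to [0, 1]):

* **AMF** — an edge-preserving *adaptive manifold filter* response: the
  image is projected onto K smooth manifolds in the joint space–range
  domain with Gaussian range weights `exp(-(η - f)²/σ_r²)`, blurred along
  each manifold at spatial scale `σ_s`, and gathered as a normalized ratio.
  This is the local background term `L_B`.
* **MSF** — the *modified spatial frequency* on a sliding 3×3 window:
  `MSF = sqrt(SF² + DF²)`, the RMS first-difference energy along rows,
  columns and both diagonals. This is the local detail term `L_H`.
* **MLC** — the *modified local contrast* `MLC = MSF / AMF` (with
  `MLC = MSF` where the filter response is exactly zero).

The decision map selects, per pixel, the source with the larger contrast —
`D(i,j) = 1` if `MLC^x ≥ MLC^y`, else `0` — and the fused image is the pure
selection `F = I^x·D + I^y·(1−D)`: every fused pixel is a bitwise copy of a
source pixel. Defaults are `σ_s = 14` px, `σ_r = 0.10`, window radius 1.

Quality is scored by total mutual information
`MI = MI(x:F) + MI(y:F)` (256-bin joint histograms, bits) and by the
edge-preservation index `Q^AB/F ∈ [0,1]` (Sobel edge strength/orientation
transfer through the reference sigmoid constants; its attainable ceiling is
0.9748, see the vignette).

## Worked example

```r
library(amfuse)

p <- generate_phantom_pair(size = 256, seed = 1, noise_sigma = 0.01)
p
#> phantom_pair: 256 x 256, seed 1, noise sigma 0.01; mask_x 6.3%, mask_y 10.2% of pixels

res <- fuse(p$img_x, p$img_y)   # sigma_s = 14, sigma_r = 0.10
res
#> fusion_result: 256 x 256; 46.8% of pixels taken from source x

decision_accuracy(res$decision, p$mask_x, p$mask_y)
#> [1] 0.9712

avg <- fuse_average(p$img_x, p$img_y)
fusion_mutual_information(p$img_x, p$img_y, res$fused)  # 5.6843 bits
fusion_mutual_information(p$img_x, p$img_y, avg)        # 4.5892 bits
edge_similarity(p$img_x, p$img_y, res$fused)            # 0.6040
edge_similarity(p$img_x, p$img_y, avg)                  # 0.3630
```

The phantom pair puts bone-like structure (ring, trabecular disc) in
modality A and soft-tissue texture in modality B over a shared low-contrast
background. The decision map recovers the truly dominant modality on 97% of
interior ground-truth pixels, and the selective fusion beats pixel
averaging on both metrics: averaging halves the amplitude of any structure
present in only one modality, which costs it ~1.1 bits of MI and ~0.24 of
`Q^AB/F` here.

### Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "amfuse.R", package = "amfuse"))')
Rscript "$CLI" phantom --out-prefix p --seed 7
Rscript "$CLI" fuse p_x.png p_y.png -o fused.png --decision-map d.png
Rscript "$CLI" metrics p_x.png p_y.png fused.png
# MI=6.126883
# QABF=0.709346
```

Inputs are 8/16-bit grayscale PNG or TIFF; all commands are deterministic
given their inputs and flags, and parameters may also come from a flat YAML
config file (flags win).

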