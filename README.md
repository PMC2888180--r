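# fibrilmorph

Quantitative morphometry of fibrillar networks — such as extracellular
collagen fibrils in scanning electron micrographs of cartilage — from
grayscale raster images.

Tissue degradation (enzymatic cleavage, osteoarthritis, culture at
non-physiological oxygen levels) leaves a structural signature in the
collagen network: fibrils become more tangled, more branched, less straight.
`fibrilmorph` measures that signature. It reduces a micrograph to a
one-pixel-wide fibril skeleton (Canny edge detection → morphological closing
→ topology-preserving thinning), decomposes the skeleton into a graph of
endpoints, junctions and line segments, and summarizes each specimen with
two statistics:

* **Bending ratio** — the mean-squared end-to-end distance of the skeleton
  segments divided by their mean-squared contour length,
  `BR = ⟨R²⟩ / ⟨L²⟩`. Exactly 1 for perfectly straight segments; lower for
  curved, tangled networks.
* **Persistence length (Lp)** — the arc length over which a fibril's tangent
  direction decorrelates, estimated under the planar worm-like-chain model,
  either from the end-to-end scaling law
  `⟨R²(s)⟩ = 4·Lp·s − 8·Lp²·(1 − e^(−s/(2·Lp)))` or from the tangent
  correlation `⟨cos θ(s)⟩ = e^(−s/(2·Lp))`.

Group comparisons (Mann-Whitney for two conditions, one-way ANOVA with
Bonferroni post hoc tests for more) operate on per-image summaries.

Because raw micrographs of this kind are rarely available, the package
includes a synthetic worm-like-chain fibril-image generator with known
ground truth (`synthetic_image_spec()`, `generate_dataset()`), so the whole
chain — simulation → extraction → measurement → statistics — is validated by
parameter recovery. See the vignette (`vignettes/fibril-morphometry.Rmd`)
for the model, the estimators, the numerical corrections and the known
limitations.

## Worked example

A two-condition in-silico experiment — a "healthy-like" network (persistence
length 100 px, branch probability 0.005 per step) against a "degraded-like"
network (30 px, 0.05) — with 10 images per condition:

```r
library(fibrilmorph)

cfg <- pipeline_config(seed = 42)
res <- run_pipeline(cfg, conditions = list(
  healthy  = list(persistence_length = 100, branch_probability = 0.005),
  degraded = list(persistence_length = 30,  branch_probability = 0.05)
), n_images = 10)
print(res)
#> <pipeline_result> 2 condition(s), 20 image summaries
#>   healthy: 56 segments, bending ratio 0.7816, Lp 90.3 px
#>   degraded: 194 segments, bending ratio 0.7310, Lp 21.7 px
#>   bending_ratio: mann_whitney p = 0.4274
#>   persistence_length: mann_whitney p = 0.0002461
```

Reading the output: the degraded condition fragments into many more
segments (194 vs 56 — branching creates junctions, and junctions cut
fibrils), its pooled bending ratio drops from 0.78 to 0.73, and its
estimated persistence length collapses from 90 px to 22 px (the generating
values were 100 and 30 px; at 10 images the per-image persistence length
separates cleanly, p ≈ 2e-4, while the noisier per-image bending ratio does
not yet reach significance — it does at 30 images per condition, the size
used in the validation suite). Percent reductions relative to the healthy
condition:

```r
su <- res$summaries
relative_change(mean(su$bending_ratio[su$condition == "healthy"], na.rm = TRUE),
                mean(su$bending_ratio[su$condition == "degraded"], na.rm = TRUE))
#> [1] 4.652937
relative_change(mean(su$persistence_length[su$condition == "healthy"], na.rm = TRUE),
                mean(su$persistence_length[su$condition == "degraded"], na.rm = TRUE))
#> [1] 68.17914
```

With `out_dir = "..."`, `run_pipeline()` also writes every artifact — 16-bit
TIFF images, ground-truth path CSVs, segment tables, per-condition
morphometry JSON, comparison JSON, the fully resolved configuration and
seed, and a manifest with an MD5 hash per file. Two runs with the same seed
produce byte-identical outputs.

To measure real micrographs instead: `run_pipeline(cfg, mode =
"measure_real", images = list(condition_a = c("a1.tif", ...)))`, or the
lower-level `read_gray_image()` → `extract_image()` →
`summarize_condition()`. A thin command-line front end with
`simulate | extract | measure | compare | pipeline` verbs is installed at
`inst/cli/fibril.R`.

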