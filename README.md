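# noduleCurriculum

Difficulty-aware (curriculum) training support for lung nodule detection
on 2D chest-CT slices. Detectors for pulmonary nodules face extremely
heterogeneous training data — lesion counts from 0 to many, areas from
tens to thousands of pixels, elongated irregular shapes, and wildly
varying slice quality — and uniform random shuffling feeds the hardest
samples to the network from the first step. This package scores per-slice
detection difficulty, fuses two complementary difficulty sources, and
emits a three-stage easy-to-hard training schedule that any external
detector framework (e.g. a YOLO-family trainer) can consume. It is aimed
at researchers building or benchmarking CT detection pipelines; it never
trains a detector itself.

## The model

Every training slice gets a hybrid difficulty score

```
c_hybrid = a * c_manual + (1 - a) * c_det ,        a in [0, 1]  (default 0.2)
```

**Handcrafted score** `c_manual = f_cnt + f_size + f_shape + f_qual`,
four fixed clinical rules — nodule count (0.5/1.0/2.5/4.0 for 0/1/2–3/≥4
nodules), smallest-nodule area (1.0 above 1000 px, 2.0 in 400–1000 px,
3.0 below, 0.5 with no nodule), shape irregularity (aspect ratio > 2:
0.5/1.0/2.0 for none/one/several) and image quality (0.5/1.0/2.0 for
high/medium/low, where high means Laplacian variance > 500 and contrast
> 30) — so `c_manual` lies in [2, 11].

**Model-driven score**, from a teacher detector's predictions on slices
its training never saw:

```
c_det = clip( 3.0 * (1 - p_bar)
            + 3.0 * |N_pred - N_gt| / max(N_gt, 1)
            + 1.0 * min(0.5 * N_pred, 2.0),   0.5, 8.0 )
```

with `p_bar` the mean post-NMS box confidence (or one minus the mean
top-5 pre-NMS candidate score when no box survives NMS).

Slices are tiered as simple (`c_hybrid <= 3`), medium (`<= 6`) or complex
(`> 6`) and assigned to three cumulative stages (512/640/768 px,
50/100/100 epochs, lr 0.003/0.002/0.001, with matching loss-weight and
augmentation triples). Around this core the package provides the full
supporting pipeline: slice quality metrics, CLAHE, aspect-preserving
pad-and-resize, sub-3 mm nodule filtering, 1:2 nodule-oriented slice
sampling, patient-level 80/10/10 and teacher 72/8/20 splits, proportional
and fixed-size data-efficiency subsets, a from-scratch mAP50 / mAP50–95
evaluator, YOLO label I/O, and a controllable synthetic CT-like fixture
generator.

## Worked example

Everything below runs on synthetic data — no download needed.

```r
library(noduleCurriculum)

spec <- fixtureSpec(nPatients = 30L, slicesPerPatient = 10L, seed = 7L)
res  <- curriculumPipeline(spec = spec, seed = 7L)

res$records
#> SliceSet: 300 slice(s) from 30 patient(s); 196 nodule-bearing, 104 negative

head(res$scores[, c("sliceId", "cManual", "cDet", "cHybrid", "tier")], 5)
#>     sliceId cManual     cDet  cHybrid   tier
#> 1 P001_s001     8.5 3.983759 4.887007 medium
#> 2 P001_s002     8.5 2.291681 3.533345 medium
#> 3 P001_s003     8.5 2.787588 3.930071 medium
#> 4 P001_s004     3.0 1.092053 1.473643 simple
#> 5 P001_s005     5.0 5.386811 5.309449 medium

res$manifest
#> CurriculumManifest: stage sizes 84 / 218 / 300 (a = 0.2)

res$evaluation
#> EvalResult: mAP50 0.6952, mAP50-95 0.5672, precision 0.8742, recall 0.6966 (TP 264, FP 38, FN 115)
```

Reading the output: the first slice carries several small nodules
(`cManual` 8.5) but the simulated teacher handles it reasonably
(`cDet` 4.0), so at `a = 0.2` it lands mid-curriculum. Stage 1 trains on
the 84 easiest samples, stage 2 on 218, and stage 3 on the full 300. The
evaluation block scores the simulated teacher (quality 0.7) against the
synthetic ground truth with the package's own mAP implementation: it
recovers about 70% of nodules at IoU 0.5 with 87% precision at the 0.1
confidence operating point.

Individual pieces are available directly:

```r
modelDifficulty(0.9, 2, 2)        # 1.3
fuseDifficulty(3.0, 1.3, a = 0.2) # 1.64
assignTier(c(3.0, 6.0, 6.01))     # "simple" "medium" "complex"
baselineConfig()$lossWeights      # box 5.0, cls 2.0, dfl 0.3
```

A command-line front end wrapping the same functions ships at
`inst/cli/noduleCurriculum.R` with subcommands `synth`, `preprocess`,
`split`, `subset`, `score-manual`, `score-model`, `fuse`,
`build-curriculum`, `sweep-a` and `evaluate`.

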