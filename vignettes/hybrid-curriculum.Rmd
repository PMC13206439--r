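---
title: "Hybrid difficulty scoring and curriculum construction for lung nodule detection"
author: "noduleCurriculum"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid difficulty scoring and curriculum construction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noduleCurriculum)
```

## The problem

Training an object detector for pulmonary nodules on 2D chest-CT slices is
hampered by extreme sample heterogeneity: lesion size spans orders of
magnitude, slices carry anywhere from zero to many nodules, morphology
varies from compact round opacities to elongated irregular lesions, and
slice quality (sharpness, contrast) differs across scanners and
reconstructions. Uniform random shuffling presents the hardest samples to
the network from the first gradient step, which can destabilize early
optimization. Curriculum learning instead orders samples from easy to hard.
The crux is the *difficulty score*: this package computes it from two
complementary sources, fuses them, and emits a three-stage training
schedule that any external detector framework can consume. The package
never trains a detector itself; it is a detector-agnostic scoring,
scheduling and evaluation toolkit.

## The difficulty model

### Handcrafted difficulty

Each slice receives
$$c_{manual} = f_{cnt} + f_{size} + f_{shape} + f_{qual},$$
four fixed, clinically interpretable rules:

| factor | driver | values |
|---|---|---|
| $f_{cnt}$ | nodule count | 0.5 (none), 1.0 (one), 2.5 (2–3), 4.0 (≥4) |
| $f_{size}$ | smallest nodule area | 0.5 (none), 1.0 (>1000 px), 2.0 (400–1000 px), 3.0 (<400 px) |
| $f_{shape}$ | irregular nodules (aspect ratio > 2) | 0.5 (none), 1.0 (one), 2.0 (several) |
| $f_{qual}$ | image quality tier | 0.5 (high), 1.0 (medium), 2.0 (low) |

so $c_{manual} \in [2.0, 11.0]$. More nodules, smaller nodules, elongated
shapes and poorer image quality all read as "harder". The 400/1000 px area
bands are interpreted at the stored 512×512 working resolution (pixel
thresholds are only meaningful at a fixed scale), with both band endpoints
assigned to the middle band as printed. Because the wording of the shape
rule mixes "low aspect-ratio variance" with "extreme aspect ratios", the
regular case is operationalized as *no* irregular nodule, which keeps the
three-way rule total and deterministic. Nodule areas are exact mask
foreground counts when a segmentation mask exists and box areas otherwise.

The quality tier is *high* iff the Laplacian variance of the slice (3×3
discrete Laplacian, variance taken within the lung region) exceeds 500 and
the contrast exceeds 30 on the 8-bit scale. Only the high boundary is
prescribed; the low boundary is a package choice, set at roughly the high
thresholds scaled down three-fold (Laplacian variance ≤ 150 or contrast
≤ 15), and is configurable. "Contrast" is deliberately the simplest scalar
consistent with an 8-bit "> 30" rule: the intensity standard deviation
within the lung region. A separate "structural conspicuity" notion is not
implemented as a third metric because no quantitative definition exists
for it; the tier is fully determined by the two thresholded metrics.

### Model-driven difficulty

A teacher detector, trained on data disjoint from the slices being scored,
supplies per-slice prediction summaries, from which
$$c_{det} = \mathrm{clip}\!\left(\lambda_1 (1-\bar p)
 + \lambda_2 \frac{|N_{pred}-N_{gt}|}{\max(N_{gt},1)}
 + \lambda_3 \min(0.5\,N_{pred},\,2.0),\; 0.5,\; 8.0\right)$$
with $\lambda_1=\lambda_2=3.0$, $\lambda_3=1.0$. The three terms penalize
low prediction confidence, disagreement between predicted and annotated
nodule counts, and overly dense prediction behaviour (the density term
saturates at $2\lambda_3$ from four boxes on). $\bar p$ is the mean
confidence of the post-NMS boxes; when no box survives NMS it falls back
to one minus the mean of the top-5 pre-NMS candidate scores, so a slice
where the detector almost — but not quite — fired still reads as hard.
Fewer than five pre-NMS candidates are zero-padded before averaging: that
biases $\bar p$ upward (slice looks easy) exactly when the detector truly
found nothing above threshold, which is the conservative direction. A
slice entirely missing from the prediction files is scored with
$N_{pred}=0$ and $\bar p = 0$ (worst case, with a warning): missing output
is itself evidence of difficulty, and the pipeline stays total. All
post-NMS boxes supplied are used for $\bar p$ without an additional
confidence floor, since none is prescribed.

To keep the score honest, `teacherSplit()` carves the training patients
into 72% teacher-training / 8% teacher-validation / 20% scoring held-out
(80/20, then 90/10 within the 80), and `scoreHeldout()` refuses to score
any slice whose patient is outside the held-out set, naming the offending
patients. One ambiguity is worth recording: difficulty scores are defined
on the held-out 20%, yet the curriculum stages the *full* training set,
and no rotation scheme is prescribed for propagating $c_{det}$ to the
teacher's own training slices. The package therefore treats the teacher as
an external prediction source that may cover any slice set; the leakage
guard is enforced whenever a teacher split is supplied, and the synthetic
end-to-end demonstration simply scores all slices with the simulated
teacher.

### Fusion and tiers

$$c_{hybrid} = a\,c_{manual} + (1-a)\,c_{det}, \qquad a \in [0,1],$$
a convex combination, so $c_{hybrid}$ always lies between its two inputs.
$a=1$ is a purely handcrafted curriculum, $a=0$ purely detector-driven;
the default $a=0.2$ is the ablation optimum and is exposed as a parameter
(`sweepMixing()` rebuilds the curriculum over a grid of $a$). Tiers are
*simple* ($c \le 3$), *medium* ($3 < c \le 6$) and *complex* ($c > 6$).

## The schedule

`buildCurriculum()` emits nested stage manifests — positives by difficulty
tier, negatives by image-quality tier — together with the stage
configurations:

| stage | resolution | epochs | lr | loss (box/cls/dfl) | augmentation | data |
|---|---|---|---|---|---|---|
| 1 | 512 | 50 | 0.003 | 2.0 / 4.0 / 0.1 | 3°, 5%, 10% | simple + high-quality negatives |
| 2 | 640 | 100 | 0.002 | 5.0 / 2.0 / 0.5 | 8°, 10%, 20% | + medium (both kinds) |
| 3 | 768 | 100 | 0.001 | 7.0 / 1.5 / 1.0 | 12°, 15%, 30% | full training set |

Stage inclusion is cumulative ("expanded to include"), so
stage 1 ⊆ stage 2 ⊆ stage 3 and stage 3 covers everything. Negative
slices are staged by their quality tier rather than by $c_{hybrid}$: the
schedule's wording ties negatives to quality ("high-quality negative
samples"), and quality is the only graded notion available for a slice
with no annotation. Negatives still receive a $c_{manual}$ (their count
and size factors are pinned at 0.5), so they participate in score tables
and sweeps. Whether later stages re-initialize or continue from the
previous stage's weights is left to the consuming trainer; the manifest
records the choice as provenance rather than enforcing one. The loss
weights and augmentation values are emitted as opaque configuration for
the trainer — the package attaches no semantics to them.

`baselineConfig()` emits the matching no-curriculum reference
configuration (640 px, batch 32, ≤500 epochs, SGD lr $10^{-4}$, momentum
0.937, weight decay $5\times10^{-4}$, patience 30, box/cls/dfl =
5.0/2.0/0.3, evaluation at confidence 0.1 and IoU 0.5).

## Surrounding pipeline

*Preprocessing.* The toolkit accepts slices that have already been
lung-cropped (or full slices plus lung masks); lung segmentation itself is
out of scope. HU-valued inputs are windowed to the standard lung window
[−1000, 400] before anything else (`windowToByte()`). Quality metrics are
computed per slice; nodules under 3 mm diameter are removed (strictly
"< 3 mm", so a 3.0 mm nodule survives; diameter is the larger box extent
in mm — a conservative, mask-free definition, since no other is given);
all nodule-bearing slices are kept while non-nodule slices are retained at
an approximate 1:2 complement, best-quality-first with seeded tie-breaks;
CLAHE (clip limit 2.0, 8×8 tiles — conventional defaults, configurable)
enhances local contrast; and `padResize()` scales to a square target with
aspect preserved and symmetric padding, carrying the boxes through the
same affine map (invertible to within 0.5 px).

*Splits and subsets.* All sampling is patient-atomic: a patient's slices
never straddle a boundary. `splitPatients()` realizes the 80/10/10
train/validation/test split by seeded shuffle plus greedy assignment to
the largest remaining slice-count deficit, which keeps realized slice
fractions within a few percentage points of the targets.
`proportionalSubsets()` (fractions such as 1/2, 1/5, 1/10, n seeded folds)
and `fixedSizeSubset()` (patients appended in seeded order until the
target slice count is first reached, boundary patient included whole,
conventional seed 42) reproduce the two data-efficiency protocols.

*Evaluation.* `evaluateDetections()` is a from-scratch implementation of
detection scoring: greedy one-to-one matching in descending confidence
order (each ground truth matched at most once; the standard convention
behind the printed metric names, which define TP/FP/FN but not the
matcher), precision = TP/(TP+FP) and recall = TP/(TP+FN) with zero
denominators giving 0, AP as the exact all-point area under the monotone
precision envelope (no 11- or 101-point sampling — deterministic and
exactly testable), mAP50 = AP(0.50) and mAP50–95 the mean over
τ ∈ {0.50, …, 0.95}. AP is computed over the full ranking micro-pooled
across slices; the precision/recall operating point applies the 0.1
confidence threshold at IoU 0.5. These conventions are recorded in the
result's metadata. Parity with any particular framework's internal
evaluator is not promised — only with the printed definitions.

## The synthetic generator

`generateDataset()` exists so that every operation above is testable
without any data download. A slice is a circular low-intensity "lung"
region on a brighter body background, overlaid with a smoothed random
field (intensity heterogeneity), fine noise whose amplitude sets the
measured lung contrast, up to five bright filled elliptical nodules, and
an optional global Gaussian blur. The knobs map directly onto the
difficulty factors: nodule count distribution, area and aspect-ratio
ranges straddling the 400/1000 px and 2:1 thresholds, and blur/contrast
ranges straddling the Laplacian-variance 500 and contrast 30 thresholds.
Pixel spacing defaults to 0.7 mm/px — a typical chest-CT in-plane value —
so the 3 mm filter is exercisable. Generation is fully deterministic given
the spec, and the recorded per-nodule area is the exact rasterized mask
count. When random placement cannot fit the drawn nodule count without
overlap (crowding), the slice keeps the nodules that fit; a spec whose
*smallest* configurable nodule cannot fit the lung region is rejected
outright.

`simulateTeacher()` stands in for the external teacher with a single
quality knob $q$: each true nodule is detected with probability $q$,
detected boxes are jittered with noise ∝ (1−q), per-box confidence is
Beta-distributed with mean $q$ (bounded in [0,1], one knob), spurious
boxes arrive at Poisson rate 0.5 (1−q), and five pre-NMS scores of
amplitude (1−q) are always emitted. At $q=1$ it returns the ground truth
with confidence 1.0.

What the generator does *not* emulate: anatomy (vessels, airways, pleura —
the structures that cause realistic false positives), HU calibration,
inter-scanner texture differences, 3D continuity across slices, and
annotation noise. Passing tests therefore demonstrate that the scoring
rules, protocols and evaluator are implemented exactly as specified — not
that the curriculum improves any real detector; that claim requires GPU
training on real data and is outside this package's scope.

## Numerical choices and degenerate inputs

- Boxes are 0-based half-open intervals (x = column, y = row), so areas
  and IoU are exact integer-free arithmetic and YOLO label round-trips
  hold to within 0.5 px quantization.
- Component labelling for mask-to-box derivation is 8-connected (the
  blob-labelling standard); the 4-connected labels of the underlying
  image library are merged across diagonals by union-find.
- A constant image has zero Laplacian variance and zero contrast (tier
  low) and passes through CLAHE unchanged.
- Tie-breaks: the patient shuffle and the within-tier negative ordering
  are seeded; all derived seeds stay below $2^{31}$.
- Degenerate evaluation: no ground truth → AP reported 0 with a warning;
  no predictions → recall 0. `TP + FN` equals the ground-truth count at
  every threshold by construction.
- Empirically mAP50–95 ≤ mAP50 on all tested inputs; the suite asserts
  it on random instances rather than assuming it.

## Problem sizes used in the test suite

The shipped tests and the acceptance script run entirely on synthetic
data at deliberately small scale, chosen to exercise every rule while
keeping the suite quick: cohorts of 6–30 patients at 96–192 px for the
pipeline tests, a 100 nodule / 1000 non-nodule cohort at 64 px for the
slice-sampling ratio, 100 patients for the split protocols, $10^4$ random
draws for the score oracles, and ≥100 random small instances for the
evaluator-versus-brute-force comparison.

## Limitations

The factor coefficients, thresholds and λ-weights are heuristic design
rules inherited from their source setting (a large low-dose chest-CT
benchmark); they are exposed as configuration but no claim of optimality
on other datasets is made. The schedule is static — it does not adapt to
the model's evolving state. Difficulty is per-slice, not per-nodule, and
strictly 2D.
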