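---
title: "Pathomic gland morphometry and tile classification for H&E prostate histology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathomic gland morphometry and tile classification for H&E prostate histology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histomorph)
```

## The problem

Prostate cancer is graded by the Gleason system: a pathologist recognizes
architectural patterns — well-formed discrete glands (pattern 3), cribriform
or fused poorly-formed glands (pattern 4), sheets of cells with little or no
lumen (pattern 5) — and annotates regions of each pattern on whole-slide
images. Annotating whole-mount slides by hand is slow and subject to
inter-observer variability, which motivates classifiers that label slide
regions automatically.

histomorph implements the *handcrafted-feature* route to that goal: tiles cut
from a slide are reduced to a small vector of interpretable gland
morphometrics and classified with a bagged decision-tree ensemble. The
package covers the full path — tiling and annotation masking, stain-based
tissue segmentation, gland reconstruction, feature summarization,
classification at three levels of grading specificity, and evaluation — plus
a seeded synthetic-histology generator that stands in for patient slides,
which are never distributable.

## Tiling and annotation masks

A slide of width $W$ and height $H$ is divided into half-open, 0-based pixel
boxes of a fixed tile size (3,000 px for the feature pathway), with look-up
tables mapping grid column/row to pixel ranges (`build_tile_grid()`). Edge
boxes are clipped for bookkeeping but never selected: a clipped tile has a
different denominator in the coverage fraction and would not be comparable.

Annotations arrive as one binary mask per class (eight classes: benign,
atrophy, HGPIN, seminal vesicle, G3, G4 cribriform, G4 non-cribriform, G5). A
*non-tissue* mask — background, lumen, bright artifacts — is subtracted from
every class mask first; we detect non-tissue as pixels whose darkest channel
is still bright ($\min(R,G,B) \ge 220$ after 3×3 median smoothing), a simple
rule that is configurable because scanners differ.

A tile belongs to a region of interest (ROI) when **strictly more than 50%**
of its pixels carry that ROI's annotation. From each connected ROI exactly 5
eligible tiles are sampled without replacement (seeded); ROIs with fewer than
5 eligible tiles are dropped entirely, and unlabeled benign tissue is sampled
at 15 tiles per slide rather than per ROI. Sub-tiles of 1,024 px for
patch-based models use a 3×3 anchor grid at offsets $\{0, 988, 1976\}$: three
1,024 px sub-tiles overlap slightly inside a 3,000 px tile, so a fully masked
tile yields exactly 9 sub-tiles. The overlap is a design choice: $3 \times
1024 > 3000$ forces either overlap or fewer sub-tiles, and 9 is the natural
maximum.

## Stain segmentation

H&E stain amounts mix linearly in optical-density space,
$OD = -\log_{10}((I+1)/256)$ per 8-bit channel. Each pixel's OD vector is
unmixed against a 3×3 matrix of unit-norm stain vectors — the widely
published hematoxylin $(0.65, 0.70, 0.29)$ and eosin $(0.07, 0.99, 0.11)$
directions with their normalized cross product as the residual — by solving
the linear system per pixel; negative concentrations are clipped to zero.
Classification is then:

* **lumen/background** where total OD $< 0.15$ (faintly stained pixels;
  configurable). Lumen and slide background are one class at this stage —
  they are optically identical — and background is resolved later by the
  non-tissue mask;
* **epithelium** where the hematoxylin concentration strictly exceeds eosin;
* **stroma** otherwise, with exact ties going to stroma.

Cleanup passes (a 3×3 majority filter; reassignment of epithelium/lumen
objects under 30 px; filling of lumen pinholes under 50 px that are fully
surrounded by epithelium) remove speckle noise while preserving the
stroma/epithelium/lumen partition. The thresholds are stated defaults at the
analysis scale, pinned by tests, not published values. On whole-slide scans
at 0.34 µm/px the analysis runs on a factor-8 block-mean reduction; coverage
fractions are always computed at full resolution.

## Gland morphometry

Each 8-connected lumen component of at least 8 px that does not touch the
tile border seeds one gland; border-touching lumina are excluded because the
gland is clipped and its features would misrepresent the histology.
Epithelium within 20 px of a kept lumen is assigned to its nearest lumen by
geodesic propagation through epithelium (EBImage's seeded Voronoi
propagation), forming the epithelial ring. In cribriform masses every
internal lumen seeds its own gland — the alternative (one gland per mass) is
equally defensible; per-lumen glands make the feature distributions of
cribriform tiles distinctive, which is the point of the class.

Six features per gland:

| feature | definition |
|---|---|
| luminal area | lumen pixel count |
| epithelial area | ring pixel count |
| luminal roundness | $4\pi A / P^2$ with $P$ the lumen's contour length, clipped to 1 |
| epithelial roundness | $4\pi A_{epi} / P_{outer}^2$ with $P_{outer}$ the outer contour of ring ∪ lumen |
| wall thickness | mean distance from outer-boundary pixels to the nearest lumen pixel |
| cell fraction | $100 \cdot A_{epi} / (A_{epi} + A_{lumen})$ |

Epithelial roundness deliberately uses the *ring's* area with the *outer*
perimeter: for an annulus it equals $(1 - (r/R)^2)$ times the outline's
isoperimetric ratio, so it blends wall fullness with shape. The alternative
(filled-gland roundness) is constant 1 for every round-outlined gland and
carries no information beyond luminal roundness.

Perimeters are measured as smoothed-contour polygon lengths: the boundary
pixel chain is vertex-averaged with its second neighbors before summing edge
lengths. Raw chain-code length overestimates smooth digital boundaries by
about 5.5% (pixel quantization); the smoothed polygon tracks exact disc and
ellipse perimeters within about 1% for radii ≥ 20 px, which the geometry
tests pin down.

Two whole-tile features — stromal and epithelial area fractions — complete
the set of eight. Each tile is summarized as **mean, median and variance** of
each feature over its glands: 8 × 3 = 24 slots. The whole-tile scalars place
their value in the mean and median slots with variance 0, so the schema is
uniform (9,345 tiles × 24 slots = 224,280 values at the scale of a full
training cohort). Variance uses the population ($n$) denominator so that a
one-gland tile is determinate: mean = median, variance 0. Gland summaries are
unweighted by gland size. Tiles with no glands (epithelial sheets) zero-fill
the 18 gland slots; the gland count is carried for bookkeeping but is not a
classifier input.

## Classification

Features are z-scored with parameters fitted on training rows only
(`zscore_fit()` / `zscore_apply()`; constant columns get a sentinel sd of 1
and a flag). The classifier is bootstrap aggregation of unpruned CART trees
(rpart, `cp = 0`, `minsplit = 5`, no pruning), 100 learners by default; each
learner trains on its own with-replacement resample of the training rows
under a seed derived from the master seed and learner index, so the model is
a pure function of (data, seed). Prediction is majority vote; ties break to
the tied class with the highest mean per-learner posterior, then to
class-list order. Ensemble size and tree depth are stated defaults — the
bagged-ensemble framework this follows does not prescribe them — and the
single-learner case is pinned to a directly fitted tree in the tests.

Three label schemes map the eight annotation classes to model classes, with
non-cancer (NC) always pooling benign, atrophy, HGPIN and seminal vesicle:

* `all_grades`: G3, G4CG, G4NC, G5, NC (chance level 20%)
* `hg_vs_lg`: HG = G4CG ∪ G4NC ∪ G5, LG = G3, NC (chance level 33%)
* `nc_vs_ca`: CA = all Gleason patterns, NC

`run_scheme_suite()` refits normalization per scheme, trains, and evaluates
on a held-out split, rejecting any patient present in both splits when
patient ids are given. Evaluation reports carry the confusion matrix
(rows = true), one-vs-rest sensitivity/specificity/PPV/NPV with explicit
undefined flags when a denominator is zero (rare classes do produce empty
test cells), and tile-weighted overall accuracy (trace over total — the
natural reading of a confusion matrix; class-averaged accuracy would differ
under imbalance). Predictions can be painted back onto slide-sized maps with
a fixed class palette; overlapping sub-tile boxes resolve last-writer-wins in
manifest order, which is adequate for qualitative maps.

## The synthetic generator

Patient slides cannot ship with a package, so all tests and benchmarks run
on synthetic tiles that emulate the gross architecture the features respond
to: white elliptical lumina, hematoxylin-purple epithelial walls,
eosin-pink stroma, flat fills plus per-pixel Gaussian RGB noise
(sd = `noise_sd` × 255, default 0.02) and an optional 1 px Gaussian blur for
scanner softness. Morphology is controlled per class:

* **benign**: 2–4 large, near-circular, thin-walled glands (lumen radius
  40–60 px at the 512 px reference tile, wall 8–14 px);
* **atrophy**: 8–14 small thin-walled glands (radius 18–32, wall 3–6);
* **HGPIN**: benign-sized lumina with markedly thicker epithelium (wall 14–22);
* **seminal vesicle**: 1–2 large eccentric glands (radius 45–65, wall 12–20,
  eccentricity 0.2–0.5);
* **G3**: 14–24 small discrete glands (radius 8–16, wall 7–12);
* **G4CG**: one large epithelial mass (radius 90–140) perforated by 5
  internal lumina of radius 9–15 (cribriform);
* **G4NC**: 9–16 glands whose epithelium may overlap and fuse (only lumina
  are kept disjoint), the defining trait of non-cribriform pattern 4;
* **G5**: 2–4 solid epithelial sheets with no lumen at all — the limiting
  case of "minimal lumen".

These numbers are package defaults chosen to caricature each pattern's
textbook architecture; no quantitative per-class morphology is published for
them, and they are deliberately not presented as derived from any dataset.
Radii and walls scale linearly with tile size and gland counts with tile
area, so a 3,000 px tile (the whole-slide tile size, later reduced by 8)
carries the same architecture density as the 512 px reference.

Placement is rejection sampling with at most 100 attempts per gland;
configurations too dense to place fail loudly rather than silently thinning.
Generation is a pure function of (spec, seed): per-tile seeds derive from
(master seed, class, index), the caller's RNG state is restored afterwards,
and repeated calls are byte-identical — the determinism tests hash the
emitted PNGs. Every rendered gland is recorded in a ground-truth table
(center, rendered lumen and ring pixel areas, the sampled wall thickness,
border contact), which is what the segmentation and morphometry tests
compare against. For fused and cribriform classes the per-gland epithelial
area is recorded from each gland's own rasterization before fusion, so
shared pixels are double-counted there; exact-recovery tests therefore use
the discrete-gland classes.

What the generator does **not** emulate: nucleus-level texture, stain-batch
and scanner variation, tissue folds and artifacts, and the long-tailed class
imbalance of real cohorts. Passing the benchmark therefore shows that the
pipeline measures the geometry it claims to measure and that those
measurements separate architecturally distinct classes; it says nothing
about accuracy on real slides, where texture (which these features ignore)
carries much of the grading signal.

## The synthetic benchmark and its problem sizes

`run_benchmark()` generates 100 tiles per class for six classes (benign,
atrophy, G3, G4CG, G4NC, G5 — both non-cancer classes and all four
patterns), extracts features from the rendered images only, splits 2/3–1/3
stratified by class, and runs the three schemes. Benchmark tiles are 384 px
and analyzed at full resolution: this keeps the morphology-to-analysis-scale
ratio of whole-slide tiles (3,000 px reduced by 8) while doing a fraction of
the pixel work, and one full benchmark completes in a few minutes on one
CPU. The test suite asserts held-out NC-vs-CA accuracy ≥ 0.90, five-class
accuracy ≥ 0.40 (twice chance), and the difficulty ordering
nc_vs_ca ≥ hg_vs_lg ≥ all_grades — coarser partitions of the same signal
cannot be harder on this generator.

## Numerical choices and edge cases

* Strict ">" at exactly 50% coverage; one shared threshold constant for both
  tile sizes.
* Class-map ties (hematoxylin = eosin) go to stroma; vote ties break by mean
  posterior, then class order — both documented and tested.
* The majority filter changes a pixel only when some class strictly exceeds
  the pixel's own neighborhood count, so clean maps are fixed points.
* Undefined metrics are `NA` plus a flag, rendered as "—" in text and empty
  fields in CSV — never NaN propagation.
* Masks are stored as single-channel PNGs whose pixel value is the class
  index, with the color table kept in code (`annotation_palette()`); this
  round-trips losslessly where palette-indexed writing is unavailable.
* Seeds derived from the master seed use 32-bit modular arithmetic and stay
  below $2^{31}$.

## Known limitations

* Features are purely architectural; patterns that differ in nuclear texture
  but not gland geometry (the hard part of real Gleason grading) are outside
  what this feature set can express — sheets without glands reduce to "no
  glands, high epithelial fraction".
* Wall thickness via boundary-to-lumen distances assumes the ring hugs its
  lumen; for strongly non-convex fused rings it reports the mixture.
* Stain vectors are fixed, not estimated per slide; real cohorts with stain
  drift would need per-slide vector estimation, which is out of scope.
* The whole-tile variance slots are zero-filled by construction; had the
  source pipeline computed them over sub-regions the slot values would
  differ, though the slot count would not.
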