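---
title: "Methods: models, parameters and design choices in phagoscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in phagoscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagoscreen)
```

# Scope

phagoscreen analyses image-based synaptosome phagocytosis screens in
microglia-like cells, from per-field image measurements through assay
quality control, hit calling, morphological phenotyping, and a
transcriptomic follow-up that decides which compounds measurably perturb
gene expression. Because raw screening plates and sequencing libraries are
rarely shareable, the package ships synthetic-data generators with known
ground truth; every downstream stage is exercised and validated against
that ground truth.

# The phagocytic index and assay quality control

The unit of measurement is the image field: a cell count (nuclei inside
IBA1+ cytoplasm) and the pixel area of engulfed pHrodo-labelled
synaptosome signal. pHrodo fluoresces only at phagolysosomal pH, so
above-threshold signal inside a cell indicates engulfed material. The
well-level **phagocytic index** (PI) is the ratio of totals over the
well's non-excluded fields,

$$\mathrm{PI} = \frac{\sum_f A_f}{\sum_f N_f},$$

not the mean of per-field ratios; fields with few cells therefore do not
dominate. `phagocytic_index()` errors when the total cell count is zero.

Assay quality is summarized by two control-separation statistics over
per-well PIs of the DMSO negative control and the cytochalasin D (an
actin-polymerization inhibitor) positive control:

* **Z'-factor** $= 1 - 3(\sigma_+ + \sigma_-)/|\mu_+ - \mu_-|$, with
  sample (n−1) standard deviations. Z' ≥ 0.5 is the conventional bar for
  an excellent screening window.
* **SSMD** $= (\mu_- - \mu_+)/\sqrt{\sigma_-^2 + \sigma_+^2}$, signed so
  a phagocytosis-inhibiting positive control gives a positive value;
  values above 5 indicate a robust assay.

Both are invariant under common positive rescaling of the PIs, and Z' is
bounded above by 1 (attained only with two zero-variance groups); these
invariants are tested.

A note on joint attainability: for any two control groups,
$(\sigma_- + \sigma_+)^2 \le 2(\sigma_-^2 + \sigma_+^2)$, which couples
the two statistics — at a given control separation, Z' ≈ 0.5 caps the
achievable SSMD near 8.7 (equality at $\sigma_-=\sigma_+$). The
generator's control defaults were therefore chosen to land in the
quality regime practitioners report for this assay class (Z' ≈ 0.5–0.6,
SSMD ≈ 9) rather than to reproduce any particular published pair
exactly.

# Exclusion filters

Filters run in a fixed, idempotent order: over-segmentation (field
level), then aggregation, then toxicity (well level).

* **Over-segmentation.** The underlying high-content pipelines name this
  filter without defining it, so the rule here is an explicit robust
  outlier test: a field whose cell count exceeds
  `median + k·MAD` (default `k = 5`, scaled MAD) of the same-plate DMSO
  fields is excluded from PI sums. Plates with fewer than 8 fields skip
  the filter with a warning; the statistic is too unstable below that.
* **Toxicity.** Wells retaining strictly fewer than 10% of the DMSO mean
  cell count indicate possible toxicity. The boundary is strict
  (`< 10%`): a well at exactly 10% is retained. The DMSO reference is
  per-plate by default (absorbing plate effects; a screen-wide reference
  is available), and the rule is applied per compound by default — the
  replicate-mean relative cell count decides, and all replicate wells of
  a toxic compound are excluded together, which matches how whole
  compounds, not stray wells, are dropped from screens. A per-well mode
  is available.

# Hit calling

Per-compound Z-scores standardize the mean PI of a compound's
non-excluded replicate wells. Two references are implemented because both
appear in screening practice: the DMSO well distribution (`vs_dmso`,
default) and the distribution of per-compound means across the library
(`vs_library`). The mode is recorded in the output. Replicates are
aggregated by the mean (not the median) before scoring — with three
replicate wells the median is noisier.

Inhibitor hits are non-toxic compounds with `z ≤ −2`, inclusive, and
activators are reported symmetrically at `z ≥ +2`; toxicity takes
precedence over any Z-score. With the `vs_dmso` reference the null
Z-scores of 3-well compound means have a standard deviation near
$1/\sqrt{3}$, so the ±2 threshold is conservative against false hits.

The secondary confirmation screen uses per-field PIs (15 fields): the
compound-to-DMSO ratio of mean per-field PI, with SEM propagated from the
compound group's field-level SEM divided by the DMSO mean. Compounds
classify as: `toxic` (same <10% rule, dominant), `confirmed_inhibitor`
(ratio ≤ 0.5, inclusive), `weak_inhibitor` (0.5 < ratio < 1 − δ),
`activator` (ratio > 1 + δ), otherwise `no_effect`; δ defaults to 0.05
and absorbs assay-level ratio noise around 1. Missing secondary data
yields `not_tested`. Primary/secondary concordance is the Pearson
correlation over paired compounds with a t-test p-value on n − 2 degrees
of freedom.

# Imaging

`segment_cells()` is a documented stand-in for an interactive
high-content pipeline whose exact parameters are never printed in papers:
median background subtraction, Gaussian smoothing (σ = 2 px), Otsu
foreground on IBA1, nuclei-seeded propagation (watershed) to split
touching cells, and a 50 px minimum object size to suppress debris.
Boundary-touching cells are retained. Equivalence can only be claimed
against this documented recipe, not against any specific proprietary
pipeline; the tests therefore validate against rendered ground truth
(Jaccard ≥ 0.9 per cell on disjoint cells, exact counts, watershed
splitting of touching ellipses).

Shape features follow the region-properties conventions:

* **solidity** = pixel area / convex-hull pixel area. The hull area is
  the number of pixel centers satisfying every half-plane of the hull
  (with tolerance, so boundary pixels count); the test suite checks it
  against an independent point-in-polygon rasterization.
* **eccentricity** is that of the ellipse with identical second central
  moments (0 = circle, → 1 = line). This convention is stated explicitly
  because "eccentricity" has competing definitions (e.g. axis ratio).

Both features are rotation-robust (< 0.05 change under 45° rotation) and
solidity is scale-invariant (±0.02 under 2× upscaling) — tested on
rendered shapes. A rendered 2:1 ellipse recovers the analytic
$\sqrt{1 - (b/a)^2} = 0.866$ within 0.02.

# Morphotyping

Cells classify by two thresholds per feature into **ramified** (low
solidity, high eccentricity — branched, surveillant-like), **ameboid**
(high solidity, low eccentricity — compact, activated-like), **rod**
(both mid), and **ambiguous** (discordant quadrants, e.g. a compact but
elongated cell). Ambiguous is a first-class label so the classes
partition feature space. Published work does not print numeric cutoffs,
so by default they are derived as tertiles of the screen's own DMSO cell
population (with a fixed-value override); the derivation is recorded in
the threshold object. This module reports morphotypes only; it makes no
claim about activation state, for which morphology is at best a proxy.

Compound phenotypes aggregate field means and then compound means
(matching how per-compound dots are built from 5–15 fields), and PCA runs
on standardized compound-level means, not single cells. Loadings are
orthonormal with a fixed sign convention (largest-magnitude loading
positive) so outputs are reproducible across BLAS implementations.

# RNA activity

The transcriptomic stage starts at a gene × well count matrix (alignment
and barcode demultiplexing are out of scope). The differential-expression
engine is deliberately simple and fully documented, rather than a wrapped
black box:

* **Normalization**: median-of-ratios size factors (geometric-mean
  reference over genes nonzero in all wells; positive-count fallback with
  a warning), rescaled to geometric mean 1. They agree with the standard
  implementation of the same estimator (cross-checked in a test).
* **Test**: per-gene negative-binomial Wald test. The dispersion is a
  pooled method-of-moments estimate
  $\hat\alpha = (\hat v_w - \bar\mu)/\bar\mu^2$ floored at $10^{-8}$;
  the log2 fold-change uses normalized group means with a 0.5
  pseudocount; the Wald statistic
  $\log(\hat\mu_1/\hat\mu_2)\big/\sqrt{(1/\hat\mu_1+\hat\alpha)/n_1 +
  (1/\hat\mu_2+\hat\alpha)/n_2}$ is referred to a t distribution on
  $n_1+n_2-2$ degrees of freedom. The t reference (not the normal) is
  the deliberate choice here: the variance in the denominator is
  estimated from the same handful of wells, and the statistic has the
  structure of a pooled-variance two-sample t on the log scale; a normal
  reference is anticonservative at n = 4 per group. Under a null
  simulation the p < 0.05 fraction is 0.05 within ±0.02 (tested).
  Results will differ numerically from shrinkage-based NB frameworks;
  validation is by simulation recovery, not replication of any published
  DEG table.
* **DEG count**: adjusted p < 0.1 and |log2FC| > 1, both strict, with
  Benjamini–Hochberg adjustment implemented as explicit step-up
  arithmetic (cross-checked against `p.adjust`).

A compound is **RNA-active** when its DEG count strictly exceeds the 95th
percentile (nearest-rank convention) of an empirical DMSO-vs-DMSO null:
repeated disjoint random splits of the DMSO wells of the same group size,
each tested like a compound. Strict ">" implements "more DEG than 95% of
the null comparisons". Because null DEG counts concentrate at zero, the
realized false-active rate is usually far below 5%. Published protocols
do not state the null's group size or draw count; the defaults here are
group size equal to the per-compound replicate count and 100 draws, and
both are recorded in the output. Wells carry a batch label and
comparisons default to within-batch designs.

Pathway-level interpretation is a generic hypergeometric
over-representation test (`ora_enrichment()`); proprietary pathway
activation scores are out of scope.

# The synthetic-data generators

The generators define the study conditions; they are not tuning knobs.

**Screen generator** (`simulate_screen()`): 96-well plates, controls in
fixed columns, compound replicates placed on different plates (as
screening designs do, to decouple compound and plate effects). Field PIs
are log-normal around the well expectation — PI is a positive ratio, and
no field-level variance is published for this assay class, so the
field-level CV of 0.30 is an assumption, documented as such, not an
estimate. With 12 fields per well this yields well-level control SDs
that put the assay window at Z' ≈ 0.59 and SSMD ≈ 9.4 in expectation
(the control-convergence test checks the closed forms at 1000 wells).
Defaults: baseline PI 1.0; cytochalasin D multiplier 0.12 with
field-level CV 1.0 (positive-control residual uptake is variable);
inhibitors at multiplier 0.5 (expected `vs_dmso` z ≈ −5.8, comfortably
past the −2 threshold at 3 replicates); activators at 1.5; toxicity as
binomial thinning of Poisson(100) cell counts to 5% — the simplest
mechanism consistent with a <10% survival threshold. Morphology shifts
are class-wise deltas plus per-compound jitter with a built-in
solidity–eccentricity correlation of −0.9, reflecting how strongly
anticorrelated the two features are in microglial populations.

**Field renderer** (`render_field()`): elliptical cells with known
centroid, axes, orientation and IBA1 intensity; nucleus disks; pHrodo
puncta placed on cell pixels ("inside") or with their whole disk clear of
cells ("outside"); constant background (0.05), additive Gaussian noise
(SD 0.01), 512×512 px default with 30–80 px cells. An error is raised if
cells overlap beyond a configurable cap, since the assay assumes
resolvable cells. The returned masks are the exact painted regions, which
is what makes segmentation testable. Limitations: no point-spread
function, no autofluorescence, no intensity gradients — and rendered
cells are convex, so their solidity is ≈ 1; the ramified (low-solidity)
morphotype exists in the screen-table generator but cannot be rendered as
an ellipse. Passing imaging tests therefore demonstrate correctness of
the measurement code on resolvable, convex cells, not segmentation
performance on real ramified microglia.

**Counts generator** (`simulate_counts()`): gene baselines log-normal
(meanlog log 50, sdlog 1 — emulating a matrix already filtered to
reliably detected genes, as DE practice filters low-count genes), NB
dispersion 0.1 (typical for well-replicated bulk counts), log-normal
library-size multipliers (sdlog 0.1), and for active compounds 300
planted DE genes at |log2FC| = 2, half up, half down. Wells of inactive
compounds are exchangeable with DMSO wells by construction, which is what
makes the empirical null's calibration testable.

All three generators are deterministic given their config (the seed is
part of the config), and the write paths (TSV, MTX triplet, multi-page
TIFF) are byte-reproducible — tested by hashing re-runs.

# Problem sizes used in the validation suite

The shipped tests validate at sizes chosen to make sampling noise small
relative to the tested tolerances while staying desk-scale: 20 simulated
489-compound screens for hit recovery (sensitivity ≥ 0.9 at a false-hit
rate ≤ 0.05); 1000 control wells for the closed-form Z'/SSMD convergence
(5%); 100 compounds for morphological correlation recovery (±0.05);
3000 genes for NB-test calibration (±0.02 on the rejection rate); and
20 simulated count screens each for null calibration and planted-active
detection of the RNA-activity rule.

# Known limitations

* The image pipeline is a documented recipe, not a reimplementation of
  any specific high-content software; parameters that are interactive
  choices elsewhere are explicit arguments here.
* The NB engine has no dispersion shrinkage across genes; at very small
  replicate counts its power is below that of shrinkage-based methods,
  and its DEG counts are not comparable across engines.
* Synthetic images are optically naive (no PSF, uniform background,
  convex cells); they validate measurement logic, not robustness to real
  microscopy artifacts.
* Dose–response fitting is out of scope: a single-dose ratio ≤ 0.5 is
  reported as "confirmed inhibitor", which implies only an apparent IC50
  at or below the screening dose.
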