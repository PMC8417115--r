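---
title: "Methods: brightfield IHC quantification and temporal proteome analysis"
author: "tiquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: brightfield IHC quantification and temporal proteome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tiquant)
```

tiquant implements two analysis chains used to profile how tumors respond
to an intervention over time — here framed around attenuated *Salmonella*
(YB1) versus PBS-injected control mice: quantification of marker
expression in brightfield immunohistochemistry (IHC) scans, and a
label-free quantitative (LFQ) proteomics cascade over seven sampling
timepoints (6 h, 12 h, 24 h, 2 d, 3 d, 7 d, 14 d) with four replicates
per group. Both chains ship with synthetic-data generators carrying full
ground truth, so every stage is testable without any external data.

# Brightfield IHC quantification

## Optical density and color deconvolution

Brightfield stains absorb light multiplicatively, so they mix additively
in optical density (Beer–Lambert): a pixel with stain amounts
$a = (a_\mathrm{hem}, a_\mathrm{marker}, a_\mathrm{res})$ transmits
$I_c = 255\cdot 10^{-(aM)_c}$ in channel $c$, where the rows of $M$ are
the unit-norm OD vectors of the stains. `rgbToOD()` applies
$OD_c = -\log_{10}(\max(I_c, 1)/255)$ — the clamp at 1 keeps a fully
absorbed pixel finite at $\log_{10}255 \approx 2.41$, and a blank pixel
maps to exactly 0. `deconvolveStains()` inverts the mixing per pixel,
$c = OD\,M^{-1}$, which is exact up to 8-bit quantization.

The default basis `hdabStainMatrix()` is the fixed hematoxylin/DAB
matrix

```{r}
stainBasis(hdabStainMatrix())
```

with row 1 assigned to hematoxylin (nuclear counterstain), row 2 to the
DAB-like marker chromogen and row 3 to the residual channel — the
standard H-DAB ordering. The residual amount is held at zero during
synthesis because the quantification contrasts one marker against the
nuclear counterstain. Small negative unmixed amounts can arise from
noise; they are kept in the raw concentration maps for diagnostics and
clipped at zero only when building the signal channel.

## Thresholding convention

Published per-marker thresholds for this kind of assay are stated on a
0–255 scale without specifying the channel they apply to. tiquant
defines the **stain signal channel**
$s = \mathrm{round}(255\,(1 - 10^{-\max(c,0)}))$ — the amount of light a
pure stain of concentration $c$ would absorb — and calls a pixel stained
iff $s \ge$ threshold. This makes the thresholds interpretable as
"absorbed 8-bit intensity due to that stain alone". The defaults are

```{r}
markerThresholds()
```

Any other convention (raw channel, inverted channel) can be emulated by
supplying custom thresholds or a custom stain matrix; the choice is
deliberately surfaced rather than buried.

## Nucleus segmentation

Nucleus area is used as the denominator of the expression statistic
because cytoplasm boundaries are ill-defined in these sections; the
underlying assumption is a roughly constant nucleus/cytoplasm area
ratio across regions. `segmentNuclei()` runs a piecewise-constant
(Chan–Vese) level set on the hematoxylin concentration map: the map is
rescaled to $[0,1]$, the contour is initialized at the Otsu threshold,
and $\phi$ evolves by explicit gradient descent on the Chan–Vese energy
with curvature weight $\mu = 0.1$, regularized delta ($\varepsilon=1$),
time step 0.5, and a 100-iteration budget with early stopping once the
foreground stops changing. The final foreground is split into connected
components; components under `minAreaPx = 40` px (debris at the default
0.25 µm/px scale, where real nuclei occupy well over 100 px) are
discarded. The evolution contains no randomness, so segmentation is a
deterministic function of the image and parameters. On noise-free
synthetic images the recovered area matches the painted masks
essentially exactly because the data term dominates the weak curvature
term at sharp boundaries.

The cited family of level-set detectors admits many variants; the
region-based Chan–Vese energy with Otsu initialization was chosen as
the canonical member, and all its controls (`mu`, `maxIter`, `dt`,
`minAreaPx`) are exposed.

## ROIs and the S/N statistic

`extractROIs()` automates what is a manual step on real slides: nine
regions of interest per section, either as a deterministic 3×3 grid
(default) or seeded random placement, each ROI representing roughly a
250 µm × 480 µm field at 40× (≈ 0.25 µm/px; pixel size is exposed as a
parameter because scanners differ). Per ROI, `computeSN()` counts
stained pixels S and nucleus pixels N and reports S/N; an ROI with no
segmented nucleus is flagged undefined and excluded from group
statistics rather than contributing a 0 or an infinity.

Group comparison (`compareMarkers()`) pools ROI ratios across replicate
sections — 3 sections × 9 ROIs = 27 ratios per group by default,
matching common practice for this statistic — and applies the
two-sample Kolmogorov–Smirnov test (`ksCompare()`), exact (conditional
permutation distribution) when $n_1 n_2 \le 10^4$ and tie-free,
asymptotic otherwise. A per-section-mean mode is available for readers
who prefer treating the section, not the ROI, as the experimental
unit; with n = 3 per group it has almost no power, which is exactly
why pooling is the field's default. Significance tiers follow the
printed convention `* < 0.05`, `** < 0.01`, `**** < 0.0001` (there is
no `***` tier in this convention; `significanceTier()` implements the
mapping literally).

## Synthetic image generator

`simulateIHCImage()` inverts the measurement model: elliptical nuclei
(uniform random centers, semi-axes 5–9 px, orientation) and elliptical
marker blobs are painted as stain amounts (hematoxylin 0.6 OD, marker
0.8 OD — mid-range absorbances typical of well-stained sections), then
composited through the stain matrix with 8-bit rounding. Gaussian read
noise (SD in intensity units) is added after quantization and clipped,
the simplest model that still stresses the thresholds. Nuclei are
placed by rejection sampling with a 2 px margin so planted nuclei stay
disjoint — that keeps nucleus-count recovery tests exact. The painted
masks and their ratio are returned as ground truth.

What the generator does **not** emulate: tissue texture, stain
gradients within a nucleus, touching/overlapping nuclei, chromatic
aberration and uneven illumination. Passing the round-trip tests
therefore demonstrates correctness of the quantification chain under
its own measurement model, not robustness to every histological
artifact; the noise-sweep tests (SD ≤ 3 intensity units keeps area
error within 15 %) probe the first step beyond the clean regime.

# Temporal proteome cascade

## Filters

Two identification-quality gates precede statistics, in this order:

1. `filterUniquePeptides()` — keep proteins with ≥ 1 unique peptide.
2. `filterPresence()` — a protein is *testable* at a timepoint iff it
   has ≥ 2 observed intensities in **both** the YB1 and PBS samples of
   that timepoint; the analysis set is the union of testable proteins
   across timepoints. The per-timepoint reading (rather than a single
   global removal) matches per-timepoint testing downstream; a global
   mode can be emulated by intersecting the testable matrix.

Both filters are idempotent and are verified against exhaustive
recount oracles in the test suite.

## Normalization

`vsnNormalize()` provides variance stabilization as a two-step
contract: median-ratio scaling to a geometric-mean pseudo-reference
(computed over proteins observed in every sample), followed by the
generalized log
$\mathrm{glog}_2(x) = \log_2\big((x + \sqrt{x^2 + \lambda^2})/2\big)$
with $\lambda$ set to the 1st percentile of the scaled intensities.
After scaling, the matrix is anchored to the geometric mean of its
reference-complete cells, so normalized values are log2-ratio-like and
invariant to multiplying any sample by a constant — the absolute scale
carries no information in a relative-quantification experiment, and
group contrasts (log2 fold changes) are unaffected. This parametric
form delivers the properties downstream stages rely on (variance
stabilization near the detection limit, scale equivariance, $\log_2$
behaviour for abundant proteins) without the full arsinh
maximum-likelihood calibration, whose extra parameters are not
identifiable from the synthetic designs used here.

## Left-censored imputation

LFQ missingness is predominantly missing-not-at-random: low-abundance
values fall below detection. `imputeQRILC()` follows the
quantile-regression reading of that assumption. Per sample, the
observed values are treated as the upper order statistics of a normal
sample of known total size; regressing them on standard-normal
quantiles of their plotting positions estimates $(\hat\mu,
\hat\sigma)$ of the complete distribution. Missing cells are then drawn
from $N(\hat\mu, \hat\sigma)$ truncated **above** at the sample's 1 %
point ($\hat\mu + \hat\sigma\,z_{0.01}$) — deep left-tail draws,
implemented by inverse-CDF so they are reproducible under a seed.
Parameter recovery (µ within 2 %, σ within 10 % at 30 % censoring) is
checked in the acceptance suite. A sample with fewer than 10 observed
values is rejected as unidentifiable rather than silently imputed.

## Moderated t and DE calling

Differential expression per timepoint uses the empirical-Bayes
moderated t-test. Per-protein pooled variances $s_g^2$ (df $d_g =
n_1+n_2-2$) are modelled as $s_g^2 \sim s_0^2 F(d_g, d_0)$;
`fitModerationPrior()` estimates $(d_0, s_0^2)$ by the method of
moments on $\log s_g^2$ (digamma/trigamma matching, Newton inverse
trigamma), returning $d_0 = \infty$ with $s_0^2 = \overline{s^2}$ when
the spread of $\log s^2$ is at or below its sampling expectation. The
statistic is
$\tilde t = \frac{\bar y_1 - \bar y_2}{s_\mathrm{post}\sqrt{1/n_1 + 1/n_2}},
\quad s^2_\mathrm{post} = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g},$
referred to $t_{d_0+d_g}$ (normal for $d_0 = \infty$; the ordinary
pooled t for $d_0 = 0$). The prior is fit per timepoint, matching
per-timepoint volcano-style analyses; fitting one prior across all
timepoints is possible by passing an explicit prior. The test suite
cross-checks the whole path against an independent implementation
(limma) to numerical precision.

`callDE()` flags a protein/timepoint when $p \le 0.05$ and
$|\log_2\mathrm{FC}| \ge 1$. Method descriptions of this style of
analysis sometimes state the looser one-sided "fold change > 1,
p < 0.05"; the two-sided two-fold reading is the default here because
it is the form under which headline DE counts are reported, and the
literal one-sided reading is available via `scale = "natural"`. No
multiple-testing correction enters the flag itself — the headline
counts are defined on raw p-values — but Benjamini–Hochberg adjusted
p-values are reported per timepoint alongside.

## Temporal modules

`buildProfiles()` assembles one 7-vector of log2 fold changes per DE
protein; timepoints where a protein was not testable contribute 0
("no evidence of change") and are flagged, the alternative of dropping
such proteins being selectable by filtering on the flags. Profiles are
clustered **unstandardized**: log2FC values are already commensurate
across timepoints, and z-scoring would erase amplitude differences
that are biologically meaningful here (a `standardize` option exists).

`kmeansModules()` is Lloyd's algorithm with k-means++ seeding, best of
50 restarts by within-cluster SS, and empty-cluster repair by
re-seeding from the farthest point — deterministic under one seed. k
is fixed at 6, mirroring the module structure this analysis is built
around (two down-regulated modules bottoming at 24 h/2 d, four
up-regulated modules peaking at 24 h, 2 d, 7 d, 14 d — see
`defaultModuleShapes()`); an elbow diagnostic can be computed from
`withinSS` over k but is deliberately not used for selection.
`wardHclust()` complements this with Ward's minimum-variance
agglomeration (merge heights equal to the increase in within-cluster
SS), and `moduleSummary()` reports each module's centroid, peak/trough
timepoint and size.

## Synthetic proteome generator

`simulateProteome()` draws per-protein baseline log2 abundance from
$N(20, 2^2)$ (≈ $10^6$ raw intensity, the typical LFQ center) and adds
replicate noise $N(0, 0.5^2)$ — the within-group variability scale at
which moderated testing is routinely exercised. The generator's
specification names a single baseline SD; separating between-protein
spread (needed for abundance-dependent missingness to act across
proteins) from replicate noise required one extra parameter
(`noiseSdLog`), a deliberate design choice documented here. A fraction
`deFraction = 0.4` of proteins receives a group×time effect
`effectLog2FC × module shape`; 0.4 reflects the DE prevalence scale
(about 1100 of 2700 quantified proteins) that this class of experiment
reports, and the default effect size of 2 log2 units matches the
strongest reported marker responses (e.g. a +2.9 log2FC innate-immunity
receptor peaking at 2 d). Censoring is a single global detection
limit: each value goes missing with probability
$\mathrm{logistic}((c_q - x)/0.5)$, $c_q$ the 15th percentile of all
log2 intensities — i.e. ~15 % missingness concentrated at low
abundance, with a soft shoulder rather than a hard cut. Unique-peptide
counts are $1 + \mathrm{Pois}(2)$ with 5 % forced zeros so the
identification filter is exercised.

Not emulated: peptide-level evidence, shared/razor peptides,
correlated replicate structure (batch effects), heteroscedasticity
beyond the glog-stabilized regime, and any annotation layer (GO
enrichment is out of scope). Power and FDP numbers from this generator
characterize the pipeline under these conditions, not MaxQuant output
at large.

# Numerical choices and degenerate inputs

* Deconvolution requires an invertible basis; singular matrices error,
  naming the dependent rows. Rows are renormalized to unit norm before
  inversion (the shipped matrix rows are unit norm to 4 decimals
  already).
* `stainSignal()` clips negative concentrations at zero; the raw maps
  keep them.
* All-zero hematoxylin maps segment to zero components (not an error);
  uniform maps have no Otsu split and likewise return zero components.
* KS ties: $D$ is evaluated at pooled unique points; exact p assumes
  continuity, so ties emit a warning and fall back to the asymptotic
  distribution.
* k-means ties in assignment break to the lowest centroid index;
  restarts and seeding consume one RNG stream, so a single seed fixes
  the whole clustering.
* Ward heights are computed on squared distances scaled so each merge
  height equals its ΔSS; two points therefore merge at half their
  squared Euclidean distance.
* Tumor volumes use length × width² / 2; a width exceeding length
  warns (likely swapped calipers) rather than erroring.

# Problem sizes used by the test and acceptance suites

The shipped suites run entirely on synthetic data sized for a single
CPU: 240 × 144 px images (12 nuclei — the density of a representative
40× field crop) with 20-seed round-trips; 50-cohort power runs at 3
sections × 9 ROIs per group; proteome runs at 2,000 proteins × 56
samples with 6-seed averaging; module recovery at 600 profiles. These
sizes were chosen so each property is measured with comfortable
Monte-Carlo margins; all generators scale to larger sizes by argument.

# Known limitations

* The stain matrix is fixed, not estimated from the image
  (Macenko/SVD-style estimation is out of scope); images stained with
  substantially different protocols need a user-supplied matrix.
* Connected components are not split, so touching nuclei count as one;
  the generator avoids this regime by construction and real tissue at
  high density will undercount nuclei (S/N is less sensitive to this
  than counts, since area is preserved).
* The presence filter and per-timepoint testing assume the fixed
  2 × 7 × 4 design; unbalanced designs work but the validity checks
  expect every group × timepoint cell populated.
* Imputation assumes one global detection limit per sample and
  normality on the glog2 scale; strongly multimodal samples would bias
  the censored fit.
* DE flags use raw p-values by design; users wanting FDR-controlled
  sets should threshold the reported `p_adj` instead.
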