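# tiquant

Quantitative analysis of tumor responses to a bacterial (or other)
intervention, from two kinds of raw evidence:

1. **Brightfield IHC images** — how much of a marker (iNOS, CD3, C3,
   CD68, ...) is expressed in a tissue section, measured as the ratio
   of stained area to nucleus area (S/N) and compared between treated
   and control groups.
2. **Label-free proteome time courses** — which proteins change between
   treated (YB1) and control (PBS) tumors across seven timepoints
   (6 h – 14 d, four replicates each), and what temporal modules those
   changes form.

It is aimed at imaging/proteomics analysts who want the bespoke parts
of this workflow — stain unmixing with a fixed basis, level-set nucleus
segmentation, censored-normal imputation, moderated testing, temporal
clustering — as tested, scriptable R functions rather than a chain of
one-off scripts. Both pipelines come with synthetic-data generators
that carry complete ground truth, so the whole chain is verifiable end
to end on any machine.

## The statistics at the core

**IHC arm.** Stains mix additively in optical density
(Beer–Lambert), so a pixel's OD vector is unmixed per pixel as
`c = OD · M⁻¹` with the H-DAB stain basis

```
M = | 0.650 0.704 0.286 |   (hematoxylin)
    | 0.268 0.570 0.776 |   (DAB-like marker)
    | 0.711 0.423 0.561 |   (residual)
```

The marker concentration map is mapped to a 0–255 signal channel
`s = 255(1 − 10⁻ᶜ)` and binarized at per-marker thresholds (C3 70,
CD3 10, CD11c 30, CD68 20, F4/80 70, iNOS 70, Ly6G 25, CD19 10);
nuclei are segmented from the hematoxylin map by a Chan–Vese level set
initialized at the Otsu threshold. Per region of interest (9 per
section), `S/N = stained px / nucleus px`; groups are compared by the
two-sample Kolmogorov–Smirnov test (exact permutation distribution for
small samples) with tiers `* < 0.05`, `** < 0.01`, `**** < 0.0001`.

**Proteome arm.** After unique-peptide and presence (≥ 2 observed per
group per timepoint) filters, intensities are median-ratio scaled and
glog2-transformed, missing values are imputed from a left-censored
normal fit (QRILC-style truncated draws), and each timepoint is tested
with the empirical-Bayes moderated t

    s²_post = (d₀s₀² + d_g s_g²)/(d₀ + d_g),
    t̃ = log2FC / (s_post √(1/n₁ + 1/n₂)),  df = d₀ + d_g

with the prior (d₀, s₀²) fit by method of moments on log s². Proteins
with `p ≤ 0.05` and `|log2FC| ≥ 1` at ≥ 1 timepoint are DE and their
7-point log2FC profiles are grouped into k = 6 temporal modules by
k-means (k-means++ seeding, 50 restarts), with Ward hierarchical
clustering as a companion view.

## Worked example

```r
library(tiquant)

## --- IHC: simulate a section, quantify a marker over 9 ROIs ---
sim <- simulateIHCImage(seed = 42)          # 240x144 px, 12 nuclei
q <- quantifyMarker(sim$image, "iNOS", rois = extractROIs(240, 144, 9))
q[, c("roi", "S_px", "N_px", "ratio", "defined")]
#>   roi S_px N_px  ratio defined
#> 1   1   96  182 0.5275    TRUE
#> 2   2    0    0     NA   FALSE     <- ROI without nuclei: excluded
#> 3   3    0  173 0.0000    TRUE
#> 4   4   58  388 0.1495    TRUE
#> 5   5  180  112 1.6071    TRUE
#> ...
sim$truth$trueSN
#> [1] 0.2204    # whole-frame truth; the whole-frame pipeline ratio matches

## --- compare a treated cohort (3x marker area) against control ---
tr <- simulateIHCCohort(seed = 10, nMarkerBlobs = 12)  # 3 images x 9 ROIs
ct <- simulateIHCCohort(seed = 11, nMarkerBlobs = 4)
compareMarkers(tr, ct)
#>   marker n1 n2 excluded1 excluded2     D       p tier     method
#> 1   iNOS 27 27         0         0 0.444 0.00966   ** asymptotic
```

The planted 3-fold difference in marker area is detected at tier `**`:
the KS statistic D = 0.44 is the largest gap between the two empirical
S/N distributions, and 27 ratios per group put p below 0.01.

```r
## --- proteome: simulate 1000 proteins, run the DE cascade ---
psim <- simulateProteome(nProteins = 1000, seed = 1)
de <- runDEPipeline(psim$experiment, seed = 1)
de$countsByTimepoint
#>  6h 12h 24h  2d  3d  7d 14d
#>  26 111 180 191 180 173 134
de$unionCount
#> [1] 368       # proteins DE at >= 1 timepoint (400 planted)

## --- temporal modules of the DE proteins ---
prof <- buildProfiles(de$results)
km <- kmeansModules(prof$profiles, k = 6, seed = 1)
moduleSummary(km$labels, prof$profiles)[, 1:4]
#>   module  n peakTimepoint troughTimepoint
#> 1      1 97           24h             14d
#> 2      2 54            2d             14d
#> 3      3 84            6h              2d
#> 4      4 76            7d              6h
#> ...
```

DE counts peak at 24 h–2 d and the recovered modules peak/trough at
distinct timepoints, mirroring the planted module shapes
(`defaultModuleShapes()`).

Command-line wrappers over the same functions live in `inst/scripts/`
(`simulate-ihc.R`, `quantify.R`, `proteome-run.R`).

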