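---
title: "Methods: infrared chemotaxonomy of silk with silkir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: infrared chemotaxonomy of silk with silkir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(silkir)
```

## The measurement and its artefacts

Attenuated total reflection infrared (ATR-IR) spectroscopy probes the
chemistry of a sample pressed against an internal-reflection crystal. For
silk feedstocks and cocoons, the mid-infrared fingerprint carries protein
backbone bands (amide I/II/III), crystallinity markers from poly-alanine
(A)~n~ and poly(alanine–glycine) (AG)~n~ β-sheet domains, and bands from
non-protein components: the sericin glue protein, calcium oxalate crystals
excreted onto some cocoons, and plant-derived phenolics/tannins.

Two instrumental artefacts dominate between-measurement variation and must
be removed before any chemistry is compared:

* an **additive offset** (detector/baseline level), and
* a **multiplicative gain** from variable contact between a rough, porous
  cocoon and the crystal.

The pre-processing chain mirrors the standard protocol for such data:

1. **Offset subtraction** — subtract the mean absorbance over
   1900–1950 cm^-1^, a window free of silk bands.
2. **Area normalization** — rescale so the integrated absorbance over the
   800–1900 cm^-1^ fingerprint equals a constant (default 1; any positive
   constant is equivalent downstream, because correlation PCA and min–max
   scaling are scale-invariant).
3. **First derivative** (multivariate stage only) — a Savitzky–Golay
   smoothed derivative, window 9 points, polynomial order 2. The method is
   not forced by the protocol; SG is the standard chemometric choice and
   controls the noise amplification that makes the *second* derivative
   less attractive. Edge points are evaluated from the terminal window's
   fitted polynomial, so a globally linear spectrum has an exactly
   constant derivative everywhere.

Steps 1–2 cancel the gain and offset artefacts *exactly* — for any
spectrum `A`, gain `g > 0` and constant `c`, pre-processing `g*A + c`
equals pre-processing `A`. This identity is enforced by a property test,
and the synthetic generator (below) produces exactly these artefacts, so
generator and analysis assumptions are mutually consistent end to end.

## Band integration and the marker panel

Marker content is quantified as a **baseline-corrected band area**: the
trapezoidal integral over the band window minus the area under the chord
joining the spectrum values (linearly interpolated) at the two window
limits. Numerical choices, all exactly reproducible:

* trapezoid rule on the native grid with interpolated values at the exact
  window limits (matching common commercial software);
* a single interpolated anchor at each limit, not a multi-point average —
  the simplest reading of "a linear baseline between the interval limits";
* negative areas (concave-down local baselines) are reported as-is;
  clipping would bias the min–max scaling downstream.

The default five-marker panel uses the windows 740–800 (calcium oxalate,
779 cm^-1^ mode), 931–983 ((A)~n~ β-sheet, 961 cm^-1^), 984–1006 ((AG)~n~
β-sheet, 975/998 cm^-1^, chosen to exclude the 961 cm^-1^ band),
1094–1135 (phenolics) and 1384–1403 cm^-1^ (sericin serine marker). Where
published descriptions of these windows conflict, the definitions of the
plotted composition figures were taken as canonical; the panel is a plain
tibble (`marker_panel()`) and fully configurable.

Per-species composition (`aggregate_by_species()`) reports the mean and
*sample* standard deviation (n−1) per species × layer, then min–max
scales each marker's means to [0, 1] **pooled across layers** — inner and
outer layers share one axis, as composition figures plot them together. A
marker whose means are all equal has no scale; its scaled values are
defined as 0 and a warning is raised.

## Classification: correlation PCA + LDA

The multivariate analysis runs on first-derivative spectra (2853
variables on the default 500–6000 cm^-1^ grid — the unique uniform grid
consistent with that range and variable count).

**Pearson PCA** is PCA on the correlation matrix: variables are
standardized to unit variance before the eigendecomposition (computed via
the SVD of the standardized matrix; a dense `eigen(cor(X))` serves as the
test oracle). Standardization makes results invariant to per-variable
rescaling. Constant variables carry no correlation information and are
dropped with a warning, recorded in the model. Default retained
components: 10 for feedstock-style runs, 40 for cocoon-style runs.

**LDA** maximizes between-species over within-species scatter of the PC
scores. Implementation contract:

* the pooled within-class covariance is shrunk toward its diagonal,
  `(1−s)·S + s·diag(S)`, default `s = 1e-4`, guarding near-singularity;
  `s = 0` with singular scatter raises an error advising shrinkage;
* scatter matrices use 1/n normalization, so the model is a function of
  class moments only — duplicating every training spectrum changes
  nothing;
* discriminant factors are scaled to unit pooled within-class covariance
  and ordered by decreasing discrimination eigenvalue, with percent
  discrimination reported per factor;
* classification assigns the **nearest class centroid in factor space**
  under equal priors (ties, which have probability zero for continuous
  data, go to the first label in sorted order). In the whitened factor
  space this is the classical Fisher-LDA rule; the original protocol does
  not state its decision rule, and this is the natural reading of its
  "discrimination function" language.

Hold-out validation uses a single random split (e.g. 27 of 52 feedstock
spectra for training, or 962 of 1162 cocoon spectra). Splits default to
**stratified by species** with largest-remainder allocation and at least
one training spectrum per class, guaranteeing every species can be
predicted; a pure-random mode reproduces the literal "randomly selected"
protocol. All randomness flows from one explicit seed recorded in the
outputs. Hit rates are reported at species and genus level; a genus is a
coarsening of species, so the genus rate can never be lower.

## Species trees

Species centroids of the 10 largest-discrimination factors feed a Ward
agglomerative clustering of their pairwise Euclidean distances. Merge
heights are reported on the **Euclidean scale** (two singletons merge at
their Euclidean distance), so distance thresholds quoted on that scale —
e.g. grouping species closer than 525 — apply directly; because Ward
implementations differ on this convention, the squared scale is available
behind `height_scale = "squared"`. The agglomerative (bottom-up) form is
the one consistent with "starting from singleton clusters".

`cut_tree()` groups species connected by merges **strictly below** the
threshold. `to_newick()` exports the ultrametric tree with every
root-to-tip path equal to half the root merge height. `compare_trees()`
quantifies agreement with a reference phylogeny: Robinson–Foulds distance
on unrooted topologies, its normalization by the maximum 2(n−3), and the
Pearson correlation of cophenetic distance matrices when both trees carry
branch lengths. The original comparison of spectral and genetic trees was
visual; these statistics are the package's quantitative counterpart.

## The synthetic generator

No raw spectra were deposited with the original study, so the package
ships a forward simulator that provides labelled ground truth for every
stage. A spectrum is composed as

```
A(v) = gain * sum_k c_k * B_k(v) + offset + slope * v + noise(v)
```

where the component spectra `B_k` are sums of pseudo-Voigt peaks
(70% Gaussian by default) at the classic silk band positions — 961 for
(A)~n~, 975/998 for (AG)~n~, 1315/779 for calcium oxalate, ~1103 for
phenolics, ~1395/1058 for sericin, the amide envelope, and broad water
bands. Band *positions* come from published assignments; widths
(10–40 cm^-1^ in the fingerprint) and relative amplitudes are free
parameters fixed once in a versioned library (`peak_library()`), chosen
to be qualitatively realistic, not to reproduce any real silk spectrum.

Concentrations follow a genus → species → replicate hierarchy: genus
profiles, lognormal per-species offsets (fixed by a scenario-level seed,
so a scenario is a deterministic object), and lognormal replicate noise
(`within_species_cv`). This is the minimal structure that makes both
species-level discrimination and genus-level tree recovery non-trivially
testable. The measurement model draws a lognormal contact gain, a normal
baseline offset and slope, and white noise — exactly the artefacts the
pre-processing removes (gain, offset) or tolerates (slope, noise).

Bundled scenarios:

* `paperlike_scenario()` — 35 species in 5 genus-level groups × 2 cocoon
  layers × 18 replicates (1260 spectra): one phenolic-rich group, one
  calcium-oxalate-rich group, one highly crystalline (A)~n~ group, one
  (AG)~n~ group with sericin-rich outer layers, one intermediate group;
  outer layers enriched in oxalate/phenolics/sericin.
* `feedstock_scenario()` — six feedstock species, 52 spectra, component
  differences far exceeding the replicate spread, emulating a
  strongly-separated identification study.
* `marker_recovery_scenario()` — independent uniform marker
  concentrations per species on top of a constant amorphous scaffold that
  dominates the normalization area, so scaled composition means can be
  compared to the generating concentrations by rank correlation.
* `simulate_latent_mixture()` — random nonnegative mixtures of exactly 10
  latent pseudo-Voigt components, for rank-structure checks.

### What the noise fraction of the latent mixture means

The rank-structure property of interest is "data from 10 latent
components with at most a 5% noise share keep ≥ 90% of correlation-PCA
variance in 10 components". For that statement the noise share must be
measured in the domain the PCA decomposes: standardized first-derivative
spectra, where every variable counts equally. White noise that accounts
for 5% of raw-domain variance accounts for roughly 25% of
derivative-domain variance (differentiation attenuates smooth signal, not
noise), and under that reading the property is unattainable for *any*
generator. `simulate_latent_mixture()` therefore calibrates its
white-noise standard deviation (by root finding) so that the mean
per-variable noise share of the derivative-domain variance equals
`noise_frac`. The latent components tile the whole simulated range, so no
channel is strictly signal-free — as with real derivative spectra.

### What `scale_noise()` scales

Noise-robustness experiments multiply `within_species_cv` and `noise_sd`.
The contact gain and baseline offset are *not* scaled: pre-processing
cancels them exactly, so inflating them cannot make classification harder
— at large factors they only produce unphysical spectra whose integrated
fingerprint absorbance is negative, which `normalize_area()` correctly
rejects.

### What the generator does not emulate

ATR optics (depth-dependent band distortion, anomalous dispersion),
instrument line-shape, polarization and fibre-orientation effects,
atmospheric CO~2~/water-vapour lines, and scatter artefacts are all out
of scope. Passing recovery tests therefore demonstrate the *statistical*
consistency of the pipeline with its own assumptions, not performance on
real silk spectra.

## Test and validation problem sizes

The validation suite runs the full pipeline at reduced sizes chosen to
exercise every stage while keeping each run in seconds: genus-recovery
uses `paperlike_scenario(n_per = 6)` on a 500–2000 cm^-1^ fingerprint
grid (420 spectra × ~780 variables, 20 simulation seeds), and
noise-robustness uses the 52-spectrum feedstock scenario at noise
multipliers 1/3/10/30 × 20 seeds. Generator defaults remain full-scale
(18 replicates per species per layer on the 2853-point grid).

## Known limitations

* `read_jdx()` handles only simple `(X++(Y..Y))` XYDATA blocks; CSV is
  the canonical interchange format.
* Only the single-random-split validation protocol is implemented — no
  cross-validation, kernel or regularized discriminants beyond diagonal
  shrinkage, and no variable selection.
* Band quantification is window integration only; no curve fitting or
  amide-I deconvolution.
* Trees carry no bootstrap support; comparison with a reference phylogeny
  is purely topological/cophenetic.

```{r session}
sessionInfo()
```
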