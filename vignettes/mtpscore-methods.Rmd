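---
title: "Tile-based HER2/CK immunofluorescence scoring: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tile-based HER2/CK immunofluorescence scoring: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Chromogenic HER2 immunohistochemistry is scored by eye on a four-level
ordinal scale (0, 1+, 2+, 3+), and equivocal cases are resolved by FISH,
which counts *HER2* gene copies per cell. Quantitative immunofluorescence
on tissue sections promises a continuous readout of HER2 protein
expression, but two obstacles stand between a fluorescence mosaic and a
number a pathologist can trust: the HER2 signal must be read only where it
is meaningful (epithelial cell membranes, not stroma and not nuclei), and
slide-to-slide staining variation must be cancelled so that cases stained
in different sessions remain comparable.

`mtpscore` implements a tile-based answer. A stained slide is acquired as
a mosaic of tiles in three channels: DAPI (nuclei), pan-cytokeratin (CK,
all epithelial cells) and HER2. Each tile is reduced to two numbers — its
mean CK and mean HER2 intensity over an epithelial, non-nuclear region of
interest — and the distribution of the per-tile HER2/CK ratio across a
case is summarised by a Gaussian fit. Normalising the fitted mean and
width by the same quantities of an IHC 3+ positive control stained in the
same batch yields the M-, Σ- and MTP-scores. Because no patient images are
distributed with the package, a seeded synthetic generator reproduces the
statistical structure this pipeline assumes, and every stage is tested
against generator ground truth.

## Per-tile quantification

For each tile the CK channel is thresholded with Otsu's criterion —
the threshold maximising the between-class variance of the intensity
distribution — to delineate epithelium. The implementation is exact
rather than histogram-quantised: every cut between consecutive distinct
intensity values is scored, which makes the result reproducible down to
the pixel and testable against brute-force enumeration. The DAPI channel
is thresholded the same way; the nuclear mask is dilated by
`dilation_radius` (default 1 pixel, guarding against partial-volume bleed
at the nuclear rim, since membranous HER2 abuts nuclei) and subtracted.

Otsu's method always finds *a* split, including in tiles that contain no
epithelium at all, so two guards empty the ROI of degenerate tiles: the CK
foreground must cover at least `min_foreground_fraction` (1%) of the tile,
and the CK threshold must exceed `noise_floor` (0.05 on the [0, 1]
intensity scale); otherwise Otsu is merely splitting background noise. The
same floor is applied to the DAPI threshold so that tiles without nuclei
are not eroded by a hallucinated nuclear mask. Tiles whose ROI is smaller
than `min_roi_pixels` (50) are marked invalid: means over a handful of
pixels are not stable measurements.

## Case-wise tile filtering

Tiles with little or no epithelium show a low tile-averaged CK signal and
must not contribute ratios. The per-tile CK means of a case are typically
bimodal — a dim stromal mode and a bright epithelial mode — and the lower
threshold is chosen by Otsu on that distribution. Three safeguards decide
whether the Otsu split is believed:

* the split must explain at least `bimodality_cutoff` (0.9) of the total
  variance. This cut-off must sit well above what unimodal data can reach:
  a unimodal normal attains ~0.64 at its best split and a uniform ~0.75,
  whereas two tight separated modes approach 1;
* the brightest `upper_filter_frac` tail is set aside before the
  assessment, because a rare saturating artifact tile otherwise reads as a
  spurious "bright mode" and pulls the threshold above the epithelium it
  should protect;
* the lower class must be dim, not merely distinct: its mean must fall
  below `lower_mode_ratio_max` (0.5) of the upper-class mean. Stroma sits
  near background; micro-structure inside a homogeneous epithelial mode
  does not.

When any safeguard fails the distribution is treated as unimodal and the
`fallback_percentile` (10th) of the CK means is used instead. After the
lower filter, the `floor(0.05 n)` brightest-CK tiles among the survivors
are removed — the guard against saturating fluorophore agglomerates — with
ties broken by tile id so filtering is deterministic. All safeguards are
expressed as ratios, so the filters commute with a global intensity
rescaling of the batch, a property the scoring relies on and the tests
assert.

Cases with fewer than `min_tiles` (20) usable tiles are reported
unscorable rather than silently emptied, mirroring the exclusion of
epithelium-poor slides from a clinical series.

## Ratio histogram, Gaussian fit and scores

Retained tiles contribute `her2_mean / ck_mean`. Because a case-level
staining-quality factor multiplies both channels equally, it cancels in
the ratio — this is the reason CK serves as the normalisation channel.
Ratios are histogrammed over `[0, max ratio of the batch]` (shared support
keeps cases of one batch comparable) with Freedman–Diaconis bin widths by
default; the bin rule is configuration, not substance.

A Gaussian `a·exp(−(x−µ)²/2σ²)` is fitted to the (bin centre, frequency)
pairs by Levenberg–Marquardt least squares, initialised from the
histogram's weighted moments. A single chi-square reweighting pass follows:
each bin is weighted by the reciprocal of the binomial variance the first
fit predicts for its frequency. On histograms built from a few dozen tiles
this improves the efficiency of the width estimate substantially (in a
Monte-Carlo at n = 60 tiles the relative SD of σ̂ falls from ~0.14 to
~0.11) at the price of a small positive bias that cancels in the
control-normalised score. Goodness of fit is judged on the unweighted
pass: its adjusted R² asks whether the histogram is Gaussian-shaped at
all, which is what the QC cut-off polices. Fits with adjusted R² below
`r2_min` (0.5) are excluded — the cut-off is the smallest round value that
rejects degenerate, epithelium-poor cases whose fits land just below 0.49
— as are cases with fewer than three occupied bins or non-converged fits.

Scores are defined relative to the batch's IHC 3+ positive control:
M = µ_case/µ_control, Σ = σ_case/σ_control, MTP = M·Σ. The positive
control therefore scores (1, 1, 1) identically, and a failed control fit
renders the whole batch unscorable, because the reference itself is gone.
The negative control is carried through for scatter-plot context and
baseline reporting; it does not enter the normalisation.

## Cohort analysis

Copy-number classes use closed lower bounds: Negative below 4, Equivocal
from 4 to below 6, Positive from 6. Score-versus-copy-number association
is summarised by the Pearson coefficient on the raw values and by the
exponent α of a power law `score ~ x^α`, fitted by ordinary least squares
in log–log space; non-positive values are excluded from the log fit with a
warning. Correlating against the *HER2*/CEP17 ratio instead is a matter of
passing `x_variable = "her2_cep17"`.

Intratumoural heterogeneity — two spatially distinct subclones with
different HER2 expression — produces a bimodal ratio distribution. The
package quantifies what is otherwise a visual impression: 1- and
2-component Gaussian mixtures are fitted (`mclust`), and a case is flagged
when the 2-component model wins by more than `bic_margin` (10) BIC units
*and* the component means are separated by more than `separation` (2)
pooled standard deviations. Both conditions together avoid flagging
heavy-tailed unimodal cases.

## The synthetic cohort generator

The generator emulates exactly the structure the analysis exploits, and
nothing more. Per tile: a disc-shaped CK+ epithelial region covering
30–60% of the tile (tiles contain epithelium with probability
`epithelial_fraction`, default 0.7), DAPI+ nuclear discs inside it with CK
and HER2 suppressed, a tile-level HER2 intensity drawn from
`Normal(e, cv·e)` truncated at zero, additive Gaussian pixel noise
(SD 0.01) and clipping to [0, 1]. A saturating CK disc is burned into a
random 2% of tiles, giving the upper filter something real to remove. Per
case: a staining-quality factor (log-normal, SD 0.1) multiplies CK and
HER2 equally, so the ratio-based scoring must — and does — cancel it.

The map from the ground-truth copy-number proxy to the expression level is
a monotone power law `e(n) = 0.6 (n/15)^1` spanning copy numbers 1.9–15;
it is a simulation choice, not an inferred biological law (real cohorts
contain copy-number-gain cases without overexpression, which this default
deliberately does not model). The tile-level dispersion grows with
expression, `cv(e) = 0.08 + 0.25 e`, reproducing the wider ratio
histograms of amplified tumours; with these defaults the ground-truth MTP
curve is convex (α ≈ 2.4) and its ideal Pearson correlation with the copy
number proxy is ≈ 0.95, consistent with the cohort-level behaviour the
method is designed to exhibit. Cohorts are organised in batches of 5 with
exactly one positive (IHC 3+) and one negative (IHC 0) control each.

What the generator does *not* emulate: optical PSF and stitching
artifacts, membranous (ring-shaped) HER2 localisation, cell-scale texture,
or any tissue morphology beyond "epithelial blob with nuclei". Passing
tests therefore demonstrate the correctness of the computation under the
stated statistical assumptions, not clinical performance on tissue.

Determinism is strict: every tile's RNG state derives from the case seed
and tile index, generation never touches the global RNG stream, and
identical (phenotype, seed) pairs yield bit-identical mosaics.

## Binding kinetics

The staining rationale rests on pseudo-first-order Langmuir kinetics of
antibody–antigen recognition at a surface. With association rate `k_on`
(M⁻¹s⁻¹; the per-molar convention makes `k_on·c_bulk` a rate, as the time
constant requires), dissociation rate `k_off` (s⁻¹) and bulk antibody
concentration `c_bulk` (M):

* desorption time `t_d = 1/k_off` (~10³ s for IgG),
* recognition time constant `τ = 1/(k_on c_bulk + k_off)` (~10² s),
* equilibrium occupancy `θ_eq = c_bulk/(c_bulk + K_D)` with
  `K_D = k_off/k_on`,
* occupancy `θ(t) = θ_eq (1 − e^{−t/τ})`, independent of surface antigen
  density.

Since τ is an order of magnitude below t_d, a few minutes of incubation
suffice and the bound-antibody signal stays proportional to antigen across
a concentration gradient — the basis of the simulated spotting experiment,
in which a 2-minute series with 2% multiplicative noise yields a Pearson
coefficient above 0.96. Long incubations lose this proportionality; the
package models that loss phenomenologically with a hyperbolic response
`b(1+k_sat)/(b+k_sat)` of the bound density `b`, chosen only to reproduce
the qualitative short- vs long-incubation contrast (saturation constant
`k_sat = 0.2`). It recovers the proportional model as `k_sat → ∞`, and a
longer incubation — higher occupancy — pushes the series deeper into
saturation. No mechanistic claim (epitope depletion, detector saturation,
steric crowding) is attached to it.

## Numerical choices and problem sizes

* Intensities are normalised to [0, 1] by the dtype maximum on read;
  16-bit TIFF round-trips are exact up to one quantisation step (the
  writer truncates rather than rounds).
* The exact-value Otsu threshold is reported as the midpoint of the
  optimal gap between consecutive intensities; a constant image returns
  its constant and is treated as having no foreground.
* Ties in the brightest-tile filter are broken lexicographically by tile
  id; `floor` is used for the 5% count, so fewer than 20 survivors lose no
  tile.
* The test suite exercises image-level paths at 64×64-pixel tiles; the
  cohort-recovery checks run the full pipeline at 128×128 pixels with 100
  tiles per case and 25 cases in 5 batches, and the exponent-recovery
  check zeroes all noise parameters (pixel noise, per-channel background,
  staining variation, artifacts) with a small constant dispersion (0.04)
  so the histogram remains fittable.
* Heterogeneity flagging defaults (`bic_margin = 10`, `separation = 2`)
  are deliberately conservative; fit failures default to "not flagged"
  rather than propagate.

## Known limitations

* The Gaussian-fit σ at realistic per-case tile counts (tens of tiles) has
  ~10% relative noise even after reweighting; Σ- and MTP-scores inherit
  it. Cohorts with many more tiles per case (as slide mosaics provide)
  shrink this proportionally.
* The lower CK threshold assumes stroma is dim; tissues whose
  non-epithelial compartment autofluoresces brightly in the CK channel
  would defeat the bimodality safeguards and require a manual threshold.
* The heterogeneity flag models exactly two subclones; gradual expression
  gradients are reported as (correctly) unimodal.
* The saturation model is phenomenological; its constant has no physical
  unit attached beyond the normalised bound-density scale.
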