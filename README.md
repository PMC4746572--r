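# mtpscore

Tile-based dual-channel immunofluorescence quantification and HER2 scoring
for tissue-section mosaics, with a seeded synthetic-cohort generator and a
Langmuir binding-kinetics module.

## What it does

HER2 status in breast carcinoma is routinely read as an ordinal IHC score
(0–3+) with FISH gene-copy counting (*N*<sub>FISH</sub>) for equivocal
cases. `mtpscore` implements a continuous, image-based alternative on
three-channel fluorescence mosaics (DAPI / cytokeratin / HER2):

1. **Per-tile ROI quantification** — Otsu auto-thresholding of the CK
   channel delineates epithelium; the dilated DAPI nuclear mask is
   subtracted (HER2 is a membrane marker); each tile yields one mean CK
   and one mean HER2 signal.
2. **Case-wise tile filtering** — tiles with little or no epithelium fall
   below a case-specific lower CK threshold (Otsu on the per-tile CK means
   with bimodality safeguards, percentile fallback); the
   `floor(0.05 n)` brightest-CK tiles are removed as saturating-artifact
   guards.
3. **Ratio scoring** — the tile-wise HER2/CK ratio (CK normalisation
   cancels staining-quality variation) is histogrammed and fitted with a
   Gaussian. With the batch's IHC 3+ positive control as reference:

   *M* = µ/µ<sub>ctrl</sub>, Σ = σ/σ<sub>ctrl</sub>, **MTP = M · Σ**.

   Fits with adjusted R² < 0.5 are excluded by QC.
4. **Cohort analysis** — FISH classification (Negative < 4 ≤ Equivocal
   < 6 ≤ Positive), Pearson correlation and power-law fits
   (score ∼ x^α) of scores against *N*<sub>FISH</sub> or the HER2/CEP17
   ratio, and Gaussian-mixture (BIC) flagging of two-subclone
   heterogeneity.
5. **Binding kinetics** — pseudo-first-order Langmuir model:
   τ = 1/(k<sub>on</sub>c<sub>bulk</sub> + k<sub>off</sub>),
   t<sub>d</sub> = 1/k<sub>off</sub>, θ(t) = θ<sub>eq</sub>(1 − e^(−t/τ)),
   plus a simulated antigen-spotting series quantifying why a 2-minute
   incubation keeps the antibody signal proportional to antigen while
   1-hour incubations saturate.

No patient data ship with the package: a deterministic synthetic generator
(`cohort_spec()`, `generate_cohort()`, `generate_tile()`) produces
three-channel tile mosaics and cohort tables with the statistical
structure the analysis assumes, including ground truth for every stage.

## Worked example

```r
library(mtpscore)

derive_kinetics(kinetic_params(k_on = 1e6, k_off = 1e-3, c_bulk = 1e-8))
#> $tau 90.9  $t_d 1000  $k_d_eq 1e-09  $theta_eq 0.909

spec <- cohort_spec(n_cases = 10, batch_size = 5, tiles_per_case = 80,
                    imaging = imaging_params(tile_size = 64), seed = 11)
coh  <- generate_cohort(spec)
meas <- lapply(coh$phenotypes,
               function(p) measure_case(generate_case_images(p, spec$imaging)))
res  <- score_cohort(meas, coh$records, default_config())
res$scores
#>    case_id        role n_tiles_retained    mu  sigma m_score sigma_score mtp_score qc_status
#> 1  case_01 pos_control               52 1.406 0.3534   1.000      1.0000   1.00000      pass
#> 2  case_02 neg_control               39 0.221 0.0178   0.157      0.0502   0.00790      pass
#> 3  case_03        case               53 0.720 0.0958   0.512      0.2711   0.13872      pass
#> 4  case_04        case               61 0.448 0.0530   0.318      0.1501   0.04780      pass
#> ...
correlate_scores(res$scores, coh$records)
#>   score_name   rho alpha n_cases
#> 1          M 0.998 0.921       6
#> 2      Sigma 0.991 1.375       6
#> 3        MTP 0.961 2.296       6
```

Reading it: each row is one case; `mu`/`sigma` are the fitted mean and
width of its HER2/CK ratio histogram; both positive controls score
exactly (1, 1, 1); scores rise monotonically with the ground-truth copy
number, and the MTP-score tracks it with Pearson ρ = 0.96 on this small
demonstration cohort.

The same pipeline runs from the shell (`inst/cli/mtpscore`):

```sh
Rscript inst/cli/mtpscore simulate --out cohort_dir --n-cases 10 --batch-size 5 --seed 11
Rscript inst/cli/mtpscore score --cohort cohort_dir/cohort.csv --images cohort_dir --out results_dir
Rscript inst/cli/mtpscore kinetics --t 120
```

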