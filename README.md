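# bmpgrad

Quantitative analysis of how the BMP signalling gradient patterns the
dorsal–ventral (DV) axis of the zebrafish gastrula.

During gastrulation, a ventral-to-dorsal gradient of BMP activity — read
out as nuclear phosphorylated Smad5 (pSmad5) — directs target genes into
nested ventral expression domains (*sizzled* narrow, *foxi1*
intermediate, *bambia* broad). Three models could explain how a cell
interprets the gradient at its position θ (DV angle, 0° ventral → 180°
dorsal):

* **threshold**: express gene *g* iff pSmad5(θ) ≥ T_g (a gene-specific
  concentration);
* **slope**: express iff |d pSmad5/dθ| ≥ S_g (a gene-specific spatial
  derivative);
* **duration**: express iff signalling above a common minimal level has
  lasted ≥ D_g minutes.

`bmpgrad` implements the full measurement chain used to discriminate
these models, plus a synthetic-embryo generator with known ground truth
so every stage is testable without imaging data:

* monotone Hermite gradient profiles for wild-type, *chordin*-mutant
  (laterally expanded, dorsally steepened) and *bmp7*-null (flat)
  genotypes, carrying the canonical boundary readouts — 60 / 25 / 7 %
  of maximum pSmad5 and slopes 1.4 / 0.76 / 0.35 A.U./degree at the
  *sizzled* / *foxi1* / *bambia* boundaries;
* spherical geometry: sphere fitting, gradient-based DV orientation,
  angular coordinates, rigid registration, 4,800-triangle surface
  patches;
* angular intensity profiles (40-µm bands and whole-cloud), locally
  weighted smoothing, slope estimation, censored-mean correction for
  zero-clipped noise, 8×8 expression heat maps and DV cluster calls;
* expression-boundary detection at 10 % of maximum with pSmad5 level
  and slope readouts at each boundary;
* the three in-silico experiments — genotype reshape comparison
  (Welch t-tests and relative deviations), ligand-pulse duration test,
  uniform-concentration dissociated-cell assay — combined into a model
  verdict.

## Worked example

Simulate five wild-type embryos under the threshold model, quantify
them, and compare against a *chordin*-mutant cohort:

```r
library(bmpgrad)
embryos <- simulate_cohort("wild_type", n_embryos = 5, seed_base = 1)
calls   <- quantify_cohort(embryos)
summarize_calls(calls)
#>      gene boundary_deg level_au level_pct_max slope_au_per_deg ... n
#> 1  bambia        135.1     7.59          7.45            0.310 ... 5
#> 2   foxi1        104.9    25.64         25.18            0.845 ... 5
#> 3 sizzled         74.6    60.93         59.81            1.307 ... 5
#> 4     ved        135.2     7.58          7.45            0.310 ... 5
```

Each row is a gene's expression boundary averaged over the cohort: the
DV angle where smoothed FISH falls to 10 % of its maximum, the pSmad5
level there (in A.U. and as % of the profile maximum) and the gradient
slope magnitude. The recovered levels (59.8 / 25.2 / 7.5 % of max)
match the generating thresholds (60 / 25 / 7 A.U. on a max-100
profile).

```r
chd <- simulate_cohort("chordin_mutant", n_embryos = 5, seed_base = 100)
compare_genotypes(calls, quantify_cohort(chd))
#>     gene level_wt level_mut slope_wt slope_mut rho_level rho_slope ...
#>  sizzled    60.93     58.59    1.307     0.745    0.0384     0.430
#>    foxi1    25.64     25.30    0.845     0.593    0.0133     0.298
#>   bambia     7.59      6.61    0.310     0.608    0.1292     0.959
#>      ved     7.58      6.60    0.310     0.607    0.1301     0.962
#> threshold model supported: TRUE
#> slope model supported:     FALSE
```

Although the *chordin* mutant's gradient is reshaped (half the lateral
slope, twice the dorsal slope), the pSmad5 *level* at each boundary is
conserved (relative deviations ≤ 0.13) while the *slope* at the same
boundaries shifts by 30–96 % — the signature of concentration-threshold
interpretation. `simulate_pulse_experiment()` and
`simulate_dissociated_assay()` with `duration_test()` /
`concentration_test()` complete the verdict against the duration model.

See `vignettes/gradient-interpretation.Rmd` for the model, estimator
and calibration details.

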