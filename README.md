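# telonoise

Simulation and analysis of **telomere-adjacent gene expression noise** —
the elevated cell-to-cell and population-to-population expression
variability of genes sitting next to telomeres, driven by reversible
chromatin silencing (telomere position effect).

`telonoise` is aimed at quantitative biologists studying expression noise
in fungi (the motivating system is the subtelomeric *TLO* gene family of
*Candida albicans*) and at methodologists who need a tested, seedable
reference implementation of the statistics this literature uses:

* **Variability statistics** — coefficient of variation (sd/mean, n−1
  denominator), per-gene cross-condition mean CV, ΔCT relative abundance
  (`2^-ΔCT` against a control gene), two-sided variance-ratio (F) tests.
* **Flow cytometry** — measurable-scatter gating and the quantile-based
  **Robust CV**, `100·0.5·(P84.13 − P15.87)/median`, which equals
  `100·σ/median` for a Gaussian.
* **Dual-reporter noise decomposition** — with both channels scaled to unit
  mean, `η²int = ⟨(g−r)²⟩/2`, `η²ext = ⟨gr⟩ − 1`, `η²tot = η²int + η²ext`
  (exactly), plus a paired t-test of the components across populations.
* **Resampling tests** — a bootstrap gene-set variability test (mean CV of
  a set against random same-size sets, 97.5%-quantile critical value), a
  CV-ratio label-randomisation test, and a lower-tailed mother–daughter
  permutation test of expression heritability. All empirical p-values use
  the add-one estimator and can never be zero.
* **Positional analysis** — telomere-rank assignment from BED-like
  coordinates, rank-by-rank gene-set scans, and distance trends.
* **Image quantification** — z-stack sum projection and the 4×4-pixel
  region protocol: mean of three background-subtracted nuclear boxes per
  nucleus.
* **Synthetic data** — a two-state (telegraph) chromatin-toggling
  generator for all of the above: per-cell and dual-allele fluorescence,
  colony founder effects with heritable state, mother–daughter pedigrees,
  multi-condition expression matrices with rank-graded switching rates,
  debris-laden flow event streams, and rendered nuclear image stacks with
  ground truth.

Everything is tidyverse-shaped: data frames in, tibbles out, `tidy()` /
`glance()` for fitted results, `autoplot()` for resampling nulls.

## Worked example

Twelve dual-reporter populations of 50 cells from a toggling locus
(`mu_on = 100`, `mu_off = 5`, intrinsic CV 0.3, extrinsic log-sd 0.15),
decomposed and compared:

```r
library(telonoise)
library(dplyr)

p <- telegraph_params(k_on = 0.5, k_off = 0.5, mu_on = 100, mu_off = 5,
                      cv_intrinsic = 0.3, sigma_extrinsic = 0.15,
                      cv_measurement = 0)
cells <- purrr::map(1:12, ~ make_telegraph_population(
  p, 50, seed = 100 + .x, n_alleles = 2,
  population_id = sprintf("pop%02d", .x))) |> bind_rows()
dec <- decompose_noise(cells)
head(dec, 3)
#> # A tibble: 3 × 6
#>   population_id n_cells eta_int2 eta_ext2 eta_tot2 r_channels
#>   <chr>           <int>    <dbl>    <dbl>    <dbl>      <dbl>
#> 1 pop01              50    0.267    0.719    0.986      0.729
#> 2 pop02              50    0.171    0.862    1.03       0.835
#> 3 pop03              50    0.178    0.738    0.916      0.806

paired_component_test(dec)
#> # A tibble: 1 × 5
#>   statistic    df     p.value mean_intrinsic_fraction n_populations
#>       <dbl> <dbl>       <dbl>                   <dbl>         <int>
#> 1     -11.9    11 0.000000122                   0.172            12
```

The decomposition splits each population's squared noise into an intrinsic
(allele-autonomous) and an extrinsic (cell-wide, including the shared
chromatin state) component; here the shared ON/OFF state dominates, so the
intrinsic fraction is low and the paired t-test finds extrinsic
significantly larger.

Heritability of the chromatin state across a mother–daughter pedigree
(10 pairs × 50 cells, slow switching):

```r
ped <- simulate_pedigree(telegraph_params(sigma_extrinsic = 0.2), seed = 7)
res <- pedigree_permutation_test(ped, n_perm = 2000, seed = 8)
res
#> <telonoise resampling test>
#>   statistic: mean |difference in mean ln(expression)| = 0.4915
#>   null: 2000 resamples; critical value (5% tail) = 0.7232
#>   empirical p = 0.01499 (significant)
```

True pairs differ by 0.49 ln-units on average while randomised affiliations
differ far more (5% null quantile 0.72), so the expression state is
significantly heritable. `tidy(res)` gives the one-row summary and
`autoplot(res)` the null histogram with the observed statistic.

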