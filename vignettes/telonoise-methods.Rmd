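---
title: "Quantifying telomere-adjacent gene expression noise with telonoise"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying telomere-adjacent gene expression noise with telonoise}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telonoise)
library(dplyr)
```

## The problem

Genes located next to telomeres are subject to reversible chromatin
silencing: heterochromatin nucleated at the telomere spreads inward and
switches a locus between a transcriptionally active and a silent state. In
fungal genomes — the motivating system is the subtelomeric *TLO* gene family
of *Candida albicans* — this toggling produces two distinct signatures of
expression variability:

* **cell-to-cell noise**: within one population, cells span a wide range of
  expression because each cell's locus may be open or closed, and
* **population-to-population plasticity**: colonies founded by single cells
  inherit the founder's chromatin state, so independent isogenic populations
  differ in mean expression far more than technical error allows.

`telonoise` implements the quantitative toolkit needed to measure both
signatures and to test whether they behave as position-dependent, heritable,
toggling-driven phenomena: variability statistics, dual-reporter noise
decomposition, bespoke bootstrap/permutation tests, telomere-rank positional
scans, region-based image quantification — and a synthetic-data generator
that produces every input with the statistical structure those analyses
assume, including ground truth for recovery tests.

## The generative model

All simulators share a two-state **telegraph** model
([`telegraph_params()`]). A locus toggles between an active state (mean
expression $\mu_{on}$, arbitrary fluorescence units) and a silent state
($\mu_{off} < \mu_{on}$) at rates $k_{on}, k_{off}$ (events per cell
generation). For a single time point, cells are drawn from the stationary
distribution, $P(\text{active}) = k_{on}/(k_{on}+k_{off})$; locked modes
(`locked_on`, `locked_off`) pin every cell to one state, mirroring selection
for or against expression of a counter-selectable marker (growth without
uracil versus 5-FOA). Measured expression of allele $a$ in cell $c$ is

$$ y_{ca} = E_c \,\mu_{s(c)}\, I_{ca} + \varepsilon_{ca}, $$

* $E_c$: a **shared extrinsic factor**, lognormal with unit mean and
  log-scale sd `sigma_extrinsic` — cell-wide differences (ribosomes,
  cell size, microenvironment) that hit all alleles equally;
* $I_{ca}$: a **per-allele intrinsic factor**, lognormal with unit mean and
  CV `cv_intrinsic` — allele-autonomous fluctuation;
* $\varepsilon_{ca}$: additive Gaussian **measurement noise** with sd
  `cv_measurement` times the pre-noise intensity, truncated at zero (the
  truncated count is reported in the `n_clipped` attribute).

Lognormal noise was chosen because fluorescence intensities are positive and
right-skewed in practice; no distribution is implied by the measurement
designs themselves. In two-allele (dual-reporter) mode both alleles share
$E_c$ *and* the chromatin state but draw independent $I_{ca}$, so the
inter-channel covariance carries exactly the extrinsic-plus-state component.
`telegraph_noise_components()` gives the resulting closed forms, used as the
parameter-recovery oracle: with $v_e = e^{\sigma^2}-1$, $v_i = cv_i^2$, and
$m_1, m_2$ the first two moments of the state mean,
$\eta^2_{ext} = (1+v_e)m_2/m_1^2 - 1$ and
$\eta^2_{int} = (1+v_e)(m_2/m_1^2)\,v_i$.

### Heritable structure: colonies and pedigrees

`simulate_colonies()` grows each colony as a synchronous binary tree: a
founder state is drawn, and every daughter flips state with probability
`p_switch_per_division` at each of `generations` divisions. Colony regions
are contiguous sectors of the lineage leaf order — a deliberate proxy for
spatial sectors of a colony, not a spatially explicit growth model. Slow
switching produces founder effects (large between-colony variance of colony
means); fast switching (the phenotype of deleting the silencing
deacetylase, e.g. *SIR2*) drives every colony to the same stationary
mixture. `simulate_pedigree()` applies the same process to mother/daughter
population pairs sharing one founder state, the design behind the
heritability permutation test.

### Replicate-level expression matrices

`simulate_expression_matrix()` emulates a multi-condition RNA-Seq design
(default 11 conditions × 2 biological replicates) over a synthetic genome of
`n_arms` chromosome arms whose telegraph parameters depend on telomere rank.
A subtlety matters here: if each replicate value were a *single* stationary
draw, the switching rates would be invisible — only the stationary fraction
would matter, and "slow" versus "fast" toggling would be indistinguishable.
Biological replicates are cultures grown from founder cells, so each value
is modelled as the mean of a small founder-seeded population (64 cells, 6
divisions, per-division flip probability $1-e^{-k}$). Slow toggling then
yields founder-dominated, near-bimodal replicate means (high CV across
replicates), fast toggling well-mixed replicates (low CV), at identical mean
occupancy — which is the phenomenon the rank-graded analyses look for.

### Rendered image stacks

`render_nuclei_stack()` renders nuclei as 2-D Gaussian spots (peak amplitude
equal to the cell's latent signal) on a grid, split across 8 focal planes
with Gaussian axial weights, plus a uniform or graded background and
optional per-frame Gaussian read noise or Poisson counting noise. It emits
the three 4×4-pixel nuclear and three adjacent background boxes per cell
that the quantifier consumes, and a truth table whose `expected_signal` is
the value of the box estimator applied to the *noiseless* rendering — so
recovery tests compare like with like and are exact when noise is off.

## The estimators

* **CV** (`coefficient_of_variation()`): sample sd (n−1 denominator — the
  measurement protocols do not pin down the denominator, so the unbiased
  sample form is used throughout) over the mean. `gene_condition_cv()`
  computes per-condition CVs across replicates and averages them unweighted
  across conditions (equal weighting chosen; replicate-count weighting is
  not, since designs are balanced); conditions with fewer than two
  replicates are skipped, never imputed, and non-positive means raise
  rather than emit infinities.
* **Robust CV** (`robust_cv()`): $100 \cdot 0.5\,(P_{84.13} -
  P_{15.87})/\mathrm{median}$, the quantile-based dispersion reported by
  flow-cytometry software. Percentiles use linear interpolation between
  order statistics (index $p(n-1)$, `stats::quantile` type 7). For a
  Gaussian the half-spread between those percentiles is exactly $\sigma$.
  FL1 is treated on the linear scale as exported; no log transform is
  applied first (switchable by transforming the input).
* **Gating** (`gate_events()`): "measurable" forward/side scatter is
  interpreted as strictly positive, with configurable instrument
  thresholds. Gating is idempotent and the gated fraction is recorded.
* **Dual-reporter decomposition** (`decompose_noise()`): the classic
  two-reporter estimators on channels pre-scaled to unit mean:
  $\eta^2_{int} = \langle (g-r)^2 \rangle / 2$, $\eta^2_{ext} = \langle g r
  \rangle - 1$, $\eta^2_{tot} = \eta^2_{int} + \eta^2_{ext}$ exactly.
  Unit-mean scaling stops unequal fluorophore brightness masquerading as
  intrinsic noise. Slightly negative extrinsic estimates are reported raw
  with a warning — clamping would bias `paired_component_test()`, the
  paired t-test of $\eta^2_{int}$ versus $\eta^2_{ext}$ across independent
  populations.
* **Nuclear quantification** (`nuclear_intensity()`): background is the
  pooled mean of the three background boxes; each 4×4 nuclear box is
  background-subtracted and the three values averaged. The pairwise
  (box-by-box) alternative is exposed via `background = "paired"`; the two
  coincide whenever the background boxes agree, and the pooled form is the
  default because it uses all 48 background pixels for each region.
  Negative signals are kept (count logged) so downstream CVs stay unbiased.

## The resampling tests

All empirical p-values use the add-one estimator $(1 + \#\{\text{null at
least as extreme}\})/(B+1)$, which is never zero and respects the
$1/(B+1)$ floor. Tail orientation is explicit per test: the gene-set and
CV-ratio tests are upper-tailed (is the target *more* variable?), the
pedigree test lower-tailed (are true pairs *more similar* than random?).
Nulls are also summarised by their 2.5/5/95/97.5% quantiles, with the
97.5% (or 5%) quantile reported as the critical value.

* `geneset_variability_test()`: observed = mean `mean_cv` of the target
  set; null = means of random same-size gene sets sampled uniformly
  *without* replacement within a set and independently across sets.
* `cv_ratio_test()`: observed = CV ratio between two cell groups; null =
  ratios after randomising group labels on the pooled cells, preserving
  group sizes.
* `pedigree_permutation_test()`: populations are summarised by the mean of
  per-cell ln intensities (the per-population mean was chosen over a
  per-cell aggregation, which the experimental description leaves
  ambiguous; the median is exposed as an option), and daughter labels are
  permuted among mothers as full random relabelings — derangements are not
  enforced, matching the idea of "randomized affiliations". Both the
  5%-quantile criterion and the empirical p are reported, since either can
  serve as the decision rule.
* `subsample_cells()` equalises cell counts across strains before noise
  comparisons; the draw depends on sorted cell ids, so results are
  invariant to input row order.

All resamplers consume a mandatory integer seed and restore the caller's
RNG state, and every generator is bit-reproducible given its seed.

## Positional analysis

`assign_telomere_ranks()` places each gene (0-based, half-open coordinates)
on the arm whose telomere is nearer to its closest edge (ties go left;
a centromere table overrides the midpoint split), computes
distance-to-telomere from that edge, and ranks genes within arms (rank 1 =
most telomere-proximal; distance ties broken by gene id).
`positional_group_scan()` forms, for each starting rank $k$, the set of the
`group_size` genes with rank ≥ k closest to the telomeres (ordered by rank,
then distance — with 8 arms and sets of 16 this pairs ranks $k$ and $k+1$,
generalising the pooling of two genes per arm across arms) and tests each
set with the gene-set bootstrap. `distance_trend()` regresses `mean_cv` on
either distance-to-telomere or distance-from-centromere; both orientations
are emitted because published axes differ between figures and the two are
mirror images within an arm.

## Scenarios, problem sizes and reproducibility

`run_scenario()` packages eight end-to-end analyses (gene-set CV, positional
scan, dual reporter, pedigree, colony founder effect, flow noise, lock
selection, image recovery) behind `scenario_config()`: synthetic inputs in,
deterministic JSON report out, with provenance (parameters, seed, package
version) written next to any on-disk output. The test suite and
`scripts/acceptance.R` exercise the pipeline at sizes chosen to make
Monte-Carlo error small relative to the asserted effects while keeping a
full run in minutes on one core: populations of 10,000–20,000 cells for CV
and component-recovery checks, 500-gene/8-arm genomes with 2,000–5,000
bootstrap sets, 200 replicate simulations for power and type-I rates, and
50-nucleus image frames over 10 seeds.

## What the synthetic data do and do not show

The generator reproduces the *statistical structure* the analyses assume:
a two-state expression mixture, shared extrinsic scale, heritable founder
states, position-graded switching rates, debris-contaminated event streams,
and spot-plus-background images. It deliberately omits much of real data's
texture: no cell-cycle or bursty transcription kinetics beyond the
two-state mixture, no spatially explicit colony microenvironments, no
optical aberrations or segmentation errors, no instrument-specific
compensation. Passing recovery and calibration tests therefore shows the
*estimators and tests* are correct and well calibrated under their stated
assumptions — not that real measurements satisfy those assumptions.

Two modelling questions were left genuinely open by the biology and are
exposed rather than decided:

* **Mean preservation under locking.** Experimentally, locking a locus ON
  or OFF can reduce variability with little change in mean expression; a
  pure two-state mixture cannot lock to either state at unchanged mean.
  The generator does not impose mean preservation mechanistically —
  state-conditional means are independently configurable, so users can
  emulate either behaviour.
* **Fast switching as the silencing-mutant analogue.** Loss of the
  silencing HDAC is modelled as fast per-division toggling
  (`p_switch_per_division` ≥ 0.5), which lowers both between-colony and
  within-colony variability while leaving stationary occupancy unchanged —
  one of several mechanisms consistent with the phenotype.

## Worked example

```{r example}
p <- telegraph_params(k_on = 0.5, k_off = 0.5, mu_on = 100, mu_off = 5,
                      cv_intrinsic = 0.3, sigma_extrinsic = 0.15,
                      cv_measurement = 0)
cells <- purrr::map(1:12, ~ make_telegraph_population(
  p, 50, seed = 100 + .x, n_alleles = 2,
  population_id = sprintf("pop%02d", .x))) |> bind_rows()
dec <- decompose_noise(cells)
head(dec, 3)
paired_component_test(dec)
```

```{r pedigree}
ped <- simulate_pedigree(telegraph_params(sigma_extrinsic = 0.2), seed = 7)
res <- pedigree_permutation_test(ped, n_perm = 2000, seed = 8)
tidy(res)
```

```{r plot, fig.width = 5, fig.height = 3}
autoplot(res)
```

## Known limitations

* Stationary-state sampling (not time-course integration) represents
  single-time-point populations; a discrete per-division flip approximates
  continuous toggling, so rates above ~1 event/generation saturate.
* The paired t-test on noise components assumes approximately normal
  paired differences across populations; with very few populations the
  permutation machinery is the safer tool.
* The image quantifier matches a manual-annotation protocol; it performs
  no segmentation, deconvolution or flat-field correction by design.
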