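---
title: "Methods: electron/carbon balance accounting and community statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: electron/carbon balance accounting and community statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fermbal)
```

## Scope and model

`fermbal` analyses batch xylose electro-fermentation experiments in
microbial electrolysis cells. One *reactor batch* is described by a spec
(applied potential vs SHE, liquid volume, initial substrate, duration), an
endpoint metabolite panel (ethanol and acetate in µmol L⁻¹, hydrogen as an
absolute amount in µmol, optional biomass as µmol L⁻¹ of C₅H₇O₂N), and
either a chronoamperometry trace or its integrated charge. The package
computes, per reactor:

* the substrate degradation rate (mass-loss fraction of the initial
  substrate);
* per-product charges $C = F\,b\,V\,\Delta C$ with $F = 96{,}485$ C mol⁻¹ e⁻,
  $C_{\mathrm{H_2}} = 2 F n_{\mathrm{H_2}}$, and $C_I = \int I\,dt$;
* Coulombic efficiency $\mathrm{CE} = |C_I| / (F\,b\,V\,\Delta C\,M^{-1})
  \times 100\,\%$ with $b = 20$ e⁻ per mol xylose, and cathodic gas recovery
  $r_{CAT} = C_{\mathrm{H_2}} / |C_I| \times 100\,\%$;
* the carbon conversion efficiency (CCE) and electron conversion efficiency
  (ECE) partitions of the consumed substrate.

Only direct fermentation of xylose to ethanol, acetate and hydrogen is
accounted; secondary oxidation of the products is assumed negligible, and no
kinetic or thermodynamic modelling is attempted. Stoichiometrically the
accounting assumes the EMP route, in which 0.6 mol xylose yields 1 mol
pyruvate and hence 1 mol ethanol (with CO₂) or 1 mol acetate (with CO₂ and
2 H₂).

## Two electron conventions, kept apart

Two distinct electron bookkeepings are standard in this field and both are
needed:

* **Net transfer coefficients** `coulomb_b` (ethanol 3.4, acetate 0.6, H₂ 2,
  xylose 20 e⁻ mol⁻¹) convert a product concentration change into the
  coulombs implied by its formation from 0.6 mol xylose. These feed the
  product-charge equation and the CE denominator.
* **Full-oxidation electron equivalents** `electron_equiv` (xylose 20,
  ethanol 12, acetate 8, H₂ 2, biomass 20 e⁻ mol⁻¹) express each pool's
  total reducing power. These feed the ECE partition.

They live side by side in `species_constants()` and each equation uses only
its own column. The conventions imply two exact identities that hold for
*any* panel: the ECE ethanol share is $\tfrac{12/20}{2/5} = 1.5$ times the
CCE ethanol share, and the acetate (8/20 = 2/5) and biomass (20/20 = 5/5)
shares coincide across the two partitions. The test suite asserts both on
randomly drawn panels; they are useful consistency alarms for any externally
supplied partition table.

## Units and conventions

* The product-charge equation takes the concentration change directly as a
  *molar* quantity (µmol L⁻¹); no molar-mass division is applied inside the
  function. This is the only reading under which the per-product charges of
  the benchmark fixture reproduce their published integer values.
* Hydrogen is an absolute amount (µmol per reactor), not a concentration,
  because headspace gas is measured per reactor. For the ECE share, H₂ moles
  are compared against consumed-substrate moles (concentration × volume).
  A constant `molar_gas_volume()` (24.03 L mol⁻¹) is provided for
  volume-to-mole conversion when H₂ arrives as a gas volume.
* CE and $r_{CAT}$ use $|C_I|$ so that a reactor with net-negative exchanged
  charge (possible at a slightly cathodic applied potential) still reports
  positive efficiencies; the sign of $C_I$ is preserved in the report's
  charge table.
* Product yields are per mole of substrate *consumed*, not supplied; this is
  the convention under which all five fixture yields reproduce their
  published values simultaneously.
* A no-potential control is a spec with `applied_potential = NA` and no
  trace; CE and $r_{CAT}$ are reported as `NA` (not applicable), never as
  zero.
* Charge integration is the trapezoidal rule on the samples as given, with
  hours converted to seconds; no resampling or smoothing. Trace smoothing
  exists as an explicit, opt-in `smooth_trace()` step and is disabled in all
  tests.
* Each partition reports an `unaccounted` pool equal to 100 % minus the
  assigned shares; it may be negative only alongside the report's
  `overshoot` flag, which signals an inconsistent panel rather than being
  silently clipped.

## Trace summaries

`find_current_peak()` is the global maximum with ties broken by earliest
time. `segment_cycles()` reproduces the fed-batch operating rule of an
acclimating cell: a refeed threshold of 0.001 V by default (the operating
rule of the experiment the package models), with a one-sample hysteresis so
a single noisy sample below threshold cannot split a cycle. Cycle peaks and
bounds are reported per cycle; `peak_ratio()` compares two cycles'
acclimation gain.

## Community statistics

The community stage operates on OTU count tables (samples × taxa) and
follows the standard amplicon workflow. The standard computations stand on
**vegan**, **picante** and **ape** behind the package's interface:
rarefaction without replacement (`vegan::rrarefy`), Shannon diversity
(`vegan::diversity`), Bray–Curtis dissimilarity (`vegan::vegdist`), NMDS
(`vegan::metaMDS`, Kruskal stress-1 with monotone regression and random
restarts) and PERMANOVA (`vegan::adonis2`). Chao1 is implemented in the
package so both the bias-corrected form $S_{obs} + F_1(F_1-1)/(2(F_2+1))$
(default; defined when $F_2 = 0$) and the classic form are available, and is
cross-checked against `vegan::estimateR` in the tests. Faith's PD uses
`picante::pd`; basal polytomies are resolved with zero-length edges first,
which leaves PD unchanged.

Choices a user should know:

* **Shannon log base** defaults to 2 and is an explicit argument, because
  conventions differ between pipelines and the choice rescales the index.
* **Faith's PD includes the root path** by default (the "whole tree"
  reading); `include_root = FALSE` gives the minimal-spanning variant.
* **NMDS defaults**: $k = 2$, 20 random restarts, stress tolerance 10⁻⁶,
  300 iterations; coordinates are centred, and results are reproducible
  under the seed argument. The per-iteration stress trajectory of the
  underlying optimiser is not exposed; quality is judged by the final
  stress-1 value, which the tests require to be below 0.01 on
  configurations that embed exactly in the plane.
* **PERMANOVA** defaults to 9,999 permutations of the sample labels, seeded.
  With few samples the attainable p-value floor is set by the number of
  distinct relabellings, not by the permutation count.
* **Group tests** are Welch's t (unequal variances) per family, with a 95 %
  CI on the difference of means and *raw* p-values; multiplicity correction
  is left to the caller (`stats::p.adjust`) so the default matches the
  single-family confidence-interval display this analysis is usually read
  from. When both groups have zero variance the CI degenerates to the point
  difference and no t statistic is reported.
* **Rarefaction depth** defaults to the smallest sample total; samples below
  an explicit depth are dropped with a warning rather than silently padded.

## The synthetic-data generator

The generator exists so that every analysis stage has inputs with known
ground truth; its defaults describe a desk-scale version of the experiment
the package models.

* `make_current_pulse()` builds a single-peak trace that is Gaussian in
  log-time. The shape is an invented convenience: only the peak height, peak
  time and total charge are treated as meaningful, and the pulse width is
  solved by root-finding (`stats::uniroot` on the trapezoidal integral of
  the emitted grid) so the integral matches the target charge essentially
  exactly when noise is off. Infeasible targets (charge exceeding
  peak × duration) raise an error naming the violated bound. Noise is
  additive Gaussian, expressed as a fraction of the peak height, off by
  default.
* `make_reactor_batch()` writes the metabolite panel *exactly* consistent
  with the configured consumption and yields, so the analyser must return
  the configuration (the generator/analyzer round trip is tested to 10⁻³
  relative and is the module's acceptance surface). Biomass, whose assay
  basis varies between labs, is back-computed to close the carbon balance to
  a configured unaccounted fraction; configurations whose products already
  exceed the available carbon are rejected.
* `make_community()` draws Dirichlet-multinomial samples: a baseline taxon
  profile is drawn once (Dirichlet with concentration 2 over 50 taxa mapped
  to 12 families — small enough for brute-force oracles), pre-treatment
  samples scatter around it with precision `concentration` (default 200),
  and post-treatment samples redistribute mass so the configured dominance
  families (default 2) jointly hold the configured relative abundance
  (default 0.9, inside the 0.54–0.997 dominance range such experiments
  report). Sequencing depth defaults to 2,000 reads per sample — deliberate
  desk scale; the rarefaction constant 63,933 used by full-scale amplicon
  runs of this design is documented but not the default. The tree is a
  random coalescent over the taxa with exponential branch lengths.
* All randomness flows through the mandatory `seed`; identical seeds give
  identical objects.

What the generator does *not* emulate: compositional sequencing artefacts
(chimeras, contamination, variable library sizes), overdispersion structure
beyond the Dirichlet-multinomial, real trace noise (drift, spikes,
electrode fouling), and any kinetic coupling between the current trace and
the metabolite panel. Passing tests therefore demonstrate the correctness of
the accounting and statistics, not robustness to real-world measurement
pathologies.

## The benchmark fixture

`make_benchmark_fixture()` returns the five-reactor benchmark (control, −0.058,
+0.242, +0.542, +0.842 V vs SHE) populated with published endpoint values
and integrated charges; it drives the acceptance tests and
`scripts/acceptance.R`. Two published inconsistencies are carried as-is
rather than reconciled: the +0.242 V reactor's hydrogen amount (0.12 µmol)
does not match its separately published hydrogen charge (0.118 C; 2F × 0.12
µmol gives 0.023 C), and the +0.542 V consumption is taken as 95.5 % (the
value consistent with its published yield) although 92.4 % also appears in
the source record. Published Coulombic efficiencies for these reactors are
*not* reproducible from the CE equation with the published inputs (the
inputs actually used are unstated); the package follows the equation
literally and treats those four numbers as non-targets.

## Numerical choices and degenerate inputs

* Comparisons against published figures in the tests use one unit in the
  last printed digit, since several published values were themselves
  computed from rounded intermediates.
* Zero consumption makes yields, CE and the partitions undefined: these
  error rather than return 0/0 artifacts. Zero exchanged charge makes
  $r_{CAT}$ undefined (error), while a zero product concentration is a
  legitimate 0.
* `integrate_current` requires strictly increasing timestamps; duplicate or
  unordered times are rejected rather than sorted silently.
* Peak-detection ties take the earliest time, making rankings deterministic.
* Problem sizes in the default test run are deliberately small — ≤ 10
  samples per group, 20–50 taxa, 99–999 permutations, 200 replicates for
  the p-value-uniformity check — chosen so every check runs from a cold
  start in seconds while keeping binomial error well inside the asserted
  bands.

## Limitations

* The balance is endpoint-based; it cannot attribute charge or carbon over
  time within a batch.
* Biomass handling assumes the C₅H₇O₂N composition; organisms far from that
  elemental formula bias the biomass shares.
* The CCE/ECE partitions ignore CO₂ (not measured in this design), which is
  the main legitimate contributor to the `unaccounted` pool.
* PERMANOVA assumes exchangeable samples under the null; structured designs
  (repeated measures, blocks) need a restricted permutation scheme not
  exposed here.
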