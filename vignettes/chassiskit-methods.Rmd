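---
title: "Methods behind chassiskit: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind chassiskit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chassiskit)
library(dplyr)
```

chassiskit characterizes the genetic toolbox of *Synechococcus* sp.
PCC 7002: neutral integration sites, transformation efficiency, promoter
strength and regulation from a fluorescent reporter, and diurnal
regulation from qRT-PCR. This vignette explains the models and the
conventions the package commits to, including the places where the
underlying experimental conventions are ambiguous and a choice had to be
made.

## Neutral-site discovery

A *neutral site* is a genomic region where a cassette can be integrated
without measurable cost, operationalized here purely from annotation: a
maximal run of positions covered by **no** annotated feature on either
strand. Features are merged across strands and overlaps before
complementing (`IRanges::reduce()` then `gaps()`), because neutrality
requires the absence of anything annotated, not merely of genes on one
strand. Three conventions matter:

* **Coordinates are 1-based inclusive throughout**, with
  `length = end − start + 1`. The GFF3 reader keeps its native
  convention; the GenBank feature-table reader's locations are already
  1-based inclusive; BED output converts to 0-based half-open at the
  boundary.
* **"Greater than 1 kb" is strict**: a 1000-bp gap is excluded,
  a 1001-bp gap is kept. The default `min_len = 1000` reproduces the
  three-site result on the PCC 7002 chromosome (the shortest reference
  site, NS1, is 1026 bp).
* **The chromosome is linear by default.** PCC 7002's chromosome is
  circular, but the reference sites are internal, so linearity is
  harmless there; `circular = TRUE` joins an unannotated run touching
  the sequence end with one touching the origin into a single
  wrap-around gap (reported with `start > end`).

Annotated pseudogenes count as features and are never reported as
neutral: at least one annotated PCC 7002 pseudogene was later shown to
be functional, so "pseudogene" is not evidence of neutrality. Which
feature types enter the mask is a configuration knob
(`feature_types`, default `"gene"`) because the underlying scan's
feature set is not documented; for typical bacterial annotations gene
and CDS footprints coincide.

Candidate gaps get homology arms placed just inside their boundaries
(5′ arm anchored at the gap start, 3′ arm at the gap end, the cassette
between them), which mirrors how the reference NS1/NS2 constructs were
built (500-bp arms inside a 1026-bp gap) and fails cleanly when
`2 × arm_length` exceeds the gap. Predicted outcome tiers follow the
observed positive-fraction groupings: `below_minimum` (< 250 bp,
integration unreliable), `low` (250–499 bp, around 34% of colonies
PCR-positive), `moderate` (500–749 bp, around 61%), `high` (≥ 750 bp,
above 86%).

## Transformation efficiency

Efficiency is colony count corrected for plating dilution, expressed per
fmol of DNA, and scaled by the fraction of screened colonies with
confirmed integration:

$$\mathrm{eff} = \frac{\mathrm{cfu} \times \mathrm{dilution}}{\mathrm{fmol}}
  \times \frac{n_{\mathrm{positive}}}{n_{\mathrm{screened}}}$$

The mass-to-moles conversion assumes an average molecular weight of
**650 g mol⁻¹ per base pair** of double-stranded DNA, the standard
laboratory convention; it is a `mw_per_bp` argument because some
protocols use 660. Replicates aggregate as unweighted means with the
sample (n − 1) SD, the convention used for every reported value in the
package. Positive fractions are applied **per plate** rather than pooled
across replicates; with similar screen sizes per plate the two
conventions agree in expectation, and the per-plate form keeps each
observation self-contained.

## Promoter characterization

The reporter pipeline turns plate-reader time courses into the
tabulated quantities in four steps.

1. **Wild-type normalization at matched OD.** Undiluted fluorescence
   (`fluorescence × dilution_factor`; saturated wells are recorded at a
   known dilution) is divided by the wild-type undiluted signal linearly
   interpolated at the same OD730. Normalizing at matched cell density,
   not matched time, controls for the growth stage of the culture.
   Samples outside the wild-type OD range are dropped with a warning —
   extrapolation would manufacture data.
2. **Interpolation onto the reference OD grid** (0.4, 0.7, 1.0, 3.0,
   5.0), the densities at which the reference transcriptomic profiles
   were collected. Interpolation is piecewise linear and exact on
   piecewise-linear inputs; grid points outside the measured range are
   `NA`. On piecewise-linear data, normalization and gridding commute —
   a property the test suite checks — so the order of the two steps is
   not a hidden degree of freedom.
3. **Slope and regulatory class.** An OLS line is fitted to the
   replicate-mean profile over the grid (replicates are averaged first
   because the tabulated quantities are per-promoter means;
   per-replicate profiles remain available as an attribute). The class
   uses the fitted line evaluated at the grid endpoints,
   $\rho = (f_{5.0} - f_{0.4})/f_{0.4}$: more than +30% is
   stationary-phase expression, less than −30% linear-phase, otherwise
   constitutive. Working on the fitted line rather than the raw
   endpoints makes the rule noise-robust and exactly scale-invariant;
   the threshold is an argument. The slopes are fitted to the five grid
   points, not to all raw time points, since the grid is where
   fluorescence and transcript profiles are commensurable.
4. **Strength tier.** Mean normalized fluorescence with a two-sample
   equal-variance t test against the wild type (two-tailed, α = 0.05,
   per-replicate means as the experimental units, no multiple-testing
   correction since none is part of the reference convention). Tier
   cuts at 1.5 / 2 / 10 fold: promoters not significantly above
   1.5-fold are not useful expression tools; 2–10-fold is the moderate
   group; ≥ 10-fold the strong group. The 6–30-fold interval is empty
   in the reference panel, so the moderate/strong cut at 10 is
   unambiguous there; all cuts are arguments. When replicate variance
   is exactly zero (noise-free simulations), the t statistic's limit is
   taken instead: p = 1 for equal means, p = 0 otherwise.

Correlation between fluorescence and transcript profiles is Pearson's
product-moment coefficient over the shared non-missing grid points
(at least 3), undefined (NA) under zero variance.

## Diurnal qRT-PCR

Relative quantification follows 2^−ΔΔCT with the amplification
efficiency assumed to be exactly 2 (no Pfaffl-style efficiency
correction in this version). Technical replicates (default 3) are
averaged **on the C_T scale** before any exponentiation; no-template and
no-RT controls are excluded by label or an `is_control` flag. ΔC_T is
target minus reference (*rnpA* by default, a stable housekeeping gene),
ΔΔC_T is light minus dark, so a promoter up-regulated in the light has a
negative ΔΔC_T and a ratio above 1. The construction makes the ratio
exactly invariant to per-replicate plate offsets, which the suite checks
as a property.

Ratios convert to **signed fold-changes**: ratios ≥ 1 stay as is,
ratios < 1 become −1/ratio, so −1.33 means a 25% reduction in the light.
Biological replicates (default 2) average on the signed scale with the
sample SD; significance is the equal-variance t test on the replicate
ΔC_T values, light versus dark. Panel summaries count strains with
signed > 2, 1.5 < signed ≤ 2, and signed < 0, and report the mean of the
**unsigned ratios** (negative values converted back through
1/|signed| before averaging). The reciprocal-then-average convention is
used because it is the one that exactly reproduces the reference
panel's overall light-response mean of 1.31; averaging signed values
does not. Whether the reported spread on that mean is the SD of ratios
or of signed values is ambiguous in the reference convention; the
package reports the SD of ratios and treats only the mean as
authoritative.

## The synthetic-data generator

Every analysis stage has a generative inverse, so correctness is tested
as parameter recovery rather than against opaque fixtures.

* **Growth** is piecewise exponential-then-linear, continuous at the
  switch OD: cultures under moderate light show a very short
  exponential phase and then grow linearly, light-limited. Defaults:
  initial OD730 0.05, specific rate 0.25 h⁻¹ up to OD 0.4, then
  0.0334 OD730 h⁻¹ (the reference wild-type mean) for 240 h sampled
  every 12 h — long enough to span the full reference OD grid, sparse
  enough to keep simulations cheap.
* **Fluorescence noise is multiplicative lognormal** (plate-reader error
  scales with signal), mean-1 parameterized by a coefficient of
  variation. The default `noise_cv = 0.1` is a calibration choice — no
  noise magnitude is documented for the reference instrument — and sits
  at the upper end of what a well-maintained plate reader produces.
  Pattern shapes are linear in OD and centred so the grid mean equals
  the planted strength; the planted rise/fall (`pattern_span`, default
  0.6) sits well beyond the ±30% rule so that classification failures
  measure noise, not boundary effects. Detector saturation is emulated
  with power-of-ten dilutions, exercising the dilution-recording path.
* **C_T noise is additive Gaussian** on the cycle scale (the
  conventional error model for qPCR), with the target's light C_T
  shifted by −log₂(ratio).
* **Colony counts are Poisson** at the expectation implied by the
  efficiency formula, with binomial PCR screens, so the estimator is
  unbiased by construction and the tests verify it empirically.
* **Annotations** tile the chromosome completely except the planted
  gaps, with inter-feature spaces capped far below the detection
  threshold, so the planted gaps are provably the only recoverable
  ones.

Each generator draws from a pseudo-random stream derived from the seed
and a call-site label, so adding a generator to a study never perturbs
the output of existing ones, and a fixed seed gives byte-identical
files (written provenance blocks deliberately omit wall-clock
timestamps for the same reason).

What the generator does **not** emulate: pigment-dependent optical
interference (reabsorption of reporter emission by phycobiliproteins
and chlorophyll), plate position effects, autofluorescence drift,
qPCR amplification efficiencies below 2, and inter-biological-replicate
variance components beyond technical noise. Passing recovery tests
therefore demonstrate the pipeline's algebra and its robustness to the
modelled noise, not robustness to every artifact of real instruments.

## Numerical choices and problem sizes

* p-values come from the closed form
  $p = I_{\nu/(\nu+t^2)}(\nu/2, 1/2)$ (regularized incomplete beta via
  `pbeta`), cross-checked in the tests against numeric quadrature of
  the t density at 1e−10 and against `stats::t.test`.
* OLS and Pearson correlation use the textbook centred-sum formulas;
  constant predictors and zero-variance vectors are rejected or
  reported missing rather than silently propagated.
* Interpolation never extrapolates; missing grid points stay `NA` and
  downstream steps skip them.
* Tie-breaks in flanking-locus assignment are deterministic (longest
  extent, then coordinates, then locus tag), making gap reports
  invariant to input record order.
* Simulation sizes in the tests and the acceptance script — a ~3-Mb
  planted chromosome, 100 randomized genomes against the per-base
  oracle, 200 seeds per regulatory class, 500-seed qPCR and 1000-draw
  efficiency Monte-Carlos — were chosen to give stable Monte-Carlo
  estimates (binomial SEs well under the tolerances tested) while
  keeping the full suite around a minute of compute.

## Known limitations

* The qPCR sampling theory at the default study design (3 technical
  replicates at 0.3-cycle noise, 2 biological replicates) puts the
  median relative error of a recovered ratio near 12%; cutting it below
  10% requires a third biological replicate or lower-noise chemistry.
  The package reports what the design delivers rather than assuming a
  more favourable one.
* Strength tiers depend on the wild-type comparison; with a single
  replicate no significance can be assessed and promoters report as
  `not_significant` regardless of fold.
* The GenBank reader handles simple `start..end` and
  `complement(start..end)` locations only — enough for bacterial gene
  tables; joined/multi-interval locations are rejected explicitly.
* No blank/background subtraction beyond wild-type normalization, and
  no spectral-overlap correction; in heavily pigmented strains both can
  bias absolute (though less so relative) fluorescence.
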