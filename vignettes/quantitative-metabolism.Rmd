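---
title: "Quantitative metabolism of tumour-progression cell panels: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative metabolism of tumour-progression cell panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncoflux)
```

oncoflux implements the quantitative stages of a cell-line metabolism study:
extracellular-flux bioenergetics, natural-abundance correction of
stable-isotope-labelling (SIL) measurements, and the downstream
normalisation/significance statistics. This vignette explains the models,
the parameters that matter, and the choices made where the design was
genuinely open. The motivating application is a colorectal
adenoma-to-carcinoma cell-line panel, but nothing in the code is specific to
that system.

## 1. Extracellular-flux bioenergetics

### The assay and its normalisation

A mitochondrial stress test records oxygen consumption rate (OCR,
pmol O~2~/min) and extracellular acidification rate (ECAR, mpH/min) per well
over measurement cycles, with sequential injections of oligomycin (ATP
synthase inhibitor), FCCP (uncoupler), antimycin A + rotenone (electron
transport inhibitors) and optionally monensin (ionophore eliciting maximal
glycolysis). Because wells differ in cell number, every raw rate is divided
by the well's crystal-violet OD~595~ (`normalize_plate()`). This makes all
downstream quantities exactly invariant to a common rescaling of a well's
rates and OD — a property the test suite checks.

### Phase aggregation

The injections partition the cycle grid into half-open phases. Each phase is
collapsed to one rate per well (`summarize_phases()`). Which cycle(s) best
represent a phase is not uniquely determined by the assay; the defaults are

| phase | aggregator | why |
|---|---|---|
| basal | mean | steady state, average out cycle noise |
| oligomycin | min | full ATP-synthase inhibition |
| FCCP | max | peak uncoupled respiration |
| antimycin/rotenone | min | residual non-mitochondrial OCR |
| monensin | max | peak glycolytic acidification |

Extremum aggregators track the post-injection extreme and are robust to
injection transients, but they are *biased* estimators of a noisy plateau
(the minimum of three noisy cycles sits below the plateau by about
0.85 sd). Plateau-recovery checks in the test suite therefore use the `mean`
aggregator for every phase, the unbiased estimator; the aggregator choice is
configurable and always recorded in the output metadata.

### Respiratory parameters

From the phase aggregates (`respiratory_params()`):
non-mitochondrial OCR = post-antimycin/rotenone rate; mitochondrial OCR =
basal − non-mito; coupled OCR = basal − oligomycin; proton leak =
oligomycin − non-mito; maximal respiratory capacity MRC = post-FCCP OCR
(a configuration switch subtracts non-mito instead, default off); spare
respiratory capacity SRC = MRC − basal.

Noise can push derived rates negative. These are clamped to zero and the
well flagged, with the unclamped values retained in `*_raw` columns. To keep
the accounting identity `mito = coupled + leak` exact even under clamping,
the reported mitochondrial OCR is defined as the sum of the clamped
components; on clean data all three equal the naive differences. Wells with
clamped glycolytic terms are excluded from group averages by default
(`group_scope(exclude_flagged = TRUE)`), mirroring the routine QC pruning of
technical replicates.

### ATP production rates

`atp_fluxes()` decomposes ATP production at two states — basal, and maximal
(monensin-phase ECAR with FCCP-phase OCR). ECAR is converted to a total
proton production rate via the medium buffering power BP; the respiratory
(CO~2~/bicarbonate) contribution is subtracted using the carbonic-acid
equilibrium at the assay pH:

$$PPR_{tot} = \frac{ECAR}{BP},\qquad
PPR_{resp} = \frac{10^{pH - pK_1}}{1 + 10^{pH - pK_1}}
\cdot \frac{maxH^+}{O_2} \cdot OCR_{mito}$$

$$J_{ATP\text{-}glyc} = \max(PPR_{tot} - PPR_{resp},\,0)\cdot
\frac{ATP}{lactate} + OCR_{mito}\cdot 2\cdot P/O_{glyc}$$

$$J_{ATP\text{-}OxPhos} = OCR_{coupled}\cdot 2\cdot P/O_{oxphos}
+ OCR_{mito}\cdot 2\cdot P/O_{TCA}$$

The glycolytic index is `100 * J_glyc / (J_glyc + J_ox)` at baseline. The
default coefficients are the glucose-oxidation set
(`bioenergetic_coefficients()`): pK~1~ 6.093 at 37 °C, maximal H^+^/O~2~ 1.0,
ATP/lactate 1.0, P/O~glyc~ 0.167 (2 ATP per glucose over 12 O),
P/O~oxphos~ 2.486, P/O~TCA~ 0.121. Buffering power is medium-specific; the
default 0.1 mpH/pmol H^+^ suits standard bicarbonate-free assay medium in a
96-well format, but strict mode refuses to run without an explicit value.
Every result object echoes the coefficient set used.

Two properties are enforced rather than hoped for: totals decompose exactly
(`total = glyc + ox`), and the index is monotone — more acidification never
lowers it, more coupled respiration never raises it. Zero OCR with positive
ECAR gives index 100; a dead well (all rates zero) yields a flagged missing
index rather than 0/0.

```{r atp-example}
coef <- bioenergetic_coefficients(buffering_power = 0.1)
sim <- simulate_flux_plate(seed = 1)
ps <- summarize_phases(normalize_plate(sim$plate, sim$od), sim$protocol)
af <- atp_fluxes(ps, respiratory_params(ps), coef)
group_scope(af)[c("group", "j_atp_glyc_basal", "j_atp_ox_basal",
                  "glycolytic_index")]
```

### Nutrient-restriction ratios and group tests

Restriction experiments are summarised as paired per-replicate ratios
(restricted / replete) with a two-sided one-sample t-test against 1
(`nutrient_stress_ratio()`); zero-variance or single-replicate inputs are
reported as "not computable" instead of fabricating a p-value. Cross-group
comparisons use one-way ANOVA with Tukey HSD or Student's t
(`group_compare()`), with the conventional star coding at
0.05/0.01/0.001/0.0001.

## 2. Natural-abundance correction of SIL measurements

GC/MS intensities of a derivatized metabolite fragment mix the tracer signal
with natural heavy isotopes of every atom in the fragment — including the
C/H/Si that TBDMS derivatization adds. `build_correction_matrix()` builds the
forward model from the fragment's elemental formula: column *j* is the
theoretical mass-shift distribution when exactly *j* backbone carbons carry
label, i.e. the convolution of a tracer-purity binomial over the *j*
labelled positions, the natural-abundance distribution of the remaining
carbons, and those of all other elements. Defaults: IUPAC abundances
(overridable), tracer purity 0.99 (typical of commercial U-^13^C tracers),
and a row range of `n_tracer_carbons + 4` mass shifts — the +4 tail captures
most of the Si/S/O envelope; whatever spills past it is recorded per column
as truncated mass, so column sums remain auditable.

`correct_mid()` inverts the model by non-negative least squares
(`pracma::lsqnonneg`), then renormalises to a mass-isotopomer distribution
(MID) summing to 1. Non-negativity matters: with noisy data an unconstrained
solve can return small negative fractions, which are not valid MIDs. An
unconstrained solver with clamping is available (`solver = "pinv"`) and
agrees on clean data; the clamped mass is reported. The fit residual and the
matrix condition number are attached as diagnostics, and an ill-conditioned
matrix triggers a warning rather than silent garbage.

Summaries follow directly: fractional enrichment is `1 - m+0`
(`total_enrichment()`), isotopologue ratios such as m+5 glutamate / m+5
glutamine index glutaminolysis (`isotopologue_ratio()`, flagged when the
denominator is zero), relative abundance is total ion intensity over the
internal standard per cell (`relative_abundance()`), and heatmap matrices
use the log~2~ ratio-to-arithmetic-mean transform (`ratio_to_mean()`), which
is invariant to row scaling and satisfies `mean(2^row) = 1`.

The packaged fragment registry (`fragment_registry()`) ships curated
TBDMS [M−57]^+^ formulas for common TCA intermediates and amino acids. These
are editable defaults: laboratories differ in the ions they quantify, and
the registry should be checked against the local method before absolute
interpretation.

## 3. Proteomics and growth statistics

`differential_proteome()` reproduces the standard TMT downstream chain:
within-sample total normalisation (equal column sums), log~2~ transform,
per-protein Welch t-test with Satterthwaite degrees of freedom, BH
adjustment, and a conjunctive significance rule — BH q < 0.05 **and**
−log~10~ p > 1.3 **and** |log~2~ FC| > 0.48 (≈1.4-fold). The raw-p and FDR
filters are partially redundant; both are enforced as stated, favouring
fidelity over parsimony. Fold changes are differences of log~2~ group means,
matching the scale on which the test runs. Proteins constant across all
samples get p = 1 with a flag instead of NaN.

Growth and apoptosis series are normalised as in live-cell imaging practice:
confluence (or OD~595~) relative to the first timepoint
(`relative_growth()`), and caspase-reporter green-object counts divided by
relative confluence (`relative_apoptosis()`), with per-timepoint flags where
confluence is missing.

## 4. What the simulators emulate — and what they do not

Every stage has a generator returning data plus a serialised
`synthetic_truth` (parameters + seed; JSON at 17 significant digits, so
round-trips are bit-exact).

* `simulate_flux_plate()`: phase-plateau traces with a shared well
  cell-number factor scaling both rates and OD~595~ (log-normal, sd 0.2),
  additive Gaussian rate noise (sd 5 instrument units), and 1% multiplicative
  OD reading noise. Defaults: 12 wells/group (within the 6–15 technical
  replicates typical of 96-well stress tests), 3 cycles/phase, and a
  four-group plateau design in which an early-adenoma-like group has low
  ECAR and high spare capacity while progressed groups are more glycolytic.
  Not emulated: injection transients, drift within phases, edge-well
  effects.
* `simulate_labelling()`: intensities are `abundance * (correction_matrix
  %*% truth_MID)` with 5% multiplicative log-normal noise by default — the
  same forward model the correction stage inverts, which is exactly what
  makes recovery tests meaningful. Ground-truth MIDs default to a
  glutamine-anaplerosis-like pattern (glutamine/glutamate m+5, TCA
  intermediates m+4-dominated). Not emulated: chromatographic peak overlap,
  detector saturation, mass-resolution effects.
* `simulate_omics()`: log-normal proteomes with effects added on the log~2~
  scale (default measurement sd 0.1 log~2~ units, typical TMT triplicate
  precision) and logistic confluence curves with multiplicative noise.
  Not emulated: correlated proteins, missingness, batch structure.

Passing recovery tests on these simulations demonstrates that the
*computational* chain is correct and calibrated under its stated noise
model; it does not validate the noise model itself against any particular
instrument.

## 5. Numerical choices and problem sizes

* NNLS inversion; renormalisation after solving; residuals and clamped mass
  reported, never silently discarded.
* Negative derived rates clamp to 0 with flags (never errors), preserving
  plate-level analysis of noisy wells.
* Validation errors name the offending well/cell; no silent pseudocounts
  anywhere (a zero abundance in a ratio-to-mean matrix is an error, not an
  imputation).
* Test-suite Monte-Carlo sizes were chosen to make the binomial error of
  each estimated rate small relative to its acceptance margin: 50 random
  fragments against the enumeration oracle, 1000 round-trip pairs, 100
  labelling seeds × 8 metabolites, 200 plate seeds × 24 group-phases, 30
  null proteomes of 2000 proteins.
* The spike-detection power check runs at measurement sd 0.05 ("small
  noise"): at the default sd 0.1, a +1 log~2~ effect in 3 vs 3 sits near the
  BH threshold with 50/2000 true effects, and power is a property of the
  small-noise regime, not of the significance rule.

## 6. Known limitations

* The correction model assumes integer mass shifts (unit-resolution GC/MS);
  it does not model mass-accuracy separation of isobaric species.
* Tracer impurity is modelled as ^12^C at labelled positions; exotic tracer
  impurity spectra are not supported.
* The ATP decomposition is a steady-state accounting, not a kinetic model;
  coupling efficiency and leak thermodynamics are out of scope.
* Registry fragment formulas are curated defaults, not instrument-validated
  constants.
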