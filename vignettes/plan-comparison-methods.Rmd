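---
title: "Methods: dose-volume, radiobiological and cohort comparison of radiotherapy plans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dose-volume, radiobiological and cohort comparison of radiotherapy plans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtcohort)
```

## The problem

Comparative planning studies ask whether a newer delivery technique
(IMRT, VMAT) actually buys anything over conformal radiotherapy (CRT)
for a given tumor site. The unit of evidence is a balanced cohort: each
patient planned under every modality, each plan reduced to a metric
panel, and the panels compared statistically. `rtcohort` implements that
chain — DVH reduction, plan-quality indices, Niemierko radiobiology,
compliance checking, and the ANOVA/Tukey cohort comparison — over voxel
dose grids and binary structure masks, plus a synthetic thorax cohort
generator so the chain is fully testable without clinical data.

## DVH engine

A structure's voxels are selected by mask truth at voxel centers; there
is no partial-volume weighting. This whole-voxel convention keeps every
DVH quantity exactly checkable against brute-force voxel counting, which
is how the test suite validates the engine. Doses are binned on
`[0, max dose in structure]`; the cumulative curve follows the
"volume receiving at least d" convention, evaluated exactly at bin edges
and linearly interpolated between them. Point metrics (Dmax, Dmean,
Dmin) are always taken from raw voxel values, never from the binned
curve, so they carry no binning error; Dmax is the single-voxel maximum
with no D0.03cc surrogate.

The default bin width is 0.05 Gy — at most 0.1% of a typical 60 Gy
prescription, well below the precision at which plan metrics are
reported. Halving or refining it changes VxGy/Dx queries by less than
one bin, a convergence property the tests assert. `dose_at_volume()`
returns the smallest dose whose cumulative volume falls to the queried
percentage; on plateaus of the cumulative curve (dose ranges containing
no voxels) this resolves to the upper end of the plateau, the
conservative choice for D1-type near-maximum queries.

The core computes exclusively in Gy. Files may declare cGy (volume
bundles through their JSON sidecar, DVH CSVs through a `dose_cgy`
column) and are converted at the I/O boundary; reports print doses in
cGy, the tabulation convention of the clinical literature, with the unit
in every column header. A single-unit core prevents silent 100× errors.

## Plan-quality indices

With prescription dose $D_p$: $HI = (D_1 - D_{99})/D_p \times 100\%$.
Conformity uses the prescription isodose by default
(`isodose_fraction = 1`), configurable to the common 95% variant:
$CI = V_{T,Pi}/V_{Pi}$, $\mathrm{coverage} = V_{T,Pi}/V_T$ and
$CN = CI \times \mathrm{coverage}$, where $V_{Pi}$ counts body voxels at
or above the isodose (not the whole grid) and the target is intersected
with the body. The identity $CN = CI \times \mathrm{coverage}$ is
asserted on every evaluation. An underdosed plan with an empty isodose
region reports $CI = CN = 0$ rather than erroring, so batch cohort runs
never abort.

The compliance checker applies the standard acceptance rules — PTV
V95 ≥ 95%, cord Dmax < 45 Gy, lung V20 < 30%, lung V30 < 20% — with
strict inequality for the "less than" limits and an inclusive bound for
coverage, each rule evaluated independently and a missing metric
reported unevaluable (failing the overall check) rather than dropped.

## Niemierko radiobiology

$EUD = \left(\sum_i v_i D_i^a\right)^{1/a}$ is computed in log space for
stability at large $|a|$. The exponent $a$ is structure-specific:
negative for tumors (cold spots dominate), 1 for parallel organs like
lung (EUD is then exactly the mean dose), large positive for serial
organs like cord. TCP and NTCP share the sigmoid
$1/(1+(D_{50}/EUD)^{4\gamma_{50}})$ with the half-effect dose TCD50
(tumor) or TD50 (normal tissue). The shipped registry (also at
`inst/extdata/radiobio_params.json`) carries the standard Niemierko /
Okunieff constants: esophageal tumor {TCD50 49.09 Gy, γ50 2.16, a −13},
cord {66.5, 3, 13}, lung {24.5, 2, 1}, heart {48, 3, 3}, brainstem
{65, 3, 7}.

Two numerical choices matter:

- **Zero-dose floor.** With $a < 0$ a single zero-dose voxel annihilates
  the power mean. Doses are floored at 0.01 Gy (with a warning) before
  negative-exponent means; whether published analyses floor here is
  generally unstated, and the floor only matters for targets with truly
  cold voxels.
- **Slope parameter.** The esophageal entry also records a 4.14 %/Gy
  slope value alongside γ50 = 2.16. The registry defaults to the γ50
  column; `slope_mode = "slope50"` substitutes the alternative where
  recorded. Published mean TCP/NTCP tables are often not recoverable
  from published mean EUDs under either choice, because per-patient
  values were averaged after the nonlinear sigmoid; this package
  therefore treats such cells as non-reproducible and asserts only
  fixed-point and monotonicity properties plus its own computed values.

## Cohort statistics

Cells are mean ± SD (n−1 denominator; SD 0 reported for a single
observation). The modality effect is tested per metric with classical
one-way fixed-effects ANOVA and Tukey HSD pairwise post hoc p-values
(Tukey–Kramer for unequal group sizes), delegated to `stats::aov()` /
`stats::TukeyHSD()`; the test suite cross-checks both against
independent sums-of-squares and studentized-range computations. Two
degenerate cases are handled explicitly: no between-group variance
(identical, permuted, or all-constant groups) reports F = 0, p = 1, and
zero pooled within-group variance reports pairwise p = 1 for equal
means and 0 otherwise.

Two statistically debatable conventions are kept deliberately, because
they match how such studies are reported: pairwise p-values are emitted
for all pairs regardless of the omnibus ANOVA (the stricter ANOVA-gated
mode is available as `gate_on_anova = TRUE`), and the paired structure
of the cohort (the same patients under every modality) is ignored in
favor of plain one-way ANOVA, although a repeated-measures model would
be more powerful. Neither choice affects the directional findings the
pipeline asserts. No multiple-testing correction is applied across
metrics.

## The synthetic cohort

The phantom is an elliptical-cylinder body (semi-axes 112 × 92 mm)
holding two lateral lung ellipsoids, an anterior heart, a posterior
midline cord cylinder and a centered cranio-caudally elongated PTV
(semi-axes a, a, 2.5a) whose volume is drawn uniformly from
158.3–378.9 cm³, the span reported for middle-thoracic esophageal
planning target volumes. Organ sizes get ±5% per-phantom jitter.
The default grid is 64 × 64 × 48 voxels at 4 mm isotropic — a
desk-scale resolution at which one dose distribution generates in well
under a second and the full eight-patient, three-modality pipeline runs
in about ten seconds on one CPU; those are the problem sizes used by the
tests and the acceptance script. Voxelization at centers reproduces
analytic ellipsoid volumes within 2% at this resolution.

Dose is modelled per modality:

- **CRT**: two phases of open slab beams — an APPA opposed pair to
  36 Gy, then off-cord anterior obliques (65°/295°) to 24 Gy with an
  explicit cord block (8% transmission) — with a generous 12 mm field
  margin. Each slab has a sigmoid penumbra, exponential depth
  attenuation (0.0035 mm⁻¹) and a small scatter bath.
- **IMRT / VMAT**: half of the dose as corridor slabs along the beam
  directions (five static beams at 0/72/144/216/288°, or a 181°→180°
  clockwise arc sampled at 36 directions) and half as a conformal
  component — a 3-D sigmoid falling off around the margin-expanded PTV —
  standing in for the optimizer's modulated result, with a 6 mm margin
  and a larger scatter bath. A pure slab superposition cannot
  simultaneously keep lung V20 compliant and produce the modulated-
  delivery signature (tight high-dose conformity plus a wide low-dose
  bath); splitting the dose into conformal and corridor parts is the
  package's modelling choice for exactly that signature.

Each phase is normalized to its phase prescription at the PTV median;
smooth correlated noise (0.5 Gy SD) is added and the composite rescaled
so the PTV median equals the prescription within 0.1 Gy. Seeds are
derived per patient and per modality from the root seed, so adding a
patient never perturbs existing ones and the whole cohort — and every
file the pipeline writes — is byte-reproducible per (configuration,
seed).

The generator makes **no claim of dosimetric realism**: there is no
heterogeneity correction (lungs attenuate like water), no build-up
region, no divergence in the cranio-caudal direction, no inverse
optimization, and the beam-model constants (margins, penumbra, bath
amplitudes, conformal fraction, shield transmission) are pinned defaults
chosen once so that the characteristic qualitative contrasts between
modalities hold with margin on the default cohort: IMRT/VMAT show larger
lung V5/V10 and healthy-tissue V5, smaller lung V30 and better CN than
CRT, and every plan passes the compliance rules. Passing tests on this
cohort therefore demonstrate that the *evaluation pipeline* is correct
and that the generator reproduces the expected *direction* of modality
differences — not that any specific clinical cohort's numeric values are
reproduced. Cohort means of nonlinear quantities (TCP, NTCP) in
particular are averages of per-plan sigmoid outputs and are not
comparable to a sigmoid of averaged EUDs.

## Known limitations

- Whole-voxel masks bias volumes of small or thin structures (the cord
  is the worst case at 4 mm resolution); partial-volume weighting is out
  of scope.
- No attempt is made to reproduce any commercial treatment planning
  system's DVH binning or interpolation, so exact numeric agreement with
  TPS-reported metrics is not expected.
- The statistics module assumes one observation per (patient, modality,
  metric); repeated-measures designs, nonparametric alternatives and
  multiplicity control are out of scope.
- LQ-based fractionation correction (EQD2), seriality models and
  Lyman–Kutcher–Burman NTCP are not implemented; the radiobiology is
  strictly the Niemierko EUD formulation.
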