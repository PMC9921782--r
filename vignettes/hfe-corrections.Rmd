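---
title: "Element-count and partial molar volume corrections for hydration free energies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Element-count and partial molar volume corrections for hydration free energies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Computed hydration free energies (HFEs) of small organic molecules carry two
entangled error sources: the solvation model and the solute force field.
Integral-equation implicit solvents such as 3D-RISM systematically
overestimate HFEs, largely through a pressure artifact that grows with the
solute's partial molar volume (PMV); independent of the solvent model, the
non-bonded parameters of a general-purpose force field can be mistuned for
particular chemical elements. `hfecorr` implements three post-hoc linear
corrections that separate and quantify these effects on a benchmark set with
experimental HFEs, and the cross-validation protocol needed to fit and audit
them honestly.

## The correction models

For a molecule with computed HFE $\Delta G_{\mathrm{calc}}$, PMV $v$ (Å$^3$)
and $N_i$ atoms of element $i$, the corrected HFE is

* **PMVC** (pressure-like PMV correction):
  $\Delta G_{\mathrm{calc}} + a\,v + b$. The slope $a$ (kcal/mol/Å$^3$,
  negative in practice) absorbs the pressure overestimation; $b$ (kcal/mol)
  is an intercept.
* **ECC** (element count correction):
  $\Delta G_{\mathrm{calc}} + \sum_i c_i N_i$, one coefficient $c_i$
  (kcal/mol per atom) per chemical element. There is deliberately **no
  intercept and no PMV term**: the per-element coefficients are an
  unspecified element-wise correction to the solvent model, the force field,
  or both, and the fitter never silently adds an intercept column.
* **PMVECC**: both groups together,
  $\Delta G_{\mathrm{calc}} + a\,v + b + \sum_i c_i N_i$. Once the PMV term
  has removed the bulk pressure error, the residual element coefficients
  become a per-element diagnostic of force-field (Lennard–Jones)
  deficiencies: large residual coefficients for Cl, Br, I and P indicate
  parameters that merit adjustment, and corrections fitted to explicit
  solvent HFEs show the same pattern.

All three are linear in their parameters, so one fitter serves all kinds.
The model assumes atoms are solvent-exposed; for solutes with many buried
atoms the per-element additivity underlying the ECC breaks down, and a
fitted correction is not expected to transfer (see Limitations).

## Fitting protocol

Coefficients are fitted by ordinary least squares with leave-one-out
cross-validation (`loo_fit()`): $n$ molecules give $n$ fits, each omitting
one molecule, and the omitted molecule's corrected HFE is its out-of-sample
prediction. The reported coefficients are the per-parameter mean over folds.

**Which side is regressed.** The response is the correction each molecule
needs, $y = \Delta G_{\mathrm{exp}} - \Delta G_{\mathrm{calc}}$, regressed
on the design row of the chosen kind ($[v, 1]$, element counts, or both).
This is algebraically identical to fitting the corrected-HFE equation for
$\Delta G_{\mathrm{exp}}$ and keeps a single design-matrix layout —
`[a, b, elements…]` in a fixed, canonical (atomic-number) element order —
shared bit-for-bit between fitting and application: `correction_term()` is
exactly the dot product of `design_row()` with the coefficient vector.

**Numerical route.** Each fold is solved through a pivoted QR decomposition,
not the normal equations; rank-deficient designs (an element present in no
training molecule, perfectly collinear counts) are an error naming the
dependent columns rather than a silent drop. The test suite checks the QR
path against an independent normal-equations refit oracle to $10^{-10}$ and
against the closed-form leverage identity
$\hat y_{-i} = \hat y_i - h_{ii} r_i / (1 - h_{ii})$.

**Dispersion measures.** Three are computed because they answer different
questions:

* `coeff_sd` — the SD of each coefficient across the $n$ leave-one-out fits.
  This is the dispersion usually quoted next to LOO-averaged coefficients,
  but it is *small by construction*: each fold differs from the full fit by
  a single observation's influence, so the fold SD scales like
  $\mathrm{SE}(\hat\beta)/\sqrt{n}$.
* `coeff_sem` — `coeff_sd`$/\sqrt{n}$, the standard error of the mean of the
  fold values.
* `coeff_se_jack` — the jackknife standard error,
  $\sqrt{\tfrac{n-1}{n}\sum_i (\beta_{-i} - \bar\beta)^2}$, which is the
  fold-based estimator of the *coefficient's own* standard error
  ($\approx \sqrt{n} \times$ `coeff_sd`). This is the quantity to use for
  coverage statements such as "the true value lies within 3 standard errors";
  using the raw fold SD there would understate the uncertainty by a factor
  of $\sqrt{n}$ (about 25 at $n = 642$). The package's recovery validation
  uses the jackknife SE for exactly this reason.

Elements carried by fewer than 5 molecules trigger a loud warning
(`min_element_support` controls the hard floor): their folds are unstable,
as phosphorus — present in only 14 molecules of a typical benchmark set —
illustrates.

## Error statistics

`error_stats()` reports the benchmark conventions: slope of predicted vs
experimental with intercept (the scatter-plot convention), MUE, mean signed
error, RMSE, maximum absolute error, and $R^2$ as the **squared Pearson
correlation** (not the coefficient of determination — the field's usage for
these benchmarks). `relative_error()` averages $|\epsilon|$ with
$\epsilon = (\Delta G_{\mathrm{pred}} - \Delta G_{\mathrm{exp}})/\Delta
G_{\mathrm{exp}}$, restricted to molecules with
$\Delta G_{\mathrm{exp}} < -5$ kcal/mol so the denominator is never small;
the mean of absolute values was chosen as the aggregation because it is the
conservative reading when only headline percentages are quoted.
`bootstrap_stats()` resamples molecule pairs with replacement (default 1000
rounds, seeded) and reports the SD of each statistic's bootstrap
distribution as its uncertainty — the standard bootstrap estimator of a
statistic's standard error; point values always come from the unresampled
data, and resamples with zero experimental variance are redrawn with bounded
retries.

## Flexibility screening

Single-conformer HFE calculations are only trustworthy for rigid molecules.
The screen consumes per-frame energy traces from cheap implicit-solvent MD:
`dg_frames` is defined as the aqueous-minus-vacuum potential energy of each
saved conformation — the caller controls what is in that column, which keeps
the classifier estimator-agnostic. A molecule is **rigid** iff

* the sample SD of `dg_frames` is ≤ 0.4 kcal/mol (flexibility contributes
  little to the HFE), **and**
* the first frame's value is within 0.2 kcal/mol of the whole-trajectory
  estimate (the deposited conformer is not an outlier).

Both boundaries are inclusive. The difference is taken as an absolute value:
the threshold semantics are only meaningful two-sided, although the signed
value is what one would plot. The trajectory estimate is the two-state
Bennett acceptance ratio (`bar_free_energy()`) when cross-evaluated
energies of both ensembles are available — BAR reduces to the two-state case
of its multistate generalization, which is all this screen needs — else the
mean of `dg_frames`. BAR solves the self-consistent Bennett equation by
bracketed root finding to $10^{-10}$ kcal/mol with
$k_B = 0.0019872041$ kcal/mol/K; a root outside ±$10^6$ kcal/mol is
reported as insufficient phase-space overlap. `exp_avg_free_energy()`
provides the one-sided Zwanzig estimator, computed with a max-shift so large
gaps cannot overflow.

## The synthetic-data generator

`simulate_molecules()` exists so the fitting, statistics and classification
machinery can be validated against known ground truth without any external
data. It emulates only the *statistical structure* the corrections assume:

* element compositions drawn from a palette weighted like a typical
  small-molecule hydration benchmark (H/C common, O/N moderate, F/Cl/Br/S
  uncommon, I/P rare — so rank-deficiency handling is exercised
  realistically), 5–30 atoms per molecule;
* PMVs additive in atom counts with per-element volumes of Bondi-sphere
  magnitude (5–35 Å$^3$; configuration, not science) plus Gaussian noise
  (SD 5 Å$^3$);
* experimental HFEs uniform on $[-25, 5]$ kcal/mol, the span of such
  benchmarks;
* computed HFEs set to experiment minus the true model's correction plus
  Gaussian noise, default SD 0.5 kcal/mol — the scale of typical
  explicit-solvent benchmark uncertainties. The default true model is the
  published PMVECC coefficient set, so defaults reproduce study-like
  conditions (642 molecules, 12 parameters).

The generator resamples (bounded retries) until every palette element occurs
in at least two molecules, which guarantees full-rank leave-one-out folds.
`simulate_traces()` draws Gaussian traces with a controlled frame SD and a
first-frame offset, and emits the label the threshold rule implies for the
*population* parameters. What passing these tests shows is that the
estimators are correct for data obeying the linear model and Gaussian
assumptions; it says nothing about conformational sampling adequacy,
non-additive chemistry, or correlated errors in real calculations.

## Validation problem sizes

The shipped validation uses 642-molecule sets at noise 0 (exact recovery to
$10^{-8}$) and 0.5 kcal/mol (a 100-seed coverage sweep of all 12
coefficients against 3 jackknife SEs), 50-molecule sets for the
brute-force LOO oracle, $10^5$ samples per side for BAR against the Gaussian
work-distribution closed form $\Delta G = \mu - \sigma^2/2k_BT$, and 300
traces of $10^4$ frames for classification accuracy. These sizes make the
whole suite run in well under a minute while keeping Monte-Carlo error far
from the assertion margins.

## Degenerate inputs and tie-breaks

* A molecule with all counts zero and $v = 0$ receives exactly $b$.
* Element symbols are case-normalized (`"CL"` → `"Cl"`); formulas are parsed
  as Hill notation with implicit count 1.
* Applying a model to an element it was never fitted for is an error by
  default (the correction is not transferable); `permissive = TRUE` treats
  such elements as zero with a warning.
* PDB atom-name fallback (only when element columns are absent): two-letter
  halogen-style names (`CL1`) resolve to the halogen; ambiguous names like
  `CA` resolve to carbon for small-molecule HETATM records, with a warning —
  benchmark-scale solutes carry no metals.
* AMBER topologies prefer the atomic-number section; mass-based inference
  rejects masses further than 0.5 u from any standard atomic weight.
* Serialized models store 17 significant digits so read-after-write
  reproduces coefficients bit-exactly.

## Limitations

* The corrections are strictly linear and per-element; they cannot fix
  conformational-sampling error, and fitted coefficients are not
  transferable to chemistry (elements, buried-atom fractions) outside the
  training set.
* Only the two-state BAR is implemented; multistate estimators are out of
  scope.
* The flexibility screen classifies from whatever energy column it is
  given; whether that column is a GB+SA energy or another per-frame estimate
  is the caller's contract.
* No experimental HFE database ships with the package; users supply their
  own per-molecule tables.
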