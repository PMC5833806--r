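---
title: "Modelling MOMP sensitivity from BCL-2 protein profiles"
author: "bcl2dose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling MOMP sensitivity from BCL-2 protein profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcl2dose)
```

## The scientific problem

Commitment to mitochondrial apoptosis is controlled by the BCL-2 protein
family. Stress-induced BH3-only proteins (BIM, PUMA, NOXA) activate the
pore-forming effectors BAX and BAK, while the anti-apoptotic guardians
BCL2, BCL(X)L and MCL1 sequester both the initiators and the activated
effectors. When enough active effector escapes this buffering, BAX/BAK
oligomers permeabilize the mitochondrial outer membrane (MOMP) and the
cell dies. Because the family is redundant and competitive, no single
protein level predicts chemosensitivity well; the balance of the whole
network does.

`bcl2dose` turns measured absolute concentrations of the five proteins
into a single interpretable score: the **stress dose eta**, the minimal
total BH3-only production over a 12 h stress window that triggers MOMP in
a mass-action ODE model of the interaction network. A cell line with a
high eta tolerates more stress before committing to apoptosis — it is
predicted resistant; a low eta predicts sensitivity. Selective
antagonists of BCL2 (ABT-199/Venetoclax), BCL(X)L (WEHI-539) and MCL1
(A-1210477) can be added in silico to ask which guardian a resistant
line actually depends on.

## The reaction network

The model is a deterministic mass-action network of 71 species and 126
elementary reactions, shipped as a JSON model-definition file and loaded
with `default_model()`. Its building blocks:

* **Sequestration.** Each guardian binds each BH3-only initiator
  reversibly (9 complexes), and each guardian binds each active effector
  (6 complexes). Selectivity lives in the dissociation constants: BIM and
  PUMA bind all three guardians in the low-nM range, NOXA is effectively
  MCL1-selective (its affinity for BCL2/BCL(X)L is set in the tens of uM,
  i.e. negligible), and BCL2 binds active BAK only weakly. Individual
  pairs can be switched off entirely (`bcl2_model(kd = list(BCL2.NOXA =
  Inf))`), so restricted binding spectra are a configuration choice, not
  a code change.
* **Activation.** BIM and PUMA bind inactive BAX/BAK in a transient
  complex that converts to the active effector and releases the
  activator (catalytic direct activation). Active effectors also
  activate their own inactive pools (auto-activation), giving the
  characteristic all-or-none switch.
* **Pore assembly.** Active BAX and BAK co-oligomerize by irreversible
  monomer addition into mixed oligomers of sizes 2-8; every composition
  (i molecules BAXa, j molecules BAKa) is a distinct species. Oligomers
  of size >= 6 are designated pores; the MOMP readout is their summed
  concentration.
* **Turnover.** The ten monomeric species degrade with first-order
  rates (fast for the short-lived BH3-only proteins and MCL1, slow for
  the stable guardians and effectors); complexes are treated as
  protected from turnover. The stress input is a step-function
  production of BIM, PUMA and NOXA at a common rate.

The published description of this architecture enumerates its reactions
only in supplementary material that is not redistributed here, so the
shipped file is a *reconstruction*: the mechanistic structure above with
literature-style rate constants, built programmatically by
`bcl2_model()` and fixed so that the network comprises exactly the
published counts of 126 reactions over 71 species. The file name
(`bcl2_network_reconstructed.json`) and the model name record this
provenance. Conclusions that depend on exact rate values (e.g. the
numeric eta of a given cell line) therefore carry the reconstruction's
uncertainty; structural conclusions (monotonicity, conservation,
ranking behaviour under perturbations) are robust to it.

```{r structure}
net <- default_model()
net
```

## Units, integration and numerical choices

Concentrations are uM and time is hours everywhere inside the package;
drug affinities quoted in nM are converted at the boundary
(`binding_rates_from_kd()`). The ODE system is integrated with
`deSolve::lsoda`, a stiff-capable switching method, at absolute and
relative tolerances of 1e-6 by default — nM-scale dissociation constants
next to uM concentrations make parts of the trajectory stiff. Step
inputs never straddle an integration segment: the solver is restarted at
input discontinuities. Mass-action rates are evaluated on the raw state
(no clamping inside the right-hand side), which lets sub-tolerance
negative excursions relax back naturally; trajectories are clipped to
zero afterwards and excursions beyond 100x the absolute tolerance raise
a warning. Every simulation is deterministic: identical networks,
inputs and tolerances reproduce trajectories bitwise.

Each protein's total across free and complexed forms (weighted by
stoichiometry, e.g. a size-6 oligomer with 4 BAXa counts 4 toward BAX)
is declared as a conservation group in the model file and verified
symbolically against the stoichiometry matrix at build time;
`check_conservation()` verifies it numerically on trajectories. With
production and degradation disabled the observed drift is at the
solver-tolerance level (~1e-13 relative over 12 h).

## The stress dose eta

`compute_eta()` drives the network with equal constant production rates
of BIM, PUMA and NOXA over a 12 h window (the simulation horizon equals
the window by default; a post-production margin is configurable) and
reports eta = rate x 12 h, the total production of each initiator
minimally required for the peak pore amount to reach the MOMP threshold.
The default threshold (0.05 uM of pores, i.e. about 0.3 uM of effector
monomers assembled) is a property of the model file, chosen together
with the rate constants so that the measured panel spans a wide dynamic
range of finite eta values; it is configurable per run.

The minimal dose is located by bisection on `[0, eta_upper_bound]` with
a relative tolerance of 1e-3 and at most 40 iterations. The default
upper bound is 10x the summed guardian concentration of the profile — in
a mass-action model the required dose cannot exceed the buffering
capacity by a large factor. Degenerate cases are reported explicitly
rather than numerically: MOMP with no stress at all yields eta = 0 with
status `momp_at_zero`; a profile that cannot reach the threshold below
the bound (e.g. BAX = BAK = 0) yields status `resistant_beyond_bound`
and `eta = NA`. The MOMP indicator is checked at both bracket endpoints
before refinement, and peak pore amount is monotone in the production
rate across the bracket in all regimes we exercise, so bisection and
exhaustive grid search agree to within their respective tolerances
(verified against a 1000-point grid oracle on a reduced two-protein
fixture in the test suite).

Antagonists enter as one extra species with initial concentration
`0.5 x nominal dose` — the factor 0.5 accounts for drug degradation and
active extrusion over the treatment window — plus a reversible binding
reaction against their target only, with the forward rate shared with
the model's generic protein-protein association constant and the reverse
rate set by K_D. Shipped K_D defaults for ABT-199, WEHI-539 and
A-1210477 are literature-typical values and deliberately marked
non-authoritative in `inst/extdata/antagonists.json`; they are fields of
`antagonist()`, not constants of the model. The in-silico dose scans in
`eta_dose_curve()` reuse the antagonist-free network at dose zero, so
scan curves start exactly at the baseline eta. The `pore_synergy_grid()`
analysis converts peak pore amounts to effect fractions by normalizing
to the grid maximum — a package convention, documented here because any
saturating normalization would do — and feeds them to the Webb CI.

```{r eta, eval = FALSE}
panel <- tnbc_panel()
eta_table(panel)
```

(Each eta is one bisection of ~20 ODE solves and takes a few seconds;
the calls are marked `eval = FALSE` to keep the vignette source light.)

## Synergy analytics

`fraction_affected()` is `1 - viability`. Two complementary additivity
references are implemented:

* **Webb fractional product.** `webb_ci(fu_a, fu_b, fu_combo) =
  fu_combo / (fu_a fu_b)`. The orientation is chosen so that CI < 1
  means synergy, matching the classification thresholds (CI < 0.3 strong
  synergy, < 1 synergy, > 1 antagonism) applied exactly. CI is undefined
  (NA) where a single agent already kills everything.
* **Loewe additivity.** Single-agent curves are fitted by variable-slope
  four-parameter logistic least squares (`fit_drc()`, Levenberg-
  Marquardt with box constraints keeping floor/ceiling in [0, 1]); data
  non-monotone beyond a 0.15 cumulative-decrease tolerance fall back to
  isotonic regression plus interpolation with a warning, and flat curves
  are flagged inactive. `loewe_prediction()` solves
  `d_A/D_A(fa) + d_B/D_B(fa) = 1` by bracketed root finding on the
  jointly achievable effect range; when the observed effect exceeds both
  single-agent maxima the prediction clamps at the range boundary and
  the cell is flagged saturated. Excess = observed - predicted, with
  single-agent rows/columns set to zero by construction. On sham
  self-combinations the excess vanishes (the classic consistency axiom),
  and the root finder matches a dense grid scan to 1e-4.

`isobologram()` interpolates iso-effect dose pairs at a chosen effect
level and returns the straight additivity segment between the
single-agent iso-effect doses; contour points below the segment indicate
synergy. Matrix-level CI summaries are reported as mean +/- SD over
nonzero dose pairs — the aggregation rule is a convention of this
package, since figure-level aggregation conventions vary.

## Profiling statistics

`lysate_concentration()` implements the quantitative-immunoblot
calibration: a linear intensity-vs-mass standard curve per protein gives
the loaded mass, dividing by cells per lane gives the per-cell mass, and
`(per-cell mass / molecular weight) / reference cell volume` (default
3.1 pL, an imaging-derived HeLa volume) gives the molar cellular
concentration. Intensities below the blank clamp to zero with a flag;
loads outside the calibrated range warn about extrapolation.

`pa_aa_ratio()` is `(BAK + BAX) / (BCL2 + MCL1 + BCL(X)L)`. On the
shipped panel exactly two lines (HDQ-P1 and MDA-MB-231) fall below 1,
BAK exceeds BAX everywhere except BT549, and MCL1 has by far the lowest
panel mean — structural facts the test suite pins down.

`correlate()` wraps `cor.test` (Spearman by default, average ranks for
ties; Pearson on request) and reports the squared coefficient alongside,
because rank-based R^2 and linear-fit R^2 are different conventions and
both appear in this literature; p-values are two-sided and uncorrected.
`cluster_profiles()` clusters raw uM concentration vectors (Euclidean
distance, no standardization — the profiles are absolute concentrations
and rescaling would change the question) with complete linkage or
seeded multi-restart k-means; a `standardize` flag enables z-scoring.
Whether the reference analyses standardized before clustering is not
documented, so panel cluster memberships are treated as soft,
metric-dependent observations, not test assertions. `fit_ic50()` reuses
the 4PL machinery on viability curves and flags fits with no transition
in range as unbounded.

## Synthetic data: what it emulates, what it does not

The generators exist so that every pipeline stage has inputs with known
ground truth:

* `sample_profiles()` draws concentrations log-uniformly within
  per-protein ranges defaulting to the observed panel extremes
  (0.001-4.581 uM). Log-uniform, not Gaussian, because the measured
  panel spans >3 orders of magnitude.
* `survival_from_eta()` maps eta to a surviving fraction through a
  scaled logistic in log eta (range 0.05-0.95, slope 1.5 per log unit,
  centred on the geometric mean of the supplied doses) plus truncated
  Gaussian noise clipped to [0, 1]. The slope was fixed once, when the
  generator was written, so that rank recovery at the documented noise
  level (SD 0.05 on n = 8) is informative rather than trivial or flaky;
  the test suite requires a mean Spearman rho >= 0.9 over 200 seeds.
* `synth_dose_matrix()` builds 6x6 fraction-affected grids from two 4PL
  curves under Bliss independence, Loewe-additive sham combination, or
  boosted synergy/antagonism (the combination's unaffected fraction
  raised to `1 +/- boost` on interior cells only, so the single-agent
  margins stay exact).

All generators are pure functions of config + seed. They emulate the
*statistical structure* the analysis assumes — monotone eta-survival
link, known interaction truth, heteroscedastic-free noise — and none of
the biology that makes real data hard: plate effects, batch drift,
non-monotone off-target toxicity, correlated replicate noise, or
measurement error in the protein concentrations themselves. Passing the
recovery tests therefore demonstrates that the estimators are correct
and well-conditioned at realistic noise, not that real experiments will
reach the same effect sizes.

## Problem sizes and verification

The shipped analyses run at deliberately modest sizes: one 12 h
simulation of the 71-species network takes ~0.2 s, one eta bisection a
few seconds, and the full panel about 20 s. The test suite verifies the
engine against closed-form oracles (bimolecular equilibrium quadratic,
second-order decay, linear ramp inputs), conservation against the
stoichiometry matrix, bisection against grid search, the Loewe solver
against a dense scan, Spearman-with-ties against a brute-force rank
oracle, and the unit-conversion chain against a hand-computed example.
The acceptance script (`scripts/acceptance.R`) recomputes the headline
quantities from scratch on each run.

## Known limitations

* The reaction inventory and rate constants are a reconstruction
  calibrated to published structural counts, not a verbatim transcript;
  absolute eta values are model-relative scores, comparable within the
  package but not directly to scores from other parameterizations.
* No pharmacokinetics: antagonist exposure is a constant effective
  concentration over the stress window.
* Nothing downstream of MOMP (caspase activation, clearance) is
  modelled; survival links are empirical.
* Stochastic single-cell effects are out of scope — the model is
  deterministic and population-averaged.
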