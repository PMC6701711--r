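---
title: "Effective shunt estimation and the predictive-validity framework"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Effective shunt estimation and the predictive-validity framework}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(effshunt)
library(dplyr)
```

## The problem

Quantifying a pulmonary oxygenation defect from routine data is harder than
it looks. The indices in everyday use — the PaO2/FiO2 (P/F) ratio and the
alveolar–arterial (A–a) difference — are *tension*-based: they change
markedly and non-linearly when the inspired oxygen fraction changes, even
when the lungs themselves do not. *Content*-based measures (true shunt
fraction from a pulmonary artery catheter) track the lung much better but
need invasive measurements.

`effshunt` implements a content-based index that needs nothing beyond a
single arterial blood gas (ABG): the **effective shunt fraction (ES)** — the
pure right-to-left shunt that would, in a three-compartment lung, produce
the observed oxygenation impairment. Real patients almost never have pure
shunt; ES deliberately folds shunt and ventilation–perfusion (V/Q)
heterogeneity into one intuitive number, the "equivalent shunt".

The package also implements the machinery needed to *test* such an index:

* a multi-compartment steady-state gas-exchange simulator,
* a database (DB) method that inverts the simulator by matching a measured
  ABG against a precomputed grid of model runs,
* a synthetic ICU weaning-cohort generator, and
* a predictive-validity pipeline that scores each index by how well it
  predicts PaO2 after a *reduction* in FiO2, assuming the index itself is
  unchanged.

## The model

### Oxygen carriage

Saturation follows a Hill-type closed form with a PO2-dependent
cooperativity coefficient and a P50 shifted multiplicatively by pH, PCO2,
temperature and 2,3-DPG. At the standard state (pH 7.40, PCO2 40 mmHg,
37 °C, DPG 4.65 mmol/l) the model's P50 is 26.8 mmHg = 3.5731 kPa; acidosis,
hypercapnia and fever shift it right (the Bohr effect), and the tests pin
this constant and the shift directions as regression contracts. 2,3-DPG is
fixed at its standard concentration because it is not measured clinically.

Content combines the bound and dissolved terms,

$$C_{O_2} = 1.34 \cdot \mathrm{Hb} \cdot S_{O_2}(P_{O_2})
           + 0.0225 \cdot P_{O_2} \quad [\mathrm{ml\,dl^{-1}}],$$

with the Hüfner capacity (1.34 ml/g) and plasma solubility
(0.0225 ml dl⁻¹ kPa⁻¹) both configurable through `phys_assumptions()`.
Because content is strictly monotone in tension, the reverse map is computed
by bracketed bisection on [0.05, 300] kPa to an absolute tolerance of
1e-8 kPa (`po2_from_content()`); a monotone objective makes bisection
unconditionally safe, and the round trip is tested to better than
1e-6 kPa across the physiological range.

### The effective shunt

With end-capillary content \(C_{c'}\) evaluated at the alveolar PO2 from the
simplified alveolar gas equation
\(P_AO_2 = F_IO_2(P_b - P_{H_2O}) - P_aCO_2/\mathrm{RER}\)
and arterial content \(C_a\) at the measured PaO2,

$$ES = \frac{C_{c'} - C_a}{C_{c'} - C_a + \mathrm{VO_2}/Q}.$$

The denominator follows from substituting the Fick rearrangement
\(C_v = C_a - \mathrm{VO_2}/Q\) into the classical shunt equation; the sign
of the VO2/Q term must be **positive** for the ratio to stay in [0, 1) and
for the prediction round trip below to be exact. VO2/Q is expressed in
content units (0.25 l min⁻¹ over 6.5 l min⁻¹ → 3.85 ml dl⁻¹). The
inspired-gas correction term of the full alveolar gas equation is available
behind `full = TRUE`; it is below 0.3 kPa at RER 0.8 and vanishes at RER 1,
so the simplified form is the default.

Prediction at a new FiO2 inverts the same relationship: the predicted
arterial content is \(C_{c'}(\text{new } P_AO_2) - \frac{ES}{1-ES}
\mathrm{VO_2}/Q\), converted back to a tension. Predicting at *unchanged*
settings therefore returns the measured PaO2 exactly (to the inversion
tolerance) — a self-consistency identity the acceptance tests enforce for
all three analytic measures.

### Assumed constants

RER (0.8), cardiac output (6.5 l/min) and VO2 (0.25 l/min) are assumed, not
measured. They are mid-physiological defaults, configurable individually or
from a YAML file (`read_assumptions()`). `es_sensitivity()` sweeps RER
0.8–1.1, Q 3–15 l/min and VO2 0.15–1 l/min over a reference record grid and
reports the resulting ES spread. Two honest caveats: (i) extreme joint
combinations (say VO2 = 1 l/min at Q = 3 l/min) imply a negative
mixed-venous content and are flagged `feasible = FALSE` rather than
silently averaged in; (ii) over the *full joint* ranges the ES value does
move substantially (the reported bound is about 0.6–0.7 at its worst, driven
by the VO2/Q ratio), so the sweep's value is in making that dependence
visible, not in pretending it away. What matters for ranking indices is that
the same constants are applied to every record.

## The simulator

The integrated gas-exchange model is the package's own reconstruction of
the standard compartmental description, and is documented as such.
`steady_state_batch()` solves, for each run:

1. **Perfusion split.** A shunt fraction receives mixed-venous blood; the
   remaining perfusion is divided equally across N = 50 compartments whose
   V/Q ratios are log-normally spaced (spread `vq_sigma`, equal-probability
   normal quantile midpoints, normalised so total alveolar ventilation is
   exact). `vq_sigma = 0` collapses to a single ideal compartment.
2. **Per-compartment gas.** Each compartment's alveolar PO2 solves the
   ventilation–perfusion mass balance with the full content model
   (vectorised bisection); end-capillary blood equilibrates with the
   compartment gas.
3. **Mixing and Fick.** Arterial content mixes the shunt and compartment
   streams; mixed-venous content is updated by \(C_v = C_a -
   \mathrm{VO_2}/Q\); the loop repeats until successive contents agree to
   1e-6 ml/dl, with Aitken acceleration every third step (typical runs
   converge in 4–10 iterations).
4. **CO2 and pH.** CO2 carriage is linearised: PaCO2 follows the alveolar
   ventilation equation from VA and VCO2 = VO2·RER, and pH follows from
   PaCO2 by a base-excess-zero Henderson–Hasselbalch relation (HCO3
   24 mmol/l). This is sufficient because the pipeline conditions on the
   measured PaCO2 and only oxygen predictions are scored.

Two structural consequences are worth stating. Because the Fick constraint
pins total oxygen uptake, the `vq_sigma = 0` case is solvable in closed form
— and the ideal compartment then reproduces the alveolar gas equation
*exactly*, which is why the ES formula recovers a simulated pure shunt with
essentially zero bias (the acceptance suite bounds it at 0.01; the measured
bias is ~1e-10). With `vq_sigma > 0`, ES exceeds the latent pure shunt — by
design, since it absorbs heterogeneity into an equivalent shunt.

Infeasible inputs (a VO2 the residual pulmonary blood flow cannot deliver —
e.g. high shunt at low cardiac output and haemoglobin) raise a classed error
in strict mode, or return flagged `NA` rows in batch mode.

## The DB method

`build_db()` tabulates steady states over a grid: shunt 0–0.5 (step 0.025),
`vq_sigma` 0–2 (step 0.25), Q 3–9 l/min (step 1.5), Hb {80, 110, 140} g/l,
and the common clinical FiO2 settings — about 48,000 runs, built in about a
minute. All runs are conditioned on a normocapnic reference PaCO2
(5.3 kPa) with alveolar ventilation tuned analytically (the linearised CO2
relation makes the "retune VA to hit the target PaCO2" root-finding
closed-form). The grid has no PaCO2 axis; queries far from normocapnia
therefore return empty match sets — reported, never an error — and this is
the main structural limitation of the shipped database.

`match_abg()` keeps every run within ±0.5 kPa of the measured PaO2 and
±0.3 kPa of the measured PaCO2 (mirroring the pipeline's stability window),
with FiO2 exact-to-grid and Hb matched to the nearest grid value.
`db_predict()` re-simulates each matched run at the new FiO2/PaCO2 and
averages the predicted PaO2. `constrain_state()` intersects the matched
parameter combinations across one or two ABGs: the two-ABG envelope is a
subset of the one-ABG envelope by construction, and strictly smaller in the
vast majority of synthetic patients — the quantitative form of the
observation that a second blood gas at a different FiO2 pins down the
shunt/heterogeneity trade-off that a single ABG cannot resolve.

## The synthetic cohort

`generate_cohort()` emulates what the pipeline needs from an ICU weaning
population: per-patient latent shunt ~ Beta(2,5)·0.5 (mean ≈ 0.14, close to
the reported clinical ES distribution), V/Q spread ~ Gamma(2, 0.3) truncated
at 2, Q ~ N(6.5, 1.2) on [3, 12], Hb ~ N(105, 18) on [60, 170]; FiO2
trajectories that stay or step down through the common clinical settings;
ventilation to a fixed normocapnic PaCO2 target; and additive Gaussian
measurement noise (0.5 kPa on PaO2, 0.15 kPa on PaCO2, truncated at
physiological bounds) chosen so the synthetic unchanged-FiO2 noise floor is
of the same order as the clinical baseline. `inject_fio2_transcription_errors()`
optionally corrupts FiO2 to an adjacent setting, mimicking clinician entry
errors.

What the generator does **not** model — and what passing tests therefore do
not show about real data: longitudinal disease evolution, recruitment or
suction events, absorption atelectasis, analyser drift, between-patient
PaCO2 targets, or any deviation of real oxygen carriage from the package's
own dissociation model. The generator shares its forward model with the
indices being scored, so synthetic cohorts can rank the measures and verify
the algebra, but the absolute MAE values on synthetic data say nothing
about the clinical MAE values.

## The predictive-validity pipeline

`filter_pairs()` forms every ordered within-patient pair taken within
3 hours, both on mechanical ventilation, with FiO2 *reduced* (weaning-only,
which limits absorption-atelectasis noise) and |ΔPaCO2| < 0.3 kPa (strict;
differences are rounded to nine decimals first so decimal analyser values
sit on the intended side of the boundary). A `consecutive_only` switch
restricts to adjacent samples; the default pairs every qualifying
combination, which means one record can appear in several pairs — the U
tests below therefore treat pairs as exchangeable rather than strictly
independent, a caveat shared with any pairing rule of this kind.

`evaluate_validity()` computes each measure on the first gas, predicts the
second PaO2, and summarises |error| by its median (MAE). Prediction
failures — an infeasible A-a prediction, an ES content below the attainable
range, an empty DB match — are counted per measure and excluded pairwise by
default; `failure_policy = "drop_pair"` drops the pair for all measures so
the medians stay comparable. `compare_errors()` runs the Kruskal–Wallis
omnibus test and all pairwise two-sided Mann–Whitney U tests with Bonferroni
correction (exact enumeration for small untied samples, tie-corrected
normal approximation otherwise; all-tied input reports p = 1).
`baseline_error()` scores unchanged-FiO2 pairs, whose median |ΔPaO2| is the
noise floor no measure can beat — with pure Gaussian noise of sd σ it
converges to σ√2·Φ⁻¹(0.75) ≈ 0.95 σ, which the tests verify.

On seeded synthetic cohorts (200 patients, noise on, heterogeneous latents)
the ranking MAE(ES) < MAE(P/F) < MAE(A–a) is reproduced with all pairwise
Bonferroni-adjusted p-values far below 0.05. The problem sizes used
throughout (200-patient cohorts, the default database grid, 50-patient
envelope sets, 60-pair DB scoring subsets) were chosen so a full run
completes in a few minutes on a single core while leaving the statistical
conclusions unambiguous.

## Numerical choices and edge cases

* All tensions are kPa internally; conversion (1 kPa = 7.50062 mmHg) happens
  only in `read_abg()`/`write_abg()` and the CLI.
* Barometric pressure 101.325 kPa and water-vapour pressure 6.27 kPa at
  37 °C (standard sea-level values); temperature defaults to 37 °C and
  measured tensions are used as analyser-reported, without temperature
  correction.
* Supra-alveolar PaO2 (noise or FiO2 transcription error): A–a and ES clamp
  to zero and the record is tagged `supra_alveolar`, never dropped silently.
* Missing haemoglobin falls back to 110 g/l with a warning and a
  `hb_imputed` tag; ES is only weakly Hb-sensitive.
* Degenerate statistical input (all-tied errors) reports p = 1 rather than
  raising.
* Carboxy- and methaemoglobin are excluded from the content model; CO2
  carriage inside the simulator is linearised; MIGET-style inert-gas
  recovery and time-dependent dynamics are out of scope.

## Known limitations

ES remains a summary of a heterogeneous organ: it is not independent of
FiO2, alveolar ventilation or intracardiac shunting, and the assumed
VO2/Q materially scales its absolute value. The DB database is conditioned
on normocapnia and a fixed parameter grid, so its inferences are
grid-resolution- and reconstruction-dependent. The synthetic cohort shares
the package's own physiology, which is the right tool for verifying
algebraic and statistical machinery but cannot validate the model against
patients.
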