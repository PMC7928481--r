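---
title: "Methods: sparse-profile NCA of tramadol and its metabolites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sparse-profile NCA of tramadol and its metabolites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(koalapk)
```

## The analysis problem

A single subcutaneous bolus of tramadol is given to a small number of
koalas (2 mg/kg to two animals, 4 mg/kg to four), and plasma is sampled at
0.25, 0.5, 1, 2, 4, 6, 8 and 12 h. The assay quantifies the parent drug
and its two main metabolites — M1 (O-desmethyltramadol, the active,
µ-opioid-binding metabolite) and M2 (N-desmethyltramadol, considered
inactive) — down to an LLOQ of 15.63 ng/mL. The questions the pipeline
answers are the standard ones for a first PK description in a new species:
how fast is the drug absorbed and cleared, how much active metabolite is
formed, how long does M1 stay above concentrations associated with
analgesia in humans, and are the kinetics dose-linear?

Everything is estimated non-compartmentally: no structural model is fitted
to the animal data, and every index is a functional of the observed
concentration–time points.

## NCA conventions and their rationale

**Peak.** Cmax and Tmax are read directly from the uncensored
observations; ties go to the earliest time. No interpolation is attempted:
with a 15-minute first sample and absorption this fast, the observed peak
is the defensible estimate.

**Terminal phase.** `kel` is the negative OLS slope of log concentration
over a suffix of the samples strictly after Tmax. By default every suffix
with at least 3 points is fitted and the one with the highest adjusted R²
wins, ties (within 1e-9) going to the longer window — the usual
"best-fit lambda-z" automation. An explicit point list can override the
automation (down to 2 points) to reproduce a hand-picked published fit;
the report logs every selection because this is the analysis's one
subjective step. A profile whose candidate windows all have non-negative
slope has no identifiable terminal phase and is reported as such.

**Censoring.** Below-LLOQ (BLQ) values are zero before Tmax (drug not yet
absorbed in quantifiable amounts) and excluded at or after Tmax (the value
is unknown, not zero, during elimination). BLQ is encoded in data files as
a literal token rather than a number so a censored value can never leak
into an integral.

**AUC/AUMC.** "Log-linear trapezoidal" is implemented as
linear-up/log-down, the common NCA reading: rising or flat intervals (or
intervals touching zero) use the arithmetic trapezoid, strictly falling
positive intervals use `(C1−C2)Δt/ln(C1/C2)`, which is exact under
mono-exponential decline between samples. The first-moment integral uses
the same interval classification, with the log-down increment integrated
in closed form under the exponential interpolant
(`(C1t1−C2t2)/k + (C1−C2)/k²`, `k = ln(C1/C2)/Δt`) for consistency; a
linear-moment fallback is selectable. Integration runs from the first
sample to the last positive observation; a pure linear method is available
for sensitivity checks.

**Extrapolation and derived indices.** The tail beyond `tlast` is
`Clast/kel` for AUC and `Clast·tlast/kel + Clast/kel²` for AUMC. Then
`t1/2 = ln2/kel`, `MRT = AUMC0–∞/AUC0–∞`, `Cl/F = Dose/AUC0–∞` (per kg,
mg/kg over ng·h/mL, reported in L/kg/h and mL/min/kg), and
`Vz/F = (Cl/F)/kel`. With no intravenous arm, F is unidentified and all
clearances/volumes are apparent. Dose-normalized Cmax and AUC divide by
the *total* administered dose in mg, matching how such tables are usually
printed; Cl/F uses the nominal per-kg dose rate. In the shipped reference
dose table one subject's recorded weight (9.1 kg) is the value consistent
with its recorded total dose at the nominal rate, since the three printed
numbers cannot all be exact simultaneously.

**Group summaries.** Median (even n: midpoint of the central pair), mean,
sample SD (n−1), range. SD of a single value is reported as absent, not 0.

## Exposure metrics

The M1:tramadol AUC ratio is computed, per dose group, from the group
*median* AUCs over the common 0–12 h window (the convention used when
per-animal profiles are noisy and n is small); the median of per-subject
ratios is reported alongside. Time above a threshold is accumulated within
the observed window only — no extrapolation beyond `tlast` — with
crossings located by linear interpolation by default, or log-linear where
both bracketing concentrations are positive. The default thresholds,
100 ng/mL (tramadol) and 36 ng/mL (M1), are the conventional human
minimally effective concentrations and are configuration, not conclusions:
the package predicts exposure relative to a reference line, it does not
claim analgesia. Dose-linearity uses a classical fixed-effects one-way
ANOVA on Cmax/dose and AUC/dose per analyte at α = 0.05, with no
multiplicity correction (six tests are reported separately, as is
customary in small descriptive PK studies).

## Bioanalytical calculations

Calibration is a weighted least-squares line of response on nominal
concentration with weights ∝ 1/x by default; with assay noise roughly
proportional to concentration this prevents the 500 ng/mL standard from
dominating the fit and demonstrably improves relative accuracy at the
15.62 ng/mL end (the test suite verifies this on 500 simulated curves).
The curve range is recorded and back-calculated values outside it are
flagged, never clamped. QC acceptance is precision CV strictly < 15 % and
accuracy in [80 %, 120 %] inclusive — the boundary behaviour is pinned by
tests because regulatory readings differ exactly at the edges. The curve
low end (15.62) and the LLOQ/QC level (15.63) are kept as distinct
constants rather than reconciled. Percent bound from ultrafiltration is
`100 − free/total·100`; non-specific membrane binding is reported
alongside but not subtracted, appropriate when it is verified negligible
(< 0.5 %). A free concentration above total is flagged as a finding and
propagated, never silently truncated. Binding summaries are emitted both
pooled and per spiking level, since published means can be computed either
way.

## The synthetic generator

The generator is a one-compartment disposition model with first-order
subcutaneous absorption and first-order formation of each named
metabolite:

- parent: `C(t) = F·D·ka/(V(ka−ke))·(e^{−ke·t} − e^{−ka·t})`, with the
  L'Hôpital limit `F·D·ka·t·e^{−ka·t}/V` used when `|ka−ke|` falls below
  1e-9 relative;
- metabolite: the three-exponential catenary solution with formation rate
  `fm·ke`, requiring pairwise-distinct rates.

Defaults (the `koala-4mgkg` preset) encode the study conditions: 4
subjects at 4 mg/kg (the `koala-2mgkg` preset: 2 at 2 mg/kg), body weight
uniform on 6.8–9.0 kg, V = 8.6 L/kg and ke = 0.24 /h (matching the
observed median apparent volume and terminal slope, t1/2 ≈ 2.9 h), ka =
8 /h so the analytic Tmax `ln(ka/ke)/(ka−ke) ≈ 0.45 h` lands inside the
observed 0.25–0.5 h window, M1 with km = 0.028 /h (terminal t1/2 ≈ 24.8 h)
and fm = 0.27, M2 with km = 0.094 /h (t1/2 ≈ 7.4 h) and fm = 0.48, chosen
so the noiseless 0–12 h metabolite AUCs sit near the observed medians
(M1 ≈ 830, M2 ≈ 1170 ng·h/mL at 4 mg/kg) and the M1:parent ratio falls at
≈ 0.49, between the two observed dose groups (0.33 and 0.50). Assay error
is 10 % proportional CV plus additive SD = LLOQ/3, consistent with an
assay whose QCs pass a < 15 % precision rule; between-subject variability
is lognormal with 30 % CV on rates and volumes (formation fractions stay
fixed so they always sum below 1). Elimination-rate-limited metabolite
kinetics (km < ke) are the default mechanism for M1's long half-life; a
`flip-flop` preset (ka < ke) covers the alternative the observed data
cannot distinguish, and a `fast-metabolizer` preset (ke = 0.53 /h)
reproduces the one conspicuously fast animal for heterogeneous-group
testing.

What the generator does *not* emulate — and hence what passing recovery
tests do not show about real data: multiphasic distribution (the
one-compartment parent underpredicts the observed Cmax at matched AUC),
the early metabolite Tmax (2–8 h) seen in vivo, which is incompatible with
a one-compartment catenary chain whose metabolite half-life is 25 h
(within 12 h such a chain is still near its peak — the report therefore
supports profiles whose terminal phase is not evaluable, carrying
Cmax/Tmax/AUC0–tlast with the extrapolated indices absent), enantiomer
kinetics, and correlated assay errors.

## Numerical choices and degenerate inputs

Adjusted R² ties break toward more points at a 1e-9 tolerance (noiseless
profiles make many windows numerically perfect). R² is computed directly
from residual and total sums of squares to behave on exact fits. Equal
maxima take the earliest Tmax. Profiles entirely censored, with fewer
than 2 usable points, with non-positive thresholds, or with AUC windows
that do not match all raise typed, contextual errors rather than returning
NA. Dose consistency (`dose ≈ rate × weight`) is enforced at 1 % to absorb
table rounding. Validation is reporting, not gating: findings carry
subject/analyte/time context and an empty findings table defines a clean
dataset; only a profile with no dose event at all aborts an analysis run.

## Problem sizes used in tests

Recovery and property tests run at the scale of the study they emulate
(2–6 subjects, 8-point schedules), with dense-schedule variants
(0.05–48 h at 0.05 h) where an estimator's asymptotic accuracy is the
property under test, 500 replicates for the calibration-weighting
comparison, and exact enumeration (15 label permutations) for the ANOVA
cross-check. These sizes make the whole suite run in well under a minute
while keeping Monte-Carlo error far below the asserted tolerances.

## Known limitations

Single dosing event per subject; no compartmental fitting or
bioavailability estimation; thresholds are human-derived reference lines;
the M1 terminal half-life from a 12 h window is an early-elimination-phase
estimate and is treated as such (the reference table's metabolite rows
deliberately carry no infinity extrapolation).
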