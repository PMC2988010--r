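---
title: "Competing-risks methods in criskit: models, conventions, and what the tests establish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Competing-risks methods in criskit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(criskit)
```

## 1. Data model

A cohort is one row per subject: a strictly positive follow-up time `T`
measured from a common origin (disease diagnosis in the motivating
registry), an event code `D` in `0..K` with `0` censored, and covariates
with a declared schema (numeric, or categorical with ordered levels and
a reference level). A categorical covariate with `L` levels encodes to
exactly `L − 1` dummy columns; the reference profile is the all-zero
row. There is no delayed entry in the public data model — the internal
Cox engine accepts `(start, stop]` rows, because the Fine–Gray
expansion, the Lunn–McNeil augmentation and the time-dependent
diagnostics need them, but cohort files carry a single duration. Tied
times are allowed and preserved: tie handling belongs to the estimators,
not the data layer.

## 2. Nonparametric estimators

**Kaplan–Meier.** Product-limit with Greenwood variance. The tie
convention, stated because bit-exact tests depend on it: events at a
time `t` are processed together, and censorings tied with `t` leave the
risk set *after* the event, so they count as at risk at `t`.

**Naive 1 − KM.** Treats competing causes as censoring. It is included
deliberately, labelled `naive`, as the bias demonstration: it
overestimates the cumulative incidence of a cause whenever competing
events occur, and the test suite asserts the dominance
`naive(t) ≥ AJ(t)` pointwise with strict excess whenever a competing
event precedes the last target event.

**Aalen–Johansen.** The plug-in `Î_k(t) = Σ_{t_j ≤ t} Ŝ(t_j−) d_kj/n_j`
with `Ŝ` the *product-limit* all-cause survival,
`Π (1 − Σ_k d_kj/n_j)` — not `exp(−Λ̂)`. This choice makes the
conservation identity `Σ_k Î_k(t) + Ŝ(t) = 1` hold to machine precision
at every event time instead of approximately; the suite asserts it at
1e−12. Variances use the standard delta-method (counting-process)
estimator and agree with the `survival` package's multistate standard
errors; log(−log) confidence bands are derived output for plotting and
carry no test weight.

## 3. The Cox engine

All three model families reduce to one primitive: a weighted Cox partial
likelihood over `(start, stop]` rows with strata. Conventions:

- **Ties: Breslow by default, Efron optional.** Breslow keeps two exact
  invariances the suite relies on — duplicating a row is identical to
  doubling its weight, and it is the convention of the
  subdistribution-hazards literature. The source study does not state a
  tie method; since its data are not available, exact numeric
  replication of its tables is a non-goal anyway.
- **Convergence:** Newton–Raphson, relative log-likelihood change
  `< 1e-9`, at most 50 iterations, up to 5 step-halvings. A coefficient
  passing `|β| > 15` flags a monotone likelihood: the fit is returned,
  flagged, with a warning rather than an error, so callers can inspect
  it. Collinear designs are rejected up front via the conditioning of
  the information matrix, naming the offending columns.
- **Inference:** Wald, normal quantile (1.959964 at 95%). The
  percent-change column `(HR − 1) × 100` supports the narrative
  "x% higher hazard" reading of coefficient tables.
- **Robust variance:** sandwich from score residuals aggregated by
  subject. It is *mandatory* for IPCW-weighted (Fine–Gray) fits, where
  the model-based inverse information is not valid; it is optional
  elsewhere. We deliberately do **not** assert robust ≥ model-based —
  that inequality is not generally true — and validate the Fine–Gray
  variance through CI coverage on simulated data instead.
- **Determinism:** the engine consumes no randomness; sums are
  accumulated in sorted-time order, so identical inputs give identical
  fits across platforms.

**Proportionality diagnostics.** Two complementary routes: exported
`log(−log S_KM)` curves per group for the few-level columns, and a
refit per covariate adding the time-dependent interaction `x · log t`
evaluated at event times (rows are split at event times, which is exact
for step-constant time-dependence). The reported p-value is the Wald
test of the interaction. One-at-a-time refits were chosen over a single
joint refit to avoid collinearity among interactions; this is a design
choice where the field uses both.

## 4. Cause-specific model and its CIF

One Cox fit per cause with the other causes censored. Two deliberate
interface decisions:

- `exp(−Λ_k(t; z))` is **not** exposed as a "survival for cause k":
  without the other causes it has no marginal interpretation. Only the
  all-cause survival and the per-cause CIFs appear in outputs, and a
  test guards the interface against such a name reappearing.
- The combined survival inside the CIF plug-in uses the product-limit
  form over the summed per-cause increments. Consequences, both tested:
  conservation is exact on the event grid, and the null-covariate
  prediction equals Aalen–Johansen to 1e−12 (the underlying source
  leaves the plug-in unspecified; this is the package's choice). The
  `exp(−ΣΛ)` form remains available as a cross-check option.
- If a profile pushes a pooled discrete increment above 1 (a
  probability overflow, possible for extreme `e^{β′z}` on sparse risk
  sets), the offending jumps are renormalized to mass 1 with a warning,
  which keeps conservation exact rather than clipping it broken.
- Prediction grids have step-function semantics: a requested time reads
  the curve at the latest event time at or before it.
- A cause with fewer than 10 events is still fitted but tagged with a
  "minor risk" advisory in reports, reflecting the unreliability of
  minor-risk subdistribution interpretation discussed below.

## 5. Fine–Gray

The expansion keeps a subject failing from a competing cause at `T_i`
in the risk set afterwards, as one row per target-cause event time in
`(T_i, t_max]` with weight `w_i(t) = Ĝ(t−)/Ĝ(T_i−)`, `Ĝ` the
Kaplan–Meier of the censoring distribution estimated *unconditionally*
on the whole cohort (no covariate-dependent censoring weights — a
stated non-goal). Administrative censoring (a single censoring atom)
needs no special casing: the same weights are correct. With no
censoring all weights are 1 and the construction is provably identical
to recoding competing events as censored beyond the largest time — an
equality the suite asserts at 1e−8, alongside coefficient-and-variance
agreement with the independent `finegray` + weighted-`coxph`
construction of the `survival` package at 1e−8. The baseline
subdistribution cumulative hazard is weighted Breslow, and
`I_k(t; z) = 1 − exp(−Λ̂*_0k(t) e^{β̂′z})`.

## 6. Lunn–McNeil

Full covariate×type interactions (no shared-effect layout — matching
the parameterization that reports separate per-risk covariate effects
plus one risk-type term; a reduced common-effect layout is out of
scope). Reference type is cause 1, so the exponentiated type indicator
reads "dominant risk vs minor risk". The stratified fit is numerically
identical to the separate cause-specific fits — coefficients,
covariance blocks and per-stratum baselines, asserted at 1e−6 — and its
CIF prediction delegates to the same plug-in, so the curves coincide.
The unstratified fit assumes proportional baseline hazards across
types; its CIF reconstruction scales the shared baseline by
`exp(riskType_k + interactions_k′z)` per type and reuses the shared
plug-in (the source figures do not specify their construction; this is
the package's choice). Duplication-induced ties are harmless: at most
one of a subject's rows carries an event, and in stratified mode the
rows live in different strata.

## 7. Gray's test and the log-rank test

Gray's K-sample score compares group-wise subdistribution-hazard
increments on modified risk sets
`R_g(t) = Y_g(t)(1 − F̂_kg(t−))/Ŝ_g(t−)` (group-specific product-limit
curves; this is the IPCW-adjusted count of subjects "still at risk" on
the subdistribution scale), with weight `(1 − F̂_pooled(t−))^ρ` and
`ρ = 0` as the default family member. The variance is the
hypergeometric-style counting-process form evaluated on the weighted
risk sets, with the usual tie correction. Two safeguards back this
bespoke statistic: with one cause it collapses *exactly* to the
log-rank chi-square (asserted at 1e−8 against both the internal
log-rank and `survival::survdiff`), and a seeded permutation p-value is
available as an internal oracle — the suite checks chi-square and
permutation p agree within Monte-Carlo error on null fixtures, and that
empirical type-I error at α = 0.05 lies in [0.03, 0.07] over 500
simulated null cohorts. The statistic is invariant to group relabeling
and to monotone time transforms. No trend tests, stratification or
covariate adjustment: the test is defined unadjusted.

## 8. Simulators: the stated world

`simulate_cause_specific()` draws independent per-cause latent times
with cumulative hazard `base_k t^{shape_k} e^{β_k′z}`; the minimum and
argmin give `(T, D)`. This latent construction induces exactly the
stated cause-specific hazards. `simulate_fine_gray()` uses the standard
mixture construction — `P(cause 1 | z) = 1 − (1 − p)^{e^{β₁′z}}`,
cause-1 times by inverting the induced subdistribution on a unit
exponential time scale, cause-2 times exponential given not cause 1 —
so cause 1 satisfies proportional subdistribution hazards with
coefficient β₁ *by construction*, which is what makes the recovery and
coverage experiments meaningful. Each generator consumes a single
seeded stream in fixed order, giving byte-identical CSVs for identical
specs.

**The diabetes-like preset** states the world of the motivating
registry rather than tuning to it: n = 8254; `male ~ Bernoulli(0.45)`;
age at diagnosis Normal(47.2, 14) truncated at 20 and cut at 40/60;
uniform accrual over a 26-year window with administrative censoring at
the window end; cause-specific log hazard ratios taken from the
published cause-specific column (male log 1.513 / log 1.377; age-group
effects likewise); and the two constant baseline hazards calibrated by
deterministic nested root-finding (tolerance 1e−12, hence reproducible)
so the *expected* event fractions are 0.024 (minor risk) and 0.179
(dominant risk) under that covariate distribution and censoring. The
realized fractions of a draw are binomially noisy around these targets
— the preset is calibrated in expectation, never forced to exact
counts.

What the preset does **not** emulate: the registry's reported median
follow-up (about 8.2 years; uniform accrual over 26 years yields about
10 — the published information on the censoring distribution is too
thin to match both the event mix and the median, and the event mix
drives every demonstration, so it won); within-subject dependence
between risks; non-constant baseline hazards; and any transition from
the minor event to death (death after the minor event is absorbed by
that endpoint, a stated non-goal). A green test on this world therefore
establishes correctness of the estimators under proportional constant
cause-specific hazards with unbalanced risks — not fidelity to the
original registry's unpublished microdata, whose exact table values are
explicitly not acceptance targets.

The minor-risk phenomenon the discussion warns about is reproduced
qualitatively, with fixed seeds: a covariate that raises only the
dominant-cause hazard (h₁ = 0.01, h₂ = 0.04·e^{1.0z}, n = 4000,
administrative censoring at 20) yields a Fine–Gray coefficient for the
*minor* cause well below 0 (observed ≈ −0.47) while the cause-specific
coefficient stays near 0 (observed ≈ 0.03) — the direction of the
published age>60 contrast on the minor risk (cause-specific HR 1.405
vs subdistribution HR 0.53).

## 9. Numerical choices and degenerate inputs, collected

- Event-first convention at tied event/censoring times, everywhere.
- Cohorts with no events: KM warns and returns the constant-1 curve;
  Cox fitting errors.
- A cause with zero events: cause-specific fitting skips it with a
  warning, and CIF prediction for it is an error.
- Single-level factors encode to an all-zero column with a
  non-identifiability warning (the fit will then reject the singular
  design).
- IPCW weights with `Ĝ = 0` (possible only past the last censoring
  atom) drop the affected follow-on rows with a warning.
- Report rounding: HR/CI to 3 decimals, p-values floored at `<0.001`;
  the machine-readable CSVs keep full precision.
- Config files are JSON rather than YAML: no YAML parser is available
  in the dependency budget, and the config schema loses nothing in
  JSON.

## 10. Known limitations

No left truncation or interval censoring; no time-varying covariates in
the Fine–Gray model; no clustered/frailty extensions; the
time-dependent diagnostic covers only the `x · log t` alternative; the
Gray test variance is the hypergeometric analogue rather than the
original counting-process estimator (the permutation oracle and the
calibration experiment bound the consequences); and the acceptance
suite's parameter-recovery experiments run at n = 1000 with 200
replicates — comfortably inside the compute budget, at the cost of
wider Monte-Carlo bands than an overnight run would give.
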