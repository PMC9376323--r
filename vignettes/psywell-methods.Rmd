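---
title: "Models and methods in psywell"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in psywell}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psywell)
```

psywell implements a screening-and-prediction pipeline for psychological
well-being built around the SCL-90 symptom checklist: factor scoring and
total-score screening, a two-level fuzzy comprehensive evaluation model, a
from-scratch backpropagation network with an error-feedback adaptive
learning rate, and mediation/moderation regression for the
mindfulness–rumination–well-being pathway. This vignette describes each
model, its assumptions, the tunable parameters, and the design choices made
where the underlying methodology left the design open.

## SCL-90 scoring

The SCL-90 has 90 items answered on a 1–5 Likert severity scale. Nine
symptom factors (somatization, obsessive-compulsive, interpersonal
sensitivity, depression, anxiety, hostility, phobic anxiety, paranoid
ideation, psychoticism) cover 83 of the items under the default mapping;
the remaining 7 form an `OTHER` set. The factor-level statistic is the
*mean* item response per factor (not the sum); the screening statistic is
the raw *total* over all 90 items, which ranges over 90–450 and does not
depend on the factor assignment.

Two mapping dialects exist because the published item table assigns item 35
to both the obsessive-compulsive and the psychoticism factor while
simultaneously stating that exactly 7 items are unassigned — the two claims
are incompatible. The default `"corrected"` dialect substitutes item 38
(the unique single-item substitution that restores a clean partition of
`1:90` with a 7-item remainder) for the duplicated 35 in the
obsessive-compulsive factor. The `"verbatim"` dialect keeps the table as
printed for auditability; under it item 35 counts toward two factor means
and 8 items are left over, and the partition property is waived.

```{r}
m <- scl90_mapping()
lengths(m$factor_items)
```

**Screening threshold.** The total-score cutoff defaults to 160,
inclusive: a total of exactly 160 screens positive (judgment value 2). This
value separates the negative-screen total (115) from the positive-screen
totals (160–185) in the reference comparison table this package reproduces
in its tests, and matches conventional SCL-90 total-score screening
practice. It is configurable over 90–450. Missing item responses are
rejected rather than imputed; no imputation rule is defensible without
population norms, which are out of scope.

## Two-level fuzzy comprehensive evaluation

Twelve factors enter the fuzzy model: the nine SCL-90 factor means plus
three categorical demographics — household registration type (`hukou`),
family composition, and only-child status. They are organised in four
groups of three (bodily symptoms F1/F5/F9, outward interaction F3/F6/F7,
inner character and mood F2/F4/F8, background information F10/F11/F12).
Note that factor numbers follow the item table throughout; an alternative
published renumbering of the same semantic groupings is not used.

**Membership functions.** Scalar factors map to a membership vector over
four ordered grades (healthy, mild, moderate, severe) through a
piecewise-linear (triangular-partition) family with apexes at the scale
floor and at the breakpoints 1.6, 2.0 and 2.7 on the factor-mean scale,
with shoulders at the two scale ends. The printed form of the membership
formula in the source methodology is typographically corrupted (its fourth
branch is not well-formed); only the three breakpoints were taken as
authoritative, and the standard triangular reconstruction around them is
used. This family guarantees that memberships sum to exactly 1 and that at
most two adjacent grades are active — both properties are tested. The
breakpoint positions are configurable through `grade_set()`.

**Categorical factors.** No membership rule for the demographic factors is
given by the source methodology, so they are table-driven: each category
carries a configurable membership distribution (`default_risk_tables()`).
The defaults are mildly informative — rural registration, non-intact
family composition, and non-only-child status shift a little mass toward
higher severity — reflecting the reported direction of association in poor
student cohorts; they are deliberately weak so that the SCL-90 factors
dominate the evaluation.

**Weights.** Factor weights may be supplied directly or elicited from
expert importance intervals by set-valued statistical iteration
(`set_valued_weights()`): each of `n_iterations` (default 3) memoryless
rounds accumulates interval midpoints over the participating experts —
every expert when resampling is off (deterministic), a fresh bootstrap
sample of experts per round when it is on — and the final weights are the
normalized means. Uniform weights are the default at both levels.

**Composition and defuzzification.** The default composition operator is
the weighted average `B_j = Σ_i W_i R_ij` (M(·,+)); max–min composition
`B_j = max_i min(W_i, R_ij)` is available by flag, because the source
methodology never names its operator and both are standard. The final grade
is the maximum-membership grade; ties break toward the *lowest* severity,
an explicit rule chosen so that a screening decision is never escalated on
the strength of a tie. Grades collapse to the binary judgment used by
total-score screening: grade 1 → judgment 1, grades 2–4 → judgment 2. An
optional pre-filter keeps only the `q` groups with the largest first-level
weights; the default `q` keeps all four groups (no filtering).

## Backpropagation network

A single-hidden-layer feed-forward network predicts the screening judgment
from the 12 factor inputs. Activation is the unipolar logistic
`f(x) = 1/(1 + e^{-x})` (the printed activation formula in the source
methodology is internally inconsistent; the logistic matches its "unipolar
sigmoid" naming). The loss is the squared-error sum `E = ½ Σ (d_k − O_k)²`,
minimised by the delta rule with per-sample (online) updates by default —
batch mode is available — and bias units handled as fixed unit inputs at
index 0 of each layer.

**Adaptive learning rate.** After each epoch the rate η is multiplied by
1.05 if the epoch error decreased, by 0.7 if it grew by more than 4%, and
held otherwise. The rate is clamped to `[1e-5, 0.95]` to prevent unbounded
growth under a long run of 1.05 steps; the source schedule states no bound.
Training stops when the epoch error reaches the configured expected error
or at `max_epochs`. The whole trajectory (per-epoch error and rate) is
returned so the η-ratio invariant — every consecutive ratio is exactly
1.05, 0.7 or 1 before clamping — can be audited.

**Defaults.** `n_hidden = 8` (unstated in the source; a small hidden layer
is adequate for 12 inputs), `eta0 = 0.5`, symmetric uniform initialisation
of half-width 0.5, no momentum (none is introduced by the source). Inputs
are scaled to [0, 1]: factor means linearly from [1, 5]; the three
demographics as ordered risk scores (urban 0 / rural 1; both-parents 0 /
single-parent 0.5 / other 1; only-child 0 / not 1). A 12-input layer rules
out one-hot expansion of the categoricals, hence the score encoding. The
output encoding is binary by default (one output, thresholded at 0.5 with
ties toward the negative screen); a one-hot grade output is supported.

Correctness rests on a finite-difference gradient check (analytic
backpropagation gradients against central differences at `h = 1e-4`,
relative error below 1e-6 on random instances) rather than on any
convergence anecdote; convergence is additionally smoke-tested on XOR and
on the synthetic screening task, where held-out accuracy above 0.9 is
reached with the labels a deterministic function of the inputs.

## Mediation and moderation

The mindfulness (x) → rumination (m) → well-being (y) pathway is analysed
by the classical three-regression procedure: total effect `y ~ x` (path c),
first stage `m ~ x` (path a), and joint model `y ~ x + m` (paths b and c′).
All fits solve the normal equations directly (`ols_fit()`), and for OLS on
a common sample the decomposition `c = c′ + a·b` is an algebraic identity,
tested to 1e-10. The indirect effect `a·b` gets a nonparametric percentile
bootstrap interval (default 2000 resamples, 2.5/97.5 percentiles — the
source names no interval method). Classification: *none* if the interval
covers zero; otherwise *full* when the direct path c′ is not significant
(two-sided p ≥ 0.05, a threshold the source does not state) and *partial*
when it is.

**Fit index.** The source methodology reports a "mediation index" of 0.9
for its fitted model without defining the quantity. psywell operationalizes
it as the multiple correlation R of the joint model (`fit_index² = R²` of
`y ~ x + m`) — the most natural reading of a model-fit level on a 0–1
scale. This is an interpretation, stated prominently as such. Which
well-being composite that figure referred to is likewise unstated; the
package computes the index for whatever outcome it is given. Note the
related published pair R = 0.3800 and R² = 0.172 is mutually inconsistent
(0.38² = 0.1444), which underlines that these cohort-specific values cannot
be targeted without the cohort data. Under the synthetic strong-path
conditions exercised by the acceptance material (a = b = 0.7, residual sd
0.5, c′ = 0.2, n = 500) the population value of the index is
`sqrt(1 − σ²/var(y))` ≈ 0.84, and that is what the pipeline reports.

Stepwise regression (`stepwise_select()`) is forward-only with a partial-F
inclusion threshold of `alpha_in = 0.07`, the inclusion standard used in
the anxiety analysis this mirrors. Moderation (`moderate()`) centers x and
m before forming their product, so the product-term coefficient is
interpretable in the presence of main effects. The two-group utility
(`group_compare()`) is a Welch t test computed directly from group moments,
with the convention t = 0, p = 1 for two constant equal groups.

## Synthetic data

`gen_scl90()` emulates a questionnaire cohort through a latent-distress
item-response model: respondent distress `z ~ N(severity_mean,
severity_sd²)`, item propensity `base + loading·z + noise`, discretised at
the fixed thresholds 0.5, 1.5, 2.5, 3.5 into responses 1–5. With the
default `base = 0` and unit noise a zero-distress respondent answers 1
about 69% of the time and 1–2 about 93% of the time — SCL-90 populations
are floor-heavy, and the thresholds were chosen once to reproduce that
modal 1–2 response and then frozen. Demographics are independent of
severity by default (the association with well-being claimed for real
cohorts can be emulated by conditioning externally). `gen_mediation()`
draws `x ~ N(0,1)`, `m = a·x + e₁`, `y = b·m + c′·x + e₂` with independent
normal residuals. `gen_expert_intervals()` draws per-expert interval
centers around factor-importance anchors with dispersion `0.5 /
concentration` (identical experts at `concentration = Inf`).

What the generators do *not* emulate: item-level factor cross-loadings,
ordinal response styles (acquiescence, extreme responding), measurement
non-invariance across demographic groups, and missingness. Tests passing
on this synthetic material therefore establish the correctness and
statistical behaviour of the algorithms, not the field validity of any
particular threshold on real cohorts.

## Numerical choices and problem sizes

* Membership normalization is exact by construction and asserted to 1e-9;
  composition is checked against loop oracles to 1e-12.
* OLS uses a QR rank check before solving the normal equations, and errors
  name the collinear columns; fits require n ≥ 10.
* Gradient checks use central differences at `h = 1e-4` (truncation error
  O(h²) ≈ 1e-8 relative, comfortably inside the 1e-6 assertion).
* Simulation-based tests use 100–200 replicates at n = 500–2000 and the
  bootstrap uses 2000 resamples where the procedure under test prescribes
  it; these sizes give the binomial assertions (e.g. ≥95 of 100) margins of
  several standard errors while keeping the default test run under about a
  minute.
* All stochastic components take explicit integer seeds; every generator
  is a pure function of (parameters, seed).

## Known limitations

* The screening threshold, grade breakpoints and demographic risk tables
  are screening conventions, not estimates; real-cohort calibration would
  require deposited data that does not exist.
* The fuzzy model's monotonicity in severity is verified for uniform
  shifts with fixed demographics; non-uniform shifts can in principle move
  mass non-monotonically between adjacent grades.
* The network offers no regularisation or early stopping beyond the
  expected-error criterion, matching the scope of the method it
  implements; it is a screening aid, not a clinical classifier.
* The mediation module handles a single mediator with complete data; no
  SEM, multiple mediators, or missing-data machinery.
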