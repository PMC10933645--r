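---
title: "Two-step multilevel VAR networks for twice-daily EMA data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step multilevel VAR networks for twice-daily EMA data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`emanet` estimates three networks from experience-sampling panels that
measure a small set of self-regulation constructs twice a day (a morning
and an afternoon occasion) over consecutive weekdays: a directed
*temporal* network of lag-1 within-person effects, an undirected
*contemporaneous* network of same-occasion residual associations, and an
undirected *between-person* network of trait-level associations. This
vignette documents the model, the estimation choices, the synthetic-data
generator used to validate the pipeline, and what the validation does and
does not establish.

## The data model

An occasion is a `(person, day, slot)` triple with `slot` either `AM` or
`PM`. Values live on a 0–100 visual-analog or percentage scale. Two
structural features of the twice-daily weekday design shape everything
downstream:

* **Lag pairs never span a night.** The only lag-1 step with a
  homogeneous interpretation is morning → afternoon of the same day;
  overnight steps mix sleep and a much longer interval into the
  coefficient. `build_lag_pairs()` therefore pairs each day's AM and PM
  occasions and constructs no PM → next-AM rows.
* **Within/between decomposition by person means.** Morning predictors
  are centered at the person's mean over *all* observed occasions (both
  slots), so lagged coefficients capture momentary deviations; the person
  means themselves enter as level-2 covariates and carry the
  between-person signal. Using all occasions (rather than only paired
  days) gives the better-estimated mean; under the generator's
  missing-completely-at-random compliance this choice is unbiased either
  way.

## Step one: node-wise mixed models

For each node $j$, with $c_{pd,k}$ the centered morning value of node
$k$ and $\hat m_{pk}$ the person mean,

$$
y_{pd,\mathrm{PM},j} \;=\; \nu_j
  + \sum_{k \ne j} \gamma_{jk}\,\hat m_{pk}
  + \sum_{k} \bigl(\beta_{jk} + u_{p,jk}\bigr)\, c_{pd,k}
  + b_{pj} + \varepsilon_{pd,j},
$$

with random intercept $b_{pj}$ and random slopes $u_{p,jk}$ estimated by
REML via `lme4`. The node's own person mean is omitted from the fixed
part: the random intercept absorbs that person-level variation, and
including it alongside the intercept would leave the between-person
regression ill-separated. Row sets are complete-case per node (no
imputation anywhere in the package; missingness acts through row
availability).

Design choices that were genuinely open, and how they were settled:

* **Diagonal random-effects covariance.** Slopes are mutually
  independent (`||` in the `lme4` formula). A fully correlated $V{+}1$
  dimensional random-effects covariance is poorly identified with ~9 lag
  rows per person at $V = 4$ and routinely fails to converge; the
  diagonal structure is the common choice in multilevel-VAR software. A
  `netfit_options(random = ...)` switch exposes intercept-only and
  no-random-effects variants (the latter exists for oracle testing
  against closed-form least squares).
* **Wald z inference.** Fixed-effect p-values use the normal
  approximation $2\Phi(-|\hat\beta/\mathrm{se}|)$ rather than
  Satterthwaite degrees of freedom. With hundreds of lag rows the two
  are indistinguishable; the choice is portable and matches common
  practice. Its small-sample behavior is checked empirically (below).
* **Raw scale by default.** Variables are analyzed on their 0–100
  instrument scale, so coefficients are interpretable in scale points;
  `standardize = TRUE` rescales by grand SDs. Internally the optimizer
  always works on unit-variance copies of outcome and predictors — this
  is purely numerical (0–100 scales trip `lme4`'s gradient checks) and
  estimates are mapped back exactly.
* **Convergence fallback ladder.** If a node model fails to converge,
  random slopes are dropped one at a time, smallest estimated variance
  first (deterministic tie-break by node order), then the model falls
  back to a random intercept; every fallback is recorded in the fit and
  the network metadata. A node is declared unestimable only if the
  intercept-only model also fails. Boundary ("singular") fits with a
  zero variance component are not treated as failures: a zero slope
  variance is a legitimate estimate.

**Residuals** are observed minus fitted values *including* the predicted
(shrunken) random effects: what remains is the within-occasion
innovation that step two targets.

## The three networks

* **Temporal:** entry $[j,k]$ of the $\beta$ matrix is the directed edge
  $k \to j$ (morning $k$ predicting afternoon $j$); the diagonal holds
  autoregressive self-loops. Random-slope SDs $\tau_{jk}$ quantify how
  much the coupling varies from person to person and are reported
  alongside.
* **Between-person:** the coefficient pairs $(\gamma_{jk},
  \gamma_{kj})$ of a node-wise Gaussian graphical model combine into a
  partial correlation by the signed geometric mean
  $\mathrm{sign}(\gamma_{jk})\sqrt{\gamma_{jk}\gamma_{kj}}$, which is
  exact when both regressions come from the same inverse-covariance
  structure. Pairs with conflicting signs have no coherent sign; the
  edge is set to 0 and flagged rather than averaged.
* **Contemporaneous:** each node's step-one residual is regressed on all
  other nodes' residuals (aligned on the intersection of rows used by
  every node fit) with a per-person random intercept; coefficient pairs
  combine as above.

Both symmetric networks are exactly symmetric by construction and carry
both directional p-values per edge.

## Edge selection

All p-values are Benjamini–Hochberg adjusted (`stats::p.adjust`).
Adjustment is pooled *within* each network by default — the $V^2$
temporal p-values, and the $2\binom{V}{2}$ directional p-values of each
symmetric network — with global pooling available as an option, since
the granularity is a reporting convention rather than a substantive
commitment. Temporal edges are selected on their own adjusted p;
symmetric edges under the "or" rule (either direction's adjusted
p < .05; an "and" rule is provided, and the or-selected set provably
contains the and-selected set). Reported weight for a symmetric edge is
the signed-geometric-mean partial correlation, not either directional
coefficient.

## The synthetic-study generator

Because raw EMA panels of this kind are rarely shareable, validation
rests on a generator whose ground truth is known exactly
(`true_model()`, `simulate_panel()`):

1. person means $m_p \sim \mathrm{MVN}(\mu, \Sigma_B)$;
2. a person lag matrix $B_p = B + \Delta_p$ with independent
   $\Delta_{p,jk} \sim N(0, T_{jk}^2)$;
3. each day a *fresh* morning deviation
   $\delta^{AM} \sim \mathrm{MVN}(0, \Sigma_{AM})$ — no overnight
   carry-over, matching the estimator's lag structure (an overnight
   carry-over mode can be added for misspecification studies but the
   default generator and estimator commit to the same assumption);
4. $\delta^{PM} = B_p\,\delta^{AM} + \varepsilon$,
   $\varepsilon \sim \mathrm{MVN}(0, \Sigma_C)$;
5. observed value $= m_p + \delta$; each occasion is observed per
   modality (self-report vs. task) with its compliance probability.

Covariances are built from target partial-correlation matrices by
inverting the unit-diagonal precision $K_{jk} = -\rho_{jk}$ and
rescaling to target SDs, so inverting the built covariance returns the
requested partials exactly — the closed-form oracle used throughout the
tests (`build_covariance()`, `partial_cor()`).

The shipped preset (`paper_preset()`, `inst/extdata/paper_preset.yaml`)
encodes the design and the estimated networks of a published twice-daily
adolescent self-regulation study as generating truth: 62 persons × 9
weekdays × AM/PM; compliance .85 (self-report) and .793 (task); five
nonzero lag-1 effects (self-loops for self-control .170, response
inhibition .184, rumination .268, a near-null anger self-loop −.006;
response inhibition → self-control .174; rumination → anger .189) with
their person-to-person slope SDs; one contemporaneous partial
correlation (anger–self-control −.138); and three between-person
partials centred on anger (−.491 self-control, −.150 response
inhibition, .291 rumination). Two quantities the study's tables do not
determine were fixed once as generator conventions:

* **Between/within variance split.** Only total SDs are reported, so the
  preset splits them by an intraclass correlation of 0.5 — a typical
  value for momentary affect and performance measures — giving between
  and within SDs of total$/\sqrt2$ each (`icc` is a preset knob).
* **Morning-deviation dispersion** $\Sigma_{AM}$ defaults to $\Sigma_C$;
  nothing in a fitted afternoon model identifies it separately.

Values are *not* clipped to [0, 100] by default: truncation biases every
linear estimate, and the recovery suite exists to test the estimator,
not the instrument's floor effects. `clip = TRUE` exists for realism
demonstrations and for writing files (the strict readers enforce the
instrument range at read time). Item-level (`simulate_items()`, with the
closed-form implied α) and trial-level (`simulate_trials()`, 4 × 50
trials, 10 no-go per block, withhold probability value/100) layers make
the scoring and reliability modules testable end to end.

## What the validation shows — problem sizes and tolerances

The test suite's empirical anchors, all generated in code at run time:

* **Parameter recovery** on one simulated study of 600 persons × 60 days
  at full compliance: every temporal coefficient within ±0.05 of truth
  (slope SDs within ±0.08), contemporaneous partials within ±0.05,
  between-person partials within ±0.07. The wider between band is
  honest: with 600 persons a partial correlation is estimated with a
  standard error near 0.04, and the estimator is verified to track the
  *sample* person means' partial correlations to well under 0.01 — the
  remaining error is person sampling, which no estimator can remove.
* **Oracle equivalence:** with random effects off, node estimates match
  hand-built normal equations to 1e-6, and both symmetric networks match
  partial correlations obtained by inverting the sample covariance
  (exactly, algebraically; to 0.02 against the generating truth at
  10^4 rows).
* **Calibration under no signal:** 200 replications at the study's own
  size (62 × 9, compliance .85/.793) with an all-null truth give Wald
  type-I error close to the nominal 5% (empirically slightly
  conservative) and an average false-edge share per network below the
  5% target under OR-rule FDR selection.
* **Closed-form anchors:** BH step-up against a literal textbook oracle,
  Cronbach's α against the covariance formula, Spearman–Brown against
  its formula, generator reliabilities against their closed forms,
  lag-pair counts against the design.

Degenerate inputs are handled explicitly: constant outcomes, all-missing
persons, zero-variance item sums, sessions without no-go trials, empty
p-value lists and non-positive-definite partial structures all raise
informative errors rather than propagating NaNs; ties in the fallback
ladder break deterministically; estimated partial correlations are
clamped to [−1, 1].

## Limitations

The generator emulates the *estimator's own* data model plus compliance
missingness. Passing recovery tests therefore shows the pipeline is
correct and well calibrated, not that the model is right for real
adolescents: real data bring floor effects on skewed anger scales,
circadian and weekend structure, overnight carry-over, reactivity, and
non-random missingness, none of which are generated by default. Results
on the preset should be read as "the method recovers this structure when
the world matches its assumptions." Bayesian estimation, idiographic
(person-specific) networks, lags beyond morning → afternoon, and
signal-detection task scoring are out of scope.
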