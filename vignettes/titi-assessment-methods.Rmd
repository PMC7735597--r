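---
title: "Methods: an age-structured Bayesian assessment of the New Zealand tītī"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an age-structured Bayesian assessment of the New Zealand tītī}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the population model and its assumptions, the observation model, the
priors, the sampler, the model-selection machinery, the synthetic-data
generator, and the design choices made where the design was genuinely
open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The population model

The tītī population of the New Zealand region is represented by fifteen
age classes (0–14) censused post-breeding on 31 March. Class 0 is fully
grown chicks; class 14 is a recycling plus group that accumulates all
older birds. Model year `t = 1` is the 1976 season and `t = 30` is 2005,
so a trajectory has 29 transitions — the exponent `1/29` in every
annualised growth rate follows from this convention, which is fixed
package-wide.

Four mortality mechanisms act at distinct points of the life cycle:

* **Weka depredation** removes a fraction `w = 0.11` of breeding attempts
  before chicks are counted. `w` is a fixed regional input, not an
  estimated parameter.
* **Chick harvest** removes the count `H_t` immediately after the census
  and before first-year survival acts, exactly as the `n[1,t]` equation
  writes it.
* **Fisheries bycatch** multiplies every survival transition by
  `(1 - b_t)` with `b_t = B_t / N_t`: all birds, breeders and
  non-breeders alike, are treated as equally vulnerable. Bycatch is set
  to zero from the 2002 season onward (post-driftnet-ban levels are
  negligible relative to the population), and the `forcing_series()`
  constructor enforces this.
* **Climate** enters through scaled logistic links between the annual
  rates and twelve-month means of the monthly Troup Southern Oscillation
  Index: `s_a = 0.98 * plogis(alpha_s + beta_s z_s)` and
  `f = 0.9 * plogis(alpha_f + beta_f z_f)`. The ceilings 0.98 and 0.9 are
  fixed biological maxima. Juvenile survival is `r * s_a` with
  `r ∈ [0, 1]` estimated, so it inherits the survival link.

The survival covariate for year `t` averages April of calendar year
`1975 + t` through the following March (the survival interval closed by
the census that ends year `t`); the fecundity covariate averages October
of `1974 + t` (just before egg laying) through the following September.
Monthly values are never imputed: a missing month is an error naming the
month. SOI values are stored on the scale whose annual means match the
covariate axis of the fitted links (roughly −2 to +1 over the study
period), not the ×10 Troup convention.

Lagged variants shift which covariate drives which year: an `S-1` model
drives survival in year `t` with the covariate of year `t + 1`, an `S+1`
model with that of year `t − 1`, and `NoS`/`NoF` models hold the rate
constant. The candidate set crosses survival and fecundity lags −1, 0, +1,
and `expand_lag_grid()` implements the boundary rule: whenever the
best-fitting model sits on the edge of the lag grid spanned by the fitted
set, the model one step beyond is proposed, until fit worsens — this is
how the `S-2F0` member of the default thirteen-model set arose.

Density dependence, sex structure, island-level subpopulations and
immigration are deliberately out of scope.

### Initial age structure and run-in

No age-resolved abundance estimates exist for 1976, so the initial age
*structure* is derived rather than estimated: an initializer Leslie matrix
is built from fixed central rates, its stable-age distribution seeds a
five-year run-in with all rates frozen at their year-1 values, and the
resulting vector — rescaled so that adults equal the estimated parameter
`N1a` — becomes model year 1. Three open choices were resolved as follows:

* *Initializer rates.* The vague priors have no meaningful means to plug
  in, and the published first/second-year survival figures for the
  congeneric short-tailed shearwater are not reproduced anywhere we can
  cite numerically; `leslie_initializer()` therefore defaults to
  documented central values (`s_a = 0.95`, `s_j = 0.665`, `f = 0.52`,
  maturity at (7.5, 1.9)) and is fully configurable. The five-year run-in
  washes the choice out of the final age structure, which the tests
  verify indirectly through parameter recovery.
* *Run-in harvest and bycatch rates.* The run-in needs constant rates
  `h` and `b`, but the data provide counts. They are computed once from
  the `N1a`-scaled stable-age vector (`h = H_1 / n0`, `b = B_1 / N`),
  with no fixed-point iteration: the run-in only shapes the age
  distribution, and iterating would change the result by well under a
  percent while complicating reproducibility.
* *Lag structure at the boundary.* The year-1 rates honour the model's
  lag (the link is evaluated at `t = 1` with the lag applied), which is
  why the covariate table extends two years before the study period.

Abundance is held in individuals internally; millions appear only at the
I/O surface and in the `N1a` parameter (whose prior is stated in
millions). This avoids unit mistakes against the 2005 chick estimate.

## Observation model and priors

Five independent data sources constrain the model, each entering as a
normal likelihood term:

| Quantity | Value (SE) | Model counterpart |
|---|---|---|
| Scaled CPUE, 19 years in 1979–92, 1994–98 | series | `k * n[0,t]`, SD `sigma_obs` |
| Adult-abundance trend | 0.983 (0.002) | `(N_a[30]/N_a[1])^(1/29)` |
| Adult-survival logit, 1996–2004 | 2.987 (0.422) | window mean of `log(s/(0.98−s))` |
| Fecundity logit, 1997–99 ∪ 2003–05 | 0.08 (0.108) | window mean of `log(f/(0.9−f))` |
| Juvenile-survival logit, 1996–2003 | 0.266 (0.155) | `r_j ×` window mean of `qlogis(s_j)` |
| 2005 chick abundance (millions) | 2.787 (0.132) | `n[0,30] / 1e6` |

The juvenile constraint's extra scaling `r_j ∈ [0, 1]` absorbs the known
downward bias of mark–recapture juvenile survival (emigrants counted as
deaths). The published point estimates are used verbatim as data: the
adult value 2.987 does not equal `log(0.952/0.028) ≈ 3.53` recomputed
from the published survival rate, and the fecundity value 0.08 does not
equal `log(0.52/0.38) ≈ 0.31` — the originals were presumably averaged
across island-level logits — so no reconciliation is attempted. CPUE
exists only for the Rama (surface-catching) harvest period; 1993 and all
years outside 1979–1998 are rejected at validation, and that whitelist is
enforced both in `observation_data()` and in `validate_inputs()`.

Priors: `beta_s`, `beta_f` (and, symmetrically, `alpha_s`, `alpha_f`,
which need *some* prior for the posterior to exist) are N(0, 100²);
`k` and `sigma_obs` uniform on [0, 1000]; `r`, `r_j` uniform on [0, 1];
`N1a` uniform on [0, 100] million adults. Age at maturity `(mu_p,
sigma_p)` has a bivariate normal prior centred at (7.5, 1.9); the
covariance matrix of the underlying estimate is not published, so the
default is diagonal with SDs (0.5, 0.25) — weakly informative around the
published means, configurable through `prior_config()`, and flagged here
as an assumption.

## Sampling

`fit()` is a bespoke adaptive random-walk Metropolis sampler targeting
`log_posterior()` directly. Bounded parameters are mapped to an unbounded
scale (logit for `r`, `r_j`, `k/1000`, `sigma_obs/1000`, `N1a/100`; log
for `sigma_p`) with the Jacobian included. The proposal covariance is the
running empirical covariance scaled by `2.38²/d`, with a global scale
tuned to a 0.234 acceptance target; adaptation gains decay as `1/it`
(diminishing adaptation), which in practice matters more for run-to-run
agreement of the posterior than freezing the proposal after burn-in.

Initialisation defaults to a data-informed heuristic (catchability from
the CPUE magnitude over the chick estimate, `N1a` from the chick estimate
inflated by the trend) polished by a short Nelder–Mead climb;
`init = "prior"` provides pure prior-rejection initialisation. Chains use
deterministic seed offsets, so a fixed seed yields bit-identical draws.

Convergence is summarised by the Gelman–Rubin potential scale reduction
factor per parameter; `fit()` warns above 1.05 and errors above 1.2 (both
thresholds configurable, and set to `Inf` in exploratory or very short
runs). Full-scale settings are two chains of 200,000 iterations, half
burn-in, thinned 1-in-20; all tests and desk scripts use scaled-down
chains (2 × 3,000 to 2 × 40,000 depending on the check), sizes chosen so
the whole suite runs comfortably on one CPU.

When process error is active, the year-specific disturbances are updated
in a second block with preconditioned Crank–Nicolson proposals, which
leave the N(0, σ²) prior invariant so the acceptance ratio is the
likelihood ratio alone. Latents are updated in random sub-blocks
(default 8) because single-block updates stall at large process SDs;
with near-zero SDs a full block is cheapest (`eps_block` in
`mcmc_settings()`).

## Model selection and averaging

WAIC is computed pointwise as `W = −2(lppd − p_waic)` with the
variance-based penalty. What counts as a "data point" is an open choice;
the package treats every independent likelihood factor as one point — the
19 CPUE observations plus the five constraints, 24 in all — configurable
to CPUE-only. Weights follow `exp(−ΔW/2)` normalisation, with ties in the
selection table broken by canonical model name for reproducibility.

Model averaging pools posterior draws: a fixed pooled size (default
10,000) is allocated across models by the deterministic largest-remainder
rule on the weights and filled by seeded resampling. Averaging is only
meaningful for quantities with the same interpretation in every model —
trajectories, growth rates, CPUE predictions, and parameters whose
meaning does not depend on the lag structure. `averaged_parameter()`
refuses link slopes unless all pooled models share the identical lag on
that axis.

A caution the synthetic experiments make vivid: at the study's data size
(19 CPUE points and aggregate constraints), *lag selection is fragile*.
With observation noise at realistic levels, a synthetic dataset generated
from an `S-1F0` truth is sometimes best fit by a neighbouring or even
mirrored lag; with noise reduced several-fold the true lag wins
decisively on every replicate. The WAIC weights spread across several lag
models should be read as genuine model uncertainty, which is exactly why
model-averaged quantities are preferred for reporting.

## Counterfactuals and sensitivity analyses

`run_counterfactual()` re-projects every posterior draw with one
mechanism removed, leaving all other sampled parameters untouched:
`H ≡ 0`, `B ≡ 0`, `w = 0`, or a link slope set to zero. "No relationship
between SOI and adult survival" is implemented as `beta_s = 0`, the rate
becoming each draw's intercept-only value — the most literal removal of
the relationship; because `s_j = r s_a`, juvenile survival is flattened
with it. (Fixing survival at its time-averaged fitted value instead is a
defensible alternative; the package keeps the literal reading.) Growth
percentages use total abundance by default, with an adult-only option.
Relative 2005 impacts are reported as the ratio of baseline to scenario
population, matching the counterfactual framing "relative to the
population in the absence of X".

The process-error sensitivity modifies the best model by adding
`eps_s[t] ~ N(0, sigma_s²)` and `eps_f[t] ~ N(0, sigma_f²)` inside the
link arguments. The "high" SDs are solved in closed form so that a ±2σ
disturbance at the observed covariate extremes makes true adult survival
span 0.65–0.97 and true fecundity 0.2–0.8:
`sigma = ±(alpha + beta z − log(bound/(max − bound)))/2`, the configured
SD being the larger of the two sides. A side whose bound is already
exceeded without noise contributes zero (no disturbance is needed on that
side); both sides vanishing is an error. The defaults recompute these SDs
from the fitted link coefficients rather than hard-coding any particular
solution, since the solutions depend on posterior means.

The input-perturbation suite refits the best model with one substitution
at a time: fecundity estimate at 0.8×/1.2× (logit recomputed), maximum
fecundity 0.8, maximum survival 0.999, trend ±0.01, and harvest/bycatch
series rescaled. The published upper and lower harvest/bycatch series are
not reproducible from any table, so the multipliers (defaults 0.75/1.25
for harvest, 0.5/2 for bycatch, with a variant holding post-1990 bycatch
at its 1990 level) are explicit, documented arguments — including the
low-bycatch variant that the sensitivity discussion uses but the printed
variant table omits.

## The synthetic-data generator

The generator replaces three inputs the study cannot ship — the
confidential scaled CPUE, the harvest/bycatch series, and the exact
covariate table — with seeded stand-ins, and records the full truth:

* **SOI**: a stationary monthly AR(1) (coefficient 0.65, innovation SD
  1.0, mean −0.45) spanning 1972–2008. The slightly negative mean mirrors
  the El Niño-heavy study period and puts the annual survival-covariate
  extremes near the observed −2 to +1 range. Real SOI has mild skewness
  and long-memory features the AR(1) does not reproduce; only the range
  and persistence structure matter for the links.
* **Truth trajectory and forcing, jointly**: the truth parameters
  (`alpha_s = 3.8`, `beta_s = 0.8`, `alpha_f = 0`, `beta_f = 0.35`,
  `r = 0.6`, `r_j = 0.9`, `N1a = 20M`, maturity (7.5, 1.9)) were chosen
  once so the generated population sits in the published envelope — a
  year-1 total of roughly 30 million declining 1–3% per year with 2005
  chicks near 2–3 million — under an `S-1F0` generating model. Harvest
  takes a seeded uniform 7–15% of each year's chicks (mean 0.11); bycatch
  follows a piecewise-linear pulse from 0.004 of the population in 1976
  to a 0.016 peak in 1986, collapsing to zero after 1991. Both counts are
  computed inside the truth projection so forcing and trajectory are
  exactly consistent.
* **Observations**: drawn from the observation model around the truth
  transforms with the published SEs; `noise_free = TRUE` emits the
  transforms exactly for oracle tests. CPUE uses an arbitrary catchability
  of `1e-5` per chick so the index is O(10) — the real scaling is
  confidential, and only relative year-to-year changes carry information.

What passing tests on this generator do and do not show: they demonstrate
that the estimation machinery recovers known parameters from data with
the study's size, noise and forcing structure; they cannot validate the
biological adequacy of the model for the real population (island
heterogeneity, non-ENSO climate drivers, density dependence are all
outside the generator by construction, as is the weaker burrow-harvest
CPUE of the early season).

## Numerical choices

* Posterior support violations and projection failures (harvest exceeding
  chicks, bycatch exceeding the population, non-finite abundance) are
  encoded as `−Inf` with a reason attribute; the sampler treats them as
  rejections.
* The stable-age solver takes the dominant eigenpair from `eigen()`,
  rejects complex or negative dominant structure, and flags reducible
  matrices whose stable age distribution would be degenerate. Agreement
  with 500-step power iteration and the one-step eigen identity are
  tested to 1e−8 relative error.
* The projection is validated against an independently written scalar
  loop oracle on 1,000 random instances to 1e−12 — the generator and the
  likelihood share the projection code on purpose (the shared code *is*
  the product), and the oracle guards against self-confirming bugs.
* All CSV output uses 17 significant digits, so reruns are bitwise
  comparable; every stochastic entry point takes an explicit seed and
  derives sub-seeds deterministically.
* Ties in the WAIC table break by model name; largest-remainder
  allocation makes pooled-draw counts deterministic given the weights.

## Known limitations

The sampler is a general-purpose random-walk scheme: weakly identified
directions (`r_j`, the `alpha_s`/`r` ridge) mix slowly, and short chains
can misrank adjacent lag models — the acceptance checks therefore test
coverage and distributional agreement, not point equality. The run-in
rate approximation and the generator's run-in produce age structures that
differ from the fitted pipeline's by well under a percent, which is
invisible at the study's noise level but would matter for a
noise-free-data exercise. Management-strategy projection beyond 2005 is
out of scope.
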