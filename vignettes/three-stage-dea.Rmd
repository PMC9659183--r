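---
title: "Three-stage DEA with stochastic frontier input adjustment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Three-stage DEA with stochastic frontier input adjustment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tsdea)
```

## The problem

Cross-unit efficiency comparisons — here, the operational efficiency of
basic medical insurance across 31 provinces over four years — face a
well-known confounding problem: a unit may look wasteful either because its
management is wasteful, because it operates in an unfavourable environment
(a poor region, weak fiscal capacity), or because of plain luck. The Fried
three-stage design separates these:

1. **Stage 1** measures each unit's input-oriented efficiency against the
   empirical frontier of its own period, and extracts the *total input
   slack* per input — the full distance between the observed input bundle
   and its frontier reference point.
2. **Stage 2** regresses each input's slacks on observable environmental
   covariates with a stochastic frontier, splits the unexplained residual
   into one-sided inefficiency and symmetric noise, and raises every unit's
   inputs to the level implied by the *worst* observed environment and the
   *worst* noise draw, so that all units face a level playing field.
3. **Stage 3** re-measures efficiency on the adjusted inputs with the
   original outputs; remaining differences are attributable to management.

## Stage 1: the envelopment programs

For a target unit with inputs $x_0$ and outputs $y_0$ among $n$ units, the
input-oriented envelopment program is

$$\min_{\theta, \lambda, S^-, S^+} \theta
  \quad \text{s.t.} \quad X\lambda + S^- = \theta x_0,\;
  Y\lambda - S^+ = y_0,\; \lambda \ge 0,\, S^\pm \ge 0,$$

with the convexity constraint $\sum_j \lambda_j = 1$ added under variable
returns to scale (the BCC model) and omitted under constant returns (CCR).
Technical efficiency is the CRS score (TE), pure technical efficiency the
VRS score (PTE), and scale efficiency SE = TE/PTE, so TE = PTE × SE by
construction. A unit is *valid* (fully efficient) when $\theta = 1$ with
zero slacks, *weakly valid* when $\theta = 1$ with nonzero slack, *invalid*
when $\theta < 1$.

Numerical choices:

* Each period is enveloped as its own cross-section; periods are never
  pooled into one frontier.
* The default solver strategy is **two-phase**: minimise $\theta$, then
  maximise the slack sum at the fixed optimum. The classical
  non-Archimedean single program ($\min \theta - \varepsilon \, e^\top S$)
  is available as `slack_phase = "epsilon"` with $\varepsilon = 10^{-6}$;
  the two agree on $\theta$ to $10^{-8}$ on random instances, but finite
  $\varepsilon$ programs are numerically fragile, hence the default.
* `unity_tolerance = 1e-6` decides frontier membership, because LP solvers
  return scores like 0.9999999997 for frontier units.
* Every dimension is normalised by its slice mean before the solve (DEA is
  units-invariant), so the simplex works on numbers of order one even when
  inputs range from ratios to counts in the hundreds of thousands.
* The envelopment LPs are solved by the package's own dense two-phase
  primal simplex with Bland's anti-cycling rule. These programs are small
  but routinely degenerate — frontier units sit on several binding
  constraints at once — and the implementation is validated against a
  closed-form oracle (CRS, single ratio) and a vertex-enumeration oracle
  (VRS) on thousands of random instances.
* Intensity weights $\lambda$ can have alternate optima; only $\theta$,
  total slacks and validity are treated as deterministic outputs.

## Stage 2: frontier regression of the slacks

For each input $n$, the total slack of observation $i$ is modelled as

$$s_{ni} = z_i^\top \beta_n + v_{ni} + u_{ni}, \qquad
  v \sim N(0, \sigma_v^2),\; u \sim N^+(0, \sigma_u^2),$$

estimated by maximum likelihood in the Battese–Corra parameterisation
$\sigma^2 = \sigma_u^2 + \sigma_v^2$, $\gamma = \sigma_u^2/\sigma^2$. One
regression per input (three in the motivating application), fitted on the
pooled unit-period sample by default (`pooled = FALSE` fits per period). An
intercept is always included. Covariates are standardised internally for
optimiser stability and coefficients reported on the raw scale, matching
how such tables are published. Optimisation is BFGS from the OLS solution
crossed with a grid of starting $\gamma$ values; the reported likelihood
never falls below the OLS likelihood, and the one-sided LR statistic
$2(\ell - \ell_{OLS})$ is referred to the 50:50 mixed $\chi^2$ of Kodde and
Palm (5% critical value 2.706 for one restriction).

The residual split uses the JLMS conditional mean

$$E[u \mid \varepsilon] = \sigma^* \left[
  \frac{\phi(a)}{\Phi(a)} + a \right], \qquad
  a = \frac{\varepsilon \lambda}{\sigma},\;
  \sigma^* = \frac{\sigma \lambda}{1 + \lambda^2}
           = \frac{\sigma_u \sigma_v}{\sigma},\;
  \lambda = \frac{\sigma_u}{\sigma_v},$$

evaluated with log-scale Mills ratios so it stays finite and positive for
arbitrarily negative residuals (the far tail decays like
$\sigma^{*2}/|\mu^*|$, i.e. polynomially, not exponentially). The noise
estimate is $\hat v = \varepsilon - E[u \mid \varepsilon]$, so fitted value,
inefficiency and noise reconstruct each slack exactly. In the pure-noise
limit $\gamma = 0$ the inefficiency is defined as zero.

The input correction is

$$x^*_{ni} = x_{ni} + \left[\max_i(z_i^\top \hat\beta_n) - z_i^\top \hat\beta_n\right]
           + \left[\max_i(\hat v_{ni}) - \hat v_{ni}\right],$$

with maxima over the estimation sample. Both brackets are non-negative, so
adjusted inputs dominate the originals, and the observation attaining both
maxima — worst environment and worst luck — is left untouched.

Two modelling clarifications we adopted where the source presentation is
ambiguous: the inefficiency distribution is $N^+(0, \sigma_u^2)$ (two
distinct variances are required for the decomposition and for reporting
$\sigma^2$ and $\gamma$ separately), and the JLMS scale factor is
$\sigma\lambda/(1+\lambda^2) = \sigma_u\sigma_v/\sigma$, the standard form.

## Stage 3

Both envelopment programs are re-solved on the adjusted inputs with the
original outputs, rebuilding the full TE/PTE/SE decomposition. When the
stage-2 fits carry no environmental effect and no noise spread, stage-3
scores equal stage-1 scores exactly — the adjustment is a no-op.

## Tunable parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `rts` / decomposition | CRS + VRS | TE, PTE, SE per unit-period |
| `slack_rts` | `"vrs"` | which stage-1 run supplies the stage-2 slacks |
| `slack_phase` | `"two_phase"` | slack handling; `"epsilon"` for the classical single LP |
| `epsilon` | `1e-6` | non-Archimedean constant (epsilon mode only) |
| `unity_tolerance` | `1e-6` | frontier membership threshold |
| `pooled` | `TRUE` | one stage-2 regression per input over all periods |
| `gamma_starts` | 0.05–0.9 | optimiser start grid for the variance split |

The frontier-count convention reports a unit as "on the frontier" when its
across-period *mean* score equals 1 at three decimals, matching how the
published province tables are summarised (not when any single year is 1).

A lower-is-better output (the epidemic morbidity rate in the motivating
indicator system) violates DEA's output monotonicity if used as is. The
published analysis uses it unchanged; the package follows that default but
provides `invert_output()` (the order-reversing map
$x \mapsto \max x + \min x - x$, which preserves positivity) for users who
want the defensible variant. The generator's `morbidity = "adverse"` mode
produces data for exercising that path.

## What the synthetic generator emulates

`simulate_panel()` draws panels from exactly the model class stage 2
assumes, with all ground truth recorded, so every stage is testable without
the undeposited yearbook data:

* **Scales** follow the published descriptive table: three inputs around
  263 / 319,278 / 524 units, outputs around 200 / 215 / 1,650, environment
  covariates on GDP-per-capita, expenditure and ratio scales.
* **Size structure**: a latent log-normal unit size drives the expenditure
  outputs (elasticities 1 and 0.35) and, mildly, the first two environment
  covariates; the rate-like output has elasticity 0. This reproduces the
  strong input-output correlations (~0.7–0.9) of the published correlation
  screen. Independent uniform draws over the printed ranges would instead
  overdisperse the cross-section so much that half the units become
  vacuously efficient and the stage-2 likelihood degenerates.
* **Frontier**: efficient inputs are an inverse Cobb–Douglas in the
  outputs with exponents summing to 0.8, so returns to scale are genuinely
  variable.
* **Slack**: each observed input adds $z^\top\beta + u + v$ with
  $\gamma = 0.7$, $\sigma = 0.12$ of the input scale, a baseline slack of
  0.30 of scale, and per-standard-deviation environment effects of 3–12% of
  scale whose signs mirror the published stage-2 pattern (GDP and social
  security spending reduce slack everywhere; the fiscal ratio raises slack
  in the capital inputs). The first covariate follows a within-unit growth
  path, mimicking GDP persistence.
* **Positivity**: observations falling below 5% of the input scale are
  redrawn (up to 50 times, then an error); for every kept observation the
  additive identity `observed = efficient + zb + u + v` holds exactly.
* The recorded management-only efficiency is
  $\text{mean}_n\, x^{\text{eff}}_n / (x^{\text{eff}}_n + u_n)$, the input
  contraction attributable to management alone.

## What passing tests do and do not show

The generator draws slacks from the very model stage 2 fits, so parameter
recovery there is a well-posed check of the estimator, not of the method's
realism. Two honest caveats, both visible in the test suite:

* **Measured DEA slacks are not model slacks.** The empirical frontier is
  estimated, so measured total slacks carry a point mass at zero (30–40% of
  observations on default panels — comparable to the share of score-1
  province-years in the published stage-1 table). Under such censoring the
  half-normal MLE often sits at the $\gamma = 1$ boundary with attenuated
  environment slopes. The package reports this honestly through the
  `converged`/`boundary` flags rather than hiding it; with strong
  environment effects the slopes are recovered essentially always.
* **$\gamma$ is hard at n = 124.** At the pooled panel size the MLE of
  $\gamma$ is median-accurate (median error ≤ 0.15 at $\gamma = 0.7$) but
  has heavy sampling spread, including occasional wrong-skew collapses to
  $\hat\gamma \approx 0$; its RMSE is ~0.29. This is a finite-sample
  property of the estimator itself, reproduced by direct simulation from
  the model.
* **Rank recovery improves on average, modestly.** Across default-condition
  seeds, stage-3 ranks correlate with the true management efficiency at
  least as well as stage-1 ranks in roughly two thirds of runs; the
  improvement is small because the frontier-approximation error — which the
  adjustment cannot remove — dominates both stages equally. With strong
  environments the *direction* of the adjustment is sharply identified:
  units helped by their environment lose ground from stage 1 to stage 3
  almost surely.

Problem sizes used in the shipped tests: 1,000 random instances for the
solver-oracle equivalence, 100 replicates for parameter-recovery and
sign-recovery properties, 200 replicates for the null size of the one-sided
LR test, and 50 seeded default panels (31 × 4) for the end-to-end
rank-recovery property.

## Worked example

```{r example, eval = FALSE}
sim <- simulate_panel(sim_config(), seed = 1)
res <- three_stage_dea(sim$panel)
res
summary(res)
truth_comparison(sim, res)[c("rho_stage1", "rho_stage3")]
autoplot(res)
```

## Known limitations

* Only input-oriented radial models; no output orientation,
  super-efficiency, SBM/additive models, or Malmquist indices.
* Only the half-normal inefficiency distribution; no truncated-normal or
  exponential variants, and no panel-SFA time-varying inefficiency.
* The second stage inherits the classical critique of regressing
  mass-at-zero slacks with a continuous frontier model; the package
  implements the canonical design faithfully and surfaces the boundary
  diagnostics instead of switching to a censored-regression variant.
* The published province tables can be aggregated and checked (and are,
  in the test suite), but the underlying yearbook microdata are not
  deposited, so the published efficiency values themselves cannot be
  re-derived from raw data.
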