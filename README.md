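# tsdea

Three-stage data envelopment analysis (DEA) with stochastic-frontier input
adjustment, for panels of decision-making units — the design used to
measure the operational efficiency of basic medical insurance across
Chinese provinces, and more generally any setting where measured
inefficiency mixes management, environment and luck.

## Who this is for

Health-systems and public-economics researchers who want to score units
(provinces, hospitals, funds) on multiple inputs and outputs, and who need
efficiency estimates that are not confounded by observable environmental
conditions or statistical noise.

## The method

**Stage 1.** For each unit with inputs $x_0$, outputs $y_0$, solve the
input-oriented envelopment program

$$\min \theta \quad \text{s.t.}\quad X\lambda + S^- = \theta x_0,\;\;
Y\lambda - S^+ = y_0,\;\; \lambda \ge 0,$$

with $\sum_j \lambda_j = 1$ under variable returns to scale (BCC) and
without it under constant returns (CCR). TE is the CRS score, PTE the VRS
score, SE = TE/PTE. Each period is enveloped as its own cross-section. The
*total* input slack $x_0 - X\lambda = (1-\theta)x_0 + S^-$ feeds stage 2.

**Stage 2.** Per input, a half-normal stochastic frontier
$s_i = z_i^\top\beta + v_i + u_i$ with $v \sim N(0,\sigma_v^2)$,
$u \sim N^+(0,\sigma_u^2)$ (Battese–Corra: $\sigma^2 = \sigma_u^2 +
\sigma_v^2$, $\gamma = \sigma_u^2/\sigma^2$), fitted by maximum
likelihood. Residuals are split by the JLMS conditional mean
$E[u|\varepsilon] = \sigma^*[\phi(a)/\Phi(a) + a]$, and inputs are raised
to the worst observed environment and luck:
$x^* = x + [\max(z^\top\hat\beta) - z^\top\hat\beta] + [\max(\hat v) - \hat v]$.

**Stage 3.** Re-solve both envelopment programs on the adjusted inputs;
remaining inefficiency is attributable to management.

The envelopment LPs are solved by the package's own dense two-phase
simplex with Bland's rule (these small programs are routinely degenerate),
validated against closed-form and vertex-enumeration oracles.

## Worked example

```r
library(tsdea)
sim <- simulate_panel(sim_config(), seed = 1)   # 31 units x 4 periods
res <- three_stage_dea(sim$panel)
res
#> Three-stage DEA result: 31 units x 4 periods
#>   stage 1: mean TE 0.865, 1 frontier unit(s)
#>   stage 3: mean TE 0.904, 1 frontier unit(s), min 0.781 (U29)
summary(res)
#> # A tibble: 2 x 5
#>   stage  grand_mean_te frontier_count min_unit min_mean_te
#> 1 stage1         0.865              1 U27            0.698
#> 2 stage3         0.904              1 U29            0.781
glance(res$sfa$fund_income)[c("lr_one_sided", "sigma_sq", "gamma")]
#>   lr_one_sided sigma_sq gamma
#> 1         44.2    2705. 1.000
```

Reading this: stage-1 mean technical efficiency over the 124 unit-periods
is 0.865; after removing the fitted environment and luck components from
the input slacks, the mean rises to 0.904 and the worst unit changes — the
environment, not management, made U27 look worst. The stage-2 fit for the
first input finds its slacks overwhelmingly one-sided (gamma at the upper
boundary, LR = 44.2 against the no-inefficiency null), which the package
reports via `converged`/`boundary` flags rather than hiding.

`printed_fixtures()` ships the published 31-province stage-1 and
stage-1-vs-stage-3 efficiency tables, and `efficiency_summary()` aggregates
any long score table (grand mean, per-period means, frontier count by the
mean-equals-one-at-3-decimals convention, worst unit).

Other entry points: `dea_efficiency()` / `dea_decompose()` (stage 1 alone),
`sfa_fit()` + `tidy()` / `glance()` (stage 2 alone), `jlms()`,
`adjust_inputs()`, `read_panel()` / `write_panel()`, `describe_panel()`,
`pearson_screen()`, `export_report()`, `autoplot()` on results and fits,
and `simulate_panel()` / `truth_comparison()` for validation studies.

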