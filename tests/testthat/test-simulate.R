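test_that("the generator is deterministic per seed and distinct across seeds", {
  a <- simulate_panel(sim_config(n_units = 6, n_periods = 2), seed = 3)
  b <- simulate_panel(sim_config(n_units = 6, n_periods = 2), seed = 3)
  c <- simulate_panel(sim_config(n_units = 6, n_periods = 2), seed = 4)
  expect_identical(as.data.frame(a$panel), as.data.frame(b$panel))
  expect_identical(a$truth, b$truth)
  expect_false(isTRUE(all.equal(as.data.frame(a$panel),
                                as.data.frame(c$panel))))
})

test_that("recorded truth reconstructs every observed input exactly", {
  sim <- simulate_panel(sim_config(), seed = 6)
  d <- as.data.frame(sim$panel)
  for (v in attr(sim$panel, "input_cols")) {
    tr <- sim$truth[sim$truth$input == v, ]
    expect_equal(nrow(tr), nrow(d))
    expect_equal(d[[v]], tr$x_eff + tr$zb + tr$u + tr$v, tolerance = 1e-12)
    expect_true(all(tr$u >= 0))
    expect_true(all(tr$x_eff > 0))
  }
  expect_true(all(sim$true_efficiency$true_eff > 0 &
                    sim$true_efficiency$true_eff <= 1))
})

test_that("generated variables respect the configured envelopes", {
  cfg <- sim_config()
  sim <- simulate_panel(cfg, seed = cfg$seed)
  desc <- describe_panel(sim$panel)
  for (o in names(cfg$output_ranges)) {
    r <- cfg$output_ranges[[o]]
    row <- desc[desc$variable == o, ]
    expect_gte(row$min, r[1])
    expect_lte(row$max, r[2])
  }
  for (e in names(cfg$env_ranges)) {
    r <- cfg$env_ranges[[e]]
    row <- desc[desc$variable == e, ]
    expect_gte(row$min, r[1] - 1e-9)
    expect_lte(row$max, r[2] + 1e-9)
  }
  expect_true(all(as.data.frame(sim$panel)[attr(sim$panel, "input_cols")] >
                    0))
})

test_that("marginal moments match the clipped-lognormal closed form", {
  # the rate-like output is iid across observations: its clipped-lognormal
  # mean has a closed form to compare against at n = 10,000
  cfg <- sim_config(n_units = 2500, n_periods = 4)
  sim <- simulate_panel(cfg, seed = 99)
  x <- sim$panel$morbidity_rate
  r <- cfg$output_ranges$morbidity_rate
  mu <- log(cfg$output_centers[["morbidity_rate"]])
  s <- cfg$output_noise_sd
  la <- (log(r[1]) - mu) / s
  lb <- (log(r[2]) - mu) / s
  m_clip <- r[1] * stats::pnorm(la) +
    exp(mu + s^2 / 2) * (stats::pnorm(lb - s) - stats::pnorm(la - s)) +
    r[2] * (1 - stats::pnorm(lb))
  expect_equal(mean(x), m_clip, tolerance = 4 * stats::sd(x) /
                 sqrt(length(x)) / m_clip)
})

test_that("shrinking the composed error drives stage-1 efficiency to one", {
  te_at <- function(sfrac) {
    cfg <- sim_config(n_units = 10, n_periods = 1, gamma = 0,
                      beta_frac = matrix(0, 3, 3), intercept_frac = 0,
                      sigma_frac = sfrac)
    sim <- simulate_panel(cfg, seed = 15)
    mean(dea_efficiency(sim$panel, rts = "vrs")$theta)
  }
  te_hi <- te_at(0.15)
  te_lo <- te_at(0.01)
  expect_gt(te_lo, te_hi)
  expect_gt(te_lo, 0.95)
})

test_that("an infeasible slack configuration fails with a retry diagnostic", {
  cfg <- sim_config(n_units = 6, n_periods = 2, intercept_frac = -5,
                    retry_cap = 5)
  expect_error(simulate_panel(cfg, seed = 1), "redraws")
})

test_that("strongly negative environment effects are recovered in sign", {
  # beta strongly negative on the first covariate; the stage-2 fit on the
  # measured DEA slacks should carry a negative sign nearly always
  cfg <- sim_config(beta_frac = matrix(c(-0.25, 0, 0,
                                         -0.25, 0, 0,
                                         -0.25, 0, 0), 3, byrow = TRUE),
                    intercept_frac = 0.45)
  neg <- vapply(1:100, function(seed) {
    sim <- simulate_panel(cfg, seed = seed)
    eff <- dea_efficiency(sim$panel, rts = "vrs")
    dat <- as.data.frame(sim$panel)[attr(sim$panel, "env_cols")]
    dat$.slack <- eff$total_slack_fund_income
    f <- suppressWarnings(
      sfa_fit(.slack ~ gdp_per_capita + ss_employment_exp + fiscal_ratio,
              data = dat))
    unname(coef(f)["gdp_per_capita"] < 0)
  }, logical(1))
  expect_gte(mean(neg), 0.95)
})
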