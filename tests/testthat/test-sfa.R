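test_that("jlms reproduces the zero-residual closed form and stays stable", {
  # eps = 0, sigma_u = sigma_v = 1: sigma* phi(0)/Phi(0) = (1/sqrt(2)) * 2 phi(0)
  expect_equal(jlms(0, sigma = sqrt(2), lambda = 1),
               (1 / sqrt(2)) * stats::dnorm(0) / stats::pnorm(0),
               tolerance = 1e-12)
  expect_equal(jlms(0, sigma = sqrt(2), lambda = 1), 0.5641896,
               tolerance = 1e-6)

  # strictly increasing in the residual
  g <- jlms(seq(-5, 5, by = 0.25), sigma = sqrt(2), lambda = 1)
  expect_true(all(diff(g) > 0))

  # deep negative residual: finite, positive, small, and on the Mills
  # asymptote sigma*^2 / |mu*| (the conditional mean decays like 1/|eps|)
  v <- jlms(-40, sigma = sqrt(2), lambda = 1)
  expect_true(is.finite(v) && v > 0 && v < 0.03)
  sigma_u <- sigma_v <- 1
  mu_star <- -40 * sigma_u^2 / 2
  s_star <- sigma_u * sigma_v / sqrt(2)
  expect_equal(v, s_star^2 / abs(mu_star), tolerance = 0.01)

  expect_error(jlms(0, sigma = 0, lambda = 1), "sigma")
  expect_error(jlms(0, sigma = 1, lambda = -1), "lambda")
})

test_that("jlms agrees with numerical integration over a parameter grid", {
  for (sigma in c(0.5, sqrt(2), 3)) {
    for (lam in c(0.3, 1, 2.5)) {
      for (eps in c(-3, -1, -0.3, 0, 0.3, 1, 3)) {
        expect_equal(jlms(eps, sigma, lam),
                     jlms_integral_oracle(eps, sigma, lam),
                     tolerance = 1e-6)
      }
    }
  }
})

test_that("the frontier likelihood never falls below its OLS start", {
  for (seed in 1:5) {
    d <- sfa_sample(150, beta0 = 2, beta1 = -1, gamma = 0.6, sigma_sq = 2,
                    seed = seed)
    f <- suppressWarnings(sfa_fit(y ~ z, data = d))
    expect_gte(f$logLik, f$logLik_ols - 1e-6)
    expect_gte(f$lr_one_sided, 0)
    expect_true(f$sigma_sq > 0)
    expect_true(f$gamma >= 0 && f$gamma <= 1)
  }
})

test_that("coefficients are reported on the raw covariate scale", {
  d <- sfa_sample(300, beta0 = -5, beta1 = 2, gamma = 0.7, sigma_sq = 4,
                  seed = 9)
  f1 <- sfa_fit(y ~ z, data = d)
  d2 <- d; d2$z <- d2$z * 1000
  f2 <- sfa_fit(y ~ z, data = d2)
  expect_equal(coef(f2)[["z"]], coef(f1)[["z"]] / 1000, tolerance = 1e-4)
  expect_equal(f2$fitted, f1$fitted, tolerance = 1e-4)
  expect_equal(f2$gamma, f1$gamma, tolerance = 1e-4)
})

test_that("tidy and glance expose the Battese-Corra parameterisation", {
  d <- sfa_sample(200, beta0 = 1, beta1 = 0.5, gamma = 0.5, sigma_sq = 1,
                  seed = 3)
  f <- suppressWarnings(sfa_fit(y ~ z, data = d))
  td <- tidy(f)
  expect_equal(td$term, c("(Intercept)", "z", "sigma_sq", "gamma"))
  expect_true(all(c("estimate", "std.error", "statistic", "p.value")
                  %in% names(td)))
  gl <- glance(f)
  expect_equal(gl$lr_one_sided, max(0, 2 * (gl$logLik - gl$logLik_ols)))
  expect_equal(gl$nobs, 200L)
})

test_that("residual decomposition reconstructs every slack exactly", {
  d <- sfa_sample(200, beta0 = 3, beta1 = 1.5, gamma = 0.7, sigma_sq = 2,
                  seed = 12)
  f <- suppressWarnings(sfa_fit(y ~ z, data = d))
  dc <- sfa_decompose(f)
  expect_true(all(dc$u > 0))
  expect_equal(dc$.fitted + dc$u + dc$v, d$y, tolerance = 1e-10)

  # estimated noise tracks the true noise draws at gamma = 0.7, n = 500
  set.seed(77)
  n <- 500
  z <- runif(n, 0, 5)
  sv <- sqrt(0.3 * 4); su <- sqrt(0.7 * 4)
  v_true <- rnorm(n, 0, sv)
  dd <- data.frame(z = z, y = -5 + 2 * z + v_true + abs(rnorm(n)) * su)
  fd <- suppressWarnings(sfa_fit(y ~ z, data = dd))
  dcd <- sfa_decompose(fd)
  expect_gt(stats::cor(dcd$v, v_true), 0.5)
})

test_that("the pure-noise limit attributes everything to noise, with warning", {
  f <- fake_fit(c(1, 2, 3), gamma = 0)
  f$residuals <- c(0.5, -0.2, 0.1)
  expect_warning(dc <- sfa_decompose(f), "gamma = 0")
  expect_equal(dc$u, c(0, 0, 0))
  expect_equal(dc$v, f$residuals)
})

test_that("an exact linear fit degenerates with a clear diagnostic", {
  d <- data.frame(z = 1:20)
  d$y <- 2 * d$z + 1
  expect_error(sfa_fit(y ~ z, data = d), "degenerate")
  expect_error(sfa_fit(y ~ z, data = d[1:2, ]), "at least")
})

test_that("gamma is recovered at the pooled panel size with correct signs", {
  # slack data drawn from the stage-2 model class at n = 124
  ests <- vapply(1:100, function(seed) {
    set.seed(seed)
    n <- 124; scl <- 262.86
    z1 <- rnorm(n); z2 <- rnorm(n); z3 <- rnorm(n)
    zb <- scl * (0.30 - 0.10 * z1 - 0.08 * z2 + 0.04 * z3)
    sig <- 0.12 * scl
    s <- zb + sqrt(0.3) * sig * rnorm(n) + sqrt(0.7) * sig * abs(rnorm(n))
    f <- suppressWarnings(sfa_fit(s ~ z1 + z2 + z3,
                                  data = data.frame(s, z1, z2, z3)))
    c(f$gamma, coef(f)[2], coef(f)[3], coef(f)[4])
  }, numeric(4))
  expect_lte(stats::median(abs(ests[1, ] - 0.7)), 0.15)
  # strong effects (>= 2/3 residual sd per sd of z) never flip sign;
  # the weak one (1/3 residual sd) may rarely
  expect_equal(mean(ests[2, ] < 0), 1)
  expect_equal(mean(ests[3, ] < 0), 1)
  expect_gte(mean(ests[4, ] > 0), 0.95)
})
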