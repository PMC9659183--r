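# Independent oracles used by the DEA and JLMS tests. These never call the
# package's own solver or formula.

# closed-form CRS score for 1 input / 1 output: ratio to the best ratio
crs_ratio_oracle <- function(x, y) (y / x) / max(y / x)

# VRS score for 1 input / 1 output by enumerating convex combinations of
# observation pairs on the input-output plane
vrs_vertex_oracle <- function(x, y, j0) {
  y0 <- y[j0]
  cand <- x[y >= y0]
  n <- length(x)
  for (j in seq_len(n)) for (k in seq_len(n)) {
    if (y[j] < y0 && y[k] > y0) {
      w <- (y0 - y[k]) / (y[j] - y[k])
      cand <- c(cand, w * x[j] + (1 - w) * x[k])
    }
  }
  min(cand) / x[j0]
}

# brute-force posterior mean of the truncated-normal u | eps by numerical
# integration (the JLMS quantity, computed without the JLMS formula)
jlms_integral_oracle <- function(eps, sigma, lam) {
  sigma_u <- sigma * lam / sqrt(1 + lam^2)
  sigma_v <- sigma / sqrt(1 + lam^2)
  mu_star <- eps * sigma_u^2 / sigma^2
  s_star <- sigma_u * sigma_v / sigma
  num <- stats::integrate(function(u) u * stats::dnorm(u, mu_star, s_star),
                          0, Inf, rel.tol = 1e-12, abs.tol = 1e-300)$value
  den <- stats::integrate(function(u) stats::dnorm(u, mu_star, s_star),
                          0, Inf, rel.tol = 1e-12, abs.tol = 1e-300)$value
  num / den
}

# quick panel builders
panel_1x1 <- function(x, y, period = "t1") {
  dmu_panel(data.frame(unit = sprintf("d%02d", seq_along(x)),
                       period = period, x = x, y = y),
            inputs = "x", outputs = "y")
}

rand_panel_1x1 <- function(n) panel_1x1(runif(n, 0.5, 10), runif(n, 0.5, 10))

# half-normal frontier sample in the Battese-Corra parameterisation
sfa_sample <- function(n, beta0, beta1, gamma, sigma_sq, seed) {
  set.seed(seed)
  z <- runif(n, 0, 5)
  su <- sqrt(gamma * sigma_sq)
  sv <- sqrt((1 - gamma) * sigma_sq)
  data.frame(z = z,
             y = beta0 + beta1 * z + rnorm(n, 0, sv) + abs(rnorm(n)) * su)
}

# a fabricated sfa_fit-shaped object for contract tests that need exact
# fitted values and noise estimates
fake_fit <- function(fitted, gamma = 0.5) {
  structure(list(fitted = fitted, residuals = rep(0, length(fitted)),
                 gamma = gamma, sigma_sq = 1, lambda = 1,
                 coefficients = c(`(Intercept)` = 0), n = length(fitted)),
            class = "sfa_fit")
}
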