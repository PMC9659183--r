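#' Configuration for the synthetic panel generator
#'
#' Defaults emulate the province-by-year basic-medical-insurance panel the
#' three-stage analysis was designed for: 31 units over 4 periods, three
#' inputs on the scales of fund income (CNY 1e8), health technicians
#' (persons) and government health expenditure (CNY 1e8), three outputs on
#' the scales of fund expenditure (CNY 1e8), epidemic morbidity per 100,000
#' and resident health insurance expenditure (CNY), and three environmental
#' covariates (GDP per capita, social security and employment expenditure,
#' fiscal revenue/expenditure ratio).
#'
#' The data-generating process instantiates the stage-2 model class.
#' Outputs are driven by a latent log-normal unit "size" factor (big
#' provinces spend more and insure more; rate-like outputs do not scale),
#' which reproduces the strong cross-correlation between inputs and outputs
#' that real yearbook panels show and keeps dispersion near the published
#' standard deviations rather than at full-range-uniform levels. Efficient
#' inputs come from an inverse Cobb-Douglas frontier on the outputs
#' (exponents summing below 1, so returns to scale are genuinely variable),
#' and observed inputs add an environment term `z' beta`, a half-normal
#' inefficiency draw `u` and Gaussian noise `v`, per input.
#' `beta`, `sigma` and the frontier level are expressed as fractions of each
#' input's scale so one set of defaults serves all three input magnitudes;
#' `beta` signs mirror the published stage-2 pattern (GDP and social
#' security spending reduce slack in every input; the fiscal ratio raises
#' slack in the capital inputs and reduces it in the labour input).
#'
#' @param n_units,n_periods Panel dimensions. Defaults 31 and 4.
#' @param output_ranges Named list of `c(min, max)` per output; generated
#'   values are clipped into these.
#' @param output_centers Central (roughly median) level per output.
#' @param size_sd Standard deviation of the latent log unit-size factor.
#' @param size_elasticity Per-output elasticity with respect to unit size
#'   (1 for totals, 0 for rates).
#' @param output_noise_sd Log-scale idiosyncratic output noise.
#' @param input_scales Named vector of input magnitudes.
#' @param alpha Matrix (inputs x outputs) of Cobb-Douglas exponents;
#'   each row should sum below 1.
#' @param env_ranges Named list of `c(min, max)` per environmental
#'   covariate; the first covariate gets within-unit persistence (a GDP-like
#'   growth path), the second a persistent unit level with small noise, the
#'   third is drawn independently.
#' @param beta_frac Matrix (inputs x env) of slack responses per standard
#'   deviation of the covariate, as fractions of the input scale.
#' @param intercept_frac Baseline slack level as a fraction of input scale.
#' @param gamma True inefficiency share `sigma_u^2 / sigma^2` in `[0, 1]`.
#' @param sigma_frac Composed-error standard deviation `sigma` as a fraction
#'   of input scale.
#' @param frontier_frac Frontier level as a fraction of input scale.
#' @param floor_frac Positivity floor for observed inputs, as a fraction of
#'   input scale; observations falling below are redrawn.
#' @param retry_cap Redraw attempts per observation before erroring.
#' @param morbidity `"benefit"` (default) generates every output
#'   higher-is-better; `"adverse"` records the morbidity-like output on its
#'   realistic lower-is-better scale (use [invert_output()] before DEA).
#' @param seed Default seed used by [simulate_panel()].
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(
    n_units = 31, n_periods = 4,
    output_ranges = list(fund_expenditure = c(3.5, 682.7),
                         morbidity_rate = c(80.8, 589.41),
                         resident_expenditure = c(271.5, 3739.7)),
    output_centers = c(fund_expenditure = 200,
                       morbidity_rate = 215,
                       resident_expenditure = 1650),
    size_sd = 0.5,
    size_elasticity = c(1, 0, 0.35),
    output_noise_sd = 0.25,
    input_scales = c(fund_income = 262.86,
                     health_technicians = 319278,
                     gov_health_expenditure = 524.42),
    alpha = matrix(c(0.5, 0.1, 0.2,
                     0.2, 0.4, 0.2,
                     0.3, 0.2, 0.3), nrow = 3, byrow = TRUE),
    env_ranges = list(gdp_per_capita = c(28497, 164889),
                      ss_employment_exp = c(107.92, 1998.67),
                      fiscal_ratio = c(0.10, 0.88)),
    beta_frac = matrix(c(-0.10, -0.08,  0.04,
                         -0.10, -0.12, -0.05,
                         -0.08, -0.06,  0.03), nrow = 3, byrow = TRUE),
    intercept_frac = 0.30,
    gamma = 0.7, sigma_frac = 0.12, frontier_frac = 0.65,
    floor_frac = 0.05, retry_cap = 50,
    morbidity = c("benefit", "adverse"),
    seed = 20171231) {
  morbidity <- match.arg(morbidity)
  stopifnot(n_units >= 2, n_periods >= 1,
            gamma >= 0, gamma <= 1, sigma_frac > 0, frontier_frac > 0,
            all(alpha > 0), all(vapply(output_ranges,
                                       function(r) r[1] > 0 && r[1] < r[2],
                                       logical(1))))
  structure(list(n_units = n_units, n_periods = n_periods,
                 output_ranges = output_ranges,
                 output_centers = output_centers, size_sd = size_sd,
                 size_elasticity = size_elasticity,
                 output_noise_sd = output_noise_sd,
                 input_scales = input_scales,
                 alpha = alpha, env_ranges = env_ranges,
                 beta_frac = beta_frac, intercept_frac = intercept_frac,
                 gamma = gamma, sigma_frac = sigma_frac,
                 frontier_frac = frontier_frac, floor_frac = floor_frac,
                 retry_cap = retry_cap, morbidity = morbidity, seed = seed),
            class = "sim_config")
}

#' Generate a synthetic DMU panel with recorded ground truth
#'
#' Draws a panel from the process described in [sim_config()] and records
#' everything the recovery tests need: the efficient input levels, the
#' environment contribution `z' beta`, and the inefficiency and noise draws
#' per observation and input. For every kept (non-redrawn-beyond-cap)
#' observation the additive identity
#' `observed = efficient + zb + u + v` holds exactly.
#'
#' The scalar `true_eff` per observation is the management-only efficiency
#' `mean over inputs of x_eff / (x_eff + u)` — the input contraction a
#' perfectly informed evaluator would attribute to management, which is what
#' stage 3 is supposed to recover.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A list: `panel` (a [dmu_panel()]), `truth` (long tibble: `unit`,
#'   `period`, `input`, `x_eff`, `zb`, `u`, `v`, `retries`),
#'   `true_efficiency` (tibble `unit`, `period`, `true_eff`), `config`.
#' @examples
#' sim <- simulate_panel(sim_config(n_units = 6, n_periods = 2), seed = 42)
#' describe_panel(sim$panel)
#' @export
simulate_panel <- function(config = sim_config(), seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  nu <- config$n_units
  np <- config$n_periods
  nobs <- nu * np
  units <- sprintf("U%02d", seq_len(nu))
  periods <- sprintf("t%d", seq_len(np))
  unit <- rep(units, each = np)
  period <- rep(periods, times = nu)

  onames <- names(config$output_ranges)
  inames <- names(config$input_scales)
  enames <- names(config$env_ranges)

  # latent unit size: totals scale with it, rates do not
  size <- exp(stats::rnorm(nu, 0, config$size_sd))
  size_obs <- rep(size, each = np)

  # outputs: size-structured log-normal around the configured centres,
  # clipped into the configured ranges (benefit scale)
  O <- matrix(NA_real_, nobs, length(onames), dimnames = list(NULL, onames))
  for (m in seq_along(onames)) {
    r <- config$output_ranges[[m]]
    y <- config$output_centers[[m]] *
      size_obs^config$size_elasticity[m] *
      exp(stats::rnorm(nobs, 0, config$output_noise_sd))
    O[, m] <- pmin(pmax(y, r[1]), r[2])
  }

  # env: first covariate (GDP-like) persistent with growth and mildly
  # size-linked, second (total spending) size-linked and persistent,
  # rest independent
  Z <- matrix(NA_real_, nobs, length(enames), dimnames = list(NULL, enames))
  r1 <- config$env_ranges[[1]]
  ctr1 <- exp(mean(log(r1)))
  base1 <- pmin(pmax(ctr1 * size^0.2 * exp(stats::rnorm(nu, 0, 0.3)),
                     r1[1]), r1[2] * 0.8)
  g1 <- stats::runif(nu, 1.04, 1.10)
  Z[, 1] <- pmin(rep(base1, each = np) * rep(g1, each = np)^
                   (rep(seq_len(np), nu) - 1), r1[2])
  if (length(enames) >= 2) {
    r2 <- config$env_ranges[[2]]
    ctr2 <- exp(mean(log(r2)))
    base2 <- pmin(pmax(ctr2 * size^0.7 * exp(stats::rnorm(nu, 0, 0.3)),
                       r2[1]), r2[2])
    Z[, 2] <- pmin(pmax(rep(base2, each = np) *
                          (1 + stats::rnorm(nobs, 0, 0.05)), r2[1]), r2[2])
  }
  if (length(enames) >= 3)
    for (j in 3:length(enames)) {
      rj <- config$env_ranges[[j]]
      Z[, j] <- stats::runif(nobs, rj[1], rj[2])
    }
  Zs <- scale(Z)

  mids <- config$output_centers
  truth <- list()
  Xobs <- matrix(NA_real_, nobs, length(inames),
                 dimnames = list(NULL, inames))
  Ueff <- matrix(NA_real_, nobs, length(inames))
  for (n in seq_along(inames)) {
    scl <- config$input_scales[[n]]
    x_eff <- config$frontier_frac * scl *
      apply(sweep(O, 2, mids, "/"), 1,
            function(yr) prod(yr^config$alpha[n, ]))
    zb <- scl * (config$intercept_frac +
                   drop(Zs %*% config$beta_frac[n, ]))
    sig <- config$sigma_frac * scl
    su <- sqrt(config$gamma) * sig
    sv <- sqrt(1 - config$gamma) * sig
    u <- abs(stats::rnorm(nobs)) * su
    v <- stats::rnorm(nobs) * sv
    x <- x_eff + zb + u + v
    thr <- config$floor_frac * scl
    retries <- integer(nobs)
    for (i in which(x < thr)) {
      repeat {
        retries[i] <- retries[i] + 1L
        if (retries[i] > config$retry_cap)
          stop("simulate_panel(): observation ", i, " of input '",
               inames[n], "' cannot be kept positive after ",
               config$retry_cap, " redraws; the configured slack level ",
               "is too negative relative to the frontier", call. = FALSE)
        u[i] <- abs(stats::rnorm(1)) * su
        v[i] <- stats::rnorm(1) * sv
        x[i] <- x_eff[i] + zb[i] + u[i] + v[i]
        if (x[i] >= thr) break
      }
    }
    Xobs[, n] <- x
    Ueff[, n] <- x_eff / (x_eff + u)
    truth[[inames[n]]] <- tibble::tibble(
      unit = unit, period = period, input = inames[n],
      x_eff = x_eff, zb = zb, u = u, v = v, retries = retries)
  }

  if (config$morbidity == "adverse" && "morbidity_rate" %in% onames) {
    b <- O[, "morbidity_rate"]
    O[, "morbidity_rate"] <- (max(b) + min(b)) - b
  }

  d <- tibble::as_tibble(cbind(
    tibble::tibble(unit = unit, period = period),
    tibble::as_tibble(Xobs), tibble::as_tibble(O),
    tibble::as_tibble(Z)))
  panel <- dmu_panel(d, inputs = inames, outputs = onames, env = enames)
  list(panel = panel,
       truth = dplyr::bind_rows(truth),
       true_efficiency = tibble::tibble(unit = unit, period = period,
                                        true_eff = rowMeans(Ueff)),
       config = config)
}
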