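#' JLMS conditional inefficiency
#'
#' The Jondrow-Lovell-Materov-Schmidt conditional mean `E[u | eps]` of a
#' half-normal inefficiency term `u ~ N+(0, sigma_u^2)` given the composed
#' residual `eps = v + u`, `v ~ N(0, sigma_v^2)`:
#'
#' `E[u | eps] = sigma_star * (phi(a) / Phi(a) + a)`
#'
#' with `a = eps * lambda / sigma`, `lambda = sigma_u / sigma_v`,
#' `sigma^2 = sigma_u^2 + sigma_v^2`, and
#' `sigma_star = sigma * lambda / (1 + lambda^2) = sigma_u * sigma_v / sigma`.
#'
#' The Mills ratio is evaluated on the log scale
#' (`exp(dnorm(log) - pnorm(log))`), so the result stays finite and strictly
#' positive for arbitrarily negative residuals.
#'
#' @param epsilon Composed residual(s), vectorised.
#' @param sigma Total standard deviation `sqrt(sigma_u^2 + sigma_v^2)` (> 0).
#' @param lambda Ratio `sigma_u / sigma_v` (> 0).
#' @return `E[u | eps]`, same length as `epsilon`; strictly positive.
#' @examples
#' jlms(0, sigma = sqrt(2), lambda = 1)  # = (1/sqrt(2)) * dnorm(0)/pnorm(0)
#' @export
jlms <- function(epsilon, sigma, lambda) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0)
    stop("jlms(): sigma must be a positive scalar", call. = FALSE)
  if (!is.numeric(lambda) || length(lambda) != 1L || !is.finite(lambda) ||
      lambda <= 0)
    stop("jlms(): lambda must be a positive scalar", call. = FALSE)
  a <- epsilon * lambda / sigma
  sigma_star <- sigma * lambda / (1 + lambda^2)
  mills <- exp(stats::dnorm(a, log = TRUE) - stats::pnorm(a, log.p = TRUE))
  sigma_star * (mills + a)
}

# log-likelihood of the half-normal frontier on *standardised* covariates;
# par = c(beta, log(sigma^2), w) with gamma = plogis(w)
sfa_loglik <- function(par, y, X) {
  k <- ncol(X)
  beta <- par[seq_len(k)]
  ls2 <- par[k + 1L]
  w <- min(max(par[k + 2L], -30), 30)
  gamma <- stats::plogis(w)
  sigma2 <- exp(ls2)
  sigma <- sqrt(sigma2)
  lambda <- sqrt(gamma / (1 - gamma))
  eps <- y - drop(X %*% beta)
  sum(log(2) - 0.5 * log(2 * pi) - 0.5 * ls2 - eps^2 / (2 * sigma2) +
        stats::pnorm(eps * lambda / sigma, log.p = TRUE))
}

#' Fit a half-normal stochastic frontier to input slacks
#'
#' Maximum-likelihood estimation of the slack-response frontier
#' `s_i = z_i' beta + v_i + u_i` with symmetric noise
#' `v ~ N(0, sigma_v^2)` and one-sided inefficiency `u ~ N+(0, sigma_u^2)`,
#' in the Battese-Corra parameterisation `sigma^2 = sigma_u^2 + sigma_v^2`,
#' `gamma = sigma_u^2 / sigma^2`. One such regression is fitted per input;
#' the response is that input's total DEA slack and the covariates are the
#' environmental variables.
#'
#' Covariates are standardised internally for optimiser stability;
#' coefficients (and their covariance) are reported back on the raw scale.
#' Optimisation uses BFGS from several starts — the OLS solution combined
#' with a grid of `gamma` values — and keeps the best likelihood. The
#' one-sided LR statistic `2 * (logL - logL_OLS)` tests `gamma = 0` against
#' the frontier; its null reference is the 50:50 mixed chi-square of Kodde
#' and Palm (5% critical value 2.706 for one restriction).
#'
#' @param formula Model formula, e.g. `slack ~ gdp + ssee + ratio`.
#' @param data Data frame containing the response and covariates.
#' @param gamma_starts Grid of starting values for `gamma`.
#' @param maxit BFGS iteration cap per start.
#' @return An object of class `sfa_fit` with raw-scale `coefficients`,
#'   `vcov`, `sigma_sq`, `gamma`, `sigma_u`, `sigma_v`, `lambda`, `logLik`,
#'   `logLik_ols`, `lr_one_sided`, `converged`, `boundary`, `fitted`
#'   (`z' beta`), `residuals` (composed), and `n`.
#' @export
sfa_fit <- function(formula, data, gamma_starts = c(0.05, 0.3, 0.6, 0.9),
                    maxit = 500) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  Xraw <- stats::model.matrix(attr(mf, "terms"), mf)
  n <- length(y)
  k <- ncol(Xraw)
  if (n < k + 2L)
    stop("sfa_fit(): need at least ", k + 2L, " observations", call. = FALSE)

  has_int <- "(Intercept)" %in% colnames(Xraw)
  ctr <- colMeans(Xraw)
  scl <- apply(Xraw, 2, stats::sd)
  if (has_int) {
    ctr["(Intercept)"] <- 0
    scl["(Intercept)"] <- 1
  }
  if (any(scl == 0))
    stop("sfa_fit(): constant covariate '",
         colnames(Xraw)[scl == 0][1L], "'", call. = FALSE)
  Xs <- sweep(sweep(Xraw, 2, ctr), 2, scl, "/")

  ols <- stats::lm.fit(Xs, y)
  b_ols <- ols$coefficients
  s2_mle <- sum(ols$residuals^2) / n
  if (s2_mle < 1e-12 * max(1, mean(y^2)))
    stop("sfa_fit(): residual variance is (numerically) zero; the ",
         "frontier likelihood is degenerate. The slacks are an exact ",
         "linear function of the covariates.", call. = FALSE)
  ll_ols <- -n / 2 * (log(2 * pi * s2_mle) + 1)

  best <- NULL
  for (g in gamma_starts) {
    sigma2_0 <- s2_mle / (1 - 2 * g / pi)
    b0 <- b_ols
    if (has_int)
      b0["(Intercept)"] <- b0["(Intercept)"] - sqrt(2 * g * sigma2_0 / pi)
    par0 <- c(b0, log(sigma2_0), stats::qlogis(g))
    fit <- tryCatch(
      stats::optim(par0, sfa_loglik, y = y, X = Xs, method = "BFGS",
                   control = list(fnscale = -1, maxit = maxit,
                                  reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value > best$value))
      best <- fit
  }
  if (is.null(best))
    stop("sfa_fit(): no optimiser start converged", call. = FALSE)

  par <- best$par
  ll <- best$value
  beta_s <- par[seq_len(k)]
  sigma_sq <- exp(par[k + 1L])
  gamma <- stats::plogis(min(max(par[k + 2L], -30), 30))
  boundary <- gamma < 1e-4 || gamma > 1 - 1e-4
  converged <- best$convergence == 0L
  if (boundary)
    warning("sfa_fit(): gamma estimate at the boundary (",
            signif(gamma, 3), "); the one-sided error component is ",
            if (gamma < 0.5) "essentially absent" else "dominant",
            call. = FALSE)

  # covariance via the observed information (standardised scale)
  V <- tryCatch({
    H <- stats::optimHess(par, sfa_loglik, y = y, X = Xs)
    solve(-H)
  }, error = function(e) matrix(NA_real_, k + 2L, k + 2L))
  if (!all(is.finite(diag(V))) || any(diag(V) < 0)) converged <- converged && !boundary

  # back-transform beta to the raw scale: beta_raw = Tm %*% beta_std
  Tm <- diag(1 / scl, k)
  if (has_int) {
    i0 <- which(colnames(Xraw) == "(Intercept)")
    Tm[i0, ] <- -ctr / scl
    Tm[i0, i0] <- 1
  }
  beta_raw <- drop(Tm %*% beta_s)
  names(beta_raw) <- colnames(Xraw)
  Vb_raw <- Tm %*% V[seq_len(k), seq_len(k), drop = FALSE] %*% t(Tm)
  dimnames(Vb_raw) <- list(colnames(Xraw), colnames(Xraw))
  sigma_sq_se <- sigma_sq * sqrt(V[k + 1L, k + 1L])
  gamma_se <- gamma * (1 - gamma) * sqrt(V[k + 2L, k + 2L])

  fitted_raw <- unname(drop(Xraw %*% beta_raw))
  structure(list(
    call = match.call(), formula = formula,
    coefficients = beta_raw,
    se = sqrt(pmax(diag(Vb_raw), 0)),
    vcov = Vb_raw,
    sigma_sq = sigma_sq, sigma_sq_se = sigma_sq_se,
    gamma = gamma, gamma_se = gamma_se,
    sigma_u = sqrt(gamma * sigma_sq),
    sigma_v = sqrt((1 - gamma) * sigma_sq),
    lambda = sqrt(gamma / max(1 - gamma, 1e-12)),
    logLik = ll, logLik_ols = ll_ols,
    lr_one_sided = max(0, 2 * (ll - ll_ols)),
    converged = converged, boundary = boundary,
    fitted = fitted_raw, residuals = unname(y - fitted_raw),
    n = n), class = "sfa_fit")
}

#' @export
print.sfa_fit <- function(x, ...) {
  cat("Half-normal stochastic frontier (Battese-Corra)\n")
  cat("  n =", x$n, " logLik =", format(x$logLik, digits = 6),
      " LR(one-sided) =", format(x$lr_one_sided, digits = 4), "\n")
  cat("  sigma^2 =", format(x$sigma_sq, digits = 6),
      " gamma =", format(x$gamma, digits = 4), "\n")
  print(round(rbind(estimate = x$coefficients, std.error = x$se), 4))
  invisible(x)
}

#' Tidy an SFA fit
#'
#' Coefficient-level summary in the broom convention, with the variance
#' parameters appended as terms `sigma_sq` and `gamma`. `statistic` is the
#' asymptotic z ratio and `p.value` its two-sided normal tail (`gamma` has
#' no p-value: its natural test is the one-sided LR, see [glance.sfa_fit()]).
#'
#' @param x An `sfa_fit`.
#' @param ... Unused.
#' @return A tibble `term`, `estimate`, `std.error`, `statistic`, `p.value`.
#' @export
tidy.sfa_fit <- function(x, ...) {
  est <- c(x$coefficients, sigma_sq = x$sigma_sq, gamma = x$gamma)
  se <- c(x$se, x$sigma_sq_se, x$gamma_se)
  z <- est / se
  p <- 2 * stats::pnorm(-abs(z))
  p[length(p)] <- NA_real_
  tibble::tibble(term = names(est), estimate = unname(est),
                 std.error = unname(se), statistic = unname(z),
                 p.value = unname(p))
}

#' Glance at an SFA fit
#'
#' @param x An `sfa_fit`.
#' @param ... Unused.
#' @return A one-row tibble with `logLik`, `logLik_ols`, `lr_one_sided`,
#'   `sigma_sq`, `gamma`, `nobs`, `converged`.
#' @export
glance.sfa_fit <- function(x, ...) {
  tibble::tibble(logLik = x$logLik, logLik_ols = x$logLik_ols,
                 lr_one_sided = x$lr_one_sided, sigma_sq = x$sigma_sq,
                 gamma = x$gamma, nobs = x$n, converged = x$converged)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Decompose composed residuals into inefficiency and noise
#'
#' Applies the JLMS conditional mean to every residual of an [sfa_fit()]:
#' `u = E[u | eps]` and `v = eps - u`, so that
#' `z' beta + u + v` reconstructs the observed slack exactly. In the
#' pure-noise limit `gamma = 0` the inefficiency is defined as 0 and all of
#' the residual is noise (with a warning).
#'
#' @param fit An [sfa_fit()].
#' @return A tibble `.fitted` (`z' beta`), `.resid` (composed residual),
#'   `u` (conditional inefficiency, >= 0), `v` (noise estimate).
#' @export
sfa_decompose <- function(fit) {
  stopifnot(inherits(fit, "sfa_fit"))
  eps <- fit$residuals
  if (fit$gamma < 1e-12) {
    warning("sfa_decompose(): gamma = 0; all residual variation is noise",
            call. = FALSE)
    u <- rep(0, length(eps))
  } else {
    u <- jlms(eps, sigma = sqrt(fit$sigma_sq), lambda = fit$lambda)
  }
  tibble::tibble(.fitted = fit$fitted, .resid = eps, u = u, v = eps - u)
}

#' Adjust inputs to a common environment and common luck
#'
#' The Fried three-stage input correction: every unit's input is raised to
#' the level it would need under the least favourable observed environment
#' and the worst observed noise draw,
#'
#' `x* = x + (max(z' beta) - z' beta) + (max(v) - v)`
#'
#' with the maxima taken over the estimation sample (all rows of `panel`).
#' Both correction terms are non-negative, so `x* >= x` elementwise, and the
#' observation attaining both maxima is left unchanged. Outputs are copied
#' untouched.
#'
#' @param panel A [dmu_panel()] whose rows are, in order, the observations
#'   the fits were estimated on.
#' @param fits A named list of [sfa_fit()] objects, one per input column.
#' @param decomps Optional named list of [sfa_decompose()] results matching
#'   `fits`; computed from `fits` when omitted.
#' @return A new [dmu_panel()] with adjusted inputs.
#' @export
adjust_inputs <- function(panel, fits, decomps = NULL) {
  icols <- input_cols(panel)
  if (!all(icols %in% names(fits)))
    stop("adjust_inputs(): need one fit per input column (",
         paste(setdiff(icols, names(fits)), collapse = ", "), " missing)",
         call. = FALSE)
  if (is.null(decomps))
    decomps <- purrr::map(fits[icols], sfa_decompose)
  out <- tibble::as_tibble(as.data.frame(panel))
  for (v in icols) {
    fit <- fits[[v]]
    dc <- decomps[[v]]
    if (length(fit$fitted) != nrow(panel) || nrow(dc) != nrow(panel))
      stop("adjust_inputs(): observation mismatch between panel and the ",
           "fit for '", v, "'", call. = FALSE)
    zb <- dc$.fitted
    vhat <- dc$v
    out[[v]] <- out[[v]] + (max(zb) - zb) + (max(vhat) - vhat)
  }
  dmu_panel(out, inputs = icols, outputs = output_cols(panel),
            env = env_cols(panel))
}
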