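#' DEA configuration defaults
#'
#' Collects the numerical knobs of the envelopment solver.
#'
#' * `slack_phase` — `"two_phase"` (default) solves the radial program
#'   first, then maximises the slack sum at the fixed optimal score; this is
#'   numerically robust. `"epsilon"` solves the single non-Archimedean
#'   program `min theta - epsilon * (sum of slacks)` with a small finite
#'   `epsilon`, retained for fidelity with classical software.
#' * `epsilon` — the finite non-Archimedean constant, used only in epsilon
#'   mode. Default `1e-6`.
#' * `unity_tolerance` — scores within this distance of 1 (and slacks within
#'   it of 0) count as frontier membership. LP solvers routinely return
#'   0.9999999997 for frontier units. Default `1e-6`.
#'
#' @param slack_phase `"two_phase"` or `"epsilon"`.
#' @param epsilon Positive scalar, epsilon mode only.
#' @param unity_tolerance Positive scalar for frontier membership.
#' @return A list of class `dea_config`.
#' @export
dea_config <- function(slack_phase = c("two_phase", "epsilon"),
                       epsilon = 1e-6, unity_tolerance = 1e-6) {
  slack_phase <- match.arg(slack_phase)
  stopifnot(epsilon > 0, unity_tolerance > 0)
  structure(list(slack_phase = slack_phase, epsilon = epsilon,
                 unity_tolerance = unity_tolerance), class = "dea_config")
}

# Solve the input-oriented envelopment program for one DMU.
# X: m x n inputs (columns = DMUs), Y: s x n outputs, j0: target column.
dea_solve_one <- function(X, Y, j0, rts = c("crs", "vrs"),
                          config = dea_config()) {
  rts <- match.arg(rts)
  n <- ncol(X)
  m <- nrow(X)
  s <- nrow(Y)
  # units invariance: normalise each dimension by its slice mean so the
  # simplex works on O(1) numbers regardless of the variables' raw scales
  sx <- rowMeans(X)
  sy <- rowMeans(Y)
  X <- X / sx
  Y <- Y / sy
  x0 <- X[, j0]
  y0 <- Y[, j0]
  vrs_row <- if (rts == "vrs") 1L else 0L

  if (config$slack_phase == "epsilon") {
    # vars: theta, lambda (n), s_in (m), s_out (s)
    nv <- 1L + n + m + s
    obj <- c(1, rep(0, n), rep(-config$epsilon, m + s))
    A <- matrix(0, m + s + vrs_row, nv)
    A[seq_len(m), 1L] <- -x0
    A[seq_len(m), 1L + seq_len(n)] <- X
    A[seq_len(m), 1L + n + seq_len(m)] <- diag(m)
    A[m + seq_len(s), 1L + seq_len(n)] <- Y
    A[m + seq_len(s), 1L + n + m + seq_len(s)] <- -diag(s)
    dir <- rep("==", m + s)
    rhs <- c(rep(0, m), y0)
    if (vrs_row) {
      A[m + s + 1L, 1L + seq_len(n)] <- 1
      dir <- c(dir, "==")
      rhs <- c(rhs, 1)
    }
    sol <- lp_solve(obj, A, dir, rhs)
    if (sol$status != "optimal")
      stop("DEA solver failure (", sol$status, ") for DMU ", j0, call. = FALSE)
    theta <- sol$x[1L]
    lambda <- sol$x[1L + seq_len(n)]
    s_in <- sol$x[1L + n + seq_len(m)]
    s_out <- sol$x[1L + n + m + seq_len(s)]
  } else {
    # phase 1: radial score
    obj <- c(1, rep(0, n))
    A <- rbind(cbind(-x0, X), cbind(matrix(0, s, 1L), Y))
    dir <- c(rep("<=", m), rep(">=", s))
    rhs <- c(rep(0, m), y0)
    if (vrs_row) {
      A <- rbind(A, c(0, rep(1, n)))
      dir <- c(dir, "==")
      rhs <- c(rhs, 1)
    }
    sol1 <- lp_solve(obj, A, dir, rhs)
    if (sol1$status != "optimal")
      stop("DEA solver failure (", sol1$status, ") for DMU ", j0,
           call. = FALSE)
    theta <- sol1$value
    # phase 2: maximise slack sum at fixed theta
    nv <- n + m + s
    obj2 <- c(rep(0, n), rep(1, m + s))
    A2 <- matrix(0, m + s + vrs_row, nv)
    A2[seq_len(m), seq_len(n)] <- X
    A2[seq_len(m), n + seq_len(m)] <- diag(m)
    A2[m + seq_len(s), seq_len(n)] <- Y
    A2[m + seq_len(s), n + m + seq_len(s)] <- -diag(s)
    dir2 <- rep("==", m + s)
    rhs2 <- c(theta * x0, y0)
    if (vrs_row) {
      A2[m + s + 1L, seq_len(n)] <- 1
      dir2 <- c(dir2, "==")
      rhs2 <- c(rhs2, 1)
    }
    sol2 <- lp_solve(obj2, A2, dir2, rhs2, maximize = TRUE)
    if (sol2$status != "optimal")
      stop("DEA slack-phase failure (", sol2$status, ") for DMU ", j0,
           call. = FALSE)
    lambda <- sol2$x[seq_len(n)]
    s_in <- sol2$x[n + seq_len(m)]
    s_out <- sol2$x[n + m + seq_len(s)]
  }

  theta <- min(max(theta, 0), 1 + config$unity_tolerance)
  if (theta > 1) theta <- 1
  s_in[s_in < 0 & s_in > -1e-9] <- 0
  s_out[s_out < 0 & s_out > -1e-9] <- 0
  total <- x0 - as.vector(X %*% lambda)
  ident <- (1 - theta) * x0 + s_in
  if (any(abs(total - ident) > 1e-6 * pmax(1, abs(x0))))
    stop("internal DEA inconsistency: (1 - theta) x + s_in != x - X lambda",
         call. = FALSE)
  total[total < 0 & total > -1e-7] <- 0
  if (any(total < 0))
    stop("internal DEA inconsistency: negative total input slack",
         call. = FALSE)
  list(theta = theta, lambda = lambda, s_in = s_in * sx, s_out = s_out * sy,
       total_slack = total * sx,
       validity = classify_validity(theta, s_in, s_out,
                                    config$unity_tolerance))
}

#' Classify a DMU's DEA validity
#'
#' A DMU is `valid` (fully efficient) when its radial score is 1 and every
#' slack is 0, `weakly_valid` when the score is 1 but some slack is nonzero,
#' and `invalid` when the score is below 1 — all judged within
#' `unity_tolerance`.
#'
#' @param theta Radial efficiency score.
#' @param s_in,s_out Input and output slack vectors.
#' @param unity_tolerance Frontier tolerance (see [dea_config()]).
#' @return One of `"valid"`, `"weakly_valid"`, `"invalid"`.
#' @export
classify_validity <- function(theta, s_in, s_out, unity_tolerance = 1e-6) {
  if (theta < 1 - unity_tolerance) return("invalid")
  if (all(abs(c(s_in, s_out)) <= unity_tolerance)) "valid" else "weakly_valid"
}

# split a panel into per-period matrices
panel_slices <- function(panel) {
  icols <- input_cols(panel)
  ocols <- output_cols(panel)
  split(seq_len(nrow(panel)), panel$period) |>
    purrr::map(function(idx) {
      list(idx = idx,
           units = panel$unit[idx],
           X = t(as.matrix(as.data.frame(panel)[idx, icols, drop = FALSE])),
           Y = t(as.matrix(as.data.frame(panel)[idx, ocols, drop = FALSE])))
    })
}

#' Input-oriented DEA efficiency for every unit-period
#'
#' Solves the input-oriented envelopment program for each DMU, period by
#' period (each period is its own cross-section; periods are never pooled
#' into one frontier). Under `rts = "vrs"` the convexity constraint
#' `sum(lambda) = 1` is imposed (the BCC model); under `"crs"` it is dropped
#' (the CCR model).
#'
#' Besides the radial score, the result carries the residual input slacks
#' `slack_<input>`, output slacks `oslack_<output>`, and the *total* input
#' slacks `total_slack_<input>` = `x - X lambda` = `(1 - theta) x + s_in`
#' (radial shortfall plus residual slack) — the quantity the stage-2
#' frontier regressions explain.
#'
#' @param panel A [dmu_panel()].
#' @param rts `"vrs"` (BCC) or `"crs"` (CCR).
#' @param config A [dea_config()].
#' @return A tibble with one row per unit-period: `unit`, `period`,
#'   `theta`, `validity`, slack columns, and a list-column `lambda` of named
#'   intensity-weight vectors.
#' @examples
#' p <- dmu_panel(data.frame(unit = c("A", "B"), period = 1,
#'                           x = c(2, 4), y = c(2, 2)),
#'                inputs = "x", outputs = "y")
#' dea_efficiency(p, rts = "crs")
#' @export
dea_efficiency <- function(panel, rts = c("vrs", "crs"),
                           config = dea_config()) {
  rts <- match.arg(rts)
  icols <- input_cols(panel)
  ocols <- output_cols(panel)
  res <- purrr::map_dfr(panel_slices(panel), function(sl) {
    n <- length(sl$idx)
    purrr::map_dfr(seq_len(n), function(j) {
      r <- tryCatch(dea_solve_one(sl$X, sl$Y, j, rts = rts, config = config),
                    error = function(e)
                      stop("DEA failure for unit '", sl$units[j], "': ",
                           conditionMessage(e), call. = FALSE))
      row <- tibble::tibble(unit = sl$units[j],
                            period = panel$period[sl$idx[j]],
                            theta = r$theta, validity = r$validity)
      row[paste0("slack_", icols)] <- as.list(r$s_in)
      row[paste0("oslack_", ocols)] <- as.list(r$s_out)
      row[paste0("total_slack_", icols)] <- as.list(r$total_slack)
      row$lambda <- list(stats::setNames(r$lambda, sl$units))
      row
    })
  })
  # restore panel row order
  key <- paste(panel$unit, panel$period, sep = "\r")
  res[match(key, paste(res$unit, res$period, sep = "\r")), ]
}

#' TE / PTE / SE decomposition
#'
#' Runs both the CRS (CCR) and VRS (BCC) envelopment programs per period and
#' reports technical efficiency `TE` (CRS score), pure technical efficiency
#' `PTE` (VRS score) and scale efficiency `SE = TE / PTE`, with the validity
#' class of the VRS solve. `PTE >= TE` always (the VRS frontier envelops no
#' tighter than CRS), so `SE <= 1`.
#'
#' @param panel A [dmu_panel()].
#' @param config A [dea_config()].
#' @return A tibble `unit`, `period`, `TE`, `PTE`, `SE`, `validity`.
#' @export
dea_decompose <- function(panel, config = dea_config()) {
  vrs <- dea_efficiency(panel, rts = "vrs", config = config)
  crs <- dea_efficiency(panel, rts = "crs", config = config)
  tibble::tibble(unit = vrs$unit, period = vrs$period,
                 TE = crs$theta, PTE = vrs$theta,
                 SE = crs$theta / vrs$theta,
                 validity = vrs$validity)
}

#' Total input slack from a radial solution
#'
#' The total (radial plus residual) input slack
#' `(1 - theta) * x + s_in`, i.e. the full distance between an observed
#' input bundle and its frontier reference point `X lambda`.
#'
#' @param theta Radial score.
#' @param x Observed input vector of the target DMU.
#' @param s_in Residual input slack vector.
#' @return Per-input total slack (non-negative).
#' @export
total_slack <- function(theta, x, s_in) {
  out <- (1 - theta) * x + s_in
  out[out < 0 & out > -1e-9] <- 0
  if (any(out < 0))
    stop("total_slack(): negative total slack", call. = FALSE)
  out
}
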