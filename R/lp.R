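# Dense two-phase primal simplex for the envelopment programs.
#
# The problems solved here are small (a few dozen variables, under ten
# constraints), dense, and frequently degenerate: frontier DMUs sit on the
# boundary of several constraints at once, which is exactly where generic
# tableau implementations mis-pivot. This solver therefore switches to
# Bland's rule after an initial Dantzig phase, recomputes reduced costs from
# the basis every iteration (no cost-row drift), and treats |x| < tol as
# zero throughout.

#' @keywords internal
#' @noRd
lp_solve <- function(obj, A, dir, rhs, maximize = FALSE, tol = 1e-9) {
  stopifnot(is.matrix(A), length(obj) == ncol(A),
            length(dir) == nrow(A), length(rhs) == nrow(A))
  if (maximize) obj <- -obj
  m <- nrow(A)
  n <- ncol(A)

  # normalise to rhs >= 0
  flip <- rhs < 0
  if (any(flip)) {
    A[flip, ] <- -A[flip, , drop = FALSE]
    rhs[flip] <- -rhs[flip]
    dir[flip] <- chartr("<>", "><", dir[flip])
  }

  n_le <- sum(dir == "<=")
  n_ge <- sum(dir == ">=")
  # columns: original | slacks (<=) | surplus (>=) | artificials (>= and =)
  n_art <- n_ge + sum(dir == "==" | dir == "=")
  Nfull <- n + n_le + n_ge + n_art
  Tm <- matrix(0, m, Nfull + 1L)
  Tm[, seq_len(n)] <- A
  Tm[, Nfull + 1L] <- rhs

  basis <- integer(m)
  sl <- n
  su <- n + n_le
  ar <- n + n_le + n_ge
  for (i in seq_len(m)) {
    if (dir[i] == "<=") {
      sl <- sl + 1L
      Tm[i, sl] <- 1
      basis[i] <- sl
    } else if (dir[i] == ">=") {
      su <- su + 1L
      ar <- ar + 1L
      Tm[i, su] <- -1
      Tm[i, ar] <- 1
      basis[i] <- ar
    } else {
      ar <- ar + 1L
      Tm[i, ar] <- 1
      basis[i] <- ar
    }
  }
  art_cols <- seq.int(n + n_le + n_ge + 1L, length.out = n_art)

  run <- function(Tm, basis, cost, active) {
    N1 <- ncol(Tm) - 1L
    max_iter <- 100L * (m + N1)
    iter <- 0L
    repeat {
      iter <- iter + 1L
      if (iter > max_iter) return(list(status = "maxiter", Tm = Tm, basis = basis))
      red <- drop(cost[basis] %*% Tm[, active, drop = FALSE]) - cost[active]
      cand <- which(red > tol)
      if (!length(cand)) return(list(status = "optimal", Tm = Tm, basis = basis))
      jj <- if (iter > 3L * (m + N1)) cand[1L] else cand[which.max(red[cand])]
      j <- active[jj]
      col <- Tm[, j]
      pos <- which(col > tol)
      if (!length(pos)) return(list(status = "unbounded", Tm = Tm, basis = basis))
      ratio <- Tm[pos, N1 + 1L] / col[pos]
      sel <- pos[ratio <= min(ratio) + tol]
      i <- sel[which.min(basis[sel])]   # Bland tie-break
      piv <- Tm[i, j]
      Tm[i, ] <- Tm[i, ] / piv
      upd <- which(abs(Tm[, j]) > 0 & seq_len(m) != i)
      if (length(upd))
        Tm[upd, ] <- Tm[upd, , drop = FALSE] - outer(Tm[upd, j], Tm[i, ])
      Tm[, j] <- 0
      Tm[i, j] <- 1
      basis[i] <- j
      next
    }
  }

  # phase 1
  if (n_art > 0L) {
    cost1 <- numeric(Nfull)
    cost1[art_cols] <- 1       # minimise the artificial total
    r1 <- run(Tm, basis, cost1, seq_len(Nfull))
    Tm <- r1$Tm
    basis <- r1$basis
    if (r1$status != "optimal" ||
        sum(Tm[basis %in% art_cols, Nfull + 1L]) > 1e-7)
      return(list(status = "infeasible", x = NULL, value = NA_real_))
    # drive lingering artificials out of the basis (degenerate rows)
    for (i in which(basis %in% art_cols)) {
      piv_cols <- setdiff(which(abs(Tm[i, seq_len(Nfull)]) > tol), art_cols)
      if (length(piv_cols)) {
        j <- piv_cols[1L]
        Tm[i, ] <- Tm[i, ] / Tm[i, j]
        upd <- which(abs(Tm[, j]) > 0 & seq_len(m) != i)
        if (length(upd))
          Tm[upd, ] <- Tm[upd, , drop = FALSE] - outer(Tm[upd, j], Tm[i, ])
        Tm[, j] <- 0
        Tm[i, j] <- 1
        basis[i] <- j
      } # else: redundant row; leave the zero artificial basic
    }
  }

  # phase 2 over non-artificial columns (keep zero-level artificials frozen)
  active <- setdiff(seq_len(Nfull), art_cols)
  cost2 <- numeric(Nfull)
  cost2[seq_len(n)] <- obj     # run() minimises
  r2 <- run(Tm, basis, cost2, active)
  if (r2$status == "unbounded")
    return(list(status = "unbounded", x = NULL, value = NA_real_))
  if (r2$status != "optimal")
    return(list(status = r2$status, x = NULL, value = NA_real_))
  Tm <- r2$Tm
  basis <- r2$basis
  x <- numeric(Nfull)
  x[basis] <- Tm[, Nfull + 1L]
  sol <- x[seq_len(n)]
  val <- sum(obj * sol)
  list(status = "optimal", x = sol, value = if (maximize) -val else val)
}
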