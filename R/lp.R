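# Dense linear programming used by FBA, FVA, the parsimonious optimizer
# and the sparse-basis extraction. A self-contained two-phase tableau
# simplex with Bland's anti-cycling rule: guaranteed finite termination
# and no reliance on fragile pivot heuristics. All flux variables carry
# finite bounds (the package's +/-1000 default), so every problem is a
# bounded polytope and phase 2 can never meet an unbounded ray.

# Solve max/min obj'v subject to
#   A_eq v = b_eq,  A_ge v >= b_ge,  lb <= v <= ub.
# Returns list(status, objective, solution); status in
# {"optimal", "infeasible", "failed"}.
solve_lp <- function(obj, A_eq, b_eq, lb, ub, A_ge = NULL, b_ge = NULL,
                     maximize = TRUE, tol = 1e-9) {
  n <- length(obj)
  stopifnot(length(lb) == n, length(ub) == n)
  big <- 1e6
  lb <- pmax(lb, -big)
  ub <- pmin(ub, big)
  if (any(lb > ub)) {
    return(list(status = "infeasible", objective = NA_real_,
                solution = rep(NA_real_, n)))
  }
  A_eq <- as.matrix(A_eq)
  # drop linearly dependent equality rows (closed cycles make S rank
  # deficient); consistency of dropped rows is verified on the solution
  A_eq_full <- A_eq
  b_eq_full <- b_eq
  if (nrow(A_eq) > 1) {
    qrA <- qr(t(A_eq))
    keep <- sort(qrA$pivot[seq_len(qrA$rank)])
    A_eq <- A_eq[keep, , drop = FALSE]
    b_eq <- b_eq[keep]
  }
  # shift x = v - lb >= 0; upper bounds become <= rows
  A <- rbind(diag(n), A_eq,
             if (!is.null(A_ge) && nrow(as.matrix(A_ge))) as.matrix(A_ge))
  b <- c(ub - lb, as.numeric(b_eq - A_eq %*% lb),
         if (!is.null(A_ge) && nrow(as.matrix(A_ge)))
           as.numeric(b_ge - as.matrix(A_ge) %*% lb))
  sense <- c(rep("<=", n), rep("=", nrow(A_eq)),
             rep(">=", length(b) - n - nrow(A_eq)))
  cost <- if (maximize) -obj else obj
  res <- simplex_two_phase(cost, A, b, sense, tol = tol)
  if (res$status != "optimal") {
    return(list(status = res$status, objective = NA_real_,
                solution = rep(NA_real_, n)))
  }
  v <- res$x[seq_len(n)] + lb
  resid <- max(abs(A_eq_full %*% v - b_eq_full))
  if (resid > 1e-6 * max(1, max(abs(b_eq_full)))) {
    return(list(status = "infeasible", objective = NA_real_,
                solution = rep(NA_real_, n)))
  }
  list(status = "optimal", objective = sum(obj * v), solution = v)
}

# min cost'x s.t. A x (sense) b, x >= 0, via two-phase tableau simplex.
simplex_two_phase <- function(cost, A, b, sense, tol = 1e-9,
                              max_iter = 50000L) {
  m <- nrow(A)
  n <- ncol(A)
  # normalize rows to b >= 0
  flip <- b < 0
  A[flip, ] <- -A[flip, , drop = FALSE]
  b[flip] <- -b[flip]
  sense[flip] <- c("<=" = ">=", ">=" = "<=", "=" = "=")[sense[flip]]
  # slack / surplus columns
  n_slack <- sum(sense != "=")
  T_slack <- matrix(0, m, n_slack)
  slack_rows <- which(sense != "=")
  for (i in seq_along(slack_rows)) {
    T_slack[slack_rows[i], i] <- if (sense[slack_rows[i]] == "<=") 1 else -1
  }
  # artificial columns for rows without a unit starting column
  art_rows <- which(sense != "<=")
  n_art <- length(art_rows)
  T_art <- matrix(0, m, n_art)
  if (n_art) T_art[cbind(art_rows, seq_len(n_art))] <- 1
  Tab <- cbind(A, T_slack, T_art, b)
  n_tot <- n + n_slack + n_art
  basis <- integer(m)
  basis[slack_rows[sense[slack_rows] == "<="]] <-
    n + which(sense[slack_rows] == "<=")
  basis[art_rows] <- n + n_slack + seq_len(n_art)

  pivot <- function(Tab, basis, allowed, costvec) {
    # returns list(Tab, basis, status); Bland's rule throughout
    cB <- costvec[basis]
    for (it in seq_len(max_iter)) {
      red <- costvec[allowed] - as.numeric(cB %*% Tab[, allowed, drop = FALSE])
      ent_rel <- which(red < -tol)
      if (!length(ent_rel)) return(list(Tab = Tab, basis = basis,
                                        status = "optimal"))
      j <- allowed[min(ent_rel)]
      col <- Tab[, j]
      pos <- which(col > tol)
      if (!length(pos)) return(list(Tab = Tab, basis = basis,
                                    status = "unbounded"))
      ratios <- Tab[pos, n_tot + 1] / col[pos]
      rmin <- min(ratios)
      cand <- pos[ratios <= rmin + tol]
      i <- cand[which.min(basis[cand])]
      Tab[i, ] <- Tab[i, ] / Tab[i, j]
      upd <- setdiff(seq_len(nrow(Tab)), i)
      Tab[upd, ] <- Tab[upd, ] - outer(Tab[upd, j], Tab[i, ])
      basis[i] <- j
      cB <- costvec[basis]
    }
    list(Tab = Tab, basis = basis, status = "failed")
  }

  if (n_art) {
    cost1 <- c(rep(0, n + n_slack), rep(1, n_art))
    ph1 <- pivot(Tab, basis, seq_len(n_tot), cost1)
    if (ph1$status != "optimal") return(list(status = "failed"))
    Tab <- ph1$Tab
    basis <- ph1$basis
    if (sum(cost1[basis] * Tab[, n_tot + 1]) > 1e-7) {
      return(list(status = "infeasible"))
    }
    # drive residual zero-level artificials out of the basis
    art_cols <- n + n_slack + seq_len(n_art)
    for (i in which(basis %in% art_cols)) {
      row <- Tab[i, seq_len(n + n_slack)]
      j <- which(abs(row) > tol)
      if (length(j)) {
        j <- j[1]
        Tab[i, ] <- Tab[i, ] / Tab[i, j]
        upd <- setdiff(seq_len(m), i)
        Tab[upd, ] <- Tab[upd, ] - outer(Tab[upd, j], Tab[i, ])
        basis[i] <- j
      }
      # an all-zero row is redundant; its artificial stays basic at zero
    }
  }
  cost2 <- c(cost, rep(0, n_slack + n_art))
  allowed <- seq_len(n + n_slack)
  ph2 <- pivot(Tab, basis, allowed, cost2)
  if (ph2$status == "unbounded") return(list(status = "failed"))
  if (ph2$status != "optimal") return(list(status = ph2$status))
  Tab <- ph2$Tab
  basis <- ph2$basis
  x_full <- rep(0, n_tot)
  x_full[basis] <- Tab[, n_tot + 1]
  list(status = "optimal", x = x_full[seq_len(n)],
       objective = sum(cost * x_full[seq_len(n)]))
}
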