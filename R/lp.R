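# Dense two-phase primal simplex for the small steady-state flux programs
# used by the producibility screen. Bland's rule prevents cycling; problems
# here have a few dozen variables at most.

# Core: min c'x s.t. Ax = b, x >= 0, given a starting feasible basis.
# Returns list(status, x, basis). Basis columns must be linearly independent.
simplex_core <- function(A, b, cost, basis, tol = 1e-9, max_iter = 10000L) {
  m <- nrow(A)
  for (it in seq_len(max_iter)) {
    B <- A[, basis, drop = FALSE]
    xb <- solve(B, b)
    y <- solve(t(B), cost[basis])
    reduced <- cost - as.numeric(crossprod(A, y))
    reduced[basis] <- 0
    enter <- which(reduced < -tol)
    if (length(enter) == 0) {
      x <- numeric(ncol(A))
      x[basis] <- xb
      return(list(status = "optimal", x = x, basis = basis))
    }
    j <- min(enter)                       # Bland's rule
    d <- solve(B, A[, j])
    pos <- which(d > tol)
    if (length(pos) == 0) return(list(status = "unbounded"))
    ratio <- xb[pos] / d[pos]
    cand <- pos[ratio <= min(ratio) + tol]
    leave <- cand[which.min(basis[cand])]  # Bland's rule on leaving index
    basis[leave] <- j
  }
  list(status = "unsolved")
}

# Two-phase driver: min c'x s.t. Ax = b (b >= 0 after sign-fix), x >= 0.
solve_lp_standard <- function(A, b, cost, tol = 1e-9) {
  m <- nrow(A); n <- ncol(A)
  flip <- b < 0
  A[flip, ] <- -A[flip, , drop = FALSE]
  b[flip] <- -b[flip]
  # phase 1: artificials
  A1 <- cbind(A, diag(m))
  c1 <- c(numeric(n), rep(1, m))
  res1 <- simplex_core(A1, b, c1, basis = n + seq_len(m), tol = tol)
  if (res1$status != "optimal") return(list(status = res1$status))
  if (sum(res1$x[n + seq_len(m)]) > 1e-7) return(list(status = "infeasible"))
  basis <- res1$basis
  # drive remaining zero-valued artificials out of the basis
  keep_rows <- rep(TRUE, m)
  art <- which(basis > n)
  for (k in art) {
    # pivot in any non-basic structural column with a nonzero entry in row k
    Binv_row <- solve(t(A1[, basis, drop = FALSE]),
                      as.numeric(seq_len(m) == k))
    entries <- as.numeric(crossprod(A1[, seq_len(n), drop = FALSE], Binv_row))
    j <- which(abs(entries) > 1e-7 & !(seq_len(n) %in% basis))
    if (length(j)) basis[k] <- min(j) else keep_rows[k] <- FALSE  # redundant row
  }
  if (!all(keep_rows)) {
    A <- A[keep_rows, , drop = FALSE]
    b <- b[keep_rows]
    basis <- basis[keep_rows]
    A1 <- cbind(A, diag(nrow(A)))
  }
  res2 <- simplex_core(cbind(A, matrix(0, nrow(A), 0)), b, cost, basis, tol = tol)
  if (res2$status != "optimal") return(list(status = res2$status))
  list(status = "optimal", x = res2$x[seq_len(n)])
}

# Bounded-variable LP: optimize obj'v s.t. S v = 0 style equalities
# (Aeq v = beq), lb <= v <= ub, plus optional >= rows (Age v >= bge).
# Shifts to the nonnegative orthant and adds slack/surplus columns.
solve_lp_bounded <- function(obj, Aeq, beq, lb, ub, Age = NULL, bge = NULL,
                             maximize = TRUE) {
  n <- length(obj)
  rng <- ub - lb
  # x = v - lb;  rows: Aeq x = beq - Aeq lb;  x + s = rng;  Age x - t = bge - Age lb
  nge <- if (is.null(Age)) 0L else nrow(Age)
  A <- rbind(cbind(Aeq, matrix(0, nrow(Aeq), n + nge)),
             cbind(diag(n), diag(n), matrix(0, n, nge)),
             if (nge) cbind(Age, matrix(0, nge, n), -diag(nge)))
  b <- c(beq - as.numeric(Aeq %*% lb), rng,
         if (nge) bge - as.numeric(Age %*% lb))
  cost <- c(if (maximize) -obj else obj, numeric(n + nge))
  res <- solve_lp_standard(A, b, cost)
  if (res$status != "optimal") return(res)
  v <- res$x[seq_len(n)] + lb
  list(status = "optimal", v = v, objective = sum(obj * v))
}
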