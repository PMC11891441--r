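# Dense two-phase primal simplex with Bland's anti-cycling rule.
#
# Written in-package because no LP interface is available in the offline
# environment and boot::simplex (the only base-adjacent candidate) fails with
# division-by-zero on the degenerate, rank-deficient equality systems FBA
# produces (e.g. all-zero right-hand sides). Dense O(m^3) per iteration:
# entirely adequate for the toy-scale models this package targets, and
# documented as unsuitable for genome-scale networks.

# minimize cost' x  subject to  A x = b, x >= 0, with rank(A) == nrow(A).
# Returns list(status = "optimal"|"infeasible"|"unbounded", x, value).
lp_standard_form <- function(A, b, cost, tol = 1e-9) {
  m <- nrow(A); n <- ncol(A)
  if (m == 0L) {
    # no constraints: minimum is 0 at x = 0 unless some cost is negative
    if (any(cost < -tol)) return(list(status = "unbounded"))
    return(list(status = "optimal", x = numeric(n), value = 0))
  }
  neg <- b < 0
  A[neg, ] <- -A[neg, , drop = FALSE]
  b[neg] <- -b[neg]

  iterate <- function(Afull, bvec, cvec, basis) {
    repeat {
      B <- Afull[, basis, drop = FALSE]
      xB <- solve(B, bvec)
      y <- solve(t(B), cvec[basis])
      red <- cvec - as.numeric(crossprod(Afull, y))
      red[basis] <- 0
      entering <- which(red < -tol)
      if (!length(entering)) {
        x <- numeric(ncol(Afull)); x[basis] <- pmax(xB, 0)
        return(list(status = "optimal", basis = basis, x = x,
                    value = sum(cvec[basis] * xB)))
      }
      j <- min(entering)                           # Bland: smallest index enters
      d <- solve(B, Afull[, j])
      pos <- which(d > tol)
      if (!length(pos)) return(list(status = "unbounded"))
      ratios <- pmax(xB[pos], 0) / d[pos]
      tmin <- min(ratios)
      cand <- pos[ratios <= tmin + tol]
      leave <- cand[which.min(basis[cand])]        # Bland: smallest index leaves
      basis[leave] <- j
    }
  }

  # phase 1: artificial basis
  Aa <- cbind(A, diag(m))
  c1 <- c(rep(0, n), rep(1, m))
  p1 <- iterate(Aa, b, c1, basis = n + seq_len(m))
  if (p1$status != "optimal" || p1$value > 1e-7) return(list(status = "infeasible"))
  basis <- p1$basis
  # pivot lingering zero-level artificials out (rank(A) = m guarantees a pivot)
  for (k in seq_along(basis)) {
    if (basis[k] > n) {
      B <- Aa[, basis, drop = FALSE]
      for (j in seq_len(n)) {
        if (j %in% basis) next
        d <- solve(B, Aa[, j])
        if (abs(d[k]) > tol) { basis[k] <- j; break }
      }
    }
  }
  if (any(basis > n)) return(list(status = "infeasible"))  # defensive; full rank forbids this

  p2 <- iterate(A, b, cost, basis)
  if (p2$status != "optimal") return(p2)
  list(status = "optimal", x = p2$x[seq_len(n)], value = p2$value)
}

# maximize obj' v  subject to  S v = 0 (rows may carry nonzero rhs after the
# lb shift), lb <= v <= ub. Used by fba().
lp_box_constrained <- function(S, obj, lb, ub) {
  n <- length(obj)
  free <- (ub - lb) > 1e-12
  rhs <- as.numeric(-S %*% lb)
  if (!any(free)) {
    feasible <- all(abs(rhs) <= 1e-9)
    return(list(status = if (feasible) "optimal" else "infeasible",
                value = if (feasible) sum(obj * lb) else 0))
  }
  A <- S[, free, drop = FALSE]
  zero_row <- apply(A == 0, 1, all)
  if (any(zero_row & abs(rhs) > 1e-9)) return(list(status = "infeasible", value = 0))
  A <- A[!zero_row, , drop = FALSE]
  rhs <- rhs[!zero_row]
  if (nrow(A) > 0L) {                  # keep an independent row subset
    qa <- qr(t(A))
    keep <- sort(qa$pivot[seq_len(qa$rank)])
    if (qr(t(cbind(A, rhs)))$rank > qa$rank) {
      return(list(status = "infeasible", value = 0))
    }
    A <- A[keep, , drop = FALSE]
    rhs <- rhs[keep]
  }
  nf <- sum(free)
  width <- (ub - lb)[free]
  # standard form: variables x (shifted fluxes) and slacks s, x + s = width
  Astd <- rbind(cbind(A, matrix(0, nrow(A), nf)),
                cbind(diag(nf), diag(nf)))
  bstd <- c(rhs, width)
  cost <- c(-obj[free], rep(0, nf))    # minimize -objective
  res <- lp_standard_form(Astd, bstd, cost)
  if (res$status != "optimal") return(list(status = res$status, value = 0))
  v <- lb
  v[free] <- res$x[seq_len(nf)] + lb[free]
  list(status = "optimal", value = sum(obj * v), fluxes = v)
}
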