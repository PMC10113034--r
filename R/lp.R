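# Compact two-phase dense simplex (Bland's rule, so no cycling) for the
# small linear programs arising from collision graphs. Standard form:
# minimise c'x subject to A x = b, x >= 0. Row signs are normalised so
# b >= 0; phase 1 drives artificial variables out of the basis.

lp_solve_min <- function(cvec, A, b, tol = 1e-9) {
  m <- nrow(A); n <- ncol(A)
  if (m == 0) return(list(status = "optimal", x = numeric(n), value = 0))
  flip <- b < 0
  A[flip, ] <- -A[flip, , drop = FALSE]
  b[flip] <- -b[flip]

  # tableau: columns = n structural + m artificial + rhs
  Tb <- cbind(A, diag(m), b)
  basis <- n + seq_len(m)
  pivot <- function(Tb, r, c) {
    Tb[r, ] <- Tb[r, ] / Tb[r, c]
    for (i in seq_len(nrow(Tb))) {
      if (i != r && abs(Tb[i, c]) > tol) Tb[i, ] <- Tb[i, ] - Tb[i, c] * Tb[r, ]
    }
    Tb
  }
  run_simplex <- function(Tb, basis, obj) {
    # obj: objective row over all columns (reduced costs maintained manually)
    repeat {
      red <- obj[seq_len(length(obj) - 1)]
      red[basis] <- 0
      enter <- which(red < -tol)
      if (!length(enter)) return(list(Tb = Tb, basis = basis, obj = obj))
      e <- enter[1]                        # Bland: smallest index
      ratios <- ifelse(Tb[, e] > tol, Tb[, ncol(Tb)] / Tb[, e], Inf)
      if (all(!is.finite(ratios))) return(list(unbounded = TRUE))
      r <- which(ratios == min(ratios))
      r <- r[which.min(basis[r])]          # Bland on leaving variable
      Tb <- pivot(Tb, r, e)
      obj <- obj - obj[e] * c(Tb[r, ])
      basis[r] <- e
    }
  }
  # phase 1: minimise sum of artificials
  obj1 <- c(rep(0, n), rep(1, m), 0)
  for (i in seq_len(m)) obj1 <- obj1 - c(Tb[i, ])   # reduce over basis
  res <- run_simplex(Tb, basis, obj1)
  if (isTRUE(res$unbounded)) return(list(status = "infeasible"))
  phase1_val <- -res$obj[length(res$obj)]
  if (phase1_val > 1e-7) return(list(status = "infeasible"))
  Tb <- res$Tb; basis <- res$basis
  # drive any lingering artificial basics out where possible
  for (i in seq_len(m)) {
    if (basis[i] > n) {
      cand <- which(abs(Tb[i, seq_len(n)]) > tol)
      if (length(cand)) {
        Tb <- pivot(Tb, i, cand[1])
        basis[i] <- cand[1]
      }
    }
  }
  # phase 2 on structural columns only
  Tb2 <- Tb[, c(seq_len(n), n + m + 1), drop = FALSE]
  drop_rows <- which(basis > n)
  if (length(drop_rows)) {   # redundant rows (zero over structurals)
    Tb2 <- Tb2[-drop_rows, , drop = FALSE]
    basis <- basis[-drop_rows]
  }
  obj2 <- c(cvec, 0)
  for (i in seq_along(basis)) obj2 <- obj2 - cvec[basis[i]] * c(Tb2[i, ])
  res2 <- run_simplex(Tb2, basis, obj2)
  if (isTRUE(res2$unbounded)) return(list(status = "unbounded"))
  x <- numeric(n)
  x[res2$basis] <- res2$Tb[, ncol(res2$Tb)]
  list(status = "optimal", x = x, value = sum(cvec * x))
}
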