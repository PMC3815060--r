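# Dense two-phase primal simplex for the desk-scale flux LPs.
# Solves: min obj'y  s.t.  D y = d (d >= 0), y >= 0, using an explicit
# tableau with Bland's anti-cycling rule. Problem sizes here are tens of
# variables, where the dense tableau is both fast and easy to audit.

# One simplex phase. `allowed` masks columns that may enter the basis.
simplex_iterate <- function(T, basis, cost, allowed, tol = 1e-9) {
  m <- nrow(T); ncols <- ncol(T) - 1L
  repeat {
    cb <- cost[basis]
    red <- cost[seq_len(ncols)] -
      as.vector(cb %*% T[, seq_len(ncols), drop = FALSE])
    cand <- which(red < -tol & allowed)
    if (!length(cand)) {
      return(list(T = T, basis = basis, status = "optimal"))
    }
    j <- cand[1]                                   # Bland: lowest index
    col <- T[, j]
    pos <- which(col > tol)
    if (!length(pos)) return(list(status = "unbounded"))
    ratios <- T[pos, ncols + 1L] / col[pos]
    mins <- pos[ratios <= min(ratios) + 1e-12]
    i <- mins[which.min(basis[mins])]              # Bland: lowest basic index
    T[i, ] <- T[i, ] / T[i, j]
    for (k in seq_len(m)) {
      if (k != i && abs(T[k, j]) > 0) T[k, ] <- T[k, ] - T[k, j] * T[i, ]
    }
    basis[i] <- j
  }
}

# min obj'y s.t. D y = d, y >= 0. Returns y, value and status
# ("optimal", "infeasible", "unbounded").
lp_solve_min <- function(obj, D, d, tol = 1e-8) {
  stopifnot(all(d >= 0))
  m <- nrow(D); n <- ncol(D)
  T <- cbind(D, diag(m), d)
  basis <- n + seq_len(m)                          # artificial start basis
  cost1 <- c(rep(0, n), rep(1, m))
  ph1 <- simplex_iterate(T, basis, cost1, allowed = rep(TRUE, n + m))
  if (ph1$status != "optimal") return(list(status = ph1$status))
  resid <- sum(ph1$T[ph1$basis > n, n + m + 1L])
  if (resid > tol) return(list(status = "infeasible"))
  T <- ph1$T; basis <- ph1$basis
  # drive lingering zero-valued artificials out of the basis so they can
  # never re-enter the solution in phase 2; all-zero rows are redundant
  drop_rows <- integer(0)
  for (i in which(basis > n)) {
    piv <- which(abs(T[i, seq_len(n)]) > tol)
    if (length(piv)) {
      j <- piv[1]
      T[i, ] <- T[i, ] / T[i, j]
      for (k in seq_len(nrow(T))) {
        if (k != i && abs(T[k, j]) > 0) T[k, ] <- T[k, ] - T[k, j] * T[i, ]
      }
      basis[i] <- j
    } else {
      drop_rows <- c(drop_rows, i)
    }
  }
  if (length(drop_rows)) {
    T <- T[-drop_rows, , drop = FALSE]
    basis <- basis[-drop_rows]
  }
  cost2 <- c(obj, rep(0, m))
  ph2 <- simplex_iterate(T, basis, cost2,
                         allowed = c(rep(TRUE, n), rep(FALSE, m)))
  if (ph2$status != "optimal") return(list(status = ph2$status))
  y <- numeric(n)
  keep <- ph2$basis <= n
  y[ph2$basis[keep]] <- ph2$T[keep, n + m + 1L]
  list(y = y, value = sum(obj * y), status = "optimal")
}

# max cc'x s.t. A x = b, 0 <= x <= u (finite u). Upper bounds enter as
# slack rows x + s = u; rows with negative b are flipped first.
lp_solve_box <- function(cc, A, b, u) {
  n <- length(cc)
  neg <- b < 0
  A[neg, ] <- -A[neg, , drop = FALSE]
  b[neg] <- -b[neg]
  D <- rbind(cbind(A, matrix(0, nrow(A), n)),
             cbind(diag(n), diag(n)))
  d <- c(b, u)
  res <- lp_solve_min(c(-cc, rep(0, n)), D, d)
  if (res$status != "optimal") return(res)
  list(x = res$y[seq_len(n)], value = -res$value, status = "optimal")
}
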