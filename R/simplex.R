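# Dense two-phase primal simplex for equality-form linear programs:
#
#     minimize  c'z   subject to  A z = b,  z >= 0
#
# sized for the SBM efficiency programs (a handful of constraints, up
# to a few hundred variables). Bland's anti-cycling rule guarantees
# termination on the degenerate, zero-right-hand-side constraints the
# Charnes-Cooper linearization produces. Phase 1 minimizes the sum of
# artificial variables from the all-artificial basis; phase 2 then
# minimizes c over the feasible basis, after pivoting any residual
# (degenerate) artificials out.
#
# Returns list(status = "optimal" | "infeasible" | "unbounded",
#              z, value).
solve_lp_eq <- function(cvec, A, b, tol = 1e-9, max_iter = NULL) {
  A <- as.matrix(A)
  m <- nrow(A)
  n <- ncol(A)
  stopifnot(length(cvec) == n, length(b) == m)
  # normalize to b >= 0
  neg <- b < 0
  A[neg, ] <- -A[neg, , drop = FALSE]
  b[neg] <- -b[neg]
  if (is.null(max_iter)) max_iter <- 50L * (n + m) + 1000L

  # tableau over original + artificial columns
  Tb <- cbind(A, diag(m), b)
  basis <- n + seq_len(m)

  run_phase <- function(Tb, basis, obj, ncols) {
    # obj: cost vector over the ncols structural columns
    for (it in seq_len(max_iter)) {
      cb <- obj[basis]
      # reduced costs: obj - cb' B^-1 A, with tableau already in basis form
      red <- obj - drop(cb %*% Tb[, seq_len(ncols), drop = FALSE])
      red[basis] <- 0
      enter <- which(red < -tol)
      if (!length(enter)) {
        return(list(Tb = Tb, basis = basis, optimal = TRUE))
      }
      j <- min(enter) # Bland
      col <- Tb[, j]
      pos <- which(col > tol)
      if (!length(pos)) {
        return(list(Tb = Tb, basis = basis, optimal = FALSE)) # unbounded
      }
      ratio <- Tb[pos, ncols + 1L] / col[pos]
      rmin <- min(ratio)
      cand <- pos[ratio <= rmin + tol]
      i <- cand[which.min(basis[cand])] # Bland tie-break
      piv <- Tb[i, j]
      Tb[i, ] <- Tb[i, ] / piv
      for (r in seq_len(m)) {
        if (r != i && abs(Tb[r, j]) > 0) Tb[r, ] <- Tb[r, ] - Tb[r, j] * Tb[i, ]
      }
      basis[i] <- j
    }
    stop("solve_lp_eq: iteration limit reached")
  }

  ncols <- n + m
  obj1 <- c(rep(0, n), rep(1, m))
  ph1 <- run_phase(Tb, basis, obj1, ncols)
  Tb <- ph1$Tb
  basis <- ph1$basis
  phase1_val <- sum(obj1[basis] * Tb[, ncols + 1L])
  if (phase1_val > 1e-7) {
    return(list(status = "infeasible", z = NULL, value = NA_real_))
  }
  # pivot leftover artificials (degenerate, value 0) out of the basis
  for (i in which(basis > n)) {
    piv_col <- which(abs(Tb[i, seq_len(n)]) > tol & !(seq_len(n) %in% basis))
    if (length(piv_col)) {
      j <- piv_col[1]
      piv <- Tb[i, j]
      Tb[i, ] <- Tb[i, ] / piv
      for (r in seq_len(m)) {
        if (r != i && abs(Tb[r, j]) > 0) Tb[r, ] <- Tb[r, ] - Tb[r, j] * Tb[i, ]
      }
      basis[i] <- j
    }
    # else: redundant row, artificial stays at zero; harmless in phase 2
  }
  obj2 <- c(cvec, rep(1e9, m)) # artificials penalized so they stay at 0
  ph2 <- run_phase(Tb, basis, obj2, ncols)
  if (!ph2$optimal) {
    return(list(status = "unbounded", z = NULL, value = NA_real_))
  }
  Tb <- ph2$Tb
  basis <- ph2$basis
  z <- numeric(n)
  keep <- basis <= n
  z[basis[keep]] <- Tb[keep, ncols + 1L]
  list(status = "optimal", z = z, value = sum(cvec * z))
}
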