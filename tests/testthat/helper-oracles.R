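# Independent oracles used across the suite. Each one recomputes the
# quantity from first principles, sharing no code with the package
# implementation it checks.

# LS-SVR via the (m+1)-dimensional KKT saddle system
#   [0  1'] [b]     [0]
#   [1  A ] [alpha] [y],  A = K + I/gamma
# solved with a generic dense solve.
oracle_lssvr <- function(X, y, sigma, gamma) {
  m <- nrow(X)
  K <- matrix(0, m, m)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      K[i, j] <- exp(-sum((X[i, ] - X[j, ])^2) / (2 * sigma^2))
    }
  }
  A <- K + diag(m) / gamma
  M <- rbind(c(0, rep(1, m)), cbind(rep(1, m), A))
  sol <- solve(M, c(0, y))
  list(b = sol[1], alpha = sol[-1])
}

# Prediction by the literal sum over training points.
oracle_predict <- function(X_train, alpha, b, sigma, Xq) {
  vapply(seq_len(nrow(Xq)), function(j) {
    s <- 0
    for (i in seq_len(nrow(X_train))) {
      s <- s + alpha[i] *
        exp(-sum((Xq[j, ] - X_train[i, ])^2) / (2 * sigma^2))
    }
    s + b
  }, numeric(1))
}

# Exhaustive pairwise dominance over a DEA table: DMU k is dominated if
# some other DMU has <= inputs, >= desirable outputs, <= undesirable
# outputs, with at least one strict inequality.
oracle_dominated <- function(tab, k) {
  n <- length(tab$dmu_ids)
  for (j in setdiff(seq_len(n), k)) {
    le_in <- all(tab$inputs[j, ] <= tab$inputs[k, ])
    ge_g <- all(tab$good_outputs[j, ] >= tab$good_outputs[k, ])
    le_b <- all(tab$bad_outputs[j, ] <= tab$bad_outputs[k, ])
    strict <- any(tab$inputs[j, ] < tab$inputs[k, ]) ||
      any(tab$good_outputs[j, ] > tab$good_outputs[k, ]) ||
      any(tab$bad_outputs[j, ] < tab$bad_outputs[k, ])
    if (le_in && ge_g && le_b && strict) return(TRUE)
  }
  FALSE
}

# Brute-force SBM score for tiny tables by vertex enumeration of the
# Charnes-Cooper polytope: the equality system is rebuilt here from the
# model definition, every basic solution is enumerated with a generic
# dense solve, and the *fractional* SBM objective is evaluated at each
# feasible vertex after undoing the transformation. Exponential in the
# variable count, so only for <= 4 DMUs and small dimension.
oracle_sbm <- function(tab, k, rts = "crs") {
  x0 <- tab$inputs[k, ]
  yg0 <- tab$good_outputs[k, ]
  yb0 <- tab$bad_outputs[k, ]
  X <- tab$inputs
  Yg <- tab$good_outputs
  Yb <- tab$bad_outputs
  n <- nrow(X)
  m <- length(x0)
  sg <- length(yg0)
  sb <- length(yb0)
  nv <- 1 + n + m + sg + sb
  E <- NULL
  rhs <- NULL
  add <- function(row, r) {
    E <<- rbind(E, row)
    rhs <<- c(rhs, r)
  }
  norm_row <- numeric(nv)
  norm_row[1] <- 1
  norm_row[1 + n + m + seq_len(sg)] <- 1 / ((sg + sb) * yg0)
  norm_row[1 + n + m + sg + seq_len(sb)] <- 1 / ((sg + sb) * yb0)
  add(norm_row, 1)
  for (i in seq_len(m)) {
    row <- numeric(nv)
    row[1] <- x0[i]
    row[1 + seq_len(n)] <- -X[, i]
    row[1 + n + i] <- -1
    add(row, 0)
  }
  for (r in seq_len(sg)) {
    row <- numeric(nv)
    row[1] <- yg0[r]
    row[1 + seq_len(n)] <- -Yg[, r]
    row[1 + n + m + r] <- 1
    add(row, 0)
  }
  for (r in seq_len(sb)) {
    row <- numeric(nv)
    row[1] <- yb0[r]
    row[1 + seq_len(n)] <- -Yb[, r]
    row[1 + n + m + sg + r] <- -1
    add(row, 0)
  }
  if (rts == "vrs") {
    row <- numeric(nv)
    row[1] <- -1
    row[1 + seq_len(n)] <- 1
    add(row, 0)
  }
  nc <- nrow(E)
  best <- Inf
  for (cols in utils::combn(nv, nc, simplify = FALSE)) {
    B <- E[, cols, drop = FALSE]
    if (abs(det(B)) < 1e-10) next
    z <- numeric(nv)
    z[cols] <- solve(B, rhs)
    if (any(z < -1e-9)) next
    t <- z[1]
    if (t <= 1e-12) next
    s_in <- z[1 + n + seq_len(m)] / t
    s_g <- z[1 + n + m + seq_len(sg)] / t
    s_b <- z[1 + n + m + sg + seq_len(sb)] / t
    rho <- (1 - mean(s_in / x0)) /
      (1 + (sum(s_g / yg0) + sum(s_b / yb0)) / (sg + sb))
    best <- min(best, rho)
  }
  best
}

# Small noiseless panel with the outcome proportional to one predictor.
proportional_panel <- function(driver = "temperature", beta = 3,
                               n_regions = 10L, seed = 11L) {
  cfg <- panel_config(
    n_regions = n_regions,
    response = list(family = "linear",
                    coef = stats::setNames(beta, driver), intercept = 0),
    noise_sd = 0, seed = seed)
  simulate_panel(cfg)
}
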