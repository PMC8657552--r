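#' Search settings for the random direct search
#'
#' @param sigma0,gamma0 Positive starting values for the kernel width and
#'   regularization weight. The defaults `(1, 1)` suit predictors
#'   normalized to `[0, 1]`.
#' @param epsilon Accuracy threshold on the in-sample objective `G`
#'   (squared outcome units); the search stops as soon as the incumbent
#'   `G` falls to or below it.
#' @param max_iter Iteration cap `N`.
#' @param step_mode `"signed"` (default) draws each step uniformly on
#'   `(-1, 1)` and rejects candidates with a non-positive coordinate, so
#'   the search can move in any direction; `"literal"` draws steps
#'   uniformly on `(0, 1)` only, so both parameters can only grow from
#'   their starting point.
#' @return A list of class `"search_config"`.
#' @export
search_config <- function(sigma0 = 1, gamma0 = 1, epsilon = 1e-6,
                          max_iter = 500L,
                          step_mode = c("signed", "literal")) {
  step_mode <- match.arg(step_mode)
  stopifnot(sigma0 > 0, gamma0 > 0, epsilon >= 0, max_iter >= 1)
  structure(list(sigma0 = sigma0, gamma0 = gamma0, epsilon = epsilon,
                 max_iter = as.integer(max_iter), step_mode = step_mode),
            class = "search_config")
}

#' Random direct search over (sigma, gamma)
#'
#' Derivative-free hyperparameter tuning of the LS-SVR: starting from
#' `(sigma0, gamma0)`, repeatedly propose a random step in both
#' coordinates, evaluate the in-sample objective [lssvr_objective()] at
#' the candidate, and accept the candidate iff `G` does not increase.
#' The search stops when `G <= epsilon` or after `max_iter` iterations,
#' and returns the incumbent as the tuned pair.
#'
#' The accepted-`G` sequence is non-increasing by construction, and the
#' whole trajectory is reproducible from the RNG state: call
#' `set.seed()` before `direct_search()` (the function draws from R's
#' global RNG stream and sets no seed itself).
#'
#' @inheritParams lssvr
#' @param config A [search_config()].
#' @return A list with
#'   \describe{
#'     \item{sigma, gamma}{the tuned pair.}
#'     \item{objective}{the incumbent `G` at termination.}
#'     \item{trace}{a data frame with one row per iteration:
#'       `k`, `sigma_prop`, `gamma_prop`, `g_prop`, `accepted`,
#'       `g_current`. Proposals outside the positive quadrant are
#'       recorded with `g_prop = NA` and `accepted = FALSE`.}
#'   }
#' @examples
#' set.seed(7)
#' X <- matrix(runif(30), 15, 2)
#' y <- sin(3 * X[, 1]) + X[, 2]^2
#' res <- direct_search(X, y, search_config(max_iter = 50))
#' res$sigma; res$gamma; res$objective
#' @export
direct_search <- function(X, y, config = search_config()) {
  stopifnot(inherits(config, "search_config"))
  X <- as.matrix(X)
  y <- as.numeric(y)
  sigma <- config$sigma0
  gamma <- config$gamma0
  g_cur <- lssvr_objective(X, y, sigma, gamma)
  n <- config$max_iter
  trace <- data.frame(k = integer(n), sigma_prop = numeric(n),
                      gamma_prop = numeric(n), g_prop = numeric(n),
                      accepted = logical(n), g_current = numeric(n))
  used <- 0L
  k <- 1L
  while (g_cur > config$epsilon && k <= n) {
    if (config$step_mode == "signed") {
      lam_s <- stats::runif(1, -1, 1)
      lam_g <- stats::runif(1, -1, 1)
    } else {
      lam_s <- stats::runif(1, 0, 1)
      lam_g <- stats::runif(1, 0, 1)
    }
    s_new <- sigma + lam_s
    g_new <- gamma + lam_g
    if (s_new > 0 && g_new > 0) {
      g_prop <- tryCatch(lssvr_objective(X, y, s_new, g_new),
                         error = function(e) {
                           warning("direct_search: candidate (sigma=",
                                   signif(s_new, 4), ", gamma=",
                                   signif(g_new, 4), ") rejected: ",
                                   conditionMessage(e), call. = FALSE)
                           NA_real_
                         })
      acc <- is.finite(g_prop) && g_prop <= g_cur
    } else {
      g_prop <- NA_real_
      acc <- FALSE
    }
    if (acc) {
      sigma <- s_new
      gamma <- g_new
      g_cur <- g_prop
    }
    used <- used + 1L
    trace[used, ] <- list(k, s_new, g_new, g_prop, acc, g_cur)
    k <- k + 1L
  }
  list(sigma = sigma, gamma = gamma, objective = g_cur,
       trace = trace[seq_len(used), , drop = FALSE])
}

#' Objective surface on a hyperparameter grid
#'
#' Evaluates `G(sigma, gamma)` at every node of the outer product of the
#' two grids; a diagnostic and testing aid for [direct_search()].
#'
#' @inheritParams lssvr
#' @param sigma_grid,gamma_grid Positive numeric vectors.
#' @return A `length(sigma_grid) x length(gamma_grid)` matrix with
#'   dimnames set to the grid values.
#' @export
objective_surface <- function(X, y, sigma_grid, gamma_grid) {
  stopifnot(all(sigma_grid > 0), all(gamma_grid > 0))
  G <- matrix(NA_real_, length(sigma_grid), length(gamma_grid),
              dimnames = list(signif(sigma_grid, 6), signif(gamma_grid, 6)))
  for (i in seq_along(sigma_grid)) {
    for (j in seq_along(gamma_grid)) {
      G[i, j] <- lssvr_objective(X, y, sigma_grid[i], gamma_grid[j])
    }
  }
  G
}
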