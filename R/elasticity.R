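#' Multiply one predictor column by (1 + delta)
#'
#' One-at-a-time perturbation used by the elasticity analysis: column
#' `j` is scaled by `1 + delta` (1% increase by default), all other
#' columns are untouched.
#'
#' @param X Numeric matrix.
#' @param j Column index or name.
#' @param delta Relative change, `> -1` (default 0.01).
#' @return The perturbed matrix.
#' @export
perturb_predictor <- function(X, j, delta = 0.01) {
  X <- as.matrix(X)
  if (is.character(j)) j <- match(j, colnames(X))
  if (is.na(j) || j < 1 || j > ncol(X)) {
    stop("perturb_predictor: invalid column index")
  }
  if (delta <= -1) stop("perturb_predictor: delta must exceed -1")
  X[, j] <- X[, j] * (1 + delta)
  X
}

#' Elasticity of a fitted model to one predictor
#'
#' Mean relative change of the model's prediction when predictor `j`
#' is increased by `delta` (default 1%) in every observation:
#' \deqn{E_j = \frac{1}{m} \sum_i
#'   \frac{\hat y(x_i \text{ with } x_{ij}(1+\delta)) - \hat y(x_i)}
#'        {\hat y(x_i)}.}
#' The result is a dimensionless fraction: `E_j = 0.01` means a 1%
#' predictor increase moves the prediction by 1% on average (0.01 x 100
#' = 1 percentage point per 1%).
#'
#' When the predictors were normalized before fitting, pass the raw
#' matrix together with the normalizer: the 1% change is applied on the
#' raw scale and mapped through the same transform the model was
#' trained on, so the elasticity refers to a real 1% change in the
#' variable, not 1% of its normalized value.
#'
#' @param model A fitted [lssvr()] model.
#' @param X Predictor matrix on the scale indicated by `normalizer`
#'   (raw scale if a normalizer is given, otherwise the model's own
#'   scale).
#' @param j Column index or name to perturb.
#' @param delta Relative perturbation (default 0.01).
#' @param normalizer Optional normalizer state from
#'   [normalize_columns()] mapping raw predictors to the model's scale.
#' @param tol Guard: error if any base prediction has absolute value
#'   below `tol` (the relative change would blow up).
#' @return A scalar fraction.
#' @export
elasticity <- function(model, X, j, delta = 0.01, normalizer = NULL,
                       tol = 1e-8) {
  X <- as.matrix(X)
  to_model_scale <- function(M) {
    if (is.null(normalizer)) M else
      as.matrix(apply_normalizer(as.data.frame(M), normalizer))
  }
  base <- predict(model, to_model_scale(X))
  if (any(abs(base) < tol)) {
    stop("elasticity: base prediction within ", tol,
         " of zero; relative change undefined")
  }
  pert <- predict(model, to_model_scale(perturb_predictor(X, j, delta)))
  mean((pert - base) / base)
}

#' Region-by-predictor elasticity table
#'
#' The full sensitivity analysis: for the national aggregate and each
#' region independently, tune `(sigma, gamma)` by [direct_search()],
#' fit the four-indicator LS-SVR (all four climate variables, `REE`,
#' and the six controls -- 11 predictors), and record the elasticity of
#' the outcome to a 1% increase in each predictor.
#'
#' Predictors are min-max normalized per series before fitting; the 1%
#' perturbation is applied on the raw scale and passed through the same
#' normalizer, and predictions stay on the raw outcome scale, so the
#' entries are scale-free fractions comparable across regions.
#'
#' @inheritParams evaluate_model
#' @param regions Regions to analyse (each gets its own row);
#'   `"national"` is prepended unless `include_national = FALSE`.
#' @param delta Relative perturbation (default 0.01 = 1%).
#' @param include_national Prepend the nation-aggregated series.
#' @return A data frame: one row per region, one column per predictor,
#'   plus `region`, `sigma`, `gamma`. Regions whose fit fails are kept
#'   as all-`NA` rows with a warning.
#' @export
elasticity_table <- function(panel, outcome,
                             regions = unique(panel$region),
                             config = search_config(), delta = 0.01,
                             seed = 1L, include_national = TRUE) {
  preds <- setting_predictors("four_indicators")
  rows <- if (include_national) c("national", setdiff(regions, "national"))
          else setdiff(regions, "national")
  out <- data.frame(region = rows, stringsAsFactors = FALSE)
  for (p in preds) out[[p]] <- NA_real_
  out$sigma <- NA_real_
  out$gamma <- NA_real_
  for (i in seq_along(rows)) {
    r <- rows[i]
    res <- tryCatch({
      dat <- region_series(panel, r, outcome)
      norm <- normalize_columns(dat, preds, method = "minmax")
      Xn <- as.matrix(norm$data[preds])
      Xraw <- as.matrix(dat[preds])
      y <- dat[[outcome]]
      set.seed(seed + i)
      tuned <- direct_search(Xn, y, config)
      fit <- lssvr(Xn, y, tuned$sigma, tuned$gamma)
      e <- vapply(preds, function(p) {
        elasticity(fit, Xraw, p, delta, normalizer = norm$state)
      }, numeric(1))
      c(e, sigma = tuned$sigma, gamma = tuned$gamma)
    }, error = function(err) {
      warning("elasticity_table: region '", r, "' failed: ",
              conditionMessage(err), call. = FALSE)
      NULL
    })
    if (!is.null(res)) out[i, c(preds, "sigma", "gamma")] <- as.list(res)
  }
  attr(out, "outcome") <- outcome
  attr(out, "delta") <- delta
  out
}
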