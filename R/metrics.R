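#' Forecast-accuracy metrics: MPE, MSE, SDE
#'
#' The three error measures used to compare model settings:
#' \describe{
#'   \item{`mpe`}{mean percentage error,
#'     \eqn{\frac{1}{T}\sum_t (y_t - \hat y_t)/y_t}. Signed by default,
#'     so over- and under-prediction can cancel; set `absolute = TRUE`
#'     for the mean absolute percentage error.}
#'   \item{`mse`}{mean squared error,
#'     \eqn{\frac{1}{T}\sum_t (y_t - \hat y_t)^2}.}
#'   \item{`sde`}{the square root of the MSE -- the standard deviation
#'     scale of the prediction errors, `sde(y, yhat)^2 == mse(y, yhat)`.}
#' }
#'
#' @param y Observed values (`y_t` must be nonzero for `mpe`).
#' @param yhat Forecasts, same length.
#' @param absolute For `mpe`, take absolute relative errors.
#' @return A scalar.
#' @export
mpe <- function(y, yhat, absolute = FALSE) {
  check_lengths(y, yhat)
  if (any(y == 0)) {
    stop("mpe: y is zero at index ", which(y == 0)[1],
         "; relative error undefined")
  }
  r <- (y - yhat) / y
  if (absolute) r <- abs(r)
  mean(r)
}

#' @rdname mpe
#' @export
mse <- function(y, yhat) {
  check_lengths(y, yhat)
  mean((y - yhat)^2)
}

#' @rdname mpe
#' @export
sde <- function(y, yhat) {
  sqrt(mse(y, yhat))
}

check_lengths <- function(y, yhat) {
  if (length(y) != length(yhat)) {
    stop("metric: 'y' and 'yhat' must have equal length (",
         length(y), " vs ", length(yhat), ")")
  }
  if (!is.numeric(y) || !is.numeric(yhat)) stop("metric: numeric input only")
  invisible(TRUE)
}

error_metrics <- function(y, yhat, absolute_mpe = FALSE) {
  c(mpe = mpe(y, yhat, absolute = absolute_mpe),
    mse = mse(y, yhat),
    sde = sde(y, yhat))
}

# The five model settings compared before elasticity analysis: one
# climate variable at a time, or all four together, always alongside
# REE and the six controls.
model_settings <- function() {
  c(stats::setNames(as.list(climate_vars), climate_vars),
    list(four_indicators = climate_vars))
}

# Build the predictor matrix for a setting on (a subset of) the panel.
setting_predictors <- function(setting) {
  climate <- model_settings()[[setting]]
  if (is.null(climate)) {
    stop("unknown model setting '", setting, "'; use one of: ",
         paste(names(model_settings()), collapse = ", "))
  }
  c(climate, "REE", control_vars)
}

#' Fit and score one model setting on one region
#'
#' Runs the full per-series modeling path: select the setting's
#' predictors (one climate variable plus `REE` plus the six controls --
#' 8 predictors -- or all four climate variables for the
#' `"four_indicators"` setting -- 11 predictors), min-max normalize the
#' predictors, tune `(sigma, gamma)` by [direct_search()], fit the
#' LS-SVR, predict in-sample, and return the (MPE, MSE, SDE) triple on
#' the outcome's own scale.
#'
#' @param panel Panel data frame (see [read_panel()]), already carrying
#'   an `REE` column.
#' @param outcome One of `"VTH"`, `"OWT"`, `"NOI"`.
#' @param setting One of `"temperature"`, `"humidity"`,
#'   `"precipitation"`, `"sunshine"`, `"four_indicators"`.
#' @param region A region id, or `"national"` for the nation-aggregated
#'   series (outcomes summed, predictors averaged across regions by
#'   year).
#' @param config A [search_config()].
#' @param seed Integer seed for the direct search.
#' @return Named numeric vector `(mpe, mse, sde)` with attributes
#'   `sigma` and `gamma` (the tuned pair).
#' @export
evaluate_model <- function(panel, outcome, setting = "four_indicators",
                           region = "national", config = search_config(),
                           seed = 1L) {
  dat <- region_series(panel, region, outcome)
  preds <- setting_predictors(setting)
  missing <- setdiff(c(outcome, preds), names(dat))
  if (length(missing)) {
    stop("evaluate_model: panel lacks column(s): ",
         paste(missing, collapse = ", "))
  }
  if (nrow(dat) < 3L) stop("evaluate_model: fewer than 3 rows for ", region)
  norm <- normalize_columns(dat, preds, method = "minmax")
  X <- as.matrix(norm$data[preds])
  y <- dat[[outcome]]
  set.seed(seed)
  tuned <- direct_search(X, y, config)
  fit <- lssvr(X, y, tuned$sigma, tuned$gamma)
  out <- error_metrics(y, predict(fit, X))
  attr(out, "sigma") <- tuned$sigma
  attr(out, "gamma") <- tuned$gamma
  out
}

# Extract one region's year-ordered series, or the national aggregate
# (outcome summed, predictors averaged over regions within year).
region_series <- function(panel, region, outcome) {
  if (identical(region, "national")) {
    agg_sum <- stats::aggregate(panel[outcome_vars],
                                by = list(year = panel$year), FUN = sum)
    keep <- intersect(predictor_vars, names(panel))
    agg_mean <- stats::aggregate(panel[keep],
                                 by = list(year = panel$year), FUN = mean)
    dat <- merge(agg_sum, agg_mean, by = "year")
    dat$region <- "national"
  } else {
    dat <- panel[panel$region == region, , drop = FALSE]
    if (nrow(dat) == 0L) stop("no rows for region '", region, "'")
  }
  dat[order(dat$year), , drop = FALSE]
}

#' Compare the five model settings across regions
#'
#' Computes [evaluate_model()] for every (setting, region) pair and the
#' per-setting averages of MPE, MSE and SDE over the regions, the basis
#' for choosing the model used in elasticity analysis. The
#' four-indicator setting is flagged as the selected basic model: with
#' all four climate variables acting at once it is the realistic
#' specification, whatever the in-sample error ranking says.
#'
#' @inheritParams evaluate_model
#' @param regions Character vector of region ids; may include
#'   `"national"`. Averages are taken over the non-national rows when
#'   any exist.
#' @return A list with `summary` (data frame: setting x mpe/mse/sde
#'   averages plus a `selected` flag), and `detail` (per-region rows
#'   with tuned `sigma`, `gamma`).
#' @export
compare_models <- function(panel, outcome, regions = unique(panel$region),
                           config = search_config(), seed = 1L) {
  settings <- names(model_settings())
  detail <- NULL
  for (s in settings) {
    for (r in regions) {
      em <- evaluate_model(panel, outcome, s, r, config,
                           seed = seed + setting_offset(s, r, regions))
      detail <- rbind(detail, data.frame(
        setting = s, region = r, mpe = em[["mpe"]], mse = em[["mse"]],
        sde = em[["sde"]], sigma = attr(em, "sigma"),
        gamma = attr(em, "gamma"), stringsAsFactors = FALSE))
    }
  }
  avg_rows <- if (any(detail$region != "national")) {
    detail[detail$region != "national", , drop = FALSE]
  } else detail
  summary <- do.call(rbind, lapply(settings, function(s) {
    d <- avg_rows[avg_rows$setting == s, , drop = FALSE]
    data.frame(setting = s, mpe = mean(d$mpe), mse = mean(d$mse),
               sde = mean(d$sde), stringsAsFactors = FALSE)
  }))
  summary$selected <- summary$setting == "four_indicators"
  list(summary = summary, detail = detail, outcome = outcome)
}

# Deterministic per-(setting, region) seed offset so each series gets an
# independent but reproducible search stream.
setting_offset <- function(setting, region, regions) {
  si <- match(setting, names(model_settings()))
  ri <- match(region, regions)
  (si - 1L) * (length(regions) + 1L) + ri
}
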