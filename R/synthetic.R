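# Column-role constants used across the pipeline.
climate_vars <- c("temperature", "humidity", "precipitation", "sunshine")
control_vars <- c("GDPPC", "UL", "PD", "MP", "LAD", "NHCI")
outcome_vars <- c("VTH", "OWT", "NOI")
predictor_vars <- c(climate_vars, "REE", control_vars)

#' Configuration for the synthetic panel generator
#'
#' Describes a region-by-year panel to simulate: how many regions, which
#' years, how volatile the climate series are, what the true (noiseless)
#' response of each health outcome to the predictors is, and how much
#' observation noise sits on top of it.
#'
#' The response is specified by a family plus a named coefficient vector
#' over predictor columns:
#' \describe{
#'   \item{`"constant"`}{`y = intercept`; every true elasticity is 0.}
#'   \item{`"linear"`}{`y = intercept + sum(beta_j * x_j)`.}
#'   \item{`"loglinear"`}{`y = exp(intercept + sum(beta_j * log x_j))`;
#'     the true elasticity of `x_j` is `0.01 * beta_j` regardless of
#'     where it is evaluated.}
#'   \item{`"smooth"`}{`y = intercept + sum(beta_j * x_j) +
#'     sum(beta_j^2/2 * x_j^2 / mean_j)` -- a curved but monotone
#'     surface used to exercise the nonlinear fit path.}
#' }
#'
#' @param n_regions Number of regions (default 30).
#' @param years Integer vector of consecutive years (default
#'   `2002:2016`).
#' @param response A list with elements `family` (one of the names
#'   above), `coef` (named numeric vector over predictor columns;
#'   unnamed predictors have zero effect) and `intercept`. A single
#'   spec is applied to all three outcomes; alternatively a named list
#'   of specs, one per outcome (`VTH`, `OWT`, `NOI`).
#' @param noise_sd Standard deviation of additive Gaussian observation
#'   noise on the outcome scale (0 for noiseless panels). The default 50
#'   is roughly half a percent of the typical outcome level under the
#'   default response, a modest reporting error for yearly
#'   institutional counts.
#' @param climate_volatility Relative fluctuation amplitude of the
#'   climate series around their regional means (default 0.08, several
#'   times larger than the smooth drift of the outcome trend, mirroring
#'   panels where weather varies much more year-to-year than aggregate
#'   health-care use does).
#' @param seed Integer RNG seed; the same config always generates the
#'   same panel.
#' @return A list of class `"panel_config"`.
#' @export
panel_config <- function(n_regions = 30L,
                         years = 2002:2016,
                         response = list(
                           family = "loglinear",
                           coef = c(temperature = 0.25, humidity = 0.15,
                                    precipitation = 0.08, sunshine = 0.10,
                                    REE = 0.20, GDPPC = 0.15, UL = 0.10,
                                    PD = 0.08, MP = 0.12, LAD = 0.10,
                                    NHCI = 0.05),
                           intercept = 3),
                         noise_sd = 50,
                         climate_volatility = 0.08,
                         seed = 1L) {
  if (!is.numeric(n_regions) || n_regions < 1) {
    stop("panel_config: n_regions must be >= 1")
  }
  years <- as.integer(years)
  if (length(years) < 3L || any(diff(years) != 1L)) {
    stop("panel_config: need at least 3 consecutive years")
  }
  if (noise_sd < 0) stop("panel_config: noise_sd must be >= 0")
  if (!is.null(response$family)) {
    response <- stats::setNames(rep(list(response), 3), outcome_vars)
  }
  if (!setequal(names(response), outcome_vars)) {
    stop("panel_config: response must be one spec or one per outcome (",
         paste(outcome_vars, collapse = ", "), ")")
  }
  for (nm in outcome_vars) {
    sp <- response[[nm]]
    if (!sp$family %in% c("constant", "linear", "loglinear", "smooth")) {
      stop("panel_config: unknown response family '", sp$family, "'")
    }
    bad <- setdiff(names(sp$coef), predictor_vars)
    if (length(bad)) {
      stop("panel_config: response coefficients reference unknown ",
           "predictor(s): ", paste(bad, collapse = ", "))
    }
  }
  structure(list(n_regions = as.integer(n_regions), years = years,
                 response = response, noise_sd = noise_sd,
                 climate_volatility = climate_volatility,
                 seed = as.integer(seed)),
            class = "panel_config")
}

# Evaluate one response spec (noiseless) on a predictor data frame.
response_surface <- function(spec, X, col_means = NULL) {
  co <- spec$coef
  if (is.null(co)) co <- numeric(0)
  b0 <- if (is.null(spec$intercept)) 0 else spec$intercept
  n <- nrow(X)
  switch(spec$family,
    constant = rep(b0, n),
    linear = {
      y <- rep(b0, n)
      for (v in names(co)) y <- y + co[[v]] * X[[v]]
      y
    },
    loglinear = {
      ly <- rep(b0, n)
      for (v in names(co)) ly <- ly + co[[v]] * log(X[[v]])
      exp(ly)
    },
    smooth = {
      if (is.null(col_means)) {
        col_means <- vapply(X[names(co)], mean, numeric(1))
      }
      y <- rep(b0, n)
      for (v in names(co)) {
        y <- y + co[[v]] * X[[v]] + (co[[v]]^2 / 2) * X[[v]]^2 / col_means[[v]]
      }
      y
    },
    stop("unknown response family"))
}

# Analytic elasticity of the noiseless response at the predictor means:
# 0.01 * xbar_j * f'_j(xbar) / f(xbar), i.e. relative outcome change per
# 1% relative increase of predictor j, expressed as a fraction.
response_elasticities <- function(spec, X) {
  co <- spec$coef
  out <- stats::setNames(rep(0, length(predictor_vars)), predictor_vars)
  if (spec$family == "constant" || is.null(co) || !length(co)) return(out)
  xbar <- vapply(X[predictor_vars], mean, numeric(1))
  mid <- as.data.frame(as.list(xbar))
  f0 <- response_surface(spec, mid, col_means = xbar)
  for (v in names(co)) {
    deriv <- switch(spec$family,
      linear = co[[v]],
      loglinear = f0 * co[[v]] / xbar[[v]],
      smooth = co[[v]] + co[[v]]^2 * xbar[[v]] / xbar[[v]])
    out[[v]] <- 0.01 * xbar[[v]] * deriv / f0
  }
  out
}

#' Simulate a regional health/climate panel with known ground truth
#'
#' Generates a complete panel (regions x years) carrying the three
#' health outcomes, four climate variables, an eco-efficiency proxy
#' `REE` and six socio-economic controls, plus the analytic elasticity
#' of every predictor so downstream estimates can be checked against
#' ground truth.
#'
#' Structure of the simulated series: each climate variable is a
#' region-specific mean plus an AR(1) fluctuation whose amplitude is
#' `climate_volatility` times the mean, so climate fluctuates visibly
#' more than the smooth upward trends given to `REE` and the controls.
#' Outcomes are the noiseless response surface evaluated on the
#' predictors plus iid Gaussian noise, floored at a small positive
#' constant so relative errors stay well-defined.
#'
#' @param config A [panel_config()].
#' @return A list with
#'   \describe{
#'     \item{panel}{data frame with columns `region`, `year`, the three
#'       outcomes, and the eleven predictors.}
#'     \item{truth}{named list per outcome of ground-truth elasticity
#'       vectors (fractions; `0.01` means a 1% predictor increase moves
#'       the outcome by 1%).}
#'   }
#' @examples
#' sim <- simulate_panel(panel_config(n_regions = 3, seed = 42))
#' head(sim$panel)
#' sim$truth$VTH
#' @export
simulate_panel <- function(config = panel_config()) {
  stopifnot(inherits(config, "panel_config"))
  set.seed(config$seed)
  nr <- config$n_regions
  yrs <- config$years
  ny <- length(yrs)
  regions <- sprintf("R%02d", seq_len(nr))
  n <- nr * ny

  ar1 <- function(n, phi = 0.5, sd = 1) {
    e <- stats::rnorm(n, sd = sd * sqrt(1 - phi^2))
    as.numeric(stats::filter(e, phi, method = "recursive"))
  }

  df <- data.frame(region = rep(regions, each = ny),
                   year = rep(yrs, nr), stringsAsFactors = FALSE)

  # climate: regional mean level + AR(1) fluctuation (volatile year-to-year)
  clim_base <- c(temperature = 14, humidity = 65, precipitation = 900,
                 sunshine = 1900)
  for (v in climate_vars) {
    mu <- clim_base[[v]] * stats::runif(nr, 0.7, 1.3)
    fluct <- unlist(lapply(seq_len(nr), function(r) {
      mu[r] * config$climate_volatility * ar1(ny)
    }))
    df[[v]] <- pmax(rep(mu, each = ny) + fluct, 0.05 * rep(mu, each = ny))
  }

  # REE proxy: slow upward trend in (0, 1], mild noise
  tgrid <- (seq_len(ny) - 1) / (ny - 1)
  ree0 <- stats::runif(nr, 0.25, 0.55)
  ree1 <- stats::runif(nr, 0.15, 0.35)
  ree <- unlist(lapply(seq_len(nr), function(r) {
    ree0[r] + ree1[r] * tgrid + stats::rnorm(ny, sd = 0.01)
  }))
  df$REE <- pmin(pmax(ree, 0.05), 1)

  # controls: smooth regional growth (low relative volatility)
  ctrl_base <- c(GDPPC = 20000, UL = 45, PD = 400, MP = 40, LAD = 20,
                 NHCI = 800)
  ctrl_growth <- c(GDPPC = 0.9, UL = 0.35, PD = 0.15, MP = 0.5, LAD = 0.5,
                   NHCI = 0.25)
  for (v in control_vars) {
    lev <- ctrl_base[[v]] * stats::runif(nr, 0.6, 1.4)
    series <- unlist(lapply(seq_len(nr), function(r) {
      lev[r] * (1 + ctrl_growth[[v]] * tgrid) *
        (1 + stats::rnorm(ny, sd = 0.01))
    }))
    df[[v]] <- pmax(series, 0.01 * rep(lev, each = ny))
  }

  truth <- list()
  for (nm in outcome_vars) {
    sp <- config$response[[nm]]
    y <- response_surface(sp, df)
    if (config$noise_sd > 0) y <- y + stats::rnorm(n, sd = config$noise_sd)
    df[[nm]] <- pmax(y, 1e-6)
    truth[[nm]] <- response_elasticities(sp, df)
  }
  df <- df[c("region", "year", outcome_vars, predictor_vars)]
  list(panel = df, truth = truth)
}

#' Simulate a DEA table consistent with a panel config
#'
#' Generates, per region-year DMU, three positive inputs (labor,
#' capital, energy), one desirable output (GDP) and two undesirable
#' outputs (waste gas, wastewater). The first DMU is planted on the
#' efficient frontier: its inputs and undesirable outputs are strictly
#' below, and its desirable output strictly above, every other DMU's,
#' so no combination dominates it.
#'
#' @param config A [panel_config()]; the DMU ids are
#'   `"<region>:<year>"` matching [attach_ree()].
#' @return A [dea_table()].
#' @export
simulate_dea <- function(config = panel_config()) {
  stopifnot(inherits(config, "panel_config"))
  set.seed(config$seed + 1000L)
  nr <- config$n_regions
  yrs <- config$years
  ny <- length(yrs)
  n <- nr * ny
  ids <- paste(rep(sprintf("R%02d", seq_len(nr)), each = ny),
               rep(yrs, nr), sep = ":")
  rl <- function(mu, sdlog = 0.3) stats::rlnorm(n, log(mu), sdlog)
  X <- cbind(labor = rl(500), capital = rl(8000), energy = rl(3000))
  Yg <- cbind(gdp = rl(6000))
  Yb <- cbind(waste_gas = rl(120), wastewater = rl(80))
  if (n > 1) {
    # plant DMU 1 on the frontier: weakly better than everyone in every
    # dimension, strictly better in at least one
    X[1, ] <- apply(X[-1, , drop = FALSE], 2, min) * 0.9
    Yg[1, ] <- max(Yg[-1, ]) * 1.1
    Yb[1, ] <- apply(Yb[-1, , drop = FALSE], 2, min) * 0.9
  }
  dea_table(ids, X, Yg, Yb)
}
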