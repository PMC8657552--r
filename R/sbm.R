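#' Assemble a DEA table
#'
#' Bundles, per decision-making unit (DMU, here one region-year), the
#' input vector, desirable output vector and undesirable output vector
#' used by the slacks-based efficiency model. All entries must be
#' strictly positive: the SBM objective divides slacks by the observed
#' values.
#'
#' @param dmu_ids Character vector of unique DMU identifiers.
#' @param inputs Numeric matrix (`n x m_in`), resource use per DMU
#'   (e.g. labor, capital, energy).
#' @param good_outputs Numeric matrix (`n x s_g`), desirable outputs
#'   (e.g. GDP).
#' @param bad_outputs Numeric matrix (`n x s_b`), undesirable outputs
#'   (pollutants such as waste gas or wastewater).
#' @return A list of class `"dea_table"`.
#' @export
dea_table <- function(dmu_ids, inputs, good_outputs, bad_outputs) {
  inputs <- as.matrix(inputs)
  good_outputs <- as.matrix(good_outputs)
  bad_outputs <- as.matrix(bad_outputs)
  n <- length(dmu_ids)
  if (anyDuplicated(dmu_ids)) stop("dea_table: duplicated dmu_ids")
  if (nrow(inputs) != n || nrow(good_outputs) != n || nrow(bad_outputs) != n) {
    stop("dea_table: inputs, good_outputs and bad_outputs must all have one ",
         "row per DMU (", n, ")")
  }
  for (nm in c("inputs", "good_outputs", "bad_outputs")) {
    M <- get(nm)
    if (!all(is.finite(M)) || any(M <= 0)) {
      stop("dea_table: all ", nm, " entries must be finite and strictly ",
           "positive (SBM divides by observed values)")
    }
  }
  structure(list(dmu_ids = as.character(dmu_ids), inputs = inputs,
                 good_outputs = good_outputs, bad_outputs = bad_outputs),
            class = "dea_table")
}

#' Read/write a DEA table as CSV
#'
#' The CSV layout is one row per DMU with a `dmu_id` column and column
#' names prefixed `input:`, `good:`, `bad:` marking the role of each
#' variable.
#'
#' @param path File path.
#' @return `read_dea_table()` returns a [dea_table()].
#' @export
read_dea_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (nrow(df) == 0L) stop("read_dea_table: no rows in ", path)
  if (!"dmu_id" %in% names(df)) stop("read_dea_table: missing 'dmu_id' column")
  pick <- function(prefix) {
    cols <- grep(paste0("^", prefix, ":"), names(df), value = TRUE)
    if (length(cols) == 0L) stop("read_dea_table: no '", prefix, ":' columns")
    M <- as.matrix(df[cols])
    colnames(M) <- sub(paste0("^", prefix, ":"), "", cols)
    M
  }
  dea_table(df$dmu_id, pick("input"), pick("good"), pick("bad"))
}

#' @rdname read_dea_table
#' @param table A [dea_table()].
#' @export
write_dea_table <- function(table, path) {
  stopifnot(inherits(table, "dea_table"))
  tag <- function(M, p) {
    colnames(M) <- paste0(p, ":", colnames(M))
    M
  }
  df <- data.frame(dmu_id = table$dmu_ids,
                   tag(table$inputs, "input"),
                   tag(table$good_outputs, "good"),
                   tag(table$bad_outputs, "bad"),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# Solve the SBM program for one DMU against a reference set via the
# Charnes-Cooper linearization. Variables: (t, lambda[n], s_in[m],
# s_good[sg], s_bad[sb]), all >= 0. Returns rho, slacks, lambda.
sbm_solve_one <- function(x0, yg0, yb0, Xr, Ygr, Ybr, rts) {
  n <- nrow(Xr)
  m <- length(x0)
  sg <- length(yg0)
  sb <- length(yb0)
  nv <- 1 + n + m + sg + sb
  i_t <- 1L
  i_lam <- 1L + seq_len(n)
  i_sin <- 1L + n + seq_len(m)
  i_sg <- 1L + n + m + seq_len(sg)
  i_sb <- 1L + n + m + sg + seq_len(sb)

  # objective: t - (1/m) sum s_in/x0  (minimize)
  a <- numeric(nv)
  a[i_t] <- 1
  a[i_sin] <- -1 / (m * x0)

  # normalization: t + (1/(sg+sb)) (sum s_g/yg0 + sum s_b/yb0) = 1
  eq <- matrix(0, 1, nv)
  eq[1, i_t] <- 1
  eq[1, i_sg] <- 1 / ((sg + sb) * yg0)
  eq[1, i_sb] <- 1 / ((sg + sb) * yb0)
  rhs <- 1

  # t*x0 = Xr' lambda + s_in  ->  x0*t - Xr' lambda - s_in = 0
  for (i in seq_len(m)) {
    row <- numeric(nv)
    row[i_t] <- x0[i]
    row[i_lam] <- -Xr[, i]
    row[i_sin[i]] <- -1
    eq <- rbind(eq, row)
    rhs <- c(rhs, 0)
  }
  # t*yg0 = Ygr' lambda - s_g
  for (r in seq_len(sg)) {
    row <- numeric(nv)
    row[i_t] <- yg0[r]
    row[i_lam] <- -Ygr[, r]
    row[i_sg[r]] <- 1
    eq <- rbind(eq, row)
    rhs <- c(rhs, 0)
  }
  # t*yb0 = Ybr' lambda + s_b
  for (r in seq_len(sb)) {
    row <- numeric(nv)
    row[i_t] <- yb0[r]
    row[i_lam] <- -Ybr[, r]
    row[i_sb[r]] <- -1
    eq <- rbind(eq, row)
    rhs <- c(rhs, 0)
  }
  # VRS: sum lambda = t
  if (rts == "vrs") {
    row <- numeric(nv)
    row[i_t] <- -1
    row[i_lam] <- 1
    eq <- rbind(eq, row)
    rhs <- c(rhs, 0)
  }
  sol <- solve_lp_eq(a, eq, rhs)
  if (sol$status != "optimal") return(NULL)
  v <- sol$z
  t <- v[i_t]
  if (t <= 0) return(NULL)
  list(rho = sol$value,
       lambda = v[i_lam] / t,
       input_slacks = v[i_sin] / t,
       desirable_slacks = v[i_sg] / t,
       undesirable_slacks = v[i_sb] / t)
}

#' Slacks-based-measure (SBM) eco-efficiency scores
#'
#' Scores every DMU with the non-oriented slacks-based measure with
#' undesirable outputs. For the DMU under evaluation the fractional
#' program
#' \deqn{\rho = \min \frac{1 - \frac{1}{m}\sum_i s^-_i / x_{i0}}
#'   {1 + \frac{1}{s_g + s_b}\left(\sum_r s^g_r / y^g_{r0} +
#'    \sum_r s^b_r / y^b_{r0}\right)}}
#' is solved subject to the observed point being a nonnegative
#' combination of all DMUs plus input excesses \eqn{s^-}, desirable
#' shortfalls \eqn{s^g} and undesirable excesses \eqn{s^b}. The ratio is
#' linearized by the standard Charnes--Cooper transformation and solved
#' as an LP. Scores lie in `(0, 1]`, with `rho = 1` iff all slacks
#' vanish (the DMU is on the efficient frontier); the measure is
#' invariant to the units of every input and output column.
#'
#' @param table A [dea_table()].
#' @param rts Returns to scale: `"crs"` (constant, default) or `"vrs"`
#'   (variable, adds the convexity constraint on the intensity weights).
#' @param tol Slacks below `tol` (relative) are reported as zero and a
#'   score within `tol` of 1 is snapped to 1.
#' @return A data frame with one row per DMU: `dmu_id`, `score`, and
#'   list-columns `input_slacks`, `desirable_slacks`,
#'   `undesirable_slacks`. Infeasible DMUs (not expected for strictly
#'   positive data under constant returns) get `NA` score and a warning.
#' @references Tone, K. (2001) A slacks-based measure of efficiency in
#'   data envelopment analysis. *European Journal of Operational
#'   Research* 130, 498--509.
#' @examples
#' tab <- dea_table(c("a", "b"),
#'                  inputs = rbind(c(1, 2), c(2, 4)),
#'                  good_outputs = rbind(3, 3),
#'                  bad_outputs = rbind(1, 1))
#' sbm_scores(tab)
#' @export
sbm_scores <- function(table, rts = c("crs", "vrs"), tol = 1e-9) {
  stopifnot(inherits(table, "dea_table"))
  rts <- match.arg(rts)
  n <- length(table$dmu_ids)
  scores <- numeric(n)
  sl_in <- vector("list", n)
  sl_g <- vector("list", n)
  sl_b <- vector("list", n)
  for (k in seq_len(n)) {
    res <- sbm_solve_one(table$inputs[k, ], table$good_outputs[k, ],
                         table$bad_outputs[k, ], table$inputs,
                         table$good_outputs, table$bad_outputs, rts)
    if (is.null(res)) {
      warning("sbm_scores: LP infeasible for DMU '", table$dmu_ids[k], "'")
      scores[k] <- NA_real_
      sl_in[[k]] <- sl_g[[k]] <- sl_b[[k]] <- NULL
      next
    }
    zap <- function(s, ref) ifelse(abs(s) < tol * pmax(1, ref), 0, s)
    sl_in[[k]] <- zap(res$input_slacks, table$inputs[k, ])
    sl_g[[k]] <- zap(res$desirable_slacks, table$good_outputs[k, ])
    sl_b[[k]] <- zap(res$undesirable_slacks, table$bad_outputs[k, ])
    rho <- res$rho
    if (rho > 1 - tol) rho <- 1
    scores[k] <- rho
  }
  out <- data.frame(dmu_id = table$dmu_ids, score = scores,
                    stringsAsFactors = FALSE)
  out$input_slacks <- sl_in
  out$desirable_slacks <- sl_g
  out$undesirable_slacks <- sl_b
  out
}

#' Attach eco-efficiency scores to a panel
#'
#' Joins SBM scores onto a panel as the `REE` column, matching each
#' region-year row to the DMU id `"<region>:<year>"`.
#'
#' @param panel A panel data frame (see [read_panel()]).
#' @param scores The data frame returned by [sbm_scores()].
#' @return The panel with an `REE` column in `(0, 1]`.
#' @export
attach_ree <- function(panel, scores) {
  key <- paste(panel$region, panel$year, sep = ":")
  idx <- match(key, scores$dmu_id)
  if (anyNA(idx)) {
    stop("attach_ree: no DMU score for region-year(s): ",
         paste(utils::head(key[is.na(idx)], 5), collapse = ", "))
  }
  panel$REE <- scores$score[idx]
  panel
}
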