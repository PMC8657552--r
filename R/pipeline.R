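#' Read and write regional panel tables
#'
#' Panels are plain CSV, one row per (region, year), UTF-8, `.` decimal
#' separator. `read_panel()` validates the layout: a header, unique
#' (region, year) keys, numeric cells, contiguous years within each
#' region, and strictly positive outcome columns where present.
#'
#' @param path CSV path.
#' @param required Columns that must be present besides `region` and
#'   `year` (default: none).
#' @return A data frame ordered by region then year.
#' @export
read_panel <- function(path, required = character(0)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("read_panel: no rows in ", path)
  need <- c("region", "year", required)
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("read_panel: missing column(s): ", paste(missing, collapse = ", "))
  }
  key <- paste(df$region, df$year, sep = ":")
  if (anyDuplicated(key)) {
    stop("read_panel: duplicated (region, year) key: ",
         key[duplicated(key)][1])
  }
  num_cols <- setdiff(names(df), "region")
  for (v in num_cols) {
    if (!is.numeric(df[[v]])) {
      stop("read_panel: non-numeric cells in column '", v, "'")
    }
    if (anyNA(df[[v]])) {
      stop("read_panel: missing values in column '", v, "' (row ",
           which(is.na(df[[v]]))[1], ")")
    }
  }
  for (r in unique(df$region)) {
    yrs <- sort(df$year[df$region == r])
    if (any(diff(yrs) != 1L)) {
      stop("read_panel: years not contiguous for region '", r, "'")
    }
  }
  df[order(df$region, df$year), , drop = FALSE]
}

#' @rdname read_panel
#' @param table A data frame.
#' @export
write_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Column normalization with exact inverse
#'
#' Transforms the named columns either to `[0, 1]` (`"minmax"`) or to
#' mean 0 / sd 1 (`"zscore"`), keeping the per-column parameters so the
#' identical affine map can be re-applied to new values
#' ([apply_normalizer()]) or inverted exactly
#' ([invert_normalizer()]). A zero-range (or zero-sd) column is mapped
#' to 0 with a warning.
#'
#' @param data A data frame.
#' @param columns Character vector of numeric columns to transform.
#' @param method `"minmax"` or `"zscore"`.
#' @return A list with `data` (transformed copy) and `state` (the
#'   normalizer, class `"normalizer"`).
#' @export
normalize_columns <- function(data, columns, method = c("minmax", "zscore")) {
  method <- match.arg(method)
  missing <- setdiff(columns, names(data))
  if (length(missing)) {
    stop("normalize_columns: unknown column(s): ",
         paste(missing, collapse = ", "))
  }
  state <- list(method = method, params = list())
  out <- data
  for (v in columns) {
    x <- data[[v]]
    if (!is.numeric(x)) stop("normalize_columns: '", v, "' is not numeric")
    if (method == "minmax") {
      lo <- min(x); hi <- max(x)
      if (hi == lo) {
        warning("normalize_columns: zero range in '", v, "'; mapped to 0")
        out[[v]] <- rep(0, length(x))
        state$params[[v]] <- c(shift = lo, scale = 1)
      } else {
        out[[v]] <- (x - lo) / (hi - lo)
        state$params[[v]] <- c(shift = lo, scale = hi - lo)
      }
    } else {
      mu <- mean(x); s <- stats::sd(x)
      if (s == 0) {
        warning("normalize_columns: zero sd in '", v, "'; mapped to 0")
        out[[v]] <- rep(0, length(x))
        state$params[[v]] <- c(shift = mu, scale = 1)
      } else {
        out[[v]] <- (x - mu) / s
        state$params[[v]] <- c(shift = mu, scale = s)
      }
    }
  }
  class(state) <- "normalizer"
  list(data = out, state = state)
}

#' @rdname normalize_columns
#' @param state A `"normalizer"` from [normalize_columns()].
#' @export
apply_normalizer <- function(data, state) {
  stopifnot(inherits(state, "normalizer"))
  for (v in names(state$params)) {
    if (!v %in% names(data)) next
    p <- state$params[[v]]
    data[[v]] <- (data[[v]] - p[["shift"]]) / p[["scale"]]
  }
  data
}

#' @rdname normalize_columns
#' @export
invert_normalizer <- function(data, state) {
  stopifnot(inherits(state, "normalizer"))
  for (v in names(state$params)) {
    if (!v %in% names(data)) next
    p <- state$params[[v]]
    data[[v]] <- data[[v]] * p[["scale"]] + p[["shift"]]
  }
  data
}

#' Run the whole pipeline from panel + DEA table to result CSVs
#'
#' End-to-end orchestration: score eco-efficiency from the DEA table
#' ([sbm_scores()]), attach it to the panel as `REE`
#' ([attach_ree()]), then for each of the three health outcomes run the
#' five-setting model comparison ([compare_models()]) and the
#' four-indicator elasticity analysis ([elasticity_table()]), writing
#' every table to `out_dir` along with a run log recording the seed and
#' the tuned `(sigma, gamma)` per series.
#'
#' @param panel A panel data frame (or a CSV path, read with
#'   [read_panel()]).
#' @param dea A [dea_table()] (or a CSV path, read with
#'   [read_dea_table()]). `NULL` skips the efficiency stage; the panel
#'   must then already carry `REE`.
#' @param out_dir Output directory (created if absent).
#' @param regions Regions to model (default: all in the panel).
#' @param config A [search_config()].
#' @param rts Returns-to-scale for the SBM stage.
#' @param seed Master seed; every stochastic stage derives its stream
#'   from it, so two runs with the same inputs and seed write
#'   byte-identical files.
#' @return Invisibly, a list with the REE scores, comparison tables and
#'   elasticity tables.
#' @export
run_pipeline <- function(panel, dea = NULL, out_dir, regions = NULL,
                         config = search_config(), rts = "crs", seed = 1L) {
  if (is.character(panel)) panel <- read_panel(panel, required = outcome_vars)
  if (is.character(dea)) dea <- read_dea_table(dea)
  need <- c(outcome_vars, climate_vars, control_vars)
  missing <- setdiff(need, names(panel))
  if (length(missing)) {
    stop("run_pipeline: panel lacks column(s): ",
         paste(missing, collapse = ", "))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("seed: %d", seed))

  scores <- NULL
  if (!is.null(dea)) {
    scores <- sbm_scores(dea, rts = rts)
    write_table(scores[c("dmu_id", "score")],
                file.path(out_dir, "ree_scores.csv"))
    panel <- attach_ree(panel, scores)
    log_lines <- c(log_lines, sprintf("sbm: %d DMUs scored (rts=%s)",
                                      nrow(scores), rts))
  } else if (!"REE" %in% names(panel)) {
    stop("run_pipeline: no DEA table and no REE column in the panel")
  }
  if (is.null(regions)) regions <- unique(panel$region)

  comparisons <- list()
  elasticities <- list()
  for (oc in outcome_vars) {
    cmp <- compare_models(panel, oc, regions, config, seed = seed)
    write_table(cmp$summary, file.path(out_dir,
                                       paste0("comparison_", oc, ".csv")))
    write_table(cmp$detail, file.path(out_dir,
                                      paste0("comparison_", oc,
                                             "_detail.csv")))
    el <- elasticity_table(panel, oc, regions, config, seed = seed + 10000L)
    write_table(el, file.path(out_dir, paste0("elasticity_", oc, ".csv")))
    comparisons[[oc]] <- cmp
    elasticities[[oc]] <- el
    log_lines <- c(log_lines,
                   sprintf("%s: compared %d settings over %d regions; %d elasticity rows",
                           oc, nrow(cmp$summary), length(regions), nrow(el)))
  }
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(list(panel = panel, scores = scores, comparisons = comparisons,
                 elasticities = elasticities))
}
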