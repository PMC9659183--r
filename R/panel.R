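#' Construct a DMU panel
#'
#' A DMU panel is a tibble with one row per decision-making unit and period,
#' carrying strictly positive input and output quantities and (optionally)
#' environmental covariates. The roles of the columns are recorded as
#' attributes so that downstream stages never have to guess which column is
#' which. The motivating application is a province-by-year panel of basic
#' medical insurance operations: three inputs (fund income, health
#' technicians, government health expenditure), three outputs (fund
#' expenditure, epidemic morbidity rate, resident health insurance
#' expenditure) and three environmental covariates (GDP per capita, social
#' security and employment expenditure, fiscal revenue/expenditure ratio).
#'
#' @param data A data frame with one row per unit-period.
#' @param inputs,outputs,env Character vectors naming the input, output and
#'   environmental columns of `data`. `env` may be empty.
#' @param unit,period Names of the unit-label and period-label columns.
#' @return A `dmu_panel`: a tibble with columns `unit`, `period`, then the
#'   input, output and env columns, and attributes `input_cols`,
#'   `output_cols`, `env_cols`.
#' @examples
#' d <- data.frame(unit = c("a", "b"), period = 1,
#'                 x = c(2, 4), y = c(2, 2), z = c(0.3, 0.6))
#' dmu_panel(d, inputs = "x", outputs = "y", env = "z")
#' @export
dmu_panel <- function(data, inputs, outputs, env = character(),
                      unit = "unit", period = "period") {
  data <- tibble::as_tibble(data)
  needed <- c(unit, period, inputs, outputs, env)
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols))
    stop("panel schema error: missing column(s) ",
         paste0("'", missing_cols, "'", collapse = ", "), call. = FALSE)
  out <- data[needed]
  names(out)[1:2] <- c("unit", "period")
  out$unit <- as.character(out$unit)
  out$period <- as.character(out$period)

  for (v in c(inputs, outputs, env)) {
    if (!is.numeric(out[[v]]))
      stop("panel schema error: column '", v, "' is not numeric", call. = FALSE)
    if (anyNA(out[[v]])) {
      i <- which(is.na(out[[v]]))[1L]
      stop("panel validation error: missing value in '", v, "' for unit '",
           out$unit[i], "', period '", out$period[i], "'", call. = FALSE)
    }
  }
  for (v in c(inputs, outputs)) {
    bad <- which(out[[v]] <= 0)
    if (length(bad))
      stop("panel validation error: non-positive value of '", v,
           "' for unit '", out$unit[bad[1L]], "', period '",
           out$period[bad[1L]], "'", call. = FALSE)
  }
  key <- paste(out$unit, out$period, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1L]
    stop("panel validation error: duplicate (unit, period) pair: ",
         gsub("\r", ", ", d), call. = FALSE)
  }

  structure(out,
            input_cols = inputs, output_cols = outputs, env_cols = env,
            class = c("dmu_panel", class(out)))
}

#' @export
print.dmu_panel <- function(x, ...) {
  cat("# A DMU panel: ", length(unique(x$unit)), " units x ",
      length(unique(x$period)), " periods\n", sep = "")
  cat("#   inputs:  ", paste(attr(x, "input_cols"), collapse = ", "), "\n",
      "#   outputs: ", paste(attr(x, "output_cols"), collapse = ", "), "\n",
      sep = "")
  if (length(attr(x, "env_cols")))
    cat("#   env:     ", paste(attr(x, "env_cols"), collapse = ", "), "\n",
        sep = "")
  NextMethod()
  invisible(x)
}

input_cols <- function(panel) attr(panel, "input_cols")
output_cols <- function(panel) attr(panel, "output_cols")
env_cols <- function(panel) attr(panel, "env_cols")

# rebuild a dmu_panel after dplyr operations stripped attributes
as_dmu_panel_like <- function(data, template) {
  dmu_panel(data,
            inputs = input_cols(template),
            outputs = output_cols(template),
            env = env_cols(template))
}

#' Read a DMU panel from delimited files
#'
#' Reads a comma-separated UTF-8 file with a header row, one row per
#' unit-period, and builds a [dmu_panel()]. Environmental covariates may sit
#' in the same file or in a companion file (columns `unit`, `period`, then
#' the covariates) which is joined on the unit and period labels.
#'
#' @param path Path to the panel CSV.
#' @param inputs,outputs,env Column names, as in [dmu_panel()].
#' @param env_path Optional path to a separate env CSV.
#' @param unit,period Key column names (in both files).
#' @return A [dmu_panel()].
#' @export
read_panel <- function(path, inputs, outputs, env = character(),
                       env_path = NULL, unit = "unit", period = "period") {
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(env_path)) {
    envd <- readr::read_csv(env_path, show_col_types = FALSE, progress = FALSE)
    for (k in c(unit, period))
      if (!k %in% names(envd))
        stop("panel schema error: missing column '", k, "' in env file",
             call. = FALSE)
    envd[[unit]] <- as.character(envd[[unit]])
    envd[[period]] <- as.character(envd[[period]])
    data[[unit]] <- as.character(data[[unit]])
    data[[period]] <- as.character(data[[period]])
    data <- dplyr::left_join(data, envd, by = c(unit, period))
  }
  dmu_panel(data, inputs = inputs, outputs = outputs, env = env,
            unit = unit, period = period)
}

#' Write a DMU panel to delimited files
#'
#' The inverse of [read_panel()]: writes `unit`, `period` and the
#' input/output columns to `path`; if `env_path` is given the environmental
#' covariates go there (with the same key columns), otherwise they stay in
#' the main file.
#'
#' @param panel A [dmu_panel()].
#' @param path Output CSV path.
#' @param env_path Optional separate CSV path for the env covariates.
#' @return `panel`, invisibly.
#' @export
write_panel <- function(panel, path, env_path = NULL) {
  ecols <- env_cols(panel)
  if (!is.null(env_path) && length(ecols)) {
    readr::write_csv(panel[c("unit", "period", input_cols(panel),
                             output_cols(panel))], path, progress = FALSE)
    readr::write_csv(panel[c("unit", "period", ecols)], env_path,
                     progress = FALSE)
  } else {
    readr::write_csv(as.data.frame(panel), path, progress = FALSE)
  }
  invisible(panel)
}

#' Descriptive statistics for every panel variable
#'
#' Mean, sample standard deviation (n - 1 denominator), minimum and maximum
#' for each input, output and environmental variable, over all unit-period
#' records.
#'
#' @param panel A [dmu_panel()].
#' @return A tibble with columns `variable`, `role`, `mean`, `sd`, `min`,
#'   `max`.
#' @export
describe_panel <- function(panel) {
  if (!nrow(panel)) stop("describe_panel(): empty panel", call. = FALSE)
  roles <- c(stats::setNames(rep("input", length(input_cols(panel))),
                             input_cols(panel)),
             stats::setNames(rep("output", length(output_cols(panel))),
                             output_cols(panel)),
             stats::setNames(rep("env", length(env_cols(panel))),
                             env_cols(panel)))
  purrr::map_dfr(names(roles), function(v) {
    x <- panel[[v]]
    tibble::tibble(variable = v, role = roles[[v]], mean = mean(x),
                   sd = stats::sd(x), min = min(x), max = max(x))
  })
}

#' Pearson correlation screen of inputs against outputs
#'
#' Pairwise Pearson correlations with two-sided p-values over the input and
#' output variables only (environmental covariates are excluded, as is usual
#' before an efficiency analysis: the screen justifies that the chosen
#' outputs respond to the chosen inputs). Flags use the conventional star
#' levels: `***` for p < 0.01, `**` for p < 0.05.
#'
#' The screen is advisory: if no input-output pair reaches |r| >= 0.2 a
#' warning is emitted, but nothing is rejected.
#'
#' @param panel A [dmu_panel()] with at least 3 records.
#' @return A tibble with columns `var1`, `var2`, `r`, `p`, `sig`, carrying
#'   the full correlation matrix as attribute `r_matrix`. Zero-variance
#'   variables yield `NA` correlations (with a warning), never 0.
#' @export
pearson_screen <- function(panel) {
  vars <- c(input_cols(panel), output_cols(panel))
  if (nrow(panel) < 3)
    stop("pearson_screen(): need at least 3 records", call. = FALSE)
  X <- as.data.frame(panel)[vars]
  degenerate <- vars[vapply(X, function(v) stats::sd(v) == 0, logical(1))]
  if (length(degenerate))
    warning("pearson_screen(): zero variance in ",
            paste(degenerate, collapse = ", "),
            "; correlations reported as NA", call. = FALSE)
  k <- length(vars)
  rmat <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  diag(rmat) <- 1
  rows <- list()
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (j > i) {
      ok <- !(vars[i] %in% degenerate || vars[j] %in% degenerate)
      if (ok) {
        ct <- stats::cor.test(X[[i]], X[[j]], method = "pearson",
                              alternative = "two.sided")
        r <- unname(ct$estimate)
        p <- ct$p.value
      } else {
        r <- NA_real_
        p <- NA_real_
      }
      rmat[i, j] <- r
      rmat[j, i] <- r
      rows[[length(rows) + 1L]] <- tibble::tibble(
        var1 = vars[i], var2 = vars[j], r = r, p = p,
        sig = if (is.na(p)) NA_character_
              else if (p < 0.01) "***" else if (p < 0.05) "**" else "")
    }
  }
  out <- dplyr::bind_rows(rows)
  io <- out[(out$var1 %in% input_cols(panel)) !=
              (out$var2 %in% input_cols(panel)), ]
  if (nrow(io) && all(is.na(io$r) | abs(io$r) < 0.2))
    warning("pearson_screen(): no input-output pair reaches |r| >= 0.2; ",
            "the indicator system may be weakly coupled", call. = FALSE)
  attr(out, "r_matrix") <- rmat
  class(out) <- c("correlation_screen", class(out))
  out
}
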