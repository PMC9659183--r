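#' Published province-level efficiency tables
#'
#' Packaged copies of the published stage-1 efficiency table (31 Chinese
#' provinces, 2017-2020, plus the per-province 4-year means derivable from
#' it) and the stage-1 versus stage-3 TE/PTE/SE comparison table for the
#' basic-medical-insurance application. These are verbatim printed values,
#' shipped so that aggregation conventions (grand means, frontier counts,
#' the TE = PTE x SE decomposition) can be exercised against real published
#' numbers without the undeposited yearbook microdata.
#'
#' Two provinces romanize identically in the source ("Shanxi"); the second
#' occurrence (after Tibet) is relabelled `Shaanxi` so unit labels are
#' unique.
#'
#' @return A list with two tibbles:
#' \describe{
#'   \item{stage1}{columns `province`, `y2017` .. `y2020`, `mean` (the
#'     recomputed 4-year mean).}
#'   \item{comparison}{columns `province`, `te_stage1`, `pte_stage1`,
#'     `se_stage1`, `te_stage3`, `pte_stage3`, `se_stage3`.}
#' }
#' @examples
#' fx <- printed_fixtures()
#' fx$stage1[fx$stage1$province == "Henan", ]
#' @export
printed_fixtures <- function() {
  s1 <- readr::read_csv(
    system.file("extdata", "bmi_stage1_efficiency.csv", package = "tsdea",
                mustWork = TRUE),
    show_col_types = FALSE, progress = FALSE)
  s1$mean <- rowMeans(s1[paste0("y", 2017:2020)])
  cmp <- readr::read_csv(
    system.file("extdata", "bmi_stage_comparison.csv", package = "tsdea",
                mustWork = TRUE),
    show_col_types = FALSE, progress = FALSE)
  list(stage1 = s1, comparison = cmp)
}

#' Aggregate an efficiency table
#'
#' Summarises a long table of per-unit, per-period efficiency scores the way
#' cross-province efficiency studies report them: the grand mean, per-period
#' means, per-unit across-period means, the count of frontier units, and the
#' worst unit. A unit is counted "on the frontier" when its across-period
#' mean score equals 1 at `digits` decimal places (the convention used when
#' papers report "n regions in the efficiency frontier" from a table of
#' rounded means), not when any single period hits 1.
#'
#' @param scores A data frame with unit, period and score columns.
#' @param te Name of the score column. Default `"TE"`.
#' @param unit,period Names of the unit and period columns.
#' @param digits Rounding used for frontier membership. Default 3.
#' @return A list: `grand_mean`, `period_means` (tibble), `unit_means`
#'   (tibble), `frontier_count`, `frontier_units`, `min_unit`, `min_mean`.
#' @examples
#' fx <- printed_fixtures()
#' long <- tidyr::pivot_longer(fx$stage1, dplyr::starts_with("y"),
#'                             names_to = "period", values_to = "TE")
#' efficiency_summary(long, unit = "province")$grand_mean
#' @export
efficiency_summary <- function(scores, te = "TE", unit = "unit",
                               period = "period", digits = 3) {
  stopifnot(all(c(te, unit, period) %in% names(scores)))
  scores <- tibble::as_tibble(scores)
  grand <- mean(scores[[te]])
  pm <- scores |>
    dplyr::group_by(period = .data[[period]]) |>
    dplyr::summarise(mean = mean(.data[[te]]), .groups = "drop")
  um <- scores |>
    dplyr::group_by(unit = .data[[unit]]) |>
    dplyr::summarise(mean = mean(.data[[te]]), .groups = "drop")
  frontier <- um$unit[round(um$mean, digits) >= 1]
  worst <- which.min(um$mean)
  list(grand_mean = grand,
       period_means = pm,
       unit_means = um,
       frontier_count = length(frontier),
       frontier_units = frontier,
       min_unit = um$unit[worst],
       min_mean = um$mean[worst])
}
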