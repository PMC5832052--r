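#' Compare one parameter between survivors and nonsurvivors
#'
#' Summarises a cohort parameter per outcome group (mean ± SD) and applies a
#' two-sided test. The automatic policy uses Welch's t-test when both groups
#' pass a Shapiro–Wilk normality screen at 0.05 and the Mann–Whitney test
#' otherwise; categorical parameters (e.g. gender) use the chi-squared test
#' on the 2 × 2 contingency table, without continuity correction by default.
#'
#' @param records A data frame with an `outcome` column
#'   (`survivor`/`nonsurvivor`) and the parameter column.
#' @param parameter Column name to compare.
#' @param test `"auto"` (default policy above), `"t"`, `"mann_whitney"`, or
#'   `"chi2"`.
#' @param normality_alpha Shapiro screen level for the auto policy.
#' @param correct Continuity correction for the chi-squared test (default
#'   FALSE).
#' @return A one-row tibble: `parameter`, group sizes, group `mean`/`sd` (or
#'   category counts for chi-squared), `test_used`, `statistic`, `p_value`.
#' @export
compare_groups <- function(records, parameter,
                           test = c("auto", "t", "mann_whitney", "chi2"),
                           normality_alpha = 0.05, correct = FALSE) {
  test <- match.arg(test)
  stopifnot("outcome" %in% names(records))
  if (!parameter %in% names(records)) {
    stop("parameter '", parameter, "' not found in the cohort records",
         call. = FALSE)
  }
  x <- records[[parameter]]
  grp <- records$outcome
  keep <- !is.na(x) & !is.na(grp)
  x <- x[keep]; grp <- grp[keep]
  if (length(x) == 0) stop("parameter '", parameter, "' is all-missing",
                           call. = FALSE)
  gs <- x[grp == "survivor"]
  gn <- x[grp == "nonsurvivor"]
  if (length(gs) == 0 || length(gn) == 0) {
    stop("both outcome groups must be nonempty", call. = FALSE)
  }
  is_cat <- is.character(x) || is.factor(x) || is.logical(x)
  if (test == "chi2" || (test == "auto" && is_cat)) {
    tab <- table(factor(grp, levels = c("survivor", "nonsurvivor")), x)
    ht <- stats::chisq.test(tab, correct = correct)
    return(tibble(
      parameter = parameter,
      n_survivor = length(gs), n_nonsurvivor = length(gn),
      summary_survivor = paste(table(gs), collapse = " : "),
      summary_nonsurvivor = paste(table(gn), collapse = " : "),
      mean_survivor = NA_real_, sd_survivor = NA_real_,
      mean_nonsurvivor = NA_real_, sd_nonsurvivor = NA_real_,
      test_used = "chi2", statistic = unname(ht$statistic),
      p_value = ht$p.value))
  }
  if (is_cat) stop("continuous test requested on a categorical parameter",
                   call. = FALSE)
  if (test == "auto") {
    normal <- function(v) {
      length(v) >= 3 && stats::sd(v) > 0 &&
        stats::shapiro.test(v)$p.value > normality_alpha
    }
    test <- if (normal(gs) && normal(gn)) "t" else "mann_whitney"
  }
  if (test == "t" && stats::sd(gs) == 0 && stats::sd(gn) == 0) {
    stop("zero variance in both groups: t-test undefined", call. = FALSE)
  }
  ht <- if (test == "t") {
    stats::t.test(gs, gn, var.equal = FALSE)
  } else {
    stats::wilcox.test(gs, gn, exact = FALSE, correct = FALSE)
  }
  fmt <- function(v) sprintf("%.2f ± %.2f", mean(v), stats::sd(v))
  tibble(
    parameter = parameter,
    n_survivor = length(gs), n_nonsurvivor = length(gn),
    summary_survivor = fmt(gs), summary_nonsurvivor = fmt(gn),
    mean_survivor = mean(gs), sd_survivor = stats::sd(gs),
    mean_nonsurvivor = mean(gn), sd_nonsurvivor = stats::sd(gn),
    test_used = test, statistic = unname(ht$statistic),
    p_value = ht$p.value)
}

#' Group-comparison table over several parameters
#'
#' One [compare_groups()] row per parameter, in the given order — the layout
#' of a survivors-versus-nonsurvivors comparison table (parameter, group
#' mean ± SD, P value).
#'
#' @inheritParams compare_groups
#' @param parameters Character vector of column names.
#' @param ... Passed to [compare_groups()].
#' @return A tibble with one row per parameter.
#' @export
cohort_table <- function(records, parameters, ...) {
  stopifnot(length(parameters) >= 1)
  purrr::map_dfr(parameters, function(p) compare_groups(records, p, ...))
}

#' Write a cohort comparison table to CSV
#'
#' @param table A tibble from [cohort_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Scatter plot of the prognostic ratio by outcome
#'
#' Dot plot of the ratio of injured lung volume fraction for survivors and
#' nonsurvivors, with optional reference lines (the all-survive / none-survive
#' bands reported at 0.8 and 0.3).
#'
#' @param records Cohort data with `outcome` and `ratio` columns.
#' @param ref_lines Numeric ratio reference levels (default `c(0.3, 0.8)`).
#' @return A ggplot object.
#' @export
plot_ratio_scatter <- function(records, ref_lines = c(0.3, 0.8)) {
  ggplot2::ggplot(records,
                  ggplot2::aes(x = .data$outcome, y = .data$ratio)) +
    ggplot2::geom_jitter(width = 0.1, height = 0, alpha = 0.7) +
    ggplot2::geom_hline(yintercept = ref_lines, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "ratio of injured lung volume fraction") +
    ggplot2::theme_minimal()
}
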