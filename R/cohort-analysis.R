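#' Signed percent change between two positive values
#'
#' `100 * (later - earlier) / earlier`; negative for a decrease, positive
#' for an increase. Vectorised. Reporting layers round half away from zero
#' to integer percent; full precision is returned here.
#'
#' @param earlier,later Positive numeric vectors (recycled).
#' @return Signed percent change(s), full precision.
#' @examples
#' percent_change(0.73, 0.63)  # -13.7
#' @export
percent_change <- function(earlier, later) {
  if (any(!is.finite(earlier)) || any(earlier <= 0)) {
    abort("'earlier' values must be finite and > 0",
          class = "iosmodel_invalid_input")
  }
  100 * (later - earlier) / earlier
}

new_test_report <- function(comparison, statistic, df, p, flag = NA_character_) {
  tibble::tibble(comparison = comparison, statistic = statistic, df = df,
                 p_value = p, significant = !is.na(p) & p < 0.05, flag = flag)
}

#' Paired t-test on before/after measurements
#'
#' Classic paired Student's t on the within-subject differences
#' (`after - before`), two-sided p from the t distribution with `n - 1`
#' degrees of freedom. Identical lists give `t = 0, p = 1`. Zero-variance
#' differences with a nonzero mean have an infinite statistic; the limiting
#' `p = 0` is reported with a `"zero_variance"` flag rather than an error.
#'
#' @param before,after Equal-length numeric vectors (n >= 2), paired by
#'   subject.
#' @param comparison Label carried into the report row.
#' @return A one-row tibble: `comparison`, `statistic`, `df`, `p_value`,
#'   `significant` (at alpha = 0.05), `flag`.
#' @export
paired_t <- function(before, after, comparison = "paired") {
  n <- length(before)
  if (length(after) != n) abort("before/after must have equal length",
                                class = "iosmodel_invalid_input")
  if (n < 2) abort("paired t-test needs at least 2 pairs",
                   class = "iosmodel_insufficient_data")
  d <- after - before
  if (sd(d) == 0) {
    if (mean(d) == 0) return(new_test_report(comparison, 0, n - 1, 1))
    return(new_test_report(comparison, sign(mean(d)) * Inf, n - 1, 0,
                           flag = "zero_variance"))
  }
  tt <- t.test(after, before, paired = TRUE)
  new_test_report(comparison, unname(tt$statistic), unname(tt$parameter),
                  tt$p.value)
}

#' Welch two-sample t-test
#'
#' Between-group comparison for unequal group sizes and variances (Welch
#' statistic with Welch-Satterthwaite degrees of freedom). Used for
#' comparisons between independent groups, where a paired test is
#' impossible.
#'
#' @param group_a,group_b Numeric vectors, each n >= 2.
#' @param comparison Label carried into the report row.
#' @return A one-row tibble as in [paired_t()].
#' @export
two_sample_t <- function(group_a, group_b, comparison = "two-sample") {
  if (length(group_a) < 2 || length(group_b) < 2) {
    abort("each group needs at least 2 observations",
          class = "iosmodel_insufficient_data")
  }
  if (sd(group_a) == 0 && sd(group_b) == 0) {
    if (mean(group_a) == mean(group_b)) {
      return(new_test_report(comparison, 0,
                             length(group_a) + length(group_b) - 2, 1))
    }
    return(new_test_report(comparison,
                           sign(mean(group_a) - mean(group_b)) * Inf,
                           length(group_a) + length(group_b) - 2, 0,
                           flag = "zero_variance"))
  }
  tt <- t.test(group_a, group_b, var.equal = FALSE)
  new_test_report(comparison, unname(tt$statistic), unname(tt$parameter),
                  tt$p.value)
}

#' Ordinary least-squares line and Pearson correlation
#'
#' @param x,y Numeric vectors of equal length, n >= 2; `x` must not be
#'   constant.
#' @return A one-row tibble: `slope`, `intercept`, `r`, `r_squared`, `n`.
#' @export
linear_fit <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length",
                                    class = "iosmodel_invalid_input")
  if (length(x) < 2) abort("linear fit needs at least 2 points",
                           class = "iosmodel_insufficient_data")
  if (sd(x) == 0) abort("x is constant; fit is degenerate",
                        class = "iosmodel_degenerate_fit")
  fit <- lm(y ~ x)
  r <- if (sd(y) == 0) 0 else unname(cor(x, y))
  tibble::tibble(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r = r, r_squared = r^2, n = length(x))
}

#' Compute per-record IOS indices for a cohort
#'
#' @param cohort An `ios_cohort` tibble from [generate_cohort()] or
#'   [read_spectra()].
#' @return The cohort keys plus one column per index (`r5`, `r20`, `fdr`,
#'   `x5`, `fres`, `ax`).
#' @export
cohort_indices <- function(cohort) {
  keys <- dplyr::select(tibble::as_tibble(cohort),
                        "subject_id", "group", "visit", "condition")
  dplyr::bind_cols(keys, purrr::map_dfr(cohort$spectrum, compute_indices))
}

#' Fit an equivalent-circuit model to every record of a cohort
#'
#' @inheritParams cohort_indices
#' @param model `"eric"` or `"aric"`.
#' @param options A [fit_options()]; defaults to `fit_options(model)`.
#' @return The cohort keys plus fitted parameter columns, `objective` and
#'   `converged`.
#' @export
fit_cohort <- function(cohort, model = c("eric", "aric"), options = NULL) {
  model <- match.arg(model)
  if (is.null(options)) options <- fit_options(model)
  keys <- dplyr::select(tibble::as_tibble(cohort),
                        "subject_id", "group", "visit", "condition")
  fits <- purrr::map_dfr(cohort$spectrum, function(s) {
    f <- fit_model(s, options = options)
    out <- tibble::as_tibble(as.list(f$parameters))
    out$objective <- f$objective
    out$converged <- f$converged
    out
  })
  dplyr::bind_cols(keys, model = model, fits)
}

#' Cell means of indices and fitted parameters
#'
#' Arithmetic means per (group, visit, condition) cell of the IOS indices
#' and (optionally) fitted model parameters, with the per-cell n. Cells in
#' which an index is undefined for some record keep `NA` with an explicit
#' `n_missing` count rather than being silently dropped.
#'
#' @param indices Output of [cohort_indices()].
#' @param fits Optional output of [fit_cohort()] (one model) or a
#'   row-bound combination of several models.
#' @return A tibble with one row per (group, visit, condition) cell (and
#'   per model when `fits` is supplied), columns `n`, mean indices and mean
#'   parameters.
#' @export
summarize_cohort <- function(indices, fits = NULL) {
  if (nrow(indices) == 0) abort("empty dataset", class = "iosmodel_invalid_input")
  idx <- indices |>
    dplyr::group_by(.data$group, .data$visit, .data$condition) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_missing_ax = sum(is.na(.data$ax)),
      dplyr::across(c("r5", "r20", "fdr", "x5", "fres", "ax"),
                    ~ mean(.x, na.rm = TRUE)),
      .groups = "drop")
  if (is.null(fits)) return(idx)
  par_cols <- intersect(c("Rc", "I", "Rp", "Cp", "Ce", "objective"), names(fits))
  fit_means <- fits |>
    dplyr::group_by(.data$model, .data$group, .data$visit, .data$condition) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(par_cols), mean),
                     .groups = "drop")
  dplyr::left_join(fit_means, idx, by = c("group", "visit", "condition"))
}

# the three study cells in visit order
cell_levels <- function() c("2006 preB", "2008 preB", "2008 postB")

#' Growth and bronchodilator percent changes from cell means
#'
#' Computes, per group and variable, the percent change of the cell means
#' from first-visit pre-bronchodilator to second-visit pre-bronchodilator
#' ("growth") and from second-visit pre- to post-bronchodilator
#' ("bronchodilator"). Changes are computed on cell means, not as means of
#' per-subject changes, and reported both at full precision and rounded
#' half-away-from-zero to integer percent.
#'
#' @param means A tibble with columns `group`, `visit`, `condition`,
#'   `parameter`, `value` — one mean per study cell and variable (e.g. from
#'   [load_fixture()] or a pivoted [summarize_cohort()] output).
#' @return A tibble: `group`, `parameter`, `effect`
#'   (`"growth"`/`"bronchodilator"`), `percent`, `percent_rounded`.
#' @export
percent_change_report <- function(means) {
  need <- c("group", "visit", "condition", "parameter", "value")
  if (!all(need %in% names(means))) {
    abort(paste("means must have columns", paste(need, collapse = ", ")),
          class = "iosmodel_invalid_input")
  }
  wide <- means |>
    dplyr::mutate(cell = paste(.data$visit, .data$condition)) |>
    dplyr::select("group", "parameter", "cell", "value") |>
    tidyr::pivot_wider(names_from = "cell", values_from = "value")
  for (cell in cell_levels()) {
    if (!cell %in% names(wide)) {
      abort(sprintf("means are missing the '%s' cell", cell),
            class = "iosmodel_invalid_input")
    }
  }
  wide |>
    dplyr::mutate(
      growth = percent_change(.data[["2006 preB"]], .data[["2008 preB"]]),
      bronchodilator = percent_change(.data[["2008 preB"]], .data[["2008 postB"]])) |>
    dplyr::select("group", "parameter", "growth", "bronchodilator") |>
    tidyr::pivot_longer(c("growth", "bronchodilator"),
                        names_to = "effect", values_to = "percent") |>
    dplyr::mutate(percent_rounded = round_half_away(.data$percent))
}

#' Full cohort study report
#'
#' Composes the whole statistical surface of a longitudinal bronchodilator
#' study on one cohort: cell means of indices and fitted parameters, the
#' growth/bronchodilator percent-change table, within-group paired t-tests
#' (growth: first vs second visit pre-bronchodilator; bronchodilator:
#' second-visit pre vs post), between-group Welch t-tests (impaired vs
#' healthy at each study cell) and pooled correlations (compliance vs
#' reactance area, peripheral resistance vs fdR, and between-model
#' parameter agreement). No multiple-testing correction is applied; rows
#' carry raw p-values with an alpha = 0.05 flag.
#'
#' @inheritParams cohort_indices
#' @param models Which circuit models to fit, subset of
#'   `c("eric", "aric")`.
#' @param fit_opts Optional named list of [fit_options()] per model.
#' @return A list of class `ios_report` with tibbles `summary`,
#'   `percent_change`, `paired_tests`, `group_tests`, `correlations`, plus
#'   the intermediate `indices` and `fits` tables.
#' @export
study_report <- function(cohort, models = c("eric", "aric"), fit_opts = NULL) {
  if (nrow(cohort) == 0) abort("empty dataset", class = "iosmodel_invalid_input")
  models <- match.arg(models, several.ok = TRUE)
  indices <- cohort_indices(cohort)
  fits <- purrr::map_dfr(models, function(m) {
    fit_cohort(cohort, m, options = fit_opts[[m]] %||% fit_options(m))
  })
  summary <- summarize_cohort(indices, fits)

  long_idx <- indices |>
    tidyr::pivot_longer(c("r5", "fdr", "ax"), names_to = "parameter",
                        values_to = "value") |>
    dplyr::select("subject_id", "group", "visit", "condition", "parameter", "value")
  long_fit <- fits |>
    tidyr::pivot_longer(dplyr::any_of(c("Rp", "Cp")), names_to = "par",
                        values_to = "value") |>
    dplyr::mutate(parameter = paste(.data$model, .data$par, sep = "_")) |>
    dplyr::select("subject_id", "group", "visit", "condition", "parameter", "value")
  long <- dplyr::bind_rows(long_idx, long_fit)

  means <- long |>
    dplyr::group_by(.data$group, .data$visit, .data$condition, .data$parameter) |>
    dplyr::summarise(value = mean(.data$value, na.rm = TRUE), .groups = "drop")
  pct <- percent_change_report(means)

  paired_tests <- purrr::map_dfr(
    dplyr::distinct(long, .data$group, .data$parameter) |> purrr::transpose(),
    function(cell) {
      sub <- dplyr::filter(long, .data$group == cell$group,
                           .data$parameter == cell$parameter)
      wide <- sub |>
        dplyr::mutate(cell = paste(.data$visit, .data$condition)) |>
        dplyr::select("subject_id", "cell", "value") |>
        tidyr::pivot_wider(names_from = "cell", values_from = "value") |>
        tidyr::drop_na()
      dplyr::bind_rows(
        paired_t(wide[["2006 preB"]], wide[["2008 preB"]],
                 sprintf("%s %s growth (2006 preB vs 2008 preB)",
                         cell$group, cell$parameter)),
        paired_t(wide[["2008 preB"]], wide[["2008 postB"]],
                 sprintf("%s %s bronchodilator (2008 preB vs 2008 postB)",
                         cell$group, cell$parameter)))
    })

  group_tests <- purrr::map_dfr(
    dplyr::distinct(long, .data$visit, .data$condition, .data$parameter) |>
      purrr::transpose(),
    function(cell) {
      sub <- dplyr::filter(long, .data$visit == cell$visit,
                           .data$condition == cell$condition,
                           .data$parameter == cell$parameter) |>
        tidyr::drop_na("value")
      two_sample_t(sub$value[sub$group == "SAI"], sub$value[sub$group == "H"],
                   sprintf("SAI vs H %s %s %s", cell$parameter,
                           cell$visit, cell$condition))
    })

  correlations <- report_correlations(indices, fits, models)

  structure(list(summary = summary, percent_change = pct,
                 paired_tests = paired_tests, group_tests = group_tests,
                 correlations = correlations,
                 indices = indices, fits = fits),
            class = "ios_report")
}

# pooled over all visit-conditions, as study scatter plots conventionally are
report_correlations <- function(indices, fits, models) {
  keyed <- dplyr::left_join(
    indices,
    fits |>
      dplyr::select("subject_id", "visit", "condition", "model",
                    dplyr::any_of(c("Rp", "Cp"))) |>
      tidyr::pivot_wider(names_from = "model",
                         values_from = dplyr::any_of(c("Rp", "Cp")),
                         names_glue = "{model}_{.value}"),
    by = c("subject_id", "visit", "condition"))
  rows <- list()
  for (m in models) {
    cp <- keyed[[paste0(m, "_Cp")]]
    rp <- keyed[[paste0(m, "_Rp")]]
    ok <- !is.na(keyed$ax) & !is.na(cp)
    rows[[paste0(m, "_cp_vs_ax")]] <-
      dplyr::mutate(linear_fit(keyed$ax[ok], cp[ok]),
                    comparison = paste(m, "Cp vs AX"))
    rows[[paste0(m, "_rp_vs_fdr")]] <-
      dplyr::mutate(linear_fit(keyed$fdr, rp),
                    comparison = paste(m, "Rp vs fdR"))
  }
  if (all(c("eric", "aric") %in% models)) {
    rows$cp_agreement <- dplyr::mutate(
      linear_fit(keyed$eric_Cp, keyed$aric_Cp),
      comparison = "aric Cp vs eric Cp")
    rows$rp_agreement <- dplyr::mutate(
      linear_fit(keyed$eric_Rp, keyed$aric_Rp),
      comparison = "aric Rp vs eric Rp")
  }
  dplyr::bind_rows(rows) |>
    dplyr::select("comparison", dplyr::everything())
}

#' @export
print.ios_report <- function(x, ...) {
  cat("IOS cohort study report\n")
  cat("  records:", nrow(x$indices), "\n")
  cat("  cells:\n")
  print(x$summary, n = Inf)
  cat("  percent changes (cell means):\n")
  print(x$percent_change, n = Inf)
  invisible(x)
}

#' Write the tables of a study report to a directory
#'
#' Writes `summary.csv`, `percent_change.csv`, `paired_tests.csv`,
#' `group_tests.csv`, `correlations.csv`, `indices.csv` and `fits.csv`
#' with deterministic content for a given report.
#'
#' @param report An `ios_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "ios_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("summary", "percent_change", "paired_tests", "group_tests",
               "correlations", "indices", "fits")) {
    readr::write_csv(report[[nm]], file.path(dir, paste0(nm, ".csv")))
  }
  invisible(dir)
}
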