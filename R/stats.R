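#' Remove extreme values by interquartile-range fences
#'
#' Values below `Q1 - k * IQR` or above `Q3 + k * IQR` are removed, with
#' quartiles computed by linear interpolation between order statistics
#' (`quantile()` type 7). The order of kept values is preserved. Fewer than 4
#' values pass through unchanged with a warning.
#'
#' @param values numeric vector.
#' @param k fence multiplier (> 0, default 3).
#' @return List with `kept` and `removed` numeric vectors.
#' @export
iqr_filter <- function(values, k = 3) {
  stopifnot(is.numeric(values), k > 0)
  if (length(values) < 4) {
    warning("fewer than 4 values; IQR filter passes all through", call. = FALSE)
    return(list(kept = values, removed = numeric(0)))
  }
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  out <- values < q[1] - k * iqr | values > q[2] + k * iqr
  list(kept = values[!out], removed = values[out])
}

#' One-way analysis of variance across groups
#'
#' Classic equal-variance F test. Degenerate inputs with zero within-group
#' variance follow the documented convention: p = 1 (F = 0) when all group
#' means are equal, p = 0 (F = Inf) otherwise.
#'
#' @param groups list of two or more numeric vectors, each of length >= 2.
#' @return List with `statistic` (F), `p_value`, `df` (between, within) and
#'   `n_per_group`.
#' @export
one_way_anova <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2,
            all(vapply(groups, length, integer(1)) >= 2))
  y <- unlist(groups)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  ssw <- sum(unlist(lapply(groups, function(v) sum((v - mean(v))^2))))
  df <- c(length(groups) - 1, length(y) - length(groups))
  if (ssw == 0) {
    means <- vapply(groups, mean, numeric(1))
    equal <- diff(range(means)) == 0
    return(list(statistic = if (equal) 0 else Inf,
                p_value = if (equal) 1 else 0,
                df = df, n_per_group = lengths(groups)))
  }
  ft <- stats::oneway.test(y ~ g, var.equal = TRUE)
  list(statistic = unname(ft$statistic), p_value = ft$p.value,
       df = unname(ft$parameter), n_per_group = lengths(groups))
}

#' Two-sided Mann-Whitney U test
#'
#' Exact null distribution when both samples are tie-free and
#' `n_a * n_b <= 400`; otherwise the normal approximation with the usual tie
#' and continuity corrections (identical samples sit at the null centre and
#' give p = 1).
#'
#' @param a,b numeric samples (nonempty).
#' @param exact `"auto"` (default rule above), `TRUE` or `FALSE`.
#' @return List with `statistic` (U for sample `a`), `p_value`, `n_a`, `n_b`
#'   and `exact` (logical, which path was used).
#' @export
mann_whitney_u <- function(a, b, exact = "auto") {
  stopifnot(length(a) >= 1, length(b) >= 1)
  ties <- anyDuplicated(c(a, b)) > 0
  use_exact <- if (identical(exact, "auto"))
    !ties && length(a) * length(b) <= 400
  else isTRUE(exact)
  if (use_exact && ties)
    stop("exact Mann-Whitney null is unavailable with ties", call. = FALSE)
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided",
                       exact = use_exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = min(1, wt$p.value),
       n_a = length(a), n_b = length(b), exact = use_exact)
}

#' Construct a long-format metric series
#'
#' @param metric `"thickness_um"`, `"mu_mm_inv"` or `"pigmentation"`.
#' @param records `data.frame` with columns `mouse_id`, `group`, `site`,
#'   `month`, `value`; one value per (mouse, site, month).
#' @return A `metric_series` data.frame with a `metric` attribute.
#' @export
metric_series <- function(metric, records) {
  metric <- match.arg(metric, c("thickness_um", "mu_mm_inv", "pigmentation"))
  need <- c("mouse_id", "group", "site", "month", "value")
  stopifnot(all(need %in% names(records)))
  records <- records[need]
  key <- paste(records$mouse_id, records$site, records$month)
  if (anyDuplicated(key))
    stop("duplicate (mouse, site, month) records in metric series", call. = FALSE)
  structure(records, metric = metric, class = c("metric_series", "data.frame"))
}

.comparison_row <- function(metric, site, test, comparison, group_a, group_b,
                            month_a, month_b, statistic, p_value, n_a, n_b,
                            n_outliers_removed) {
  data.frame(metric = metric, site = site, test = test,
             comparison = comparison, group_a = group_a, group_b = group_b,
             month_a = month_a, month_b = month_b,
             statistic = statistic, p_value = p_value,
             n_a = n_a, n_b = n_b,
             n_outliers_removed = n_outliers_removed,
             stringsAsFactors = FALSE)
}

# Values of one group x site x month cell.
.cell <- function(series, group, site, month)
  series$value[series$group == group & series$site == site &
                 series$month == month]

#' Run the longitudinal group-comparison plan
#'
#' Per imaging site: a one-way ANOVA across the four groups at baseline and
#' at the final month; Mann-Whitney U follow-ups only at sites whose
#' final-month ANOVA falls below `alpha`. The follow-up set is: each group at
#' baseline vs the same group at the final month (4 tests), control vs each
#' UV-exposed group at the final month (3 tests), and UVR control vs each
#' treated group at the final month (2 tests). IQR outlier removal (fence
#' multiplier `iqr_k`) is applied per group x site x month cell before the
#' Mann-Whitney tests only; p-values are reported raw, without
#' multiple-testing correction.
#'
#' @param series a [metric_series()] containing all four groups at both the
#'   baseline and final months.
#' @param alpha ANOVA gate level (default 0.05).
#' @param iqr_k IQR fence multiplier for outlier removal (default 3).
#' @param baseline_month,final_month months compared (defaults 0 and 7).
#' @return `data.frame` of comparison rows (one per test).
#' @export
run_comparison_plan <- function(series, alpha = 0.05, iqr_k = 3,
                                baseline_month = 0, final_month = 7) {
  stopifnot(inherits(series, "metric_series"), alpha > 0, alpha <= 1)
  metric <- attr(series, "metric")
  sites <- intersect(.sites, unique(series$site))
  for (g in .groups) for (m in c(baseline_month, final_month)) for (s in sites)
    if (length(.cell(series, g, s, m)) == 0)
      stop(sprintf("missing data for group %s, site %s, month %d", g, s, m),
           call. = FALSE)
  out <- list()
  for (s in sites) {
    anova_rows <- lapply(c(baseline_month, final_month), function(m) {
      res <- one_way_anova(lapply(.groups, .cell, series = series,
                                  site = s, month = m))
      .comparison_row(metric, s, "anova", sprintf("groups_at_month_%d", m),
                      "all", "all", m, m, res$statistic, res$p_value,
                      sum(res$n_per_group), sum(res$n_per_group), 0L)
    })
    out <- c(out, anova_rows)
    gate_p <- anova_rows[[2]]$p_value
    if (!is.na(gate_p) && gate_p < alpha) {
      fcell <- function(g, m) iqr_filter(.cell(series, g, s, m), k = iqr_k)
      mw_row <- function(comparison, ga, ma, gb, mb) {
        ca <- fcell(ga, ma); cb <- fcell(gb, mb)
        res <- mann_whitney_u(ca$kept, cb$kept)
        .comparison_row(metric, s, "mann_whitney", comparison, ga, gb, ma, mb,
                        res$statistic, res$p_value, res$n_a, res$n_b,
                        length(ca$removed) + length(cb$removed))
      }
      for (g in .groups)
        out <- c(out, list(mw_row(sprintf("%s_month_%d_vs_%d", g,
                                          baseline_month, final_month),
                                  g, baseline_month, g, final_month)))
      for (g in setdiff(.groups, "control"))
        out <- c(out, list(mw_row(sprintf("control_vs_%s", g),
                                  "control", final_month, g, final_month)))
      for (g in c("uvr_nmn", "uvr_pl"))
        out <- c(out, list(mw_row(sprintf("uvr_control_vs_%s", g),
                                  "uvr_control", final_month, g, final_month)))
    }
  }
  do.call(rbind, out)
}

#' Monthly group means and per-group linear trends
#'
#' @param series a [metric_series()] with at least two months.
#' @return List with `means` (group x site x month mean table) and `trends`
#'   (OLS slope of the monthly means vs month, per group x site, in metric
#'   units per month).
#' @export
longitudinal_summary <- function(series) {
  stopifnot(inherits(series, "metric_series"))
  if (length(unique(series$month)) < 2)
    stop("longitudinal summary needs at least two months", call. = FALSE)
  means <- aggregate(value ~ group + site + month, data = series, FUN = mean)
  names(means)[names(means) == "value"] <- "mean_value"
  trends <- do.call(rbind, by(means, list(means$group, means$site), function(d) {
    sl <- if (nrow(d) >= 2) unname(coef(stats::lm(mean_value ~ month, d))[2]) else NA_real_
    data.frame(group = d$group[1], site = d$site[1], slope = sl,
               n_months = nrow(d), stringsAsFactors = FALSE)
  }))
  rownames(trends) <- NULL
  list(means = means, trends = trends)
}
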