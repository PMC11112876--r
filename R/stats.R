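# Summary statistics and the per-protomer nonparametric comparison.

#' Box-plot style summary of a metric distribution
#'
#' Mean, sample s.d., quartiles by linear interpolation between order
#' statistics (quantile type 7), Tukey whiskers at the most extreme values
#' within 1.5 IQR of the quartiles, and the outliers beyond them.
#'
#' @param values non-empty numeric vector.
#' @return list of class `metric_summary`: `n`, `mean`, `sd`, `median`,
#'   `q1`, `q3`, `whisker_low`, `whisker_high`, `outliers`.
#' @examples
#' summarize_metric(c(1:9, 100))
#' @export
summarize_metric <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("summarize_metric on empty input")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[3] + 1.5 * iqr
  inside <- values >= lo & values <= hi
  structure(list(
    n = length(values),
    mean = mean(values),
    sd = if (length(values) > 1L) stats::sd(values) else 0,
    median = q[2],
    q1 = q[1],
    q3 = q[3],
    whisker_low = min(values[inside]),
    whisker_high = max(values[inside]),
    outliers = sort(values[!inside])
  ), class = "metric_summary")
}

#' @export
print.metric_summary <- function(x, ...) {
  cat(sprintf(
    "n=%d mean=%.4g sd=%.4g median=%.4g [q1 %.4g, q3 %.4g] outliers: %d\n",
    x$n, x$mean, x$sd, x$median, x$q1, x$q3, length(x$outliers)))
  invisible(x)
}

#' Kruskal-Wallis rank test over k groups
#'
#' Tie-corrected H statistic with the chi-square approximation
#' (df = k - 1), via [stats::kruskal.test]. Degenerate all-identical data
#' returns H = 0, p = 1 (the test statistic is undefined there; no
#' evidence against the null).
#'
#' @param groups list of >= 2 numeric vectors, each non-empty, total
#'   n >= 3.
#' @return list of class `kw_result`: `H`, `df`, `p_value`,
#'   `tie_corrected` (whether ties were present and corrected for).
#' @examples
#' kruskal_wallis(list(1:3, 4:6, 7:9))$H  # 7.2
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("kruskal_wallis needs at least 2 groups")
  }
  n <- lengths(groups)
  if (any(n == 0L)) stop("all groups must be non-empty")
  x <- unlist(groups, use.names = FALSE)
  if (length(x) < 3L) stop("total sample size must be >= 3")
  g <- factor(rep(seq_along(groups), n))
  if (length(unique(x)) == 1L) {
    res <- list(H = 0, df = length(groups) - 1L, p_value = 1,
                tie_corrected = TRUE)
  } else {
    kt <- stats::kruskal.test(x, g)
    res <- list(H = unname(kt$statistic), df = unname(kt$parameter),
                p_value = unname(kt$p.value),
                tie_corrected = anyDuplicated(x) > 0L)
  }
  structure(res, class = "kw_result")
}

#' @export
print.kw_result <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4g, df = %d, p = %.4g%s\n",
              x$H, x$df, x$p_value,
              if (x$tie_corrected) " (tie-corrected)" else ""))
  invisible(x)
}

#' Per-protomer comparison of a metric against a reference condition
#'
#' For each protomer label present in both conditions, runs a two-group
#' Kruskal-Wallis test (equivalent to a two-sided rank test) between the
#' reference and comparison values pooled over frames (and replicas), and
#' flags the protomer significant when p < `alpha`. This mirrors the
#' per-protomer asterisks of a mutant-vs-wild-type box-plot panel. No
#' multiple-testing correction is applied by default; `adjust =
#' "bonferroni"` multiplies p by the number of protomers.
#'
#' @param metric_table data.frame with columns `condition`, `protomer`,
#'   `value` containing exactly the reference and one other condition.
#' @param reference label of the reference condition.
#' @param alpha significance level (default 0.05).
#' @param adjust `"none"` (default) or `"bonferroni"`.
#' @return data.frame with one row per protomer: `protomer`, `n_ref`,
#'   `n_cmp`, `H`, `p_value`, `significant`.
#' @export
compare_to_reference <- function(metric_table, reference, alpha = 0.05,
                                 adjust = c("none", "bonferroni")) {
  adjust <- match.arg(adjust)
  stopifnot(all(c("condition", "protomer", "value") %in% names(metric_table)))
  conds <- unique(metric_table$condition)
  if (!(reference %in% conds) || length(conds) != 2L) {
    stop("metric_table must hold the reference and exactly one other condition")
  }
  other <- setdiff(conds, reference)
  ref_tab <- metric_table[metric_table$condition == reference, ]
  cmp_tab <- metric_table[metric_table$condition == other, ]
  protomers <- sort(unique(metric_table$protomer))
  if (!all(protomers %in% ref_tab$protomer) ||
      !all(protomers %in% cmp_tab$protomer)) {
    stop("a protomer label is missing from one of the conditions")
  }
  rows <- lapply(protomers, function(p) {
    a <- ref_tab$value[ref_tab$protomer == p]
    b <- cmp_tab$value[cmp_tab$protomer == p]
    kw <- kruskal_wallis(list(a, b))
    p_adj <- if (adjust == "bonferroni") {
      min(1, kw$p_value * length(protomers))
    } else kw$p_value
    data.frame(protomer = p, n_ref = length(a), n_cmp = length(b),
               H = kw$H, p_value = p_adj, significant = p_adj < alpha,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
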