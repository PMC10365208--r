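# Cohort comparisons: Mann-Whitney U with the standard significance tiers,
# group medians, metadata-driven stratification.

#' Map a p value to significance stars
#'
#' Tiers: `P < 0.05` (*), `P < 0.005` (**), `P < 0.0005` (***), else `ns`.
#'
#' @param p P value(s).
#' @return Character vector of `"ns"`, `"*"`, `"**"`, `"***"`.
#' @export
p_stars <- function(p) {
  dplyr::case_when(p < 0.0005 ~ "***",
                   p < 0.005 ~ "**",
                   p < 0.05 ~ "*",
                   TRUE ~ "ns")
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison. In `auto` mode the exact null distribution
#' is used when `n1 * n2 <= 400` and the pooled sample is tie-free;
#' otherwise the normal approximation with tie and continuity corrections.
#' The U statistic is reported for the first sample
#' (`U(x, y) + U(y, x) = n1 * n2`).
#'
#' @param x,y Numeric samples.
#' @param mode `"auto"`, `"exact"` or `"approx"`.
#' @return A list of class `cm_mwu`: `U`, `p`, `n1`, `n2`, `method`, `stars`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
#' @export
mann_whitney_u <- function(x, y, mode = c("auto", "exact", "approx")) {
  mode <- match.arg(mode)
  abort_if(length(x) == 0 || length(y) == 0, "empty sample")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- switch(mode,
                  auto = length(x) * length(y) <= 400 && !ties,
                  exact = TRUE,
                  approx = FALSE)
  if (exact && ties) {
    rlang::warn("ties present: falling back to the normal approximation")
    exact <- FALSE
  }
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE,
                       alternative = "two.sided"))
  structure(list(U = unname(wt$statistic), p = wt$p.value,
                 n1 = length(x), n2 = length(y),
                 method = if (exact) "exact" else "normal-approximation",
                 stars = p_stars(wt$p.value)),
            class = "cm_mwu")
}

#' @export
print.cm_mwu <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g (n1 = %d, n2 = %d), p = %.4g %s [%s]\n",
              x$U, x$n1, x$n2, x$p, x$stars, x$method))
  invisible(x)
}

#' Stratified group comparisons
#'
#' For each stratum, compares every pair of groups on a metric with the
#' Mann-Whitney U test and reports group medians. P values are reported
#' unadjusted by default (`p_adjust = "none"`); a Bonferroni option is
#' available.
#'
#' @param data Tibble with one row per observation (cell, event or
#'   experiment).
#' @param metric Name of the value column (string).
#' @param group_by Name of the group label column (string).
#' @param strata Optional name of a stratum column (string); `NULL` treats
#'   the table as a single stratum.
#' @param mode Passed to [mann_whitney_u()].
#' @param p_adjust `"none"` (default) or `"bonferroni"`.
#' @return Tibble: `stratum`, `group1`, `group2`, `n1`, `n2`, `median1`,
#'   `median2`, `U`, `p`, `stars`, `method`. Comparisons with an empty
#'   group are skipped with a warning.
#' @export
stratify_and_compare <- function(data, metric, group_by, strata = NULL,
                                 mode = "auto", p_adjust = c("none", "bonferroni")) {
  p_adjust <- match.arg(p_adjust)
  abort_if(!metric %in% names(data), paste0("no column `", metric, "`"))
  abort_if(!group_by %in% names(data), paste0("no column `", group_by, "`"))
  strata_vals <- if (is.null(strata)) "(all)" else
    unique(stats::na.omit(data[[strata]]))
  rows <- list()
  for (s in strata_vals) {
    d <- if (is.null(strata)) data else data[!is.na(data[[strata]]) &
                                               data[[strata]] == s, , drop = FALSE]
    d <- d[!is.na(d[[metric]]), , drop = FALSE]
    groups <- sort(unique(d[[group_by]]))
    if (length(groups) < 2) {
      rlang::warn(sprintf("stratum '%s': fewer than 2 non-empty groups, skipped", s))
      next
    }
    for (pair in utils::combn(groups, 2, simplify = FALSE)) {
      xv <- d[[metric]][d[[group_by]] == pair[1]]
      yv <- d[[metric]][d[[group_by]] == pair[2]]
      if (!length(xv) || !length(yv)) {
        rlang::warn(sprintf("stratum '%s': empty group in %s vs %s, skipped",
                            s, pair[1], pair[2]))
        next
      }
      tst <- mann_whitney_u(xv, yv, mode = mode)
      rows[[length(rows) + 1]] <- tibble::tibble(
        stratum = as.character(s), group1 = pair[1], group2 = pair[2],
        n1 = tst$n1, n2 = tst$n2,
        median1 = stats::median(xv), median2 = stats::median(yv),
        U = tst$U, p = tst$p, method = tst$method)
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) && p_adjust == "bonferroni")
    out$p <- pmin(out$p * nrow(out), 1)
  if (nrow(out)) out$stars <- p_stars(out$p)
  out
}
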