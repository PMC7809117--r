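# Conventional group comparisons for the cohort tables: two-sample tests on
# continuous summary parameters and chi-square / Fisher tests on categorical
# clinical variables.

#' Two-sample comparison of a continuous variable
#'
#' `method = "t"` is the pooled-variance two-sided independent t-test;
#' `"mannwhitney"` is the two-sided Mann-Whitney U test with normal
#' approximation and tie correction; `"auto"` uses the t-test when both
#' groups pass Shapiro-Wilk normality at alpha = 0.05 and the Mann-Whitney
#' test otherwise (groups too small for Shapiro-Wilk fall back to
#' Mann-Whitney).
#'
#' @param values numeric vector.
#' @param labels two-level group label per value.
#' @param method `"auto"`, `"t"` or `"mannwhitney"`.
#' @return list with `statistic`, `p`, and the `method` actually used.
#' @export
two_sample_compare <- function(values, labels,
                               method = c("auto", "t", "mannwhitney")) {
  method <- match.arg(method)
  labels <- as.character(labels)
  lv <- unique(labels)
  if (length(lv) != 2L) stop("need exactly two groups")
  a <- values[labels == lv[1]]
  b <- values[labels == lv[2]]
  if (length(a) < 2L || length(b) < 2L) stop("each group needs >= 2 values")
  if (method == "auto") {
    normal <- function(x) {
      if (length(x) < 3L || length(unique(x)) < 3L) return(FALSE)
      stats::shapiro.test(x)$p.value >= 0.05
    }
    method <- if (normal(a) && normal(b)) "t" else "mannwhitney"
  }
  if (method == "t") {
    ht <- stats::t.test(a, b, var.equal = TRUE)
    list(statistic = unname(ht$statistic), p = ht$p.value, method = "t")
  } else {
    ht <- suppressWarnings(
      stats::wilcox.test(a, b, exact = FALSE, correct = FALSE)
    )
    list(statistic = unname(ht$statistic), p = ht$p.value,
         method = "mannwhitney")
  }
}

#' Categorical group test on a contingency table
#'
#' `"chi2"` is Pearson's chi-square without continuity correction; `"fisher"`
#' is the exact two-sided test (hypergeometric for 2x2, with the standard
#' two-sided rule: sum of all table probabilities no larger than the observed
#' one). `"auto"` uses Fisher whenever any expected cell count is below 5.
#'
#' @param table r x c matrix of nonnegative integer counts (r, c >= 2).
#' @param method `"auto"`, `"chi2"` or `"fisher"`.
#' @return list with `p` and the `method` used (and `statistic` for chi2).
#' @export
categorical_test <- function(table, method = c("auto", "chi2", "fisher")) {
  method <- match.arg(method)
  table <- as.matrix(table)
  if (nrow(table) < 2L || ncol(table) < 2L) stop("table must be at least 2x2")
  if (any(table < 0) || any(table != round(table))) {
    stop("table must contain nonnegative integer counts")
  }
  if (sum(table) == 0) stop("zero-total table")
  if (method == "auto") {
    expected <- outer(rowSums(table), colSums(table)) / sum(table)
    method <- if (any(expected < 5)) "fisher" else "chi2"
  }
  if (method == "fisher") {
    ht <- stats::fisher.test(table)
    list(p = ht$p.value, method = "fisher")
  } else {
    ht <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
    list(p = ht$p.value, statistic = unname(ht$statistic), method = "chi2")
  }
}

#' Cohort summary table of kinematic parameters
#'
#' Group mean and sample (n-1) standard deviation for every summary
#' parameter, with the two-sample p-value and the test actually used.
#'
#' @param summaries data.frame with one `summary_parameters` row per subject
#'   (e.g. rbind of [summarize_profile()] outputs).
#' @param labels group label per subject.
#' @param method test policy passed to [two_sample_compare()].
#' @param reference label treated as the first (reference) group column.
#' @return data.frame with one row per parameter: means, SDs, p, test.
#' @export
summarize_cohort <- function(summaries, labels, method = "auto",
                             reference = "good") {
  labels <- as.character(labels)
  lv <- unique(labels)
  if (length(lv) != 2L) stop("need exactly two groups")
  if (reference %in% lv) lv <- c(reference, setdiff(lv, reference))
  params <- names(summaries)[vapply(summaries, is.numeric, logical(1))]
  rows <- lapply(params, function(pp) {
    v <- summaries[[pp]]
    ok <- !is.na(v)
    cmp <- two_sample_compare(v[ok], labels[ok], method = method)
    data.frame(
      parameter = pp,
      mean_1 = mean(v[ok & labels == lv[1]]),
      sd_1 = stats::sd(v[ok & labels == lv[1]]),
      mean_2 = mean(v[ok & labels == lv[2]]),
      sd_2 = stats::sd(v[ok & labels == lv[2]]),
      p = cmp$p, test = cmp$method
    )
  })
  out <- do.call(rbind, rows)
  names(out)[2:5] <- c(paste0("mean_", lv[1]), paste0("sd_", lv[1]),
                       paste0("mean_", lv[2]), paste0("sd_", lv[2]))
  out
}
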