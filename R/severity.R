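#' Pearson association between severity scores and centroid distance
#'
#' Standard Pearson correlation with a two-sided t-based p-value.
#' Incomplete pairs are dropped pairwise and the remaining n is reported.
#'
#' @param severity,d2 numeric vectors of equal length (severity scores and
#'   squared Mahalanobis distances from the control centroid).
#' @return a `severity_association` list: `r`, `p_value`, `n`, `df`.
#' @export
severity_association <- function(severity, d2) {
  if (length(severity) != length(d2)) stop("inputs must have equal length")
  ok <- complete.cases(severity, d2)
  x <- severity[ok]; y <- d2[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance in severity or distance values")
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  structure(list(r = unname(ct$estimate), p_value = ct$p.value,
                 n = length(x), df = unname(ct$parameter)),
            class = "severity_association")
}

#' @export
print.severity_association <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f, P = %.3g, N = %d\n", x$r, x$p_value, x$n))
  invisible(x)
}

#' Two-group comparison of severity (or distance) values
#'
#' Welch's unequal-variance t-test by default (group sizes and variances in
#' this design are typically unbalanced), with the pooled-variance variant
#' behind `pooled = TRUE`. Also reports mean and SEM per group in the
#' mean-plus-SEM table layout.
#'
#' @param a,b numeric vectors (missing values dropped); each needs >= 2
#'   values.
#' @param pooled use the pooled-variance (Student) variant.
#' @param group_names labels for the two groups.
#' @return a `group_comparison` list: per-group `n`, `mean`, `sem`;
#'   `t`, `df`, `p_value`, `variant`.
#' @export
group_ttest <- function(a, b, pooled = FALSE,
                        group_names = c("group1", "group2")) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L) stop("each group needs at least 2 values")
  tt <- t.test(a, b, var.equal = pooled)
  sem <- function(v) sd(v) / sqrt(length(v))
  structure(list(
    group_names = group_names,
    n = c(length(a), length(b)),
    mean = c(mean(a), mean(b)),
    sem = c(sem(a), sem(b)),
    t = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value,
    variant = if (pooled) "pooled" else "welch"
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  for (i in 1:2) {
    cat(sprintf("  %s: %.3f ± %.3f (n = %d)\n",
                x$group_names[i], x$mean[i], x$sem[i], x$n[i]))
  }
  cat(sprintf("  t = %.3f, df = %.1f, P = %.3g (%s t-test)\n",
              x$t, x$df, x$p_value, x$variant))
  invisible(x)
}

#' Summary tables of classification results by group and gender
#'
#' Per stratum (diagnostic group x gender): n, mean and SEM of the squared
#' Mahalanobis distance from the control centroid; plus per-group
#' assignment counts and percentages. SEM is `NA` for singleton strata.
#'
#' @param results per-case classification data frame with `subject_id`,
#'   `assigned`, and a `d2_<reference>` column (from [score_case()] /
#'   [classify_cohort()]).
#' @param subjects cohort metadata with `subject_id`, `group`, `gender`.
#' @param d2_column name of the distance column; default is the first
#'   column starting with `d2_`.
#' @return a `cohort_summary` list with `d2_table` and `assignment_table`
#'   data frames.
#' @export
summarize_groups <- function(results, subjects, d2_column = NULL) {
  if (!nrow(results)) stop("no classification results to summarize")
  if (is.null(d2_column)) {
    d2_column <- grep("^d2_", names(results), value = TRUE)[1L]
  }
  if (is.na(d2_column)) stop("no d2_ column found in results")
  results <- results[, setdiff(names(results), c("group", "gender")),
                     drop = FALSE]
  merged <- merge(subjects, results, by = "subject_id", sort = FALSE)
  sem <- function(v) if (length(v) < 2L) NA_real_ else sd(v) / sqrt(length(v))

  strata <- unique(merged[, c("group", "gender")])
  strata <- strata[order(strata$group, strata$gender), , drop = FALSE]
  d2_table <- do.call(rbind, lapply(seq_len(nrow(strata)), function(i) {
    v <- merged[[d2_column]][merged$group == strata$group[i] &
                               merged$gender == strata$gender[i]]
    data.frame(group = strata$group[i], gender = strata$gender[i],
               n = length(v), mean = mean(v), sem = sem(v),
               stringsAsFactors = FALSE)
  }))

  groups <- unique(merged$group)
  assigned_levels <- sort(unique(merged$assigned))
  assignment_table <- do.call(rbind, lapply(groups, function(g) {
    sub <- merged[merged$group == g, ]
    cnt <- table(factor(sub$assigned, levels = assigned_levels))
    data.frame(group = g, assigned = assigned_levels,
               n = as.integer(cnt),
               pct = 100 * as.integer(cnt) / nrow(sub),
               stringsAsFactors = FALSE)
  }))
  structure(list(d2_table = d2_table, assignment_table = assignment_table,
                 d2_column = d2_column),
            class = "cohort_summary")
}
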