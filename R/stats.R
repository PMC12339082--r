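#' Shapiro-Wilk normality test with explicit guards
#'
#' Thin wrapper around the Royston-approximation Shapiro-Wilk test that
#' turns the degenerate inputs of small cohort tables into classed errors.
#'
#' @param x numeric sample, 3 <= n <= 5000.
#' @return list with `statistic` (W) and `p_value`.
#' @export
shapiro_wilk <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3 || n > 5000)
    oq_stop("Shapiro-Wilk requires 3 <= n <= 5000", "oq_sample_size_error")
  if (diff(range(x)) == 0)
    oq_stop("constant sample: normality is undefined",
            "oq_degenerate_sample_error")
  sw <- stats::shapiro.test(x)
  list(statistic = unname(sw$statistic), p_value = sw$p.value)
}

#' Normality-gated two-group comparison
#'
#' Runs an unpaired two-sided Student t-test when the Shapiro-Wilk test
#' does not reject normality (p >= `alpha`) in both groups, and a
#' two-sided Mann-Whitney (Wilcoxon rank-sum) test otherwise. The
#' Mann-Whitney branch uses the exact null distribution when the smaller
#' group has at most 8 untied observations, and the tie-corrected normal
#' approximation otherwise. Constant samples count as non-normal.
#'
#' @param a,b numeric samples (n >= 3 each); `a` is the baseline group for
#'   the percent difference.
#' @param alpha significance level of the normality gate.
#' @return object of class `group_comparison`: `test_name`, `statistic`,
#'   `p_value`, `n_a`, `n_b`, `mean_a`, `mean_b`, `percent_difference`
#'   (100 x (mean_b - mean_a) / mean_a).
#' @export
compare_two_groups <- function(a, b, alpha = 0.05) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 3 || length(b) < 3)
    oq_stop("each group needs at least 3 observations", "oq_sample_size_error")
  normal <- function(x) {
    tryCatch(shapiro_wilk(x)$p_value >= alpha,
             oq_degenerate_sample_error = function(e) FALSE)
  }
  use_t <- normal(a) && normal(b)
  if (use_t) {
    ht <- stats::t.test(a, b, var.equal = TRUE)
    test_name <- "t-test"
  } else {
    exact <- min(length(a), length(b)) <= 8 && !any(duplicated(c(a, b)))
    ht <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                              correct = TRUE))
    test_name <- "Mann-Whitney"
  }
  ma <- mean(a); mb <- mean(b)
  structure(list(test_name = test_name,
                 statistic = unname(ht$statistic),
                 p_value = ht$p.value,
                 n_a = length(a), n_b = length(b),
                 mean_a = ma, mean_b = mb,
                 percent_difference = if (ma != 0) 100 * (mb - ma) / ma
                                      else NA_real_),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: p = %.4g, means %.3g vs %.3g (%+.1f%%), n = %d/%d\n",
              x$test_name, x$p_value, x$mean_a, x$mean_b,
              x$percent_difference, x$n_a, x$n_b))
  invisible(x)
}

#' Percent difference of a mutant mean against a wild-type baseline
#' @param mean_wt baseline (wild-type) mean.
#' @param mean_mut comparison (mutant) mean.
#' @return 100 x (mean_mut - mean_wt) / mean_wt.
#' @export
percent_difference <- function(mean_wt, mean_mut) {
  if (any(mean_wt == 0))
    oq_stop("zero baseline mean", "oq_division_error")
  100 * (mean_mut - mean_wt) / mean_wt
}

#' Validate a long-format cohort table
#'
#' @param df data.frame with columns `sample_id`, `genotype` (WT/MUT),
#'   `sex` (M/F), `age_group`, `site`, `measure`, `value`.
#' @return the validated data.frame (invisibly classed `cohort_table`).
#' @export
cohort_table <- function(df) {
  need <- c("sample_id", "genotype", "sex", "age_group", "site", "measure",
            "value")
  miss <- setdiff(need, names(df))
  if (length(miss))
    oq_stop(paste("cohort table lacks columns:", paste(miss, collapse = ", ")),
            "oq_format_error")
  key <- paste(df$sample_id, df$site, df$measure)
  if (anyDuplicated(key))
    oq_stop("duplicate (sample_id, site, measure) keys", "oq_format_error")
  if (any(!is.finite(df$value)))
    oq_stop("non-finite measurement values", "oq_domain_error")
  class(df) <- unique(c("cohort_table", class(df)))
  invisible(df)
}

#' Two-way factorial analysis with Tukey post-hoc comparisons
#'
#' Type-II sums-of-squares ANOVA (appropriate for the unbalanced cohorts)
#' of one measure against two crossed factors, by default bone site and
#' genotype, followed by Tukey HSD family-wise comparisons over the site
#' levels (or over all site-by-genotype cells on request).
#'
#' @param table long-format cohort data.frame (see [cohort_table()]).
#' @param measure measure name to analyse.
#' @param factors character vector of two factor columns.
#' @param tukey_family `"site"` compares levels of the first factor;
#'   `"cells"` compares all factor-combination cells.
#' @return list of class `two_way_anova`: `anova` (data.frame with term,
#'   sum_sq, df, F, p), `tukey` (data.frame of pairwise contrasts with
#'   adjusted p-values), `n`.
#' @export
two_way_anova_tukey <- function(table, measure,
                                factors = c("site", "genotype"),
                                tukey_family = c("site", "cells")) {
  tukey_family <- match.arg(tukey_family)
  stopifnot(length(factors) == 2, all(factors %in% names(table)))
  d <- table[table$measure == measure, , drop = FALSE]
  if (!nrow(d))
    oq_stop(sprintf("no rows for measure '%s'", measure), "oq_domain_error")
  f1 <- factor(d[[factors[1]]])
  f2 <- factor(d[[factors[2]]])
  if (nlevels(f1) < 2 || nlevels(f2) < 2)
    oq_stop("each factor needs at least two levels", "oq_design_error")
  cells <- table(f1, f2)
  if (any(cells < 2)) {
    bad <- which(cells < 2, arr.ind = TRUE)[1, ]
    oq_stop(sprintf("cell (%s = %s, %s = %s) has fewer than 2 observations",
                    factors[1], levels(f1)[bad[1]],
                    factors[2], levels(f2)[bad[2]]),
            "oq_design_error")
  }
  dd <- data.frame(value = d$value, f1 = f1, f2 = f2)
  fit <- stats::aov(value ~ f1 * f2, data = dd)
  a2 <- car::Anova(stats::lm(value ~ f1 * f2, data = dd), type = 2)
  terms <- rownames(a2)
  pretty <- gsub("f1", factors[1], gsub("f2", factors[2], terms))
  atab <- data.frame(term = pretty, sum_sq = a2[["Sum Sq"]],
                     df = a2[["Df"]], F = a2[["F value"]],
                     p = a2[["Pr(>F)"]], row.names = NULL)
  if (tukey_family == "site") {
    tk <- stats::TukeyHSD(fit, which = "f1")[["f1"]]
  } else {
    fitc <- stats::aov(value ~ cell,
                       data = data.frame(value = dd$value,
                                         cell = interaction(f1, f2)))
    tk <- stats::TukeyHSD(fitc, which = "cell")[["cell"]]
  }
  tukey <- data.frame(contrast = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"], row.names = NULL)
  structure(list(anova = atab, tukey = tukey, n = nrow(dd),
                 measure = measure, factors = factors,
                 tukey_family = tukey_family),
            class = "two_way_anova")
}

#' @export
print.two_way_anova <- function(x, ...) {
  cat(sprintf("Two-way type-II ANOVA of '%s' (%s x %s, n = %d)\n",
              x$measure, x$factors[1], x$factors[2], x$n))
  print(x$anova, digits = 4)
  cat(sprintf("Tukey HSD over %s:\n", x$tukey_family))
  print(x$tukey, digits = 4)
  invisible(x)
}
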