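test_that("Shapiro-Wilk wrapper guards its domain and detects non-normality", {
  set.seed(2)
  expect_lt(shapiro_wilk(runif(500))$p_value, 0.05)
  expect_error(shapiro_wilk(c(1, 2)), class = "oq_sample_size_error")
  expect_error(shapiro_wilk(rep(3.2, 10)), class = "oq_degenerate_sample_error")
  expect_error(shapiro_wilk(rnorm(6000)), class = "oq_sample_size_error")
})

test_that("the normality gate keeps its nominal type-I error", {
  set.seed(99)
  rej <- mean(replicate(2000, shapiro_wilk(rnorm(50))$p_value < 0.05))
  expect_lt(abs(rej - 0.05), 0.015)
})

test_that("two-group comparison picks the documented branch", {
  # identical samples: no difference
  gc <- compare_two_groups(1:5, 1:5)
  expect_equal(gc$percent_difference, 0)
  expect_gt(gc$p_value, 0.99)
  # hand-computed Student t for the printed toy samples
  a <- 1:5; b <- 6:10
  gc2 <- compare_two_groups(a, b)
  expect_equal(gc2$test_name, "t-test")
  sp2 <- (4 * var(a) + 4 * var(b)) / 8
  t_oracle <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 5 + 1 / 5))
  expect_equal(gc2$statistic, t_oracle, tolerance = 1e-10)
  expect_equal(gc2$p_value, 2 * pt(t_oracle, 8), tolerance = 1e-10)
  expect_equal(gc2$percent_difference, 100 * (8 - 3) / 3)
  # a lognormal sample fails the gate and routes to Mann-Whitney
  set.seed(8)
  gc3 <- compare_two_groups(rnorm(40, 10, 1), exp(rnorm(40, 2, 1.2)))
  expect_equal(gc3$test_name, "Mann-Whitney")
  # constant samples count as non-normal rather than erroring out
  gc4 <- compare_two_groups(rep(5, 6), c(1, 2, 3, 4, 6, 7))
  expect_equal(gc4$test_name, "Mann-Whitney")
  expect_error(compare_two_groups(1:2, 1:5), class = "oq_sample_size_error")
})

test_that("two-group comparison holds its nominal type-I error", {
  set.seed(17)
  rej <- mean(replicate(2000,
    compare_two_groups(rnorm(10), rnorm(10))$p_value < 0.05))
  expect_lt(abs(rej - 0.05), 0.015)
})

test_that("percent difference is the mutant-over-wild-type ratio statistic", {
  expect_equal(percent_difference(100, 82), -18)
  expect_equal(percent_difference(7, 7), 0)
  expect_equal(percent_difference(50, 75), 50)
  expect_error(percent_difference(0, 5), class = "oq_division_error")
})

test_that("cohort tables are validated", {
  df <- data.frame(sample_id = c("a", "a"), genotype = "WT", sex = "M",
                   age_group = "8W", site = "Ct", measure = "ca_mean",
                   value = c(1, 2))
  expect_error(cohort_table(df), class = "oq_format_error")
  df$site <- c("Ct", "Ms")
  expect_s3_class(suppressWarnings(cohort_table(df)), "cohort_table")
  df$value[1] <- NaN
  expect_error(cohort_table(df), class = "oq_domain_error")
})

balanced_toy <- function(noise = 0, seed = 1) {
  set.seed(seed)
  d <- expand.grid(site = c("Ct", "Es", "Ms"), genotype = c("WT", "MUT"),
                   rep = 1:4)
  site_eff <- c(Ct = 10, Es = 6, Ms = 2)
  gen_eff <- c(WT = 0, MUT = -3)
  d$value <- site_eff[d$site] + gen_eff[d$genotype] + rnorm(nrow(d), 0, noise)
  d$sample_id <- paste0("s", seq_len(nrow(d)))
  d$sex <- "M"; d$age_group <- "8W"; d$measure <- "m"
  d
}

test_that("a noise-free additive design separates factors completely", {
  res <- two_way_anova_tukey(balanced_toy(noise = 1e-3), "m")
  p <- setNames(res$anova$p, res$anova$term)
  ss <- setNames(res$anova$sum_sq, res$anova$term)
  expect_lt(p[["site"]], 1e-10)
  expect_lt(p[["genotype"]], 1e-10)
  # additive truth: interaction carries (numerically) no variance
  expect_lt(ss[["site:genotype"]], 1e-4 * ss[["site"]])
})

test_that("balanced two-way ANOVA reproduces the textbook SS decomposition", {
  d <- balanced_toy(noise = 1, seed = 3)
  res <- two_way_anova_tukey(d, "m")
  # oracle: sums of squares from group means
  gm <- mean(d$value)
  m_site <- tapply(d$value, d$site, mean)
  m_gen <- tapply(d$value, d$genotype, mean)
  m_cell <- tapply(d$value, interaction(d$site, d$genotype), mean)
  ss_site <- 8 * sum((m_site - gm)^2)
  ss_gen <- 12 * sum((m_gen - gm)^2)
  ss_cells <- 4 * sum((m_cell - gm)^2)
  ss_int <- ss_cells - ss_site - ss_gen
  ss_tot <- sum((d$value - gm)^2)
  ss <- setNames(res$anova$sum_sq, res$anova$term)
  expect_equal(ss[["site"]], ss_site, tolerance = 1e-8)
  expect_equal(ss[["genotype"]], ss_gen, tolerance = 1e-8)
  expect_equal(ss[["site:genotype"]], ss_int, tolerance = 1e-8)
  expect_equal(sum(ss), ss_tot, tolerance = 1e-8)
})

test_that("Tukey flags exactly the pairs involving a shifted group", {
  set.seed(12)
  d <- data.frame(
    site = rep(c("Ct", "Es", "Ms"), each = 8),
    genotype = rep(c("WT", "MUT"), 12),
    value = c(rnorm(8, 10, 0.5), rnorm(8, 10, 0.5), rnorm(8, 16, 0.5)),
    sex = "M", age_group = "8W", measure = "m")
  d$sample_id <- paste0("s", seq_len(nrow(d)))
  res <- two_way_anova_tukey(d, "m")
  tk <- res$tukey
  involves_ms <- grepl("Ms", tk$contrast)
  expect_true(all(tk$p_adj[involves_ms] < 0.01))
  expect_true(all(tk$p_adj[!involves_ms] > 0.1))
  # adjusted p-values are monotone in the absolute mean difference
  o <- order(abs(tk$diff))
  expect_true(all(diff(tk$p_adj[o]) <= 1e-12))
})

test_that("ANOVA genotype factor holds its type-I error under the null", {
  set.seed(31)
  rej <- mean(replicate(2000, {
    d <- data.frame(site = rep(c("Ct", "Es", "Ms"), each = 8),
                    genotype = rep(c("WT", "MUT"), 12),
                    value = rnorm(24),
                    sex = "M", age_group = "8W", measure = "m",
                    sample_id = paste0("s", 1:24))
    res <- two_way_anova_tukey(d, "m")
    res$anova$p[res$anova$term == "genotype"] < 0.05
  }))
  expect_lt(abs(rej - 0.05), 0.015)
})

test_that("degenerate designs raise design errors naming the cell", {
  d <- balanced_toy()
  d <- d[!(d$site == "Ms" & d$genotype == "MUT"), ]
  err <- tryCatch(two_way_anova_tukey(d, "m"), error = identity)
  expect_s3_class(err, "oq_design_error")
  expect_match(conditionMessage(err), "Ms")
  expect_error(two_way_anova_tukey(balanced_toy()[1:8, ], "m"),
               class = "oq_design_error")
})
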