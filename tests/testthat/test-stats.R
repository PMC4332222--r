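test_that("correlate reproduces exact relationships and identities", {
  x <- seq(0.5, 3, by = 0.25)
  r <- suppressWarnings(correlate(x, 10^x, log_y = TRUE))  # exact fit warns in summary.lm
  expect_equal(r$r, 1, tolerance = 1e-12)
  expect_equal(r$r2, 1, tolerance = 1e-12)
  expect_equal(r$slope, 1, tolerance = 1e-9)
  # anti-monotone: Spearman exactly -1
  r2 <- correlate(x, exp(-x))
  expect_equal(r2$r_s, -1)
  # r2 equals squared Pearson r for simple regression
  set.seed(3)
  xx <- rnorm(40); yy <- 2 * xx + rnorm(40)
  rc <- correlate(xx, yy)
  expect_equal(rc$r2, rc$r^2, tolerance = 1e-12)
  # validation
  expect_error(correlate(1:2, 1:2), class = "lungfot_stats_error")
  expect_error(correlate(rep(1, 5), 1:5), class = "lungfot_stats_error")
  expect_error(correlate(1:5, c(-1, 1, 2, 3, 4), log_y = TRUE),
               class = "lungfot_stats_error")
})

test_that("spearman is invariant under strictly monotone transforms", {
  set.seed(7)
  g <- rep(0:3, times = c(6, 4, 7, 6))
  v <- exp(g + rnorm(length(g), 0, 0.5)) + 1
  r1 <- correlate(g, v)$r_s
  expect_equal(correlate(g, log(v))$r_s, r1, tolerance = 1e-12)
  expect_equal(correlate(g, v^3)$r_s, r1, tolerance = 1e-12)
})

test_that("two-group ANOVA F equals the squared pooled t statistic", {
  set.seed(11)
  d <- data.frame(y = c(rnorm(8, 0), rnorm(12, 1)),
                  g = rep(c("a", "b"), c(8, 12)))
  cg <- compare_groups(d, "y", "g", method = "bonferroni")
  tt <- t.test(y ~ g, data = d, var.equal = TRUE)
  expect_equal(cg$anova_table$F_value[1], unname(tt$statistic)^2,
               tolerance = 1e-9)
})

test_that("group comparisons behave at the null and under huge shifts", {
  set.seed(13)
  base <- rnorm(10)
  d0 <- data.frame(y = c(base, base), g = rep(c("a", "b"), each = 10))
  cg0 <- compare_groups(d0, "y", "g", method = "bonferroni")
  expect_lt(cg0$anova_table$F_value[1], 1e-12)
  expect_equal(cg0$pairwise$p_adj, 1)
  d1 <- data.frame(y = c(rnorm(10), rnorm(10) + 10), g = rep(c("a", "b"), each = 10))
  cg1 <- compare_groups(d1, "y", "g", method = "bonferroni")
  expect_lt(cg1$pairwise$p_adj, 0.001)
  # bonferroni is min(1, m * raw)
  set.seed(14)
  d3 <- data.frame(y = rnorm(30), g = rep(c("a", "b", "c"), 10))
  cg3 <- compare_groups(d3, "y", "g", method = "bonferroni")
  expect_equal(cg3$pairwise$p_adj, pmin(1, cg3$pairwise$p_raw * 3))
  # tukey path returns all pairwise contrasts
  cgt <- compare_groups(d3, "y", "g")
  expect_equal(nrow(cgt$pairwise), 3)
})

test_that("grade and frequency effects are significant on the synthetic cohort", {
  co <- generate_cohort(seed = 1)
  rows <- lapply(names(co$records), function(key) {
    if (!grepl("peep4$", key)) return(NULL)
    mech <- to_mechanics(estimate_impedance(co$records[[key]], co$protocol))
    id <- sub("_peep[0-9.]+$", "", key)
    data.frame(animal_id = id,
               grade = co$animals$grade[co$animals$animal_id == id],
               freq = mech$freq_hz, E_L = mech$E_L)
  })
  tab <- do.call(rbind, rows)
  tab$freq <- factor(tab$freq)
  cg <- compare_groups(tab, "E_L", c("grade", "freq"), block = "animal_id")
  an <- cg$anova_table
  expect_lt(an$p[an$term == "grade"], 0.05)
  expect_lt(an$p[an$term == "freq"], 0.05)
  expect_lt(an$p[an$term == "grade:freq"], 0.05)
})

test_that("grade correlation uses the ordinal coding and log scale", {
  set.seed(17)
  tab <- data.frame(grade_num = rep(0:3, times = c(12, 4, 7, 6)))
  tab$E_het <- 10^(tab$grade_num / 2) * exp(rnorm(nrow(tab), 0, 0.1))
  gc <- grade_correlation(tab)
  expect_gt(gc$r_s, 0.9)
  expect_gt(gc$r, 0.9)
  # perfectly separated: Spearman exactly 1 (up to tie handling in grades)
  tab2 <- data.frame(grade_num = rep(0:3, each = 5),
                     E_het = rep(c(1, 10, 100, 1000), each = 5))
  expect_equal(suppressWarnings(grade_correlation(tab2))$r_s, 1, tolerance = 1e-9)
  # shuffled labels: association collapses
  set.seed(18)
  tab3 <- tab; tab3$grade_num <- sample(tab$grade_num)
  expect_lt(abs(grade_correlation(tab3)$r_s), 0.45)
  expect_error(grade_correlation(data.frame(grade_num = rep(1, 5),
                                            E_het = 1:5)),
               class = "lungfot_stats_error")
})
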