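test_that("2^-ddCt arithmetic matches its closed form", {
  r <- fold_change_ddct(24, 20, 25, 20)
  expect_equal(r$ddct, -1)
  expect_equal(r$fold_change, 2)
  expect_equal(fold_change_ddct(26, 22, 25, 21)$fold_change, 1)
  # shifting every Ct by a constant changes nothing
  a <- fold_change_ddct(24.3, 20.1, 25.7, 20.4)
  b <- fold_change_ddct(24.3 + 3, 20.1 + 3, 25.7 + 3, 20.4 + 3)
  expect_equal(a$fold_change, b$fold_change)
  expect_error(fold_change_ddct(NA, 20, 25, 20), "finite")
  expect_warning(fold_change_ddct(45, 20, 25, 20), "typical")
})

test_that("max-normalization rescales each replicate to a unit maximum", {
  expect_equal(max_normalize(c(2, 4, 8)), c(0.25, 0.5, 1))
  expect_equal(max_normalize(5), 1)
  v <- c(1, 3, 2, 6)
  g <- c("a", "a", "b", "b")
  expect_equal(max_normalize(v, g), max_normalize(v * 7.3, g))
  out <- max_normalize(c(4, 4, 1), rep("a", 3))
  expect_equal(sum(out == 1), 2)       # tied maxima all become 1
  expect_true(all(out > 0 & out <= 1))
  expect_error(max_normalize(c(-1, 0)), "non-positive")
})

test_that("fractionation log-ratio behaves on the stated domain", {
  expect_equal(fractionation_log_ratio(10, 1)$log_ratio, 1)
  expect_equal(fractionation_log_ratio(3.7, 3.7)$log_ratio, 0)
  expect_equal(fractionation_log_ratio(8, 1, base = 2)$log_ratio, 3)
  expect_error(fractionation_log_ratio(0, 1), "strictly positive")
})

test_that("pooled-variance Student t matches the textbook formula", {
  same <- student_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  x <- c(1, 2, 3); y <- c(2, 3, 4)
  got <- student_t_test(x, y)
  oracle <- student_t_oracle(x, y)
  expect_equal(got$statistic, oracle$statistic, tolerance = 1e-12)
  expect_equal(abs(got$statistic), 1.224745, tolerance = 1e-6)
  expect_equal(got$df, 4)
  expect_equal(got$p_value, oracle$p_value, tolerance = 1e-12)
  expect_equal(got$p_value, 0.2878641, tolerance = 1e-6)

  flipped <- student_t_test(y, x)
  expect_equal(flipped$statistic, -got$statistic)
  expect_equal(flipped$p_value, got$p_value)
  expect_error(student_t_test(1, c(1, 2)), "at least two")
})

test_that("ANOVA omnibus and Bonferroni-adjusted pairwise comparisons", {
  g_same <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  res <- anova_bonferroni(g_same)
  expect_equal(res$f_statistic, 0)
  expect_equal(res$p_value, 1)

  g <- list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(5, 6, 7))
  res2 <- anova_bonferroni(g)
  expect_equal(res2$n_comparisons, 3L)
  expect_equal(res2$comparisons$p_adjusted,
               pmin(1, 3 * res2$comparisons$p_raw))
  expect_true(all(res2$comparisons$p_adjusted >=
                  res2$comparisons$p_raw))
  expect_true(all(res2$comparisons$p_adjusted <= 1))
  # omnibus agrees with aov run independently
  dat <- data.frame(v = unlist(g), grp = rep(names(g), each = 3))
  ref <- anova(aov(v ~ grp, dat))
  expect_equal(res2$f_statistic, ref[["F value"]][1], tolerance = 1e-12)

  expect_error(anova_bonferroni(list(a = 1:3, b = 1:3)), "three groups")
  expect_error(anova_bonferroni(list(a = 1, b = 1:3, c = 1:3)),
               "at least two")
})

test_that("replicate-level relative expression feeds the induction screen", {
  sim <- simulate_ct_experiment(true_fold = 4, n_reps = 3, noise_sd = 0.2,
                                seed = 42)
  expr <- relative_expression_table(sim$ct_table, "target", "reference",
                                    baseline = "baseline")
  expect_equal(nrow(expr), 6L)
  scr <- induction_screen(expr, baseline = "baseline")
  expect_true(scr$flags$induced[scr$flags$condition == "treated"])
  expect_equal(dim(scr$heatmap), c(1L, 1L))

  # zero noise recovers the planted fold exactly
  exact <- simulate_ct_experiment(true_fold = 2, n_reps = 2,
                                  noise_sd = 0, seed = 1)
  ct <- exact$ct_table
  f <- fold_change_ddct(
    ct$ct[ct$condition == "treated" & ct$gene == "target"][1],
    ct$ct[ct$condition == "treated" & ct$gene == "reference"][1],
    ct$ct[ct$condition == "baseline" & ct$gene == "target"][1],
    ct$ct[ct$condition == "baseline" & ct$gene == "reference"][1])
  expect_equal(f$fold_change, 2)

  expect_error(induction_screen(expr, baseline = "nope"), "baseline")
  # a gene missing at a timepoint is excluded with a warning
  expr_miss <- rbind(expr,
                     data.frame(gene = "other", condition = "baseline",
                                replicate = 1:3, value = c(1, 1.1, 0.9)),
                     data.frame(gene = "other", condition = "treated",
                                replicate = 1, value = 2))
  expect_warning(induction_screen(expr_miss, baseline = "baseline"),
                 "excluded")
})
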