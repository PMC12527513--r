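balanced_scores <- function(means, n_per_cell = 20, sd = 1, seed = 1) {
  # two k levels per viz so the interaction is estimable
  grid <- tidyr::expand_grid(viz = names(means), k = c(10, 50),
                             rep = seq_len(n_per_cell))
  withr::with_seed(seed, dplyr::mutate(
    grid, score = rnorm(nrow(grid), mean = means[viz], sd = sd)
  ))
}

test_that("two-way ANOVA terms and F statistics are location invariant", {
  d <- balanced_scores(c(MARCv1 = 4, MARCv2 = 5, BP = 3, FP = 4), seed = 2)
  a1 <- analyze_scores(d)
  a2 <- analyze_scores(dplyr::mutate(d, score = score + 100))
  expect_equal(a1$anova$statistic, a2$anova$statistic, tolerance = 1e-10)
  expect_equal(a1$tukey$estimate, a2$tukey$estimate, tolerance = 1e-10)
  expect_equal(a1$anova$term, c("viz", "k", "viz:k", "Residuals"))
  expect_equal(nrow(a1$tukey), 6)  # all visualization pairs
})

test_that("Tukey comparisons reproduce the closed form for two groups", {
  d <- balanced_scores(c(A = 4, B = 5), n_per_cell = 30, seed = 3)
  res <- analyze_scores(d)
  expect_equal(nrow(res$tukey), 1)
  cell_means <- tapply(d$score, d$viz, mean)
  diff_hat <- unname(cell_means["B"] - cell_means["A"])
  expect_equal(res$tukey$estimate, diff_hat, tolerance = 1e-10)
  n_g <- 60
  df_resid <- res$anova$df[res$anova$term == "Residuals"]
  se_diff <- sqrt(res$mse * 2 / n_g)
  p_oracle <- stats::ptukey(abs(diff_hat) / se_diff * sqrt(2), nmeans = 2,
                            df = df_resid, lower.tail = FALSE)
  expect_equal(res$tukey$adj_p_value, p_oracle, tolerance = 1e-8)
  expect_equal(res$tukey$std_estimate, diff_hat / sqrt(res$mse),
               tolerance = 1e-10)
})

test_that("score analysis enforces factor structure and cell coverage", {
  d <- balanced_scores(c(A = 4, B = 5), seed = 4)
  expect_error(analyze_scores(dplyr::filter(d, viz == "A")), "2 levels")
  holes <- dplyr::filter(d, !(viz == "A" & k == 10))
  expect_error(analyze_scores(holes), "empty design cells")
  # excluded rows are dropped before fitting
  with_excl <- dplyr::mutate(d, excluded = viz == "A" & k == 10 & rep > 10)
  expect_equal(nrow(analyze_scores(with_excl)$anova), 4)
})

test_that("Tukey family-wise error is near nominal under the null", {
  design <- build_design(80, seed = 1)
  reps <- 200
  hits <- vapply(seq_len(reps), function(i) {
    scores <- simulate_scores(design, seed = 20000 + i)
    any(analyze_scores(scores)$tukey$adj_p_value < 0.05)
  }, logical(1))
  fwer <- mean(hits)
  mc3 <- 3 * sqrt(0.05 * 0.95 / reps)
  expect_lt(abs(fwer - 0.05), mc3 + 0.02)
})

test_that("duration model collapses to ordinary regression without person variance", {
  design <- build_design(120, seed = 6)
  d <- simulate_durations(design, viz_effects = c(FP = 20), sd_person = 0,
                          sd_resid = 10, seed = 7)
  suppressWarnings(fit <- analyze_durations(d))
  k_c <- as.numeric(d$k) - mean(as.numeric(d$k))
  ols <- lm(page_duration ~ stats::relevel(factor(viz), "MARCv2") * k_c,
            data = d)
  # the boundary (singular) mixed fit agrees with OLS up to optimizer slack
  expect_lt(max(abs(unname(fit$fixed$estimate) - unname(coef(ols)))), 0.01)
})

test_that("centering the number of studies makes interactions shift-invariant", {
  design <- build_design(60, seed = 8)
  d <- simulate_durations(design, viz_effects = c(BP = 10), slope_k = 0.3,
                          seed = 9)
  f1 <- analyze_durations(d)
  f2 <- analyze_durations(dplyr::mutate(d, k = k + 100))
  inter <- grepl(":", f1$fixed$term)
  expect_equal(f1$fixed$estimate[inter], f2$fixed$estimate[inter],
               tolerance = 1e-8)
  expect_equal(f1$k_center + 100, f2$k_center)
  expect_equal(f1$reference, "MARCv2")
})

test_that("a simulated viewing-time effect is recovered within its CI", {
  design <- build_design(200, seed = 10)
  reps <- 60
  covered <- vapply(seq_len(reps), function(i) {
    d <- simulate_durations(design, viz_effects = c(FP = 30), seed = 30000 + i)
    fit <- analyze_durations(d)
    row <- fit$fixed[fit$fixed$term == "vizFP", ]
    abs(row$estimate - 30) <= qnorm(0.975) * row$se
  }, logical(1))
  expect_gte(mean(covered), 0.9)
})
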