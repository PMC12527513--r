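test_that("inverse-variance weights match direct arithmetic and preserve order", {
  w_equal <- compute_weights(tibble::tibble(
    study_id = c("a", "b"), smd = c(0, 0), se = c(0.1, 0.1)
  ))
  expect_equal(w_equal$rel_weight, c(0.5, 0.5))

  w <- compute_weights(toy_meta())
  expect_equal(w$weight, c(100, 25))
  expect_equal(w$rel_weight, c(0.8, 0.2))
  expect_equal(w$study_id, c("a", "b"))
})

test_that("non-positive or non-finite standard errors are rejected by study id", {
  bad <- tibble::tibble(study_id = c("a", "b"), smd = c(0.1, 0.1),
                        se = c(0.1, -0.1))
  expect_error(compute_weights(bad), "'b'")
  bad$se <- c(0.1, Inf)
  expect_error(compute_weights(bad), "'b'")
  expect_error(compute_weights(dplyr::mutate(toy_meta(), study_id = c("a", "a"))),
               "duplicate")
  expect_error(compute_weights(toy_meta()[0, ]), "at least one study")
})

test_that("fixed-effects pooling reproduces closed-form values", {
  equal <- pool_fixed(tibble::tibble(study_id = c("a", "b"),
                                     smd = c(0.1, 0.3), se = c(0.1, 0.1)))
  expect_equal(equal$estimate, 0.2)

  p <- pool_fixed(toy_meta(), level = 0.95)
  expect_equal(p$estimate, 0.14)
  expect_equal(p$se, 1 / sqrt(125), tolerance = 1e-12)
  expect_equal(p$ci_low, 0.14 - qnorm(0.975) / sqrt(125), tolerance = 1e-12)
  expect_equal(p$ci_high, 0.14 + qnorm(0.975) / sqrt(125), tolerance = 1e-12)
  expect_equal(round(c(p$ci_low, p$ci_high), 4), c(-0.0353, 0.3153))

  single <- pool_fixed(tibble::tibble(study_id = "only", smd = 0.25, se = 0.05))
  expect_equal(single$estimate, 0.25)
  expect_equal(single$se, 0.05)

  expect_error(pool_fixed(toy_meta(), level = 1.2), "between 0 and 1")
})

test_that("pooling agrees with an independent meta-analytic routine", {
  skip_if_not_installed("metafor")
  d <- random_meta(25, seed = 11)
  p <- pool_fixed(d)
  fit <- metafor::rma(yi = d$smd, sei = d$se, method = "FE")
  expect_equal(p$estimate, as.numeric(fit$beta), tolerance = 1e-10)
  expect_equal(p$se, fit$se, tolerance = 1e-10)
})

test_that("weights and pooling match brute-force oracles on random datasets", {
  for (seed in 1:25) {
    k <- withr::with_seed(seed, sample(1:100, 1))
    d <- random_meta(k, seed = seed + 1000)
    w <- compute_weights(d)
    expect_equal(sum(w$rel_weight), 1, tolerance = 1e-9)
    expect_equal(w$weight, 1 / d$se^2, tolerance = 1e-12)
    p <- pool_fixed(d)
    o <- pool_oracle(d$smd, d$se)
    expect_equal(p$estimate, o$estimate, tolerance = 1e-12)
    expect_equal(p$se, o$se, tolerance = 1e-12)
    expect_equal(p$ci_low, o$ci_low, tolerance = 1e-12)
    if (k >= 2) expect_lt(p$se, min(d$se))
  }
})

test_that("confidence intervals narrow monotonically as studies accumulate", {
  widths <- sapply(1:10, function(k) {
    d <- tibble::tibble(study_id = paste0("s", 1:k),
                        smd = rep(0.2, k), se = rep(0.15, k))
    p <- pool_fixed(d)
    p$ci_high - p$ci_low
  })
  expect_true(all(diff(widths) < 0))
})

test_that("CRT SMD variance reduces to the non-clustered closed form at rho = 0", {
  expect_equal(crt_smd_variance(50, 50, 1, rho = 0, delta = 0), 0.04)
  grid <- expand.grid(n1 = c(40, 100, 240), n2 = c(40, 120),
                      n = c(1, 5, 20), d = c(0, 0.15, 0.5))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    expect_equal(crt_smd_variance(g$n1, g$n2, g$n, 0, g$d),
                 smd_variance_simple(g$n1, g$n2, g$d), tolerance = 1e-12)
  }
})

test_that("clustering inflates the mean-difference term by the design effect", {
  # with delta = 0 only the leading term remains
  v0 <- crt_smd_variance(200, 200, 10, rho = 0, delta = 0)
  v2 <- crt_smd_variance(200, 200, 10, rho = 0.2, delta = 0)
  expect_equal(v2 / v0, 1 + (10 - 1) * 0.2, tolerance = 1e-12)
})

test_that("CRT SMD variance is non-decreasing in the intraclass correlation", {
  grid <- expand.grid(m = c(4, 12, 30), n = c(5, 20, 60), d = c(0, 0.15, 0.6))
  rhos <- seq(0, 0.95, by = 0.05)
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    v <- crt_smd_variance(g$m * g$n, g$m * g$n, g$n, rhos, g$d)
    expect_true(all(v > 0))
    expect_true(all(diff(v) >= -1e-12))
  }
})

test_that("CRT SMD variance rejects invalid inputs", {
  expect_error(crt_smd_variance(50, 50, 5, rho = 1, delta = 0), "\\[0, 1\\)")
  expect_error(crt_smd_variance(50, 50, 5, rho = -0.1, delta = 0), "\\[0, 1\\)")
  expect_error(crt_smd_variance(50, 50, 60, rho = 0.1, delta = 0),
               "may not exceed")
})
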