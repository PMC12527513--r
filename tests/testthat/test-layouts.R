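test_that("MARC marks sit at (smd, relative weight) with area tracking weight", {
  equal <- tibble::tibble(study_id = c("a", "b"), smd = c(-0.1, 0.4),
                          se = c(0.2, 0.2))
  lay <- marc_layout(equal, version = "v1")
  expect_equal(lay$marks$y, c(0.5, 0.5))
  expect_equal(lay$marks$area[1], lay$marks$area[2])

  lay2 <- marc_layout(toy_meta(), version = "v1")
  expect_equal(lay2$marks$y, c(0.8, 0.2))
  expect_equal(lay2$summary_y, 1.0)
  expect_true(all(lay2$marks$y < lay2$summary_y))
  expect_error(marc_layout(toy_meta()[0, ]), "at least one study")
})

test_that("MARCv1 keeps a single scale summing study weights to one", {
  d <- random_meta(40, seed = 2)
  lay <- marc_layout(d, version = "v1")
  expect_equal(sum(lay$marks$y), 1, tolerance = 1e-9)
  expect_equal(lay$summary_y, 1.0)
  expect_true(all(lay$marks$y < 1.0))
  # rank concordance: y, area, and relative weight order identically
  w <- compute_weights(d)$rel_weight
  expect_equal(rank(lay$marks$y), rank(w))
  expect_equal(rank(lay$marks$area), rank(w))
})

test_that("mark color is a total function of the sign of the effect", {
  d <- tibble::tibble(study_id = c("n", "z", "p"), smd = c(-0.2, 0, 0.2),
                      se = c(0.1, 0.1, 0.1))
  lay <- marc_layout(d, version = "v1")
  expect_equal(lay$marks$color, c("negative", "zero", "positive"))
})

test_that("MARCv2 rescales the study pane and leaves the cloud untouched", {
  d <- tibble::tibble(study_id = paste0("s", 1:100), smd = rep(0.15, 100),
                      se = rep(0.1, 100))
  lay <- marc_layout(d, version = "v2")
  studies <- lay$panes[lay$panes$pane == "studies", ]
  expect_equal(studies$y_max, 1.15 * 0.01, tolerance = 1e-12)
  expect_true(all(lay$marks$y > 0))
  expect_equal(lay$panes$height, c(1, 3))

  wide <- marc_layout(d, version = "v2", padding = 2)
  expect_identical(lay$cloud$dots, wide$cloud$dots)  # pane independence
  expect_equal(wide$panes$y_max[wide$panes$pane == "studies"], 2 * 0.01)
})

test_that("MARC layouts carry the interpretive annotations and hover text", {
  lay <- marc_layout(toy_meta(), version = "v2")
  expect_setequal(lay$annotations$id,
                  c("certainty_arrows", "decreased_label", "increased_label"))
  expect_match(lay$marks$hover[1], "Study a")
  expect_match(lay$marks$hover[1], "SMD: 0.10")
  expect_match(lay$marks$hover[1], "Relative weight: 80.0%")
})

test_that("summary cloud dots are deterministic quantiles inside the CI", {
  p <- pool_fixed(toy_meta())
  one <- summary_cloud(p, n_dots = 1)
  expect_equal(one$dots$x, p$estimate)
  expect_equal(one$dots$y_offset, 0)

  cl <- summary_cloud(p, n_dots = 50)
  expect_true(all(cl$dots$x >= p$ci_low & cl$dots$x <= p$ci_high))
  expect_identical(cl$dots, summary_cloud(p, n_dots = 50)$dots)
  expect_error(summary_cloud(p, n_dots = 0), ">= 1")
})

test_that("cloud quantiles are symmetric and densest near the estimate", {
  p0 <- structure(list(estimate = 0, se = 0.1,
                       ci_low = -0.196, ci_high = 0.196, level = 0.95, k = 5,
                       method = "fixed"), class = "pooled_effect")
  cl <- summary_cloud(p0, n_dots = 41)
  expect_equal(sort(cl$dots$x), sort(-cl$dots$x), tolerance = 1e-12)
  gaps <- diff(sort(cl$dots$x))
  mid <- length(gaps) %/% 2
  expect_lt(min(gaps[mid], gaps[mid + 1]), min(gaps[1], gaps[length(gaps)]))
})

test_that("forest layout squares, whiskers and diamond follow the definitions", {
  equal <- tibble::tibble(study_id = c("a", "b"), smd = c(0.1, 0.5),
                          se = c(0.1, 0.1))
  lay <- forest_layout(equal)
  expect_equal(lay$marks$area[1], lay$marks$area[2])
  expect_equal(lay$marks$ci_high - lay$marks$x, rep(qnorm(0.975) * 0.1, 2),
               tolerance = 1e-12)
  expect_equal(round(lay$marks$ci_high[1] - lay$marks$x[1], 3), 0.196)
  p <- pool_fixed(equal)
  expect_equal(lay$diamond$x_left, p$ci_low)
  expect_equal(lay$diamond$x_right, p$ci_high)
  expect_match(lay$marks$hover[1], "Weight: 100.0")
  # row count grows with k, unlike MARC whose vertical scale is continuous
  expect_equal(lay$n_rows, 3)
  expect_equal(forest_layout(random_meta(30, 1))$n_rows, 31)
  expect_false("n_rows" %in% names(marc_layout(equal)))
})

test_that("bar layout lengths equal |smd| and preserve input order", {
  d <- tibble::tibble(study_id = c("x", "y", "z"), smd = c(0.3, 0, -0.2),
                      se = c(0.1, 0.1, 0.1), n_students = c(100L, 80L, 60L))
  lay <- bar_layout(d)
  expect_equal(lay$marks$bar_length, c(0.3, 0, 0.2), tolerance = 1e-12)
  expect_equal(lay$marks$study_id, c("x", "y", "z"))
  expect_equal(lay$marks$row, 1:3)
  expect_match(lay$marks$hover[1], "# of students: 100")

  no_n <- d[, c("study_id", "smd", "se")]
  expect_warning(lay2 <- bar_layout(no_n), "n_students")
  expect_false(any(grepl("students", lay2$marks$hover)))
  expect_equal(lay2$marks$bar_length, c(0.3, 0, 0.2))
})

test_that("study relabeling permutes ids deterministically under a seed", {
  d <- random_meta(10, seed = 4)
  r1 <- relabel_studies(d, seed = 9)
  r2 <- relabel_studies(d, seed = 9)
  expect_identical(r1$study_id, r2$study_id)
  expect_setequal(r1$study_id, paste0("Study ", 1:10))
  expect_equal(r1$smd, d$smd)  # only labels change
})
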