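# Fully resolved plot layouts. Every number that appears in a rendered
# figure is computed here; renderers only map these numbers to pixels.

#' Beeswarm cloud for a pooled effect
#'
#' Represents the pooled effect's uncertainty as a frequency display: a
#' fixed number of dots placed at deterministic normal quantiles of the
#' pooled sampling distribution, truncated to the confidence interval, with
#' vertical offsets assigned by a collision-avoiding swarm packing. Dots
#' are densest near the estimate, and for a symmetric quantile scheme the
#' dot positions are symmetric about it.
#'
#' @param pooled A `"pooled_effect"` from [pool_fixed()].
#' @param n_dots Number of dots G (>= 1); dot i sits at the i/(G+1) normal
#'   quantile. Default 50.
#' @param dot_gap Minimal center-to-center spacing of dots, as a fraction
#'   of the CI width (controls the packing radius).
#' @return A list of class `"summary_cloud"`: `dots` (tibble of `x`,
#'   `y_offset`), `center` (the pooled estimate), plus `ci_low`/`ci_high`.
#' @examples
#' p <- pool_fixed(tibble::tibble(study_id = "a", smd = 0.2, se = 0.05))
#' summary_cloud(p, n_dots = 9)
#' @export
summary_cloud <- function(pooled, n_dots = 50, dot_gap = 0.04) {
  stopifnot(inherits(pooled, "pooled_effect"))
  if (!is.numeric(n_dots) || length(n_dots) != 1 || n_dots < 1) {
    abort("`n_dots` must be a single count >= 1.")
  }
  n_dots <- as.integer(n_dots)
  probs <- seq_len(n_dots) / (n_dots + 1)
  x <- qnorm(probs, mean = pooled$estimate, sd = pooled$se)
  x <- pmin(pmax(x, pooled$ci_low), pooled$ci_high)
  width <- max(pooled$ci_high - pooled$ci_low, .Machine$double.eps)
  r <- dot_gap * width
  y <- swarm_offsets(x, r)
  structure(
    list(dots = tibble::tibble(x = x, y_offset = y),
         center = pooled$estimate,
         ci_low = pooled$ci_low, ci_high = pooled$ci_high),
    class = "summary_cloud"
  )
}

# Deterministic greedy swarm packing: dots are placed in order of distance
# from the median x; each takes the smallest |offset| (0, +-r/2, +-r, ...)
# at which it clears all previously placed dots by at least r (euclidean,
# with x and offset on the same scale).
swarm_offsets <- function(x, r) {
  n <- length(x)
  y <- numeric(n)
  ord <- order(abs(x - stats::median(x)), seq_len(n))
  placed_x <- numeric(0)
  placed_y <- numeric(0)
  cand <- function(step) {
    offs <- c(0, as.vector(rbind(seq_len(200) * step, -seq_len(200) * step)))
    offs
  }
  for (i in ord) {
    for (off in cand(r / 2)) {
      near <- abs(placed_x - x[i]) < r
      if (!any(near) ||
          all((placed_x[near] - x[i])^2 + (placed_y[near] - off)^2 >= r^2 * 0.999)) {
        y[i] <- off
        placed_x <- c(placed_x, x[i])
        placed_y <- c(placed_y, off)
        break
      }
    }
  }
  y
}

# Shared mark table: positions, areas, colors and hover text for studies.
build_marks <- function(data, y, area, hover, smd_digits = 2) {
  tibble::tibble(
    study_id = as.character(data$study_id),
    x = data$smd,
    y = y,
    area = area,
    color = dplyr::case_when(data$smd < 0 ~ "negative",
                             data$smd > 0 ~ "positive",
                             TRUE ~ "zero"),
    hover = hover
  )
}

hover_marc <- function(data, rel_weight, smd_digits = 2, weight_digits = 1) {
  sprintf("Study %s\nSMD: %s\nRelative weight: %s%%",
          data$study_id,
          formatC(data$smd, digits = smd_digits, format = "f"),
          formatC(100 * rel_weight, digits = weight_digits, format = "f"))
}

#' MARC plot layout
#'
#' Resolves a meta-analytic dataset and its pooled effect into the full
#' geometry of a Meta-Analytic Rain Cloud plot. Study marks sit at
#' (`smd`, relative weight) with mark *area* proportional to relative
#' weight; marks left of zero are classed "negative" (decreased scores,
#' shaded red) and right of zero "positive" (increased scores, blue). The
#' pooled effect appears as a beeswarm cloud:
#'
#' * **v1** — one vertical scale; the cloud sits at `y = 1.0`, the combined
#'   weight of all studies, above every mark.
#' * **v2** — the cloud moves to its own upper pane with an independent
#'   vertical scale, and the lower (study) pane is rescaled to
#'   `[0, padding * max relative weight]` so that for large k the marks do
#'   not pool illegibly at the axis.
#'
#' @inheritParams validate_meta
#' @param version `"v1"` or `"v2"`.
#' @param level Confidence level for the pooled effect.
#' @param n_dots Dots in the summary cloud.
#' @param padding Head-room factor for the v2 lower-pane upper limit.
#' @param pane_heights Relative heights of (summary, studies) panes in v2.
#' @return A list of class `"marc_layout"` with elements `version`,
#'   `marks`, `cloud`, `summary_y`, `panes` (per-pane y ranges), `pooled`,
#'   `annotations`, and `zero_line`.
#' @examples
#' studies <- tibble::tibble(study_id = c("a", "b"),
#'                           smd = c(0.1, 0.3), se = c(0.1, 0.2))
#' marc_layout(studies, version = "v1")
#' @export
marc_layout <- function(data, version = c("v2", "v1"), level = 0.95,
                        n_dots = 50, padding = 1.15, pane_heights = c(1, 3)) {
  version <- match.arg(version)
  data <- compute_weights(data)
  pooled <- pool_fixed(data, level = level)
  cloud <- summary_cloud(pooled, n_dots = n_dots)
  marks <- build_marks(data, y = data$rel_weight, area = data$rel_weight,
                       hover = hover_marc(data, data$rel_weight))
  if (version == "v1") {
    summary_y <- 1.0
    panes <- tibble::tibble(pane = "all", y_min = 0,
                            y_max = 1.0, height = 1)
  } else {
    summary_y <- 0  # cloud pane has its own scale centered on its offsets
    panes <- tibble::tibble(
      pane = c("summary", "studies"),
      y_min = c(NA_real_, 0),
      y_max = c(NA_real_, padding * max(marks$y)),
      height = pane_heights
    )
  }
  structure(
    list(version = version, marks = marks, cloud = cloud,
         summary_y = summary_y, panes = panes, pooled = pooled,
         annotations = marc_annotations(), zero_line = 0),
    class = c("marc_layout", "plot_layout")
  )
}

marc_annotations <- function() {
  tibble::tibble(
    id = c("certainty_arrows", "decreased_label", "increased_label"),
    text = c("More certain ←  → Less certain",
             "Decreased scores", "Increased scores"),
    side = c("y", "left", "right")
  )
}

#' Forest plot layout
#'
#' The conventional meta-analysis display, resolved to numbers: one row
#' per study (top to bottom in input order) with a square at the effect
#' size whose area is proportional to the raw inverse-variance weight, CI
#' whiskers `smd +/- z * se`, and a diamond on the bottom row spanning the
#' pooled confidence interval exactly. Hover text carries the raw weight.
#'
#' @inheritParams marc_layout
#' @return A list of class `"forest_layout"`: `marks` (with `ci_low`,
#'   `ci_high` whisker ends and `row`), `diamond`, `pooled`, `zero_line`,
#'   `n_rows`.
#' @export
forest_layout <- function(data, level = 0.95) {
  data <- compute_weights(data)
  pooled <- pool_fixed(data, level = level)
  z <- qnorm(1 - (1 - level) / 2)
  k <- nrow(data)
  marks <- build_marks(data, y = k - seq_len(k) + 1, area = data$weight,
                       hover = sprintf("Study %s\nSMD: %s\nWeight: %s",
                                       data$study_id,
                                       formatC(data$smd, digits = 2, format = "f"),
                                       formatC(data$weight, digits = 1, format = "f")))
  marks$row <- seq_len(k)
  marks$ci_low <- data$smd - z * data$se
  marks$ci_high <- data$smd + z * data$se
  structure(
    list(marks = marks,
         diamond = tibble::tibble(x_left = pooled$ci_low,
                                  x_center = pooled$estimate,
                                  x_right = pooled$ci_high, row = 0),
         pooled = pooled, zero_line = 0, n_rows = k + 1),
    class = c("forest_layout", "plot_layout")
  )
}

#' Bar plot layout
#'
#' Horizontal bars from the zero line of length `|smd|`, one row per study
#' in input order, as used by research clearinghouses for effect-size
#' displays. Hover text carries the student sample size; if `n_students`
#' is absent the layout is still valid but hover omits it (with a warning).
#' A summary bar for the pooled estimate is included as the bottom row.
#'
#' @inheritParams marc_layout
#' @return A list of class `"bar_layout"`: `marks` (with `bar_length`,
#'   `row`), `summary_bar`, `pooled`, `zero_line`, `n_rows`.
#' @export
bar_layout <- function(data, level = 0.95) {
  data <- validate_meta(data)
  pooled <- pool_fixed(data, level = level)
  k <- nrow(data)
  has_n <- "n_students" %in% names(data) && !anyNA(data$n_students)
  if (!has_n) {
    warn("`n_students` missing; bar hover text will omit sample size.")
    hover <- sprintf("Study %s\nSMD: %s", data$study_id,
                     formatC(data$smd, digits = 2, format = "f"))
  } else {
    hover <- sprintf("Study %s\nSMD: %s\n# of students: %d", data$study_id,
                     formatC(data$smd, digits = 2, format = "f"),
                     as.integer(data$n_students))
  }
  marks <- build_marks(data, y = k - seq_len(k) + 1, area = abs(data$smd),
                       hover = hover)
  marks$row <- seq_len(k)
  marks$bar_length <- abs(data$smd)
  structure(
    list(marks = marks,
         summary_bar = tibble::tibble(x = pooled$estimate,
                                      bar_length = abs(pooled$estimate),
                                      row = 0),
         pooled = pooled, zero_line = 0, n_rows = k + 1),
    class = c("bar_layout", "plot_layout")
  )
}

#' Randomize study labels
#'
#' Relabels studies with a seeded random permutation of fresh IDs, as done
#' when the same dataset is shown repeatedly in an experiment and labels
#' must not be matchable across displays.
#'
#' @inheritParams validate_meta
#' @param seed Integer seed for the permutation.
#' @param prefix Label prefix for the new IDs.
#' @return The tibble with `study_id` replaced.
#' @export
relabel_studies <- function(data, seed, prefix = "Study ") {
  data <- validate_meta(data)
  ids <- withr::with_seed(seed, sample(nrow(data)))
  dplyr::mutate(data, study_id = paste0(prefix, ids))
}
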