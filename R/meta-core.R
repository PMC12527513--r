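# Effect-size data model, inverse-variance weighting, fixed-effects pooling,
# and the CRT SMD sampling variance used by the simulator and the plots.

#' Validate a meta-analytic effect-size table
#'
#' A meta-analytic dataset is an ordinary data frame with one row per study
#' and at least the columns `study_id`, `smd` (standardized mean difference)
#' and `se` (its standard error). Optional columns carry sample-size
#' metadata: `n_students`, `n_clusters_t`, `n_clusters_c`, `cluster_size`.
#'
#' @param data A data frame of study effect sizes.
#' @return The input as a tibble, invisibly validated.
#' @examples
#' validate_meta(tibble::tibble(study_id = c("a", "b"),
#'                              smd = c(0.1, 0.3), se = c(0.1, 0.2)))
#' @export
validate_meta <- function(data) {
  if (!is.data.frame(data)) {
    abort("`data` must be a data frame of study effect sizes.")
  }
  data <- tibble::as_tibble(data)
  missing_cols <- setdiff(c("study_id", "smd", "se"), names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("`data` is missing required column(s): ",
                 paste0("`", missing_cols, "`", collapse = ", "), "."))
  }
  if (nrow(data) < 1) {
    abort("`data` must contain at least one study (k >= 1).")
  }
  ids <- as.character(data$study_id)
  if (anyNA(ids) || any(!nzchar(ids))) {
    abort("every `study_id` must be a non-empty label.")
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    abort(paste0("duplicate study_id(s): ",
                 paste0("'", dup, "'", collapse = ", "), "."))
  }
  bad <- !is.finite(data$se) | data$se <= 0
  if (any(bad)) {
    abort(paste0("`se` must be finite and > 0; offending study_id(s): ",
                 paste0("'", ids[bad], "'", collapse = ", "), "."))
  }
  if (any(!is.finite(data$smd))) {
    abort(paste0("`smd` must be finite; offending study_id(s): ",
                 paste0("'", ids[!is.finite(data$smd)], "'", collapse = ", "),
                 "."))
  }
  data
}

#' Inverse-variance weights for a meta-analytic dataset
#'
#' Computes the fixed-effects meta-analytic weight of each study,
#' \eqn{w_j = 1/se_j^2}, and its relative weight \eqn{w_j / \sum w_j} (the
#' study's share of the total evidence; the quantity a MARC plot maps to the
#' y axis and to dot size).
#'
#' @inheritParams validate_meta
#' @return The input tibble with columns `weight` (raw inverse-variance
#'   weight) and `rel_weight` (summing to 1) appended; row order preserved.
#' @examples
#' studies <- tibble::tibble(study_id = c("a", "b"),
#'                           smd = c(0.1, 0.3), se = c(0.1, 0.2))
#' compute_weights(studies)
#' @export
compute_weights <- function(data) {
  data <- validate_meta(data)
  w <- 1 / data$se^2
  dplyr::mutate(data, weight = w, rel_weight = w / sum(w))
}

#' Fixed-effects pooled estimate
#'
#' Pools study effect sizes under a fixed-effects (common-effect) model:
#' the estimate is the inverse-variance weighted mean
#' \eqn{\hat\delta = \sum w_j d_j / \sum w_j}, its standard error
#' \eqn{(\sum w_j)^{-1/2}}, and the confidence interval is the usual normal
#' (Wald) interval.
#'
#' @inheritParams validate_meta
#' @param level Confidence level in (0, 1); defaults to 0.95, the
#'   forest-plot convention.
#' @param method Pooling model; only `"fixed"` is implemented. The argument
#'   exists so random-effects pooling can be added without changing call
#'   sites.
#' @return An object of class `"pooled_effect"`: a list with elements
#'   `estimate`, `se`, `ci_low`, `ci_high`, `level`, `k`, and `method`.
#'   Use [tidy.pooled_effect()] / [glance.pooled_effect()] for tibbles.
#' @examples
#' studies <- tibble::tibble(study_id = c("a", "b"),
#'                           smd = c(0.1, 0.3), se = c(0.1, 0.2))
#' pool_fixed(studies)
#' @export
pool_fixed <- function(data, level = 0.95, method = c("fixed")) {
  method <- match.arg(method)
  data <- validate_meta(data)
  if (!is.numeric(level) || length(level) != 1 || level <= 0 || level >= 1) {
    abort("`level` must be a single number strictly between 0 and 1.")
  }
  w <- 1 / data$se^2
  est <- sum(w * data$smd) / sum(w)
  se <- 1 / sqrt(sum(w))
  z <- qnorm(1 - (1 - level) / 2)
  structure(
    list(estimate = est, se = se,
         ci_low = est - z * se, ci_high = est + z * se,
         level = level, k = nrow(data), method = method),
    class = "pooled_effect"
  )
}

#' @export
print.pooled_effect <- function(x, ...) {
  cat(sprintf("Fixed-effects pooled SMD (k = %d)\n", x$k))
  cat(sprintf("  estimate = %.4f  se = %.4f  %g%% CI [%.4f, %.4f]\n",
              x$estimate, x$se, 100 * x$level, x$ci_low, x$ci_high))
  invisible(x)
}

#' Tidy a pooled effect
#'
#' @param x A `"pooled_effect"` object from [pool_fixed()].
#' @param ... Unused.
#' @return A one-row tibble with `estimate`, `se`, `ci_low`, `ci_high`.
#' @export
tidy.pooled_effect <- function(x, ...) {
  tibble::tibble(term = "pooled_smd", estimate = x$estimate, se = x$se,
                 ci_low = x$ci_low, ci_high = x$ci_high)
}

#' Model-level summary of a pooled effect
#'
#' @inheritParams tidy.pooled_effect
#' @return A one-row tibble with `k`, `level`, and `method`.
#' @export
glance.pooled_effect <- function(x, ...) {
  tibble::tibble(k = x$k, level = x$level, method = x$method)
}

#' Generic tidiers
#'
#' `tidy()` returns a tibble of per-term results; `glance()` a one-row
#' model-level summary (the broom convention).
#' @param x An object.
#' @param ... Passed to methods.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Sampling variance of a CRT standardized mean difference
#'
#' Variance of the standardized mean difference from a two-arm
#' cluster-randomized trial when the effect is standardized by the *total*
#' (within- plus between-cluster) standard deviation, for equal cluster
#' sizes:
#' \deqn{v = \frac{N^T + N^C}{N^T N^C}\,(1 + (n - 1)\rho) + \frac{\delta^2}{2h},}
#' where \eqn{n} is the common cluster size, \eqn{N = N^T + N^C}, and
#' \deqn{h = \frac{[(N-2) - 2(n-1)\rho]^2}
#'   {(N-2)(1-\rho)^2 + n(N-2n)\rho^2 + 2(N-2n)\rho(1-\rho)}}
#' is the effective degrees of freedom of the total-variance estimate.
#' At \eqn{\rho = 0} this reduces to the familiar non-clustered form
#' \eqn{(N^T + N^C)/(N^T N^C) + \delta^2 / (2(N-2))}; the leading term is
#' the simple-random-sampling variance inflated by the design effect
#' \eqn{1 + (n-1)\rho}.
#'
#' @param n_total_t,n_total_c Total students in the treatment / control arm.
#' @param cluster_size Students per cluster \eqn{n} (common to all clusters);
#'   must not exceed either arm total. Arm totals that are not multiples of
#'   `cluster_size` are accepted: the formula uses totals and the common
#'   cluster size directly, so a non-integral cluster count is interpreted
#'   as an average cluster size.
#' @param rho Intraclass correlation \eqn{\rho \in [0, 1)}.
#' @param delta True standardized mean difference (enters the second-order
#'   term only).
#' @return The sampling variance of the SMD estimate (strictly positive).
#'   Vectorized over all arguments.
#' @examples
#' crt_smd_variance(50, 50, cluster_size = 1, rho = 0, delta = 0)  # 0.04
#' @export
crt_smd_variance <- function(n_total_t, n_total_c, cluster_size, rho, delta) {
  args <- vctrs_recycle(n_total_t = n_total_t, n_total_c = n_total_c,
                        cluster_size = cluster_size, rho = rho, delta = delta)
  with(args, {
    if (any(!is.finite(rho) | rho < 0 | rho >= 1)) {
      abort("`rho` must lie in [0, 1).")
    }
    if (any(n_total_t < 1 | n_total_c < 1)) {
      abort("arm totals must be positive.")
    }
    if (any(cluster_size < 1)) {
      abort("`cluster_size` must be >= 1.")
    }
    if (any(cluster_size > n_total_t | cluster_size > n_total_c)) {
      abort("`cluster_size` may not exceed either arm total.")
    }
    N <- n_total_t + n_total_c
    n <- cluster_size
    lead <- (N / (n_total_t * n_total_c)) * (1 + (n - 1) * rho)
    num <- (N - 2) * (1 - rho)^2 + n * (N - 2 * n) * rho^2 +
      2 * (N - 2 * n) * rho * (1 - rho)
    h <- ((N - 2) - 2 * (n - 1) * rho)^2 / num
    lead + delta^2 / (2 * h)
  })
}

# Recycle scalar arguments against the longest one (base-R stand-in for
# vctrs recycling; keeps crt_smd_variance vectorized without a dependency).
vctrs_recycle <- function(...) {
  args <- list(...)
  n <- max(lengths(args))
  bad <- lengths(args) != 1L & lengths(args) != n
  if (any(bad)) {
    abort(paste0("arguments must have length 1 or ", n, ": ",
                 paste(names(args)[bad], collapse = ", ")))
  }
  lapply(args, rep_len, length.out = n)
}
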