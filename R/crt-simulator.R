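# Generator of meta-analytic datasets: correlated lognormal sample sizes,
# CRT standard errors, unbiased normal effect-size draws around a true SMD.

#' Simulation configuration for the CRT meta-analysis generator
#'
#' Bundles the truth parameters of the data-generating model: each study is
#' a two-arm cluster-randomized trial with equal arm sizes, the true
#' standardized mean difference is `delta`, the intraclass correlation is
#' `rho`, and the (clusters per arm, students per cluster) pair is drawn
#' from a correlated bivariate lognormal.
#'
#' @param k Number of studies per dataset (>= 1).
#' @param delta True standardized mean difference. Default 0.15, a small
#'   effect on the education-research scale.
#' @param rho Intraclass correlation in \[0, 1). Default 0.20, a standard
#'   planning value for school-clustered achievement outcomes.
#' @param size_log_mean Length-2 vector of log-scale means for (clusters
#'   per arm, students per cluster). Defaults to `log(c(12, 40))`.
#' @param size_log_cov 2x2 log-scale covariance matrix (symmetric positive
#'   semi-definite). The default gives sdlog 0.4 and 0.5 with correlation
#'   -0.2 (larger trials tend to have slightly smaller clusters).
#' @param seed Integer RNG seed; every draw from the config is reproducible.
#' @param level Confidence level used when the simulator's output is pooled.
#' @return A list of class `"sim_config"`.
#' @examples
#' sim_config(k = 20, seed = 1)
#' @export
sim_config <- function(k = 20, delta = 0.15, rho = 0.2,
                       size_log_mean = log(c(12, 40)),
                       size_log_cov = matrix(c(0.4^2, -0.2 * 0.4 * 0.5,
                                               -0.2 * 0.4 * 0.5, 0.5^2), 2, 2),
                       seed = NULL, level = 0.95) {
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k != round(k)) {
    abort("`k` must be a single integer >= 1.")
  }
  if (!is.numeric(rho) || length(rho) != 1 || rho < 0 || rho >= 1) {
    abort("`rho` must lie in [0, 1).")
  }
  if (length(size_log_mean) != 2) {
    abort("`size_log_mean` must have length 2.")
  }
  size_log_cov <- as.matrix(size_log_cov)
  if (!all(dim(size_log_cov) == c(2, 2)) ||
      max(abs(size_log_cov - t(size_log_cov))) > 1e-8 ||
      any(eigen(size_log_cov, symmetric = TRUE,
                only.values = TRUE)$values < -1e-8)) {
    abort("`size_log_cov` must be a symmetric positive semi-definite 2x2 matrix.")
  }
  structure(
    list(k = as.integer(k), delta = delta, rho = rho,
         size_log_mean = as.numeric(size_log_mean),
         size_log_cov = size_log_cov,
         seed = if (is.null(seed)) NULL else as.integer(seed),
         level = level),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("CRT meta-analysis simulator config: k = %d, delta = %g, rho = %g\n",
              x$k, x$delta, x$rho))
  cat(sprintf("  size log-means (%.3f, %.3f), seed %s\n",
              x$size_log_mean[1], x$size_log_mean[2],
              if (is.null(x$seed)) "unset" else x$seed))
  invisible(x)
}

# Bivariate lognormal on the log scale; continuous draws, no rounding.
draw_lognormal_pairs <- function(n, mu, sigma) {
  exp(MASS::mvrnorm(n, mu = mu, Sigma = sigma))
}

#' Draw cluster/student sample sizes for simulated studies
#'
#' Draws `k` (clusters per arm, students per cluster) pairs from the
#' config's correlated lognormal, rounds half-up to integers with a floor
#' of 2 clusters per arm and 2 students per cluster (so CRT variances stay
#' finite), and assumes equal treatment and control arms.
#'
#' @param config A [sim_config()].
#' @param k Number of draws; defaults to `config$k`.
#' @return A tibble with columns `m_per_arm`, `n_per_cluster`,
#'   `n_total_t`, `n_total_c` (arm totals, `m_per_arm * n_per_cluster`).
#' @examples
#' draw_sample_sizes(sim_config(k = 3, seed = 7))
#' @export
draw_sample_sizes <- function(config, k = config$k) {
  stopifnot(inherits(config, "sim_config"))
  draw <- function() {
    raw <- draw_lognormal_pairs(k, config$size_log_mean, config$size_log_cov)
    m <- pmax(2L, as.integer(floor(raw[, 1] + 0.5)))
    n <- pmax(2L, as.integer(floor(raw[, 2] + 0.5)))
    tibble::tibble(m_per_arm = m, n_per_cluster = n,
                   n_total_t = m * n, n_total_c = m * n)
  }
  if (is.null(config$seed)) draw() else withr::with_seed(config$seed, draw())
}

#' Simulate one meta-analytic dataset
#'
#' Generates a dataset of `config$k` cluster-randomized trials: sample
#' sizes are drawn first (see [draw_sample_sizes()]), each study's standard
#' error is the square root of [crt_smd_variance()] at the drawn sizes and
#' the true `delta` and `rho`, and the observed effect is an unbiased
#' normal draw `smd ~ N(delta, se^2)`. The single seeded RNG stream is
#' consumed in documented order — all sizes first, then all effects — so
#' the size draws can be reproduced independently.
#'
#' @param config A [sim_config()].
#' @return A meta-analytic tibble (see [validate_meta()]) with columns
#'   `study_id`, `smd`, `se`, `n_students`, `n_clusters_t`, `n_clusters_c`,
#'   `cluster_size`.
#' @examples
#' simulate_meta(sim_config(k = 5, seed = 42))
#' @export
simulate_meta <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  run <- function() {
    sizes <- {
      raw <- draw_lognormal_pairs(config$k, config$size_log_mean,
                                  config$size_log_cov)
      m <- pmax(2L, as.integer(floor(raw[, 1] + 0.5)))
      n <- pmax(2L, as.integer(floor(raw[, 2] + 0.5)))
      tibble::tibble(m_per_arm = m, n_per_cluster = n,
                     n_total_t = m * n, n_total_c = m * n)
    }
    v <- crt_smd_variance(sizes$n_total_t, sizes$n_total_c,
                          sizes$n_per_cluster, config$rho, config$delta)
    se <- sqrt(v)
    tibble::tibble(
      study_id = sprintf("S%03d", seq_len(config$k)),
      smd = rnorm(config$k, mean = config$delta, sd = se),
      se = se,
      n_students = sizes$n_total_t + sizes$n_total_c,
      n_clusters_t = sizes$m_per_arm,
      n_clusters_c = sizes$m_per_arm,
      cluster_size = sizes$n_per_cluster
    )
  }
  if (is.null(config$seed)) run() else withr::with_seed(config$seed, run())
}

#' Summarize one or more simulated meta-analytic datasets
#'
#' Produces a per-dataset summary table in the shape of a meta-analytic
#' data overview: number of studies, fixed-effects pooled estimate with
#' standard error and confidence interval, the range of study standard
#' errors, and the total number of students.
#'
#' @param datasets A single meta-analytic data frame or a (possibly named)
#'   list of them.
#' @param level Confidence level for the pooled intervals.
#' @return A tibble with one row per dataset: `dataset`, `k`, `estimate`,
#'   `se`, `ci_low`, `ci_high`, `min_study_se`, `max_study_se`,
#'   `total_students`.
#' @examples
#' ds <- lapply(c(5, 10), function(k) simulate_meta(sim_config(k, seed = k)))
#' summarize_datasets(ds)
#' @export
summarize_datasets <- function(datasets, level = 0.95) {
  if (is.data.frame(datasets)) datasets <- list(datasets)
  if (length(datasets) < 1) abort("need at least one dataset.")
  nms <- names(datasets)
  if (is.null(nms) || any(!nzchar(nms))) {
    nms <- paste0("dataset", seq_along(datasets))
  }
  purrr::map2_dfr(datasets, nms, function(d, nm) {
    d <- validate_meta(d)
    p <- pool_fixed(d, level = level)
    tibble::tibble(
      dataset = nm, k = nrow(d),
      estimate = p$estimate, se = p$se,
      ci_low = p$ci_low, ci_high = p$ci_high,
      min_study_se = min(d$se), max_study_se = max(d$se),
      total_students = if ("n_students" %in% names(d))
        sum(d$n_students) else NA_integer_
    )
  })
}
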