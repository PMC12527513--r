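# Pre-registered analysis contracts: two-factor ANOVA with interaction on
# scores plus Tukey pairwise visualization comparisons, and a two-level
# mixed model for page durations (repeated measures nested within people).

#' Analyze scores: two-way ANOVA and Tukey pairwise comparisons
#'
#' Fits `score ~ viz * k` (both factors) by ordinary two-factor ANOVA with
#' interaction and computes Tukey-adjusted pairwise differences in mean
#' score for every visualization pair, with a standardized effect for each
#' pair (difference divided by the root mean squared error), controlling
#' the family-wise error rate at `1 - conf_level`.
#'
#' @param records Score records: tibble with `viz`, `k`, `score` (one row
#'   per participant-condition). Rows flagged `excluded` are dropped if an
#'   `excluded` column is present.
#' @param conf_level Family-wise confidence level for the Tukey intervals.
#' @return An object of class `"score_analysis"` with elements `anova`
#'   (tidy table: term, df, sumsq, meansq, statistic, p.value), `tukey`
#'   (tidy table: contrast, estimate, std_estimate, conf_low, conf_high,
#'   adj_p_value), `mse`, and `fit` (the underlying `aov` object).
#' @export
analyze_scores <- function(records, conf_level = 0.95) {
  records <- tibble::as_tibble(records)
  if ("excluded" %in% names(records)) {
    records <- dplyr::filter(records, !.data$excluded)
  }
  needed <- c("viz", "k", "score")
  if (!all(needed %in% names(records))) {
    abort("`records` needs columns `viz`, `k`, `score`.")
  }
  records <- dplyr::mutate(records, viz = factor(.data$viz),
                           k = factor(.data$k))
  if (nlevels(records$viz) < 2 || nlevels(records$k) < 2) {
    abort("need at least 2 levels of `viz` and of `k` with replication.")
  }
  cell_n <- dplyr::count(records, .data$viz, .data$k)
  if (nrow(cell_n) < nlevels(records$viz) * nlevels(records$k)) {
    abort("empty design cells: the interaction degrees of freedom are not estimable.")
  }
  fit <- aov(score ~ viz * k, data = records)
  an <- anova(fit)
  anova_tbl <- tibble::tibble(
    term = rownames(an), df = an$Df, sumsq = an$`Sum Sq`,
    meansq = an$`Mean Sq`, statistic = an$`F value`, p.value = an$`Pr(>F)`
  )
  mse <- anova_tbl$meansq[anova_tbl$term == "Residuals"]
  tk <- TukeyHSD(fit, which = "viz", conf.level = conf_level)$viz
  tukey_tbl <- tibble::tibble(
    contrast = rownames(tk),
    estimate = tk[, "diff"],
    std_estimate = tk[, "diff"] / sqrt(mse),
    conf_low = tk[, "lwr"], conf_high = tk[, "upr"],
    adj_p_value = tk[, "p adj"]
  )
  structure(
    list(anova = anova_tbl, tukey = tukey_tbl, mse = mse,
         conf_level = conf_level, fit = fit),
    class = "score_analysis"
  )
}

#' @export
print.score_analysis <- function(x, ...) {
  cat("Two-way ANOVA (score ~ viz * k)\n")
  print(as.data.frame(x$anova), row.names = FALSE, digits = 4)
  cat(sprintf("\nTukey pairwise visualization comparisons (FWER %g%%), MSE = %.3f\n",
              100 * (1 - x$conf_level), x$mse))
  print(as.data.frame(x$tukey), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @rdname analyze_scores
#' @param x A `"score_analysis"`.
#' @param ... Unused.
#' @export
tidy.score_analysis <- function(x, ...) x$tukey

#' @rdname analyze_scores
#' @export
glance.score_analysis <- function(x, ...) {
  inter <- x$anova[x$anova$term == "viz:k", ]
  tibble::tibble(mse = x$mse, interaction_f = inter$statistic,
                 interaction_p = inter$p.value)
}

#' Analyze page durations with a two-level mixed model
#'
#' Fits a linear mixed-effects model for page duration (seconds spent on a
#' visualization's questions) with repeated measurements nested within
#' participants: fixed effects for visualization type (treatment-coded
#' against a configurable reference), the number of studies centered at
#' its sample mean, and their interactions; a random intercept per
#' participant. With a centered k, the model intercept is the reference
#' visualization's mean duration at an average number of studies.
#'
#' @param sheets Tibble with `participant_id`, `viz`, `k`, and
#'   `page_duration`; rows flagged `excluded` are dropped if present.
#' @param reference Reference level of `viz` (default `"MARCv2"` when
#'   present, else the first level).
#' @return An object of class `"duration_analysis"` with `fixed` (tidy
#'   tibble: term, estimate, se, statistic), `ranef_sd` (participant
#'   intercept and residual SDs), `singular` (logical), `k_center`, and
#'   `fit` (the `lmerMod`).
#' @export
analyze_durations <- function(sheets, reference = NULL) {
  sheets <- tibble::as_tibble(sheets)
  if ("excluded" %in% names(sheets)) {
    sheets <- dplyr::filter(sheets, !.data$excluded)
  }
  needed <- c("participant_id", "viz", "k", "page_duration")
  if (!all(needed %in% names(sheets))) {
    abort("`sheets` needs columns `participant_id`, `viz`, `k`, `page_duration`.")
  }
  reps <- dplyr::count(sheets, .data$participant_id)
  if (all(reps$n < 2)) {
    abort("need >= 2 observations per participant for a within-person model.")
  }
  lv <- unique(as.character(sheets$viz))
  if (is.null(reference)) {
    reference <- if ("MARCv2" %in% lv) "MARCv2" else lv[1]
  }
  if (!reference %in% lv) abort("`reference` is not a level of `viz`.")
  k_center <- mean(as.numeric(sheets$k))
  d <- dplyr::mutate(sheets,
                     viz = stats::relevel(factor(.data$viz), ref = reference),
                     k_c = as.numeric(.data$k) - k_center)
  fit <- lme4::lmer(page_duration ~ viz * k_c + (1 | participant_id),
                    data = d, REML = TRUE)
  singular <- lme4::isSingular(fit)
  if (singular) {
    warn("mixed-model fit is singular (participant variance ~ 0); estimates reported anyway.")
  }
  co <- summary(fit)$coefficients
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(
    list(
      fixed = tibble::tibble(term = rownames(co), estimate = co[, "Estimate"],
                             se = co[, "Std. Error"],
                             statistic = co[, "t value"]),
      ranef_sd = setNames(vc$sdcor, vc$grp),
      singular = singular, reference = reference, k_center = k_center,
      fit = fit
    ),
    class = "duration_analysis"
  )
}

#' @export
print.duration_analysis <- function(x, ...) {
  cat(sprintf("Two-level model of page duration (reference: %s, k centered at %.1f)%s\n",
              x$reference, x$k_center,
              if (x$singular) " [singular fit]" else ""))
  print(as.data.frame(x$fixed), row.names = FALSE, digits = 4)
  cat("Random-effect SDs:\n")
  print(round(x$ranef_sd, 3))
  invisible(x)
}

#' @rdname analyze_durations
#' @param x A `"duration_analysis"`.
#' @param ... Unused.
#' @export
tidy.duration_analysis <- function(x, ...) x$fixed

#' @rdname analyze_durations
#' @export
glance.duration_analysis <- function(x, ...) {
  tibble::tibble(singular = x$singular,
                 sd_participant = x$ranef_sd[["participant_id"]],
                 sd_residual = x$ranef_sd[["Residual"]])
}
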