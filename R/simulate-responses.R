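# Synthetic respondents for exercising the experiment pipeline. These
# emulate the structure of survey data (scores out of 7, page durations
# with a per-person level), not any empirical human-subject result.

#' Simulate score records for a survey design
#'
#' Draws a score out of 7 for every participant-condition in a design as
#' `Binomial(7, p)`, with the per-cell probability of a correct answer on
#' the logit scale: `qlogis(base_p) + viz effect + k effect`. With all
#' effects zero this is an exchangeable null, suitable for calibration
#' studies of the score analysis.
#'
#' @param design A `"design_plan"` from [build_design()].
#' @param viz_effects,k_effects Named numeric vectors of logit shifts per
#'   factor level (missing levels get 0).
#' @param base_p Baseline probability of answering an item correctly.
#' @param seed Integer seed.
#' @return A score-record tibble: `participant_id`, `viz`, `k`, `score`.
#' @export
simulate_scores <- function(design, viz_effects = c(), k_effects = c(),
                            base_p = 0.6, seed = 1) {
  stopifnot(inherits(design, "design_plan"))
  cond <- design$conditions
  eff <- function(levels, effects) {
    out <- rep(0, length(levels))
    hit <- as.character(levels) %in% names(effects)
    out[hit] <- effects[as.character(levels)[hit]]
    out
  }
  p <- stats::plogis(stats::qlogis(base_p) +
                       eff(cond$viz, viz_effects) + eff(cond$k, k_effects))
  withr::with_seed(seed, {
    tibble::tibble(participant_id = cond$participant_id,
                   viz = cond$viz, k = cond$k,
                   score = stats::rbinom(nrow(cond), size = 7, prob = p))
  })
}

#' Simulate page durations for a survey design
#'
#' Generates per-condition page durations (seconds) with a participant
#' random intercept and additive visualization and centered-k effects:
#' `duration = mean + viz effect + slope_k * (k - mean k) + person + noise`.
#'
#' @param design A `"design_plan"`.
#' @param mean_duration Grand mean duration in seconds at the reference
#'   visualization and average k.
#' @param viz_effects Named numeric vector of additive shifts (seconds).
#' @param slope_k Seconds per unit of centered k.
#' @param sd_person Between-participant SD of the random intercept.
#' @param sd_resid Residual SD.
#' @param seed Integer seed.
#' @return A tibble: `participant_id`, `viz`, `k`, `page_duration`.
#' @export
simulate_durations <- function(design, mean_duration = 120,
                               viz_effects = c(), slope_k = 0,
                               sd_person = 30, sd_resid = 25, seed = 1) {
  stopifnot(inherits(design, "design_plan"))
  cond <- design$conditions
  withr::with_seed(seed, {
    person <- rnorm(design$n_participants, 0, sd_person)
    names(person) <- design$assignment$participant_id
    eff <- rep(0, nrow(cond))
    hit <- cond$viz %in% names(viz_effects)
    eff[hit] <- viz_effects[cond$viz[hit]]
    k_c <- as.numeric(cond$k) - mean(as.numeric(cond$k))
    tibble::tibble(
      participant_id = cond$participant_id, viz = cond$viz, k = cond$k,
      page_duration = pmax(1, mean_duration + eff + slope_k * k_c +
                             person[cond$participant_id] +
                             rnorm(nrow(cond), 0, sd_resid))
    )
  })
}

#' Simulate a long-format response sheet
#'
#' Produces item-level answers (Q1–Q8) for every participant-condition in
#' a design, against a supplied answer key, with a configurable
#' probability of answering each scored item correctly. Wrong
#' multiple-choice answers are drawn from a fixed distractor; the Q5
#' slider answer is the key value plus noise. Includes participant-level
#' `attention_passed` and `total_duration` columns so the sheet feeds
#' [score_responses()] directly.
#'
#' @param design A `"design_plan"`.
#' @param key Answer key (`question`, `correct`), one row per question.
#' @param p_correct Probability each scored item is answered correctly.
#' @param seed Integer seed.
#' @return A long response-sheet tibble.
#' @export
simulate_responses <- function(design, key = default_answer_key(),
                               p_correct = 0.7, seed = 1) {
  stopifnot(inherits(design, "design_plan"))
  cond <- design$conditions
  key <- tibble::as_tibble(key)
  withr::with_seed(seed, {
    grid <- tidyr::expand_grid(
      cond[, c("participant_id", "viz", "k")],
      question = paste0("Q", 1:8)
    ) |>
      dplyr::left_join(key[, c("question", "correct")], by = "question")
    hit <- stats::runif(nrow(grid)) < p_correct
    slider <- grid$question == "Q5"
    answer <- ifelse(hit, as.character(grid$correct), "distractor")
    slider_true <- as_num(grid$correct[slider])
    answer[slider] <- as.character(
      round(slider_true + ifelse(hit[slider], 0,
                                 sample(c(-0.2, 0.2), sum(slider), TRUE)), 3))
    dplyr::mutate(grid,
                  answer = answer,
                  attention_passed = TRUE,
                  total_duration = 600,
                  page_duration = 120,
                  correct = NULL)
  })
}

#' Default answer key skeleton
#'
#' A placeholder key covering Q1–Q8 for simulation and testing: items
#' Q1–Q4, Q6, Q7 have categorical answers, Q5 a slider value, and Q8 a
#' free-range answer that is never scored. Real studies supply their own
#' key.
#'
#' @param q5 True slider value for Q5.
#' @return A tibble with `question` and `correct`.
#' @export
default_answer_key <- function(q5 = 0.15) {
  tibble::tibble(
    question = paste0("Q", 1:8),
    correct = c("A", "B", "C", "D", as.character(q5), "A", "B", "0.1-0.2")
  )
}
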