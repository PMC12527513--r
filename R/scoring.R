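# Questionnaire scoring: seven 0/1-scored items (Q1-Q7) per viewed
# visualization, an exploratory item (Q8) that never enters the score, a
# slider item (Q5) scored within a tolerance, and participant-level
# exclusion rules (attention check, minimum total duration).

score_questions <- function() paste0("Q", 1:7)

#' Score questionnaire responses
#'
#' Scores each participant-condition response set against an answer key.
#' Items Q1–Q7 are scored 0/1 (correct/incorrect), so the score is an
#' integer out of 7; Q8 is exploratory and never counted. Q5 is a slider
#' on \[-0.5, 0.5\]: it is correct when the answer is within
#' `slider_tolerance` of the key, and answers outside the slider range are
#' flagged invalid. Participants who fail the attention check or whose
#' total survey duration is under `min_duration` seconds are marked
#' excluded (their rows carry `excluded = TRUE` and a reason; their scores
#' are still computed for audit).
#'
#' @param responses Long response sheet: one row per participant x
#'   condition x question with columns `participant_id`, `viz`, `k`,
#'   `question` ("Q1".."Q8"), `answer`, and participant-level columns
#'   `attention_passed` (logical) and `total_duration` (seconds); an
#'   optional `page_duration` column (seconds per condition) is carried
#'   through.
#' @param key Answer key: tibble with `question` and `correct` columns,
#'   either one row per question (same key for every condition) or keyed
#'   per condition with additional `viz` and `k` columns.
#' @param slider_tolerance Half-width within which the Q5 slider answer
#'   counts as correct. Default 0.05 (one tick of the slider's range).
#' @param min_duration Minimum total duration in seconds; below it the
#'   participant is excluded. Default 180 (the 3-minute rule).
#' @return A tibble with one row per participant-condition:
#'   `participant_id`, `viz`, `k`, `score` (0–7), `n_invalid` (answers
#'   outside the slider range), `excluded`, `exclusion_reason`, and
#'   `page_duration` if supplied.
#' @export
score_responses <- function(responses, key, slider_tolerance = 0.05,
                            min_duration = 180) {
  responses <- tibble::as_tibble(responses)
  needed <- c("participant_id", "viz", "k", "question", "answer",
              "attention_passed", "total_duration")
  missing_cols <- setdiff(needed, names(responses))
  if (length(missing_cols) > 0) {
    abort(paste0("`responses` is missing column(s): ",
                 paste0("`", missing_cols, "`", collapse = ", "), "."))
  }
  key <- tibble::as_tibble(key)
  if (!all(c("question", "correct") %in% names(key))) {
    abort("`key` needs `question` and `correct` columns.")
  }
  per_condition_key <- all(c("viz", "k") %in% names(key))
  covered <- unique(key$question)
  if (!all(paste0("Q", 1:8) %in% covered)) {
    abort("`key` must cover Q1..Q8.")
  }

  join_by <- if (per_condition_key) c("question", "viz", "k") else "question"
  scored <- responses |>
    dplyr::left_join(dplyr::rename(key, .key = "correct"), by = join_by) |>
    dplyr::mutate(
      .invalid = .data$question == "Q5" & is.finite(as_num(.data$answer)) &
        (as_num(.data$answer) < -0.5 | as_num(.data$answer) > 0.5),
      .correct = dplyr::case_when(
        .data$question == "Q5" & .data$.invalid ~ FALSE,
        .data$question == "Q5" ~
          abs(as_num(.data$answer) - as_num(.data$.key)) <= slider_tolerance,
        TRUE ~ as.character(.data$answer) == as.character(.data$.key)
      ),
      .correct = !is.na(.data$.correct) & .data$.correct
    )
  if (any(scored$.invalid)) {
    warn(sprintf("%d Q5 answer(s) outside the slider range [-0.5, 0.5].",
                 sum(scored$.invalid)))
  }

  dur_col <- "page_duration" %in% names(responses)
  out <- scored |>
    dplyr::filter(.data$question %in% score_questions()) |>
    dplyr::group_by(.data$participant_id, .data$viz, .data$k) |>
    dplyr::summarise(
      score = sum(.data$.correct),
      n_invalid = sum(.data$.invalid),
      attention_passed = .data$attention_passed[1],
      total_duration = .data$total_duration[1],
      page_duration = if (dur_col) .data$page_duration[1] else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::mutate(
      exclusion_reason = dplyr::case_when(
        !.data$attention_passed ~ "failed attention check",
        .data$total_duration < min_duration ~
          sprintf("total duration under %g s", min_duration),
        TRUE ~ NA_character_
      ),
      excluded = !is.na(.data$exclusion_reason)
    ) |>
    dplyr::select("participant_id", "viz", "k", "score", "n_invalid",
                  "page_duration", "excluded", "exclusion_reason")
  if (!dur_col) out$page_duration <- NULL
  out
}

as_num <- function(x) suppressWarnings(as.numeric(x))
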