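# Confounded 4x4 factorial design: visualization type x number of studies,
# confounded into 4 blocks per pattern so each participant sees 4 of the
# 16 treatment combinations, one per visualization type.

viz_levels_default <- c("MARCv1", "MARCv2", "BP", "FP")
k_levels_default <- c(10L, 20L, 50L, 100L)

# Default confounding patterns: Latin-square aliasing. Pattern p assigns
# block b, visualization v the k level with index (b-1 + m_p*(v-1)) mod 4,
# with multiplier m_p in {1, 2, 3}. Every pattern partitions the 16
# combinations into 4 blocks, each containing each visualization once.
default_patterns <- function(k_levels = k_levels_default) {
  lapply(1:3, function(m) {
    outer(0:3, 0:3, function(b, v) (b + m * v) %% 4 + 1)
  })
}

validate_patterns <- function(patterns, n_viz = 4, n_k = 4) {
  if (!is.list(patterns) || length(patterns) < 1) {
    abort("`patterns` must be a non-empty list of block-by-viz index matrices.")
  }
  for (i in seq_along(patterns)) {
    p <- patterns[[i]]
    if (!is.matrix(p) || !all(dim(p) == c(n_viz, n_k))) {
      abort(sprintf("pattern %d must be a %dx%d matrix of k-level indices.",
                    i, n_viz, n_k))
    }
    if (!all(p %in% seq_len(n_k))) {
      abort(sprintf("pattern %d contains k-level indices outside 1..%d.",
                    i, n_k))
    }
    # blocks must partition all (viz, k) combinations
    combos <- paste(col(p), p)
    if (anyDuplicated(combos)) {
      abort(sprintf(
        "pattern %d does not partition the %d treatment combinations.",
        i, n_viz * n_k))
    }
  }
  patterns
}

#' Build a confounded factorial survey design
#'
#' Constructs the survey design for a 4 x 4 factorial experiment
#' (visualization type x number of studies k) in which the 16 treatment
#' combinations are confounded into 4 blocks so that each participant
#' views only 4 visualizations — one of each visualization type, with
#' varying k. Several confounding patterns (default 3) are used so that
#' interactions remain estimable in some replicates; patterns x blocks
#' survey blocks result (12 by default). Participants are assigned to
#' survey blocks evenly (imbalance at most 1) and at random, and each
#' participant's 4 conditions are presented in random order.
#'
#' @param n_participants Number of participants (>= 1).
#' @param seed Integer seed driving block assignment and condition order.
#' @param viz_levels,k_levels Factor levels; defaults are the four
#'   visualization types `MARCv1`, `MARCv2`, `BP`, `FP` and
#'   k = 10, 20, 50, 100.
#' @param patterns Optional list of confounding patterns, each a
#'   `length(viz_levels) x length(k_levels)`-consistent matrix `P` with
#'   `P[b, v]` the k-level index shown in block `b` for visualization `v`.
#'   Each pattern must partition all treatment combinations across blocks
#'   (validated). Defaults to three Latin-square aliasing patterns.
#' @return A list of class `"design_plan"`: `survey_blocks` (tibble of
#'   pattern, block, viz, k), `assignment` (tibble of participant_id,
#'   pattern, block), `conditions` (one row per participant-condition with
#'   presentation `position`), and counts (`n_combinations`,
#'   `n_survey_blocks`, `conditions_per_participant`, `full_replicates` =
#'   `floor(n_participants / n_combinations)`).
#' @examples
#' design <- build_design(16, seed = 1)
#' design$n_survey_blocks
#' @export
build_design <- function(n_participants, seed = 1,
                         viz_levels = viz_levels_default,
                         k_levels = k_levels_default,
                         patterns = NULL) {
  if (!is.numeric(n_participants) || length(n_participants) != 1 ||
      n_participants < 1) {
    abort("`n_participants` must be a single count >= 1.")
  }
  n_participants <- as.integer(n_participants)
  n_viz <- length(viz_levels)
  n_k <- length(k_levels)
  if (is.null(patterns)) patterns <- default_patterns(k_levels)
  patterns <- validate_patterns(patterns, n_viz = n_viz, n_k = n_k)

  survey_blocks <- purrr::map_dfr(seq_along(patterns), function(p) {
    m <- patterns[[p]]
    tidyr::expand_grid(block = seq_len(n_viz), viz_i = seq_len(n_k)) |>
      dplyr::mutate(pattern = p,
                    viz = viz_levels[.data$viz_i],
                    k = k_levels[m[cbind(.data$block, .data$viz_i)]]) |>
      dplyr::select("pattern", "block", "viz", "k")
  })
  block_ids <- dplyr::distinct(survey_blocks, pattern, block)
  n_blocks <- nrow(block_ids)

  assignment <- withr::with_seed(seed, {
    # even assignment: cycle a random block order, extras land on random
    # blocks, then shuffle across participants
    slots <- rep(sample(n_blocks), length.out = n_participants)
    slots <- sample(slots)
    dplyr::bind_cols(
      tibble::tibble(participant_id = sprintf("P%04d", seq_len(n_participants))),
      block_ids[slots, ]
    )
  })

  conditions <- assignment |>
    dplyr::left_join(survey_blocks, by = c("pattern", "block"),
                     relationship = "many-to-many")
  conditions <- withr::with_seed(seed + 1L, {
    conditions |>
      dplyr::group_by(participant_id) |>
      dplyr::mutate(position = sample(dplyr::n())) |>
      dplyr::ungroup() |>
      dplyr::arrange(participant_id, position)
  })

  structure(
    list(survey_blocks = survey_blocks, assignment = assignment,
         conditions = conditions,
         viz_levels = viz_levels, k_levels = k_levels,
         n_participants = n_participants,
         n_combinations = n_viz * n_k,
         n_survey_blocks = n_blocks,
         conditions_per_participant = n_viz,
         full_replicates = n_participants %/% (n_viz * n_k),
         seed = as.integer(seed)),
    class = "design_plan"
  )
}

#' @export
print.design_plan <- function(x, ...) {
  cat(sprintf("Confounded factorial design: %d x %d = %d combinations\n",
              length(x$viz_levels), length(x$k_levels), x$n_combinations))
  cat(sprintf("  %d survey blocks, %d participants (%d conditions each), %d full replicates\n",
              x$n_survey_blocks, x$n_participants,
              x$conditions_per_participant, x$full_replicates))
  invisible(x)
}

#' Tidy a design plan
#'
#' @param x A `"design_plan"` from [build_design()].
#' @param ... Unused.
#' @return A tibble with one row per participant-condition: participant
#'   id, pattern, block, viz, k, and presentation position.
#' @export
tidy.design_plan <- function(x, ...) {
  x$conditions
}
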