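# Shared fixtures and independent oracles, built in code.

toy_meta <- function() {
  tibble::tibble(study_id = c("a", "b"), smd = c(0.1, 0.3), se = c(0.1, 0.2))
}

random_meta <- function(k, seed) {
  withr::with_seed(seed, tibble::tibble(
    study_id = paste0("s", seq_len(k)),
    smd = rnorm(k, 0.2, 0.4),
    se = runif(k, 0.02, 0.6)
  ))
}

# Brute-force fixed-effects pooling: explicit accumulation loops, no reuse
# of package internals.
pool_oracle <- function(smd, se, level = 0.95) {
  sw <- 0
  swd <- 0
  for (j in seq_along(smd)) {
    w <- 1 / (se[j] * se[j])
    sw <- sw + w
    swd <- swd + w * smd[j]
  }
  est <- swd / sw
  s <- 1 / sqrt(sw)
  z <- qnorm(1 - (1 - level) / 2)
  list(estimate = est, se = s, ci_low = est - z * s, ci_high = est + z * s)
}

# Non-clustered large-sample SMD variance with the (N - 2) df convention.
smd_variance_simple <- function(n1, n2, d) {
  (n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2 - 2))
}

# A full-credit long response sheet for one participant viewing the four
# conditions of one design block.
sheet_for <- function(answers, key = default_answer_key(),
                      total_duration = 600, attention = TRUE) {
  tibble::tibble(
    participant_id = "P1", viz = "MARCv2", k = 20,
    question = paste0("Q", seq_along(answers)),
    answer = answers,
    attention_passed = attention,
    total_duration = total_duration,
    page_duration = 120
  )
}
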