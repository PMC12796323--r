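# Shared fixture builders; everything is generated in code at test time.

# A trial table with `reps` trials at every level of a design's grid,
# built directly (faster than block-wise enumeration for Monte-Carlo sizes).
grid_trials <- function(design, reps, task = design$task,
                        condition = "none", participant = "P01") {
  s <- rep(design$levels, each = reps)
  data.frame(participant = participant, task = task, block = 1L,
             trial_index = seq_along(s), asynchrony_ms = s,
             condition = condition, response = NA_character_,
             stringsAsFactors = FALSE)
}

# Both-task trial table for one participant at `reps` trials per level.
both_task_trials <- function(design, reps) {
  rbind(grid_trials(design, reps, task = "ownership"),
        grid_trials(design, reps, task = "simultaneity"))
}

# A trial table with prescribed yes-counts per signed level.
counts_to_trials <- function(levels, n, n_yes, task = "ownership") {
  do.call(rbind, lapply(seq_along(levels), function(i) {
    data.frame(participant = "P01", task = task, block = 1L,
               trial_index = seq_len(n[i]), asynchrony_ms = levels[i],
               condition = "none",
               response = rep(c("yes", "no"), c(n_yes[i], n[i] - n_yes[i])),
               stringsAsFactors = FALSE)
  }))
}

# Analytic spectrum object (no signal behind it) for estimator edge cases.
analytic_spectrum <- function(freqs, power) {
  structure(list(freqs = freqs, power = power,
                 resolution = freqs[2] - freqs[1], n_segments = 1L,
                 window_s = NA, overlap = NA,
                 padded_length = NA, fs = NA),
            class = "eeg_spectrum")
}

# Independent posterior log-odds of a common cause, re-derived from the
# generative densities (oracle for the closed-form threshold).
oracle_log_odds <- function(x, p_same, sigma, sigma_s) {
  log(p_same) + dnorm(x, 0, sigma, log = TRUE) -
    log(1 - p_same) - dnorm(x, 0, sqrt(sigma^2 + sigma_s^2), log = TRUE)
}
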