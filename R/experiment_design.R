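#' Asynchrony designs of the visuotactile judgment experiments
#'
#' Four fixed designs are encoded, one per experiment/task combination of the
#' study: a body-ownership judgment task with widely spaced asynchronies
#' (`"E1_own"`), a fine-grained simultaneity judgment task (`"E1_sim"`), the
#' EEG experiment design shared by both tasks (`"E2"`), and the reduced
#' brain-stimulation design (`"E3"`). Each design is a symmetric grid of
#' signed visuotactile asynchronies (ms; negative = rubber hand touched
#' first), with a fixed number of repetitions of every asynchrony per block.
#'
#' @param experiment_id One of `"E1_own"`, `"E1_sim"`, `"E2"`, `"E3"`.
#' @param task `"ownership"` or `"simultaneity"`. For `"E1_own"`/`"E1_sim"`
#'   the task is implied and the argument may be omitted.
#'
#' @return An object of class `asynchrony_design`: a list with fields
#'   `experiment`, `task`, `levels` (signed ms), `reps_per_block`,
#'   `n_blocks`, `taps_per_trial`, `trial_duration_s`,
#'   `intertap_jitter_ms` (metadata only, unused by the model) and
#'   `sigma_s` (ms), the fixed standard deviation of the asynchrony
#'   distribution assumed under the separate-causes hypothesis of the
#'   causal-inference model (293 ms for E2, 290 ms for E3; `NA` for the
#'   first experiment, where the model is not fitted).
#' @export
#' @examples
#' d <- build_design("E2", "ownership")
#' length(d$levels) * d$reps_per_block  # trials per block: 45
build_design <- function(experiment_id,
                         task = c("ownership", "simultaneity")) {
  specs <- list(
    E1_own = list(levels = c(0, 50, 150, 300, 500), reps = 4L, blocks = 3L,
                  task = "ownership", taps = 6L, dur = 12,
                  jitter = c(2000, 2000), sigma_s = NA_real_),
    E1_sim = list(levels = c(0, 50, 100, 150, 200, 300, 400, 500),
                  reps = 12L, blocks = 2L, task = "simultaneity",
                  taps = 1L, dur = 1, jitter = c(2000, 3500),
                  sigma_s = NA_real_),
    E2 = list(levels = c(0, 100, 200, 300, 400), reps = 5L, blocks = 3L,
              task = NA, taps = 6L, dur = 7.2, jitter = c(1100, 1300),
              sigma_s = 293),
    E3 = list(levels = c(0, 100, 200, 400), reps = 5L, blocks = 2L,
              task = NA, taps = 6L, dur = 6.6, jitter = c(1000, 1200),
              sigma_s = 290)
  )
  if (!experiment_id %in% names(specs))
    stop_vtbci(sprintf("unknown experiment design '%s' (expected one of %s)",
                       experiment_id, paste(names(specs), collapse = ", ")),
               "vtbci_unknown_design")
  sp <- specs[[experiment_id]]
  task <- if (!is.na(sp$task)) sp$task else match.arg(task)
  levels <- sort(c(-sp$levels[sp$levels > 0], sp$levels))
  structure(list(
    experiment = experiment_id,
    task = task,
    levels = levels,
    reps_per_block = sp$reps,
    n_blocks = sp$blocks,
    taps_per_trial = sp$taps,
    trial_duration_s = sp$dur,
    intertap_jitter_ms = sp$jitter,
    sigma_s = sp$sigma_s
  ), class = "asynchrony_design")
}

#' @export
print.asynchrony_design <- function(x, ...) {
  cat(sprintf("Asynchrony design %s (%s task)\n", x$experiment, x$task))
  cat(sprintf("  levels (ms): %s\n", paste(x$levels, collapse = ", ")))
  cat(sprintf("  %d reps/level/block x %d blocks (%d trials/block)\n",
              x$reps_per_block, x$n_blocks,
              length(x$levels) * x$reps_per_block))
  if (!is.na(x$sigma_s))
    cat(sprintf("  sigma_s = %g ms\n", x$sigma_s))
  invisible(x)
}

#' Enumerate randomized trials from a design
#'
#' Expands a design into a trial table: within every block each asynchrony
#' level appears exactly `reps_per_block` times, in an order shuffled
#' uniformly at random (deterministically for a fixed seed).
#'
#' @param design An [build_design()] object.
#' @param n_blocks Number of blocks (default: the design's `n_blocks`).
#' @param seed Integer seed for the trial-order shuffle, or `NULL` to use
#'   the current RNG stream.
#' @param participant Participant identifier written into every row.
#' @param condition Stimulation condition label (`"none"`, `"low"`,
#'   `"sham"` or `"high"`).
#'
#' @return A `data.frame` with columns `participant`, `task`, `block`,
#'   `trial_index`, `asynchrony_ms`, `condition`, `response` (initialised
#'   to `NA`; filled by the simulators or by real data).
#' @export
enumerate_trials <- function(design, n_blocks = design$n_blocks, seed = NULL,
                             participant = "P01", condition = "none") {
  stopifnot(inherits(design, "asynchrony_design"), n_blocks >= 0)
  per_block <- rep(design$levels, each = design$reps_per_block)
  with_seed(seed, {
    rows <- lapply(seq_len(n_blocks), function(b) {
      data.frame(
        participant = participant,
        task = design$task,
        block = b,
        trial_index = seq_along(per_block),
        asynchrony_ms = sample(per_block),
        condition = condition,
        response = NA_character_,
        stringsAsFactors = FALSE
      )
    })
    if (n_blocks == 0L) empty_trial_table() else do.call(rbind, rows)
  })
}

empty_trial_table <- function() {
  data.frame(participant = character(), task = character(),
             block = integer(), trial_index = integer(),
             asynchrony_ms = numeric(), condition = character(),
             response = character(), stringsAsFactors = FALSE)
}

trial_table_columns <- c("participant", "task", "block", "trial_index",
                         "asynchrony_ms", "condition", "response")

#' Read / write trial tables
#'
#' Trial tables are plain comma-separated text with a header row and columns
#' `participant, task, block, trial_index, asynchrony_ms, condition,
#' response`.
#'
#' @param trials A trial-table `data.frame`.
#' @param path File path.
#' @return `read_trials()` returns the trial table; `write_trials()` returns
#'   `path` invisibly.
#' @export
write_trials <- function(trials, path) {
  stopifnot(all(trial_table_columns %in% names(trials)))
  utils::write.csv(trials[, trial_table_columns], path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  missing <- setdiff(trial_table_columns, names(tr))
  if (length(missing))
    stop_vtbci(paste("trial table missing columns:",
                     paste(missing, collapse = ", ")),
               "vtbci_bad_table")
  tr$response <- as.character(tr$response)
  tr
}
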