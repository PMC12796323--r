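#' Model observers for response simulation
#'
#' `bci_observer()` bundles the parameters of the causal-inference
#' observer: task-specific common-cause priors, sensory noise SD, lapse
#' rate, and the fixed stimulus-distribution SD. `gaussian_observer()`
#' describes a purely descriptive observer whose yes-probability is a
#' scaled Gaussian of the asynchrony — the generative counterpart of the
#' temporal-binding-window fit.
#'
#' @param p_same_own,p_same_sim Common-cause priors for the body-ownership
#'   and simultaneity tasks, in (0, 1).
#' @param sigma Sensory noise SD (ms).
#' @param lapse Lapse probability in \[0, 1\].
#' @param sigma_s Stimulus-distribution SD (ms).
#' @return A parameter list of class `bci_observer` /
#'   `gaussian_observer`.
#' @export
bci_observer <- function(p_same_own = 0.7, p_same_sim = 0.7, sigma = 150,
                         lapse = 0.02, sigma_s = 293) {
  stopifnot(p_same_own > 0, p_same_own < 1, p_same_sim > 0, p_same_sim < 1,
            sigma > 0, lapse >= 0, lapse <= 1, sigma_s > 0)
  structure(list(p_same_own = p_same_own, p_same_sim = p_same_sim,
                 sigma = sigma, lapse = lapse, sigma_s = sigma_s),
            class = "bci_observer")
}

#' @rdname bci_observer
#' @param amplitude Peak yes-probability in (0, 1\].
#' @param mu Centre of the Gaussian (ms).
#' @param sd Width of the Gaussian (ms) — the true temporal binding window.
#' @export
gaussian_observer <- function(amplitude = 0.95, mu = 0, sd = 150) {
  stopifnot(amplitude > 0, amplitude <= 1, sd > 0)
  structure(list(amplitude = amplitude, mu = mu, sd = sd),
            class = "gaussian_observer")
}

#' Simulate yes/no responses from the causal-inference observer
#'
#' For every trial a noisy measurement `x ~ Normal(s, sigma^2)` is drawn
#' and the observer reports yes iff `x^2 < K` (see
#' [decision_threshold()]; when `K` is undefined, never via the decision
#' rule). With probability `lapse` the decision is replaced by a fair coin
#' flip. The task column selects the applicable prior. Per-condition noise
#' can be injected via `sigma_by_condition` to emulate a
#' stimulation-modulated observer.
#'
#' @param observer A [bci_observer()].
#' @param trials Trial table (responses are overwritten).
#' @param seed RNG seed or `NULL`.
#' @param sigma_by_condition Optional named vector of noise SDs keyed by
#'   condition label, overriding `observer$sigma` per trial.
#' @return The trial table with `response` filled in.
#' @export
simulate_bci_responses <- function(observer, trials, seed = NULL,
                                   sigma_by_condition = NULL) {
  stopifnot(inherits(observer, "bci_observer"))
  n <- nrow(trials)
  if (n == 0L) return(trials)
  p_same <- ifelse(trials$task == "ownership",
                   observer$p_same_own, observer$p_same_sim)
  sigma <- if (is.null(sigma_by_condition)) rep(observer$sigma, n)
           else unname(sigma_by_condition[trials$condition])
  if (anyNA(sigma))
    stop_vtbci("sigma_by_condition missing a condition present in trials",
               "vtbci_bad_input")
  th <- decision_threshold(p_same, sigma, observer$sigma_s)
  with_seed(seed, {
    x <- stats::rnorm(n, trials$asynchrony_ms, sigma)
    decide <- th$defined & (x^2 < th$K)
    lapsing <- stats::runif(n) < observer$lapse
    coin <- stats::runif(n) < 0.5
    yes <- ifelse(lapsing, coin, decide)
    trials$response <- ifelse(yes, "yes", "no")
    trials
  })
}

#' Simulate yes/no responses from the Gaussian observer
#'
#' Yes with probability `amplitude * exp(-(s - mu)^2 / (2 sd^2))`,
#' independently per trial.
#'
#' @inheritParams simulate_bci_responses
#' @param observer A [gaussian_observer()].
#' @return The trial table with `response` filled in.
#' @export
simulate_gaussian_observer <- function(observer, trials, seed = NULL) {
  stopifnot(inherits(observer, "gaussian_observer"))
  n <- nrow(trials)
  if (n == 0L) return(trials)
  p <- observer$amplitude *
    exp(-(trials$asynchrony_ms - observer$mu)^2 / (2 * observer$sd^2))
  with_seed(seed, {
    trials$response <- ifelse(stats::runif(n) < p, "yes", "no")
    trials
  })
}

#' Specification of a synthetic EEG-like signal
#'
#' A single-channel signal made of an alpha-band sinusoid of known
#' frequency riding on a 1/f-shaped ("aperiodic") noise background plus
#' white measurement noise — the minimal structure the spectral stage must
#' handle.
#'
#' @param fs Sampling rate (Hz); must exceed twice the alpha frequency.
#' @param duration_s Signal duration (s); default 240 (a 4-minute
#'   resting-state recording).
#' @param alpha_freq Oscillation frequency (Hz).
#' @param alpha_amp Oscillation amplitude (arbitrary units).
#' @param aperiodic_offset log10-power offset of the background.
#' @param aperiodic_exponent Background decay: power proportional to
#'   `10^offset / f^exponent`; must be >= 0.
#' @param noise_sd SD of additive white noise.
#' @return A list of class `eeg_spec`.
#' @export
eeg_spec <- function(fs = 512, duration_s = 240, alpha_freq = 10,
                     alpha_amp = 1, aperiodic_offset = 0,
                     aperiodic_exponent = 1, noise_sd = 0.1) {
  stopifnot(fs > 2 * alpha_freq, duration_s > 0, aperiodic_exponent >= 0)
  structure(list(fs = fs, duration_s = duration_s, alpha_freq = alpha_freq,
                 alpha_amp = alpha_amp, aperiodic_offset = aperiodic_offset,
                 aperiodic_exponent = aperiodic_exponent,
                 noise_sd = noise_sd),
            class = "eeg_spec")
}

#' Synthesize an EEG-like signal
#'
#' The aperiodic background is realised by spectrally shaping white
#' Gaussian noise in the frequency domain (amplitude scaled by
#' `sqrt(10^offset / f^exponent)`, DC removed), which is deterministic
#' given the seed. The sinusoid's phase is drawn uniformly.
#'
#' @param spec An [eeg_spec()].
#' @param seed RNG seed or `NULL`.
#' @return Numeric vector of samples with attributes `fs` and `spec`.
#' @export
synthesize_eeg <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "eeg_spec"))
  n <- round(spec$fs * spec$duration_s)
  t <- (seq_len(n) - 1) / spec$fs
  with_seed(seed, {
    phase <- stats::runif(1, 0, 2 * pi)
    osc <- spec$alpha_amp * sin(2 * pi * spec$alpha_freq * t + phase)
    w <- stats::rnorm(n)
    # two-sided frequency grid of the DFT
    f <- spec$fs * c(0, seq_len(n - 1)) / n
    f <- pmin(f, spec$fs - f)  # fold to physical frequency
    gain <- sqrt(10^spec$aperiodic_offset / pmax(f, .Machine$double.eps) ^
                   spec$aperiodic_exponent)
    gain[1] <- 0  # no DC
    shaped <- Re(stats::fft(stats::fft(w) * gain, inverse = TRUE)) / n
    white <- if (spec$noise_sd > 0) stats::rnorm(n, 0, spec$noise_sd) else 0
    sig <- osc + shaped + white
    attr(sig, "fs") <- spec$fs
    attr(sig, "spec") <- spec
    sig
  })
}

#' Default cohort parameter priors
#'
#' Uniform sampling ranges bracketing plausible fitted values of the
#' observer parameters and the individual alpha frequency.
#'
#' @param p_same,sigma,lapse,alpha_freq Length-2 numeric ranges.
#' @return A named list of ranges.
#' @export
cohort_priors <- function(p_same = c(0.3, 0.95), sigma = c(60, 350),
                          lapse = c(0, 0.1), alpha_freq = c(8.5, 12.5)) {
  list(p_same = p_same, sigma = sigma, lapse = lapse,
       alpha_freq = alpha_freq)
}

#' Simulate a cohort of linked observers
#'
#' Draws `n_participants` observers from the priors, optionally coupling
#' the sensory noise to the alpha frequency through a linear link
#' `sigma = intercept + slope * alpha_freq + Normal(0, noise)` (truncated
#' below at 1 ms), then generates behavioural trials for both tasks from
#' the causal-inference observer and an EEG spec per participant. With a
#' negative slope this reproduces the qualitative structure in which
#' faster alpha goes with less uncertain asynchrony information.
#'
#' @param n_participants Cohort size.
#' @param design An [build_design()] object (both tasks are simulated on
#'   its grid; its `sigma_s` is used when defined, else 293 ms).
#' @param priors See [cohort_priors()].
#' @param iaf_link `NULL`, or `list(slope =, intercept =, noise =)` in
#'   ms/Hz, ms, ms.
#' @param seed RNG seed or `NULL`.
#' @param alpha_amp,noise_sd,eeg_duration_s EEG generation settings shared
#'   by the cohort.
#' @return A list with `params` (one row per participant: truth),
#'   `trials` (all participants, both tasks) and `eeg_specs` (list of
#'   [eeg_spec()], one per participant).
#' @export
simulate_cohort <- function(n_participants, design = build_design("E2"),
                            priors = cohort_priors(), iaf_link = NULL,
                            seed = NULL, alpha_amp = 1, noise_sd = 0.1,
                            eeg_duration_s = 240) {
  sigma_s <- if (is.na(design$sigma_s)) 293 else design$sigma_s
  with_seed(seed, {
    if (n_participants == 0L) {
      return(list(params = data.frame(), trials = empty_trial_table(),
                  eeg_specs = list()))
    }
    u <- function(rng, n) stats::runif(n, rng[1], rng[2])
    n <- n_participants
    params <- data.frame(
      participant = sprintf("S%02d", seq_len(n)),
      p_same_own = u(priors$p_same, n),
      p_same_sim = u(priors$p_same, n),
      sigma = u(priors$sigma, n),
      lapse = u(priors$lapse, n),
      alpha_freq = u(priors$alpha_freq, n),
      stringsAsFactors = FALSE
    )
    if (!is.null(iaf_link)) {
      params$sigma <- iaf_link$intercept +
        iaf_link$slope * params$alpha_freq +
        stats::rnorm(n, 0, iaf_link$noise)
      params$sigma <- pmax(params$sigma, 1)
    }
    own <- design; own$task <- "ownership"
    sim <- design; sim$task <- "simultaneity"
    trials <- do.call(rbind, lapply(seq_len(n), function(i) {
      obs <- bci_observer(params$p_same_own[i], params$p_same_sim[i],
                          params$sigma[i], params$lapse[i], sigma_s)
      rbind(
        simulate_bci_responses(obs, enumerate_trials(
          own, participant = params$participant[i])),
        simulate_bci_responses(obs, enumerate_trials(
          sim, participant = params$participant[i]))
      )
    }))
    eeg_specs <- lapply(seq_len(n), function(i) {
      eeg_spec(fs = 512, duration_s = eeg_duration_s,
               alpha_freq = params$alpha_freq[i], alpha_amp = alpha_amp,
               aperiodic_offset = 0, aperiodic_exponent = 1,
               noise_sd = noise_sd)
    })
    names(eeg_specs) <- params$participant
    list(params = params, trials = trials, eeg_specs = eeg_specs)
  })
}

#' Simulate a stimulation-condition cohort with condition-dependent noise
#'
#' Every participant is measured under the three stimulation conditions
#' (low / sham / high) on the same design; the sensory noise is scaled per
#' condition (`sigma_factors`), while the common-cause priors stay
#' constant — the generative regime under which the noise-modulation model
#' variant is the true model.
#'
#' @param n_participants Cohort size.
#' @param design Design for each condition block (default the reduced
#'   stimulation design).
#' @param priors See [cohort_priors()]; `sigma` here is the sham-condition
#'   noise.
#' @param sigma_factors Named multipliers for the three conditions.
#' @param seed RNG seed or `NULL`.
#' @return A list with `params` (truth, including per-condition sigmas)
#'   and `trials`.
#' @export
simulate_tacs_cohort <- function(n_participants,
                                 design = build_design("E3"),
                                 priors = cohort_priors(),
                                 sigma_factors = c(low = 1.5, sham = 1,
                                                   high = 0.7),
                                 seed = NULL) {
  sigma_s <- if (is.na(design$sigma_s)) 290 else design$sigma_s
  with_seed(seed, {
    u <- function(rng, n) stats::runif(n, rng[1], rng[2])
    n <- n_participants
    params <- data.frame(
      participant = sprintf("S%02d", seq_len(n)),
      p_same_own = u(priors$p_same, n),
      p_same_sim = u(priors$p_same, n),
      sigma_sham = u(priors$sigma, n),
      lapse = u(priors$lapse, n),
      stringsAsFactors = FALSE
    )
    params$sigma_low <- pmin(params$sigma_sham * sigma_factors[["low"]], 990)
    params$sigma_high <- pmax(params$sigma_sham * sigma_factors[["high"]], 2)
    own <- design; own$task <- "ownership"
    sim <- design; sim$task <- "simultaneity"
    trials <- do.call(rbind, lapply(seq_len(n), function(i) {
      obs <- bci_observer(params$p_same_own[i], params$p_same_sim[i],
                          params$sigma_sham[i], params$lapse[i], sigma_s)
      sbc <- c(low = params$sigma_low[i], sham = params$sigma_sham[i],
               high = params$sigma_high[i])
      do.call(rbind, lapply(c("low", "sham", "high"), function(cond) {
        rbind(
          simulate_bci_responses(obs, enumerate_trials(
            own, participant = params$participant[i], condition = cond),
            sigma_by_condition = sbc),
          simulate_bci_responses(obs, enumerate_trials(
            sim, participant = params$participant[i], condition = cond),
            sigma_by_condition = sbc)
        )
      }))
    }))
    list(params = params, trials = trials)
  })
}

#' Read / write EEG signals as plain text
#'
#' Single-column delimited text; the sampling rate travels in a YAML
#' sidecar (`<path>.meta.yml`) with fields `fs` and `n_samples`.
#'
#' @param signal Numeric vector with an `fs` attribute (or pass `fs`).
#' @param path File path.
#' @param fs Sampling rate; defaults to `attr(signal, "fs")`.
#' @return `read_eeg_signal()` returns the signal with `fs` attached.
#' @export
write_eeg_signal <- function(signal, path, fs = attr(signal, "fs")) {
  stopifnot(!is.null(fs))
  utils::write.table(data.frame(amplitude = as.numeric(signal)), path,
                     row.names = FALSE, col.names = TRUE, quote = FALSE)
  yaml::write_yaml(list(fs = fs, n_samples = length(signal)),
                   paste0(path, ".meta.yml"))
  invisible(path)
}

#' @rdname write_eeg_signal
#' @export
read_eeg_signal <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".meta.yml"))
  x <- utils::read.table(path, header = TRUE)$amplitude
  if (length(x) != meta$n_samples)
    stop_vtbci("signal length disagrees with sidecar metadata",
               "vtbci_bad_input")
  attr(x, "fs") <- meta$fs
  x
}
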