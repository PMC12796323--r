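#' Run configuration for the validation pipelines
#'
#' A nested list of every setting the pipelines need, round-trippable
#' through YAML (see [write_run_config()]). All randomness is controlled
#' by the explicit seeds it carries.
#'
#' @param experiment_id Design to simulate on (default `"E2"`).
#' @param n_participants Cohort size (default 46).
#' @param priors See [cohort_priors()].
#' @param iaf_link `NULL` or `list(slope, intercept, noise)` coupling
#'   sigma (ms) to alpha frequency (Hz).
#' @param seed Master seed.
#' @param n_starts Multistart count for the observer-model fits.
#' @param fit_variant Model variant fitted in recovery runs.
#' @param fit_bci Whether the end-to-end run also fits the observer model
#'   (the Gaussian TBW is always fitted).
#' @param eeg Spectral settings: `duration_s`, `alpha_amp`, `noise_sd`.
#' @param output_dir Optional directory; when set, every run writes its
#'   config, a log of seeds, and all stage tables there.
#' @return A list of class `vtbci_config`.
#' @export
run_config <- function(experiment_id = "E2", n_participants = 46,
                       priors = cohort_priors(),
                       iaf_link = list(slope = -30, intercept = 500,
                                       noise = 20),
                       seed = 1L, n_starts = 25L, fit_variant = "single",
                       fit_bci = TRUE,
                       eeg = list(duration_s = 240, alpha_amp = 1,
                                  noise_sd = 0.1),
                       output_dir = NULL) {
  structure(list(experiment_id = experiment_id,
                 n_participants = n_participants, priors = priors,
                 iaf_link = iaf_link, seed = seed, n_starts = n_starts,
                 fit_variant = fit_variant, fit_bci = fit_bci, eeg = eeg,
                 output_dir = output_dir), class = "vtbci_config")
}

#' Read / write a run configuration as YAML
#'
#' @param config A [run_config()].
#' @param path File path.
#' @return `read_run_config()` returns the config; the writer returns
#'   `path` invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}

pipeline_log <- function(dir, lines) {
  if (is.null(dir)) return(invisible())
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cat(lines, file = file.path(dir, "run.log"), sep = "\n", append = TRUE)
}

write_stage_table <- function(dir, name, df) {
  if (is.null(dir)) return(invisible())
  utils::write.csv(df, file.path(dir, paste0(name, ".csv")),
                   row.names = FALSE, quote = FALSE)
}

#' Parameter-recovery study on a synthetic cohort
#'
#' Simulates a cohort of causal-inference observers on the configured
#' design, fits each participant's observer model back, and tabulates
#' truth against estimate, together with the behavioural summaries (TBW,
#' signal-detection indices). Deterministic for a fixed config.
#'
#' @param config A [run_config()].
#' @return Class `recovery_report`: `truth`, `estimates` (per-participant
#'   fitted parameters and fit quality), `behavior`
#'   ([psychophysics_summary()] output), and `recovery` (per-parameter
#'   bias, RMSE, and the fraction within the study tolerances: 0.07 for
#'   the priors, 15% relative for sigma, 0.03 for the lapse).
#' @export
run_parameter_recovery <- function(config = run_config()) {
  cohort <- simulate_cohort(config$n_participants,
                            design = build_design(config$experiment_id),
                            priors = config$priors,
                            iaf_link = config$iaf_link,
                            seed = config$seed,
                            alpha_amp = config$eeg$alpha_amp,
                            noise_sd = config$eeg$noise_sd,
                            eeg_duration_s = config$eeg$duration_s)
  design <- build_design(config$experiment_id)
  sigma_s <- if (is.na(design$sigma_s)) 293 else design$sigma_s
  fits <- lapply(split(cohort$trials, cohort$trials$participant),
                 function(tr) {
                   fit_bci(tr, sigma_s, variant = config$fit_variant,
                           config = bci_fit_config(
                             n_starts = config$n_starts,
                             seed = config$seed))
                 })
  fits <- fits[cohort$params$participant]
  est <- do.call(rbind, lapply(names(fits), function(id) {
    f <- fits[[id]]
    data.frame(participant = id, t(f$params), logL = f$logL, r2 = f$r2,
               aic = f$aic, bic = f$bic, stringsAsFactors = FALSE)
  }))
  behavior <- psychophysics_summary(cohort$trials, seed = config$seed)
  truth <- cohort$params
  tol_ok <- function(est, tru, abs_tol = NULL, rel_tol = NULL) {
    if (!is.null(abs_tol)) abs(est - tru) <= abs_tol
    else abs(est - tru) / tru <= rel_tol
  }
  rec <- data.frame(
    parameter = c("p_same_own", "p_same_sim", "sigma", "lapse"),
    bias = c(mean(est$p_same_own - truth$p_same_own),
             mean(est$p_same_sim - truth$p_same_sim),
             mean(est$sigma - truth$sigma),
             mean(est$lapse - truth$lapse)),
    rmse = c(sqrt(mean((est$p_same_own - truth$p_same_own)^2)),
             sqrt(mean((est$p_same_sim - truth$p_same_sim)^2)),
             sqrt(mean((est$sigma - truth$sigma)^2)),
             sqrt(mean((est$lapse - truth$lapse)^2))),
    within_tol = c(mean(tol_ok(est$p_same_own, truth$p_same_own, 0.07)),
                   mean(tol_ok(est$p_same_sim, truth$p_same_sim, 0.07)),
                   mean(tol_ok(est$sigma, truth$sigma, rel_tol = 0.15)),
                   mean(tol_ok(est$lapse, truth$lapse, 0.03)))
  )
  out <- structure(list(truth = truth, estimates = est, behavior = behavior,
                        recovery = rec, config = config),
                   class = "recovery_report")
  if (!is.null(config$output_dir)) {
    dir <- config$output_dir
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_run_config(config, file.path(dir, "config.yml"))
    write_stage_table(dir, "truth", truth)
    write_stage_table(dir, "estimates", est)
    write_stage_table(dir, "behavior", behavior)
    write_stage_table(dir, "recovery", rec)
    pipeline_log(dir, c(sprintf("stage=recovery seed=%d n=%d starts=%d",
                                config$seed, config$n_participants,
                                config$n_starts)))
  }
  out
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("Parameter recovery on %d synthetic participants (%s design)\n",
              nrow(x$truth), x$config$experiment_id))
  print(transform(x$recovery, bias = signif(bias, 3),
                  rmse = signif(rmse, 3)))
  invisible(x)
}

#' End-to-end pipeline: linked EEG and behaviour
#'
#' Simulates a cohort whose sensory noise is coupled to the alpha
#' frequency, then estimates on each synthetic participant — through the
#' package's own analysis path, blind to the generating values — the
#' aperiodic-corrected IAF from the synthetic EEG and the ownership-task
#' TBW (optionally also the observer-model sigma), and reports the
#' cross-participant correlations. With the default negative link the
#' estimated IAF should correlate negatively with the estimated TBW and
#' sigma.
#'
#' @param config A [run_config()] with a non-`NULL` `iaf_link`.
#' @return Class `endtoend_report`: per-participant table (`truth` +
#'   `iaf_hat`, `tbw_hat`, `sigma_hat`) and `correlations` (Pearson r and
#'   p for IAF vs TBW and, if fitted, IAF vs sigma).
#' @export
run_end_to_end <- function(config = run_config()) {
  cohort <- simulate_cohort(config$n_participants,
                            design = build_design(config$experiment_id),
                            priors = config$priors,
                            iaf_link = config$iaf_link,
                            seed = config$seed,
                            alpha_amp = config$eeg$alpha_amp,
                            noise_sd = config$eeg$noise_sd,
                            eeg_duration_s = config$eeg$duration_s)
  design <- build_design(config$experiment_id)
  sigma_s <- if (is.na(design$sigma_s)) 293 else design$sigma_s
  ids <- cohort$params$participant
  per <- lapply(seq_along(ids), function(i) {
    id <- ids[i]
    sig <- synthesize_eeg(cohort$eeg_specs[[id]],
                          seed = (config$seed + 7L * i) %% .Machine$integer.max)
    spec <- welch_psd(sig)
    iaf <- iaf_corrected(spec)
    tr <- cohort$trials[cohort$trials$participant == id, , drop = FALSE]
    own <- tr[tr$task == "ownership", , drop = FALSE]
    tbw <- fit_gaussian_tbw(proportion_yes(own), seed = config$seed)
    sigma_hat <- if (isTRUE(config$fit_bci)) {
      fit_bci(tr, sigma_s, variant = "single",
              config = bci_fit_config(n_starts = config$n_starts,
                                      seed = config$seed))$params[["sigma"]]
    } else NA_real_
    data.frame(participant = id, iaf_hat = iaf$freq,
               iaf_success = iaf$success, tbw_hat = tbw$sd,
               sigma_hat = sigma_hat, stringsAsFactors = FALSE)
  })
  est <- do.call(rbind, per)
  tab <- merge(cohort$params, est, by = "participant")
  ok <- tab$iaf_success & !is.na(tab$iaf_hat)
  cor_tbw <- correlate(tab$iaf_hat[ok], tab$tbw_hat[ok])
  cor_sigma <- if (isTRUE(config$fit_bci))
    correlate(tab$iaf_hat[ok], tab$sigma_hat[ok]) else NULL
  out <- structure(list(
    table = tab,
    n_iaf_success = sum(ok),
    correlations = list(iaf_tbw = cor_tbw, iaf_sigma = cor_sigma),
    config = config), class = "endtoend_report")
  if (!is.null(config$output_dir)) {
    dir <- config$output_dir
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_run_config(config, file.path(dir, "config.yml"))
    write_stage_table(dir, "endtoend", tab)
    pipeline_log(dir, sprintf(
      "stage=endtoend seed=%d n=%d r_iaf_tbw=%.4f p=%.4g",
      config$seed, config$n_participants, cor_tbw$r, cor_tbw$p_two_sided))
  }
  out
}

#' @export
print.endtoend_report <- function(x, ...) {
  ct <- x$correlations$iaf_tbw
  cat(sprintf(
    "End-to-end run: %d participants, %d with a detected alpha peak\n",
    nrow(x$table), x$n_iaf_success))
  cat(sprintf("  r(IAF_hat, TBW_hat) = %.3f (p = %.3g)\n",
              ct$r, ct$p_two_sided))
  cs <- x$correlations$iaf_sigma
  if (!is.null(cs))
    cat(sprintf("  r(IAF_hat, sigma_hat) = %.3f (p = %.3g)\n",
                cs$r, cs$p_two_sided))
  invisible(x)
}
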