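#' Decision threshold of the causal-inference observer
#'
#' The observer reports a common cause whenever the noisy internal
#' measurement `x` of the asynchrony satisfies `|x| < sqrt(K)`, with
#'
#' \deqn{K = \frac{\sigma^2(\sigma_s^2+\sigma^2)}{\sigma_s^2}
#'   \left(2\log\frac{p_{same}}{1-p_{same}} +
#'   \log\frac{\sigma_s^2+\sigma^2}{\sigma^2}\right)}
#'
#' `K` becomes non-positive when the common-cause prior is so low that the
#' separate-causes category is the maximum a posteriori report for every
#' `x`; that state is returned as `defined = FALSE`, not an error.
#'
#' @param p_same Prior probability of a common cause, in (0, 1).
#' @param sigma Sensory noise SD of the asynchrony measurement (ms).
#' @param sigma_s Fixed SD of the assumed asynchrony distribution under
#'   separate causes (ms).
#' @return A list with `K` (ms^2), `k` (`sqrt(K)` in ms, `NA` when
#'   undefined) and `defined`.
#' @export
#' @examples
#' decision_threshold(0.5, 290, 290)$k  # 290 * sqrt(2 log 2)
decision_threshold <- function(p_same, sigma, sigma_s) {
  stopifnot(all(p_same > 0 & p_same < 1), all(sigma > 0), all(sigma_s > 0))
  v <- sigma_s^2 + sigma^2
  bracket <- 2 * log(p_same / (1 - p_same)) + log(v / sigma^2)
  K <- sigma^2 * v / sigma_s^2 * bracket
  defined <- K > 0
  list(K = K, k = ifelse(defined, sqrt(pmax(K, 0)), NA_real_),
       defined = defined)
}

#' Predicted probability of a "yes" (common cause) report
#'
#' The model's psychometric function: with lapse rate `lambda` the observer
#' guesses (yes with probability 1/2), otherwise reports yes when the
#' measurement falls inside the decision window, so
#' \deqn{p(\hat C = 1 | s) = 0.5\lambda + (1-\lambda)\,
#'   [\Phi((k-s)/\sigma) - \Phi((-k-s)/\sigma)]}
#' When the threshold is undefined the bracket is zero and the prediction is
#' `0.5 * lapse`. All arguments recycle, so the function is vectorised over
#' trials.
#'
#' @param s Signed asynchrony (ms).
#' @param p_same,sigma,sigma_s See [decision_threshold()].
#' @param lapse Lapse (random-guess) probability in \[0, 1\].
#' @return Probability of a yes report, in \[0, 1\].
#' @export
predict_p_yes <- function(s, p_same, sigma, sigma_s, lapse = 0) {
  stopifnot(all(lapse >= 0 & lapse <= 1))
  n <- max(length(s), length(p_same), length(sigma), length(sigma_s),
           length(lapse))
  s <- rep_len(s, n); p_same <- rep_len(p_same, n)
  sigma <- rep_len(sigma, n); sigma_s <- rep_len(sigma_s, n)
  lapse <- rep_len(lapse, n)
  th <- decision_threshold(p_same, sigma, sigma_s)
  inside <- numeric(n)
  d <- th$defined
  inside[d] <- stats::pnorm((th$k[d] - s[d]) / sigma[d]) -
    stats::pnorm((-th$k[d] - s[d]) / sigma[d])
  0.5 * lapse + (1 - lapse) * inside
}

# Posterior log-odds of a common cause given a measurement x (the decision
# variable d); used as the independent check that sqrt(K) is the point of
# posterior equality.
bci_log_posterior_odds <- function(x, p_same, sigma, sigma_s) {
  # p(x|C=1) = N(x; 0, sigma^2); p(x|C=2) = N(x; 0, sigma^2 + sigma_s^2)
  log(p_same) + stats::dnorm(x, 0, sigma, log = TRUE) -
    log(1 - p_same) - stats::dnorm(x, 0, sqrt(sigma^2 + sigma_s^2),
                                   log = TRUE)
}

# ---- parameter plumbing for the three model variants ---------------------

variant_n_par <- c(single = 4L, sigma_varies = 6L, psame_varies = 8L)

variant_par_names <- function(variant, conditions = c("low", "sham", "high")) {
  switch(variant,
    single = c("p_same_own", "p_same_sim", "sigma", "lapse"),
    sigma_varies = c("p_same_own", "p_same_sim",
                     paste0("sigma_", conditions), "lapse"),
    psame_varies = c(paste0("p_same_own_", conditions),
                     paste0("p_same_sim_", conditions), "sigma", "lapse"),
    stop_vtbci(paste("unknown model variant:", variant), "vtbci_bad_variant")
  )
}

# Map a named parameter vector to per-row (task, condition) p_same and sigma.
variant_row_params <- function(par, variant, task, condition) {
  if (variant == "single") {
    list(p_same = ifelse(task == "ownership", par[["p_same_own"]],
                         par[["p_same_sim"]]),
         sigma = rep(par[["sigma"]], length(task)))
  } else if (variant == "sigma_varies") {
    list(p_same = ifelse(task == "ownership", par[["p_same_own"]],
                         par[["p_same_sim"]]),
         sigma = unname(par[paste0("sigma_", condition)]))
  } else {
    stem <- ifelse(task == "ownership", "p_same_own_", "p_same_sim_")
    list(p_same = unname(par[paste0(stem, condition)]),
         sigma = rep(par[["sigma"]], length(task)))
  }
}

# Fast negative log-likelihood closure over aggregated counts: parameter
# lookups are resolved to integer indices once, so the optimizer's inner
# loop is pure vector arithmetic.
negll_factory <- function(agg, sigma_s, variant, nm) {
  s <- agg$asynchrony_ms
  n <- agg$n
  n_yes <- agg$n_yes
  ip <- match(switch(variant,
    single = ifelse(agg$task == "ownership", "p_same_own", "p_same_sim"),
    sigma_varies = ifelse(agg$task == "ownership", "p_same_own",
                          "p_same_sim"),
    psame_varies = paste0(ifelse(agg$task == "ownership", "p_same_own_",
                                 "p_same_sim_"), agg$condition)), nm)
  is <- match(switch(variant,
    single = rep("sigma", nrow(agg)),
    sigma_varies = paste0("sigma_", agg$condition),
    psame_varies = rep("sigma", nrow(agg))), nm)
  il <- match("lapse", nm)
  ss2 <- sigma_s^2
  eps <- 1e-9
  function(par) {
    ps <- par[ip]
    sg <- par[is]
    v <- ss2 + sg^2
    K <- sg^2 * v / ss2 * (2 * log(ps / (1 - ps)) + log(v / sg^2))
    k <- sqrt(pmax(K, 0))
    inside <- ifelse(K > 0,
                     stats::pnorm((k - s) / sg) - stats::pnorm((-k - s) / sg),
                     0)
    p <- 0.5 * par[il] + (1 - par[il]) * inside
    p <- pmin(pmax(p, eps), 1 - eps)
    -sum(n_yes * log(p) + (n - n_yes) * log1p(-p))
  }
}

# Collapse a trial table to (task, condition, level) counts; the Bernoulli
# likelihood only depends on these sufficient statistics.
aggregate_trials <- function(trials) {
  ok <- trials$response %in% c("yes", "no")
  tr <- trials[ok, , drop = FALSE]
  key <- interaction(tr$task, tr$condition, tr$asynchrony_ms, drop = TRUE)
  agg <- do.call(rbind, lapply(split(tr, key), function(g) {
    data.frame(task = g$task[1], condition = g$condition[1],
               asynchrony_ms = g$asynchrony_ms[1],
               n = nrow(g), n_yes = sum(g$response == "yes"),
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  agg
}

#' Log-likelihood of the causal-inference model
#'
#' Sum over trials of the Bernoulli log-probability of the observed yes/no
#' response under [predict_p_yes()]. Predicted probabilities are clamped to
#' `[eps, 1 - eps]` so a zero-lapse fit cannot produce `-Inf`.
#'
#' @param par Named parameter vector (see [fit_bci()] for names per
#'   variant).
#' @param trials Trial table with `response` in `"yes"`/`"no"` (other rows
#'   are ignored).
#' @param sigma_s Stimulus-distribution SD (ms).
#' @param variant `"single"`, `"sigma_varies"` or `"psame_varies"`.
#' @param eps Probability clamp, default `1e-9`.
#' @return The log-likelihood (a scalar).
#' @export
bci_log_likelihood <- function(par, trials, sigma_s, variant = "single",
                               eps = 1e-9) {
  agg <- if (is.data.frame(trials) && "n_yes" %in% names(trials)) trials
         else aggregate_trials(trials)
  rp <- variant_row_params(par, variant, agg$task, agg$condition)
  p <- predict_p_yes(agg$asynchrony_ms, rp$p_same, rp$sigma, sigma_s,
                     par[["lapse"]])
  p <- pmin(pmax(p, eps), 1 - eps)
  sum(agg$n_yes * log(p) + (agg$n - agg$n_yes) * log1p(-p))
}

#' Fitting configuration for the causal-inference model
#'
#' @param n_starts Number of multistart initial points (uniform draws
#'   within bounds), as in the study protocol's 100 initial parameter
#'   combinations.
#' @param n_refine Number of the best-scoring initial points (by raw
#'   log-likelihood) from which the local optimizer is actually run.
#'   Defaults to `n_starts` (every draw is refined); smaller values keep
#'   the global search breadth of `n_starts` while capping the number of
#'   local optimizations.
#' @param warm_start For the condition variants, additionally seed the
#'   search from the fitted single-condition model expanded to the
#'   variant's parameterisation (a nested-model warm start).
#' @param p_same_bounds,sigma_bounds,lapse_bounds Box bounds on the
#'   parameters.
#' @param seed Base seed for the start draws.
#' @param exact_paper_bic If `TRUE`, [bic()] uses the printed form
#'   `n_trial * log(n_par)` instead of the standard `n_par * log(n_trial)`.
#' @return A list of settings for [fit_bci()].
#' @export
bci_fit_config <- function(n_starts = 100L,
                           n_refine = NULL,
                           warm_start = TRUE,
                           p_same_bounds = c(0.001, 0.999),
                           sigma_bounds = c(1, 1000),
                           lapse_bounds = c(0, 0.3),
                           seed = 1L,
                           exact_paper_bic = FALSE) {
  list(n_starts = as.integer(n_starts),
       n_refine = as.integer(n_refine %||% n_starts),
       warm_start = isTRUE(warm_start),
       p_same_bounds = p_same_bounds,
       sigma_bounds = sigma_bounds, lapse_bounds = lapse_bounds,
       seed = seed, exact_paper_bic = exact_paper_bic)
}

variant_bounds <- function(variant, config) {
  nm <- variant_par_names(variant)
  lower <- upper <- numeric(length(nm))
  names(lower) <- names(upper) <- nm
  is_p <- grepl("^p_same", nm)
  is_s <- grepl("^sigma", nm)
  lower[is_p] <- config$p_same_bounds[1]; upper[is_p] <- config$p_same_bounds[2]
  lower[is_s] <- config$sigma_bounds[1]; upper[is_s] <- config$sigma_bounds[2]
  lower["lapse"] <- config$lapse_bounds[1]; upper["lapse"] <- config$lapse_bounds[2]
  list(lower = lower, upper = upper)
}

#' Fit the causal-inference observer by maximum likelihood
#'
#' Bounded maximisation of [bci_log_likelihood()] for one participant, via
#' L-BFGS-B restarted from `n_starts` seeded uniform draws within the
#' bounds; the best local optimum is returned. Three variants are
#' supported: the 4-parameter model (`"single"`: `p_same_own`,
#' `p_same_sim`, `sigma`, `lapse`), a 6-parameter model in which the
#' sensory noise differs between stimulation conditions
#' (`"sigma_varies"`), and an 8-parameter model in which the common-cause
#' priors differ between conditions (`"psame_varies"`). In both variants
#' the lapse rate is shared, as are (for `"sigma_varies"`) the two priors
#' and (for `"psame_varies"`) the noise.
#'
#' @param trials Trial table of one participant (both tasks; for the
#'   condition variants all three conditions must be present).
#' @param sigma_s Stimulus-distribution SD (ms).
#' @param variant Model variant (see above).
#' @param config See [bci_fit_config()].
#' @return An object of class `bci_fit`: named `params`, `logL`, `n_par`,
#'   `n_trial`, `r2` (normalised pseudo-R2 vs. a coin-flip null), `aic`,
#'   `bic`, `n_starts`, `best_start`, `convergence`.
#' @export
fit_bci <- function(trials, sigma_s, variant = c("single", "sigma_varies",
                                                 "psame_varies"),
                    config = bci_fit_config()) {
  variant <- match.arg(variant)
  agg <- aggregate_trials(trials)
  if (is.null(agg) || nrow(agg) == 0L)
    stop_vtbci("no scored trials to fit", "vtbci_fit_failure")
  if (variant != "single") {
    have <- unique(agg$condition)
    need <- c("low", "sham", "high")
    if (!all(need %in% have))
      stop_vtbci(paste("condition variant requires conditions",
                       paste(need, collapse = "/"), "- found:",
                       paste(have, collapse = "/")), "vtbci_fit_failure")
  }
  n_trial <- sum(agg$n)
  bounds <- variant_bounds(variant, config)
  nm <- names(bounds$lower)
  npar <- length(nm)

  starts <- with_seed(config$seed, {
    m <- matrix(stats::runif(config$n_starts * npar), ncol = npar)
    sweep(sweep(m, 2, bounds$upper - bounds$lower, "*"), 2, bounds$lower, "+")
  })
  colnames(starts) <- nm

  if (variant != "single" && config$warm_start) {
    single_cfg <- config
    single_cfg$warm_start <- FALSE
    single <- fit_bci(trials, sigma_s, "single", single_cfg)$params
    expanded <- vapply(nm, function(p) {
      if (p %in% names(single)) single[[p]]
      else if (grepl("^sigma_", p)) single[["sigma"]]
      else if (grepl("^p_same_own", p)) single[["p_same_own"]]
      else single[["p_same_sim"]]
    }, numeric(1))
    starts <- rbind(starts, expanded)
  }

  neg_ll <- negll_factory(agg, sigma_s, variant, nm)

  # The likelihood surface has genuine plateaus (regions where the decision
  # threshold is undefined and some parameters drop out), which stall
  # line-search methods; the local search therefore runs Nelder-Mead in a
  # logit-transformed unconstrained space, with a final L-BFGS-B polish in
  # the raw bounded space.
  rng <- bounds$upper - bounds$lower
  to_z <- function(x) stats::qlogis(
    pmin(pmax((x - bounds$lower) / rng, 1e-8), 1 - 1e-8))
  to_x <- function(z) bounds$lower + rng * stats::plogis(z)
  neg_ll_z <- function(z) neg_ll(to_x(z))

  # screen every start by raw likelihood, refine the most promising ones
  # (the nested warm start, when present, is always refined)
  screen <- apply(starts, 1, neg_ll)
  refine <- order(screen)[seq_len(min(config$n_refine, nrow(starts)))]
  warm_row <- which(rownames(starts) == "expanded")
  refine <- union(refine, warm_row)
  best <- NULL
  failures <- character()
  for (i in refine) {
    res <- tryCatch(
      stats::optim(to_z(starts[i, ]), neg_ll_z, method = "Nelder-Mead",
                   control = list(maxit = 2000L, reltol = 1e-10)),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, conditionMessage(res))
      next
    }
    if (is.null(best) || res$value < best$value) {
      best <- res
      best$start <- i
    }
  }
  if (is.null(best))
    stop_vtbci(paste("all optimizer starts failed;",
                     "first error:", failures[1]), "vtbci_fit_failure")
  best$par <- to_x(best$par)
  polish <- tryCatch(
    stats::optim(best$par, neg_ll, method = "L-BFGS-B",
                 lower = bounds$lower, upper = bounds$upper,
                 control = list(maxit = 500L, factr = 1e3)),
    error = function(e) NULL)
  if (!is.null(polish) && polish$value < best$value) {
    polish$start <- best$start
    best <- polish
  }

  params <- best$par
  names(params) <- nm
  logL <- -best$value
  structure(list(
    variant = variant,
    params = params,
    logL = logL,
    n_par = npar,
    n_trial = n_trial,
    r2 = pseudo_r2(logL, n_trial),
    aic = aic(logL, npar),
    bic = bic(logL, npar, n_trial, exact_paper = config$exact_paper_bic),
    sigma_s = sigma_s,
    n_starts = config$n_starts,
    best_start = best$start,
    convergence = best$convergence
  ), class = "bci_fit")
}

#' @export
print.bci_fit <- function(x, ...) {
  cat(sprintf("Causal-inference model fit (%s, %d parameters)\n",
              x$variant, x$n_par))
  print(round(x$params, 4))
  cat(sprintf("  logL = %.3f on %d trials; pseudo-R2 = %.3f\n",
              x$logL, x$n_trial, x$r2))
  cat(sprintf("  AIC = %.2f, BIC = %.2f (best of %d starts)\n",
              x$aic, x$bic, x$n_starts))
  invisible(x)
}

#' Likelihood-based goodness of fit against a coin-flip null
#'
#' Coefficient of determination
#' \deqn{R^2 = 1 - \exp(-\tfrac{2}{n}(\log L - \log L_0))}
#' with the null model a discrete uniform over the two responses
#' (`logL0 = n log 0.5`), normalised by its maximum attainable value
#' \deqn{\max R^2 = 1 - \exp(\tfrac{2}{n} \log L_0)}
#' so a perfect predictor scores 1 and the null scores 0.
#'
#' @param logL Maximised log-likelihood (must be \eqn{\le 0}).
#' @param n_trial Number of binary responses.
#' @return The normalised pseudo-R2 in \[0, 1\] (up to rounding).
#' @export
pseudo_r2 <- function(logL, n_trial) {
  if (n_trial <= 0)
    stop_vtbci("pseudo_r2 needs n_trial >= 1", "vtbci_bad_input")
  stopifnot(logL <= 1e-8)
  logL0 <- n_trial * log(0.5)
  r2 <- 1 - exp(-2 / n_trial * (logL - logL0))
  r2max <- 1 - exp(2 / n_trial * logL0)
  r2 / r2max
}

#' Information criteria
#'
#' `aic(logL, n_par) = 2 n_par - 2 logL`. `bic()` defaults to the standard
#' `n_par log(n_trial) - 2 logL`; `exact_paper = TRUE` selects the variant
#' `n_trial log(n_par) - 2 logL` used verbatim in some reports.
#'
#' @param logL Maximised log-likelihood.
#' @param n_par Number of free parameters.
#' @param n_trial Number of trials.
#' @param exact_paper Use the transposed penalty (see above).
#' @return The criterion value (lower is better).
#' @export
aic <- function(logL, n_par) 2 * n_par - 2 * logL

#' @rdname aic
#' @export
bic <- function(logL, n_par, n_trial, exact_paper = FALSE) {
  penalty <- if (exact_paper) n_trial * log(n_par) else n_par * log(n_trial)
  penalty - 2 * logL
}

#' Compare condition-dependent model variants across participants
#'
#' Per participant, the difference in AIC and BIC between the
#' noise-modulation fit and the prior-modulation fit
#' (`sigma_varies` minus `psame_varies`; negative favours noise
#' modulation), summed across participants. A percentile bootstrap CI of
#' the summed difference is computed by drawing `resample_size`
#' differences with replacement and summing, `n_boot` times.
#'
#' @param fits_sigma,fits_psame Lists of [fit_bci()] results, paired by
#'   participant (same names or same order).
#' @param n_boot Bootstrap replicates (default 10000).
#' @param resample_size Differences drawn per replicate; default the number
#'   of participants. (The study protocol drew 15.)
#' @param seed RNG seed for the bootstrap.
#' @return Class `bci_comparison`: per-participant `delta_aic`/`delta_bic`,
#'   their sums, and 95% percentile CIs of each sum.
#' @export
compare_models <- function(fits_sigma, fits_psame, n_boot = 10000L,
                           resample_size = NULL, seed = NULL) {
  n <- length(fits_sigma)
  if (length(fits_psame) != n || n == 0L)
    stop_vtbci("fits must be non-empty lists paired by participant",
               "vtbci_unpaired")
  if (!is.null(names(fits_sigma)) && !is.null(names(fits_psame))) {
    if (!setequal(names(fits_sigma), names(fits_psame)))
      stop_vtbci("participant names differ between fit lists",
                 "vtbci_unpaired")
    fits_psame <- fits_psame[names(fits_sigma)]
  }
  resample_size <- resample_size %||% n
  d_aic <- vapply(seq_len(n),
                  function(i) fits_sigma[[i]]$aic - fits_psame[[i]]$aic,
                  numeric(1))
  d_bic <- vapply(seq_len(n),
                  function(i) fits_sigma[[i]]$bic - fits_psame[[i]]$bic,
                  numeric(1))
  boot_ci <- function(d) {
    sums <- vapply(seq_len(n_boot),
                   function(b) sum(sample(d, resample_size, replace = TRUE)),
                   numeric(1))
    stats::quantile(sums, c(0.025, 0.975), names = FALSE, type = 7)
  }
  # one seeded stream for both criteria, in a fixed order
  cis <- with_seed(seed, list(aic = boot_ci(d_aic), bic = boot_ci(d_bic)))
  structure(list(
    delta_aic = d_aic, delta_bic = d_bic,
    sum_delta_aic = sum(d_aic), sum_delta_bic = sum(d_bic),
    ci_aic = cis$aic, ci_bic = cis$bic,
    n_boot = n_boot, resample_size = resample_size, n_participants = n
  ), class = "bci_comparison")
}

#' @export
print.bci_comparison <- function(x, ...) {
  cat(sprintf("Model comparison over %d participants (noise - prior variant)\n",
              x$n_participants))
  cat(sprintf("  sum dAIC = %.2f, 95%% CI [%.2f, %.2f]\n",
              x$sum_delta_aic, x$ci_aic[1], x$ci_aic[2]))
  cat(sprintf("  sum dBIC = %.2f, 95%% CI [%.2f, %.2f]\n",
              x$sum_delta_bic, x$ci_bic[1], x$ci_bic[2]))
  cat(sprintf("  bootstrap: %d resamples of size %d\n",
              x$n_boot, x$resample_size))
  invisible(x)
}
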