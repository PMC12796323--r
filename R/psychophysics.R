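#' Proportion of yes responses per asynchrony
#'
#' Aggregates a trial table to one row per signed asynchrony. Rows with a
#' missing response are dropped (a message reports how many).
#'
#' @param trials Trial table with `asynchrony_ms` and `response`.
#' @return A `data.frame` with columns `asynchrony_ms`, `n_trials`,
#'   `n_yes`, `p_yes`, sorted by asynchrony.
#' @export
proportion_yes <- function(trials) {
  ok <- trials$response %in% c("yes", "no")
  dropped <- nrow(trials) - sum(ok)
  if (dropped > 0)
    message(sprintf("proportion_yes: dropping %d trial(s) without a response",
                    dropped))
  tr <- trials[ok, , drop = FALSE]
  if (nrow(tr) == 0L)
    return(data.frame(asynchrony_ms = numeric(), n_trials = integer(),
                      n_yes = integer(), p_yes = numeric()))
  out <- do.call(rbind, lapply(split(tr, tr$asynchrony_ms), function(g) {
    data.frame(asynchrony_ms = g$asynchrony_ms[1], n_trials = nrow(g),
               n_yes = sum(g$response == "yes"))
  }))
  out$p_yes <- out$n_yes / out$n_trials
  out <- out[order(out$asynchrony_ms), ]
  rownames(out) <- NULL
  out
}

#' Fit a scaled Gaussian to a proportion-yes curve (temporal binding window)
#'
#' Least-squares fit of `p(s) = amplitude * exp(-(s - mu)^2 / (2 sd^2))` to
#' the per-level yes proportions; the fitted `sd` is the temporal binding
#' window (TBW). The amplitude is free (peak yes-rates rarely reach 1 and
#' pinning the amplitude biases the width). Fitting uses bounded
#' Levenberg-Marquardt from `n_starts` seeded random initial points, with
#' an L-BFGS-B fallback when the LM step fails.
#'
#' @param curve Output of [proportion_yes()] (needs >= 4 distinct levels).
#' @param n_starts Multistart count (default 20).
#' @param seed Seed for the start draws.
#' @param sd_bounds Bounds on the fitted width (ms).
#' @return Class `psychometric_fit`: `amplitude`, `mu`, `sd` (the TBW,
#'   ms), `r2`, `converged`.
#' @export
fit_gaussian_tbw <- function(curve, n_starts = 20L, seed = 1L,
                             sd_bounds = c(1, 2000)) {
  if (nrow(curve) < 4L)
    stop_vtbci("need at least 4 distinct asynchrony levels",
               "vtbci_bad_input")
  s <- curve$asynchrony_ms
  p <- curve$p_yes
  if (length(unique(p)) == 1L) {
    # flat curve: width unidentifiable
    return(structure(list(amplitude = max(p[1], 1e-6), mu = 0,
                          sd = sd_bounds[2], r2 = NA_real_,
                          converged = FALSE),
                     class = "psychometric_fit"))
  }
  lower <- c(amplitude = 1e-6, mu = min(s), sd = sd_bounds[1])
  upper <- c(amplitude = 1, mu = max(s), sd = sd_bounds[2])
  sse <- function(par) {
    sum((p - par[1] * exp(-(s - par[2])^2 / (2 * par[3]^2)))^2)
  }
  starts <- with_seed(seed, {
    m <- matrix(stats::runif(n_starts * 3), ncol = 3)
    m <- sweep(sweep(m, 2, upper - lower, "*"), 2, lower, "+")
    # include one data-driven start
    rbind(c(max(p), s[which.max(p)], max(diff(range(s)) / 4, sd_bounds[1])),
          m)
  })
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    st <- pmin(pmax(starts[i, ], lower), upper)
    fit <- tryCatch({
      lm <- minpack.lm::nls.lm(
        par = st,
        lower = lower, upper = upper,
        fn = function(par) p - par[1] * exp(-(s - par[2])^2 / (2 * par[3]^2)),
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                             ptol = 1e-14))
      list(par = lm$par, value = sum(lm$fvec^2), ok = lm$info %in% 1:4)
    }, error = function(e) NULL)
    if (is.null(fit)) {
      fit <- tryCatch({
        o <- stats::optim(st, sse, method = "L-BFGS-B", lower = lower,
                          upper = upper, control = list(factr = 1e4))
        list(par = o$par, value = o$value, ok = o$convergence == 0)
      }, error = function(e) NULL)
    }
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best))
    stop_vtbci("all Gaussian-fit starts failed", "vtbci_fit_failure")
  ss_tot <- sum((p - mean(p))^2)
  r2 <- 1 - best$value / ss_tot
  at_bound <- best$par[3] >= sd_bounds[2] - 1e-6 ||
    best$par[3] <= sd_bounds[1] + 1e-6
  structure(list(amplitude = unname(best$par[1]), mu = unname(best$par[2]),
                 sd = unname(best$par[3]), r2 = r2,
                 converged = best$ok && !at_bound),
            class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf(
    "Gaussian psychometric fit: amplitude %.3f, mu %.1f ms, TBW %.1f ms\n",
    x$amplitude, x$mu, x$sd))
  cat(sprintf("  R2 = %s, converged = %s\n",
              ifelse(is.na(x$r2), "NA", sprintf("%.4f", x$r2)), x$converged))
  invisible(x)
}

#' Half-trial edge-corrected response rate
#'
#' Rates of exactly 0 or 1 make the normal quantile infinite; the standard
#' correction adds (or subtracts) half a trial: `0 -> 0.5/n`,
#' `n -> (n - 0.5)/n`. Interior counts are untouched.
#'
#' @param count Yes count, `0 <= count <= n`.
#' @param n Number of trials (>= 1).
#' @return The padded rate, strictly inside (0, 1).
#' @export
pad_rate <- function(count, n) {
  if (any(n < 1)) stop_vtbci("pad_rate: n must be >= 1", "vtbci_bad_input")
  stopifnot(all(count >= 0), all(count <= n))
  ifelse(count == 0, 0.5 / n, ifelse(count == n, (n - 0.5) / n, count / n))
}

#' Signal-detection analysis by asynchrony magnitude
#'
#' Synchronous trials (`s = 0`) are the signal; each non-zero asynchrony
#' magnitude (positive and negative pooled) is a noise level. Per level:
#' hit rate `H` from the 0-ms trials, false-alarm rate `FA` from that
#' level's trials (both half-trial padded), and
#' `d' = z(H) - z(FA)`, `bias = -0.5 (z(H) + z(FA))` with `z` the exact
#' standard-normal quantile.
#'
#' @param trials Trial table containing 0-ms trials.
#' @return Class `sdt_table`: a `data.frame` (one row per `|s| > 0` level:
#'   `abs_asynchrony_ms`, `n_noise`, `fa_rate`, `dprime`, `bias`) with
#'   attributes `hit_rate`, `n_signal`, `mean_bias` and `auc_dprime`
#'   (trapezoidal area of d' over `|s|`, `NA` with a single level).
#' @export
sdt_by_asynchrony <- function(trials) {
  ok <- trials$response %in% c("yes", "no")
  tr <- trials[ok, , drop = FALSE]
  sig <- tr[tr$asynchrony_ms == 0, , drop = FALSE]
  if (nrow(sig) == 0L)
    stop_vtbci("no synchronous (0 ms) trials: hit rate undefined",
               "vtbci_bad_input")
  H <- pad_rate(sum(sig$response == "yes"), nrow(sig))
  zH <- stats::qnorm(H)
  noise <- tr[tr$asynchrony_ms != 0, , drop = FALSE]
  noise$abs_s <- abs(noise$asynchrony_ms)
  tab <- do.call(rbind, lapply(split(noise, noise$abs_s), function(g) {
    fa <- pad_rate(sum(g$response == "yes"), nrow(g))
    zFA <- stats::qnorm(fa)
    data.frame(abs_asynchrony_ms = g$abs_s[1], n_noise = nrow(g),
               fa_rate = fa, dprime = zH - zFA, bias = -0.5 * (zH + zFA))
  }))
  tab <- tab[order(tab$abs_asynchrony_ms), ]
  rownames(tab) <- NULL
  attr(tab, "hit_rate") <- H
  attr(tab, "n_signal") <- nrow(sig)
  attr(tab, "mean_bias") <- mean(tab$bias)
  attr(tab, "auc_dprime") <- if (nrow(tab) >= 2) auc_dprime(tab) else NA_real_
  class(tab) <- c("sdt_table", "data.frame")
  tab
}

#' Area under the d' curve
#'
#' Trapezoidal integral of d' as a function of the absolute asynchrony
#' (ms), levels sorted ascending; an overall sensitivity index in units of
#' d' x ms. Not normalised by the asynchrony span.
#'
#' @param sdt An [sdt_by_asynchrony()] table (or any data frame with
#'   `abs_asynchrony_ms` and `dprime`).
#' @return The area (d' x ms).
#' @export
auc_dprime <- function(sdt) {
  if (nrow(sdt) < 2L)
    stop_vtbci("AUC needs at least 2 asynchrony levels", "vtbci_bad_input")
  o <- order(sdt$abs_asynchrony_ms)
  x <- sdt$abs_asynchrony_ms[o]
  y <- sdt$dprime[o]
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Per-participant psychophysics summary
#'
#' Convenience wrapper: for every participant x task x condition cell of a
#' trial table, the Gaussian TBW fit and the signal-detection summary.
#'
#' @param trials Trial table (any number of participants).
#' @param ... Passed to [fit_gaussian_tbw()].
#' @return A `data.frame` with one row per cell: `participant`, `task`,
#'   `condition`, `tbw_ms`, `fit_r2`, `converged`, `auc_dprime`,
#'   `mean_bias`, `hit_rate`.
#' @export
psychophysics_summary <- function(trials, ...) {
  key <- interaction(trials$participant, trials$task, trials$condition,
                     drop = TRUE)
  out <- lapply(split(trials, key), function(g) {
    fit <- fit_gaussian_tbw(proportion_yes(g), ...)
    sdt <- sdt_by_asynchrony(g)
    data.frame(participant = g$participant[1], task = g$task[1],
               condition = g$condition[1], tbw_ms = fit$sd, fit_r2 = fit$r2,
               converged = fit$converged,
               auc_dprime = attr(sdt, "auc_dprime"),
               mean_bias = attr(sdt, "mean_bias"),
               hit_rate = attr(sdt, "hit_rate"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
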