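test_that("decision threshold solves the posterior-equality equation", {
  # equal prior, sigma = sigma_s: closed form k = sigma * sqrt(2 log 2)
  th <- decision_threshold(0.5, 290, 290)
  expect_equal(th$k, 290 * sqrt(2 * log(2)), tolerance = 1e-9)

  # vanishing prior: the common-cause report is never optimal
  expect_false(decision_threshold(1e-9, 150, 290)$defined)

  # random parameter draws: posterior log-odds vanish at +-k, are positive
  # inside and negative outside
  set.seed(21)
  for (i in 1:10) {
    p_same <- runif(1, 0.05, 0.95)
    sigma <- runif(1, 30, 400)
    sigma_s <- runif(1, 150, 400)
    th <- decision_threshold(p_same, sigma, sigma_s)
    if (!th$defined) next
    for (x in c(-th$k, th$k))
      expect_lt(abs(oracle_log_odds(x, p_same, sigma, sigma_s)), 1e-6)
    expect_gt(oracle_log_odds(0.9 * th$k, p_same, sigma, sigma_s), 0)
    expect_lt(oracle_log_odds(1.1 * th$k, p_same, sigma, sigma_s), 0)
  }
})

test_that("predicted psychometric function is a valid even curve", {
  s <- seq(-600, 600, by = 50)
  # full lapse: coin flip everywhere
  expect_equal(predict_p_yes(s, 0.7, 150, 293, lapse = 1), rep(0.5, length(s)))
  # window far wider than the noise: certainty at synchrony
  expect_gte(predict_p_yes(0, 0.999999, 10, 290, lapse = 0), 0.99999)
  # undefined threshold: only the lapse coin remains
  expect_equal(predict_p_yes(s, 1e-9, 150, 290, lapse = 0.1),
               rep(0.05, length(s)))

  set.seed(22)
  for (i in 1:8) {
    p_same <- runif(1, 0.05, 0.95); sigma <- runif(1, 40, 350)
    lapse <- runif(1, 0, 0.3)
    p <- predict_p_yes(s, p_same, sigma, 293, lapse)
    expect_equal(p, rev(p), tolerance = 1e-12)          # even in s
    half <- p[s >= 0]
    expect_true(all(diff(half) <= 1e-12))               # nonincreasing in |s|
    expect_true(all(p >= 0.5 * lapse - 1e-12 &
                      p <= 1 - 0.5 * lapse + 1e-12))    # lapse bounds
  }
})

test_that("log-likelihood equals a naive per-trial summation", {
  d <- build_design("E2")
  obs <- bci_observer(0.75, 0.55, 180, 0.05, 293)
  tr <- simulate_bci_responses(obs, both_task_trials(d, 7), seed = 23)
  set.seed(24)
  for (i in 1:5) {
    par <- c(p_same_own = runif(1, 0.1, 0.9), p_same_sim = runif(1, 0.1, 0.9),
             sigma = runif(1, 50, 300), lapse = runif(1, 0, 0.2))
    # independent oracle: re-derive the trial probability row by row
    naive <- sum(vapply(seq_len(nrow(tr)), function(j) {
      p_same <- if (tr$task[j] == "ownership") par[["p_same_own"]]
                else par[["p_same_sim"]]
      v <- 293^2 + par[["sigma"]]^2
      K <- par[["sigma"]]^2 * v / 293^2 *
        (2 * log(p_same / (1 - p_same)) + log(v / par[["sigma"]]^2))
      inside <- if (K > 0) {
        k <- sqrt(K)
        pnorm((k - tr$asynchrony_ms[j]) / par[["sigma"]]) -
          pnorm((-k - tr$asynchrony_ms[j]) / par[["sigma"]])
      } else 0
      p <- 0.5 * par[["lapse"]] + (1 - par[["lapse"]]) * inside
      p <- min(max(p, 1e-9), 1 - 1e-9)
      if (tr$response[j] == "yes") log(p) else log(1 - p)
    }, numeric(1)))
    expect_equal(bci_log_likelihood(par, tr, 293), naive, tolerance = 1e-10)
  }
  # a fully lapsing observer scores n log(1/2) whatever the data
  par <- c(p_same_own = 0.7, p_same_sim = 0.7, sigma = 150, lapse = 1)
  expect_equal(bci_log_likelihood(par, tr, 293), nrow(tr) * log(0.5))
})

test_that("maximum-likelihood fitting recovers generating parameters", {
  d <- build_design("E2")
  truth <- c(p_same_own = 0.8, p_same_sim = 0.6, sigma = 150, lapse = 0.02)
  obs <- bci_observer(0.8, 0.6, 150, 0.02, 293)
  tr <- simulate_bci_responses(obs, both_task_trials(d, 200), seed = 25)
  fit <- fit_bci(tr, 293, "single",
                 bci_fit_config(n_starts = 50, n_refine = 10, seed = 1))
  expect_lt(abs(fit$params[["p_same_own"]] - 0.8), 0.07)
  expect_lt(abs(fit$params[["p_same_sim"]] - 0.6), 0.07)
  expect_lt(abs(fit$params[["sigma"]] - 150) / 150, 0.15)
  expect_lt(abs(fit$params[["lapse"]] - 0.02), 0.05)
  # the optimum cannot fall below the generating truth
  expect_gte(fit$logL, bci_log_likelihood(truth, tr, 293))
  expect_equal(fit$n_par, 4L)
  expect_equal(fit$n_trial, nrow(tr))
  expect_gt(fit$r2, 0)
  expect_lte(fit$r2, 1)

  # noise variant on data with equal noise across conditions: the three
  # fitted noise parameters agree
  tr3 <- do.call(rbind, lapply(c("low", "sham", "high"), function(cond)
    simulate_bci_responses(obs, both_task_trials(d, 40) |>
                             transform(condition = cond), seed = 26)))
  fit3 <- fit_bci(tr3, 293, "sigma_varies",
                  bci_fit_config(n_starts = 50, n_refine = 10, seed = 2))
  sig <- fit3$params[c("sigma_low", "sigma_sham", "sigma_high")]
  expect_lt((max(sig) - min(sig)) / mean(sig), 0.10)
  expect_equal(fit3$n_par, 6L)

  empty <- both_task_trials(d, 2)
  expect_error(fit_bci(empty, 293, "single"), class = "vtbci_fit_failure")
  tr_nc <- simulate_bci_responses(obs, both_task_trials(d, 2), seed = 1)
  expect_error(fit_bci(tr_nc, 293, "sigma_varies"),
               class = "vtbci_fit_failure")
})

test_that("pseudo-R2, AIC and BIC follow their definitions", {
  n <- 100
  logL0 <- n * log(0.5)
  expect_equal(pseudo_r2(logL0, n), 0)
  expect_equal(pseudo_r2(0, n), 1)
  # direct evaluation of the normalised likelihood-R2 at half the null
  logL <- 0.5 * logL0
  direct <- (1 - exp(-2 / n * (logL - logL0))) / (1 - exp(2 / n * logL0))
  expect_equal(pseudo_r2(logL, n), direct)
  expect_error(pseudo_r2(-10, 0), class = "vtbci_bad_input")

  expect_equal(aic(-100, 4), 208)
  expect_equal(bic(-100, 6, 210), 6 * log(210) + 200)
  expect_equal(bic(-100, 6, 210, exact_paper = TRUE), 210 * log(6) + 200)
  # equal likelihood: the 6-parameter model wins by 4 AIC points
  expect_equal(aic(-100, 6) - aic(-100, 8), -4)
})

test_that("bootstrap model comparison is seeded and degenerate-safe", {
  fits_a <- lapply(1:10, function(i) list(aic = 100, bic = 110))
  fits_b <- lapply(1:10, function(i) list(aic = 104, bic = 114))
  cmp <- compare_models(fits_a, fits_b, n_boot = 200, resample_size = 15,
                        seed = 5)
  expect_equal(cmp$delta_aic, rep(-4, 10))
  expect_equal(cmp$sum_delta_aic, -40)
  expect_equal(cmp$ci_aic, c(-60, -60))   # 15 draws of -4, any resample
  expect_equal(cmp$ci_bic, c(-60, -60))

  # a single bootstrap draw gives a point interval
  set.seed(6)
  fits_c <- lapply(1:8, function(i) list(aic = rnorm(1, 100, 5), bic = 100))
  fits_d <- lapply(1:8, function(i) list(aic = rnorm(1, 100, 5), bic = 100))
  one <- compare_models(fits_c, fits_d, n_boot = 1, seed = 7)
  expect_equal(one$ci_aic[1], one$ci_aic[2])

  # seeded reproducibility
  c1 <- compare_models(fits_c, fits_d, n_boot = 500, seed = 8)
  c2 <- compare_models(fits_c, fits_d, n_boot = 500, seed = 8)
  expect_identical(c1$ci_aic, c2$ci_aic)

  expect_error(compare_models(fits_a, fits_b[1:5]), class = "vtbci_unpaired")
  named_a <- setNames(fits_a, paste0("S", 1:10))
  named_b <- setNames(fits_b, paste0("T", 1:10))
  expect_error(compare_models(named_a, named_b), class = "vtbci_unpaired")
})

test_that("wider sensory noise widens the fitted binding window", {
  d <- build_design("E2")
  tbw <- vapply(c(80, 150, 260), function(sg) {
    curve <- data.frame(asynchrony_ms = d$levels, n_trials = 1,
                        p_yes = predict_p_yes(d$levels, 0.7, sg, 293, 0.02))
    fit_gaussian_tbw(curve, seed = 1)$sd
  }, numeric(1))
  expect_true(all(diff(tbw) > 0))
})
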