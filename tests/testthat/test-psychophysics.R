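test_that("proportion aggregation conserves counts", {
  tr <- counts_to_trials(0, 10, 7)
  curve <- proportion_yes(tr)
  expect_equal(curve$p_yes, 0.7)

  tr <- counts_to_trials(c(-100, 0, 100), c(10, 20, 10), c(0, 0, 0))
  expect_true(all(proportion_yes(tr)$p_yes == 0))

  d <- build_design("E2")
  tr <- simulate_bci_responses(bci_observer(), grid_trials(d, 13), seed = 1)
  curve <- proportion_yes(tr)
  expect_equal(sum(curve$n_trials), nrow(tr))
  expect_equal(curve$asynchrony_ms, sort(d$levels))

  tr$response[3] <- NA_character_
  expect_message(curve2 <- proportion_yes(tr), "dropping 1")
  expect_equal(sum(curve2$n_trials), nrow(tr) - 1L)
  expect_equal(nrow(proportion_yes(counts_to_trials(0, 1, 1)[0, ])), 0L)
})

test_that("Gaussian TBW fit inverts noiseless curves exactly", {
  d <- build_design("E2")
  for (truth in list(c(a = 0.95, mu = 0, sd = 150),
                     c(a = 0.80, mu = 40, sd = 220))) {
    curve <- data.frame(
      asynchrony_ms = d$levels, n_trials = 100,
      n_yes = NA,
      p_yes = truth["a"] * exp(-(d$levels - truth["mu"])^2 /
                                 (2 * truth["sd"]^2)))
    fit <- fit_gaussian_tbw(curve, seed = 2)
    expect_lt(abs(fit$sd - truth["sd"]), 1e-6)
    expect_lt(abs(fit$mu - truth["mu"]), 1e-6)
    expect_lt(abs(fit$amplitude - truth["a"]), 1e-8)
    expect_equal(fit$r2, 1, tolerance = 1e-9)
    expect_true(fit$converged)
  }
  # degenerate flat curve: width unidentifiable, flagged at the bound
  flat <- data.frame(asynchrony_ms = d$levels, n_trials = 10, n_yes = 5,
                     p_yes = 0.5)
  fit <- fit_gaussian_tbw(flat, seed = 2)
  expect_false(fit$converged)
  expect_equal(fit$sd, 2000)
  expect_error(fit_gaussian_tbw(flat[1:3, ]), class = "vtbci_bad_input")
})

test_that("TBW is recovered from binomial sampling noise", {
  d <- build_design("E2")
  g <- gaussian_observer(amplitude = 0.95, mu = 0, sd = 150)
  err <- vapply(1:20, function(seed) {
    tr <- simulate_gaussian_observer(g, grid_trials(d, 200), seed = seed)
    fit_gaussian_tbw(proportion_yes(tr), seed = seed)$sd - 150
  }, numeric(1))
  expect_gte(mean(abs(err) <= 15), 0.95)
  expect_lt(median(abs(err)), 15)
})

test_that("padding corrects only extreme rates", {
  expect_equal(pad_rate(0, 20), 0.025)
  expect_equal(pad_rate(20, 20), 0.975)
  expect_equal(pad_rate(7, 10), 0.7)
  expect_equal(pad_rate(c(0, 3, 10), 10), c(0.05, 0.3, 0.95))
  expect_error(pad_rate(0, 0), class = "vtbci_bad_input")
  # interior counts untouched for every n
  for (n in c(5, 20, 100)) {
    k <- 1:(n - 1)
    expect_equal(pad_rate(k, n), k / n)
  }
})

test_that("signal-detection table follows the z-score definitions", {
  # constructed counts: H = 16/20, FA = 4/40 at 100 ms, 1/40 at 200 ms
  tr <- counts_to_trials(c(0, -100, 100, -200, 200),
                         c(20, 20, 20, 20, 20), c(16, 2, 2, 1, 0))
  sdt <- sdt_by_asynchrony(tr)
  H <- 16 / 20
  expect_equal(attr(sdt, "hit_rate"), H)
  expect_equal(sdt$fa_rate, c(4 / 40, 1 / 40))
  expect_equal(sdt$dprime, qnorm(H) - qnorm(c(0.1, 0.025)))
  expect_equal(sdt$bias, -0.5 * (qnorm(H) + qnorm(c(0.1, 0.025))))

  # chance-level symmetric performance: d' = 0, bias = 0
  tr <- counts_to_trials(c(0, -100, 100), c(20, 10, 10), c(10, 5, 5))
  sdt <- sdt_by_asynchrony(tr)
  expect_equal(sdt$dprime, 0)
  expect_equal(sdt$bias, 0)

  # equal padded rates everywhere (all zero counts, equal cell sizes so
  # the half-trial correction matches): d' identically 0
  tr <- counts_to_trials(c(0, 100, 200), rep(20, 3), rep(0, 3))
  expect_true(all(sdt_by_asynchrony(tr)$dprime == 0))

  expect_error(sdt_by_asynchrony(counts_to_trials(c(-100, 100), c(5, 5),
                                                  c(1, 1))),
               class = "vtbci_bad_input")
})

test_that("d' area under the curve matches independent quadrature", {
  flat <- data.frame(abs_asynchrony_ms = c(100, 200, 300, 400),
                     dprime = 1.7)
  expect_equal(auc_dprime(flat), 300 * 1.7)
  tri <- data.frame(abs_asynchrony_ms = c(100, 400), dprime = c(0, 2))
  expect_equal(auc_dprime(tri), 300)
  set.seed(42)
  for (i in 1:5) {
    x <- sort(sample(50:500, 6))
    y <- rnorm(6)
    tab <- data.frame(abs_asynchrony_ms = x, dprime = y)
    expect_equal(auc_dprime(tab), pracma::trapz(x, y), tolerance = 1e-12)
  }
  expect_error(auc_dprime(flat[1, , drop = FALSE]),
               class = "vtbci_bad_input")
})

test_that("per-participant summary covers every cell", {
  coh <- simulate_tacs_cohort(2, seed = 12)
  summ <- psychophysics_summary(coh$trials, n_starts = 5, seed = 1)
  expect_equal(nrow(summ), 2 * 2 * 3)  # participants x tasks x conditions
  expect_true(all(is.finite(summ$tbw_ms)))
  expect_true(all(is.finite(summ$auc_dprime)))
})
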