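test_that("Welch PSD localizes pure tones at the nominal resolution", {
  t <- (0:(512 * 60 - 1)) / 512
  sp <- welch_psd(sin(2 * pi * 10 * t), fs = 512)
  expect_lte(sp$resolution, 0.167)
  expect_lt(abs(sp$freqs[which.max(sp$power)] - 10), sp$resolution + 1e-12)
  expect_true(all(diff(sp$freqs) > 0))
  expect_true(all(sp$power >= 0))

  # zero signal, short-epoch padding, and the empty-signal error
  z <- welch_psd(rep(0, 5120), fs = 512)
  expect_true(all(z$power == 0))
  short <- welch_psd(rnorm(512), fs = 512)   # 1-s epoch < 6-s window
  expect_equal(short$n_segments, 1L)
  expect_error(welch_psd(numeric(0), fs = 512), class = "vtbci_bad_input")

  # white noise: averaged periodogram is flat across octave bands
  set.seed(31)
  w <- welch_psd(rnorm(512 * 240), fs = 512)
  bands <- list(c(4, 8), c(8, 16), c(16, 32))
  means <- vapply(bands, function(b)
    mean(w$power[w$freqs >= b[1] & w$freqs < b[2]]), numeric(1))
  expect_true(all(abs(means / mean(means) - 1) < 0.1))
})

test_that("relative power normalises, scales and tracks alpha amplitude", {
  x <- synthesize_eeg(eeg_spec(duration_s = 60), seed = 32)
  sp <- welch_psd(x)
  expect_equal(relative_power(sp, band = c(1, 40), total_range = c(1, 40)), 1)
  rp <- relative_power(sp)
  expect_gt(rp, 0); expect_lt(rp, 1)
  # invariant under uniform rescaling of the signal
  sp2 <- welch_psd(5 * as.numeric(x), fs = 512)
  expect_equal(relative_power(sp2), rp, tolerance = 1e-12)
  # monotone in the injected alpha amplitude
  rps <- vapply(c(0.3, 1, 2), function(a) {
    relative_power(welch_psd(synthesize_eeg(
      eeg_spec(duration_s = 60, alpha_amp = a), seed = 33)))
  }, numeric(1))
  expect_true(all(diff(rps) > 0))
  # zero power inside the band
  flat <- analytic_spectrum(seq(1, 40, by = 0.5), rep(1, 79))
  flat$power[flat$freqs >= 8 & flat$freqs <= 13] <- 0
  expect_equal(relative_power(flat), 0)
  expect_error(relative_power(flat, band = c(100, 110)),
               class = "vtbci_bad_input")
})

test_that("classic peak picking flags edge artifacts and ties", {
  x <- synthesize_eeg(eeg_spec(alpha_freq = 10, duration_s = 60), seed = 34)
  est <- iaf_classic(welch_psd(x))
  expect_true(est$success)
  expect_lt(abs(est$freq - 10), 2 / 6)  # within a bin of the injected tone

  f <- seq(1, 40, by = 1 / 6)
  smooth_1f <- analytic_spectrum(f, 1 / f)
  est <- iaf_classic(smooth_1f)
  expect_false(est$success)
  expect_equal(est$freq, 8, tolerance = 1 / 6)

  flat <- analytic_spectrum(f, rep(1, length(f)))
  est <- iaf_classic(flat)
  expect_false(est$success)
  expect_equal(est$freq, 8, tolerance = 1 / 6)  # tie broken to the low edge
})

test_that("aperiodic fit recovers the background exponent", {
  f <- seq(0.5, 40, by = 0.25)
  exact <- analytic_spectrum(f, 2 / f)
  expect_lt(abs(fit_aperiodic(exact)$exponent - 1), 1e-6)

  set.seed(35)
  white <- welch_psd(rnorm(512 * 120), fs = 512)
  expect_lt(abs(fit_aperiodic(white)$exponent), 0.1)

  x <- synthesize_eeg(eeg_spec(alpha_amp = 0, aperiodic_exponent = 1.5,
                               noise_sd = 0, duration_s = 120), seed = 36)
  expect_lt(abs(fit_aperiodic(welch_psd(x))$exponent - 1.5), 0.1)

  few <- analytic_spectrum(seq(3, 5, by = 0.5), rep(1, 5))
  expect_error(fit_aperiodic(few), class = "vtbci_bad_input")
})

test_that("corrected peak estimation finds genuine alpha only", {
  x <- synthesize_eeg(eeg_spec(alpha_freq = 10.4), seed = 37)
  est <- iaf_corrected(welch_psd(x))
  expect_true(est$success)
  expect_lt(abs(est$freq - 10.4), 0.2)

  for (sd in 1:3) {
    bare <- synthesize_eeg(eeg_spec(alpha_amp = 0, noise_sd = 0), seed = sd)
    expect_false(iaf_corrected(welch_psd(bare))$success)
  }

  # two peaks riding on 1/f: the larger one (11.5 Hz) wins
  f <- seq(1, 40, by = 1 / 6)
  bump <- function(f0, h, w) h * exp(-(f - f0)^2 / (2 * w^2))
  two <- analytic_spectrum(f, (1 / f) * 10^(bump(9.5, 0.8, 0.4) +
                                              bump(11.5, 1.2, 0.4)))
  est <- iaf_corrected(two, aperiodic = fit_aperiodic(two))
  expect_true(est$success)
  expect_lt(abs(est$freq - 11.5), 0.2)
})

test_that("region-of-interest aggregation averages successful electrodes", {
  ok <- function(f) structure(list(freq = f, method = "classic",
                                   success = TRUE, peak_prominence = 1),
                              class = "iaf_estimate")
  bad <- structure(list(freq = NA_real_, method = "classic",
                        success = FALSE, peak_prominence = NA_real_),
                   class = "iaf_estimate")
  expect_equal(roi_iaf(list(ok(10.2), ok(10.2)))$freq, 10.2)
  r <- roi_iaf(list(ok(10.0), ok(10.4), bad))
  expect_equal(r$freq, 10.2)
  expect_equal(r$n_success, 2L)
  expect_error(roi_iaf(list(bad, bad)), class = "vtbci_undefined_iaf")

  # averaging 6 jittery electrodes beats the typical single electrode:
  # weak alpha over a strong 1/f background at a short duration, so each
  # electrode's peak bin genuinely varies
  n_seeds <- 40
  roi_err <- c()
  per_el <- matrix(NA_real_, n_seeds, 6)
  for (seed in seq_len(n_seeds)) {
    ests <- lapply(1:6, function(e) {
      x <- synthesize_eeg(eeg_spec(alpha_freq = 10.2, alpha_amp = 0.6,
                                   aperiodic_offset = 3, duration_s = 30),
                          seed = 1000 * seed + e)
      iaf_corrected(welch_psd(x))
    })
    ok_e <- vapply(ests, function(e) isTRUE(e$success), logical(1))
    if (any(ok_e)) roi_err <- c(roi_err, roi_iaf(ests)$freq - 10.2)
    per_el[seed, ] <- vapply(ests, function(e)
      if (isTRUE(e$success)) e$freq - 10.2 else NA_real_, numeric(1))
  }
  rmse_el <- apply(per_el, 2, function(v) sqrt(mean(v[!is.na(v)]^2)))
  expect_lt(sqrt(mean(roi_err^2)), median(rmse_el))
})
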