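#' Welch power spectral density
#'
#' Averaged modified periodogram: the signal is cut into Hann-tapered
#' segments of `window_s` seconds with fractional `overlap`, each segment
#' zero-padded so the frequency-bin spacing does not exceed
#' `target_resolution`; one-sided periodograms are averaged. A signal
#' shorter than one window (e.g. a 1-s task epoch) is zero-padded to
#' `window_s` and treated as a single segment.
#'
#' @param signal Numeric vector of samples.
#' @param fs Sampling rate (Hz); defaults to the signal's `fs` attribute.
#' @param window_s Segment length (s), default 6.
#' @param overlap Fractional segment overlap, default 0.5.
#' @param target_resolution Maximum bin spacing (Hz), default 0.167.
#' @return Class `eeg_spectrum`: list with `freqs` (Hz, 0..fs/2), `power`
#'   (PSD, unit^2/Hz), `resolution`, `n_segments`, `window_s`, `overlap`,
#'   `padded_length`, `fs`.
#' @export
welch_psd <- function(signal, fs = attr(signal, "fs"), window_s = 6,
                      overlap = 0.5, target_resolution = 0.167) {
  if (is.null(fs)) stop_vtbci("sampling rate fs required", "vtbci_bad_input")
  x <- as.numeric(signal)
  if (length(x) == 0L)
    stop_vtbci("empty signal", "vtbci_bad_input")
  L <- round(window_s * fs)
  nfft <- max(L, ceiling(fs / target_resolution))
  nfft <- stats::nextn(nfft, c(2, 3, 5))
  if (length(x) < L) {
    segments <- list(c(x, rep(0, L - length(x))))
  } else {
    step <- max(1L, round(L * (1 - overlap)))
    starts <- seq(1L, length(x) - L + 1L, by = step)
    segments <- lapply(starts, function(i) x[i:(i + L - 1L)])
  }
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, L - 1) / (L - 1))  # Hann
  scale <- fs * sum(w^2)
  n_keep <- floor(nfft / 2) + 1L
  acc <- numeric(n_keep)
  for (seg in segments) {
    padded <- c(seg * w, rep(0, nfft - L))
    spec <- Mod(stats::fft(padded)[seq_len(n_keep)])^2 / scale
    # one-sided: double everything except DC and (for even nfft) Nyquist
    spec[-1] <- spec[-1] * 2
    if (nfft %% 2 == 0) spec[n_keep] <- spec[n_keep] / 2
    acc <- acc + spec
  }
  power <- acc / length(segments)
  freqs <- (seq_len(n_keep) - 1) * fs / nfft
  structure(list(freqs = freqs, power = power, resolution = fs / nfft,
                 n_segments = length(segments), window_s = window_s,
                 overlap = overlap, padded_length = nfft, fs = fs),
            class = "eeg_spectrum")
}

#' @export
print.eeg_spectrum <- function(x, ...) {
  cat(sprintf(
    "Welch PSD: %d bins to %.1f Hz (resolution %.4f Hz, %d segment(s))\n",
    length(x$freqs), max(x$freqs), x$resolution, x$n_segments))
  invisible(x)
}

band_index <- function(spec, band) {
  which(spec$freqs >= band[1] & spec$freqs <= band[2])
}

#' Relative band power
#'
#' Power summed over `band` divided by power summed over `total_range`;
#' invariant under uniform rescaling of the signal.
#'
#' @param spec An [welch_psd()] spectrum.
#' @param band Frequency band (Hz), default the alpha band (8, 13).
#' @param total_range Normalising range (Hz), default (1, 40).
#' @return A fraction in \[0, 1\].
#' @export
relative_power <- function(spec, band = c(8, 13), total_range = c(1, 40)) {
  ib <- band_index(spec, band)
  it <- band_index(spec, total_range)
  if (length(ib) == 0L)
    stop_vtbci("band contains no frequency bins", "vtbci_bad_input")
  tot <- sum(spec$power[it])
  if (tot == 0) return(0)
  sum(spec$power[ib]) / tot
}

#' Decibel z-score normalisation of a spectrum
#'
#' `10 log10(power)` per bin, then z-scored across the bins of `range`.
#' A reporting/visualisation transform only: it is monotone per spectrum,
#' so peak locations are unaffected and the IAF estimators operate on raw
#' (or aperiodic-corrected) power.
#'
#' @param spec An [welch_psd()] spectrum.
#' @param range Frequency range to normalise over (Hz).
#' @return Data frame with `freq_hz` and `power_zdb`.
#' @export
zscore_db <- function(spec, range = c(1, 40)) {
  i <- band_index(spec, range)
  db <- 10 * log10(pmax(spec$power[i], .Machine$double.xmin))
  data.frame(freq_hz = spec$freqs[i], power_zdb = (db - mean(db)) / stats::sd(db))
}

iaf_estimate <- function(freq, method, success, prominence = NA_real_) {
  structure(list(freq = freq, method = method, success = success,
                 peak_prominence = prominence), class = "iaf_estimate")
}

#' @export
print.iaf_estimate <- function(x, ...) {
  cat(sprintf("IAF (%s): %s, success = %s\n", x$method,
              ifelse(is.na(x$freq), "undefined", sprintf("%.2f Hz", x$freq)),
              x$success))
  invisible(x)
}

#' Classic alpha-peak individual alpha frequency
#'
#' The frequency of maximal power within the alpha band, ties broken
#' toward the lower frequency. When the maximum sits on a band edge and is
#' not a local maximum of the full spectrum the estimate is flagged
#' `success = FALSE`: on a 1/f-dominated spectrum the band maximum is just
#' the aperiodic slope hitting the band edge, not an alpha peak.
#'
#' @param spec An [welch_psd()] spectrum.
#' @param band Alpha band (Hz), default (8, 13).
#' @return An `iaf_estimate` with `method = "classic"`.
#' @export
iaf_classic <- function(spec, band = c(8, 13)) {
  i <- band_index(spec, band)
  if (length(i) == 0L)
    stop_vtbci("band contains no frequency bins", "vtbci_bad_input")
  pw <- spec$power[i]
  j <- i[which.max(pw)]  # which.max takes the first (lowest-freq) tie
  at_edge <- j == i[1] || j == i[length(i)]
  p <- spec$power
  is_local_max <- j > 1L && j < length(p) &&
    p[j] >= p[j - 1L] && p[j] >= p[j + 1L] &&
    (p[j] > p[j - 1L] || p[j] > p[j + 1L])
  flat_tie <- sum(pw == max(pw)) > 1L
  success <- !(at_edge && !is_local_max) && !flat_tie
  iaf_estimate(spec$freqs[j], "classic", success)
}

#' Fit the aperiodic (1/f) background of a spectrum
#'
#' Ordinary least-squares line in `log10(power)` versus `log10(freq)` over
#' `fit_range`, excluding the alpha-adjacent band so an oscillatory peak
#' cannot tilt the fit. A deliberately simple stand-in for full spectral
#' parameterisation: adequate for peak-location correction.
#'
#' @param spec An [welch_psd()] spectrum.
#' @param fit_range Frequencies used for the fit (Hz), default (3, 40).
#' @param exclude Band excluded from the fit (Hz), default (7, 14).
#' @return Class `aperiodic_fit`: `offset` (log10-power at 1 Hz),
#'   `exponent` (power ~ 1/f^exponent), `fit_range`, `exclude`,
#'   `n_bins`.
#' @export
fit_aperiodic <- function(spec, fit_range = c(3, 40), exclude = c(7, 14)) {
  i <- band_index(spec, fit_range)
  i <- i[spec$freqs[i] < exclude[1] | spec$freqs[i] > exclude[2]]
  i <- i[spec$power[i] > 0 & spec$freqs[i] > 0]
  if (length(i) < 10L)
    stop_vtbci("fewer than 10 usable bins for the aperiodic fit",
               "vtbci_bad_input")
  lf <- log10(spec$freqs[i])
  lp <- log10(spec$power[i])
  co <- stats::coef(stats::lm(lp ~ lf))
  structure(list(offset = unname(co[1]), exponent = -unname(co[2]),
                 fit_range = fit_range, exclude = exclude,
                 n_bins = length(i)), class = "aperiodic_fit")
}

# Topographic prominence of peak `j` within `y[idx]`: height above the
# higher of the two bases reached before ascending past the peak height.
peak_prominence <- function(y, idx, j) {
  pos <- match(j, idx)
  yy <- y[idx]
  left <- if (pos == 1L) yy[1] else {
    run <- yy[seq_len(pos - 1L)]
    higher <- which(run > yy[pos])
    min(yy[(if (length(higher)) max(higher) + 1L else 1L):(pos - 1L)])
  }
  right <- if (pos == length(yy)) yy[length(yy)] else {
    run <- yy[(pos + 1L):length(yy)]
    higher <- which(run > yy[pos])
    hi <- if (length(higher)) pos + min(higher) - 1L else length(yy)
    min(yy[(pos + 1L):hi])
  }
  yy[pos] - max(left, right)
}

#' Aperiodic-corrected individual alpha frequency
#'
#' Subtracts the fitted 1/f background in log10 space and picks, within the
#' alpha band, the highest interior local maximum of the residual whose
#' topographic prominence reaches `min_prominence`. With no such peak the
#' estimate is returned as unsuccessful — the expected outcome on spectra
#' without clear alpha, which this estimator must flag rather than invent.
#'
#' @param spec An [welch_psd()] spectrum.
#' @param band Alpha band (Hz), default (8, 13).
#' @param aperiodic An [fit_aperiodic()] result for the same spectrum
#'   (fitted on demand when omitted).
#' @param min_prominence Minimum residual prominence, in log10-power units
#'   (default 0.5, i.e. 5 dB: well above the residual fluctuations of an
#'   averaged periodogram of a 4-minute recording, well below a genuine
#'   oscillatory peak).
#' @return An `iaf_estimate` with `method = "aperiodic_corrected"`.
#' @export
iaf_corrected <- function(spec, band = c(8, 13), aperiodic = NULL,
                          min_prominence = 0.5) {
  if (is.null(aperiodic)) aperiodic <- fit_aperiodic(spec)
  usable <- which(spec$power > 0 & spec$freqs > 0)
  resid <- rep(NA_real_, length(spec$freqs))
  resid[usable] <- log10(spec$power[usable]) -
    (aperiodic$offset - aperiodic$exponent * log10(spec$freqs[usable]))
  ib <- intersect(band_index(spec, band), usable)
  if (length(ib) < 3L)
    return(iaf_estimate(NA_real_, "aperiodic_corrected", FALSE))
  interior <- ib[-c(1L, length(ib))]
  is_peak <- vapply(interior, function(j) {
    !is.na(resid[j - 1L]) && !is.na(resid[j + 1L]) &&
      resid[j] > resid[j - 1L] && resid[j] >= resid[j + 1L]
  }, logical(1))
  peaks <- interior[is_peak]
  if (length(peaks) == 0L)
    return(iaf_estimate(NA_real_, "aperiodic_corrected", FALSE))
  prom <- vapply(peaks, function(j) peak_prominence(resid, ib, j), numeric(1))
  keep <- prom >= min_prominence
  if (!any(keep))
    return(iaf_estimate(NA_real_, "aperiodic_corrected", FALSE))
  peaks <- peaks[keep]; prom <- prom[keep]
  j <- peaks[which.max(resid[peaks])]
  iaf_estimate(spec$freqs[j], "aperiodic_corrected", TRUE,
               prom[which.max(resid[peaks])])
}

#' Region-of-interest alpha frequency
#'
#' Averages the successful per-electrode estimates of a region of
#' interest; fails when no electrode yields a usable peak.
#'
#' @param estimates A list of `iaf_estimate` objects (one per electrode).
#' @return A list with `freq` (mean IAF, Hz), `n_success` and `n_total`.
#' @export
roi_iaf <- function(estimates) {
  ok <- vapply(estimates, function(e) isTRUE(e$success), logical(1))
  if (!any(ok))
    stop_vtbci("no successful IAF estimate in the region of interest",
               "vtbci_undefined_iaf")
  freqs <- vapply(estimates[ok], function(e) e$freq, numeric(1))
  list(freq = mean(freqs), n_success = sum(ok), n_total = length(estimates))
}
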