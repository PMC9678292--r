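#' Welch power spectral density with 1 Hz bins
#'
#' Averaged windowed periodograms with segment length equal to the sampling
#' rate, so the frequency grid runs from 0 to the Nyquist frequency in
#' exactly 1 Hz steps.  Hann window, 50% overlap.  One-sided density,
#' normalised so that the density summed over all bins times the 1 Hz bin
#' width approximates the mean power (variance, for a DC-free stream) of
#' the signal.
#'
#' @param v numeric sample stream.
#' @param fs sampling rate in Hz; must be a whole number of samples per
#'   second and no longer than the stream.
#' @param window `"hann"` (default) or `"rect"`.
#' @param overlap fractional segment overlap (default 0.5).
#' @return An object of class `psd`: list with `freq` (Hz, `0:(fs/2)`) and
#'   `density` (V^2/Hz).
#' @export
welch_psd <- function(v, fs, window = c("hann", "rect"), overlap = 0.5) {
  window <- match.arg(window)
  nseg <- as.integer(round(fs))
  if (length(v) < nseg) stop("parameter error: stream shorter than one window (fs samples)")
  # periodic Hann
  w <- if (window == "hann") 0.5 - 0.5 * cos(2 * pi * (0:(nseg - 1)) / nseg)
       else rep(1, nseg)
  hop <- max(1L, as.integer(round(nseg * (1 - overlap))))
  starts <- seq(1L, length(v) - nseg + 1L, by = hop)
  u <- sum(w^2)
  nbin <- nseg %/% 2L + 1L
  acc <- numeric(nbin)
  for (s in starts) {
    seg <- v[s:(s + nseg - 1L)] * w
    sp <- abs(stats::fft(seg))^2
    acc <- acc + sp[seq_len(nbin)]
  }
  dens <- acc / (length(starts) * fs * u)
  # one-sided: double everything except DC (and Nyquist when nseg is even)
  scale <- rep(2, nbin); scale[1] <- 1
  if (nseg %% 2L == 0L) scale[nbin] <- 1
  structure(list(freq = (seq_len(nbin) - 1L) * fs / nseg,
                 density = dens * scale),
            class = "psd")
}

#' @export
print.psd <- function(x, ...) {
  cat(sprintf("Welch PSD: %d bins, %g-%g Hz, total power %.4g V^2\n",
              length(x$freq), min(x$freq), max(x$freq),
              sum(x$density) * diff(x$freq[1:2])))
  invisible(x)
}

#' @export
plot.psd <- function(x, ...) {
  graphics::plot(x$freq, x$density, type = "l", log = "y",
                 xlab = "frequency (Hz)", ylab = "power density (V²/Hz)",
                 ...)
  invisible(x)
}

#' Band noise power from a PSD
#'
#' Sums density times the 1 Hz bin width over the closed band
#' `[lo, hi]` — by default 5 to 125 Hz, the muscle-noise band that excludes
#' eye-movement and drift below 5 Hz.
#'
#' @param psd a [welch_psd()] result.
#' @param lo,hi band edges in Hz, inclusive.
#' @return Band power in V^2.
#' @export
band_noise_power <- function(psd, lo = 5, hi = 125) {
  if (hi > max(psd$freq) + 1e-9) stop("parameter error: hi above Nyquist bin")
  if (lo > hi) stop("parameter error: lo > hi")
  df <- psd$freq[2] - psd$freq[1]
  sel <- psd$freq >= lo - 1e-9 & psd$freq <= hi + 1e-9
  sum(psd$density[sel]) * df
}

#' Event-triggered average (evoked potential)
#'
#' Averages fixed-length epochs of the stream aligned at each event time
#' (plus an optional alignment latency).  Epochs that would run outside the
#' stream are dropped and counted.
#'
#' @param v numeric sample stream.
#' @param events event times in seconds.
#' @param pre_s seconds before the event included in the epoch.
#' @param post_s seconds after the event included in the epoch.
#' @param fs sampling rate (Hz).
#' @param latency_s alignment shift added to every event time (e.g. a
#'   transmission latency, or the filter's inner-channel delay).
#' @return An object of class `evoked`: `time` (s relative to the event),
#'   `average`, `n_epochs`, `n_dropped`, `fs`.
#' @export
event_triggered_average <- function(v, events, pre_s = 0.2, post_s = 0.6,
                                    fs, latency_s = 0) {
  npre <- as.integer(round(pre_s * fs))
  npost <- as.integer(round(post_s * fs))
  len <- npre + npost + 1L
  acc <- numeric(len)
  used <- 0L; dropped <- 0L
  for (tv in events) {
    i0 <- as.integer(round((tv + latency_s) * fs)) + 1L  # event sample, 1-based
    lo <- i0 - npre; hi <- i0 + npost
    if (lo < 1L || hi > length(v)) { dropped <- dropped + 1L; next }
    acc <- acc + v[lo:hi]
    used <- used + 1L
  }
  if (used == 0L) stop("data error: no usable epochs")
  structure(list(time = (seq_len(len) - 1L - npre) / fs,
                 average = acc / used, n_epochs = used,
                 n_dropped = dropped, fs = fs),
            class = "evoked")
}

#' @export
print.evoked <- function(x, ...) {
  cat(sprintf("Event-triggered average: %d epochs (%d dropped), %.3f..%.3f s, peak %.3g\n",
              x$n_epochs, x$n_dropped, min(x$time), max(x$time),
              max(abs(x$average))))
  invisible(x)
}

#' @export
plot.evoked <- function(x, ...) {
  graphics::plot(x$time, x$average, type = "l", xlab = "time from event (s)",
                 ylab = "amplitude", ...)
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}

#' Median evoked peak power in the 300-500 ms window
#'
#' The signal-power estimate: median of the squared evoked-average samples
#' over the closed window 300 to 500 ms after the event.  The median (rather
#' than the mean or maximum) deliberately underestimates slightly, matching
#' what a real-time system averaging over seconds would see.
#'
#' @param evoked an [event_triggered_average()] result.
#' @param window the power window in seconds after the event.
#' @return Power in V^2.
#' @export
p300_signal_power <- function(evoked, window = c(0.3, 0.5)) {
  if (min(evoked$time) > window[1] + 1e-9 || max(evoked$time) < window[2] - 1e-9)
    stop("parameter error: power window outside the evoked waveform")
  sel <- evoked$time >= window[1] - 1e-9 & evoked$time <= window[2] + 1e-9
  stats::median(evoked$average[sel]^2)
}

#' Signal-to-noise ratio
#'
#' `SNR = signal_power / noise_power`, in linear form and decibels.
#'
#' @param signal_power median evoked peak power (V^2).
#' @param noise_power summed 5-125 Hz band power (V^2).
#' @return List with `ratio` and `db` (`10*log10(ratio)`).
#' @export
compute_snr <- function(signal_power, noise_power) {
  stopifnot(signal_power >= 0)
  if (!(noise_power > 0)) stop("undefined SNR: noise power must be > 0")
  ratio <- signal_power / noise_power
  list(ratio = ratio, db = 10 * log10(ratio))
}

#' SNR improvement of a filtered variant over the unfiltered inner channel
#'
#' By default reports `filtered - inner` in dB so that an improvement is
#' positive.  The opposite orientation (`inner - filtered`) is available as
#' `convention = "inner_minus_filtered"`.
#'
#' @param snr_inner_db SNR of the unfiltered inner channel (dB).
#' @param snr_filtered_db SNR of the filter output (dB).
#' @param convention sign convention.
#' @return Improvement in dB (vectorised).
#' @export
delta_snr <- function(snr_inner_db, snr_filtered_db,
                      convention = c("improvement", "inner_minus_filtered")) {
  convention <- match.arg(convention)
  stopifnot(all(is.finite(snr_inner_db)), all(is.finite(snr_filtered_db)))
  d <- snr_filtered_db - snr_inner_db
  if (convention == "inner_minus_filtered") d <- -d
  d
}

#' Paired significance test on per-subject SNR improvements
#'
#' Two-sided paired test that the mean difference between two per-subject
#' improvement vectors (or one vector against zero) is nonzero.  Paired
#' t-test by default, Wilcoxon signed-rank selectable.  Degenerate
#' zero-variance differences are handled: all-zero differences give p = 1
#' (no evidence), a constant nonzero difference is reported at the
#' double-precision underflow floor.
#'
#' @param deltas_a per-subject improvements (dB).
#' @param deltas_b comparison vector, or a scalar 0 to test against no
#'   improvement.
#' @param method `"t"` or `"wilcoxon"`.
#' @return The p-value.
#' @export
paired_significance <- function(deltas_a, deltas_b = 0,
                                method = c("t", "wilcoxon")) {
  method <- match.arg(method)
  if (length(deltas_b) == 1L) deltas_b <- rep(deltas_b, length(deltas_a))
  if (length(deltas_a) != length(deltas_b))
    stop("parameter error: length mismatch")
  if (length(deltas_a) < 3L) stop("parameter error: need >= 3 pairs")
  d <- deltas_a - deltas_b
  if (stats::sd(d) == 0) {
    return(if (mean(d) == 0) 1 else .Machine$double.xmin)
  }
  if (method == "t")
    stats::t.test(d)$p.value
  else
    stats::wilcox.test(d, exact = FALSE)$p.value
}

#' Thermal (Johnson) noise RMS of a resistive source
#'
#' `sqrt(4 k_B T R B)`: the uncorrelated noise floor that an adaptive
#' canceller cannot remove (it passes through unchanged because it does not
#' correlate with the reference channel).
#'
#' @param temperature_k absolute temperature (K); body temperature 310 K.
#' @param resistance_ohm source resistance (ohm).
#' @param bandwidth_hz bandwidth (Hz).
#' @return RMS noise voltage in volts.
#' @examples
#' thermal_noise_rms()  # ~65 nV for 1 kOhm over 250 Hz at 310 K
#' @export
thermal_noise_rms <- function(temperature_k = 310, resistance_ohm = 1000,
                              bandwidth_hz = 250) {
  kb <- 1.380649e-23
  sqrt(4 * kb * temperature_k * resistance_ohm * bandwidth_hz)
}

#' SNR report for one filter variant
#' @param variant variant label.
#' @param signal_power median evoked peak power (V^2).
#' @param noise_power 5-125 Hz band power (V^2).
#' @return An object of class `snr_report`.
#' @export
snr_report <- function(variant, signal_power, noise_power) {
  stopifnot(signal_power >= 0, noise_power >= 0)
  snr <- if (noise_power > 0 && signal_power > 0)
    10 * log10(signal_power / noise_power) else NA_real_
  structure(list(variant = variant, signal_power = signal_power,
                 noise_power = noise_power, snr_db = snr),
            class = "snr_report")
}

#' @export
print.snr_report <- function(x, ...) {
  cat(sprintf("SNR report [%s]: signal %.4g V^2, noise %.4g V^2, SNR %.2f dB\n",
              x$variant, x$signal_power, x$noise_power, x$snr_db))
  invisible(x)
}

#' Evaluate one filter variant on a noise session and a P300 session
#'
#' Runs the chosen variant over both sessions (for the deep neural filter
#' the network learns from scratch on each session, as it must for every
#' new subject), takes the noise power as the summed 5-125 Hz Welch band
#' power of the filtered noise session, and the signal power as the median
#' 300-500 ms power of the filtered P300 session's event-triggered average.
#' For variants that delay the inner channel (dnf, lms) the epoch alignment
#' is shifted by the same delay so the power window stays centred on the
#' evoked peak.
#'
#' @param noise_session a [recording] of the jaw-clench (EMG noise) session.
#' @param p300_session a [recording] of the oddball session, with events.
#' @param config a [run_config]; `config$variant` picks the filter.
#' @param eta_noise,eta_p300 learning rates for the two sessions (the
#'   reference amplitude differs between tasks, so the nominal rates are
#'   set to equalise the effective rate).
#' @param latency_s extra alignment latency for the evoked average (e.g.
#'   0.1 s for wireless-acquisition recordings; 0 for synthetic sessions).
#' @param noise_band noise band in Hz.
#' @param p300_window signal-power window in seconds after the event.
#' @param normalize_x for the deep neural filter, rescale the noise
#'   reference to the published input operating regime (see
#'   [normalize_reference()]) so the published per-task learning rates
#'   apply regardless of the sessions' absolute amplitudes.  On by default
#'   for the study protocol.
#' @return An `snr_report`.
#' @export
evaluate_variant <- function(noise_session, p300_session,
                             config = run_config(),
                             eta_noise = 2.5, eta_p300 = NULL,
                             latency_s = 0, noise_band = c(5, 125),
                             p300_window = c(0.3, 0.5),
                             normalize_x = TRUE) {
  stopifnot(inherits(noise_session, "recording"),
            inherits(p300_session, "recording"))
  # the published P300-task rate (10) compensates that task's smaller
  # reference amplitude; with the reference normalized, both sessions sit
  # at the same amplitude and the same rate applies to both
  if (is.null(eta_p300)) eta_p300 <- if (normalize_x) eta_noise else 10
  norm <- normalize_x && config$variant == "dnf"
  fit_noise <- run_variant(noise_session, config, eta = eta_noise,
                           normalize_x = norm)
  fit_p300 <- run_variant(p300_session, config, eta = eta_p300,
                          normalize_x = norm)
  psd <- welch_psd(fit_noise$e, noise_session$fs)
  noise_power <- band_noise_power(psd, noise_band[1], noise_band[2])
  evoked <- event_triggered_average(
    fit_p300$e, p300_session$events, pre_s = 0.2, post_s = 0.7,
    fs = p300_session$fs,
    latency_s = latency_s + fit_p300$delay / p300_session$fs)
  signal_power <- p300_signal_power(evoked, p300_window)
  snr_report(config$variant, signal_power, noise_power)
}

#' Multi-subject SNR comparison of filter variants
#'
#' Generates (or accepts) per-subject session pairs, evaluates each variant
#' on each subject, and assembles the per-subject SNR table, the
#' improvement (delta SNR) of each adaptive variant over the unfiltered
#' inner channel, and paired significance tests.
#'
#' @param subjects either an integer number of synthetic subjects or a list
#'   of `list(noise = recording, p300 = recording)` pairs.
#' @param seeds integer seeds, one per synthetic subject.
#' @param variants character vector of variants to evaluate (always
#'   includes `"none"` as reference).
#' @param config base [run_config].
#' @param ... passed to [evaluate_variant()].
#' @return An object of class `snr_study`: `table` (data.frame: subject,
#'   variant, signal_power, noise_power, snr_db), `delta` (data.frame:
#'   subject, variant, delta_db), `summary` (mean and sd of delta per
#'   variant), `p_values` (each variant vs 0 and dnf vs lms when both
#'   present).
#' @export
snr_study <- function(subjects = 10, seeds = seq_len(subjects) * 101L,
                      variants = c("dnf", "lms"),
                      config = run_config(), ...) {
  if (is.numeric(subjects)) {
    subjects <- lapply(seeds, function(s)
      list(noise = synthesize_recording(session1_spec(seed = s))$recording,
           p300 = synthesize_recording(session2_spec(seed = s + 1L))$recording))
  }
  variants <- union("none", variants)
  rows <- list()
  for (i in seq_along(subjects)) {
    for (v in variants) {
      cfg <- modify_config(config, variant = v,
                           seed = config$seed + i)
      rep <- evaluate_variant(subjects[[i]]$noise, subjects[[i]]$p300,
                              cfg, ...)
      rows[[length(rows) + 1L]] <-
        data.frame(subject = i, variant = v,
                   signal_power = rep$signal_power,
                   noise_power = rep$noise_power, snr_db = rep$snr_db)
    }
  }
  tab <- do.call(rbind, rows)
  inner <- tab$snr_db[tab$variant == "none"]
  filt <- setdiff(variants, "none")
  delta <- do.call(rbind, lapply(filt, function(v) {
    data.frame(subject = seq_along(subjects), variant = v,
               delta_db = delta_snr(inner, tab$snr_db[tab$variant == v]))
  }))
  smry <- do.call(rbind, lapply(filt, function(v) {
    d <- delta$delta_db[delta$variant == v]
    data.frame(variant = v, mean_delta_db = mean(d), sd_delta_db = stats::sd(d))
  }))
  pv <- list()
  for (v in filt)
    pv[[paste0(v, "_vs_none")]] <-
      paired_significance(delta$delta_db[delta$variant == v], 0)
  if (all(c("dnf", "lms") %in% filt))
    pv[["dnf_vs_lms"]] <-
      paired_significance(delta$delta_db[delta$variant == "dnf"],
                          delta$delta_db[delta$variant == "lms"])
  structure(list(table = tab, delta = delta, summary = smry,
                 p_values = pv),
            class = "snr_study")
}

#' @export
print.snr_study <- function(x, ...) {
  cat("SNR study over", length(unique(x$table$subject)), "subjects\n")
  for (i in seq_len(nrow(x$summary)))
    cat(sprintf("  %-8s delta SNR = %.2f +/- %.2f dB\n",
                x$summary$variant[i], x$summary$mean_delta_db[i],
                x$summary$sd_delta_db[i]))
  for (nm in names(x$p_values))
    cat(sprintf("  p(%s) = %.3g\n", nm, x$p_values[[nm]]))
  invisible(x)
}
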