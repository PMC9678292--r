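test_that("Welch PSD has 1 Hz bins and satisfies Parseval", {
  fs <- 250
  expect_error(welch_psd(numeric(100), fs), "parameter error")
  psd0 <- welch_psd(numeric(1000), fs)
  expect_equal(psd0$density, numeric(length(psd0$density)))
  expect_equal(psd0$freq, 0:125)
  expect_equal(diff(psd0$freq[1:2]), 1)

  # unit 10 Hz sine: total power 0.5 within 2%
  t <- seq(0, 60, by = 1 / fs)
  psd <- welch_psd(sin(2 * pi * 10 * t), fs)
  expect_equal(sum(psd$density) * 1, 0.5, tolerance = 0.02)

  # white noise: total power ~ variance within 5%
  set.seed(12)
  v <- rnorm(120 * fs, sd = 3e-6)
  psd <- welch_psd(v, fs)
  expect_equal(sum(psd$density), var(v), tolerance = 0.05)

  # Parseval holds for structured signals too (standing check)
  out <- short_session1(seed = 2, duration_s = 20)
  for (ch in list(out$recording$inner, out$recording$outer)) {
    psd <- welch_psd(ch, out$recording$fs)
    expect_equal(sum(psd$density), mean(ch^2), tolerance = 0.05)
  }
})

test_that("band power sums density over the closed 5-125 Hz band", {
  fs <- 250
  flat <- structure(list(freq = 0:125, density = rep(0.01, 126)),
                    class = "psd")
  expect_equal(band_noise_power(flat, 5, 125), 1.21)

  t <- seq(0, 60, by = 1 / fs)
  below <- welch_psd(sin(2 * pi * 3 * t), fs)   # 3 Hz: below the band
  expect_lt(band_noise_power(below), 0.5 * 0.01)
  inband <- welch_psd(0.7 * sin(2 * pi * 35 * t), fs)
  expect_equal(band_noise_power(inband), 0.7^2 / 2, tolerance = 0.02)
  expect_error(band_noise_power(flat, 5, 200), "parameter error")
})

test_that("event-triggered averaging aligns, drops and averages correctly", {
  fs <- 250
  template <- sin(2 * pi * 5 * seq(0, 0.8, by = 1 / fs)) *
    exp(-seq(0, 0.8, by = 1 / fs))
  nrep <- 10
  gap <- numeric(0.2 * fs)
  v <- c(numeric(fs), rep(c(template, gap), nrep))
  events <- fs / fs + 0.2 + (seq_len(nrep) - 1) * (length(template) + length(gap)) / fs
  # identical epochs: average equals one epoch
  ev <- event_triggered_average(v, events, pre_s = 0.1, post_s = 0.5, fs = fs)
  one <- event_triggered_average(v, events[1], pre_s = 0.1, post_s = 0.5,
                                 fs = fs)
  expect_equal(ev$average, one$average, tolerance = 1e-12)
  expect_equal(ev$n_epochs, nrep)

  # latency shifts alignment by round(latency * fs) samples
  ev_lat <- event_triggered_average(v, events, pre_s = 0.1, post_s = 0.5,
                                    fs = fs, latency_s = 0.1)
  shift <- 0.1 * fs
  expect_equal(ev_lat$average[1:(length(ev$average) - shift)],
               ev$average[(shift + 1):length(ev$average)], tolerance = 1e-12)

  # out-of-bounds epochs are dropped and counted
  ev_edge <- event_triggered_average(v, c(0.0, events), pre_s = 0.5,
                                     post_s = 0.5, fs = fs)
  expect_equal(ev_edge$n_dropped, 1L)
  expect_error(event_triggered_average(v, 1e6, fs = fs), "data error")

  # residual noise shrinks like 1/sqrt(N)
  set.seed(5)
  resid_rms <- function(N) {
    tmpl <- rep(0, 0.3 * fs)
    sig <- rep(tmpl, N) + rnorm(N * length(tmpl))
    evs <- (seq_len(N) - 1) * length(tmpl) / fs + 0.1
    ev <- event_triggered_average(sig, evs, pre_s = 0.05, post_s = 0.15,
                                  fs = fs)
    sqrt(mean(ev$average^2))
  }
  ratio <- resid_rms(25) / resid_rms(100)
  expect_equal(ratio, 2, tolerance = 0.35)  # sqrt(100/25) = 2
})

test_that("evoked peak power is the median square over 300-500 ms", {
  fs <- 250
  tm <- seq(-0.2, 0.7, by = 1 / fs)
  ev <- structure(list(time = tm, average = rep(10e-6, length(tm)),
                       n_epochs = 1L, n_dropped = 0L, fs = fs),
                  class = "evoked")
  expect_equal(p300_signal_power(ev), 1e-10)
  ev$average <- numeric(length(tm))
  expect_equal(p300_signal_power(ev), 0)

  # raised-cosine bump: compare against direct enumeration
  bump <- ifelse(abs(tm - 0.4) <= 0.1,
                 10e-6 * 0.5 * (1 + cos(2 * pi * (tm - 0.4) / 0.2)), 0)
  ev$average <- bump
  sel <- tm >= 0.3 & tm <= 0.5
  expect_equal(p300_signal_power(ev), median(bump[sel]^2))
  ev_short <- ev; ev_short$time <- tm - 1
  expect_error(p300_signal_power(ev_short), "parameter error")
})

test_that("SNR arithmetic and its sign conventions", {
  expect_equal(compute_snr(1e-10, 1e-10)$db, 0)
  expect_equal(compute_snr(1e-9, 1e-10)$db, 10)
  expect_equal(compute_snr(1e-10, 4e-10)$db, -6.0206, tolerance = 1e-4)
  expect_error(compute_snr(1, 0), "noise power")
  # monotonicity
  expect_gt(compute_snr(2e-10, 1e-10)$db, compute_snr(1e-10, 1e-10)$db)
  expect_lt(compute_snr(1e-10, 2e-10)$db, compute_snr(1e-10, 1e-10)$db)

  expect_equal(delta_snr(-20, -16), 4)
  expect_equal(delta_snr(-12, -12), 0)
  expect_equal(delta_snr(-20, -16, convention = "inner_minus_filtered"), -4)
})

test_that("paired significance testing matches the t distribution", {
  expect_equal(paired_significance(rep(2, 5), rep(2, 5)), 1)
  expect_equal(paired_significance(rep(5, 5), rep(0, 5)),
               .Machine$double.xmin)
  expect_error(paired_significance(1:4, 1:3), "length mismatch")

  set.seed(8)
  d <- rnorm(18, mean = 2, sd = 1)
  p <- paired_significance(d, 0)
  tstat <- mean(d) / (sd(d) / sqrt(18))
  expect_equal(p, 2 * pt(-abs(tstat), df = 17), tolerance = 1e-6)
  expect_lt(paired_significance(d, 0, method = "wilcoxon"), 0.01)
})

test_that("variant evaluation is reproducible and rewards denoising", {
  s1 <- short_session1(seed = 31, duration_s = 30)$recording
  s2 <- short_session2(seed = 32, duration_s = 90)$recording
  cfg <- run_config(variant = "dnf", seed = 5)
  r1 <- evaluate_variant(s1, s2, cfg)
  r2 <- evaluate_variant(s1, s2, cfg)
  expect_equal(r1$snr_db, r2$snr_db)
  expect_s3_class(r1, "snr_report")

  # variant "none" equals direct arithmetic on the conditioned streams
  r0 <- evaluate_variant(s1, s2, run_config(variant = "none"))
  d1 <- condition_channel(s1$inner, 0.5, s1$fs, 1000)
  d2 <- condition_channel(s2$inner, 0.5, s2$fs, 1000)
  np <- band_noise_power(welch_psd(d1, s1$fs))
  ev <- event_triggered_average(d2, s2$events, pre_s = 0.2, post_s = 0.7,
                                fs = s2$fs)
  sp <- p300_signal_power(ev)
  expect_equal(r0$noise_power, np, tolerance = 1e-12)
  expect_equal(r0$signal_power, sp, tolerance = 1e-12)
  expect_equal(r0$snr_db, 10 * log10(sp / np), tolerance = 1e-10)
})

test_that("thermal noise of a 1 kOhm source over the EEG band is tens of nV", {
  expect_equal(thermal_noise_rms(310, 1000, 250), 6.54e-8, tolerance = 1e-3)
  # scales with sqrt of each argument
  expect_equal(thermal_noise_rms(310, 4000, 250),
               2 * thermal_noise_rms(310, 1000, 250))
})
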