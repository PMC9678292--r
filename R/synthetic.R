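#' Specification for a synthetic compound-electrode session
#'
#' All parameters of the two-channel signal model.  The inner channel is
#' `d = b + m + c` — background EEG `b`, muscle noise `m`, evoked signal
#' `c` — and the outer ring channel is `x = h * (r + alpha * c)` with
#' `r` (the total noise `b + m`), `h` a mild first-order low-pass (the noise
#' reaches the ring as a filtered version of itself) and `alpha` the small
#' crosstalk of the evoked signal into the ring.
#'
#' Default amplitudes (10 uV EEG RMS, 10 uV evoked peak, 50 uV burst EMG,
#' 5 uV tonic EMG) put the inner-channel SNR in the range observed with
#' real compound-electrode recordings (roughly -20 to -5 dB).
#'
#' @param fs sampling rate (Hz).
#' @param duration_s session length (s).
#' @param eeg_band background-EEG passband (Hz).
#' @param eeg_rms background-EEG RMS (V).
#' @param emg_band muscle-noise passband (Hz); upper edge capped below
#'   Nyquist.
#' @param emg_tonic_rms RMS of the always-on muscle tone (V).
#' @param emg_burst_rms RMS at the peak of a clench burst (V).
#' @param burst_period_s one clench every this many seconds.
#' @param burst_duration_s clench envelope length (s).
#' @param oddball_gap_s `(min, max)` seconds between oddball stimuli.
#' @param p300_amp evoked-response peak amplitude (V).
#' @param p300_center_s evoked peak latency after the stimulus (s).
#' @param p300_width_s full width of the raised-cosine evoked bump (s).
#' @param alpha crosstalk fraction of the evoked signal into the outer
#'   ring, `0 <= alpha < 1`.
#' @param h_cutoff_hz cutoff of the first-order low-pass modelling the
#'   noise path to the ring (Hz).
#' @param seed integer RNG seed; the same spec reproduces the session
#'   bitwise.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(fs = 500, duration_s = 120,
                           eeg_band = c(0.5, 30), eeg_rms = 10e-6,
                           emg_band = c(20, min(125, 0.475 * fs)),
                           emg_tonic_rms = 5e-6, emg_burst_rms = 50e-6,
                           burst_period_s = 15, burst_duration_s = 2,
                           oddball_gap_s = c(7, 13),
                           p300_amp = 10e-6, p300_center_s = 0.4,
                           p300_width_s = 0.2, alpha = 0.05,
                           h_cutoff_hz = 100, seed = 1L) {
  stopifnot(fs > 0, duration_s > 0,
            eeg_band[1] > 0, eeg_band[2] < fs / 2, eeg_band[1] < eeg_band[2],
            emg_band[1] > 0, emg_band[2] < fs / 2, emg_band[1] < emg_band[2],
            eeg_rms >= 0, emg_tonic_rms >= 0, emg_burst_rms >= 0,
            p300_amp >= 0, alpha >= 0, alpha < 1,
            h_cutoff_hz > 0, is.infinite(h_cutoff_hz) || h_cutoff_hz < fs / 2)
  structure(list(fs = fs, duration_s = duration_s, eeg_band = eeg_band,
                 eeg_rms = eeg_rms, emg_band = emg_band,
                 emg_tonic_rms = emg_tonic_rms,
                 emg_burst_rms = emg_burst_rms,
                 burst_period_s = burst_period_s,
                 burst_duration_s = burst_duration_s,
                 oddball_gap_s = oddball_gap_s, p300_amp = p300_amp,
                 p300_center_s = p300_center_s,
                 p300_width_s = p300_width_s, alpha = alpha,
                 h_cutoff_hz = h_cutoff_hz, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Canonical session specs
#'
#' `session1_spec` is the jaw-clench EMG-noise session: 120 s at 500 Hz,
#' one clench every 15 s, no oddball stimuli.  `session2_spec` is the
#' oddball (P300) session: 300 s at 250 Hz, stimuli every 7-13 s, tonic
#' muscle noise only (no clenches).
#'
#' @param seed RNG seed.
#' @param ... overrides passed to [synthetic_spec()].
#' @return A `synthetic_spec`.
#' @export
session1_spec <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(fs = 500, duration_s = 120, p300_amp = 0, seed = seed),
    list(...))
  do.call(synthetic_spec, args)
}

#' @rdname session1_spec
#' @export
stationary_spec <- function(seed = 3L, ...) {
  # constant-power muscle noise (degenerate burst envelope): stationary
  # correlated noise in both channels, for convergence diagnostics; 240 s
  # is about four times the observed convergence time at eta = 2.5, so the
  # first/last windows straddle convergence
  args <- utils::modifyList(
    list(fs = 500, duration_s = 240, p300_amp = 0,
         emg_tonic_rms = 5e-6, emg_burst_rms = 5e-6, seed = seed),
    list(...))
  do.call(synthetic_spec, args)
}

#' @rdname session1_spec
#' @export
session2_spec <- function(seed = 2L, ...) {
  args <- utils::modifyList(
    list(fs = 250, duration_s = 300, emg_burst_rms = 0, seed = seed),
    list(...))
  do.call(synthetic_spec, args)
}

# band-limited unit-RMS Gaussian noise, built in the frequency domain:
# white Gaussian noise whose spectrum is masked to the closed band, so the
# out-of-band power is zero by construction (a generator runs offline, so
# no causal realization is needed)
band_noise <- function(n, band, fs) {
  wn <- stats::rnorm(n)
  sp <- stats::fft(wn)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)  # two-sided frequency axis
  sp[f < band[1] | f > band[2]] <- 0
  v <- Re(stats::fft(sp, inverse = TRUE)) / n
  v / sqrt(mean(v^2))
}

iir_filter_from <- function(ba) iir_filter(ba$b, ba$a)

#' Generate the background-EEG component
#'
#' Gaussian noise band-passed to the EEG band and scaled to the requested
#' RMS.  Uses the current RNG stream; seed via [synthesize_recording()] or
#' `set.seed`.
#'
#' @param spec a [synthetic_spec].
#' @return Numeric stream `b` of `fs * duration_s` samples (V).
#' @export
gen_background_eeg <- function(spec) {
  n <- as.integer(round(spec$fs * spec$duration_s))
  if (spec$eeg_rms == 0) return(numeric(n))
  spec$eeg_rms * band_noise(n, spec$eeg_band, spec$fs)
}

#' Generate the muscle-noise component
#'
#' Amplitude-modulated band-limited Gaussian noise: a single unit-RMS
#' carrier in the muscle band (roughly flat above 20 Hz) whose envelope sits
#' at `emg_tonic_rms` between clenches and rises smoothly (raised-cosine) to
#' `emg_burst_rms` during each clench.  Clenches are centred at
#' `(k - 1/2) * burst_period_s`, giving `duration_s / burst_period_s`
#' bursts.
#'
#' @param spec a [synthetic_spec].
#' @return List with `m` (stream, V) and `bursts` (onset times, s).
#' @export
gen_emg <- function(spec) {
  n <- as.integer(round(spec$fs * spec$duration_s))
  if (spec$emg_tonic_rms == 0 && spec$emg_burst_rms == 0)
    return(list(m = numeric(n), bursts = numeric(0)))
  carrier <- band_noise(n, spec$emg_band, spec$fs)
  env <- rep(spec$emg_tonic_rms, n)
  bursts <- numeric(0)
  if (spec$emg_burst_rms > 0 && spec$burst_period_s > 0) {
    nb <- floor(spec$duration_s / spec$burst_period_s)
    centers <- (seq_len(nb) - 0.5) * spec$burst_period_s
    t <- (seq_len(n) - 1L) / spec$fs
    for (ct in centers) {
      sel <- abs(t - ct) <= spec$burst_duration_s / 2
      shape <- 0.5 * (1 + cos(2 * pi * (t[sel] - ct) / spec$burst_duration_s))
      env[sel] <- spec$emg_tonic_rms +
        (spec$emg_burst_rms - spec$emg_tonic_rms) * shape
    }
    bursts <- centers - spec$burst_duration_s / 2
  }
  list(m = env * carrier, bursts = bursts)
}

#' Generate the evoked-response component
#'
#' Oddball stimuli at gaps uniform on `oddball_gap_s`; each adds a
#' raised-cosine bump of amplitude `p300_amp`, centred `p300_center_s`
#' after the stimulus with full width `p300_width_s`.
#'
#' @param spec a [synthetic_spec].
#' @return List with `c` (stream, V) and `events` (stimulus times, s).
#' @export
gen_evoked <- function(spec) {
  n <- as.integer(round(spec$fs * spec$duration_s))
  cstream <- numeric(n)
  events <- numeric(0)
  tcur <- stats::runif(1, spec$oddball_gap_s[1], spec$oddball_gap_s[2])
  while (tcur + spec$p300_center_s + spec$p300_width_s / 2 < spec$duration_s) {
    events <- c(events, tcur)
    tcur <- tcur + stats::runif(1, spec$oddball_gap_s[1], spec$oddball_gap_s[2])
  }
  if (spec$p300_amp > 0 && length(events)) {
    t <- (seq_len(n) - 1L) / spec$fs
    for (ev in events) {
      ctr <- ev + spec$p300_center_s
      sel <- abs(t - ctr) <= spec$p300_width_s / 2
      cstream[sel] <- cstream[sel] + spec$p300_amp * 0.5 *
        (1 + cos(2 * pi * (t[sel] - ctr) / spec$p300_width_s))
    }
  }
  list(c = cstream, events = events)
}

#' Synthesize a two-channel compound-electrode recording
#'
#' Draws all components under the spec's seed and assembles the signal
#' model exactly: inner channel `d = b + m + c`; outer ring channel
#' `x = h * (r + alpha * c)` with `r` the total noise `b + m` and `h` a
#' causal first-order
#' low-pass.  The same spec (including seed) reproduces the recording
#' bitwise.
#'
#' @param spec a [synthetic_spec].
#' @return List with `recording` (a [recording] carrying the oddball event
#'   times) and `truth` (class `ground_truth`: streams `b`, `m`, `c`, `r`,
#'   `events`, `bursts`).
#' @examples
#' out <- synthesize_recording(session1_spec(seed = 7, duration_s = 5))
#' out$recording
#' stopifnot(identical(out$recording$inner,
#'                     out$truth$b + out$truth$m + out$truth$c))
#' @export
synthesize_recording <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  b <- gen_background_eeg(spec)
  emg <- gen_emg(spec)
  evo <- gen_evoked(spec)
  r <- b + emg$m
  inner <- r + evo$c
  ref_in <- r + spec$alpha * evo$c
  outer <- if (is.infinite(spec$h_cutoff_hz)) ref_in  # h = identity
  else apply_filter(
    iir_filter_from(signal::butter(1, spec$h_cutoff_hz / (spec$fs / 2),
                                   "low")), ref_in)
  rec <- recording(inner, outer, fs = spec$fs,
                   events = if (spec$p300_amp > 0) evo$events else numeric(0),
                   label = sprintf("synthetic fs=%g dur=%gs seed=%d",
                                   spec$fs, spec$duration_s, spec$seed))
  truth <- structure(list(b = b, m = emg$m, c = evo$c, r = r,
                          events = evo$events, bursts = emg$bursts),
                     class = "ground_truth")
  list(recording = rec, truth = truth)
}
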