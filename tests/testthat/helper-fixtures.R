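# small in-code fixtures shared across test files

# a short deterministic two-channel recording with physiological scale
tiny_recording <- function(n = 1000, fs = 250, seed = 1) {
  set.seed(seed)
  recording(inner = rnorm(n) * 10e-6, outer = rnorm(n) * 10e-6, fs = fs,
            label = "tiny")
}

# short synthetic sessions (seconds, not minutes) for pipeline tests
short_session1 <- function(seed = 1, duration_s = 10)
  synthesize_recording(session1_spec(seed = seed, duration_s = duration_s))

short_session2 <- function(seed = 2, duration_s = 60)
  synthesize_recording(session2_spec(seed = seed, duration_s = duration_s))

# steady-state amplitude of a filtered sine (last cycles only)
steady_amplitude <- function(coefs, f, fs, cycles = 50, settle_s = 5) {
  t <- seq(0, settle_s + cycles / f, by = 1 / fs)
  y <- apply_filter(coefs, sin(2 * pi * f * t))
  max(abs(tail(y, round(fs * cycles / f / 2))))
}
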