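#' Causal IIR filter with internal state
#'
#' Wraps rational transfer-function coefficients together with a delay-memory
#' state so a stream can be filtered one sample at a time.  The state is a
#' direct-form-II-transposed register; processing a stream sample-by-sample
#' is identical to block processing.
#'
#' @param b numerator coefficients.
#' @param a denominator coefficients; `a[1]` must be 1 (it is normalised if
#'   not).
#' @return An object of class `iir_filter` (an environment holding `b`, `a`
#'   and the state vector `z`).
#' @export
iir_filter <- function(b, a = 1) {
  b <- as.numeric(b); a <- as.numeric(a)
  if (length(a) < 1 || a[1] == 0) stop("denominator leading coefficient must be nonzero")
  b <- b / a[1]; a <- a / a[1]
  n <- max(length(a), length(b))
  # poles strictly inside the unit circle
  if (length(a) > 1) {
    r <- Mod(polyroot(rev(a)))
    if (any(r >= 1 + 1e-10)) stop("unstable filter: pole on or outside the unit circle")
  }
  f <- new.env(parent = emptyenv())
  f$b <- c(b, rep(0, n - length(b)))
  f$a <- c(a, rep(0, n - length(a)))
  f$z <- rep(0, n - 1)
  class(f) <- "iir_filter"
  f
}

#' @export
print.iir_filter <- function(x, ...) {
  cat("Causal IIR filter: order", length(x$z), "\n")
  invisible(x)
}

#' Reset a filter's internal state to zero
#' @param coefs an [iir_filter].
#' @export
reset_filter <- function(coefs) {
  coefs$z[] <- 0
  invisible(coefs)
}

#' Advance a causal filter by one sample
#'
#' Direct-form-II-transposed update: returns one output sample and advances
#' the internal state, so that streaming a vector through `filter_sample`
#' equals one call to [apply_filter()].
#'
#' @param coefs an [iir_filter] (state is updated in place).
#' @param sample one input sample.
#' @return The output sample.
#' @export
filter_sample <- function(coefs, sample) {
  if (!is.finite(sample)) stop("non-finite input sample")
  b <- coefs$b; a <- coefs$a; z <- coefs$z
  nz <- length(z)
  y <- b[1] * sample + (if (nz) z[1] else 0)
  if (nz > 0) {
    for (k in seq_len(nz - 1))
      z[k] <- b[k + 1] * sample + z[k + 1] - a[k + 1] * y
    z[nz] <- b[nz + 1] * sample - a[nz + 1] * y
    coefs$z <- z
  }
  y
}

#' Filter a whole stream (block form)
#'
#' Applies the filter to a vector starting from the filter's current state,
#' advancing the state past the end of the block.  Equivalent to repeated
#' [filter_sample()] calls.
#'
#' @param coefs an [iir_filter].
#' @param x numeric vector.
#' @return Filtered vector of the same length.
#' @export
apply_filter <- function(coefs, x) {
  stopifnot(all(is.finite(x)))
  if (any(coefs$z != 0)) {
    # resume from a mid-stream state: plain per-sample loop
    return(vapply(x, function(s) filter_sample(coefs, s), numeric(1)))
  }
  out <- as.numeric(signal::filter(coefs$b, coefs$a, c(x)))
  coefs$z <- final_state(coefs$b, coefs$a, x, out)
  out
}

# state register after a block, given input x and zero-state output y
final_state <- function(b, a, x, y) {
  nz <- length(b) - 1
  z <- rep(0, nz)
  if (nz == 0) return(z)
  n <- length(x)
  for (k in seq_len(nz)) {
    # z_k[n] = sum_{j>k} b_j x[n-(j-k)] - a_j y[n-(j-k)]  (DF2T unrolled)
    acc <- 0
    for (j in (k + 1):(nz + 1)) {
      idx <- n - (j - k) + 1
      if (idx >= 1) acc <- acc + b[j] * x[idx] - a[j] * y[idx]
    }
    z[k] <- acc
  }
  z
}

#' Design a Butterworth high-pass filter
#'
#' @param order filter order (2 for the conditioning chain).
#' @param fc cutoff frequency in Hz; the magnitude response at `fc` is
#'   1/sqrt(2) of the passband gain.
#' @param fs sampling rate in Hz.
#' @return An [iir_filter].
#' @export
design_highpass <- function(order, fc, fs) {
  if (!(fc > 0 && fc < fs / 2)) stop("parameter error: need 0 < fc < fs/2")
  if (order < 1) stop("parameter error: order >= 1")
  ba <- signal::butter(order, fc / (fs / 2), type = "high")
  iir_filter(ba$b, ba$a)
}

#' Design a 50 Hz Butterworth notch (band-stop) filter
#'
#' Second-order Butterworth band-stop centred on the 50 Hz mains frequency.
#'
#' @param fs sampling rate in Hz.
#' @param half_width half-width of the stopband in Hz (stopband is
#'   `50 - half_width` to `50 + half_width`).
#' @return An [iir_filter].
#' @export
design_notch50 <- function(fs, half_width = 2.5) {
  if (!(50 + half_width < fs / 2) || half_width <= 0)
    stop("parameter error: notch band must lie below Nyquist")
  ba <- signal::butter(2, c(50 - half_width, 50 + half_width) / (fs / 2),
                       type = "stop")
  iir_filter(ba$b, ba$a)
}

#' Magnitude response of a designed filter
#' @param coefs an [iir_filter].
#' @param f frequencies (Hz) at which to evaluate.
#' @param fs sampling rate in Hz.
#' @return Magnitude of the transfer function on the unit circle at `f`.
#' @export
filter_gain <- function(coefs, f, fs) {
  w <- exp(-2i * pi * f / fs)
  num <- vapply(w, function(z) sum(coefs$b * z^(seq_along(coefs$b) - 1)),
                complex(1))
  den <- vapply(w, function(z) sum(coefs$a * z^(seq_along(coefs$a) - 1)),
                complex(1))
  Mod(num / den)
}

#' Condition a raw channel: 50 Hz notch, high-pass, gain
#'
#' The standard conditioning applied to both electrode channels before
#' filtering: a 2nd-order Butterworth 50 Hz notch, a 2nd-order Butterworth
#' high-pass at `fc`, then multiplication by `gain` so that physiological
#' microvolt signals land around plus/minus 0.2 at the network input.  All
#' filters start from zero state and run causally.
#'
#' @param raw numeric sample stream (V).
#' @param fc high-pass cutoff (Hz).
#' @param fs sampling rate (Hz).
#' @param gain dimensionless output scale.
#' @param notch_halfwidth notch half-width (Hz).
#' @return Conditioned stream, same length.
#' @export
condition_channel <- function(raw, fc, fs, gain = 1000,
                              notch_halfwidth = 2.5) {
  if (!length(raw)) stop("empty stream")
  bs <- design_notch50(fs, notch_halfwidth)
  hp <- design_highpass(2, fc, fs)
  gain * apply_filter(hp, apply_filter(bs, raw))
}

#' Delay a stream by an integer number of samples
#'
#' `out[k] = in[k - n]` for `k > n`, zero before; length preserved.  Used to
#' delay the inner channel by `floor(ntaps/2)` so the network's delay line
#' sees artefacts before they must be cancelled.
#'
#' @param stream numeric vector.
#' @param n non-negative integer delay in samples.
#' @return Delayed vector of the same length.
#' @export
delay_stream <- function(stream, n) {
  if (n < 0) stop("parameter error: delay must be >= 0")
  n <- as.integer(n)
  if (n == 0L) return(stream)
  len <- length(stream)
  c(rep(0, min(n, len)), stream[seq_len(max(0L, len - n))])
}

#' Tapped delay line
#'
#' A fixed-length buffer of the most recent samples, newest first, feeding
#' the network's first layer.  Initialised to zeros.
#'
#' @param ntaps buffer length.
#' @return An object of class `delay_line` (an environment with field `buf`).
#' @export
delay_line <- function(ntaps) {
  stopifnot(ntaps >= 1)
  dl <- new.env(parent = emptyenv())
  dl$buf <- rep(0, as.integer(ntaps))
  class(dl) <- "delay_line"
  dl
}

#' Push a sample into a delay line and return the tap vector
#'
#' @param line a [delay_line] (updated in place).
#' @param sample new sample.
#' @return The tap vector `(x[n], x[n-1], ..., x[n-ntaps+1])`.
#' @export
push_tap <- function(line, sample) {
  line$buf <- c(sample, line$buf[-length(line$buf)])
  line$buf
}
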