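#' LMS-adaptive FIR state
#'
#' Holds the FIR coefficient vector, the learning rate and the delay line of
#' the least-mean-squares baseline filter.  Weights initialise to zero.
#'
#' @param ntaps FIR length; matches the deep filter's delay line for a fair
#'   comparison.
#' @param mu LMS learning rate.
#' @param weights optional initial coefficient vector.
#' @return An object of class `lms_state` (an environment).
#' @export
lms_state <- function(ntaps, mu, weights = rep(0, ntaps)) {
  stopifnot(ntaps >= 1, mu >= 0, length(weights) == ntaps,
            all(is.finite(weights)))
  st <- new.env(parent = emptyenv())
  st$weights <- as.numeric(weights)
  st$mu <- mu
  st$line <- delay_line(ntaps)
  class(st) <- "lms_state"
  st
}

#' One LMS step
#'
#' `y = sum_k w_k x[n-k]`, `e = d - y`, then `w_k <- w_k + mu * x[n-k] * e`.
#'
#' @param state an [lms_state] (updated in place).
#' @param d_delayed delayed conditioned inner sample.
#' @param x conditioned reference sample.
#' @return The error/output sample `e`.
#' @export
lms_step <- function(state, d_delayed, x) {
  if (!is.finite(d_delayed) || !is.finite(x)) stop("non-finite input sample")
  taps <- push_tap(state$line, x)
  y <- sum(state$weights * taps)
  e <- d_delayed - y
  state$weights <- state$weights + state$mu * taps * e
  e
}

#' Fit the LMS-adaptive FIR baseline to a recording
#'
#' Identical conditioning and inner-channel delay as [dnf()], with a linear
#' FIR filter adapted by the least-mean-squares rule in place of the deep
#' network.  Weights start at zero.
#'
#' @param rec a [recording].
#' @param config a [run_config]; `config$mu` is the LMS rate (defaults to
#'   the session's `eta`).
#' @param ... overrides for `config` fields.
#' @return An object of class `c("lms_fit", "anc_fit")`; components as in
#'   [dnf()] minus the network (with `weights` the final FIR coefficients).
#' @export
lms_filter <- function(rec, config = run_config(variant = "lms"), ...) {
  stopifnot(inherits(rec, "recording"))
  config <- modify_config(config, ...)
  cp <- condition_pair(rec, config)
  core <- lms_core(cp$d, cp$x, rep(0, config$ntaps), config$mu)
  structure(
    list(e = as.numeric(core$e), y = as.numeric(core$y),
         d = cp$d, x = cp$x, weights = as.numeric(core$weights),
         fs = rec$fs, events = rec$events,
         delay = config$ntaps %/% 2L, config = config,
         variant = "lms", label = rec$label),
    class = c("lms_fit", "anc_fit"))
}

#' @rdname run_dnf
#' @export
run_lms <- function(rec, config = run_config(variant = "lms")) {
  stopifnot(config$variant == "lms")
  lms_filter(rec, config)
}

#' Surface-Laplacian baseline: direct ring subtraction
#'
#' The non-adaptive comparison filter: the raw outer-ring signal is
#' subtracted from the raw inner signal, and DC and 50 Hz interference are
#' removed *after* the subtraction (0.5 Hz high-pass and 50 Hz notch), then
#' the gain is applied so the output is on the same conditioned scale as
#' the adaptive variants.
#'
#' @param rec a [recording].
#' @param config a [run_config].
#' @param ... overrides for `config` fields.
#' @return An object of class `c("laplace_fit", "anc_fit")`; `y` is the raw
#'   outer channel scaled for reference, `e` the filtered difference.  No
#'   delay is applied (`delay = 0`).
#' @export
laplace_filter <- function(rec, config = run_config(variant = "laplace"), ...) {
  stopifnot(inherits(rec, "recording"))
  config <- modify_config(config, ...)
  s <- rec$inner - rec$outer
  hp <- design_highpass(2, 0.5, rec$fs)
  bs <- design_notch50(rec$fs, config$notch_halfwidth)
  e <- config$gain * apply_filter(hp, apply_filter(bs, s))
  structure(
    list(e = e, y = config$gain * rec$outer,
         d = config$gain * rec$inner, x = config$gain * rec$outer,
         fs = rec$fs, events = rec$events, delay = 0L, config = config,
         variant = "laplace", label = rec$label),
    class = c("laplace_fit", "anc_fit"))
}

#' @rdname run_dnf
#' @export
run_laplace <- function(rec, config = run_config(variant = "laplace")) {
  stopifnot(config$variant == "laplace")
  laplace_filter(rec, config)
}

#' Pass-through variant: conditioned inner channel, no filtering
#'
#' The "unfiltered" reference against which the adaptive variants are
#' compared: the inner channel after standard conditioning only.
#'
#' @param rec a [recording].
#' @param config a [run_config].
#' @param ... overrides for `config` fields.
#' @return An object of class `c("none_fit", "anc_fit")` with `e` the
#'   conditioned inner stream and zero remover.
#' @export
passthrough_filter <- function(rec, config = run_config(variant = "none"), ...) {
  stopifnot(inherits(rec, "recording"))
  config <- modify_config(config, ...)
  d <- condition_channel(rec$inner, config$fcd, rec$fs, config$gain,
                         config$notch_halfwidth)
  structure(
    list(e = d, y = rep(0, length(d)), d = d,
         x = condition_channel(rec$outer, config$fcx, rec$fs, config$gain,
                               config$notch_halfwidth),
         fs = rec$fs, events = rec$events, delay = 0L, config = config,
         variant = "none", label = rec$label),
    class = c("none_fit", "anc_fit"))
}

#' Dispatch a filter variant by name
#' @param rec a [recording].
#' @param config a [run_config]; `config$variant` picks the filter.
#' @param ... overrides for `config` fields.
#' @return An `anc_fit`.
#' @export
run_variant <- function(rec, config = run_config(), ...) {
  config <- modify_config(config, ...)
  switch(config$variant,
         dnf = dnf(rec, config),
         lms = lms_filter(rec, config),
         laplace = laplace_filter(rec, config),
         none = passthrough_filter(rec, config))
}
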