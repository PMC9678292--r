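#' Funnel layer sizing
#'
#' Computes the per-layer neuron counts of the funnel architecture: widths
#' shrink geometrically from the tap count down to a single output neuron,
#' `I(l) = floor(ntaps / b^(l-1))` with `b = exp(log(ntaps)/(L-1))`, so that
#' `I(1) = ntaps` and `I(L) = 1`.
#'
#' @param ntaps delay-line length (first-layer width).
#' @param nlayers number of layers `L`.
#' @return Integer vector of length `nlayers`, non-increasing, ending in 1.
#' @examples
#' compute_layer_sizes(50, 6)  # 50 22 10 4 2 1
#' @export
compute_layer_sizes <- function(ntaps, nlayers) {
  if (ntaps < 1 || nlayers < 1) stop("parameter error: ntaps and nlayers must be >= 1")
  ntaps <- as.integer(ntaps); nlayers <- as.integer(nlayers)
  if (nlayers == 1L) return(1L)  # degenerate funnel: one neuron over the taps
  b <- exp(log(ntaps) / (nlayers - 1))
  # small epsilon guards floor against 49.999... when ntaps/b^(l-1) is an
  # exact integer up to floating point
  sizes <- as.integer(floor(ntaps / b^(seq_len(nlayers) - 1) + 1e-9))
  sizes[nlayers] <- 1L
  sizes
}

#' Tap count suggested by the reference high-pass cutoff
#'
#' The delay line should span roughly one period of the lowest frequency
#' admitted into the noise reference, `ntaps = fs / fcx`.  Provided as a
#' helper; the default operating tap count is 50.
#'
#' @param fs sampling rate (Hz).
#' @param fcx reference-channel high-pass cutoff (Hz).
#' @return Suggested tap count (integer).
#' @export
suggest_ntaps <- function(fs, fcx) as.integer(round(fs / fcx))

#' Initialise a deep-neural-filter network
#'
#' Builds a bias-free, fully connected tanh network with the given layer
#' widths.  Every weight is drawn independently and uniformly from
#' `(0, init_scale]`; a frozen copy of the initial weights is stored so the
#' per-layer weight distance can be traced during learning.  There are no
#' bias terms anywhere, which keeps the processing DC-free.
#'
#' @param sizes per-layer neuron counts (see [compute_layer_sizes()]).
#' @param seed integer RNG seed; the same seed reproduces the network
#'   exactly.
#' @param init_scale upper bound of the uniform initialisation; 1 reproduces
#'   the published `(0, 1]` initialisation, `1/ntaps` gives a fan-in-scaled
#'   alternative that avoids early tanh saturation.
#' @param ntaps input (delay-line) length; defaults to `sizes[1]`.
#' @return An object of class `dnf_network` (an environment): fields
#'   `sizes`, `weights` (list of matrices, layer l maps layer l-1
#'   activations — or the tap vector for l = 1 — to pre-activations),
#'   `initial_weights`, `eta`, and per-sample caches `a`, `z`, `taps`.
#' @export
init_network <- function(sizes, seed = 1L, init_scale = 1,
                         ntaps = sizes[1], eta = 2.5) {
  sizes <- as.integer(sizes)
  stopifnot(length(sizes) >= 1, all(sizes >= 1), sizes[length(sizes)] == 1L,
            init_scale > 0)
  set.seed(as.integer(seed))
  nl <- length(sizes)
  fan_in <- c(as.integer(ntaps), sizes[-nl])
  weights <- vector("list", nl)
  for (l in seq_len(nl)) {
    n <- sizes[l] * fan_in[l]
    # uniform on (0, init_scale]: 1 - runif() in [0,1) maps to (0,1]
    weights[[l]] <- matrix((1 - stats::runif(n)) * init_scale,
                           nrow = sizes[l], ncol = fan_in[l])
  }
  net <- new.env(parent = emptyenv())
  net$sizes <- sizes
  net$ntaps <- as.integer(ntaps)
  net$weights <- weights
  net$initial_weights <- weights
  net$eta <- eta
  net$a <- NULL; net$z <- NULL; net$taps <- NULL
  class(net) <- "dnf_network"
  net
}

#' @export
print.dnf_network <- function(x, ...) {
  cat("Deep neural filter network:", paste(x$sizes, collapse = "-"),
      "neurons,", x$ntaps, "taps, eta =", x$eta, "\n")
  invisible(x)
}

#' Forward pass: synthesize the remover from the tap vector
#'
#' Propagates the tap vector through the bias-free tanh layers:
#' `a^l = tanh(W^l a^(l-1))` with `a^0` the tap vector, ending in the scalar
#' remover `y = tanh(z^L)`.  Activations and pre-activations are cached for
#' the backward step.  Because tanh is bounded, `|y| < 1` always.
#'
#' @param net a [dnf_network] (caches updated in place).
#' @param taps tap vector of length `ntaps`.
#' @return The remover sample `y`.
#' @export
forward_pass <- function(net, taps) {
  if (length(taps) != net$ntaps) stop("tap vector length must equal ntaps")
  if (!all(is.finite(taps))) stop("non-finite tap value")
  nl <- length(net$sizes)
  a <- vector("list", nl); z <- vector("list", nl)
  prev <- taps
  for (l in seq_len(nl)) {
    z[[l]] <- as.numeric(net$weights[[l]] %*% prev)
    a[[l]] <- tanh(z[[l]])
    prev <- a[[l]]
  }
  net$a <- a; net$z <- z; net$taps <- taps
  a[[nl]][1]
}

#' Backward pass: online weight update from one error sample
#'
#' One step of per-sample backpropagation.  The output-layer delta is the
#' error sample itself (the published update omits the output tanh
#' derivative; set `output_derivative = TRUE` for the conventional rule);
#' hidden deltas backpropagate through `tanh'(z) = 1 - tanh(z)^2`; every
#' weight is incremented by `eta * a * delta` with no clipping.
#'
#' @param net a [dnf_network] with cached activations from [forward_pass()].
#' @param e error sample `e[n] = d[n] - y[n]`.
#' @param eta learning rate; defaults to the network's.
#' @param output_derivative include `tanh'(z^L)` in the output delta.
#' @return The network, invisibly.
#' @export
backward_update <- function(net, e, eta = net$eta,
                            output_derivative = FALSE) {
  if (is.null(net$a)) stop("state error: no cached activations; run forward_pass first")
  nl <- length(net$sizes)
  delta <- vector("list", nl)
  delta[[nl]] <- if (output_derivative) e * (1 - tanh(net$z[[nl]])^2) else e
  if (nl > 1) {
    for (l in (nl - 1):1) {
      back <- as.numeric(crossprod(net$weights[[l + 1]], delta[[l + 1]]))
      delta[[l]] <- back * (1 - net$a[[l]]^2)
    }
  }
  inputs <- c(list(net$taps), net$a[-nl])
  for (l in seq_len(nl))
    net$weights[[l]] <- net$weights[[l]] +
      eta * delta[[l]] %*% t(inputs[[l]])
  net$a <- NULL; net$z <- NULL; net$taps <- NULL
  invisible(net)
}

#' Per-layer Euclidean distance of the weights from their initial values
#' @param net a [dnf_network].
#' @return Numeric vector, one distance per layer (0 for a fresh network).
#' @export
weight_distance <- function(net) {
  vapply(seq_along(net$weights), function(l)
    sqrt(sum((net$weights[[l]] - net$initial_weights[[l]])^2)), numeric(1))
}

#' One deep-neural-filter step
#'
#' Pushes the conditioned reference sample into the delay line, runs the
#' forward pass, subtracts the remover from the delayed conditioned inner
#' sample, and applies the weight update with that error.  Learning is on
#' unconditionally: one update per sample.
#'
#' @param net a [dnf_network].
#' @param d_delayed delayed conditioned inner-channel sample.
#' @param x conditioned outer-channel (noise reference) sample.
#' @param line a [delay_line] of length `ntaps`.
#' @param eta learning rate; defaults to the network's.
#' @param output_derivative see [backward_update()].
#' @return The output/error sample `e = d_delayed - y`.
#' @export
dnf_step <- function(net, d_delayed, x, line, eta = net$eta,
                     output_derivative = FALSE) {
  taps <- push_tap(line, x)
  y <- forward_pass(net, taps)
  e <- d_delayed - y
  backward_update(net, e, eta, output_derivative)
  e
}

# shared conditioning + delay front end for dnf/lms
condition_pair <- function(rec, config) {
  d <- condition_channel(rec$inner, config$fcd, rec$fs, config$gain,
                         config$notch_halfwidth)
  x <- condition_channel(rec$outer, config$fcx, rec$fs, config$gain,
                         config$notch_halfwidth)
  list(d = delay_stream(d, config$ntaps %/% 2L), x = x)
}

#' Normalize a reference stream to a target running RMS
#'
#' Causal automatic gain control: tracks the running RMS of the stream with
#' a first-order estimator (`r2[n] = (1-beta) r2[n-1] + beta x[n]^2`,
#' `beta = 1/(tau_s * fs)`) and rescales each sample to `target_rms`.  Used
#' to put the conditioned noise reference into the tanh network's intended
#' input regime independently of source amplitude, which also makes the
#' effective learning rate amplitude-invariant.
#'
#' @param x numeric stream.
#' @param fs sampling rate (Hz).
#' @param target_rms output running RMS (0.1 puts excursions near 0.2).
#' @param tau_s estimator time constant (s).
#' @param floor_rms lower bound on the RMS estimate, guarding startup and
#'   silent stretches.
#' @return The rescaled stream.
#' @export
normalize_reference <- function(x, fs, target_rms = 0.1, tau_s = 2,
                                floor_rms = 1e-6) {
  beta <- 1 / (tau_s * fs)
  r2 <- as.numeric(signal::filter(beta, c(1, -(1 - beta)), x^2,
                                  init.y = target_rms^2))
  target_rms * x / pmax(sqrt(r2), floor_rms)
}

#' Fit a deep neural filter to a two-channel recording
#'
#' The main fitting function.  Conditions both channels (50 Hz notch,
#' Butterworth high-pass, gain), delays the inner channel by
#' `floor(ntaps/2)` samples, then runs the sample-by-sample deep neural
#' filter over the whole recording: at every sample the network synthesizes
#' a remover `y[n]` from the tapped delay line over the noise reference and
#' the output is `e[n] = d[n] - y[n]`, which is simultaneously the error
#' that drives one backpropagation update.  There is no separate training
#' phase; learning is on for the entire record.
#'
#' @param rec a [recording].
#' @param config a [run_config]; individual fields can be overridden via
#'   `...`.
#' @param ... overrides for `config` fields (e.g. `eta = 10`).
#' @return An object of class `c("dnf_fit", "anc_fit")` with components
#'   `e` (denoised output stream), `y` (remover stream), `d` (delayed
#'   conditioned inner), `x` (conditioned reference), `weight_distance`
#'   (matrix, one row per logged sample, one column per layer), `network`
#'   (final [dnf_network]), `fs`, `events`, `delay` (samples), `config`.
#' @examples
#' rec <- synthesize_recording(session1_spec(seed = 1, duration_s = 10))$recording
#' fit <- dnf(rec, seed = 1)
#' fit
#' @export
dnf <- function(rec, config = run_config(), ...) {
  stopifnot(inherits(rec, "recording"))
  config <- modify_config(config, ...)
  sizes <- compute_layer_sizes(config$ntaps, config$nlayers)
  net <- init_network(sizes, seed = config$seed,
                      init_scale = config$init_scale,
                      ntaps = config$ntaps, eta = config$eta)
  cp <- condition_pair(rec, config)
  if (config$normalize_x)
    cp$x <- normalize_reference(cp$x, rec$fs)
  core <- dnf_core(cp$d, cp$x, net$weights, config$eta,
                   config$output_derivative, config$log_every)
  net$weights <- core$weights
  wd <- core$weight_distance
  colnames(wd) <- paste0("layer", seq_along(sizes))
  structure(
    list(e = as.numeric(core$e), y = as.numeric(core$y),
         d = cp$d, x = cp$x, weight_distance = wd, network = net,
         fs = rec$fs, events = rec$events,
         delay = config$ntaps %/% 2L, config = config,
         variant = "dnf", label = rec$label),
    class = c("dnf_fit", "anc_fit"))
}

modify_config <- function(config, ...) {
  dots <- list(...)
  if (!length(dots)) return(config)
  fields <- unclass(config)
  bad <- setdiff(names(dots), names(fields))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  fields[names(dots)] <- dots
  # mu follows eta unless explicitly set
  if ("eta" %in% names(dots) && !"mu" %in% names(dots))
    fields$mu <- dots$eta
  do.call(run_config, fields)
}

#' Convergence diagnostic: reference/output correlation over time
#'
#' Learning converges when the correlation between the noise reference and
#' the error signal weakens — the per-tap update is proportional to
#' `x[n-k] * e[n]`, so the magnitude of those cross-correlations is what
#' learning drives toward zero.  This computes the maximum absolute Pearson
#' cross-correlation between `e[n]` and `x[n-k]` over the tap lags
#' `k = 0..ntaps-1`, separately for the first and last `window_s` seconds.
#'
#' @param fit an `anc_fit` (deep-neural-filter or LMS).
#' @param window_s window length at each end of the record (s).
#' @return List with `first`, `last` (max absolute cross-correlation in
#'   each window) and `converged` (`last < first`).
#' @export
convergence_diagnostic <- function(fit, window_s = 20) {
  n <- length(fit$e)
  nw <- as.integer(window_s * fit$fs)
  stopifnot(nw >= 2L, 2L * nw <= n)
  ntaps <- fit$config$ntaps
  maxcc <- function(e, x) {
    max(vapply(0:(ntaps - 1L), function(k) {
      m <- length(e) - k
      abs(stats::cor(e[(k + 1):(k + m)], x[1:m]))
    }, numeric(1)))
  }
  first <- maxcc(fit$e[1:nw], fit$x[1:nw])
  last <- maxcc(fit$e[(n - nw + 1):n], fit$x[(n - nw + 1):n])
  list(first = first, last = last, converged = last < first)
}

#' Spec-style runner: filter a recording under a configuration
#'
#' Thin wrappers dispatching on `config$variant`; `run_dnf`, [run_lms()]
#' and [run_laplace()] are the function-style equivalents of [dnf()],
#' [lms_filter()] and [laplace_filter()].
#'
#' @param rec a [recording].
#' @param config a [run_config] with `variant = "dnf"`.
#' @return A `dnf_fit` (see [dnf()]).
#' @export
run_dnf <- function(rec, config = run_config(variant = "dnf")) {
  stopifnot(config$variant == "dnf")
  dnf(rec, config)
}

#' @export
print.anc_fit <- function(x, ...) {
  cat(sprintf("%s noise-cancellation fit%s\n",
              toupper(x$variant),
              if (nzchar(x$label)) paste0(" on '", x$label, "'") else ""))
  cat(sprintf("  %d samples at %g Hz; inner-channel delay %d samples\n",
              length(x$e), x$fs, x$delay))
  cat(sprintf("  output RMS %.4g (conditioned units), remover RMS %.4g\n",
              sqrt(mean(x$e^2)), sqrt(mean(x$y^2))))
  invisible(x)
}

#' @export
residuals.anc_fit <- function(object, ...) object$e

#' @export
fitted.anc_fit <- function(object, ...) object$y

#' @export
coef.dnf_fit <- function(object, ...) object$network$weights

#' @export
coef.lms_fit <- function(object, ...) object$weights

#' Plot a noise-cancellation fit
#'
#' Draws the delayed conditioned inner channel, the noise reference, the
#' remover and the filter output against time, plus (for the deep neural
#' filter) the per-layer weight-distance trace.
#'
#' @param x an `anc_fit`.
#' @param which `"signals"`, `"weights"` or both.
#' @param ... unused.
#' @export
plot.anc_fit <- function(x, which = c("signals", "weights"), ...) {
  which <- match.arg(which, several.ok = TRUE)
  t <- seq_along(x$e) / x$fs
  has_w <- "weights" %in% which && !is.null(x$weight_distance)
  if ("signals" %in% which) {
    op <- graphics::par(mfrow = c(4, 1), mar = c(2, 4, 1, 1))
    on.exit(graphics::par(op))
    for (nm in c("d", "x", "y", "e")) {
      graphics::plot(t, x[[nm]], type = "l",
                     xlab = "", ylab = nm)
    }
  }
  if (has_w) {
    wd <- x$weight_distance
    tw <- seq_len(nrow(wd)) * x$config$log_every / x$fs
    graphics::matplot(tw, wd, type = "l", lty = 1,
                      xlab = "time (s)", ylab = "weight distance")
    graphics::legend("topleft", colnames(wd), col = seq_len(ncol(wd)),
                     lty = 1, cex = 0.7, bty = "n")
  }
  invisible(x)
}
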