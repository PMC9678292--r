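test_that("funnel layer sizing shrinks geometrically to one neuron", {
  expect_identical(compute_layer_sizes(50, 6), c(50L, 22L, 10L, 4L, 2L, 1L))
  expect_identical(compute_layer_sizes(1, 6), rep(1L, 6))
  expect_identical(compute_layer_sizes(16, 5), c(16L, 8L, 4L, 2L, 1L))
  # non-increasing, endpoints pinned, for a sweep of shapes
  for (ntaps in c(2, 7, 31, 100))
    for (L in c(2, 4, 9)) {
      s <- compute_layer_sizes(ntaps, L)
      expect_length(s, L)
      expect_equal(s[1], ntaps)
      expect_equal(s[L], 1L)
      expect_true(all(diff(s) <= 0))
    }
  expect_error(compute_layer_sizes(0, 6), "parameter error")
  expect_error(compute_layer_sizes(50, 0), "parameter error")
  expect_identical(suggest_ntaps(500, 5), 100L)
})

test_that("network initialisation is seeded, positive and snapshotted", {
  sizes <- compute_layer_sizes(10, 4)
  n1 <- init_network(sizes, seed = 42)
  n2 <- init_network(sizes, seed = 42)
  expect_identical(n1$weights, n2$weights)
  w <- unlist(n1$weights)
  expect_true(all(w > 0 & w <= 1))  # default init_scale = 1: (0, 1]
  expect_equal(weight_distance(n1), rep(0, 4))
  n3 <- init_network(sizes, seed = 43)
  expect_false(identical(n1$weights, n3$weights))
})

test_that("forward pass is bias-free, odd, bounded and linearisable", {
  net <- init_network(compute_layer_sizes(8, 3), seed = 1, ntaps = 8)
  # all-zero taps: exactly zero everywhere (DC-freedom, no biases)
  expect_identical(forward_pass(net, numeric(8)), 0)
  expect_true(all(vapply(net$a, function(a) all(a == 0), logical(1))))

  set.seed(2)
  for (i in 1:10) {
    taps <- rnorm(8)
    yp <- forward_pass(net, taps)
    ym <- forward_pass(net, -taps)
    expect_equal(ym, -yp, tolerance = 1e-12)  # tanh is odd
    expect_lt(abs(yp), 1)
  }

  # small-signal regime: tanh network ~ product of weight matrices
  taps <- rnorm(8) * 1e-6
  y <- forward_pass(net, taps)
  lin <- as.numeric(Reduce(`%*%`, rev(net$weights)) %*% taps)
  expect_lt(abs(y - lin), 1e-6 * abs(lin))
  expect_error(forward_pass(net, rep(NA_real_, 8)), "finite")
  expect_error(forward_pass(net, numeric(3)), "length")
})

test_that("backward update follows the published learning rule", {
  net <- init_network(compute_layer_sizes(6, 3), seed = 5, ntaps = 6)
  w0 <- net$weights
  forward_pass(net, rnorm(6) * 0.1)
  backward_update(net, e = 0)            # zero error: no change
  expect_identical(net$weights, w0)
  forward_pass(net, rnorm(6) * 0.1)
  backward_update(net, e = 0.5, eta = 0)  # zero rate: no change
  expect_identical(net$weights, w0)
  expect_error(backward_update(net, 0.1), "state error")  # caches consumed

  # deltas match central-difference gradients of the output pre-activation
  set.seed(11)
  for (trial in 1:10) {
    net <- init_network(compute_layer_sizes(4, 3), seed = trial, ntaps = 4)
    for (l in seq_along(net$weights))
      net$weights[[l]] <- matrix(rnorm(length(net$weights[[l]])),
                                 nrow = nrow(net$weights[[l]]))
    taps <- rnorm(4) * 0.5
    W <- net$weights
    forward_pass(net, taps)
    backward_update(net, e = 1, eta = 1)
    zL <- function(W) {
      prev <- taps
      for (l in seq_along(W)) {
        z <- as.numeric(W[[l]] %*% prev)
        if (l < length(W)) prev <- tanh(z)
      }
      z
    }
    h <- 1e-6
    for (l in seq_along(W)) {
      grad <- W[[l]]
      for (i in seq_along(grad)) {
        Wp <- W; Wm <- W
        Wp[[l]][i] <- Wp[[l]][i] + h
        Wm[[l]][i] <- Wm[[l]][i] - h
        grad[i] <- (zL(Wp) - zL(Wm)) / (2 * h)
      }
      update <- net$weights[[l]] - W[[l]]
      expect_lt(max(abs(update - grad) / pmax(abs(grad), 1e-8)), 1e-5)
    }
  }
})

test_that("dnf_step cancels, learns unconditionally, and is deterministic", {
  cfg <- compute_layer_sizes(5, 3)
  net <- init_network(cfg, seed = 3, ntaps = 5)
  line <- delay_line(5)
  # zero reference so far: y = 0, e = d
  e <- dnf_step(net, d_delayed = 0.25, x = 0, line)
  expect_identical(e, 0.25)

  run_stream <- function(seed) {
    net <- init_network(cfg, seed = seed, ntaps = 5, eta = 0.5)
    line <- delay_line(5)
    set.seed(99)
    d <- rnorm(50) * 0.1; x <- rnorm(50) * 0.1
    vapply(seq_along(d), function(i) dnf_step(net, d[i], x[i], line),
           numeric(1))
  }
  expect_identical(run_stream(3), run_stream(3))
  expect_false(identical(run_stream(3), run_stream(4)))
})

test_that("R reference steps and the compiled core agree exactly", {
  ntaps <- 6; L <- 4
  sizes <- compute_layer_sizes(ntaps, L)
  set.seed(21)
  d <- rnorm(300) * 0.05
  x <- rnorm(300) * 0.05
  for (outd in c(FALSE, TRUE)) {
    net <- init_network(sizes, seed = 8, ntaps = ntaps, eta = 1.5)
    core <- dnf_core(d, x, net$weights, 1.5, outd, 1L)
    netR <- init_network(sizes, seed = 8, ntaps = ntaps, eta = 1.5)
    line <- delay_line(ntaps)
    eR <- vapply(seq_along(d), function(i)
      dnf_step(netR, d[i], x[i], line, output_derivative = outd), numeric(1))
    expect_equal(as.numeric(core$e), eR, tolerance = 1e-13)
    expect_equal(core$weights, netR$weights, tolerance = 1e-13)
    expect_equal(as.numeric(core$weight_distance[300, ]),
                 weight_distance(netR), tolerance = 1e-12)
  }
})

test_that("the full filter conserves length, bounds the remover, logs distance", {
  out <- short_session1(seed = 9, duration_s = 6)
  fit <- dnf(out$recording, seed = 2)
  n <- length(out$recording)
  expect_length(fit$e, n)
  expect_length(fit$y, n)
  expect_true(all(abs(fit$y) < 1))
  expect_true(all(is.finite(fit$weight_distance)))
  expect_equal(nrow(fit$weight_distance), n)
  expect_equal(fit$delay, 25L)
  # distance starts near 0 (first sample barely moves the weights)
  expect_lt(fit$weight_distance[1, 1], 1e-2)
  # same config and seed reproduce the run exactly
  fit2 <- dnf(out$recording, seed = 2)
  expect_identical(fit$e, fit2$e)
  # residuals/fitted accessors
  expect_identical(residuals(fit), fit$e)
  expect_identical(fitted(fit), fit$y)
  expect_identical(coef(fit), fit$network$weights)
})

test_that("a zero recording passes through as exact zeros (DC-freedom)", {
  rec <- recording(numeric(800), numeric(800), 250)
  fit <- dnf(rec, seed = 1)
  expect_identical(fit$y, numeric(800))
  expect_identical(fit$e, numeric(800))
})

test_that("degenerate one-layer filter in the linear regime follows the LMS rule", {
  ntaps <- 8
  set.seed(31)
  d <- rnorm(1000) * 1e-4
  x <- rnorm(1000) * 1e-4
  eta <- 0.5
  net <- init_network(compute_layer_sizes(ntaps, 1), seed = 12,
                      ntaps = ntaps, eta = eta)
  st <- lms_state(ntaps, mu = eta, weights = as.numeric(net$weights[[1]]))
  line <- delay_line(ntaps)
  e_dnf <- vapply(seq_along(d), function(i) dnf_step(net, d[i], x[i], line),
                  numeric(1))
  e_lms <- vapply(seq_along(d), function(i) lms_step(st, d[i], x[i]),
                  numeric(1))
  expect_lt(max(abs(e_dnf - e_lms)), 1e-3 * max(abs(e_lms)))
})
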