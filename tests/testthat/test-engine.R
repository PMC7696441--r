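# gradient and contract checks on the compiled network engine, via the
# internal entry points (compile_spec / init_params / .cnn_loss_grad)

numeric_grad <- function(f, params, eps = 1e-6) {
  g <- numeric(length(params))
  for (i in seq_along(params)) {
    up <- params; up[i] <- up[i] + eps
    dn <- params; dn[i] <- dn[i] - eps
    g[i] <- (f(up) - f(dn)) / (2 * eps)
  }
  g
}

loss_grad_setup <- function(batch_norm, seed = 1L) {
  spec <- tiny_spec(8L, 2L, dropout = 0, batch_norm = batch_norm)
  compiled <- spikecnn:::compile_spec(spec)
  set.seed(seed)
  # fully random parameters (non-zero biases) keep the check away from the
  # measure-zero ReLU kinks and max-pool ties, where one-sided derivatives
  # differ and central differences are meaningless
  params <- rnorm(compiled$n_params, 0, 0.4)
  x <- matrix(rnorm(5 * 8), 5, 8)
  y <- c(1L, 2L, 1L, 2L, 2L)
  rmu <- numeric(max(compiled$n_bn, 1))
  rv <- rep(1, max(compiled$n_bn, 1))
  list(spec = spec, compiled = compiled, params = params, x = x, y = y,
       rmu = rmu, rv = rv)
}

test_that("analytic gradients match numerical differentiation", {
  for (bn in c("none", "first", "all")) {
    s <- loss_grad_setup(bn)
    f <- function(p) spikecnn:::.cnn_loss_grad(s$x, s$y, s$compiled$meta,
                                               s$compiled$drop, p, s$rmu, s$rv,
                                               TRUE, 2L)$loss
    analytic <- spikecnn:::.cnn_loss_grad(s$x, s$y, s$compiled$meta,
                                          s$compiled$drop, s$params,
                                          s$rmu, s$rv, TRUE, 2L)$grad
    numeric <- numeric_grad(f, s$params)
    denom <- pmax(abs(analytic) + abs(numeric), 1e-8)
    expect_lt(max(abs(analytic - numeric) / denom), 1e-5)
  }
})

test_that("inference-mode gradients (running batch-norm stats) also check out", {
  s <- loss_grad_setup("first", seed = 3L)
  rmu <- rnorm(length(s$rmu), 0, 0.1)
  rv <- runif(length(s$rv), 0.5, 2)
  f <- function(p) spikecnn:::.cnn_loss_grad(s$x, s$y, s$compiled$meta,
                                             s$compiled$drop, p, rmu, rv,
                                             FALSE, 2L)$loss
  analytic <- spikecnn:::.cnn_loss_grad(s$x, s$y, s$compiled$meta,
                                        s$compiled$drop, s$params, rmu, rv,
                                        FALSE, 2L)$grad
  numeric <- numeric_grad(f, s$params)
  denom <- pmax(abs(analytic) + abs(numeric), 1e-8)
  expect_lt(max(abs(analytic - numeric) / denom), 1e-5)
})

test_that("the slide-pooling variant backpropagates correctly too", {
  spec <- build_model_spec(12L, 2L, conv_filters = c(2L, 3L, 3L, 2L),
                           dense_units = c(6L, 4L), dropout_rate = 0,
                           pooling = "slide")
  compiled <- spikecnn:::compile_spec(spec)
  set.seed(5)
  params <- rnorm(compiled$n_params, 0, 0.4)
  x <- matrix(rnorm(4 * 12), 4, 12)
  y <- c(1L, 2L, 2L, 1L)
  rmu <- numeric(max(compiled$n_bn, 1)); rv <- rep(1, max(compiled$n_bn, 1))
  f <- function(p) spikecnn:::.cnn_loss_grad(x, y, compiled$meta, compiled$drop,
                                             p, rmu, rv, TRUE, 2L)$loss
  analytic <- spikecnn:::.cnn_loss_grad(x, y, compiled$meta, compiled$drop,
                                        params, rmu, rv, TRUE, 2L)$grad
  numeric <- numeric_grad(f, params)
  denom <- pmax(abs(analytic) + abs(numeric), 1e-8)
  expect_lt(max(abs(analytic - numeric) / denom), 1e-5)
})
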