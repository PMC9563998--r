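test_that("kernel field has one K*K kernel per pixel per group", {
  spec <- involution_spec(channels = 4, kernel_size = 3, groups = 1,
                          reduction = 2)
  x <- array(rnorm(5 * 4 * 4), c(5, 4, 4))
  k <- generate_kernels(x, spec, involution_params(spec, 1))
  expect_equal(dim(k), c(5, 4, 9))  # K*K*G = 9

  spec2 <- involution_spec(channels = 8, kernel_size = 5, groups = 2,
                           reduction = 4)
  x2 <- array(rnorm(3 * 3 * 8), c(3, 3, 8))
  k2 <- generate_kernels(x2, spec2, involution_params(spec2, 1))
  expect_equal(dim(k2)[3], 5 * 5 * 2)
})

test_that("kernels depend only on the pixel's own feature vector", {
  spec <- involution_spec(channels = 4, kernel_size = 3, reduction = 2)
  par <- involution_params(spec, 2)
  # constant input: all per-pixel kernels identical
  xc <- array(1.3, c(4, 6, 4))
  k <- generate_kernels(xc, spec, par)
  expect_true(all(abs(sweep(k, 3, k[1, 1, ])) < 1e-12))
  # spatial specificity: differing pixels get differing kernels
  xr <- array(rnorm(4 * 6 * 4), c(4, 6, 4))
  kr <- generate_kernels(xr, spec, par)
  expect_gt(max(abs(kr[1, 1, ] - kr[2, 3, ])), 1e-6)
})

test_that("kernel generation matches an independent per-pixel computation", {
  spec <- involution_spec(channels = 4, kernel_size = 3, groups = 1,
                          reduction = 2)
  par <- involution_params(spec, 7)
  set.seed(42)
  x <- array(rnorm(4 * 5 * 4), c(4, 5, 4))
  got <- generate_kernels(x, spec, par)
  # oracle: W1 . sigma(W0 x_ij) looped pixel by pixel, with the
  # normalization statistics of sigma computed in a separate first pass
  zs <- matrix(0, 4 * 5, 2)
  i <- 0
  for (jj in 1:5) for (ii in 1:4) {
    i <- i + 1
    zs[i, ] <- par$w0 %*% x[ii, jj, ] + par$b0
  }
  mu <- colMeans(zs)
  va <- colMeans(sweep(zs, 2, mu)^2)
  want <- array(0, dim(got))
  for (ii in 1:4) for (jj in 1:5) {
    z <- par$w0 %*% x[ii, jj, ] + par$b0
    z <- (z - mu) / sqrt(va + 1e-5)
    z <- pmax(z * par$n_gamma + par$n_beta, 0)
    want[ii, jj, ] <- par$w1 %*% z + par$b1
  }
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("multiply-add matches the naive nested-loop reference", {
  set.seed(1)
  for (rep in 1:10) {
    spec <- rand_invol_spec()
    h <- sample(2:8, 1); w <- sample(2:8, 1)
    x <- array(rnorm(h * w * spec$channels), c(h, w, spec$channels))
    k <- generate_kernels(x, spec, involution_params(spec, rep))
    expect_lt(max(abs(involution_forward(x, k, spec) -
                        involution_reference(x, k, spec))), 1e-10)
  }
})

test_that("center-one-hot kernels reproduce the input exactly", {
  set.seed(2)
  spec <- involution_spec(channels = 6, kernel_size = 5, groups = 3,
                          reduction = 2)
  x <- array(rnorm(7 * 4 * 6), c(7, 4, 6))
  y <- involution_forward(x, identity_kernels(7, 4, spec), spec)
  expect_identical(y, x)
})

test_that("degenerate 1x1 neighborhood is a per-channel scalar product", {
  spec <- involution_spec(channels = 3, kernel_size = 1, groups = 1,
                          reduction = 1)
  x <- array(c(2, -1, 4), c(1, 1, 3))
  k <- array(1.5, c(1, 1, 1))
  expect_equal(involution_forward(x, k, spec),
               array(1.5 * c(2, -1, 4), c(1, 1, 3)))
})

test_that("channel groups share kernels: G=1 commutes with permutation", {
  set.seed(3)
  spec <- involution_spec(channels = 6, kernel_size = 3, groups = 1,
                          reduction = 2)
  x <- array(rnorm(5 * 5 * 6), c(5, 5, 6))
  k <- generate_kernels(x, spec, involution_params(spec, 4))
  perm <- sample(6)
  # with one shared kernel per pixel, permuting channels before the
  # multiply-add equals permuting its output
  y_perm <- involution_forward(x[, , perm], k, spec)
  y <- involution_forward(x, k, spec)
  expect_equal(y_perm, y[, , perm])
})

test_that("group indexing follows the blocked channel-sharing convention", {
  # 32 channels with 16 channels per kernel means 2 groups
  spec <- involution_spec(channels = 32, kernel_size = 3, groups = 2)
  expect_equal(involution_group(0:31, spec), rep(0:1, each = 16))
  spec1 <- involution_spec(channels = 8, kernel_size = 3, groups = 8)
  expect_equal(involution_group(0:7, spec1), 0:7)
})

test_that("involution layer keeps spatial dims and handles zero input", {
  spec <- involution_spec(channels = 4, kernel_size = 3, reduction = 2)
  par <- involution_params(spec, 1)
  for (hw in list(c(1, 1), c(2, 5), c(8, 3))) {
    x <- array(rnorm(prod(hw) * 4), c(hw, 4))
    expect_equal(dim(involution_layer(x, spec, par)), dim(x))
  }
  # zero input, zero biases: pre-activation output is exactly zero
  x0 <- array(0, c(4, 4, 4))
  expect_true(all(involution_layer(x0, spec, par, activation = FALSE) == 0))
})

test_that("spec validation and shape contracts reject bad input", {
  expect_error(involution_spec(channels = 4, kernel_size = 4), "odd")
  expect_error(involution_spec(channels = 4, groups = 3), "divide")
  expect_error(involution_spec(channels = 4, reduction = 3), "divide")
  spec <- involution_spec(channels = 4, kernel_size = 3, reduction = 2)
  x <- array(0, c(3, 3, 5))
  expect_error(generate_kernels(x, spec, involution_params(spec, 1)),
               "channels")
})

test_that("strided involution samples the strided grid", {
  set.seed(4)
  spec1 <- involution_spec(channels = 4, kernel_size = 3, reduction = 2)
  spec2 <- involution_spec(channels = 4, kernel_size = 3, reduction = 2,
                           stride = 2)
  par <- involution_params(spec1, 5)
  x <- array(rnorm(6 * 6 * 4), c(6, 6, 4))
  y2 <- involution_forward(x, generate_kernels(x, spec2, par), spec2)
  expect_equal(dim(y2), c(3, 3, 4))
})

test_that("autodiff gradient of the involution stage matches finite differences", {
  cfg <- network_config(depth = 1, base_channels = 4, dense_layers = 1,
                        growth = 2,
                        involution = list(kernel_size = 3, groups = 2,
                                          reduction = 2), seed = 9)
  m <- init_model(cfg)
  # evaluation point chosen away from ReLU/argmax kinks, where central
  # differences are valid
  set.seed(11)
  xb <- array(runif(4 * 4 * 1 * 3), c(4, 4, 1, 3))
  tb <- array(rbinom(16, 1, 0.4), c(4, 4, 1, 1))
  loss_at <- function(params) {
    store <- new.env(); store$p <- params
    state <- new.env(); state$stats <- m$bn
    net <- lodgeseg:::net_new(cfg, store, state, training = TRUE)
    out <- lodgeseg:::net_build(net, lodgeseg:::tp_emit(net$tp, xb))
    lodgeseg:::tp_value(net$tp,
                        lodgeseg:::nn_tversky(net$tp, out, tb, 0.7, 0.3, 1e-6))
  }
  store <- new.env(); store$p <- m$params
  state <- new.env(); state$stats <- m$bn
  net <- lodgeseg:::net_new(cfg, store, state, training = TRUE)
  out <- lodgeseg:::net_build(net, lodgeseg:::tp_emit(net$tp, xb))
  g <- lodgeseg:::tp_backward(
    net$tp, lodgeseg:::nn_tversky(net$tp, out, tb, 0.7, 0.3, 1e-6))
  eps <- 1e-6
  for (nm in c("enc1.inv.w0", "enc1.inv.w1", "enc1.inv.b1",
               "enc1.inv.bn.gamma")) {
    for (i in c(1, length(m$params[[nm]]))) {
      pp <- m$params[[nm]]
      p_hi <- m$params; p_hi[[nm]][i] <- pp[i] + eps
      p_lo <- m$params; p_lo[[nm]][i] <- pp[i] - eps
      fd <- (loss_at(p_hi) - loss_at(p_lo)) / (2 * eps)
      expect_equal(g[[nm]][i], fd, tolerance = 1e-4,
                   label = paste("grad", nm, i))
    }
  }
})
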