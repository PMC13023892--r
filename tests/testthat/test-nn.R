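# Finite-difference validation of every layer's backward pass, plus the
# optimizer-level invariants.  The central-difference oracle is independent
# of the analytic gradients it checks.

check_layer_grads <- function(layer, xdim, name, tol = 1e-6) {
  set.seed(42)
  params <- layer$init()
  state <- layer$state0()
  x <- array(rnorm(prod(xdim)), xdim)
  fwd <- layer$fwd(params, state, x, TRUE)
  W <- array(rnorm(length(fwd$y)),
             if (is.null(dim(fwd$y))) length(fwd$y) else dim(fwd$y))
  bwd <- layer$bwd(params, fwd$cache, W)
  gx <- num_grad(function(xx) sum(layer$fwd(params, state, xx, TRUE)$y * W), x)
  expect_lt(max_relerr(bwd$dx, gx), tol)
  flat <- unlist(params)
  if (length(flat) > 0) {
    restore <- function(new, old) {
      if (is.list(old)) mapply(restore, new, old, SIMPLIFY = FALSE)
      else { if (!is.null(dim(old))) dim(new) <- dim(old); new }
    }
    gp <- num_grad(function(pv) {
      p2 <- restore(utils::relist(pv, params), params)
      sum(layer$fwd(p2, state, x, TRUE)$y * W)
    }, flat)
    expect_lt(max_relerr(unlist(bwd$grads), gp), tol)
  }
  invisible(NULL)
}

test_that("analytic gradients of all layers match finite differences", {
  nn <- asNamespace("mwstroke")
  cases <- list(
    list(nn$nn_conv(3L, 4L, 3L, 3L, 2L, 2L, 1L, 1L), c(3, 6, 6, 2), "conv2d"),
    list(nn$nn_conv(5L, 4L, 1L, 5L, 1L, 1L, 0L, 2L), c(5, 1, 8, 2), "conv1d"),
    list(nn$nn_bn(4L), c(4, 3, 3, 2), "batchnorm"),
    list(nn$nn_maxpool(2L, 2L), c(3, 4, 4, 2), "maxpool"),
    list(nn$nn_maxpool(3L, 3L, 2L, 2L, 1L, 1L), c(2, 5, 5, 2), "maxpool-pad"),
    list(nn$nn_gap(), c(4, 3, 3, 2), "gap"),
    list(nn$nn_linear(5L, 3L), c(5, 4), "linear"),
    list(nn$nn_lstm(4L, 3L, 2L), c(4, 3, 2), "lstm"),
    list(nn$nn_resblock(3L, 5L, 2L), c(3, 6, 6, 2), "resblock-proj"),
    list(nn$nn_resblock(3L, 3L, 1L), c(3, 4, 4, 2), "resblock-identity"))
  for (cs in cases) check_layer_grads(cs[[1]], cs[[2]], cs[[3]])
})

test_that("weighted cross-entropy matches hand arithmetic and reduces cleanly", {
  lc <- loss_config(w0 = 1, w1 = 5)
  # y = 1, p = 0.5, w1 = 5 -> 5 ln 2 per sample
  expect_equal(weighted_ce(0.5, 1, lc), 5 * log(2), tolerance = 1e-12)
  # confident correct prediction for the normal class -> ~0
  expect_lt(weighted_ce(1e-9, 0, lc), 1e-5)
  # batch of two averages the per-sample terms
  a <- weighted_ce(0.3, 1, lc); b <- weighted_ce(0.2, 0, lc)
  expect_equal(weighted_ce(c(0.3, 0.2), c(1, 0), lc), (a + b) / 2,
               tolerance = 1e-12)
  # w1 = w0 = 1 equals unweighted binary cross-entropy
  set.seed(13)
  p <- runif(50, 0.01, 0.99); y <- rbinom(50, 1, 0.5)
  expect_equal(weighted_ce(p, y, loss_config(1, 1)),
               mean(-(y * log(p) + (1 - y) * log(1 - p))), tolerance = 1e-12)
  # loss is nonnegative
  expect_gte(weighted_ce(p, y, lc), 0)
  # gradient of the fused softmax + loss matches finite differences
  nn <- asNamespace("mwstroke")
  z <- matrix(rnorm(8), 2, 4); yy <- c(1, 0, 1, 1)
  g <- nn$weighted_ce_grad(nn$softmax_cols(z), yy, lc)
  gn <- num_grad(function(zz) weighted_ce(nn$softmax_cols(matrix(zz, 2)), yy, lc), z)
  expect_lt(max_relerr(g, gn), 1e-6)
})

test_that("gradient clipping and Adam behave as specified", {
  nn <- asNamespace("mwstroke")
  g <- list(a = matrix(3, 2, 2), b = rep(4, 5))
  norm0 <- sqrt(sum(unlist(g)^2))
  gc <- nn$clip_grads(g, 1.0)
  expect_lte(sqrt(sum(unlist(gc)^2)), 1 + 1e-6)
  expect_equal(unlist(gc), unlist(g) / norm0, tolerance = 1e-12)
  # below the threshold nothing changes
  gs <- nn$clip_grads(list(a = 1e-3), 1.0)
  expect_identical(gs$a, 1e-3)
  # one Adam step moves parameters against the gradient
  p <- list(w = matrix(1, 2, 2))
  opt <- nn$adam_init(p)
  st <- nn$adam_step(p, list(w = matrix(1, 2, 2)), opt, lr = 0.1)
  expect_true(all(st$params$w < 1))
  # weight decay adds wd * param to the gradient: zero grad still shrinks
  st2 <- nn$adam_step(p, list(w = matrix(0, 2, 2)), opt, lr = 0.1,
                      weight_decay = 0.1)
  expect_true(all(st2$params$w < 1))
})

test_that("dropout is seeded and inference mode is deterministic", {
  nn <- asNamespace("mwstroke")
  do <- nn$nn_dropout(0.5)
  x <- array(1, c(4, 4))
  set.seed(77); y1 <- do$fwd(list(), list(), x, TRUE)$y
  set.seed(77); y2 <- do$fwd(list(), list(), x, TRUE)$y
  expect_identical(y1, y2)
  expect_identical(do$fwd(list(), list(), x, FALSE)$y, x)
  # inverted scaling preserves the expectation
  set.seed(1)
  big <- array(1, c(200, 200))
  yb <- do$fwd(list(), list(), big, TRUE)$y
  expect_lt(abs(mean(yb) - 1), 0.05)
})
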