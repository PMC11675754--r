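# Analytic gradients of every primitive are checked against central finite
# differences through a shared parameterised harness.

num_grad <- function(f, x, eps = 1e-5) {
  g <- array(0, dim(x) %||% length(x))
  for (i in seq_along(x)) {
    xp <- x; xm <- x
    xp[i] <- x[i] + eps
    xm[i] <- x[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

rel_err <- function(a, b) max(abs(a - b)) / max(1e-8, max(abs(a), abs(b)))

test_that("convolution layers backpropagate exactly", {
  set.seed(1)
  cases <- list(
    list(stride = 1L, pad = 1L, dil = 1L),
    list(stride = 2L, pad = 2L, dil = 2L))
  for (cs in cases) {
    x <- rand_arr(5, 6, 3, 2)
    p <- conv2d_init(3, 3, 4, bias = TRUE)
    fw <- conv2d_fw(x, p, cs$stride, cs$pad, cs$dil)
    g <- rand_arr(dim(fw$out)[1], dim(fw$out)[2], 4, 2)
    bk <- conv2d_bw(p, fw$cache, g)
    expect_lt(rel_err(bk$gx, num_grad(function(v)
      sum(conv2d_fw(v, p, cs$stride, cs$pad, cs$dil)$out * g), x)), 1e-6)
    expect_lt(rel_err(bk$grads$w, num_grad(function(v) {
      q <- p; q$w <- v
      sum(conv2d_fw(x, q, cs$stride, cs$pad, cs$dil)$out * g)
    }, p$w)), 1e-6)
    expect_equal(bk$grads$b, as.vector(num_grad(function(v) {
      q <- p; q$b <- v
      sum(conv2d_fw(x, q, cs$stride, cs$pad, cs$dil)$out * g)
    }, p$b)), tolerance = 1e-6)
  }
})

test_that("transposed convolution backpropagates exactly", {
  set.seed(2)
  x <- rand_arr(3, 4, 5, 2)
  p <- convt2d_init(2, 5, 3)
  fw <- convt2d_fw(x, p)
  expect_identical(dim(fw$out), c(6L, 8L, 3L, 2L))
  g <- rand_arr(6, 8, 3, 2)
  bk <- convt2d_bw(p, fw$cache, g)
  expect_lt(rel_err(bk$gx,
                    num_grad(function(v) sum(convt2d_fw(v, p)$out * g), x)),
            1e-6)
  expect_lt(rel_err(bk$grads$w, num_grad(function(v) {
    q <- p; q$w <- v; sum(convt2d_fw(x, q)$out * g)
  }, p$w)), 1e-6)
})

test_that("normalization layers backpropagate exactly", {
  set.seed(3)
  x <- rand_arr(4, 4, 4, 3)
  g <- rand_arr(4, 4, 4, 3)
  # batch norm in training mode
  p <- list(g = runif(4, 0.5, 1.5), b = rnorm(4))
  ctx <- function() list(buffers = new.env(), training = TRUE)
  fw <- bn_fw(x, p, ctx(), "t")
  bk <- bn_bw(p, fw$cache, g)
  expect_lt(rel_err(bk$gx, num_grad(function(v)
    sum(bn_fw(v, p, ctx(), "t")$out * g), x)), 1e-5)
  expect_lt(rel_err(bk$grads$g, num_grad(function(v) {
    q <- p; q$g <- v; sum(bn_fw(x, q, ctx(), "t")$out * g)
  }, p$g)), 1e-5)
  # group norm
  fg <- gn_fw(x, p, groups = 2L)
  bg <- gn_bw(p, fg$cache, g)
  expect_lt(rel_err(bg$gx, num_grad(function(v)
    sum(gn_fw(v, p, 2L)$out * g), x)), 1e-5)
  # layer norm on tokens
  tk <- rand_arr(5, 4, 2)
  gt <- rand_arr(5, 4, 2)
  fl <- ln_fw(tk, p)
  bl <- ln_bw(p, fl$cache, gt)
  expect_lt(rel_err(bl$gx, num_grad(function(v)
    sum(ln_fw(v, p)$out * gt), tk)), 1e-5)
})

test_that("batch norm tracks running statistics for eval mode", {
  set.seed(4)
  p <- list(g = rep(1, 3), b = rep(0, 3))
  buf <- new.env()
  ctx <- list(buffers = buf, training = TRUE)
  x <- rand_arr(8, 8, 3, 4) + 2
  for (i in 1:80) bn_fw(x, p, ctx, "t")
  ev <- bn_fw(x, p, list(buffers = buf, training = FALSE), "t")
  # after many updates on constant data the eval output matches train output
  tr <- bn_fw(x, p, ctx, "t")
  expect_equal(ev$out, tr$out, tolerance = 2e-2)
})

test_that("pooling, upsampling and activations are exact", {
  set.seed(5)
  x <- rand_arr(6, 6, 2, 2)
  fw <- maxpool2_fw(x)
  expect_identical(dim(fw$out), c(3L, 3L, 2L, 2L))
  g <- rand_arr(3, 3, 2, 2)
  expect_lt(rel_err(maxpool2_bw(fw$cache, g), num_grad(function(v)
    sum(maxpool2_fw(v)$out * g), x)), 1e-5)
  fu <- upsample_nearest_fw(x, 2L)
  expect_identical(dim(fu$out), c(12L, 12L, 2L, 2L))
  expect_identical(fu$out[1, 1, 1, 1], x[1, 1, 1, 1])
  expect_identical(fu$out[2, 2, 1, 1], x[1, 1, 1, 1])
  r <- relu_fw(x)
  expect_identical(r$out, pmax(x, 0))
  ge <- gelu_fw(x)
  expect_equal(ge$out, x * pnorm(x))
  sg <- sigmoid_fw(x)
  expect_equal(sg$out, 1 / (1 + exp(-x)))
})

test_that("linear layers on token tensors backpropagate exactly", {
  set.seed(6)
  x <- rand_arr(5, 3, 2)
  p <- linear_init(3, 4)
  fw <- linear_fw(x, p)
  g <- rand_arr(5, 4, 2)
  bk <- linear_bw(p, fw$cache, g)
  expect_lt(rel_err(bk$gx, num_grad(function(v)
    sum(linear_fw(v, p)$out * g), x)), 1e-6)
  expect_lt(rel_err(bk$grads$w, num_grad(function(v) {
    q <- p; q$w <- v; sum(linear_fw(x, q)$out * g)
  }, p$w)), 1e-6)
})
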