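test_that("decoder double-conv block honors its contract", {
  set.seed(1)
  ctx <- list(buffers = new.env(), training = TRUE)
  p <- dc_init(8L, 4L)
  x <- rand_arr(6, 6, 8, 2)
  got <- dc_fw(x, p, ctx, "t")
  expect_identical(dim(got$out), c(6L, 6L, 4L, 2L))
  expect_true(all(got$out >= 0))                     # final ReLU
  # hand count: 8*4*9 + 2*4 (bn) + 4*4*9 + 2*4 (bn), bias-free convs
  expect_identical(n_params(dc_init(8L, 4L)), 8L * 4L * 9L + 8L +
                     4L * 4L * 9L + 8L)
})

test_that("cost accounting reproduces the published model sizes", {
  u <- count_costs(unet_spec())
  l <- count_costs(lightunet_spec())
  # learnable + norm-statistics state, the convention of the printed sizes
  expect_identical(u$parameters, 31037698)
  expect_identical(u$buffers, 11776)
  expect_identical(u$params_m, 31.05)
  expect_identical(l$params_m, 0.49)
  expect_identical(round(l$state / u$state, 3), 0.016)
  # exact analytic MACs and their internal consistency (ratio ~ 62)
  expect_identical(u$macs_g, 192.69)
  expect_identical(l$macs_g, 3.06)
  expect_gt(u$macs / l$macs, 60)
  expect_lt(u$macs / l$macs, 64)
})

test_that("width scaling follows the square law on the dominant terms", {
  base <- count_costs(unet_spec())$parameters
  for (s in c(1 / 2, 1 / 4, 1 / 8)) {
    p <- count_costs(unet_spec(width_factor = s))$parameters
    expect_equal(p / (base * s^2), 1, tolerance = 0.02)
  }
  expect_error(unet_spec(width_factor = 1 / 128), "width")
})

test_that("layout-based counts agree with allocated weights for both families", {
  ts <- tiny_unet_spec(64L)
  m <- build_unet(ts, seed = 1)
  expect_identical(count_costs(ts)$parameters, as.double(n_params(m$params)))
  ss <- tiny_s2ag_spec(64L)
  sm <- build_s2agscunet(ss, seed = 2)
  expect_identical(count_costs(ss)$parameters,
                   as.double(n_params(sm$params)))
  # spec -> model -> introspected spec round trip
  expect_identical(introspect_spec(m), ts)
})

test_that("single-conv MAC arithmetic matches the hand count", {
  # conv 3 -> 4 channels, 3x3 kernel, stride 1, pad 1 on an 8x8 grid
  r <- cost_row("c", "conv", 3, 4, 3, 8, 8, 8, 8)
  expect_identical(row_macs(r[1, ]), 4 * 3 * 9 * 64)
  expect_error(row_macs(cost_row("x", "warp", 1, 1, 1, 1, 1, 1, 1)[1, ]),
               "unsupported layer kind")
})

test_that("unet forward/backward wire the skip concatenation correctly", {
  set.seed(2)
  m <- build_unet(tiny_unet_spec(32L), seed = 3)
  x <- rand_arr(32, 32, 3, 2)
  ctx <- list(buffers = m$buffers, training = TRUE)
  fw <- net_forward(m, x, ctx)
  expect_identical(dim(fw$out), c(32L, 32L, 2L, 2L))
  g <- rand_arr(32, 32, 2, 2, sd = 0.01)
  bk <- net_backward(m, fw$cache, g)
  fp <- flatten_params(m$params)
  fg <- flatten_params(bk$grads)
  expect_identical(sort(names(fp)), sort(names(fg)))
  # full-gradient directional derivative against central differences
  set.seed(4)
  v <- lapply(fp, function(a) {
    r <- rnorm(length(a)); if (!is.null(dim(a))) dim(r) <- dim(a); r
  })
  nv <- sqrt(sum(vapply(v, function(a) sum(a^2), 0)))
  v <- lapply(v, function(a) a / nv)
  ana <- sum(mapply(function(gr, vv) sum(gr * vv), fg[names(fp)], v))
  eps <- 1e-4
  loss_of <- function(par) {
    mm <- m; mm$params <- par
    sum(net_forward(mm, x, list(buffers = mm$buffers,
                                training = TRUE))$out * g)
  }
  num <- (loss_of(unflatten_into(m$params, mapply(function(a, vv) a + eps * vv,
                                                  fp, v, SIMPLIFY = FALSE))) -
          loss_of(unflatten_into(m$params, mapply(function(a, vv) a - eps * vv,
                                                  fp, v, SIMPLIFY = FALSE)))) /
    (2 * eps)
  expect_equal(ana, num, tolerance = 1e-3)
})

test_that("the assembled gated network runs end to end and is deterministic", {
  set.seed(5)
  sm <- build_s2agscunet(tiny_s2ag_spec(64L), seed = 6)
  x <- rand_arr(64, 64, 3, 1)
  z1 <- model_logits(sm, x)
  z2 <- model_logits(sm, x)
  expect_identical(dim(z1), c(64L, 64L, 2L, 1L))
  expect_identical(z1, z2)
  pr <- predict(sm, x)
  expect_identical(dim(pr), c(64L, 64L, 1L))
  expect_true(all(pr %in% c(0L, 1L)))
})

test_that("most parameters of the large gated network sit in the frozen trunk", {
  lg <- count_costs(network_spec("s2agscunet",
                                 encoder = encoder_config("large")))
  trunk <- count_trunk_parameters(encoder_config("large"),
                                  include_classifier = FALSE)
  frac <- trunk / lg$parameters
  expect_gt(frac, 0.8)
  # regression of the exact split: 212.6 M trunk of 253.6 M total
  expect_identical(round(trunk / 1e6, 1), 212.6)
  expect_identical(round(lg$parameters / 1e6, 1), 253.6)
})

test_that("checkpoints round-trip weights, spec and buffers", {
  m <- build_unet(tiny_unet_spec(32L), seed = 7)
  x <- array(runif(32 * 32 * 3), c(32, 32, 3, 1))
  z0 <- model_logits(m, x)   # materializes bn buffers
  f <- tempfile(fileext = ".ckpt")
  save_checkpoint(m, f)
  m2 <- load_checkpoint(f)
  expect_identical(m2$spec, m$spec)
  expect_identical(m2$params, m$params)
  expect_identical(model_logits(m2, x), z0)
  unlink(f)
})
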