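test_that("adapter is the residual-free bottleneck composition", {
  set.seed(1)
  p <- adapter_init(8L, 0.25)
  x <- rand_arr(5, 8, 2)
  got <- adapter_fw(x, p)
  expect_identical(dim(got$out), dim(x))
  # independent evaluation of GeLU(up(GeLU(down(x)))) with plain matrix ops
  ref <- x
  for (n in 1:2) {
    h <- gelu_ref(x[, , n] %*% p$down$w +
                    matrix(p$down$b, 5, 2, byrow = TRUE))
    ref[, , n] <- gelu_ref(h %*% p$up$w + matrix(p$up$b, 5, 8, byrow = TRUE))
  }
  expect_equal(got$out, ref, tolerance = 1e-12)

  # all-zero parameters force an all-zero output (GeLU(0) = 0)
  p0 <- rapply(p, function(a) { a[] <- 0; a }, how = "replace")
  expect_true(all(adapter_fw(x, p0)$out == 0))

  # closed-form parameter count at the published width
  expect_identical(n_params(adapter_init(144L, 0.25)),
                   144L * 36L + 36L + 36L * 144L + 144L)
})

test_that("pyramid geometry follows the shape law", {
  # published large variant: channels 144/288/576/1152, spatial /4.../32
  sh <- pyramid_shapes(encoder_config("large"), 512, 512)
  expect_identical(sh$channels, c(144L, 288L, 576L, 1152L))
  expect_identical(sh$height, c(128L, 64L, 32L, 16L))
  expect_error(pyramid_shapes(encoder_config("large"), 100, 100),
               "divisible by 32")

  # property: real forwards of tiny variants match the arithmetic
  set.seed(2)
  for (case in list(list(e = 4L, s = 32L), list(e = 8L, s = 64L))) {
    cfg <- encoder_config("tiny", embed_dim = case$e, pos_grid = 8L)
    enc <- encoder_init(cfg, seed = case$e)
    pyr <- encode(enc, array(runif(case$s^2 * 3), c(case$s, case$s, 3, 1)))
    sh <- pyramid_shapes(cfg, case$s, case$s)
    for (i in 1:4) {
      expect_identical(dim(pyr[[i]])[3], sh$channels[i])
      expect_identical(dim(pyr[[i]])[1], sh$height[i])
    }
  }
  enc <- encoder_init(encoder_config("tiny"), seed = 1)
  expect_error(encode(enc, array(0, c(100, 100, 3, 1))), "divisible by 32")
})

test_that("trunk parameter accounting matches the published scale", {
  large <- encoder_config("large")
  expect_identical(round(count_trunk_parameters(large) / 1e6), 214)
  # adapters never enter the trunk count
  expect_identical(count_trunk_parameters(large),
                   count_trunk_parameters(
                     encoder_config("large", adapter_ratio = 0.5)))
  # analytic count equals a brute-force enumeration of the allocated arrays
  cfg <- encoder_config("tiny", embed_dim = 8L)
  enc <- encoder_init(cfg, seed = 3)
  sp <- encoder_param_split(enc)
  expect_identical(count_trunk_parameters(cfg, include_classifier = FALSE),
                   as.double(sp$trunk))
})

test_that("freezing leaves the trunk bit-identical under optimization", {
  set.seed(4)
  spec <- tiny_s2ag_spec(32L, freeze = "trunk")
  model <- build_s2agscunet(spec, seed = 5)
  fp0 <- flatten_params(model$params)
  x <- rand_arr(32, 32, 3, 2)
  y <- array(sample(0:1, 32 * 32 * 2, TRUE), c(32, 32, 2))
  ctx <- list(buffers = model$buffers, training = TRUE)
  fw <- net_forward(model, x, ctx)
  lg <- ce_loss_grad(fw$out, y)
  bk <- net_backward(model, fw$cache, lg$glogits)
  st <- adam_step(model$params, bk$grads, adam_init(), lr = 1e-3)
  fp1 <- flatten_params(st$params)

  frozen <- vapply(fp0, is_frozen, TRUE)
  adapters <- grepl("\\.adapter\\.", names(fp0))
  # trunk = everything in the encoder except adapters
  trunk <- grepl("^encoder", names(fp0)) & !adapters
  expect_identical(unname(frozen), unname(trunk))
  for (nm in names(fp0)[trunk])
    expect_identical(as.vector(fp1[[nm]]), as.vector(fp0[[nm]]))
  # adapters (and at least one neck/decoder weight) moved
  moved <- vapply(names(fp0), function(nm)
    !isTRUE(all.equal(as.vector(fp1[[nm]]), as.vector(fp0[[nm]]))), TRUE)
  expect_true(all(moved[adapters]))
  expect_true(any(moved[grepl("^neck", names(fp0))]))
  expect_true(any(moved[grepl("^decoder", names(fp0))]))
  # trainable count is total minus trunk
  expect_identical(sum(lengths(fp0[!frozen])),
                   sum(lengths(fp0)) - sum(lengths(fp0[trunk])))
})

test_that("encoder forward is deterministic for fixed weights", {
  enc <- encoder_init(encoder_config("tiny"), seed = 6)
  x <- array(runif(32 * 32 * 3 * 2), c(32, 32, 3, 2))
  expect_identical(encode(enc, x), encode(enc, x))
})
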