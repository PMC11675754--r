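test_that("cross-entropy matches closed forms and hand arithmetic", {
  set.seed(1)
  y <- array(sample(0:1, 4 * 4 * 2, TRUE), c(4, 4, 2))
  # uniform prediction costs exactly ln 2 per pixel
  expect_equal(ce_loss(array(0, c(4, 4, 2, 2)), y)$total, log(2))
  # saturated correct prediction costs (numerically) nothing
  zgood <- array(0, c(4, 4, 2, 2))
  zgood[, , 1, ][y == 0] <- 20; zgood[, , 2, ][y == 0] <- -20
  zgood[, , 1, ][y == 1] <- -20; zgood[, , 2, ][y == 1] <- 20
  expect_lt(ce_loss(zgood, y)$total, 1e-6)
  # two-pixel hand example: logits (1,0) and (0,2), labels (0,1)
  zh <- array(0, c(1, 2, 2, 1))
  zh[1, 1, , 1] <- c(1, 0); zh[1, 2, , 1] <- c(0, 2)
  yh <- array(c(0L, 1L), c(1, 2, 1))
  expect_equal(ce_loss(zh, yh)$total,
               mean(c(-log(exp(1) / (exp(1) + 1)),
                      -log(exp(2) / (1 + exp(2))))))
  expect_error(ce_loss(zh, array(c(0L, 2L), c(1, 2, 1))), "\\{0, 1\\}")
})

test_that("distillation loss identities hold on random grids", {
  set.seed(2)
  for (i in 1:5) {
    d <- c(3, 3, 2, 2)
    zs <- rand_arr(3, 3, 2, 2); zt <- rand_arr(3, 3, 2, 2)
    y <- array(sample(0:1, 9 * 2, TRUE), c(3, 3, 2))
    # alpha = 1 collapses to plain cross-entropy exactly
    expect_identical(kd_loss(zs, zt, y, distill_config(alpha = 1))$total,
                     ce_loss(zs, y)$total)
    # identical distributions have zero divergence
    expect_equal(kd_loss(zs, zs, y, distill_config())$kl_term, 0)
    # divergence is never negative
    expect_gte(kd_loss(zs, zt, y, distill_config())$kl_term, 0)
  }
  expect_error(distill_config(alpha = 1.2), "alpha")
  expect_error(distill_config(temperature = 0), "temperature")
})

test_that("one-pixel distillation example matches hand arithmetic", {
  # student logits (0,0), teacher (2,0), T = 2, alpha = 0.5
  zs <- array(c(0, 0), c(1, 1, 2, 1))
  zt <- array(c(2, 0), c(1, 1, 2, 1))
  y <- array(1L, c(1, 1, 1))
  cfg <- distill_config(alpha = 0.5, temperature = 2)
  got <- kd_loss(zs, zt, y, cfg)
  pt <- exp(c(1, 0)) / sum(exp(c(1, 0)))       # softmax((2,0)/2)
  ps <- c(0.5, 0.5)                            # softmax((0,0)/2)
  kl <- sum(pt * (log(pt) - log(ps)))
  ce <- -log(0.5)
  expect_equal(got$kl_term, kl, tolerance = 1e-12)
  expect_equal(got$total, 0.5 * ce + 0.5 * 4 * kl, tolerance = 1e-12)
})

test_that("temperature-squared scaling preserves the distillation signal", {
  set.seed(3)
  zs <- rand_arr(4, 4, 2, 1); zt <- rand_arr(4, 4, 2, 1)
  y <- array(sample(0:1, 16, TRUE), c(4, 4, 1))
  w <- vapply(c(10, 100), function(Tt) {
    k <- kd_loss(zs, zt, y, distill_config(alpha = 0, temperature = Tt))
    Tt^2 * k$kl_term
  }, 0)
  # the weighted term converges to a finite nonzero limit as T grows
  expect_gt(w[1], 0)
  expect_equal(w[1], w[2], tolerance = 0.05)
})

test_that("the distillation gradient matches finite differences", {
  set.seed(4)
  zs <- rand_arr(2, 2, 2, 1); zt <- rand_arr(2, 2, 2, 1)
  y <- array(sample(0:1, 4, TRUE), c(2, 2, 1))
  cfg <- distill_config(alpha = 0.3, temperature = 2.5)
  lg <- kd_loss_grad(zs, zt, y, cfg)
  eps <- 1e-6
  for (i in seq_along(zs)) {
    zp <- zs; zp[i] <- zs[i] + eps
    zm <- zs; zm[i] <- zs[i] - eps
    ng <- (kd_loss(zp, zt, y, cfg)$total - kd_loss(zm, zt, y, cfg)$total) /
      (2 * eps)
    expect_equal(lg$glogits[i], ng, tolerance = 1e-5)
  }
})

test_that("training reduces the loss, is seeded, and respects lr = 0", {
  db <- scene_batch(12, size = 64, seed = 100)
  cfg <- distill_config(epochs = 5, batch_size = 8, lr = 1e-3, seed = 1)
  f1 <- train(build_unet(tiny_unet_spec(64L), seed = 1), db, cfg)
  expect_lt(f1$log$loss[5], f1$log$loss[1])
  f2 <- train(build_unet(tiny_unet_spec(64L), seed = 1), db, cfg)
  expect_identical(f1$model$params, f2$model$params)
  expect_identical(f1$log, f2$log)
  cfg0 <- distill_config(epochs = 1, batch_size = 8, lr = 0, seed = 1)
  f0 <- train(build_unet(tiny_unet_spec(64L), seed = 2), db, cfg0)
  expect_identical(f0$model$params,
                   build_unet(tiny_unet_spec(64L), seed = 2)$params)
  # non-finite losses abort with a diagnostic rather than looping on
  broken <- build_unet(tiny_unet_spec(64L), seed = 3)
  broken$params$head$w[] <- NaN
  expect_error(train(broken, db, cfg), "non-finite loss")
  expect_error(train(build_unet(tiny_unet_spec(64L), seed = 3),
                     list(images = db$images[, , , 0, drop = FALSE],
                          masks = db$masks[, , 0, drop = FALSE]), cfg),
               "empty")
})

test_that("distilling with alpha = 1 is numerically identical to training", {
  db <- scene_batch(8, size = 64, seed = 200)
  teacher <- build_s2agscunet(tiny_s2ag_spec(64L), seed = 9)
  cfg <- distill_config(alpha = 1, temperature = 2, epochs = 2,
                        batch_size = 4, seed = 5)
  s1 <- build_unet(tiny_unet_spec(64L), seed = 6)
  s2 <- build_unet(tiny_unet_spec(64L), seed = 6)
  ft <- train(s1, db, cfg)
  fd <- distill(teacher, s2, db, cfg)
  expect_identical(ft$model$params, fd$model$params)
  expect_identical(ft$log$loss, fd$log$loss)
})

test_that("the teacher is immutable throughout distillation", {
  db <- scene_batch(8, size = 64, seed = 300)
  teacher <- build_s2agscunet(tiny_s2ag_spec(64L), seed = 10)
  model_logits(teacher, db$images[, , , 1, drop = FALSE])  # touch buffers
  before <- list(params = teacher$params, buffers = as.list(teacher$buffers))
  student <- build_unet(tiny_unet_spec(64L), seed = 11)
  fd <- distill(teacher, student, db,
                distill_config(alpha = 0.5, epochs = 2, batch_size = 4,
                               seed = 7))
  expect_identical(teacher$params, before$params)
  expect_identical(as.list(teacher$buffers), before$buffers)
  # both loss components are logged separately and the soft term shrinks
  expect_true(all(c("ce_term", "kl_term") %in% names(fd$log)))
  expect_lt(fd$log$kl_term[2], fd$log$kl_term[1] + 1e-9)
})
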