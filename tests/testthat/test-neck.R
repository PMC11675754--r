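# The neck blocks (attention gate, SRU, CRU, RFB) are verified against
# independent direct-formula oracles written out in plain arithmetic.

ctxf <- function() list(buffers = new.env(), training = TRUE)

test_that("attention gate matches the direct gating formula on a toy", {
  set.seed(1)
  # 2x2 single-channel skip and decoder features, hand-set 1x1 weights
  xs <- array(c(0.3, -0.5, 1.2, 0.7), c(2, 2, 1, 1))
  xd <- array(c(-0.2, 0.9, 0.4, -1.1), c(2, 2, 1, 1))
  p <- gate_init(1L, 1L, cm = 1L)
  p$ws$w[] <- 0.8;  p$ws$b <- 0.1
  p$wd$w[] <- -0.6; p$wd$b <- 0.05
  p$wr$w[] <- 1.3;  p$wr$b <- -0.2
  got <- gate_fw(xs, xd, p, target = "decoder")
  # independent evaluation: sigmoid(wr * relu(ws*xs + bs + wd*xd + bd) + br) * xd
  a <- 0.8 * xs[, , 1, 1] + 0.1 + (-0.6) * xd[, , 1, 1] + 0.05
  r <- pmax(a, 0)
  gmap <- 1 / (1 + exp(-(1.3 * r - 0.2)))
  expect_equal(got$out[, , 1, 1], gmap * xd[, , 1, 1], tolerance = 1e-12)
  expect_equal(got$gate[, , 1, 1], gmap, tolerance = 1e-12)
  # gating the skip path instead
  got2 <- gate_fw(xs, xd, p, target = "skip")
  expect_equal(got2$out[, , 1, 1], gmap * xs[, , 1, 1], tolerance = 1e-12)
})

test_that("zero response weights force a flat 0.5 gate", {
  set.seed(2)
  xs <- rand_arr(4, 4, 3, 2)
  xd <- rand_arr(2, 2, 5, 2)
  p <- gate_init(3L, 5L)
  p$wr$w[] <- 0; p$wr$b[] <- 0
  got <- gate_fw(xs, xd, p, target = "decoder")
  up <- upsample_nearest_fw(xd, 2L)$out
  expect_identical(got$out, 0.5 * up)
})

test_that("gate values are strictly inside (0, 1) for finite inputs", {
  set.seed(3)
  for (i in 1:5) {
    p <- gate_init(2L, 4L)
    got <- gate_fw(rand_arr(4, 4, 2, 1, sd = 5), rand_arr(4, 4, 4, 1, sd = 5),
                   p)
    expect_true(all(got$gate > 0 & got$gate < 1))
  }
  expect_error(gate_fw(rand_arr(4, 4, 3, 1), rand_arr(4, 4, 4, 1),
                       gate_init(2L, 4L)), "channel mismatch")
})

test_that("SRU informativeness weights and reconstruction match the rule", {
  p <- sru_init(4L)
  p$gn$g <- c(4, 3, 2, 1)
  expect_equal(sru_weights(p), c(0.4, 0.3, 0.2, 0.1))

  set.seed(4)
  x <- rand_arr(3, 3, 4, 1)
  p$gn$b <- rnorm(4) / 10
  got <- sru_fw(x, p, groups = 2L, threshold = 0.5)
  expect_identical(dim(got$out), dim(x))
  # independent trace: group norm, sigmoid(gn * w), hard split at 0.5,
  # cross-reconstruction of the two channel halves
  gn <- array(0, dim(x))
  for (g in 1:2) {
    ch <- (g - 1) * 2 + 1:2
    v <- x[, , ch, 1]
    gn[, , ch, 1] <- (v - mean(v)) / sqrt(mean((v - mean(v))^2) + 1e-5)
  }
  for (c in 1:4) gn[, , c, 1] <- gn[, , c, 1] * p$gn$g[c] + p$gn$b[c]
  w <- p$gn$g / sum(p$gn$g)
  rw <- 1 / (1 + exp(-sweep(gn, 3, w, "*")))
  x1 <- gn * (rw >= 0.5)
  x2 <- gn * (rw < 0.5)
  ref <- array(0, dim(x))
  ref[, , 1:2, ] <- x1[, , 1:2, , drop = FALSE] + x2[, , 3:4, , drop = FALSE]
  ref[, , 3:4, ] <- x1[, , 3:4, , drop = FALSE] + x2[, , 1:2, , drop = FALSE]
  expect_equal(got$out, ref, tolerance = 1e-10)
})

test_that("CRU preserves shape and its merge weights sum to one", {
  set.seed(5)
  x <- rand_arr(4, 4, 8, 2)
  p <- cru_init(8L)
  got <- cru_fw(x, p)
  expect_identical(dim(got$out), dim(x))
  a1 <- got$cache$a1
  expect_true(all(a1 > 0 & a1 < 1))   # pairwise softmax over the two streams

  # zero convolution weights: both streams trace to the brute-force rule
  p0 <- p
  for (nm in names(p0)) p0[[nm]]$w[] <- 0
  got0 <- cru_fw(x, p0)
  # all convs zero => Y1 = 0 and Y2 = cat(0, squeezed low) = 0, merge = 0
  expect_true(all(got0$out == 0))

  # 2-channel toy still runs (squeeze floors at one channel)
  x2 <- rand_arr(3, 3, 2, 1)
  p2 <- cru_init(2L)
  expect_identical(dim(cru_fw(x2, p2)$out), dim(x2))
  expect_error(cru_init(8L, split_ratio = 1.2), "split ratio")
})

test_that("RFB keeps spatial size, maps channels, and collapses at zero", {
  set.seed(6)
  x <- rand_arr(6, 6, 8, 2)
  p <- rfb_init(8L, 4L)
  got <- rfb_fw(x, p, ctxf(), "t")
  expect_identical(dim(got$out), c(6L, 6L, 4L, 2L))
  # zero weights with batch-norm shift zero give an all-zero output
  p0 <- rapply(p, function(a) { a[] <- 0; a }, how = "replace")
  got0 <- rfb_fw(x, p0, ctxf(), "t")
  expect_true(all(got0$out == 0))
  # receptive field of the deepest branch: 1x1 reduce then 3x3 dilation 7
  expect_identical(rfb_branch_receptive_field(4L), 15L)
  expect_error(rfb_init(8L, 0L), "positive")
})

test_that("neck blocks never change spatial resolution", {
  set.seed(7)
  for (hw in c(4L, 6L)) {
    x <- rand_arr(hw, hw, 8, 1)
    expect_identical(dim(rfb_fw(x, rfb_init(8L, 8L), ctxf(), "t")$out)[1:2],
                     c(hw, hw))
    expect_identical(dim(sru_fw(x, sru_init(8L), groups = 4L)$out)[1:2],
                     c(hw, hw))
    expect_identical(dim(cru_fw(x, cru_init(8L))$out)[1:2], c(hw, hw))
  }
})

test_that("exported block wrappers mirror the internal implementations", {
  set.seed(8)
  x <- rand_arr(4, 4, 8, 1)
  expect_identical(dim(rfb_forward(x, 4L, seed = 1)), c(4L, 4L, 4L, 1L))
  expect_identical(sru_forward(x), sru_fw(x, sru_init(8L))$out)
  expect_identical(dim(cru_forward(x)), dim(x))
  xs <- rand_arr(4, 4, 2, 1); xd <- rand_arr(2, 2, 4, 1)
  p <- gate_params(2L, 4L)
  g <- attention_gate(xs, xd, p)
  expect_identical(dim(g), c(4L, 4L, 4L, 1L))
  expect_true(all(attr(g, "gate") > 0 & attr(g, "gate") < 1))
  tk <- rand_arr(5, 8, 1)
  pa <- adapter_params(8L)
  expect_identical(adapter_forward(tk, pa), adapter_fw(tk, pa)$out)
  expect_error(adapter_forward(rand_arr(5, 4, 1), pa), "channel mismatch")
  d <- decoder_block(x, 4L, seed = 2)
  expect_identical(dim(d), c(4L, 4L, 4L, 1L))
  expect_true(all(d >= 0))
})
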