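# Primitive differentiable layers.
#
# Feature maps are arrays with dim c(H, W, C, N); token tensors are arrays
# with dim c(L, C, N) where L unrolls a (h, w) grid h-fastest, so a token
# tensor can be reshaped to (h, w, C, N) without copying semantics.
#
# Every `*_fw` returns list(out=..., cache=...); the matching `*_bw` takes the
# cache and the upstream gradient and returns list(gx=..., grads=...) where
# `grads` mirrors the layer's parameter list.  Convolution backward recomputes
# im2col rather than caching the patch matrix, trading ~30% compute for a much
# smaller activation footprint.

conv_out_size <- function(size, k, stride, pad, dil = 1) {
  (size + 2 * pad - dil * (k - 1) - 1) %/% stride + 1L
}

conv2d_init <- function(k, cin, cout, bias = FALSE) {
  p <- list(w = init_array(c(k, k, cin, cout), fan_in = k * k * cin))
  if (bias) p$b <- numeric(cout)
  p
}

conv2d_fw <- function(x, p, stride = 1L, pad = 0L, dil = 1L) {
  d <- dim(x); k <- dim(p$w)[1]; cin <- dim(p$w)[3]; cout <- dim(p$w)[4]
  stopifnot(d[3] == cin)
  ho <- conv_out_size(d[1], k, stride, pad, dil)
  wo <- conv_out_size(d[2], k, stride, pad, dil)
  om <- conv_fwd_gemm(x, d[1], d[2], d[3], d[4],
                      matrix(p$w, k * k * cin, cout),
                      k, stride, pad, dil)
  if (!is.null(p$b)) om <- sweep(om, 2, p$b, "+")
  out <- pm_to_nchw(om, ho * wo, cout, d[4])
  dim(out) <- c(ho, wo, cout, d[4])
  list(out = out,
       cache = list(x = x, stride = stride, pad = pad, dil = dil))
}

conv2d_bw <- function(p, cache, gout) {
  x <- cache$x; d <- dim(x)
  k <- dim(p$w)[1]; cin <- dim(p$w)[3]; cout <- dim(p$w)[4]
  go <- dim(gout)
  gm <- nchw_to_pm(gout, go[1] * go[2], cout, go[4])
  r <- conv_bwd_gemm(x, d[1], d[2], d[3], d[4],
                     matrix(p$w, k * k * cin, cout), gm,
                     k, cache$stride, cache$pad, cache$dil)
  grads <- list(w = r$gw)
  dim(grads$w) <- dim(p$w)
  if (!is.null(p$b)) grads$b <- colSums(gm)
  gx <- r$gx
  dim(gx) <- d
  list(gx = gx, grads = grads)
}

# Grouped convolution: channel-sliced ordinary convolutions.
conv2d_grouped_fw <- function(x, p, groups, stride = 1L, pad = 0L) {
  if (groups == 1L) return(conv2d_fw(x, p, stride, pad))
  d <- dim(x); k <- dim(p$w)[1]
  cig <- d[3] %/% groups; cog <- dim(p$w)[4] %/% groups
  outs <- vector("list", groups); caches <- vector("list", groups)
  for (g in seq_len(groups)) {
    ci <- (g - 1) * cig + seq_len(cig); co <- (g - 1) * cog + seq_len(cog)
    # grouped weight layout: dim (k, k, cin/groups, cout); slice output chans
    pg <- list(w = p$w[, , , co, drop = FALSE])
    if (!is.null(p$b)) pg$b <- p$b[co]
    r <- conv2d_fw(x[, , ci, , drop = FALSE], pg, stride, pad)
    outs[[g]] <- r$out; caches[[g]] <- r$cache
  }
  out <- array(0, c(dim(outs[[1]])[1:2], cog * groups, d[4]))
  for (g in seq_len(groups))
    out[, , (g - 1) * cog + seq_len(cog), ] <- outs[[g]]
  list(out = out, cache = list(caches = caches, groups = groups,
                               cig = cig, cog = cog, k = k, d = d))
}

conv2d_grouped_bw <- function(p, cache, gout) {
  if (is.null(cache$groups)) return(conv2d_bw(p, cache, gout))
  g_ <- cache$groups; cig <- cache$cig; cog <- cache$cog; k <- cache$k
  gx <- array(0, cache$d)
  gw <- array(0, dim(p$w)); gb <- if (!is.null(p$b)) numeric(length(p$b))
  for (g in seq_len(g_)) {
    ci <- (g - 1) * cig + seq_len(cig); co <- (g - 1) * cog + seq_len(cog)
    pg <- list(w = array(p$w[, , , co], c(k, k, cig, cog)))
    if (!is.null(p$b)) pg$b <- p$b[co]
    r <- conv2d_bw(pg, cache$caches[[g]], gout[, , co, , drop = FALSE])
    gx[, , ci, ] <- r$gx
    gw[, , , co] <- r$grads$w
    if (!is.null(gb)) gb[co] <- r$grads$b
  }
  grads <- list(w = gw); if (!is.null(gb)) grads$b <- gb
  list(gx = gx, grads = grads)
}

# Transposed convolution, kernel k, stride k (the U-Net upsampling case).
# Weight layout: dim c(k, k, cout, cin).
convt2d_init <- function(k, cin, cout, bias = TRUE) {
  p <- list(w = init_array(c(k, k, cout, cin), fan_in = cin))
  if (bias) p$b <- numeric(cout)
  p
}

convt2d_fw <- function(x, p) {
  d <- dim(x); k <- dim(p$w)[1]; cout <- dim(p$w)[3]; cin <- dim(p$w)[4]
  stopifnot(d[3] == cin)
  xm <- matrix(aperm(x, c(1, 2, 4, 3)), d[1] * d[2] * d[4], cin)
  wm <- matrix(p$w, k * k * cout, cin)
  cols <- xm %*% t(wm)
  ho <- d[1] * k; wo <- d[2] * k
  out <- col2im_nchw(cols, ho, wo, cout, d[4], k, k, 0L, 1L)
  dim(out) <- c(ho, wo, cout, d[4])
  if (!is.null(p$b)) out <- out + bcast_c(p$b, dim(out))
  list(out = out, cache = list(x = x))
}

convt2d_bw <- function(p, cache, gout) {
  x <- cache$x; d <- dim(x)
  k <- dim(p$w)[1]; cout <- dim(p$w)[3]; cin <- dim(p$w)[4]
  go <- dim(gout)
  gcols <- im2col_nchw(gout, go[1], go[2], cout, go[4], k, k, 0L, 1L)
  wm <- matrix(p$w, k * k * cout, cin)
  gxm <- gcols %*% wm
  gx <- aperm(array(gxm, c(d[1], d[2], d[4], cin)), c(1, 2, 4, 3))
  xm <- matrix(aperm(x, c(1, 2, 4, 3)), d[1] * d[2] * d[4], cin)
  gw <- array(crossprod(gcols, xm), dim(p$w))
  grads <- list(w = gw)
  if (!is.null(p$b)) grads$b <- channel_sums(gout)
  list(gx = gx, grads = grads)
}

maxpool2_fw <- function(x) {
  d <- dim(x)
  r <- maxpool2_nchw(x, d[1], d[2], d[3], d[4])
  out <- r$out
  dim(out) <- c(d[1] %/% 2L, d[2] %/% 2L, d[3], d[4])
  list(out = out, cache = list(idx = r$idx, len = length(x), d = d))
}

maxpool2_bw <- function(cache, gout) {
  g <- maxpool2_back(gout, cache$idx, cache$len)
  dim(g) <- cache$d
  g
}

# Batch normalization over (H, W, N) per channel.  Running statistics live in
# the model's buffer environment under `path`; training mode uses batch
# statistics and updates the buffers, eval mode reads the buffers.
bn_init <- function(c) list(g = rep(1, c), b = numeric(c))

bn_buffers_init <- function(ctx, path, c) {
  if (is.null(ctx$buffers[[path]]))
    ctx$buffers[[path]] <- list(rm = numeric(c), rv = rep(1, c))
  invisible(NULL)
}

bn_fw <- function(x, p, ctx, path, eps = 1e-5, momentum = 0.1) {
  d <- dim(x); hw <- d[1] * d[2]; m <- hw * d[4]
  bn_buffers_init(ctx, path, d[3])
  if (isTRUE(ctx$training)) {
    st <- chan_stats(x, hw, d[3], d[4])
    mu <- st$mu; v <- st$var
    buf <- ctx$buffers[[path]]
    buf$rm <- (1 - momentum) * buf$rm + momentum * mu
    buf$rv <- (1 - momentum) * buf$rv + momentum * v * m / max(1, m - 1)
    ctx$buffers[[path]] <- buf
  } else {
    buf <- ctx$buffers[[path]]
    mu <- buf$rm; v <- buf$rv
  }
  invstd <- 1 / sqrt(v + eps)
  out <- bn_apply(x, hw, d[3], d[4], p$g, p$b, mu, invstd)
  dim(out) <- d
  list(out = out, cache = list(x = x, mu = mu, invstd = invstd,
                               training = isTRUE(ctx$training)))
}

bn_bw <- function(p, cache, gout) {
  d <- dim(gout)
  r <- bn_backward(cache$x, gout, d[1] * d[2], d[3], d[4],
                   p$g, cache$mu, cache$invstd, cache$training)
  gx <- r$gx
  dim(gx) <- d
  list(gx = gx, grads = list(g = r$gg, b = r$gb))
}

# Group normalization (per sample, per channel group over H, W).
gn_init <- function(c) list(g = rep(1, c), b = numeric(c))

gn_fw <- function(x, p, groups, eps = 1e-5) {
  d <- dim(x); cg <- d[3] %/% groups
  stopifnot(d[3] %% groups == 0)
  xg <- array(x, c(d[1] * d[2] * cg, groups, d[4]))
  mu <- colMeans(xg)
  xc <- xg - rep(mu, each = d[1] * d[2] * cg)
  v <- colMeans(xc * xc)
  invstd <- 1 / sqrt(v + eps)
  xhat <- array(xc * rep(invstd, each = d[1] * d[2] * cg), d)
  out <- xhat * bcast_c(p$g, d) + bcast_c(p$b, d)
  list(out = out,
       cache = list(xhat = xhat, invstd = invstd, groups = groups, d = d))
}

gn_bw <- function(p, cache, gout) {
  d <- cache$d; groups <- cache$groups; cg <- d[3] %/% groups
  m <- d[1] * d[2] * cg
  xhat <- cache$xhat
  gg <- channel_sums(gout * xhat)
  gb <- channel_sums(gout)
  gxh <- gout * bcast_c(p$g, d)
  gxg <- array(gxh, c(m, groups, d[4]))
  xhg <- array(xhat, c(m, groups, d[4]))
  s1 <- colSums(gxg); s2 <- colSums(gxg * xhg)
  gx <- (gxg - rep(s1, each = m) / m - xhg * rep(s2, each = m) / m) *
    rep(cache$invstd, each = m)
  list(gx = array(gx, d), grads = list(g = gg, b = gb))
}

relu_fw <- function(x) {
  out <- relu_fwd(x)
  dim(out) <- dim(x)
  list(out = out, cache = out)
}
relu_bw <- function(cache, gout) {
  g <- relu_bwd(gout, cache)
  dim(g) <- dim(gout)
  g
}

gelu_fw <- function(x) {
  ph <- stats::pnorm(x)
  list(out = x * ph, cache = list(x = x, ph = ph))
}
gelu_bw <- function(cache, gout)
  gout * (cache$ph + cache$x * stats::dnorm(cache$x))

sigmoid_fw <- function(x) {
  s <- 1 / (1 + exp(-x))
  list(out = s, cache = s)
}
sigmoid_bw <- function(cache, gout) gout * cache * (1 - cache)

# Nearest-neighbour upsampling by an integer factor.
upsample_nearest_fw <- function(x, factor = 2L) {
  d <- dim(x)
  ri <- rep(seq_len(d[1]), each = factor)
  ci <- rep(seq_len(d[2]), each = factor)
  list(out = x[ri, ci, , , drop = FALSE], cache = list(d = d, factor = factor))
}

upsample_nearest_bw <- function(cache, gout) {
  d <- cache$d; f <- cache$factor
  g <- array(gout, c(f, d[1], f, d[2], d[3], d[4]))
  array(colSums(aperm(g, c(1, 3, 2, 4, 5, 6)), dims = 2), d)
}

# Token helpers: tokens are (L, C, N) arrays.
tok2mat <- function(x) {
  d <- dim(x)
  matrix(aperm(x, c(1, 3, 2)), d[1] * d[3], d[2])
}
mat2tok <- function(m, L, N) {
  aperm(array(m, c(L, N, ncol(m))), c(1, 3, 2))
}

linear_init <- function(cin, cout) {
  list(w = init_array(c(cin, cout), fan_in = cin), b = numeric(cout))
}

linear_fw <- function(x, p) {
  d <- dim(x)
  m <- tok2mat(x) %*% p$w
  m <- sweep(m, 2, p$b, "+")
  list(out = mat2tok(m, d[1], d[3]), cache = list(x = x))
}

linear_bw <- function(p, cache, gout) {
  d <- dim(cache$x)
  gm <- tok2mat(gout)
  xm <- tok2mat(cache$x)
  list(gx = mat2tok(gm %*% t(p$w), d[1], d[3]),
       grads = list(w = crossprod(xm, gm), b = colSums(gm)))
}

ln_init <- function(c) list(g = rep(1, c), b = numeric(c))

# Layer norm over the channel dimension of (L, C, N) tokens.
ln_fw <- function(x, p, eps = 1e-6) {
  d <- dim(x)
  xp <- aperm(x, c(2, 1, 3))                      # (C, L*N)
  xm <- matrix(xp, d[2], d[1] * d[3])
  mu <- colMeans(xm)
  xc <- sweep(xm, 2, mu)
  v <- colMeans(xc * xc)
  invstd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2, invstd, "*")
  out <- aperm(array(xhat * p$g + p$b, c(d[2], d[1], d[3])), c(2, 1, 3))
  list(out = out, cache = list(xhat = xhat, invstd = invstd, d = d))
}

ln_bw <- function(p, cache, gout) {
  d <- cache$d; C <- d[2]
  gm <- matrix(aperm(gout, c(2, 1, 3)), C, d[1] * d[3])
  xhat <- cache$xhat
  gg <- rowSums(gm * xhat); gb <- rowSums(gm)
  gxh <- gm * p$g
  s1 <- colSums(gxh); s2 <- colSums(gxh * xhat)
  gx <- sweep(gxh - rep(s1, each = C) / C - sweep(xhat, 2, s2 / C, "*"),
              2, cache$invstd, "*")
  list(gx = aperm(array(gx, c(C, d[1], d[3])), c(2, 1, 3)),
       grads = list(g = gg, b = gb))
}

# Reshape (H,W,C,N) logits to a (H*W*N, C) matrix with classes as columns,
# and back.  Used by the softmax losses and by prediction binarization.
chan_mat <- function(z) {
  d <- dim(z)
  nchw_to_pm(z, d[1] * d[2], d[3], d[4])
}

mat_chan <- function(m, d) {
  array(pm_to_nchw(m, d[1] * d[2], d[3], d[4]), d)
}

# Row-wise numerically stable softmax of a (pixels, classes) matrix.
softmax_rows <- function(m) {
  mx <- m[, 1]
  for (k in seq_len(ncol(m))[-1]) mx <- pmax(mx, m[, k])
  e <- exp(m - mx)
  e / rowSums(e)
}
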