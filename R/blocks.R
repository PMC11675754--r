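# Composite network blocks.
#
# `ctx` is a list carrying the mutable buffer environment and the training
# flag; `path` namespaces batch-norm running statistics within it.

# ---- decoder double-conv block: ReLU(BN(Conv(ReLU(BN(Conv(x)))))) ----------

dc_init <- function(cin, cout) {
  list(conv1 = conv2d_init(3, cin, cout),
       bn1 = bn_init(cout),
       conv2 = conv2d_init(3, cout, cout),
       bn2 = bn_init(cout))
}

dc_fw <- function(x, p, ctx, path) {
  c1 <- conv2d_fw(x, p$conv1, pad = 1L)
  b1 <- bn_fw(c1$out, p$bn1, ctx, paste0(path, ".bn1"))
  r1 <- relu_fw(b1$out)
  c2 <- conv2d_fw(r1$out, p$conv2, pad = 1L)
  b2 <- bn_fw(c2$out, p$bn2, ctx, paste0(path, ".bn2"))
  r2 <- relu_fw(b2$out)
  list(out = r2$out,
       cache = list(c1 = c1$cache, b1 = b1$cache, r1 = r1$cache,
                    c2 = c2$cache, b2 = b2$cache, r2 = r2$cache))
}

dc_bw <- function(p, cache, gout) {
  g <- relu_bw(cache$r2, gout)
  b2 <- bn_bw(p$bn2, cache$b2, g)
  c2 <- conv2d_bw(p$conv2, cache$c2, b2$gx)
  g <- relu_bw(cache$r1, c2$gx)
  b1 <- bn_bw(p$bn1, cache$b1, g)
  c1 <- conv2d_bw(p$conv1, cache$c1, b1$gx)
  list(gx = c1$gx,
       grads = list(conv1 = c1$grads, bn1 = b1$grads,
                    conv2 = c2$grads, bn2 = b2$grads))
}

# ---- bottleneck adapter: GeLU(up(GeLU(down(x)))) on (L, C, N) tokens -------

adapter_init <- function(c, ratio = 0.25) {
  m <- max(1L, floor(c * ratio))
  list(down = linear_init(c, m), up = linear_init(m, c))
}

adapter_fw <- function(x, p) {
  d <- linear_fw(x, p$down)
  g1 <- gelu_fw(d$out)
  u <- linear_fw(g1$out, p$up)
  g2 <- gelu_fw(u$out)
  list(out = g2$out,
       cache = list(d = d$cache, g1 = g1$cache, u = u$cache, g2 = g2$cache))
}

adapter_bw <- function(p, cache, gout) {
  g <- gelu_bw(cache$g2, gout)
  u <- linear_bw(p$up, cache$u, g)
  g <- gelu_bw(cache$g1, u$gx)
  d <- linear_bw(p$down, cache$d, g)
  list(gx = d$gx, grads = list(down = d$grads, up = u$grads))
}

# ---- basic conv unit: conv (no bias) + BN + ReLU ---------------------------

bc_init <- function(k, cin, cout) {
  list(conv = conv2d_init(k, cin, cout), bn = bn_init(cout))
}

bc_fw <- function(x, p, ctx, path, pad = 0L, dil = 1L, act = TRUE) {
  cv <- conv2d_fw(x, p$conv, pad = pad, dil = dil)
  bn <- bn_fw(cv$out, p$bn, ctx, paste0(path, ".bn"))
  if (act) {
    r <- relu_fw(bn$out)
    out <- r$out; rc <- r$cache
  } else { out <- bn$out; rc <- NULL }
  list(out = out, cache = list(cv = cv$cache, bn = bn$cache, r = rc,
                               pad = pad, dil = dil))
}

bc_bw <- function(p, cache, gout) {
  if (!is.null(cache$r)) gout <- relu_bw(cache$r, gout)
  bn <- bn_bw(p$bn, cache$bn, gout)
  cv <- conv2d_bw(p$conv, cache$cv, bn$gx)
  list(gx = cv$gx, grads = list(conv = cv$grads, bn = bn$grads))
}

# ---- receptive-field block: four dilated branches + fused residual --------

RFB_DILATIONS <- c(1L, 3L, 5L, 7L)

rfb_init <- function(cin, cout) {
  if (cout <= 0) stop("rfb: out_channels must be positive", call. = FALSE)
  if (cin < 4) stop("rfb: needs at least 4 input channels", call. = FALSE)
  br <- lapply(RFB_DILATIONS, function(d)
    list(red = bc_init(1, cin, cout), dconv = bc_init(3, cout, cout)))
  names(br) <- paste0("br", seq_along(RFB_DILATIONS))
  c(br, list(fuse = bc_init(3, 4 * cout, cout), res = bc_init(1, cin, cout)))
}

rfb_fw <- function(x, p, ctx, path) {
  d <- dim(x); cout <- dim(p$res$conv$w)[4]
  bouts <- vector("list", 4); bcaches <- vector("list", 4)
  for (i in 1:4) {
    rd <- bc_fw(x, p[[paste0("br", i)]]$red, ctx, paste0(path, ".br", i, ".red"))
    dv <- bc_fw(rd$out, p[[paste0("br", i)]]$dconv, ctx,
                paste0(path, ".br", i, ".dconv"),
                pad = RFB_DILATIONS[i], dil = RFB_DILATIONS[i])
    bouts[[i]] <- dv$out
    bcaches[[i]] <- list(red = rd$cache, dconv = dv$cache)
  }
  cat_ <- array(0, c(d[1], d[2], 4 * cout, d[4]))
  for (i in 1:4) cat_[, , (i - 1) * cout + seq_len(cout), ] <- bouts[[i]]
  fu <- bc_fw(cat_, p$fuse, ctx, paste0(path, ".fuse"), pad = 1L, act = FALSE)
  rs <- bc_fw(x, p$res, ctx, paste0(path, ".res"), act = FALSE)
  r <- relu_fw(fu$out + rs$out)
  list(out = r$out,
       cache = list(br = bcaches, fuse = fu$cache, res = rs$cache,
                    r = r$cache, cout = cout))
}

rfb_bw <- function(p, cache, gout) {
  g <- relu_bw(cache$r, gout)
  fu <- bc_bw(p$fuse, cache$fuse, g)
  rs <- bc_bw(p$res, cache$res, g)
  cout <- cache$cout
  grads <- list(fuse = fu$grads, res = rs$grads)
  gx <- rs$gx
  for (i in 1:4) {
    gb <- fu$gx[, , (i - 1) * cout + seq_len(cout), , drop = FALSE]
    dv <- bc_bw(p[[paste0("br", i)]]$dconv, cache$br[[i]]$dconv, gb)
    rd <- bc_bw(p[[paste0("br", i)]]$red, cache$br[[i]]$red, dv$gx)
    gx <- gx + rd$gx
    grads[[paste0("br", i)]] <- list(red = rd$grads, dconv = dv$grads)
  }
  list(gx = gx, grads = grads)
}

# Effective receptive field of branch i (1x1 reduce then 3x3 dilated conv).
rfb_branch_receptive_field <- function(i) 1L + 2L * RFB_DILATIONS[i]

# ---- SRU: spatial reconstruction unit --------------------------------------

sru_init <- function(c) list(gn = gn_init(c))

# Normalized group-norm scale weights (the channel informativeness scores).
sru_weights <- function(p) p$gn$g / sum(p$gn$g)

sru_fw <- function(x, p, groups = 4L, threshold = 0.5) {
  d <- dim(x)
  if (d[3] %% 2L != 0L) stop("sru: channel count must be even", call. = FALSE)
  gn <- gn_fw(x, p$gn, groups)
  w <- sru_weights(p)
  rw <- 1 / (1 + exp(-gn$out * bcast_c(w, d)))
  info <- rw >= threshold
  x1 <- gn$out * info
  x2 <- gn$out * !info
  h <- d[3] %/% 2L
  lo <- seq_len(h); hi <- h + lo
  out <- array(0, d)
  out[, , lo, ] <- x1[, , lo, , drop = FALSE] + x2[, , hi, , drop = FALSE]
  out[, , hi, ] <- x1[, , hi, , drop = FALSE] + x2[, , lo, , drop = FALSE]
  list(out = out, cache = list(gn = gn$cache, info = info, h = h, d = d))
}

sru_bw <- function(p, cache, gout) {
  d <- cache$d; h <- cache$h
  lo <- seq_len(h); hi <- h + lo
  g1 <- array(0, d); g2 <- array(0, d)
  g1[, , lo, ] <- gout[, , lo, , drop = FALSE]
  g2[, , hi, ] <- gout[, , lo, , drop = FALSE]
  g1[, , hi, ] <- gout[, , hi, , drop = FALSE]
  g2[, , lo, ] <- gout[, , hi, , drop = FALSE]
  ggn <- g1 * cache$info + g2 * !cache$info
  b <- gn_bw(p$gn, cache$gn, ggn)
  list(gx = b$gx, grads = list(gn = b$grads))
}

# ---- CRU: channel reconstruction unit --------------------------------------

cru_init <- function(c, split_ratio = 0.5, squeeze = 2L, groups = 2L) {
  if (split_ratio <= 0 || split_ratio >= 1)
    stop("cru: split ratio must lie in (0,1)", call. = FALSE)
  if (c < 2) stop("cru: needs at least 2 channels", call. = FALSE)
  up <- max(1L, round(c * split_ratio)); low <- c - up
  squ <- max(1L, up %/% squeeze); sql <- max(1L, low %/% squeeze)
  g <- if (squ %% groups == 0L && c %% groups == 0L) groups else 1L
  list(sq1 = conv2d_init(1, up, squ),
       gwc = list(w = init_array(c(3, 3, squ %/% g, c), fan_in = 9 * squ %/% g)),
       pwc1 = conv2d_init(1, squ, c),
       sq2 = conv2d_init(1, low, sql),
       pwc2 = conv2d_init(1, sql, c - sql))
}

cru_dims <- function(p) {
  up <- dim(p$sq1$w)[3]; low <- dim(p$sq2$w)[3]
  list(up = up, low = low, c = dim(p$pwc1$w)[4],
       squ = dim(p$sq1$w)[4], sql = dim(p$sq2$w)[4],
       g = dim(p$sq1$w)[4] %/% dim(p$gwc$w)[3])
}

cru_fw <- function(x, p) {
  d <- dim(x); dm <- cru_dims(p)
  stopifnot(d[3] == dm$up + dm$low)
  up <- x[, , seq_len(dm$up), , drop = FALSE]
  low <- x[, , dm$up + seq_len(dm$low), , drop = FALSE]
  s1 <- conv2d_fw(up, p$sq1)
  s2 <- conv2d_fw(low, p$sq2)
  gw <- conv2d_grouped_fw(s1$out, p$gwc, groups = dm$g, pad = 1L)
  pw1 <- conv2d_fw(s1$out, p$pwc1)
  y1 <- gw$out + pw1$out
  pw2 <- conv2d_fw(s2$out, p$pwc2)
  y2 <- array(0, dim(y1))
  y2[, , seq_len(dm$c - dm$sql), ] <- pw2$out
  y2[, , dm$c - dm$sql + seq_len(dm$sql), ] <- s2$out
  hw <- d[1] * d[2]
  m1 <- matrix(colSums(matrix(y1, hw, dm$c * d[4])), dm$c, d[4]) / hw
  m2 <- matrix(colSums(matrix(y2, hw, dm$c * d[4])), dm$c, d[4]) / hw
  a1 <- 1 / (1 + exp(m2 - m1))             # pairwise softmax over the streams
  a1b <- array(rep(as.vector(a1), each = hw), dim(y1))
  out <- a1b * y1 + (1 - a1b) * y2
  list(out = out,
       cache = list(s1 = s1$cache, s2 = s2$cache, gw = gw$cache,
                    pw1 = pw1$cache, pw2 = pw2$cache,
                    y1 = y1, y2 = y2, a1 = a1, dm = dm, d = d))
}

cru_bw <- function(p, cache, gout) {
  d <- cache$d; dm <- cache$dm; hw <- d[1] * d[2]
  a1b <- array(rep(as.vector(cache$a1), each = hw), dim(cache$y1))
  ga1 <- matrix(colSums(matrix(gout * (cache$y1 - cache$y2),
                               hw, dm$c * d[4])), dm$c, d[4])
  gm <- ga1 * cache$a1 * (1 - cache$a1) / hw
  gmb <- array(rep(as.vector(gm), each = hw), dim(cache$y1))
  gy1 <- a1b * gout + gmb
  gy2 <- (1 - a1b) * gout - gmb
  pw2 <- conv2d_bw(p$pwc2, cache$pw2,
                   gy2[, , seq_len(dm$c - dm$sql), , drop = FALSE])
  gs2 <- pw2$gx + gy2[, , dm$c - dm$sql + seq_len(dm$sql), , drop = FALSE]
  s2 <- conv2d_bw(p$sq2, cache$s2, gs2)
  gw <- conv2d_grouped_bw(p$gwc, cache$gw, gy1)
  pw1 <- conv2d_bw(p$pwc1, cache$pw1, gy1)
  s1 <- conv2d_bw(p$sq1, cache$s1, gw$gx + pw1$gx)
  gx <- array(0, d)
  gx[, , seq_len(dm$up), ] <- s1$gx
  gx[, , dm$up + seq_len(dm$low), ] <- s2$gx
  list(gx = gx,
       grads = list(sq1 = s1$grads, gwc = gw$grads, pwc1 = pw1$grads,
                    sq2 = s2$grads, pwc2 = pw2$grads))
}

# ---- gated attention on skip connections -----------------------------------

gate_init <- function(cs, cd, cm = NULL) {
  if (is.null(cm)) cm <- max(1L, cd %/% 2L)
  list(ws = conv2d_init(1, cs, cm, bias = TRUE),
       wd = conv2d_init(1, cd, cm, bias = TRUE),
       wr = conv2d_init(1, cm, 1L, bias = TRUE))
}

# Literal gating rule: sigmoid(W_R ReLU(W_S x_s + W_D x_d)) applied
# elementwise to `target` ("decoder": x_d, "skip": x_s).  x_d is upsampled to
# the skip resolution first when the grids differ.
gate_fw <- function(xs, xd, p, target = c("decoder", "skip")) {
  target <- match.arg(target)
  ds <- dim(xs); dd <- dim(xd)
  up <- NULL
  if (ds[1] != dd[1]) {
    f <- ds[1] %/% dd[1]
    stopifnot(ds[1] == dd[1] * f, ds[2] == dd[2] * f)
    up <- upsample_nearest_fw(xd, f)
    xd <- up$out
  }
  if (dim(p$ws$w)[3] != ds[3] || dim(p$wd$w)[3] != dim(xd)[3])
    stop("gate: channel mismatch with parameters", call. = FALSE)
  cs <- conv2d_fw(xs, p$ws)
  cd <- conv2d_fw(xd, p$wd)
  r <- relu_fw(cs$out + cd$out)
  cr <- conv2d_fw(r$out, p$wr)
  sg <- sigmoid_fw(cr$out)
  tgt <- if (target == "decoder") xd else xs
  gb <- array(apply(array(sg$out, c(ds[1] * ds[2], ds[4])), 2,
                    function(col) rep(col, dim(tgt)[3])), dim(tgt))
  out <- gb * tgt
  list(out = out, gate = sg$out,
       cache = list(cs = cs$cache, cd = cd$cache, r = r$cache,
                    cr = cr$cache, sg = sg$cache, gb = gb, tgt = tgt,
                    target = target, up = up, xs = xs, xd = xd))
}

gate_bw <- function(p, cache, gout) {
  tgt <- cache$tgt; gb <- cache$gb
  d <- dim(tgt); hw <- d[1] * d[2]
  gtgt <- gb * gout
  # gradient wrt the 1-channel gate map: sum over target channels
  gg <- gout * tgt
  ggate <- array(rowSums(matrix(aperm(gg, c(1, 2, 4, 3)), hw * d[4], d[3])),
                 c(d[1], d[2], 1, d[4]))
  sg <- sigmoid_bw(cache$sg, ggate)
  cr <- conv2d_bw(p$wr, cache$cr, sg)
  r <- relu_bw(cache$r, cr$gx)
  cs <- conv2d_bw(p$ws, cache$cs, r)
  cd <- conv2d_bw(p$wd, cache$cd, r)
  gxs <- cs$gx; gxd <- cd$gx
  if (cache$target == "decoder") gxd <- gxd + gtgt else gxs <- gxs + gtgt
  if (!is.null(cache$up)) gxd <- upsample_nearest_bw(cache$up$cache, gxd)
  list(gxs = gxs, gxd = gxd,
       grads = list(ws = cs$grads, wd = cd$grads, wr = cr$grads))
}
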