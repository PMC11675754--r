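# Hierarchical four-stage image encoder (Hiera-style trunk) with bottleneck
# adapters inserted before the transformer blocks.
#
# The trunk follows the published hierarchical layout: a 7x7 stride-4 patch
# embedding, four stages of transformer blocks whose width doubles at each
# stage boundary, mask-unit windowed attention in the early stages with global
# attention later, and 2x2 max query pooling in the first block of stages
# 2-4.  The trunk is frozen by default; only the adapters train.

#' Encoder configuration
#'
#' Describes the hierarchical trunk: embedding width, per-stage depths, head
#' counts, adapter bottleneck ratio and placement, attention window sizes and
#' the freezing policy.  Stage channels are `embed_dim * 2^(i-1)`; stage `i`
#' features have spatial size `(H/2^(i+1), W/2^(i+1))`.
#'
#' @param variant `"large"` (embed 144, depths 2/6/36/4 — the published
#'   large trunk) or `"tiny"` (embed 8, depths 1/1/1/1, for tests and CPU
#'   training).
#' @param embed_dim,stage_depths,heads0,pos_grid overrides of the variant
#'   presets: stage-1 channel count, the four stage depths, stage-1 attention
#'   head count, and the side of the stored positional-embedding grid
#'   (interpolated to other input sizes).
#' @param adapter_ratio bottleneck fraction of the adapter (down-projection
#'   width = `floor(C * adapter_ratio)`).
#' @param adapter_placement `"per_block"` inserts an adapter before every
#'   transformer block; `"per_stage"` only before the first block of each
#'   stage.
#' @param window_sizes attention window (in tokens, on the pre-pool grid) per
#'   stage; `0` means global attention.
#' @param freeze `"trunk"` freezes everything but the adapters; `"none"`
#'   trains all parameters.
#' @param classes class count of the published classification head; only used
#'   by [count_trunk_parameters()] when `include_classifier = TRUE`.
#' @return An object of class `encoder_config`.
#' @export
encoder_config <- function(variant = c("large", "tiny"),
                           embed_dim = NULL, stage_depths = NULL,
                           heads0 = NULL, pos_grid = NULL,
                           adapter_ratio = 0.25,
                           adapter_placement = c("per_block", "per_stage"),
                           window_sizes = c(8L, 8L, 0L, 0L),
                           freeze = c("trunk", "none"),
                           mlp_ratio = 4L, classes = 1000L) {
  variant <- match.arg(variant)
  preset <- switch(variant,
    large = list(embed_dim = 144L, stage_depths = c(2L, 6L, 36L, 4L),
                 heads0 = 2L, pos_grid = 56L),
    tiny  = list(embed_dim = 8L, stage_depths = c(1L, 1L, 1L, 1L),
                 heads0 = 1L, pos_grid = 16L))
  cfg <- list(
    variant = variant,
    embed_dim = as.integer(embed_dim %||% preset$embed_dim),
    stage_depths = as.integer(stage_depths %||% preset$stage_depths),
    heads0 = as.integer(heads0 %||% preset$heads0),
    pos_grid = as.integer(pos_grid %||% preset$pos_grid),
    adapter_ratio = adapter_ratio,
    adapter_placement = match.arg(adapter_placement),
    window_sizes = as.integer(window_sizes),
    freeze = match.arg(freeze),
    mlp_ratio = as.integer(mlp_ratio),
    classes = as.integer(classes),
    patch_stride = 4L)
  stopifnot(length(cfg$stage_depths) == 4, all(cfg$stage_depths >= 1))
  cfg$dims <- as.integer(cfg$embed_dim * 2L^(0:3))
  cfg$heads <- as.integer(cfg$heads0 * 2L^(0:3))
  structure(cfg, class = "encoder_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Per-block layout table: stage, input/output dims, transition flag, heads,
# window size, adapter presence.
encoder_layout <- function(cfg) {
  rows <- list()
  for (s in 1:4) for (b in seq_len(cfg$stage_depths[s])) {
    transition <- (s > 1 && b == 1)
    din <- if (transition) cfg$dims[s - 1] else cfg$dims[s]
    adapter <- (cfg$adapter_placement == "per_block") || b == 1L
    rows[[length(rows) + 1]] <- data.frame(
      stage = s, block = b, din = din, dout = cfg$dims[s],
      transition = transition, heads = cfg$heads[s],
      window = cfg$window_sizes[s], adapter = adapter)
  }
  do.call(rbind, rows)
}

#' Expected feature-pyramid geometry for an input size
#'
#' Pure shape arithmetic: stage `i` of the encoder emits `embed_dim * 2^(i-1)`
#' channels at spatial size `(H / 2^(i+1), W / 2^(i+1))`.
#'
#' @param config an [encoder_config()].
#' @param height,width input image size; must be divisible by 32.
#' @return data.frame with columns `stage`, `channels`, `height`, `width`.
#' @export
pyramid_shapes <- function(config, height, width = height) {
  if (height %% 32L != 0L || width %% 32L != 0L)
    stop("input height and width must be divisible by 32", call. = FALSE)
  data.frame(stage = 1:4, channels = config$dims,
             height = as.integer(height %/% 2^(2:5)),
             width = as.integer(width %/% 2^(2:5)))
}

#' Build the encoder (trunk + adapters)
#'
#' Allocates trunk and adapter weights and applies the configured freezing
#' policy.  The trunk weights are randomly initialized; a checkpoint-import
#' hook for externally released trunk weights can be layered on top by
#' assigning into `$params` by name.
#'
#' @param config an [encoder_config()].
#' @param seed integer seed for weight initialization.
#' @return An object of class `panseg_encoder`.
#' @export
encoder_init <- function(config, seed = 0L) {
  layout <- encoder_layout(config)
  params <- with_seed(seed, {
    p <- list(
      patch = conv2d_init(7, 3L, config$embed_dim, bias = TRUE),
      pos = init_array(c(config$pos_grid, config$pos_grid, config$embed_dim),
                       fan_in = config$pos_grid^2))
    p$blocks <- lapply(seq_len(nrow(layout)), function(i) {
      row <- layout[i, ]
      b <- list(
        norm1 = ln_init(row$din),
        qkv = linear_init(row$din, 3L * row$dout),
        proj = linear_init(row$dout, row$dout),
        norm2 = ln_init(row$dout),
        mlp = list(fc1 = linear_init(row$dout, config$mlp_ratio * row$dout),
                   fc2 = linear_init(config$mlp_ratio * row$dout, row$dout)))
      if (row$transition) b$resproj <- linear_init(row$din, row$dout)
      if (row$adapter) b$adapter <- adapter_init(row$din, config$adapter_ratio)
      b
    })
    names(p$blocks) <- sprintf("b%02d", seq_len(nrow(layout)))
    p
  })
  model <- structure(
    list(config = config, layout = layout, params = params,
         buffers = new.env(parent = emptyenv())),
    class = "panseg_encoder")
  set_freeze_policy(model, config$freeze)
}

#' Apply the trunk-freezing policy
#'
#' Marks trunk parameters (patch embedding, positional embedding, every
#' transformer-block weight) as frozen so optimization updates skip them;
#' adapters remain trainable.  With `freeze = "none"` everything trains.
#'
#' @param model a `panseg_encoder` or a model containing one under
#'   `$params$encoder`.
#' @param freeze `"trunk"` or `"none"`.
#' @return the model with freeze attributes set.
#' @export
set_freeze_policy <- function(model, freeze = c("trunk", "none")) {
  freeze <- match.arg(freeze)
  enc_path <- if (inherits(model, "panseg_encoder")) "params" else
    c("params", "encoder")
  p <- model[[enc_path]]
  p <- mark_frozen(p, freeze == "trunk")
  if (freeze == "trunk") {
    for (i in seq_along(p$blocks)) {
      if (!is.null(p$blocks[[i]]$adapter))
        p$blocks[[i]]$adapter <- mark_frozen(p$blocks[[i]]$adapter, FALSE)
    }
  }
  model[[enc_path]] <- p
  if (inherits(model, "panseg_encoder")) model$config$freeze <- freeze
  model
}

# ---- attention -------------------------------------------------------------

# Window index sets for an (h, w) token grid.  A window size of 0, or one
# that does not tile the grid, falls back to a single global window.
window_indices <- function(h, w, ws) {
  if (ws <= 0L || h < ws || w < ws || h %% ws != 0L || w %% ws != 0L)
    return(list(seq_len(h * w)))
  out <- list()
  for (wb in seq_len(w %/% ws)) for (hb in seq_len(h %/% ws)) {
    rows <- (hb - 1L) * ws + seq_len(ws)
    cols <- (wb - 1L) * ws + seq_len(ws)
    out[[length(out) + 1]] <- as.vector(outer(rows, cols,
                                              function(r, c) r + (c - 1L) * h))
  }
  out
}

# Multi-head (optionally windowed, optionally query-pooled) attention on
# (L, C, N) tokens laid out on an (h, w) grid.
attention_fw <- function(xn, pb, h, w, heads, window, qpool) {
  qkv <- linear_fw(xn, pb$qkv)
  dout <- dim(pb$proj$w)[1]
  dh <- dout %/% heads
  q <- qkv$out[, seq_len(dout), , drop = FALSE]
  k <- qkv$out[, dout + seq_len(dout), , drop = FALSE]
  v <- qkv$out[, 2L * dout + seq_len(dout), , drop = FALSE]
  pool_cache <- NULL
  hq <- h; wq <- w
  if (qpool) {
    d <- dim(q)
    qg <- array(q, c(h, w, dout, d[3]))
    mp <- maxpool2_fw(qg)
    pool_cache <- mp$cache
    hq <- h %/% 2L; wq <- w %/% 2L
    q <- array(mp$out, c(hq * wq, dout, d[3]))
  }
  kv_win <- window_indices(h, w, window)
  q_win <- if (qpool && length(kv_win) > 1L)
    window_indices(hq, wq, window %/% 2L) else if (length(kv_win) > 1L)
    kv_win else list(seq_len(hq * wq))
  stopifnot(length(q_win) == length(kv_win))
  N <- dim(xn)[3]
  out <- array(0, c(hq * wq, dout, N))
  A_cache <- vector("list", length(kv_win) * heads * N)
  scale <- 1 / sqrt(dh)
  ci <- 0L
  for (wi in seq_along(kv_win)) {
    ki <- kv_win[[wi]]; qi <- q_win[[wi]]
    for (n in seq_len(N)) for (hd in seq_len(heads)) {
      cols <- (hd - 1L) * dh + seq_len(dh)
      Q <- q[qi, cols, n, drop = FALSE]; dim(Q) <- c(length(qi), dh)
      K <- k[ki, cols, n, drop = FALSE]; dim(K) <- c(length(ki), dh)
      V <- v[ki, cols, n, drop = FALSE]; dim(V) <- c(length(ki), dh)
      S <- tcrossprod(Q, K) * scale
      S <- S - apply(S, 1, max)
      E <- exp(S)
      A <- E / rowSums(E)
      out[qi, cols, n] <- A %*% V
      ci <- ci + 1L
      A_cache[[ci]] <- A
    }
  }
  pr <- linear_fw(out, pb$proj)
  list(out = pr$out,
       cache = list(qkv = qkv$cache, q = q, k = k, v = v,
                    A = A_cache, kv_win = kv_win, q_win = q_win,
                    heads = heads, dh = dh, dout = dout, scale = scale,
                    pool = pool_cache, h = h, w = w, hq = hq, wq = wq,
                    pre = out, pr = pr$cache))
}

attention_bw <- function(pb, cache, gout) {
  pr <- linear_bw(pb$proj, cache$pr, gout)
  gpre <- pr$gx
  N <- dim(gpre)[3]
  dh <- cache$dh; dout <- cache$dout; heads <- cache$heads
  gq <- array(0, dim(cache$q))
  gk <- array(0, dim(cache$k))
  gv <- array(0, dim(cache$v))
  ci <- 0L
  for (wi in seq_along(cache$kv_win)) {
    ki <- cache$kv_win[[wi]]; qi <- cache$q_win[[wi]]
    for (n in seq_len(N)) for (hd in seq_len(heads)) {
      cols <- (hd - 1L) * dh + seq_len(dh)
      ci <- ci + 1L
      A <- cache$A[[ci]]
      Q <- cache$q[qi, cols, n, drop = FALSE]; dim(Q) <- c(length(qi), dh)
      K <- cache$k[ki, cols, n, drop = FALSE]; dim(K) <- c(length(ki), dh)
      V <- cache$v[ki, cols, n, drop = FALSE]; dim(V) <- c(length(ki), dh)
      gO <- gpre[qi, cols, n, drop = FALSE]; dim(gO) <- c(length(qi), dh)
      gA <- tcrossprod(gO, V)
      gV <- crossprod(A, gO)
      gS <- A * (gA - rowSums(gA * A))
      gq[qi, cols, n] <- gq[qi, cols, n, drop = FALSE] +
        array(gS %*% K * cache$scale, c(length(qi), dh, 1))
      gk[ki, cols, n] <- gk[ki, cols, n, drop = FALSE] +
        array(crossprod(gS, Q) * cache$scale, c(length(ki), dh, 1))
      gv[ki, cols, n] <- gv[ki, cols, n, drop = FALSE] +
        array(gV, c(length(ki), dh, 1))
    }
  }
  if (!is.null(cache$pool)) {
    gqg <- maxpool2_bw(cache$pool, array(gq, c(cache$hq, cache$wq, dout, N)))
    gq <- array(gqg, c(cache$h * cache$w, dout, N))
  }
  gqkv <- array(0, c(cache$h * cache$w, 3L * dout, N))
  gqkv[, seq_len(dout), ] <- gq
  gqkv[, dout + seq_len(dout), ] <- gk
  gqkv[, 2L * dout + seq_len(dout), ] <- gv
  qkv <- linear_bw(pb$qkv, cache$qkv, gqkv)
  list(gx = qkv$gx, grads = list(qkv = qkv$grads, proj = pr$grads))
}

# ---- full encoder forward / backward --------------------------------------

# Nearest-neighbour index map from a stored pos grid to an (h, w) grid.
pos_index <- function(n_to, n_from) {
  pmin(n_from, floor((seq_len(n_to) - 0.5) * n_from / n_to) + 1L)
}

encoder_forward <- function(model, x, ctx) {
  cfg <- model$config; p <- model$params; layout <- model$layout
  d <- dim(x)
  if (d[1] %% 32L != 0L || d[2] %% 32L != 0L)
    stop("encoder input height/width must be divisible by 32 (got ",
         d[1], "x", d[2], ")", call. = FALSE)
  pe <- conv2d_fw(x, p$patch, stride = cfg$patch_stride, pad = 3L)
  pd <- dim(pe$out)
  h <- pd[1]; w <- pd[2]; N <- pd[4]
  tok <- array(pe$out, c(h * w, cfg$embed_dim, N))
  ih <- pos_index(h, cfg$pos_grid); iw <- pos_index(w, cfg$pos_grid)
  posg <- p$pos[ih, iw, , drop = FALSE]
  tok <- tok + array(posg, c(h * w, cfg$embed_dim, 1))[, , rep(1L, N), drop = FALSE]
  caches <- vector("list", nrow(layout))
  pyr <- vector("list", 4)
  for (i in seq_len(nrow(layout))) {
    row <- layout[i, ]
    pb <- p$blocks[[i]]
    cc <- list(h = h, w = w)
    if (!is.null(pb$adapter)) {
      ad <- adapter_fw(tok, pb$adapter)
      cc$adapter <- ad$cache
      tok <- ad$out
    }
    n1 <- ln_fw(tok, pb$norm1)
    cc$norm1 <- n1$cache
    if (row$transition) {
      rp <- linear_fw(n1$out, pb$resproj)
      rg <- array(rp$out, c(h, w, row$dout, N))
      mp <- maxpool2_fw(rg)
      shortcut <- array(mp$out, c((h %/% 2L) * (w %/% 2L), row$dout, N))
      cc$resproj <- rp$cache
      cc$respool <- mp$cache
    } else shortcut <- tok
    at <- attention_fw(n1$out, pb, h, w, row$heads, row$window, row$transition)
    cc$attn <- at$cache
    if (row$transition) { h <- h %/% 2L; w <- w %/% 2L }
    x1 <- shortcut + at$out
    n2 <- ln_fw(x1, pb$norm2)
    f1 <- linear_fw(n2$out, pb$mlp$fc1)
    ge <- gelu_fw(f1$out)
    f2 <- linear_fw(ge$out, pb$mlp$fc2)
    tok <- x1 + f2$out
    cc$norm2 <- n2$cache; cc$fc1 <- f1$cache; cc$gelu <- ge$cache
    cc$fc2 <- f2$cache
    caches[[i]] <- cc
    if (row$block == cfg$stage_depths[row$stage])
      pyr[[row$stage]] <- array(tok, c(h, w, row$dout, N))
  }
  list(pyr = pyr, cache = list(blocks = caches, patch = pe$cache,
                               ih = ih, iw = iw, hw0 = pd[1:2], d = d))
}

encoder_backward <- function(model, cache, gpyr) {
  cfg <- model$config; p <- model$params; layout <- model$layout
  grads <- list(blocks = vector("list", nrow(layout)))
  names(grads$blocks) <- names(p$blocks)
  gtok <- NULL
  for (i in rev(seq_len(nrow(layout)))) {
    row <- layout[i, ]
    pb <- p$blocks[[i]]
    cc <- cache$blocks[[i]]
    if (row$block == cfg$stage_depths[row$stage]) {
      gstage <- gpyr[[row$stage]]
      gs <- array(gstage, c(dim(gstage)[1] * dim(gstage)[2],
                            dim(gstage)[3], dim(gstage)[4]))
      gtok <- if (is.null(gtok)) gs else gtok + gs
    }
    g2 <- linear_bw(pb$mlp$fc2, cc$fc2, gtok)
    gg <- gelu_bw(cc$gelu, g2$gx)
    g1 <- linear_bw(pb$mlp$fc1, cc$fc1, gg)
    gn2 <- ln_bw(pb$norm2, cc$norm2, g1$gx)
    gx1 <- gtok + gn2$gx
    at <- attention_bw(pb, cc$attn, gx1)
    bg <- list(norm2 = gn2$grads, mlp = list(fc1 = g1$grads, fc2 = g2$grads),
               qkv = at$grads$qkv, proj = at$grads$proj)
    if (row$transition) {
      N <- dim(gx1)[3]
      gsh <- array(gx1, c(cc$h %/% 2L, cc$w %/% 2L, row$dout, N))
      grg <- maxpool2_bw(cc$respool, gsh)
      grp <- linear_bw(pb$resproj, cc$resproj,
                       array(grg, c(cc$h * cc$w, row$dout, N)))
      bg$resproj <- grp$grads
      gn1_in <- at$gx + grp$gx
      gtok <- NULL
    } else {
      gn1_in <- at$gx
      gtok_res <- gx1
    }
    gn1 <- ln_bw(pb$norm1, cc$norm1, gn1_in)
    bg$norm1 <- gn1$grads
    gtok <- if (row$transition) gn1$gx else gtok_res + gn1$gx
    if (!is.null(pb$adapter)) {
      ad <- adapter_bw(pb$adapter, cc$adapter, gtok)
      bg$adapter <- ad$grads
      gtok <- ad$gx
    }
    grads$blocks[[i]] <- bg
  }
  h <- cache$hw0[1]; w <- cache$hw0[2]
  N <- dim(gtok)[3]
  gpos <- array(0, dim(p$pos))
  gsum <- array(0, c(h * w, cfg$embed_dim))
  for (n in seq_len(N)) gsum <- gsum + gtok[, , n]
  gsum <- array(gsum, c(h, w, cfg$embed_dim))
  for (a in seq_len(h)) for (b in seq_len(w))
    gpos[cache$ih[a], cache$iw[b], ] <-
      gpos[cache$ih[a], cache$iw[b], ] + gsum[a, b, ]
  gpe <- array(gtok, c(h, w, cfg$embed_dim, N))
  pt <- conv2d_bw(p$patch, cache$patch, gpe)
  grads$patch <- pt$grads
  grads$pos <- gpos
  list(gx = pt$gx, grads = grads)
}

#' Run the encoder and return the four-level feature pyramid
#'
#' @param model a `panseg_encoder` from [encoder_init()].
#' @param x image batch, array `(H, W, 3, N)` with values in `[0, 1]`; `H`
#'   and `W` must be divisible by 32.
#' @return list of four arrays; level `i` has `embed_dim * 2^(i-1)` channels
#'   at `(H/2^(i+1), W/2^(i+1))`.
#' @export
encode <- function(model, x) {
  stopifnot(inherits(model, "panseg_encoder"))
  ctx <- list(buffers = model$buffers, training = FALSE)
  encoder_forward(model, x, ctx)$pyr
}

#' Analytic trunk parameter count
#'
#' Counts the trunk weights of an encoder configuration: patch embedding,
#' positional embedding, and all transformer-block weights.  Adapters are
#' always excluded.  `include_classifier = TRUE` (default) additionally counts
#' the final norm and classification head of the published classification
#' release of the trunk — the convention under which the widely quoted size
#' of the large variant (214 M) is reproduced; the segmentation encoder
#' itself carries no head.
#'
#' @param config an [encoder_config()].
#' @param include_classifier count the published release's final norm and
#'   `classes`-way linear head.
#' @return parameter count (double).
#' @export
count_trunk_parameters <- function(config, include_classifier = TRUE) {
  cfg <- config
  total <- 3 * cfg$embed_dim * 49 + cfg$embed_dim       # patch embed (bias)
  total <- total + cfg$pos_grid^2 * cfg$embed_dim       # positional embedding
  layout <- encoder_layout(cfg)
  for (i in seq_len(nrow(layout))) {
    row <- layout[i, ]
    din <- row$din; dout <- row$dout
    total <- total + 2 * din                            # norm1
    total <- total + din * 3 * dout + 3 * dout          # qkv
    total <- total + dout * dout + dout                 # attention proj
    total <- total + 2 * dout                           # norm2
    hid <- cfg$mlp_ratio * dout
    total <- total + dout * hid + hid + hid * dout + dout  # mlp
    if (row$transition) total <- total + din * dout + dout # residual proj
  }
  if (include_classifier) {
    total <- total + 2 * cfg$dims[4]                    # final norm
    total <- total + cfg$dims[4] * cfg$classes + cfg$classes
  }
  total
}

# Runtime parameter count of an encoder split into trunk and adapters.
encoder_param_split <- function(model) {
  fp <- flatten_params(model$params)
  ad <- grepl("\\.adapter\\.", names(fp))
  list(trunk = sum(vapply(fp[!ad], length, 0L)),
       adapters = sum(vapply(fp[ad], length, 0L)))
}

#' @export
print.panseg_encoder <- function(x, ...) {
  sp <- encoder_param_split(x)
  cat("Hierarchical encoder (", x$config$variant, " variant)\n", sep = "")
  cat("  stage channels: ", paste(x$config$dims, collapse = ", "), "\n",
      sep = "")
  cat("  depths: ", paste(x$config$stage_depths, collapse = "/"),
      "; heads: ", paste(x$config$heads, collapse = "/"), "\n", sep = "")
  cat(sprintf("  trunk params: %s (%s)\n", format(sp$trunk, big.mark = ","),
              if (identical(x$config$freeze, "trunk")) "frozen" else
                "trainable"))
  cat(sprintf("  adapter params: %s (trainable)\n",
              format(sp$adapters, big.mark = ",")))
  invisible(x)
}
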