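# Exact architecture cost accounting.
#
# Models are walked as declarative layer tables; parameters are counted
# exactly and multiply-accumulate operations (MACs) analytically for
# convolution, transposed convolution, linear and attention layers.
# Normalization and activation element operations are excluded from MACs.
# Parameter totals are reported both as learnable weights and as model state
# (learnable + batch-norm running statistics); the published baseline sizes
# (31.05 M / 0.49 M) correspond to the state convention.

cost_row <- function(name, kind, cin = 0, cout = 0, k = 0,
                     hin = 0, win = 0, hout = 0, wout = 0,
                     bias = FALSE, norm = "", groups = 1, tokens = 0,
                     macs = NA_real_, pcount = 0) {
  data.frame(name = name, kind = kind, cin = cin, cout = cout, k = k,
             hin = hin, win = win, hout = hout, wout = wout,
             bias = bias, norm = norm, groups = groups, tokens = tokens,
             macs = macs, pcount = pcount, stringsAsFactors = FALSE)
}

row_params <- function(r) {
  p <- switch(r$kind,
    conv = r$k^2 * (r$cin / r$groups) * r$cout + if (r$bias) r$cout else 0,
    convt = r$k^2 * r$cin * r$cout + if (r$bias) r$cout else 0,
    linear = r$cin * r$cout + r$cout,
    attn = 0,
    param = r$pcount,
    stop("unsupported layer kind in cost accounting: ", r$kind,
         call. = FALSE))
  buf <- 0
  if (nzchar(r$norm)) {
    p <- p + 2 * r$cout                     # affine scale + shift
    if (r$norm == "bn") buf <- 2 * r$cout   # running mean + variance
  }
  c(params = p, buffers = buf)
}

row_macs <- function(r) {
  if (!is.na(r$macs)) return(r$macs)
  switch(r$kind,
    conv = r$k^2 * (r$cin / r$groups) * r$cout * r$hout * r$wout,
    convt = r$k^2 * r$cin * r$cout * r$hin * r$win,
    linear = r$tokens * r$cin * r$cout,
    param = 0,
    stop("unsupported layer kind in cost accounting: ", r$kind,
         call. = FALSE))
}

# Double conv block rows (bias-free convs + BN).
dc_rows <- function(name, cin, cout, h, w) {
  rbind(cost_row(paste0(name, ".conv1"), "conv", cin, cout, 3,
                 h, w, h, w, norm = "bn"),
        cost_row(paste0(name, ".conv2"), "conv", cout, cout, 3,
                 h, w, h, w, norm = "bn"))
}

unet_layout_rows <- function(spec, input_size) {
  w <- spec$widths
  H <- input_size[2]; W <- input_size[3]
  rows <- dc_rows("enc1", input_size[1], w[1], H, W)
  h <- H; v <- W
  for (i in 2:4) {
    h <- h %/% 2L; v <- v %/% 2L
    rows <- rbind(rows, dc_rows(paste0("enc", i), w[i - 1], w[i], h, v))
  }
  h <- h %/% 2L; v <- v %/% 2L
  rows <- rbind(rows, dc_rows("bott", w[4], w[5], h, v))
  for (i in 4:1) {
    rows <- rbind(rows,
      cost_row(paste0("up", i), "convt", w[i + 1], w[i], 2,
               h, v, 2L * h, 2L * v, bias = TRUE))
    h <- 2L * h; v <- 2L * v
    rows <- rbind(rows, dc_rows(paste0("dec", i), 2L * w[i], w[i], h, v))
  }
  rbind(rows, cost_row("head", "conv", w[1], spec$classes, 1,
                       h, v, h, v, bias = TRUE))
}

rfb_rows <- function(name, cin, cout, h, w) {
  rows <- NULL
  for (i in 1:4) {
    rows <- rbind(rows,
      cost_row(paste0(name, ".br", i, ".red"), "conv", cin, cout, 1,
               h, w, h, w, norm = "bn"),
      cost_row(paste0(name, ".br", i, ".dconv"), "conv", cout, cout, 3,
               h, w, h, w, norm = "bn"))
  }
  rbind(rows,
        cost_row(paste0(name, ".fuse"), "conv", 4 * cout, cout, 3,
                 h, w, h, w, norm = "bn"),
        cost_row(paste0(name, ".res"), "conv", cin, cout, 1,
                 h, w, h, w, norm = "bn"))
}

cru_rows <- function(name, c, h, w) {
  up <- max(1L, round(c * 0.5)); low <- c - up
  squ <- max(1L, up %/% 2L); sql <- max(1L, low %/% 2L)
  g <- if (squ %% 2L == 0L && c %% 2L == 0L) 2L else 1L
  rbind(cost_row(paste0(name, ".sq1"), "conv", up, squ, 1, h, w, h, w),
        cost_row(paste0(name, ".gwc"), "conv", squ, c, 3, h, w, h, w,
                 groups = g),
        cost_row(paste0(name, ".pwc1"), "conv", squ, c, 1, h, w, h, w),
        cost_row(paste0(name, ".sq2"), "conv", low, sql, 1, h, w, h, w),
        cost_row(paste0(name, ".pwc2"), "conv", sql, c - sql, 1, h, w, h, w))
}

s2ag_layout_rows <- function(spec, input_size) {
  ecfg <- spec$encoder
  H <- input_size[2]; W <- input_size[3]
  h <- H %/% 4L; w <- W %/% 4L
  rows <- rbind(
    cost_row("encoder.patch", "conv", input_size[1], ecfg$embed_dim, 7,
             H, W, h, w, bias = TRUE),
    cost_row("encoder.pos", "param",
             pcount = ecfg$pos_grid^2 * ecfg$embed_dim))
  layout <- encoder_layout(ecfg)
  for (i in seq_len(nrow(layout))) {
    r <- layout[i, ]
    L <- h * w
    nm <- sprintf("encoder.b%02d", i)
    if (r$adapter) {
      m <- max(1L, floor(r$din * ecfg$adapter_ratio))
      rows <- rbind(rows,
        cost_row(paste0(nm, ".adapter.down"), "linear", r$din, m, tokens = L),
        cost_row(paste0(nm, ".adapter.up"), "linear", m, r$din, tokens = L))
    }
    rows <- rbind(rows,
      cost_row(paste0(nm, ".norm1"), "param", cout = r$din, norm = "ln",
               pcount = 0, macs = 0),
      cost_row(paste0(nm, ".qkv"), "linear", r$din, 3L * r$dout, tokens = L))
    hq <- h; wq <- w
    if (r$transition) { hq <- h %/% 2L; wq <- w %/% 2L }
    Lq <- hq * wq
    ws <- r$window
    lkv <- if (ws > 0L && h %% ws == 0L && h >= ws) ws^2 else L
    dh <- r$dout %/% r$heads
    rows <- rbind(rows,
      cost_row(paste0(nm, ".attn"), "attn",
               macs = 2 * Lq * lkv * dh * r$heads),
      cost_row(paste0(nm, ".proj"), "linear", r$dout, r$dout, tokens = Lq))
    if (r$transition)
      rows <- rbind(rows, cost_row(paste0(nm, ".resproj"), "linear",
                                   r$din, r$dout, tokens = L))
    rows <- rbind(rows,
      cost_row(paste0(nm, ".norm2"), "param", cout = r$dout, norm = "ln",
               macs = 0),
      cost_row(paste0(nm, ".mlp.fc1"), "linear", r$dout,
               ecfg$mlp_ratio * r$dout, tokens = Lq),
      cost_row(paste0(nm, ".mlp.fc2"), "linear", ecfg$mlp_ratio * r$dout,
               r$dout, tokens = Lq))
    h <- hq; w <- wq
  }
  D <- spec$neck_widths; C <- ecfg$dims
  for (i in 1:4) {
    hi <- H %/% 2L^(i + 1L); wi <- W %/% 2L^(i + 1L)
    nm <- paste0("neck.stage", i)
    rows <- rbind(rows,
      rfb_rows(paste0(nm, ".rfb"), C[i], D[i], hi, wi),
      cost_row(paste0(nm, ".sru.gn"), "param", cout = D[i], norm = "gn",
               macs = 0),
      cru_rows(paste0(nm, ".cru"), D[i], hi, wi))
  }
  for (i in 3:1) {
    hi <- H %/% 2L^(i + 1L); wi <- W %/% 2L^(i + 1L)
    cm <- max(1L, D[i] %/% 2L)
    rows <- rbind(rows,
      cost_row(paste0("decoder.up", i), "convt", D[i + 1], D[i], 2,
               hi %/% 2L, wi %/% 2L, hi, wi, bias = TRUE),
      cost_row(paste0("decoder.gate", i, ".ws"), "conv", D[i], cm, 1,
               hi, wi, hi, wi, bias = TRUE),
      cost_row(paste0("decoder.gate", i, ".wd"), "conv", D[i], cm, 1,
               hi, wi, hi, wi, bias = TRUE),
      cost_row(paste0("decoder.gate", i, ".wr"), "conv", cm, 1, 1,
               hi, wi, hi, wi, bias = TRUE),
      dc_rows(paste0("decoder.dec", i), 2L * D[i], D[i], hi, wi))
  }
  f1 <- D[1]; f2 <- max(2L, D[1] %/% 2L)
  h4 <- H %/% 4L; w4 <- W %/% 4L
  rbind(rows,
        cost_row("decoder.fin1", "convt", D[1], f1, 2, h4, w4,
                 2L * h4, 2L * w4, bias = TRUE, norm = "bn"),
        cost_row("decoder.fin2", "convt", f1, f2, 2, 2L * h4, 2L * w4,
                 4L * h4, 4L * w4, bias = TRUE, norm = "bn"),
        cost_row("decoder.head", "conv", f2, spec$classes, 1,
                 H, W, H, W, bias = TRUE))
}

#' Parameter and MAC cost report
#'
#' Counts parameters exactly and multiply-accumulates analytically for a
#' network spec (or a built model) at a concrete input size.  MACs cover
#' convolution, transposed convolution, linear and attention layers;
#' normalization and activations are excluded.  `parameters` counts learnable
#' weights; `state` additionally counts batch-norm running statistics — the
#' convention under which the published baseline model sizes are reproduced.
#'
#' @param x a [network_spec()] or `panseg_model`.
#' @param input_size `(C, H, W)`; defaults to the spec's.
#' @return object of class `cost_report`: list with `parameters`, `buffers`,
#'   `state`, `macs`, `params_m` (state in millions, 2 dp), `macs_g` (MACs in
#'   G, 2 dp), and the per-layer `table`.
#' @export
count_costs <- function(x, input_size = NULL) {
  spec <- if (inherits(x, "panseg_model")) x$spec else x
  stopifnot(inherits(spec, "network_spec"))
  input_size <- as.integer(input_size %||% spec$input_size)
  rows <- switch(spec$family,
                 unet = unet_layout_rows(spec, input_size),
                 s2agscunet = s2ag_layout_rows(spec, input_size))
  pp <- t(vapply(seq_len(nrow(rows)),
                 function(i) row_params(rows[i, ]), c(params = 0, buffers = 0)))
  mm <- vapply(seq_len(nrow(rows)), function(i) row_macs(rows[i, ]), 0)
  rows$params <- pp[, "params"]; rows$buffers <- pp[, "buffers"]
  rows$macs_total <- mm
  parameters <- sum(rows$params); buffers <- sum(rows$buffers)
  macs <- sum(mm)
  structure(list(parameters = parameters, buffers = buffers,
                 state = parameters + buffers, macs = macs,
                 params_m = round((parameters + buffers) / 1e6, 2),
                 macs_g = round(macs / 1e9, 2),
                 input_size = input_size, family = spec$family,
                 table = rows),
            class = "cost_report")
}

#' @export
print.cost_report <- function(x, ...) {
  cat(sprintf("%s @ input %s\n", x$family,
              paste(x$input_size, collapse = "x")))
  cat(sprintf("  parameters : %s learnable + %s norm stats = %.2f M state\n",
              format(x$parameters, big.mark = ","),
              format(x$buffers, big.mark = ","), x$state / 1e6))
  cat(sprintf("  MACs       : %.2f G\n", x$macs / 1e9))
  invisible(x)
}
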