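# Network assembly: the UNet baseline, the 1/8-width LightUNet student, and
# the adapter-tuned hierarchical-encoder segmentation network (S2AgScUNet),
# plus exact parameter and multiply-accumulate accounting.

#' Declarative network specification
#'
#' @param family `"unet"` (the baseline encoder-decoder; `width_factor = 1/8`
#'   gives the LightUNet student) or `"s2agscunet"` (hierarchical frozen
#'   trunk + adapters + receptive-field/reconstruction neck + gated skips).
#' @param width_factor multiplies the base widths; the student uses 1/8.
#' @param base_widths channel widths of the five U-Net levels.
#' @param classes output classes (2: background/tooth, softmax head).
#' @param input_size `(C, H, W)` used for cost accounting.
#' @param encoder an [encoder_config()] (s2agscunet only).
#' @param neck_widths per-stage output channels of the neck / decoder
#'   schedule (s2agscunet only).
#' @param gate_target `"decoder"` applies the attention gate to the decoder
#'   feature (the literal gating rule); `"skip"` gates the skip path.
#' @param sru_groups group count of the SRU group normalization.
#' @return object of class `network_spec`.
#' @export
network_spec <- function(family = c("unet", "s2agscunet"),
                         width_factor = 1,
                         base_widths = c(64L, 128L, 256L, 512L, 1024L),
                         classes = 2L,
                         input_size = c(3L, 512L, 512L),
                         encoder = NULL,
                         neck_widths = c(64L, 128L, 256L, 512L),
                         gate_target = c("decoder", "skip"),
                         sru_groups = 4L) {
  family <- match.arg(family)
  spec <- list(family = family, width_factor = width_factor,
               classes = as.integer(classes), input_size = as.integer(input_size),
               gate_target = match.arg(gate_target),
               sru_groups = as.integer(sru_groups))
  if (family == "unet") {
    w <- base_widths * width_factor
    if (any(w < 1)) stop("width_factor makes a level width < 1", call. = FALSE)
    if (any(w != round(w)))
      stop("width_factor must scale all widths to whole numbers", call. = FALSE)
    spec$widths <- as.integer(round(w))
  } else {
    spec$encoder <- encoder %||% encoder_config("large")
    spec$neck_widths <- as.integer(neck_widths)
  }
  structure(spec, class = "network_spec")
}

#' @rdname network_spec
#' @export
unet_spec <- function(width_factor = 1, input_size = c(3L, 512L, 512L),
                      classes = 2L)
  network_spec("unet", width_factor = width_factor, input_size = input_size,
               classes = classes)

#' @rdname network_spec
#' @export
lightunet_spec <- function(input_size = c(3L, 512L, 512L), classes = 2L)
  unet_spec(width_factor = 1 / 8, input_size = input_size, classes = classes)

# ---- UNet ------------------------------------------------------------------

#' Build a UNet-family model
#'
#' Four encoder levels with 2x2 max pooling, a bottleneck, four decoder
#' levels with transposed-convolution upsampling and skip concatenation, and
#' a 1x1 softmax head.  Convolutions in the double-conv blocks are bias-free
#' and followed by batch norm + ReLU.
#'
#' @param spec a [network_spec()] with `family = "unet"`.
#' @param seed weight-initialization seed.
#' @return object of class `panseg_model`.
#' @export
build_unet <- function(spec, seed = 0L) {
  stopifnot(inherits(spec, "network_spec"), spec$family == "unet")
  w <- spec$widths
  params <- with_seed(seed, {
    p <- list(enc1 = dc_init(spec$input_size[1], w[1]),
              enc2 = dc_init(w[1], w[2]),
              enc3 = dc_init(w[2], w[3]),
              enc4 = dc_init(w[3], w[4]),
              bott = dc_init(w[4], w[5]))
    for (i in 4:1) {
      p[[paste0("up", i)]] <- convt2d_init(2, w[i + 1], w[i])
      p[[paste0("dec", i)]] <- dc_init(2L * w[i], w[i])
    }
    p$head <- conv2d_init(1, w[1], spec$classes, bias = TRUE)
    p
  })
  structure(list(spec = spec, params = params,
                 buffers = new.env(parent = emptyenv())),
            class = "panseg_model")
}

unet_forward <- function(model, x, ctx) {
  p <- model$params
  cache <- list()
  e <- vector("list", 4)
  h <- x
  for (i in 1:4) {
    dci <- dc_fw(h, p[[paste0("enc", i)]], ctx, paste0("enc", i))
    e[[i]] <- dci$out
    mp <- maxpool2_fw(dci$out)
    h <- mp$out
    cache[[paste0("enc", i)]] <- dci$cache
    cache[[paste0("pool", i)]] <- mp$cache
  }
  bt <- dc_fw(h, p$bott, ctx, "bott")
  cache$bott <- bt$cache
  h <- bt$out
  for (i in 4:1) {
    up <- convt2d_fw(h, p[[paste0("up", i)]])
    cc <- array(0, c(dim(up$out)[1:2], 2L * dim(up$out)[3], dim(up$out)[4]))
    wch <- dim(up$out)[3]
    cc[, , seq_len(wch), ] <- e[[i]]
    cc[, , wch + seq_len(wch), ] <- up$out
    dci <- dc_fw(cc, p[[paste0("dec", i)]], ctx, paste0("dec", i))
    h <- dci$out
    cache[[paste0("up", i)]] <- up$cache
    cache[[paste0("dec", i)]] <- dci$cache
    cache[[paste0("w", i)]] <- wch
  }
  hd <- conv2d_fw(h, p$head)
  cache$head <- hd$cache
  list(out = hd$out, cache = cache)
}

unet_backward <- function(model, cache, gout) {
  p <- model$params
  grads <- list()
  hd <- conv2d_bw(p$head, cache$head, gout)
  grads$head <- hd$grads
  g <- hd$gx
  gskip <- vector("list", 4)
  for (i in 1:4) {
    dci <- dc_bw(p[[paste0("dec", i)]], cache[[paste0("dec", i)]], g)
    grads[[paste0("dec", i)]] <- dci$grads
    wch <- cache[[paste0("w", i)]]
    gskip[[i]] <- dci$gx[, , seq_len(wch), , drop = FALSE]
    gup <- dci$gx[, , wch + seq_len(wch), , drop = FALSE]
    up <- convt2d_bw(p[[paste0("up", i)]], cache[[paste0("up", i)]], gup)
    grads[[paste0("up", i)]] <- up$grads
    g <- up$gx
  }
  bt <- dc_bw(p$bott, cache$bott, g)
  grads$bott <- bt$grads
  g <- bt$gx
  for (i in 4:1) {
    g <- maxpool2_bw(cache[[paste0("pool", i)]], g)
    g <- g + gskip[[i]]
    dci <- dc_bw(p[[paste0("enc", i)]], cache[[paste0("enc", i)]], g)
    grads[[paste0("enc", i)]] <- dci$grads
    g <- dci$gx
  }
  list(gx = g, grads = grads)
}

# ---- S2AgScUNet ------------------------------------------------------------

#' Build the adapter-tuned hierarchical-encoder segmentation network
#'
#' Encoder pyramid -> per-stage receptive-field block, spatial then channel
#' reconstruction -> attention-gated skip connections -> double-conv decoder
#' with transposed-convolution upsampling -> two upsampling stages back to
#' input resolution -> 1x1 softmax head.  The trunk is frozen per the
#' encoder's freeze policy.
#'
#' @param spec a [network_spec()] with `family = "s2agscunet"`.
#' @param seed weight-initialization seed.
#' @return object of class `panseg_model`.
#' @export
build_s2agscunet <- function(spec, seed = 0L) {
  stopifnot(inherits(spec, "network_spec"), spec$family == "s2agscunet")
  enc <- encoder_init(spec$encoder, seed = seed)
  D <- spec$neck_widths
  C <- spec$encoder$dims
  params <- with_seed(seed + 1L, {
    p <- list(encoder = enc$params)
    p$neck <- lapply(1:4, function(i)
      list(rfb = rfb_init(C[i], D[i]),
           sru = sru_init(D[i]),
           cru = cru_init(D[i])))
    names(p$neck) <- paste0("stage", 1:4)
    p$decoder <- list()
    for (i in 3:1) {
      p$decoder[[paste0("up", i)]] <- convt2d_init(2, D[i + 1], D[i])
      p$decoder[[paste0("gate", i)]] <- gate_init(D[i], D[i])
      p$decoder[[paste0("dec", i)]] <- dc_init(2L * D[i], D[i])
    }
    f1 <- D[1]; f2 <- max(2L, D[1] %/% 2L)
    p$decoder$fin1 <- convt2d_init(2, D[1], f1)
    p$decoder$finbn1 <- bn_init(f1)
    p$decoder$fin2 <- convt2d_init(2, f1, f2)
    p$decoder$finbn2 <- bn_init(f2)
    p$decoder$head <- conv2d_init(1, f2, spec$classes, bias = TRUE)
    p
  })
  model <- structure(list(spec = spec, params = params,
                          buffers = new.env(parent = emptyenv())),
                     class = "panseg_model")
  set_freeze_policy(model, spec$encoder$freeze)
}

# Lightweight encoder view over the embedded encoder parameters, so the
# encoder forward/backward can be reused unchanged.
s2ag_encoder_view <- function(model) {
  structure(list(config = model$spec$encoder,
                 layout = encoder_layout(model$spec$encoder),
                 params = model$params$encoder,
                 buffers = model$buffers),
            class = "panseg_encoder")
}

s2ag_forward <- function(model, x, ctx) {
  spec <- model$spec; p <- model$params
  D <- spec$neck_widths
  ef <- encoder_forward(s2ag_encoder_view(model), x, ctx)
  cache <- list(encoder = ef$cache)
  nk <- vector("list", 4)
  for (i in 1:4) {
    path <- paste0("neck.stage", i)
    rf <- rfb_fw(ef$pyr[[i]], p$neck[[i]]$rfb, ctx, paste0(path, ".rfb"))
    sr <- sru_fw(rf$out, p$neck[[i]]$sru, groups = spec$sru_groups)
    cr <- cru_fw(sr$out, p$neck[[i]]$cru)
    nk[[i]] <- cr$out
    cache[[paste0("neck", i)]] <-
      list(rfb = rf$cache, sru = sr$cache, cru = cr$cache)
  }
  h <- nk[[4]]
  for (i in 3:1) {
    up <- convt2d_fw(h, p$decoder[[paste0("up", i)]])
    gt <- gate_fw(nk[[i]], up$out, p$decoder[[paste0("gate", i)]],
                  target = spec$gate_target)
    cc <- array(0, c(dim(up$out)[1:2], 2L * D[i], dim(up$out)[4]))
    if (spec$gate_target == "decoder") {
      cc[, , seq_len(D[i]), ] <- nk[[i]]
      cc[, , D[i] + seq_len(D[i]), ] <- gt$out
    } else {
      cc[, , seq_len(D[i]), ] <- gt$out
      cc[, , D[i] + seq_len(D[i]), ] <- up$out
    }
    dci <- dc_fw(cc, p$decoder[[paste0("dec", i)]], ctx,
                 paste0("decoder.dec", i))
    h <- dci$out
    cache[[paste0("lvl", i)]] <- list(up = up$cache, gate = gt$cache,
                                      dec = dci$cache)
  }
  f1 <- convt2d_fw(h, p$decoder$fin1)
  b1 <- bn_fw(f1$out, p$decoder$finbn1, ctx, "decoder.finbn1")
  r1 <- relu_fw(b1$out)
  f2 <- convt2d_fw(r1$out, p$decoder$fin2)
  b2 <- bn_fw(f2$out, p$decoder$finbn2, ctx, "decoder.finbn2")
  # no activation directly before the classifier: zero-mean features let the
  # 1x1 head push evidence in both directions
  hd <- conv2d_fw(b2$out, p$decoder$head)
  cache$fin <- list(f1 = f1$cache, b1 = b1$cache, r1 = r1$cache,
                    f2 = f2$cache, b2 = b2$cache,
                    head = hd$cache)
  list(out = hd$out, cache = cache)
}

s2ag_backward <- function(model, cache, gout) {
  spec <- model$spec; p <- model$params
  D <- spec$neck_widths
  grads <- list(decoder = list())
  fin <- cache$fin
  hd <- conv2d_bw(p$decoder$head, fin$head, gout)
  grads$decoder$head <- hd$grads
  b2 <- bn_bw(p$decoder$finbn2, fin$b2, hd$gx)
  grads$decoder$finbn2 <- b2$grads
  f2 <- convt2d_bw(p$decoder$fin2, fin$f2, b2$gx)
  grads$decoder$fin2 <- f2$grads
  g <- relu_bw(fin$r1, f2$gx)
  b1 <- bn_bw(p$decoder$finbn1, fin$b1, g)
  grads$decoder$finbn1 <- b1$grads
  f1 <- convt2d_bw(p$decoder$fin1, fin$f1, b1$gx)
  grads$decoder$fin1 <- f1$grads
  g <- f1$gx
  gneck <- vector("list", 4)
  for (i in 1:3) gneck[[i]] <- 0
  for (i in 1:3) {
    lvl <- cache[[paste0("lvl", i)]]
    dci <- dc_bw(p$decoder[[paste0("dec", i)]], lvl$dec, g)
    grads$decoder[[paste0("dec", i)]] <- dci$grads
    if (spec$gate_target == "decoder") {
      gskip_direct <- dci$gx[, , seq_len(D[i]), , drop = FALSE]
      ggate <- dci$gx[, , D[i] + seq_len(D[i]), , drop = FALSE]
      gup_direct <- 0
    } else {
      ggate <- dci$gx[, , seq_len(D[i]), , drop = FALSE]
      gup_direct <- dci$gx[, , D[i] + seq_len(D[i]), , drop = FALSE]
      gskip_direct <- 0
    }
    gt <- gate_bw(p$decoder[[paste0("gate", i)]], lvl$gate, ggate)
    grads$decoder[[paste0("gate", i)]] <- gt$grads
    gneck[[i]] <- gskip_direct + gt$gxs
    gup <- gup_direct + gt$gxd
    up <- convt2d_bw(p$decoder[[paste0("up", i)]], lvl$up, gup)
    grads$decoder[[paste0("up", i)]] <- up$grads
    g <- up$gx
  }
  gneck[[4]] <- g
  gpyr <- vector("list", 4)
  grads$neck <- vector("list", 4)
  names(grads$neck) <- paste0("stage", 1:4)
  for (i in 1:4) {
    nc <- cache[[paste0("neck", i)]]
    cr <- cru_bw(p$neck[[i]]$cru, nc$cru, gneck[[i]])
    sr <- sru_bw(p$neck[[i]]$sru, nc$sru, cr$gx)
    rf <- rfb_bw(p$neck[[i]]$rfb, nc$rfb, sr$gx)
    grads$neck[[i]] <- list(rfb = rf$grads, sru = sr$grads, cru = cr$grads)
    gpyr[[i]] <- rf$gx
  }
  eb <- encoder_backward(s2ag_encoder_view(model), cache$encoder, gpyr)
  grads$encoder <- eb$grads
  list(gx = eb$gx, grads = grads)
}

# ---- shared model interface ------------------------------------------------

net_forward <- function(model, x, ctx) {
  switch(model$spec$family,
         unet = unet_forward(model, x, ctx),
         s2agscunet = s2ag_forward(model, x, ctx),
         stop("unknown model family: ", model$spec$family, call. = FALSE))
}

net_backward <- function(model, cache, gout) {
  switch(model$spec$family,
         unet = unet_backward(model, cache, gout),
         s2agscunet = s2ag_backward(model, cache, gout))
}

#' Forward pass returning class logits
#'
#' @param model a `panseg_model`.
#' @param x image batch `(H, W, 3, N)` in `[0, 1]`.
#' @param training use batch statistics and record nothing; eval mode uses
#'   the stored running statistics.
#' @return logits array `(H, W, classes, N)`.
#' @export
model_logits <- function(model, x, training = FALSE) {
  ctx <- list(buffers = model$buffers, training = training)
  net_forward(model, x, ctx)$out
}

#' Predicted binary masks (argmax over the softmax classes)
#'
#' @param object a `panseg_model`.
#' @param x image batch `(H, W, 3, N)`.
#' @param ... unused.
#' @return integer mask array `(H, W, N)` with values in `{0, 1}`.
#' @export
predict.panseg_model <- function(object, x, ...) {
  z <- model_logits(object, x)
  d <- dim(z)
  m <- chan_mat(z)
  pred <- max.col(m, ties.method = "first") - 1L
  array(as.integer(pred), c(d[1], d[2], d[4]))
}

#' @export
print.panseg_model <- function(x, ...) {
  cr <- count_costs(x$spec)
  cat("panseg model, family: ", x$spec$family, "\n", sep = "")
  if (x$spec$family == "unet")
    cat("  widths: ", paste(x$spec$widths, collapse = ", "),
        "  (width factor ", format(x$spec$width_factor), ")\n", sep = "")
  cat(sprintf("  parameters: %s learnable (state %.2f M incl. norm stats)\n",
              format(cr$parameters, big.mark = ","), cr$state / 1e6))
  cat(sprintf("  MACs at %s: %.2f G\n",
              paste(x$spec$input_size, collapse = "x"), cr$macs / 1e9))
  invisible(x)
}

# Introspect a built model back into its declarative spec (round-trip check).
introspect_spec <- function(model) {
  sp <- model$spec
  if (sp$family == "unet") {
    w <- vapply(1:4, function(i) dim(model$params[[paste0("enc", i)]]$conv1$w)[4],
                0L)
    w5 <- dim(model$params$bott$conv1$w)[4]
    stopifnot(identical(c(w, w5), sp$widths))
  }
  sp
}

# ---- checkpoints -----------------------------------------------------------

#' Save / load a model checkpoint
#'
#' The checkpoint embeds the declarative spec, all weights and the
#' normalization running statistics.
#'
#' @param model a `panseg_model` or `panseg_encoder`.
#' @param path file path.
#' @return `load_checkpoint` returns the restored model.
#' @export
save_checkpoint <- function(model, path) {
  obj <- unclass(model)
  obj$buffers <- as.list(model$buffers)
  obj$.class <- class(model)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  cls <- obj$.class
  obj$.class <- NULL
  buf <- new.env(parent = emptyenv())
  for (nm in names(obj$buffers)) buf[[nm]] <- obj$buffers[[nm]]
  obj$buffers <- buf
  structure(obj, class = cls)
}
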