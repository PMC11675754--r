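# User-facing functional wrappers over the internal block implementations.
# Standalone calls run in training mode (batch statistics) with a transient
# buffer store; inside a model the blocks share the model's buffers instead.

standalone_ctx <- function() {
  list(buffers = new.env(parent = emptyenv()), training = TRUE)
}

#' Apply a bottleneck adapter to a token tensor
#'
#' Computes `GeLU(up(GeLU(down(x))))` — the residual-free bottleneck used to
#' tune the frozen trunk.
#'
#' @param x token array `(L, C, N)`.
#' @param params adapter parameters from [adapter_params()].
#' @return array of the same shape.
#' @export
adapter_forward <- function(x, params) {
  if (dim(x)[2] != dim(params$down$w)[1])
    stop("adapter: channel mismatch", call. = FALSE)
  adapter_fw(x, params)$out
}

#' @rdname adapter_forward
#' @param channels token channel count.
#' @param ratio bottleneck fraction.
#' @export
adapter_params <- function(channels, ratio = 0.25)
  adapter_init(as.integer(channels), ratio)

#' Attention-gated skip fusion
#'
#' `sigma(W_R ReLU(W_S x_s + W_D x_d)) * target`, with `x_d` upsampled to
#' the skip resolution when the grids differ.
#'
#' @param x_s skip feature `(H, W, Cs, N)`.
#' @param x_d decoder feature `(h, w, Cd, N)`.
#' @param params gate parameters from [gate_params()].
#' @param target which feature the gate multiplies.
#' @return gated feature array; the gate map is attached as attribute
#'   `"gate"`.
#' @export
attention_gate <- function(x_s, x_d, params,
                           target = c("decoder", "skip")) {
  r <- gate_fw(x_s, x_d, params, target = match.arg(target))
  structure(r$out, gate = r$gate)
}

#' @rdname attention_gate
#' @param skip_channels,decoder_channels,intermediate_channels 1x1
#'   projection widths (intermediate defaults to half the decoder width).
#' @export
gate_params <- function(skip_channels, decoder_channels,
                        intermediate_channels = NULL)
  gate_init(as.integer(skip_channels), as.integer(decoder_channels),
            cm = if (is.null(intermediate_channels)) NULL
                 else as.integer(intermediate_channels))

#' Receptive-field block
#'
#' Four parallel dilated branches (dilations 1/3/5/7), concatenated, fused
#' and added to a 1x1 residual; spatial size preserved, channels mapped to
#' `out_channels`.
#'
#' @param x feature map `(H, W, C, N)` with `C >= 4`.
#' @param out_channels output channel count.
#' @param params optional parameters (initialized from a seed otherwise).
#' @param seed initialization seed when `params` is missing.
#' @return feature map `(H, W, out_channels, N)`.
#' @export
rfb_forward <- function(x, out_channels, params = NULL, seed = 0L) {
  if (is.null(params))
    params <- with_seed(seed, rfb_init(dim(x)[3], as.integer(out_channels)))
  rfb_fw(x, params, standalone_ctx(), "rfb")$out
}

#' Spatial reconstruction unit
#'
#' Group normalization, informativeness weights `gamma / sum(gamma)`, a
#' sigmoid gate thresholded at 0.5, and cross-reconstruction of the two
#' channel halves.
#'
#' @param x feature map `(H, W, C, N)` with even `C` divisible by `groups`.
#' @param params list with `gn = list(g, b)`; initialized if missing.
#' @param groups group-norm group count.
#' @param threshold gate threshold.
#' @return feature map of the same shape.
#' @export
sru_forward <- function(x, params = NULL, groups = 4L, threshold = 0.5) {
  if (is.null(params)) params <- sru_init(dim(x)[3])
  sru_fw(x, params, groups = groups, threshold = threshold)$out
}

#' Channel reconstruction unit
#'
#' Split-transform-merge: squeezed group+pointwise transforms of the upper
#' channel split, pointwise+reuse of the lower, merged by a per-channel
#' pairwise softmax of pooled responses.
#'
#' @param x feature map `(H, W, C, N)` with `C >= 2`.
#' @param params optional parameters from an internal initializer.
#' @param seed initialization seed when `params` is missing.
#' @return feature map of the same shape.
#' @export
cru_forward <- function(x, params = NULL, seed = 0L) {
  if (is.null(params)) params <- with_seed(seed, cru_init(dim(x)[3]))
  cru_fw(x, params)$out
}

#' UNet decoder block
#'
#' Two rounds of (3x3 convolution, batch norm, ReLU); spatial size
#' preserved.
#'
#' @param x feature map `(H, W, C, N)`.
#' @param out_channels output channel count.
#' @param params optional block parameters.
#' @param seed initialization seed when `params` is missing.
#' @return feature map `(H, W, out_channels, N)`, elementwise nonnegative.
#' @export
decoder_block <- function(x, out_channels, params = NULL, seed = 0L) {
  if (is.null(params))
    params <- with_seed(seed, dc_init(dim(x)[3], as.integer(out_channels)))
  dc_fw(x, params, standalone_ctx(), "dc")$out
}
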