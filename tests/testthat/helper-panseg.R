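# Shared fixtures and small utilities for the test suite.

tiny_unet_spec <- function(size = 32L, wf = 1 / 8)
  unet_spec(width_factor = wf, input_size = c(3L, size, size))

tiny_s2ag_spec <- function(size = 32L, freeze = "trunk")
  network_spec("s2agscunet",
               encoder = encoder_config("tiny", freeze = freeze),
               neck_widths = c(8L, 16L, 32L, 64L),
               input_size = c(3L, size, size))

mean_iou <- function(model, ds, chunk = 10L) {
  n <- dim(ds$images)[4]
  iou <- numeric(n)
  for (b0 in seq(1L, n, by = chunk)) {
    idx <- b0:min(n, b0 + chunk - 1L)
    p <- predict(model, ds$images[, , , idx, drop = FALSE])
    for (k in seq_along(idx))
      iou[idx[k]] <- metrics_from_counts(
        confusion_counts(p[, , k], ds$masks[, , idx[k]]))$iou
  }
  mean(iou)
}

rand_arr <- function(..., sd = 1) array(stats::rnorm(prod(c(...)), sd = sd),
                                        c(...))

# Reference GeLU used by independent oracles.
gelu_ref <- function(x) x * stats::pnorm(x)

# Internal primitives exercised directly by the unit tests.
internals <- c(
    "conv2d_init", "conv2d_fw", "conv2d_bw", "conv2d_grouped_fw",
    "convt2d_init", "convt2d_fw", "convt2d_bw",
    "maxpool2_fw", "maxpool2_bw", "bn_init", "bn_fw", "bn_bw",
    "gn_init", "gn_fw", "gn_bw", "ln_init", "ln_fw", "ln_bw",
    "linear_init", "linear_fw", "linear_bw", "relu_fw", "gelu_fw",
    "sigmoid_fw", "upsample_nearest_fw",
    "dc_init", "dc_fw", "dc_bw", "adapter_init", "adapter_fw", "adapter_bw",
    "rfb_init", "rfb_fw", "rfb_branch_receptive_field",
    "sru_init", "sru_fw", "sru_weights", "cru_init", "cru_fw",
    "gate_init", "gate_fw", "gate_bw",
    "flatten_params", "n_params", "encoder_layout", "encoder_forward",
    "encoder_param_split", "net_forward", "net_backward",
    "chan_mat", "mat_chan", "softmax_rows", "cost_row", "row_macs",
    "row_params", "with_seed", "adam_init", "adam_step", "scene_batch",
    "kd_loss_grad", "ce_loss_grad", "is_frozen", "unflatten_into",
    "introspect_spec", "s2ag_encoder_view")
for (nm in internals) assign(nm, utils::getFromNamespace(nm, "panseg"))
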