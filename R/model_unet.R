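# Reference U-Net baseline, pinned to the widely circulated community
# Keras implementation: filter ladder 64-128-256-512 with a 1024-channel
# bridge, two biased 3x3 same-padded convolutions per level, no
# normalisation layers, decoder levels of 2x upsampling followed by a 2x2
# "up-convolution" halving the channels, and a head of a 2-filter 3x3 conv
# plus a 1-filter 1x1 sigmoid conv. This exact topology totals 31,031,685
# parameters, all trainable.

build_unet_graph <- function(input_size, dropout_rate = 0.5) {
  if (input_size %% 16L != 0L)
    stop("input_size must be divisible by 16 for 4 pooling levels")
  filters <- c(64L, 128L, 256L, 512L)
  g <- new_graph_builder(c(input_size, input_size, 1L))
  skips <- character(4L)
  for (l in 1:4) {
    gb_add(g, sprintf("enc%d_conv1", l), "conv", k = 3L, c_out = filters[l])
    gb_add(g, sprintf("enc%d_relu1", l), "relu")
    gb_add(g, sprintf("enc%d_conv2", l), "conv", k = 3L, c_out = filters[l])
    gb_add(g, sprintf("enc%d_relu2", l), "relu",
           label = sprintf("Encoder %d", l))
    if (l == 4L) gb_add(g, "enc4_drop", "dropout", rate = dropout_rate)
    skips[l] <- g$last
    gb_add(g, sprintf("enc%d_pool", l), "maxpool")
  }
  gb_add(g, "bridge_conv1", "conv", k = 3L, c_out = 1024L)
  gb_add(g, "bridge_relu1", "relu")
  gb_add(g, "bridge_conv2", "conv", k = 3L, c_out = 1024L)
  gb_add(g, "bridge_relu2", "relu", label = "Bridge")
  gb_add(g, "bridge_drop", "dropout", rate = dropout_rate)
  for (l in 4:1) {
    gb_add(g, sprintf("dec%d_up", l), "upsample")
    gb_add(g, sprintf("dec%d_upconv", l), "conv", k = 2L, c_out = filters[l])
    gb_add(g, sprintf("dec%d_uprelu", l), "relu")
    gb_add(g, sprintf("dec%d_cat", l), "concat",
           inputs = c(skips[l], g$last))
    gb_add(g, sprintf("dec%d_conv1", l), "conv", k = 3L, c_out = filters[l])
    gb_add(g, sprintf("dec%d_relu1", l), "relu")
    gb_add(g, sprintf("dec%d_conv2", l), "conv", k = 3L, c_out = filters[l])
    gb_add(g, sprintf("dec%d_relu2", l), "relu",
           label = sprintf("Decoder %d", l))
  }
  gb_add(g, "head_conv", "conv", k = 3L, c_out = 2L)
  gb_add(g, "head_relu", "relu")
  gb_add(g, "out_conv", "conv", k = 1L, c_out = 1L)
  gb_add(g, "out_sigmoid", "sigmoid", label = "Output")
  g
}

#' Layer table for the baseline U-Net
#'
#' @inheritParams build_unet_baseline
#' @return a tibble (see [cnnres_spec()] for columns).
#' @export
unet_spec <- function(input_size = 160L, dropout_rate = 0.5) {
  gb_spec(build_unet_graph(input_size, dropout_rate))
}

#' Build the reference U-Net baseline
#'
#' @param input_size square single-channel input side, divisible by 16.
#' @param dropout_rate dropout after encoder level 4 and the bridge.
#' @param init `"he_normal"` or `"zeros"`.
#' @return a `seg_network` object.
#' @seealso [build_cnnres()]
#' @export
build_unet_baseline <- function(input_size = 160L, dropout_rate = 0.5,
                                init = "he_normal") {
  g <- build_unet_graph(input_size, dropout_rate)
  structure(list(arch = "unet", nodes = g$nodes,
                 params = init_params(g$nodes, init), spec = gb_spec(g),
                 convention = list(bn_epsilon = 1e-3, bn_momentum = 0.99),
                 input_shape = c(input_size, input_size, 1L)),
            class = "seg_network")
}
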