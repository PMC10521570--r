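# Elementwise / channelwise layer operations on (H, W, C, N) arrays.
# Convolution and max-pooling are compiled (see src/nn_ops.cpp); everything
# here is cheap enough in vectorised R.

# Per-channel sum of an (H, W, C, N) array -> length-C vector.
channel_sum <- function(x) {
  d <- dim(x)
  cs <- colSums(matrix(x, d[1L] * d[2L], d[3L] * d[4L]))
  rowSums(matrix(cs, d[3L], d[4L]))
}

# Broadcast a length-C vector across (H, W, C, N); relies on R recycling
# over the trailing N dimension.
channel_expand <- function(v, d) {
  rep(v, each = d[1L] * d[2L])
}

relu_fwd <- function(x) {
  mask <- x > 0
  list(y = x * mask, cache = mask)
}

relu_bwd <- function(gy, cache) gy * cache

sigmoid_fwd <- function(x) {
  y <- 1 / (1 + exp(-x))
  list(y = y, cache = y)
}

sigmoid_bwd <- function(gy, cache) gy * cache * (1 - cache)

upsample2_fwd <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1L]), each = 2L), rep(seq_len(d[2L]), each = 2L), , ,
    drop = FALSE]
}

upsample2_bwd <- function(gy) {
  d <- dim(gy)
  o1 <- seq(1L, d[1L], by = 2L); e1 <- seq(2L, d[1L], by = 2L)
  o2 <- seq(1L, d[2L], by = 2L); e2 <- seq(2L, d[2L], by = 2L)
  gy[o1, o2, , , drop = FALSE] + gy[e1, o2, , , drop = FALSE] +
    gy[o1, e2, , , drop = FALSE] + gy[e1, e2, , , drop = FALSE]
}

concat_fwd <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(da[1L] == db[1L], da[2L] == db[2L], da[4L] == db[4L])
  y <- array(0, c(da[1L], da[2L], da[3L] + db[3L], da[4L]))
  y[, , seq_len(da[3L]), ] <- a
  y[, , da[3L] + seq_len(db[3L]), ] <- b
  list(y = y, c_a = da[3L], c_b = db[3L])
}

concat_bwd <- function(gy, c_a, c_b) {
  list(ga = gy[, , seq_len(c_a), , drop = FALSE],
       gb = gy[, , c_a + seq_len(c_b), , drop = FALSE])
}

dropout_fwd <- function(x, rate, training) {
  if (!training || rate <= 0) return(list(y = x, cache = NULL))
  mask <- (runif(length(x)) >= rate) / (1 - rate)
  list(y = x * mask, cache = mask)
}

dropout_bwd <- function(gy, cache) {
  if (is.null(cache)) gy else gy * cache
}

# Batch normalisation over (H, W, N) per channel.
bn_fwd <- function(x, p, eps, momentum, training) {
  d <- dim(x)
  m <- d[1L] * d[2L] * d[4L]
  if (training) {
    mu <- channel_sum(x) / m
    xc <- x - channel_expand(mu, d)
    v <- channel_sum(xc * xc) / m
    inv_sd <- 1 / sqrt(v + eps)
    xhat <- xc * channel_expand(inv_sd, d)
    running <- list(
      running_mean = momentum * p$running_mean + (1 - momentum) * mu,
      running_var  = momentum * p$running_var + (1 - momentum) * v
    )
    y <- xhat * channel_expand(p$gamma, d) + channel_expand(p$beta, d)
    list(y = y, cache = list(xhat = xhat, inv_sd = inv_sd, gamma = p$gamma),
         running = running)
  } else {
    inv_sd <- 1 / sqrt(p$running_var + eps)
    xhat <- (x - channel_expand(p$running_mean, d)) *
      channel_expand(inv_sd, d)
    y <- xhat * channel_expand(p$gamma, d) + channel_expand(p$beta, d)
    list(y = y, cache = NULL, running = NULL)
  }
}

bn_bwd <- function(gy, cache) {
  d <- dim(gy)
  m <- d[1L] * d[2L] * d[4L]
  xhat <- cache$xhat
  gxhat <- gy * channel_expand(cache$gamma, d)
  ggamma <- channel_sum(gy * xhat)
  gbeta <- channel_sum(gy)
  s1 <- channel_sum(gxhat)
  s2 <- channel_sum(gxhat * xhat)
  gx <- channel_expand(cache$inv_sd / m, d) *
    (m * gxhat - channel_expand(s1, d) - xhat * channel_expand(s2, d))
  list(gx = gx, ggamma = ggamma, gbeta = gbeta)
}
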