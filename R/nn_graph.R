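# A small static-graph engine for encoder-decoder segmentation networks.
#
# A network is a list of nodes in topological order. Each node names its
# input node(s); activations flow as (H, W, C, N) arrays. The graph builder
# performs shape propagation at construction time, so the layer table
# (the "model spec") and the allocated parameters always agree.

SUPPORTED_OPS <- c("input", "conv", "bn", "relu", "maxpool", "upsample",
                   "concat", "add", "dropout", "sigmoid")

# Mutable builder: accumulates nodes and per-layer spec rows.
new_graph_builder <- function(input_shape) {
  env <- new.env(parent = emptyenv())
  env$nodes <- list()
  env$shapes <- list(input = input_shape)
  env$rows <- list(list(name = "input", op = "input", kernel = NA_integer_,
                        stride = NA_integer_, out_h = input_shape[1L],
                        out_w = input_shape[2L], out_c = input_shape[3L],
                        trainable = 0, non_trainable = 0,
                        label = NA_character_))
  env$last <- "input"
  env
}

gb_add <- function(g, name, op, inputs = g$last, label = NA_character_,
                   k = NA_integer_, c_out = NA_integer_, bias = TRUE,
                   rate = NA_real_) {
  if (!op %in% SUPPORTED_OPS) stop("unknown op: ", op)
  if (name %in% names(g$shapes)) stop("duplicate node name: ", name)
  sh <- g$shapes[[inputs[1L]]]
  if (is.null(sh)) stop("unknown input node: ", inputs[1L])
  c_in <- sh[3L]
  trainable <- 0; non_trainable <- 0; stride <- 1L
  out <- sh
  if (op == "conv") {
    out[3L] <- c_out
    trainable <- k * k * c_in * c_out + if (bias) c_out else 0
  } else if (op == "bn") {
    trainable <- 2 * c_in
    non_trainable <- 2 * c_in
  } else if (op == "maxpool") {
    if (sh[1L] %% 2L || sh[2L] %% 2L)
      stop("maxpool at node '", name, "': odd spatial size ",
           sh[1L], "x", sh[2L])
    out[1L] <- sh[1L] %/% 2L; out[2L] <- sh[2L] %/% 2L
    k <- 2L; stride <- 2L
  } else if (op == "upsample") {
    out[1L] <- sh[1L] * 2L; out[2L] <- sh[2L] * 2L
    k <- 2L; stride <- 2L
  } else if (op %in% c("concat", "add")) {
    sh2 <- g$shapes[[inputs[2L]]]
    if (is.null(sh2)) stop("unknown input node: ", inputs[2L])
    if (any(sh[1:2] != sh2[1:2]))
      stop("spatial mismatch at node '", name, "'")
    if (op == "concat") out[3L] <- sh[3L] + sh2[3L]
    else if (sh[3L] != sh2[3L]) stop("channel mismatch at add node '", name, "'")
  }
  g$nodes[[name]] <- list(name = name, op = op, inputs = inputs, k = k,
                          c_in = c_in, c_out = out[3L], bias = bias,
                          rate = rate)
  g$shapes[[name]] <- out
  g$rows[[length(g$rows) + 1L]] <- list(
    name = name, op = op,
    kernel = if (is.na(k)) NA_integer_ else as.integer(k),
    stride = as.integer(stride),
    out_h = out[1L], out_w = out[2L], out_c = out[3L],
    trainable = trainable, non_trainable = non_trainable, label = label)
  g$last <- name
  invisible(name)
}

gb_spec <- function(g) {
  rows <- g$rows
  tibble::tibble(
    layer = vapply(rows, function(r) r$name, character(1)),
    op = vapply(rows, function(r) r$op, character(1)),
    kernel = vapply(rows, function(r) as.integer(r$kernel), integer(1)),
    stride = vapply(rows, function(r) as.integer(r$stride), integer(1)),
    out_h = vapply(rows, function(r) as.integer(r$out_h), integer(1)),
    out_w = vapply(rows, function(r) as.integer(r$out_w), integer(1)),
    out_c = vapply(rows, function(r) as.integer(r$out_c), integer(1)),
    trainable = vapply(rows, function(r) as.numeric(r$trainable), numeric(1)),
    non_trainable = vapply(rows, function(r) as.numeric(r$non_trainable),
                           numeric(1)),
    label = vapply(rows, function(r) r$label, character(1))
  )
}

# Allocate parameter arrays for a built graph.
#
# Convolution weights use the He-normal (variance-scaling) initialiser,
# sd = sqrt(2 / fan_in); biases start at zero; batch-norm starts at the
# identity transform with zeroed running statistics.
init_params <- function(nodes, init = c("he_normal", "zeros")) {
  init <- match.arg(init)
  params <- list()
  for (nd in nodes) {
    if (nd$op == "conv") {
      n_w <- nd$k * nd$k * nd$c_in * nd$c_out
      w <- if (init == "he_normal") {
        rnorm(n_w, 0, sqrt(2 / (nd$k * nd$k * nd$c_in)))
      } else numeric(n_w)
      dim(w) <- c(nd$k, nd$k, nd$c_in, nd$c_out)
      p <- list(w = w)
      if (nd$bias) p$b <- numeric(nd$c_out)
      params[[nd$name]] <- p
    } else if (nd$op == "bn") {
      c <- nd$c_in
      params[[nd$name]] <- list(gamma = rep(1, c), beta = numeric(c),
                                running_mean = numeric(c),
                                running_var = rep(1, c))
    }
  }
  params
}

#' @export
print.seg_network <- function(x, ...) {
  cat("<seg_network> ", x$arch, ", input ",
      paste(x$input_shape, collapse = "x"), "\n", sep = "")
  rpt <- count_parameters(x)
  cat("  layers: ", nrow(x$spec), "   parameters: ",
      format(rpt$total, big.mark = ","), " (",
      format(rpt$trainable, big.mark = ","), " trainable, ",
      format(rpt$non_trainable, big.mark = ","), " non-trainable)\n",
      sep = "")
  invisible(x)
}

# Map node name -> names of nodes that consume its output.
node_consumers <- function(nodes) {
  cons <- list()
  for (nd in nodes) {
    for (inp in nd$inputs) cons[[inp]] <- c(cons[[inp]], nd$name)
  }
  cons
}

#' Run a forward pass through a segmentation network
#'
#' @param model a `seg_network` object.
#' @param x input batch, an (H, W, C, N) array or a single (H, W) matrix /
#'   (H, W, C) array, which is promoted.
#' @param training logical; in training mode batch-norm uses batch
#'   statistics (and records running-statistic updates) and dropout is
#'   active. In evaluation mode the network is deterministic.
#' @param keep_activations keep every node output (needed for backprop).
#' @return a list with `out` (the network output), and when
#'   `keep_activations` is `TRUE` also `outs`, `caches` and `running`.
#' @export
nn_forward <- function(model, x, training = FALSE, keep_activations = training) {
  x <- promote_batch(x, model$input_shape)
  nodes <- model$nodes
  params <- model$params
  outs <- list(input = x)
  caches <- list()
  running <- list()
  conv <- model$convention
  bn_eps <- if (!is.null(conv$bn_epsilon)) conv$bn_epsilon else 1e-3
  bn_mom <- if (!is.null(conv$bn_momentum)) conv$bn_momentum else 0.99
  for (nd in nodes) {
    a <- outs[[nd$inputs[1L]]]
    y <- switch(nd$op,
      conv = .conv2d_fwd(a, params[[nd$name]]$w, params[[nd$name]]$b),
      bn = {
        r <- bn_fwd(a, params[[nd$name]], bn_eps, bn_mom, training)
        if (keep_activations) caches[[nd$name]] <- r$cache
        if (training) running[[nd$name]] <- r$running
        r$y
      },
      relu = {
        r <- relu_fwd(a)
        if (keep_activations) caches[[nd$name]] <- r$cache
        r$y
      },
      maxpool = {
        r <- .maxpool2_fwd(a)
        if (keep_activations)
          caches[[nd$name]] <- list(idx = r$idx, xdim = dim(a))
        r$y
      },
      upsample = upsample2_fwd(a),
      concat = {
        r <- concat_fwd(a, outs[[nd$inputs[2L]]])
        if (keep_activations)
          caches[[nd$name]] <- list(c_a = r$c_a, c_b = r$c_b)
        r$y
      },
      add = a + outs[[nd$inputs[2L]]],
      dropout = {
        r <- dropout_fwd(a, nd$rate, training)
        if (keep_activations) caches[[nd$name]] <- r$cache
        r$y
      },
      sigmoid = {
        r <- sigmoid_fwd(a)
        if (keep_activations) caches[[nd$name]] <- r$cache
        r$y
      },
      stop("unknown op ", nd$op))
    outs[[nd$name]] <- y
    if (!keep_activations) {
      # free inputs no longer needed? keep simple: retain all (desk scale)
    }
  }
  out <- outs[[nodes[[length(nodes)]]$name]]
  if (keep_activations) list(out = out, outs = outs, caches = caches,
                             running = running)
  else list(out = out)
}

# Backward pass: grad_out is dLoss/d(network output).
# Returns per-node parameter gradients.
nn_backward <- function(model, fwd, grad_out) {
  nodes <- model$nodes
  params <- model$params
  outs <- fwd$outs
  caches <- fwd$caches
  gacc <- list()
  last <- nodes[[length(nodes)]]$name
  gacc[[last]] <- grad_out
  pgrads <- list()
  add_grad <- function(name, g) {
    cur <- gacc[[name]]
    gacc[[name]] <<- if (is.null(cur)) g else cur + g
  }
  for (i in rev(seq_along(nodes))) {
    nd <- nodes[[i]]
    gy <- gacc[[nd$name]]
    if (is.null(gy)) next  # dead branch (cannot happen in our graphs)
    gacc[[nd$name]] <- NULL
    switch(nd$op,
      conv = {
        r <- .conv2d_bwd(outs[[nd$inputs[1L]]], params[[nd$name]]$w, gy,
                         nd$bias)
        pg <- list(w = r$gw)
        if (nd$bias) pg$b <- r$gb
        pgrads[[nd$name]] <- pg
        add_grad(nd$inputs[1L], r$gx)
      },
      bn = {
        r <- bn_bwd(gy, caches[[nd$name]])
        pgrads[[nd$name]] <- list(gamma = r$ggamma, beta = r$gbeta)
        add_grad(nd$inputs[1L], r$gx)
      },
      relu = add_grad(nd$inputs[1L], relu_bwd(gy, caches[[nd$name]])),
      maxpool = {
        cc <- caches[[nd$name]]
        add_grad(nd$inputs[1L], .maxpool2_bwd(gy, cc$idx, cc$xdim))
      },
      upsample = add_grad(nd$inputs[1L], upsample2_bwd(gy)),
      concat = {
        cc <- caches[[nd$name]]
        r <- concat_bwd(gy, cc$c_a, cc$c_b)
        add_grad(nd$inputs[1L], r$ga)
        add_grad(nd$inputs[2L], r$gb)
      },
      add = {
        add_grad(nd$inputs[1L], gy)
        add_grad(nd$inputs[2L], gy)
      },
      dropout = add_grad(nd$inputs[1L], dropout_bwd(gy, caches[[nd$name]])),
      sigmoid = add_grad(nd$inputs[1L], sigmoid_bwd(gy, caches[[nd$name]])),
      stop("unknown op ", nd$op))
  }
  pgrads
}

# Promote a matrix / 3-D array to a 4-D (H, W, C, N) batch.
promote_batch <- function(x, input_shape) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L, 1L)
  else if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  d <- dim(x)
  if (length(d) != 4L || any(d[1:3] != input_shape))
    stop("input batch must be ", paste(input_shape, collapse = "x"),
         " (xN); got ", paste(d, collapse = "x"))
  x
}

#' Count model parameters
#'
#' Computes parameter totals twice: from the allocated parameter arrays
#' ("framework" count) and from the closed-form per-layer formulas
#' (k\\*k\\*C_in\\*C_out + C_out for a biased convolution; 2C trainable plus 2C
#' non-trainable running statistics for a batch-normalisation layer). The
#' two routes must agree exactly; a mismatch raises an error naming the
#' first differing layer.
#'
#' @param model a `seg_network` (or a model spec tibble, in which case only
#'   the closed-form route is available).
#' @return a `param_count_report`: list with `trainable`, `non_trainable`,
#'   `total` and a per-layer tibble `layers`.
#' @export
count_parameters <- function(model) {
  if (tibble::is_tibble(model)) {
    spec <- model
    params <- NULL
  } else {
    spec <- model$spec
    params <- model$params
  }
  if (!is.null(params)) {
    for (i in seq_len(nrow(spec))) {
      nm <- spec$layer[i]
      p <- params[[nm]]
      fw_tr <- if (is.null(p)) 0 else
        sum(vapply(p[names(p) %in% c("w", "b", "gamma", "beta")], length,
                   integer(1)))
      fw_nt <- if (is.null(p)) 0 else
        sum(vapply(p[names(p) %in% c("running_mean", "running_var")], length,
                   integer(1)))
      if (fw_tr != spec$trainable[i] || fw_nt != spec$non_trainable[i])
        stop("parameter count mismatch at layer '", nm, "': allocated ",
             fw_tr, "+", fw_nt, " vs closed-form ", spec$trainable[i], "+",
             spec$non_trainable[i])
    }
  }
  rpt <- list(trainable = sum(spec$trainable),
              non_trainable = sum(spec$non_trainable),
              total = sum(spec$trainable) + sum(spec$non_trainable),
              layers = spec)
  class(rpt) <- "param_count_report"
  rpt
}

#' @export
print.param_count_report <- function(x, ...) {
  cat("Parameters: total ", format(x$total, big.mark = ","), "\n",
      "  trainable:     ", format(x$trainable, big.mark = ","), "\n",
      "  non-trainable: ", format(x$non_trainable, big.mark = ","), "\n",
      sep = "")
  invisible(x)
}
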