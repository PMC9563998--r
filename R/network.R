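#' Segmentation network configuration
#'
#' Describes the encoder-decoder lodging-segmentation network. Each encoder
#' level applies a 3x3 convolution (+BN+ReLU), optionally an involution
#' layer (+BN+ReLU) and a dense block, then records a 2x2 max-pooling with
#' argmax indices. The decoder mirrors the encoder: index-preserving
#' unpooling, concatenation with the level's skip feature, and two 3x3
#' convolutions. A 1x1 convolution with a single output map and a sigmoid
#' produces per-pixel lodging scores in (0, 1). With
#' \code{use_involution = FALSE, use_dense = FALSE} the build is the plain
#' U-Net baseline (each level then gets a second 3x3 convolution instead).
#'
#' @param depth number of pooling levels (default 4); input tiles must have
#'   sides divisible by \code{2^depth}.
#' @param base_channels channels of the first encoder level (default 64);
#'   level \code{l} uses \code{base_channels * 2^(l-1)}.
#' @param in_channels input channels (3 for RGB).
#' @param out_maps output feature maps (1 for binary lodging).
#' @param dense_layers layers per dense block (default 2).
#' @param growth channels added by each dense layer; default
#'   \code{level_width / 4} (at least 1).
#' @param use_involution include an involution layer per encoder level.
#' @param use_dense include a dense block per encoder level.
#' @param involution list with \code{kernel_size}, \code{groups},
#'   \code{reduction} applied at every level's width.
#' @param seed seed for parameter initialization (fan-in-scaled uniform).
#' @return object of class \code{network_config}.
#' @export
network_config <- function(depth = 4, base_channels = 64, in_channels = 3,
                           out_maps = 1, dense_layers = 2, growth = NULL,
                           use_involution = TRUE, use_dense = TRUE,
                           involution = list(kernel_size = 7, groups = 1,
                                             reduction = 4),
                           seed = 42) {
  depth <- as.integer(depth)
  base_channels <- as.integer(base_channels)
  if (depth < 1) stop("network_config: depth must be >= 1")
  if (base_channels < 1) stop("network_config: base_channels must be >= 1")
  if (out_maps != 1) stop("network_config: out_maps must be 1 for binary segmentation")
  if (dense_layers < 1) stop("network_config: dense_layers must be >= 1")
  cfg <- structure(list(
    depth = depth, base_channels = base_channels,
    in_channels = as.integer(in_channels), out_maps = as.integer(out_maps),
    dense_layers = as.integer(dense_layers), growth = growth,
    use_involution = isTRUE(use_involution), use_dense = isTRUE(use_dense),
    involution = involution, seed = as.integer(seed)),
    class = "network_config")
  if (cfg$use_involution) {
    for (l in seq_len(depth)) {
      # validates divisibility of every level width by G and r
      invisible(level_invol_spec(cfg, l))
    }
  }
  cfg
}

#' Plain U-Net baseline configuration
#'
#' Convenience wrapper: [network_config()] with involution and dense blocks
#' disabled (two plain 3x3 convolutions per encoder level).
#'
#' @param ... passed to [network_config()].
#' @return a \code{network_config}.
#' @export
unet_config <- function(...) {
  network_config(..., use_involution = FALSE, use_dense = FALSE)
}

level_width <- function(cfg, l) cfg$base_channels * 2L^(l - 1L)

level_growth <- function(cfg, l) {
  if (is.null(cfg$growth)) max(1L, level_width(cfg, l) %/% 4L)
  else as.integer(cfg$growth)
}

level_invol_spec <- function(cfg, l) {
  iv <- cfg$involution
  involution_spec(channels = level_width(cfg, l),
                  kernel_size = iv$kernel_size %||% 7,
                  groups = iv$groups %||% 1,
                  reduction = iv$reduction %||% 4)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- parameter store ---------------------------------------------------

net_new <- function(cfg, store, state, training = FALSE, creating = FALSE) {
  net <- new.env(parent = emptyenv())
  net$tp <- tp_new()
  net$cfg <- cfg
  net$store <- store
  net$state <- state
  net$training <- training
  net$creating <- creating
  net
}

net_param <- function(net, name, dims, init = c("uniform", "zeros", "ones"),
                      fan_in = NULL) {
  init <- match.arg(init)
  p <- net$store$p[[name]]
  if (is.null(p)) {
    if (!net$creating)
      stop("unknown parameter '", name, "': checkpoint/config mismatch")
    p <- switch(init,
      uniform = {
        lim <- sqrt(6 / fan_in)
        array(runif(prod(dims), -lim, lim), dim = dims)
      },
      zeros = array(0, dim = dims),
      ones = array(1, dim = dims))
    if (length(dims) == 2L) p <- matrix(p, dims[1], dims[2])
    net$store$p[[name]] <- p
  }
  tp_param(net$tp, p, name)
}

net_bn <- function(net, xid, name) {
  C <- dim4(tp_value(net$tp, xid))[4]
  gid <- net_param(net, paste0(name, ".gamma"), C, "ones")
  bid <- net_param(net, paste0(name, ".beta"), C, "zeros")
  if (is.null(net$state$stats[[name]]))
    net$state$stats[[name]] <- list(mean = numeric(C), var = rep(1, C))
  nn_bn(net$tp, xid, gid, bid, name, net$state, net$training)
}

layer_cbr <- function(net, xid, name, K, out_ch) {
  in_ch <- dim4(tp_value(net$tp, xid))[4]
  Wid <- net_param(net, paste0(name, ".W"), c(K * K * in_ch, out_ch),
                   "uniform", fan_in = K * K * in_ch)
  bid <- net_param(net, paste0(name, ".b"), out_ch, "zeros")
  y <- nn_conv(net$tp, xid, K, Wid, bid)
  y <- net_bn(net, y, paste0(name, ".bn"))
  nn_relu(net$tp, y)
}

layer_invol <- function(net, xid, name, spec) {
  C <- spec$channels
  Cm <- C %/% spec$reduction
  KKG <- spec$kernel_size^2 * spec$groups
  # kernel generator: 1x1 bottleneck W1 . sigma(W0 . x), sigma = BN + ReLU
  w0 <- net_param(net, paste0(name, ".w0"), c(C, Cm), "uniform", fan_in = C)
  b0 <- net_param(net, paste0(name, ".b0"), Cm, "zeros")
  z <- nn_conv(net$tp, xid, 1L, w0, b0)
  z <- net_bn(net, z, paste0(name, ".nbn"))
  z <- nn_relu(net$tp, z)
  w1 <- net_param(net, paste0(name, ".w1"), c(Cm, KKG), "uniform", fan_in = Cm)
  b1 <- net_param(net, paste0(name, ".b1"), KKG, "zeros")
  ker <- nn_conv(net$tp, z, 1L, w1, b1)
  y <- nn_invol(net$tp, xid, ker, spec$kernel_size, spec$groups)
  y <- net_bn(net, y, paste0(name, ".bn"))
  nn_relu(net$tp, y)
}

# dense block on the tape: layer t consumes the concatenation of the block
# input and all previous layers' outputs; the block output concatenates all
dense_block_tape <- function(net, xid, name, n_layers, growth) {
  feats <- list(xid)
  for (t in seq_len(n_layers)) {
    inp <- if (length(feats) == 1L) feats[[1L]] else nn_concat(net$tp, feats)
    y <- layer_cbr(net, inp, sprintf("%s.dense%d", name, t), 3L, growth)
    feats <- c(feats, y)
  }
  nn_concat(net$tp, feats)
}

# full encoder-decoder assembly on an existing tape; returns the sigmoid
# score node id
net_build <- function(net, xid) {
  cfg <- net$cfg
  d <- dim4(tp_value(net$tp, xid))
  div <- 2L^cfg$depth
  if (d[1] %% div || d[2] %% div)
    stop("network input ", d[1], "x", d[2],
         ": tile sides must be divisible by 2^depth = ", div)
  if (d[4] != cfg$in_channels)
    stop("network input has ", d[4], " channels, config expects ",
         cfg$in_channels)
  skips <- vector("list", cfg$depth)
  idxs <- vector("list", cfg$depth)
  sizes <- vector("list", cfg$depth)
  cur <- xid
  for (l in seq_len(cfg$depth)) {
    w <- level_width(cfg, l)
    cur <- layer_cbr(net, cur, sprintf("enc%d.conv", l), 3L, w)
    if (cfg$use_involution)
      cur <- layer_invol(net, cur, sprintf("enc%d.inv", l),
                         level_invol_spec(cfg, l))
    if (cfg$use_dense) {
      cur <- dense_block_tape(net, cur, sprintf("enc%d", l),
                              cfg$dense_layers, level_growth(cfg, l))
    } else if (!cfg$use_involution) {
      cur <- layer_cbr(net, cur, sprintf("enc%d.conv2", l), 3L, w)
    }
    skips[[l]] <- cur
    sizes[[l]] <- dim4(tp_value(net$tp, cur))
    pr <- nn_pool(net$tp, cur)
    idxs[[l]] <- pr$idx
    cur <- pr$id
  }
  wb <- cfg$base_channels * 2L^cfg$depth
  cur <- layer_cbr(net, cur, "bott.conv1", 3L, wb)
  cur <- layer_cbr(net, cur, "bott.conv2", 3L, wb)
  for (l in seq.int(cfg$depth, 1L)) {
    s_l <- sizes[[l]][4]
    cur <- layer_cbr(net, cur, sprintf("dec%d.proj", l), 1L, s_l)
    cur <- nn_unpool(net$tp, cur, idxs[[l]], sizes[[l]][1], sizes[[l]][2])
    cur <- nn_concat(net$tp, list(cur, skips[[l]]))
    w <- level_width(cfg, l)
    cur <- layer_cbr(net, cur, sprintf("dec%d.conv1", l), 3L, w)
    cur <- layer_cbr(net, cur, sprintf("dec%d.conv2", l), 3L, w)
  }
  in_ch <- dim4(tp_value(net$tp, cur))[4]
  Wh <- net_param(net, "head.W", c(in_ch, cfg$out_maps), "uniform",
                  fan_in = in_ch)
  bh <- net_param(net, "head.b", cfg$out_maps, "zeros")
  cur <- nn_conv(net$tp, cur, 1L, Wh, bh)
  nn_sigmoid(net$tp, cur)
}

## ---- public pooling surface --------------------------------------------

#' Max pooling with retained argmax locations
#'
#' 2x2/stride-2 max pooling that records, per window and channel, where the
#' retained maximum sat. Ties are broken by the first position in the scan
#' order (0,0), (1,0), (0,1), (1,1) (row offset, column offset). The record
#' is what index-preserving [unpool()] needs to place values back.
#'
#' @param x \code{H x W} matrix or \code{H x W x C} array with even
#'   \code{H} and \code{W}.
#' @return object of class \code{pool_record}: \code{pooled} (halved dims),
#'   \code{indices} (within-window position \code{du + 2*dv} per retained
#'   maximum) and the \code{input_dim}.
#' @export
max_pool_with_indices <- function(x) {
  d <- dim(x)
  two_d <- length(d) == 2L
  if (two_d) dim(x) <- d <- c(d, 1L)
  if (d[1] %% 2L || d[2] %% 2L)
    stop("max_pool_with_indices: spatial dims must be even, got ",
         d[1], "x", d[2])
  x4 <- x
  dim(x4) <- c(d[1], d[2], 1L, d[3])
  r <- cpp_maxpool(x4, d[1], d[2], 1L, d[3])
  do <- c(d[1] %/% 2L, d[2] %/% 2L, d[3])
  pooled <- array(r$pooled, do)
  idx <- array(r$idx, do)
  if (two_d) {
    pooled <- matrix(pooled, do[1], do[2])
    idx <- matrix(idx, do[1], do[2])
  }
  structure(list(pooled = pooled, indices = idx, input_dim = d),
            class = "pool_record")
}

#' Index-preserving unpooling
#'
#' Doubles the spatial dimensions of a pooled map, placing each retained
#' value exactly at its recorded argmax location and zero everywhere else —
#' the decoder-side enlargement that reuses the encoder's pooling
#' information.
#'
#' @param rec a [max_pool_with_indices()] record, or a pooled map when
#'   \code{indices} is given separately.
#' @param indices argmax positions (only when \code{rec} is a plain map).
#' @param target_shape \code{c(H, W)} of the output (default: the recorded
#'   input dims).
#' @return map of the target shape, same rank as the pooled input.
#' @export
unpool <- function(rec, indices = NULL, target_shape = NULL) {
  if (inherits(rec, "pool_record")) {
    pooled <- rec$pooled
    indices <- rec$indices
    target_shape <- target_shape %||% rec$input_dim[1:2]
  } else pooled <- rec
  if (is.null(indices)) stop("unpool: indices are required")
  d <- dim(pooled)
  two_d <- length(d) == 2L
  if (two_d) {
    dim(pooled) <- d <- c(d, 1L)
    dim(indices) <- d
  }
  if (!identical(dim(indices), d))
    stop("unpool: indices shape does not match the pooled map")
  if (is.null(target_shape)) target_shape <- 2L * d[1:2]
  if (target_shape[1] != 2L * d[1] || target_shape[2] != 2L * d[2])
    stop("unpool: target shape ", paste(target_shape, collapse = "x"),
         " is not double of ", d[1], "x", d[2])
  x4 <- pooled
  dim(x4) <- c(d[1], d[2], 1L, d[3])
  i4 <- indices
  dim(i4) <- c(d[1], d[2], 1L, d[3])
  y <- cpp_unpool(x4, as.integer(i4), as.integer(target_shape[1]),
                  as.integer(target_shape[2]), 1L, d[3])
  dim(y) <- c(target_shape[1], target_shape[2], d[3])
  if (two_d) matrix(y, target_shape[1], target_shape[2]) else y
}

## ---- standalone dense block --------------------------------------------

conv_single <- function(x, W, b, K) {
  d <- dim(x)
  x4 <- x
  dim(x4) <- c(d[1], d[2], 1L, d[3])
  cols <- cpp_im2col(x4, d[1], d[2], 1L, d[3], K)
  y <- cols %*% W
  y <- y + rep(b, each = nrow(y))
  array(y, dim = c(d[1], d[2], ncol(W)))
}

norm_relu_single <- function(x) {
  d <- dim(x)
  m <- matrix(x, d[1] * d[2], d[3])
  mu <- colMeans(m)
  va <- colMeans(sweep(m, 2, mu)^2)
  array(pmax(sweep(sweep(m, 2, mu), 2, sqrt(va + 1e-5), "/"), 0), dim = d)
}

#' Parameters for a standalone dense block
#'
#' @param in_channels channels of the block input.
#' @param dense_layers number of layers.
#' @param growth channels produced by each layer.
#' @param seed seed for the fan-in-scaled uniform draws.
#' @return list of per-layer \code{W}/\code{b} pairs.
#' @export
dense_block_params <- function(in_channels, dense_layers, growth, seed = 1) {
  set.seed(as.integer(seed))
  pars <- vector("list", dense_layers)
  cin <- in_channels
  for (t in seq_len(dense_layers)) {
    fan <- 9L * cin
    pars[[t]] <- list(
      W = matrix(runif(fan * growth, -sqrt(6 / fan), sqrt(6 / fan)),
                 fan, growth),
      b = numeric(growth))
    cin <- cin + growth
  }
  pars
}

#' Dense feature-reuse block
#'
#' Layer \code{t} consumes the channel-concatenation of the block input and
#' the outputs of layers \code{1..t-1} (full cross-linking, DenseNet style);
#' the block output concatenates the input with every layer's output, so it
#' has \code{C_in + dense_layers * growth} channels.
#'
#' @param x \code{H x W x C} feature map.
#' @param dense_layers number of layers in the block.
#' @param growth channels added by each layer.
#' @param params from [dense_block_params()]; generated from \code{seed}
#'   when NULL.
#' @param seed seed used when \code{params} is NULL.
#' @param zero_layers indices of layers whose output is forced to zero
#'   (perturbation probes of the cross-linking).
#' @param return_layers also return each layer's output.
#' @return the concatenated block output, or (with
#'   \code{return_layers = TRUE}) \code{list(out, layers)}.
#' @export
dense_block <- function(x, dense_layers, growth, params = NULL, seed = 1,
                        zero_layers = integer(0), return_layers = FALSE) {
  if (dense_layers < 1) stop("dense_block: dense_layers must be >= 1")
  d <- dim(x)
  if (length(d) != 3L) stop("dense_block: x must be H x W x C")
  if (is.null(params))
    params <- dense_block_params(d[3], dense_layers, growth, seed)
  feats <- list(x)
  layers <- vector("list", dense_layers)
  for (t in seq_len(dense_layers)) {
    inp <- array(unlist(feats), dim = c(d[1], d[2],
                                        sum(vapply(feats, function(f) dim(f)[3], 0))))
    y <- norm_relu_single(conv_single(inp, params[[t]]$W, params[[t]]$b, 3L))
    if (t %in% zero_layers) y[] <- 0
    layers[[t]] <- y
    feats <- c(feats, list(y))
  }
  out <- array(unlist(feats), dim = c(d[1], d[2], d[3] + dense_layers * growth))
  if (return_layers) list(out = out, layers = layers) else out
}

## ---- model object ------------------------------------------------------

#' Initialize a segmentation model
#'
#' Allocates all parameters of the network described by \code{cfg}
#' (deterministically from \code{cfg$seed}) by tracing one forward pass on a
#' minimal dummy tile, and initializes the batch-normalization running
#' statistics.
#'
#' @param cfg a [network_config()].
#' @return object of class \code{lodge_model}: list with \code{cfg},
#'   \code{params} (arrays keyed by a stable layer-path naming scheme, e.g.
#'   \code{"enc1.conv.W"}) and \code{bn} (running statistics).
#' @export
init_model <- function(cfg) {
  store <- new.env(parent = emptyenv())
  store$p <- list()
  state <- new.env(parent = emptyenv())
  state$stats <- list()
  set.seed(cfg$seed)
  side <- 2L^cfg$depth
  net <- net_new(cfg, store, state, training = FALSE, creating = TRUE)
  xid <- tp_emit(net$tp, array(0, dim = c(side, side, 1L, cfg$in_channels)))
  net_build(net, xid)
  structure(list(cfg = cfg, params = store$p, bn = state$stats),
            class = "lodge_model")
}

model_env <- function(model) {
  store <- new.env(parent = emptyenv())
  store$p <- model$params
  state <- new.env(parent = emptyenv())
  state$stats <- model$bn
  list(store = store, state = state)
}

# accepts H x W x C (single tile) or H x W x N x C (batch); images on a
# 0..255 scale are mapped to [0, 1]
as_batch <- function(x) {
  d <- dim(x)
  if (length(d) == 3L) dim(x) <- c(d[1], d[2], 1L, d[3])
  else if (length(d) != 4L) stop("input must be H x W x C or H x W x N x C")
  if (max(x) > 1.5) x <- x / 255
  x
}

#' Forward pass of a segmentation model
#'
#' @param model a [init_model()] result (possibly trained).
#' @param x input tile \code{H x W x C} or batch \code{H x W x N x C};
#'   8-bit (0..255) inputs are rescaled to \[0, 1\].
#' @param training use batch statistics in the normalization layers
#'   (default FALSE: inference mode with running averages, deterministic).
#' @return per-pixel lodging scores in (0, 1): \code{H x W} matrix for a
#'   single tile, \code{H x W x N} array for a batch.
#' @export
model_forward <- function(model, x, training = FALSE) {
  single <- length(dim(x)) == 3L
  xb <- as_batch(x)
  env <- model_env(model)
  net <- net_new(model$cfg, env$store, env$state, training = training)
  xid <- tp_emit(net$tp, xb)
  out <- tp_value(net$tp, net_build(net, xid))
  d <- dim(out)
  if (single) matrix(out, d[1], d[2]) else array(out, d[c(1, 2, 3)])
}

#' Count trainable parameters
#'
#' @param model a \code{lodge_model}.
#' @param prefix optional layer-path prefix filter (e.g. \code{"enc1.inv"}).
#' @return total number of parameter entries.
#' @export
count_params <- function(model, prefix = NULL) {
  nms <- names(model$params)
  if (!is.null(prefix)) nms <- nms[startsWith(nms, prefix)]
  sum(vapply(model$params[nms], length, numeric(1)))
}

#' @export
print.lodge_model <- function(x, ...) {
  cat(sprintf(
    "lodging segmentation model: depth %d, base %d, %s%s%d parameters\n",
    x$cfg$depth, x$cfg$base_channels,
    if (x$cfg$use_involution) "involution, " else "",
    if (x$cfg$use_dense) "dense blocks, " else "",
    count_params(x)))
  invisible(x)
}

## ---- checkpointing -----------------------------------------------------

#' Save a model checkpoint
#'
#' A single archive holding all parameter grids keyed by layer path, the
#' batch-normalization running statistics, the network configuration used to
#' build them, and (optionally) a training history.
#'
#' @param model a \code{lodge_model}.
#' @param path file to write.
#' @param history optional training history to store alongside.
#' @return \code{path}, invisibly.
#' @export
save_checkpoint <- function(model, path, history = NULL) {
  saveRDS(list(format = "lodgeseg-checkpoint-1", cfg = model$cfg,
               params = model$params, bn = model$bn, history = history),
          path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path checkpoint file from [save_checkpoint()].
#' @param cfg optional [network_config()]; if supplied, loading is refused
#'   unless it matches the configuration stored in the checkpoint.
#' @return the restored \code{lodge_model} (training history, if stored, is
#'   attached as attribute \code{"history"}).
#' @export
load_checkpoint <- function(path, cfg = NULL) {
  ck <- readRDS(path)
  if (!identical(ck$format, "lodgeseg-checkpoint-1"))
    stop("load_checkpoint: ", path, " is not a lodgeseg checkpoint")
  if (!is.null(cfg) && !identical(unclass(cfg), unclass(ck$cfg)))
    stop("load_checkpoint: checkpoint was built with a different ",
         "network config; refusing to load")
  m <- structure(list(cfg = ck$cfg, params = ck$params, bn = ck$bn),
                 class = "lodge_model")
  attr(m, "history") <- ck$history
  m
}
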