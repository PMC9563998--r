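#' Training configuration
#'
#' Defaults follow the study protocol for the full-scale task: Adam with
#' initial learning rate 0.001, batch size 10, 100 epochs, Tversky loss,
#' 80/20 train/test split. Epochs are routinely lowered for desk-scale
#' smoke runs.
#'
#' @param learning_rate Adam step size (> 0).
#' @param batch_size tiles per gradient step (>= 1).
#' @param epochs training epochs (>= 1).
#' @param loss a [tversky_params()].
#' @param train_fraction fraction of tiles used for training; the held-out
#'   remainder doubles as the validation set for curve logging.
#' @param seed seed covering initialization, data order and splitting.
#' @param checkpoint optional path: the best-validation-loss model is saved
#'   there.
#' @return object of class \code{train_config}.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 10,
                         epochs = 100, loss = tversky_params(),
                         train_fraction = 0.8, seed = 1,
                         checkpoint = NULL) {
  if (learning_rate < 0) stop("train_config: learning_rate must be >= 0")
  if (batch_size < 1) stop("train_config: batch_size must be >= 1")
  if (epochs < 1) stop("train_config: epochs must be >= 1")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), loss = loss,
                 train_fraction = train_fraction, seed = as.integer(seed),
                 checkpoint = checkpoint),
            class = "train_config")
}

adam_new <- function() {
  e <- new.env(parent = emptyenv())
  e$m <- list(); e$v <- list(); e$t <- 0L
  e
}

adam_step <- function(store, grads, ad, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  ad$t <- ad$t + 1L
  bc1 <- 1 - beta1^ad$t
  bc2 <- 1 - beta2^ad$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    m <- ad$m[[nm]]
    v <- ad$v[[nm]]
    if (is.null(m)) { m <- g * 0; v <- g * 0 }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    ad$m[[nm]] <- m
    ad$v[[nm]] <- v
    store$p[[nm]] <- store$p[[nm]] - lr * (m / bc1) / (sqrt(v / bc2) + eps)
  }
}

# pairs: list of list(image HxWxC 0..255, mask HxW); returns (H,W,N,C) batch
# scaled to [0,1] plus (H,W,N,1) truth
assemble_batch <- function(pairs, idx) {
  n <- length(idx)
  d <- dim(pairs[[idx[1]]]$image)
  xb <- array(0, dim = c(d[1], d[2], n, d[3]))
  tb <- array(0, dim = c(d[1], d[2], n, 1L))
  for (k in seq_len(n)) {
    xb[, , k, ] <- pairs[[idx[k]]]$image
    tb[, , k, 1] <- pairs[[idx[k]]]$mask
  }
  if (max(xb) > 1.5) xb <- xb / 255
  list(x = xb, t = tb)
}

load_pairs <- function(data) {
  if (is.data.frame(data)) {
    lapply(seq_len(nrow(data)), function(i)
      list(image = read_raster(data$image[i]), mask = read_mask(data$mask[i])))
  } else data
}

batched_eval <- function(cfg, store, state, pairs, idx, batch_size, tv) {
  # inference-mode forward over a tile set: Tversky loss on pooled soft
  # counts, Dice on pooled hard counts at threshold 0.5
  loss_num <- 0; conf <- list(tp = 0, fp = 0, fn = 0, tn = 0)
  preds <- 0; npix <- 0
  sTP <- 0; sFN <- 0; sFP <- 0
  for (chunk in split(idx, ceiling(seq_along(idx) / batch_size))) {
    b <- assemble_batch(pairs, chunk)
    net <- net_new(cfg, store, state, training = FALSE)
    out <- tp_value(net$tp, net_build(net, tp_emit(net$tp, b$x)))
    p <- as.numeric(out); t <- as.numeric(b$t)
    sTP <- sTP + sum(p * t)
    sFN <- sFN + sum((1 - p) * t)
    sFP <- sFP + sum(p * (1 - t))
    hp <- (p >= 0.5) * 1
    conf$tp <- conf$tp + sum(hp == 1 & t == 1)
    conf$fp <- conf$fp + sum(hp == 1 & t == 0)
    conf$fn <- conf$fn + sum(hp == 0 & t == 1)
    conf$tn <- conf$tn + sum(hp == 0 & t == 0)
  }
  loss <- 1 - (sTP + tv$epsilon) /
    (sTP + tv$alpha * sFN + tv$beta * sFP + tv$epsilon)
  list(loss = loss, metrics = seg_metrics(conf))
}

#' Train a segmentation model
#'
#' Seeded end-to-end: the train/validation split, parameter initialization,
#' and per-epoch data order all derive from \code{cfg$seed} (and the
#' network seed). After each epoch the held-out tiles are evaluated in
#' inference mode; the parameters of the best-validation-loss epoch are the
#' ones returned (and checkpointed if \code{cfg$checkpoint} is set).
#'
#' @param data list of \code{list(image, mask)} pairs (e.g. from
#'   [make_scenes()]), or a manifest data.frame with \code{image}/\code{mask}
#'   path columns.
#' @param net_cfg a [network_config()].
#' @param cfg a [train_config()].
#' @param quiet suppress per-epoch progress lines.
#' @return object of class \code{lodge_train_report}: the trained
#'   \code{model}, \code{history} data.frame (per-epoch training and
#'   validation loss, validation Dice), \code{best_epoch}, final held-out
#'   \code{metrics}, \code{wall_clock_s}, and the configs.
#' @export
train_model <- function(data, net_cfg, cfg = train_config(), quiet = TRUE) {
  t0 <- Sys.time()
  pairs <- load_pairs(data)
  if (!length(pairs)) stop("train_model: empty dataset")
  sp <- split_pairs(length(pairs), cfg$train_fraction, cfg$seed)
  if (!length(sp$train) || !length(sp$test))
    stop("train_model: empty train or validation split")
  model <- init_model(net_cfg)
  store <- new.env(parent = emptyenv()); store$p <- model$params
  state <- new.env(parent = emptyenv()); state$stats <- model$bn
  ad <- adam_new()
  tv <- cfg$loss
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0), val_dice = numeric(0))
  best <- list(loss = Inf, params = NULL, bn = NULL, epoch = 0L)
  set.seed(cfg$seed + 1L)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample(sp$train)
    ep_loss <- 0; nb <- 0
    for (chunk in split(ord, ceiling(seq_along(ord) / cfg$batch_size))) {
      b <- assemble_batch(pairs, chunk)
      net <- net_new(net_cfg, store, state, training = TRUE)
      out <- net_build(net, tp_emit(net$tp, b$x))
      lid <- nn_tversky(net$tp, out, b$t, tv$alpha, tv$beta, tv$epsilon)
      loss <- tp_value(net$tp, lid)
      if (!is.finite(loss))
        stop("train_model: non-finite training loss at epoch ", ep,
             " (diverged); lower the learning rate")
      grads <- tp_backward(net$tp, lid)
      if (cfg$learning_rate > 0)
        adam_step(store, grads, ad, cfg$learning_rate)
      ep_loss <- ep_loss + loss; nb <- nb + 1
    }
    ev <- batched_eval(net_cfg, store, state, pairs, sp$test,
                       cfg$batch_size, tv)
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = ep_loss / nb,
                                   val_loss = ev$loss,
                                   val_dice = ev$metrics$dice))
    if (!quiet)
      message(sprintf("epoch %3d  train %.4f  val %.4f  dice %.4f",
                      ep, ep_loss / nb, ev$loss, ev$metrics$dice))
    if (ev$loss < best$loss)
      best <- list(loss = ev$loss, params = store$p, bn = state$stats,
                   epoch = ep)
  }
  model$params <- best$params
  model$bn <- best$bn
  ev <- batched_eval(net_cfg, model_env(model)$store, model_env(model)$state,
                     pairs, sp$test, cfg$batch_size, tv)
  if (!is.null(cfg$checkpoint)) save_checkpoint(model, cfg$checkpoint, hist)
  structure(list(model = model, history = hist, best_epoch = best$epoch,
                 metrics = ev$metrics, split = sp,
                 wall_clock_s = as.numeric(difftime(Sys.time(), t0,
                                                    units = "secs")),
                 net_cfg = net_cfg, train_cfg = cfg,
                 checkpoint = cfg$checkpoint),
            class = "lodge_train_report")
}

#' @export
print.lodge_train_report <- function(x, ...) {
  cat(sprintf(
    "training report: %d epochs (best %d), final val dice %.4f, %.1f s\n",
    nrow(x$history), x$best_epoch, x$metrics$dice, x$wall_clock_s))
  invisible(x)
}

#' Predict a lodging mask for a whole raster
#'
#' Tile -> forward -> stitch: the raster is cut with \code{tiling}
#' (zero-padding edges so output dims equal input dims), each tile is
#' scored by the model, overlapping scores are averaged, and the average is
#' thresholded.
#'
#' @param model a trained \code{lodge_model} (or checkpoint path).
#' @param image \code{H x W x C} raster on the 0..255 or 0..1 scale.
#' @param tiling a [tiling_spec()]; tile side must satisfy the model's
#'   divisibility constraint. Default: the model's native 256 window,
#'   padded edges.
#' @param threshold score cut for the binary mask (default 0.5).
#' @param batch_size tiles scored per forward pass.
#' @return \code{list(mask, scores)}, both \code{H x W}; \code{mask} is
#'   \{0, 1\}, \code{scores} the stitched per-pixel probabilities.
#' @export
predict_raster <- function(model, image,
                           tiling = tiling_spec(tile = 256,
                                                edge_policy = "pad"),
                           threshold = 0.5, batch_size = 10) {
  if (is.character(model)) model <- load_checkpoint(model)
  d <- dim(image)
  if (length(d) == 2L) dim(image) <- d <- c(d, 1L)
  if (d[3] != model$cfg$in_channels)
    stop("predict_raster: raster has ", d[3],
         " channels, model expects ", model$cfg$in_channels)
  tiles <- tile_raster(image, NULL, tiling)
  if (!length(tiles)) stop("predict_raster: no tiles to score")
  env <- model_env(model)
  score_tiles <- vector("list", length(tiles))
  for (chunk in split(seq_along(tiles),
                      ceiling(seq_along(tiles) / batch_size))) {
    n <- length(chunk)
    xb <- array(0, dim = c(tiling$tile, tiling$tile, n, d[3]))
    for (k in seq_len(n)) xb[, , k, ] <- tiles[[chunk[k]]]$image
    if (max(xb) > 1.5) xb <- xb / 255
    net <- net_new(model$cfg, env$store, env$state, training = FALSE)
    out <- tp_value(net$tp, net_build(net, tp_emit(net$tp, xb)))
    for (k in seq_len(n))
      score_tiles[[chunk[k]]] <- list(values = matrix(out[, , k, 1],
                                                      tiling$tile,
                                                      tiling$tile),
                                      row = tiles[[chunk[k]]]$row,
                                      col = tiles[[chunk[k]]]$col)
  }
  scores <- stitch_tiles(score_tiles, d[1:2], what = "values")
  mask <- (scores >= threshold) * 1
  list(mask = mask, scores = scores)
}

#' Evaluate a predicted mask against ground truth
#'
#' @param pred \{0, 1\} predicted mask.
#' @param truth \{0, 1\} reference mask of the same shape.
#' @return list with \code{counts} ([confusion()]) and \code{metrics}
#'   ([seg_metrics()]).
#' @export
evaluate_masks <- function(pred, truth) {
  counts <- confusion(pred, truth)
  list(counts = counts, metrics = seg_metrics(counts))
}

#' Evaluate many mask pairs with pooled aggregation
#'
#' Per-image metrics plus an aggregate computed from the summed confusion
#' counts (count pooling, not metric averaging).
#'
#' @param preds,truths lists of aligned \{0, 1\} masks.
#' @return list with \code{per_image} (list of metric lists),
#'   \code{pooled_counts} and \code{aggregate} metrics.
#' @export
evaluate_many <- function(preds, truths) {
  stopifnot(length(preds) == length(truths))
  counts <- Map(confusion, preds, truths)
  pooled <- pool_confusion(counts)
  list(per_image = lapply(counts, seg_metrics),
       pooled_counts = pooled,
       aggregate = seg_metrics(pooled))
}
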