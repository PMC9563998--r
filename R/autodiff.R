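# Minimal reverse-mode tape over dense arrays.
#
# Every feature map on the tape is an (H, W, N, C) array (batch in dim 3,
# channels last) so its (H*W*N) x C matrix view is a zero-copy reshape.
# Each node stores a value, its parent ids and a vector-Jacobian closure;
# backward walks nodes in reverse creation order, which is a valid
# topological order because ops only consume already-emitted nodes.

tp_new <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- list()
  tp$params <- integer(0)
  tp
}

tp_emit <- function(tp, value, parents = integer(0), vjp = NULL) {
  id <- length(tp$nodes) + 1L
  tp$nodes[[id]] <- list(value = value, parents = parents, vjp = vjp)
  id
}

tp_value <- function(tp, id) {
  force(id)  # ops passed inline may emit their node while being forced
  tp$nodes[[id]]$value
}

tp_param <- function(tp, value, name) {
  id <- tp_emit(tp, value)
  tp$params <- c(tp$params, stats::setNames(id, name))
  id
}

# Returns the gradient of node `loss_id` w.r.t. every registered parameter,
# as a named list aligned with tp$params.
tp_backward <- function(tp, loss_id, seed_grad = 1) {
  force(loss_id)  # may emit its node while being forced
  n <- length(tp$nodes)
  grads <- vector("list", n)
  grads[[loss_id]] <- seed_grad
  for (id in seq.int(n, 1L)) {
    g <- grads[[id]]
    if (is.null(g)) next
    nd <- tp$nodes[[id]]
    if (!is.null(nd$vjp) && length(nd$parents)) {
      pg <- nd$vjp(g)
      for (k in seq_along(nd$parents)) {
        if (is.null(pg[[k]])) next
        p <- nd$parents[[k]]
        grads[[p]] <- if (is.null(grads[[p]])) pg[[k]] else grads[[p]] + pg[[k]]
      }
      grads[id] <- list(NULL)  # release interior-node gradient storage
    }
  }
  out <- lapply(tp$params, function(i) grads[[i]])
  names(out) <- names(tp$params)
  out
}

dim4 <- function(x) {
  d <- dim(x)
  stopifnot(length(d) == 4L)
  d
}

mat_view <- function(x) {
  d <- dim4(x)
  dim(x) <- c(d[1] * d[2] * d[3], d[4])
  x
}

arr_view <- function(x, d) {
  dim(x) <- d
  x
}

# column-wise broadcast add/multiply over the (R x C) matrix view
bcast_col <- function(m, v) rep(v, each = nrow(m))

## ---- primitive layers --------------------------------------------------

# stride-1 "same" convolution; W is a (K*K*C_in) x C_out matrix whose row
# order matches cpp_im2col's (u, v, c) patch order, b a length-C_out bias.
nn_conv <- function(tp, xid, K, Wid, bid) {
  x <- tp_value(tp, xid)
  d <- dim4(x)
  W <- tp_value(tp, Wid)
  b <- tp_value(tp, bid)
  cols <- cpp_im2col(x, d[1], d[2], d[3], d[4], K)
  y <- cols %*% W
  y <- y + bcast_col(y, b)
  tp_emit(tp, arr_view(y, c(d[1], d[2], d[3], ncol(W))),
          parents = c(xid, Wid, bid),
          vjp = function(g) {
            gm <- mat_view(g)
            gx <- cpp_col2im(gm %*% t(W), d[1], d[2], d[3], d[4], K)
            list(arr_view(gx, d), crossprod(cols, gm), colSums(gm))
          })
}

# Batch normalization over all pixels of the batch, per channel.
# `state` is an environment holding running statistics under `name`;
# training mode normalizes by batch moments and updates the running
# averages, inference mode uses the stored averages.
nn_bn <- function(tp, xid, gid, bid, name, state, training,
                  momentum = 0.1, eps = 1e-5) {
  x <- tp_value(tp, xid)
  d <- dim4(x)
  xm <- mat_view(x)
  gamma <- tp_value(tp, gid)
  beta <- tp_value(tp, bid)
  R <- nrow(xm)
  if (training) {
    mu <- colMeans(xm)
    xc <- xm - bcast_col(xm, mu)
    va <- colMeans(xc * xc)
    st <- state$stats[[name]]
    state$stats[[name]] <- list(
      mean = (1 - momentum) * st$mean + momentum * mu,
      var  = (1 - momentum) * st$var + momentum * va)
  } else {
    st <- state$stats[[name]]
    mu <- st$mean
    va <- st$var
    xc <- xm - bcast_col(xm, mu)
  }
  inv <- 1 / sqrt(va + eps)
  xhat <- xc * bcast_col(xc, inv)
  y <- xhat * bcast_col(xhat, gamma) + bcast_col(xhat, beta)
  tp_emit(tp, arr_view(y, d),
          parents = c(xid, gid, bid),
          vjp = function(g) {
            gm <- mat_view(g)
            dxhat <- gm * bcast_col(gm, gamma)
            ggamma <- colSums(gm * xhat)
            gbeta <- colSums(gm)
            if (training) {
              s1 <- colMeans(dxhat)
              s2 <- colMeans(dxhat * xhat)
              dx <- (dxhat - bcast_col(dxhat, s1) - xhat * bcast_col(xhat, s2)) *
                bcast_col(dxhat, inv)
            } else {
              dx <- dxhat * bcast_col(dxhat, inv)
            }
            list(arr_view(dx, d), ggamma, gbeta)
          })
}

nn_relu <- function(tp, xid) {
  x <- tp_value(tp, xid)
  y <- pmax(x, 0)
  tp_emit(tp, y, parents = xid,
          vjp = function(g) list(g * (x > 0)))
}

nn_sigmoid <- function(tp, xid) {
  x <- tp_value(tp, xid)
  y <- 1 / (1 + exp(-x))
  tp_emit(tp, y, parents = xid,
          vjp = function(g) list(g * y * (1 - y)))
}

# 2x2/stride-2 max pooling; returns list(id, idx) where idx is plain data
# (the recorded argmax positions), not a tape node.
nn_pool <- function(tp, xid) {
  x <- tp_value(tp, xid)
  d <- dim4(x)
  if (d[1] %% 2L || d[2] %% 2L)
    stop("max_pool_with_indices: spatial dims must be even, got ",
         d[1], "x", d[2])
  r <- cpp_maxpool(x, d[1], d[2], d[3], d[4])
  do <- c(d[1] %/% 2L, d[2] %/% 2L, d[3], d[4])
  idx <- arr_view(r$idx, do)
  id <- tp_emit(tp, arr_view(r$pooled, do), parents = xid,
                vjp = function(g) {
                  list(arr_view(cpp_maxpool_bwd(g, idx, d[1], d[2], d[3], d[4]), d))
                })
  list(id = id, idx = idx)
}

nn_unpool <- function(tp, xid, idx, H, W) {
  x <- tp_value(tp, xid)
  d <- dim4(x)
  if (!identical(dim(idx), dim(x)))
    stop("unpool: index shape ", paste(dim(idx), collapse = "x"),
         " does not match input shape ", paste(d, collapse = "x"))
  if (H != 2L * d[1] || W != 2L * d[2])
    stop("unpool: target ", H, "x", W, " is not double of ", d[1], "x", d[2])
  y <- cpp_unpool(x, idx, H, W, d[3], d[4])
  tp_emit(tp, arr_view(y, c(H, W, d[3], d[4])), parents = xid,
          vjp = function(g) {
            list(arr_view(cpp_unpool_bwd(g, idx, H, W, d[3], d[4]), d))
          })
}

# concatenate along the channel axis (dim 4)
nn_concat <- function(tp, xids) {
  xids <- as.integer(unlist(xids))
  vals <- lapply(xids, tp_value, tp = tp)
  ds <- lapply(vals, dim4)
  base <- ds[[1]][1:3]
  for (d in ds) stopifnot(identical(d[1:3], base))
  chans <- vapply(ds, function(d) d[4], integer(1) + 0)
  y <- array(unlist(vals, use.names = FALSE), dim = c(base, sum(chans)))
  lens <- vapply(vals, length, numeric(1))
  offs <- cumsum(c(0, lens))
  tp_emit(tp, y, parents = as.integer(xids),
          vjp = function(g) {
            g <- as.numeric(g)
            lapply(seq_along(xids), function(k) {
              arr_view(g[(offs[k] + 1):offs[k + 1]], ds[[k]])
            })
          })
}

# involution multiply-add: per-pixel kernels from the tape node `kid`
nn_invol <- function(tp, xid, kid, K, G) {
  x <- tp_value(tp, xid)
  ker <- tp_value(tp, kid)
  d <- dim4(x)
  dk <- dim4(ker)
  if (dk[4] != K * K * G)
    stop("involution: kernel field has ", dk[4],
         " slices, expected K*K*G = ", K * K * G)
  if (!identical(dk[1:3], d[1:3]))
    stop("involution: kernel spatial/batch dims do not match input")
  if (G > d[4]) stop("involution: groups G = ", G, " exceed channels C = ", d[4])
  y <- cpp_invol_fwd(x, ker, d[1], d[2], d[3], d[4], K, G)
  tp_emit(tp, arr_view(y, d), parents = c(xid, kid),
          vjp = function(g) {
            r <- cpp_invol_bwd(x, ker, g, d[1], d[2], d[3], d[4], K, G)
            list(arr_view(r$gx, d), arr_view(r$gker, dk))
          })
}

# Soft Tversky loss node: TP/FN/FP are sums of predicted probabilities over
# positive/negative label pixels, so the node is differentiable in pred.
nn_tversky <- function(tp, pid, truth, alpha, beta, eps) {
  p <- tp_value(tp, pid)
  t <- as.numeric(truth)
  pv <- as.numeric(p)
  TP <- sum(pv * t)
  FN <- sum((1 - pv) * t)
  FP <- sum(pv * (1 - t))
  num <- TP + eps
  den <- TP + alpha * FN + beta * FP + eps
  tl <- 1 - num / den
  tp_emit(tp, tl, parents = pid,
          vjp = function(g) {
            # d/dp of 1 - num/den with dTP=t, dFN=-t, dFP=1-t
            dden <- t - alpha * t + beta * (1 - t)
            gp <- -(t * den - num * dden) / (den * den)
            list(arr_view(g * gp, dim(p)))
          })
}
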