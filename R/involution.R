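#' Involution operator hyperparameters
#'
#' The involution operator is the dual of convolution: instead of one kernel
#' shared across all spatial positions with channel-specific weights, it
#' generates a distinct \code{K x K} kernel at every pixel from that pixel's
#' own feature vector, and shares each kernel across a group of channels.
#' \code{groups} counts how many kernels are generated per pixel: with
#' \code{C} channels and \code{C/G} channels sharing one kernel there are
#' \code{G} groups (e.g. 32 channels with 16 channels per kernel gives
#' \code{G = 2}).
#'
#' @param channels number of input/output channels \code{C}.
#' @param kernel_size odd neighborhood side \code{K} (default 7).
#' @param groups number of channel groups \code{G} sharing a kernel
#'   (default 1: all channels at a pixel use the same kernel).
#' @param reduction bottleneck reduction ratio \code{r} of the kernel
#'   generator: its hidden width is \code{C / r} (default 4).
#' @param stride sampling stride of the output grid (default 1).
#' @return an object of class \code{involution_spec}.
#' @examples
#' involution_spec(channels = 16, kernel_size = 3)
#' @export
involution_spec <- function(channels, kernel_size = 7, groups = 1,
                            reduction = 4, stride = 1) {
  channels <- as.integer(channels)
  kernel_size <- as.integer(kernel_size)
  groups <- as.integer(groups)
  reduction <- as.integer(reduction)
  stride <- as.integer(stride)
  if (channels < 1) stop("involution_spec: channels must be >= 1")
  if (kernel_size < 1 || kernel_size %% 2L == 0L)
    stop("involution_spec: kernel_size must be odd and positive, got ",
         kernel_size)
  if (groups < 1 || channels %% groups != 0L)
    stop("involution_spec: groups (", groups,
         ") must divide channels (", channels, ")")
  if (reduction < 1 || channels %% reduction != 0L)
    stop("involution_spec: reduction (", reduction,
         ") must divide channels (", channels, ")")
  if (stride < 1) stop("involution_spec: stride must be >= 1")
  structure(list(channels = channels, kernel_size = kernel_size,
                 groups = groups, reduction = reduction, stride = stride),
            class = "involution_spec")
}

#' @export
print.involution_spec <- function(x, ...) {
  cat(sprintf("involution spec: C=%d K=%d G=%d r=%d stride=%d\n",
              x$channels, x$kernel_size, x$groups, x$reduction, x$stride))
  invisible(x)
}

#' Channel-to-group assignment of the involution operator
#'
#' Channel \code{k} (0-based) uses the kernel of group
#' \code{floor(k * G / C)} (0-based), i.e. consecutive blocks of
#' \code{C / G} channels share one kernel.
#'
#' @param k 0-based channel index (vectorized).
#' @param spec an [involution_spec()].
#' @return 0-based group indices.
#' @export
involution_group <- function(k, spec) {
  as.integer(floor(k * spec$groups / spec$channels))
}

#' Initialize parameters of an involution layer
#'
#' The kernel-generating function is a two-layer pointwise bottleneck
#' \code{H = W1 sigma(W0 x)} where \code{W0} maps \code{C -> C/r},
#' \code{W1} maps \code{C/r -> K*K*G}, and \code{sigma} is normalization
#' followed by a rectified-linear activation. Weights are drawn from a
#' fan-in-scaled uniform distribution; biases start at zero and the
#' normalization at identity.
#'
#' @param spec an [involution_spec()].
#' @param seed integer seed for the weight draws.
#' @return named list of parameter arrays (\code{w0, b0, n_gamma, n_beta,
#'   w1, b1, bn_gamma, bn_beta} plus output-normalization slots used by
#'   [involution_layer()]).
#' @export
involution_params <- function(spec, seed = 1) {
  set.seed(as.integer(seed))
  C <- spec$channels
  Cm <- C %/% spec$reduction
  KKG <- spec$kernel_size^2 * spec$groups
  lim0 <- sqrt(6 / C)
  lim1 <- sqrt(6 / Cm)
  list(
    w0 = matrix(runif(Cm * C, -lim0, lim0), nrow = Cm, ncol = C),
    b0 = numeric(Cm),
    n_gamma = rep(1, Cm), n_beta = numeric(Cm),
    w1 = matrix(runif(KKG * Cm, -lim1, lim1), nrow = KKG, ncol = Cm),
    b1 = numeric(KKG),
    out_gamma = rep(1, C), out_beta = numeric(C)
  )
}

#' Generate the per-pixel involution kernel field
#'
#' Applies the bottleneck generator \code{W1 sigma(W0 x_ij)} independently at
#' every pixel of \code{x} (or at every \code{stride}-th pixel), where
#' \code{sigma} normalizes the hidden activations (zero mean, unit variance
#' over the map, then an affine rescale) and rectifies them. The result is a
#' kernel field with one \code{K x K} kernel per pixel per channel group.
#'
#' @param x numeric \code{H x W x C} feature map.
#' @param spec an [involution_spec()]; \code{spec$channels} must equal
#'   \code{dim(x)[3]}.
#' @param params parameters from [involution_params()].
#' @return \code{H' x W' x (K*K*G)} array (\code{H' = ceiling(H/stride)}),
#'   slice \code{u + K*v + K*K*g + 1} holding the weight for neighborhood
#'   offset \code{(u - floor(K/2), v - floor(K/2))} of group \code{g}.
#' @export
generate_kernels <- function(x, spec, params) {
  d <- dim(x)
  if (length(d) != 3L)
    stop("generate_kernels: x must be H x W x C, got ",
         paste(d, collapse = "x"), " (rank ", length(d), ")")
  if (d[3] != spec$channels)
    stop("generate_kernels: x has ", d[3], " channels but spec$channels = ",
         spec$channels)
  s <- spec$stride
  rows <- seq(1L, d[1], by = s)
  cols <- seq(1L, d[2], by = s)
  xs <- x[rows, cols, , drop = FALSE]
  ds <- dim(xs)
  xm <- matrix(xs, nrow = ds[1] * ds[2], ncol = ds[3])
  z <- xm %*% t(params$w0)
  z <- z + rep(params$b0, each = nrow(z))
  # sigma: normalization (per hidden channel, over all positions) + ReLU
  mu <- colMeans(z)
  va <- colMeans(sweep(z, 2, mu)^2)
  zh <- sweep(sweep(z, 2, mu), 2, sqrt(va + 1e-5), "/")
  zh <- sweep(sweep(zh, 2, params$n_gamma, "*"), 2, params$n_beta, "+")
  zh <- pmax(zh, 0)
  k <- zh %*% t(params$w1)
  k <- k + rep(params$b1, each = nrow(k))
  array(k, dim = c(ds[1], ds[2], spec$kernel_size^2 * spec$groups))
}

#' Apply a field of per-pixel kernels to a feature map
#'
#' The involution multiply-add: output channel \code{k} at pixel
#' \code{(i, j)} is the sum over the \code{K x K} neighborhood of the input
#' channel \code{k}, weighted by the kernel generated at \code{(i, j)} for
#' channel \code{k}'s group. Stride 1 uses zero padding of
#' \code{floor(K/2)} so the output keeps the input's spatial size; for
#' \code{stride > 1} the output is the strided grid of sampled pixels.
#'
#' @param x \code{H x W x C} feature map.
#' @param kernels kernel field from [generate_kernels()] (matching stride).
#' @param spec the [involution_spec()] used to generate \code{kernels}.
#' @return feature map with \code{C} channels on the (possibly strided) grid.
#' @export
involution_forward <- function(x, kernels, spec) {
  d <- dim(x)
  if (length(d) != 3L || d[3] != spec$channels)
    stop("involution_forward: x must be H x W x C with C = spec$channels")
  K <- spec$kernel_size
  G <- spec$groups
  dk <- dim(kernels)
  if (length(dk) != 3L || dk[3] != K * K * G)
    stop("involution_forward: kernel field third dim is ", dk[3],
         ", expected K*K*G = ", K * K * G)
  s <- spec$stride
  if (s == 1L) {
    if (!identical(dk[1:2], d[1:2]))
      stop("involution_forward: kernel spatial dims ",
           paste(dk[1:2], collapse = "x"), " do not match input ",
           paste(d[1:2], collapse = "x"))
    x4 <- x
    dim(x4) <- c(d[1], d[2], 1L, d[3])
    k4 <- kernels
    dim(k4) <- c(dk[1], dk[2], 1L, dk[3])
    y <- cpp_invol_fwd(x4, k4, d[1], d[2], 1L, d[3], K, G)
    return(array(y, dim = d))
  }
  # strided output = stride-1 output sampled on the strided grid, with the
  # kernel field already generated on that grid
  rows <- seq(1L, d[1], by = s)
  cols <- seq(1L, d[2], by = s)
  if (!identical(dk[1:2], c(length(rows), length(cols))))
    stop("involution_forward: kernel field does not match the strided grid")
  full <- array(0, dim = c(d[1], d[2], K * K * G))
  full[rows, cols, ] <- kernels
  x4 <- x
  dim(x4) <- c(d[1], d[2], 1L, d[3])
  dim(full) <- c(d[1], d[2], 1L, K * K * G)
  y <- array(cpp_invol_fwd(x4, full, d[1], d[2], 1L, d[3], K, G), dim = d)
  y[rows, cols, , drop = FALSE]
}

#' Full involution layer
#'
#' Composition kernel generation -> involution multiply-add -> normalization
#' -> rectified-linear activation, the "Involution + BN + ReLU" stage of the
#' segmentation network's encoder.
#'
#' @inheritParams generate_kernels
#' @param activation apply the trailing normalization + ReLU (default TRUE);
#'   set FALSE to obtain the raw multiply-add output.
#' @return feature map of the same shape as \code{x} (stride 1).
#' @export
involution_layer <- function(x, spec, params, activation = TRUE) {
  k <- generate_kernels(x, spec, params)
  y <- involution_forward(x, k, spec)
  if (!activation) return(y)
  d <- dim(y)
  ym <- matrix(y, nrow = d[1] * d[2], ncol = d[3])
  mu <- colMeans(ym)
  va <- colMeans(sweep(ym, 2, mu)^2)
  ym <- sweep(sweep(ym, 2, mu), 2, sqrt(va + 1e-5), "/")
  ym <- sweep(sweep(ym, 2, params$out_gamma, "*"), 2, params$out_beta, "+")
  array(pmax(ym, 0), dim = d)
}

#' Naive reference involution (testing oracle)
#'
#' A direct transcription of the operator's definition as nested loops over
#' output pixel, channel and neighborhood offset. Quadratically slower than
#' [involution_forward()] but independent of it; intended for verification
#' on small inputs.
#'
#' @inheritParams involution_forward
#' @return same as [involution_forward()] (stride 1 only).
#' @export
involution_reference <- function(x, kernels, spec) {
  d <- dim(x)
  K <- spec$kernel_size
  pad <- K %/% 2
  y <- array(0, dim = d)
  for (i in seq_len(d[1]))
    for (j in seq_len(d[2]))
      for (k in seq_len(d[3])) {
        g <- involution_group(k - 1L, spec)
        acc <- 0
        for (u in seq_len(K))
          for (v in seq_len(K)) {
            ii <- i + (u - 1L) - pad
            jj <- j + (v - 1L) - pad
            if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2]) next
            acc <- acc + kernels[i, j, (u - 1L) + K * (v - 1L) + K * K * g + 1L] *
              x[ii, jj, k]
          }
        y[i, j, k] <- acc
      }
  y
}
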