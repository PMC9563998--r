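#' Sliding-window tiling parameters
#'
#' @param tile window side in pixels (default 256, the training tile size).
#' @param stride window step (default = \code{tile}: non-overlapping).
#' @param edge_policy what to do with remainders not covered by a full
#'   window: \code{"drop"} them or \code{"pad"} the raster with zeros so
#'   every pixel is covered.
#' @return object of class \code{tiling_spec}.
#' @export
tiling_spec <- function(tile = 256, stride = tile,
                        edge_policy = c("drop", "pad")) {
  tile <- as.integer(tile)
  stride <- as.integer(stride)
  edge_policy <- match.arg(edge_policy)
  if (tile < 1) stop("tiling_spec: tile must be >= 1")
  if (stride < 1 || stride > tile)
    stop("tiling_spec: stride must satisfy 1 <= stride <= tile")
  structure(list(tile = tile, stride = stride, edge_policy = edge_policy),
            class = "tiling_spec")
}

# 0-based window origins covering an extent of length n
tile_origins <- function(n, tile, stride, edge_policy) {
  if (n < tile)
    return(if (edge_policy == "pad") 0L else integer(0))
  k <- as.integer(ceiling((n - tile) / stride)) + 1L
  o <- (seq_len(k) - 1L) * stride
  if (edge_policy == "drop") o <- o[o + tile <= n]
  o
}

#' Cut a raster (and aligned mask) into training tiles
#'
#' Deterministic row-major enumeration of sliding-window tiles. Origins are
#' 0-based (row, col) offsets into the source raster, with half-open
#' extents, so tiles can later be stitched back. Under
#' \code{edge_policy = "pad"} windows extending past the border are
#' zero-padded (mask padding is 0 = not lodged).
#'
#' @param image \code{H x W x C} raster (or \code{H x W} matrix).
#' @param mask optional aligned \code{H x W} \{0, 1\} mask.
#' @param spec a [tiling_spec()].
#' @return object of class \code{lodge_tiles}: list of tiles, each
#'   \code{list(image, mask, row, col)}, with the source dimensions in
#'   \code{attr(, "full_dim")}. Empty (with a warning) if the raster is
#'   smaller than one window under \code{edge_policy = "drop"}.
#' @export
tile_raster <- function(image, mask = NULL, spec = tiling_spec()) {
  d <- dim(image)
  if (length(d) == 2L) dim(image) <- d <- c(d, 1L)
  if (!is.null(mask) && !identical(dim(mask), d[1:2]))
    stop("tile_raster: image and mask dimensions differ")
  ro <- tile_origins(d[1], spec$tile, spec$stride, spec$edge_policy)
  co <- tile_origins(d[2], spec$tile, spec$stride, spec$edge_policy)
  if (!length(ro) || !length(co)) {
    warning("tile_raster: raster ", d[1], "x", d[2],
            " smaller than one ", spec$tile, "-pixel window; no tiles")
    return(structure(list(), class = "lodge_tiles", full_dim = d[1:2]))
  }
  t_ <- spec$tile
  out <- vector("list", length(ro) * length(co))
  k <- 0L
  for (r in ro) for (cl in co) {
    k <- k + 1L
    rows <- (r + 1L):min(r + t_, d[1])
    cols <- (cl + 1L):min(cl + t_, d[2])
    img <- array(0, dim = c(t_, t_, d[3]))
    img[seq_along(rows), seq_along(cols), ] <- image[rows, cols, , drop = FALSE]
    mk <- NULL
    if (!is.null(mask)) {
      mk <- matrix(0, t_, t_)
      mk[seq_along(rows), seq_along(cols)] <- mask[rows, cols]
    }
    out[[k]] <- list(image = img, mask = mk, row = r, col = cl)
  }
  structure(out, class = "lodge_tiles", full_dim = d[1:2])
}

#' Reassemble tiles into a full-size map
#'
#' Inverse of [tile_raster()]: values are placed back at their recorded
#' origins; where tiles overlap, per-pixel averaging is applied (so
#' stitching probability maps before thresholding is well defined). On the
#' non-overlapping stride the round trip \code{tile -> stitch} is exact.
#' Pixels covered by no tile are 0 and counted in the \code{"coverage"}
#' attribute.
#'
#' @param tiles a \code{lodge_tiles} object, or a plain list of
#'   \code{list(values, row, col)} with matrix \code{values}.
#' @param full_shape \code{c(H, W)} of the target map (default: recorded
#'   source dims).
#' @param what which tile field to stitch when \code{tiles} is a
#'   \code{lodge_tiles} object (\code{"mask"} or \code{"values"}).
#' @param threshold optional: binarize the averaged map at this value
#'   (\code{>= threshold} becomes 1).
#' @return \code{H x W} matrix with attribute \code{"coverage"} = fraction
#'   of pixels covered by at least one tile.
#' @export
stitch_tiles <- function(tiles, full_shape = attr(tiles, "full_dim"),
                         what = c("mask", "values"), threshold = NULL) {
  what <- match.arg(what)
  if (is.null(full_shape)) stop("stitch_tiles: full_shape is required")
  H <- full_shape[1]; W <- full_shape[2]
  acc <- matrix(0, H, W)
  cnt <- matrix(0, H, W)
  for (tl in tiles) {
    v <- tl[[what]] %||% tl$values %||% tl$mask
    if (is.null(v)) stop("stitch_tiles: tile has no '", what, "' field")
    dv <- dim(v)
    if (tl$row < 0 || tl$col < 0 || tl$row >= H || tl$col >= W)
      stop("stitch_tiles: tile origin (", tl$row, ",", tl$col,
           ") outside the ", H, "x", W, " target")
    rows <- (tl$row + 1L):min(tl$row + dv[1], H)
    cols <- (tl$col + 1L):min(tl$col + dv[2], W)
    acc[rows, cols] <- acc[rows, cols] + v[seq_along(rows), seq_along(cols)]
    cnt[rows, cols] <- cnt[rows, cols] + 1
  }
  covered <- cnt > 0
  acc[covered] <- acc[covered] / cnt[covered]
  if (!is.null(threshold)) acc <- (acc >= threshold) * 1
  attr(acc, "coverage") <- mean(covered)
  acc
}

## ---- augmentation ------------------------------------------------------

#' Augmentation recipe
#'
#' Geometric operations (rotate, flip) are always applied identically to
#' image and mask; photometric operations (filter = smoothing blur, noise =
#' clipped additive Gaussian) touch the image only.
#'
#' @param ops ordered subset of \code{c("rotate", "flip", "filter",
#'   "noise")}.
#' @param angles candidate rotation angles, each in \{90, 180, 270\}
#'   degrees (counterclockwise); one is drawn per call.
#' @param axes candidate flip axes, \code{"horizontal"} (left-right) and/or
#'   \code{"vertical"} (up-down).
#' @param filter_width side of the box smoothing kernel (odd, default 3).
#' @param noise_sd standard deviation of the additive Gaussian noise on the
#'   0..255 scale.
#' @param seed seed making the drawn angle/axis/noise reproducible.
#' @return object of class \code{augmentation_spec}.
#' @export
augmentation_spec <- function(ops = c("rotate", "flip", "filter", "noise"),
                              angles = c(90, 180, 270),
                              axes = c("horizontal", "vertical"),
                              filter_width = 3, noise_sd = 5, seed = 1) {
  ops <- match.arg(ops, several.ok = TRUE)
  if (!all(angles %in% c(90, 180, 270)))
    stop("augmentation_spec: rotation angles must be in {90, 180, 270} ",
         "(arbitrary angles would change the tile size)")
  axes <- match.arg(axes, c("horizontal", "vertical"), several.ok = TRUE)
  if (filter_width < 1 || filter_width %% 2 == 0)
    stop("augmentation_spec: filter_width must be odd")
  structure(list(ops = ops, angles = angles, axes = axes,
                 filter_width = as.integer(filter_width),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "augmentation_spec")
}

# counterclockwise rotation: element (i, j) of an H x W matrix moves to
# (W - j + 1, i) of the W x H result
rot90_ccw <- function(m) t(m)[ncol(m):1, , drop = FALSE]

rotate_mat <- function(m, angle) {
  switch(as.character(angle),
         "90" = rot90_ccw(m),
         "180" = rot90_ccw(rot90_ccw(m)),
         "270" = rot90_ccw(rot90_ccw(rot90_ccw(m))),
         stop("rotate: angle must be 90, 180 or 270, got ", angle))
}

flip_mat <- function(m, axis) {
  if (axis == "horizontal") m[, ncol(m):1, drop = FALSE]
  else m[nrow(m):1, , drop = FALSE]
}

apply_channels <- function(image, f) {
  d <- dim(image)
  out <- NULL
  for (c in seq_len(d[3])) {
    r <- f(image[, , c])
    if (is.null(out)) out <- array(0, dim = c(dim(r), d[3]))
    out[, , c] <- r
  }
  out
}

box_blur <- function(image, width) {
  d <- dim(image)
  x4 <- image
  dim(x4) <- c(d[1], d[2], 1L, d[3])
  cols <- cpp_im2col(x4, d[1], d[2], 1L, d[3], as.integer(width))
  # averaging kernel per channel: block-diagonal mean over the window
  k2 <- width * width
  out <- array(0, dim = d)
  for (c in seq_len(d[3])) {
    blk <- cols[, ((c - 1) * k2 + 1):(c * k2), drop = FALSE]
    out[, , c] <- matrix(rowMeans(blk), d[1], d[2])
  }
  out
}

#' Apply one augmentation draw to an image/mask pair
#'
#' Operations are applied in the order listed in \code{spec$ops}; the
#' rotation angle, flip axis and noise are drawn reproducibly from
#' \code{spec$seed}. The geometric part acts identically on image and mask;
#' the mask is returned bit-identical under purely photometric ops.
#'
#' @param image \code{H x W x C} tile (square for 90/270-degree rotations).
#' @param mask aligned \code{H x W} \{0, 1\} mask (or NULL).
#' @param spec an [augmentation_spec()].
#' @return \code{list(image, mask, tag)}; \code{tag} records the applied
#'   operations (e.g. \code{"rot90+fliph+noise"}).
#' @export
augment <- function(image, mask = NULL, spec = augmentation_spec()) {
  d <- dim(image)
  if (length(d) == 2L) dim(image) <- d <- c(d, 1L)
  set.seed(spec$seed)
  tags <- character(0)
  for (op in spec$ops) {
    if (op == "rotate") {
      ang <- if (length(spec$angles) == 1L) spec$angles else sample(spec$angles, 1)
      if (ang %in% c(90, 270) && d[1] != d[2])
        stop("augment: 90/270-degree rotation of a non-square ",
             d[1], "x", d[2], " tile would change its size")
      image <- apply_channels(image, function(m) rotate_mat(m, ang))
      if (!is.null(mask)) mask <- rotate_mat(mask, ang)
      tags <- c(tags, paste0("rot", ang))
    } else if (op == "flip") {
      ax <- if (length(spec$axes) == 1L) spec$axes else sample(spec$axes, 1)
      image <- apply_channels(image, function(m) flip_mat(m, ax))
      if (!is.null(mask)) mask <- flip_mat(mask, ax)
      tags <- c(tags, paste0("flip", substr(ax, 1, 1)))
    } else if (op == "filter") {
      image <- box_blur(image, spec$filter_width)
      tags <- c(tags, "filter")
    } else if (op == "noise") {
      image <- image + array(rnorm(length(image), 0, spec$noise_sd),
                             dim = dim(image))
      image <- pmin(pmax(image, 0), 255)
      tags <- c(tags, "noise")
    }
  }
  list(image = image, mask = mask, tag = paste(tags, collapse = "+"))
}

## ---- dataset splitting -------------------------------------------------

#' Random train/test split
#'
#' Disjoint, exhaustive, seeded-reproducible partition of \code{n} items
#' (e.g. 15,000 tiles at fraction 0.8 give exactly 12,000 train and 3,000
#' test indices).
#'
#' @param n number of items (or a list whose length is used).
#' @param train_fraction fraction assigned to training, in (0, 1).
#' @param seed RNG seed.
#' @return \code{list(train, test)} of index vectors.
#' @export
split_pairs <- function(n, train_fraction = 0.8, seed = 1) {
  if (is.list(n)) n <- length(n)
  n <- as.integer(n)
  if (n < 2) stop("split_pairs: need at least 2 items to split")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("split_pairs: train_fraction must be in (0, 1)")
  set.seed(as.integer(seed))
  n_train <- round(n * train_fraction)
  n_train <- min(max(n_train, 1L), n - 1L)
  tr <- sort(sample.int(n, n_train))
  list(train = tr, test = setdiff(seq_len(n), tr))
}

## ---- flight-altitude simulation ----------------------------------------

#' Flight-altitude resampling parameters
#'
#' The ground-sample distance of a fixed camera grows proportionally with
#' flight altitude, so imagery captured at \code{source_height_m} can be
#' degraded to a higher \code{target_height_m} by downscaling the linear
#' dimensions by \code{source/target} (20 m to 80 m: factor 1/4; 20 m to
#' 120 m: factor 1/6).
#'
#' @param source_height_m altitude the raster was captured at (meters).
#' @param target_height_m altitude to simulate (must be >= source).
#' @return object of class \code{height_sim} with the linear \code{scale}.
#' @export
height_sim <- function(source_height_m = 20, target_height_m) {
  if (target_height_m < source_height_m)
    stop("height_sim: target altitude (", target_height_m,
         " m) must be >= source altitude (", source_height_m, " m)")
  structure(list(source_height_m = source_height_m,
                 target_height_m = target_height_m,
                 scale = source_height_m / target_height_m),
            class = "height_sim")
}

#' Resample a raster
#'
#' \code{"cubic"} uses cubic-convolution (Keys, a = -0.5) interpolation —
#' the kernel used for the altitude simulation; \code{"nearest"} is for
#' label masks, which must stay binary and are never interpolated with
#' cubic kernels.
#'
#' @param image \code{H x W x C} raster or \code{H x W} matrix.
#' @param out_h,out_w target dimensions.
#' @param method \code{"cubic"} or \code{"nearest"}.
#' @return resampled raster of the same rank as the input.
#' @export
resize_raster <- function(image, out_h, out_w,
                          method = c("cubic", "nearest")) {
  method <- match.arg(method)
  d <- dim(image)
  two_d <- length(d) == 2L
  if (two_d) dim(image) <- d <- c(d, 1L)
  if (out_h < 1 || out_w < 1)
    stop("resize_raster: target size ", out_h, "x", out_w, " is degenerate")
  out <- if (method == "cubic")
    cpp_resize_cubic(image, d[1], d[2], d[3], as.integer(out_h),
                     as.integer(out_w))
  else
    cpp_resize_nearest(image, d[1], d[2], d[3], as.integer(out_h),
                       as.integer(out_w))
  dim(out) <- c(out_h, out_w, d[3])
  if (two_d) matrix(out, out_h, out_w) else out
}

#' Simulate a higher flight altitude
#'
#' Downscales the raster by cubic-convolution interpolation with the linear
#' factor \code{source/target}; output dims are
#' \code{round(dims * scale)}. An attached \code{"gsd"} attribute, if
#' present on the input, is rescaled accordingly.
#'
#' @param image \code{H x W x C} raster.
#' @param sim a [height_sim()].
#' @return the downscaled raster.
#' @export
simulate_height <- function(image, sim) {
  d <- dim(image)
  oh <- round(d[1] * sim$scale)
  ow <- round(d[2] * sim$scale)
  if (oh < 1 || ow < 1)
    stop("simulate_height: scale ", sim$scale,
         " collapses the raster to zero size")
  out <- resize_raster(image, oh, ow, "cubic")
  if (!is.null(attr(image, "gsd")))
    attr(out, "gsd") <- attr(image, "gsd") / sim$scale
  out
}

#' Peak signal-to-noise ratio between two rasters
#'
#' \code{10 * log10(MAX^2 / MSE)} in decibels, with \code{MAX = 255} for
#' 8-bit data. If the test raster is smaller than the reference (e.g. an
#' altitude-simulated image), it is first re-expanded to the reference size
#' by cubic-convolution interpolation. Identical rasters return \code{Inf}.
#'
#' @param reference reference raster.
#' @param test degraded raster of the same, or smaller, size.
#' @param max_value peak representable value (default 255).
#' @return PSNR in dB (\code{Inf} for identical inputs).
#' @export
psnr <- function(reference, test, max_value = 255) {
  dr <- dim(reference)
  dt <- dim(test)
  if (!identical(dr[1:2], dt[1:2]))
    test <- resize_raster(test, dr[1], dr[2], "cubic")
  mse <- mean((as.numeric(reference) - as.numeric(test))^2)
  if (mse == 0) return(Inf)
  10 * log10(max_value^2 / mse)
}
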