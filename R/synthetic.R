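#' Synthetic lodging-scene parameters
#'
#' Describes a generated test scene: a textured standing-canopy background
#' containing irregular lodged patches that are brighter and smoother than
#' the canopy — the visual contrast that makes lodged wheat separable in
#' aerial RGB imagery. Patch geometry is drawn before any photometric
#' texture, so masks depend only on geometry parameters and the seed, never
#' on the noise draws.
#'
#' @param height,width scene size in pixels.
#' @param lodging_fraction target fraction of lodged pixels in \[0, 1).
#' @param n_patches number of lodged patches.
#' @param canopy list: \code{base} RGB of standing canopy (0..255),
#'   \code{grain} pixel scale of the canopy texture, \code{contrast}
#'   texture amplitude (0..255 scale).
#' @param lodged list: \code{brightness} relative brightening of lodged
#'   areas (default 0.22, i.e. +22 percent), \code{smooth} attenuation of
#'   high-frequency texture inside patches in \[0, 1\] (1 = fully smooth).
#' @param noise_sd sd of the additive sensor noise (0..255 scale).
#' @param seed RNG seed; the same seed reproduces the scene bit-for-bit.
#' @return object of class \code{scene_spec}.
#' @export
scene_spec <- function(height = 256, width = 256, lodging_fraction = 0.2,
                       n_patches = 3,
                       canopy = list(base = c(82, 106, 58), grain = 2,
                                     contrast = 14),
                       lodged = list(brightness = 0.22, smooth = 0.7),
                       noise_sd = 6, seed = 1) {
  if (lodging_fraction < 0 || lodging_fraction >= 1)
    stop("scene_spec: lodging_fraction must be in [0, 1)")
  if (height < 8 || width < 8) stop("scene_spec: scene must be >= 8x8")
  if (n_patches < 1) stop("scene_spec: n_patches must be >= 1")
  structure(list(height = as.integer(height), width = as.integer(width),
                 lodging_fraction = lodging_fraction,
                 n_patches = as.integer(n_patches),
                 canopy = canopy, lodged = lodged,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "scene_spec")
}

# band-limited noise: white noise on a coarse grid, cubic-upsampled
smooth_noise <- function(h, w, scale) {
  ch <- max(2L, as.integer(ceiling(h / scale)))
  cw <- max(2L, as.integer(ceiling(w / scale)))
  coarse <- matrix(rnorm(ch * cw), ch, cw)
  resize_raster(coarse, h, w, "cubic")
}

# smoothed irregular blobs: anisotropic bumps modulated by low-frequency
# noise, thresholded at the quantile that realizes the requested fraction
make_lodging_mask <- function(spec) {
  h <- spec$height; w <- spec$width
  if (spec$lodging_fraction == 0) return(matrix(0, h, w))
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  field <- matrix(-Inf, h, w)
  for (p in seq_len(spec$n_patches)) {
    cy <- runif(1, 0.1 * h, 0.9 * h)
    cx <- runif(1, 0.1 * w, 0.9 * w)
    sy <- runif(1, 0.10, 0.25) * h
    sx <- runif(1, 0.10, 0.25) * w
    bump <- exp(-((yy - cy)^2 / (2 * sy^2) + (xx - cx)^2 / (2 * sx^2)))
    bump <- bump * (1 + 0.6 * smooth_noise(h, w, min(h, w) / 6))
    field <- pmax(field, bump)
  }
  thr <- quantile(field, 1 - spec$lodging_fraction, names = FALSE)
  (field > thr) * 1
}

#' Generate one synthetic lodging scene
#'
#' Returns an 8-bit RGB canopy image and its exact ground-truth mask. The
#' mask is the union of the generated patches; lodged pixels are brightened
#' by \code{lodged$brightness} and their high-frequency texture attenuated
#' by \code{lodged$smooth}, then zero-mean Gaussian sensor noise is added
#' and clipped to 0..255. The realized lodged fraction is kept within 20
#' percent (relative) of the request by bounded re-sampling.
#'
#' @param spec a [scene_spec()].
#' @return \code{list(image, mask)}: \code{H x W x 3} array (0..255) and
#'   aligned \code{H x W} \{0, 1\} matrix.
#' @export
make_scene <- function(spec = scene_spec()) {
  set.seed(spec$seed)
  req <- spec$lodging_fraction
  mask <- NULL
  for (attempt in 1:10) {
    m <- make_lodging_mask(spec)
    real <- mean(m)
    if (req == 0 || abs(real - req) <= 0.2 * req) { mask <- m; break }
  }
  if (is.null(mask))
    stop("make_scene: could not realize lodging fraction ", req,
         " with ", spec$n_patches, " patches after 10 attempts")
  h <- spec$height; w <- spec$width
  cp <- spec$canopy; ld <- spec$lodged
  shading <- smooth_noise(h, w, min(h, w) / 4)     # slow illumination drift
  grain <- smooth_noise(h, w, cp$grain)            # plant-scale texture
  grain_s <- grain * (1 - ld$smooth)               # flattened, smoother straw
  bright <- 1 + ld$brightness
  image <- array(0, dim = c(h, w, 3))
  for (c in 1:3) {
    chan_grain <- grain + 0.4 * matrix(rnorm(h * w), h, w)
    canopy <- cp$base[c] * (1 + 0.06 * shading) + cp$contrast * chan_grain
    lodged <- cp$base[c] * bright * (1 + 0.06 * shading) +
      cp$contrast * grain_s + if (c < 3) 8 else 0  # straw-yellow cast
    image[, , c] <- canopy * (1 - mask) + lodged * mask
  }
  image <- image + array(rnorm(h * w * 3, 0, spec$noise_sd), dim = dim(image))
  image <- round(pmin(pmax(image, 0), 255))  # 8-bit RGB, as a UAV camera emits
  list(image = image, mask = mask)
}

#' Generate a dataset of synthetic scenes on disk
#'
#' Writes \code{n_scenes} image/mask PNG pairs plus a manifest. Per-scene
#' seeds are drawn from the master seed, so the whole dataset is
#' reproducible and no two scenes are identical.
#'
#' @param n_scenes number of scenes (0 gives an empty manifest).
#' @param spec template [scene_spec()]; its \code{seed} field is replaced
#'   per scene.
#' @param dir output directory (created if missing).
#' @param seed master seed.
#' @return data.frame manifest (image path, mask path, per-scene seed,
#'   realized lodged fraction), also written to \code{dir/manifest.tsv}.
#' @export
make_dataset <- function(n_scenes, spec = scene_spec(), dir, seed = 1) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("make_dataset: cannot create directory ", dir)
  if (n_scenes == 0) {
    manifest <- data.frame(image = character(0), mask = character(0),
                           seed = integer(0), lodged_fraction = numeric(0))
    write_manifest(manifest, file.path(dir, "manifest.tsv"))
    return(manifest)
  }
  set.seed(as.integer(seed))
  seeds <- sample.int(.Machine$integer.max - 1L, n_scenes)
  rows <- vector("list", n_scenes)
  for (i in seq_len(n_scenes)) {
    sp <- spec
    sp$seed <- seeds[i]
    sc <- make_scene(sp)
    ifn <- sprintf("scene_%04d.png", i)
    mfn <- sprintf("mask_%04d.png", i)
    write_raster(sc$image, file.path(dir, ifn))
    write_mask(sc$mask, file.path(dir, mfn))
    rows[[i]] <- data.frame(image = ifn, mask = mfn, seed = seeds[i],
                            lodged_fraction = mean(sc$mask))
  }
  manifest <- do.call(rbind, rows)
  # on-disk manifest carries paths relative to its own directory, so seeded
  # dataset builds are byte-identical wherever they land
  write_manifest(manifest, file.path(dir, "manifest.tsv"))
  manifest$image <- file.path(dir, manifest$image)
  manifest$mask <- file.path(dir, manifest$mask)
  manifest
}

#' Generate a list of in-memory scenes
#'
#' Convenience wrapper over [make_scene()] for tests and smoke training:
#' same per-scene seed derivation as [make_dataset()] but nothing touches
#' the disk.
#'
#' @inheritParams make_dataset
#' @return list of \code{list(image, mask)} pairs.
#' @export
make_scenes <- function(n_scenes, spec = scene_spec(), seed = 1) {
  set.seed(as.integer(seed))
  seeds <- sample.int(.Machine$integer.max - 1L, n_scenes)
  lapply(seq_len(n_scenes), function(i) {
    sp <- spec
    sp$seed <- seeds[i]
    make_scene(sp)
  })
}
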