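test_that("non-overlapping tiling enumerates row-major offsets", {
  img <- array(runif(512 * 512 * 3), c(512, 512, 3))
  msk <- matrix(rbinom(512^2, 1, 0.2), 512)
  tl <- tile_raster(img, msk, tiling_spec(tile = 256))
  expect_length(tl, 4)
  offs <- t(sapply(tl, function(t) c(t$row, t$col)))
  expect_equal(offs, rbind(c(0, 0), c(0, 256), c(256, 0), c(256, 256)))
  expect_true(all(sapply(tl, function(t) all(dim(t$image)[1:2] == 256))))
})

test_that("a tile-sized raster yields exactly itself", {
  img <- array(runif(256 * 256 * 3), c(256, 256, 3))
  tl <- tile_raster(img, NULL, tiling_spec(tile = 256))
  expect_length(tl, 1)
  expect_equal(tl[[1]]$image, img)
  expect_equal(c(tl[[1]]$row, tl[[1]]$col), c(0, 0))
})

test_that("edge policies handle remainders by padding or dropping", {
  img <- array(runif(600 * 600), c(600, 600, 1))
  pad <- tile_raster(img, NULL, tiling_spec(tile = 256, edge_policy = "pad"))
  expect_length(pad, 9)  # ceiling(600/256)^2
  drop <- tile_raster(img, NULL, tiling_spec(tile = 256, edge_policy = "drop"))
  expect_length(drop, 4)
  small <- array(runif(100 * 100), c(100, 100, 1))
  expect_warning(none <- tile_raster(small, NULL,
                                     tiling_spec(tile = 256,
                                                 edge_policy = "drop")),
                 "smaller")
  expect_length(none, 0)
})

test_that("tile then stitch is exact on the non-overlapping stride", {
  set.seed(1)
  for (i in 1:5) {
    h <- sample(100:400, 1); w <- sample(100:400, 1)
    msk <- matrix(rbinom(h * w, 1, 0.3) * 1, h)
    tl <- tile_raster(array(0, c(h, w, 1)), msk,
                      tiling_spec(tile = 64, edge_policy = "pad"))
    back <- stitch_tiles(tl, c(h, w))
    expect_identical(unname(back[, ]), msk, label = sprintf("%dx%d", h, w))
    expect_equal(attr(back, "coverage"), 1)
    expect_true(all(back %in% c(0, 1)))
  }
})

test_that("overlapping tiles are averaged; constant tiles stay constant", {
  t1 <- list(values = matrix(0.6, 4, 4), row = 0, col = 0)
  t2 <- list(values = matrix(0.6, 4, 4), row = 0, col = 2)
  out <- stitch_tiles(list(t1, t2), c(4, 6), what = "values")
  expect_true(all(abs(out - 0.6) < 1e-12))
  hard <- stitch_tiles(list(t1, t2), c(4, 6), what = "values",
                       threshold = 0.5)
  expect_true(all(hard == 1))
})

test_that("flips are involutions and act identically on image and mask", {
  set.seed(2)
  img <- array(runif(16 * 16 * 3, 0, 255), c(16, 16, 3))
  msk <- matrix(rbinom(256, 1, 0.3), 16)
  sp <- augmentation_spec(ops = "flip", axes = "horizontal")
  once <- augment(img, msk, sp)
  twice <- augment(once$image, once$mask, sp)
  expect_equal(twice$image, img)
  expect_equal(twice$mask, msk)
})

test_that("photometric ops leave the mask bit-identical", {
  set.seed(3)
  img <- array(runif(16 * 16 * 3, 0, 255), c(16, 16, 3))
  msk <- matrix(rbinom(256, 1, 0.3), 16)
  out <- augment(img, msk, augmentation_spec(ops = c("filter", "noise")))
  expect_identical(out$mask, msk)
  expect_gt(max(abs(out$image - img)), 0)
  expect_true(all(out$image >= 0 & out$image <= 255))
})

test_that("rotation moves a marked pixel to the coordinate the index map predicts", {
  n <- 8
  for (case in 1:6) {
    r <- sample(n, 1); cl <- sample(n, 1)
    msk <- matrix(0, n, n); msk[r, cl] <- 1
    img <- array(0, c(n, n, 1)); img[r, cl, 1] <- 255
    out <- augment(img, msk, augmentation_spec(ops = "rotate", angles = 90))
    # counterclockwise quarter turn: (i, j) -> (W - j + 1, i)
    expect_equal(which(out$mask == 1, arr.ind = TRUE)[1, ],
                 c(row = n - cl + 1, col = r))
    expect_equal(out$mask, out$image[, , 1] / 255)
  }
  expect_error(augment(array(0, c(4, 6, 1)), NULL,
                       augmentation_spec(ops = "rotate", angles = 90)),
               "non-square")
  expect_error(augmentation_spec(ops = "rotate", angles = 45), "90")
})

test_that("augmentation is reproducible under a fixed seed", {
  set.seed(4)
  img <- array(runif(8 * 8 * 3, 0, 255), c(8, 8, 3))
  msk <- matrix(rbinom(64, 1, 0.5), 8)
  sp <- augmentation_spec(seed = 77)
  a <- augment(img, msk, sp)
  b <- augment(img, msk, sp)
  expect_identical(a, b)
})

test_that("splitting 15,000 tiles at 0.8 gives exactly 12,000 / 3,000", {
  sp <- split_pairs(15000, 0.8, seed = 21)
  expect_length(sp$train, 12000)
  expect_length(sp$test, 3000)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_equal(sort(c(sp$train, sp$test)), 1:15000)
  expect_identical(sp, split_pairs(15000, 0.8, seed = 21))
  expect_false(identical(sp$train, split_pairs(15000, 0.8, seed = 22)$train))
  expect_error(split_pairs(1, 0.8), "at least 2")
})

test_that("altitude simulation scales dims by the height ratio", {
  img <- array(runif(1600 * 1200 * 3), c(1600, 1200, 3))
  out80 <- simulate_height(img, height_sim(20, 80))
  expect_equal(dim(out80), c(400, 300, 3))
  out120 <- simulate_height(img, height_sim(20, 120))
  expect_equal(dim(out120), c(267, 200, 3))  # round(1600/6), round(1200/6)
  expect_error(height_sim(20, 10), ">=")
  expect_error(simulate_height(array(0, c(4, 4, 1)), height_sim(1, 100)),
               "zero size")
})

test_that("cubic resampling is the identity at scale 1 and preserves constants", {
  set.seed(5)
  img <- array(runif(32 * 32 * 3, 0, 255), c(32, 32, 3))
  expect_equal(simulate_height(img, height_sim(20, 20)), img,
               tolerance = 1e-12)
  cst <- array(117, c(60, 40, 3))
  down <- simulate_height(cst, height_sim(20, 80))
  expect_equal(dim(down), c(15, 10, 3))
  expect_true(all(abs(down - 117) < 1e-9))
})

test_that("increasing target height never increases the pixel count", {
  img <- array(0, c(240, 240, 1))
  sizes <- sapply(c(20, 40, 80, 120), function(hm)
    prod(dim(simulate_height(img, height_sim(20, hm)))[1:2]))
  expect_true(all(diff(sizes) <= 0))
})

test_that("masks are resized by nearest neighbor and stay binary", {
  set.seed(6)
  msk <- matrix(rbinom(64 * 64, 1, 0.3), 64)
  small <- resize_raster(msk, 16, 16, "nearest")
  expect_true(all(small %in% c(0, 1)))
  expect_equal(dim(small), c(16, 16))
})

test_that("PSNR matches its closed form", {
  ref <- array(0, c(10, 10, 1))
  t1 <- array(1, c(10, 10, 1))           # MSE = 1
  expect_equal(psnr(ref, t1), 10 * log10(255^2), tolerance = 1e-9)
  expect_equal(psnr(ref, t1), 48.1308, tolerance = 1e-4)
  t2 <- array(sqrt(0.5), c(10, 10, 1))   # MSE halved
  expect_equal(psnr(ref, t2) - psnr(ref, t1), 10 * log10(2),
               tolerance = 1e-9)  # +3.01 dB
  expect_identical(psnr(ref, ref), Inf)
})

test_that("PSNR re-expands a downsampled raster before comparing", {
  set.seed(7)
  img <- array(runif(64 * 64 * 3, 0, 255), c(64, 64, 3))
  down <- simulate_height(img, height_sim(20, 40))
  v <- psnr(img, down)
  expect_true(is.finite(v) && v > 10)
})

test_that("rasters and masks survive a disk round trip", {
  img <- round(array(runif(24 * 16 * 3, 0, 255), c(24, 16, 3)))
  fp <- tempfile(fileext = ".png")
  write_raster(img, fp)
  expect_equal(read_raster(fp), img, tolerance = 1e-9)
  ft <- tempfile(fileext = ".tif")
  write_raster(img, ft)
  expect_equal(read_raster(ft), img, tolerance = 1e-9)
  msk <- matrix(rbinom(24 * 16, 1, 0.4), 24)
  fm <- tempfile(fileext = ".png")
  write_mask(msk, fm)
  expect_identical(read_mask(fm), msk * 1)
  unlink(c(fp, ft, fm))
})
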