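test_that("single-sphere configs give trivially connected shapes, deterministically", {
  cfg <- test_synth_config(sphere_count = c(1L, 1L))
  set.seed(5)
  sh <- make_nodule_shape(cfg)
  expect_length(sh$radii, 1)
  expect_true(nodule_is_connected(sh))
  set.seed(5)
  sh2 <- make_nodule_shape(cfg)
  expect_identical(sh, sh2)
})

test_that("multi-sphere draws stay connected and inside the bounding box", {
  cfg <- test_synth_config()
  set.seed(7)
  for (rep in 1:200) {
    sh <- make_nodule_shape(cfg)
    expect_true(nodule_is_connected(sh))
    expect_true(all(abs(sh$centers) <= cfg$bbox_halfwidth))
    expect_true(all(sh$radii >= cfg$radius[1] & sh$radii <= cfg$radius[2]))
  }
  # voxelized flood-fill oracle on a subsample (slow)
  set.seed(8)
  for (rep in 1:15) {
    sh <- make_nodule_shape(cfg)
    expect_true(oracle_shape_connected(sh, pitch = 0.4))
  }
})

test_that("a bounding box smaller than the maximum radius is rejected", {
  cfg <- test_synth_config(radius = c(2, 3.5), bbox_halfwidth = 3)
  expect_error(make_nodule_shape(cfg), "bounding box")
})

test_that("phantom backgrounds are deterministic, bounded, and lose their rib band when its amplitude is zero", {
  cfg <- test_synth_config(noise_sd = 0)
  set.seed(3); b1 <- make_background(cfg)
  set.seed(3); b2 <- make_background(cfg)
  expect_identical(b1, b2)
  expect_true(all(b1 >= 0 & b1 <= 1))
  # spectral check along rows: the rib frequency dominates with amp > 0
  cfg_rib <- test_synth_config(noise_sd = 0, rib_amp = 0.1)
  cfg_flat <- test_synth_config(noise_sd = 0, rib_amp = 0)
  set.seed(3); br <- make_background(cfg_rib)
  set.seed(3); bf <- make_background(cfg_flat)
  spectrum_of <- function(img) {
    # profile down a column through the left lung field, where the band lives
    j <- round(0.3 * ncol(img))
    col <- img[, j] - mean(img[, j])
    Mod(stats::fft(col))^2
  }
  rib_bin <- cfg_rib$rib_freq + 1
  expect_gt(spectrum_of(br)[rib_bin], 10 * spectrum_of(bf)[rib_bin])
  # with the band disabled, the rib frequency is buried in the smooth
  # lung-field spectrum: below 1% of the total AC power
  sp_flat <- spectrum_of(bf)
  expect_lt(sp_flat[rib_bin], 0.01 * sum(sp_flat[-1]))
})

test_that("embedding respects its algebraic endpoints", {
  cfg <- test_synth_config(noise_sd = 0)
  set.seed(9)
  bg <- make_background(cfg)
  z <- structure(matrix(0, 32, 32), class = c("attenuation_map", "matrix"))
  e0 <- embed_nodule(bg, z, 0.7)
  expect_identical(e0$positive, bg)       # empty map: identity
  expect_identical(sum(e0$label), 0)      # and empty label
  sh <- make_shape(c(0, 0, 0), 3, 0.3)
  am <- project_attenuation(sh, 32, c(15, 15))
  e1 <- embed_nodule(bg, am, 1, polarity = "dark")
  full <- bg * exp(-unclass(am))
  expect_equal(e1$positive[unclass(am) > 0], full[unclass(am) > 0],
               tolerance = 1e-12)
  expect_error(embed_nodule(bg, am, 0), "blend_ratio")
  expect_error(embed_nodule(bg, am, 1.2), "blend_ratio")
})

test_that("the label is the thresholded support of the attenuation map", {
  cfg <- test_synth_config(noise_sd = 0)
  set.seed(10)
  bg <- make_background(cfg)
  sh <- make_shape(c(0, 0, 0), 3, 0.3)
  am <- project_attenuation(sh, 32, c(15, 15))
  lab <- embed_nodule(bg, am, 0.5, label_threshold = 0.01)$label
  expect_identical(lab, (unclass(am) > 0.01 * max(am)) * 1)
  # threshold trims the rim: label support is a subset of the footprint
  expect_true(all(lab[unclass(am) == 0] == 0))
})

test_that("the embedding difference grows monotonically with the blend ratio", {
  cfg <- test_synth_config(noise_sd = 0)
  set.seed(12)
  bg <- make_background(cfg)
  sh <- make_shape(c(0, 0, 0), 3, 0.4)
  am <- project_attenuation(sh, 32, c(15, 15))
  prev <- matrix(0, 32, 32)
  for (a in c(0.2, 0.5, 0.8, 1.0)) {
    diffmap <- abs(embed_nodule(bg, am, a)$positive - bg)
    expect_true(all(diffmap - prev >= -1e-12))
    prev <- diffmap
  }
})

test_that("generated pairs satisfy the full invariant suite over 100 seeds", {
  cfg <- test_synth_config()
  for (seed in 1:100) {
    pr <- generate_pair(cfg, seed)
    expect_true(validate_image_pair(pr))
    expect_gt(sum(pr$label), 0)
  }
})

test_that("pairs are bit-reproducible and respect the with_nodule flag", {
  cfg <- test_synth_config()
  p1 <- generate_pair(cfg, 42)
  p2 <- generate_pair(cfg, 42)
  expect_identical(p1, p2)
  p3 <- generate_pair(cfg, 43, with_nodule = FALSE)
  expect_identical(p3$positive, p3$negative)
  expect_identical(sum(p3$label), 0)
  # differences are confined to the dilated footprint
  outside <- dilate1(p1$footprint) == 0
  expect_identical(p1$positive[outside], p1$negative[outside])
  expect_true(any(p1$positive != p1$negative))
})

test_that("datasets round-trip through disk with the declared split sizes", {
  cfg <- test_synth_config()
  d1 <- file.path(tempdir(), "ds1"); d2 <- file.path(tempdir(), "ds2")
  on.exit(unlink(c(d1, d2), recursive = TRUE), add = TRUE)
  m1 <- generate_dataset(10, cfg, seed = 77, val_fraction = 0.2, out_dir = d1)
  expect_identical(as.integer(table(m1$split)[c("train", "val")]), c(8L, 2L))
  # same seed, fresh directory: byte-identical manifest
  generate_dataset(10, cfg, seed = 77, val_fraction = 0.2, out_dir = d2)
  expect_identical(readLines(file.path(d1, "manifest.csv")),
                   readLines(file.path(d2, "manifest.csv")))
  m <- read_manifest(file.path(d1, "manifest.csv"))
  for (i in seq_len(nrow(m))) {
    pos <- read_gray(cadpair:::manifest_path(m, "positive_path", i))
    neg <- read_gray(cadpair:::manifest_path(m, "negative_path", i))
    lab <- read_gray(cadpair:::manifest_path(m, "label_path", i))
    expect_identical(dim(pos), c(32L, 32L))
    expect_identical(dim(pos), dim(neg))
    expect_identical(dim(pos), dim(lab))
    expect_true(all(lab %in% c(0, 1)))
  }
})
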