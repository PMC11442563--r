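tiny_model <- function() model_config(levels = 2, base_channels = 4,
                                      input_size = 16)

test_that("network output is nonnegative, shape-preserving, and finite across seeds", {
  mc <- tiny_model()
  for (seed in 1:20) {
    p <- init_params(mc, seed)
    set.seed(seed + 500)
    img <- matrix(stats::runif(256), 16, 16)
    f <- net_forward(p, mc, img)
    expect_identical(dim(f), c(16L, 16L))
    expect_gte(min(f), 0)
    expect_true(all(is.finite(f)))
  }
  p <- init_params(mc, 1)
  img <- matrix(0.5, 16, 16)
  expect_identical(net_forward(p, mc, img), net_forward(p, mc, img))
  expect_error(net_forward(p, mc, matrix(0.5, 8, 8)), "input size")
})

test_that("model config enforces the divisibility invariant", {
  expect_error(model_config(levels = 4, input_size = 20), "divisible")
  mc <- model_config(levels = 4, base_channels = 2, input_size = 32)
  expect_identical(mc$channels, c(2L, 4L, 8L, 16L))
})

test_that("positive and negative passes share one parameter set", {
  mc <- tiny_model()
  p <- init_params(mc, 3)
  set.seed(33)
  img <- matrix(stats::runif(256), 16, 16)
  f1 <- net_forward(p, mc, img)
  # perturb one weight: both "branches" (same function) must move identically
  p2 <- p
  p2$enc1.w1[1] <- p2$enc1.w1[1] + 0.05
  g1 <- net_forward(p2, mc, img)
  expect_identical(g1, net_forward(p2, mc, img))
  expect_false(identical(f1, g1))
})

test_that("best-epoch selection maximizes validation R-CPM with earliest-tie rule", {
  ck <- function(e, r) list(epoch = e, params = list(), val_rcpm = r)
  expect_identical(select_best_epoch(list(ck(1, 0.4)))$epoch, 1)
  cks <- list(ck(1, 0.1), ck(2, 0.5), ck(3, 0.5))
  expect_identical(select_best_epoch(cks)$epoch, 2)
  set.seed(44)
  for (rep in 1:20) {
    r <- round(stats::runif(6), 2)
    cks <- lapply(seq_along(r), function(i) ck(i, r[i]))
    best <- select_best_epoch(cks)
    expect_identical(best$epoch, which(r == max(r))[1])
  }
  expect_error(select_best_epoch(list()), "no checkpoints")
})

test_that("paired training runs, checkpoints every epoch, and reacts to the loss weights", {
  cfg <- test_synth_config()
  dir <- file.path(tempdir(), "train_bk")
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  man <- generate_dataset(8, cfg, seed = 21, val_fraction = 0.25,
                          out_dir = dir)
  mc <- model_config(levels = 2, base_channels = 4, input_size = 32)
  d1 <- train_detector(man, mc, train_config(epochs = 1, batch_size = 4,
                                             seed = 5))
  expect_length(d1$checkpoints, 1)
  expect_s3_class(d1, "cad_detector")
  expect_true(d1$checkpoints[[1]]$val_rcpm >= 0 &&
                d1$checkpoints[[1]]$val_rcpm <= 1)
  # same seed, different weights: the necmos term changes the loss history
  d_dice <- train_detector(man, mc,
                           train_config(epochs = 2, batch_size = 4, seed = 5,
                                        weights = loss_weights(1, 0, 0)))
  d_both <- train_detector(man, mc,
                           train_config(epochs = 2, batch_size = 4, seed = 5,
                                        weights = loss_weights(1, 1, 0)))
  expect_false(identical(d_dice$history$train_loss, d_both$history$train_loss))
})

test_that("two training runs with identical seeds produce identical loss curves", {
  cfg <- test_synth_config()
  dir <- file.path(tempdir(), "train_det")
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  man <- generate_dataset(6, cfg, seed = 22, val_fraction = 0.34,
                          out_dir = dir)
  mc <- model_config(levels = 2, base_channels = 4, input_size = 32)
  tc <- train_config(epochs = 2, batch_size = 3, seed = 9)
  d1 <- train_detector(man, mc, tc)
  d2 <- train_detector(man, mc, tc)
  expect_identical(d1$history, d2$history)
  expect_identical(d1$params, d2$params)
})

test_that("fine-tuning with zero epochs is the identity and lesion-free manifests run through the degenerate dice branch", {
  cfg <- test_synth_config()
  dir <- file.path(tempdir(), "ft")
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  man <- generate_dataset(6, cfg, seed = 23, val_fraction = 0.34,
                          out_dir = dir)
  mc <- model_config(levels = 2, base_channels = 4, input_size = 32)
  p <- init_params(mc, 2)
  tc <- train_config(epochs = 1, seed = 3)
  single <- data.frame(case_id = man$case_id, image_path = man$positive_path,
                       label_path = man$label_path)
  attr(single, "dir") <- attr(man, "dir")
  expect_identical(fine_tune_single(p, mc, single, tc, epochs = 0), p)
  # negatives only: empty labels everywhere
  negs <- data.frame(case_id = man$case_id, image_path = man$negative_path,
                     label_path = NA_character_)
  attr(negs, "dir") <- attr(man, "dir")
  p2 <- fine_tune_single(p, mc, negs, tc, epochs = 1)
  expect_false(identical(p2, p))
  expect_true(all(vapply(p2, function(x) all(is.finite(x)), TRUE)))
})

test_that("prediction resamples mismatched images and reports candidates reproducibly", {
  mc <- model_config(levels = 2, base_channels = 4, input_size = 32)
  det <- structure(list(params = init_params(mc, 4), model_config = mc),
                   class = "cad_detector")
  img <- matrix(0.5, 64, 64)
  expect_message(maps <- predict(det, img, type = "map"), "resampling")
  expect_identical(dim(maps[[1]]), c(32L, 32L))
  t1 <- predict(det, matrix(0.2, 32, 32))
  t2 <- predict(det, matrix(0.2, 32, 32))
  expect_identical(t1, t2)
})

test_that("run-length encoding of pixel sets round-trips", {
  set.seed(66)
  for (rep in 1:20) {
    px <- sort(sample(1:500, sample(1:60, 1)))
    expect_identical(rle_decode(rle_encode(px)), px)
  }
})
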