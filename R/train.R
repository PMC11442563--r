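#' Training configuration
#'
#' @param epochs Number of passes over the training pairs (>= 1).
#' @param batch_size Pairs per optimizer step.
#' @param learning_rate Adam step size.
#' @param weights A [loss_weights()] object; set `w_necmos`/`w_nac` to 0
#'   to ablate the paired terms.
#' @param seed Seed governing initialization and batch shuffling.
#' @param iou_min IoU threshold used for validation FROC matching.
#' @param verbose Print one line per epoch.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 10L, batch_size = 8L, learning_rate = 1e-3,
                         weights = loss_weights(), seed = 1L, iou_min = 0.1,
                         verbose = FALSE) {
  stopifnot(epochs >= 0, batch_size >= 1, learning_rate > 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, weights = weights,
                 seed = as.integer(seed), iou_min = iou_min,
                 verbose = verbose),
            class = "train_config")
}

load_pairs <- function(manifest, split = NULL) {
  rows <- if (is.null(split)) seq_len(nrow(manifest))
          else which(manifest$split == split)
  lapply(rows, function(i) {
    list(case_id = manifest$case_id[i],
         positive = read_gray(manifest_path(manifest, "positive_path", i)),
         negative = read_gray(manifest_path(manifest, "negative_path", i)),
         label = read_gray(manifest_path(manifest, "label_path", i)))
  })
}

#' Score a set of loaded pairs with a parameter set
#'
#' Runs the network over every positive and negative image, extracts
#' candidates, and assembles one [case_detections()] per image: positive
#' images carry their labeled lesions, negative images carry none but
#' still enter the false-positive denominator.
#'
#' @param params,config Network parameters and [model_config()].
#' @param pairs List from the internal pair loader (or any list with
#'   `positive`, `negative`, `label`, `case_id` entries).
#' @return List of `case_detections`, two per pair.
#' @keywords internal
score_pairs <- function(params, config, pairs) {
  out <- list()
  for (pr in pairs) {
    fp <- net_forward(params, config, pr$positive)
    fn <- net_forward(params, config, pr$negative)
    out[[length(out) + 1]] <- case_detections(
      paste0(pr$case_id, "_pos"),
      extract_candidates(fp, paste0(pr$case_id, "_pos")),
      label_lesions(pr$label))
    out[[length(out) + 1]] <- case_detections(
      paste0(pr$case_id, "_neg"),
      extract_candidates(fn, paste0(pr$case_id, "_neg")),
      list())
  }
  out
}

#' Train a lesion detector on positive/negative pairs
#'
#' Both images of every pair pass through the same network (shared
#' parameters); the combined three-term loss is backpropagated from both
#' outputs and gradients are averaged over the batch before each Adam
#' step. After every epoch the model is scored on the validation split and
#' a checkpoint (parameters + validation R-CPM) is recorded; the returned
#' detector exposes the best epoch under the R-CPM criterion.
#'
#' @param manifest Manifest `data.frame` from [generate_dataset()] /
#'   [read_manifest()], containing `train` and `val` splits.
#' @param model_config A [model_config()].
#' @param train_config A [train_config()].
#' @return A `cad_detector` object with elements `params` (best-epoch
#'   parameters), `checkpoints`, `best_epoch`, `history`, and the two
#'   configs.
#' @export
train_detector <- function(manifest, model_config, train_config) {
  train_pairs <- load_pairs(manifest, "train")
  val_pairs <- load_pairs(manifest, "val")
  if (length(train_pairs) == 0) stop("training split is empty")
  if (length(val_pairs) == 0) stop("validation split is empty")
  w <- train_config$weights
  params <- init_params(model_config, train_config$seed)
  opt <- adam_init(params)
  set.seed(train_config$seed + 1L)
  need_neg <- w$w_necmos > 0 || w$w_nac > 0
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_rcpm = numeric())
  checkpoints <- list()
  zero_map <- matrix(0, model_config$input_size, model_config$input_size)
  for (epoch in seq_len(train_config$epochs)) {
    ord <- sample(length(train_pairs))
    losses <- numeric(0)
    for (start in seq(1, length(ord), by = train_config$batch_size)) {
      batch <- ord[start:min(start + train_config$batch_size - 1, length(ord))]
      grads <- NULL
      for (i in batch) {
        pr <- train_pairs[[i]]
        fwd_p <- net_forward(params, model_config, pr$positive, want_cache = TRUE)
        f_neg <- zero_map
        fwd_n <- NULL
        if (need_neg) {
          fwd_n <- net_forward(params, model_config, pr$negative, want_cache = TRUE)
          f_neg <- fwd_n$f
        }
        loss <- combined_loss(fwd_p$f, f_neg, pr$label, w)
        if (!is.finite(loss))
          stop("non-finite loss at epoch ", epoch, ", case ", pr$case_id,
               " (max f+ = ", max(fwd_p$f), ", max f- = ", max(f_neg), ")")
        losses <- c(losses, loss)
        lg <- combined_loss_grad(fwd_p$f, f_neg, pr$label, w)
        g <- net_backward(params, model_config, fwd_p$cache, lg$d_pos)
        if (need_neg && any(lg$d_neg != 0)) {
          gn <- net_backward(params, model_config, fwd_n$cache, lg$d_neg)
          for (nm in names(g)) g[[nm]] <- g[[nm]] + gn[[nm]]
        }
        if (is.null(grads)) grads <- g
        else for (nm in names(g)) grads[[nm]] <- grads[[nm]] + g[[nm]]
      }
      for (nm in names(grads)) grads[[nm]] <- grads[[nm]] / length(batch)
      st <- adam_step(params, grads, opt, train_config$learning_rate)
      params <- st$params
      opt <- st$state
    }
    val_cases <- score_pairs(params, model_config, val_pairs)
    val_rcpm <- r_cpm(froc(val_cases, train_config$iou_min))
    checkpoints[[epoch]] <- list(epoch = epoch, params = params,
                                 val_rcpm = val_rcpm)
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = mean(losses),
                                         val_rcpm = val_rcpm))
    if (train_config$verbose)
      message(sprintf("epoch %d: train loss %.4f, val R-CPM %.3f",
                      epoch, mean(losses), val_rcpm))
  }
  best <- select_best_epoch(checkpoints)
  structure(list(params = best$params, best_epoch = best$epoch,
                 checkpoints = checkpoints, history = history,
                 model_config = model_config, train_config = train_config),
            class = "cad_detector")
}

#' Pick the best checkpoint by validation R-CPM
#'
#' Ties are broken in favor of the earliest epoch.
#'
#' @param checkpoints Nonempty list of checkpoints (`epoch`, `params`,
#'   `val_rcpm`).
#' @return The winning checkpoint.
#' @export
select_best_epoch <- function(checkpoints) {
  if (length(checkpoints) == 0) stop("no checkpoints to select from")
  rcpms <- vapply(checkpoints, `[[`, 0, "val_rcpm")
  checkpoints[[which.max(rcpms)]]  # which.max returns the first maximum
}

#' Dice-only fine-tuning on single images
#'
#' Optimizes the log-Dice objective alone on a manifest of single images
#' with (possibly empty) labels — no negative twins required, so the mode
#' works on ordinary labeled radiographs, emulating leave-one-case-out
#' fine-tuning. Lesion-free images train through the degenerate Dice
#' branch `-epsilon / (sum f + epsilon)`, which (via the log form) still
#' pushes spurious output mass down. With `epochs = 0` the parameters are
#' returned untouched.
#'
#' @param params Starting parameters.
#' @param model_config The matching [model_config()].
#' @param manifest `data.frame` with columns `case_id`, `image_path`, and
#'   optionally `label_path` (`NA` or missing = lesion-free image).
#' @param train_config A [train_config()]; only the Dice weight and
#'   epsilon of its `weights` are used.
#' @param epochs Number of fine-tuning epochs (overrides the config).
#' @return Updated parameter list.
#' @export
fine_tune_single <- function(params, model_config, manifest, train_config,
                             epochs = train_config$epochs) {
  if (epochs == 0) return(params)
  S <- model_config$input_size
  imgs <- lapply(seq_len(nrow(manifest)), function(i) {
    lab_path <- if ("label_path" %in% names(manifest)) manifest$label_path[i]
                else NA
    list(image = read_gray(manifest_path(manifest, "image_path", i)),
         label = if (is.na(lab_path)) matrix(0, S, S)
                 else read_gray(manifest_path(manifest, "label_path", i)))
  })
  w <- loss_weights(w_dice = 1, w_necmos = 0, w_nac = 0,
                    epsilon = train_config$weights$epsilon)
  opt <- adam_init(params)
  set.seed(train_config$seed + 2L)
  zero_map <- matrix(0, S, S)
  for (epoch in seq_len(epochs)) {
    for (i in sample(length(imgs))) {
      it <- imgs[[i]]
      fwd <- net_forward(params, model_config, it$image, want_cache = TRUE)
      lg <- combined_loss_grad(fwd$f, zero_map, it$label, w)
      g <- net_backward(params, model_config, fwd$cache, lg$d_pos)
      st <- adam_step(params, g, opt, train_config$learning_rate)
      params <- st$params
      opt <- st$state
    }
  }
  params
}

#' Mean soft Dice coefficient of a parameter set over a manifest split
#' @param params,config Network parameters and config.
#' @param pairs Loaded pairs (positive images and labels are used).
#' @return Mean of `(2 sum(s t) + eps) / (sum s + sum t + eps)` with
#'   squashed outputs.
#' @keywords internal
mean_dice_coef <- function(params, config, pairs, epsilon = 1) {
  mean(vapply(pairs, function(pr) {
    s <- squash(net_forward(params, config, pr$positive))
    -dice_loss(s, pr$label, epsilon)
  }, 0))
}

#' @export
print.cad_detector <- function(x, ...) {
  cat("Paired-loss lesion detector\n")
  cat(sprintf("  levels %d, base channels %d, input %dx%d (%s params)\n",
              x$model_config$levels, x$model_config$base_channels,
              x$model_config$input_size, x$model_config$input_size,
              format(sum(vapply(x$params, length, 0L)), big.mark = ",")))
  w <- x$train_config$weights
  cat(sprintf("  loss weights: dice %g, necmos %g, nac %g\n",
              w$w_dice, w$w_necmos, w$w_nac))
  cat(sprintf("  trained %d epochs; best epoch %d (val R-CPM %.3f)\n",
              nrow(x$history), x$best_epoch,
              x$checkpoints[[x$best_epoch]]$val_rcpm))
  invisible(x)
}

#' @export
summary.cad_detector <- function(object, ...) {
  print(object)
  cat("\nEpoch history:\n")
  print(object$history, row.names = FALSE)
  invisible(object)
}

#' @export
plot.cad_detector <- function(x, ...) {
  graphics::par(mfrow = c(1, 2))
  graphics::plot(x$history$epoch, x$history$train_loss, type = "b",
                 xlab = "Epoch", ylab = "Mean training loss", ...)
  graphics::plot(x$history$epoch, x$history$val_rcpm, type = "b",
                 xlab = "Epoch", ylab = "Validation R-CPM", ylim = c(0, 1), ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  invisible(x)
}

#' Predict likelihood maps and candidates for new images
#'
#' @param object A `cad_detector`.
#' @param images A matrix, a list of matrices, or a character vector of
#'   image paths. Images whose size differs from the model input are
#'   resampled (nearest neighbor) with a message.
#' @param type `"candidates"` (default) for a candidate table, `"map"` for
#'   the raw likelihood maps.
#' @param ... Unused.
#' @return For `"map"`, a list of likelihood matrices; for
#'   `"candidates"`, a `data.frame` `(case_id, candidate_id, likelihood,
#'   n_pixels, pixels)` with run-length-encoded pixel sets.
#' @export
predict.cad_detector <- function(object, images, type = c("candidates", "map"),
                                 ...) {
  type <- match.arg(type)
  if (is.character(images)) {
    ids <- basename(images)
    images <- lapply(images, read_gray)
  } else if (is.matrix(images)) {
    ids <- "image_1"
    images <- list(images)
  } else ids <- names(images) %||% paste0("image_", seq_along(images))
  S <- object$model_config$input_size
  maps <- lapply(seq_along(images), function(i) {
    img <- images[[i]]
    if (!identical(dim(img), c(S, S))) {
      message("resampling ", ids[i], " from ",
              paste(dim(img), collapse = "x"), " to ", S, "x", S)
      img <- resize_nearest(img, S)
    }
    net_forward(object$params, object$model_config, img)
  })
  names(maps) <- ids
  if (type == "map") return(maps)
  candidate_table(maps)
}

#' Nearest-neighbor image resampling
#' @param img Matrix.
#' @param size Target side length.
#' @return `size` x `size` matrix.
#' @export
resize_nearest <- function(img, size) {
  ri <- pmin(nrow(img), pmax(1, round(seq(1, nrow(img), length.out = size))))
  ci <- pmin(ncol(img), pmax(1, round(seq(1, ncol(img), length.out = size))))
  img[ri, ci]
}

#' Tabulate candidates from a set of likelihood maps
#'
#' @param maps Named list of likelihood matrices.
#' @return `data.frame` with one row per candidate; pixel sets are stored
#'   as run-length-encoded strings (`start:length` comma separated, linear
#'   column-major indices).
#' @export
candidate_table <- function(maps) {
  rows <- list()
  for (id in names(maps)) {
    cands <- extract_candidates(maps[[id]], id)
    for (j in seq_along(cands)) {
      rows[[length(rows) + 1]] <- data.frame(
        case_id = id, candidate_id = j,
        likelihood = cands[[j]]$likelihood,
        n_pixels = length(cands[[j]]$pixels),
        pixels = rle_encode(cands[[j]]$pixels))
    }
  }
  if (length(rows) == 0)
    return(data.frame(case_id = character(), candidate_id = integer(),
                      likelihood = numeric(), n_pixels = integer(),
                      pixels = character()))
  do.call(rbind, rows)
}

#' Run-length encode / decode a sorted pixel index set
#' @param pixels Integer vector of linear indices.
#' @return Character scalar of `start:length` runs.
#' @export
rle_encode <- function(pixels) {
  pixels <- sort(pixels)
  breaks <- c(0, which(diff(pixels) != 1), length(pixels))
  runs <- vapply(seq_len(length(breaks) - 1), function(k) {
    seg <- pixels[(breaks[k] + 1):breaks[k + 1]]
    paste0(seg[1], ":", length(seg))
  }, "")
  paste(runs, collapse = ",")
}

#' @rdname rle_encode
#' @param code Encoded string.
#' @export
rle_decode <- function(code) {
  parts <- strsplit(code, ",")[[1]]
  unlist(lapply(parts, function(p) {
    sl <- as.integer(strsplit(p, ":")[[1]])
    seq(sl[1], length.out = sl[2])
  }))
}
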