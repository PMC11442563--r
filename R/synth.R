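#' Configuration for the positive/negative pair simulator
#'
#' Collects every knob of the synthetic data generator: nodule geometry
#' (sphere count, radii, bounding box, attenuation), embedding (blend-ratio
#' range, label support threshold, display polarity), and the procedural
#' phantom background (lung-field ellipses, rib band frequency/amplitude,
#' vignetting, additive noise). All lengths are in pixels / voxels.
#'
#' @param image_size Side of the square image in pixels (>= 32).
#' @param sphere_count Integer range `c(lo, hi)` of spheres per nodule.
#' @param radius Range of sphere radii in voxels.
#' @param bbox_halfwidth Half-width of the cube that must contain every
#'   sphere center; default `2 * max(radius)`.
#' @param attenuation Range of the per-shape attenuation coefficient
#'   (per unit length, arbitrary units).
#' @param blend_ratio Range (within `(0, 1]`) of the embedding
#'   interpolation ratio; smaller ratios give fainter nodules.
#' @param label_threshold Fraction of the attenuation map's maximum below
#'   which a pixel is excluded from the binary label (trims the
#'   anti-aliased rim of the projected footprint).
#' @param nodule_polarity `"bright"` (nodules add opacity on standard
#'   radiograph display) or `"dark"` (plain Beer-Lambert darkening).
#' @param lung_centers 2x2 matrix of relative `(u, v)` lung-field centers.
#' @param lung_axes 2x2 matrix of relative ellipse semi-axes.
#' @param base_level,lung_level Background and lung-field brightness.
#' @param rib_freq Rib band frequency in cycles per image height.
#' @param rib_amp Rib band amplitude (0 disables the bands).
#' @param vignette Strength of the radial brightness falloff.
#' @param noise_sd Standard deviation of the additive Gaussian noise.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(image_size = 128,
                         sphere_count = c(2L, 6L),
                         radius = c(4, 12),
                         bbox_halfwidth = NULL,
                         attenuation = c(0.02, 0.08),
                         blend_ratio = c(0.3, 1.0),
                         label_threshold = 0.01,
                         nodule_polarity = c("bright", "dark"),
                         lung_centers = rbind(c(0.30, 0.48), c(0.70, 0.48)),
                         lung_axes = rbind(c(0.17, 0.30), c(0.17, 0.30)),
                         base_level = 0.22,
                         lung_level = 0.45,
                         rib_freq = 9,
                         rib_amp = 0.05,
                         vignette = 0.25,
                         noise_sd = 0.01) {
  nodule_polarity <- match.arg(nodule_polarity)
  if (is.null(bbox_halfwidth)) bbox_halfwidth <- 2 * max(radius)
  cfg <- list(image_size = as.integer(image_size),
              sphere_count = as.integer(sphere_count), radius = radius,
              bbox_halfwidth = bbox_halfwidth, attenuation = attenuation,
              blend_ratio = blend_ratio, label_threshold = label_threshold,
              nodule_polarity = nodule_polarity, lung_centers = lung_centers,
              lung_axes = lung_axes, base_level = base_level,
              lung_level = lung_level, rib_freq = rib_freq, rib_amp = rib_amp,
              vignette = vignette, noise_sd = noise_sd)
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  stopifnot(cfg$image_size >= 32,
            length(cfg$sphere_count) == 2, cfg$sphere_count[1] >= 1,
            cfg$sphere_count[1] <= cfg$sphere_count[2],
            length(cfg$radius) == 2, cfg$radius[1] > 0,
            cfg$radius[1] <= cfg$radius[2],
            cfg$attenuation[1] > 0, cfg$attenuation[1] <= cfg$attenuation[2],
            cfg$blend_ratio[1] > 0, cfg$blend_ratio[2] <= 1,
            cfg$blend_ratio[1] <= cfg$blend_ratio[2],
            cfg$label_threshold >= 0, cfg$label_threshold < 1,
            cfg$noise_sd >= 0, cfg$rib_amp >= 0)
  invisible(cfg)
}

#' Draw a random union-of-spheres nodule solid
#'
#' A 3-D nodule is a union of overlapping spheres: the first sphere sits at
#' the origin and every later sphere is attached to a randomly chosen
#' predecessor at a center distance below `r_parent + 0.85 * r_new`, which
#' guarantees the center-to-union distance stays below the new radius and
#' hence the solid is connected. Centers are kept inside the configured
#' bounding cube by rejection sampling. Draws come from the current RNG
#' state, so the shape is reproducible under `set.seed()`.
#'
#' @param config A [synth_config()].
#' @return A `nodule_shape` with fields `centers` (n x 3 matrix, voxel
#'   units), `radii` (length n), and `attenuation` (scalar coefficient).
#' @export
make_nodule_shape <- function(config) {
  validate_synth_config(config)
  B <- config$bbox_halfwidth
  if (max(config$radius) > B)
    stop("bounding box (halfwidth ", B, ") cannot contain the maximum radius ",
         max(config$radius))
  n <- if (config$sphere_count[1] == config$sphere_count[2])
    config$sphere_count[1]
  else sample(config$sphere_count[1]:config$sphere_count[2], 1)
  radii <- stats::runif(n, config$radius[1], config$radius[2])
  centers <- matrix(0, n, 3)
  for (k in seq_len(n)[-1]) {
    ok <- FALSE
    for (try in 1:100) {
      parent <- if (k == 2) 1L else sample.int(k - 1L, 1L)
      dir <- stats::rnorm(3)
      dir <- dir / sqrt(sum(dir^2))
      d <- stats::runif(1) * (radii[parent] + 0.85 * radii[k])
      cand <- centers[parent, ] + d * dir
      if (all(abs(cand) <= B)) { centers[k, ] <- cand; ok <- TRUE; break }
    }
    if (!ok) centers[k, ] <- centers[parent, ]  # coincident center still overlaps
  }
  structure(list(centers = centers, radii = radii,
                 attenuation = stats::runif(1, config$attenuation[1],
                                            config$attenuation[2])),
            class = "nodule_shape")
}

#' Check connectivity of a sphere-union solid
#'
#' Each sphere after the first must overlap the union of its predecessors:
#' the distance from its center to that union (`min_j max(0, |c_k - c_j| -
#' r_j)`) must be strictly less than its radius.
#'
#' @param shape A `nodule_shape`.
#' @return `TRUE` if the union is connected under this criterion.
#' @export
nodule_is_connected <- function(shape) {
  n <- length(shape$radii)
  if (n == 1) return(TRUE)
  for (k in 2:n) {
    d <- sqrt(colSums((t(shape$centers[seq_len(k - 1), , drop = FALSE]) -
                         shape$centers[k, ])^2))
    to_union <- min(pmax(0, d - shape$radii[seq_len(k - 1)]))
    if (to_union >= shape$radii[k]) return(FALSE)
  }
  TRUE
}

#' Orthographic X-ray projection of a nodule solid
#'
#' Simulates a parallel-beam X-ray: for every pixel, the ray travels along
#' the depth axis through the sphere union, and the pixel value is the
#' attenuation coefficient times the exact ray-union intersection length.
#' Per-sphere chords are analytic (`2 * sqrt(r^2 - d^2)`) and overlaps are
#' handled by merging the per-ray chord intervals, so overlapping spheres
#' are never double counted. Pixel centers sit at integer coordinates,
#' 0-based, row-major.
#'
#' @param shape A `nodule_shape` (x maps to image column, y to row, z to
#'   the ray direction).
#' @param image_size Side of the square output map in pixels.
#' @param offset Length-2 vector `(row, col)`: image position of the
#'   shape's coordinate origin.
#' @return Matrix of nonnegative path integrals with compact support
#'   (class `attenuation_map`).
#' @export
project_attenuation <- function(shape, image_size, offset) {
  S <- as.integer(image_size)
  n <- length(shape$radii)
  # bounds: every projected sphere disk must land inside the image
  rows <- shape$centers[, 2] + offset[1]
  cols <- shape$centers[, 1] + offset[2]
  if (any(rows - shape$radii < 0) || any(rows + shape$radii > S - 1) ||
      any(cols - shape$radii < 0) || any(cols + shape$radii > S - 1))
    stop("projected nodule footprint out of image bounds")

  y <- matrix(0:(S - 1), S, S)          # row coordinate
  x <- matrix(0:(S - 1), S, S, byrow = TRUE)  # column coordinate
  lo <- array(NA_real_, c(S, S, n))
  hi <- array(NA_real_, c(S, S, n))
  for (k in seq_len(n)) {
    d2 <- (x - cols[k])^2 + (y - rows[k])^2
    hit <- d2 < shape$radii[k]^2
    h <- sqrt(pmax(0, shape$radii[k]^2 - d2))
    cz <- shape$centers[k, 3]
    lo[, , k][hit] <- (cz - h)[hit]
    hi[, , k][hit] <- (cz + h)[hit]
  }
  nhit <- apply(!is.na(lo), c(1, 2), sum)
  len <- matrix(0, S, S)
  single <- nhit == 1
  if (any(single)) {
    tot <- apply(hi - lo, c(1, 2), sum, na.rm = TRUE)
    len[single] <- tot[single]
  }
  multi <- which(nhit >= 2)
  for (p in multi) {
    i <- ((p - 1) %% S) + 1
    j <- ((p - 1) %/% S) + 1
    a <- lo[i, j, ]; b <- hi[i, j, ]
    keep <- !is.na(a)
    len[p] <- interval_union_length(a[keep], b[keep])
  }
  structure(len * shape$attenuation, class = c("attenuation_map", "matrix"))
}

# total length of the union of intervals [a_i, b_i]
interval_union_length <- function(a, b) {
  o <- order(a)
  a <- a[o]; b <- b[o]
  total <- 0
  cur_a <- a[1]; cur_b <- b[1]
  for (i in seq_along(a)[-1]) {
    if (a[i] > cur_b) {
      total <- total + (cur_b - cur_a)
      cur_a <- a[i]; cur_b <- b[i]
    } else cur_b <- max(cur_b, b[i])
  }
  total + (cur_b - cur_a)
}

#' Procedural phantom radiograph background
#'
#' A lesion-free stand-in for a normal chest radiograph: two bright
#' elliptical lung fields with soft edges, periodic rib-like bands masked
#' to the lung fields, smooth radial vignetting, and additive Gaussian
#' noise, all clipped to `[0, 1]`. Deterministic given the RNG state.
#'
#' @param config A [synth_config()].
#' @return `image_size` x `image_size` matrix in `[0, 1]`.
#' @export
make_background <- function(config) {
  validate_synth_config(config)
  S <- config$image_size
  v <- matrix(seq(0, 1, length.out = S), S, S)          # row coord
  u <- matrix(seq(0, 1, length.out = S), S, S, byrow = TRUE)
  img <- matrix(config$base_level, S, S)
  lung_mask <- matrix(0, S, S)
  for (k in 1:2) {
    e <- ((u - config$lung_centers[k, 1]) / config$lung_axes[k, 1])^2 +
         ((v - config$lung_centers[k, 2]) / config$lung_axes[k, 2])^2
    m <- 1 / (1 + exp((e - 1) / 0.08))
    lung_mask <- pmax(lung_mask, m)
  }
  img <- img + config$lung_level * lung_mask
  img <- img + config$rib_amp *
    sin(2 * pi * (config$rib_freq * v + 0.15 * u)) * lung_mask
  r2 <- (u - 0.5)^2 + (v - 0.5)^2
  img <- img * (1 - config$vignette * 2 * r2)
  if (config$noise_sd > 0)
    img <- img + matrix(stats::rnorm(S * S, 0, config$noise_sd), S, S)
  pmin(pmax(img, 0), 1)
}

#' Embed a projected nodule into a background image
#'
#' Applies Beer-Lambert attenuation `exp(-attmap)` to the background — on
#' the inverted scale for the `"bright"` polarity, where increased opacity
#' raises displayed brightness — and linearly interpolates between the
#' background and the fully embedded image with `blend_ratio`, emulating a
#' random-strength, indistinct lesion. The binary label is the part of the
#' attenuation map above `label_threshold` of its maximum.
#'
#' @param background Matrix in `[0, 1]`.
#' @param attmap Nonnegative attenuation path-integral map (same shape).
#' @param blend_ratio Scalar in `(0, 1]`.
#' @param label_threshold Relative support threshold for the label.
#' @param polarity `"bright"` or `"dark"` nodule rendering.
#' @return List with `positive` (clipped to `[0, 1]`) and binary `label`.
#' @export
embed_nodule <- function(background, attmap, blend_ratio,
                         label_threshold = 0.01,
                         polarity = c("bright", "dark")) {
  polarity <- match.arg(polarity)
  check_same_shape(background, unclass(attmap))
  if (blend_ratio <= 0 || blend_ratio > 1)
    stop("blend_ratio must lie in (0, 1]")
  att <- unclass(attmap)
  trans <- exp(-att)
  embedded <- if (polarity == "dark") background * trans
              else 1 - (1 - background) * trans
  blended <- (1 - blend_ratio) * background + blend_ratio * embedded
  # blend only on the footprint so pixels the nodule cannot touch stay
  # bit-identical to the background
  positive <- background
  inside <- att > 0
  positive[inside] <- pmin(pmax(blended[inside], 0), 1)
  m <- max(attmap)
  label <- (unclass(attmap) > label_threshold * m) * 1
  list(positive = positive, label = label)
}

#' Generate one positive/negative image pair
#'
#' Produces a lesion-free phantom background (the negative image) and, when
#' `with_nodule` is `TRUE`, a positive twin made by projecting a fresh
#' sphere-union nodule into a lung field of the *same* background, plus its
#' pixel-level binary label. The two images are identical outside the
#' nodule footprint — the property that paired contrastive training
#' exploits. Fully reproducible from `seed` and `config`.
#'
#' @param config A [synth_config()].
#' @param seed Integer seed for this pair.
#' @param with_nodule Embed a nodule? If `FALSE` the positive image equals
#'   the negative and the label is all-zero.
#' @return An `image_pair` with fields `positive`, `negative`, `label`,
#'   `footprint` (binary support of the projected nodule), `blend_ratio`,
#'   `seed`, `nodule`.
#' @export
generate_pair <- function(config, seed, with_nodule = TRUE) {
  validate_synth_config(config)
  set.seed(seed)
  negative <- make_background(config)
  S <- config$image_size
  if (!with_nodule) {
    z <- matrix(0, S, S)
    return(structure(list(positive = negative, negative = negative,
                          label = z, footprint = z, blend_ratio = 1,
                          seed = seed, nodule = NULL), class = "image_pair"))
  }
  shape <- make_nodule_shape(config)
  rf <- max(sqrt(rowSums(shape$centers[, 1:2, drop = FALSE]^2)) + shape$radii)
  margin <- ceiling(rf) + 1
  if (2 * margin >= S - 1)
    stop("nodule footprint too large for the configured image size")
  k <- sample(1:2, 1)
  ang <- stats::runif(1, 0, 2 * pi)
  rad <- sqrt(stats::runif(1)) * 0.6
  off_col <- (config$lung_centers[k, 1] + rad * cos(ang) * config$lung_axes[k, 1]) * (S - 1)
  off_row <- (config$lung_centers[k, 2] + rad * sin(ang) * config$lung_axes[k, 2]) * (S - 1)
  off_row <- min(max(off_row, margin), S - 1 - margin)
  off_col <- min(max(off_col, margin), S - 1 - margin)
  blend <- stats::runif(1, config$blend_ratio[1], config$blend_ratio[2])
  attmap <- project_attenuation(shape, S, c(off_row, off_col))
  emb <- embed_nodule(negative, attmap, blend, config$label_threshold,
                      config$nodule_polarity)
  structure(list(positive = emb$positive, negative = negative,
                 label = emb$label, footprint = (unclass(attmap) > 0) * 1,
                 blend_ratio = blend, seed = seed, nodule = shape),
            class = "image_pair")
}

#' Binary dilation by one pixel (3x3 structuring element)
#' @param mask Binary matrix.
#' @return Dilated binary matrix.
#' @keywords internal
dilate1 <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  out <- matrix(0, H, W)
  for (di in -1:1) for (dj in -1:1) {
    si <- max(1, 1 - di):min(H, H - di)
    sj <- max(1, 1 - dj):min(W, W - dj)
    out[si + di, sj + dj] <- pmax(out[si + di, sj + dj], mask[si, sj])
  }
  out
}

#' Validate the structural invariants of an image pair
#'
#' Checks shapes, value ranges, label consistency, and pair locality: the
#' positive and negative images must agree exactly outside the nodule
#' footprint dilated by one pixel.
#'
#' @param pair An `image_pair`.
#' @return `TRUE` invisibly; otherwise an error describing the violation.
#' @export
validate_image_pair <- function(pair) {
  stopifnot(inherits(pair, "image_pair"))
  check_same_shape(pair$positive, pair$negative)
  check_same_shape(pair$positive, pair$label)
  if (any(pair$positive < 0 | pair$positive > 1) ||
      any(pair$negative < 0 | pair$negative > 1))
    stop("image values outside [0, 1]")
  if (!all(pair$label %in% c(0, 1))) stop("label is not binary")
  if (pair$blend_ratio <= 0 || pair$blend_ratio > 1)
    stop("blend_ratio outside (0, 1]")
  outside <- dilate1(pair$footprint) == 0
  if (!identical(pair$positive[outside], pair$negative[outside]))
    stop("positive and negative differ outside the dilated footprint")
  if (!is.null(pair$nodule) && sum(pair$label) == 0)
    stop("nodule requested but label is empty")
  invisible(TRUE)
}

#' Synthesize a paired dataset on disk
#'
#' Writes `n_cases` positive/negative/label image triplets plus a manifest
#' table. Per-case seeds are drawn once from the master seed, and the
#' train/validation split is a seeded random assignment of
#' `round(val_fraction * n_cases)` cases, so the whole dataset — including
#' the manifest bytes — is reproducible from `(seed, config)`. Paths in the
#' manifest are relative to its own directory.
#'
#' @param n_cases Number of pairs (>= 2).
#' @param config A [synth_config()].
#' @param seed Master integer seed.
#' @param val_fraction Fraction of cases assigned to the validation split.
#' @param out_dir Output directory (created if missing).
#' @param format `"png"` (8-bit grayscale) or `"rds"` (lossless float).
#' @return The manifest `data.frame`, invisibly; written to
#'   `out_dir/manifest.csv`.
#' @export
generate_dataset <- function(n_cases, config, seed, val_fraction = 0.1,
                             out_dir, format = c("png", "rds")) {
  format <- match.arg(format)
  stopifnot(n_cases >= 2, val_fraction >= 0, val_fraction < 1)
  dir.create(file.path(out_dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  set.seed(seed)
  case_seeds <- sample.int(.Machine$integer.max - 1L, n_cases)
  n_val <- round(val_fraction * n_cases)
  val_idx <- sample.int(n_cases, n_val)
  split <- rep("train", n_cases)
  split[val_idx] <- "val"
  rows <- vector("list", n_cases)
  for (i in seq_len(n_cases)) {
    pair <- generate_pair(config, case_seeds[i])
    id <- sprintf("case_%05d", i)
    ext <- format
    pp <- file.path("images", paste0(id, "_pos.", ext))
    np <- file.path("images", paste0(id, "_neg.", ext))
    lp <- file.path("images", paste0(id, "_label.", ext))
    write_gray(pair$positive, file.path(out_dir, pp), format)
    write_gray(pair$negative, file.path(out_dir, np), format)
    write_gray(pair$label, file.path(out_dir, lp), format)
    rows[[i]] <- data.frame(case_id = id, positive_path = pp,
                            negative_path = np, label_path = lp,
                            split = split[i], seed = case_seeds[i],
                            blend_ratio = pair$blend_ratio)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  attr(manifest, "dir") <- out_dir
  invisible(manifest)
}

write_gray <- function(img, path, format) {
  if (format == "png") png::writePNG(img, path) else saveRDS(img, path)
}

#' Read a grayscale image written by the synthesizer
#' @param path PNG or RDS file path.
#' @return Matrix in `[0, 1]`.
#' @export
read_gray <- function(path) {
  if (grepl("\\.rds$", path)) return(readRDS(path))
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img
}

#' Read a dataset manifest
#'
#' @param path Path to a `manifest.csv` written by [generate_dataset()].
#' @return `data.frame` with attribute `dir` used to resolve the relative
#'   image paths.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  attr(m, "dir") <- dirname(normalizePath(path))
  m
}

manifest_path <- function(manifest, column, i) {
  d <- attr(manifest, "dir")
  p <- manifest[[column]][i]
  if (!is.null(d) && !grepl("^/", p)) file.path(d, p) else p
}
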