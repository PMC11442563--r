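# Independent brute-force oracles. These deliberately avoid the package's
# vectorized code paths: explicit pixel loops, flood fills, and exhaustive
# enumerations, kept slow and obvious.

oracle_dice <- function(f, t, eps = 1) {
  num <- 0; sf <- 0; st <- 0
  for (i in seq_along(f)) {
    num <- num + f[i] * t[i]
    sf <- sf + f[i]
    st <- st + t[i]
  }
  -(2 * num + eps) / (sf + st + eps)
}

oracle_necmos <- function(f) {
  m <- -Inf
  for (i in seq_along(f)) if (f[i] > m) m <- f[i]
  m
}

oracle_nac <- function(fp, fn, t) {
  mp <- -Inf; mn <- -Inf
  for (i in seq_along(t)) {
    if (t[i] == 1) {
      if (fp[i] > mp) mp <- fp[i]
      if (fn[i] > mn) mn <- fn[i]
    }
  }
  -min(1, mp - mn)
}

oracle_combined <- function(fp, fn, t, w_dice, w_necmos, w_nac, eps = 1) {
  s <- fp / (1 + fp)
  w_dice * (-log(-oracle_dice(s, t, eps))) +
    w_necmos * oracle_necmos(fn) +
    w_nac * oracle_nac(fp, fn, t)
}

# recursive flood fill labeling (independent of the C++ union-find/BFS)
oracle_label <- function(mask, connectivity = 8) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  nb <- if (connectivity == 8)
    expand.grid(di = -1:1, dj = -1:1)[-5, ]
  else data.frame(di = c(-1, 1, 0, 0), dj = c(0, 0, -1, 1))
  cur <- 0L
  for (j in seq_len(W)) for (i in seq_len(H)) {
    if (!mask[i, j] || lab[i, j] > 0) next
    cur <- cur + 1L
    queue <- list(c(i, j))
    lab[i, j] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(nb))) {
        qi <- p[1] + nb$di[k]; qj <- p[2] + nb$dj[k]
        if (qi >= 1 && qi <= H && qj >= 1 && qj <= W &&
            mask[qi, qj] && lab[qi, qj] == 0) {
          lab[qi, qj] <- cur
          queue[[length(queue) + 1]] <- c(qi, qj)
        }
      }
    }
  }
  lab
}

oracle_auroc <- function(scores, is_pos) {
  ps <- scores[is_pos]; ns <- scores[!is_pos]
  conc <- 0
  for (p in ps) for (n in ns)
    conc <- conc + if (p > n) 1 else if (p == n) 0.5 else 0
  conc / (length(ps) * length(ns))
}

# exhaustive per-threshold FROC recount straight from the definitions
oracle_froc_point <- function(cases, theta, iou_min = 0.1) {
  n_lesions <- 0; detected <- 0; fps <- 0
  for (cs in cases) {
    n_lesions <- n_lesions + length(cs$lesions)
    surviving <- Filter(function(cd) cd$likelihood >= theta, cs$candidates)
    for (les in cs$lesions) {
      hit <- FALSE
      for (cd in surviving) {
        ii <- length(intersect(cd$pixels, les))
        uu <- length(union(cd$pixels, les))
        if (ii / uu >= iou_min) hit <- TRUE
      }
      detected <- detected + hit
    }
    for (cd in surviving) {
      is_tp <- FALSE
      for (les in cs$lesions) {
        ii <- length(intersect(cd$pixels, les))
        uu <- length(union(cd$pixels, les))
        if (ii / uu >= iou_min) is_tp <- TRUE
      }
      fps <- fps + !is_tp
    }
  }
  c(sensitivity = detected / n_lesions, fp_per_case = fps / length(cases))
}

# voxel-marching estimate of the union volume and of per-ray path lengths
oracle_voxel_project <- function(shape, image_size, offset, pitch) {
  lim <- max(abs(shape$centers)) + max(shape$radii) + pitch
  zs <- seq(-lim, lim, by = pitch)
  map <- matrix(0, image_size, image_size)
  for (row in 0:(image_size - 1)) {
    for (col in 0:(image_size - 1)) {
      x <- col - offset[2]; y <- row - offset[1]
      # quick reject: outside every sphere's disk
      d2 <- (x - shape$centers[, 1])^2 + (y - shape$centers[, 2])^2
      if (all(d2 >= shape$radii^2)) next
      inside <- rep(FALSE, length(zs))
      for (k in seq_along(shape$radii)) {
        inside <- inside | (d2[k] + (zs - shape$centers[k, 3])^2 <
                              shape$radii[k]^2)
      }
      map[row + 1, col + 1] <- sum(inside) * pitch * shape$attenuation
    }
  }
  map
}

oracle_voxel_volume <- function(shape, pitch) {
  lim <- max(abs(shape$centers)) + max(shape$radii) + pitch
  gs <- seq(-lim, lim, by = pitch)
  count <- 0
  for (z in gs) {
    sl <- matrix(FALSE, length(gs), length(gs))
    for (k in seq_along(shape$radii)) {
      r2 <- shape$radii[k]^2 - (z - shape$centers[k, 3])^2
      if (r2 <= 0) next
      sl <- sl | (outer((gs - shape$centers[k, 2])^2,
                        (gs - shape$centers[k, 1])^2, "+") < r2)
    }
    count <- count + sum(sl)
  }
  count * pitch^3
}

# voxelized connectivity check of a sphere union (single connected blob?)
oracle_shape_connected <- function(shape, pitch = 0.5) {
  lim <- max(abs(shape$centers)) + max(shape$radii) + pitch
  gs <- seq(-lim, lim, by = pitch)
  n <- length(gs)
  vox <- array(FALSE, c(n, n, n))
  for (k in seq_along(shape$radii)) {
    dx2 <- (gs - shape$centers[k, 1])^2
    dy2 <- (gs - shape$centers[k, 2])^2
    dz2 <- (gs - shape$centers[k, 3])^2
    for (iz in which(dz2 < shape$radii[k]^2)) {
      r2 <- shape$radii[k]^2 - dz2[iz]
      vox[, , iz] <- vox[, , iz] | (outer(dy2, dx2, "+") < r2)
    }
  }
  idx <- which(vox, arr.ind = TRUE)
  if (nrow(idx) == 0) return(FALSE)
  # 6-connectivity flood fill from the first voxel
  key <- function(m) (m[, 1] - 1) + n * ((m[, 2] - 1) + n * (m[, 3] - 1))
  all_keys <- sort(key(idx))
  seen <- new.env(hash = TRUE)
  stack <- all_keys[1]
  assign(as.character(all_keys[1]), TRUE, envir = seen)
  visited <- 0
  keyset <- as.character(all_keys)
  has <- new.env(hash = TRUE)
  for (k in keyset) assign(k, TRUE, envir = has)
  while (length(stack)) {
    k <- stack[length(stack)]; stack <- stack[-length(stack)]
    visited <- visited + 1
    i <- k %% n; rest <- k %/% n; j <- rest %% n; z <- rest %/% n
    for (d in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                   c(0, 0, 1), c(0, 0, -1))) {
      ni <- i + d[1]; nj <- j + d[2]; nz <- z + d[3]
      if (ni < 0 || ni >= n || nj < 0 || nj >= n || nz < 0 || nz >= n) next
      nk <- ni + n * (nj + n * nz)
      ck <- as.character(nk)
      if (exists(ck, envir = has, inherits = FALSE) &&
          !exists(ck, envir = seen, inherits = FALSE)) {
        assign(ck, TRUE, envir = seen)
        stack <- c(stack, nk)
      }
    }
  }
  visited == length(all_keys)
}

# small scripted detection sets for metric tests
random_cases <- function(n_cases, seed, p_lesion = 0.6) {
  set.seed(seed)
  lapply(seq_len(n_cases), function(i) {
    lesions <- list()
    if (stats::runif(1) < p_lesion)
      lesions <- list(sample(1:400, sample(5:20, 1)))
    n_cand <- sample(0:4, 1)
    candidates <- lapply(seq_len(n_cand), function(j) {
      overlap_truth <- length(lesions) > 0 && stats::runif(1) < 0.5
      px <- if (overlap_truth)
        unique(c(sample(lesions[[1]], ceiling(length(lesions[[1]]) / 2)),
                 sample(1:400, 3)))
      else sample(401:800, sample(3:15, 1))
      list(pixels = px, likelihood = stats::runif(1), case_id = paste0("c", i))
    })
    case_detections(paste0("c", i), candidates, lesions)
  })
}

test_synth_config <- function(...) {
  args <- utils::modifyList(
    list(image_size = 32, sphere_count = c(2L, 4L), radius = c(1.8, 3.5),
         bbox_halfwidth = 4, attenuation = c(0.02, 0.07),
         noise_sd = 0.02, rib_freq = 5),
    list(...))
  do.call(synth_config, args)
}

make_shape <- function(centers, radii, attenuation = 0.1) {
  structure(list(centers = matrix(centers, ncol = 3, byrow = TRUE),
                 radii = radii, attenuation = attenuation),
            class = "nodule_shape")
}
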