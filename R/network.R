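#' Encoder-decoder model configuration
#'
#' A U-shaped image-to-image network: `levels` resolution levels with
#' max-pool (stride 2) downsampling, nearest-neighbor upsampling, and
#' encoder-decoder shortcut concatenation. Each level holds one
#' (optionally residual) double 3x3 convolution block; channel width
#' doubles per level from `base_channels`. The final 1x1 convolution is
#' clipped by a ReLU so every output pixel lies in `[0, +Inf)` — the
#' nonnegative-output contract the candidate extractor and the Necmos/Nac
#' losses rely on. An optional dense (flatten + fully connected) residual
#' block can be enabled at the bottleneck. The full-scale reference setup
#' (9 levels at 1024 px with the dense bottleneck) is expressible; the
#' default is a small CPU-friendly variant, since the loss design is
#' architecture-agnostic.
#'
#' @param levels Number of resolution levels (>= 2).
#' @param base_channels Channels at the finest level.
#' @param input_size Input image side; must be divisible by
#'   `2^(levels - 1)`.
#' @param residual Use residual (projection-shortcut) conv blocks.
#' @param use_bottleneck_dense Insert a dense residual block at the
#'   bottleneck.
#' @return A `model_config` list with derived per-level channel widths.
#' @export
model_config <- function(levels = 3L, base_channels = 8L, input_size = 32L,
                         residual = TRUE, use_bottleneck_dense = FALSE) {
  levels <- as.integer(levels)
  input_size <- as.integer(input_size)
  stopifnot(levels >= 2, base_channels >= 1)
  if (input_size %% 2^(levels - 1) != 0)
    stop("input_size must be divisible by 2^(levels - 1)")
  structure(list(levels = levels, base_channels = as.integer(base_channels),
                 input_size = input_size, residual = residual,
                 use_bottleneck_dense = use_bottleneck_dense,
                 channels = as.integer(base_channels * 2^(0:(levels - 1)))),
            class = "model_config")
}

relu <- function(x) pmax(x, 0)

he_w <- function(k, cin, cout) {
  matrix(stats::rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
         k * k * cin, cout)
}

init_block <- function(params, prefix, cin, cout, residual) {
  params[[paste0(prefix, ".w1")]] <- he_w(3, cin, cout)
  params[[paste0(prefix, ".b1")]] <- rep(0, cout)
  params[[paste0(prefix, ".w2")]] <- he_w(3, cout, cout)
  params[[paste0(prefix, ".b2")]] <- rep(0, cout)
  if (residual && cin != cout) {
    params[[paste0(prefix, ".wp")]] <- he_w(1, cin, cout)
    params[[paste0(prefix, ".bp")]] <- rep(0, cout)
  }
  params
}

#' Initialize network parameters
#'
#' He-normal initialization of every convolution; the output bias starts
#' slightly positive so the final ReLU is active at initialization.
#'
#' @param config A [model_config()].
#' @param seed Integer seed.
#' @return Named flat list of parameter arrays.
#' @export
init_params <- function(config, seed = 1L) {
  set.seed(seed)
  ch <- config$channels
  L <- config$levels
  p <- list()
  for (l in seq_len(L)) {
    cin <- if (l == 1) 1L else ch[l - 1]
    p <- init_block(p, paste0("enc", l), cin, ch[l], config$residual)
  }
  if (config$use_bottleneck_dense) {
    hb <- config$input_size / 2^(L - 1)
    n <- hb * hb * ch[L]
    p[["dense.W"]] <- matrix(stats::rnorm(n * n, 0, sqrt(2 / n)), n, n)
    p[["dense.b"]] <- rep(0, n)
  }
  for (l in seq_len(L - 1))
    p <- init_block(p, paste0("dec", l), ch[l] + ch[l + 1], ch[l],
                    config$residual)
  p[["out.w"]] <- he_w(1, ch[1], 1L)
  p[["out.b"]] <- 0.1
  p
}

block_fwd <- function(x, p, prefix, residual) {
  w1 <- p[[paste0(prefix, ".w1")]]; b1 <- p[[paste0(prefix, ".b1")]]
  w2 <- p[[paste0(prefix, ".w2")]]; b2 <- p[[paste0(prefix, ".b2")]]
  a1 <- conv2d_fwd(x, w1, b1, 3L)
  r1 <- relu(a1)
  a2 <- conv2d_fwd(r1, w2, b2, 3L)
  if (residual) {
    wp <- p[[paste0(prefix, ".wp")]]
    if (!is.null(wp)) a2 <- a2 + conv2d_fwd(x, wp, p[[paste0(prefix, ".bp")]], 1L)
    else a2 <- a2 + x
  }
  list(y = relu(a2), cache = list(x = x, r1 = r1, m1 = a1 > 0, m2 = a2 > 0))
}

block_bwd <- function(gy, p, prefix, cache, residual, grads) {
  g2 <- gy * cache$m2
  bw2 <- conv2d_bwd(cache$r1, p[[paste0(prefix, ".w2")]], g2, 3L)
  grads[[paste0(prefix, ".w2")]] <- grads[[paste0(prefix, ".w2")]] + bw2$gw
  grads[[paste0(prefix, ".b2")]] <- grads[[paste0(prefix, ".b2")]] + as.vector(bw2$gb)
  ga1 <- bw2$gx * cache$m1
  bw1 <- conv2d_bwd(cache$x, p[[paste0(prefix, ".w1")]], ga1, 3L)
  grads[[paste0(prefix, ".w1")]] <- grads[[paste0(prefix, ".w1")]] + bw1$gw
  grads[[paste0(prefix, ".b1")]] <- grads[[paste0(prefix, ".b1")]] + as.vector(bw1$gb)
  gx <- bw1$gx
  if (residual) {
    wp <- p[[paste0(prefix, ".wp")]]
    if (!is.null(wp)) {
      bwp <- conv2d_bwd(cache$x, wp, g2, 1L)
      grads[[paste0(prefix, ".wp")]] <- grads[[paste0(prefix, ".wp")]] + bwp$gw
      grads[[paste0(prefix, ".bp")]] <- grads[[paste0(prefix, ".bp")]] + as.vector(bwp$gb)
      gx <- gx + bwp$gx
    } else gx <- gx + g2
  }
  list(gx = gx, grads = grads)
}

maxpool_fwd <- function(x) {
  H <- dim(x)[1]
  i1 <- seq(1, H, 2); i2 <- i1 + 1
  a <- x[i1, i1, , drop = FALSE]; b <- x[i2, i1, , drop = FALSE]
  c_ <- x[i1, i2, , drop = FALSE]; d <- x[i2, i2, , drop = FALSE]
  y <- pmax(pmax(a, b), pmax(c_, d))
  # first-match tie-break so the backward pass routes each gradient once
  ma <- a == y
  mb <- (b == y) & !ma
  mc <- (c_ == y) & !ma & !mb
  md <- !ma & !mb & !mc
  list(y = y, masks = list(ma, mb, mc, md))
}

maxpool_bwd <- function(gy, masks, H) {
  C <- dim(gy)[3]
  gx <- array(0, c(H, H, C))
  i1 <- seq(1, H, 2); i2 <- i1 + 1
  gx[i1, i1, ] <- gy * masks[[1]]
  gx[i2, i1, ] <- gy * masks[[2]]
  gx[i1, i2, ] <- gy * masks[[3]]
  gx[i2, i2, ] <- gy * masks[[4]]
  gx
}

upsample_fwd <- function(x) {
  h <- dim(x)[1]
  x[rep(seq_len(h), each = 2), rep(seq_len(h), each = 2), , drop = FALSE]
}

upsample_bwd <- function(gy) {
  H <- dim(gy)[1]
  i1 <- seq(1, H, 2); i2 <- i1 + 1
  gy[i1, i1, , drop = FALSE] + gy[i2, i1, , drop = FALSE] +
    gy[i1, i2, , drop = FALSE] + gy[i2, i2, , drop = FALSE]
}

#' Run the network forward
#'
#' @param params Parameter list from [init_params()].
#' @param config The matching [model_config()].
#' @param image `input_size` x `input_size` matrix.
#' @param want_cache Keep intermediate activations for backprop.
#' @param output_leak Backward-pass subgradient of the output ReLU on its
#'   clipped side, applied only when the *entire* output map is clipped.
#'   With a hard subgradient everywhere, a few suppression-heavy batches
#'   can drive every output pre-activation negative — an absorbing state
#'   with an identically zero gradient from which training never recovers.
#'   In that state (and only there) the clipped side passes `output_leak`
#'   (default 0.01) so the Dice term can revive lesion pixels; during
#'   normal training the subgradient is exact. Set to 0 to disable.
#' @return The nonnegative likelihood map (matrix); with `want_cache`, a
#'   list `(f, cache)`.
#' @export
net_forward <- function(params, config, image, want_cache = FALSE,
                        output_leak = 0.01) {
  S <- config$input_size
  if (!identical(dim(image), c(S, S)))
    stop("image size ", paste(dim(image), collapse = "x"),
         " does not match configured input size ", S)
  L <- config$levels
  x <- array(image, c(S, S, 1))
  skips <- vector("list", L - 1)
  caches <- list(enc = vector("list", L), pool = vector("list", L - 1),
                 dec = vector("list", L - 1))
  for (l in seq_len(L - 1)) {
    bf <- block_fwd(x, params, paste0("enc", l), config$residual)
    skips[[l]] <- bf$y
    caches$enc[[l]] <- bf$cache
    mp <- maxpool_fwd(bf$y)
    caches$pool[[l]] <- mp$masks
    x <- mp$y
  }
  bf <- block_fwd(x, params, paste0("enc", L), config$residual)
  caches$enc[[L]] <- bf$cache
  x <- bf$y
  if (config$use_bottleneck_dense) {
    v <- as.vector(x)
    a <- params$dense.W %*% v + params$dense.b
    z <- v + a
    caches$dense <- list(v = v, mz = z > 0)
    x <- array(relu(z), dim(x))
  }
  for (l in rev(seq_len(L - 1))) {
    up <- upsample_fwd(x)
    cat_in <- array(c(skips[[l]], up), c(dim(up)[1], dim(up)[2],
                                         dim(skips[[l]])[3] + dim(up)[3]))
    bf <- block_fwd(cat_in, params, paste0("dec", l), config$residual)
    caches$dec[[l]] <- c(bf$cache, list(skip_ch = dim(skips[[l]])[3]))
    x <- bf$y
  }
  a_out <- conv2d_fwd(x, params$out.w, params$out.b, 1L)
  f <- relu(a_out[, , 1])
  if (!want_cache) return(f)
  # escape hatch for the all-dead-output absorbing state (see output_leak);
  # an unconditional leak is harmful under Adam, whose per-parameter
  # normalization inflates the tiny leak gradients to full-size steps
  m <- (a_out[, , 1] > 0) * 1
  if (all(m == 0)) m[] <- output_leak
  caches$out <- list(x = x, m = m)
  list(f = f, cache = caches)
}

#' Backpropagate a loss gradient through the network
#'
#' @param params,config As in [net_forward()].
#' @param cache Cache returned by `net_forward(..., want_cache = TRUE)`.
#' @param g_f Gradient of the loss with respect to the output map.
#' @return Named list of parameter gradients (same shapes as `params`).
#' @export
net_backward <- function(params, config, cache, g_f) {
  L <- config$levels
  grads <- lapply(params, function(p) p * 0)
  g <- array(g_f * cache$out$m, c(dim(g_f), 1))
  bo <- conv2d_bwd(cache$out$x, params$out.w, g, 1L)
  grads$out.w <- grads$out.w + bo$gw
  grads$out.b <- grads$out.b + as.vector(bo$gb)
  g <- bo$gx
  # decoder runs coarse-to-fine in the forward pass, so the gradient walks
  # the decoder blocks fine-to-coarse (l = 1 .. L-1), peeling off each
  # shortcut gradient for the encoder sweep below
  skip_grad <- vector("list", L - 1)
  for (l in seq_len(L - 1)) {
    bb <- block_bwd(g, params, paste0("dec", l), cache$dec[[l]],
                    config$residual, grads)
    grads <- bb$grads
    sk <- cache$dec[[l]]$skip_ch
    skip_grad[[l]] <- bb$gx[, , seq_len(sk), drop = FALSE]
    g <- upsample_bwd(bb$gx[, , -seq_len(sk), drop = FALSE])
  }
  if (config$use_bottleneck_dense) {
    gz <- as.vector(g) * cache$dense$mz
    grads$dense.W <- grads$dense.W + gz %*% t(cache$dense$v)
    grads$dense.b <- grads$dense.b + gz
    g <- array(gz + as.vector(t(params$dense.W) %*% gz), dim(g))
  }
  bb <- block_bwd(g, params, paste0("enc", L), cache$enc[[L]],
                  config$residual, grads)
  grads <- bb$grads
  g <- bb$gx
  for (l in rev(seq_len(L - 1))) {
    Hl <- config$input_size / 2^(l - 1)
    g <- maxpool_bwd(g, cache$pool[[l]], Hl)
    g <- g + skip_grad[[l]]
    bb <- block_bwd(g, params, paste0("enc", l), cache$enc[[l]],
                    config$residual, grads)
    grads <- bb$grads
    g <- bb$gx
  }
  grads
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Adam optimizer state and update
#' @param params Parameter list.
#' @return Opaque optimizer state.
#' @keywords internal
adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
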