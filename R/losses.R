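#' Squash a nonnegative likelihood map into \[0, 1)
#'
#' The detector network outputs raw per-pixel lesion likelihoods in
#' `[0, +Inf)`. The soft Dice loss is defined for maps in `[0, 1]`, so the
#' elementwise transfer `f -> f / (1 + f)` is applied before the Dice term
#' only; the Necmos and Nac terms operate on the raw outputs.
#'
#' @param f Numeric matrix (or array) of nonnegative likelihoods.
#' @return A map of the same shape with values in `[0, 1)`.
#' @seealso [dice_loss()], [combined_loss()]
#' @export
#' @examples
#' squash(matrix(c(0, 1, 3), 1))  # 0, 0.5, 0.75
squash <- function(f) {
  if (any(f < 0)) stop("squash() requires a nonnegative map")
  f / (1 + f)
}

check_same_shape <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("map shapes differ: ", paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"))
}

#' Soft Dice loss
#'
#' Continuous relaxation of the Dice overlap between a likelihood map
#' `f` in `[0, 1]` and a binary label `t`:
#' \deqn{l_{Dice}(f,t) = -\frac{2\sum_x f(x)t(x) + \epsilon}
#'   {\sum_x f(x) + \sum_x t(x) + \epsilon}}
#' The small constant `epsilon` avoids division by zero. The value lies in
#' `[-1, 0)`; for an all-zero label the loss reduces exactly to
#' `-epsilon / (sum(f) + epsilon)`, which is why plain Dice training learns
#' almost nothing from lesion-free images.
#'
#' @param f Likelihood map with values in `[0, 1]` (use [squash()] on raw
#'   network output first).
#' @param t Binary label map of the same shape, values in `{0, 1}`.
#' @param epsilon Positive stabilizer, default 1.
#' @return Scalar loss in `[-1, 0)`.
#' @export
dice_loss <- function(f, t, epsilon = 1) {
  check_same_shape(f, t)
  if (epsilon <= 0) stop("epsilon must be > 0")
  if (any(f < 0) || any(f > 1)) stop("dice_loss() requires f in [0, 1]")
  -(2 * sum(f * t) + epsilon) / (sum(f) + sum(t) + epsilon)
}

#' Negative-case maximum output suppression (Necmos) loss
#'
#' The maximum raw network output over a lesion-free image:
#' \deqn{l_{Necmos}(f_-) = \max_{x \in \Omega} f_-(x)}
#' Because a candidate region is any connected component of the
#' strictly-positive output, a negative image yields zero false positives
#' if and only if this maximum is zero. Penalizing it is therefore a direct
#' false-positive suppression term.
#'
#' @param f_neg Nonnegative likelihood map of the negative image.
#' @return Scalar `>= 0`; zero iff the map is identically zero.
#' @export
necmos_loss <- function(f_neg) {
  if (length(f_neg) == 0) stop("necmos_loss() on an empty map")
  if (any(f_neg < 0)) stop("necmos_loss() requires a nonnegative map")
  max(f_neg)
}

#' Normal-abnormal contrastive (Nac) loss
#'
#' Contrasts the paired positive and negative likelihood maps inside the
#' true lesion region `R = {x : t(x) = 1}`:
#' \deqn{l_{Nac}(f_+, f_-, t) = -\min\{1,\ \max_{x \in R} f_+(x)
#'   - \max_{x \in R} f_-(x)\}}
#' Driving this term down pushes the detector to score the lesion higher on
#' the diseased image than on the same location of its healthy twin; the
#' clip at 1 stops the difference from being rewarded without bound.
#'
#' @param f_pos,f_neg Nonnegative likelihood maps of the positive and
#'   negative image of a pair (same shape).
#' @param t Binary label map; must contain at least one 1 — the loss is
#'   undefined for an empty lesion region and the call is refused.
#' @return Scalar in `[-1, +Inf)`.
#' @export
nac_loss <- function(f_pos, f_neg, t) {
  check_same_shape(f_pos, f_neg)
  check_same_shape(f_pos, t)
  if (any(f_pos < 0) || any(f_neg < 0)) stop("nac_loss() requires nonnegative maps")
  r <- t > 0
  if (!any(r)) stop("nac_loss() is undefined for an empty lesion region")
  -min(1, max(f_pos[r]) - max(f_neg[r]))
}

#' Loss weights for the combined objective
#'
#' @param w_dice,w_necmos,w_nac Nonnegative term weights.
#' @param epsilon Positive Dice stabilizer (default 1).
#' @return A `loss_weights` list.
#' @export
loss_weights <- function(w_dice = 1, w_necmos = 1, w_nac = 1, epsilon = 1) {
  stopifnot(w_dice >= 0, w_necmos >= 0, w_nac >= 0, epsilon > 0)
  structure(list(w_dice = w_dice, w_necmos = w_necmos, w_nac = w_nac,
                 epsilon = epsilon), class = "loss_weights")
}

#' Combined three-term training loss
#'
#' Weighted combination of the log-Dice, Necmos, and Nac terms on one
#' positive/negative pair of raw (nonnegative, unsquashed) network outputs:
#' \deqn{l = w_{Dice} \cdot D + w_{Necmos} \cdot l_{Necmos}(f_-)
#'   + w_{Nac} \cdot l_{Nac}(f_+, f_-, t)}
#' where \eqn{D = -\log(-l_{Dice}(f_+/(1+f_+), t))} is the negative log of
#' the soft Dice coefficient. The soft Dice loss lies in `[-1, 0)`, so its
#' raw logarithm is undefined; the log-Dice form is finite, shares the same
#' minimizer, and steepens the gradient for poor overlaps. The squashing
#' transfer is applied to the Dice term only: Necmos and Nac are defined on
#' the raw `[0, +Inf)` range.
#'
#' When `weights$w_nac == 0` an empty lesion region is tolerated (the Nac
#' term is skipped); otherwise `t` must be nonempty.
#'
#' @param f_pos,f_neg Raw nonnegative likelihood maps of a pair.
#' @param t Binary label map for the positive image.
#' @param weights A [loss_weights()] object.
#' @return Scalar loss (finite for any valid input).
#' @export
combined_loss <- function(f_pos, f_neg, t, weights = loss_weights()) {
  s <- squash(f_pos)
  d <- -log(-dice_loss(s, t, weights$epsilon))
  l <- weights$w_dice * d + weights$w_necmos * necmos_loss(f_neg)
  if (weights$w_nac > 0)
    l <- l + weights$w_nac * nac_loss(f_pos, f_neg, t)
  l
}

#' Analytic gradient of the combined loss
#'
#' Gradients of [combined_loss()] with respect to the raw maps `f_pos` and
#' `f_neg`, used to seed backpropagation through the network. The max-type
#' terms (Necmos, Nac) route their gradient to the first-encountered argmax
#' pixel; the Nac gradient vanishes where its clip at 1 is active. These
#' conventions agree with finite differences away from max ties and the
#' clip kink.
#'
#' @inheritParams combined_loss
#' @return List with elements `d_pos` and `d_neg`, same shapes as the maps.
#' @export
combined_loss_grad <- function(f_pos, f_neg, t, weights = loss_weights()) {
  eps <- weights$epsilon
  d_pos <- array(0, dim = dim(f_pos))
  d_neg <- array(0, dim = dim(f_neg))

  if (weights$w_dice > 0) {
    s <- squash(f_pos)
    num <- 2 * sum(s * t) + eps         # l_dice = -num / den
    den <- sum(s) + sum(t) + eps
    # D = -log(num/den); dD/ds = 1/den - 2 t / num, chain via ds/df = 1/(1+f)^2
    dD_ds <- 1 / den - 2 * t / num
    d_pos <- d_pos + weights$w_dice * dD_ds / (1 + f_pos)^2
  }
  if (weights$w_necmos > 0 && max(f_neg) > 0) {
    # at f_neg == 0 the term sits at its minimum; 0 is a valid subgradient
    i <- which.max(f_neg)
    d_neg[i] <- d_neg[i] + weights$w_necmos
  }
  if (weights$w_nac > 0) {
    r <- t > 0
    if (!any(r)) stop("nac gradient is undefined for an empty lesion region")
    ri <- which(r)
    diff <- max(f_pos[ri]) - max(f_neg[ri])
    if (diff < 1) {  # clip inactive
      ip <- ri[which.max(f_pos[ri])]
      im <- ri[which.max(f_neg[ri])]
      d_pos[ip] <- d_pos[ip] - weights$w_nac
      d_neg[im] <- d_neg[im] + weights$w_nac
    }
  }
  list(d_pos = d_pos, d_neg = d_neg)
}
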