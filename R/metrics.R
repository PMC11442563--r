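#' Extract scored candidate regions from a likelihood map
#'
#' The detected pixel set is `{x : f(x) > 0}`; its connected components
#' under 8-connectivity are the candidate regions, and each candidate's
#' likelihood is the maximum map value inside it. Pixel sets are stored as
#' 1-based linear (column-major) indices into the map.
#'
#' @param f Nonnegative likelihood map (matrix).
#' @param case_id Identifier attached to every candidate.
#' @param connectivity 4 or 8 (default 8).
#' @return List of candidates, each `list(pixels, likelihood, case_id)`.
#' @export
extract_candidates <- function(f, case_id = "case", connectivity = 8L) {
  if (any(f < 0)) stop("likelihood map must be nonnegative")
  lab <- label_components(f > 0, as.integer(connectivity))
  n <- max(lab)
  if (n == 0) return(list())
  lapply(seq_len(n), function(j) {
    px <- which(lab == j)
    list(pixels = px, likelihood = max(f[px]), case_id = case_id)
  })
}

#' Intersection over union of two pixel sets
#'
#' @param a,b Pixel index vectors on the same grid.
#' @return `|a \U2229 b| / |a \U222A b|`; raises an error when both sets
#'   are empty (the ratio is undefined).
#' @export
iou <- function(a, b) {
  if (length(a) == 0 && length(b) == 0)
    stop("IoU of two empty sets is undefined")
  length(intersect(a, b)) / length(union(a, b))
}

#' Bundle one case's detections and ground truth
#'
#' @param case_id Case identifier.
#' @param candidates List from [extract_candidates()].
#' @param lesions List of ground-truth lesion pixel sets (possibly empty).
#' @return A `case_detections` object; `is_positive_case` is `TRUE` iff
#'   the case has at least one lesion.
#' @export
case_detections <- function(case_id, candidates, lesions = list()) {
  structure(list(case_id = case_id, candidates = candidates,
                 lesions = lesions,
                 is_positive_case = length(lesions) > 0),
            class = "case_detections")
}

#' Split a binary label image into lesion pixel sets
#' @param label Binary matrix.
#' @param connectivity 4 or 8.
#' @return List of pixel index vectors, one per connected lesion.
#' @export
label_lesions <- function(label, connectivity = 8L) {
  lab <- label_components(label > 0, as.integer(connectivity))
  n <- max(lab)
  lapply(seq_len(n), function(j) which(lab == j))
}

#' Match candidates to lesions at an IoU threshold
#'
#' A candidate is a true positive iff its IoU with at least one lesion is
#' `>= iou_min`; every other candidate is a false positive. Each lesion's
#' hit likelihood is the maximum likelihood over the true-positive
#' candidates that match it (`NA` when missed). Several candidates may
#' legitimately hit the same lesion without creating false positives.
#'
#' @param dets A [case_detections()] object.
#' @param iou_min IoU threshold (default 0.1).
#' @return List with `tp` (logical per candidate) and `lesion_hits`
#'   (numeric per lesion, `NA` = missed).
#' @export
match_candidates <- function(dets, iou_min = 0.1) {
  nc <- length(dets$candidates)
  nl <- length(dets$lesions)
  tp <- logical(nc)
  lesion_hits <- rep(NA_real_, nl)
  if (nc > 0 && nl > 0) {
    for (j in seq_len(nc)) {
      cand <- dets$candidates[[j]]
      for (l in seq_len(nl)) {
        if (iou(cand$pixels, dets$lesions[[l]]) >= iou_min) {
          tp[j] <- TRUE
          lesion_hits[l] <- max(lesion_hits[l], cand$likelihood, na.rm = TRUE)
        }
      }
    }
  }
  list(tp = tp, lesion_hits = lesion_hits)
}

#' Free-response ROC curve over a set of cases
#'
#' Sweeps the decision threshold over the sorted unique candidate
#' likelihoods (plus `Inf`); a candidate survives at threshold `theta` iff
#' its likelihood is `>= theta` (closed rule, no interpolation). At each
#' threshold, sensitivity is the fraction of all lesions hit by a
#' surviving true-positive candidate, and the false-positive rate is the
#' number of surviving false-positive candidates divided by the number of
#' evaluated cases — positives and negatives alike.
#'
#' @param cases List of [case_detections()] (>= 1 lesion in total).
#' @param iou_min IoU threshold for candidate/lesion matching.
#' @return A `froc_curve`: data.frame `(threshold, sensitivity,
#'   fp_per_case)`, thresholds decreasing.
#' @export
froc <- function(cases, iou_min = 0.1) {
  n_cases <- length(cases)
  stopifnot(n_cases >= 1)
  hit_lik <- numeric(0)
  fp_lik <- numeric(0)
  all_lik <- numeric(0)
  n_lesions <- 0
  for (cs in cases) {
    m <- match_candidates(cs, iou_min)
    n_lesions <- n_lesions + length(cs$lesions)
    hit_lik <- c(hit_lik, m$lesion_hits[!is.na(m$lesion_hits)])
    fp_lik <- c(fp_lik, vapply(cs$candidates[!m$tp], `[[`, 0, "likelihood"))
    all_lik <- c(all_lik, vapply(cs$candidates, `[[`, 0, "likelihood"))
  }
  if (n_lesions == 0) stop("FROC requires at least one ground-truth lesion")
  thresholds <- c(Inf, sort(unique(all_lik), decreasing = TRUE))
  sens <- vapply(thresholds, function(th) sum(hit_lik >= th) / n_lesions, 0)
  fpc <- vapply(thresholds, function(th) sum(fp_lik >= th) / n_cases, 0)
  structure(data.frame(threshold = thresholds, sensitivity = sens,
                       fp_per_case = fpc),
            class = c("froc_curve", "data.frame"),
            n_cases = n_cases, n_lesions = n_lesions)
}

#' Sensitivity at a false-positive rate
#'
#' Maximum sensitivity over the operating points whose false positives per
#' case do not exceed `rate`; 0 when no point qualifies. Step-function
#' convention — no interpolation between operating points.
#'
#' @param curve A [froc()] curve.
#' @param rate Nonnegative FPs/case bound.
#' @return Scalar sensitivity in `[0, 1]`.
#' @export
sensitivity_at_fp_rate <- function(curve, rate) {
  if (rate < 0) stop("rate must be nonnegative")
  ok <- curve$fp_per_case <= rate
  if (!any(ok)) return(0)
  max(curve$sensitivity[ok])
}

#' R-CPM: mean FROC sensitivity at 1/8, 1/4, 1/2, and 1 FPs per case
#'
#' @param curve A [froc()] curve.
#' @return Scalar in `[0, 1]`.
#' @export
r_cpm <- function(curve) {
  mean(vapply(c(1 / 8, 1 / 4, 1 / 2, 1),
              function(r) sensitivity_at_fp_rate(curve, r), 0))
}

#' Case-level ROC curve
#'
#' Scores each case by its maximum candidate likelihood (0 when the
#' likelihood map produced no candidates) and classifies cases as
#' lesion-present vs lesion-free. AUROC uses the rank (Mann-Whitney)
#' statistic with ties counted one half.
#'
#' @param cases List of [case_detections()]; needs at least one positive
#'   and one negative case.
#' @return A `roc_curve`: data.frame `(threshold, sensitivity,
#'   specificity)` with attribute `auroc`.
#' @export
case_roc <- function(cases) {
  score <- vapply(cases, function(cs) {
    if (length(cs$candidates) == 0) 0
    else max(vapply(cs$candidates, `[[`, 0, "likelihood"))
  }, 0)
  pos <- vapply(cases, `[[`, TRUE, "is_positive_case")
  if (!any(pos) || all(pos))
    stop("case-level ROC needs both positive and negative cases")
  rk <- rank(score)  # average ranks handle ties as half-concordances
  auroc <- (sum(rk[pos]) - sum(pos) * (sum(pos) + 1) / 2) /
    (sum(pos) * sum(!pos))
  thresholds <- c(Inf, sort(unique(score), decreasing = TRUE))
  sens <- vapply(thresholds, function(th) mean(score[pos] >= th), 0)
  spec <- vapply(thresholds, function(th) mean(score[!pos] < th), 0)
  structure(data.frame(threshold = thresholds, sensitivity = sens,
                       specificity = spec),
            class = c("roc_curve", "data.frame"), auroc = auroc)
}

#' Area under a case-level ROC curve
#' @param curve A [case_roc()] curve.
#' @return Scalar AUROC in `[0, 1]`.
#' @export
auroc <- function(curve) attr(curve, "auroc")

#' Sensitivity at a specificity bound
#'
#' Maximum sensitivity over thresholds achieving specificity `>= spec`;
#' 0 when none does.
#'
#' @param curve A [case_roc()] curve.
#' @param spec Specificity bound in `[0, 1]` (default 0.8).
#' @return Scalar sensitivity.
#' @export
sensitivity_at_specificity <- function(curve, spec = 0.8) {
  if (spec < 0 || spec > 1) stop("spec must lie in [0, 1]")
  ok <- curve$specificity >= spec
  if (!any(ok)) return(0)
  max(curve$sensitivity[ok])
}

#' @export
print.froc_curve <- function(x, ...) {
  cat("FROC curve:", attr(x, "n_lesions"), "lesions over",
      attr(x, "n_cases"), "cases;", nrow(x), "operating points\n")
  cat(sprintf("  R-CPM %.3f, sensitivity %.3f @ 0.2 FP/case\n",
              r_cpm(x), sensitivity_at_fp_rate(x, 0.2)))
  invisible(x)
}

#' @export
plot.froc_curve <- function(x, ...) {
  graphics::plot(x$fp_per_case, x$sensitivity, type = "s",
                 xlab = "False positives per case", ylab = "Sensitivity",
                 ylim = c(0, 1), ...)
  invisible(x)
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("Case-level ROC: AUROC %.3f, sensitivity %.3f @ specificity 0.8\n",
              auroc(x), sensitivity_at_specificity(x, 0.8)))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  graphics::plot(1 - x$specificity, x$sensitivity, type = "s",
                 xlab = "1 - specificity", ylab = "Sensitivity",
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}
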