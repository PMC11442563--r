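test_that("candidate extraction partitions the strictly-positive set", {
  expect_identical(extract_candidates(matrix(0, 8, 8)), list())
  f <- matrix(0, 8, 8); f[3, 3] <- 0.3
  cands <- extract_candidates(f)
  expect_length(cands, 1)
  expect_identical(cands[[1]]$pixels, which(f > 0))
  expect_identical(cands[[1]]$likelihood, 0.3)
  set.seed(13)
  for (rep in 1:20) {
    f <- matrix(pmax(0, stats::runif(100) - 0.6), 10, 10)
    cands <- extract_candidates(f)
    pix <- sort(unlist(lapply(cands, `[[`, "pixels")))
    expect_identical(pix, which(f > 0))           # exact cover
    expect_identical(anyDuplicated(pix), 0L)      # pairwise disjoint
    for (cd in cands) expect_identical(cd$likelihood, max(f[cd$pixels]))
  }
})

test_that("connected components agree with a flood-fill oracle under both connectivities", {
  # two blobs touching only diagonally
  f <- matrix(0, 6, 6)
  f[2:3, 2:3] <- 0.5
  f[4:5, 4:5] <- 0.7
  expect_length(extract_candidates(f, connectivity = 8), 1)
  expect_length(extract_candidates(f, connectivity = 4), 2)
  set.seed(14)
  for (rep in 1:20) {
    f <- matrix(pmax(0, stats::runif(144) - 0.55), 12, 12)
    for (conn in c(4L, 8L)) {
      got <- extract_candidates(f, connectivity = conn)
      want <- oracle_label(f > 0, conn)
      expect_identical(length(got), max(want))
      # identical partition up to label order
      got_sets <- lapply(got, function(cd) sort(cd$pixels))
      want_sets <- lapply(seq_len(max(want)), function(j) which(want == j))
      expect_setequal(sapply(got_sets, paste, collapse = ","),
                      sapply(want_sets, paste, collapse = ","))
    }
  }
})

test_that("iou follows set arithmetic and rejects the empty-empty case", {
  expect_identical(iou(1:5, 1:5), 1)
  expect_identical(iou(1:5, 6:10), 0)
  expect_identical(iou(1:8, 5:12), 4 / 12)
  expect_error(iou(integer(0), integer(0)), "undefined")
})

test_that("candidate matching enforces the IoU threshold at its exact boundary", {
  lesion <- 1:1000
  # intersection 100 of union 1000 -> IoU exactly 0.100
  cand_tp <- list(pixels = 901:1000, likelihood = 0.9, case_id = "c")
  # intersection 99, subset of the lesion so the union stays 1000: IoU 0.099
  cand_fp <- list(pixels = 902:1000, likelihood = 0.8, case_id = "c")
  expect_identical(iou(cand_tp$pixels, lesion), 0.100)
  expect_identical(iou(cand_fp$pixels, lesion), 0.099)
  m <- match_candidates(case_detections("c", list(cand_tp, cand_fp),
                                        list(lesion)), iou_min = 0.1)
  expect_identical(m$tp, c(TRUE, FALSE))
  expect_identical(m$lesion_hits, 0.9)
})

test_that("matching handles empty detections and multiple hits per lesion", {
  dets <- case_detections("c", list(), list(1:10))
  m <- match_candidates(dets)
  expect_identical(m$tp, logical(0))
  expect_true(is.na(m$lesion_hits))
  # two candidates hitting one lesion: both TP, no FPs, hit = max likelihood
  c1 <- list(pixels = 1:10, likelihood = 0.4, case_id = "c")
  c2 <- list(pixels = 3:9, likelihood = 0.6, case_id = "c")
  m2 <- match_candidates(case_detections("c", list(c1, c2), list(1:10)))
  expect_identical(m2$tp, c(TRUE, TRUE))
  expect_identical(m2$lesion_hits, 0.6)
})

test_that("froc operating points match an exhaustive per-threshold recount", {
  # perfect detector: one case, one lesion, one exact candidate
  cs <- case_detections("c", list(list(pixels = 1:10, likelihood = 0.9,
                                       case_id = "c")), list(1:10))
  curve <- froc(list(cs))
  expect_identical(max(curve$sensitivity), 1)
  expect_identical(curve$fp_per_case[curve$sensitivity == 1][1], 0)
  # all-FP detector never reaches positive sensitivity
  cs2 <- case_detections("c", list(list(pixels = 100:110, likelihood = 0.9,
                                        case_id = "c")), list(1:10))
  curve2 <- froc(list(cs2))
  expect_true(all(curve2$sensitivity == 0))
  # scripted random sets vs the enumeration oracle
  for (seed in 1:5) {
    cases <- random_cases(20, seed)
    if (sum(vapply(cases, function(x) length(x$lesions), 0)) == 0) next
    curve <- froc(cases)
    for (k in seq_len(nrow(curve))) {
      pt <- oracle_froc_point(cases, curve$threshold[k])
      expect_equal(curve$sensitivity[k], pt[["sensitivity"]])
      expect_equal(curve$fp_per_case[k], pt[["fp_per_case"]])
    }
  }
})

test_that("froc curves are monotone as the threshold drops", {
  for (seed in 1:100) {
    cases <- random_cases(8, seed + 1000)
    if (sum(vapply(cases, function(x) length(x$lesions), 0)) == 0) next
    curve <- froc(cases)  # thresholds decreasing
    expect_true(all(diff(curve$sensitivity) >= 0))
    expect_true(all(diff(curve$fp_per_case) >= 0))
  }
})

test_that("sensitivity at an FP rate uses the step-function convention", {
  curve <- structure(data.frame(threshold = c(Inf, 0.9, 0.5, 0.2),
                                sensitivity = c(0, 0.3, 0.6, 0.9),
                                fp_per_case = c(0, 0.1, 0.5, 2.0)),
                     class = c("froc_curve", "data.frame"))
  expect_identical(sensitivity_at_fp_rate(curve, 10), 0.9)   # unconstrained
  expect_identical(sensitivity_at_fp_rate(curve, 0.5), 0.6)
  expect_identical(sensitivity_at_fp_rate(curve, 0.49), 0.3) # no interpolation
  expect_identical(sensitivity_at_fp_rate(curve, 0), 0)      # only the Inf point
  expect_error(sensitivity_at_fp_rate(curve, -1), "nonnegative")
})

test_that("r_cpm averages the four canonical operating points", {
  curve <- structure(data.frame(threshold = c(Inf, 4, 3, 2, 1),
                                sensitivity = c(0, 0.2, 0.4, 0.6, 0.8),
                                fp_per_case = c(0, 1 / 8, 1 / 4, 1 / 2, 1)),
                     class = c("froc_curve", "data.frame"))
  expect_identical(r_cpm(curve), 0.5)
  # perfect detector
  cs <- case_detections("c", list(list(pixels = 1:10, likelihood = 0.9,
                                       case_id = "c")), list(1:10))
  expect_identical(r_cpm(froc(list(cs))), 1)
  # detector with no TP at all
  cs2 <- case_detections("c", list(), list(1:10))
  expect_identical(r_cpm(froc(list(cs2))), 0)
})

test_that("froc metrics are invariant to case order and duplicated operating points", {
  cases <- random_cases(15, 99)
  curve <- froc(cases)
  curve_rev <- froc(rev(cases))
  expect_equal(r_cpm(curve), r_cpm(curve_rev))
  expect_equal(sensitivity_at_fp_rate(curve, 0.2),
               sensitivity_at_fp_rate(curve_rev, 0.2))
  dup <- rbind(curve, curve)
  expect_equal(r_cpm(dup), r_cpm(curve))
})

test_that("case-level ROC reproduces the all-pairs concordance AUROC", {
  mk <- function(score, pos) {
    cands <- if (score > 0)
      list(list(pixels = 1:3, likelihood = score, case_id = "x"))
    else list()
    case_detections("x", cands, if (pos) list(1:3) else list())
  }
  # perfect separation
  cases <- c(lapply(c(0.9, 0.8), mk, pos = TRUE),
             lapply(c(0.2, 0.1), mk, pos = FALSE))
  expect_identical(auroc(case_roc(cases)), 1)
  expect_identical(sensitivity_at_specificity(case_roc(cases), 0.8), 1)
  # all scores identical: chance
  cases2 <- c(lapply(c(0.5, 0.5), mk, pos = TRUE),
              lapply(c(0.5, 0.5), mk, pos = FALSE))
  expect_identical(auroc(case_roc(cases2)), 0.5)
  # scripted scores vs O(n^2) oracle
  set.seed(123)
  for (rep in 1:10) {
    scores <- round(stats::runif(10), 1)  # ties likely
    pos <- c(rep(TRUE, 5), rep(FALSE, 5))
    cases3 <- mapply(mk, scores, pos, SIMPLIFY = FALSE)
    expect_equal(auroc(case_roc(cases3)), oracle_auroc(scores, pos))
  }
  expect_error(case_roc(lapply(c(0.4, 0.6), mk, pos = TRUE)), "both")
})

test_that("roc curves are monotone and candidate-free cases score zero", {
  mk <- function(score, pos) {
    cands <- if (score > 0)
      list(list(pixels = 1:3, likelihood = score, case_id = "x"))
    else list()
    case_detections("x", cands, if (pos) list(1:3) else list())
  }
  cases <- mapply(mk, c(0.7, 0, 0.3, 0.5, 0, 0.2),
                  c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE), SIMPLIFY = FALSE)
  curve <- case_roc(cases)
  expect_true(all(diff(curve$sensitivity) >= 0))   # thresholds decreasing
  expect_true(all(diff(curve$specificity) <= 0))
  expect_identical(sensitivity_at_specificity(curve, 0), max(curve$sensitivity))
  expect_error(sensitivity_at_specificity(curve, 1.5), "spec")
})
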