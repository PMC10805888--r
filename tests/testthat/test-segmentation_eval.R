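test_that("confusion counts tabulate pixels exactly", {
  gt <- block_mask(4, 4, 0, 0, 2, 2)
  pred <- block_mask(4, 4, 1, 1, 2, 2)
  cc <- confusion_counts(gt, pred)
  expect_equal(cc, list(tp = 1L, fp = 3L, tn = 9L, fn = 3L))
  same <- confusion_counts(gt, gt)
  expect_equal(same$fp + same$fn, 0L)
  zero <- confusion_counts(block_mask(3, 5), block_mask(3, 5))
  expect_equal(zero$tn, 15L)
  expect_error(confusion_counts(block_mask(3, 3), block_mask(4, 4)), "3x3")
})

test_that("area scores implement the standard formulas and conventions", {
  sc <- area_scores(list(tp = 1, fp = 3, tn = 9, fn = 3))
  expect_equal(sc$DSC, 0.25)
  expect_equal(sc$JC, 1 / 7)
  expect_equal(sc$PPV, 0.25)
  expect_equal(sc$Rec, 0.25)
  expect_equal(sc$Acc, 10 / 16)
  # F2 = 5pr/(4p+r) equals v when p = r = v
  expect_equal(sc$F2, 0.25)
  sc2 <- area_scores(list(tp = 6, fp = 2, tn = 5, fn = 3))
  p <- 6 / 8; r <- 6 / 9
  expect_equal(sc2$F2, 5 * p * r / (4 * p + r))
  expect_gte(sc2$F2, min(p, r)); expect_lte(sc2$F2, max(p, r))
  # empty/empty convention
  expect_equal(area_scores(list(tp = 0, fp = 0, tn = 9, fn = 0)),
               list(DSC = 1, JC = 1, PPV = 1, Rec = 1, Acc = 1, F2 = 1))
  # empty GT, non-empty prediction
  sc3 <- area_scores(list(tp = 0, fp = 4, tn = 5, fn = 0))
  expect_equal(sc3$DSC, 0); expect_equal(sc3$F2, 0); expect_equal(sc3$Acc, 5 / 9)
})

test_that("DSC and JC satisfy their algebraic identity on random masks", {
  set.seed(5)
  for (i in 1:25) {
    gt <- matrix(rbinom(100, 1, 0.4), 10, 10)
    pred <- matrix(rbinom(100, 1, 0.4), 10, 10)
    sc <- area_scores(confusion_counts(gt, pred))
    expect_equal(sc$DSC, 2 * sc$JC / (1 + sc$JC), tolerance = 1e-12)
  }
})

test_that("boundary extraction keeps only non-interior foreground pixels", {
  m <- block_mask(7, 7, 1, 1, 4, 4)
  b <- boundary_points(m)
  expect_equal(nrow(b), 12)              # 4x4 block: 16 pixels minus 4 interior
  expect_true(all(m[cbind(b[, "y"] + 1, b[, "x"] + 1)] == 1))
  # pixels on the image edge are boundary even without background neighbours
  full <- block_mask(3, 3, 0, 0, 3, 3)
  expect_equal(nrow(boundary_points(full)), 8)
  expect_equal(nrow(boundary_points(block_mask(3, 3))), 0)
})

test_that("average Hausdorff distance is symmetric and matches brute force", {
  A <- cbind(x = c(0, 2), y = c(0, 2))
  expect_equal(average_hausdorff(A, A), 0)
  expect_equal(average_hausdorff(cbind(0, 0), cbind(3, 4)), 5)
  expect_equal(average_hausdorff(A[0, , drop = FALSE], A, empty_penalty = 9), 9)
  expect_equal(average_hausdorff(A[0, , drop = FALSE], A[0, , drop = FALSE]), 0)
  set.seed(13)
  for (i in 1:20) {
    G <- cbind(x = runif(10, 0, 50), y = runif(10, 0, 50))
    E <- cbind(x = runif(10, 0, 50), y = runif(10, 0, 50))
    expect_equal(average_hausdorff(G, E), oracle_avg_hausdorff(G, E),
                 tolerance = 1e-9)
    expect_equal(average_hausdorff(G, E), average_hausdorff(E, G),
                 tolerance = 1e-12)
  }
})

test_that("Hausdorff normalisation divides by the set maximum", {
  nh <- normalise_hausdorff(c(2, 4, 8))
  expect_equal(nh$hd_norm, c(0.25, 0.5, 1))
  expect_equal(nh$one_minus_hd, c(0.75, 0.5, 0))
  expect_equal(normalise_hausdorff(5)$hd_norm, 1)
  expect_equal(normalise_hausdorff(c(0, 3))$one_minus_hd[1], 1)
  expect_equal(normalise_hausdorff(c(0, 0))$hd_norm, c(0, 0))  # max-guard
  expect_error(normalise_hausdorff(numeric(0)))
})

test_that("mask-pair scoring handles empty-mask conventions and translation invariance", {
  gt <- block_mask(20, 20, 4, 4, 6, 6)
  s <- score_mask_pair(gt, gt)
  expect_equal(s$DSC, 1); expect_equal(s$Hd_raw, 0)
  # both empty
  s0 <- score_mask_pair(block_mask(20, 20), block_mask(20, 20))
  expect_equal(s0$DSC, 1); expect_equal(s0$Hd_raw, 0); expect_equal(s0$Acc, 1)
  # prediction empty -> overlap scores 0, distance = image diagonal
  s1 <- score_mask_pair(gt, block_mask(20, 20))
  expect_equal(s1$DSC, 0)
  expect_equal(s1$Hd_raw, sqrt(800))
  # translating both masks together changes nothing
  gt2 <- block_mask(20, 20, 9, 8, 6, 6)
  pr <- block_mask(20, 20, 5, 4, 6, 6)
  pr2 <- block_mask(20, 20, 10, 8, 6, 6)
  expect_equal(score_mask_pair(gt, pr), score_mask_pair(gt2, pr2))
})

test_that("dilating a correct prediction lowers PPV and never lowers recall", {
  gt <- block_mask(20, 20, 5, 5, 6, 6)
  dil <- block_mask(20, 20, 4, 4, 8, 8)
  s_exact <- score_mask_pair(gt, gt)
  s_dil <- score_mask_pair(gt, dil)
  expect_lt(s_dil$PPV, s_exact$PPV)
  expect_gte(s_dil$Rec, s_exact$Rec)
})

test_that("per-split aggregation averages per frame", {
  gt <- list(f1 = block_mask(12, 12, 2, 2, 4, 4),
             f2 = block_mask(12, 12, 2, 2, 4, 4),
             f3 = block_mask(12, 12, 3, 3, 4, 4))
  pred <- list(f1 = gt$f1, f2 = block_mask(12, 12, 4, 2, 4, 4), f3 = gt$f3)
  scores <- evaluate_segmentation(gt, pred,
                                  splits = c(f1 = "data3", f2 = "data3",
                                             f3 = "data1"))
  expect_equal(nrow(scores), 3)
  expect_equal(max(scores$Hd_norm), 1)   # normalised by run maximum
  agg <- aggregate_split(scores)
  d3 <- agg[agg$split == "data3" & agg$metric == "DSC", ]
  expect_equal(d3$mean, mean(scores$DSC[1:2]))
  expect_equal(d3$n, 2)
  expect_equal(agg[agg$split == "data1" & agg$metric == "DSC", "sd"], 0)
  # spreadsheet-style recomputation of every split mean
  for (m in c("DSC", "PPV", "F2")) {
    for (sp in c("data1", "data3")) {
      expect_equal(agg[agg$split == sp & agg$metric == m, "mean"],
                   mean(scores[scores$split == sp, m]))
    }
  }
  expect_error(evaluate_segmentation(gt, pred[1:2]), "f3")
})

test_that("masks round-trip through 8-bit PNG", {
  m <- block_mask(9, 11, 2, 3, 4, 3)
  p <- tempfile(fileext = ".png")
  write_mask(m, p)
  expect_identical(read_mask(p), m)
})
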