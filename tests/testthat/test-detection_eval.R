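test_that("bounding-box IoU matches a unit-pixel rasterisation oracle", {
  expect_equal(bbox_iou(c(0, 0, 4, 4), c(0, 0, 4, 4)), 1)
  expect_equal(bbox_iou(c(0, 0, 2, 2), c(5, 5, 2, 2)), 0)
  expect_equal(bbox_iou(c(0, 0, 2, 2), c(1, 1, 2, 2)), 1 / 7)
  expect_equal(bbox_iou(c(0, 0, 0, 0), c(0, 0, 0, 0)), 0)  # zero-area convention
  set.seed(11)
  for (i in 1:50) {
    a <- c(sample(0:6, 2, TRUE), sample(1:6, 2, TRUE))
    b <- c(sample(0:6, 2, TRUE), sample(1:6, 2, TRUE))
    expect_equal(bbox_iou(a, b), oracle_iou_raster(a, b), tolerance = 1e-12)
    expect_equal(bbox_iou(a, b), bbox_iou(b, a))
  }
})

test_that("greedy matching is one-to-one and confidence-ordered", {
  gt <- data.frame(x = 0, y = 0, w = 10, h = 10)
  det <- data.frame(x = 0, y = 0, w = 10, h = 10, confidence = 0.9)
  m <- match_detections(det, gt, 0.5)
  expect_true(m$tp)
  expect_equal(m$n_missed, 0)

  two <- data.frame(x = c(0, 1), y = c(0, 0), w = 10, h = 10,
                    confidence = c(0.6, 0.9))
  m <- match_detections(two, gt, 0.5)
  expect_equal(m$tp, c(FALSE, TRUE))  # higher confidence wins the only GT

  # empty inputs are legal
  m0 <- match_detections(det[0, ], gt, 0.5)
  expect_equal(m0$n_missed, 1)
  expect_length(m0$tp, 0)
})

test_that("greedy matching equals the exhaustive lexicographic-assignment oracle", {
  set.seed(23)
  for (case in 1:40) {
    ng <- sample(1:2, 1); nd <- sample(1:3, 1)
    gts <- data.frame(x = sample(0:8, ng, TRUE), y = sample(0:8, ng, TRUE),
                      w = sample(3:8, ng, TRUE), h = sample(3:8, ng, TRUE))
    dets <- data.frame(x = sample(0:8, nd, TRUE), y = sample(0:8, nd, TRUE),
                       w = sample(3:8, nd, TRUE), h = sample(3:8, nd, TRUE),
                       confidence = round(runif(nd), 3))
    thr <- sample(c(0.1, 0.3, 0.5), 1)
    got <- match_detections(dets, gts, thr)
    want <- oracle_match(dets, gts, thr)
    expect_equal(got$tp, want$tp,
                 info = sprintf("case %d (ng=%d nd=%d thr=%.1f)", case, ng, nd, thr))
  }
})

test_that("interpolated AP follows the max-to-the-right envelope", {
  # single TP on a single GT
  crv <- pr_curve(TRUE, 0.9, n_gt = 1)
  expect_equal(interpolated_ap(crv), 1)
  # FP ranked above the TP halves the interpolated precision at r = 1
  crv <- pr_curve(c(FALSE, TRUE), c(0.9, 0.8), n_gt = 1)
  expect_equal(interpolated_ap(crv), 0.5)
  # FP ranked below the TP does not affect AP
  crv <- pr_curve(c(TRUE, FALSE), c(0.9, 0.8), n_gt = 1)
  expect_equal(interpolated_ap(crv), 1)
  expect_true(all(diff(crv$p_interp) <= 0))
  expect_error(pr_curve(TRUE, 0.9, n_gt = 0), "ground-truth")
})

test_that("interpolated AP matches the independent oracle on random cases", {
  set.seed(7)
  for (i in 1:300) {
    n <- sample(1:10, 1)
    tp <- runif(n) < 0.5
    conf <- round(runif(n), 2)  # duplicates induce ties
    n_gt <- max(1, sum(tp) + sample(0:3, 1))
    got <- interpolated_ap(pr_curve(tp, conf, n_gt))
    expect_equal(got, oracle_ap(tp, conf, n_gt), tolerance = 1e-9)
  }
})

test_that("evaluate_detection scores perfect predictions at 1 and strata independently", {
  gts <- data.frame(frame_id = rep(c("f1", "f2"), each = 2),
                    x = c(0, 200, 10, 300), y = c(0, 200, 10, 300),
                    w = c(50, 250, 50, 250), h = c(50, 250, 50, 250))
  gts$size_category <- categorize_polyp_size(gts$w, gts$h, c(540, 720))
  perfect <- cbind(gts[, c("frame_id", "x", "y", "w", "h")], confidence = 0.9)
  res <- evaluate_detection(perfect, gts)
  expect_true(all(res$ap == 1))
  expect_equal(res$ap_mean, 1)
  expect_equal(res$ap_small, 1)
  expect_equal(res$ap_large, 1)
  expect_true(is.na(res$ap_medium))  # absent stratum reported as absent
  expect_equal(res$ar, 1)

  # drop every small GT's detection: AP_small collapses, AP_large untouched
  only_large <- perfect[gts$size_category == "large", ]
  res2 <- evaluate_detection(only_large, gts)
  expect_equal(res2$ap_small, 0)
  expect_equal(res2$ap_large, 1)
  expect_error(evaluate_detection(perfect, gts[0, ]), "ground-truth")
})

test_that("pooled AP equals the oracle on a multi-frame fixture", {
  set.seed(41)
  gts <- data.frame(frame_id = rep(paste0("f", 1:5), times = c(1, 2, 1, 1, 1)),
                    x = sample(0:60, 6), y = sample(0:60, 6),
                    w = sample(20:40, 6), h = sample(20:40, 6))
  dets <- do.call(rbind, lapply(seq_len(nrow(gts)), function(i) {
    jit <- sample(-6:6, 2)
    data.frame(frame_id = gts$frame_id[i], x = gts$x[i] + jit[1],
               y = gts$y[i] + jit[2], w = gts$w[i], h = gts$h[i],
               confidence = round(runif(1), 3))
  }))
  dets <- rbind(dets, data.frame(frame_id = "f3", x = 500, y = 500, w = 30,
                                 h = 30, confidence = 0.55))
  for (thr in c(0.5, 0.75)) {
    flags <- unlist(lapply(paste0("f", 1:5), function(f) {
      oracle_match(dets[dets$frame_id == f, ], gts[gts$frame_id == f, ], thr)$tp
    }))
    conf <- unlist(lapply(paste0("f", 1:5), function(f)
      dets$confidence[dets$frame_id == f]))
    want <- oracle_ap(flags, conf, nrow(gts))
    got <- evaluate_detection(dets, gts, thresholds = thr)$ap_mean
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("AP is monotone under tail FPs and in the IoU threshold", {
  set.seed(99)
  gts <- data.frame(frame_id = "f1", x = c(0, 40), y = c(0, 40),
                    w = c(20, 20), h = c(20, 20))
  dets <- data.frame(frame_id = "f1", x = c(2, 41, 70), y = c(1, 39, 70),
                     w = c(20, 22, 10), h = c(19, 20, 10),
                     confidence = c(0.9, 0.8, 0.7))
  base <- evaluate_detection(dets, gts)
  with_fp <- rbind(dets, data.frame(frame_id = "f1", x = 100, y = 100,
                                    w = 5, h = 5, confidence = 0))
  expect_lte(evaluate_detection(with_fp, gts)$ap_mean, base$ap_mean)
  expect_true(all(diff(base$ap) <= 1e-12))  # non-increasing in threshold
  # bit-for-bit reproducibility
  expect_identical(evaluate_detection(dets, gts), evaluate_detection(dets, gts))
})

test_that("detection tables round-trip through CSV and COCO-dialect JSON", {
  frames <- tiny_frames(2, split = "data3", h = 100, w = 120)
  inst <- data.frame(frame_id = frames$frame_id, x = c(1, 5), y = c(2, 6),
                     w = c(10, 12), h = c(11, 13),
                     size_category = "small", stringsAsFactors = FALSE)
  dets <- data.frame(frame_id = frames$frame_id, x = c(1.5, 5.5), y = c(2, 6),
                     w = c(10, 12), h = c(11, 13), confidence = c(0.9, 0.35),
                     stringsAsFactors = FALSE)
  fc <- tempfile(fileext = ".csv")
  write_detections(dets, fc)
  expect_equal(read_detections(fc), dets)
  fg <- tempfile(fileext = ".json"); fd <- tempfile(fileext = ".json")
  write_coco_ground_truth(frames, inst, fg)
  write_coco_detections(dets, fd)
  expect_equal(read_coco_ground_truth(fg)$w, inst$w)
  back <- read_coco_detections(fd)
  expect_equal(back$confidence, dets$confidence)
  expect_equal(back$frame_id, dets$frame_id)
})
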