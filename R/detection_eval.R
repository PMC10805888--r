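#' Intersection-over-union of two bounding boxes
#'
#' Boxes are `c(x, y, w, h)` in pixels, half-open. Returns the ratio of
#' intersection area to union area; 0 for disjoint boxes, and by convention
#' 0 when both boxes have zero area.
#'
#' @param a,b numeric vectors `c(x, y, w, h)` with non-negative `w`, `h`.
#' @return a number in `[0, 1]`.
#' @export
bbox_iou <- function(a, b) {
  if (any(c(a[3], a[4], b[3], b[4]) < 0)) stop("box width/height must be >= 0")
  iw <- min(a[1] + a[3], b[1] + b[3]) - max(a[1], b[1])
  ih <- min(a[2] + a[4], b[2] + b[4]) - max(a[2], b[2])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  union <- a[3] * a[4] + b[3] * b[4] - inter
  if (union <= 0) return(0)
  inter / union
}

# IoU matrix between rows of two (x,y,w,h) matrices.
iou_matrix <- function(A, B) {
  out <- matrix(0, nrow(A), nrow(B))
  for (i in seq_len(nrow(A)))
    for (j in seq_len(nrow(B)))
      out[i, j] <- bbox_iou(A[i, ], B[j, ])
  out
}

#' Match detections to ground-truth boxes within one frame
#'
#' Greedy one-to-one matching: detections are processed in descending
#' confidence (ties broken by the larger best-available IoU, then input
#' order) and each is assigned to the unmatched ground-truth box of highest
#' IoU provided that IoU is at or above `iou_threshold`; otherwise the
#' detection is a false positive.
#'
#' @param dets `data.frame` with columns `x, y, w, h, confidence` (one frame).
#' @param gts `data.frame` with columns `x, y, w, h` (one frame).
#' @param iou_threshold acceptance threshold (inclusive).
#' @return list with `tp` (logical per detection, in input order),
#'   `matched_gt` (index into `gts` or `NA`), `iou` (IoU of the match or 0),
#'   and `n_missed` (ground-truth boxes left unmatched).
#' @export
match_detections <- function(dets, gts, iou_threshold = 0.5) {
  nd <- nrow(dets) %||% 0L
  ng <- nrow(gts) %||% 0L
  tp <- logical(nd); matched <- rep(NA_integer_, nd); miou <- numeric(nd)
  if (nd == 0L)
    return(list(tp = tp, matched_gt = matched, iou = miou, n_missed = ng))
  M <- if (ng) iou_matrix(as.matrix(dets[, c("x", "y", "w", "h")]),
                          as.matrix(gts[, c("x", "y", "w", "h")]))
       else matrix(0, nd, 0)
  best_iou <- if (ng) apply(M, 1, max) else numeric(nd)
  ord <- order(-dets$confidence, -best_iou, seq_len(nd))
  gt_free <- rep(TRUE, ng)
  for (i in ord) {
    if (!ng) break
    cand <- which(gt_free)
    if (!length(cand)) next
    j <- cand[which.max(M[i, cand])]
    if (M[i, j] >= iou_threshold) {
      tp[i] <- TRUE; matched[i] <- j; miou[i] <- M[i, j]; gt_free[j] <- FALSE
    }
  }
  list(tp = tp, matched_gt = matched, iou = miou, n_missed = sum(gt_free))
}

#' Precision-recall curve from confidence-ranked detection outcomes
#'
#' Builds the interpolated precision-recall curve used by the AP metric:
#' detections (already flagged TP/FP) are ranked by descending confidence,
#' cumulative precision and recall are evaluated at every rank, and the
#' curve is reduced to its unique recall values with the raw precision
#' reached there and the interpolated precision
#' `p_interp(r) = max over recalls >= r of p(r)`, which is non-increasing.
#'
#' @param tp logical TP flag per detection.
#' @param confidence numeric confidence per detection.
#' @param n_gt number of ground-truth boxes (positives) in the pool.
#' @return a `pr_curve` data.frame with columns `recall`, `precision`,
#'   `p_interp`, and attribute `n_gt`.
#' @export
pr_curve <- function(tp, confidence, n_gt) {
  if (n_gt <= 0) stop("pr_curve requires at least one ground-truth box")
  ord <- order(-confidence, seq_along(confidence))
  tp <- tp[ord]
  ctp <- cumsum(tp)
  rec <- ctp / n_gt
  prec <- ctp / seq_along(tp)
  # interpolated precision: running max from the right
  pint <- rev(cummax(rev(prec)))
  # keep the first rank attaining each recall value (the rank of the TP);
  # its running max is exactly max over all recalls >= r
  keep <- !duplicated(rec)
  out <- data.frame(recall = rec[keep], precision = prec[keep],
                    p_interp = pint[keep])
  out <- out[order(out$recall), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_gt") <- n_gt
  class(out) <- c("pr_curve", "data.frame")
  out
}

#' Interpolated average precision of a precision-recall curve
#'
#' The area under the interpolated precision envelope,
#' `AP = sum_n (r_{n+1} - r_n) * p_interp(r_{n+1})` with recall increments
#' measured from `r = 0`.
#'
#' @param curve a [pr_curve()] result.
#' @return a number in `[0, 1]`.
#' @export
interpolated_ap <- function(curve) {
  if (!nrow(curve)) return(0)
  r <- curve$recall; p <- curve$p_interp
  sum(diff(c(0, r)) * p)
}

# Match every frame at one IoU threshold; returns pooled per-detection
# flags plus total gt count. `dets`/`gts` are full tables with frame_id.
.match_all_frames <- function(dets, gts, thr) {
  frames <- unique(c(dets$frame_id, gts$frame_id))
  tp <- logical(nrow(dets)); matched_cat <- rep(NA_character_, nrow(dets))
  for (f in frames) {
    di <- which(dets$frame_id == f)
    gi <- which(gts$frame_id == f)
    if (!length(di)) next
    m <- match_detections(dets[di, , drop = FALSE], gts[gi, , drop = FALSE], thr)
    tp[di] <- m$tp
    if (length(gi) && "size_category" %in% names(gts))
      matched_cat[di] <- ifelse(is.na(m$matched_gt), NA_character_,
                                gts$size_category[gi][m$matched_gt])
  }
  list(tp = tp, matched_cat = matched_cat)
}

#' Evaluate bounding-box detection over a frame set
#'
#' Pools detections from all frames, matches them per frame at each IoU
#' threshold (default 0.50 to 0.95 in steps of 0.05), and reports the
#' interpolated AP per threshold, their mean, size-stratified AP
#' (small/medium/large, using the ground-truth box's size category), and
#' average recall (the mean over thresholds of the final recall). For a
#' size stratum the ground truth is restricted to that category and
#' detections inherit the stratum of their matched ground-truth box;
#' detections matched to other strata or left unmatched count against the
#' unstratified AP only.
#'
#' @param dets `data.frame` with columns `frame_id, x, y, w, h, confidence`.
#' @param gts `data.frame` with columns `frame_id, x, y, w, h` and
#'   optionally `size_category`.
#' @param thresholds IoU thresholds.
#' @return an `ap_result` list: `ap` (named per threshold), `ap_mean`,
#'   `ap_small`, `ap_medium`, `ap_large` (NA for absent strata), `ar`,
#'   `ar_small`, `ar_medium`, `ar_large`, `n_gt`.
#' @export
evaluate_detection <- function(dets, gts, thresholds = seq(0.5, 0.95, by = 0.05)) {
  if (!nrow(gts)) stop("evaluate_detection requires at least one ground-truth box")
  if (!"confidence" %in% names(dets)) stop("detections need a confidence column")
  strata <- if ("size_category" %in% names(gts)) .size_categories else character()
  ap <- numeric(length(thresholds)); names(ap) <- sprintf("%.2f", thresholds)
  rec_final <- numeric(length(thresholds))
  ap_strat <- matrix(NA_real_, length(thresholds), length(strata),
                     dimnames = list(NULL, strata))
  rec_strat <- ap_strat
  for (ti in seq_along(thresholds)) {
    m <- .match_all_frames(dets, gts, thresholds[ti])
    crv <- pr_curve(m$tp, dets$confidence, nrow(gts))
    ap[ti] <- interpolated_ap(crv)
    rec_final[ti] <- if (nrow(dets)) max(crv$recall) else 0
    for (s in strata) {
      n_s <- sum(gts$size_category == s)
      if (!n_s) next
      keep <- which(!is.na(m$matched_cat) & m$matched_cat == s)
      if (length(keep)) {
        crv_s <- pr_curve(m$tp[keep], dets$confidence[keep], n_s)
        ap_strat[ti, s] <- interpolated_ap(crv_s)
        rec_strat[ti, s] <- max(crv_s$recall)
      } else {
        ap_strat[ti, s] <- 0; rec_strat[ti, s] <- 0
      }
    }
  }
  strat_mean <- function(M, s)
    if (s %in% colnames(M) && !all(is.na(M[, s]))) mean(M[, s]) else NA_real_
  out <- list(ap = ap, ap_mean = mean(ap),
              ap_small = strat_mean(ap_strat, "small"),
              ap_medium = strat_mean(ap_strat, "medium"),
              ap_large = strat_mean(ap_strat, "large"),
              ar = mean(rec_final),
              ar_small = strat_mean(rec_strat, "small"),
              ar_medium = strat_mean(rec_strat, "medium"),
              ar_large = strat_mean(rec_strat, "large"),
              n_gt = nrow(gts), thresholds = thresholds)
  class(out) <- "ap_result"
  out
}

#' @export
print.ap_result <- function(x, ...) {
  cat(sprintf("AP@[0.50:0.95] = %.3f  (AP50 %.3f, AP75 %.3f)\n",
              x$ap_mean, x$ap["0.50"], x$ap["0.75"]))
  cat(sprintf("  size-stratified: small %s, medium %s, large %s\n",
              format(round(x$ap_small, 3)), format(round(x$ap_medium, 3)),
              format(round(x$ap_large, 3))))
  cat(sprintf("  AR = %.3f over %d ground-truth boxes\n", x$ar, x$n_gt))
  invisible(x)
}

#' Read / write detection tables
#'
#' CSV layout `frame_id,x,y,w,h,confidence`, plus a minimal COCO-dialect
#' JSON reader/writer: ground truth as
#' `{images, annotations, categories}`, detections as a flat array of
#' `{image_id, bbox, score, category_id}`.
#'
#' @param path file path.
#' @param dets detection `data.frame`.
#' @return the `data.frame` read, or invisibly `path` when writing.
#' @export
read_detections <- function(path) {
  if (!file.exists(path)) stop("detections file not found: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(frame_id = "character"))
}

#' @rdname read_detections
#' @export
write_detections <- function(dets, path) {
  utils::write.csv(dets[, c("frame_id", "x", "y", "w", "h", "confidence")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_detections
#' @param frames manifest rows for the frames referenced (gives image sizes).
#' @param instances ground-truth instance table.
#' @export
write_coco_ground_truth <- function(frames, instances, path) {
  img_id <- seq_len(nrow(frames))
  obj <- list(
    images = data.frame(id = img_id, file_name = frames$frame_id,
                        height = frames$height_px, width = frames$width_px),
    annotations = data.frame(
      id = seq_len(nrow(instances)),
      image_id = img_id[match(instances$frame_id, frames$frame_id)],
      bbox = I(lapply(seq_len(nrow(instances)), function(i)
        as.numeric(instances[i, c("x", "y", "w", "h")]))),
      area = instances$w * instances$h,
      iscrowd = 0L, category_id = 1L),
    categories = data.frame(id = 1L, name = "polyp"))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname read_detections
#' @export
read_coco_ground_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ann <- obj$annotations
  bb <- do.call(rbind, ann$bbox)
  data.frame(frame_id = obj$images$file_name[match(ann$image_id, obj$images$id)],
             x = bb[, 1], y = bb[, 2], w = bb[, 3], h = bb[, 4],
             stringsAsFactors = FALSE)
}

#' @rdname read_detections
#' @export
write_coco_detections <- function(dets, path) {
  obj <- lapply(seq_len(nrow(dets)), function(i) list(
    image_id = dets$frame_id[i],
    bbox = as.numeric(dets[i, c("x", "y", "w", "h")]),
    score = dets$confidence[i], category_id = 1L))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname read_detections
#' @export
read_coco_detections <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  bb <- do.call(rbind, obj$bbox)
  data.frame(frame_id = as.character(obj$image_id),
             x = bb[, 1], y = bb[, 2], w = bb[, 3], h = bb[, 4],
             confidence = obj$score, stringsAsFactors = FALSE)
}
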