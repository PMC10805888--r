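#' @title Binary-mask segmentation metrics
#' @description
#' Masks are integer or logical matrices (rows = y, columns = x) with
#' nonzero entries marking polyp pixels. Per-frame scores cover the
#' area-based metrics (Dice, Jaccard, precision, recall, accuracy, F2) and
#' the average Hausdorff distance between mask boundaries; the latter is
#' normalised per evaluation run by the maximum distance observed over the
#' whole test set.
#' @name segmentation-metrics
NULL

#' Pixel confusion counts between two binary masks
#'
#' @param gt,pred binary masks of identical shape.
#' @return list with integer `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(gt, pred) {
  if (!all(dim(gt) == dim(pred)))
    stop("mask shapes differ: ", paste(dim(gt), collapse = "x"), " vs ",
         paste(dim(pred), collapse = "x"))
  g <- gt != 0; p <- pred != 0
  tp <- sum(g & p); fp <- sum(!g & p); fn <- sum(g & !p)
  list(tp = tp, fp = fp, tn = length(g) - tp - fp - fn, fn = fn)
}

#' Area-based segmentation scores from confusion counts
#'
#' `DSC = 2tp/(2tp+fp+fn)`, `JC = tp/(tp+fp+fn)`, `PPV = tp/(tp+fp)`,
#' `Rec = tp/(tp+fn)`, `Acc = (tp+tn)/total`, `F2 = 5*p*r/(4p+r)`.
#' Degenerate denominators follow the empty-mask conventions: when both
#' masks are empty every score is 1; when exactly one is empty the overlap
#' scores are 0 (accuracy stays the pixel fraction classified correctly).
#'
#' @param c a [confusion_counts()] list.
#' @return named list `DSC, JC, PPV, Rec, Acc, F2`.
#' @export
area_scores <- function(c) {
  tp <- c$tp; fp <- c$fp; tn <- c$tn; fn <- c$fn
  total <- tp + fp + tn + fn
  if (tp + fp + fn == 0)             # both masks empty
    return(list(DSC = 1, JC = 1, PPV = 1, Rec = 1, Acc = 1, F2 = 1))
  div <- function(num, den) if (den > 0) num / den else 0
  p <- div(tp, tp + fp)
  r <- div(tp, tp + fn)
  list(DSC = div(2 * tp, 2 * tp + fp + fn),
       JC = div(tp, tp + fp + fn),
       PPV = p, Rec = r,
       Acc = (tp + tn) / total,
       F2 = div(5 * p * r, 4 * p + r))
}

#' Boundary pixels of a binary mask
#'
#' A foreground pixel is a boundary pixel unless all 8 of its neighbours
#' are also foreground (pixels on the image edge are always boundary).
#' Coordinates are 0-based `(x, y)`.
#'
#' @param mask binary mask matrix.
#' @return two-column matrix of `(x, y)` coordinates (0 rows if the mask
#'   is empty).
#' @export
boundary_points <- function(mask) {
  m <- (mask != 0) * 1L
  h <- nrow(m); w <- ncol(m)
  if (!sum(m)) return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("x", "y"))))
  pad <- matrix(0L, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- m
  interior <- matrix(TRUE, h, w)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    interior <- interior & (pad[(2 + dy):(h + 1 + dy),
                                (2 + dx):(w + 1 + dx)] == 1L)
  }
  idx <- which(m == 1L & !interior, arr.ind = TRUE)
  cbind(x = idx[, 2] - 1, y = idx[, 1] - 1)
}

#' Average Hausdorff distance between two point sets
#'
#' The symmetric mean of the two directed average nearest-neighbour
#' Euclidean distances,
#' `H_d(G, E) = ( mean_g min_e d(g,e) + mean_e min_g d(g,e) ) / 2`.
#' When exactly one set is empty the configured penalty (typically the
#' image diagonal) is returned; when both are empty the distance is 0.
#'
#' @param G,E two-column coordinate matrices.
#' @param empty_penalty distance reported when exactly one set is empty.
#' @return non-negative number.
#' @export
average_hausdorff <- function(G, E, empty_penalty = 0) {
  nG <- nrow(G) %||% 0L; nE <- nrow(E) %||% 0L
  if (nG == 0L && nE == 0L) return(0)
  if (nG == 0L || nE == 0L) return(empty_penalty)
  d_ge <- .directed_avg_nn(G, E)
  d_eg <- .directed_avg_nn(E, G)
  (d_ge + d_eg) / 2
}

# mean over rows of A of the distance to the nearest row of B, chunked so
# the pairwise block never exceeds ~4e6 doubles.
.directed_avg_nn <- function(A, B) {
  nA <- nrow(A); nB <- nrow(B)
  chunk <- max(1L, floor(4e6 / nB))
  tot <- 0
  bx <- B[, 1]; by <- B[, 2]
  for (s in seq(1L, nA, by = chunk)) {
    e <- min(nA, s + chunk - 1L)
    dx <- outer(A[s:e, 1], bx, "-")
    dy <- outer(A[s:e, 2], by, "-")
    d2 <- dx * dx + dy * dy
    tot <- tot + sum(sqrt(apply(d2, 1, min)))
  }
  tot / nA
}

#' Normalise per-frame Hausdorff distances over a test set
#'
#' Divides every per-frame distance by the maximum distance observed in the
#' set (all splits pooled), so values lie in `[0, 1]`; also returns
#' `1 - Hd_norm`, for which higher means closer boundaries. An all-zero
#' input maps to all zeros.
#'
#' @param hd numeric vector of raw per-frame distances.
#' @return list with `hd_norm` and `one_minus_hd`.
#' @export
normalise_hausdorff <- function(hd) {
  if (!length(hd)) stop("no Hausdorff distances to normalise")
  mx <- max(hd)
  norm <- if (mx > 0) hd / mx else rep(0, length(hd))
  list(hd_norm = norm, one_minus_hd = 1 - norm)
}

#' Score one ground-truth / prediction mask pair
#'
#' Computes the area metrics from the pixel confusion table and the raw
#' average Hausdorff distance between mask boundaries (or, with
#' `hausdorff_on = "foreground"`, between all foreground pixels). For the
#' empty-mask cases the conventions are: both empty gives all area scores 1
#' and distance 0; exactly one empty gives DSC = JC = PPV = Rec = F2 = 0 and
#' distance equal to the image diagonal.
#'
#' @param gt,pred binary masks of identical shape.
#' @param hausdorff_on `"boundary"` (default) or `"foreground"`.
#' @return one-row `data.frame` with `DSC, JC, PPV, Rec, Acc, F2, Hd_raw`.
#' @export
score_mask_pair <- function(gt, pred, hausdorff_on = c("boundary", "foreground")) {
  hausdorff_on <- match.arg(hausdorff_on)
  cc <- confusion_counts(gt, pred)
  sc <- area_scores(cc)
  pts <- function(m) if (hausdorff_on == "boundary") boundary_points(m) else {
    idx <- which(m != 0, arr.ind = TRUE)
    cbind(x = idx[, 2] - 1, y = idx[, 1] - 1)
  }
  diag_px <- sqrt(nrow(gt)^2 + ncol(gt)^2)
  hd <- average_hausdorff(pts(gt), pts(pred), empty_penalty = diag_px)
  data.frame(DSC = sc$DSC, JC = sc$JC, PPV = sc$PPV, Rec = sc$Rec,
             Acc = sc$Acc, F2 = sc$F2, Hd_raw = hd)
}

#' Evaluate segmentation over a set of frames
#'
#' Scores every ground-truth/prediction mask pair, then normalises the
#' Hausdorff distances by the maximum over the whole run (all splits
#' pooled).
#'
#' @param gt_masks,pred_masks named lists of masks, keyed by `frame_id`.
#' @param splits named character vector mapping `frame_id` to split.
#' @inheritParams score_mask_pair
#' @return `data.frame` with one row per frame:
#'   `frame_id, split, DSC, JC, PPV, Rec, Acc, F2, Hd_raw, Hd_norm,
#'   one_minus_Hd`.
#' @export
evaluate_segmentation <- function(gt_masks, pred_masks, splits = NULL,
                                  hausdorff_on = "boundary") {
  ids <- names(gt_masks)
  missing_pred <- setdiff(ids, names(pred_masks))
  if (length(missing_pred))
    stop("missing prediction masks for: ", paste(missing_pred, collapse = ", "))
  rows <- lapply(ids, function(f)
    score_mask_pair(gt_masks[[f]], pred_masks[[f]], hausdorff_on))
  out <- do.call(rbind, rows)
  out <- cbind(frame_id = ids,
               split = if (is.null(splits)) NA_character_ else
                 unname(splits[ids]),
               out, stringsAsFactors = FALSE)
  nh <- normalise_hausdorff(out$Hd_raw)
  out$Hd_norm <- nh$hd_norm
  out$one_minus_Hd <- nh$one_minus_hd
  rownames(out) <- NULL
  out
}

#' Aggregate per-frame segmentation scores by split
#'
#' Unweighted per-frame mean and standard deviation of each metric within
#' each split.
#'
#' @param scores a per-frame score `data.frame` (see
#'   [evaluate_segmentation()]).
#' @param metrics metric columns to aggregate.
#' @return `data.frame` with columns `split, metric, mean, sd, n`.
#' @export
aggregate_split <- function(scores,
                            metrics = c("DSC", "JC", "PPV", "Rec", "Acc",
                                        "F2", "Hd_raw", "Hd_norm",
                                        "one_minus_Hd")) {
  metrics <- intersect(metrics, names(scores))
  splits <- unique(scores$split)
  rows <- list()
  for (sp in splits) {
    sub <- scores[scores$split == sp, , drop = FALSE]
    for (m in metrics) {
      rows[[length(rows) + 1L]] <- data.frame(
        split = sp, metric = m, mean = mean(sub[[m]]),
        sd = if (nrow(sub) > 1) stats::sd(sub[[m]]) else 0,
        n = nrow(sub), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read / write binary masks as 8-bit PNG
#'
#' Masks are written as single-channel 8-bit PNG with foreground 255; on
#' reading, any nonzero pixel (first channel for multi-channel files)
#' counts as polyp.
#'
#' @param path PNG file path.
#' @param mask binary mask matrix.
#' @return integer 0/1 matrix, or invisibly `path` when writing.
#' @export
read_mask <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  (img > 0) * 1L
}

#' @rdname read_mask
#' @export
write_mask <- function(mask, path) {
  png::writePNG((mask != 0) * 1.0, path)
  invisible(path)
}

#' Per-frame score table I/O
#'
#' @param scores per-frame score `data.frame`.
#' @param path CSV path.
#' @return read `data.frame`, or invisibly `path`.
#' @export
write_seg_scores <- function(scores, path) {
  utils::write.csv(scores, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_seg_scores
#' @export
read_seg_scores <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(frame_id = "character"))
}
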