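# Independent oracles used to cross-check the implementation. Each is
# deliberately written as brute force / enumeration, sharing no code with
# the package's own algorithms.

# IoU of integer-coordinate boxes by counting unit pixels.
oracle_iou_raster <- function(a, b) {
  cells <- function(bx) {
    if (bx[3] <= 0 || bx[4] <= 0) return(character(0))
    g <- expand.grid(x = seq(bx[1], bx[1] + bx[3] - 1),
                     y = seq(bx[2], bx[2] + bx[4] - 1))
    paste(g$x, g$y)
  }
  ca <- cells(a); cb <- cells(b)
  u <- length(union(ca, cb))
  if (u == 0) return(0)
  length(intersect(ca, cb)) / u
}

# Interpolated AP by direct evaluation of the definition: at every distinct
# recall value, p_interp is the max precision over all confidence cutoffs
# reaching at least that recall.
oracle_ap <- function(tp, confidence, n_gt) {
  ord <- order(-confidence, seq_along(confidence))
  tp <- tp[ord]
  n <- length(tp)
  prec <- numeric(n); rec <- numeric(n)
  for (k in seq_len(n)) {
    prec[k] <- sum(tp[1:k]) / k
    rec[k] <- sum(tp[1:k]) / n_gt
  }
  rs <- sort(unique(rec))
  rs <- rs[rs > 0]
  if (!length(rs)) return(0)
  ap <- 0; prev <- 0
  for (r in rs) {
    pint <- max(prec[rec >= r])
    ap <- ap + (r - prev) * pint
    prev <- r
  }
  ap
}

# Greedy matching as lexicographic maximisation: enumerate every injective
# assignment of detections (in descending-confidence order) to ground
# truths at IoU >= thr, and keep the assignment whose IoU vector is
# lexicographically largest.
oracle_match <- function(dets, gts, thr) {
  nd <- nrow(dets); ng <- nrow(gts)
  M <- matrix(0, nd, ng)
  for (i in seq_len(nd)) for (j in seq_len(ng))
    M[i, j] <- oracle_iou_raster(as.numeric(dets[i, c("x", "y", "w", "h")]),
                                 as.numeric(gts[j, c("x", "y", "w", "h")]))
  best_iou <- if (ng) apply(M, 1, max) else numeric(nd)
  ord <- order(-dets$confidence, -best_iou, seq_len(nd))
  choices <- lapply(seq_len(nd), function(i) c(NA, seq_len(ng)))
  grid <- do.call(expand.grid, choices)
  best_vec <- NULL; best_assign <- NULL
  for (g in seq_len(nrow(grid))) {
    asg <- as.integer(grid[g, ])
    used <- asg[!is.na(asg)]
    if (anyDuplicated(used)) next
    ok <- TRUE
    iou_vec <- numeric(nd)
    for (pos in seq_len(nd)) {
      i <- ord[pos]
      j <- asg[i]
      if (!is.na(j)) {
        if (M[i, j] < thr) { ok <- FALSE; break }
        iou_vec[pos] <- M[i, j]
      }
    }
    if (!ok) next
    if (is.null(best_vec) || .lex_gt(iou_vec, best_vec)) {
      best_vec <- iou_vec; best_assign <- asg
    }
  }
  list(tp = !is.na(best_assign), matched_gt = best_assign)
}

.lex_gt <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] > b[i] + 1e-12) return(TRUE)
    if (a[i] < b[i] - 1e-12) return(FALSE)
  }
  FALSE
}

# Average Hausdorff by a plain double loop.
oracle_avg_hausdorff <- function(G, E) {
  dmin <- function(P, Q) {
    out <- numeric(nrow(P))
    for (i in seq_len(nrow(P))) {
      best <- Inf
      for (j in seq_len(nrow(Q))) {
        d <- sqrt((P[i, 1] - Q[j, 1])^2 + (P[i, 2] - Q[j, 2])^2)
        if (d < best) best <- d
      }
      out[i] <- best
    }
    out
  }
  (mean(dmin(G, E)) + mean(dmin(E, G))) / 2
}

# Friedman chi-square straight from the rank-sum formula.
oracle_friedman_stat <- function(scores) {
  n <- nrow(scores); k <- ncol(scores)
  R <- t(apply(scores, 1, rank))
  rbar <- colMeans(R)
  12 * n / (k * (k + 1)) * sum((rbar - (k + 1) / 2)^2)
}
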