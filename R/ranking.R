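#' @title Leaderboard ranking
#' @description
#' Each leaderboard criterion (average score, deviation score, inference
#' time) is ranked individually, rank 1 being best under the criterion's
#' direction and exact ties receiving the average of the tied positions.
#' Inference times may first be collapsed into bands (by default < 50 ms,
#' 50--100 ms, > 100 ms). Per-criterion ranks are then averaged per team,
#' optionally rounded (half away from zero), and converted to dense final
#' ranks; residual ties can be broken by a designated criterion.
#' @name ranking
NULL

#' Rank teams on one criterion
#'
#' @param values named numeric vector (one value per team).
#' @param direction `"higher_better"` or `"lower_better"`.
#' @return named numeric vector of ranks (1 = best; ties averaged).
#' @export
rank_criterion <- function(values, direction = c("higher_better", "lower_better")) {
  direction <- match.arg(direction)
  if (length(values) < 2) stop("ranking requires at least two teams")
  if (any(!is.finite(values)))
    stop("non-finite criterion value for team(s): ",
         paste(names(values)[!is.finite(values)], collapse = ", "))
  v <- if (direction == "higher_better") -values else values
  r <- rank(v, ties.method = "average")
  names(r) <- names(values)
  r
}

#' Band a lower-is-better criterion into ordered categories
#'
#' Replaces each value by its band index: band 1 for values at or below the
#' first edge, band 2 up to the second edge, and so on (a value exactly on
#' an edge falls in the lower band). The default edges `c(50, 100)` give
#' the three inference-time bands < 50 ms, 50--100 ms and > 100 ms.
#'
#' @param values named numeric vector (lower is better).
#' @param edges strictly increasing band edges.
#' @return named integer vector of band indices.
#' @export
band_values <- function(values, edges = c(50, 100)) {
  if (is.unsorted(edges, strictly = TRUE)) stop("band edges must be strictly increasing")
  b <- vapply(values, function(v) sum(v > edges) + 1L, integer(1))
  names(b) <- names(values)
  b
}

# round half away from zero ("round them" on mean ranks)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Aggregate per-criterion ranks into a final leaderboard
#'
#' Averages the per-criterion ranks of each team (all criteria equally
#' weighted), optionally rounds the mean (half away from zero), and sorts
#' ascending to obtain dense final ranks: teams with the same (rounded)
#' mean share a rank and the next distinct mean takes the next integer.
#' Residual ties can be broken by a tie-break criterion (higher value
#' wins), in which case the tied teams receive consecutive ranks; without
#' one the tie is reported unresolved.
#'
#' @param ranks a matrix or data.frame, teams in rows (rownames), one
#'   column per criterion, entries being the per-criterion ranks.
#' @param round_means round the mean rank before the final sort?
#' @param tiebreak optional named numeric vector (higher is better) used to
#'   break residual ties.
#' @return a `rank_table` data.frame: `team, mean_rank, rounded_mean,
#'   final_rank, tie_unresolved`, ordered by final rank.
#' @export
aggregate_ranks <- function(ranks, round_means = TRUE, tiebreak = NULL) {
  ranks <- as.matrix(ranks)
  if (is.null(rownames(ranks))) stop("rank matrix needs team rownames")
  mean_rank <- rowMeans(ranks)
  key <- if (round_means) round_half_away(mean_rank) else mean_rank
  teams <- rownames(ranks)
  tb <- if (is.null(tiebreak)) rep(0, length(teams)) else {
    if (!all(teams %in% names(tiebreak)))
      stop("tiebreak values missing for some teams")
    tiebreak[teams]
  }
  ord <- order(key, -tb, teams)
  key_o <- key[ord]; tb_o <- tb[ord]
  final <- integer(length(ord))
  unresolved <- logical(length(ord))
  nxt <- 1L
  i <- 1L
  while (i <= length(ord)) {
    grp <- which(key_o == key_o[i])
    grp <- grp[grp >= i]
    if (length(grp) == 1L || is.null(tiebreak)) {
      final[grp] <- nxt
      if (length(grp) > 1L) unresolved[grp] <- TRUE
      nxt <- nxt + 1L
    } else {
      # tie-break orders the group; equal tiebreak values still share a rank
      j <- grp[1]
      while (j <= grp[length(grp)]) {
        same <- which(tb_o == tb_o[j] & key_o == key_o[j])
        same <- same[same >= j]
        final[same] <- nxt
        if (length(same) > 1L) unresolved[same] <- TRUE
        nxt <- nxt + 1L
        j <- same[length(same)] + 1L
      }
    }
    i <- grp[length(grp)] + 1L
  }
  out <- data.frame(team = teams[ord],
                    mean_rank = unname(mean_rank[ord]),
                    rounded_mean = if (round_means) unname(key_o) else NA_real_,
                    final_rank = final,
                    tie_unresolved = unresolved,
                    stringsAsFactors = FALSE)
  class(out) <- c("rank_table", "data.frame")
  out
}

#' Apply elimination rules to a leaderboard
#'
#' Removes teams whose reported inference time exceeds the limit (default
#' two seconds) or whose task score falls more than the relative tolerance
#' (default 10%) below the baseline's worst-split score, or below an
#' absolute score floor (e.g. average AP below 0.10 or DSC below 0.50).
#'
#' @param scores named numeric vector: the task score per team (higher
#'   better).
#' @param time_ms named numeric vector: reported inference time per team.
#' @param baseline_worst baseline model's score on its worst split
#'   (`NULL` to skip the relative rule).
#' @param time_limit_ms elimination threshold on time (default 2000).
#' @param rel_tolerance relative shortfall versus baseline (default 0.10).
#' @param score_floor absolute score floor (`NULL` to skip).
#' @return data.frame `team, eliminated, reason`.
#' @export
eliminate <- function(scores, time_ms, baseline_worst = NULL,
                      time_limit_ms = 2000, rel_tolerance = 0.10,
                      score_floor = NULL) {
  teams <- names(scores)
  reason <- character(length(teams))
  for (i in seq_along(teams)) {
    r <- character()
    if (time_ms[[teams[i]]] > time_limit_ms) r <- c(r, "time")
    if (!is.null(baseline_worst) &&
        scores[i] < baseline_worst * (1 - rel_tolerance))
      r <- c(r, "below baseline")
    if (!is.null(score_floor) && scores[i] < score_floor)
      r <- c(r, "score floor")
    reason[i] <- paste(r, collapse = "+")
  }
  data.frame(team = teams, eliminated = nzchar(reason), reason = reason,
             stringsAsFactors = FALSE)
}

#' Friedman test with Nemenyi post-hoc on per-frame scores
#'
#' Ranks the methods within every frame, applies the Friedman chi-square
#' test (via [stats::friedman.test()]), and computes all pairwise Nemenyi
#' p-values from the studentized range distribution:
#' `q_ij = |Rbar_i - Rbar_j| / sqrt(k(k+1)/(6N))`, `p_ij =
#' P(Q_{k,Inf} >= q_ij * sqrt(2))`.
#'
#' @param scores numeric matrix, frames in rows, methods in columns; no
#'   missing cells.
#' @return list with `statistic`, `df`, `p_value`, `mean_ranks`, and
#'   `pairwise` (symmetric matrix of Nemenyi p-values).
#' @export
friedman_nemenyi <- function(scores) {
  scores <- as.matrix(scores)
  if (ncol(scores) < 3) stop("need at least three methods")
  if (nrow(scores) < 2) stop("need at least two frames")
  if (any(!is.finite(scores))) stop("missing or non-finite cells are not allowed")
  ft <- stats::friedman.test(scores)
  # every frame ranking all methods equal leaves the tie-corrected
  # statistic 0/0; report no evidence of a difference
  if (!is.finite(ft$statistic)) {
    ft$statistic[] <- 0
    ft$p.value <- 1
  }
  k <- ncol(scores); n <- nrow(scores)
  R <- t(apply(scores, 1, rank))
  rbar <- colMeans(R)
  se <- sqrt(k * (k + 1) / (6 * n))
  q <- abs(outer(rbar, rbar, "-")) / se
  pw <- stats::ptukey(q * sqrt(2), nmeans = k, df = Inf, lower.tail = FALSE)
  diag(pw) <- 1
  dimnames(pw) <- list(colnames(scores), colnames(scores))
  list(statistic = unname(ft$statistic), df = unname(ft$parameter),
       p_value = ft$p.value, mean_ranks = rbar, pairwise = pw)
}
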