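#' @title Generalisability deviation score (dev_g)
#' @description
#' The deviation score summarises the performance gap between a seen
#' reference test split (split `data3`, sequences from centres present in
#' training) and each unseen split (`data1`: unseen modality; `data2`,
#' `data4`: unseen centre). Per metric category `k` the absolute difference
#' `|seen_k - unseen_k|` is taken; in the default *gated* mode a category
#' contributes only when the unseen score falls outside the relative
#' tolerance band `[seen_k*(1-tl), seen_k*(1+tl)]`, so deviations within
#' expected fluctuation count as zero. The *literal* mode is the plain mean
#' absolute deviation. For detection the categories are the AP variants
#' `mean, small, medium, large` with tolerance 0.10; for segmentation the
#' metric set `DSC, F2, PPV, Rec, Hd` (Hausdorff entering as its normalised
#' [0,1] form) with tolerance 0.05.
#' @name devg
NULL

#' Deviation configuration for a task
#'
#' @param task `"detection"` or `"segmentation"`.
#' @param tolerance relative tolerance `tl` in `[0, 1)`; defaults to 0.10
#'   for detection and 0.05 for segmentation.
#' @param mode `"gated"` (default) or `"literal"`.
#' @param categories metric categories; defaults per task.
#' @return a `deviation_config` list.
#' @export
deviation_config <- function(task = c("detection", "segmentation"),
                             tolerance = NULL, mode = c("gated", "literal"),
                             categories = NULL) {
  task <- match.arg(task)
  mode <- match.arg(mode)
  tolerance <- tolerance %||% if (task == "detection") 0.10 else 0.05
  if (tolerance < 0 || tolerance >= 1) stop("tolerance must be in [0, 1)")
  categories <- categories %||% if (task == "detection")
    c("mean", "small", "medium", "large") else
    c("DSC", "F2", "PPV", "Rec", "Hd")
  structure(list(task = task, tolerance = tolerance, mode = mode,
                 categories = categories), class = "deviation_config")
}

#' Deviation between a seen and an unseen split
#'
#' @param seen,unseen named numeric vectors of scores in `[0, 1]` covering
#'   the configured categories.
#' @param cfg a [deviation_config()].
#' @return non-negative deviation (mean over categories).
#' @export
pairwise_deviation <- function(seen, unseen, cfg = deviation_config()) {
  for (k in cfg$categories) {
    if (!k %in% names(seen)) stop("seen scores missing category '", k, "'")
    if (!k %in% names(unseen)) stop("unseen scores missing category '", k, "'")
  }
  s <- seen[cfg$categories]; u <- unseen[cfg$categories]
  dev <- abs(s - u)
  if (cfg$mode == "gated") {
    lo <- s * (1 - cfg$tolerance); hi <- s * (1 + cfg$tolerance)
    dev[u >= lo & u <= hi] <- 0
  }
  mean(dev)
}

#' Overall dev_g from per-pair deviations
#'
#' The unweighted mean of the per-pair deviations (one per unseen split).
#'
#' @param pair_devs numeric vector of per-pair deviations.
#' @return their mean.
#' @export
overall_devg <- function(pair_devs) {
  if (!length(pair_devs)) stop("no pairwise deviations supplied")
  mean(pair_devs)
}

#' Deviation table across unseen splits
#'
#' Computes the per-pair deviation of every unseen split against the
#' reference split and the overall dev_g.
#'
#' @param scores_by_split named list of per-split score vectors (names are
#'   split labels).
#' @param reference seen reference split label (default `"data3"`).
#' @param cfg a [deviation_config()].
#' @return a `devg_result` list with `pairs` (data.frame `pair, deviation`),
#'   `overall`, `reference`, `config`.
#' @export
deviation_table <- function(scores_by_split, reference = "data3",
                            cfg = deviation_config()) {
  if (!reference %in% names(scores_by_split))
    stop("reference split '", reference, "' absent from scores")
  unseen <- setdiff(names(scores_by_split), reference)
  if (!length(unseen)) stop("no unseen splits to compare")
  dev <- vapply(unseen, function(sp)
    pairwise_deviation(scores_by_split[[reference]], scores_by_split[[sp]],
                       cfg), numeric(1))
  ref_n <- sub("^data", "", reference)
  pairs <- data.frame(
    pair = paste0("dev_g_", sub("^data", "", unseen), "-", ref_n),
    split = unseen, deviation = unname(dev), stringsAsFactors = FALSE)
  structure(list(pairs = pairs, overall = overall_devg(dev),
                 reference = reference, config = cfg),
            class = "devg_result")
}

#' @export
print.devg_result <- function(x, ...) {
  cat(sprintf("dev_g (%s, %s mode, tl = %.2f), reference %s\n",
              x$config$task, x$config$mode, x$config$tolerance, x$reference))
  for (i in seq_len(nrow(x$pairs)))
    cat(sprintf("  %s = %.3f\n", x$pairs$pair[i], x$pairs$deviation[i]))
  cat(sprintf("  overall dev_g = %.3f\n", x$overall))
  invisible(x)
}

#' Write a deviation report
#'
#' One CSV row per team and pair plus an `overall` row each, and a JSON
#' sidecar echoing tolerance and mode.
#'
#' @param results named list of `devg_result` objects (one per team).
#' @param csv_path,meta_path output paths (`NULL` to skip).
#' @return the report `data.frame`, invisibly.
#' @export
write_devg_report <- function(results, csv_path = NULL, meta_path = NULL) {
  rows <- lapply(names(results), function(team) {
    r <- results[[team]]
    rbind(data.frame(team = team, pair = r$pairs$pair, mode = r$config$mode,
                     deviation = r$pairs$deviation, stringsAsFactors = FALSE),
          data.frame(team = team, pair = "overall", mode = r$config$mode,
                     deviation = r$overall, stringsAsFactors = FALSE))
  })
  df <- do.call(rbind, rows)
  if (!is.null(csv_path)) utils::write.csv(df, csv_path, row.names = FALSE)
  if (!is.null(meta_path)) {
    cfg <- results[[1]]$config
    jsonlite::write_json(list(task = cfg$task, tolerance = cfg$tolerance,
                              mode = cfg$mode, categories = cfg$categories,
                              reference = results[[1]]$reference),
                         meta_path, auto_unbox = TRUE)
  }
  invisible(df)
}
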