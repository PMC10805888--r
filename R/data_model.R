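#' @title Dataset manifest model
#' @description
#' A manifest is a plain `data.frame` with one row per frame and columns
#' `frame_id, centre_id, modality, split, sequence_id, frame_index,
#' height_px, width_px, image_path, mask_path`. Polyp instances live in a
#' second `data.frame` with columns `frame_id, x, y, w, h, size_category`.
#' Coordinates are 0-based, x rightward, y downward; boxes are
#' `(x, y, w, h)` over the half-open region `[x, x+w) x [y, y+h)`.
#' @name manifest-model
NULL

.centres <- paste0("C", 1:6)
.modalities <- c("WLE", "NBI")
.splits <- c("train", "data1", "data2", "data3", "data4")
.size_categories <- c("small", "medium", "large")

.manifest_cols <- c("frame_id", "centre_id", "modality", "split",
                    "sequence_id", "frame_index", "height_px", "width_px",
                    "image_path", "mask_path")
.instance_cols <- c("frame_id", "x", "y", "w", "h", "size_category")

#' Classify a polyp bounding box as small, medium or large
#'
#' Boxes are first rescaled from their native frame resolution to a common
#' reference resolution (default 540x720) with independent per-axis scale
#' factors, then classified. Under the default `"area"` rule the scaled box
#' area `a` is compared against the 100x100 and 200x200 pixel landmarks:
#' small when `a < 100^2`, large when `a > 200^2`, medium otherwise (both
#' boundaries fall in the closed middle interval). The `"side"` rule instead
#' requires both scaled sides below 100 px (small) or both above 200 px
#' (large).
#'
#' @param w,h box width(s) and height(s) in native pixels; vectorised.
#' @param native_size `c(height, width)` of the native frame, or a 2-column
#'   matrix (one row per box).
#' @param reference_size `c(height, width)` of the common reference frame.
#' @param rule `"area"` (default) or `"side"`.
#' @return character vector in `c("small", "medium", "large")`.
#' @examples
#' categorize_polyp_size(50, 50, c(540, 720))    # "small"
#' categorize_polyp_size(100, 100, c(540, 720))  # boundary -> "medium"
#' categorize_polyp_size(300, 300, c(1080, 1440))  # scaled 150x150 -> "medium"
#' @export
categorize_polyp_size <- function(w, h, native_size = c(540, 720),
                                  reference_size = c(540, 720),
                                  rule = c("area", "side")) {
  rule <- match.arg(rule)
  if (any(w <= 0) || any(h <= 0))
    stop("invalid polyp instance: bounding box dimensions must be positive")
  if (is.matrix(native_size)) {
    nh <- native_size[, 1]; nw <- native_size[, 2]
  } else {
    nh <- native_size[1]; nw <- native_size[2]
  }
  if (any(nh <= 0) || any(nw <= 0)) stop("native frame size must be positive")
  sw <- w * (reference_size[2] / nw)
  sh <- h * (reference_size[1] / nh)
  if (rule == "area") {
    a <- sw * sh
    ifelse(a < 100^2, "small", ifelse(a > 200^2, "large", "medium"))
  } else {
    ifelse(sw < 100 & sh < 100, "small",
           ifelse(sw > 200 & sh > 200, "large", "medium"))
  }
}

#' Validate a frame manifest and its polyp instances
#'
#' Checks the structural invariants of the benchmark layout: known centres,
#' modalities and splits; split constraints (`data1` frames are NBI,
#' `data2`/`data4` frames come from the held-out centre C6, `data3` frames
#' are WLE from centres C1--C5, training frames are WLE from C1--C5);
#' `frame_index` present exactly when `sequence_id` is, with unique
#' `(sequence_id, frame_index)` pairs; unique frame ids; instances referring
#' only to existing frames, lying within frame bounds, and carrying the size
#' category implied by their rescaled box.
#'
#' @param frames manifest `data.frame` (see [manifest-model]).
#' @param instances optional instance `data.frame`.
#' @param size_rule size-classification rule passed to
#'   [categorize_polyp_size()].
#' @return invisibly `TRUE`; stops with a message listing offenders otherwise.
#' @export
validate_manifest <- function(frames, instances = NULL, size_rule = "area") {
  probs <- character()
  miss <- setdiff(setdiff(.manifest_cols, c("image_path", "mask_path")),
                  names(frames))
  if (length(miss))
    stop("manifest is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(frames$frame_id))
    probs <- c(probs, paste("duplicated frame_id:",
      paste(unique(frames$frame_id[duplicated(frames$frame_id)]), collapse = ", ")))
  if (!all(frames$centre_id %in% .centres))
    probs <- c(probs, "unknown centre_id values")
  if (!all(frames$modality %in% .modalities))
    probs <- c(probs, "unknown modality values")
  if (!all(frames$split %in% .splits))
    probs <- c(probs, "unknown split values")
  bad <- frames$split == "data1" & frames$modality != "NBI"
  if (any(bad, na.rm = TRUE))
    probs <- c(probs, paste("data1 frames must be NBI:",
                            paste(frames$frame_id[bad], collapse = ", ")))
  bad <- frames$split %in% c("data2", "data4") & frames$centre_id != "C6"
  if (any(bad, na.rm = TRUE))
    probs <- c(probs, paste("data2/data4 frames must come from C6:",
                            paste(frames$frame_id[bad], collapse = ", ")))
  bad <- frames$split == "data3" &
    (!(frames$centre_id %in% .centres[1:5]) | frames$modality != "WLE")
  if (any(bad, na.rm = TRUE))
    probs <- c(probs, paste("data3 frames must be WLE from C1-C5:",
                            paste(frames$frame_id[bad], collapse = ", ")))
  bad <- frames$split == "train" &
    (!(frames$centre_id %in% .centres[1:5]) | frames$modality != "WLE")
  if (any(bad, na.rm = TRUE))
    probs <- c(probs, paste("train frames must be WLE from C1-C5:",
                            paste(frames$frame_id[bad], collapse = ", ")))
  has_seq <- !is.na(frames$sequence_id)
  has_idx <- !is.na(frames$frame_index)
  if (any(has_seq != has_idx))
    probs <- c(probs, "frame_index must be present iff sequence_id is")
  if (any(has_idx & frames$frame_index < 0, na.rm = TRUE))
    probs <- c(probs, "frame_index must be non-negative")
  key <- paste(frames$sequence_id, frames$frame_index)[has_seq & has_idx]
  if (anyDuplicated(key))
    probs <- c(probs, "(sequence_id, frame_index) pairs must be unique")
  if (any(frames$height_px <= 0 | frames$width_px <= 0))
    probs <- c(probs, "frame dimensions must be positive")

  if (!is.null(instances) && nrow(instances)) {
    miss <- setdiff(.instance_cols, names(instances))
    if (length(miss))
      stop("instance table is missing columns: ", paste(miss, collapse = ", "))
    dangling <- setdiff(instances$frame_id, frames$frame_id)
    if (length(dangling))
      probs <- c(probs, paste("instances refer to unknown frames:",
                              paste(dangling, collapse = ", ")))
    idx <- match(instances$frame_id, frames$frame_id)
    ok <- !is.na(idx)
    if (any(instances$w[ok] <= 0 | instances$h[ok] <= 0))
      probs <- c(probs, "instance boxes must have positive width and height")
    oob <- ok & (instances$x < 0 | instances$y < 0 |
                   instances$x + instances$w > frames$width_px[idx] |
                   instances$y + instances$h > frames$height_px[idx])
    if (any(oob, na.rm = TRUE))
      probs <- c(probs, paste("instance boxes outside frame bounds:",
                              paste(instances$frame_id[oob], collapse = ", ")))
    if (all(ok)) {
      want <- categorize_polyp_size(
        instances$w, instances$h,
        native_size = cbind(frames$height_px[idx], frames$width_px[idx]),
        rule = size_rule)
      bad <- instances$size_category != want
      if (any(bad))
        probs <- c(probs, paste("size_category inconsistent with box size:",
                                paste(instances$frame_id[bad], collapse = ", ")))
    }
  }
  if (length(probs)) stop("manifest validation failed:\n  ",
                          paste(probs, collapse = "\n  "))
  invisible(TRUE)
}

#' Summarise a manifest
#'
#' Tabulates per-split and per-centre frame counts, per-size-category
#' instance counts, the number of null frames (frames with no polyp
#' instance), and the total instance count.
#'
#' @inheritParams validate_manifest
#' @return a `manifest_summary` list with components `n_frames`,
#'   `per_split`, `per_centre`, `per_size`, `n_null_frames`,
#'   `total_instances`.
#' @export
summarize_manifest <- function(frames, instances = NULL) {
  if (is.null(instances))
    instances <- data.frame(frame_id = character(), x = numeric(),
                            y = numeric(), w = numeric(), h = numeric(),
                            size_category = character())
  dangling <- setdiff(instances$frame_id, frames$frame_id)
  if (length(dangling))
    stop("instances refer to frames absent from the manifest: ",
         paste(dangling, collapse = ", "))
  per_split <- table(factor(frames$split, levels = .splits))
  per_centre <- table(factor(frames$centre_id, levels = .centres))
  per_size <- table(factor(instances$size_category, levels = .size_categories))
  out <- list(
    n_frames = nrow(frames),
    per_split = as.integer(per_split),
    per_centre = as.integer(per_centre),
    per_size = as.integer(per_size),
    n_null_frames = sum(!(frames$frame_id %in% instances$frame_id)),
    total_instances = nrow(instances))
  names(out$per_split) <- .splits
  names(out$per_centre) <- .centres
  names(out$per_size) <- .size_categories
  class(out) <- "manifest_summary"
  out
}

#' @export
print.manifest_summary <- function(x, ...) {
  cat("Manifest:", x$n_frames, "frames,", x$total_instances,
      "polyp instances,", x$n_null_frames, "null frames\n")
  cat("  per split: ",
      paste(names(x$per_split), x$per_split, sep = "=", collapse = " "), "\n")
  cat("  per centre:",
      paste(names(x$per_centre), x$per_centre, sep = "=", collapse = " "), "\n")
  cat("  per size:  ",
      paste(names(x$per_size), x$per_size, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Compose a challenge round from per-split quotas
#'
#' Selects a deterministic subset of a manifest for a given evaluation
#' round. Within each quoted split frames are ordered by `frame_id`; when
#' the quota is below the number available, a seeded sample (without
#' replacement) of the ordered frames is taken, so the same manifest,
#' quotas and seed always give the identical subset.
#'
#' @param frames manifest `data.frame`.
#' @param quotas named integer vector, e.g. `c(data1 = 50, data2 = 50,
#'   data3 = 50)`.
#' @param seed integer seed used only when a quota is strictly below the
#'   frames available in that split.
#' @return the selected rows of `frames`, ordered by split then `frame_id`.
#' @export
compose_round <- function(frames, quotas, seed = 1L) {
  picked <- lapply(names(quotas), function(sp) {
    avail <- frames[frames$split == sp, , drop = FALSE]
    avail <- avail[order(avail$frame_id), , drop = FALSE]
    q <- quotas[[sp]]
    if (q > nrow(avail))
      stop("quota for split '", sp, "' (", q, ") exceeds available frames (",
           nrow(avail), ")")
    if (q == nrow(avail)) return(avail)
    keep <- with_seed(seed + match(sp, .splits),
                      function() sort(sample.int(nrow(avail), q)))
    avail[keep, , drop = FALSE]
  })
  out <- do.call(rbind, picked)
  rownames(out) <- NULL
  out
}

#' Read / write manifest and instance tables
#'
#' CSV round-trip for the two benchmark tables. Missing `sequence_id` /
#' `frame_index` / path fields are written as empty strings and read back
#' as `NA`.
#'
#' @param path file path.
#' @param frames,instances the tables to write.
#' @return the `data.frame` read, or invisibly `path` when writing.
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(frame_id = "character"))
  for (col in c("sequence_id", "image_path", "mask_path"))
    if (col %in% names(df)) df[[col]][!nzchar(as.character(df[[col]])) |
                                        is.na(df[[col]])] <- NA
  df
}

#' @rdname read_manifest
#' @export
write_manifest <- function(frames, path) {
  utils::write.csv(frames, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname read_manifest
#' @export
read_instances <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(frame_id = "character"))
}

#' @rdname read_manifest
#' @export
write_instances <- function(instances, path) {
  utils::write.csv(instances, path, row.names = FALSE, na = "")
  invisible(path)
}
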