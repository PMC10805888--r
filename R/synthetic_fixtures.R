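#' @title Synthetic challenge fixtures
#' @description
#' Seeded generators that emulate the *structure* of a multi-centre
#' colonoscopy benchmark — six centres, two modalities, a training split
#' and four test splits (unseen modality, unseen-centre single frames,
#' seen-centre sequences, unseen-centre sequences), null frames, and a
#' small/medium/large polyp-size mixture on 540x720 frames — without any
#' appearance model. Polyps are rendered as randomly perturbed ellipses
#' (low-order radial Fourier perturbation) into binary masks; predictions
#' are derived from the ground truth by dropping, jittering and adding
#' blobs under a controllable severity so the generalisation gap between
#' splits is a known quantity.
#' @name synthetic-fixtures
NULL

#' Scene specification for the ground-truth generator
#'
#' Defaults mirror the benchmark's composition: test split quotas 135
#' (data1), 86 (data2), 124 (data3) and 432 (data4) on 540x720 frames, a
#' null-frame probability of 0.17 and a small/medium/large mixture of
#' 144/296/261 (the test-set instance counts). The training quota defaults
#' to 3242 frames; pass a smaller count for desk-scale fixtures.
#'
#' @param frame_size `c(height, width)` in pixels.
#' @param counts named vector of frames per split.
#' @param null_prob probability that a frame contains no polyp.
#' @param size_mixture named probabilities for `small`, `medium`, `large`.
#' @param polyp_rate mean extra polyps per non-null frame (instance count
#'   is `1 + rpois(polyp_rate)`).
#' @param seq_len_mean mean sequence length for sequence splits.
#' @param seed integer seed; all generator randomness flows from it.
#' @return a `scene_spec` list.
#' @export
scene_spec <- function(frame_size = c(540, 720),
                       counts = c(train = 3242, data1 = 135, data2 = 86,
                                  data3 = 124, data4 = 432),
                       null_prob = 0.17,
                       size_mixture = c(small = 144, medium = 296,
                                        large = 261) / 701,
                       polyp_rate = 0.25,
                       seq_len_mean = 10,
                       seed = 1L) {
  stopifnot(all(frame_size > 0), all(counts >= 0), null_prob >= 0,
            null_prob <= 1, seq_len_mean >= 1)
  size_mixture <- size_mixture / sum(size_mixture)
  # blobs are sampled at the 540x720 reference scale and shrunk to the
  # native frame, so any frame a tenth of the reference or larger can hold
  # the whole size taxonomy; below that the rendered polyps degenerate
  if (frame_size[1] < 54 || frame_size[2] < 72)
    stop("infeasible spec: frames below 54x72 px cannot render the ",
         "polyp-size taxonomy")
  structure(list(frame_size = frame_size, counts = counts,
                 null_prob = null_prob, size_mixture = size_mixture,
                 polyp_rate = polyp_rate, seq_len_mean = seq_len_mean,
                 seed = seed),
            class = "scene_spec")
}

#' Perturbation specification for the prediction simulator
#'
#' Controls the error structure of simulated predictions: each
#' ground-truth polyp is missed with `miss_prob`; survivors are offset
#' (`offset_sd` px), rescaled (log-normal, `scale_sd`), and get fresh
#' boundary noise (`boundary_noise` px); spurious blobs appear at
#' `fp_rate` per frame (Poisson). Detection confidence is
#' `conf_base - conf_penalty * (1 - IoU) + N(0, conf_noise_sd)`, clipped
#' to `[0, 1]`. `severity` multiplies `miss_prob`, `fp_rate`, `offset_sd`,
#' `scale_sd` and `boundary_noise` per split, which is how a known
#' generalisation gap between the seen and unseen splits is injected.
#'
#' @param miss_prob,fp_rate,boundary_noise,offset_sd,scale_sd see above.
#' @param conf_base,conf_penalty,conf_noise_sd confidence model.
#' @param severity named per-split multipliers (default all 1).
#' @param seed integer seed.
#' @return a `perturbation_spec` list.
#' @export
perturbation_spec <- function(miss_prob = 0.10, fp_rate = 0.10,
                              boundary_noise = 2, offset_sd = 6,
                              scale_sd = 0.05, conf_base = 0.95,
                              conf_penalty = 0.5, conf_noise_sd = 0.05,
                              severity = c(train = 1, data1 = 1, data2 = 1,
                                           data3 = 1, data4 = 1),
                              seed = 1L) {
  stopifnot(miss_prob >= 0, miss_prob <= 1, fp_rate >= 0,
            boundary_noise >= 0, offset_sd >= 0, scale_sd >= 0,
            all(severity >= 0))
  structure(list(miss_prob = miss_prob, fp_rate = fp_rate,
                 boundary_noise = boundary_noise, offset_sd = offset_sd,
                 scale_sd = scale_sd, conf_base = conf_base,
                 conf_penalty = conf_penalty, conf_noise_sd = conf_noise_sd,
                 severity = severity, seed = seed),
            class = "perturbation_spec")
}

# --- blob model -----------------------------------------------------------

# Sample blob parameters for one polyp of a target size category. Sides
# are drawn at the 540x720 reference scale, away from the 100/200 px class
# boundaries so the rendered bbox stays in category, then converted to the
# native frame scale (independent per-axis factors, the inverse of the
# mapping used by categorize_polyp_size).
.sample_blob <- function(category, frame_size) {
  h <- frame_size[1]; w <- frame_size[2]
  side <- switch(category,
                 small = stats::runif(1, 40, 90),
                 medium = stats::runif(1, 110, 190),
                 large = stats::runif(1, 215, 330))
  aspect <- exp(stats::runif(1, -0.25, 0.25))
  bw <- side * sqrt(aspect) * (w / 720)
  bh <- side / sqrt(aspect) * (h / 540)
  # radial Fourier perturbation, modes 2..4, total amplitude <= 0.15 so the
  # blob stays simply connected and the bbox near the nominal side
  amp <- stats::runif(3, 0, 0.05)
  phase <- stats::runif(3, 0, 2 * pi)
  margin_x <- bw / 2 * 1.2 + 2; margin_y <- bh / 2 * 1.2 + 2
  list(cx = stats::runif(1, margin_x, w - margin_x),
       cy = stats::runif(1, margin_y, h - margin_y),
       rx = bw / 2, ry = bh / 2, amp = amp, phase = phase,
       category = category)
}

# Rasterise one blob into an existing mask (modified in place by return).
# Pixel (x, y) is inside when its centre lies within the perturbed ellipse.
.render_blob <- function(mask, b) {
  h <- nrow(mask); w <- ncol(mask)
  rmax_x <- b$rx * 1.3; rmax_y <- b$ry * 1.3
  x0 <- max(0, floor(b$cx - rmax_x)); x1 <- min(w - 1, ceiling(b$cx + rmax_x))
  y0 <- max(0, floor(b$cy - rmax_y)); y1 <- min(h - 1, ceiling(b$cy + rmax_y))
  if (x1 < x0 || y1 < y0) return(mask)
  xs <- x0:x1; ys <- y0:y1
  u <- outer(rep(1, length(ys)), (xs - b$cx) / b$rx)
  v <- outer((ys - b$cy) / b$ry, rep(1, length(xs)))
  rho <- sqrt(u^2 + v^2)
  th <- atan2(v, u)
  lim <- 1 + b$amp[1] * cos(2 * th + b$phase[1]) +
    b$amp[2] * cos(3 * th + b$phase[2]) +
    b$amp[3] * cos(4 * th + b$phase[3])
  inside <- rho <= lim
  sub <- mask[ys + 1, xs + 1, drop = FALSE]
  sub[inside] <- 1L
  mask[ys + 1, xs + 1] <- sub
  mask
}

# Tight bbox (x, y, w, h) of a mask's foreground; NULL when empty.
.mask_bbox <- function(mask) {
  idx <- which(mask != 0, arr.ind = TRUE)
  if (!nrow(idx)) return(NULL)
  x0 <- min(idx[, 2]) - 1; x1 <- max(idx[, 2]) - 1
  y0 <- min(idx[, 1]) - 1; y1 <- max(idx[, 1]) - 1
  c(x = x0, y = y0, w = x1 - x0 + 1, h = y1 - y0 + 1)
}

# Split layout: centre pool, modality and whether frames form sequences.
.split_layout <- list(
  train = list(centres = paste0("C", 1:5), modality = "WLE", sequences = FALSE),
  data1 = list(centres = paste0("C", 1:5), modality = "NBI", sequences = FALSE),
  data2 = list(centres = "C6", modality = "WLE", sequences = FALSE),
  data3 = list(centres = paste0("C", 1:5), modality = "WLE", sequences = TRUE),
  data4 = list(centres = "C6", modality = "WLE", sequences = TRUE))

#' Generate seeded synthetic ground truth
#'
#' Produces a manifest, per-frame binary masks and a polyp-instance table
#' matching the benchmark layout. Polyps are perturbed-ellipse blobs;
#' within a sequence the blob parameters evolve by a bounded Gaussian
#' random walk (reflected at the frame boundary) so consecutive frames are
#' correlated. Fully reproducible from `spec$seed`.
#'
#' @param spec a [scene_spec()].
#' @param mask_sink optional `function(frame_id, mask)`; when supplied each
#'   rendered mask is handed to it (e.g. written straight to disk) instead
#'   of being accumulated in memory, and the returned `masks` list is
#'   empty. Benchmark-scale fixtures (thousands of 540x720 frames) should
#'   be generated this way; [generate_challenge_fixture()] does so
#'   automatically when given an output directory.
#' @return a `gt_fixture` list: `frames` (manifest), `instances`, `masks`
#'   (named list of 0/1 matrices), `blobs` (per-frame blob parameters),
#'   `spec`.
#' @export
generate_ground_truth <- function(spec = scene_spec(), mask_sink = NULL) {
  with_seed(spec$seed,
            function() .generate_ground_truth_impl(spec, mask_sink))
}

.generate_ground_truth_impl <- function(spec, mask_sink = NULL) {
  h <- spec$frame_size[1]; w <- spec$frame_size[2]
  frames <- list(); instances <- list(); masks <- list(); blobs <- list()
  cats <- names(spec$size_mixture)
  for (sp in names(spec$counts)) {
    n <- spec$counts[[sp]]
    if (!n) next
    lay <- .split_layout[[sp]]
    made <- 0L; seq_no <- 0L
    while (made < n) {
      if (lay$sequences) {
        seq_no <- seq_no + 1L
        len <- min(n - made, 1L + stats::rpois(1, spec$seq_len_mean - 1))
        sid <- sprintf("%s_seq%03d", sp, seq_no)
      } else {
        len <- 1L
        sid <- NA_character_
      }
      centre <- sample(lay$centres, 1)
      is_null <- stats::runif(1) < spec$null_prob
      n_polyp <- if (is_null) 0L else 1L + stats::rpois(1, spec$polyp_rate)
      bl <- lapply(seq_len(n_polyp), function(i)
        .sample_blob(sample(cats, 1, prob = spec$size_mixture),
                     spec$frame_size))
      for (t in seq_len(len)) {
        made <- made + 1L
        fid <- sprintf("%s_%05d", sp, made)
        if (t > 1L) {         # random-walk evolution within a sequence
          bl <- lapply(bl, function(b) {
            b$cx <- .reflect(b$cx + stats::rnorm(1, 0, 4), b$rx * 1.2 + 2,
                             w - b$rx * 1.2 - 2)
            b$cy <- .reflect(b$cy + stats::rnorm(1, 0, 4), b$ry * 1.2 + 2,
                             h - b$ry * 1.2 - 2)
            s <- exp(stats::rnorm(1, 0, 0.02))
            b$rx <- b$rx * s; b$ry <- b$ry * s
            b
          })
        }
        mask <- matrix(0L, h, w)
        inst <- list()
        for (b in bl) {
          mask <- .render_blob(mask, b)
          single <- .render_blob(matrix(0L, h, w), b)
          bb <- .mask_bbox(single)
          if (is.null(bb)) next
          inst[[length(inst) + 1L]] <- data.frame(
            frame_id = fid, x = bb["x"], y = bb["y"], w = bb["w"], h = bb["h"],
            size_category = categorize_polyp_size(bb["w"], bb["h"],
                                                  native_size = c(h, w)),
            stringsAsFactors = FALSE)
        }
        frames[[length(frames) + 1L]] <- data.frame(
          frame_id = fid, centre_id = centre, modality = lay$modality,
          split = sp, sequence_id = sid,
          frame_index = if (is.na(sid)) NA_integer_ else t - 1L,
          height_px = h, width_px = w,
          image_path = NA_character_, mask_path = NA_character_,
          stringsAsFactors = FALSE)
        if (is.null(mask_sink)) masks[[fid]] <- mask
        else mask_sink(fid, mask)
        blobs[[fid]] <- bl
        if (length(inst)) instances[[length(instances) + 1L]] <-
            do.call(rbind, inst)
        if (made >= n) break
      }
    }
  }
  frames <- do.call(rbind, frames); rownames(frames) <- NULL
  instances <- if (length(instances)) do.call(rbind, instances) else
    data.frame(frame_id = character(), x = numeric(), y = numeric(),
               w = numeric(), h = numeric(), size_category = character(),
               stringsAsFactors = FALSE)
  rownames(instances) <- NULL
  structure(list(frames = frames, instances = instances, masks = masks,
                 blobs = blobs, spec = spec), class = "gt_fixture")
}

.reflect <- function(x, lo, hi) {
  if (lo >= hi) return((lo + hi) / 2)
  if (x < lo) x <- lo + (lo - x)
  if (x > hi) x <- hi - (x - hi)
  min(max(x, lo), hi)
}

#' Simulate predictions from a ground-truth fixture
#'
#' Applies the perturbation model of [perturbation_spec()] to every frame:
#' ground-truth polyps are dropped, jittered and re-rendered; spurious
#' blobs are added; detection boxes and confidences are derived from the
#' predicted blobs. Per-split severity multipliers scale the error rates.
#'
#' @param gt a `gt_fixture` from [generate_ground_truth()]. Only its
#'   manifest, instance table and blob parameters are consulted, so a
#'   ground truth generated with a `mask_sink` works unchanged.
#' @param pspec a [perturbation_spec()].
#' @param mask_sink optional `function(frame_id, mask)` streaming each
#'   predicted mask out instead of accumulating it (see
#'   [generate_ground_truth()]).
#' @return list with `masks` (named list of predicted masks; empty when a
#'   sink is used) and `detections` (`data.frame`
#'   `frame_id, x, y, w, h, confidence`).
#' @export
simulate_predictions <- function(gt, pspec = perturbation_spec(),
                                 mask_sink = NULL) {
  with_seed(pspec$seed,
            function() .simulate_predictions_impl(gt, pspec, mask_sink))
}

.simulate_predictions_impl <- function(gt, pspec, mask_sink = NULL) {
  h <- gt$spec$frame_size[1]; w <- gt$spec$frame_size[2]
  pred_masks <- list(); det_rows <- list()
  for (i in seq_len(nrow(gt$frames))) {
    fid <- gt$frames$frame_id[i]
    sp <- gt$frames$split[i]
    sev <- if (sp %in% names(pspec$severity)) pspec$severity[[sp]] else 1
    miss <- min(1, pspec$miss_prob * sev)
    mask <- matrix(0L, h, w)
    gt_boxes <- gt$instances[gt$instances$frame_id == fid, , drop = FALSE]
    bi <- 0L
    for (b in gt$blobs[[fid]]) {
      bi <- bi + 1L
      if (stats::runif(1) < miss) next
      nb <- b
      nb$cx <- .reflect(b$cx + stats::rnorm(1, 0, pspec$offset_sd * sev),
                        2, w - 2)
      nb$cy <- .reflect(b$cy + stats::rnorm(1, 0, pspec$offset_sd * sev),
                        2, h - 2)
      s <- exp(stats::rnorm(1, 0, pspec$scale_sd * sev))
      nb$rx <- b$rx * s; nb$ry <- b$ry * s
      bn <- pspec$boundary_noise * sev / max(1, (b$rx + b$ry) / 2)
      nb$amp <- pmax(0, pmin(0.15, b$amp + stats::rnorm(3, 0, bn)))
      nb$phase <- b$phase + stats::rnorm(3, 0, bn)
      single <- .render_blob(matrix(0L, h, w), nb)
      bb <- .mask_bbox(single)
      if (is.null(bb)) next
      mask[single == 1L] <- 1L
      iou <- if (bi <= nrow(gt_boxes))
        bbox_iou(as.numeric(gt_boxes[bi, c("x", "y", "w", "h")]),
                 as.numeric(bb)) else 0
      conf <- pspec$conf_base - pspec$conf_penalty * (1 - iou) +
        stats::rnorm(1, 0, pspec$conf_noise_sd)
      det_rows[[length(det_rows) + 1L]] <- data.frame(
        frame_id = fid, x = bb["x"], y = bb["y"], w = bb["w"], h = bb["h"],
        confidence = min(1, max(0, conf)), stringsAsFactors = FALSE)
    }
    n_fp <- stats::rpois(1, pspec$fp_rate * sev)
    for (k in seq_len(n_fp)) {
      fb <- .sample_blob(sample(c("small", "medium"), 1), gt$spec$frame_size)
      single <- .render_blob(matrix(0L, h, w), fb)
      bb <- .mask_bbox(single)
      if (is.null(bb)) next
      mask[single == 1L] <- 1L
      conf <- pspec$conf_base - pspec$conf_penalty +
        stats::rnorm(1, 0, pspec$conf_noise_sd)
      det_rows[[length(det_rows) + 1L]] <- data.frame(
        frame_id = fid, x = bb["x"], y = bb["y"], w = bb["w"], h = bb["h"],
        confidence = min(1, max(0, conf)), stringsAsFactors = FALSE)
    }
    if (is.null(mask_sink)) pred_masks[[fid]] <- mask
    else mask_sink(fid, mask)
  }
  detections <- if (length(det_rows)) do.call(rbind, det_rows) else
    data.frame(frame_id = character(), x = numeric(), y = numeric(),
               w = numeric(), h = numeric(), confidence = numeric(),
               stringsAsFactors = FALSE)
  rownames(detections) <- NULL
  list(masks = pred_masks, detections = detections)
}

#' Generate a full challenge fixture
#'
#' One call producing ground truth plus one or more teams' simulated
#' predictions, optionally written to a directory tree (manifest and
#' instance CSVs, mask PNGs under `masks/`, per-team prediction masks under
#' `pred/<team>/masks/` with a detection CSV, and a fixture descriptor
#' JSON recording the specs and seeds). With an output directory, masks
#' are streamed to disk as they are rendered — one frame in memory at a
#' time — so benchmark-scale fixtures generate in bounded memory; the
#' returned object then carries empty `masks` lists and the files are the
#' interface.
#'
#' @param spec a [scene_spec()].
#' @param pspecs a single [perturbation_spec()] or a named list (one per
#'   team).
#' @param dir optional output directory.
#' @return list with `gt` and `predictions` (named per team; single
#'   unnamed pspec becomes team `"team1"`).
#' @export
generate_challenge_fixture <- function(spec = scene_spec(),
                                       pspecs = perturbation_spec(),
                                       dir = NULL) {
  if (inherits(pspecs, "perturbation_spec")) pspecs <- list(team1 = pspecs)
  if (is.null(dir)) {
    gt <- generate_ground_truth(spec)
    preds <- lapply(pspecs, function(ps) simulate_predictions(gt, ps))
    return(list(gt = gt, predictions = preds))
  }
  mdir <- file.path(dir, "masks")
  dir.create(mdir, recursive = TRUE, showWarnings = FALSE)
  gt <- generate_ground_truth(spec, mask_sink = function(fid, mask)
    write_mask(mask, file.path(mdir, paste0(fid, ".png"))))
  write_manifest(gt$frames, file.path(dir, "manifest.csv"))
  write_instances(gt$instances, file.path(dir, "instances.csv"))
  preds <- list()
  for (team in names(pspecs)) {
    td <- file.path(dir, "pred", team, "masks")
    dir.create(td, recursive = TRUE, showWarnings = FALSE)
    preds[[team]] <- simulate_predictions(
      gt, pspecs[[team]], mask_sink = function(fid, mask)
        write_mask(mask, file.path(td, paste0(fid, ".png"))))
    write_detections(preds[[team]]$detections,
                     file.path(dir, "pred", team, "detections.csv"))
  }
  desc <- list(frame_size = gt$spec$frame_size,
               counts = as.list(gt$spec$counts),
               null_prob = gt$spec$null_prob,
               size_mixture = as.list(gt$spec$size_mixture),
               seed = gt$spec$seed, teams = names(preds))
  jsonlite::write_json(desc, file.path(dir, "fixture.json"), auto_unbox = TRUE)
  list(gt = gt, predictions = preds)
}

#' @rdname generate_challenge_fixture
#' @param gt,preds fixture pieces as returned above.
#' @export
write_fixture <- function(gt, preds, dir) {
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  write_manifest(gt$frames, file.path(dir, "manifest.csv"))
  write_instances(gt$instances, file.path(dir, "instances.csv"))
  for (fid in names(gt$masks))
    write_mask(gt$masks[[fid]], file.path(dir, "masks", paste0(fid, ".png")))
  for (team in names(preds)) {
    td <- file.path(dir, "pred", team, "masks")
    dir.create(td, recursive = TRUE, showWarnings = FALSE)
    for (fid in names(preds[[team]]$masks))
      write_mask(preds[[team]]$masks[[fid]], file.path(td, paste0(fid, ".png")))
    write_detections(preds[[team]]$detections,
                     file.path(dir, "pred", team, "detections.csv"))
  }
  desc <- list(frame_size = gt$spec$frame_size, counts = as.list(gt$spec$counts),
               null_prob = gt$spec$null_prob,
               size_mixture = as.list(gt$spec$size_mixture),
               seed = gt$spec$seed, teams = names(preds))
  jsonlite::write_json(desc, file.path(dir, "fixture.json"), auto_unbox = TRUE)
  invisible(dir)
}
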