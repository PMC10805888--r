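# Small in-code fixtures shared across test files.

# A binary mask with a filled rectangle (0-based half-open box coords).
block_mask <- function(h, w, x = NULL, y = NULL, bw = 0, bh = 0) {
  m <- matrix(0L, h, w)
  if (!is.null(x) && bw > 0 && bh > 0)
    m[(y + 1):(y + bh), (x + 1):(x + bw)] <- 1L
  m
}

# A minimal valid one-frame manifest.
tiny_frames <- function(n = 1, split = "data3", centre = "C1",
                        modality = "WLE", h = 16, w = 16) {
  if (n == 0) return(tiny_frames(1, split, centre, modality, h, w)[0, ])
  data.frame(frame_id = sprintf("%s_%03d", split, seq_len(n)),
             centre_id = centre, modality = modality, split = split,
             sequence_id = NA_character_, frame_index = NA_integer_,
             height_px = h, width_px = w,
             image_path = NA_character_, mask_path = NA_character_,
             stringsAsFactors = FALSE)
}

# Desk-scale scene spec used where the full 540x720 resolution is not the
# point of the test.
small_scene <- function(seed = 1, counts = c(train = 0, data1 = 6, data2 = 6,
                                             data3 = 6, data4 = 6),
                        frame = c(135, 180), ...) {
  scene_spec(frame_size = frame, counts = counts, seed = seed, ...)
}
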