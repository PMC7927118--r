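# shared fixture builders: Gaussian-blob images and movies with known
# ground truth, and bare tracks for the metric tests

blob_image <- function(H, W, centers, sigma = 3, peak = 180) {
  img <- matrix(0, H, W)
  xs <- matrix(rep(0:(W - 1), each = H), H, W)
  ys <- matrix(rep(0:(H - 1), W), H, W)
  for (k in seq_len(nrow(centers)))
    img <- img + peak * exp(-((xs - centers[k, 1])^2 + (ys - centers[k, 2])^2) /
                              (2 * sigma^2))
  img
}

# movie from a list of per-cell position matrices (frame-aligned, NA = absent)
render_movie <- function(cell_positions, T, H, W, sigma = 3, peak = 180,
                         pixel_size_um = 1, frame_interval_min = 10) {
  frames <- array(0, c(T, H, W))
  for (pos in cell_positions) {
    for (t in seq_len(min(T, nrow(pos)))) {
      if (any(is.na(pos[t, ]))) next
      frames[t, , ] <- frames[t, , ] +
        blob_image(H, W, matrix(pos[t, ], 1), sigma, peak)
    }
  }
  ft_movie(round(frames), pixel_size_um, frame_interval_min, 8L)
}

# integer-pixel shift of an image, zero-filled
shift_image <- function(m, dx, dy) {
  out <- matrix(0, nrow(m), ncol(m))
  out[(1 + dy):nrow(m), (1 + dx):ncol(m)] <-
    m[1:(nrow(m) - dy), 1:(ncol(m) - dx)]
  out
}

# signal trace with given channel values (already on the normalised scale
# unless normalized = FALSE)
make_trace <- function(r = NULL, g = NULL, b = NULL, normalized = TRUE,
                       cell_id = "C1") {
  n <- max(length(r), length(g), length(b))
  df <- data.frame(frame = seq_len(n),
                   r = if (is.null(r)) NA_real_ else r,
                   g = if (is.null(g)) NA_real_ else g,
                   b = if (is.null(b)) NA_real_ else b)
  structure(df, cell_id = cell_id, diameter_px = 9,
            normalized = normalized, class = c("ft_trace", "data.frame"))
}

# bare track for metric/evaluation tests (no imaging involved)
make_track <- function(positions, id = "C1", parent_id = NA_character_,
                       birth_frame = 1L, divides = FALSE,
                       corrected_frames = integer(0),
                       daughter_ids = character(0)) {
  positions <- matrix(as.numeric(positions), ncol = 2L,
                      dimnames = list(NULL, c("x", "y")))
  last <- birth_frame + nrow(positions) - 1L
  structure(list(id = id, parent_id = parent_id, birth_frame = birth_frame,
                 last_frame = last, positions = positions,
                 division_frame = if (divides) last else NULL,
                 daughter_ids = daughter_ids,
                 corrected_frames = as.integer(corrected_frames),
                 end_reason = if (divides) "divided" else "movie_end"),
            class = "ft_track")
}

# straight-line track: n frames stepping (dx, dy) px per frame from (x0, y0)
line_track <- function(n, dx = 1, dy = 0, x0 = 0, y0 = 0, ...) {
  make_track(cbind(x0 + dx * (0:(n - 1)), y0 + dy * (0:(n - 1))), ...)
}

# minimal dividing family: parent + k daughters (daughters optionally divide)
make_family <- function(parent_frames = 10L, daughter_frames = c(20L, 20L),
                        daughters_divide = c(FALSE, FALSE), id = "C1",
                        step = 2) {
  k <- length(daughter_frames)
  dids <- paste0(id, ".", seq_len(k))
  parent <- line_track(parent_frames, dx = step, id = id, divides = TRUE,
                       daughter_ids = dids)
  tracks <- list(parent)
  for (j in seq_len(k)) {
    tracks[[j + 1L]] <- line_track(daughter_frames[j], dx = step, y0 = 5 * j,
                                   id = dids[j], parent_id = id,
                                   birth_frame = parent$last_frame + 1L,
                                   divides = daughters_divide[j])
  }
  tracks
}
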