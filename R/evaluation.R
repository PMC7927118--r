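#' Location error of tracks against a reference annotation
#'
#' Each evaluated track is matched to the reference cell whose position
#' at the track's birth frame is nearest (with a uniqueness check: two
#' tracks claiming the same reference cell is an error). Over the
#' overlapping frames, the per-frame absolute coordinate differences
#' `|dx|`, `|dy|` are reported in micrometres, axis-wise, together with
#' the maximum difference in pixels and whether any single difference
#' exceeds 20 px.
#'
#' @param tracks list of `ft_track` objects (or a `ft_lineage`).
#' @param reference `data.frame` with columns `cell_id`, `frame`, `x`,
#'   `y` (pixel coordinates, frames contiguous per cell).
#' @param pixel_size_um micrometres per pixel.
#' @return List of class `ft_evaluation`: `per_frame` (long table of
#'   `track_id`, `ref_id`, `frame`, `dx_um`, `dy_um`), `per_cell`
#'   (axis-wise mean and sd per track, max abs difference in px),
#'   `mean_dx_um`, `sd_dx_um`, `mean_dy_um`, `sd_dy_um`,
#'   `max_abs_px`, `exceeds_20px`.
#' @export
location_error <- function(tracks, reference, pixel_size_um) {
  if (inherits(tracks, "ft_lineage")) tracks <- tracks$tracks
  if (inherits(tracks, "ft_track")) tracks <- list(tracks)
  reference <- as.data.frame(reference)
  need <- c("cell_id", "frame", "x", "y")
  if (!all(need %in% names(reference)))
    stop("reference needs columns ", paste(need, collapse = ", "), call. = FALSE)
  ref_by_cell <- split(reference, reference$cell_id)

  match_ref <- function(tr) {
    p0 <- tr$positions[1L, ]
    cand <- vapply(ref_by_cell, function(rc) {
      row <- rc[rc$frame == tr$birth_frame, , drop = FALSE]
      if (nrow(row) == 0L) return(Inf)
      sqrt((row$x[1L] - p0[1L])^2 + (row$y[1L] - p0[2L])^2)
    }, 0)
    if (all(is.infinite(cand)))
      stop("no reference cell overlaps birth frame of '", tr$id, "'",
           call. = FALSE)
    names(which.min(cand))
  }
  assigned <- vapply(tracks, match_ref, "")
  if (anyDuplicated(assigned)) {
    dup <- assigned[duplicated(assigned)][1L]
    stop("ambiguous matching: tracks ",
         paste(sQuote(vapply(tracks[assigned == dup], function(t) t$id, "")),
               collapse = ", "),
         " all nearest to reference '", dup, "'", call. = FALSE)
  }

  per_frame <- Map(function(tr, rid) {
    rc <- ref_by_cell[[rid]]
    frames <- intersect(seq(tr$birth_frame, tr$last_frame), rc$frame)
    if (length(frames) == 0L)
      stop("no overlapping frames between '", tr$id, "' and reference '",
           rid, "'", call. = FALSE)
    ti <- frames - tr$birth_frame + 1L
    ri <- match(frames, rc$frame)
    data.frame(track_id = tr$id, ref_id = rid, frame = frames,
               dx_um = abs(tr$positions[ti, 1L] - rc$x[ri]) * pixel_size_um,
               dy_um = abs(tr$positions[ti, 2L] - rc$y[ri]) * pixel_size_um)
  }, tracks, assigned)
  pf <- do.call(rbind, c(per_frame, list(make.row.names = FALSE)))

  per_cell <- do.call(rbind, lapply(split(pf, pf$track_id), function(b) {
    data.frame(track_id = b$track_id[1L], ref_id = b$ref_id[1L],
               n_frames = nrow(b),
               mean_dx_um = mean(b$dx_um), sd_dx_um = stats::sd(b$dx_um),
               mean_dy_um = mean(b$dy_um), sd_dy_um = stats::sd(b$dy_um),
               max_abs_px = max(b$dx_um, b$dy_um) / pixel_size_um)
  }))
  rownames(per_cell) <- NULL
  max_abs_px <- max(pf$dx_um, pf$dy_um) / pixel_size_um
  structure(list(per_frame = pf, per_cell = per_cell,
                 mean_dx_um = mean(pf$dx_um), sd_dx_um = stats::sd(pf$dx_um),
                 mean_dy_um = mean(pf$dy_um), sd_dy_um = stats::sd(pf$dy_um),
                 max_abs_px = max_abs_px, exceeds_20px = max_abs_px > 20),
            class = "ft_evaluation")
}

#' @export
print.ft_evaluation <- function(x, ...) {
  cat(sprintf("<ft_evaluation> %d track%s, %d frame comparisons\n",
              nrow(x$per_cell), if (nrow(x$per_cell) == 1L) "" else "s",
              nrow(x$per_frame)))
  cat(sprintf("  location error: dx %.3g +/- %.3g um, dy %.3g +/- %.3g um\n",
              x$mean_dx_um, x$sd_dx_um, x$mean_dy_um, x$sd_dy_um))
  cat(sprintf("  max |d| = %.3g px%s\n", x$max_abs_px,
              if (x$exceeds_20px) " (exceeds the 20 px accuracy bound)" else ""))
  invisible(x)
}

#' Manual-intervention (correction) rate of a track
#'
#' Number of corrected frames divided by the total number of frames.
#'
#' @param track a `ft_track`.
#' @return Fraction in \[0, 1\].
#' @export
correction_rate <- function(track) {
  length(unique(track$corrected_frames)) / track_length(track)
}

#' Per-cell intensity profiles along tracks
#'
#' Raw (unnormalised) mean intensities over the signal disk at every
#' tracked position, suitable for intensity heatmaps. Grayscale movies
#' yield one value per frame; RGB movies the per-channel means.
#'
#' @param movie a [ft_movie()].
#' @param tracks list of `ft_track` objects (or a `ft_lineage`).
#' @param diameter_px signal-field diameter in pixels.
#' @return `data.frame`: `cell_id`, `frame`, `intensity` (grayscale) or
#'   `r`, `g`, `b` (RGB).
#' @export
intensity_profiles <- function(movie, tracks, diameter_px) {
  if (inherits(tracks, "ft_lineage")) tracks <- tracks$tracks
  if (inherits(tracks, "ft_track")) tracks <- list(tracks)
  rgb <- length(dim(movie$frames)) == 4L
  rows <- lapply(tracks, function(tr) {
    tr_trace <- extract_signal(movie, tr, diameter_px)
    if (rgb)
      data.frame(cell_id = tr$id, frame = tr_trace$frame,
                 r = tr_trace$r, g = tr_trace$g, b = tr_trace$b)
    else
      data.frame(cell_id = tr$id, frame = tr_trace$frame,
                 intensity = tr_trace$r)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Convert a labelled-mask stack to a reference coordinate table
#'
#' Reference annotations distributed as 16-bit labelled-mask TIFF stacks
#' (one integer label per cell, 0 background, e.g. Cell Tracking
#' Challenge "man_track" files) are reduced to the coordinate-table form
#' used by [location_error()]: per frame and label, the unweighted
#' centroid of the labelled pixels.
#'
#' @param path path to the labelled multi-page TIFF.
#' @return `data.frame` with columns `cell_id`, `frame`, `x`, `y`.
#' @export
masks_to_reference <- function(path) {
  movie <- load_stack(path, pixel_size_um = 1, frame_interval_min = 1)
  d <- movie_dim(movie)
  rows <- list()
  for (t in seq_len(d["T"])) {
    fr <- movie_frame(movie, t)
    labs <- sort(unique(as.integer(fr)))
    labs <- labs[labs > 0L]
    for (l in labs) {
      idx <- which(fr == l)
      ij <- arrayInd(idx, dim(fr))
      rows[[length(rows) + 1L]] <-
        data.frame(cell_id = paste0("R", l), frame = t,
                   x = mean(ij[, 2L] - 1), y = mean(ij[, 1L] - 1))
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out[order(out$cell_id, out$frame), ]
}
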