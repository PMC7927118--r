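#' Two-channel FUCCI phase-calling parameters
#'
#' Thresholds on per-cell min-max normalised signals for the
#' Cdt1 (red) / Geminin (green) reporter pair: the minimum signal (MS),
#' the minimum green signal in S phase (MGSS), and the minimum red signal
#' in S phase (MRSS). All default to 0.1.
#'
#' @param MS,MGSS,MRSS thresholds in \[0, 1\].
#' @return List of class `ft_fucci2`.
#' @export
fucci_params_2ch <- function(MS = 0.1, MGSS = 0.1, MRSS = 0.1) {
  v <- c(MS = MS, MGSS = MGSS, MRSS = MRSS)
  if (any(v < 0 | v > 1)) stop("thresholds must lie in [0, 1]", call. = FALSE)
  structure(as.list(v), class = "ft_fucci2")
}

#' Three-channel (PIP-FUCCI) phase-calling parameters
#'
#' Thresholds for the PCNA (red) / Geminin (green) / PIP (blue) system:
#' the maximum green-blue ratio in G1 (MGBr_G1), the minimum green-blue
#' ratio in G2 (MGBr_G2), and the minimum blue signal in G2 (MBS_G2).
#' Defaults 0.5, 0.7 and 0.1.
#'
#' @param MGBr_G1,MGBr_G2,MBS_G2 thresholds; `MGBr_G1 <= MGBr_G2`.
#' @return List of class `ft_fucci3`.
#' @export
fucci_params_3ch <- function(MGBr_G1 = 0.5, MGBr_G2 = 0.7, MBS_G2 = 0.1) {
  if (MGBr_G1 > MGBr_G2) stop("MGBr_G1 must be <= MGBr_G2", call. = FALSE)
  structure(list(MGBr_G1 = MGBr_G1, MGBr_G2 = MGBr_G2, MBS_G2 = MBS_G2),
            class = "ft_fucci3")
}

# pixels of the signal-detection disk around (x, y), clipped to bounds;
# guaranteed non-empty (falls back to the nearest pixel)
disk_pixels <- function(x, y, diameter_px, H, W) {
  r <- diameter_px / 2
  rows <- max(1L, floor(y - r) + 1L):min(H, ceiling(y + r) + 1L)
  cols <- max(1L, floor(x - r) + 1L):min(W, ceiling(x + r) + 1L)
  grid <- expand.grid(row = rows, col = cols)
  dist <- sqrt((grid$col - 1 - x)^2 + (grid$row - 1 - y)^2)
  sel <- grid[dist <= r, , drop = FALSE]
  if (nrow(sel) == 0L) {
    sel <- data.frame(row = min(max(1L, round(y) + 1L), H),
                      col = min(max(1L, round(x) + 1L), W))
  }
  sel
}

#' Extract raw channel intensities along a track
#'
#' For each frame of the track, the mean of each channel over the disk of
#' the given diameter centred on the tracked position (clipped to the
#' image bounds). The detection field should not exceed the cell
#' diameter, or neighbouring cells contaminate the signal; the diameter
#' can therefore be chosen per cell.
#'
#' @param movie an RGB (or grayscale) [ft_movie()] aligned with the track.
#' @param track a `ft_track`.
#' @param diameter_px signal-field diameter in pixels (> 0).
#' @return A `data.frame` of class `ft_trace` with columns `frame`, `r`,
#'   `g`, `b` (grayscale movies fill `r` and leave `g`, `b` at `NA`);
#'   attributes `cell_id`, `diameter_px`, `normalized = FALSE`.
#' @export
extract_signal <- function(movie, track, diameter_px) {
  stopifnot(inherits(movie, "ft_movie"), inherits(track, "ft_track"))
  if (diameter_px <= 0) stop("`diameter_px` must be > 0", call. = FALSE)
  d <- movie_dim(movie)
  if (track$birth_frame < 1L || track$last_frame > d["T"])
    stop("track frames outside movie", call. = FALSE)
  rgb <- length(dim(movie$frames)) == 4L
  n <- track_length(track)
  out <- data.frame(frame = seq(track$birth_frame, track$last_frame),
                    r = NA_real_, g = NA_real_, b = NA_real_)
  for (i in seq_len(n)) {
    t <- out$frame[i]
    px <- disk_pixels(track$positions[i, 1L], track$positions[i, 2L],
                      diameter_px, d["H"], d["W"])
    if (rgb) {
      for (ch in 1:3) {
        plane <- movie$frames[t, , , ch]
        out[i, 1L + ch] <- mean(plane[cbind(px$row, px$col)])
      }
    } else {
      plane <- movie$frames[t, , ]
      out$r[i] <- mean(plane[cbind(px$row, px$col)])
    }
  }
  structure(out, cell_id = track$id, diameter_px = diameter_px,
            normalized = FALSE, class = c("ft_trace", "data.frame"))
}

#' Per-cell min-max normalisation of a signal trace
#'
#' Each channel is rescaled to \[0, 1\] over the cell's own time series
#' (the internal RGB normalisation): subtract the trace minimum, divide
#' by the range. A constant channel maps to all zeros. Idempotent on
#' full-range input.
#'
#' @param trace a raw [extract_signal()] trace of length >= 2.
#' @return The trace with channels replaced by their normalised values
#'   and attribute `normalized = TRUE`.
#' @export
normalize_signals <- function(trace) {
  stopifnot(inherits(trace, "ft_trace"))
  if (nrow(trace) < 2L)
    stop("need at least 2 frames to normalise", call. = FALSE)
  for (ch in c("r", "g", "b")) {
    v <- trace[[ch]]
    if (all(is.na(v))) next
    rng <- range(v)
    trace[[ch]] <- if (diff(rng) == 0) rep(0, length(v)) else (v - rng[1L]) / diff(rng)
  }
  attr(trace, "normalized") <- TRUE
  trace
}

phase_levels <- c("G1", "S", "G2M", "Unknown")

#' Call cell-cycle phases from a two-channel FUCCI trace
#'
#' Decision rule for the Cdt1 (red, peaks in G1, declines in S) /
#' Geminin (green, accumulates through S and G2) pair, applied per frame
#' to the normalised signals with precedence Unknown, S, G1, G2M:
#' \itemize{
#'   \item Unknown if both channels are below MS;
#'   \item S if green >= MGSS and red >= MRSS (both reporters present);
#'   \item G1 if red >= MS and green < MGSS (red only);
#'   \item G2M if green >= MS and red < MRSS (green only).
#' }
#'
#' @param trace a [normalize_signals()] output with `r` and `g`.
#' @param params a [fucci_params_2ch()].
#' @return Character vector of per-frame labels
#'   (`"G1"`, `"S"`, `"G2M"`, `"Unknown"`), same length as the trace.
#' @export
call_phases_2ch <- function(trace, params = fucci_params_2ch()) {
  stopifnot(inherits(trace, "ft_trace"))
  if (!isTRUE(attr(trace, "normalized")))
    stop("trace must be normalised first (normalize_signals)", call. = FALSE)
  r <- trace$r; g <- trace$g
  if (any(is.na(r)) || any(is.na(g)))
    stop("two-channel calling needs red and green signals", call. = FALSE)
  out <- rep("Unknown", length(r))
  for (i in seq_along(r)) {
    out[i] <- if (r[i] < params$MS && g[i] < params$MS) "Unknown"
      else if (g[i] >= params$MGSS && r[i] >= params$MRSS) "S"
      else if (r[i] >= params$MS && g[i] < params$MGSS) "G1"
      else if (g[i] >= params$MS && r[i] < params$MRSS) "G2M"
      else "Unknown"
  }
  out
}

#' Call cell-cycle phases from a three-channel (PIP-FUCCI) trace
#'
#' PIP (blue) is present in G1 and G2 but degraded during replication,
#' while Geminin (green) is present in S and G2; PCNA (red) is carried
#' in the trace but unused by the rule. With the green/blue ratio
#' `rho = g / (b + 1e-6)`, per frame:
#' \itemize{
#'   \item G1 if `rho <= MGBr_G1` (blue dominates);
#'   \item G2M if `rho >= MGBr_G2` and `b >= MBS_G2` (both present);
#'   \item S otherwise (green without blue).
#' }
#'
#' @param trace a [normalize_signals()] output with `g` and `b`.
#' @param params a [fucci_params_3ch()].
#' @return Character vector of per-frame labels.
#' @export
call_phases_3ch <- function(trace, params = fucci_params_3ch()) {
  stopifnot(inherits(trace, "ft_trace"))
  if (!isTRUE(attr(trace, "normalized")))
    stop("trace must be normalised first (normalize_signals)", call. = FALSE)
  g <- trace$g; b <- trace$b
  if (any(is.na(g)) || any(is.na(b)))
    stop("three-channel calling needs green and blue signals", call. = FALSE)
  rho <- g / (b + 1e-6)
  ifelse(rho <= params$MGBr_G1, "G1",
         ifelse(rho >= params$MGBr_G2 & b >= params$MBS_G2, "G2M", "S"))
}

#' Overwrite phase labels in a frame range
#'
#' The scripted analogue of supervised phase correction: labels in the
#' closed 1-based range `[from_frame, till_frame]` (relative to the
#' trace) are replaced by `phase`; all others are untouched.
#'
#' @param labels character vector of phase labels.
#' @param phase one of `"G1"`, `"S"`, `"G2M"`, `"Unknown"`.
#' @param from_frame,till_frame 1-based inclusive range,
#'   `from_frame <= till_frame <= length(labels)`.
#' @return The corrected label vector.
#' @export
correct_phase <- function(labels, phase, from_frame, till_frame) {
  if (!phase %in% phase_levels)
    stop("unknown phase '", phase, "'", call. = FALSE)
  if (from_frame < 1L || till_frame > length(labels) || from_frame > till_frame)
    stop("invalid frame range [", from_frame, ", ", till_frame, "]", call. = FALSE)
  labels[from_frame:till_frame] <- phase
  labels
}

#' Write per-cell phase tables
#'
#' One row per frame: `cell_id`, `frame`, normalised `r`, `g`, `b`, and
#' the called `phase`.
#'
#' @param traces list of normalised `ft_trace` objects.
#' @param labels list of matching label vectors.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_phase_table <- function(traces, labels, path) {
  stopifnot(length(traces) == length(labels))
  rows <- Map(function(tr, lab) {
    data.frame(cell_id = attr(tr, "cell_id"), frame = tr$frame,
               r = tr$r, g = tr$g, b = tr$b, phase = lab)
  }, traces, labels)
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
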