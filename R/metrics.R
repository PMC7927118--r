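#' Basic migration measures of one trajectory
#'
#' For a track of `n` positions with pixel size `s` (um/px) and frame
#' interval `dt` (min): trajectory time `T = (n - 1) dt / 60` h, total
#' distance `D` = sum of step lengths (um), displacement `L` =
#' straight-line first-to-last distance (um), directionality `L / D`
#' (dimensionless, `NA` when `D = 0`), and average speed `D / T` (um/h).
#'
#' @param track a `ft_track` with at least 2 frames.
#' @param pixel_size_um micrometres per pixel.
#' @param frame_interval_min minutes per frame.
#' @return One-row `data.frame`: `cell_id`, `trajectory_time_h`,
#'   `total_distance_um`, `displacement_um`, `directionality`,
#'   `avg_speed_um_h`.
#' @export
trajectory_measures <- function(track, pixel_size_um, frame_interval_min) {
  stopifnot(inherits(track, "ft_track"))
  n <- nrow(track$positions)
  if (n < 2L) stop("track must span at least 2 frames", call. = FALSE)
  steps <- diff(track$positions)
  step_len <- sqrt(rowSums(steps^2)) * pixel_size_um
  D <- sum(step_len)
  L <- sqrt(sum((track$positions[n, ] - track$positions[1L, ])^2)) * pixel_size_um
  T_h <- (n - 1L) * frame_interval_min / 60
  data.frame(cell_id = track$id,
             trajectory_time_h = T_h,
             total_distance_um = D,
             displacement_um = L,
             directionality = if (D > 0) L / D else NA_real_,
             avg_speed_um_h = D / T_h)
}

#' Migration measures for every track of a lineage
#'
#' @param lineage a [build_lineage()] result.
#' @inheritParams trajectory_measures
#' @return `data.frame` with one row per track of >= 2 frames.
#' @export
lineage_measures <- function(lineage, pixel_size_um, frame_interval_min) {
  stopifnot(inherits(lineage, "ft_lineage"))
  keep <- Filter(function(t) nrow(t$positions) >= 2L, lineage$tracks)
  if (length(keep) == 0L)
    return(data.frame(cell_id = character(0), trajectory_time_h = numeric(0),
                      total_distance_um = numeric(0),
                      displacement_um = numeric(0),
                      directionality = numeric(0),
                      avg_speed_um_h = numeric(0)))
  rows <- lapply(keep, trajectory_measures, pixel_size_um = pixel_size_um,
                 frame_interval_min = frame_interval_min)
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Instantaneous speeds along a track
#'
#' `v_t = ||p_(t+1) - p_t|| * s / (dt / 60)` in um/h; one value per step,
#' so `n - 1` values for `n` frames.
#'
#' @inheritParams trajectory_measures
#' @return Numeric vector of length `n - 1`.
#' @export
instantaneous_speeds <- function(track, pixel_size_um, frame_interval_min) {
  n <- nrow(track$positions)
  if (n < 2L) stop("track must span at least 2 frames", call. = FALSE)
  steps <- diff(track$positions)
  sqrt(rowSums(steps^2)) * pixel_size_um / (frame_interval_min / 60)
}

# midpoint of the tallest histogram bin; bin width in the units of x
histogram_mode <- function(x, bin_width) {
  if (length(x) == 0L) return(NA_real_)
  if (diff(range(x)) == 0) return(x[1L])
  breaks <- seq(min(x), max(x) + bin_width, by = bin_width)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  h$mids[which.max(h$counts)]
}

#' Doubling times from dividing daughter cells
#'
#' A dividing daughter cell is born at a scripted division and divides
#' itself, so its trajectory time spans one complete cell cycle and
#' measures the doubling time directly:
#' `(division_frame - birth_frame) * dt / 60` hours.
#'
#' @param lineage a [build_lineage()] result.
#' @param frame_interval_min minutes per frame.
#' @return `data.frame` (`cell_id`, `hours`) over the dividing daughter
#'   cells, with a `summary` attribute: `mean`, `sd`, `median`, and
#'   `mode` (midpoint of the tallest histogram bin, bin width = one
#'   frame interval).
#' @export
doubling_times <- function(lineage, frame_interval_min) {
  cats <- categorize(lineage)
  ids <- cats$DividingDaughterCells
  hours <- vapply(ids, function(id) {
    tr <- lineage$tracks[[id]]
    (tr$division_frame - tr$birth_frame) * frame_interval_min / 60
  }, 0)
  out <- data.frame(cell_id = ids, hours = unname(hours),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "summary") <- c(
    mean = if (nrow(out)) mean(out$hours) else NA_real_,
    sd = if (nrow(out) > 1L) stats::sd(out$hours) else NA_real_,
    median = if (nrow(out)) stats::median(out$hours) else NA_real_,
    mode = histogram_mode(out$hours, frame_interval_min / 60))
  out
}

# all unordered sibling pairs per dividing parent
sibling_pairs <- function(lineage) {
  parents <- Filter(function(t) length(t$daughter_ids) >= 2L, lineage$tracks)
  if (length(parents) == 0L) return(NULL)
  pairs <- lapply(parents, function(p) {
    cmb <- utils::combn(p$daughter_ids, 2L)
    data.frame(a = cmb[1L, ], b = cmb[2L, ], parent = p$id,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(pairs, list(make.row.names = FALSE)))
}

#' Heterogeneity between daughter-cell pairs
#'
#' Sibling pairs are compared on their migration measures. For a
#' meaningful comparison, both daughters must have a trajectory time of
#' at least `min_trajectory_time_h` and differ in trajectory time by at
#' most `max_pair_time_diff_h`. Multi-daughter divisions contribute all
#' unordered sibling pairs.
#'
#' @param lineage a [build_lineage()] result.
#' @param measures per-cell measures from [lineage_measures()].
#' @param min_trajectory_time_h,max_pair_time_diff_h pair selection
#'   filter (defaults 10 h and 3 h).
#' @return `data.frame` with one row per qualifying pair: the two ids and
#'   absolute differences `d_total_distance_um`, `d_displacement_um`,
#'   `d_directionality`, `d_avg_speed_um_h`.
#' @export
daughter_pair_differences <- function(lineage, measures,
                                      min_trajectory_time_h = 10,
                                      max_pair_time_diff_h = 3) {
  if (min_trajectory_time_h <= 0 || max_pair_time_diff_h <= 0)
    stop("filter thresholds must be > 0", call. = FALSE)
  pairs <- sibling_pairs(lineage)
  empty <- data.frame(id_a = character(0), id_b = character(0),
                      d_total_distance_um = numeric(0),
                      d_displacement_um = numeric(0),
                      d_directionality = numeric(0),
                      d_avg_speed_um_h = numeric(0))
  if (is.null(pairs) || nrow(pairs) == 0L) return(empty)
  m <- measures[match(c(pairs$a, pairs$b), measures$cell_id), ]
  ma <- m[seq_len(nrow(pairs)), ]
  mb <- m[nrow(pairs) + seq_len(nrow(pairs)), ]
  ok <- !is.na(ma$cell_id) & !is.na(mb$cell_id) &
    ma$trajectory_time_h >= min_trajectory_time_h &
    mb$trajectory_time_h >= min_trajectory_time_h &
    abs(ma$trajectory_time_h - mb$trajectory_time_h) <= max_pair_time_diff_h
  if (!any(ok)) return(empty)
  data.frame(id_a = pairs$a[ok], id_b = pairs$b[ok],
             d_total_distance_um = abs(ma$total_distance_um - mb$total_distance_um)[ok],
             d_displacement_um = abs(ma$displacement_um - mb$displacement_um)[ok],
             d_directionality = abs(ma$directionality - mb$directionality)[ok],
             d_avg_speed_um_h = abs(ma$avg_speed_um_h - mb$avg_speed_um_h)[ok],
             row.names = NULL)
}

#' Division synchrony of daughter-cell pairs
#'
#' Only sibling pairs in which both daughters divide are compared; the
#' result is the absolute difference of their division times in hours.
#'
#' @param lineage a [build_lineage()] result.
#' @param frame_interval_min minutes per frame.
#' @return `data.frame` (`id_a`, `id_b`, `dt_division_h`) with a
#'   `summary` attribute (`mean`, `sd`, `mode`).
#' @export
division_synchrony <- function(lineage, frame_interval_min) {
  pairs <- sibling_pairs(lineage)
  out <- data.frame(id_a = character(0), id_b = character(0),
                    dt_division_h = numeric(0))
  if (!is.null(pairs) && nrow(pairs) > 0L) {
    da <- lineage$tracks[pairs$a]
    db <- lineage$tracks[pairs$b]
    fa <- vapply(da, function(t) if (is.null(t$division_frame)) NA_real_
                 else t$division_frame, 0)
    fb <- vapply(db, function(t) if (is.null(t$division_frame)) NA_real_
                 else t$division_frame, 0)
    ok <- !is.na(fa) & !is.na(fb)
    out <- data.frame(id_a = pairs$a[ok], id_b = pairs$b[ok],
                      dt_division_h = abs(fa - fb)[ok] * frame_interval_min / 60,
                      row.names = NULL)
  }
  attr(out, "summary") <- c(
    mean = if (nrow(out)) mean(out$dt_division_h) else NA_real_,
    sd = if (nrow(out) > 1L) stats::sd(out$dt_division_h) else NA_real_,
    mode = histogram_mode(out$dt_division_h, frame_interval_min / 60))
  out
}

#' Per-phase durations and fractions of a labelled cycle
#'
#' Duration of each phase = number of frames carrying its label times the
#' frame interval. Fractions are taken over G1 + S + G2M; Unknown frames
#' are excluded from the fractions and reported separately.
#'
#' @param labels per-frame phase labels (see [call_phases_2ch()]).
#' @param frame_interval_min minutes per frame.
#' @return `data.frame` (`phase`, `duration_h`, `fraction`) for G1, S,
#'   G2M, plus attribute `unknown_h`.
#' @export
phase_durations <- function(labels, frame_interval_min) {
  if (all(labels == "Unknown"))
    stop("all frames Unknown: no phase information", call. = FALSE)
  per_frame_h <- frame_interval_min / 60
  counts <- vapply(c("G1", "S", "G2M"), function(p) sum(labels == p), 0L)
  known <- sum(counts)
  out <- data.frame(phase = names(counts),
                    duration_h = unname(counts) * per_frame_h,
                    fraction = unname(counts) / known,
                    row.names = NULL)
  attr(out, "unknown_h") <- sum(labels == "Unknown") * per_frame_h
  out
}

#' Per-phase speed and directionality dynamics
#'
#' Each step is attributed to the phase of its starting frame; the
#' per-phase speed is the mean instantaneous speed over those steps.
#' Per-phase directionality is computed on the sub-path of positions at
#' frames carrying the label (net displacement of the sub-path over its
#' path length). Phases absent from the labels yield `NA`.
#'
#' @param track a `ft_track`.
#' @param labels per-frame phase labels aligned with the track.
#' @inheritParams trajectory_measures
#' @return `data.frame` (`phase`, `mean_speed_um_h`, `directionality`)
#'   for G1, S, G2M.
#' @export
per_phase_dynamics <- function(track, labels, pixel_size_um, frame_interval_min) {
  n <- nrow(track$positions)
  if (length(labels) != n)
    stop("labels must align with the track (", n, " frames)", call. = FALSE)
  v <- instantaneous_speeds(track, pixel_size_um, frame_interval_min)
  rows <- lapply(c("G1", "S", "G2M"), function(p) {
    steps <- which(labels[-n] == p)
    spd <- if (length(steps)) mean(v[steps]) else NA_real_
    pts <- track$positions[labels == p, , drop = FALSE]
    dir <- NA_real_
    if (nrow(pts) >= 2L) {
      D <- sum(sqrt(rowSums(diff(pts)^2)))
      L <- sqrt(sum((pts[nrow(pts), ] - pts[1L, ])^2))
      dir <- if (D > 0) L / D else NA_real_
    }
    data.frame(phase = p, mean_speed_um_h = spd, directionality = dir)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Terminal-speed-jump criterion
#'
#' @param jump_window_h window before division searched for jumps (h).
#' @param baseline_window_h window for the baseline mean speed (h).
#' @param baseline_fold required fold increase over the baseline mean.
#' @param neighbor_fold required fold increase over the adjacent step
#'   speeds.
#' @return List of class `ft_jump_criterion`.
#' @export
jump_criterion <- function(jump_window_h = 1, baseline_window_h = 2,
                           baseline_fold = 2.5, neighbor_fold = 3) {
  if (jump_window_h > baseline_window_h)
    stop("`jump_window_h` must not exceed `baseline_window_h`", call. = FALSE)
  if (baseline_fold <= 1 || neighbor_fold <= 1)
    stop("fold thresholds must be > 1", call. = FALSE)
  structure(list(jump_window_h = jump_window_h,
                 baseline_window_h = baseline_window_h,
                 baseline_fold = baseline_fold, neighbor_fold = neighbor_fold),
            class = "ft_jump_criterion")
}

#' Detect a terminal speed jump before division
#'
#' A dividing cell shows a terminal speed jump when one or more
#' instantaneous speeds within the last `jump_window_h` (default 1 h) of
#' G2/M phase before division are at least `baseline_fold` (default
#' 2.5x) the mean instantaneous speed over the last `baseline_window_h`
#' (default 2 h) before division, and at least `neighbor_fold` (default
#' 3x) each existing temporally adjacent step speed. The baseline mean
#' includes the candidate step; the baseline window is purely temporal
#' while the candidate step itself must start in a G2M-labelled frame.
#'
#' @param track a dividing `ft_track`.
#' @param labels per-frame phase labels aligned with the track.
#' @inheritParams trajectory_measures
#' @param criterion a [jump_criterion()].
#' @return List: `jump` (logical flag), `jump_steps` (1-based step
#'   indices into the speed series), `speeds`, `baseline_mean_um_h`.
#' @export
detect_terminal_speed_jump <- function(track, labels, pixel_size_um,
                                       frame_interval_min,
                                       criterion = jump_criterion()) {
  if (is.null(track$division_frame))
    stop("track does not end in division", call. = FALSE)
  n <- nrow(track$positions)
  if (length(labels) != n)
    stop("labels must align with the track", call. = FALSE)
  v <- instantaneous_speeds(track, pixel_size_um, frame_interval_min)
  ns <- length(v)
  k_base <- round(criterion$baseline_window_h * 60 / frame_interval_min)
  k_jump <- round(criterion$jump_window_h * 60 / frame_interval_min)
  if (ns < k_base)
    stop("track shorter than the baseline window", call. = FALSE)
  base_idx <- (ns - k_base + 1L):ns
  baseline <- mean(v[base_idx])
  cand <- (ns - k_jump + 1L):ns
  cand <- cand[labels[cand] == "G2M"]  # step t starts at frame t
  hits <- integer(0)
  for (t in cand) {
    if (v[t] < criterion$baseline_fold * baseline) next
    nb <- c(if (t > 1L) v[t - 1L], if (t < ns) v[t + 1L])
    if (length(nb) && any(v[t] < criterion$neighbor_fold * nb)) next
    hits <- c(hits, t)
  }
  list(jump = length(hits) > 0L, jump_steps = hits, speeds = v,
       baseline_mean_um_h = baseline)
}
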