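#' Tracker parameters
#'
#' @param detection a [detection_params()].
#' @param gate_px maximum accepted linking distance in pixels. `NULL`
#'   (default) uses half the ROI side at tracking time: an assignment
#'   farther than the gate marks the track lost instead of force-linking,
#'   the headless analogue of pausing supervised tracking for a correction.
#' @return A list of class `ft_tracker_params`.
#' @export
tracker_params <- function(detection = detection_params(), gate_px = NULL) {
  if (!is.null(gate_px) && gate_px <= 0) stop("`gate_px` must be > 0", call. = FALSE)
  structure(list(detection = detection, gate_px = gate_px),
            class = "ft_tracker_params")
}

new_track <- function(id, parent_id, birth_frame) {
  structure(list(id = id, parent_id = parent_id,
                 birth_frame = birth_frame, last_frame = birth_frame,
                 positions = matrix(numeric(0), 0L, 2L,
                                    dimnames = list(NULL, c("x", "y"))),
                 division_frame = NULL, daughter_ids = character(0),
                 corrected_frames = integer(0), end_reason = "movie_end"),
            class = "ft_track")
}

#' @export
print.ft_track <- function(x, ...) {
  cat(sprintf("<ft_track> %s: frames %d-%d (%d), end: %s%s\n", x$id,
              x$birth_frame, x$last_frame, x$last_frame - x$birth_frame + 1L,
              x$end_reason,
              if (length(x$daughter_ids))
                paste0(", daughters: ", paste(x$daughter_ids, collapse = ", "))
              else ""))
  invisible(x)
}

#' Number of frames a track spans
#' @param track a `ft_track`.
#' @return Integer frame count.
#' @export
track_length <- function(track) track$last_frame - track$birth_frame + 1L

# position at an absolute frame index
track_position <- function(track, frame) {
  track$positions[frame - track$birth_frame + 1L, ]
}

#' Link one track one frame forward by minimum distance
#'
#' The detection minimising the Euclidean distance to the last position is
#' the new position of the tracked cell, provided the distance does not
#' exceed `gate_px`. Equidistant detections are resolved in row-major scan
#' order (smallest `y`, then `x`).
#'
#' @param last_position numeric `c(x, y)`.
#' @param detections detection `data.frame` (see [segment_clahe()]) from
#'   the current frame's search window.
#' @param gate_px maximum accepted distance.
#' @return One-row detection `data.frame`, or `NULL` when no detection
#'   lies within the gate.
#' @export
step_track <- function(last_position, detections, gate_px) {
  if (is.null(detections) || nrow(detections) == 0L) return(NULL)
  d <- sqrt((detections$x - last_position[1L])^2 +
            (detections$y - last_position[2L])^2)
  ord <- order(d, detections$y, detections$x)
  best <- ord[1L]
  if (d[best] > gate_px) return(NULL)
  detections[best, , drop = FALSE]
}

# segment inside a square ROI centred on `centre`, return detections in
# full-image coordinates
segment_roi <- function(img, centre, side, det_params) {
  H <- nrow(img); W <- ncol(img)
  half <- side / 2
  # 0-based pixel coords -> 1-based matrix rows/cols
  c0 <- max(1L, floor(centre[1L] - half) + 1L)
  c1 <- min(W, ceiling(centre[1L] + half) + 1L)
  r0 <- max(1L, floor(centre[2L] - half) + 1L)
  r1 <- min(H, ceiling(centre[2L] + half) + 1L)
  det <- segment_frame(img[r0:r1, c0:c1, drop = FALSE], det_params)
  det$x <- det$x + (c0 - 1L)
  det$y <- det$y + (r0 - 1L)
  det
}

# validate and index scripted events
index_events <- function(events, cols) {
  if (is.null(events)) return(NULL)
  events <- as.data.frame(events)
  if (!all(cols %in% names(events)))
    stop("event table must have columns ", paste(cols, collapse = ", "),
         call. = FALSE)
  events
}

#' Track a cell (and its descendants) through a movie
#'
#' Seeds a cell on frame 1, then per frame crops a square search window
#' (side `roi_fraction` of the shorter image side) around the last
#' position, segments it, and links by minimum distance ([step_track()]).
#' Scripted [CorrectionEvent][read_correction_events] rows override the
#' position at their frame (snapped to the nearest detected centroid when
#' `use_center_of_mass` is set, else used verbatim) and are recorded in
#' `corrected_frames`. A scripted division closes the track
#' (`end_reason = "divided"`) and seeds one new track per daughter on the
#' next frame; lineage ids append `.1`, `.2`, ... to the parent id. A link
#' failure with no correction closes the track as `"lost"`.
#'
#' Cells are seeded only on the first frame; daughters inherit their birth
#' frame from the scripted division.
#'
#' @param movie a grayscale [ft_movie()].
#' @param seed_xy numeric `c(x, y)` inside frame 1 (0-based px).
#' @param params a [tracker_params()].
#' @param corrections optional `data.frame` with columns `cell_id`,
#'   `frame`, `x`, `y`, `use_center_of_mass`.
#' @param divisions optional `data.frame` with columns `cell_id`, `frame`,
#'   and daughter seed coordinates `x1`, `y1`, `x2`, `y2` (additional
#'   daughters as `x3`, `y3`, ... columns; at least two daughters).
#' @param id root lineage label (default `"C1"`).
#' @return List of `ft_track`: the seeded cell and all descendants.
#' @export
track_cell <- function(movie, seed_xy, params = tracker_params(),
                       corrections = NULL, divisions = NULL, id = "C1") {
  stopifnot(inherits(movie, "ft_movie"))
  d <- movie_dim(movie)
  if (length(dim(movie$frames)) != 3L)
    stop("tracking operates on grayscale movies", call. = FALSE)
  if (seed_xy[1L] < 0 || seed_xy[1L] >= d["W"] ||
      seed_xy[2L] < 0 || seed_xy[2L] >= d["H"])
    stop("seed outside image", call. = FALSE)
  corrections <- index_events(corrections,
                              c("cell_id", "frame", "x", "y", "use_center_of_mass"))
  divisions <- index_events(divisions, c("cell_id", "frame", "x1", "y1", "x2", "y2"))
  if (!is.null(divisions)) {
    ncoord <- grep("^x[0-9]+$", names(divisions))
    if (length(ncoord) < 2L) stop("divisions need >= 2 daughter seeds", call. = FALSE)
  }

  side <- params$detection$roi_fraction * min(d["H"], d["W"])
  gate <- if (is.null(params$gate_px)) side / 2 else params$gate_px

  done <- list()
  queue <- list(list(id = id, parent = NA_character_, birth = 1L,
                     seed = as.numeric(seed_xy)))
  while (length(queue) > 0L) {
    job <- queue[[1L]]; queue <- queue[-1L]
    tr <- new_track(job$id, job$parent, job$birth)
    img <- movie_frame(movie, job$birth)
    det <- segment_roi(img, job$seed, side, params$detection)
    hit <- step_track(job$seed, det, gate)
    pos <- if (is.null(hit)) job$seed else c(hit$x, hit$y)
    tr$positions <- matrix(pos, 1L, 2L, dimnames = list(NULL, c("x", "y")))

    my_div <- if (is.null(divisions)) NULL
              else divisions[divisions$cell_id == tr$id, , drop = FALSE]
    if (!is.null(my_div) && nrow(my_div) > 1L)
      stop("multiple divisions scripted for cell '", tr$id, "'", call. = FALSE)
    my_cor <- if (is.null(corrections)) NULL
              else corrections[corrections$cell_id == tr$id, , drop = FALSE]

    divided <- FALSE
    t <- job$birth
    repeat {
      # division closes the track at frame t
      if (!is.null(my_div) && nrow(my_div) == 1L && my_div$frame == t) {
        divided <- TRUE
        break
      }
      if (t >= d["T"]) break
      t <- t + 1L
      img <- movie_frame(movie, t)
      last <- tr$positions[nrow(tr$positions), ]
      cor_t <- if (is.null(my_cor)) NULL
               else my_cor[my_cor$frame == t, , drop = FALSE]
      if (!is.null(cor_t) && nrow(cor_t) > 0L) {
        cor_t <- cor_t[1L, ]
        pos <- c(cor_t$x, cor_t$y)
        if (isTRUE(as.logical(cor_t$use_center_of_mass))) {
          det <- segment_roi(img, pos, side, params$detection)
          hit <- step_track(pos, det, gate)
          if (!is.null(hit)) pos <- c(hit$x, hit$y)
        }
        tr$corrected_frames <- c(tr$corrected_frames, t)
      } else {
        det <- segment_roi(img, last, side, params$detection)
        hit <- step_track(last, det, gate)
        if (is.null(hit)) {  # lost: track ends at the previous frame
          tr$end_reason <- "lost"
          t <- t - 1L
          break
        }
        pos <- c(hit$x, hit$y)
      }
      tr$positions <- rbind(tr$positions, pos)
      tr$last_frame <- t
    }

    if (divided) {
      tr$end_reason <- "divided"
      tr$division_frame <- t
      if (t >= d["T"])
        stop("division on the last frame leaves no room for daughters",
             call. = FALSE)
      xs <- grep("^x[0-9]+$", names(my_div), value = TRUE)
      seeds <- lapply(xs, function(xc) {
        yc <- sub("^x", "y", xc)
        c(my_div[[xc]], my_div[[yc]])
      })
      seeds <- Filter(function(s) !any(is.na(s)), seeds)
      if (length(seeds) < 2L)
        stop("division for '", tr$id, "' needs >= 2 daughter seeds", call. = FALSE)
      for (k in seq_along(seeds)) {
        did <- paste0(tr$id, ".", k)
        tr$daughter_ids <- c(tr$daughter_ids, did)
        queue[[length(queue) + 1L]] <-
          list(id = did, parent = tr$id, birth = t + 1L, seed = seeds[[k]])
      }
    } else if (tr$end_reason != "lost") {
      tr$end_reason <- "movie_end"
    }
    if (!is.null(my_div) && nrow(my_div) == 1L && !divided)
      stop("division frame ", my_div$frame, " beyond life of '", tr$id, "'",
           call. = FALSE)
    rownames(tr$positions) <- NULL
    done[[tr$id]] <- tr
  }
  done
}

#' Assemble tracks into a lineage tree
#'
#' Validates parent/daughter links and returns a rooted forest. The
#' generation of a cell is the number of `.` separators in its id: roots
#' are G0, their daughters G1, and so on. Divisions into more than two
#' daughters are supported.
#'
#' @param tracks list of `ft_track` objects.
#' @return An object of class `ft_lineage`: list with `tracks` (named by
#'   id) and `roots` (ids of tracks without a parent).
#' @export
build_lineage <- function(tracks) {
  if (inherits(tracks, "ft_track")) tracks <- list(tracks)
  ids <- vapply(tracks, function(t) t$id, "")
  if (anyDuplicated(ids)) stop("duplicate track ids", call. = FALSE)
  names(tracks) <- ids
  for (tr in tracks) {
    if (!is.na(tr$parent_id)) {
      if (!tr$parent_id %in% ids)
        stop("orphan daughter '", tr$id, "': parent '", tr$parent_id,
             "' missing", call. = FALSE)
      expected <- sub("\\.[0-9]+$", "", tr$id)
      if (expected == tr$id || expected != tr$parent_id)
        stop("id '", tr$id, "' does not encode parent '", tr$parent_id, "'",
             call. = FALSE)
      par <- tracks[[tr$parent_id]]
      if (is.null(par$division_frame) || par$division_frame + 1L != tr$birth_frame)
        stop("birth frame of '", tr$id,
             "' does not follow parent's division", call. = FALSE)
    }
    if (!is.null(tr$division_frame) && tr$division_frame != tr$last_frame)
      stop("division frame of '", tr$id, "' is not its last frame", call. = FALSE)
    if (nrow(tr$positions) != track_length(tr))
      stop("positions of '", tr$id, "' do not cover its lifetime", call. = FALSE)
  }
  roots <- ids[vapply(tracks, function(t) is.na(t$parent_id), TRUE)]
  if (length(roots) == 0L && length(tracks) > 0L)
    stop("lineage has no root (cycle?)", call. = FALSE)
  structure(list(tracks = tracks, roots = roots), class = "ft_lineage")
}

#' Generation number of a lineage id
#' @param id lineage label such as `"C3.1.2"`.
#' @return Integer: 0 for roots (G0), 1 for their daughters (G1), ...
#' @export
generation <- function(id) {
  lengths(regmatches(id, gregexpr(".", id, fixed = TRUE)))
}

#' @export
print.ft_lineage <- function(x, ...) {
  cat(sprintf("<ft_lineage> %d track%s, %d root%s, generations G0-G%d\n",
              length(x$tracks), if (length(x$tracks) == 1L) "" else "s",
              length(x$roots), if (length(x$roots) == 1L) "" else "s",
              if (length(x$tracks)) max(generation(names(x$tracks))) else 0L))
  invisible(x)
}

#' @export
summary.ft_lineage <- function(object, ...) {
  cats <- categorize(object)
  cat("Lineage of", length(object$tracks), "tracks\n")
  for (nm in names(cats))
    cat(sprintf("  %-22s %d\n", nm, length(cats[[nm]])))
  gen <- table(generation(names(object$tracks)))
  cat("  generations:", paste(sprintf("G%s:%d", names(gen), gen), collapse = " "), "\n")
  invisible(cats)
}

#' Partition a lineage into the five trajectory categories
#'
#' The categories mirror the standard five result groups: all cells,
#' dividing cells, non-dividing cells, daughter cells, and dividing
#' daughter cells (cells born during the movie that divide themselves —
#' each one witnesses a complete cell cycle). Dividing and non-dividing
#' cells partition all cells; dividing daughters are exactly the
#' intersection of daughters and dividers.
#'
#' @param lineage a [build_lineage()] result.
#' @return Named list of character id vectors: `AllCells`,
#'   `DividingCells`, `NonDividingCells`, `DaughterCells`,
#'   `DividingDaughterCells`.
#' @export
categorize <- function(lineage) {
  stopifnot(inherits(lineage, "ft_lineage"))
  ids <- names(lineage$tracks)
  divides <- vapply(lineage$tracks, function(t) !is.null(t$division_frame), TRUE)
  daughter <- vapply(lineage$tracks, function(t) !is.na(t$parent_id), TRUE)
  list(AllCells = ids,
       DividingCells = ids[divides],
       NonDividingCells = ids[!divides],
       DaughterCells = ids[daughter],
       DividingDaughterCells = ids[divides & daughter])
}

#' Read scripted correction events
#'
#' CSV columns: `cell_id`, `frame`, `x`, `y`, `use_center_of_mass`
#' (logical or 0/1).
#' @param path CSV path.
#' @return `data.frame` suitable for [track_cell()]'s `corrections`.
#' @export
read_correction_events <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  index_events(df, c("cell_id", "frame", "x", "y", "use_center_of_mass"))
}

#' Read scripted division events
#'
#' CSV columns: `cell_id`, `frame`, then daughter seeds `x1`, `y1`, `x2`,
#' `y2` (and optionally `x3`, `y3`, ...).
#' @param path CSV path.
#' @return `data.frame` suitable for [track_cell()]'s `divisions`.
#' @export
read_division_events <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  index_events(df, c("cell_id", "frame", "x1", "y1", "x2", "y2"))
}
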