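#' Calibrated time-lapse movie
#'
#' A `ft_movie` bundles an image stack with its physical calibration. The
#' stack is stored as a numeric array of raw intensity values: `T x H x W`
#' for grayscale movies or `T x H x W x 3` for RGB-formatted FUCCI movies.
#'
#' Pixel coordinates throughout the package are 0-based with pixel centres
#' at integers: the pixel stored at matrix position `[i, j]` of a frame has
#' `y = i - 1`, `x = j - 1`. Frame indices are 1-based, so frame `t` of the
#' movie is page `t` of the originating TIFF.
#'
#' @param frames numeric array, `T x H x W` or `T x H x W x 3`, non-negative.
#' @param pixel_size_um physical pixel size in micrometres per pixel (> 0).
#' @param frame_interval_min time between consecutive frames in minutes (> 0).
#' @param bit_depth integer, 8 or 16.
#' @return An object of class `ft_movie` with elements `frames`,
#'   `pixel_size_um`, `frame_interval_min`, `bit_depth`.
#' @seealso [load_stack()], [write_stack()], [simulate_movie()]
#' @export
ft_movie <- function(frames, pixel_size_um, frame_interval_min, bit_depth = 8L) {
  if (!is.array(frames) || !(length(dim(frames)) %in% c(3L, 4L)))
    stop("`frames` must be a T x H x W or T x H x W x 3 array", call. = FALSE)
  if (length(dim(frames)) == 4L && dim(frames)[4L] != 3L)
    stop("RGB movies must have exactly 3 channels", call. = FALSE)
  if (dim(frames)[1L] < 1L) stop("movie must contain at least one frame", call. = FALSE)
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L || pixel_size_um <= 0)
    stop("`pixel_size_um` must be a single positive number", call. = FALSE)
  if (!is.numeric(frame_interval_min) || length(frame_interval_min) != 1L ||
      frame_interval_min <= 0)
    stop("`frame_interval_min` must be a single positive number", call. = FALSE)
  if (!bit_depth %in% c(8L, 16L)) stop("`bit_depth` must be 8 or 16", call. = FALSE)
  if (any(frames < 0)) stop("intensities must be non-negative", call. = FALSE)
  structure(
    list(frames = frames, pixel_size_um = pixel_size_um,
         frame_interval_min = frame_interval_min, bit_depth = as.integer(bit_depth)),
    class = "ft_movie")
}

#' @export
print.ft_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<ft_movie> %d frame%s, %d x %d px, %s, %d-bit\n",
              d[1L], if (d[1L] == 1L) "" else "s", d[3L], d[2L],
              if (length(d) == 4L) "RGB" else "grayscale", x$bit_depth))
  cat(sprintf("  calibration: %.4g um/px, %.4g min/frame\n",
              x$pixel_size_um, x$frame_interval_min))
  invisible(x)
}

#' Number of frames, height and width of a movie
#' @param movie a [ft_movie()].
#' @return Named integer vector `c(T, H, W)`.
#' @export
movie_dim <- function(movie) {
  d <- dim(movie$frames)
  c(T = d[1L], H = d[2L], W = d[3L])
}

#' Extract one frame of a movie
#' @param movie a [ft_movie()].
#' @param t 1-based frame index.
#' @return `H x W` matrix (grayscale) or `H x W x 3` array (RGB).
#' @export
movie_frame <- function(movie, t) {
  d <- dim(movie$frames)
  if (t < 1L || t > d[1L]) stop("frame index out of range", call. = FALSE)
  if (length(d) == 3L) movie$frames[t, , ] else movie$frames[t, , , ]
}

#' Load a multi-page TIFF stack as a calibrated movie
#'
#' Reads 8- or 16-bit grayscale or RGB multi-TIFF stacks. Physical
#' calibration is supplied by the caller, not parsed from TIFF metadata
#' (vendor metadata dialects vary too much to trust).
#'
#' @param path path to a multi-page TIFF file.
#' @inheritParams ft_movie
#' @return A [ft_movie()] with `T` equal to the page count.
#' @export
load_stack <- function(path, pixel_size_um, frame_interval_min) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE),
                    error = function(e) stop("cannot read TIFF '", path, "': ",
                                             conditionMessage(e), call. = FALSE))
  if (!is.list(pages)) pages <- list(pages)
  dims <- lapply(pages, dim)
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
    stop("mixed page shapes in '", path, "'", call. = FALSE)
  d <- dims[[1L]]
  rgb <- length(d) == 3L && d[3L] == 3L
  if (length(d) == 3L && !d[3L] %in% c(1L, 3L))
    stop("unsupported samples per pixel: ", d[3L], call. = FALSE)
  bits <- attr(pages[[1L]], "bits.per.sample")
  maxv <- max(vapply(pages, max, 0))
  bit_depth <- if (!is.null(bits) && bits %in% c(8L, 16L)) as.integer(bits)
               else if (maxv > 255) 16L else 8L
  # RGB pages are delivered on the [0, 1] scale; restore raw counts
  # (grayscale honours as.is and arrives as integer counts already)
  if (rgb && maxv <= 1)
    pages <- lapply(pages, function(p) round(p * (2^bit_depth - 1)))
  T <- length(pages)
  if (rgb) {
    frames <- array(0, dim = c(T, d[1L], d[2L], 3L))
    for (t in seq_len(T)) frames[t, , , ] <- pages[[t]]
  } else {
    frames <- array(0, dim = c(T, d[1L], d[2L]))
    for (t in seq_len(T)) frames[t, , ] <- if (length(d) == 3L) pages[[t]][, , 1L] else pages[[t]]
  }
  ft_movie(frames, pixel_size_um, frame_interval_min, bit_depth)
}

#' Write a movie back to a multi-page TIFF
#'
#' Pixel values are written at the movie's bit depth; the round trip
#' `write_stack()` then [load_stack()] preserves values exactly.
#'
#' @param movie a [ft_movie()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(movie, path) {
  d <- dim(movie$frames)
  scale <- 2^movie$bit_depth - 1
  pages <- lapply(seq_len(d[1L]), function(t) {
    fr <- if (length(d) == 3L) movie$frames[t, , ] else movie$frames[t, , , ]
    fr / scale
  })
  tiff::writeTIFF(pages, path, bits.per.sample = movie$bit_depth)
  invisible(path)
}

#' Read a track coordinate table
#'
#' Reads the long-format track table written by [write_results()] /
#' [write_track_table()]: columns `Cell`, `Frame`, `X_px`, `Y_px`, rows
#' grouped in one block per cell. Frames are 1-based in the file; pixel
#' coordinates are 0-based.
#'
#' @param path CSV file path.
#' @return A named list, one element per cell, each a `data.frame` with
#'   columns `frame`, `x`, `y`, frames strictly increasing and contiguous.
#' @export
read_track_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("Cell", "Frame", "X_px", "Y_px")
  if (!all(need %in% names(df)))
    stop("track table must have columns ", paste(need, collapse = ", "), call. = FALSE)
  out <- lapply(split(df, factor(df$Cell, levels = unique(df$Cell))), function(blk) {
    fr <- blk$Frame
    if (any(diff(fr) != 1L))
      stop("non-contiguous frame sequence for cell '", blk$Cell[1L], "'", call. = FALSE)
    data.frame(frame = fr, x = blk$X_px, y = blk$Y_px)
  })
  out[unique(df$Cell)]
}

#' Write tracks as a coordinate table
#'
#' @param tracks a list of `ft_track` objects or a `ft_lineage`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_track_table <- function(tracks, path) {
  df <- tracks_to_table(tracks)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# long-format coordinate table (Cell, Frame, X_px, Y_px), one block per cell
tracks_to_table <- function(tracks) {
  if (inherits(tracks, "ft_lineage")) tracks <- tracks$tracks
  if (inherits(tracks, "ft_track")) tracks <- list(tracks)
  if (length(tracks) == 0L)
    return(data.frame(Cell = character(0), Frame = integer(0),
                      X_px = numeric(0), Y_px = numeric(0)))
  blocks <- lapply(tracks, function(tr) {
    data.frame(Cell = tr$id,
               Frame = seq(tr$birth_frame, tr$last_frame),
               X_px = tr$positions[, 1L], Y_px = tr$positions[, 2L])
  })
  do.call(rbind, c(blocks, list(make.row.names = FALSE)))
}
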