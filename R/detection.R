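#' Nucleus detection parameters
#'
#' @param method `"clahe"` (CLAHE + Otsu threshold) or `"watershed"`.
#' @param min_area_px smallest accepted region, in pixels.
#' @param clahe_clip contrast-limit parameter of the adaptive histogram
#'   equalisation, as a fraction of the tile histogram (default 0.01).
#' @param h_minima depth, as a fraction of the dynamic range, below which
#'   intensity maxima are merged during the watershed flood; guards against
#'   over-segmentation (default 0.05).
#' @param roi_fraction fraction in (0, 1] of the shorter image side used as
#'   the local search window during tracking (default 0.25).
#' @return A list of class `ft_detection_params`.
#' @export
detection_params <- function(method = c("clahe", "watershed"),
                             min_area_px = 9L,
                             clahe_clip = 0.01,
                             h_minima = 0.05,
                             roi_fraction = 0.25) {
  method <- match.arg(method)
  if (min_area_px < 1L) stop("`min_area_px` must be >= 1", call. = FALSE)
  if (roi_fraction <= 0 || roi_fraction > 1)
    stop("`roi_fraction` must be in (0, 1]", call. = FALSE)
  structure(list(method = method, min_area_px = as.integer(min_area_px),
                 clahe_clip = clahe_clip, h_minima = h_minima,
                 roi_fraction = roi_fraction),
            class = "ft_detection_params")
}

# replicate-pad a matrix on the bottom/right so both dims divide k
pad_to_multiple <- function(m, k) {
  nr <- nrow(m); nc <- ncol(m)
  pr <- (k - nr %% k) %% k
  pc <- (k - nc %% k) %% k
  if (pr > 0) m <- rbind(m, m[rep(nr, pr), , drop = FALSE])
  if (pc > 0) m <- cbind(m, m[, rep(nc, pc), drop = FALSE])
  m
}

# CLAHE via EBImage, tolerant of arbitrary image sizes and tiny ROIs.
# Tiles are >= 32 px (grid capped at 8x8): smaller tiles are comparable to
# a nucleus and distort region shapes; images under 64 px (ROI crops) skip
# the adaptive step and fall through to plain Otsu thresholding.
apply_clahe <- function(norm, clahe_clip) {
  nx <- max(1L, min(8L, floor(min(dim(norm)) / 32)))
  if (nx < 2L) return(norm)
  padded <- pad_to_multiple(norm, nx)
  eq <- EBImage::clahe(padded, nx = nx, ny = nx, bins = 256L,
                       limit = max(clahe_clip * 256, 1), keep.range = TRUE)
  eq <- eq[seq_len(nrow(norm)), seq_len(ncol(norm)), drop = FALSE]
  matrix(pmin(pmax(as.numeric(eq), 0), 1), nrow(norm), ncol(norm))
}

# label matrix -> detection data.frame, dropping regions below min_area
regions_to_detections <- function(labels, raw, min_area_px) {
  labs <- as.integer(labels)
  keep <- labs > 0L
  if (!any(keep)) return(empty_detections())
  idx <- which(keep)
  lab <- labs[idx]
  ij <- arrayInd(idx, dim(labels))
  # 0-based coordinates: x = column - 1, y = row - 1
  xs <- ij[, 2L] - 1
  ys <- ij[, 1L] - 1
  vals <- raw[idx]
  area <- tabulate(lab)
  ids <- which(area >= min_area_px)
  if (length(ids) == 0L) return(empty_detections())
  det <- data.frame(
    x = vapply(ids, function(l) mean(xs[lab == l]), 0),
    y = vapply(ids, function(l) mean(ys[lab == l]), 0),
    area_px = area[ids],
    mean_intensity = vapply(ids, function(l) mean(vals[lab == l]), 0))
  det[order(det$y, det$x), , drop = FALSE]
}

empty_detections <- function() {
  data.frame(x = numeric(0), y = numeric(0), area_px = integer(0),
             mean_intensity = numeric(0))
}

# min-max normalise a frame; NULL if constant (nothing to segment)
normalize_frame <- function(img) {
  rng <- range(img)
  if (diff(rng) == 0) return(NULL)
  (img - rng[1L]) / diff(rng)
}

#' Segment nuclei by CLAHE and global thresholding
#'
#' Contrast-limited adaptive histogram equalisation separates nuclei from
#' the background; the equalised image is binarised with Otsu's threshold
#' and every above-threshold connected region of at least `min_area_px`
#' pixels is reported as one nuclear object. Positions are the unweighted
#' centre of mass of the binary region.
#'
#' @param img 2D numeric matrix of raw intensities (one movie frame or ROI
#'   crop).
#' @param params a [detection_params()].
#' @return `data.frame` with one row per detection: `x`, `y` (0-based px,
#'   fractional), `area_px`, `mean_intensity`; rows in row-major scan order
#'   (by `y`, then `x`). Empty for constant images.
#' @export
segment_clahe <- function(img, params = detection_params()) {
  stopifnot(is.matrix(img))
  norm <- normalize_frame(img)
  if (is.null(norm)) return(empty_detections())
  eq <- apply_clahe(norm, params$clahe_clip)
  thr <- EBImage::otsu(EBImage::Image(eq), range = c(0, 1))
  mask <- EBImage::Image(eq > thr)
  labels <- EBImage::bwlabel(mask)
  regions_to_detections(labels, img, params$min_area_px)
}

#' Segment nuclei by the watershed transformation
#'
#' Treats intensity as topography: bright nucleus pixels are high
#' elevations, so touching nuclei that merge into one thresholded region
#' are split along the watershed ridge lines between their intensity
#' peaks. Maxima shallower than `h_minima` (fraction of the dynamic range)
#' are merged to suppress over-segmentation.
#'
#' @inheritParams segment_clahe
#' @return As [segment_clahe()].
#' @export
segment_watershed <- function(img, params = detection_params(method = "watershed")) {
  stopifnot(is.matrix(img))
  norm <- normalize_frame(img)
  if (is.null(norm)) return(empty_detections())
  smoothed <- as.matrix(EBImage::gblur(EBImage::Image(norm), sigma = 1))
  thr <- EBImage::otsu(EBImage::Image(smoothed), range = c(0, 1))
  masked <- smoothed
  masked[smoothed <= thr] <- 0
  labels <- EBImage::watershed(EBImage::Image(masked),
                               tolerance = params$h_minima, ext = 1L)
  regions_to_detections(labels, img, params$min_area_px)
}

# dispatch on params$method
segment_frame <- function(img, params) {
  if (params$method == "watershed") segment_watershed(img, params)
  else segment_clahe(img, params)
}

#' Unweighted centre of mass of a pixel region
#'
#' All pixels of the binary region are weighted equally, matching the
#' binarised segmentation pipeline.
#'
#' @param region_pixels two-column matrix or data.frame of pixel
#'   coordinates `(x, y)`.
#' @return Numeric `c(x, y)`: the arithmetic mean of the coordinates.
#' @export
centroid <- function(region_pixels) {
  m <- as.matrix(region_pixels)
  if (nrow(m) == 0L) stop("empty region", call. = FALSE)
  c(x = mean(m[, 1L]), y = mean(m[, 2L]))
}
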