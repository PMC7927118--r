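col_letter <- function(j) {
  s <- ""
  while (j > 0L) {
    s <- paste0(LETTERS[(j - 1L) %% 26L + 1L], s)
    j <- (j - 1L) %/% 26L
  }
  s
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

sheet_xml <- function(df) {
  header <- vapply(seq_along(df), function(j)
    sprintf('<c r="%s1" t="inlineStr"><is><t>%s</t></is></c>',
            col_letter(j), xml_escape(names(df)[j])), "")
  rows <- sprintf('<row r="1">%s</row>', paste(header, collapse = ""))
  if (nrow(df) > 0L) {
    refs <- seq_len(nrow(df)) + 1L
    cols <- lapply(seq_along(df), function(j) {
      ref <- paste0(col_letter(j), refs)
      val <- df[[j]]
      cell <- if (is.numeric(val))
        sprintf('<c r="%s"><v>%s</v></c>', ref,
                formatC(val, digits = 15, format = "g"))
      else
        sprintf('<c r="%s" t="inlineStr"><is><t>%s</t></is></c>', ref,
                xml_escape(as.character(val)))
      cell[is.na(val)] <- sprintf('<c r="%s"/>', ref[is.na(val)])
      cell
    })
    body <- do.call(paste0, cols)
    rows <- c(rows, sprintf('<row r="%d">%s</row>', refs, body))
  }
  paste0('<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
         '<worksheet xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main">',
         '<sheetData>', paste(rows, collapse = ""), '</sheetData></worksheet>')
}

#' Write a minimal multi-sheet XLSX workbook
#'
#' A small OOXML writer (inline strings, no shared-string table or
#' styles) sufficient for the two-sheet result workbooks; readable by
#' standard spreadsheet tools and `readxl`.
#'
#' @param sheets named list of `data.frame`s, one per sheet.
#' @param path output `.xlsx` path.
#' @return `path`, invisibly.
#' @export
write_xlsx_sheets <- function(sheets, path) {
  stopifnot(is.list(sheets), length(sheets) >= 1L, !is.null(names(sheets)))
  tmp <- tempfile("xlsx")
  dir.create(file.path(tmp, "_rels"), recursive = TRUE)
  dir.create(file.path(tmp, "xl", "_rels"), recursive = TRUE)
  dir.create(file.path(tmp, "xl", "worksheets"), recursive = TRUE)
  n <- length(sheets)
  writeLines(paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<Types xmlns="http://schemas.openxmlformats.org/package/2006/content-types">',
    '<Default Extension="rels" ContentType="application/vnd.openxmlformats-package.relationships+xml"/>',
    '<Default Extension="xml" ContentType="application/xml"/>',
    '<Override PartName="/xl/workbook.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.sheet.main+xml"/>',
    paste(sprintf('<Override PartName="/xl/worksheets/sheet%d.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.worksheet+xml"/>',
                  seq_len(n)), collapse = ""),
    '</Types>'), file.path(tmp, "[Content_Types].xml"))
  writeLines(paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/officeDocument" Target="xl/workbook.xml"/>',
    '</Relationships>'), file.path(tmp, "_rels", ".rels"))
  writeLines(paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<workbook xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main" ',
    'xmlns:r="http://schemas.openxmlformats.org/officeDocument/2006/relationships">',
    '<sheets>',
    paste(sprintf('<sheet name="%s" sheetId="%d" r:id="rId%d"/>',
                  xml_escape(names(sheets)), seq_len(n), seq_len(n)),
          collapse = ""),
    '</sheets></workbook>'), file.path(tmp, "xl", "workbook.xml"))
  writeLines(paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    paste(sprintf('<Relationship Id="rId%d" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/worksheet" Target="worksheets/sheet%d.xml"/>',
                  seq_len(n), seq_len(n)), collapse = ""),
    '</Relationships>'), file.path(tmp, "xl", "_rels", "workbook.xml.rels"))
  for (k in seq_len(n))
    writeLines(sheet_xml(as.data.frame(sheets[[k]])),
               file.path(tmp, "xl", "worksheets", sprintf("sheet%d.xml", k)))
  if (file.exists(path)) unlink(path)
  dest <- if (grepl("^(/|[A-Za-z]:)", path)) path
          else file.path(normalizePath(dirname(path)), basename(path))
  files <- list.files(tmp, recursive = TRUE, all.files = TRUE,
                      include.dirs = FALSE)
  zip::zip(dest, files = files, root = tmp, mode = "mirror")
  unlink(tmp, recursive = TRUE)
  invisible(path)
}

#' Write the five-category result files
#'
#' One result set per trajectory category (AllCells, DividingCells,
#' NonDividingCells, DaughterCells, DividingDaughterCells), each as a
#' two-sheet XLSX workbook (sheet `Measures`: the migration measures;
#' sheet `Coordinates`: the x-y coordinates, one block per cell) plus
#' mirrored CSV pairs `<Category>_measures.csv` /
#' `<Category>_coordinates.csv`. Empty categories produce header-only
#' files.
#'
#' @param lineage a [build_lineage()] result.
#' @param measures per-cell measures from [lineage_measures()].
#' @param out_dir output directory (created if missing).
#' @param xlsx also write the XLSX workbooks (default `TRUE`).
#' @return Character vector of written paths, invisibly.
#' @export
write_results <- function(lineage, measures, out_dir, xlsx = TRUE) {
  stopifnot(inherits(lineage, "ft_lineage"))
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  cats <- categorize(lineage)
  empty_coords <- data.frame(Cell = character(0), Frame = integer(0),
                             X_px = numeric(0), Y_px = numeric(0))
  written <- character(0)
  for (nm in names(cats)) {
    ids <- cats[[nm]]
    m <- measures[measures$cell_id %in% ids, , drop = FALSE]
    coords <- if (length(ids)) tracks_to_table(lineage$tracks[ids]) else empty_coords
    f1 <- file.path(out_dir, paste0(nm, "_measures.csv"))
    f2 <- file.path(out_dir, paste0(nm, "_coordinates.csv"))
    utils::write.csv(m, f1, row.names = FALSE)
    utils::write.csv(coords, f2, row.names = FALSE)
    written <- c(written, f1, f2)
    if (xlsx) {
      fx <- file.path(out_dir, paste0(nm, ".xlsx"))
      write_xlsx_sheets(list(Measures = m, Coordinates = coords), fx)
      written <- c(written, fx)
    }
  }
  invisible(written)
}

#' Export a lineage tree with edge times
#'
#' Hierarchical export of one root and its descendants: vertices are
#' cells (dividing daughter cells flagged), edges carry the daughter's
#' time from birth to its own division or track end in hours (arrow
#' length in the tree plots).
#'
#' @param lineage a [build_lineage()] result.
#' @param root_id id of the root to export.
#' @param frame_interval_min minutes per frame.
#' @param json_path optional path; when given the tree is also written
#'   as JSON.
#' @return Nested list: `id`, `generation`, `divides`,
#'   `dividing_daughter`, `lifetime_h`, `children` (list).
#' @export
export_lineage_tree <- function(lineage, root_id, frame_interval_min,
                                json_path = NULL) {
  stopifnot(inherits(lineage, "ft_lineage"))
  if (!root_id %in% names(lineage$tracks))
    stop("unknown root '", root_id, "'", call. = FALSE)
  build <- function(id) {
    tr <- lineage$tracks[[id]]
    divides <- !is.null(tr$division_frame)
    list(id = id,
         generation = unname(generation(id)),
         divides = divides,
         dividing_daughter = divides && !is.na(tr$parent_id),
         lifetime_h = (tr$last_frame - tr$birth_frame) *
           frame_interval_min / 60,
         children = lapply(tr$daughter_ids, build))
  }
  tree <- build(root_id)
  if (!is.null(json_path))
    writeLines(jsonlite::toJSON(tree, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE), json_path)
  tree
}

#' Plot a lineage tree
#'
#' Vertices are cells, horizontal position is time; a vertical tick
#' marks each division. Dividing daughter cells are drawn in blue.
#'
#' @param x a `ft_lineage`.
#' @param frame_interval_min minutes per frame.
#' @param root_id optional root to restrict the plot to.
#' @param ... passed to [graphics::plot()].
#' @return The plotted layout (`data.frame`), invisibly.
#' @export
plot.ft_lineage <- function(x, frame_interval_min = 10, root_id = NULL, ...) {
  tracks <- x$tracks
  if (!is.null(root_id)) {
    keep <- names(tracks)[startsWith(names(tracks), root_id)]
    tracks <- tracks[keep]
  }
  if (length(tracks) == 0L) stop("nothing to plot", call. = FALSE)
  leaves <- names(tracks)[vapply(tracks, function(t)
    length(t$daughter_ids) == 0L, TRUE)]
  ypos <- stats::setNames(rep(NA_real_, length(tracks)), names(tracks))
  ypos[leaves] <- seq_along(leaves)
  repeat {
    todo <- names(ypos)[is.na(ypos)]
    if (length(todo) == 0L) break
    for (id in todo) {
      ch <- tracks[[id]]$daughter_ids
      if (all(!is.na(ypos[ch]))) ypos[id] <- mean(ypos[ch])
    }
  }
  dt_h <- frame_interval_min / 60
  dd <- categorize(x)$DividingDaughterCells
  lay <- data.frame(id = names(tracks),
                    t0 = vapply(tracks, function(t) t$birth_frame, 0) * dt_h,
                    t1 = vapply(tracks, function(t) t$last_frame, 0) * dt_h,
                    y = ypos[names(tracks)])
  graphics::plot(NA, xlim = range(lay$t0, lay$t1), ylim = range(lay$y) + c(-0.5, 0.5),
                 xlab = "time (h)", ylab = "", yaxt = "n", ...)
  for (i in seq_len(nrow(lay))) {
    id <- lay$id[i]
    col <- if (id %in% dd) "blue3" else "black"
    graphics::segments(lay$t0[i], lay$y[i], lay$t1[i], lay$y[i], col = col, lwd = 2)
    ch <- tracks[[id]]$daughter_ids
    if (length(ch))
      graphics::segments(lay$t1[i], min(ypos[ch]), lay$t1[i], max(ypos[ch]),
                         col = "grey40")
    graphics::text(lay$t1[i], lay$y[i], id, pos = 4, cex = 0.6, col = col)
  }
  invisible(lay)
}
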