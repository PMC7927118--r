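test_that("step_track links to the minimum-distance detection inside the gate", {
  det <- data.frame(x = c(12, 20), y = c(10, 10), area_px = 20,
                    mean_intensity = 100)
  hit <- step_track(c(10, 10), det, gate_px = 25)
  expect_equal(c(hit$x, hit$y), c(12, 10))

  # nearest detection beyond the gate: no link
  far <- data.frame(x = 60, y = 10, area_px = 20, mean_intensity = 100)
  expect_null(step_track(c(10, 10), far, gate_px = 25))
  expect_null(step_track(c(10, 10), det[0, ], gate_px = 25))

  # equidistant detections resolve in scan order (smallest y, then x)
  tie <- data.frame(x = c(12, 8), y = c(10, 10), area_px = 20,
                    mean_intensity = 100)
  hit <- step_track(c(10, 10), tie, gate_px = 25)
  expect_equal(hit$x, 8)
  tie2 <- data.frame(x = c(10, 10), y = c(12, 8), area_px = 20,
                     mean_intensity = 100)
  expect_equal(step_track(c(10, 10), tie2, gate_px = 25)$y, 8)
})

test_that("a moving nucleus is tracked within 1 px per frame", {
  gt <- cbind(20 + 2 * (0:19), rep(48, 20))  # 2 px/frame for 20 frames
  movie <- render_movie(list(gt), T = 20, H = 96, W = 96)
  tracks <- track_cell(movie, gt[1, ], tracker_params())
  expect_length(tracks, 1L)
  tr <- tracks[[1]]
  expect_equal(tr$end_reason, "movie_end")
  expect_equal(track_length(tr), 20L)
  err <- sqrt(rowSums((tr$positions - gt)^2))
  expect_lt(max(err), 1)
})

test_that("corrections override positions and are recorded", {
  gt <- cbind(20 + 2 * (0:19), rep(48, 20))
  movie <- render_movie(list(gt), T = 20, H = 96, W = 96)
  corr <- data.frame(cell_id = "C1", frame = 10, x = 33.5, y = 50.25,
                     use_center_of_mass = FALSE)
  tr <- track_cell(movie, gt[1, ], tracker_params(), corrections = corr)[[1]]
  expect_identical(unname(tr$positions[10, ]), c(33.5, 50.25))  # exact point
  expect_equal(tr$corrected_frames, 10L)
  expect_equal(correction_rate(tr), 1 / 20)

  # with use_center_of_mass the point snaps to the detected centroid
  corr$use_center_of_mass <- TRUE
  tr2 <- track_cell(movie, gt[1, ], tracker_params(), corrections = corr)[[1]]
  expect_lt(sqrt(sum((tr2$positions[10, ] - gt[10, ])^2)), 1)
})

test_that("scripted divisions close the parent and seed daughters", {
  par_gt <- cbind(30 + 1.5 * (0:14), rep(40, 15))          # frames 1..15
  d1_gt <- cbind(par_gt[15, 1] + 1.5 * (1:10), 30 - (0:9)) # frames 16..25
  d2_gt <- cbind(par_gt[15, 1] + 1.5 * (1:10), 50 + (0:9))
  full1 <- rbind(par_gt, d1_gt)
  full2 <- rbind(par_gt[rep(1, 15), ] * NA, d2_gt)
  movie <- render_movie(list(full1, full2), T = 25, H = 96, W = 96)
  div <- data.frame(cell_id = "C1", frame = 15,
                    x1 = d1_gt[1, 1], y1 = d1_gt[1, 2],
                    x2 = d2_gt[1, 1], y2 = d2_gt[1, 2])
  tracks <- track_cell(movie, par_gt[1, ], tracker_params(), divisions = div)
  expect_setequal(names(tracks), c("C1", "C1.1", "C1.2"))
  expect_equal(tracks[["C1"]]$end_reason, "divided")
  expect_equal(tracks[["C1"]]$division_frame, 15L)
  expect_equal(tracks[["C1"]]$last_frame, 15L)
  expect_equal(tracks[["C1.1"]]$birth_frame, 16L)
  expect_equal(tracks[["C1.2"]]$birth_frame, 16L)
  expect_equal(tracks[["C1"]]$daughter_ids, c("C1.1", "C1.2"))
  # daughters follow their own nuclei
  expect_lt(max(abs(tracks[["C1.1"]]$positions[, 2] - d1_gt[, 2])), 1)
  expect_lt(max(abs(tracks[["C1.2"]]$positions[, 2] - d2_gt[, 2])), 1)
})

test_that("invalid seeds and impossible divisions are rejected", {
  movie <- render_movie(list(cbind(rep(20, 5), rep(20, 5))), T = 5, H = 64, W = 64)
  expect_error(track_cell(movie, c(-3, 10)), "seed")
  expect_error(track_cell(movie, c(20, 200)), "seed")
  div <- data.frame(cell_id = "C1", frame = 50, x1 = 1, y1 = 1, x2 = 2, y2 = 2)
  expect_error(track_cell(movie, c(20, 20), divisions = div), "beyond life")
})

test_that("lineages assemble with generation numbering", {
  fam <- make_family()
  lin <- build_lineage(fam)
  expect_s3_class(lin, "ft_lineage")
  expect_equal(lin$roots, "C1")
  gens <- generation(names(lin$tracks))
  expect_equal(sum(gens == 0), 1L)
  expect_equal(sum(gens == 1), 2L)

  # two generations of dividers: G0:1, G1:2, G2:4
  g0 <- line_track(10, id = "C1", divides = TRUE, daughter_ids = c("C1.1", "C1.2"))
  g1 <- lapply(1:2, function(j)
    line_track(10, id = paste0("C1.", j), parent_id = "C1", birth_frame = 11L,
               divides = TRUE,
               daughter_ids = paste0("C1.", j, ".", 1:2)))
  g2 <- unlist(lapply(1:2, function(j) lapply(1:2, function(k)
    line_track(5, id = paste0("C1.", j, ".", k), parent_id = paste0("C1.", j),
               birth_frame = 21L))), recursive = FALSE)
  lin2 <- build_lineage(c(list(g0), g1, g2))
  expect_equal(as.vector(table(generation(names(lin2$tracks)))), c(1L, 2L, 4L))
})

test_that("multi-daughter divisions are supported", {
  par <- line_track(10, id = "C1", divides = TRUE,
                    daughter_ids = paste0("C1.", 1:3))
  ds <- lapply(1:3, function(j)
    line_track(8, id = paste0("C1.", j), parent_id = "C1", birth_frame = 11L))
  lin <- build_lineage(c(list(par), ds))
  gens <- generation(names(lin$tracks))
  expect_equal(sum(gens == 1), 3L)
})

test_that("inconsistent lineages are rejected", {
  orphan <- line_track(5, id = "C1.1", parent_id = "C1", birth_frame = 11L)
  expect_error(build_lineage(list(orphan)), "orphan")
  # daughter birth frame must follow the parent's division
  par <- line_track(10, id = "C1", divides = TRUE, daughter_ids = "C1.1")
  bad <- line_track(5, id = "C1.1", parent_id = "C1", birth_frame = 13L)
  expect_error(build_lineage(list(par, bad)), "division")
})

test_that("the five-category partition matches its definitions", {
  # one divider, two non-dividing daughters
  lin <- build_lineage(make_family())
  cats <- categorize(lin)
  expect_length(cats$AllCells, 3L)
  expect_equal(cats$DividingCells, "C1")
  expect_setequal(cats$NonDividingCells, c("C1.1", "C1.2"))
  expect_setequal(cats$DaughterCells, c("C1.1", "C1.2"))
  expect_length(cats$DividingDaughterCells, 0L)

  # both daughters divide: 7 cells, 2 dividing daughters
  fam <- make_family(daughters_divide = c(TRUE, TRUE))
  fam[[2]]$daughter_ids <- paste0("C1.1.", 1:2)
  fam[[3]]$daughter_ids <- paste0("C1.2.", 1:2)
  gkids <- unlist(lapply(1:2, function(j) lapply(1:2, function(k)
    line_track(5, id = paste0("C1.", j, ".", k), parent_id = paste0("C1.", j),
               birth_frame = fam[[j + 1]]$last_frame + 1L))),
    recursive = FALSE)
  cats2 <- categorize(build_lineage(c(fam, gkids)))
  expect_length(cats2$AllCells, 7L)
  expect_setequal(cats2$DividingDaughterCells, c("C1.1", "C1.2"))

  # single non-dividing cell
  cats3 <- categorize(build_lineage(list(line_track(5))))
  expect_equal(lengths(cats3)[["AllCells"]], 1L)
  expect_equal(lengths(cats3)[["NonDividingCells"]], 1L)
  expect_equal(sum(lengths(cats3)[c("DividingCells", "DaughterCells",
                                    "DividingDaughterCells")]), 0L)
})

test_that("event tables read from CSV", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(cell_id = "C1", frame = 4, x = 1, y = 2,
                       use_center_of_mass = TRUE), path, row.names = FALSE)
  ev <- read_correction_events(path)
  expect_equal(ev$frame, 4)
  write.csv(data.frame(cell_id = "C1", frame = 4, x1 = 1, y1 = 2, x2 = 3,
                       y2 = 4), path, row.names = FALSE)
  dv <- read_division_events(path)
  expect_equal(dv$x2, 3)
})
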