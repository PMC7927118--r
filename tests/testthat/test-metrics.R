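test_that("trajectory measures follow the defining arithmetic", {
  # straight path: 10 steps of 5 px at 1 um/px, 10 min/frame
  tr <- line_track(11, dx = 5)
  m <- trajectory_measures(tr, 1, 10)
  expect_equal(m$total_distance_um, 50)
  expect_equal(m$displacement_um, 50)
  expect_equal(m$directionality, 1)
  expect_equal(m$trajectory_time_h, 10 * 10 / 60)
  expect_equal(m$avg_speed_um_h, 30)

  # closed square loop: displacement 0, directionality 0
  sq <- make_track(rbind(c(0, 0), c(4, 0), c(4, 4), c(0, 4), c(0, 0)))
  ms <- trajectory_measures(sq, 1, 10)
  expect_equal(ms$displacement_um, 0)
  expect_equal(ms$directionality, 0)

  # 3-4-5 dogleg: D = 10, L = 6
  dog <- make_track(rbind(c(0, 0), c(3, 4), c(6, 0)))
  md <- trajectory_measures(dog, 1, 10)
  expect_equal(md$total_distance_um, 10)
  expect_equal(md$displacement_um, 6)
  expect_equal(md$directionality, 0.6)

  expect_error(trajectory_measures(make_track(cbind(1, 1)), 1, 10), "2 frames")
  # stationary cell: directionality undefined
  expect_true(is.na(trajectory_measures(make_track(cbind(c(2, 2), c(3, 3))),
                                        1, 10)$directionality))
})

test_that("instantaneous speeds convert steps to um/h", {
  tr <- line_track(7, dx = 1)
  expect_equal(instantaneous_speeds(tr, 1, 10), rep(6, 6))
  still <- make_track(cbind(rep(4, 5), rep(4, 5)))
  expect_equal(instantaneous_speeds(still, 1, 10), rep(0, 4))
  one <- make_track(rbind(c(0, 0), c(3, 4)))
  expect_equal(instantaneous_speeds(one, 0.65, 10), 19.5)
  expect_error(instantaneous_speeds(make_track(cbind(1, 1)), 1, 10), "2 frames")
})

test_that("doubling times are the lifetimes of dividing daughter cells", {
  par <- line_track(30, id = "C1", divides = TRUE, daughter_ids = c("C1.1", "C1.2"))
  d1 <- line_track(187, id = "C1.1", parent_id = "C1", birth_frame = 31L,
                   divides = TRUE, daughter_ids = c("C1.1.1", "C1.1.2"))
  gk <- lapply(1:2, function(k) line_track(5, id = paste0("C1.1.", k),
                                           parent_id = "C1.1", birth_frame = 218L))
  d2 <- line_track(50, id = "C1.2", parent_id = "C1", birth_frame = 31L)
  lin <- build_lineage(c(list(par, d1, d2), gk))
  dt <- doubling_times(lin, 10)
  # born frame 31, divides frame 217: 186 intervals of 10 min = 31 h
  expect_equal(dt$cell_id, "C1.1")
  expect_equal(dt$hours, 31)

  # lineage without dividing daughters: empty result
  empty <- doubling_times(build_lineage(list(line_track(10))), 10)
  expect_equal(nrow(empty), 0L)
})

test_that("doubling times recover a simulated cycle-length distribution", {
  p <- simulation_params(n_cells = 25, n_frames = 300, width = 640, height = 640,
                         cycle_mean_h = 24, cycle_sd_h = 3)
  sim <- simulate_lineage(p, seed = 31)
  dt <- doubling_times(sim$lineage, p$frame_interval_min)
  expect_gt(nrow(dt), 30)
  expect_lt(abs(mean(dt$hours) - 24), 2)
})

test_that("daughter-pair heterogeneity applies the selection filter", {
  fam <- make_family(parent_frames = 10, daughter_frames = c(80, 80))
  lin <- build_lineage(fam)
  meas <- lineage_measures(lin, 1, 10)
  # make the daughters differ in speed: scale one daughter's step
  meas$avg_speed_um_h[meas$cell_id == "C1.1"] <- 10
  meas$avg_speed_um_h[meas$cell_id == "C1.2"] <- 12
  pd <- daughter_pair_differences(lin, meas)
  expect_equal(nrow(pd), 1L)
  expect_equal(pd$d_avg_speed_um_h, 2)

  # identical twins: all differences zero
  pd0 <- daughter_pair_differences(lin, lineage_measures(lin, 1, 10))
  expect_equal(pd0$d_total_distance_um, 0)
  expect_equal(pd0$d_directionality, 0)

  # trajectory times 12 h vs 4 h fail the 3 h pairing filter
  fam2 <- make_family(parent_frames = 10, daughter_frames = c(73, 25))
  pd2 <- daughter_pair_differences(build_lineage(fam2),
                                   lineage_measures(build_lineage(fam2), 1, 10))
  expect_equal(nrow(pd2), 0L)

  # multi-daughter divisions contribute all sibling pairs
  par <- line_track(10, id = "C1", divides = TRUE,
                    daughter_ids = paste0("C1.", 1:3))
  ds <- lapply(1:3, function(j) line_track(80, id = paste0("C1.", j),
                                           parent_id = "C1", birth_frame = 11L))
  lin3 <- build_lineage(c(list(par), ds))
  pd3 <- daughter_pair_differences(lin3, lineage_measures(lin3, 1, 10))
  expect_equal(nrow(pd3), 3L)
})

test_that("division synchrony compares pairs where both daughters divide", {
  par <- line_track(10, id = "C1", divides = TRUE, daughter_ids = c("C1.1", "C1.2"))
  d1 <- line_track(90, id = "C1.1", parent_id = "C1", birth_frame = 11L,
                   divides = TRUE, daughter_ids = c("C1.1.1", "C1.1.2"))
  d2 <- line_track(102, id = "C1.2", parent_id = "C1", birth_frame = 11L,
                   divides = TRUE, daughter_ids = c("C1.2.1", "C1.2.2"))
  leaves <- c(lapply(1:2, function(k) line_track(3, id = paste0("C1.1.", k),
                                                 parent_id = "C1.1", birth_frame = 101L)),
              lapply(1:2, function(k) line_track(3, id = paste0("C1.2.", k),
                                                 parent_id = "C1.2", birth_frame = 113L)))
  lin <- build_lineage(c(list(par, d1, d2), leaves))
  sy <- division_synchrony(lin, 10)
  # divisions at frames 100 and 112: 12 intervals = 2 h
  expect_equal(sy$dt_division_h[sy$id_a == "C1.1"], 2)

  # only one daughter divides: pair excluded
  fam <- make_family(daughters_divide = c(TRUE, FALSE))
  fam[[2]]$daughter_ids <- paste0("C1.1.", 1:2)
  gk <- lapply(1:2, function(k) line_track(3, id = paste0("C1.1.", k),
                                           parent_id = "C1.1",
                                           birth_frame = fam[[2]]$last_frame + 1L))
  sy2 <- division_synchrony(build_lineage(c(fam, gk)), 10)
  expect_equal(nrow(sy2), 0L)
})

test_that("phase durations count frames and conserve total time", {
  lab <- c(rep("G1", 22), rep("S", 59), rep("G2M", 19))
  pd <- phase_durations(lab, 10)
  expect_equal(pd$fraction, c(0.22, 0.59, 0.19))
  expect_equal(sum(pd$duration_h) + attr(pd, "unknown_h"), 100 * 10 / 60)

  expect_equal(phase_durations(rep("S", 30), 20)$duration_h[2], 10)
  expect_equal(phase_durations(rep("S", 10), 10)$fraction[2], 1)
  expect_error(phase_durations(rep("Unknown", 5), 10), "Unknown")
})

test_that("per-phase dynamics attribute steps to the starting frame's phase", {
  tr <- line_track(13, dx = 1)           # constant 6 um/h at 1 um/px, 10 min
  lab <- c(rep("G1", 4), rep("S", 5), rep("G2M", 4))
  dyn <- per_phase_dynamics(tr, lab, 1, 10)
  expect_equal(dyn$mean_speed_um_h, rep(6, 3))
  expect_equal(dyn$directionality, rep(1, 3))  # straight line in every phase

  # speed 5 um/h in S, 15 in G2M (steps of 5/6 and 15/6 px at 10 min, 1 um/px)
  xs <- cumsum(c(0, rep(5 / 6, 6), rep(15 / 6, 6)))
  tr2 <- make_track(cbind(xs, 0))
  # steps 1-6 (speed 5) start in S frames, steps 7-12 (speed 15) in G2M
  lab2 <- c(rep("S", 6), rep("G2M", 7))
  dyn2 <- per_phase_dynamics(tr2, lab2, 1, 10)
  expect_equal(dyn2$mean_speed_um_h[dyn2$phase == "S"], 5)
  expect_equal(dyn2$mean_speed_um_h[dyn2$phase == "G2M"], 15)
  expect_true(is.na(dyn2$mean_speed_um_h[dyn2$phase == "G1"]))
  expect_error(per_phase_dynamics(tr2, lab2[-1], 1, 10), "align")
})

test_that("terminal speed jumps follow the fold criteria", {
  # 10 min frames: baseline window = 12 steps. Eleven steps of 8 um/h and
  # one of 30 inside the last hour: mean 9.83, 2.5x = 24.6 <= 30 and
  # 3 x 8 = 24 <= 30 -> jump
  step8 <- 8 / 6  # px per frame giving 8 um/h at 1 um/px
  sp <- rep(8, 12); sp[9] <- 30
  xs <- cumsum(c(0, sp / 6))
  tr <- make_track(cbind(xs, 0), divides = TRUE)
  res <- detect_terminal_speed_jump(tr, rep("G2M", 13), 1, 10)
  expect_true(res$jump)
  expect_equal(res$jump_steps, 9L)
  expect_equal(res$baseline_mean_um_h, mean(sp))

  # constant speed: never a jump
  const <- make_track(cbind(cumsum(rep(step8, 14)), rep(0, 14)), divides = TRUE)
  expect_false(detect_terminal_speed_jump(const, rep("G2M", 14), 1, 10)$jump)

  # spike of 20 fails the 2.5x baseline test (2.5 x 9 = 22.5 > 20)
  sp2 <- rep(8, 12); sp2[9] <- 20
  tr2 <- make_track(cbind(cumsum(c(0, sp2 / 6)), 0), divides = TRUE)
  expect_false(detect_terminal_speed_jump(tr2, rep("G2M", 13), 1, 10)$jump)

  # a spike outside G2M does not count
  lab3 <- c(rep("S", 9), rep("G2M", 4))  # step 9 starts in S
  expect_false(detect_terminal_speed_jump(tr, lab3, 1, 10)$jump)

  expect_error(detect_terminal_speed_jump(line_track(13), rep("G2M", 13), 1, 10),
               "division")
  short <- make_track(cbind(0:5, rep(0, 6)), divides = TRUE)
  expect_error(detect_terminal_speed_jump(short, rep("G2M", 6), 1, 10),
               "baseline")
})

test_that("measure identities hold on random trajectories", {
  set.seed(123)
  for (rep in 1:200) {
    n <- sample(5:60, 1)
    pos <- cbind(cumsum(rnorm(n)), cumsum(rnorm(n)))
    tr <- make_track(pos)
    m <- trajectory_measures(tr, 0.65, 10)
    expect_lte(m$displacement_um, m$total_distance_um + 1e-12)
    expect_gte(m$directionality, 0)
    expect_lte(m$directionality, 1)
    v <- instantaneous_speeds(tr, 0.65, 10)
    # mean speed x time = total distance
    expect_equal(mean(v) * m$trajectory_time_h, m$total_distance_um,
                 tolerance = 1e-9)
  }
  # directionality 1 only for monotone collinear paths
  mono <- line_track(10, dx = 2, dy = 1)
  expect_equal(trajectory_measures(mono, 1, 10)$directionality, 1)
})
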