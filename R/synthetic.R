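#' Parameters of the synthetic movie generator
#'
#' Defaults emulate the RPE (PIP-FUCCI) imaging conditions: 0.65 um/px,
#' 10 min frame interval, mean migration speed 9.3 um/h with moderate
#' persistence, cycle length 21.5 +/- 4.8 h, and phase fractions
#' G1/S/G2M = 0.22/0.59/0.19.
#'
#' @param n_cells number of founder cells seeded on frame 1.
#' @param width,height image size in pixels.
#' @param sigma_px Gaussian radius of the rendered nuclei.
#' @param peak_intensity blob peak in intensity units.
#' @param noise_sd additive Gaussian pixel noise (intensity units).
#' @param mean_speed_um_h mean migration speed.
#' @param speed_sd_frac per-step speed variability as a fraction of the
#'   mean step.
#' @param persistence directional persistence in \[0, 1): 0 is an
#'   uncorrelated random walk, values near 1 nearly straight motion.
#' @param pixel_size_um,frame_interval_min physical calibration.
#' @param n_frames movie length in frames.
#' @param cycle_mean_h,cycle_sd_h per-cell cycle length distribution
#'   (normal, truncated positive).
#' @param phase_fractions named fractions `c(G1=, S=, G2M=)` summing to 1.
#' @param fucci_mode `"none"` (grayscale), `"two_channel"`
#'   (Cdt1-red/Geminin-green) or `"three_channel"`
#'   (PCNA-red/Geminin-green/PIP-blue).
#' @param dividing if `FALSE`, cells never divide.
#' @param initial_age_fraction founder age at frame 1 as a fraction of
#'   the cycle; `NULL` (default) draws it uniformly, `0` starts all
#'   founders at the beginning of G1.
#' @param jump_injection `NULL`, or `list(prob = )`: each dividing cell
#'   of sufficient length receives, with this probability, an injected
#'   terminal speed jump guaranteed to satisfy [jump_criterion()].
#' @param bit_depth 8 or 16.
#' @return List of class `ft_sim_params`.
#' @export
simulation_params <- function(n_cells = 10L, width = 512L, height = 512L,
                              sigma_px = 3, peak_intensity = 180,
                              noise_sd = 3, mean_speed_um_h = 9.3,
                              speed_sd_frac = 0.2, persistence = 0.5,
                              pixel_size_um = 0.65, frame_interval_min = 10,
                              n_frames = 100L, cycle_mean_h = 21.5,
                              cycle_sd_h = 4.8,
                              phase_fractions = c(G1 = 0.22, S = 0.59, G2M = 0.19),
                              fucci_mode = c("none", "two_channel", "three_channel"),
                              dividing = TRUE, initial_age_fraction = NULL,
                              jump_injection = NULL, bit_depth = 8L) {
  fucci_mode <- match.arg(fucci_mode)
  if (abs(sum(phase_fractions) - 1) > 1e-9)
    stop("`phase_fractions` must sum to 1", call. = FALSE)
  if (sigma_px <= 0) stop("`sigma_px` must be > 0", call. = FALSE)
  if (persistence < 0 || persistence >= 1)
    stop("`persistence` must lie in [0, 1)", call. = FALSE)
  structure(list(n_cells = as.integer(n_cells), width = as.integer(width),
                 height = as.integer(height), sigma_px = sigma_px,
                 peak_intensity = peak_intensity, noise_sd = noise_sd,
                 mean_speed_um_h = mean_speed_um_h,
                 speed_sd_frac = speed_sd_frac, persistence = persistence,
                 pixel_size_um = pixel_size_um,
                 frame_interval_min = frame_interval_min,
                 n_frames = as.integer(n_frames), cycle_mean_h = cycle_mean_h,
                 cycle_sd_h = cycle_sd_h, phase_fractions = phase_fractions,
                 fucci_mode = fucci_mode, dividing = isTRUE(dividing),
                 initial_age_fraction = initial_age_fraction,
                 jump_injection = jump_injection,
                 bit_depth = as.integer(bit_depth)),
            class = "ft_sim_params")
}

# run `expr` under set.seed(seed), restoring the caller's RNG state
with_sim_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

rtrunc_norm_pos <- function(mean, sd, lower) {
  repeat {
    x <- stats::rnorm(1L, mean, sd)
    if (x > lower) return(x)
  }
}

# founder positions with pairwise separation >= minsep; warning flag when
# the density forces acceptance without the guarantee
place_founders <- function(n, width, height, margin, minsep) {
  pos <- matrix(NA_real_, n, 2L)
  warn <- FALSE
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(200L)) {
      p <- c(stats::runif(1L, margin, width - 1 - margin),
             stats::runif(1L, margin, height - 1 - margin))
      if (i == 1L ||
          min(sqrt(rowSums(sweep(pos[seq_len(i - 1L), , drop = FALSE], 2L, p)^2))) >= minsep) {
        pos[i, ] <- p; ok <- TRUE; break
      }
    }
    if (!ok) {
      warn <- TRUE
      pos[i, ] <- c(stats::runif(1L, margin, width - 1 - margin),
                    stats::runif(1L, margin, height - 1 - margin))
    }
  }
  list(pos = pos, warn = warn)
}

phase_from_age <- function(age_h, cycle_h, fractions) {
  frac <- min(age_h / cycle_h, 1 - 1e-12)
  cum <- unname(cumsum(fractions))
  if (frac < cum[1L]) {
    list(phase = "G1", u = frac / fractions[[1L]])
  } else if (frac < cum[2L]) {
    list(phase = "S", u = (frac - cum[1L]) / fractions[[2L]])
  } else {
    list(phase = "G2M", u = min((frac - cum[2L]) / fractions[[3L]], 1))
  }
}

reflect_into <- function(p, lo, hi) {
  for (k in 1:2) {
    while (p[k] < lo[k] || p[k] > hi[k]) {
      if (p[k] < lo[k]) p[k] <- 2 * lo[k] - p[k]
      if (p[k] > hi[k]) p[k] <- 2 * hi[k] - p[k]
    }
  }
  p
}

# make step `t` of `positions` fast enough to satisfy the jump criterion,
# shifting all later positions so other step vectors are unchanged
inject_jump <- function(positions, t, k_base, dt_h, pixel_size_um, crit) {
  v_len <- function(i) sqrt(sum((positions[i + 1L, ] - positions[i, ])^2))
  ns <- nrow(positions) - 1L
  base_idx <- (ns - k_base + 1L):ns
  S_rest <- sum(vapply(setdiff(base_idx, t), v_len, 0)) * pixel_size_um / dt_h
  nb <- c(if (t > 1L) v_len(t - 1L), if (t < ns) v_len(t + 1L)) *
    pixel_size_um / dt_h
  need <- max(crit$baseline_fold * S_rest / (k_base - crit$baseline_fold),
              if (length(nb)) crit$neighbor_fold * max(nb) else 0,
              1e-3)
  v_new <- 1.25 * need                      # um/h, strictly above both bounds
  L_px <- v_new * dt_h / pixel_size_um
  old_step <- positions[t + 1L, ] - positions[t, ]
  len <- sqrt(sum(old_step^2))
  dir <- if (len > 0) old_step / len else c(1, 0)
  delta <- dir * L_px - old_step
  idx <- (t + 1L):nrow(positions)
  positions[idx, ] <- sweep(positions[idx, , drop = FALSE], 2L, -delta)
  positions
}

#' Simulate a lineage of moving, dividing cells (no rendering)
#'
#' Generates ground-truth trajectories, divisions and phase labels under
#' a persistent-random-walk motion model and a truncated-normal cycle
#' model, without rendering pixels. [simulate_movie()] renders the same
#' ground truth into an image stack.
#'
#' @param params a [simulation_params()].
#' @param seed integer seed; the full output is a deterministic function
#'   of `params` and `seed`.
#' @return List of class `ft_simulation`: `lineage` (a `ft_lineage` of
#'   ground-truth tracks), `phases` (`cell_id`, `frame`, `phase`, `u` =
#'   position within the phase), `divisions` (scripted-division table
#'   usable by [track_cell()]), `jumps` (`cell_id`, `step`, `frame` of
#'   injected terminal speed jumps), `crowding_warning`, `params`.
#' @export
simulate_lineage <- function(params = simulation_params(), seed = 1L) {
  stopifnot(inherits(params, "ft_sim_params"))
  with_sim_seed(seed, {
    dt_h <- params$frame_interval_min / 60
    step_px <- params$mean_speed_um_h * dt_h / params$pixel_size_um
    margin <- 4 * params$sigma_px
    lo <- c(margin, margin)
    hi <- c(params$width - 1 - margin, params$height - 1 - margin)
    founders <- place_founders(params$n_cells, params$width, params$height,
                               margin, 4 * params$sigma_px)
    crit <- jump_criterion()
    k_base <- round(crit$baseline_window_h / dt_h)
    k_jump <- round(crit$jump_window_h / dt_h)

    tracks <- list()
    phases <- list()
    divisions <- list()
    jumps <- list()

    queue <- lapply(seq_len(params$n_cells), function(i) {
      cycle <- rtrunc_norm_pos(params$cycle_mean_h, params$cycle_sd_h,
                               max(2 * dt_h, 1))
      age0 <- if (is.null(params$initial_age_fraction))
        stats::runif(1L, 0, 0.95) * cycle
      else params$initial_age_fraction * cycle
      list(id = paste0("C", i), parent = NA_character_, birth = 1L,
           pos = founders$pos[i, ], age = age0, cycle = cycle,
           heading = stats::runif(1L, -pi, pi))
    })

    while (length(queue) > 0L) {
      job <- queue[[1L]]; queue <- queue[-1L]
      tr <- new_track(job$id, job$parent, job$birth)
      pos <- matrix(job$pos, 1L, 2L, dimnames = list(NULL, c("x", "y")))
      age <- job$age
      heading <- job$heading
      lab <- character(0); uu <- numeric(0)
      pu <- phase_from_age(age, job$cycle, params$phase_fractions)
      lab[1L] <- pu[["phase"]]; uu[1L] <- as.numeric(pu[["u"]])
      t <- job$birth
      div_frame <- NA_integer_
      while (t < params$n_frames) {
        age_next <- age + dt_h
        if (params$dividing && age_next >= job$cycle) {
          div_frame <- t
          break
        }
        t <- t + 1L
        heading <- heading +
          stats::rnorm(1L, 0, (1 - params$persistence) * pi)
        len <- max(0, stats::rnorm(1L, step_px,
                                   params$speed_sd_frac * step_px))
        p <- pos[nrow(pos), ] + len * c(cos(heading), sin(heading))
        p <- reflect_into(p, lo, hi)
        pos <- rbind(pos, p)
        age <- age_next
        pu <- phase_from_age(age, job$cycle, params$phase_fractions)
        lab[nrow(pos)] <- pu[["phase"]]
        uu[nrow(pos)] <- as.numeric(pu[["u"]])
      }

      divided <- !is.na(div_frame)
      # optional terminal speed jump, guaranteed to satisfy the criterion
      if (divided && !is.null(params$jump_injection) &&
          nrow(pos) - 1L >= k_base &&
          stats::runif(1L) < params$jump_injection$prob) {
        ns <- nrow(pos) - 1L
        cand <- (ns - k_jump + 1L):ns
        cand <- cand[lab[cand] == "G2M"]
        if (length(cand) > 0L) {
          tj <- if (length(cand) == 1L) cand else sample(cand, 1L)
          pos <- inject_jump(pos, tj, k_base, dt_h, params$pixel_size_um, crit)
          jumps[[length(jumps) + 1L]] <-
            data.frame(cell_id = job$id, step = tj,
                       frame = job$birth + tj - 1L)
        }
      }

      rownames(pos) <- NULL
      tr$positions <- pos
      tr$last_frame <- job$birth + nrow(pos) - 1L
      if (divided) {
        tr$end_reason <- "divided"
        tr$division_frame <- tr$last_frame
        theta <- stats::runif(1L, -pi, pi)
        off <- 1.5 * params$sigma_px * c(cos(theta), sin(theta))
        p_end <- pos[nrow(pos), ]
        seeds <- list(reflect_into(p_end + off, lo, hi),
                      reflect_into(p_end - off, lo, hi))
        for (k in 1:2) {
          did <- paste0(tr$id, ".", k)
          tr$daughter_ids <- c(tr$daughter_ids, did)
          cycle <- rtrunc_norm_pos(params$cycle_mean_h, params$cycle_sd_h,
                                   max(2 * dt_h, 1))
          queue[[length(queue) + 1L]] <-
            list(id = did, parent = tr$id, birth = tr$last_frame + 1L,
                 pos = seeds[[k]], age = 0, cycle = cycle,
                 heading = stats::runif(1L, -pi, pi))
        }
        divisions[[length(divisions) + 1L]] <-
          data.frame(cell_id = tr$id, frame = tr$division_frame,
                     x1 = seeds[[1L]][1L], y1 = seeds[[1L]][2L],
                     x2 = seeds[[2L]][1L], y2 = seeds[[2L]][2L])
      }
      tracks[[tr$id]] <- tr
      phases[[tr$id]] <- data.frame(cell_id = tr$id,
                                    frame = seq(tr$birth_frame, tr$last_frame),
                                    phase = lab, u = uu)
    }

    structure(list(
      lineage = build_lineage(tracks),
      phases = do.call(rbind, c(unname(phases), list(make.row.names = FALSE))),
      divisions = if (length(divisions))
        do.call(rbind, c(divisions, list(make.row.names = FALSE))) else NULL,
      jumps = if (length(jumps))
        do.call(rbind, c(jumps, list(make.row.names = FALSE))) else NULL,
      crowding_warning = founders$warn,
      params = params), class = "ft_simulation")
  })
}

# FUCCI reporter programs: channel levels in [0, 1] given phase and the
# position u within the phase
program_2ch <- function(phase, u) {
  switch(phase,
         G1 = c(r = 1, g = 0.05, b = 0),
         S = c(r = 1 - 0.8 * u, g = 0.3 + 0.6 * u, b = 0),
         G2M = c(r = 0.05, g = 1, b = 0))
}

program_3ch <- function(phase, u) {
  switch(phase,
         G1 = c(r = 0.5, g = 0.05, b = 1),
         S = c(r = 0.5, g = 0.4 + 0.5 * u, b = 0.05),
         G2M = c(r = 0.5, g = 1, b = 1))
}

#' Simulate a calibrated movie with ground truth
#'
#' Renders the trajectories of [simulate_lineage()] as Gaussian nuclei
#' with additive Gaussian noise. In `two_channel` mode the red (Cdt1)
#' reporter is high in G1 and declines through S while green (Geminin)
#' rises through S and stays high in G2/M; in `three_channel` mode blue
#' (PIP) is high in G1 and G2/M but low in S, green (Geminin) is high in
#' S and G2/M, and red (PCNA) is constant. Identical `params` and `seed`
#' give bit-identical output.
#'
#' @inheritParams simulate_lineage
#' @return List: `movie` (a [ft_movie()]), `truth`
#'   (the [simulate_lineage()] result).
#' @export
simulate_movie <- function(params = simulation_params(), seed = 1L) {
  truth <- simulate_lineage(params, seed)
  with_sim_seed(seed + 1L, {
    H <- params$height; W <- params$width
    T <- params$n_frames
    rgb <- params$fucci_mode != "none"
    maxval <- 2^params$bit_depth - 1
    frames <- if (rgb) array(0, c(T, H, W, 3L)) else array(0, c(T, H, W))
    ext <- ceiling(4 * params$sigma_px)
    phase_by_cell <- split(truth$phases, truth$phases$cell_id)

    for (tr in truth$lineage$tracks) {
      ph <- phase_by_cell[[tr$id]]
      for (i in seq_len(nrow(tr$positions))) {
        t <- tr$birth_frame + i - 1L
        x <- tr$positions[i, 1L]; y <- tr$positions[i, 2L]
        rows <- max(1L, floor(y) - ext + 1L):min(H, ceiling(y) + ext + 1L)
        cols <- max(1L, floor(x) - ext + 1L):min(W, ceiling(x) + ext + 1L)
        blob <- exp(-(outer((rows - 1 - y)^2, (cols - 1 - x)^2, "+")) /
                      (2 * params$sigma_px^2))
        if (!rgb) {
          frames[t, rows, cols] <- frames[t, rows, cols] +
            params$peak_intensity * blob
        } else {
          lv <- if (params$fucci_mode == "two_channel")
            program_2ch(ph$phase[i], ph$u[i])
          else program_3ch(ph$phase[i], ph$u[i])
          for (ch in 1:3)
            frames[t, rows, cols, ch] <- frames[t, rows, cols, ch] +
              params$peak_intensity * lv[ch] * blob
        }
      }
    }
    # noise and quantisation frame-by-frame to keep peak memory at one copy
    for (t in seq_len(T)) {
      if (rgb) {
        fr <- frames[t, , , ]
        if (params$noise_sd > 0)
          fr <- fr + stats::rnorm(length(fr), 0, params$noise_sd)
        frames[t, , , ] <- round(pmin(pmax(fr, 0), maxval))
      } else {
        fr <- frames[t, , ]
        if (params$noise_sd > 0)
          fr <- fr + stats::rnorm(length(fr), 0, params$noise_sd)
        frames[t, , ] <- round(pmin(pmax(fr, 0), maxval))
      }
    }
    list(movie = ft_movie(frames, params$pixel_size_um,
                          params$frame_interval_min, params$bit_depth),
         truth = truth)
  })
}
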