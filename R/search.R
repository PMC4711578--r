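#' Configuration of the bilateral-sensor searcher
#'
#' Geometry and protocol constants of the agent-based olfactory searcher.
#' The agent carries two odor sensors (antennules) at `antennule_length`
#' from the body, separated by `sensor_separation` about its heading; it
#' samples the plume at both, steers toward the sensor reporting the
#' better cue, and advances `step_length` along the new heading.  When
#' neither sensor registers a cue within the observation window it
#' backtracks to its previous position to avoid leaving the plume.
#'
#' Strategies: `"born_two"` (bilateral time-since-last-encounter, the bORN
#' cue), `"conc_two"` (bilateral instantaneous concentration),
#' `"born_one"` / `"conc_one"` (single forward sensor, sequential
#' comparison: continue straight while the cue does not deteriorate
#' relative to the previous reading, turn half the sensor separation in a
#' random direction when it does, backtrack on silence).  A backtrack
#' always re-orients by a random turn within +/-90 degrees after restoring
#' the previous position — a searcher that has lost the plume turns to
#' re-enter it.
#'
#' `delta_source` selects how the time cue is measured: `"ideal_timer"`
#' draws the exponential waiting time at the sensor directly (by
#' memorylessness the waiting time has the distribution of the time since
#' the last encounter), `"born_decoder"` mechanistically drives a bORN
#' population with sampled encounter times and reads the cue out with
#' [decode_elapsed_time()] (much slower).
#'
#' @param antennule_length Body-to-sensor distance (cm), default 5.
#' @param sensor_separation Angle between the two sensors (degrees, in
#'   (0, 180)), default 60.
#' @param step_length Distance advanced per step (cm), default 5.
#' @param max_obs_time Maximum time waited for an encounter at each
#'   position (s), default 10.
#' @param success_radius Capture radius around the source (cm), default 5.
#' @param start_heading Initial heading (degrees; 180 = up-current),
#'   default 180.
#' @param max_steps Step cap per run, default 5000.
#' @param strategy One of `"born_two"`, `"conc_two"`, `"born_one"`,
#'   `"conc_one"`.
#' @param delta_source `"ideal_timer"` (default) or `"born_decoder"`.
#' @param born_n Population size per sensor for `"born_decoder"`.
#' @param born_history Encounter history (s) the decoder population is
#'   driven with before readout.
#' @return An object of class `"search_config"`.
#' @export
search_config <- function(antennule_length = 5, sensor_separation = 60,
                          step_length = 5, max_obs_time = 10,
                          success_radius = 5, start_heading = 180,
                          max_steps = 5000,
                          strategy = c("born_two", "conc_two", "born_one",
                                       "conc_one"),
                          delta_source = c("ideal_timer", "born_decoder"),
                          born_n = 60, born_history = 30) {
  strategy <- match.arg(strategy)
  delta_source <- match.arg(delta_source)
  stopifnot(antennule_length > 0, step_length > 0, max_obs_time > 0,
            success_radius > 0, max_steps >= 1,
            sensor_separation > 0, sensor_separation < 180)
  structure(list(antennule_length = antennule_length,
                 sensor_separation = sensor_separation,
                 step_length = step_length, max_obs_time = max_obs_time,
                 success_radius = success_radius,
                 start_heading = start_heading,
                 max_steps = as.integer(max_steps), strategy = strategy,
                 delta_source = delta_source, born_n = born_n,
                 born_history = born_history),
            class = "search_config")
}

.deg2rad <- function(d) d * pi / 180

#' Sensor positions of the searcher
#'
#' Sensors sit `antennule_length` from the body at bearings
#' `heading +/- sensor_separation / 2` (left = `+`, right = `-`).  With a
#' single-sensor strategy the sensor points straight along the heading.
#'
#' @param pos Body position, cm pair.
#' @param heading Heading in degrees (0 = +x, counterclockwise).
#' @param cfg A [search_config()].
#' @return A list with cm pairs `left` and `right` (identical for
#'   single-sensor strategies).
#' @export
sensor_positions <- function(pos, heading, cfg = search_config()) {
  single <- cfg$strategy %in% c("born_one", "conc_one")
  half <- if (single) 0 else cfg$sensor_separation / 2
  al <- .deg2rad(heading + half)
  ar <- .deg2rad(heading - half)
  L <- cfg$antennule_length
  list(left = c(pos[1] + L * cos(al), pos[2] + L * sin(al)),
       right = c(pos[1] + L * cos(ar), pos[2] + L * sin(ar)))
}

# --- lean internal plume samplers (params assumed pre-validated) -----------

.mu_interval <- function(x, y, pp) {
  if (y == 0) return(pp$delta0 * exp(pp$lam * x))
  a <- pp$g * exp(pp$h * x)
  eta <- pp$p * x ^ pp$q
  if (pp$noise_sd > 0) {
    a <- max(a + stats::rnorm(1, 0, pp$noise_sd), 1e-8)
    eta <- max(eta + stats::rnorm(1, 0, pp$noise_sd), 1e-8)
  }
  a * exp(eta * abs(y))
}

.draw_conc <- function(x, y, pp) {
  gs <- function(k, b, m, d) {
    cx <- k * exp(b * x)
    if (y == 0) return(cx)
    sig <- m * x ^ d
    cx * exp(-y^2 / sig^2)
  }
  mu <- gs(pp$k, pp$b, pp$m, pp$d)
  if (y == 0) mu <- pp$c0 * exp(-pp$beta * x)
  sc <- gs(pp$scale_k, pp$scale_b, pp$scale_m, pp$scale_d)
  stats::rgamma(1, shape = mu / sc, scale = sc)
}

# time-since-last-encounter reading at one sensor; NA when silent
.sense_delta <- function(sx, sy, plume, cfg) {
  if (sx <= 0) return(NA_real_)
  if (cfg$delta_source == "ideal_timer") {
    w <- stats::rexp(1, rate = 1 / .mu_interval(sx, sy, plume))
    if (w <= cfg$max_obs_time) w else NA_real_
  } else {
    .sense_delta_born(sx, sy, plume, cfg)
  }
}

# mechanistic variant: drive a bORN population with sampled encounters and
# decode the elapsed interval at the first encounter inside the observation
# window
.sense_delta_born <- function(sx, sy, plume, cfg) {
  horizon <- cfg$born_history + cfg$max_obs_time
  enc <- sample_encounter_times(sx, sy, horizon, plume)
  enc_obs <- enc[enc > cfg$born_history]
  if (length(enc_obs) == 0) return(NA_real_)
  t_read <- enc_obs[1]
  drive <- enc[enc < t_read]
  pop <- make_population(cfg$born_n)
  raster <- simulate_population(pop, drive, duration = t_read)
  st <- state_at(raster, t_read - 1e-9)
  if (!any(st$valid)) return(NA_real_)
  decode_elapsed_time(st)$t_hat
}

# concentration reading at one sensor; NA when below detection
.sense_conc <- function(sx, sy, plume, cfg) {
  if (sx <= 0) return(NA_real_)
  cc <- .draw_conc(sx, sy, plume)
  if (cc >= plume$detect_threshold) cc else NA_real_
}

#' Probe the plume with the searcher's sensors
#'
#' Draws one observation per sensor at the current pose.  Time readings are
#' present only when an encounter occurs within `max_obs_time`
#' (exponential waiting time at the sensor's local mean interval);
#' concentration readings are present only when the single Gamma draw
#' reaches the detection threshold.  Sensors at `x <= 0` (outside the
#' modeled plume) never register a cue.
#'
#' @param pos Body position, cm pair.
#' @param heading Heading (degrees).
#' @param plume A [plume_params()].
#' @param cfg A [search_config()].
#' @return A `"sensor_reading"`: list with `delta_left`, `delta_right` (s or
#'   `NA`), `conc_left`, `conc_right` (% source or `NA`); only the fields
#'   relevant to `cfg$strategy` are populated.
#' @export
observe <- function(pos, heading, plume, cfg = search_config()) {
  sp <- sensor_positions(pos, heading, cfg)
  rd <- list(delta_left = NA_real_, delta_right = NA_real_,
             conc_left = NA_real_, conc_right = NA_real_)
  born <- cfg$strategy %in% c("born_two", "born_one")
  single <- cfg$strategy %in% c("born_one", "conc_one")
  if (born) {
    rd$delta_left <- .sense_delta(sp$left[1], sp$left[2], plume, cfg)
    rd$delta_right <- if (single) rd$delta_left
                      else .sense_delta(sp$right[1], sp$right[2], plume, cfg)
  } else {
    rd$conc_left <- .sense_conc(sp$left[1], sp$left[2], plume, cfg)
    rd$conc_right <- if (single) rd$conc_left
                     else .sense_conc(sp$right[1], sp$right[2], plume, cfg)
  }
  class(rd) <- "sensor_reading"
  rd
}

#' Decide the searcher's next action from a sensor reading
#'
#' Bilateral timing strategies steer toward the sensor with the *smaller*
#' time since the last encounter; bilateral concentration strategies steer
#' toward the *larger* concentration.  A side whose reading is absent
#' loses to a side with a cue; when both are absent the searcher
#' backtracks; exact ties are broken by a fair coin flip.
#'
#' Single-sensor strategies compare sequentially instead of bilaterally:
#' with a cue present they continue straight while the cue has not
#' deteriorated since the previous reading (`prev`), and turn in a random
#' direction when it has; on silence they backtrack.
#'
#' @param reading A [observe()] result.
#' @param cfg A [search_config()].
#' @param prev Previous cue value (s or % source) for single-sensor
#'   strategies; `NULL` when none is available yet.
#' @return One of `"turn_left"`, `"turn_right"`, `"backtrack"`,
#'   `"continue"` (single-sensor strategies only).
#' @export
decide_step <- function(reading, cfg = search_config(), prev = NULL) {
  born <- cfg$strategy %in% c("born_two", "born_one")
  single <- cfg$strategy %in% c("born_one", "conc_one")
  l <- if (born) reading$delta_left else reading$conc_left
  r <- if (born) reading$delta_right else reading$conc_right
  if (single) {
    if (is.na(l)) return("backtrack")
    worse <- !is.null(prev) && (if (born) l > prev else l < prev)
    if (!worse) return("continue")
    return(if (stats::runif(1) < 0.5) "turn_left" else "turn_right")
  }
  if (is.na(l) && is.na(r)) return("backtrack")
  if (is.na(r)) return("turn_left")
  if (is.na(l)) return("turn_right")
  if (l == r) return(if (stats::runif(1) < 0.5) "turn_left" else "turn_right")
  better_left <- if (born) l < r else l > r
  if (better_left) "turn_left" else "turn_right"
}

#' Run one olfactory search
#'
#' Iterates observe / decide / move from `start` until a sensor comes
#' within `success_radius` of the source or `max_steps` is reached.  A turn
#' rotates the heading by half the sensor separation toward the winning
#' sensor, so the body advances along that sensor's bearing; a backtrack
#' restores the previous position and then re-orients by a random turn
#' within +/-90 degrees (a searcher that registered nothing turns to
#' re-enter the plume rather than retrying the same bearing).
#' Deterministic under a fixed RNG seed.
#'
#' @param start Start position, cm pair (inside the modeled domain,
#'   `x > 0`).
#' @param plume A [plume_params()].
#' @param cfg A [search_config()].
#' @return A `"search_result"`: list with `trajectory` (matrix of body
#'   positions, one row per visited pose including the start), `steps`,
#'   `success`, `backtracks`, and per-step `headings` and `actions`.
#' @export
run_search <- function(start, plume, cfg = search_config()) {
  stopifnot(inherits(plume, "plume_params"), inherits(cfg, "search_config"),
            length(start) == 2, start[1] > 0)
  src <- plume$source_xy
  r2 <- cfg$success_radius^2
  single <- cfg$strategy %in% c("born_one", "conc_one")
  half <- if (single) 0 else cfg$sensor_separation / 2
  step <- cfg$step_length
  L <- cfg$antennule_length

  pos <- as.numeric(start)
  heading <- cfg$start_heading
  traj <- matrix(NA_real_, nrow = cfg$max_steps + 1L, ncol = 2L)
  heads <- numeric(cfg$max_steps + 1L)
  actions <- character(cfg$max_steps)
  traj[1L, ] <- pos; heads[1L] <- heading
  prev <- vector("list", cfg$max_steps)  # backtrack stack of (pos, heading)
  depth <- 0L
  steps <- 0L; backtracks <- 0L; success <- FALSE

  sensor_hit <- function(pos, heading) {
    al <- .deg2rad(heading + half); ar <- .deg2rad(heading - half)
    lx <- pos[1] + L * cos(al) - src[1]; ly <- pos[2] + L * sin(al) - src[2]
    if (lx * lx + ly * ly <= r2) return(TRUE)
    rx <- pos[1] + L * cos(ar) - src[1]; ry <- pos[2] + L * sin(ar) - src[2]
    rx * rx + ry * ry <= r2
  }

  turn <- cfg$sensor_separation / 2
  prev_cue <- NULL
  if (sensor_hit(pos, heading)) success <- TRUE
  while (!success && steps < cfg$max_steps) {
    rd <- observe(pos, heading, plume, cfg)
    act <- decide_step(rd, cfg, prev_cue)
    if (single)
      prev_cue <- if (act == "backtrack") NULL
                  else if (cfg$strategy == "born_one") rd$delta_left
                  else rd$conc_left
    if (act == "backtrack") {
      backtracks <- backtracks + 1L
      if (depth > 0L) {
        st <- prev[[depth]]; depth <- depth - 1L
        pos <- st[[1]]; heading <- st[[2]]
      }
      heading <- heading + stats::runif(1, -90, 90)
    } else {
      depth <- depth + 1L
      prev[[depth]] <- list(pos, heading)
      heading <- switch(act, turn_left = heading + turn,
                        turn_right = heading - turn, heading)
      pos <- pos + step * c(cos(.deg2rad(heading)), sin(.deg2rad(heading)))
    }
    steps <- steps + 1L
    traj[steps + 1L, ] <- pos
    heads[steps + 1L] <- heading
    actions[steps] <- act
    if (sensor_hit(pos, heading)) success <- TRUE
  }
  structure(list(trajectory = traj[seq_len(steps + 1L), , drop = FALSE],
                 steps = steps, success = success, backtracks = backtracks,
                 headings = heads[seq_len(steps + 1L)],
                 actions = actions[seq_len(steps)],
                 strategy = cfg$strategy, start = as.numeric(start)),
            class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  cat(sprintf("search_result [%s]: %s in %d steps (%d backtracks) from (%.4g, %.4g)\n",
              x$strategy, if (x$success) "found source" else "gave up",
              x$steps, x$backtracks, x$start[1], x$start[2]))
  invisible(x)
}

#' Write a search trajectory to CSV
#'
#' Columns `step`, `x_cm`, `y_cm`, `heading_deg`, `action` (the action that
#' produced each pose; the start row has action `"start"`).
#'
#' @param result A [run_search()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(result, path) {
  stopifnot(inherits(result, "search_result"))
  df <- data.frame(step = seq_len(result$steps + 1L) - 1L,
                   x_cm = result$trajectory[, 1],
                   y_cm = result$trajectory[, 2],
                   heading_deg = result$headings,
                   action = c("start", result$actions))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Monte-Carlo search performance over a grid of starting positions
#'
#' Repeats [run_search()] `n_reps` times per start and summarizes the step
#' counts.  Runs that hit `max_steps` without success are counted at
#' `max_steps` (censored) in `mean_steps` and reported separately in the
#' success-only columns.  With `seed` given, run `r` from start `i` uses
#' seed `seed + 7919 * i + r`, so calling with the same `seed` under two
#' different strategies pairs the random streams run for run.
#'
#' @param starts Data frame (or 2-column matrix) of start positions with
#'   columns `x`, `y` (cm).
#' @param plume A [plume_params()].
#' @param cfg A [search_config()].
#' @param n_reps Replicates per start, >= 2.
#' @param seed Optional integer base seed.
#' @return A data frame with one row per start: `start_x`, `start_y`,
#'   `strategy`, `n_reps`, `mean_steps`, `se_steps`, `n_success`,
#'   `mean_steps_success`, `se_steps_success`, `n_censored`.
#' @export
monte_carlo <- function(starts, plume, cfg = search_config(), n_reps = 100,
                        seed = NULL) {
  stopifnot(n_reps >= 2)
  starts <- as.data.frame(starts)
  if (!all(c("x", "y") %in% names(starts)))
    names(starts)[1:2] <- c("x", "y")
  out <- lapply(seq_len(nrow(starts)), function(i) {
    steps <- integer(n_reps); succ <- logical(n_reps)
    for (r in seq_len(n_reps)) {
      if (!is.null(seed)) set.seed(seed + 7919L * i + r)
      res <- run_search(c(starts$x[i], starts$y[i]), plume, cfg)
      steps[r] <- if (res$success) res$steps else cfg$max_steps
      succ[r] <- res$success
    }
    ok <- steps[succ]
    data.frame(start_x = starts$x[i], start_y = starts$y[i],
               strategy = cfg$strategy, n_reps = n_reps,
               mean_steps = mean(steps),
               se_steps = stats::sd(steps) / sqrt(n_reps),
               n_success = sum(succ),
               mean_steps_success = if (length(ok)) mean(ok) else NA_real_,
               se_steps_success = if (length(ok) > 1)
                 stats::sd(ok) / sqrt(length(ok)) else NA_real_,
               n_censored = sum(!succ))
  })
  do.call(rbind, out)
}
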