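# Random-dot kinematogram generators: the 2D-motion localizer field and the
# opponent-motion (paired/unpaired) field.
#
# Both generators advance dot state frame by frame at display resolution
# (default 120 Hz). Full runs at 120 Hz are large (10^7 dot-frames), so each
# generator supports two output modes: "frames" keeps every per-frame dot
# table (use for short clips and unit tests) and "stats" streams the run and
# records only summary statistics (dot counts, maximum instantaneous speed,
# maximum eccentricity, maximum age, pair-separation bounds).

#' Eccentricity-dependent dot speed profiles of the 2D-motion localizer
#'
#' Radial blocks scale dot speed with the square root of eccentricity,
#' rotational blocks with the one-eighth power (square-root scaling leaves
#' near-foveal rotation imperceptibly slow); both reach the same maximum speed
#' at the aperture edge.
#'
#' @param ecc Eccentricity in deg (vectorized).
#' @param v_max Maximum speed in deg/s, reached at `ecc = radius`.
#' @param radius Aperture radius in deg.
#' @return Speed in deg/s.
#' @export
radial_speed <- function(ecc, v_max = 12, radius = 10) v_max * sqrt(ecc / radius)

#' @rdname radial_speed
#' @export
rotational_speed <- function(ecc, v_max = 12, radius = 10) v_max * (ecc / radius)^(1 / 8)

uniform_disk <- function(n, radius) {
  r <- radius * sqrt(stats::runif(n))
  th <- stats::runif(n, 0, 2 * pi)
  cbind(x = r * cos(th), y = r * sin(th))
}

new_dot_movie <- function(frame_rate, frames, stats, aperture_radius, condition_labels) {
  structure(list(frame_rate = frame_rate, frames = frames, stats = stats,
                 aperture_radius = aperture_radius,
                 condition_labels = condition_labels),
            class = "dot_field_movie")
}

#' @export
print.dot_field_movie <- function(x, ...) {
  cat(sprintf("<dot_field_movie> %d frames @ %g Hz, aperture %g deg\n",
              x$stats$n_frames, x$frame_rate, x$aperture_radius))
  cat(sprintf("  max speed %.4f deg/s, max ecc %.3f deg, dots/frame %d..%d\n",
              x$stats$max_speed, x$stats$max_ecc,
              x$stats$min_dots, x$stats$max_dots))
  invisible(x)
}

#' Generate the 2D-motion localizer dot movie
#'
#' Limited-lifetime dots within a circular aperture. Radial blocks move dots
#' in/out with square-root eccentricity speed scaling, rotational blocks
#' rotate them with one-eighth-power scaling, static blocks freeze positions,
#' blank blocks show no dots. Dots respawn uniformly over the aperture disk
#' when their lifetime expires or they exit the aperture. Deterministic given
#' `seed`.
#'
#' @param schedule A `block_schedule` from [build_2d_schedule()].
#' @param seed Integer seed.
#' @param frame_rate Display frame rate in Hz.
#' @param n_dots Dots per frame.
#' @param lifetime Dot lifetime in seconds.
#' @param radius Aperture radius in deg.
#' @param v_max Maximum dot speed in deg/s.
#' @param store `"stats"` (streaming summary, default) or `"frames"` (keep
#'   per-frame dot tables; only sensible for short schedules).
#' @return A `dot_field_movie`; `$stats` holds `n_frames`, `n_dot_frames`,
#'   `max_speed` (instantaneous, from the kinematic rule), `max_ecc`,
#'   `max_age`, `min_dots`, `max_dots`.
#' @export
gen_2d_dot_movie <- function(schedule, seed, frame_rate = 120, n_dots = 250,
                             lifetime = 0.5, radius = 10, v_max = 12,
                             store = c("stats", "frames")) {
  store <- match.arg(store)
  known <- c("radial_in", "radial_out", "cw", "ccw", "static", "blank")
  if (!all(schedule$blocks$condition %in% known))
    stop("unknown condition label in schedule: ",
         paste(setdiff(schedule$blocks$condition, known), collapse = ", "))
  set.seed(derive_seed(seed, "dots2d"))
  dt <- 1 / frame_rate
  n_frames <- round(schedule$total_duration * frame_rate)

  pos <- uniform_disk(n_dots, radius)
  age <- stats::runif(n_dots, 0, lifetime)  # desynchronized respawns

  frames <- if (store == "frames") vector("list", n_frames) else NULL
  smax <- 0; eccmax <- 0; agemax <- 0
  mindots <- Inf; maxdots <- 0; ndotframes <- 0
  labels <- character(n_frames)

  # per-frame times; the block label governs the kinematics of the step
  for (f in seq_len(n_frames)) {
    tt <- (f - 1) * dt
    lab <- label_at_time(schedule, tt)
    labels[f] <- lab
    if (lab == "blank") {
      if (store == "frames")
        frames[[f]] <- data.frame(x = numeric(0), y = numeric(0),
                                  age = numeric(0), speed = numeric(0))
      mindots <- min(mindots, 0)
      next
    }
    # lifetime respawn
    expired <- age >= lifetime
    if (any(expired)) {
      pos[expired, ] <- uniform_disk(sum(expired), radius)
      age[expired] <- 0
    }
    ecc <- sqrt(pos[, 1]^2 + pos[, 2]^2)
    speed <- switch(lab,
      static = rep(0, n_dots),
      radial_in  = radial_speed(ecc, v_max, radius),
      radial_out = radial_speed(ecc, v_max, radius),
      cw  = rotational_speed(ecc, v_max, radius),
      ccw = rotational_speed(ecc, v_max, radius))

    smax <- max(smax, speed)
    eccmax <- max(eccmax, ecc)
    agemax <- max(agemax, age)
    mindots <- min(mindots, n_dots); maxdots <- max(maxdots, n_dots)
    ndotframes <- ndotframes + n_dots
    if (store == "frames")
      frames[[f]] <- data.frame(x = pos[, 1], y = pos[, 2], age = age, speed = speed)

    # advance state to the next frame
    if (lab %in% c("radial_in", "radial_out")) {
      dir <- if (lab == "radial_out") 1 else -1
      newr <- ecc + dir * speed * dt
      ok <- ecc > 0
      scl <- ifelse(ok, pmax(newr, 0) / pmax(ecc, 1e-12), 1)
      pos <- pos * scl
      out <- sqrt(pos[, 1]^2 + pos[, 2]^2) > radius
      if (any(out)) {
        pos[out, ] <- uniform_disk(sum(out), radius)
        age[out] <- 0
      }
    } else if (lab %in% c("cw", "ccw")) {
      omega <- ifelse(ecc > 0, speed / pmax(ecc, 1e-12), 0)
      ang <- if (lab == "ccw") omega * dt else -omega * dt
      xn <- pos[, 1] * cos(ang) - pos[, 2] * sin(ang)
      yn <- pos[, 1] * sin(ang) + pos[, 2] * cos(ang)
      pos[, 1] <- xn; pos[, 2] <- yn
    }
    age <- age + dt
  }

  st <- list(n_frames = n_frames, n_dot_frames = ndotframes,
             max_speed = smax, max_ecc = eccmax, max_age = agemax,
             min_dots = if (is.finite(mindots)) mindots else 0,
             max_dots = maxdots)
  new_dot_movie(frame_rate, frames, st, radius, labels)
}

#' Generate the opponent-motion dot movie
#'
#' 300 white dots per frame, 150 moving leftward and 150 rightward at a
#' constant 5 deg/s. In the paired condition dots come in pairs that share a
#' y-coordinate, start 0.5 deg apart, cross once, and annihilate at 0.5 deg
#' separation (lifetime 0.5 deg / 10 deg/s closing speed = 0.1 s). In the
#' unpaired condition dot y-positions are independent. Deterministic given
#' `seed`.
#'
#' @param condition `"paired"` or `"unpaired"`.
#' @param duration Seconds (> 0).
#' @param seed Integer seed.
#' @param frame_rate Frames per second.
#' @param n_dots Dots per frame (even; half leftward, half rightward).
#' @param speed Horizontal dot speed in deg/s.
#' @param max_sep Maximum pair separation in deg (sets the lifetime).
#' @param radius Aperture radius in deg.
#' @param store `"stats"` or `"frames"` as in [gen_2d_dot_movie()].
#' @return A `dot_field_movie`; in frames mode each frame table has columns
#'   `x`, `y`, `age`, `speed`, `direction` (+1 right / -1 left) and `pair_id`
#'   (NA when unpaired).
#' @export
gen_opponent_movie <- function(condition = c("paired", "unpaired"), duration,
                               seed, frame_rate = 120, n_dots = 300, speed = 5,
                               max_sep = 0.5, radius = 10,
                               store = c("stats", "frames")) {
  condition <- match.arg(condition)
  store <- match.arg(store)
  if (duration <= 0) stop("duration must be positive")
  if (n_dots %% 2 != 0) stop("n_dots must be even")
  set.seed(derive_seed(seed, "opponent", condition))
  dt <- 1 / frame_rate
  n_frames <- round(duration * frame_rate)
  lifetime <- max_sep / speed / 2 * 2  # closing speed is 2*speed over 2*max_sep... see below
  # separation runs from +max_sep to -max_sep at closing speed 2*speed:
  lifetime <- 2 * max_sep / (2 * speed)   # = max_sep / speed = 0.1 s at defaults

  frames <- if (store == "frames") vector("list", n_frames) else NULL
  smax <- 0; agemax <- 0; sepmax <- 0
  mindots <- Inf; maxdots <- 0

  if (condition == "paired") {
    n_pairs <- n_dots / 2
    ctr <- uniform_disk(n_pairs, radius - max_sep / 2)
    phase <- stats::runif(n_pairs, 0, lifetime)  # asynchronous crossings
    for (f in seq_len(n_frames)) {
      done <- phase >= lifetime
      if (any(done)) {
        ctr[done, ] <- uniform_disk(sum(done), radius - max_sep / 2)
        phase[done] <- phase[done] - lifetime
      }
      # member A moves rightward, member B leftward; they cross at mid-life
      off <- -max_sep / 2 + speed * phase
      x <- c(ctr[, 1] + off, ctr[, 1] - off)
      y <- c(ctr[, 2], ctr[, 2])
      sep <- abs(2 * off)
      sepmax <- max(sepmax, sep)
      agemax <- max(agemax, phase)
      smax <- max(smax, speed)
      mindots <- min(mindots, length(x)); maxdots <- max(maxdots, length(x))
      if (store == "frames")
        frames[[f]] <- data.frame(
          x = x, y = y, age = rep(phase, 2), speed = speed,
          direction = rep(c(1, -1), each = n_pairs),
          pair_id = rep(seq_len(n_pairs), 2))
      phase <- phase + dt
    }
  } else {
    spawn_r <- radius - max_sep  # a dot drifts at most speed*lifetime = max_sep
    pos <- uniform_disk(n_dots, spawn_r)
    dirs <- rep(c(1, -1), each = n_dots / 2)
    age <- stats::runif(n_dots, 0, lifetime)
    for (f in seq_len(n_frames)) {
      done <- age >= lifetime
      if (any(done)) {
        pos[done, ] <- uniform_disk(sum(done), spawn_r)
        age[done] <- age[done] - lifetime
      }
      x <- pos[, 1] + dirs * speed * (age - lifetime / 2)
      agemax <- max(agemax, age)
      smax <- max(smax, speed)
      mindots <- min(mindots, n_dots); maxdots <- max(maxdots, n_dots)
      if (store == "frames")
        frames[[f]] <- data.frame(x = x, y = pos[, 2], age = age, speed = speed,
                                  direction = dirs, pair_id = NA_integer_)
      age <- age + dt
    }
  }

  st <- list(n_frames = n_frames, max_speed = smax, max_age = agemax,
             max_pair_sep = if (condition == "paired") sepmax else NA_real_,
             min_dots = mindots, max_dots = maxdots,
             n_left = n_dots / 2, n_right = n_dots / 2)
  new_dot_movie(frame_rate, frames, st, radius, rep(condition, n_frames))
}

#' Export a dot movie's frames as CSV
#'
#' One row per dot per frame (frames mode only), for inspection.
#' @param movie A `dot_field_movie` generated with `store = "frames"`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dot_movie_csv <- function(movie, path) {
  if (is.null(movie$frames)) stop("movie was generated with store = 'stats'")
  rows <- lapply(seq_along(movie$frames), function(f) {
    d <- movie$frames[[f]]
    if (nrow(d) == 0) return(NULL)
    cbind(frame = f, d)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
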