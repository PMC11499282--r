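# Synthetic accelerometry with planted ground truth: instrumented-walkway
# passes, multi-day free-living wear, and comfort-questionnaire responses.

# run expr under a private RNG stream; global .Random.seed is restored
local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

#' Likert response levels
#'
#' The five response options of the comfort and wearability questionnaire,
#' from least to most favorable for a favorably-worded item.
#' @return character vector of length 5.
#' @export
likert_levels <- function() {
  c("strongly disagree", "disagree", "neutral", "agree", "strongly agree")
}

#' Subject profile
#'
#' @param subject_id identifier string.
#' @param age_years age in years, 3-17.
#' @param height_m standing height in meters; defaults to an age-based
#'   pediatric average (0.86 + 0.05 * age) when not given.
#' @param sex "F", "M" or "unknown".
#' @return a `subject_profile` list with the derived `age_group`
#'   ("3-5", "6-11" or "12-17").
#' @export
subject_profile <- function(subject_id, age_years, height_m = NULL,
                            sex = c("unknown", "F", "M")) {
  sex <- match.arg(sex)
  stopifnot(is.numeric(age_years), length(age_years) == 1L,
            age_years >= 3, age_years <= 17)
  if (is.null(height_m)) height_m <- 0.86 + 0.05 * age_years
  stopifnot(height_m >= 0.8, height_m <= 2.1)
  age_group <- if (age_years < 6) "3-5" else if (age_years < 12) "6-11" else "12-17"
  structure(list(subject_id = as.character(subject_id),
                 age_years = age_years, age_group = age_group,
                 height_m = height_m, sex = sex),
            class = "subject_profile")
}

#' Simulation configuration
#'
#' Parameters of the synthetic accelerometry generator. All randomness of a
#' simulation call flows from `seed`; no global RNG state is consumed.
#'
#' @param fs_hz sampling rate in Hz (study devices recorded at 64 Hz).
#' @param noise_sd_g standard deviation of additive white Gaussian noise, in g,
#'   applied to every axis.
#' @param seed integer seed.
#' @param vertical_axis which axis ("x", "y" or "z") carries gravity and the
#'   vertical gait component.
#' @param vertical_sign +1 or -1: sign of gravity on that axis.
#' @param impulse_g amplitude (g) of the half-sine initial-contact impulse.
#' @param impulse_s duration (s) of the impulse (~50 ms).
#' @param leg_length_factor pendulum length as a fraction of height; shared
#'   with the analyzer so spatial recovery is well-posed.
#' @param cadence_spm optional fixed cadence; when NULL it is drawn from the
#'   speed-class range in `cadence_ranges`.
#' @param step_frac optional fixed step length as a fraction of height.
#' @param cadence_ranges named list of c(lo, hi) cadence (steps/min) per speed
#'   class.
#' @param step_frac_ranges named list of c(lo, hi) step-length/height fractions
#'   per speed class.
#' @param day_schedule free-living day composition, see
#'   [default_day_schedule()].
#' @return a `sim_config` list.
#' @export
sim_config <- function(fs_hz = 64, noise_sd_g = 0.05, seed = 1L,
                       vertical_axis = c("z", "x", "y"), vertical_sign = 1,
                       impulse_g = 0.2, impulse_s = 0.05,
                       leg_length_factor = 0.53,
                       cadence_spm = NULL, step_frac = NULL,
                       cadence_ranges = list(natural = c(80, 140),
                                             fast = c(130, 180),
                                             slow = c(55, 85)),
                       step_frac_ranges = list(natural = c(0.35, 0.45),
                                               fast = c(0.42, 0.52),
                                               slow = c(0.25, 0.35)),
                       day_schedule = default_day_schedule()) {
  vertical_axis <- match.arg(vertical_axis)
  stopifnot(fs_hz >= 8, noise_sd_g >= 0, vertical_sign %in% c(-1, 1),
            impulse_g >= 0, impulse_s > 0, impulse_s < 0.2,
            leg_length_factor > 0, leg_length_factor < 1)
  structure(list(fs_hz = fs_hz, noise_sd_g = noise_sd_g, seed = as.integer(seed),
                 vertical_axis = vertical_axis, vertical_sign = vertical_sign,
                 impulse_g = impulse_g, impulse_s = impulse_s,
                 leg_length_factor = leg_length_factor,
                 cadence_spm = cadence_spm, step_frac = step_frac,
                 cadence_ranges = cadence_ranges,
                 step_frac_ranges = step_frac_ranges,
                 day_schedule = day_schedule),
            class = "sim_config")
}

#' Default free-living day schedule
#'
#' Composition of a simulated at-home day. Values are artifact choices (the
#' source study does not describe at-home activity composition) picked to be
#' realistic for ambulatory children: a 07:00-21:00 wake span, ~2 h light,
#' 45 min moderate and 15 min vigorous activity placed in contiguous chunks,
#' and 10 walking bouts per day with right-skewed (log-normal) lengths.
#'
#' @param wake_start_h,wake_end_h wake span, hours from midnight.
#' @param bouts_per_day number of walking bouts per day.
#' @param bout_meanlog,bout_sdlog log-normal parameters of bout length (s).
#' @param bout_min_s,bout_max_s truncation bounds for bout lengths.
#' @param bout_lengths_s optional explicit per-day bout lengths (overrides the
#'   distribution; recycled across days).
#' @param light_min,moderate_min,vigorous_min minutes per day of each activity
#'   class, placed in chunks of `chunk_min` minutes.
#' @param chunk_min chunk lengths (minutes) per class, named list.
#' @param nonwear_blocks device-off blocks: either a list of c(start_h, end_h)
#'   applied to every day (e.g. `list(c(0, 7), c(21, 24))` emulates a lumbar
#'   device removed for sleep), or a list of such lists, one per day (recycled
#'   over days).
#' @return a list, used as `day_schedule` inside [sim_config()].
#' @export
default_day_schedule <- function(wake_start_h = 7, wake_end_h = 21,
                                 bouts_per_day = 10,
                                 bout_meanlog = log(40), bout_sdlog = 0.7,
                                 bout_min_s = 10, bout_max_s = 300,
                                 bout_lengths_s = NULL,
                                 light_min = 120, moderate_min = 45,
                                 vigorous_min = 15,
                                 chunk_min = list(light = 20, moderate = 15,
                                                  vigorous = 5),
                                 nonwear_blocks = list()) {
  stopifnot(wake_start_h >= 0, wake_end_h <= 24, wake_start_h < wake_end_h)
  list(wake_start_h = wake_start_h, wake_end_h = wake_end_h,
       bouts_per_day = bouts_per_day, bout_meanlog = bout_meanlog,
       bout_sdlog = bout_sdlog, bout_min_s = bout_min_s,
       bout_max_s = bout_max_s, bout_lengths_s = bout_lengths_s,
       light_min = light_min, moderate_min = moderate_min,
       vigorous_min = vigorous_min, chunk_min = chunk_min,
       nonwear_blocks = nonwear_blocks)
}

# per-class sinusoid amplitudes (g) and frequencies (Hz) for non-gait activity;
# epoch-level energy is strictly ordered sedentary < light < moderate < vigorous
activity_signal_params <- function() {
  list(sedentary = c(amp = 0.15, freq = 0.8),
       light     = c(amp = 0.50, freq = 1.5),
       moderate  = c(amp = 1.20, freq = 2.0),
       vigorous  = c(amp = 2.40, freq = 2.3))
}

new_accel_recording <- function(time_s, x, y, z, fs_hz,
                                start_time = as.POSIXct("2022-05-02 00:00:00",
                                                        tz = "UTC"),
                                wear_site = "lumbar", subject_id = "S01") {
  structure(list(data = data.frame(time_s = time_s, x = x, y = y, z = z),
                 fs_hz = fs_hz, start_time = start_time,
                 wear_site = wear_site, subject_id = subject_id),
            class = "accel_recording")
}

#' @export
print.accel_recording <- function(x, ...) {
  cat(sprintf("<accel_recording> subject %s, site %s, %.1f s at %g Hz\n",
              x$subject_id, x$wear_site, nrow(x$data) / x$fs_hz, x$fs_hz))
  invisible(x)
}

# step length L and pendulum length l -> vertical CoM excursion h
# (inverse of the inverted-pendulum chord L = 2*sqrt(2*l*h - h^2))
excursion_from_step_length <- function(step_length_m, pendulum_m) {
  half <- step_length_m / 2
  if (half >= pendulum_m) stop("step length incompatible with pendulum length")
  pendulum_m - sqrt(pendulum_m^2 - half^2)
}

# vertical walking component, in g, over sample times t (s):
# pendulum-consistent CoM sinusoid at step frequency (displacement amplitude
# h/2, minimum at each initial contact) plus a half-sine impulse per IC
walk_vertical_component <- function(t, ic_times, f_step, h_m,
                                    impulse_g, impulse_s) {
  omega <- 2 * pi * f_step
  t0 <- ic_times[1]
  com <- (h_m / 2) * omega^2 / GRAVITY_MS2 * cos(omega * (t - t0))
  imp <- numeric(length(t))
  for (tic in ic_times) {
    idx <- which(t >= tic & t < tic + impulse_s)
    if (length(idx))
      imp[idx] <- imp[idx] + impulse_g * sin(pi * (t[idx] - tic) / impulse_s)
  }
  com + imp
}

#' Simulate one instrumented-walkway pass
#'
#' Generates a tri-axial lumbar accelerometer recording of a straight walking
#' pass together with its planted per-stride ground truth. The vertical axis
#' carries gravity, a center-of-mass sinusoid at step frequency whose
#' displacement amplitude matches the planted step length under the same
#' inverted-pendulum geometry used by the analyzer, and a short impulse at
#' each initial contact.
#'
#' @param profile a [subject_profile()].
#' @param speed_class "natural", "fast" or "slow".
#' @param duration_s pass duration in seconds (>= 5).
#' @param cfg a [sim_config()].
#' @return list with elements `recording` (an `accel_recording`) and `truth`
#'   (a `gait_truth`: planted contact events and per-stride metrics).
#' @export
simulate_walk_pass <- function(profile, speed_class = c("natural", "fast", "slow"),
                               duration_s = 30, cfg = sim_config()) {
  speed_class <- match.arg(speed_class)
  stopifnot(inherits(profile, "subject_profile"), duration_s >= 5)
  local_seed(cfg$seed, {
    cad <- cfg$cadence_spm
    if (is.null(cad)) {
      r <- cfg$cadence_ranges[[speed_class]]
      cad <- runif(1, r[1], r[2])
    }
    frac <- cfg$step_frac
    if (is.null(frac)) {
      r <- cfg$step_frac_ranges[[speed_class]]
      frac <- runif(1, r[1], r[2])
    }
    t_step <- 60 / cad
    if (duration_s < 2 * t_step)
      stop("duration too short for one stride at this cadence")
    pendulum_m <- cfg$leg_length_factor * profile$height_m
    step_length_m <- frac * profile$height_m
    h_m <- excursion_from_step_length(step_length_m, pendulum_m)

    ic_times <- seq(t_step / 2, duration_s - 1e-9, by = t_step)
    n_steps <- length(ic_times)
    feet <- rep_len(c("L", "R"), n_steps)
    stride_time <- 2 * t_step
    fc_times <- ic_times + 0.6 * stride_time
    fc_keep <- fc_times < duration_s
    events <- rbind(
      data.frame(time_s = ic_times, kind = "IC", foot = feet),
      data.frame(time_s = fc_times[fc_keep], kind = "FC", foot = feet[fc_keep]))
    events <- events[order(events$time_s), , drop = FALSE]
    rownames(events) <- NULL

    n_strides <- max(n_steps - 2L, 0L)
    truth <- structure(list(
      events = events,
      stride_times_s = rep(stride_time, n_strides),
      stride_lengths_m = rep(2 * step_length_m, n_strides),
      speeds_mps = rep(2 * step_length_m / stride_time, n_strides),
      cadence_spm = rep(120 / stride_time, n_strides),
      pass_speed_class = speed_class,
      step_length_m = step_length_m, h_m = h_m,
      vertical_axis = cfg$vertical_axis, vertical_sign = cfg$vertical_sign),
      class = "gait_truth")

    n <- round(duration_s * cfg$fs_hz)
    t <- (seq_len(n) - 1L) / cfg$fs_hz
    vert <- 1 + walk_vertical_component(t, ic_times, f_step = cad / 60,
                                        h_m = h_m, impulse_g = cfg$impulse_g,
                                        impulse_s = cfg$impulse_s)
    ap <- 0.08 * sin(2 * pi * (cad / 60) * t + pi / 3)
    ml <- 0.06 * sin(pi * (cad / 60) * t)
    ax <- list(x = ap, y = ml, z = numeric(n))
    ax[[cfg$vertical_axis]] <- cfg$vertical_sign * vert
    if (cfg$noise_sd_g > 0)
      for (a in c("x", "y", "z"))
        ax[[a]] <- ax[[a]] + rnorm(n, sd = cfg$noise_sd_g)
    rec <- new_accel_recording(t, ax$x, ax$y, ax$z, cfg$fs_hz,
                               subject_id = profile$subject_id)
    list(recording = rec, truth = truth)
  })
}

#' Simulate a reference walkway record for a pass
#'
#' Emulates the pressure-walkway comparator: per-pass means of the planted
#' gait truth plus zero-mean Gaussian measurement noise.
#'
#' @param truth a `gait_truth` from [simulate_walk_pass()].
#' @param noise_sd scalar, or named vector with entries among
#'   `cadence_spm`, `gait_speed_mps`, `stride_time_s`, `stride_length_m`,
#'   giving the measurement-noise standard deviation per metric.
#' @param seed integer seed, or NULL to use the current RNG stream.
#' @return one-row data.frame of per-pass reference metrics.
#' @export
simulate_reference_walkway <- function(truth, noise_sd = 0, seed = NULL) {
  stopifnot(inherits(truth, "gait_truth"))
  if (length(truth$stride_times_s) < 1L) stop("empty gait truth")
  base <- c(cadence_spm = mean(truth$cadence_spm),
            gait_speed_mps = mean(truth$speeds_mps),
            stride_time_s = mean(truth$stride_times_s),
            stride_length_m = mean(truth$stride_lengths_m))
  sds <- rep(0, 4); names(sds) <- names(base)
  if (length(noise_sd) == 1L && is.null(names(noise_sd))) {
    sds[] <- noise_sd
  } else {
    sds[names(noise_sd)] <- noise_sd
  }
  local_seed(seed, {
    out <- base + rnorm(4, sd = sds)
    as.data.frame(as.list(out))
  })
}

# integer second labels used while composing a free-living day
.CLASS_LEVELS <- c("nonwear", "sedentary", "light", "moderate", "vigorous", "gait")

# place `len` contiguous seconds of `code` uniformly at random inside runs of
# `free` (logical); returns start index or NA
place_segment <- function(free, len) {
  r <- rle(free)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values & r$lengths >= len)
  if (!length(ok)) return(NA_integer_)
  i <- ok[sample.int(length(ok), 1L)]
  starts[i] + sample.int(r$lengths[i] - len + 1L, 1L) - 1L
}

#' Simulate multi-day free-living wear
#'
#' Builds an `n_days` recording spanning whole calendar days (midnight to
#' midnight): walking bouts (same walk-signal model as
#' [simulate_walk_pass()]), non-wear blocks (gravity-only before noise),
#' and sedentary/light/moderate/vigorous activity whose epoch-level energy is
#' ordered by class. Ground truth labels are returned for every second and
#' 60-s epoch.
#'
#' The default noise level is lower than the walkway default (0.01 g): at-home
#' recordings are dominated by instrument noise at rest rather than
#' body-contact artifact.
#'
#' @param profile a [subject_profile()].
#' @param n_days number of calendar days (>= 1).
#' @param cfg a [sim_config()]; its `day_schedule` drives composition.
#' @return list with `recording` (an `accel_recording`) and `truth` (a
#'   `free_living_truth`: `bout_intervals`, `nonwear_intervals`,
#'   `intensity_epochs`, `class_seconds`).
#' @export
simulate_free_living_days <- function(profile, n_days,
                                      cfg = sim_config(noise_sd_g = 0.01)) {
  stopifnot(inherits(profile, "subject_profile"), n_days >= 1)
  fs <- cfg$fs_hz
  stopifnot(abs(fs - round(fs)) < 1e-9)
  fs <- as.integer(round(fs))
  sched <- cfg$day_schedule
  local_seed(cfg$seed, {
    day_s <- 86400L
    total_s <- n_days * day_s
    lab <- rep(2L, total_s)  # 1-based index into .CLASS_LEVELS: sedentary

    # non-wear blocks: one shared daily list, or a per-day list of lists
    nb <- sched$nonwear_blocks
    per_day <- length(nb) > 0 && is.list(nb[[1]])
    for (d in seq_len(n_days) - 1L) {
      blocks <- if (per_day) nb[[(d %% length(nb)) + 1L]] else nb
      for (b in blocks) {
        i0 <- d * day_s + round(b[1] * 3600) + 1L
        i1 <- d * day_s + round(b[2] * 3600)
        lab[i0:i1] <- 1L
      }
    }

    # placement window: wake span minus a 60-s margin at each boundary and
    # around every non-wear block, so placed segments never abut non-wear
    wake <- rep(FALSE, total_s)
    for (d in seq_len(n_days) - 1L) {
      i0 <- d * day_s + round(sched$wake_start_h * 3600) + 61L
      i1 <- d * day_s + round(sched$wake_end_h * 3600) - 60L
      if (i1 > i0) wake[i0:i1] <- TRUE
    }
    rnw <- rle(lab == 1L)
    rnw_end <- cumsum(rnw$lengths); rnw_start <- rnw_end - rnw$lengths + 1L
    for (j in which(rnw$values)) {
      wake[max(1L, rnw_start[j] - 60L):min(total_s, rnw_end[j] + 60L)] <- FALSE
    }

    # activity chunks (minute-aligned) within free wake time
    for (cls in c("light", "moderate", "vigorous")) {
      need_min <- sched[[paste0(cls, "_min")]]
      chunk <- sched$chunk_min[[cls]]
      code <- match(cls, .CLASS_LEVELS)
      for (d in seq_len(n_days) - 1L) {
        left <- need_min
        while (left > 0) {
          len_min <- min(chunk, left)
          day_idx <- d * day_s + seq_len(day_s)
          free <- wake[day_idx] & lab[day_idx] == 2L
          # minute alignment: collapse to minutes
          fmin <- matrix(free, nrow = 60)
          free_min <- apply(fmin, 2, all)
          st_min <- place_segment(free_min, len_min)
          if (is.na(st_min)) break
          i0 <- d * day_s + (st_min - 1L) * 60L + 1L
          lab[i0:(i0 + len_min * 60L - 1L)] <- code
          left <- left - len_min
        }
      }
    }

    # walking bouts at second resolution
    bout_tab <- NULL
    gait_code <- match("gait", .CLASS_LEVELS)
    for (d in seq_len(n_days) - 1L) {
      if (!is.null(sched$bout_lengths_s)) {
        lens <- round(sched$bout_lengths_s)
      } else if (sched$bouts_per_day > 0) {
        lens <- round(pmin(pmax(rlnorm(sched$bouts_per_day, sched$bout_meanlog,
                                       sched$bout_sdlog),
                                sched$bout_min_s), sched$bout_max_s))
      } else lens <- integer(0)
      for (len in lens) {
        day_idx <- d * day_s + seq_len(day_s)
        free <- wake[day_idx] & lab[day_idx] == 2L
        # reserve a 10-s sedentary margin on both sides so distinct planted
        # bouts stay resolvable as distinct walking episodes
        st <- place_segment(free, len + 20L)
        if (is.na(st))
          stop("schedule infeasible: requested walking bouts exceed free wake time")
        i0 <- d * day_s + st + 10L
        lab[i0:(i0 + len - 1L)] <- gait_code
        cad <- runif(1, cfg$cadence_ranges$natural[1], cfg$cadence_ranges$natural[2])
        frac <- runif(1, cfg$step_frac_ranges$natural[1], cfg$step_frac_ranges$natural[2])
        bout_tab <- rbind(bout_tab,
                          data.frame(start_s = i0 - 1L, end_s = i0 - 1L + len,
                                     cadence_spm = cad, step_frac = frac))
      }
    }

    # synthesize the signal segment by segment
    n <- total_s * fs
    vert <- rep(1, n)          # gravity, g
    ap <- numeric(n); ml <- numeric(n)
    act <- activity_signal_params()
    r <- rle(lab)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    pendulum_m <- cfg$leg_length_factor * profile$height_m
    bout_row <- 0L
    for (i in seq_along(r$values)) {
      code <- r$values[i]
      cls <- .CLASS_LEVELS[code]
      s0 <- (starts[i] - 1L) * fs + 1L
      s1 <- ends[i] * fs
      idx <- s0:s1
      tt <- (idx - 1L) / fs
      if (cls == "nonwear") next
      if (cls == "gait") {
        bout_row <- bout_row + 1L
        b <- bout_tab[bout_tab$start_s == starts[i] - 1L, ][1, ]
        t_step <- 60 / b$cadence_spm
        step_len <- b$step_frac * profile$height_m
        h_m <- excursion_from_step_length(step_len, pendulum_m)
        dur <- r$lengths[i]
        ics <- b$start_s + seq(t_step / 2, dur - 1e-9, by = t_step)
        vert[idx] <- 1 + walk_vertical_component(tt, ics, b$cadence_spm / 120 * 2,
                                                 h_m, cfg$impulse_g, cfg$impulse_s)
        ap[idx] <- 0.08 * sin(2 * pi * (b$cadence_spm / 60) * tt)
        ml[idx] <- 0.06 * sin(pi * (b$cadence_spm / 60) * tt)
      } else {
        p <- act[[cls]]
        ph <- runif(3, 0, 2 * pi)
        # amplitude ramps at segment edges: movement starts/stops smoothly, so
        # filter transients do not bleed across adjacent (non-wear) epochs
        tr_rel <- tt - tt[1]
        ramp_s <- min(2, r$lengths[i] / 4)
        env <- pmin(1, tr_rel / ramp_s, (r$lengths[i] - tr_rel) / ramp_s)
        vert[idx] <- 1 + env * p["amp"] * sin(2 * pi * p["freq"] * tt + ph[1])
        ap[idx] <- env * 0.7 * p["amp"] * sin(2 * pi * p["freq"] * tt + ph[2])
        ml[idx] <- env * 0.5 * p["amp"] * sin(2 * pi * p["freq"] * tt + ph[3])
      }
    }
    ax <- list(x = ap, y = ml, z = numeric(n))
    ax[[cfg$vertical_axis]] <- cfg$vertical_sign * vert
    if (cfg$noise_sd_g > 0)
      for (a in c("x", "y", "z"))
        ax[[a]] <- ax[[a]] + rnorm(n, sd = cfg$noise_sd_g)
    rec <- new_accel_recording((seq_len(n) - 1L) / fs, ax$x, ax$y, ax$z, fs,
                               subject_id = profile$subject_id)

    # truth tables
    runs <- function(code) {
      rr <- rle(lab == code)
      e <- cumsum(rr$lengths); s <- e - rr$lengths + 1L
      keep <- rr$values
      data.frame(start_s = s[keep] - 1, end_s = e[keep])
    }
    nonwear_intervals <- runs(1L)
    # 60-s epoch intensity truth: majority second label; gait counts as light
    lab_epoch <- .CLASS_LEVELS[apply(matrix(lab, nrow = 60L), 2L, function(v) {
      v[v == gait_code] <- 3L
      as.integer(names(which.max(table(v))))
    })]
    class_seconds <- vapply(seq_along(.CLASS_LEVELS),
                            function(k) sum(lab == k), numeric(1))
    names(class_seconds) <- .CLASS_LEVELS
    truth <- structure(list(
      bout_intervals = if (is.null(bout_tab))
        data.frame(start_s = numeric(0), end_s = numeric(0),
                   cadence_spm = numeric(0), step_frac = numeric(0))
      else bout_tab[order(bout_tab$start_s), ],
      nonwear_intervals = nonwear_intervals,
      intensity_epochs = data.frame(
        epoch_start_s = (seq_along(lab_epoch) - 1) * 60,
        intensity = lab_epoch),
      class_seconds = class_seconds),
      class = "free_living_truth")
    list(recording = rec, truth = truth)
  })
}

#' Simulate comfort-questionnaire responses
#'
#' Draws `n_subjects` x 10 Likert responses i.i.d. from a distribution over
#' the five response levels.
#'
#' @param n_subjects number of respondents.
#' @param response_distribution probability vector of length 5 over
#'   [likert_levels()] (least to most favorable); must sum to 1.
#' @param seed integer seed.
#' @return data.frame with `subject_id` and columns `q01`..`q10` (character).
#' @export
simulate_questionnaire <- function(n_subjects,
                                   response_distribution = rep(0.2, 5),
                                   seed = 1L) {
  p <- response_distribution
  if (length(p) != 5L || any(p < 0) || abs(sum(p) - 1) > 1e-8)
    stop("response_distribution must be 5 non-negative probabilities summing to 1")
  local_seed(seed, {
    m <- matrix(sample(likert_levels(), n_subjects * 10L, replace = TRUE,
                       prob = p),
                nrow = n_subjects)
    df <- as.data.frame(m, stringsAsFactors = FALSE)
    names(df) <- sprintf("q%02d", 1:10)
    cbind(data.frame(subject_id = sprintf("S%03d", seq_len(n_subjects))), df)
  })
}

#' Write / read accelerometry CSV
#'
#' CSV dialect: `timestamp` (ISO-8601, millisecond precision) and `x`, `y`,
#' `z` in g.
#'
#' @param recording an `accel_recording`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_accel_csv <- function(recording, path) {
  stopifnot(inherits(recording, "accel_recording"))
  ts <- recording$start_time + recording$data$time_s
  df <- data.frame(timestamp = format(ts, "%Y-%m-%dT%H:%M:%OS3", tz = "UTC"),
                   x = recording$data$x, y = recording$data$y,
                   z = recording$data$z)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_accel_csv
#' @param wear_site,subject_id metadata attached to the returned recording.
#' @export
read_accel_csv <- function(path, wear_site = "lumbar", subject_id = "S01") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("timestamp", "x", "y", "z") %in% names(df)))
  ts <- as.POSIXct(df$timestamp, format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
  time_s <- as.numeric(ts) - as.numeric(ts[1])
  # infer rate from the full span: robust to millisecond timestamp rounding
  fs <- (length(time_s) - 1) / (time_s[length(time_s)] - time_s[1])
  new_accel_recording(time_s, df$x, df$y, df$z, round(fs, 3),
                      start_time = ts[1], wear_site = wear_site,
                      subject_id = subject_id)
}

#' Write / read ground-truth JSON sidecar
#'
#' Intervals are seconds from recording start, half-open.
#' @param truth a `gait_truth` or `free_living_truth`.
#' @param path output file.
#' @export
write_truth_json <- function(truth, path) {
  kind <- class(truth)[1]
  jsonlite::write_json(c(list(kind = kind), unclass(truth)), path,
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  kind <- obj$kind
  obj$kind <- NULL
  for (nm in names(obj)) if (is.list(obj[[nm]]) && !is.data.frame(obj[[nm]]) &&
                             all(vapply(obj[[nm]], is.atomic, logical(1))) &&
                             length(unique(lengths(obj[[nm]]))) == 1L)
    obj[[nm]] <- as.data.frame(obj[[nm]])
  structure(obj, class = kind)
}
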