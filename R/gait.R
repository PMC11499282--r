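# Gait event detection and temporal/spatial metrics from lumbar vertical
# acceleration: smoothing-wavelet contact detection, then an inverted-pendulum
# step-length model driven by the doubly integrated vertical signal.

#' Gait algorithm parameters
#'
#' @param stride_time_bounds_s admissible stride time (s); strides outside are
#'   discarded. Kept constant across walking speeds.
#' @param step_time_bounds_s admissible step time (s); contact events implying
#'   shorter steps are pruned.
#' @param cwt_center_freq center frequency (cycles per unit scale) of the
#'   Gaussian-derivative smoothing wavelet; the working scale is
#'   `cwt_center_freq * fs / f_step` with `f_step` the dominant step frequency.
#' @param lowpass_hz pre-integration low-pass cutoff (Hz).
#' @param spatial_lowpass_hz low-pass cutoff used before double integration for
#'   the displacement estimate (Hz).
#' @param highpass_hz zero-phase high-pass cutoff applied after each
#'   integration stage to suppress drift (Hz).
#' @param leg_length_factor pendulum length as a fraction of body height.
#' @param peak_frac minimum wavelet-peak depth, as a fraction of the largest
#'   peak, for a candidate contact event to be kept.
#' @return a `gait_params` list.
#' @export
gait_params <- function(stride_time_bounds_s = c(0.25, 2.25),
                        step_time_bounds_s = c(0.1, 1.5),
                        cwt_center_freq = 0.2,
                        lowpass_hz = 10,
                        spatial_lowpass_hz = 4,
                        highpass_hz = 0.5,
                        leg_length_factor = 0.53,
                        peak_frac = 0.25) {
  stopifnot(stride_time_bounds_s[1] > 0,
            stride_time_bounds_s[1] < stride_time_bounds_s[2],
            step_time_bounds_s[1] > 0,
            step_time_bounds_s[1] < step_time_bounds_s[2],
            leg_length_factor > 0, leg_length_factor < 1,
            peak_frac >= 0, peak_frac < 1)
  structure(list(stride_time_bounds_s = stride_time_bounds_s,
                 step_time_bounds_s = step_time_bounds_s,
                 cwt_center_freq = cwt_center_freq,
                 lowpass_hz = lowpass_hz,
                 spatial_lowpass_hz = spatial_lowpass_hz,
                 highpass_hz = highpass_hz,
                 leg_length_factor = leg_length_factor,
                 peak_frac = peak_frac),
            class = "gait_params")
}

#' Identify the vertical axis of a recording
#'
#' The vertical axis is the one whose gravity (low-frequency) component has the
#' largest absolute mean; the sign makes gravity positive.
#'
#' @param recording an `accel_recording`.
#' @return list with `axis` ("x"/"y"/"z"), `index` (1-3) and `sign` (+1/-1).
#' @export
find_vertical_axis <- function(recording) {
  stopifnot(inherits(recording, "accel_recording"))
  if (nrow(recording$data) < recording$fs_hz)
    stop("recording shorter than 1 s")
  mu <- vapply(recording$data[, c("x", "y", "z")], mean, numeric(1))
  if (max(abs(mu)) < 0.1)
    stop("no gravity component found: signal is (near) all-zero")
  i <- which.max(abs(mu))
  list(axis = c("x", "y", "z")[i], index = unname(i),
       sign = unname(sign(mu[i])))
}

# vertical acceleration (g), gravity-positive, from a recording
vertical_signal <- function(recording) {
  va <- find_vertical_axis(recording)
  va$sign * recording$data[[va$axis]]
}

# cross-correlation of x with a Gaussian-derivative smoothing kernel at scale
# `a` samples; response approximates minus the smoothed derivative of x
gausd_smooth <- function(x, a) {
  half <- max(3L, ceiling(4 * a))
  j <- (-half):half
  k <- -(j / a) * exp(-(j / a)^2 / 2) / sqrt(a)
  n <- length(x)
  full <- stats::convolve(x, k, type = "open")  # sum x[m] k[i - m + 1]... length n+2*half
  full[(half + 1L):(half + n)]
}

# prune peak candidates so consecutive events are >= min_sep_s apart,
# dropping the weaker member of each offending pair
enforce_min_separation <- function(times, depths, min_sep_s) {
  repeat {
    if (length(times) < 2L) break
    gaps <- diff(times)
    bad <- which(gaps < min_sep_s)
    if (!length(bad)) break
    i <- bad[1]
    drop <- if (depths[i] < depths[i + 1]) i else i + 1L
    times <- times[-drop]; depths <- depths[-drop]
  }
  list(times = times, depths = depths)
}

#' Detect initial and final contact events
#'
#' Pipeline: detrend, low-pass, cumulative integration, then a continuous
#' wavelet transform with a Gaussian-derivative smoothing wavelet whose scale
#' is tied to the dominant step frequency. Initial contacts are local minima
#' of the first-stage transform; final contacts are local maxima of its
#' differentiated (second-stage) transform. Events violating the step-time
#' bound are pruned; feet are assigned by alternation (left/right labels are
#' arbitrary up to a swap).
#'
#' @param vertical_accel vertical acceleration (g), gravity-positive.
#' @param fs_hz sampling rate (>= 20 Hz).
#' @param params a [gait_params()].
#' @return data.frame of events: `time_s`, `kind` ("IC"/"FC"), `foot`.
#' @export
detect_contact_events <- function(vertical_accel, fs_hz, params = gait_params()) {
  if (fs_hz < 20) stop("sampling rate below the 20 Hz minimum for event detection")
  n <- length(vertical_accel)
  if (n / fs_hz < 2 * params$stride_time_bounds_s[2])
    stop("signal too short: need at least two maximal stride times")
  x <- vertical_accel - mean(vertical_accel)
  if (sd(x) < 1e-6) {  # motionless
    return(data.frame(time_s = numeric(0), kind = character(0),
                      foot = character(0)))
  }
  xf <- butter_filtfilt(x, fs_hz, min(params$lowpass_hz, 0.45 * fs_hz), "low")
  v <- cumtrapz_uniform(xf, fs_hz)
  v <- v - mean(v)
  f_step <- dominant_frequency(xf, fs_hz, f_lo = 2 / params$stride_time_bounds_s[2],
                               f_hi = min(2 / params$step_time_bounds_s[1], 0.45 * fs_hz))
  a <- params$cwt_center_freq * fs_hz / f_step
  c1 <- gausd_smooth(v, a)
  edge <- ceiling(4 * a)
  valid <- function(idx) idx[idx > edge & idx <= n - edge]

  ic_idx <- valid(local_extrema(c1, "min"))
  ic_depth <- mean(c1) - c1[ic_idx]
  keep <- ic_depth >= params$peak_frac * max(ic_depth, 0)
  ic_idx <- ic_idx[keep]; ic_depth <- ic_depth[keep]
  ic <- enforce_min_separation((ic_idx - 1L) / fs_hz, ic_depth,
                               params$step_time_bounds_s[1])

  c2 <- gausd_smooth(c1, a)
  fc_idx <- valid(local_extrema(c2, "max"))
  fc_h <- c2[fc_idx] - mean(c2)
  keep <- fc_h >= params$peak_frac * max(fc_h, 0)
  fc_idx <- fc_idx[keep]; fc_h <- fc_h[keep]
  fc <- enforce_min_separation((fc_idx - 1L) / fs_hz, fc_h,
                               params$step_time_bounds_s[1])

  ev <- rbind(
    if (length(ic$times)) data.frame(time_s = ic$times, kind = "IC",
                                     foot = rep_len(c("L", "R"), length(ic$times))),
    if (length(fc$times)) data.frame(time_s = fc$times, kind = "FC",
                                     foot = "unknown"))
  if (is.null(ev) || !nrow(ev))
    return(data.frame(time_s = numeric(0), kind = character(0),
                      foot = character(0)))
  ev <- ev[order(ev$time_s), , drop = FALSE]
  # FC foot: opposite of the nearest preceding IC (stance of the other foot)
  ics <- ev[ev$kind == "IC", ]
  if (nrow(ics)) {
    fcs <- which(ev$kind == "FC")
    for (i in fcs) {
      prev <- ics$foot[ics$time_s < ev$time_s[i]]
      if (length(prev))
        ev$foot[i] <- if (tail(prev, 1) == "L") "R" else "L"
    }
  }
  rownames(ev) <- NULL
  ev
}

#' Temporal gait metrics
#'
#' Forms one stride per pair of consecutive same-foot initial contacts.
#' Strides whose duration falls outside the physiological stride-time bounds
#' (e.g. spanning a detection gap) are not formed. Double support is the sum
#' of the two contact-overlap intervals bounded by the detected final
#' contacts.
#'
#' @param events event data.frame from [detect_contact_events()].
#' @param params a [gait_params()].
#' @return a `stride_table` data.frame (possibly 0 rows when fewer than three
#'   initial contacts are available): `start_ic_s`, `end_ic_s`, `foot`,
#'   `stride_time_s`, `step_time_s`, `double_support_s`, `cadence_spm`,
#'   `stride_length_m`, `speed_mps` (spatial columns NA until
#'   [spatial_metrics()] runs).
#' @export
temporal_metrics <- function(events, params = gait_params()) {
  empty <- data.frame(start_ic_s = numeric(0), end_ic_s = numeric(0),
                      foot = character(0), stride_time_s = numeric(0),
                      step_time_s = numeric(0), double_support_s = numeric(0),
                      cadence_spm = numeric(0), stride_length_m = numeric(0),
                      speed_mps = numeric(0))
  class(empty) <- c("stride_table", "data.frame")
  ic <- events[events$kind == "IC", , drop = FALSE]
  fc <- events[events$kind == "FC", , drop = FALSE]
  if (nrow(ic) < 3L) return(empty)
  ic <- ic[order(ic$time_s), ]
  out <- NULL
  for (i in seq_len(nrow(ic) - 2L)) {
    st <- ic$time_s[i + 2L] - ic$time_s[i]
    if (st < params$stride_time_bounds_s[1] || st > params$stride_time_bounds_s[2])
      next
    step <- ic$time_s[i + 1L] - ic$time_s[i]
    if (step < params$step_time_bounds_s[1] || step > params$step_time_bounds_s[2])
      step <- NA_real_
    ds <- NA_real_
    f1 <- fc$time_s[fc$time_s > ic$time_s[i] & fc$time_s < ic$time_s[i + 1L]]
    f2 <- fc$time_s[fc$time_s > ic$time_s[i + 1L] & fc$time_s < ic$time_s[i + 2L]]
    if (length(f1) && length(f2))
      ds <- (f1[1] - ic$time_s[i]) + (f2[1] - ic$time_s[i + 1L])
    out <- rbind(out, data.frame(
      start_ic_s = ic$time_s[i], end_ic_s = ic$time_s[i + 2L],
      foot = ic$foot[i], stride_time_s = st, step_time_s = step,
      double_support_s = ds, cadence_spm = 120 / st,
      stride_length_m = NA_real_, speed_mps = NA_real_))
  }
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  class(out) <- c("stride_table", "data.frame")
  out
}

#' Spatial gait metrics via the inverted-pendulum model
#'
#' Estimates the vertical center-of-mass excursion of each step from the
#' doubly integrated, high-pass-filtered vertical acceleration (excursion =
#' max - min of displacement within the step), then applies the
#' inverted-pendulum chord formula `step_length = 2 * sqrt(2*l*h - h^2)` with
#' pendulum length `l = leg_length_factor * height`. Stride length is the sum
#' of the two step lengths; gait speed is stride length over stride time.
#'
#' @param strides a `stride_table` from [temporal_metrics()].
#' @param vertical_accel vertical acceleration (g), gravity-positive.
#' @param fs_hz sampling rate (Hz).
#' @param height_m subject height (m), > 0.
#' @param params a [gait_params()].
#' @return the stride table with `stride_length_m` and `speed_mps` filled;
#'   strides with a degenerate excursion (h >= 2l) are dropped.
#' @export
spatial_metrics <- function(strides, vertical_accel, fs_hz, height_m,
                            params = gait_params()) {
  stopifnot(height_m > 0)
  if (!nrow(strides)) return(strides)
  l <- params$leg_length_factor * height_m
  a <- (vertical_accel - mean(vertical_accel)) * GRAVITY_MS2
  a <- butter_filtfilt(a, fs_hz, min(params$spatial_lowpass_hz, 0.45 * fs_hz), "low")
  v <- cumtrapz_uniform(a, fs_hz)
  v <- butter_filtfilt(v, fs_hz, params$highpass_hz, "high")
  d <- cumtrapz_uniform(v, fs_hz)
  d <- butter_filtfilt(d, fs_hz, params$highpass_hz, "high")
  n <- length(d)
  step_len_in <- function(t0, t1) {
    i0 <- max(1L, floor(t0 * fs_hz) + 1L)
    i1 <- min(n, ceiling(t1 * fs_hz))
    if (i1 - i0 < 2L) return(NA_real_)
    h <- max(d[i0:i1]) - min(d[i0:i1])
    if (h >= 2 * l) return(NA_real_)   # degenerate pendulum geometry
    2 * sqrt(2 * l * h - h^2)
  }
  sl <- sp <- rep(NA_real_, nrow(strides))
  for (k in seq_len(nrow(strides))) {
    mid <- if (is.na(strides$step_time_s[k]))
      strides$start_ic_s[k] + strides$stride_time_s[k] / 2
    else strides$start_ic_s[k] + strides$step_time_s[k]
    s1 <- step_len_in(strides$start_ic_s[k], mid)
    s2 <- step_len_in(mid, strides$end_ic_s[k])
    if (!is.na(s1) && !is.na(s2)) {
      sl[k] <- s1 + s2
      sp[k] <- sl[k] / strides$stride_time_s[k]
    }
  }
  strides$stride_length_m <- sl
  strides$speed_mps <- sp
  strides[!is.na(strides$stride_length_m), , drop = FALSE]
}

#' Analyze a walkway pass end to end
#'
#' Convenience wrapper: vertical-axis identification, contact-event detection,
#' temporal metrics and inverted-pendulum spatial metrics, plus per-pass means.
#'
#' @param recording an `accel_recording` of a single pass.
#' @param height_m subject height (m).
#' @param params a [gait_params()].
#' @return list with `events`, `strides` and `summary` (one-row data.frame of
#'   per-pass mean cadence, stride time, stride length and gait speed).
#' @export
analyze_pass <- function(recording, height_m, params = gait_params()) {
  va <- vertical_signal(recording)
  events <- detect_contact_events(va, recording$fs_hz, params)
  strides <- temporal_metrics(events, params)
  strides <- spatial_metrics(strides, va, recording$fs_hz, height_m, params)
  summary <- if (nrow(strides)) {
    data.frame(cadence_spm = mean(strides$cadence_spm),
               stride_time_s = mean(strides$stride_time_s),
               stride_length_m = mean(strides$stride_length_m),
               gait_speed_mps = mean(strides$speed_mps),
               n_strides = nrow(strides))
  } else {
    data.frame(cadence_spm = NA_real_, stride_time_s = NA_real_,
               stride_length_m = NA_real_, gait_speed_mps = NA_real_,
               n_strides = 0L)
  }
  list(events = events, strides = strides, summary = summary)
}
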