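# Free-living gait-bout detection: windowed features, a gradient-boosted tree
# classifier, a deterministic band-power fallback, and bout post-processing.

#' Windowing configuration for bout detection
#'
#' @param window_s window length (s).
#' @param hop_s hop between window starts (s); default 50% overlap.
#' @param merge_gap_s positive windows closer than this are merged into one
#'   bout.
#' @return a list.
#' @export
window_config <- function(window_s = 3, hop_s = window_s / 2, merge_gap_s = 3) {
  stopifnot(window_s > 0, hop_s > 0, hop_s <= window_s, merge_gap_s >= 0)
  list(window_s = window_s, hop_s = hop_s, merge_gap_s = merge_gap_s)
}

#' Per-window features for gait classification
#'
#' Deterministic summary features per sliding window: per-axis mean and
#' standard deviation, signal magnitude area, dominant frequency of the
#' detrended vector magnitude in the locomotor band with its power fraction,
#' and the autocorrelation of the vertical axis at the estimated step lag.
#' Window count is `floor((T - window) / hop) + 1`.
#'
#' @param recording an `accel_recording`.
#' @param window_cfg a [window_config()].
#' @return data.frame, one row per window, first column `start_s`.
#' @export
extract_features <- function(recording, window_cfg = window_config()) {
  stopifnot(inherits(recording, "accel_recording"))
  fs <- recording$fs_hz
  w <- round(window_cfg$window_s * fs)
  hop <- round(window_cfg$hop_s * fs)
  n <- nrow(recording$data)
  if (n < w) stop("recording shorter than one window")
  n_win <- (n - w) %/% hop + 1L
  X <- recording$data$x; Y <- recording$data$y; Z <- recording$data$z
  va <- vertical_signal(recording)
  cols <- c("start_s", "mean_x", "mean_y", "mean_z", "sd_x", "sd_y", "sd_z",
            "sma", "dom_freq_hz", "dom_power_frac", "step_autocorr",
            "harmonic_ratio", "subharmonic_frac")
  out <- matrix(0, n_win, length(cols), dimnames = list(NULL, cols))
  for (k in seq_len(n_win)) {
    i0 <- (k - 1L) * hop + 1L
    ix <- i0:(i0 + w - 1L)
    xs <- X[ix]; ys <- Y[ix]; zs <- Z[ix]
    vm <- sqrt(xs^2 + ys^2 + zs^2)
    vmd <- vm - mean(vm)
    sdv <- sd(vmd)
    if (sdv > 1e-12) {
      f0 <- dominant_frequency(vmd, fs, 0.5, min(5, 0.45 * fs))
      pfrac <- band_power_fraction(vmd, fs, max(0.25, f0 - 0.5), f0 + 0.5)
      lag <- max(1L, round(fs / f0))
      vs <- va[ix] - mean(va[ix])
      ac <- if (lag < w - 2L && sd(vs) > 1e-12)
        suppressWarnings(cor(vs[1:(w - lag)], vs[(lag + 1):w])) else 0
      if (is.na(ac)) ac <- 0
      hr <- harmonic_ratio(vs, fs, f0)
      sub <- subharmonic_frac(xs, ys, zs, va[ix], fs, f0)
    } else {
      f0 <- 0; pfrac <- 0; ac <- 0; hr <- 0; sub <- 0
    }
    out[k, ] <- c((i0 - 1L) / fs, mean(xs), mean(ys), mean(zs),
                  sd(xs), sd(ys), sd(zs),
                  mean(abs(xs - mean(xs)) + abs(ys - mean(ys)) +
                         abs(zs - mean(zs))),
                  f0, pfrac, ac, hr, sub)
  }
  as.data.frame(out)
}

#' Train the gait-bout classifier
#'
#' Gradient-boosted decision trees (binary logistic) on window features.
#' Training is reproducible under `seed` and single-threaded.
#'
#' @param features data.frame from [extract_features()] (the `start_s` column
#'   is ignored).
#' @param labels logical/0-1 vector: TRUE for gait windows.
#' @param seed integer seed.
#' @param nrounds boosting rounds.
#' @return a `bout_model` list (`booster`, `feature_names`, `version`).
#' @export
train_bout_classifier <- function(features, labels, seed = 1L, nrounds = 50L) {
  labels <- as.integer(as.logical(labels))
  if (length(unique(labels)) < 2L)
    stop("both classes must be present in the training labels")
  fn <- setdiff(names(features), "start_s")
  X <- as.matrix(features[, fn])
  local_seed(seed, {
    booster <- xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = 4L,
                    eta = 0.3, nthread = 1L, seed = seed),
      data = xgboost::xgb.DMatrix(X, label = labels, nthread = 1L),
      nrounds = nrounds, verbose = 0)
    structure(list(booster = booster, feature_names = fn, version = "1"),
              class = "bout_model")
  })
}

#' Save / load a bout model
#'
#' Portable serialized format: a raw xgboost model plus a JSON header with the
#' feature names and a format version.
#' @param model a `bout_model`.
#' @param path file path (RDS container holding header + raw booster bytes).
#' @export
save_bout_model <- function(model, path) {
  stopifnot(inherits(model, "bout_model"))
  saveRDS(list(version = model$version, feature_names = model$feature_names,
               raw = xgboost::xgb.save.raw(model$booster)), path)
  invisible(path)
}

#' @rdname save_bout_model
#' @export
load_bout_model <- function(path) {
  obj <- readRDS(path)
  structure(list(booster = xgboost::xgb.load.raw(obj$raw),
                 feature_names = obj$feature_names, version = obj$version),
            class = "bout_model")
}

#' Predict gait probability per window
#' @param model a `bout_model`.
#' @param features data.frame from [extract_features()].
#' @return numeric vector of gait probabilities.
#' @export
predict_gait_windows <- function(model, features) {
  stopifnot(inherits(model, "bout_model"))
  predict(model$booster,
          xgboost::xgb.DMatrix(as.matrix(features[, model$feature_names]),
                               nthread = 1L))
}

# second-harmonic to fundamental power ratio of a detrended signal; walking's
# contact impulses leave a harmonic comb that smooth periodic motion lacks
harmonic_ratio <- function(x, fs, f0) {
  if (f0 <= 0 || 2.3 * f0 >= fs / 2) return(0)
  p1 <- band_power_fraction(x, fs, 0.75 * f0, 1.25 * f0)
  p2 <- band_power_fraction(x, fs, 1.75 * f0, 2.25 * f0)
  if (p1 <= 0) return(0)
  p2 / p1
}

# horizontal-axes power fraction at half the dominant frequency: gait has a
# stride-frequency (subharmonic) component in the mediolateral direction
subharmonic_frac <- function(xs, ys, zs, va, fs, f0) {
  if (f0 <= 0.6) return(0)
  horiz <- list(xs, ys, zs)
  # drop the axis closest to the vertical signal
  cors <- vapply(horiz, function(h) abs(suppressWarnings(cor(h, va))), numeric(1))
  cors[is.na(cors)] <- 0
  horiz <- horiz[-which.max(cors)]
  mean(vapply(horiz, function(h)
    band_power_fraction(h, fs, 0.4 * f0, 0.6 * f0), numeric(1)))
}

# merge positive windows into half-open bout intervals, bridging short gaps
windows_to_bouts <- function(start_s, positive, window_s, merge_gap_s) {
  if (!any(positive)) return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  iv <- cbind(start_s[positive], start_s[positive] + window_s)
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  out <- iv[1, , drop = FALSE]
  if (nrow(iv) > 1) for (i in 2:nrow(iv)) {
    if (iv[i, 1] <= out[nrow(out), 2] + merge_gap_s) {
      out[nrow(out), 2] <- max(out[nrow(out), 2], iv[i, 2])
    } else out <- rbind(out, iv[i, ])
  }
  data.frame(start_s = out[, 1], end_s = out[, 2])
}

# run the gait module inside each bout interval to populate strides
populate_bout_strides <- function(recording, bouts, height_m,
                                  params = gait_params()) {
  va <- vertical_signal(recording)
  fs <- recording$fs_hz
  strides <- vector("list", nrow(bouts))
  n_cycles <- integer(nrow(bouts))
  for (i in seq_len(nrow(bouts))) {
    i0 <- max(1L, floor(bouts$start_s[i] * fs) + 1L)
    i1 <- min(length(va), ceiling(bouts$end_s[i] * fs))
    seg <- va[i0:i1]
    st <- tryCatch({
      ev <- detect_contact_events(seg, fs, params)
      s <- temporal_metrics(ev, params)
      if (nrow(s) && !is.null(height_m))
        s <- spatial_metrics(s, seg, fs, height_m, params)
      s
    }, error = function(e) temporal_metrics(
      data.frame(time_s = numeric(0), kind = character(0), foot = character(0)),
      params))
    if (nrow(st)) {
      st$start_ic_s <- st$start_ic_s + bouts$start_s[i]
      st$end_ic_s <- st$end_ic_s + bouts$start_s[i]
    }
    strides[[i]] <- st
    n_cycles[i] <- nrow(st)
  }
  bouts$n_gait_cycles <- n_cycles
  structure(list(bouts = bouts, strides = strides), class = "gait_bouts")
}

#' Detect gait bouts with a trained classifier
#'
#' Classifies sliding windows, merges positive windows into bouts (gaps up to
#' `merge_gap_s` bridged), then runs the gait module inside each bout to
#' populate strides and `n_gait_cycles`.
#'
#' @param recording an `accel_recording`.
#' @param model a `bout_model` from [train_bout_classifier()].
#' @param window_cfg a [window_config()].
#' @param height_m subject height for spatial metrics (NULL skips them).
#' @param params a [gait_params()].
#' @param threshold probability threshold for a positive window.
#' @return a `gait_bouts` list: `bouts` (data.frame `start_s`, `end_s`,
#'   `n_gait_cycles`) and `strides` (list of stride tables).
#' @export
detect_gait_bouts <- function(recording, model, window_cfg = window_config(),
                              height_m = NULL, params = gait_params(),
                              threshold = 0.5) {
  feats <- extract_features(recording, window_cfg)
  prob <- predict_gait_windows(model, feats)
  bouts <- windows_to_bouts(feats$start_s, prob >= threshold,
                            window_cfg$window_s, window_cfg$merge_gap_s)
  populate_bout_strides(recording, bouts, height_m, params)
}

#' Deterministic fallback bout detector
#'
#' Thresholds the locomotor-band (1.2-4 Hz) power of the vertical axis per
#' window and requires the harmonic comb that foot-contact impulses leave in
#' the spectrum: a window is gait when the band holds at least `power_frac` of
#' the signal power, the second-harmonic/fundamental power ratio exceeds
#' `min_harmonic_ratio`, and the windowed standard deviation exceeds
#' `min_sd_g`. Needs no trained model, so the pipeline always runs.
#'
#' @inheritParams detect_gait_bouts
#' @param power_frac minimum locomotor-band power fraction.
#' @param min_sd_g minimum within-window standard deviation (g).
#' @param min_harmonic_ratio minimum second-harmonic to fundamental power
#'   ratio of the vertical signal.
#' @return a `gait_bouts` list, as [detect_gait_bouts()].
#' @export
detect_gait_bouts_bandpower <- function(recording, window_cfg = window_config(),
                                        height_m = NULL, params = gait_params(),
                                        power_frac = 0.5, min_sd_g = 0.05,
                                        min_harmonic_ratio = 5e-4) {
  fs <- recording$fs_hz
  va <- vertical_signal(recording)
  w <- round(window_cfg$window_s * fs)
  hop <- round(window_cfg$hop_s * fs)
  n <- length(va)
  if (n < w) stop("recording shorter than one window")
  n_win <- (n - w) %/% hop + 1L
  pos <- logical(n_win)
  starts <- ((seq_len(n_win) - 1L) * hop) / fs
  for (k in seq_len(n_win)) {
    ix <- ((k - 1L) * hop + 1L):((k - 1L) * hop + w)
    seg <- va[ix]
    if (sd(seg) < min_sd_g) next
    segd <- seg - mean(seg)
    bp <- band_power_fraction(segd, fs, 1.2, 4)
    if (bp < power_frac) next
    f0 <- dominant_frequency(segd, fs, 0.3, min(6, 0.45 * fs))
    pos[k] <- f0 >= 1.2 && f0 <= 4 &&
      harmonic_ratio(segd, fs, f0) >= min_harmonic_ratio
  }
  bouts <- windows_to_bouts(starts, pos, window_cfg$window_s,
                            window_cfg$merge_gap_s)
  populate_bout_strides(recording, bouts, height_m, params)
}
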