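# Epoch activity counts (open surrogate for proprietary device counts),
# Choi non-wear detection, and intensity classification with daily totals.

#' Count-computation parameters
#'
#' The count surrogate band-pass filters each axis (body-movement band),
#' rectifies, applies a deadband and clip, and sums per epoch. It is an open
#' stand-in for proprietary device counts; intensity cut-points shipped with
#' the package are calibrated against the synthetic generator's class
#' energies.
#'
#' @param band_hz band-pass corner frequencies (Hz).
#' @param order Butterworth order.
#' @param deadband_g rectified samples below this are zeroed, so a motionless
#'   (gravity + instrument noise) signal yields exactly zero counts.
#' @param clip_g rectified samples are capped here.
#' @return a `count_params` list.
#' @export
count_params <- function(band_hz = c(0.25, 2.5), order = 4L,
                         deadband_g = 0.05, clip_g = 2.5) {
  stopifnot(band_hz[1] > 0, band_hz[1] < band_hz[2],
            deadband_g >= 0, clip_g > deadband_g)
  structure(list(band_hz = band_hz, order = order,
                 deadband_g = deadband_g, clip_g = clip_g),
            class = "count_params")
}

#' Choi non-wear parameters
#'
#' Canonical parameters of the Choi non-wear algorithm on 1-min epochs.
#'
#' @param window_min minimum length (min) of a zero-count run to call non-wear.
#' @param spike_tolerance_min nonzero interruptions up to this length are
#'   absorbed when flanked by long zero runs.
#' @param flanking_zero_min required zero-run length on both sides of a spike.
#' @return a `choi_params` list.
#' @export
choi_params <- function(window_min = 90L, spike_tolerance_min = 2L,
                        flanking_zero_min = 30L) {
  stopifnot(spike_tolerance_min < window_min, flanking_zero_min > 0)
  structure(list(window_min = window_min,
                 spike_tolerance_min = spike_tolerance_min,
                 flanking_zero_min = flanking_zero_min),
            class = "choi_params")
}

#' Per-epoch activity counts
#'
#' Per axis: band-pass filter, rectify, deadband, clip, and sum per epoch
#' (unit: g.s). The vector magnitude is the Euclidean norm of the three axis
#' counts. When `cv_subepochs > 1` the within-epoch coefficient of variation
#' of sub-epoch vector-magnitude counts is also returned (used by the optional
#' two-regression intensity mode).
#'
#' @param recording an `accel_recording`.
#' @param epoch_len_s epoch length (s), default 60; must divide the day.
#' @param params a [count_params()].
#' @param cv_subepochs number of sub-epochs per epoch for the CV column.
#' @return data.frame: `epoch_start_s`, `counts_x`, `counts_y`, `counts_z`,
#'   `vector_magnitude`, `vm_cv_pct`.
#' @export
epoch_counts <- function(recording, epoch_len_s = 60, params = count_params(),
                         cv_subepochs = 6L) {
  stopifnot(inherits(recording, "accel_recording"))
  fs <- recording$fs_hz
  spe <- epoch_len_s * fs
  if (abs(spe - round(spe)) > 1e-9) stop("epoch length must be an integer number of samples")
  if (86400 %% epoch_len_s != 0) stop("epoch_len_s must divide the day cleanly")
  spe <- as.integer(round(spe))
  n <- nrow(recording$data)
  if (n < spe) stop("epoch longer than recording")
  n_ep <- n %/% spe
  used <- n_ep * spe
  rect <- matrix(0, used, 3)
  for (j in 1:3) {
    a <- recording$data[[c("x", "y", "z")[j]]][seq_len(used)]
    bp <- butter_filtfilt(a - mean(a), fs,
                          c(params$band_hz[1], min(params$band_hz[2], 0.45 * fs)),
                          "pass", params$order)
    rect[, j] <- pmin(pmax(abs(bp) - params$deadband_g, 0), params$clip_g)
  }
  ep_of <- rep(seq_len(n_ep), each = spe)
  cx <- rowsum(rect[, 1], ep_of) / fs
  cy <- rowsum(rect[, 2], ep_of) / fs
  cz <- rowsum(rect[, 3], ep_of) / fs
  vm <- sqrt(cx^2 + cy^2 + cz^2)
  vm_cv <- rep(NA_real_, n_ep)
  if (cv_subepochs > 1L && spe %% cv_subepochs == 0L) {
    sub_of <- rep(seq_len(n_ep * cv_subepochs), each = spe %/% cv_subepochs)
    sx <- rowsum(rect[, 1], sub_of) / fs
    sy <- rowsum(rect[, 2], sub_of) / fs
    sz <- rowsum(rect[, 3], sub_of) / fs
    svm <- matrix(sqrt(sx^2 + sy^2 + sz^2), nrow = cv_subepochs)
    mu <- colMeans(svm)
    s <- apply(svm, 2, sd)
    vm_cv <- ifelse(mu > 0, 100 * s / mu, 0)
  }
  data.frame(epoch_start_s = (seq_len(n_ep) - 1) * epoch_len_s,
             counts_x = as.numeric(cx), counts_y = as.numeric(cy),
             counts_z = as.numeric(cz), vector_magnitude = as.numeric(vm),
             vm_cv_pct = vm_cv)
}

#' Choi non-wear detection
#'
#' Flags non-wear on contiguous 1-min-scale epochs: a run of at least
#' `window_min` zero-count epochs is non-wear; runs may contain nonzero
#' "spikes" of up to `spike_tolerance_min` epochs when flanked by at least
#' `flanking_zero_min` zero-count epochs on both sides. Everything else is
#' wear.
#'
#' @param epochs data.frame from [epoch_counts()] (contiguous epochs).
#' @param params a [choi_params()].
#' @param epoch_len_s epoch length in seconds (to convert the minute-based
#'   parameters).
#' @return `epochs` with a logical `wear` column.
#' @export
detect_wear <- function(epochs, params = choi_params(), epoch_len_s = 60) {
  if (any(diff(epochs$epoch_start_s) != epoch_len_s))
    stop("epochs must be contiguous")
  per_min <- 60 / epoch_len_s
  win <- ceiling(params$window_min * per_min)
  spike <- floor(params$spike_tolerance_min * per_min)
  flank <- ceiling(params$flanking_zero_min * per_min)
  zero <- epochs$vector_magnitude == 0
  # absorb short nonzero spikes flanked by long zero runs
  r <- rle(zero)
  if (length(r$lengths) > 2L) {
    for (i in 2:(length(r$lengths) - 1L)) {
      if (!r$values[i] && r$lengths[i] <= spike &&
          r$values[i - 1L] && r$lengths[i - 1L] >= flank &&
          r$values[i + 1L] && r$lengths[i + 1L] >= flank) {
        r$values[i] <- TRUE
      }
    }
  }
  r2 <- rle(inverse.rle(r))
  ends <- cumsum(r2$lengths); starts <- ends - r2$lengths + 1L
  nonwear <- rep(FALSE, length(zero))
  for (i in seq_along(r2$values)) {
    if (r2$values[i] && r2$lengths[i] >= win)
      nonwear[starts[i]:ends[i]] <- TRUE
  }
  epochs$wear <- !nonwear
  epochs
}

#' Default intensity cut-points
#'
#' Vector-magnitude count cut-points (g.s per 60-s epoch) separating
#' sedentary/light, light/moderate and moderate/vigorous. Calibrated once
#' against the synthetic generator's activity-class energies (geometric
#' midpoints between adjacent class count levels); they are configuration, not
#' population claims.
#' @return named numeric vector c(c1, c2, c3).
#' @export
default_cutpoints <- function() c(c1 = 6.1, c2 = 32.0, c3 = 63.5)

#' Intensity classification and daily activity totals
#'
#' Maps each wear epoch to an intensity class by vector-magnitude cut-points
#' (`sedentary < c1 <= light < c2 <= moderate < c3 <= vigorous`); non-wear
#' epochs are labeled "nonwear" and excluded from all totals. In the optional
#' two-regression mode the within-epoch CV of counts selects between two MET
#' regression equations and MET cut-points replace count cut-points.
#'
#' @param epochs data.frame from [detect_wear()] (wear flags required).
#' @param cutpoints increasing numeric c(c1, c2, c3).
#' @param epoch_len_s epoch length (s).
#' @param two_regression optional list with `cv_threshold_pct`,
#'   `eq_low = c(intercept, slope)`, `eq_high = c(intercept, slope)` (METs as
#'   a linear function of vector magnitude) and `met_cuts = c(1.5, 3, 6)`.
#' @return list: `epochs` (with `intensity` factor) and `daily` (per-day
#'   data.frame: `day`, `wear_h`, minutes per class, `mvpa_min`,
#'   `total_vm`).
#' @export
classify_intensity <- function(epochs, cutpoints = default_cutpoints(),
                               epoch_len_s = 60, two_regression = NULL) {
  if (is.null(epochs$wear)) stop("wear flags must be computed first")
  if (is.unsorted(cutpoints, strictly = TRUE)) stop("cut-points must be increasing")
  lv <- c("sedentary", "light", "moderate", "vigorous")
  if (is.null(two_regression)) {
    cls <- cut(epochs$vector_magnitude, c(-Inf, cutpoints, Inf),
               labels = lv, right = FALSE)
  } else {
    tr <- two_regression
    eq <- ifelse(!is.na(epochs$vm_cv_pct) & epochs$vm_cv_pct <= tr$cv_threshold_pct,
                 "low", "high")
    mets <- ifelse(eq == "low",
                   tr$eq_low[1] + tr$eq_low[2] * epochs$vector_magnitude,
                   tr$eq_high[1] + tr$eq_high[2] * epochs$vector_magnitude)
    cls <- cut(mets, c(-Inf, tr$met_cuts, Inf), labels = lv, right = FALSE)
  }
  cls <- as.character(cls)
  cls[!epochs$wear] <- "nonwear"
  epochs$intensity <- factor(cls, levels = c(lv, "nonwear"))
  ep_min <- epoch_len_s / 60
  day <- epochs$epoch_start_s %/% 86400
  daily <- do.call(rbind, lapply(split(seq_len(nrow(epochs)), day), function(ix) {
    e <- epochs[ix, ]
    mins <- vapply(c(lv, "nonwear"),
                   function(k) sum(e$intensity == k) * ep_min, numeric(1))
    data.frame(day = e$epoch_start_s[1] %/% 86400,
               wear_h = sum(e$wear) * ep_min / 60,
               sedentary_min = mins["sedentary"], light_min = mins["light"],
               moderate_min = mins["moderate"], vigorous_min = mins["vigorous"],
               nonwear_min = mins["nonwear"],
               mvpa_min = mins["moderate"] + mins["vigorous"],
               total_vm = sum(e$vector_magnitude[e$wear]),
               row.names = NULL)
  }))
  rownames(daily) <- NULL
  list(epochs = epochs, daily = daily)
}
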