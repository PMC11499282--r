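# Study filtering, valid-day, compliance and daily aggregation rules.

#' Validity and filtering rules
#'
#' Thresholds used throughout the at-home analyses: minimum daily wear of 10 h
#' (lumbar) / 18 h (wrist) for a valid day, walking bouts kept only when
#' lasting 10-3000 s with at least four detected gait cycles, and subjects
#' included only with four or more valid compliant days. Boundary values are
#' retained/valid. No missing-data imputation anywhere.
#'
#' @param lumbar_min_wear_h,wrist_min_wear_h minimum wear (h) per valid day.
#' @param bout_min_s,bout_max_s retained bout duration range (s), inclusive.
#' @param min_gait_cycles minimum detected gait cycles per retained bout.
#' @param min_valid_days minimum valid compliant days for subject inclusion.
#' @return a `validity_rules` list.
#' @export
validity_rules <- function(lumbar_min_wear_h = 10, wrist_min_wear_h = 18,
                           bout_min_s = 10, bout_max_s = 3000,
                           min_gait_cycles = 4, min_valid_days = 4) {
  stopifnot(bout_min_s < bout_max_s, lumbar_min_wear_h > 0,
            wrist_min_wear_h > 0, min_gait_cycles >= 0, min_valid_days >= 1)
  structure(list(lumbar_min_wear_h = lumbar_min_wear_h,
                 wrist_min_wear_h = wrist_min_wear_h,
                 bout_min_s = bout_min_s, bout_max_s = bout_max_s,
                 min_gait_cycles = min_gait_cycles,
                 min_valid_days = min_valid_days),
            class = "validity_rules")
}

#' Filter walking bouts by the study rules
#'
#' Keeps a bout iff `bout_min_s <= duration <= bout_max_s` and
#' `n_gait_cycles >= min_gait_cycles` (boundaries retained). Idempotent.
#'
#' @param bouts data.frame with `start_s`, `end_s`, `n_gait_cycles`.
#' @param rules a [validity_rules()].
#' @return the retained subset of `bouts`.
#' @export
filter_bouts <- function(bouts, rules = validity_rules()) {
  dur <- bouts$end_s - bouts$start_s
  keep <- dur >= rules$bout_min_s & dur <= rules$bout_max_s &
    bouts$n_gait_cycles >= rules$min_gait_cycles
  bouts[keep, , drop = FALSE]
}

#' Flag valid days from daily wear time
#'
#' @param daily data.frame with `day` and `wear_h` (e.g. from
#'   [classify_intensity()]).
#' @param site "lumbar" (>= 10 h) or "wrist" (>= 18 h).
#' @param rules a [validity_rules()].
#' @return `daily` with a logical `valid` column; exactly the threshold is
#'   valid.
#' @export
flag_valid_days <- function(daily, site = c("lumbar", "wrist"),
                            rules = validity_rules()) {
  site <- match.arg(site)
  thr <- if (site == "lumbar") rules$lumbar_min_wear_h else rules$wrist_min_wear_h
  daily$valid <- daily$wear_h >= thr
  daily
}

#' Daily gait summary from retained bouts
#'
#' For each gait metric the per-bout median is taken over that bout's strides,
#' then the mean across all walking bouts within the day. The day's 95th
#' percentile gait speed is computed with linear interpolation between order
#' statistics, by default over the per-bout median speeds (set
#' `p95_on = "strides"` for the pooled per-stride alternative).
#'
#' @param gait_bouts a `gait_bouts` object whose `bouts` have already been
#'   filtered with [filter_bouts()]; pass the matching `strides` list.
#' @param day integer day index the summary is for (bouts are assumed already
#'   restricted to it), or NULL to summarize all supplied bouts as one day.
#' @param p95_on "bout_medians" (default) or "strides".
#' @return one-row data.frame of daily gait fields, or NULL when no bout
#'   remains (gait fields absent for the day).
#' @export
daily_gait_summary <- function(gait_bouts, day = NULL,
                               p95_on = c("bout_medians", "strides")) {
  p95_on <- match.arg(p95_on)
  strides <- gait_bouts$strides
  keep <- vapply(strides, function(s) nrow(s) > 0, logical(1))
  strides <- strides[keep]
  if (!length(strides)) return(NULL)
  med <- function(s, col) median(s[[col]], na.rm = TRUE)
  bm <- data.frame(
    cadence_spm = vapply(strides, med, numeric(1), col = "cadence_spm"),
    stride_time_s = vapply(strides, med, numeric(1), col = "stride_time_s"),
    stride_length_m = vapply(strides, med, numeric(1), col = "stride_length_m"),
    speed_mps = vapply(strides, med, numeric(1), col = "speed_mps"))
  speeds_for_p95 <- if (p95_on == "bout_medians") bm$speed_mps
  else unlist(lapply(strides, function(s) s$speed_mps))
  speeds_for_p95 <- speeds_for_p95[!is.na(speeds_for_p95)]
  data.frame(day = if (is.null(day)) NA_integer_ else day,
             n_bouts = nrow(bm),
             cadence_spm = mean(bm$cadence_spm, na.rm = TRUE),
             stride_time_s = mean(bm$stride_time_s, na.rm = TRUE),
             stride_length_m = mean(bm$stride_length_m, na.rm = TRUE),
             gait_speed_mps = mean(bm$speed_mps, na.rm = TRUE),
             gait_speed_p95_mps = if (length(speeds_for_p95))
               unname(quantile(speeds_for_p95, 0.95, type = 7)) else NA_real_)
}

#' Compliance summary across observed days
#'
#' Percent compliance is 100 x compliant days / total observed days; a subject
#' is included in group analyses iff compliant days >= `min_valid_days`.
#'
#' @param valid logical vector, one entry per observed day.
#' @param rules a [validity_rules()].
#' @return list: `n_days`, `n_compliant`, `percent_compliant`, `included`.
#' @export
compliance_summary <- function(valid, rules = validity_rules()) {
  if (!length(valid)) stop("no observed days")
  n <- length(valid); k <- sum(valid)
  list(n_days = n, n_compliant = k, percent_compliant = 100 * k / n,
       included = k >= rules$min_valid_days)
}
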