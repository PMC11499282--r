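# Independent oracles and small fixture builders shared across tests.

# ICC(2,1) by an explicit two-way ANOVA decomposition through stats::aov,
# independent of the package's closed-form mean-square computation
icc_aov_oracle <- function(x) {
  n <- nrow(x); k <- ncol(x)
  subj <- factor(rep(seq_len(n), k))
  rater <- factor(rep(seq_len(k), each = n))
  av <- summary(stats::aov(as.vector(x) ~ subj + rater))[[1]]
  MSR <- av["subj", "Mean Sq"]
  MSC <- av["rater", "Mean Sq"]
  MSE <- av["Residuals", "Mean Sq"]
  (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))
}

# Wilcoxon signed-rank p by brute-force enumeration of all 2^n sign patterns
wilcoxon_enum_oracle <- function(x, y, alternative = "two.sided") {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  Ws <- apply(signs, 1, function(s) sum(r[s]))
  p_le <- mean(Ws <= V + 1e-9)
  p_ge <- mean(Ws >= V - 1e-9)
  switch(alternative,
         two.sided = min(1, 2 * min(p_le, p_ge)),
         greater = p_ge,
         less = p_le)
}

# 95th percentile by explicit sort-and-interpolate between order statistics
p95_oracle <- function(v) {
  v <- sort(v)
  n <- length(v)
  h <- (n - 1) * 0.95 + 1
  lo <- floor(h)
  if (lo >= n) return(v[n])
  v[lo] + (h - lo) * (v[lo + 1] - v[lo])
}

jaccard_interval <- function(a0, a1, b0, b1) {
  inter <- max(0, min(a1, b1) - max(a0, b0))
  inter / ((a1 - a0) + (b1 - b0) - inter)
}

# contiguous 60-s epoch table with given vector-magnitude counts
make_epochs <- function(vm) {
  data.frame(epoch_start_s = (seq_along(vm) - 1) * 60,
             counts_x = vm, counts_y = 0, counts_z = 0,
             vector_magnitude = vm, vm_cv_pct = NA_real_)
}

crop_recording <- function(rec, t0, t1) {
  ix <- which(rec$data$time_s >= t0 & rec$data$time_s < t1)
  pedgait:::new_accel_recording(rec$data$time_s[ix] - rec$data$time_s[ix[1]],
                                rec$data$x[ix], rec$data$y[ix], rec$data$z[ix],
                                rec$fs_hz, wear_site = rec$wear_site,
                                subject_id = rec$subject_id)
}

# expensive shared fixture: one free-living day with known bouts, built once
.fixture_env <- new.env()
get_bout_day <- function() {
  if (is.null(.fixture_env$bout_day)) {
    prof <- subject_profile("F01", 9)
    sched <- default_day_schedule(
      wake_start_h = 8, wake_end_h = 12,
      bout_lengths_s = c(60, 45, 90, 30), bouts_per_day = 4,
      light_min = 20, moderate_min = 15, vigorous_min = 5,
      nonwear_blocks = list(c(0, 7.5), c(12.5, 24)))
    cfg <- sim_config(fs_hz = 32, noise_sd_g = 0.01, seed = 71,
                      day_schedule = sched)
    sim <- simulate_free_living_days(prof, 1, cfg)
    .fixture_env$bout_day <- list(
      profile = prof,
      recording = crop_recording(sim$recording, 7 * 3600, 13 * 3600),
      truth = sim$truth,
      offset_s = 7 * 3600)
  }
  .fixture_env$bout_day
}
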