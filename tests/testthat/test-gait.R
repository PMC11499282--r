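# Contact-event detection, temporal metrics and inverted-pendulum spatial
# metrics.

test_that("vertical axis is found by gravity direction and sign", {
  n <- 200
  rec <- pedgait:::new_accel_recording((seq_len(n) - 1) / 50,
                                       rnorm(n, 0, 0.01), rnorm(n, 0, 0.01),
                                       rnorm(n, 1, 0.01), 50)
  va <- find_vertical_axis(rec)
  expect_identical(va$axis, "z")
  expect_identical(va$sign, 1)
  rec$data$z <- -rec$data$z
  va <- find_vertical_axis(rec)
  expect_identical(va$axis, "z")
  expect_identical(va$sign, -1)
  rec0 <- pedgait:::new_accel_recording((seq_len(n) - 1) / 50,
                                        numeric(n), numeric(n), numeric(n), 50)
  expect_error(find_vertical_axis(rec0), "all-zero")
})

test_that("generator's configured vertical axis is recovered", {
  prof <- subject_profile("G01", 10)
  cfg <- sim_config(seed = 4, vertical_axis = "x", vertical_sign = -1)
  sim <- simulate_walk_pass(prof, "natural", 10, cfg)
  va <- find_vertical_axis(sim$recording)
  expect_identical(va$axis, "x")
  expect_identical(va$sign, -1)
})

test_that("a motionless signal yields no contact events", {
  ev <- detect_contact_events(rep(1, 64 * 10), 64)
  expect_identical(nrow(ev), 0L)
})

test_that("planted initial contacts are detected at the planted times", {
  prof <- subject_profile("G02", 10)
  cfg <- sim_config(noise_sd_g = 0, cadence_spm = 110, seed = 1)
  sim <- simulate_walk_pass(prof, "natural", 30, cfg)
  ev <- detect_contact_events(vertical_signal(sim$recording), 64)
  ic <- ev$time_s[ev$kind == "IC"]
  planted <- sim$truth$events$time_s[sim$truth$events$kind == "IC"]
  # all 55 planted steps minus at most a couple of edge-trimmed partials
  expect_gte(length(ic), 51)
  expect_lte(length(ic), 56)
  offs <- vapply(ic, function(t) min(abs(t - planted)), numeric(1))
  expect_lt(max(offs), 0.1)
  # events strictly increasing; ICs alternate feet
  expect_true(all(diff(ev$time_s) > 0))
  feet <- ev$foot[ev$kind == "IC"]
  expect_true(all(feet[-1] != feet[-length(feet)]))
})

test_that("detected contacts respect the physiological step-time bound", {
  prof <- subject_profile("G03", 6)
  for (seed in 1:5) {
    sim <- simulate_walk_pass(prof, "fast", 15,
                              sim_config(seed = seed, noise_sd_g = 0.05))
    ev <- detect_contact_events(vertical_signal(sim$recording), 64)
    ic <- ev$time_s[ev$kind == "IC"]
    if (length(ic) > 1) expect_gte(min(diff(ic)), gait_params()$step_time_bounds_s[1])
  }
})

test_that("detector rejects too-short or too-slow inputs", {
  expect_error(detect_contact_events(rnorm(100), 10), "20 Hz")
  expect_error(detect_contact_events(rnorm(32), 64), "too short")
})

test_that("temporal metrics follow from stated contact times", {
  ev <- data.frame(time_s = c(0, 0.5, 1, 1.5),
                   kind = "IC", foot = c("L", "R", "L", "R"))
  st <- temporal_metrics(ev)
  expect_identical(nrow(st), 2L)
  expect_equal(st$stride_time_s, c(1, 1))
  expect_equal(st$cadence_spm, c(120, 120))
  expect_equal(st$step_time_s, c(0.5, 0.5))
  # three ICs -> exactly one stride
  st3 <- temporal_metrics(ev[1:3, ])
  expect_identical(nrow(st3), 1L)
  # fewer than three ICs -> empty result, not an error
  expect_identical(nrow(temporal_metrics(ev[1:2, ])), 0L)
})

test_that("strides spanning a detection gap are not formed", {
  ev <- data.frame(time_s = c(0, 0.5, 1, 6, 6.5, 7),
                   kind = "IC", foot = rep(c("L", "R"), 3))
  st <- temporal_metrics(ev)
  # the 1 -> 6 s stride (5 s) exceeds the stride-time bound and is dropped
  expect_true(all(st$stride_time_s <= gait_params()$stride_time_bounds_s[2]))
  expect_identical(nrow(st), 2L)
})

test_that("recovered stride time matches the planted value to one sample", {
  prof <- subject_profile("G04", 12)
  sim <- simulate_walk_pass(prof, "natural", 30,
                            sim_config(seed = 2, noise_sd_g = 0, cadence_spm = 100))
  an <- analyze_pass(sim$recording, prof$height_m)
  expect_lt(abs(an$summary$stride_time_s - sim$truth$stride_times_s[1]), 1 / 64)
  expect_lt(abs(an$summary$cadence_spm - sim$truth$cadence_spm[1]), 1)
})

test_that("pendulum chord formula matches its closed form and limits", {
  # l = 0.9, h = 0.05: 2*sqrt(2*0.9*0.05 - 0.0025) = 0.59161
  h <- pedgait:::excursion_from_step_length(2 * sqrt(2 * 0.9 * 0.05 - 0.05^2), 0.9)
  expect_equal(h, 0.05, tolerance = 1e-12)
  expect_equal(pedgait:::excursion_from_step_length(0, 0.9), 0)
  expect_error(pedgait:::excursion_from_step_length(2.0, 0.9), "incompatible")
})

test_that("noise-free spatial recovery is within 10% of the planted value", {
  prof <- subject_profile("G05", 10)
  sim <- simulate_walk_pass(prof, "natural", 30,
                            sim_config(seed = 3, noise_sd_g = 0))
  an <- analyze_pass(sim$recording, prof$height_m)
  rel <- abs(an$summary$stride_length_m - sim$truth$stride_lengths_m[1]) /
    sim$truth$stride_lengths_m[1]
  expect_lt(rel, 0.10)
  # speed identity holds exactly per stride
  expect_equal(an$strides$speed_mps * an$strides$stride_time_s,
               an$strides$stride_length_m, tolerance = 1e-12)
})

test_that("doubling planted cadence halves the estimated stride time", {
  prof <- subject_profile("G06", 14)
  s1 <- simulate_walk_pass(prof, "natural", 30,
                           sim_config(seed = 4, noise_sd_g = 0, cadence_spm = 60))
  s2 <- simulate_walk_pass(prof, "natural", 30,
                           sim_config(seed = 4, noise_sd_g = 0, cadence_spm = 120))
  a1 <- analyze_pass(s1$recording, prof$height_m)
  a2 <- analyze_pass(s2$recording, prof$height_m)
  expect_equal(a1$summary$stride_time_s / a2$summary$stride_time_s, 2,
               tolerance = 0.02)
})

test_that("relative estimation error stays bounded across speed classes", {
  prof <- subject_profile("G07", 9)
  for (cls in c("natural", "fast", "slow")) {
    rels <- vapply(1:4, function(seed) {
      sim <- simulate_walk_pass(prof, cls, 25,
                                sim_config(seed = seed, noise_sd_g = 0.05))
      an <- analyze_pass(sim$recording, prof$height_m)
      abs(an$summary$stride_length_m - sim$truth$stride_lengths_m[1]) /
        sim$truth$stride_lengths_m[1]
    }, numeric(1))
    expect_lt(median(rels), 0.25)
  }
})
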