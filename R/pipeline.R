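# Reproducible study pipelines: in-clinic validation against the walkway
# reference, and the at-home daily summary with compliance and age effects.

#' Pipeline configuration
#'
#' A single serializable object holding every stage's parameters. `seed`
#' drives all simulation; a run's effective configuration can be echoed into
#' its output directory as a manifest.
#'
#' @param n_subjects cohort size.
#' @param repeats walkway repeats per speed class (the study used 3).
#' @param speed_classes walkway speed classes to simulate.
#' @param pass_duration_s walkway pass duration (s).
#' @param n_days at-home days per subject.
#' @param fs_hz sampling rate.
#' @param noise_sd_g walkway recording noise (g).
#' @param home_noise_sd_g at-home recording noise (g).
#' @param reference_noise_sd reference-walkway measurement noise (per-pass).
#' @param gait [gait_params()].
#' @param choi [choi_params()].
#' @param counts [count_params()].
#' @param cutpoints intensity cut-points.
#' @param rules [validity_rules()].
#' @param lumbar_nonwear_blocks daily device-off blocks for the lumbar site
#'   (hours); the default emulates removal for sleep.
#' @param bouts_per_day,bout_lengths_s free-living walking-bout schedule.
#' @param detect_bouts run the gait-bout stage on lumbar recordings (turn off
#'   for wear/activity-only runs).
#' @param anova_adjust pairwise multiplicity adjustment.
#' @param seed master seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(n_subjects = 40, repeats = 3,
                            speed_classes = c("natural", "fast", "slow"),
                            pass_duration_s = 30, n_days = 14,
                            fs_hz = 64, noise_sd_g = 0.05,
                            home_noise_sd_g = 0.01,
                            reference_noise_sd = 0,
                            gait = gait_params(), choi = choi_params(),
                            counts = count_params(),
                            cutpoints = default_cutpoints(),
                            rules = validity_rules(),
                            lumbar_nonwear_blocks = list(c(0, 7), c(21, 24)),
                            bouts_per_day = 10, bout_lengths_s = NULL,
                            detect_bouts = TRUE,
                            anova_adjust = "tukey", seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Fields present in the file override the defaults of [pipeline_config()];
#' nested parameter blocks (`gait`, `choi`, `counts`, `rules`) are passed to
#' their constructors so invariants are validated.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  scalar <- setdiff(names(y), c("gait", "choi", "counts", "rules",
                                "lumbar_nonwear_blocks"))
  args[scalar] <- y[scalar]
  if (!is.null(y$gait)) args$gait <- do.call(gait_params, y$gait)
  if (!is.null(y$choi)) args$choi <- do.call(choi_params, y$choi)
  if (!is.null(y$counts)) args$counts <- do.call(count_params, y$counts)
  if (!is.null(y$rules)) args$rules <- do.call(validity_rules, y$rules)
  if (!is.null(y$lumbar_nonwear_blocks))
    args$lumbar_nonwear_blocks <- lapply(y$lumbar_nonwear_blocks, unlist)
  do.call(pipeline_config, args)
}

#' Write a run manifest
#'
#' Echoes the effective configuration (plus package version) as JSON into the
#' output directory, so a run is reproducible from its outputs.
#'
#' @param config a `pipeline_config`.
#' @param out_dir output directory (created if needed).
#' @export
write_run_manifest <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package = "pedgait",
    version = as.character(utils::packageVersion("pedgait")),
    config = lapply(unclass(config), function(v)
      if (inherits(v, c("gait_params", "choi_params", "count_params",
                        "validity_rules"))) unclass(v) else v))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file.path(out_dir, "run_manifest.json"))
}

#' Sample a study-like cohort
#'
#' Ages drawn to fill the three study age groups (3-5, 6-11, 12-17 years) in
#' balanced rotation; heights follow the pediatric age-height default of
#' [subject_profile()] with individual jitter.
#'
#' @param n_subjects cohort size.
#' @param seed integer seed.
#' @return list of `subject_profile`s.
#' @export
sample_cohort <- function(n_subjects, seed = 1L) {
  local_seed(seed, {
    spans <- list(c(3, 5.99), c(6, 11.99), c(12, 17))
    lapply(seq_len(n_subjects), function(i) {
      sp <- spans[[(i - 1L) %% 3L + 1L]]
      age <- runif(1, sp[1], sp[2])
      subject_profile(sprintf("S%03d", i), age,
                      height_m = min(2.1, max(0.8, 0.86 + 0.05 * age +
                                                rnorm(1, 0, 0.04))))
    })
  })
}

#' Run the in-clinic validation pipeline
#'
#' Simulates `n_subjects` x speed classes x repeats walkway passes, extracts
#' device gait metrics with the gait module, pairs each subject's per-class
#' repeat average with the reference-walkway record, and reports ICC(2,1)
#' (with CI and agreement category) and Pearson r per metric and speed class.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory for CSV output and the run manifest.
#' @return list: `report` (metric x speed class table), `agreement` (the
#'   paired device/reference per-subject values).
#' @export
run_clinic_validation <- function(config = pipeline_config(), out_dir = NULL) {
  cohort <- sample_cohort(config$n_subjects, seed = config$seed)
  metrics <- c("cadence_spm", "gait_speed_mps", "stride_time_s", "stride_length_m")
  rows <- list(); agreement <- list()
  for (cls in config$speed_classes) {
    dev <- matrix(NA_real_, config$n_subjects, 4, dimnames = list(NULL, metrics))
    ref <- matrix(NA_real_, config$n_subjects, 4, dimnames = list(NULL, metrics))
    for (i in seq_along(cohort)) {
      prof <- cohort[[i]]
      dsum <- NULL; rsum <- NULL
      for (r in seq_len(config$repeats)) {
        seed_i <- config$seed + 7919L * i + 101L * r +
          31L * match(cls, c("natural", "fast", "slow"))
        cfg <- sim_config(fs_hz = config$fs_hz, noise_sd_g = config$noise_sd_g,
                          seed = seed_i)
        sim <- simulate_walk_pass(prof, cls, config$pass_duration_s, cfg)
        an <- tryCatch(analyze_pass(sim$recording, prof$height_m, config$gait),
                       error = function(e) NULL)
        if (is.null(an) || an$summary$n_strides < 3) next
        dsum <- rbind(dsum, an$summary[, metrics])
        rsum <- rbind(rsum, simulate_reference_walkway(
          sim$truth, config$reference_noise_sd, seed = seed_i + 1L))
      }
      if (is.null(dsum)) next
      dev[i, ] <- colMeans(dsum)
      ref[i, ] <- colMeans(rsum)
    }
    ok <- stats::complete.cases(dev) & stats::complete.cases(ref)
    for (m in metrics) {
      tab <- cbind(device = dev[ok, m], reference = ref[ok, m])
      icc <- icc_2_1(tab)
      pr <- pearson_r(tab[, 1], tab[, 2])
      rows[[length(rows) + 1L]] <- data.frame(
        metric = m, speed_class = cls, n = sum(ok),
        icc = icc$estimate, icc_low = icc$ci_low, icc_high = icc$ci_high,
        category = icc$category, pearson_r = pr$r, pearson_p = pr$p)
      agreement[[paste(m, cls, sep = ".")]] <- tab
    }
  }
  report <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(report, file.path(out_dir, "clinic_validation.csv"),
                     row.names = FALSE)
    write_run_manifest(config, out_dir)
  }
  list(report = report, agreement = agreement)
}

# at-home processing for one subject at one wear site
process_home_recording <- function(recording, profile, config,
                                   site = c("lumbar", "wrist")) {
  site <- match.arg(site)
  ep <- epoch_counts(recording, 60, config$counts)
  ep <- detect_wear(ep, config$choi)
  ci <- classify_intensity(ep, config$cutpoints)
  daily <- flag_valid_days(ci$daily, site, config$rules)
  gait_daily <- NULL
  if (site == "lumbar" && isTRUE(config$detect_bouts)) {
    gb <- detect_gait_bouts_bandpower(recording, window_config(),
                                      height_m = profile$height_m,
                                      params = config$gait)
    kept <- filter_bouts(gb$bouts, config$rules)
    keep_ix <- match(paste(kept$start_s, kept$end_s),
                     paste(gb$bouts$start_s, gb$bouts$end_s))
    for (d in daily$day[daily$valid]) {
      in_day <- kept$start_s >= d * 86400 & kept$start_s < (d + 1) * 86400
      if (!any(in_day)) next
      sub <- list(bouts = kept[in_day, , drop = FALSE],
                  strides = gb$strides[keep_ix[in_day]])
      gs <- daily_gait_summary(sub, day = d)
      gait_daily <- rbind(gait_daily, gs)
    }
  }
  list(daily = daily, gait_daily = gait_daily,
       compliance = compliance_summary(daily$valid, config$rules))
}

#' Run the at-home summary pipeline
#'
#' Simulates free-living wear for each subject (lumbar device removed for
#' sleep, wrist worn continuously), computes epoch counts, Choi wear time and
#' intensity classes, detects walking bouts, applies the study's bout and
#' valid-day filters, and reports daily summaries, per-site compliance,
#' subject inclusion flags and the age-group ANOVA. When `clinic` results are
#' supplied, the in-clinic vs at-home mixed-model contrast on gait speed is
#' added.
#'
#' @param config a [pipeline_config()].
#' @param clinic optional result of [run_clinic_validation()].
#' @param out_dir optional output directory.
#' @return list: `daily` (per subject x site), `gait_daily`, `compliance`,
#'   `anova`, and `setting_contrast` when clinic data are present.
#' @export
run_home_summary <- function(config = pipeline_config(), clinic = NULL,
                             out_dir = NULL) {
  cohort <- sample_cohort(config$n_subjects, seed = config$seed)
  daily_all <- list(); gait_all <- list(); comp_rows <- list()
  subj_speed <- rep(NA_real_, length(cohort))
  subj_mvpa <- rep(NA_real_, length(cohort))
  incl_lumbar <- logical(length(cohort)); incl_wrist <- logical(length(cohort))
  for (i in seq_along(cohort)) {
    prof <- cohort[[i]]
    sched_l <- default_day_schedule(bouts_per_day = config$bouts_per_day,
                                    bout_lengths_s = config$bout_lengths_s,
                                    nonwear_blocks = config$lumbar_nonwear_blocks)
    cfg_l <- sim_config(fs_hz = config$fs_hz, noise_sd_g = config$home_noise_sd_g,
                        seed = config$seed + 7919L * i, day_schedule = sched_l)
    sim_l <- simulate_free_living_days(prof, config$n_days, cfg_l)
    res_l <- process_home_recording(sim_l$recording, prof, config, "lumbar")
    sched_w <- default_day_schedule(bouts_per_day = 0,
                                    nonwear_blocks = list())
    cfg_w <- sim_config(fs_hz = config$fs_hz, noise_sd_g = config$home_noise_sd_g,
                        seed = config$seed + 7919L * i + 1L,
                        day_schedule = sched_w)
    sim_w <- simulate_free_living_days(prof, config$n_days, cfg_w)
    res_w <- process_home_recording(sim_w$recording, prof, config, "wrist")
    for (site in c("lumbar", "wrist")) {
      res <- if (site == "lumbar") res_l else res_w
      d <- res$daily; d$subject_id <- prof$subject_id; d$site <- site
      daily_all[[length(daily_all) + 1L]] <- d
      comp_rows[[length(comp_rows) + 1L]] <- data.frame(
        subject_id = prof$subject_id, site = site,
        age_group = prof$age_group,
        n_days = res$compliance$n_days,
        n_compliant = res$compliance$n_compliant,
        percent_compliant = res$compliance$percent_compliant,
        included = res$compliance$included)
    }
    incl_lumbar[i] <- res_l$compliance$included
    incl_wrist[i] <- res_w$compliance$included
    if (!is.null(res_l$gait_daily)) {
      g <- res_l$gait_daily; g$subject_id <- prof$subject_id
      gait_all[[length(gait_all) + 1L]] <- g
      if (incl_lumbar[i]) subj_speed[i] <- mean(g$gait_speed_mps, na.rm = TRUE)
    }
    if (incl_wrist[i])
      subj_mvpa[i] <- mean(res_w$daily$mvpa_min[res_w$daily$valid])
  }
  daily <- do.call(rbind, daily_all)
  gait_daily <- if (length(gait_all)) do.call(rbind, gait_all) else NULL
  compliance <- do.call(rbind, comp_rows)
  ages <- vapply(cohort, `[[`, character(1), "age_group")
  anova_res <- NULL
  ok <- !is.na(subj_speed)
  if (length(unique(ages[ok])) >= 2 && all(table(ages[ok]) >= 2))
    anova_res <- age_group_anova(subj_speed[ok], ages[ok],
                                 adjust = config$anova_adjust)
  out <- list(daily = daily, gait_daily = gait_daily, compliance = compliance,
              subject_gait_speed = subj_speed, subject_mvpa = subj_mvpa,
              anova = anova_res)
  if (!is.null(clinic) && !is.null(gait_daily)) {
    clin_tab <- clinic$agreement[["gait_speed_mps.natural"]]
    if (!is.null(clin_tab)) {
      n_cl <- nrow(clin_tab)
      ids <- vapply(cohort, `[[`, character(1), "subject_id")[seq_len(n_cl)]
      ag <- ages[seq_len(n_cl)]
      dat <- rbind(
        data.frame(subject = ids, setting = "in_clinic", age_group = ag,
                   value = clin_tab[, "device"]),
        data.frame(subject = gait_daily$subject_id, setting = "at_home",
                   age_group = ages[match(gait_daily$subject_id,
                                          vapply(cohort, `[[`, character(1),
                                                 "subject_id"))],
                   value = gait_daily$gait_speed_mps))
      out$setting_contrast <- tryCatch(setting_contrast_mmrm(dat),
                                       error = function(e) NULL)
    }
  }
  if (is.null(daily) || !nrow(daily) || all(!daily$valid))
    stop("no valid days in any recording")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(daily, file.path(out_dir, "daily_summary.csv"),
                     row.names = FALSE)
    if (!is.null(gait_daily))
      utils::write.csv(gait_daily, file.path(out_dir, "daily_gait.csv"),
                       row.names = FALSE)
    utils::write.csv(compliance, file.path(out_dir, "compliance.csv"),
                     row.names = FALSE)
    write_run_manifest(config, out_dir)
  }
  out
}
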