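# Agreement, correlation, signed-rank, mixed-model and ANOVA statistics.

test_that("ICC(2,1) equals 1 for identical raters and penalizes offsets", {
  x <- cbind(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5))
  r <- icc_2_1(x)
  expect_equal(r$estimate, 1, tolerance = 1e-12)
  expect_identical(r$category, "excellent")
  # constant offset: absolute agreement drops below 1 while Pearson r stays 1
  y <- cbind(x[, 1], x[, 1] + 2)
  ro <- icc_2_1(y)
  expect_lt(ro$estimate, 1)
  expect_equal(pearson_r(y[, 1], y[, 2])$r, 1, tolerance = 1e-12)
  expect_true(ro$ci_low <= ro$estimate && ro$estimate <= ro$ci_high)
})

test_that("ICC matches the brute-force ANOVA oracle to 1e-10", {
  set.seed(51)
  for (i in 1:25) {
    n <- sample(4:12, 1); k <- sample(2:3, 1)
    x <- matrix(rnorm(n * k, mean = 10), n, k)
    expect_equal(icc_2_1(x)$estimate, icc_aov_oracle(x), tolerance = 1e-10)
  }
})

test_that("ICC is invariant to a global constant, decreased by a rater offset", {
  set.seed(52)
  subj <- rnorm(10, 5, 1)
  x <- cbind(subj, subj) + matrix(rnorm(20, 0, 0.2), 10, 2)
  base <- icc_2_1(x)$estimate
  expect_equal(icc_2_1(x + 7)$estimate, base, tolerance = 1e-10)
  shifted <- x; shifted[, 2] <- shifted[, 2] + 2
  expect_lt(icc_2_1(shifted)$estimate, base)
})

test_that("degenerate all-equal table warns and returns perfect agreement", {
  x <- matrix(3, 5, 2)
  expect_warning(r <- icc_2_1(x), "zero total variance")
  expect_equal(r$estimate, 1)
  expect_equal(c(r$ci_low, r$ci_high), c(1, 1))
  expect_error(icc_2_1(matrix(1:4, 2, 2)), "at least 3")
})

test_that("agreement benchmark categories match the published cut-offs", {
  expect_identical(icc_category(0.971), "excellent")
  expect_identical(icc_category(0.578), "moderate")
  expect_identical(icc_category(0.40), "poor")
  expect_identical(icc_category(0.35), "poor")
  expect_identical(icc_category(0.59), "moderate")
  expect_identical(icc_category(0.6), "good")
  expect_identical(icc_category(0.748), "good")
  expect_identical(icc_category(0.75), "excellent")
})

test_that("Pearson correlation matches the textbook formula", {
  expect_equal(pearson_r(1:10, 1:10)$r, 1, tolerance = 1e-12)
  expect_equal(pearson_r(1:10, -(1:10))$r, -1, tolerance = 1e-12)
  set.seed(53)
  for (i in 1:10) {
    x <- rnorm(15); y <- rnorm(15)
    r_hand <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    res <- pearson_r(x, y)
    expect_equal(res$r, r_hand, tolerance = 1e-12)
    tt <- r_hand * sqrt(13 / (1 - r_hand^2))
    expect_equal(res$p, 2 * pt(-abs(tt), 13), tolerance = 1e-12)
  }
  expect_error(pearson_r(rep(1, 5), 1:5), "variance")
})

test_that("Wilcoxon exact branch equals the full enumeration oracle", {
  set.seed(54)
  for (i in 1:30) {
    n <- sample(3:9, 1)
    x <- round(rnorm(n), 1); y <- round(rnorm(n), 1)
    if (all(x - y == 0)) next
    for (alt in c("two.sided", "greater", "less")) {
      expect_equal(paired_wilcoxon(x, y, alt)$p,
                   wilcoxon_enum_oracle(x, y, alt), tolerance = 1e-10,
                   info = sprintf("iter %d alt %s", i, alt))
    }
  }
})

test_that("Wilcoxon handles a single nonzero pair, symmetry and zero diffs", {
  x <- c(1, 2, 3); y <- c(1, 2, 2.5)
  r <- paired_wilcoxon(x, y, "greater")
  expect_equal(r$n, 1)
  expect_equal(r$p, 0.5)  # smallest attainable one-sided p at n = 1
  set.seed(55)
  a <- rnorm(8); b <- rnorm(8)
  r1 <- paired_wilcoxon(a, b); r2 <- paired_wilcoxon(b, a)
  expect_equal(r1$p, r2$p, tolerance = 1e-12)
  tot <- sum(rank(abs(a - b)))
  expect_equal(r1$statistic + r2$statistic, tot, tolerance = 1e-12)
  expect_error(paired_wilcoxon(1:4, 1:4), "zero")
})

test_that("Wilcoxon normal branch approximates the exact branch for larger n", {
  set.seed(56)
  x <- rnorm(30); y <- rnorm(30, 0.3)
  pe <- paired_wilcoxon(x, y, exact_limit = 30)
  pn <- paired_wilcoxon(x, y, exact_limit = 5)
  expect_identical(pe$method, "exact")
  expect_identical(pn$method, "normal")
  expect_equal(pn$p, pe$p, tolerance = 0.05)
})

test_that("setting contrast recovers a null and a planted difference", {
  subj <- sprintf("P%02d", 1:12)
  ag <- rep(c("3-5", "6-11", "12-17"), 4)
  base <- seq(0.9, 1.5, length.out = 12)
  home <- do.call(rbind, lapply(1:12, function(i)
    data.frame(subject = subj[i], setting = "at_home", age_group = ag[i],
               value = base[i])))
  clin <- data.frame(subject = subj, setting = "in_clinic", age_group = ag,
                     value = base)
  r0 <- suppressWarnings(suppressMessages(
    setting_contrast_mmrm(rbind(home, clin))))
  expect_equal(r0$estimate, 0, tolerance = 1e-8)
  expect_true(r0$ci_low <= 0 && 0 <= r0$ci_high)

  set.seed(57)
  clin$value <- base + 0.07 + rnorm(12, 0, 0.01)
  home5 <- do.call(rbind, lapply(1:12, function(i)
    data.frame(subject = subj[i], setting = "at_home", age_group = ag[i],
               value = base[i] + rnorm(5, 0, 0.01))))
  r1 <- setting_contrast_mmrm(rbind(home5, clin))
  expect_lt(abs(r1$estimate - 0.07), 0.02)
  expect_lt(r1$p, 0.01)
  expect_error(setting_contrast_mmrm(home), "both settings")
})

test_that("age-group covariate barely moves a balanced-design estimate", {
  set.seed(58)
  n <- 30
  subj <- sprintf("P%02d", 1:n)
  ag <- rep(c("3-5", "6-11", "12-17"), each = 10)
  u <- rnorm(n, 0, 0.05)
  base <- 1 + 0.1 * (ag == "6-11") + 0.2 * (ag == "12-17") + u
  dat <- rbind(
    do.call(rbind, lapply(1:n, function(i)
      data.frame(subject = subj[i], setting = "at_home", age_group = ag[i],
                 value = base[i] + rnorm(4, 0, 0.04)))),
    data.frame(subject = subj, setting = "in_clinic", age_group = ag,
               value = base + 0.07 + rnorm(n, 0, 0.04)))
  with_cov <- setting_contrast_mmrm(dat)
  dat_nocov <- dat; dat_nocov$age_group <- "all"
  without_cov <- setting_contrast_mmrm(dat_nocov)
  se <- (with_cov$ci_high - with_cov$ci_low) / (2 * qnorm(0.975))
  expect_lt(abs(with_cov$estimate - without_cov$estimate), se)
})

test_that("age-group ANOVA reports F, p and all pairwise comparisons", {
  set.seed(59)
  g <- rep(c("3-5", "6-11", "12-17"), each = 8)
  v <- rnorm(24, rep(c(1.0, 1.2, 1.4), each = 8), 0.08)
  r <- age_group_anova(v, g)
  expect_lt(r$p, 0.01)
  expect_identical(nrow(r$pairwise), 3L)
  rn <- age_group_anova(v, g, adjust = "none")
  rb <- age_group_anova(v, g, adjust = "bonferroni")
  expect_identical(nrow(rb$pairwise), 3L)
  expect_true(all(rb$pairwise$p_adj >= rn$pairwise$p_adj - 1e-12))
  expect_error(age_group_anova(v[1:8], g[1:8]), "two groups")
  expect_error(age_group_anova(v[c(1:8, 9)], g[c(1:8, 9)]), "at least two subjects")
})

test_that("comfort scoring applies the key and demands complete 10-item sheets", {
  lv <- likert_levels()
  sheet <- data.frame(t(setNames(lv[c(5, 5, 4, 3, 2, 1, 5, 4, 1, 3)],
                                 sprintf("q%02d", 1:10))))
  s <- comfort_total(sheet)
  expect_equal(s$total, sum(c(4, 4, 3, 2, 1, 0, 4, 3, 0, 2)))
  # reverse-keying flips selected items
  key <- c(TRUE, rep(FALSE, 9))
  s2 <- comfort_total(sheet, reverse_keyed = key)
  expect_equal(s2$total, s$total - 4 + 0)
  bad <- sheet; bad$q03 <- "meh"
  expect_error(comfort_total(bad), "invalid")
  expect_error(comfort_total(sheet[, 1:9]), "10")
})
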