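# Validation and comparison statistics: ICC(2,1) with agreement benchmarks,
# Pearson correlation, paired Wilcoxon signed-rank (exact by enumeration-free
# dynamic programming), mixed-model setting contrast, age-group ANOVA, and
# comfort-questionnaire scoring.

#' Intraclass correlation ICC(2,1)
#'
#' Two-way random effects, absolute agreement, single measurement, computed
#' from the two-way ANOVA mean squares: `(MSR - MSE) / (MSR + (k-1) MSE +
#' (k/n) (MSC - MSE))` with MSR the between-subject, MSC the between-rater and
#' MSE the residual mean square. The confidence interval is the F-based
#' interval for this form.
#'
#' @param table numeric matrix, n subjects x k raters, no missing cells.
#' @param alpha confidence level is `1 - alpha`.
#' @return an `icc_result` list: `estimate`, `ci_low`, `ci_high`, `category`,
#'   `n`, `k`.
#' @export
icc_2_1 <- function(table, alpha = 0.05) {
  x <- as.matrix(table)
  if (anyNA(x)) stop("agreement table must be complete-case (no missing cells)")
  n <- nrow(x); k <- ncol(x)
  if (n < 3 || k < 2) stop("need at least 3 subjects and 2 raters")
  grand <- mean(x)
  rm_ <- rowMeans(x); cm <- colMeans(x)
  SSR <- k * sum((rm_ - grand)^2)
  SSC <- n * sum((cm - grand)^2)
  SST <- sum((x - grand)^2)
  SSE <- SST - SSR - SSC
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  if (SST < .Machine$double.eps * max(1, abs(grand))) {
    warning("zero total variance: all cells equal; agreement defined as 1")
    res <- list(estimate = 1, ci_low = 1, ci_high = 1,
                category = icc_category(1), n = n, k = k)
    class(res) <- "icc_result"
    return(res)
  }
  est <- (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))
  a <- (k * est) / (n * (1 - est))
  b <- 1 + (k * est * (n - 1)) / (n * (1 - est))
  v <- (a * MSC + b * MSE)^2 /
    ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
  FL <- stats::qf(1 - alpha / 2, n - 1, v)
  FU <- stats::qf(1 - alpha / 2, v, n - 1)
  lo <- (n * (MSR - FL * MSE)) /
    (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
  hi <- (n * (FU * MSR - MSE)) /
    (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
  res <- list(estimate = est, ci_low = min(lo, est), ci_high = max(hi, est),
              category = icc_category(est), n = n, k = k)
  class(res) <- "icc_result"
  res
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(2,1) = %.3f (%.2f, %.2f), %s agreement [n=%d, k=%d]\n",
              x$estimate, x$ci_low, x$ci_high, x$category, x$n, x$k))
  invisible(x)
}

#' Agreement benchmark category for an ICC estimate
#'
#' Benchmarks: <= 0.4 "poor", 0.4-0.59 "moderate", 0.6-0.74 "good",
#' 0.75-1 "excellent".
#'
#' @param estimate ICC estimate (<= 1).
#' @return one of "poor", "moderate", "good", "excellent".
#' @export
icc_category <- function(estimate) {
  stopifnot(estimate <= 1 + 1e-12)
  if (estimate <= 0.4) "poor"
  else if (estimate < 0.6) "moderate"
  else if (estimate < 0.75) "good"
  else "excellent"
}

#' Pearson correlation with p value
#'
#' Product-moment correlation; two-sided p from the t transform.
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return list `r`, `p`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance input")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

# exact null distribution of the doubled signed-rank statistic by dynamic
# programming over the (doubled, hence integer) ranks
signed_rank_exact_dist <- function(ranks2) {
  total <- sum(ranks2)
  counts <- rep(0, total + 1L)   # index = W2 value + 1
  counts[1] <- 1
  for (r in ranks2) {
    shifted <- c(rep(0, r), counts[seq_len(total + 1L - r)])
    counts <- counts + shifted
  }
  counts / 2^length(ranks2)
}

#' Paired Wilcoxon signed-rank test
#'
#' Zero differences are dropped; ties receive mid-ranks. For `n` nonzero
#' differences up to `exact_limit` the p value comes from the exact null
#' distribution of the rank sum (computed by dynamic programming over the
#' doubled ranks, valid under ties); otherwise a normal approximation with tie
#' correction and continuity correction is used.
#'
#' @param x,y paired numeric vectors.
#' @param alternative "two.sided" (default), "greater" or "less" (in terms of
#'   x - y).
#' @param exact_limit maximum n for the exact branch.
#' @return list: `statistic` (V, sum of ranks of positive differences),
#'   `p`, `n` (nonzero pairs), `method` ("exact"/"normal").
#' @export
paired_wilcoxon <- function(x, y, alternative = c("two.sided", "greater", "less"),
                            exact_limit = 12L) {
  alternative <- match.arg(alternative)
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (!n) stop("all paired differences are zero")
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  if (n <= exact_limit) {
    r2 <- as.integer(round(2 * r))
    dist <- signed_rank_exact_dist(r2)
    w2 <- as.integer(round(2 * V))
    total <- sum(r2)
    p_le <- sum(dist[seq_len(w2 + 1L)])
    p_ge <- sum(dist[(w2 + 1L):(total + 1L)])
    p <- switch(alternative,
                two.sided = min(1, 2 * min(p_le, p_ge)),
                greater = p_ge,
                less = p_le)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    cc <- 0.5
    z <- switch(alternative,
                two.sided = (V - mu - sign(V - mu) * cc) / sqrt(sigma2),
                greater = (V - mu - cc) / sqrt(sigma2),
                less = (V - mu + cc) / sqrt(sigma2))
    p <- switch(alternative,
                two.sided = 2 * stats::pnorm(-abs(z)),
                greater = stats::pnorm(z, lower.tail = FALSE),
                less = stats::pnorm(z))
    p <- min(1, p)
    method <- "normal"
  }
  list(statistic = V, p = p, n = n, method = method)
}

#' In-clinic vs at-home setting contrast (mixed model)
#'
#' Linear mixed model with a subject-level random intercept and fixed effects
#' for setting and age group, fitted by REML: the repeated at-home daily
#' measurements enter through the random effect. The contrast is reported as
#' in-clinic minus at-home with a Wald 95% CI; the p value uses Satterthwaite
#' degrees of freedom when `lmerTest` is installed, otherwise the normal
#' approximation.
#'
#' @param data data.frame with columns `subject`, `setting` ("in_clinic" /
#'   "at_home"), `age_group`, `value`.
#' @param conf_level confidence level.
#' @return list: `estimate` (in_clinic - at_home), `ci_low`, `ci_high`, `p`.
#' @export
setting_contrast_mmrm <- function(data, conf_level = 0.95) {
  stopifnot(all(c("subject", "setting", "age_group", "value") %in% names(data)))
  data <- data[stats::complete.cases(data[, c("subject", "setting",
                                              "age_group", "value")]), ]
  if (length(unique(data$setting)) < 2)
    stop("both settings must be present")
  both <- tapply(data$setting, data$subject,
                 function(s) length(unique(s)) == 2)
  if (sum(both) < 3)
    stop("need both settings for at least 3 subjects")
  data$setting <- factor(data$setting, levels = c("at_home", "in_clinic"))
  data$age_group <- factor(data$age_group)
  single_group <- nlevels(data$age_group) < 2
  form <- if (single_group) value ~ setting + (1 | subject)
  else value ~ setting + age_group + (1 | subject)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (requireNamespace("lmerTest", quietly = TRUE)) {
    fit <- lmerTest::lmer(form, data = data, REML = TRUE)
    co <- summary(fit)$coefficients
    est <- co["settingin_clinic", "Estimate"]
    se <- co["settingin_clinic", "Std. Error"]
    p <- co["settingin_clinic", "Pr(>|t|)"]
  } else {
    fit <- lme4::lmer(form, data = data, REML = TRUE)
    co <- summary(fit)$coefficients
    est <- co["settingin_clinic", "Estimate"]
    se <- co["settingin_clinic", "Std. Error"]
    p <- 2 * stats::pnorm(-abs(est / se))
  }
  list(estimate = est, ci_low = est - z * se, ci_high = est + z * se, p = p)
}

#' One-way age-group ANOVA with pairwise comparisons
#'
#' One-way ANOVA on per-subject summary values across age groups, with all
#' pairwise group comparisons (Tukey HSD by default; configurable to
#' unadjusted or Bonferroni pairwise t tests).
#'
#' @param value numeric vector of per-subject summaries.
#' @param age_group factor/character of group membership.
#' @param adjust "tukey", "none" or "bonferroni".
#' @return list: `F`, `p`, `pairwise` (data.frame `comparison`, `estimate`
#'   where available, `p_adj`).
#' @export
age_group_anova <- function(value, age_group,
                            adjust = c("tukey", "none", "bonferroni")) {
  adjust <- match.arg(adjust)
  g <- factor(age_group)
  if (nlevels(g) < 2) stop("need at least two groups")
  if (any(table(g) < 2)) stop("each group needs at least two subjects")
  fit <- stats::aov(value ~ g)
  av <- summary(fit)[[1]]
  Fv <- av[1, "F value"]; p <- av[1, "Pr(>F)"]
  if (adjust == "tukey") {
    tk <- stats::TukeyHSD(fit)$g
    pw <- data.frame(comparison = rownames(tk), estimate = tk[, "diff"],
                     p_adj = tk[, "p adj"], row.names = NULL)
  } else {
    pt <- stats::pairwise.t.test(value, g, p.adjust.method =
                                   if (adjust == "none") "none" else "bonferroni")
    m <- pt$p.value
    pw <- do.call(rbind, lapply(rownames(m), function(a)
      do.call(rbind, lapply(colnames(m), function(b) {
        if (is.na(m[a, b])) return(NULL)
        data.frame(comparison = paste(a, b, sep = "-"),
                   estimate = mean(value[g == a]) - mean(value[g == b]),
                   p_adj = m[a, b])
      }))))
    rownames(pw) <- NULL
  }
  list(F = Fv, p = p, pairwise = pw)
}

#' Score the comfort and wearability questionnaire
#'
#' Each of the ten items is mapped to 0-4 with 4 the most favorable response
#' ("strongly agree" for favorably-worded items; negatively-worded items are
#' reverse-keyed via `reverse_keyed`). The total ranges 0-40: 0 worst, 40 best
#' comfort. Missing or invalid responses are an error (responses are analyzed
#' complete-case).
#'
#' @param responses data.frame with exactly ten item columns (any columns
#'   named `q*`/`item*`, or all non-`subject_id` columns) holding
#'   [likert_levels()] strings.
#' @param reverse_keyed logical vector of length 10.
#' @return data.frame: per-item scores `item_01`..`item_10` and `total`.
#' @export
comfort_total <- function(responses, reverse_keyed = rep(FALSE, 10)) {
  stopifnot(length(reverse_keyed) == 10)
  df <- as.data.frame(responses)
  item_cols <- grep("^(q|item)", names(df), value = TRUE)
  if (!length(item_cols)) item_cols <- setdiff(names(df), "subject_id")
  if (length(item_cols) != 10)
    stop("exactly 10 questionnaire items are required")
  lv <- likert_levels()
  sc <- sapply(seq_along(item_cols), function(j) {
    v <- match(df[[item_cols[j]]], lv) - 1L
    if (anyNA(v)) stop("missing or invalid response in item ", item_cols[j])
    if (reverse_keyed[j]) 4L - v else v
  })
  if (is.null(dim(sc))) sc <- matrix(sc, nrow = 1)
  out <- as.data.frame(sc)
  names(out) <- sprintf("item_%02d", 1:10)
  out$total <- rowSums(sc)
  if (!is.null(df$subject_id)) out <- cbind(subject_id = df$subject_id, out)
  out
}
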