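# Group-comparison statistics, effect sizes, power analysis and the
# confidence-interval calculators used by the classification report.

#' Choose the group-comparison test from distributional checks
#'
#' Shapiro-Wilk normality in each group gates the test: if either group
#' departs from normality at p < 0.05 the Mann-Whitney U test is used;
#' otherwise Student's t, upgraded to Welch's t when an F variance-ratio
#' test rejects equal variances at p < 0.05.
#'
#' @param a,b Numeric samples (each n >= 3).
#' @return One of `"mann_whitney"`, `"student_t"`, `"welch_t"`.
#' @export
shapiro_gate <- function(a, b) {
  if (length(a) < 3 || length(b) < 3)
    stop("Shapiro-Wilk gating needs n >= 3 per group", call. = FALSE)
  if (stats::shapiro.test(a)$p.value < 0.05 ||
      stats::shapiro.test(b)$p.value < 0.05) return("mann_whitney")
  if (stats::var.test(a, b)$p.value < 0.05) "welch_t" else "student_t"
}

#' Mann-Whitney U test with normal-approximation Z and effect size r
#'
#' Reports `U = min(U_a, U_b)`, the tie-corrected normal approximation
#' with 0.5 continuity correction (the convention of standard statistics
#' packages, which the study's printed Z values follow), the two-tailed p,
#' and the rank-biserial-style effect size `r = |Z| / sqrt(N)` with N the
#' total sample size.
#'
#' @param a,b Numeric samples.
#' @return List with `U`, `Z`, `p`, `r`, `n`.
#' @export
mann_whitney <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na == 0 || nb == 0) stop("both samples must be non-empty", call. = FALSE)
  n <- na + nb
  rk <- rank(c(a, b))
  ra <- sum(rk[seq_len(na)])
  ua <- ra - na * (na + 1) / 2
  ub <- na * nb - ua
  u <- min(ua, ub)
  mu <- na * nb / 2
  ties <- table(rk)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- na * nb / 12 * (n + 1 - tie_term)
  if (sigma2 <= 0) {
    z <- 0; p <- 1
  } else {
    z_signed <- (ua - mu - sign(ua - mu) * 0.5) / sqrt(sigma2)
    if (ua == mu) z_signed <- 0
    z <- z_signed
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(U = u, Z = z, p = p, r = effect_size_r(z, n), n = n)
}

#' Effect size r from a normal-approximation Z
#'
#' `r = |Z| / sqrt(N)` with N the total sample size across both groups
#' (whole-sample convention). Values around 0.1 are small, 0.3 medium,
#' and >= 0.5 large.
#'
#' @param z Normal-approximation Z statistic.
#' @param n Total sample size.
#' @return Effect size r in `[0, 1]` (clipped).
#' @export
effect_size_r <- function(z, n) min(1, abs(z) / sqrt(n))

#' Cohen's d with pooled SD
#'
#' `d = (m1 - m2) / s_pooled` with
#' `s_pooled = sqrt(((n1-1)s1^2 + (n2-1)s2^2) / (n1+n2-2))`. Accepts
#' either raw samples or printed summaries.
#'
#' @param a,b Numeric samples; ignored when summaries are given.
#' @param m1,s1,n1,m2,s2,n2 Optional group summaries (mean, SD, n).
#' @return Cohen's d (signed).
#' @export
cohens_d <- function(a = NULL, b = NULL, m1 = mean(a), s1 = stats::sd(a),
                     n1 = length(a), m2 = mean(b), s2 = stats::sd(b),
                     n2 = length(b)) {
  if (n1 < 2 || n2 < 2) stop("need n >= 2 per group", call. = FALSE)
  sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
  if (sp == 0) stop("pooled SD is zero; d undefined", call. = FALSE)
  (m1 - m2) / sp
}

#' Domain-wise Bonferroni threshold for a movement variable
#'
#' Upper-limb regions (shoulder, elbow, wrist, hand; 4 bilateral measures
#' per side) use alpha = 0.05/4 = 0.0125; lower-limb regions (knee, ankle,
#' foot) use 0.05/3 = 0.0167; the head composite and the global activity
#' index are single primary measures tested at 0.05.
#'
#' @param variable A composite-point name (e.g. `"left_elbow"`) or
#'   `"global"`.
#' @return The adjusted two-tailed alpha.
#' @export
domain_alpha <- function(variable) {
  v <- sub("^sd_", "", variable)      # variability SDs share the region map
  v <- sub("^(left|right)_", "", v)
  switch(v,
         shoulder = , elbow = , wrist = , hand = 0.0125,
         knee = , ankle = , foot = 0.0167,
         head = , global = , global_per_height = 0.05,
         stop("unknown movement variable: ", variable, call. = FALSE))
}

#' Spearman rank correlation with t-approximation p value
#'
#' Average ranks for ties; p from the t approximation
#' `t = rho * sqrt((n-2)/(1-rho^2))` on n - 2 df, two-tailed.
#'
#' @param x,y Equal-length numeric samples (n >= 3).
#' @return List with `rho`, `p`, `n`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("need equal-length samples with n >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: correlation undefined", call. = FALSE)
  rho <- stats::cor(rank(x), rank(y))
  n <- length(x)
  if (abs(rho) >= 1) p <- 0
  else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tt), n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Height-adjusted group model for the global activity index
#'
#' OLS of the standardized global activity index on standardized group
#' membership and standardized height, reporting standardized
#' coefficients, their two-tailed p values, the overall F and adjusted
#' R-squared.
#'
#' @param global Per-subject global activity index.
#' @param group Two-level factor or 0/1 indicator (case = 1).
#' @param height_cm Per-subject height.
#' @return List with `beta` (named), `p` (named), `F`, `df`, `p_model`,
#'   `adj_r2`.
#' @export
height_adjusted_model <- function(global, group, height_cm) {
  n <- length(global)
  if (n <= 3) stop("need n > 3", call. = FALSE)
  g <- if (is.factor(group)) as.numeric(group == levels(group)[1]) else as.numeric(group)
  zs <- function(v) {
    s <- stats::sd(v)
    if (s == 0) stop("constant predictor: model is rank-deficient", call. = FALSE)
    (v - mean(v)) / s
  }
  d <- data.frame(y = zs(global), group = zs(g), height = zs(height_cm))
  fit <- stats::lm(y ~ group + height, data = d)
  if (fit$rank < 3) stop("rank-deficient model (collinear predictors)", call. = FALSE)
  sm <- summary(fit)
  co <- sm$coefficients
  list(beta = co[c("group", "height"), "Estimate"],
       p = co[c("group", "height"), "Pr(>|t|)"],
       F = unname(sm$fstatistic["value"]),
       df = unname(sm$fstatistic[c("numdf", "dendf")]),
       p_model = stats::pf(sm$fstatistic["value"], sm$fstatistic["numdf"],
                           sm$fstatistic["dendf"], lower.tail = FALSE),
       adj_r2 = sm$adj.r.squared)
}

#' Power of the two-tailed two-sample t test (noncentral t)
#'
#' Achieved power for effect size d at group sizes n1, n2:
#' `ncp = d * sqrt(n1 n2 / (n1 + n2))`, `df = n1 + n2 - 2`,
#' `power = P(|T'| > t_{1 - alpha/2, df})`.
#'
#' @param d Cohen's d.
#' @param alpha Two-tailed significance level.
#' @param n1,n2 Group sizes.
#' @return Achieved power in `[0, 1]`.
#' @export
power_t <- function(d, alpha = 0.05, n1, n2) {
  stopifnot(alpha > 0, alpha < 1, n1 >= 2, n2 >= 2)
  df <- n1 + n2 - 2
  ncp <- d * sqrt(n1 * n2 / (n1 + n2))
  tc <- stats::qt(1 - alpha / 2, df)
  stats::pt(tc, df, ncp, lower.tail = FALSE) + stats::pt(-tc, df, ncp)
}

#' Required sample size for the two-sample t test
#'
#' Smallest equal per-group n whose noncentral-t power reaches `power`;
#' returns the total sample size 2n.
#'
#' @param d Cohen's d (non-zero).
#' @param alpha Two-tailed significance level.
#' @param power Target power in (0, 1).
#' @return Total required sample size (both groups).
#' @export
required_n_t <- function(d, alpha = 0.05, power = 0.80) {
  if (d == 0) stop("d must be non-zero", call. = FALSE)
  for (n in 2:100000)
    if (power_t(d, alpha, n, n) >= power) return(2L * n)
  stop("no n <= 1e5 reaches the target power", call. = FALSE)
}

#' Wilson score interval for a proportion
#'
#' With `z` the normal quantile at the requested confidence. `successes`
#' may be fractional: the study reports every classification metric with
#' the whole-sample effective n (n = 66), so e.g. specificity 23/29 is
#' intervalled at p-hat = 23/29 with n_eff = 66.
#'
#' @param successes Number of successes (possibly fractional).
#' @param n_eff Effective sample size (>= 1).
#' @param conf Confidence level.
#' @return Numeric `c(lower, upper)` in `[0, 1]`.
#' @export
wilson_ci <- function(successes, n_eff, conf = 0.95) {
  stopifnot(n_eff >= 1, successes >= 0, successes <= n_eff)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- successes / n_eff
  den <- 1 + z^2 / n_eff
  ctr <- (p + z^2 / (2 * n_eff)) / den
  half <- z * sqrt(p * (1 - p) / n_eff + z^2 / (4 * n_eff^2)) / den
  c(lower = max(0, ctr - half), upper = min(1, ctr + half))
}

#' Hanley-McNeil confidence interval for an AUC
#'
#' Normal-approximation interval with
#' `SE^2 = (A(1-A) + (n1-1)(Q1-A^2) + (n2-1)(Q2-A^2)) / (n1 n2)`,
#' `Q1 = A/(2-A)`, `Q2 = 2A^2/(1+A)`; clipped to `[0, 1]`.
#'
#' @param auc Observed AUC in `[0, 1]`.
#' @param n1 Number of positives.
#' @param n2 Number of negatives.
#' @param conf Confidence level.
#' @return Numeric `c(lower, upper)`.
#' @export
hanley_mcneil_ci <- function(auc, n1, n2, conf = 0.95) {
  stopifnot(auc >= 0, auc <= 1, n1 >= 1, n2 >= 1)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                (n2 - 1) * (q2 - auc^2)) / (n1 * n2))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  c(lower = max(0, auc - z * se), upper = min(1, auc + z * se))
}

#' Pearson chi-square test for a 2x2 table, without continuity correction
#'
#' @param tab 2x2 matrix of counts.
#' @return List with `chi2`, `p`, `df = 1`.
#' @export
chi_square_2x2 <- function(tab) {
  stopifnot(is.matrix(tab), all(dim(tab) == 2L), all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero marginal: chi-square undefined", call. = FALSE)
  # the contract is the plain Pearson statistic; silence the small-cell
  # approximation notice raised for tiny demonstration tables
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chi2 = unname(ct$statistic), p = unname(ct$p.value), df = 1L)
}

#' Distribution-gated group comparison battery
#'
#' Runs the study's comparison logic for each movement variable: a
#' Shapiro-Wilk-gated test (Student/Welch t or Mann-Whitney U), group
#' summaries, the relevant effect size (Cohen's d or r = |Z|/sqrt(N)), and
#' the domain-wise Bonferroni threshold.
#'
#' @param features Feature `data.frame` from [feature_table()] (must carry
#'   a `group` factor with cases first).
#' @param variables Column names to compare; defaults to the 15 regional
#'   activity indices plus `global`.
#' @param gate If `FALSE`, force Mann-Whitney for all variables.
#' @return A `data.frame`, one row per variable: test used, statistic, Z,
#'   p, effect size, group medians/quartiles (or means/SDs), adjusted
#'   alpha, significance flag.
#' @export
compare_groups <- function(features,
                           variables = c(region_names(), "global"),
                           gate = TRUE) {
  stopifnot(is.factor(features$group))
  g1 <- levels(features$group)[1]
  rows <- lapply(variables, function(v) {
    a <- features[features$group == g1, v]
    b <- features[features$group != g1, v]
    test <- if (gate) shapiro_gate(a, b) else "mann_whitney"
    alpha <- domain_alpha(v)
    if (test == "mann_whitney") {
      mw <- mann_whitney(a, b)
      stat <- mw$U; z <- mw$Z; p <- mw$p; eff <- mw$r
    } else {
      tt <- stats::t.test(a, b, var.equal = (test == "student_t"))
      stat <- unname(tt$statistic); z <- NA_real_; p <- tt$p.value
      eff <- cohens_d(a, b)
    }
    qa <- stats::quantile(a, c(0.25, 0.5, 0.75), names = FALSE)
    qb <- stats::quantile(b, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(variable = v, test = test, statistic = stat, Z = z, p = p,
               effect_size = eff,
               case_median = qa[2], case_q1 = qa[1], case_q3 = qa[3],
               control_median = qb[2], control_q1 = qb[1], control_q3 = qb[3],
               case_mean = mean(a), case_sd = stats::sd(a),
               control_mean = mean(b), control_sd = stats::sd(b),
               alpha_adjusted = alpha, significant = p < alpha,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
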