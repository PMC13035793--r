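test_that("the Shapiro-Wilk gate picks the test the distributions call for", {
  set.seed(101)
  a <- rnorm(30); b <- rnorm(30)
  expect_equal(shapiro_gate(a, b), "student_t")
  expect_equal(shapiro_gate(exp(rnorm(30, 0, 1.5)), b), "mann_whitney")
  set.seed(202)
  expect_equal(shapiro_gate(rnorm(40, 0, 1), rnorm(40, 0, 4)), "welch_t")
  expect_error(shapiro_gate(c(1, 2), b), "n >= 3")
})

# Exact two-tailed Mann-Whitney p by complete enumeration (no ties).
mw_exact_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled); na <- length(a)
  u_of <- function(idx) {
    ra <- sum(rank(pooled)[idx])
    ua <- ra - na * (na + 1) / 2
    min(ua, na * (n - na) - ua)
  }
  obs <- u_of(seq_len(na))
  combos <- utils::combn(n, na)
  us <- apply(combos, 2, u_of)
  mean(us <= obs)  # two-tailed by the min-U symmetry
}

test_that("Mann-Whitney U, p and r behave on canonical cases", {
  same <- mann_whitney(1:10, 1:10)
  expect_gt(same$p, 0.9)
  expect_lt(same$r, 0.05)

  sep <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep$U, 0)
  expect_equal(mw_exact_p(c(1, 2, 3), c(4, 5, 6)), 0.1)  # 2/20 arrangements

  expect_equal(round(effect_size_r(3.20, 66), 2), 0.39)
  expect_gte(mann_whitney(rnorm(5), rnorm(6))$r, 0)  # r is non-negative
})

test_that("the normal approximation matches the reference implementation
           exactly and tracks the exact permutation p for small untied
           samples", {
  set.seed(77)
  for (rep in 1:12) {
    na <- sample(4:7, 1); nb <- sample(4:7, 1)
    a <- rnorm(na); b <- rnorm(nb, sample(c(0, 1), 1))
    mw <- mann_whitney(a, b)
    # the tie- and continuity-corrected normal approximation is the
    # convention of standard statistics software
    expect_equal(mw$p, wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value,
                 tolerance = 1e-12)
    # at n <= 7 the approximation deviates from the exact permutation p
    # by at most ~0.02 (0.025 bounds the worst case at these sizes)
    expect_lt(abs(mw$p - mw_exact_p(a, b)), 0.025)
  }
})

test_that("Cohen's d matches the printed global-activity effect and its
           algebraic identities", {
  d <- cohens_d(m1 = 0.0426, s1 = 0.0131, n1 = 37,
                m2 = 0.0335, s2 = 0.0103, n2 = 29)
  expect_equal(round(d, 2), 0.76)
  set.seed(8)
  a <- rnorm(20); b <- rnorm(25)
  expect_equal(cohens_d(a, b), -cohens_d(b, a), tolerance = 1e-12)
  expect_equal(cohens_d(m1 = 1, s1 = 2, n1 = 10, m2 = 1, s2 = 2, n2 = 10), 0)
  expect_error(cohens_d(rep(1, 5), rep(1, 5)), "zero")
})

test_that("domain-wise thresholds follow the anatomical grouping", {
  expect_equal(domain_alpha("left_elbow"), 0.0125)
  expect_equal(domain_alpha("right_wrist"), 0.0125)
  expect_equal(domain_alpha("right_foot"), 0.0167)
  expect_equal(domain_alpha("left_knee"), 0.0167)
  expect_equal(domain_alpha("head"), 0.05)
  expect_equal(domain_alpha("global"), 0.05)
  expect_error(domain_alpha("pelvis"), "unknown")
})

test_that("Spearman correlation handles perfect, reversed and tied ranks", {
  expect_equal(spearman_cor(1:10, 1:10)$rho, 1)
  expect_equal(spearman_cor(1:10, 10:1)$rho, -1)
  # hand computation: d = (-1, 1, -1, 1, 0), rho = 1 - 6*4/(5*24) = 0.8
  expect_equal(spearman_cor(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))$rho, 0.8)
  expect_error(spearman_cor(rep(1, 5), 1:5), "constant")
  # agrees with the standard implementation under ties
  set.seed(4)
  x <- sample(1:5, 30, replace = TRUE); y <- x + rnorm(30)
  expect_equal(spearman_cor(x, y)$rho,
               suppressWarnings(cor.test(x, y, method = "spearman"))$estimate[[1]],
               tolerance = 1e-12)
})

test_that("the height-adjusted model reports standardized coefficients", {
  set.seed(12)
  g <- rep(c(1, 0), c(37, 29))
  height <- rnorm(66, 132, 8)
  y <- 0.9 * g + rnorm(66)
  m <- height_adjusted_model(y, g, height)
  expect_lt(abs(m$beta[["height"]]), 0.25)       # orthogonal height
  expect_gt(m$beta[["group"]], 0.2)
  expect_error(height_adjusted_model(y, g, g), "rank-deficien")

  # recovery: mean standardized group effect over repeated cohorts
  betas <- replicate(30, {
    yy <- 0.8 * g + rnorm(66)
    height_adjusted_model(yy, g, rnorm(66, 132, 8))$beta[["group"]]
  })
  truth <- 0.8 * sd(g) / sqrt(0.8^2 * var(g) + 1)
  expect_lt(abs(mean(betas) - truth), 3 * sd(betas) / sqrt(30))
})

test_that("noncentral-t power reproduces the planning numbers and is
           monotone", {
  expect_equal(round(power_t(0.72, 0.05, 37, 29), 3), 0.816)
  expect_equal(power_t(0, 0.05, 30, 30), 0.05, tolerance = 1e-6)
  expect_equal(required_n_t(0.72, 0.05, 0.80), 64L)
  p <- sapply(c(0.2, 0.5, 0.8, 1.2), power_t, alpha = 0.05, n1 = 20, n2 = 20)
  expect_true(all(diff(p) > 0))
  pn <- sapply(c(10, 20, 40, 80), function(n) power_t(0.5, 0.05, n, n))
  expect_true(all(diff(pn) > 0))
})

test_that("Wilson intervals contain the estimate and stay in [0, 1]", {
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(5:200, 1); s <- runif(1, 0, n)
    ci <- wilson_ci(s, n)
    expect_true(ci[["lower"]] >= 0 && ci[["upper"]] <= 1)
    expect_true(ci[["lower"]] <= s / n && s / n <= ci[["upper"]])
  }
  expect_equal(wilson_ci(0, 20)[["lower"]], 0)
})

test_that("Hanley-McNeil intervals match the closed form", {
  expect_equal(unname(hanley_mcneil_ci(1, 37, 29)), c(1, 1))
  # A = 0.5, n1 = n2 = 1: SE = 0.5, interval clips to [0, 1]
  expect_equal(unname(hanley_mcneil_ci(0.5, 1, 1)), c(0, 1))
  ci <- hanley_mcneil_ci(0.85, 37, 29)
  expect_lt(ci[["lower"]], 0.85)
  expect_gt(ci[["upper"]], 0.85)
})

test_that("the 2x2 chi-square without continuity correction matches the
           demographic sex comparison and a direct formula", {
  res <- chi_square_2x2(matrix(c(11, 13, 26, 16), 2, 2))
  expect_equal(round(res$p, 3), 0.206)
  ind <- matrix(c(20, 10, 40, 20), 2, 2)  # proportional margins
  expect_equal(chi_square_2x2(ind)$chi2, 0, tolerance = 1e-12)
  expect_equal(chi_square_2x2(ind)$p, 1, tolerance = 1e-12)
  set.seed(2)
  for (rep in 1:10) {
    tab <- matrix(rpois(4, 15) + 1, 2, 2)
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    chi2 <- sum((tab - e)^2 / e)
    expect_equal(chi_square_2x2(tab)$chi2, chi2, tolerance = 1e-12)
  }
  expect_error(chi_square_2x2(matrix(c(0, 0, 3, 4), 2, 2)), "marginal")
})

test_that("the comparison battery gates tests and applies domain alphas", {
  set.seed(55)
  sim <- simulate_cohort(cohort_spec(n_group1 = 12, n_group2 = 12, seed = 3),
                         n_frames = 300)
  ft <- feature_table(sim$sessions, sim$cohort, cfg = short_qc(300))
  tab <- compare_groups(ft$features)
  expect_equal(nrow(tab), 16L)  # 15 regions + global
  expect_equal(tab$alpha_adjusted[tab$variable == "left_elbow"], 0.0125)
  expect_equal(tab$alpha_adjusted[tab$variable == "global"], 0.05)
  expect_true(all(tab$test %in% c("student_t", "welch_t", "mann_whitney")))
  expect_true(all(tab$p >= 0 & tab$p <= 1))
  forced <- compare_groups(ft$features, variables = "global", gate = FALSE)
  expect_equal(forced$test, "mann_whitney")
})
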