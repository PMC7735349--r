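# small longitudinal fixture: 3 subjects x 3 periods
stats_fixture <- function() {
  tibble::tibble(
    subject_id = rep(c("a", "b", "c"), each = 3),
    sex = rep(c("M", "F", "F"), each = 3),
    period_id = rep(c("P01", "P02", "P03"), 3),
    body_mass = c(5000, 5100, 5200, 3000, 3050, 3100, 4000, 3950, 4050),
    water_turnover = c(340, 360, 350, 220, 230, 240, 260, 270, 250)
  )
}

test_that("subject means are plain arithmetic means per subject", {
  sm <- subject_means(stats_fixture(), c("body_mass", "water_turnover"))
  expect_equal(sm$body_mass[sm$subject_id == "a"], 5100)
  expect_equal(sm$water_turnover[sm$subject_id == "b"], 230)
  one <- subject_means(stats_fixture()[1, ], "water_turnover")
  expect_equal(one$water_turnover, 340) # single period: identity
})

test_that("group summaries over subject means reproduce the cohort figures", {
  t1 <- elephant_summary()
  gs <- group_summary(t1, "water_turnover")
  expect_equal(gs$mean[gs$group == "M"], 359)
  expect_equal(round(gs$mean[gs$group == "F"]), 241)
  expect_equal(round(gs$sd[gs$group == "F"]), 28)
  expect_identical(gs$n, c(3L, 2L))
  # SD uses the n-1 denominator
  expect_equal(gs$sd[gs$group == "F"],
               sqrt(sum((c(227, 223, 273) - 241) ^ 2) / 2))
  same <- group_summary(
    tibble::tibble(subject_id = c("x", "y"), sex = "F",
                   water_turnover = c(250, 250)), "water_turnover")
  expect_equal(same$sd, 0)
})

test_that("normalizing to subject means centres every subject at 1", {
  d <- tibble::tibble(subject_id = "s", v = c(2, 4, 6))
  expect_equal(normalize_to_subject_mean(d, "v")$v, c(0.5, 1, 1.5))
  d2 <- tibble::tibble(subject_id = rep(c("s", "t"), each = 3),
                       v = c(7, 7, 7, 10, 20, 30))
  n2 <- normalize_to_subject_mean(d2, "v")
  expect_equal(n2$v[1:3], rep(1, 3))
  expect_equal(as.vector(tapply(n2$v, d2$subject_id, mean)), c(1, 1))
  # invariant under unit rescaling
  d3 <- d2
  d3$v <- d3$v * 1000
  expect_equal(normalize_to_subject_mean(d3, "v")$v, n2$v)
})

test_that("paired first-last test matches the textbook formula", {
  # no change at all
  flat <- tibble::tibble(subject_id = rep(c("a", "b", "c"), each = 2),
                         period_id = rep(c("P1", "P2"), 3),
                         v = rep(c(10, 20, 30), each = 2))
  res <- paired_first_last(flat, "v")
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  # identical non-zero differences: zero variance, documented error
  shift <- flat
  shift$v <- shift$v + rep(c(0, 1), 3)
  expect_error(paired_first_last(shift, "v"), "zero variance")
  # brute-force oracle on random first/last values
  set.seed(12)
  for (rep in 1:5) {
    n <- 6
    d <- tibble::tibble(
      subject_id = rep(letters[1:n], each = 2),
      period_id = rep(c("P1", "P2"), n),
      v = rnorm(2 * n, 100, 10))
    res <- paired_first_last(d, "v")
    diffs <- d$v[seq(2, 2 * n, 2)] - d$v[seq(1, 2 * n, 2)]
    t_ref <- mean(diffs) / (sd(diffs) / sqrt(n))
    expect_equal(res$t, t_ref, tolerance = 1e-10)
    expect_equal(res$df, n - 1)
    expect_equal(res$p, 2 * pt(-abs(t_ref), n - 1), tolerance = 1e-10)
  }
})

test_that("first/last selection is chronological within subject", {
  d <- tibble::tibble(subject_id = rep(c("a", "b"), each = 3),
                      period_id = c("P3", "P1", "P2", "P2", "P3", "P1"),
                      v = c(30, 10, 20, 2, 3, 1))
  res <- paired_first_last(d, "v")
  expect_equal(res$mean_diff, mean(c(30 - 10, 3 - 1)))
})

test_that("correlations agree with the brute-force covariance formula", {
  d <- stats_fixture()
  pooled <- cohort_correlations(d, "body_mass", "water_turnover", "pooled")
  x <- d$body_mass; y <- d$water_turnover
  r_ref <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pooled$r, r_ref, tolerance = 1e-10)
  expect_equal(pooled$df, length(x) - 2)
  expect_equal(pooled$t, r_ref * sqrt(pooled$df / (1 - r_ref^2)),
               tolerance = 1e-10)
  # perfect linear association
  lin <- tibble::tibble(subject_id = "s", x = 1:5, y = 2 * (1:5) + 3)
  expect_equal(cohort_correlations(lin, "x", "y", "pooled")$r, 1)
  anti <- tibble::tibble(subject_id = "s", x = 1:5, y = -(1:5))
  expect_equal(cohort_correlations(anti, "x", "y", "pooled")$r, -1)
  within <- cohort_correlations(d, "body_mass", "water_turnover", "within")
  expect_identical(nrow(within), 3L)
  expect_equal(within$df, rep(1, 3))
})

test_that("turnover-mass slope reproduces the cohort value of ~4.5", {
  t1 <- elephant_summary()
  expect_equal(round(turnover_mass_slope(t1), 1), 4.5)
  # two points: exact rise over run
  two <- tibble::tibble(subject_id = c("a", "b"),
                        body_mass = c(3000, 4000),
                        water_turnover = c(240, 285))
  expect_equal(turnover_mass_slope(two), 4.5, tolerance = 1e-10)
  # invariant under adding a constant to all turnovers
  two$water_turnover <- two$water_turnover + 100
  expect_equal(turnover_mass_slope(two), 4.5, tolerance = 1e-10)
})

test_that("QC anova matches hand-computed sums of squares on a balanced toy", {
  # 2 x 2 balanced, 2 replicates per cell
  y <- c(10, 12, 14, 16, 20, 22, 26, 28)
  a <- rep(c("am", "pm"), each = 4)
  b <- rep(rep(c("s1", "s2"), each = 2), 2)
  tab <- covariate_check_anova(y, a, b)
  grand <- mean(y)
  ss_a <- 4 * sum((tapply(y, a, mean) - grand)^2)
  ss_b <- 4 * sum((tapply(y, b, mean) - grand)^2)
  cell <- tapply(y, list(a, b), mean)
  ss_ab <- 2 * sum((cell - outer(tapply(y, a, mean), tapply(y, b, mean), "+")
                    + grand)^2)
  expect_equal(tab$sum_sq[tab$term == "a"], ss_a, tolerance = 1e-10)
  expect_equal(tab$sum_sq[tab$term == "b"], ss_b, tolerance = 1e-10)
  expect_equal(tab$sum_sq[tab$term == "a:b"], ss_ab, tolerance = 1e-10)
  expect_equal(tab$df[tab$term == "Residuals"], 4)
})

test_that("QC anova is well calibrated under the null", {
  set.seed(77)
  p_a <- replicate(200, {
    y <- rnorm(24)
    a <- rep(c("am", "pm"), 12)
    b <- rep(letters[1:4], each = 6)
    covariate_check_anova(y, a, b)$p[1]
  })
  # null p-values should look uniform: no excess small values
  expect_gt(mean(p_a > 0.05), 0.85)
  expect_gt(mean(p_a > 0.5), 0.3)
  # identical factor-level means give F of (numerically) zero
  y0 <- rep(c(1, 2, 3, 4), 2)
  tab0 <- covariate_check_anova(y0, rep(c("g1", "g2"), each = 4),
                                rep(c("u", "u", "v", "v"), 2))
  expect_lt(tab0$f[tab0$term == "a"], 1e-10)
})
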