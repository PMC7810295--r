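# The statistical battery, each routine against an independent oracle or a
# calibration simulation.

# brute-force sums-of-squares oracle for the one-way layout
oneway_oracle <- function(values, group) {
  group <- droplevels(as.factor(group))
  grand <- mean(values)
  ssb <- sum(tapply(values, group, function(v) length(v) * (mean(v) - grand)^2))
  ssw <- sum(tapply(values, group, function(v) sum((v - mean(v))^2)))
  df1 <- nlevels(group) - 1
  df2 <- length(values) - nlevels(group)
  f <- (ssb / df1) / (ssw / df2)
  list(f = f, p = stats::pf(f, df1, df2, lower.tail = FALSE))
}

test_that("one-way ANOVA equals the sums-of-squares decomposition", {
  set.seed(101)
  for (rep in 1:10) {
    g <- factor(rep(letters[1:4], times = sample(3:8, 4, replace = TRUE)))
    v <- rnorm(length(g), mean = as.integer(g) * runif(1, 0, 2))
    got <- one_way_anova(v, g)
    ora <- oneway_oracle(v, g)
    expect_equal(got$statistic, ora$f, tolerance = 1e-10)
    expect_equal(got$p_value, ora$p, tolerance = 1e-10)
  }
  # clearly separated groups
  got <- one_way_anova(c(0, 0, 0, 1, 1, 1) + rnorm(6, 0, 1e-4),
                       rep(c("a", "b"), each = 3))
  expect_lt(got$p_value, 1e-6)
  expect_error(one_way_anova(1:3, rep("a", 3)), class = "rfa_design_error")
})

test_that("one-way ANOVA p-values are uniform under the null", {
  set.seed(202)
  ps <- replicate(200, {
    one_way_anova(rnorm(40), rep(letters[1:4], each = 10))$p_value
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("the 2x2 factorial matches the balanced sums-of-squares oracle", {
  set.seed(303)
  for (rep in 1:5) {
    n <- 6
    sol <- rep(rep(c("deionized", "saline"), each = n), 2)
    tmp <- rep(c("ambient", "refrigerated"), each = 2 * n)
    v <- rnorm(4 * n, mean = 2 * (sol == "saline") + 1.5 * (tmp == "ambient") +
                 3 * (sol == "saline") * (tmp == "ambient"))
    got <- two_way_anova(v, sol, tmp)

    grand <- mean(v)
    m_s <- tapply(v, sol, mean); m_t <- tapply(v, tmp, mean)
    cell <- tapply(v, interaction(sol, tmp), mean)
    ss_s <- 2 * n * sum((m_s - grand)^2)
    ss_t <- 2 * n * sum((m_t - grand)^2)
    ss_cells <- n * sum((cell - grand)^2)
    ss_int <- ss_cells - ss_s - ss_t
    sse <- sum((v - ave(v, sol, tmp))^2)
    df_e <- 4 * n - 4
    expect_equal(got$solution$statistic, (ss_s / 1) / (sse / df_e), tolerance = 1e-10)
    expect_equal(got$temperature$statistic, (ss_t / 1) / (sse / df_e), tolerance = 1e-10)
    expect_equal(got$interaction$statistic, (ss_int / 1) / (sse / df_e), tolerance = 1e-10)
  }
})

test_that("the factorial excludes the untreated control and needs full cells", {
  set.seed(304)
  sol <- c(rep("none", 10), rep(c("saline", "deionized"), each = 10))
  tmp <- c(rep("none", 10), rep(c("ambient", "refrigerated"), 10))
  v <- rnorm(30)
  got <- two_way_anova(v, sol, tmp)
  expect_equal(got$solution$extra$df[2], 16) # 20 treated - 4 cells
  expect_error(
    two_way_anova(rnorm(10), rep("saline", 10), rep("ambient", 10)),
    class = "rfa_design_error"
  )
})

test_that("a pure interaction pattern is detected with good power", {
  set.seed(305)
  d <- 1.5 # in residual-sd units
  hits <- replicate(40, {
    sol <- rep(rep(c("deionized", "saline"), each = 10), 2)
    tmp <- rep(c("ambient", "refrigerated"), each = 20)
    mu <- ifelse((sol == "saline") == (tmp == "ambient"), d, -d)
    two_way_anova(rnorm(40, mu), sol, tmp)$interaction$p_value < 0.05
  })
  expect_gte(mean(hits), 0.8)
})

test_that("Tukey HSD equals the studentized-range oracle", {
  set.seed(404)
  k <- 4; n <- 7
  g <- factor(rep(letters[1:k], each = n))
  v <- rnorm(k * n, mean = as.integer(g))
  got <- tukey_hsd(v, g)
  mse <- sum((v - ave(v, g))^2) / (k * n - k)
  for (i in seq_len(nrow(got))) {
    va <- v[g == got$level_a[i]]; vb <- v[g == got$level_b[i]]
    diff <- mean(va) - mean(vb)
    se <- sqrt(mse / 2 * (1 / n + 1 / n))
    p <- stats::ptukey(abs(diff) / se, k, k * n - k, lower.tail = FALSE)
    expect_equal(got$mean_diff[i], diff, tolerance = 1e-10)
    expect_equal(got$adjusted_p[i], p, tolerance = 1e-6)
    # multiplicity: Tukey-adjusted p is never below the unadjusted t p
    # computed on the same pooled error term
    praw <- 2 * stats::pt(-abs(diff) / sqrt(mse * 2 / n), k * n - k)
    expect_gte(got$adjusted_p[i], praw - 1e-12)
  }
})

test_that("identical groups give a zero difference and p ~ 1", {
  v <- rep(c(5, 6, 7), 2)
  g <- rep(c("a", "b"), each = 3)
  got <- tukey_hsd(v, g)
  expect_equal(got$mean_diff, 0)
  expect_equal(got$adjusted_p, 1, tolerance = 1e-10)
})

test_that("Levene matches the absolute-deviation ANOVA oracle", {
  set.seed(505)
  for (center in c("median", "mean")) {
    v <- c(rnorm(15, sd = 1), rnorm(20, sd = 2.5), rnorm(12, sd = 0.5))
    g <- factor(rep(1:3, c(15, 20, 12)))
    got <- levene_test(v, g, center = center)
    ctr <- tapply(v, g, if (center == "median") median else mean)
    dev <- abs(v - ctr[g])
    ora <- oneway_oracle(dev, g)
    expect_equal(got$statistic, ora$f, tolerance = 1e-10)
    expect_equal(got$p_value, ora$p, tolerance = 1e-10)
  }
})

test_that("Levene edge cases: identical spreads, power, preconditions", {
  got <- levene_test(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3))
  expect_equal(got$statistic, 0)
  expect_equal(got$p_value, 1)

  set.seed(506)
  hits <- replicate(30, {
    v <- c(rnorm(30, sd = 1), rnorm(30, sd = 3))
    levene_test(v, rep(1:2, each = 30))$p_value < 0.05
  })
  expect_gte(mean(hits), 0.9)

  expect_error(levene_test(rnorm(5), rep("a", 5)), class = "rfa_spec_error")
})

test_that("Shapiro-Wilk keeps size under normality and power against skew", {
  set.seed(606)
  keep <- replicate(60, shapiro_wilk(rnorm(50))$p_value > 0.05)
  expect_gte(mean(keep), 0.9)
  reject <- replicate(60, shapiro_wilk(rexp(50))$p_value < 0.05)
  expect_gte(mean(reject), 0.9)
  expect_error(shapiro_wilk(c(1, 2)), class = "rfa_spec_error")
  expect_error(shapiro_wilk(rep(3, 10)), class = "rfa_degenerate_error")
})

test_that("Spearman: monotone limits and the exact permutation p-value", {
  expect_equal(spearman_correlation(1:4, c(10, 20, 30, 40))$rho, 1)
  expect_equal(spearman_correlation(1:4, c(40, 30, 20, 10))$rho, -1)

  set.seed(707)
  for (n in c(5, 7, 8)) {
    x <- rnorm(n); y <- rnorm(n)
    got <- spearman_correlation(x, y)
    expect_equal(got$method, "exact_permutation")
    ref <- stats::cor.test(x, y, method = "spearman", exact = TRUE)
    expect_equal(got$rho, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("the t approximation tracks the exact permutation p at small n", {
  set.seed(708)
  for (rep in 1:10) {
    x <- rnorm(8); y <- rnorm(8)
    exact <- spearman_correlation(x, y)
    rho <- exact$rho
    tval <- rho * sqrt((8 - 2) / (1 - rho^2))
    approx_p <- 2 * stats::pt(-abs(tval), 6)
    expect_lt(abs(approx_p - exact$p_value), 0.02)
  }
})

test_that("Spearman handles ties via midranks and rejects degenerate input", {
  got <- spearman_correlation(c(1, 2, 2, 3, 4), c(2, 3, 3, 4, 6))
  expect_equal(got$rho, stats::cor(rank(c(1, 2, 2, 3, 4)), rank(c(2, 3, 3, 4, 6))))
  expect_error(spearman_correlation(rep(1, 5), 1:5), class = "rfa_degenerate_error")
  expect_error(spearman_correlation(1:3, 1:3), class = "rfa_spec_error")
})

test_that("Tukey fences flag only genuinely extreme points", {
  expect_equal(flag_outliers(c(1, 2, 3, 4, 100)),
               c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_false(any(flag_outliers(1:20)))
  expect_false(any(flag_outliers(rep(7, 6)))) # zero IQR: fences collapse
  expect_error(flag_outliers(1:3), class = "rfa_spec_error")
})

test_that("BCa bootstrap is seeded, near-percentile for symmetric data, and flags degeneracy", {
  set.seed(808)
  x <- rnorm(100, 10, 2)
  a <- bca_bootstrap_ci(x, mean, B = 1000, seed = 21)
  b <- bca_bootstrap_ci(x, mean, B = 1000, seed = 21)
  expect_identical(a, b)
  expect_lt(a$ci_low, mean(x))
  expect_gt(a$ci_high, mean(x))

  # symmetric statistic: BCa and the plain percentile interval of the same
  # resamples nearly coincide
  set.seed(21)
  n <- length(x)
  boots <- vapply(1:1000, function(b) mean(x[sample.int(n, n, replace = TRUE)]),
                  numeric(1))
  perc <- stats::quantile(boots, c(0.025, 0.975), names = FALSE, type = 6)
  expect_lt(abs(a$ci_low - perc[1]), 0.05 * sd(x))
  expect_lt(abs(a$ci_high - perc[2]), 0.05 * sd(x))

  expect_warning(d <- bca_bootstrap_ci(rep(5, 10), mean, B = 500, seed = 1))
  expect_true(d$degenerate)
  expect_equal(d$method, "percentile")
  expect_error(bca_bootstrap_ci(1:4), class = "rfa_spec_error")
  expect_error(bca_bootstrap_ci(1:10, B = 50), class = "rfa_spec_error")
})

test_that("BCa agrees with the boot package on a fixed skewed sample", {
  set.seed(909)
  x <- rexp(60, rate = 0.3)
  ours <- bca_bootstrap_ci(x, mean, B = 5000, seed = 77)
  bt <- boot::boot(x, function(d, i) mean(d[i]), R = 5000)
  ci <- boot::boot.ci(bt, type = "bca")$bca
  scale <- sd(x) / sqrt(length(x))
  expect_lt(abs(ours$ci_low - ci[4]), 0.35 * scale)
  expect_lt(abs(ours$ci_high - ci[5]), 0.35 * scale)
})

test_that("marginal means reproduce the pooled-variance one-way intervals", {
  set.seed(111)
  samples <- data.frame(
    group = rep(c("PURERF", "SALINE23", "SALINE5", "DEI23", "DEI5"), each = 8),
    dr = rnorm(40, rep(c(22, 21, 31, 29, 25), each = 8), 4)
  )
  map <- group_factors()
  samples$solution <- map$solution[match(samples$group, map$group)]
  samples$temperature <- map$temperature[match(samples$group, map$group)]

  mm <- marginal_means(samples, "dr", "group")
  # oracle: mean_g +/- t_{.975, N-k} sqrt(MSE / n_g)
  mse <- sum((samples$dr - ave(samples$dr, samples$group))^2) / (40 - 5)
  for (i in seq_len(nrow(mm))) {
    vals <- samples$dr[samples$group == mm$level[i]]
    half <- stats::qt(0.975, 35) * sqrt(mse / 8)
    expect_equal(mm$mean[i], mean(vals), tolerance = 1e-10)
    expect_equal(mm$ci_high[i] - mm$mean[i], half, tolerance = 1e-10)
  }
  # balanced design: every arm gets the same half-width
  expect_equal(diff(range(mm$ci_high - mm$ci_low)), 0, tolerance = 1e-10)
})

test_that("factor marginals average over the other factor and append the control", {
  set.seed(112)
  samples <- data.frame(
    group = rep(c("PURERF", "SALINE23", "SALINE5", "DEI23", "DEI5"), each = 6)
  )
  map <- group_factors()
  samples$solution <- map$solution[match(samples$group, map$group)]
  samples$temperature <- map$temperature[match(samples$group, map$group)]
  samples$ar <- rnorm(30, rep(c(545, 188, 483, 542, 285), each = 6), 100)

  mm <- marginal_means(samples, "ar", "solution")
  expect_setequal(mm$level, c("deionized", "saline", "PURERF"))
  sal <- mean(tapply(samples$ar[samples$solution == "saline"],
                     samples$group[samples$solution == "saline"], mean))
  expect_equal(mm$mean[mm$level == "saline"], sal, tolerance = 1e-10)
  expect_equal(mm$mean[mm$level == "PURERF"],
               mean(samples$ar[samples$group == "PURERF"]), tolerance = 1e-10)
})

test_that("single-level summaries and bootstrap intervals behave", {
  one <- data.frame(group = rep("PURERF", 3), solution = "none",
                    temperature = "none", dr = c(1, 2, 3))
  mm <- marginal_means(one, "dr", "group")
  expect_equal(mm$mean, 2)

  set.seed(113)
  big <- data.frame(group = rep("PURERF", 100), solution = "none",
                    temperature = "none", dr = rnorm(100, 20, 3))
  par <- marginal_means(big, "dr", "group", "parametric")
  boo <- marginal_means(big, "dr", "group", "bca_bootstrap", seed = 5)
  w_par <- par$ci_high - par$ci_low
  w_boo <- boo$ci_high - boo$ci_low
  expect_lt(abs(w_par - w_boo) / w_par, 0.1)
})
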