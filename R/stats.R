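# The cohort-level statistical battery: assumption checks, one- and two-way
# ANOVA with Tukey HSD, BCa bootstrap intervals, Spearman correlation with
# an exact small-sample permutation p-value, Tukey-fence outliers, and
# estimated marginal means.

new_rfa_test <- function(name, statistic, p_value, extra = list()) {
  structure(
    list(name = name, statistic = unname(statistic),
         p_value = unname(p_value), extra = extra),
    class = "rfa_test"
  )
}

#' @export
print.rfa_test <- function(x, ...) {
  cat(sprintf("<rfa_test> %s: statistic = %.4g, p = %.4g\n",
              x$name, x$statistic, x$p_value))
  invisible(x)
}

#' Shapiro-Wilk normality test
#'
#' Thin, validated wrapper around [stats::shapiro.test()] used as the
#' normality check of the battery.
#'
#' @param values Numeric vector, `3 <= n <= 5000`, not constant.
#' @return An `rfa_test` with the W statistic and p-value.
#' @export
shapiro_wilk <- function(values) {
  values <- as.numeric(values)
  if (anyNA(values)) abort_data("Missing values are not allowed.")
  n <- length(values)
  if (n < 3 || n > 5000) {
    abort_spec("Shapiro-Wilk requires between 3 and 5000 observations.")
  }
  if (diff(range(values)) == 0) {
    abort_degenerate("Shapiro-Wilk is undefined for a constant sample.")
  }
  ht <- stats::shapiro.test(values)
  new_rfa_test("shapiro_wilk", ht$statistic, ht$p.value, list(n = n))
}

#' Levene / Brown-Forsythe homogeneity-of-variance test
#'
#' Tests equality of group variances via [car::leveneTest()]. The default
#' centering is the group median (the Brown-Forsythe variant), which is
#' also the default of the routine the field commonly uses.
#'
#' @param values Numeric vector of observations.
#' @param group Grouping factor, at least 2 levels with n >= 2 each.
#' @param center `"median"` (default) or `"mean"`.
#' @return An `rfa_test` with the F statistic, p-value and degrees of
#'   freedom.
#' @export
levene_test <- function(values, group, center = c("median", "mean")) {
  center <- match.arg(center)
  values <- as.numeric(values)
  group <- droplevels(as.factor(group))
  if (anyNA(values) || anyNA(group)) abort_data("Missing values are not allowed.")
  sizes <- table(group)
  if (length(sizes) < 2) abort_spec("Levene needs at least two groups.")
  if (any(sizes < 2)) abort_spec("Every group needs at least two observations.")
  centers <- tapply(values, group, if (center == "median") stats::median else mean)
  dev <- abs(values - centers[group])
  if (all(tapply(dev, group, stats::var) == 0)) {
    if (all(dev == 0)) {
      # all spreads identical (e.g. identical value sets): no evidence at all
      return(new_rfa_test("levene", 0, 1,
                          list(df = c(length(sizes) - 1, length(values) - length(sizes)),
                               center = center)))
    }
    abort_degenerate("Levene is undefined: zero within-group deviation spread.")
  }
  lt <- car::leveneTest(values, group, center = if (center == "median") stats::median else mean)
  new_rfa_test("levene", lt$`F value`[1], lt$`Pr(>F)`[1],
               list(df = c(lt$Df[1], lt$Df[2]), center = center,
                    group_sizes = as.integer(sizes)))
}

#' One-way analysis of variance
#'
#' Classical between/within F test of equal group means, via
#' [stats::aov()].
#'
#' @param values Numeric response vector.
#' @param group Grouping factor with at least 2 non-empty levels.
#' @return An `rfa_test` with the F statistic, p-value and df.
#' @export
one_way_anova <- function(values, group) {
  values <- as.numeric(values)
  group <- droplevels(as.factor(group))
  if (anyNA(values) || anyNA(group)) abort_data("Missing values are not allowed.")
  if (nlevels(group) < 2) abort_design("One-way ANOVA needs at least two levels.")
  if (any(table(group) == 0)) abort_design("Every level needs observations.")
  if (length(values) <= nlevels(group)) {
    abort_design("Need more observations than levels.")
  }
  fit <- stats::aov(values ~ group)
  tab <- summary(fit)[[1]]
  new_rfa_test("one_way_anova", tab$`F value`[1], tab$`Pr(>F)`[1],
               list(df = c(tab$Df[1], tab$Df[2]),
                    group_sizes = as.integer(table(group)),
                    fit = fit))
}

#' Two-way factorial analysis of variance
#'
#' Fits the crossed solution x temperature factorial with interaction on
#' the treated arms. The RF-only control has neither a solution nor a
#' temperature level, so rows with factor level `"none"` are excluded
#' before fitting (an incomplete factorial with a phantom level is
#' ill-posed); compare the control through the one-way path instead.
#'
#' @param values Numeric response vector.
#' @param solution Factor with levels among `saline`, `deionized` (and
#'   `none`, which is dropped).
#' @param temperature Factor with levels among `ambient`, `refrigerated`
#'   (and `none`, which is dropped).
#' @return A named list of three `rfa_test` objects: `solution`,
#'   `temperature`, `interaction`.
#' @export
two_way_anova <- function(values, solution, temperature) {
  values <- as.numeric(values)
  solution <- as.character(solution)
  temperature <- as.character(temperature)
  keep <- solution %in% c("saline", "deionized") &
    temperature %in% c("ambient", "refrigerated")
  if (!any(keep)) abort_design("No treated (solution x temperature) rows present.")
  values <- values[keep]
  sol <- factor(solution[keep], levels = c("deionized", "saline"))
  tmp <- factor(temperature[keep], levels = c("ambient", "refrigerated"))
  cells <- table(sol, tmp)
  if (any(cells == 0)) {
    abort_design("Every solution x temperature cell needs observations.")
  }
  fit <- stats::aov(values ~ sol * tmp)
  tab <- summary(fit)[[1]]
  rn <- trimws(rownames(tab))
  pick <- function(term) which(rn == term)
  mk <- function(term, label) {
    i <- pick(term)
    new_rfa_test(label, tab$`F value`[i], tab$`Pr(>F)`[i],
                 list(df = c(tab$Df[i], tab$Df[pick("Residuals")])))
  }
  list(
    solution = mk("sol", "two_way_solution"),
    temperature = mk("tmp", "two_way_temperature"),
    interaction = mk("sol:tmp", "two_way_interaction")
  )
}

#' Tukey HSD pairwise comparisons
#'
#' All pairwise mean differences after a one-way fit, with studentized-range
#' adjusted p-values and simultaneous confidence intervals, via
#' [stats::TukeyHSD()].
#'
#' @param values Numeric response vector.
#' @param group Grouping factor.
#' @param conf_level Simultaneous confidence level (default 0.95).
#' @return A tibble with columns `level_a`, `level_b`, `mean_diff`,
#'   `ci_low`, `ci_high`, `adjusted_p`.
#' @export
tukey_hsd <- function(values, group, conf_level = 0.95) {
  values <- as.numeric(values)
  group <- droplevels(as.factor(group))
  if (nlevels(group) < 2) abort_design("Tukey HSD needs at least two levels.")
  fit <- stats::aov(values ~ group)
  tk <- stats::TukeyHSD(fit, conf.level = conf_level)$group
  pair <- strsplit(rownames(tk), "-", fixed = TRUE)
  tibble::tibble(
    level_a = vapply(pair, `[`, "", 1),
    level_b = vapply(pair, `[`, "", 2),
    mean_diff = unname(tk[, "diff"]),
    ci_low = unname(tk[, "lwr"]),
    ci_high = unname(tk[, "upr"]),
    adjusted_p = unname(tk[, "p adj"])
  )
}

#' Bias-corrected and accelerated (BCa) bootstrap confidence interval
#'
#' Nonparametric bootstrap interval for an arbitrary statistic. The bias
#' correction `z0` is read off the fraction of bootstrap replicates below
#' the point estimate; the acceleration `a` comes from the skewness of the
#' jackknife distribution of the statistic. When the bootstrap distribution
#' is degenerate (all replicates equal, or the point estimate falls outside
#' the replicate range) the interval falls back to the plain percentile
#' interval and the result is flagged.
#'
#' @param values Numeric vector, `n >= 5`.
#' @param statistic Function of a numeric vector returning one number
#'   (default [mean()]).
#' @param B Number of bootstrap resamples, `>= 200` (default 1000).
#' @param level Confidence level in (0, 1) (default 0.95).
#' @param seed Optional integer seed; fixing it makes the interval
#'   reproducible.
#' @return A list with `estimate`, `ci_low`, `ci_high`, `method`
#'   (`"bca"` or `"percentile"`), `degenerate` flag, `B` and `level`.
#' @export
bca_bootstrap_ci <- function(values, statistic = mean, B = 1000,
                             level = 0.95, seed = NULL) {
  values <- as.numeric(values)
  n <- length(values)
  if (anyNA(values)) abort_data("Missing values are not allowed.")
  if (n < 5) abort_spec("BCa bootstrap requires at least 5 observations.")
  if (!is_number(B) || B < 200) abort_spec("Use at least 200 resamples.")
  if (!is_number(level) || level <= 0 || level >= 1) {
    abort_spec("`level` must lie strictly between 0 and 1.")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))

  theta <- statistic(values)
  boots <- vapply(
    seq_len(B),
    function(b) statistic(values[sample.int(n, n, replace = TRUE)]),
    numeric(1)
  )
  alpha <- (1 - level) / 2
  percentile <- function() {
    ci <- stats::quantile(boots, c(alpha, 1 - alpha), names = FALSE, type = 6)
    list(estimate = theta, ci_low = ci[1], ci_high = ci[2],
         method = "percentile", degenerate = TRUE, B = B, level = level)
  }
  if (diff(range(boots)) == 0) {
    warning("Degenerate bootstrap distribution; returning a percentile interval.")
    return(percentile())
  }
  prop <- mean(boots < theta)
  if (prop == 0 || prop == 1) {
    warning("Point estimate outside the bootstrap range; returning a percentile interval.")
    return(percentile())
  }
  z0 <- stats::qnorm(prop)
  jack <- vapply(seq_len(n), function(i) statistic(values[-i]), numeric(1))
  d <- mean(jack) - jack
  denom <- sum(d^2)
  a <- if (denom == 0) 0 else sum(d^3) / (6 * denom^1.5)
  za <- stats::qnorm(c(alpha, 1 - alpha))
  adj <- stats::pnorm(z0 + (z0 + za) / (1 - a * (z0 + za)))
  ci <- stats::quantile(boots, adj, names = FALSE, type = 6)
  list(estimate = theta, ci_low = ci[1], ci_high = ci[2],
       method = "bca", degenerate = FALSE, B = B, level = level)
}

# all permutations of 1..n as an integer matrix (n! rows), built level by
# level so the cost is a single allocation per recursion depth
perm_matrix <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  p <- perm_matrix(n - 1)
  m <- nrow(p)
  res <- matrix(0L, n * m, n)
  for (i in seq_len(n)) {
    rows <- ((i - 1) * m + 1):(i * m)
    res[rows, 1] <- i
    rest <- seq_len(n)[-i]
    res[rows, -1] <- matrix(rest[p], m, n - 1)
  }
  res
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' Rank correlation using midranks for ties. For `n <= 9` the two-sided
#' p-value is exact, computed by full enumeration of all `n!` permutations
#' of one margin's ranks; for larger samples the usual t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom is
#' used.
#'
#' @param x,y Paired numeric vectors, `n >= 4`, no missing values, neither
#'   constant.
#' @return A list with `rho`, `p_value`, `method`
#'   (`"exact_permutation"` or `"t_approximation"`) and `n`.
#' @export
spearman_correlation <- function(x, y) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) abort_data("`x` and `y` must be paired.")
  if (anyNA(x) || anyNA(y)) abort_data("Missing values are not allowed.")
  n <- length(x)
  if (n < 4) abort_spec("Spearman correlation requires at least 4 pairs.")
  if (diff(range(x)) == 0 || diff(range(y)) == 0) {
    abort_degenerate("Correlation is undefined for a constant vector.")
  }
  rx <- rank(x)
  ry <- rank(y)
  rho <- stats::cor(rx, ry)

  if (n <= 9) {
    perms <- perm_matrix(n)
    rxc <- rx - mean(rx)
    ryc <- ry - mean(ry)
    scale <- sqrt(sum(rxc^2) * sum(ryc^2))
    # rho for every permutation of the y-ranks in one matrix product
    rho_all <- as.vector(matrix(ryc[perms], nrow(perms), n) %*% rxc) / scale
    p <- mean(abs(rho_all) >= abs(rho) - 1e-12)
    method <- "exact_permutation"
  } else {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tval <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tval), n - 2)
    }
    method <- "t_approximation"
  }
  list(rho = rho, p_value = p, method = method, n = n)
}

#' Tukey-fence outlier flags
#'
#' Flags observations outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`, with
#' quartiles computed by linear interpolation. With zero IQR the fences
#' collapse onto the quartiles and only values away from them are flagged.
#'
#' @param values Numeric vector, `n >= 4`.
#' @return Logical mask, `TRUE` where the observation is an outlier.
#' @export
flag_outliers <- function(values) {
  values <- as.numeric(values)
  if (anyNA(values)) abort_data("Missing values are not allowed.")
  if (length(values) < 4) abort_spec("Outlier fencing requires at least 4 values.")
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  values < q[1] - 1.5 * iqr | values > q[2] + 1.5 * iqr
}

#' Estimated marginal means with confidence intervals
#'
#' Per-level means of one performance index with 95% (by default)
#' confidence intervals, in the style of the published summary tables.
#'
#' * `grouping = "group"`: marginal means of the five arms from the one-way
#'   model (pooled residual variance, which is what gives every arm the
#'   same CI half-width).
#' * `grouping = "solution"` / `"temperature"`: marginal means of the
#'   factor levels from the 2x2 factorial fitted on the treated arms,
#'   averaged over the other factor; the RF-only control is appended as its
#'   own reference level, estimated from the one-way model (it belongs to
#'   neither factor).
#'
#' `ci_method = "parametric"` uses the model-based t intervals (via
#' \pkg{emmeans}); `"bca_bootstrap"` replaces each level's interval with a
#' BCa bootstrap interval of that level's raw mean.
#'
#' @param samples Data frame with columns `group`, `solution`,
#'   `temperature` and the index column named by `index`.
#' @param index Name of the index column to summarize (e.g. `"dr"`).
#' @param grouping `"group"`, `"solution"` or `"temperature"`.
#' @param ci_method `"parametric"` or `"bca_bootstrap"`.
#' @param level Confidence level.
#' @param B Bootstrap resamples for `"bca_bootstrap"`.
#' @param seed Seed for the bootstrap path.
#' @return A tibble with columns `level`, `mean`, `ci_low`, `ci_high`, `n`,
#'   `method`.
#' @export
marginal_means <- function(samples, index,
                           grouping = c("group", "solution", "temperature"),
                           ci_method = c("parametric", "bca_bootstrap"),
                           level = 0.95, B = 1000, seed = NULL) {
  grouping <- match.arg(grouping)
  ci_method <- match.arg(ci_method)
  samples <- as.data.frame(samples)
  if (!index %in% names(samples)) {
    abort_data(sprintf("No column '%s' in `samples`.", index))
  }
  values <- as.numeric(samples[[index]])
  if (anyNA(values)) abort_data("Missing index values are not allowed.")

  level_of <- if (grouping == "group") samples$group else samples[[grouping]]
  sizes <- table(level_of)
  if (any(sizes < 2)) {
    abort_design("Every level needs at least 2 samples for an interval.")
  }

  if (ci_method == "bca_bootstrap") {
    lvls <- if (grouping == "group") {
      intersect(GROUP_LEVELS, unique(level_of))
    } else {
      c(setdiff(sort(unique(level_of)), "none"),
        if ("none" %in% level_of) "PURERF")
    }
    out <- lapply(seq_along(lvls), function(i) {
      lv <- lvls[i]
      vals <- if (lv == "PURERF" && grouping != "group") {
        values[samples$group == "PURERF"]
      } else {
        values[level_of == lv]
      }
      ci <- bca_bootstrap_ci(vals, mean, B = B, level = level,
                             seed = if (is.null(seed)) NULL else derive_seed(seed, i))
      tibble::tibble(level = lv, mean = ci$estimate,
                     ci_low = ci$ci_low, ci_high = ci$ci_high,
                     n = length(vals), method = "bca_bootstrap")
    })
    return(dplyr::bind_rows(out))
  }

  if (grouping == "group") {
    grp <- factor(samples$group, levels = intersect(GROUP_LEVELS, unique(samples$group)))
    if (nlevels(grp) == 1) {
      n <- length(values)
      se <- stats::sd(values) / sqrt(n)
      half <- stats::qt(1 - (1 - level) / 2, n - 1) * se
      return(tibble::tibble(level = levels(grp), mean = mean(values),
                            ci_low = mean(values) - half,
                            ci_high = mean(values) + half,
                            n = n, method = "parametric"))
    }
    fit <- stats::aov(values ~ grp, data = data.frame(values, grp))
    em <- as.data.frame(emmeans::emmeans(fit, "grp", level = level))
    return(tibble::tibble(
      level = as.character(em$grp), mean = em$emmean,
      ci_low = em$lower.CL, ci_high = em$upper.CL,
      n = as.integer(table(grp)[as.character(em$grp)]),
      method = "parametric"
    ))
  }

  treated <- samples$solution %in% c("saline", "deionized") &
    samples$temperature %in% c("ambient", "refrigerated")
  if (!any(treated)) abort_design("No treated rows to build factor marginals from.")
  dat <- data.frame(
    values = values[treated],
    sol = factor(samples$solution[treated]),
    tmp = factor(samples$temperature[treated])
  )
  if (any(table(dat$sol, dat$tmp) == 0)) {
    abort_design("Every solution x temperature cell needs observations.")
  }
  fit <- stats::aov(values ~ sol * tmp, data = dat)
  spec_var <- if (grouping == "solution") "sol" else "tmp"
  # averaging over the other factor is intentional here, so silence the
  # emmeans advisory about interaction involvement
  em <- suppressMessages(
    as.data.frame(emmeans::emmeans(fit, spec_var, level = level))
  )
  out <- tibble::tibble(
    level = as.character(em[[spec_var]]), mean = em$emmean,
    ci_low = em$lower.CL, ci_high = em$upper.CL,
    n = as.integer(table(dat[[spec_var]])[as.character(em[[spec_var]])]),
    method = "parametric"
  )
  if (any(samples$group == "PURERF")) {
    ctrl <- marginal_means(samples, index, "group", "parametric", level)
    out <- dplyr::bind_rows(out, ctrl[ctrl$level == "PURERF", ])
  }
  out
}
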