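# Synthetic impedance curves and cohorts.
#
# Curves are index-faithful rather than biophysical: they are constructed to
# realize prescribed delta/DR/AR values exactly in the noise-free limit,
# which is sufficient because every downstream computation consumes only
# landmarks and indices. The drop-then-rise morphology mimics the canonical
# ablation trajectory: a monotone decay to the minimum (tissue resistivity
# falling as temperature rises) followed by an accelerating rise to
# roll-off (desiccation isolating the electrode).

#' Specification of one synthetic impedance curve
#'
#' @param Z_initial Initial impedance in ohms.
#' @param dr Target Drop Ratio in percent, in `[0, 100)`.
#' @param ar Target Ascent Ratio in percent, `>= 0`.
#' @param delta Target asymmetry index in percent, in `(-100, 100)` so the
#'   minimum falls strictly inside the procedure.
#' @param t_end Procedure duration to roll-off in seconds.
#' @param dt Sampling interval in seconds.
#' @param noise_sd Standard deviation of additive Gaussian measurement
#'   noise in ohms (0 = noise-free); noisy samples are floored at 1 ohm so
#'   impedance stays positive.
#' @param decay_shape Curvature of the saturating-exponential decay from
#'   `Z_initial` to the minimum (`> 0`; small values are near-linear).
#' @param rise_exponent Exponent of the power-law rise from the minimum to
#'   roll-off (`> 1` gives the accelerating, roll-off-like profile).
#' @param seed Optional integer seed for the noise stream.
#' @return A list of class `rfa_curve_spec`.
#' @export
curve_spec <- function(Z_initial = 90, dr = 25, ar = 400, delta = 25,
                       t_end = 600, dt = 1, noise_sd = 0,
                       decay_shape = 1.5, rise_exponent = 3, seed = NULL) {
  if (!is_number(Z_initial) || Z_initial <= 0) abort_spec("Z_initial must be positive.")
  if (!is_number(dr) || dr < 0 || dr >= 100) abort_spec("dr must lie in [0, 100).")
  if (!is_number(ar) || ar < 0) abort_spec("ar must be non-negative.")
  if (!is_number(delta) || delta <= -100 || delta >= 100) {
    abort_spec("delta must lie in (-100, 100) so the minimum is inside the procedure.")
  }
  if (!is_number(t_end) || t_end <= 0) abort_spec("t_end must be positive.")
  if (!is_number(dt) || dt <= 0 || dt >= t_end) abort_spec("dt must lie in (0, t_end).")
  if (!is_number(noise_sd) || noise_sd < 0) abort_spec("noise_sd must be >= 0.")
  if (!is_number(decay_shape) || decay_shape <= 0) abort_spec("decay_shape must be > 0.")
  if (!is_number(rise_exponent) || rise_exponent <= 1) abort_spec("rise_exponent must be > 1.")
  structure(
    list(Z_initial = Z_initial, dr = dr, ar = ar, delta = delta,
         t_end = t_end, dt = dt, noise_sd = noise_sd,
         decay_shape = decay_shape, rise_exponent = rise_exponent,
         seed = seed),
    class = "rfa_curve_spec"
  )
}

#' Generate one synthetic impedance curve
#'
#' Builds the noise-free trajectory through the designed landmarks
#' `t_minimum = (1 + delta/100) * t_end / 2`,
#' `Z_minimum = Z_initial * (1 - dr/100)` and
#' `Z_end = Z_minimum * (1 + ar/100)`: a saturating-exponential decay on
#' `[0, t_minimum]` and a power-law rise on `[t_minimum, t_end]`, sampled
#' every `dt` seconds with `t_minimum` and `t_end` always included in the
#' grid so the designed landmarks are realized exactly. Gaussian noise of
#' standard deviation `noise_sd` is then added and floored at 1 ohm.
#'
#' @param spec A [curve_spec()].
#' @param sample_id Identifier for the generated curve.
#' @return An [rfa_curve()].
#' @examples
#' cv <- generate_curve(curve_spec(Z_initial = 100, dr = 20, ar = 100,
#'                                 delta = 0, t_end = 100, dt = 1))
#' compute_indices(extract_parameters(cv))
#' @export
generate_curve <- function(spec, sample_id = "synthetic") {
  stopifnot(inherits(spec, "rfa_curve_spec"))
  if (!is.null(spec$seed)) set.seed(as.integer(spec$seed))

  t_min <- (1 + spec$delta / 100) * spec$t_end / 2
  Z_min <- spec$Z_initial * (1 - spec$dr / 100)
  Z_end <- Z_min * (1 + spec$ar / 100)
  if (t_min <= 0 || t_min >= spec$t_end) {
    abort_spec("`delta` places the minimum outside (0, t_end).")
  }

  tt <- sort(unique(c(seq(0, spec$t_end, by = spec$dt), t_min, spec$t_end)))
  s <- spec$decay_shape
  u <- pmin(tt / t_min, 1)
  w <- if (s < 1e-8) 1 - u else (exp(-s * u) - exp(-s)) / (1 - exp(-s))
  Z <- Z_min + (spec$Z_initial - Z_min) * w
  rise <- tt > t_min
  v <- (tt[rise] - t_min) / (spec$t_end - t_min)
  Z[rise] <- Z_min + (Z_end - Z_min) * v^spec$rise_exponent

  if (spec$noise_sd > 0) {
    Z <- pmax(Z + stats::rnorm(length(Z), 0, spec$noise_sd), 1)
  }
  rfa_curve(t = tt, Z = Z, sample_id = sample_id)
}

# sd reconstructed from a symmetric 95% CI half-width at the study's
# per-arm sample size of 10
sd_from_ci <- function(mean, ci_high, n = 10) (ci_high - mean) / 1.96 * sqrt(n)

#' Default per-arm generator parameters for the reference cohort
#'
#' One row per study arm with the index means, reconstructed standard
#' deviations, volume distribution and volume-AR rank-correlation target
#' used by [cohort_spec()]. Means come from the published group estimates
#' ([ref_group_indices()], [ref_group_volumes()]); standard deviations are
#' reconstructed from the 95% CI half-widths as
#' `(ci_high - mean) / 1.96 * sqrt(10)` and are therefore approximations
#' (the published intervals pool variance across arms).
#'
#' @return A tibble with one row per arm.
#' @export
default_group_specs <- function() {
  idx <- ref_group_indices()
  wide <- tidyr::pivot_wider(idx, names_from = "index",
                             values_from = c("mean", "ci_low", "ci_high"))
  vols <- ref_group_volumes()
  rho <- ref_volume_ar_rho()
  tibble::tibble(
    group = wide$group,
    delta_mean = wide$mean_delta,
    delta_sd = sd_from_ci(wide$mean_delta, wide$ci_high_delta),
    dr_mean = wide$mean_dr,
    dr_sd = sd_from_ci(wide$mean_dr, wide$ci_high_dr),
    ar_mean = wide$mean_ar,
    ar_sd = sd_from_ci(wide$mean_ar, wide$ci_high_ar),
    volume_mean = vols$mean[match(wide$group, vols$group)],
    volume_sd = vols$sd[match(wide$group, vols$group)],
    volume_ar_rho = unname(rho[wide$group])
  )
}

#' Specification of a synthetic multi-arm cohort
#'
#' @param groups Per-arm parameter table in the layout of
#'   [default_group_specs()] (columns `group`, `<index>_mean`, `<index>_sd`
#'   for delta/dr/ar, `volume_mean`, `volume_sd`, `volume_ar_rho`).
#' @param n Ablations per arm (the reference design uses 10).
#' @param Z_initial_range Uniform sampling range for the initial impedance
#'   in ohms; the reference cohort observed 66-117.
#' @param t_end_range Uniform sampling range for the procedure duration in
#'   seconds.
#' @param dt Sampling interval in seconds.
#' @param noise_sd Measurement-noise standard deviation in ohms.
#' @param decay_shape,rise_exponent Curve-shape parameters, see
#'   [curve_spec()].
#' @param seed Optional integer seed; fixing it makes the whole cohort
#'   (curves included) reproducible.
#' @return A list of class `rfa_cohort_spec`.
#' @export
cohort_spec <- function(groups = default_group_specs(), n = 10,
                        Z_initial_range = c(66, 117),
                        t_end_range = c(300, 900), dt = 1, noise_sd = 2,
                        decay_shape = 1.5, rise_exponent = 3, seed = NULL) {
  groups <- tibble::as_tibble(groups)
  need <- c("group", "delta_mean", "delta_sd", "dr_mean", "dr_sd",
            "ar_mean", "ar_sd", "volume_mean", "volume_sd", "volume_ar_rho")
  miss <- setdiff(need, names(groups))
  if (length(miss)) {
    abort_spec(sprintf("`groups` lacks column(s): %s.", paste(miss, collapse = ", ")))
  }
  if (!is_number(n) || n < 1) abort_spec("`n` must be at least 1 per arm.")
  sds <- unlist(groups[c("delta_sd", "dr_sd", "ar_sd", "volume_sd")])
  if (any(sds < 0)) abort_spec("Standard deviations must be non-negative.")
  if (any(abs(groups$volume_ar_rho) > 1)) abort_spec("|rho| must not exceed 1.")
  degenerate <- groups$volume_ar_rho != 0 &
    (groups$ar_sd == 0 | groups$volume_sd == 0)
  if (any(degenerate)) {
    abort_spec("A nonzero volume-AR rho is infeasible when ar_sd or volume_sd is 0.")
  }
  if (diff(Z_initial_range) < 0 || Z_initial_range[1] <= 0) {
    abort_spec("Z_initial_range must be positive and ordered.")
  }
  if (diff(t_end_range) < 0 || t_end_range[1] <= 0) {
    abort_spec("t_end_range must be positive and ordered.")
  }
  structure(
    list(groups = groups, n = as.integer(n),
         Z_initial_range = Z_initial_range, t_end_range = t_end_range,
         dt = dt, noise_sd = noise_sd, decay_shape = decay_shape,
         rise_exponent = rise_exponent, seed = seed),
    class = "rfa_cohort_spec"
  )
}

# one truncated draw of (ar, volume) with a Gaussian copula linking their
# normal scores; rank correlation rho_s maps to the Pearson correlation of
# the scores via 2*sin(pi*rho_s/6)
draw_ar_volume <- function(ar_mean, ar_sd, vol_mean, vol_sd, rho_s) {
  r <- 2 * sin(pi * rho_s / 6)
  for (try in 1:1000) {
    z1 <- stats::rnorm(1)
    z2 <- r * z1 + sqrt(1 - r^2) * stats::rnorm(1)
    ar <- ar_mean + ar_sd * z1
    vol <- vol_mean + vol_sd * z2
    if (ar >= 0 && vol > 0) return(c(ar = ar, volume = vol))
  }
  abort_spec("Could not draw a feasible (ar, volume) pair in 1000 attempts.")
}

draw_truncated <- function(mean, sd, lower, upper) {
  for (try in 1:1000) {
    x <- stats::rnorm(1, mean, sd)
    if (x >= lower && x <= upper) return(x)
  }
  abort_spec("Could not draw a feasible truncated value in 1000 attempts.")
}

#' Generate a synthetic multi-arm cohort
#'
#' Draws per-ablation index targets from arm-wise normal distributions
#' (DR truncated to `[0, 99]`, AR to non-negative values, delta to
#' `(-95, 95)`), initial impedances uniformly on `Z_initial_range`,
#' durations uniformly on `t_end_range`, and ablation volumes jointly with
#' AR through a Gaussian copula that attains the per-arm Spearman target in
#' expectation. Each ablation's impedance curve is then built with
#' [generate_curve()].
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `rfa_cohort` with elements `curves` (named list
#'   of [rfa_curve()]) and `table` (a cohort tibble with the arm factors,
#'   the drawn volume and the per-sample generator targets in columns
#'   prefixed `target_`).
#' @examples
#' co <- generate_cohort(cohort_spec(n = 2, seed = 1))
#' co$table
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "rfa_cohort_spec"))
  if (!is.null(spec$seed)) set.seed(as.integer(spec$seed))

  map <- group_factor_map()
  curves <- list()
  rows <- vector("list", nrow(spec$groups) * spec$n)
  k <- 0L
  for (g in seq_len(nrow(spec$groups))) {
    gr <- spec$groups[g, ]
    for (i in seq_len(spec$n)) {
      k <- k + 1L
      id <- sprintf("%s_%02d", gr$group, i)
      av <- draw_ar_volume(gr$ar_mean, gr$ar_sd, gr$volume_mean,
                           gr$volume_sd, gr$volume_ar_rho)
      dr <- draw_truncated(gr$dr_mean, gr$dr_sd, 0, 99)
      delta <- draw_truncated(gr$delta_mean, gr$delta_sd, -95, 95)
      Z0 <- stats::runif(1, spec$Z_initial_range[1], spec$Z_initial_range[2])
      t_end <- stats::runif(1, spec$t_end_range[1], spec$t_end_range[2])

      cs <- curve_spec(Z_initial = Z0, dr = dr, ar = av[["ar"]],
                       delta = delta, t_end = t_end, dt = spec$dt,
                       noise_sd = spec$noise_sd,
                       decay_shape = spec$decay_shape,
                       rise_exponent = spec$rise_exponent, seed = NULL)
      curves[[id]] <- generate_curve(cs, sample_id = id)
      fac <- map[map$group == gr$group, ]
      rows[[k]] <- tibble::tibble(
        sample_id = id, group = gr$group,
        solution = fac$solution, temperature = fac$temperature,
        volume = av[["volume"]],
        target_delta = delta, target_dr = dr, target_ar = av[["ar"]],
        Z_initial = Z0, t_end = t_end
      )
    }
  }
  structure(
    list(curves = curves, table = dplyr::bind_rows(rows)),
    class = "rfa_cohort"
  )
}

#' @export
print.rfa_cohort <- function(x, ...) {
  cat(sprintf("<rfa_cohort> %d curves across %d arm(s)\n",
              length(x$curves), length(unique(x$table$group))))
  print(table(x$table$group))
  invisible(x)
}
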