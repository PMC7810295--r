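# Extraction of the seven landmark parameters of an RFA impedance curve:
# t_end, t_half, t_minimum, Z_initial, Z_half, Z_minimum, Z_end.

#' Median-filter the impedance channel of a curve
#'
#' Running-median smoothing for noisy equipment logs. The window must be an
#' odd integer of at least 3; a window of 0 or 1 returns the curve
#' unchanged. Medians are order statistics, so isolated generator spikes are
#' removed without biasing monotone stretches of the curve.
#'
#' @param curve An [rfa_curve()].
#' @param window Odd window length in samples, or 0/1 for no smoothing.
#' @return An [rfa_curve()] with a smoothed impedance channel.
#' @export
smooth_impedance <- function(curve, window = 0) {
  stopifnot(inherits(curve, "rfa_curve"))
  if (window <= 1) return(curve)
  if (window %% 2 == 0 || window < 3) {
    abort_spec("Median window must be an odd integer >= 3 (or 0 for none).")
  }
  window <- min(window, length(curve$Z) - (1 - length(curve$Z) %% 2))
  out <- curve
  out$Z <- as.numeric(stats::runmed(curve$Z, window, endrule = "median"))
  # raw channels no longer match a filtered Z; drop them to keep the
  # Ohm's-law invariant honest
  out$V <- out$I <- NULL
  out
}

#' Initial impedance of a curve
#'
#' The impedance at procedure start. By default the literal first reading
#' (`k = 1`); averaging the first `k` samples is available for noisy logs.
#'
#' @param curve An [rfa_curve()].
#' @param k Number of leading samples to average, `1 <= k <= length(curve)`.
#' @return Initial impedance in ohms.
#' @export
estimate_initial_impedance <- function(curve, k = 1) {
  stopifnot(inherits(curve, "rfa_curve"))
  if (!is_number(k) || k < 1 || k > length(curve$Z)) {
    abort_spec(sprintf(
      "`k` must be between 1 and the curve length (%d).", length(curve$Z)
    ))
  }
  mean(curve$Z[seq_len(as.integer(k))])
}

#' Locate the roll-off event of an ablation
#'
#' Roll-off is the steep impedance rise that ends the procedure, caused by
#' desiccated tissue electrically isolating the electrode. Two definitions
#' are supported:
#'
#' * `log_end` (default): the experiment was stopped at the first roll-off,
#'   so the last logged sample *is* the event: `t_end` is the final
#'   timestamp and `Z_end` the final impedance.
#' * `threshold`: the event is the earliest time, found by linear
#'   interpolation, at which impedance first reaches
#'   `factor * Z_initial` after the curve minimum; `Z_end` is exactly
#'   `factor * Z_initial`. The conventional factor is 1.5. Crossings are
#'   searched only after the minimum so that initial readings above the
#'   threshold level (possible when `Z_initial` is an average of several
#'   samples) cannot trigger a spurious detection.
#'
#' The two definitions are deliberately both available: a fixed
#' 1.5x-threshold stop level is algebraically incompatible with ascent
#' ratios of several hundred percent observed when the generator itself
#' halts at roll-off, so the choice is stamped into every downstream record.
#'
#' @param curve An [rfa_curve()].
#' @param mode `"log_end"` or `"threshold"`.
#' @param factor Threshold multiple of `Z_initial` (must exceed 1).
#' @param Z_initial Initial impedance; defaults to the curve's first sample.
#' @return A list with `t_end` (seconds) and `Z_end` (ohms).
#' @export
detect_rolloff <- function(curve, mode = c("log_end", "threshold"),
                           factor = 1.5, Z_initial = NULL) {
  stopifnot(inherits(curve, "rfa_curve"))
  mode <- match.arg(mode)
  n <- length(curve$t)
  if (mode == "log_end") {
    return(list(t_end = curve$t[n], Z_end = curve$Z[n]))
  }
  if (!is_number(factor) || factor <= 1) {
    abort_spec("`factor` must be a single number greater than 1.")
  }
  Z_initial <- Z_initial %||% estimate_initial_impedance(curve, 1)
  level <- factor * Z_initial
  i_min <- which.min(curve$Z)
  after <- seq.int(i_min, n)
  hit <- after[curve$Z[after] >= level]
  if (!length(hit)) {
    rfa_abort(
      sprintf(
        "No roll-off: impedance never reached %.6g ohm after the minimum (max %.6g ohm).",
        level, max(curve$Z[after])
      ),
      "rfa_no_rolloff_error",
      max_Z = max(curve$Z[after]), level = level
    )
  }
  j <- hit[1]
  if (j == i_min || curve$Z[j] == level) {
    t_end <- curve$t[j]
  } else {
    # linear interpolation on the bracketing segment
    t_end <- curve$t[j - 1] +
      (curve$t[j] - curve$t[j - 1]) *
        (level - curve$Z[j - 1]) / (curve$Z[j] - curve$Z[j - 1])
  }
  list(t_end = t_end, Z_end = level)
}

#' Extract the seven landmark parameters of an impedance curve
#'
#' Computes, for one ablation curve, the landmarks that parameterize the
#' canonical drop-then-rise impedance trajectory:
#'
#' * `t_end`, `Z_end` — duration to first roll-off and the impedance there
#'   (see [detect_rolloff()] for the two roll-off definitions);
#' * `t_half = t_end / 2` and `Z_half`, the impedance at `t_half` obtained
#'   by linear interpolation (sampling grids need not contain the midpoint);
#' * `t_minimum`, `Z_minimum` — the global minimum of impedance restricted
#'   to `[0, t_end]`, taking the earliest sample on ties;
#' * `Z_initial` — see [estimate_initial_impedance()].
#'
#' @param curve An [rfa_curve()].
#' @param mode Roll-off definition, `"log_end"` (default) or `"threshold"`.
#' @param factor Threshold factor for `mode = "threshold"`.
#' @param init_k Number of leading samples averaged into `Z_initial`.
#' @param median_window Odd median-filter window applied before extraction
#'   (0 = none, the default; recommended 9 for noisy logs).
#' @return A one-row tibble of class `rfa_params` with columns `sample_id`,
#'   `t_end`, `t_half`, `t_minimum`, `Z_initial`, `Z_half`, `Z_minimum`,
#'   `Z_end`, `rolloff_mode`, `threshold_factor`, `dropped_rows`.
#' @examples
#' cv <- rfa_curve(t = c(0, 25, 50, 75, 100), Z = c(100, 85, 80, 90, 150))
#' extract_parameters(cv)
#' @export
extract_parameters <- function(curve, mode = c("log_end", "threshold"),
                               factor = 1.5, init_k = 1, median_window = 0) {
  stopifnot(inherits(curve, "rfa_curve"))
  mode <- match.arg(mode)
  work <- smooth_impedance(curve, median_window)

  Z_initial <- estimate_initial_impedance(work, init_k)
  roll <- detect_rolloff(work, mode, factor = factor, Z_initial = Z_initial)
  t_end <- roll$t_end
  t_half <- t_end / 2

  in_window <- which(work$t <= t_end + 1e-9)
  i_min <- in_window[which.min(work$Z[in_window])]
  t_minimum <- work$t[i_min]
  Z_minimum <- work$Z[i_min]
  Z_half <- value_at_time(work, t_half)

  stopifnot(
    t_minimum >= 0, t_minimum <= t_end + 1e-9,
    Z_minimum <= Z_initial + 1e-9,
    Z_minimum <= Z_half + 1e-9,
    Z_minimum <= roll$Z_end + 1e-9
  )

  out <- tibble::tibble(
    sample_id = curve$sample_id,
    t_end = t_end, t_half = t_half, t_minimum = t_minimum,
    Z_initial = Z_initial, Z_half = Z_half,
    Z_minimum = Z_minimum, Z_end = roll$Z_end,
    rolloff_mode = mode,
    threshold_factor = if (mode == "threshold") factor else NA_real_,
    dropped_rows = curve$dropped_rows
  )
  class(out) <- c("rfa_params", class(out))
  out
}

#' Extract parameters for a list of curves
#'
#' Convenience wrapper mapping [extract_parameters()] over several curves
#' and binding the one-row results into a table.
#'
#' @param curves A list of [rfa_curve()] objects.
#' @inheritParams extract_parameters
#' @return A tibble with one row per curve.
#' @export
extract_parameters_all <- function(curves, mode = c("log_end", "threshold"),
                                   factor = 1.5, init_k = 1,
                                   median_window = 0) {
  mode <- match.arg(mode)
  dplyr::bind_rows(lapply(curves, extract_parameters, mode = mode,
                          factor = factor, init_k = init_k,
                          median_window = median_window))
}
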