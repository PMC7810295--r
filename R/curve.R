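#' Impedance curve recorded during a radiofrequency ablation
#'
#' Container for one ablation's impedance time series. Time is stored as
#' seconds elapsed since the start of the log: if the first timestamp is
#' nonzero the whole series is shifted so that `t[1] == 0`, because every
#' landmark time extracted from the curve is a duration, not a wall-clock
#' instant. Impedance must be strictly positive; optional raw voltage,
#' current and power channels may travel with the curve.
#'
#' @param t Numeric vector of timestamps in seconds, strictly increasing.
#' @param Z Numeric vector of impedance in ohms, same length as `t`, all
#'   values positive.
#' @param sample_id Identifier for the ablation this curve belongs to.
#' @param V,I,P Optional raw channels: voltage in volts, current in
#'   milliamps, power in watts.
#' @param source_path Path of the log the curve was read from, if any.
#' @param dropped_rows Count of log rows discarded during cleaning.
#' @param check_consistency If `TRUE` (default) and both `V` and `I` are
#'   present, verify that `Z == V / (I * 1e-3)` to within `tol` relative
#'   error.
#' @param tol Relative tolerance for the Ohm's-law consistency check.
#'
#' @return An object of class `rfa_curve`: a list with elements `sample_id`,
#'   `t`, `Z`, optional `V`, `I`, `P`, `source_path` and `dropped_rows`.
#' @examples
#' cv <- rfa_curve(t = 0:4, Z = c(100, 90, 80, 95, 150))
#' cv
#' @export
rfa_curve <- function(t, Z, sample_id = "sample", V = NULL, I = NULL, P = NULL,
                      source_path = NA_character_, dropped_rows = 0L,
                      check_consistency = TRUE, tol = 1e-9) {
  t <- as.numeric(t)
  Z <- as.numeric(Z)
  if (length(t) != length(Z)) {
    abort_data("`t` and `Z` must have the same length.")
  }
  if (length(t) < 3L) {
    abort_data(sprintf(
      "An impedance curve needs at least 3 samples, got %d.", length(t)
    ))
  }
  if (anyNA(t) || anyNA(Z) || !all(is.finite(t)) || !all(is.finite(Z))) {
    abort_data("`t` and `Z` must be finite and free of missing values.")
  }
  if (any(diff(t) <= 0)) {
    abort_data("Timestamps must be strictly increasing.")
  }
  if (any(Z <= 0)) {
    abort_data("All impedance values must be positive.")
  }
  # landmark times are durations from procedure start
  t <- t - t[1]

  for (ch in list(V = V, I = I, P = P)) {
    if (!is.null(ch) && length(ch) != length(t)) {
      abort_data("Optional channels must match the length of `t`.")
    }
  }
  if (check_consistency && !is.null(V) && !is.null(I)) {
    derived <- V / (I * 1e-3)
    rel <- abs(derived - Z) / pmax(abs(Z), .Machine$double.eps)
    if (any(rel > tol)) {
      abort_validation(sprintf(
        "Impedance disagrees with V / I beyond tolerance (max relative error %.3g).",
        max(rel)
      ))
    }
  }

  structure(
    list(
      sample_id = as.character(sample_id),
      t = t, Z = Z,
      V = V, I = I, P = P,
      source_path = source_path,
      dropped_rows = as.integer(dropped_rows)
    ),
    class = "rfa_curve"
  )
}

#' @export
print.rfa_curve <- function(x, ...) {
  cat(sprintf(
    "<rfa_curve> %s: %d samples over %.1f s, Z in [%.1f, %.1f] ohm\n",
    x$sample_id, length(x$t), x$t[length(x$t)], min(x$Z), max(x$Z)
  ))
  if (x$dropped_rows > 0) {
    cat(sprintf("  (%d log rows dropped during cleaning)\n", x$dropped_rows))
  }
  invisible(x)
}

#' @export
as.data.frame.rfa_curve <- function(x, ...) {
  out <- data.frame(sample_id = x$sample_id, t = x$t, Z = x$Z)
  for (ch in c("V", "I", "P")) if (!is.null(x[[ch]])) out[[ch]] <- x[[ch]]
  out
}

#' Impedance at an arbitrary time by linear interpolation
#'
#' Evaluates the curve between samples. Query times must lie inside the
#' recorded range; hitting a sample time exactly returns that sample's value.
#'
#' @param curve An [rfa_curve()].
#' @param t_query Numeric vector of query times in seconds.
#' @return Numeric vector of interpolated impedances in ohms.
#' @examples
#' cv <- rfa_curve(t = c(0, 2, 4), Z = c(100, 70, 90))
#' value_at_time(cv, 3) # 80
#' @export
value_at_time <- function(curve, t_query) {
  stopifnot(inherits(curve, "rfa_curve"))
  t_query <- as.numeric(t_query)
  n <- length(curve$t)
  if (any(!is.finite(t_query)) ||
      any(t_query < curve$t[1]) || any(t_query > curve$t[n])) {
    abort_domain(sprintf(
      "Query time outside the recorded range [%.6g, %.6g] s.",
      curve$t[1], curve$t[n]
    ))
  }
  stats::approx(curve$t, curve$Z, xout = t_query,
                method = "linear", ties = "ordered")$y
}
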