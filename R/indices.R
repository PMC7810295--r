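# The three performance indices derived from the landmark parameters.
# All three are ratios, so they are invariant to rescaling of the time axis
# (delta) and of the impedance axis (DR, AR).

check_params <- function(params) {
  need <- c("t_end", "t_half", "t_minimum", "Z_initial", "Z_minimum", "Z_end")
  miss <- setdiff(need, names(params))
  if (length(miss)) {
    abort_data(sprintf("Parameter table lacks column(s): %s.",
                       paste(miss, collapse = ", ")))
  }
  params
}

#' Asymmetry index delta
#'
#' Percent displacement of the impedance minimum from the procedure
#' midpoint: `delta = (t_minimum / t_half - 1) * 100`. Zero means the
#' minimum sits exactly at mid-procedure; positive values mean the minimum
#' occurs after the midpoint (the common case), negative before it.
#'
#' @param params A parameter table from [extract_parameters()] (any number
#'   of rows).
#' @return Numeric vector of delta values in percent.
#' @export
delta_index <- function(params) {
  check_params(params)
  if (any(params$t_half <= 0)) {
    abort_degenerate("Degenerate curve: t_half must be positive.")
  }
  (params$t_minimum / params$t_half - 1) * 100
}

#' Drop Ratio (DR)
#'
#' Percent decrease of impedance from its initial value to the curve
#' minimum. The literal ratio `(Z_minimum / Z_initial - 1) * 100` is
#' negative for any real drop; following the reporting convention of the
#' field, the index is returned as the positive drop magnitude `dr`, with
#' the literal signed value kept alongside as `dr_signed = -dr`.
#'
#' @inheritParams delta_index
#' @return A tibble with columns `dr` and `dr_signed`, in percent.
#' @export
drop_ratio <- function(params) {
  check_params(params)
  if (any(params$Z_initial <= 0)) {
    abort_degenerate("Z_initial must be positive.")
  }
  dr_signed <- (params$Z_minimum / params$Z_initial - 1) * 100
  tibble::tibble(dr = -dr_signed, dr_signed = dr_signed)
}

#' Ascent Ratio (AR)
#'
#' Percent rise of impedance from the curve minimum to the roll-off value:
#' `(Z_end / Z_minimum - 1) * 100`. An AR of 100% means the roll-off
#' impedance doubled the minimum; values of several hundred percent are
#' typical when the generator halts at the roll-off event itself.
#'
#' @inheritParams delta_index
#' @return Numeric vector of AR values in percent.
#' @export
ascent_ratio <- function(params) {
  check_params(params)
  if (any(params$Z_minimum <= 0)) {
    abort_degenerate("Z_minimum must be positive.")
  }
  (params$Z_end / params$Z_minimum - 1) * 100
}

#' Compute all three performance indices
#'
#' Bundles [delta_index()], [drop_ratio()] and [ascent_ratio()] for a
#' parameter table, keeping the sample identifier and the roll-off
#' definition the parameters were extracted under.
#'
#' @inheritParams delta_index
#' @return A tibble with columns `sample_id`, `delta`, `dr`, `dr_signed`,
#'   `ar`, `rolloff_mode`.
#' @examples
#' cv <- rfa_curve(t = c(0, 25, 50, 75, 100), Z = c(100, 85, 80, 90, 150))
#' compute_indices(extract_parameters(cv))
#' @export
compute_indices <- function(params) {
  check_params(params)
  ratios <- drop_ratio(params)
  tibble::tibble(
    sample_id = params$sample_id,
    delta = delta_index(params),
    dr = ratios$dr,
    dr_signed = ratios$dr_signed,
    ar = ascent_ratio(params),
    rolloff_mode = params$rolloff_mode
  )
}
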