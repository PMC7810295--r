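# Shared fixture builders: small equipment logs and landmark tables are
# constructed in code at test time.

write_log <- function(df, delim = ",", path = tempfile(fileext = ".csv")) {
  readr::write_delim(df, path, delim = delim)
  path
}

# a log whose impedance is implied by V and I (current in mA)
ohm_log <- function(t, Z, I_mA = 1000, path = tempfile(fileext = ".csv")) {
  write_log(
    data.frame(t = t, V = Z * I_mA * 1e-3, I = I_mA, P = Z * (I_mA * 1e-3)^2),
    path = path
  )
}

# a hand-specified landmark table in the layout of extract_parameters()
make_params <- function(t_end, t_minimum, Z_initial, Z_minimum, Z_end,
                        sample_id = "hand", rolloff_mode = "log_end") {
  tibble::tibble(
    sample_id = sample_id,
    t_end = t_end, t_half = t_end / 2, t_minimum = t_minimum,
    Z_initial = Z_initial, Z_half = NA_real_,
    Z_minimum = Z_minimum, Z_end = Z_end,
    rolloff_mode = rolloff_mode, threshold_factor = NA_real_,
    dropped_rows = 0L
  )
}

# quadratic drop-then-rise curve with closed-form landmarks, used as the
# analytic oracle for extraction
quad_curve <- function(Z_min = 70, a = 0.004, t_min = 260, t_end = 600,
                       dt = 1) {
  t <- seq(0, t_end, by = dt)
  rfa_curve(t = t, Z = a * (t - t_min)^2 + Z_min, sample_id = "quad")
}
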