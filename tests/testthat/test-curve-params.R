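# Landmark extraction: interpolation, roll-off detection, the seven
# parameters, and their invariances.

test_that("value_at_time interpolates linearly and respects the range", {
  cv <- rfa_curve(t = c(0, 5, 10), Z = c(100, 90, 80))
  expect_equal(value_at_time(cv, 5), 90)    # sample hit
  expect_equal(value_at_time(cv, 0), 100)   # endpoint identity
  expect_equal(value_at_time(cv, 2.5), 95)  # midpoint of a line

  cv2 <- rfa_curve(t = c(0, 2, 4), Z = c(100, 70, 90))
  expect_equal(value_at_time(cv2, 3), 80)
  expect_error(value_at_time(cv2, 4.5), class = "rfa_domain_error")
  expect_error(value_at_time(cv2, -1), class = "rfa_domain_error")
})

test_that("initial impedance averages the first k samples", {
  cv <- rfa_curve(t = 0:2, Z = c(100, 102, 98))
  expect_equal(estimate_initial_impedance(cv), 100)       # default k = 1
  expect_equal(estimate_initial_impedance(cv, k = 3), 100)
  expect_error(estimate_initial_impedance(cv, k = 0), class = "rfa_spec_error")
  expect_error(estimate_initial_impedance(cv, k = 4), class = "rfa_spec_error")
})

test_that("roll-off detection: log end and interpolated threshold crossing", {
  cv <- rfa_curve(t = c(0, 10, 20), Z = c(100, 80, 200))

  le <- detect_rolloff(cv, "log_end")
  expect_equal(le$t_end, 20)
  expect_equal(le$Z_end, 200)

  th <- detect_rolloff(cv, "threshold", factor = 1.5)
  # crossing of the 150-ohm level on the [10, 20] segment
  expect_equal(th$t_end, 10 + 10 * (150 - 80) / (200 - 80), tolerance = 1e-12)
  expect_equal(th$Z_end, 150)
})

test_that("a curve that never reaches the threshold signals no-rolloff", {
  cv <- rfa_curve(t = 0:3, Z = c(100, 80, 90, 120))
  err <- tryCatch(detect_rolloff(cv, "threshold"),
                  rfa_no_rolloff_error = function(e) e)
  expect_s3_class(err, "rfa_no_rolloff_error")
  expect_equal(err$max_Z, 120)
  expect_equal(err$level, 150)
})

test_that("the seven landmarks are read off a simple curve", {
  cv <- rfa_curve(t = c(0, 25, 50, 75, 100), Z = c(100, 85, 80, 90, 150))
  p <- extract_parameters(cv)
  expect_equal(p$t_end, 100)
  expect_equal(p$t_half, 50)
  expect_equal(p$t_minimum, 50)
  expect_equal(p$Z_initial, 100)
  expect_equal(p$Z_half, 80)
  expect_equal(p$Z_minimum, 80)
  expect_equal(p$Z_end, 150)
  expect_equal(p$rolloff_mode, "log_end")
})

test_that("degenerate shapes: symmetric minimum and monotone rise", {
  # V-shaped symmetric curve: minimum exactly at mid-procedure
  v <- rfa_curve(t = 0:10, Z = c(10:5, 6:10) * 10)
  pv <- extract_parameters(v)
  expect_equal(pv$t_minimum, pv$t_half)

  # monotonically rising curve: minimum at the start
  r <- rfa_curve(t = 0:5, Z = c(100, 110, 120, 130, 140, 160))
  pr <- extract_parameters(r)
  expect_equal(pr$t_minimum, 0)
  expect_equal(pr$Z_minimum, pr$Z_initial)
})

test_that("ties in the minimum resolve to the earliest time", {
  set.seed(7)
  for (rep in 1:20) {
    Z <- c(100, 90, 70, 80, 95, 120, 160)
    cv <- rfa_curve(t = 0:6, Z = Z)
    t_min_ref <- extract_parameters(cv)$t_minimum
    # duplicate the minimum value at a later interior position
    Z2 <- Z
    Z2[sample(4:6, 1)] <- min(Z)
    cv2 <- rfa_curve(t = 0:6, Z = pmin(Z, Z2))
    expect_equal(extract_parameters(cv2)$t_minimum, t_min_ref)
  }
})

test_that("a constant time offset in the log changes no landmark", {
  cv <- generate_curve(curve_spec(Z_initial = 95, dr = 28, ar = 300,
                                  delta = 20, t_end = 400, dt = 2))
  shifted <- rfa_curve(t = cv$t + 1234.5, Z = cv$Z, sample_id = cv$sample_id)
  p1 <- extract_parameters(cv)
  p2 <- extract_parameters(shifted)
  expect_equal(p2[-1], p1[-1])
})

test_that("log_end and threshold agree when the log ends at the 1.5x level", {
  # last sample exactly 1.5 * Z_initial
  cv <- rfa_curve(t = 0:4, Z = c(100, 80, 90, 120, 150))
  le <- extract_parameters(cv, mode = "log_end")
  th <- extract_parameters(cv, mode = "threshold", factor = 1.5)
  expect_equal(th$t_end, le$t_end, tolerance = 1e-12)
  expect_equal(th$Z_end, le$Z_end, tolerance = 1e-12)
  expect_equal(th$t_minimum, le$t_minimum)
})

test_that("extraction matches the analytic landmarks of a closed-form curve", {
  # quadratic a*(t - t_min)^2 + Z_min sampled at 1 s: all landmarks known
  a <- 0.004; t_min <- 260; Z_min <- 70; t_end <- 600
  cv <- quad_curve(Z_min = Z_min, a = a, t_min = t_min, t_end = t_end, dt = 1)
  p <- extract_parameters(cv)
  expect_equal(p$t_end, t_end)
  expect_lte(abs(p$t_minimum - t_min), 1)            # within one sample
  expect_equal(p$Z_initial, a * t_min^2 + Z_min)
  expect_equal(p$Z_minimum, Z_min, tolerance = 5e-3)
  expect_equal(p$Z_end, a * (t_end - t_min)^2 + Z_min)
  expect_equal(p$Z_half, a * (t_end / 2 - t_min)^2 + Z_min, tolerance = 5e-3)

  # threshold mode against the analytic 1.5x crossing time
  Z0 <- a * t_min^2 + Z_min
  t_cross <- t_min + sqrt((1.5 * Z0 - Z_min) / a)
  th <- extract_parameters(cv, mode = "threshold")
  expect_lte(abs(th$t_end - t_cross), 1)
  expect_equal(th$Z_end, 1.5 * Z0)
})

test_that("median smoothing requires an odd window and leaves clean curves intact", {
  cv <- quad_curve(dt = 5)
  expect_error(smooth_impedance(cv, 4), class = "rfa_spec_error")
  sm <- smooth_impedance(cv, 5)
  # running median of a monotone-piecewise curve moves points by at most
  # the local inter-sample step
  expect_lt(max(abs(sm$Z - cv$Z)), max(abs(diff(cv$Z))) * 2 + 1e-12)
  expect_identical(smooth_impedance(cv, 0), cv)
})
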