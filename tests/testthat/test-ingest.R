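test_that("raw-count conversion follows the full-scale mapping", {
  expect_identical(convert_raw_to_angular_velocity(32768), 2000)
  expect_identical(convert_raw_to_angular_velocity(0), 0)
  expect_identical(convert_raw_to_angular_velocity(-16384), -1000)
  expect_equal(convert_raw_to_angular_velocity(c(32768, -32768)),
               c(2000, -2000))
  expect_error(convert_raw_to_angular_velocity(32769), "range")
  expect_error(convert_raw_to_angular_velocity(-40000), "range")
  expect_error(convert_raw_to_angular_velocity("a"), "numeric")
})

test_that("conversion is linear and odd over the whole register range", {
  y <- -32768:32767
  w <- convert_raw_to_angular_velocity(y)
  expect_true(all(abs(w) <= 2000))
  neg <- convert_raw_to_angular_velocity(-y[y != -32768])
  expect_identical(neg, -w[y != -32768])
  expect_equal(diff(w), rep(2000 / 2^15, length(y) - 1L))
})

test_that("moving average filter matches hand-computed prefix means", {
  expect_equal(moving_average_filter(c(4, 0, 0, 0, 0), 4),
               c(4, 2, 4 / 3, 1, 0))
  expect_equal(moving_average_filter(rep(2.5, 5), 4), rep(2.5, 5))
  x <- rnorm(30)
  expect_equal(moving_average_filter(x, 1), x)
  expect_identical(moving_average_filter(numeric(0)), numeric(0))
  expect_error(moving_average_filter(1:3, 0), "width")
})

test_that("filter output stays inside the trailing min/max envelope", {
  set.seed(7)
  for (w in c(2L, 4L, 7L)) {
    x <- rnorm(100)
    y <- moving_average_filter(x, w)
    for (i in seq_along(x)) {
      win <- x[max(1, i - w + 1):i]
      expect_gte(y[i], min(win) - 1e-12)
      expect_lte(y[i], max(win) + 1e-12)
    }
  }
})

test_that("flexion extraction keeps strictly negative samples as arcades", {
  fx <- extract_flexion_samples(c(-1, 2, -3))
  expect_equal(fx$indices, c(1L, 3L))
  expect_equal(fx$magnitudes, c(1, 3))
  expect_equal(extract_flexion_samples(c(1, 2, 0.5))$indices, integer(0))
  fx2 <- extract_flexion_samples(c(-1, -2, 0.5, -4))
  expect_equal(fx2$arcade, c(1L, 1L, 2L))
  expect_equal(fx2$magnitudes, c(1, 2, 4))
  # zero is not flexion
  expect_equal(extract_flexion_samples(c(0, -1))$indices, 2L)
})

test_that("windowing emits floor(n/size) windows and conserves samples", {
  ws <- window_stream(seq_len(650), 200)
  expect_equal(ws$n_windows, 3L)
  expect_equal(ws$residual, 50L)
  expect_equal(window_stream(seq_len(199), 200)$n_windows, 0L)
  expect_equal(window_stream(seq_len(600), 200)$n_windows, 3L)
  for (n in c(0L, 13L, 200L, 457L)) {
    w <- window_stream(rnorm(n), 97L)
    expect_equal(sum(lengths(w$windows)) + w$residual, n)
    if (w$n_windows > 0) {
      expect_equal(attr(w$windows[[1]], "start_index"), 1L)
    }
  }
  expect_error(window_stream(1:5, 0), "window_size")
})

test_that("device profiles carry the two acquisition generations", {
  v1 <- device_profile("v1")
  v2 <- device_profile("v2")
  expect_equal(v1$sampling_rate_hz, 42)
  expect_equal(v1$window_size, 300L)
  expect_equal(v2$sampling_rate_hz, 50)
  expect_equal(v2$window_size, 200L)
  expect_equal(v2$window_duration_s, 4)
})

test_that("session CSV round-trips at the written precision", {
  sim <- generate_session(simulation_config(
    data.frame(improvement = 40, n_windows = 2L), seed = 11
  ))
  path <- withr::local_tempfile(fileext = ".csv")
  write_session_csv(sim$signal, path)
  back <- read_session_csv(path)
  expect_equal(back$sampling_rate_hz, sim$signal$sampling_rate_hz)
  expect_identical(back$omega_y, round(sim$signal$omega_y, 6))
  expect_identical(back$omega_x, round(sim$signal$omega_x, 6))
})

test_that("raw-count session CSVs are converted on read", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(t = (0:9) / 50, gx = 0L, gy = c(-16384L, rep(0L, 9)),
                   gz = 328L)
  write.csv(df, path, row.names = FALSE)
  sig <- read_session_csv(path)
  expect_equal(sig$omega_y[1], -1000)
  expect_equal(sig$omega_z[1], 328 / 2^15 * 2000)
  expect_equal(sig$sampling_rate_hz, 50)
})

test_that("signal container validates shape and physical range", {
  expect_error(angular_velocity_signal(1:3, 1:2, 1:3, 50), "equal length")
  expect_error(angular_velocity_signal(0, 2001, 0, 50), "2000")
  expect_error(angular_velocity_signal(0, 0, 0, -1), "positive")
  s <- angular_velocity_signal(numeric(0), numeric(0), numeric(0), 50)
  expect_equal(length(s), 0L)
})

test_that("conditioning filters every axis and windows the session", {
  sim <- generate_session(simulation_config(
    data.frame(improvement = 50, n_windows = 3L), seed = 3
  ))
  cs <- condition_session(sim$signal)
  expect_equal(cs$n_windows, 3L)
  expect_equal(cs$residual, 0L)
  expect_equal(length(cs$windows[[2]]$wy), 200L)
  expect_equal(cs$windows[[2]]$start_index, 201L)
  expect_equal(cs$windows[[1]]$wy,
               moving_average_filter(sim$signal$omega_y, 4)[1:200])
})
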