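#' Convert raw gyroscope counts to angular velocity
#'
#' The gyroscope reports signed 16-bit counts over a +/- 2000 °/s full
#' scale.  A count `y` maps to `y / 2^15 * 2000` °/s, so the nominal
#' full-scale count 2^15 = 32768 maps to exactly 2000 °/s.  The mapping is
#' linear and odd; the sign convention (flexion negative on the y axis)
#' is preserved.
#'
#' @param raw numeric vector of raw counts; magnitudes must not exceed
#'   32768 (the nominal full-scale count).
#' @return Numeric vector of angular velocities in °/s.
#' @examples
#' convert_raw_to_angular_velocity(c(32768, 0, -16384))
#' @export
convert_raw_to_angular_velocity <- function(raw) {
  if (length(raw) == 0) return(numeric(0))
  if (!is.numeric(raw)) stop("`raw` must be numeric gyroscope counts")
  bad <- !is.na(raw) & abs(raw) > 32768
  if (any(bad)) {
    stop(sprintf(
      "raw count(s) outside the 16-bit register range [-32768, 32768]: %s",
      paste(utils::head(raw[bad], 3), collapse = ", ")
    ))
  }
  raw / 2^15 * 2000
}

#' Trailing moving-average low-pass filter
#'
#' Causal mean over the current sample and the `width - 1` preceding
#' samples, used for non-movement noise reduction before feature
#' extraction.  The leading edge uses a growing prefix (mean over the
#' samples available so far) so the output has the same length as the
#' input and window bookkeeping is unaffected.
#'
#' @param x numeric signal in °/s.
#' @param width filter width in samples (default 4).
#' @return Filtered signal, same length as `x`.
#' @examples
#' moving_average_filter(c(4, 0, 0, 0, 0))  # 4, 2, 4/3, 1, 0
#' @export
moving_average_filter <- function(x, width = 4L) {
  width <- as.integer(width)
  if (width < 1L) stop("`width` must be >= 1")
  n <- length(x)
  if (n == 0L) return(numeric(0))
  cs <- cumsum(x)
  i <- seq_len(n)
  lag <- i - width
  prev <- ifelse(lag > 0L, cs[pmax(lag, 1L)], 0)
  (cs - prev) / pmin(i, width)
}

#' Extract flexion samples (negative arcades)
#'
#' Passive wrist flexion drives the y-axis angular velocity negative (the
#' sensor's positive rotation points the other way), so only the strictly
#' negative excursions of the signal carry the movement of interest.  Each
#' maximal run of consecutive negative samples is one flexion arcade.
#'
#' @param x numeric angular-velocity sequence in °/s (signed).
#' @return A list with `magnitudes` (the retained samples as positive
#'   magnitudes), `indices` (their positions in `x`), and `arcade` (an
#'   integer arcade id per retained sample; ids increase with time).
#' @examples
#' extract_flexion_samples(c(-1, -2, 0.5, -4))  # arcades {1,2} and {4}
#' @export
extract_flexion_samples <- function(x) {
  idx <- which(x < 0)
  if (length(idx) == 0L) {
    return(list(magnitudes = numeric(0), indices = integer(0),
                arcade = integer(0)))
  }
  # a new arcade starts wherever retained indices are non-consecutive
  arcade <- cumsum(c(1L, diff(idx) > 1L))
  list(magnitudes = -x[idx], indices = idx, arcade = arcade)
}

# Full-length rectified flexion trace: magnitude where the y axis indicates
# flexion, 0 elsewhere.  `values` defaults to the masking signal itself but
# can be another axis or an axis-combined norm sampled on the same clock.
flexion_trace <- function(mask_signal, values = NULL) {
  if (is.null(values)) values <- mask_signal
  stopifnot(length(values) == length(mask_signal))
  out <- numeric(length(values))
  sel <- mask_signal < 0
  out[sel] <- abs(values[sel])
  out
}

#' Split a signal into contiguous fixed-length windows
#'
#' Emits `floor(n / window_size)` contiguous non-overlapping windows; the
#' trailing residual (fewer than `window_size` samples) is reported but not
#' classified.
#'
#' @param x numeric vector, or a matrix/data.frame with one column per axis
#'   (rows are samples).
#' @param window_size samples per window (> 0).
#' @return A list with `windows` (list of slices; each keeps its
#'   `start_index` attribute, 1-based), `n_windows`, and `residual` (number
#'   of unclassified trailing samples).
#' @examples
#' window_stream(seq_len(650), 200)$residual  # 50
#' @export
window_stream <- function(x, window_size) {
  window_size <- as.integer(window_size)
  if (window_size <= 0L) stop("`window_size` must be > 0")
  n <- if (is.null(dim(x))) length(x) else nrow(x)
  k <- n %/% window_size
  windows <- vector("list", k)
  for (w in seq_len(k)) {
    from <- (w - 1L) * window_size + 1L
    to <- w * window_size
    slice <- if (is.null(dim(x))) x[from:to] else x[from:to, , drop = FALSE]
    attr(slice, "start_index") <- from
    windows[[w]] <- slice
  }
  list(windows = windows, n_windows = k, residual = n - k * window_size)
}

#' Construct an angular-velocity signal
#'
#' Container for a multi-axis angular-velocity trace in °/s with its
#' sampling rate.  All three gyroscope axes must have equal length; values
#' must be finite and within the sensor's +/- 2000 °/s full scale.
#'
#' @param omega_x,omega_y,omega_z per-axis angular velocity in °/s.
#' @param sampling_rate_hz sampling rate in Hz (42 or 50 for the two
#'   hardware generations; other positive rates are accepted).
#' @param accel optional pass-through accelerometer data (kept as-is, not
#'   used by any feature).
#' @return An object of class `"angular_velocity_signal"`.
#' @export
angular_velocity_signal <- function(omega_x, omega_y, omega_z,
                                    sampling_rate_hz, accel = NULL) {
  n <- length(omega_y)
  if (length(omega_x) != n || length(omega_z) != n) {
    stop("axes must have equal length")
  }
  vals <- c(omega_x, omega_y, omega_z)
  if (n > 0 && (!all(is.finite(vals)) || max(abs(vals)) > 2000 + 1e-9)) {
    stop("angular velocities must be finite and within +/- 2000 deg/s")
  }
  if (!is.numeric(sampling_rate_hz) || sampling_rate_hz <= 0) {
    stop("`sampling_rate_hz` must be a positive number")
  }
  structure(
    list(omega_x = as.numeric(omega_x), omega_y = as.numeric(omega_y),
         omega_z = as.numeric(omega_z),
         sampling_rate_hz = sampling_rate_hz, accel = accel),
    class = "angular_velocity_signal"
  )
}

#' @export
print.angular_velocity_signal <- function(x, ...) {
  n <- length(x$omega_y)
  cat(sprintf(
    "<angular_velocity_signal> %d samples @ %g Hz (%.1f s), y range [%.2f, %.2f] deg/s\n",
    n, x$sampling_rate_hz, n / x$sampling_rate_hz,
    if (n) min(x$omega_y) else NA, if (n) max(x$omega_y) else NA
  ))
  invisible(x)
}

#' @export
length.angular_velocity_signal <- function(x) length(x$omega_y)

#' Read a session CSV
#'
#' Two dialects are auto-detected from the header: raw counts
#' (`t,gx,gy,gz[,ax,ay,az]`, converted through
#' [convert_raw_to_angular_velocity()]) and pre-converted angular velocity
#' (`t,wx,wy,wz` in °/s).  The sampling rate is taken from the median
#' timestamp spacing unless overridden.
#'
#' @param path CSV file path.
#' @param sampling_rate_hz optional override for the inferred rate.
#' @return An [angular_velocity_signal()].
#' @export
read_session_csv <- function(path, sampling_rate_hz = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  cols <- names(df)
  if (is.null(sampling_rate_hz)) {
    if (!"t" %in% cols || nrow(df) < 2) {
      stop("cannot infer sampling rate: need a `t` column with >= 2 samples")
    }
    dt <- stats::median(diff(df$t))
    if (!is.finite(dt) || dt <= 0) stop("non-increasing timestamps in `t`")
    sampling_rate_hz <- round(1 / dt, 3)
  }
  if (all(c("gx", "gy", "gz") %in% cols)) {
    accel <- if (all(c("ax", "ay", "az") %in% cols)) {
      df[, c("ax", "ay", "az")]
    } else NULL
    angular_velocity_signal(
      convert_raw_to_angular_velocity(df$gx),
      convert_raw_to_angular_velocity(df$gy),
      convert_raw_to_angular_velocity(df$gz),
      sampling_rate_hz, accel = accel
    )
  } else if (all(c("wx", "wy", "wz") %in% cols)) {
    angular_velocity_signal(df$wx, df$wy, df$wz, sampling_rate_hz)
  } else {
    stop("unrecognised session header: expected t,gx,gy,gz[,ax,ay,az] or t,wx,wy,wz")
  }
}

#' Write a session CSV (pre-converted dialect)
#'
#' Writes `t,wx,wy,wz` with angular velocities rounded to `digits` decimal
#' places; re-reading reproduces the rounded values exactly.
#'
#' @param signal an [angular_velocity_signal()].
#' @param path output CSV path.
#' @param digits decimal places kept (default 6).
#' @return `path`, invisibly.
#' @export
write_session_csv <- function(signal, path, digits = 6L) {
  stopifnot(inherits(signal, "angular_velocity_signal"))
  n <- length(signal$omega_y)
  df <- data.frame(
    t = round((seq_len(n) - 1L) / signal$sampling_rate_hz, 6),
    wx = round(signal$omega_x, digits),
    wy = round(signal$omega_y, digits),
    wz = round(signal$omega_z, digits)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Condition a session and split it into feature windows
#'
#' Applies the processing chain in its fixed order: each gyroscope axis is
#' low-pass filtered with the trailing moving average, then the session is
#' cut into contiguous windows of the profile's size.  Flexion masking and
#' rectification happen per window during feature extraction.
#'
#' @param signal an [angular_velocity_signal()].
#' @param profile a [device_profile()]; the default picks `"v1"` or `"v2"`
#'   by matching the signal's sampling rate, falling back to `"v2"`.
#' @param window_size optional override of the profile's window size.
#' @return A list with `windows` (each a list of filtered per-axis slices
#'   `wx`, `wy`, `wz` with a `start_index`), `n_windows`, `residual`, and
#'   the `profile` used.
#' @export
condition_session <- function(signal, profile = NULL, window_size = NULL) {
  stopifnot(inherits(signal, "angular_velocity_signal"))
  if (is.null(profile)) {
    profile <- if (isTRUE(all.equal(signal$sampling_rate_hz, 42))) {
      device_profile("v1")
    } else {
      device_profile("v2")
    }
  }
  if (is.null(window_size)) window_size <- profile$window_size
  fx <- moving_average_filter(signal$omega_x, profile$filter_width)
  fy <- moving_average_filter(signal$omega_y, profile$filter_width)
  fz <- moving_average_filter(signal$omega_z, profile$filter_width)
  ws <- window_stream(cbind(wx = fx, wy = fy, wz = fz), window_size)
  windows <- lapply(ws$windows, function(m) {
    list(wx = m[, "wx"], wy = m[, "wy"], wz = m[, "wz"],
         start_index = attr(m, "start_index"))
  })
  list(windows = windows, n_windows = ws$n_windows,
       residual = ws$residual, profile = profile)
}
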