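#' Detect peaks between valleys with a prominence margin
#'
#' A sample is a peak when it is the highest value between two valleys and
#' rises at least `margin` above both of them.  Operationally: scanning
#' outward from a candidate until a higher sample (or the signal boundary)
#' is reached, the minimum encountered on each side must lie at least
#' `margin` below the candidate.  Ripples shallower than the margin never
#' create additional peaks; of two equal-height maxima separated by a
#' shallow saddle, the later one is kept.
#'
#' @param x numeric sequence of rectified flexion magnitudes (>= 0).
#' @param margin minimum peak-above-valley prominence in °/s (default 0.2,
#'   the device calibration).
#' @return A list of class `"peak_set"`: `peak_values`, `peak_indices`
#'   (1-based), `valley_indices` (one valley before each peak and one after
#'   the last, located at the minimum between consecutive peaks / towards
#'   the boundary).
#' @examples
#' detect_peaks(c(0, 1, 3, 1, 0))$peak_values  # 3
#' @export
detect_peaks <- function(x, margin = 0.2) {
  n <- length(x)
  empty <- function() {
    structure(list(peak_values = numeric(0), peak_indices = integer(0),
                   valley_indices = integer(0)), class = "peak_set")
  }
  if (n < 3L) return(empty())
  peaks <- integer(0)
  for (i in 2:(n - 1L)) {
    xi <- x[i]
    # right side: stop at the first sample >= xi (ties truncate), else boundary
    ok_right <- FALSE
    rmin <- Inf
    j <- i + 1L
    while (j <= n) {
      if (x[j] >= xi) break
      if (x[j] < rmin) rmin <- x[j]
      j <- j + 1L
    }
    if (rmin <= xi - margin) ok_right <- TRUE
    if (!ok_right) next
    # left side: stop at the first sample > xi (equal heights look through)
    ok_left <- FALSE
    lmin <- Inf
    j <- i - 1L
    while (j >= 1L) {
      if (x[j] > xi) break
      if (x[j] < lmin) lmin <- x[j]
      j <- j - 1L
    }
    if (lmin <= xi - margin) ok_left <- TRUE
    if (ok_left) peaks <- c(peaks, i)
  }
  if (length(peaks) == 0L) return(empty())
  valleys <- integer(length(peaks) + 1L)
  pre <- x[seq_len(peaks[1] - 1L)]
  valleys[1] <- which.min(pre)
  if (length(peaks) > 1L) {
    for (k in seq_len(length(peaks) - 1L)) {
      seg <- (peaks[k] + 1L):(peaks[k + 1L] - 1L)
      valleys[k + 1L] <- seg[which.min(x[seg])]
    }
  }
  post <- (peaks[length(peaks)] + 1L):n
  valleys[length(valleys)] <- post[which.min(x[post])]
  structure(
    list(peak_values = x[peaks], peak_indices = peaks,
         valley_indices = valleys),
    class = "peak_set"
  )
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("<peak_set> %d peak(s)", length(x$peak_indices)))
  if (length(x$peak_indices)) {
    cat(": ", paste(sprintf("%.3g@%d", x$peak_values, x$peak_indices),
                    collapse = ", "), sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Mean flexion angular velocity of a window
#'
#' Arithmetic mean of the rectified flexion magnitudes; zero-padding (the
#' non-flexion samples of a full-length rectified trace) is ignored.  An
#' empty window yields 0 so that every window still produces a descriptor.
#'
#' @param magnitudes rectified flexion magnitudes in °/s (zeros are treated
#'   as padding, not flexion).
#' @return Mean magnitude in °/s, 0 if no flexion samples.
#' @export
mean_angular_velocity <- function(magnitudes) {
  m <- magnitudes[magnitudes > 0]
  if (length(m) == 0L) return(0)
  mean(m)
}

#' Mean peak value of a window
#'
#' @param peaks a `"peak_set"` from [detect_peaks()].
#' @return Mean of the peak magnitudes in °/s, 0 when no peaks.
#' @export
mean_peak <- function(peaks) {
  if (length(peaks$peak_values) == 0L) return(0)
  mean(peaks$peak_values)
}

#' Count cogwheel-rigidity artefacts
#'
#' Cogwheel rigidity interrupts the passive flexion with ratchet-like
#' catches, visible as interior oscillations of a flexion arcade.  Within
#' each arcade the detector counts one artefact per significant interior
#' dip: with the arcade delimited by zero magnitude at both ends, every
#' margin-significant hump beyond the first corresponds to one
#' (local-minimum, local-maximum) rebound of depth at least
#' `dip_threshold`.
#'
#' @param magnitudes full-length rectified flexion trace (zeros outside
#'   arcades), or compact flexion magnitudes when `arcade` gives the
#'   arcade id of each sample.
#' @param arcade optional integer arcade ids (as from
#'   [extract_flexion_samples()]); derived from zero-runs when omitted.
#' @param dip_threshold minimum rebound depth in °/s (default 0.2, matching
#'   the peak-detection margin).
#' @return Non-negative integer artefact count for the window.
#' @export
count_cogwheel_artefacts <- function(magnitudes, arcade = NULL,
                                     dip_threshold = 0.2) {
  if (length(magnitudes) == 0L) return(0L)
  if (is.null(arcade)) {
    pos <- magnitudes > 0
    if (!any(pos)) return(0L)
    idx <- which(pos)
    arcade_ids <- cumsum(c(1L, diff(idx) > 1L))
    segs <- split(magnitudes[idx], arcade_ids)
  } else {
    stopifnot(length(arcade) == length(magnitudes))
    segs <- split(magnitudes, arcade)
  }
  total <- 0L
  for (seg in segs) {
    ps <- detect_peaks(c(0, seg, 0), margin = dip_threshold)
    k <- length(ps$peak_indices)
    if (k > 1L) total <- total + (k - 1L)
  }
  total
}

#' Combine gyroscope axes into a per-sample magnitude
#'
#' Euclidean norm sqrt(sum of squared axis values) per sample over the
#' selected axes, keeping °/s units.  A single axis reduces to its absolute
#' value.  When this combined magnitude feeds flexion features, the flexion
#' timing (which samples belong to arcades) is still taken from the sign of
#' the y axis.
#'
#' @param signal an [angular_velocity_signal()] or a list with elements
#'   `omega_x`/`omega_y`/`omega_z` (aliases `wx`/`wy`/`wz` accepted).
#' @param axes character subset of `c("x", "y", "z")`.
#' @return Numeric per-sample magnitude sequence in °/s.
#' @examples
#' combine_axes(list(wx = 3, wy = 4, wz = 0), c("x", "y"))  # 5
#' @export
combine_axes <- function(signal, axes) {
  if (length(axes) == 0L) stop("`axes` must name at least one axis")
  bad <- setdiff(axes, c("x", "y", "z"))
  if (length(bad)) {
    stop(sprintf("unknown axis name(s): %s", paste(bad, collapse = ", ")))
  }
  get_axis <- function(a) {
    v <- signal[[paste0("omega_", a)]]
    if (is.null(v)) v <- signal[[paste0("w", a)]]
    if (is.null(v)) stop(sprintf("signal carries no %s-axis data", a))
    v
  }
  sq <- 0
  for (a in unique(axes)) sq <- sq + get_axis(a)^2
  sqrt(sq)
}

# axis labels understood by window_features / descriptor plumbing
.axis_labels <- c("x", "y", "z", "n2", "n3")

#' Per-window feature extraction
#'
#' For each requested axis (or axis combination `"n2"` = x,y norm and
#' `"n3"` = x,y,z norm) computes the window's mean flexion angular velocity
#' `mu_omega`, mean peak value `mu_peak`, and cogwheel-artefact count
#' `delta`.  Flexion samples are the strictly negative samples of the
#' (filtered) y axis; cross-axis and combined magnitudes are sampled on
#' that same flexion mask.
#'
#' @param window a list with per-axis filtered slices `wx`, `wy`, `wz`
#'   (as produced by [condition_session()]).
#' @param axes character vector drawn from `c("x","y","z","n2","n3")`.
#' @param margin peak-detection prominence margin in °/s.
#' @param dip_threshold cogwheel rebound threshold in °/s (defaults to
#'   `margin`).
#' @return data.frame with columns `axis`, `mu_omega`, `mu_peak`, `delta`,
#'   `n_flexion`.
#' @export
window_features <- function(window, axes = "y", margin = 0.2,
                            dip_threshold = margin) {
  bad <- setdiff(axes, .axis_labels)
  if (length(bad)) {
    stop(sprintf("unknown axis label(s): %s", paste(bad, collapse = ", ")))
  }
  wy <- window$wy
  mask <- wy < 0
  rows <- lapply(axes, function(a) {
    values <- switch(a,
      x = window$wx, y = wy, z = window$wz,
      n2 = combine_axes(window, c("x", "y")),
      n3 = combine_axes(window, c("x", "y", "z"))
    )
    trace <- flexion_trace(wy, values)
    mu_omega <- if (any(mask)) mean(abs(values)[mask]) else 0
    mu_peak <- mean_peak(detect_peaks(trace, margin = margin))
    delta <- count_cogwheel_artefacts(trace, dip_threshold = dip_threshold)
    data.frame(axis = a, mu_omega = mu_omega, mu_peak = mu_peak,
               delta = delta, n_flexion = sum(mask),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Feature table for a whole session
#'
#' Conditions the session (filter, window) and extracts
#' [window_features()] for every complete window.
#'
#' @inheritParams condition_session
#' @inheritParams window_features
#' @return data.frame `window_index, axis, mu_omega, mu_peak, delta,
#'   n_flexion` (window_index is 1-based).
#' @export
session_features <- function(signal, axes = "y", profile = NULL,
                             window_size = NULL, margin = NULL,
                             dip_threshold = NULL) {
  cs <- condition_session(signal, profile = profile,
                          window_size = window_size)
  if (is.null(margin)) margin <- cs$profile$peak_margin
  if (is.null(dip_threshold)) dip_threshold <- margin
  if (cs$n_windows == 0L) {
    return(data.frame(window_index = integer(0), axis = character(0),
                      mu_omega = numeric(0), mu_peak = numeric(0),
                      delta = integer(0), n_flexion = integer(0)))
  }
  out <- lapply(seq_len(cs$n_windows), function(w) {
    f <- window_features(cs$windows[[w]], axes = axes, margin = margin,
                         dip_threshold = dip_threshold)
    cbind(window_index = w, f)
  })
  do.call(rbind, out)
}
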