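#' Configuration for the synthetic surgical-session simulator
#'
#' The simulator emulates an intraoperative rigidity assessment: an
#' examiner imposes passive wrist flexions at a roughly constant rate, and
#' as stimulation improves the rigidity the flexion arcades become higher
#' and smoother while cogwheel catches become rarer.  Flexion arcades are
#' negative half-sine pulses on the y gyroscope axis whose amplitude grows
#' linearly with the improvement percentage `r`:
#' `A(r) = base_peak_amplitude * (1 + amplitude_gain * r / 80)`.  With the
#' defaults (13 °/s base, gain 1.3) the peak amplitude runs from about
#' 13 °/s at baseline to about 30 °/s at 80 % improvement, matching the
#' published rigid / non-rigid mean peak values.  Cogwheel artefacts are
#' injected as interior notches at a Poisson rate that decreases linearly
#' with improvement through the published per-label artefact means
#' (2.6 per window at 40 %, 1.2 at 80 %).
#'
#' @param improvement_schedule data.frame `improvement` (label %, in
#'   `0..80`) and `n_windows` per label.
#' @param base_peak_amplitude flexion peak amplitude at 0 % improvement
#'   (°/s).
#' @param amplitude_gain fractional peak increase at 80 % improvement.
#' @param arcade_rate imposed flexions per second (Hz).
#' @param cogwheel_anchors named vector `c(at40 = , at80 = )`: expected
#'   artefacts per window at 40 % and 80 % improvement; the rate is linear
#'   in `r` through these anchors, truncated at 0.
#' @param noise_sd additive Gaussian sensor noise (°/s); the default
#'   0.05 °/s is typical of MEMS rate-gyroscope output after low-pass
#'   filtering, and sits safely below the 0.2 °/s peak margin.
#' @param amplitude_jitter_sd per-arcade relative amplitude jitter
#'   (the examiner's force is nearly constant; default 3 %).
#' @param cross_axis_gain fraction of the y trace leaking into x.
#' @param notch_depth_range relative depth range of a cogwheel notch.
#' @param notch_width_s notch width in seconds.
#' @param profile acquisition [device_profile()].
#' @param seed RNG seed fixing the full sample path.
#' @return A list of class `"simulation_config"`.
#' @export
simulation_config <- function(improvement_schedule = data.frame(
                                improvement = c(0, 40, 50, 60, 70, 80),
                                n_windows = 5L),
                              base_peak_amplitude = 13,
                              amplitude_gain = 1.3,
                              arcade_rate = 0.75,
                              cogwheel_anchors = c(at40 = 2.6, at80 = 1.2),
                              noise_sd = 0.05,
                              amplitude_jitter_sd = 0.03,
                              cross_axis_gain = 0.2,
                              notch_depth_range = c(0.3, 0.5),
                              notch_width_s = 0.06,
                              profile = device_profile("v2"),
                              seed = NULL) {
  stopifnot(base_peak_amplitude > 0, amplitude_gain >= 0, arcade_rate > 0,
            noise_sd >= 0, all(cogwheel_anchors >= 0))
  sched <- as.data.frame(improvement_schedule)
  if (!all(c("improvement", "n_windows") %in% names(sched))) {
    stop("`improvement_schedule` needs columns improvement, n_windows")
  }
  if (any(sched$improvement < 0 | sched$improvement > 80)) {
    stop("improvements must lie in [0, 80]")
  }
  structure(
    list(improvement_schedule = sched,
         base_peak_amplitude = base_peak_amplitude,
         amplitude_gain = amplitude_gain,
         arcade_rate = arcade_rate,
         cogwheel_anchors = cogwheel_anchors,
         noise_sd = noise_sd,
         amplitude_jitter_sd = amplitude_jitter_sd,
         cross_axis_gain = cross_axis_gain,
         notch_depth_range = notch_depth_range,
         notch_width_s = notch_width_s,
         profile = profile,
         seed = seed),
    class = "simulation_config"
  )
}

#' Expected cogwheel artefacts per window at a given improvement
#'
#' Linear in the improvement percentage through the configured anchors
#' (defaults: 2.6 per window at 40 %, 1.2 at 80 %), truncated at zero.
#'
#' @param improvement improvement percentage(s) in `[0, 80]`.
#' @param anchors named vector `c(at40 = , at80 = )`.
#' @return Expected artefact count(s) per window.
#' @export
cogwheel_mean_rate <- function(improvement,
                               anchors = c(at40 = 2.6, at80 = 1.2)) {
  slope <- (anchors[["at80"]] - anchors[["at40"]]) / 40
  pmax(0, anchors[["at40"]] + slope * (improvement - 40))
}

#' Simulate a labelled surgical session
#'
#' Generates a multi-axis angular-velocity trace whose windows follow the
#' configured improvement schedule, together with the per-window medical
#' labels and the ground-truth injected artefact counts.  Deterministic
#' under `config$seed`.
#'
#' @param config a [simulation_config()].
#' @return List with `signal` (an [angular_velocity_signal()]), `labels`
#'   (data.frame `window_index, label, valid`), and `truth`
#'   (data.frame `window_index, label, n_artefacts, peak_amplitude`).
#' @export
generate_session <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    prof <- config$profile
    fs <- prof$sampling_rate_hz
    ws <- prof$window_size
    period <- round(fs / config$arcade_rate)
    flex_len <- max(4L, round(0.45 * period))
    ext_len <- max(4L, round(0.35 * period))
    notch_w <- max(3L, round(config$notch_width_s * fs))
    sched <- config$improvement_schedule
    y_all <- list(); truth <- list()
    widx <- 0L
    for (s in seq_len(nrow(sched))) {
      r <- sched$improvement[s]
      A_r <- config$base_peak_amplitude *
        (1 + config$amplitude_gain * r / 80)
      lambda <- cogwheel_mean_rate(r, config$cogwheel_anchors)
      for (w in seq_len(sched$n_windows[s])) {
        widx <- widx + 1L
        y <- numeric(ws)
        start0 <- sample.int(10L, 1L)
        starts <- seq(start0, ws, by = period)
        starts <- starts[starts + flex_len - 1L <= ws]
        amp <- numeric(length(starts))
        for (k in seq_along(starts)) {
          a <- A_r * max(0.2, 1 + stats::rnorm(1, 0, config$amplitude_jitter_sd))
          amp[k] <- a
          i <- starts[k]:(starts[k] + flex_len - 1L)
          y[i] <- y[i] - a * sin(pi * seq(0, 1, length.out = flex_len))
          # extension (return) movement: smaller positive arcade
          e0 <- starts[k] + flex_len
          e1 <- min(ws, e0 + ext_len - 1L)
          if (e0 <= ws) {
            j <- e0:e1
            y[j] <- y[j] + 0.4 * a *
              sin(pi * seq(0, 1, length.out = ext_len))[seq_along(j)]
          }
        }
        n_art <- if (length(starts)) stats::rpois(1, lambda) else 0L
        for (k in seq_len(n_art)) {
          arc <- sample.int(length(starts), 1L)
          u <- stats::runif(1, 0.25, 0.75)
          centre <- starts[arc] + round(u * (flex_len - 1L))
          d <- stats::runif(1, config$notch_depth_range[1],
                            config$notch_depth_range[2])
          half <- (notch_w - 1L) %/% 2L
          i <- max(1L, centre - half):min(ws, centre + half)
          wgt <- sin(pi * seq(0, 1, length.out = length(i)))
          if (length(i) == 1L) wgt <- 1
          y[i] <- y[i] * (1 - d * wgt)
        }
        y <- y + stats::rnorm(ws, 0, config$noise_sd)
        y_all[[widx]] <- y
        truth[[widx]] <- data.frame(window_index = widx, label = r,
                                    n_artefacts = n_art,
                                    peak_amplitude = if (length(amp)) max(amp) else 0)
      }
    }
    y <- pmin(pmax(unlist(y_all), -2000), 2000)
    n <- length(y)
    x <- config$cross_axis_gain * y + stats::rnorm(n, 0, config$noise_sd)
    z <- stats::rnorm(n, 0, config$noise_sd)
    truth <- do.call(rbind, truth)
    list(
      signal = angular_velocity_signal(x, y, z, fs),
      labels = data.frame(window_index = truth$window_index,
                          label = truth$label, valid = TRUE),
      truth = truth
    )
  })
}

#' Generate labelled descriptor windows around a known quadratic
#'
#' Inverse of the calibration procedure, used for parameter-recovery
#' checks: given true quadratic coefficients mapping descriptor to
#' improvement, draws per-class descriptor values as Gaussian noise around
#' the point whose true improvement equals each label, so that in
#' expectation the class means sit exactly on the truth curve.
#'
#' @param truth numeric `c(a, b, c)` of `improvement = a*phi^2 + b*phi + c`.
#' @param classes label grid (see [class_set()]).
#' @param n_per_class windows per class.
#' @param noise_sd Gaussian descriptor noise (same units as phi).
#' @param seed RNG seed.
#' @return data.frame `descriptor_value, label, valid`.
#' @export
generate_labelled_windows <- function(truth, classes = class_set("restricted"),
                                      n_per_class = 25L, noise_sd = 0,
                                      seed = NULL) {
  stopifnot(length(truth) == 3L)
  phi_star <- invert_quadratic(truth, classes)
  with_seed(seed, {
    out <- lapply(seq_along(classes), function(i) {
      data.frame(
        descriptor_value = stats::rnorm(n_per_class, phi_star[i], noise_sd),
        label = classes[i], valid = TRUE
      )
    })
    do.call(rbind, out)
  })
}

# Solve a*phi^2 + b*phi + c = L for each label on a single monotone branch.
invert_quadratic <- function(truth, labels) {
  a <- truth[1]; b <- truth[2]; cc <- truth[3]
  if (abs(a) < 1e-12) {
    if (abs(b) < 1e-12) stop("degenerate truth model: a = b = 0")
    return((labels - cc) / b)
  }
  disc <- b^2 - 4 * a * (cc - labels)
  if (any(disc < 0)) {
    stop("truth quadratic never attains some requested labels")
  }
  plus <- (-b + sqrt(disc)) / (2 * a)
  minus <- (-b - sqrt(disc)) / (2 * a)
  monotone <- function(v) all(diff(v[order(labels)]) > 0) ||
    all(diff(v[order(labels)]) < 0)
  if (monotone(plus)) {
    plus
  } else if (monotone(minus)) {
    minus
  } else {
    warning("truth quadratic is not monotone over the label range; ",
            "classification regime is ambiguous")
    plus
  }
}
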