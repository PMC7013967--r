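#' Device acquisition profiles
#'
#' The inertial unit exists in two hardware generations that differ in
#' sampling rate and in the number of samples over which rigidity features
#' are extracted: the original unit streamed at 42 Hz with 300-sample
#' feature windows, while the revised unit streams at 50 Hz with 200-sample
#' windows (a 200-sample window then spans exactly 4 s of passive flexion).
#'
#' @param name `"v1"` (42 Hz, 300-sample windows) or `"v2"` (50 Hz,
#'   200-sample windows, the current default).
#' @param filter_width trailing moving-average width in samples used for
#'   non-movement noise reduction.
#' @param peak_margin minimum height (°/s) a peak must rise above both
#'   flanking valleys to be counted.
#'
#' @return A list of class `"device_profile"` with elements `name`,
#'   `sampling_rate_hz`, `window_size`, `filter_width`, `peak_margin` and
#'   `window_duration_s`.
#' @examples
#' device_profile("v2")$window_duration_s  # 4 seconds
#' @export
device_profile <- function(name = c("v2", "v1"), filter_width = 4L,
                           peak_margin = 0.2) {
  name <- match.arg(name)
  rate <- switch(name, v1 = 42, v2 = 50)
  size <- switch(name, v1 = 300L, v2 = 200L)
  structure(
    list(
      name = name,
      sampling_rate_hz = rate,
      window_size = size,
      filter_width = as.integer(filter_width),
      peak_margin = peak_margin,
      window_duration_s = size / rate
    ),
    class = "device_profile"
  )
}

#' @export
print.device_profile <- function(x, ...) {
  cat(sprintf(
    "<device_profile %s> %g Hz, %d-sample windows (%.2f s), filter width %d, peak margin %g deg/s\n",
    x$name, x$sampling_rate_hz, x$window_size, x$window_duration_s,
    x$filter_width, x$peak_margin
  ))
  invisible(x)
}

#' Published study-cohort manifest
#'
#' Bookkeeping table for the three surgical datasets on which the rigidity
#' calibration models were developed: number of patients and number of
#' evaluated flexion signals in the training and test splits of each
#' dataset.  The second dataset's training split is further divided into a
#' low baseline-rigidity cluster (UPDRS 1-2, 98 signals) and a high
#' baseline-rigidity cluster (UPDRS 3, 139 signals) for the multi-model.
#'
#' @return A data.frame with columns `dataset`, `train_patients`,
#'   `train_signals`, `test_patients`, `test_signals`.
#' @examples
#' sum(cohort_manifest()$train_signals)  # 403
#' @export
cohort_manifest <- function() {
  data.frame(
    dataset = c("I", "II", "III"),
    train_patients = c(6L, 17L, 22L),
    train_signals = c(48L, 237L, 118L),
    test_patients = c(4L, 2L, 8L),
    test_signals = c(156L, 38L, 150L),
    stringsAsFactors = FALSE
  )
}

#' Baseline-rigidity cluster sizes of the multi-model training cohort
#'
#' @return Named integer vector: `low` (UPDRS 1-2) and `high` (UPDRS 3)
#'   training-signal counts.
#' @export
baseline_cluster_sizes <- function() {
  c(low = 98L, high = 139L)
}

# Run code with a temporarily-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  code
}
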