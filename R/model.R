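#' Per-class mean descriptor values
#'
#' The calibration curve is fitted not to raw windows but to the mean
#' descriptor value of each medical-label class (the blinded experts'
#' agreed improvement percentage).  Invalid windows are excluded.
#'
#' @param values descriptor values, one per window.
#' @param labels medical labels (improvement %, discrete decile scale).
#' @param valid logical validity flags (default all valid).
#' @return data.frame `label, mean_value, n`, ordered by label.
#' @examples
#' class_means(c(2, 4, 6, 8), c(0, 0, 40, 40))
#' @export
class_means <- function(values, labels, valid = NULL) {
  if (length(values) != length(labels)) {
    stop("`values` and `labels` must have equal length")
  }
  if (is.null(valid)) valid <- rep(TRUE, length(values))
  keep <- valid & is.finite(values) & !is.na(labels)
  values <- values[keep]
  labels <- labels[keep]
  if (length(values) == 0L) stop("no valid labelled windows")
  agg <- stats::aggregate(values, by = list(label = labels),
                          FUN = function(v) c(mean(v), length(v)))
  out <- data.frame(label = agg$label, mean_value = agg$x[, 1],
                    n = as.integer(agg$x[, 2]))
  out[order(out$label), , drop = FALSE]
}

# default class grids: the original full decile set and the later
# restricted set (intermediate low improvements were hard to discriminate)
#' Medical-label class sets
#'
#' @param which `"full"` for the original decile grid 0,10,...,80 or
#'   `"restricted"` for the later grid 0,40,50,60,70,80.
#' @return Numeric vector of improvement percentages.
#' @export
class_set <- function(which = c("restricted", "full")) {
  which <- match.arg(which)
  switch(which, full = seq(0, 80, by = 10),
         restricted = c(0, 40, 50, 60, 70, 80))
}

#' Fit a second-order rigidity-improvement model
#'
#' Least-squares quadratic `improvement = a*phi^2 + b*phi + c` through the
#' per-class mean descriptor points.  Higher polynomial degrees are
#' deliberately not supported (they overfit the small number of class
#' means and respond erratically to out-of-range signals); general
#' machine-learning models are out of scope for the embedded setting.
#'
#' @param values,labels,valid labelled windows (see [class_means()]); or
#'   pass a precomputed class-mean table via `means`.
#' @param means optional data.frame `label, mean_value` to fit directly.
#' @param descriptor descriptor name the values came from.
#' @param classes permitted class set; labels outside it are rejected.
#' @param baseline_regime `"single"`, `"low"` (UPDRS 1-2) or `"high"`
#'   (UPDRS 3) for the multi-model.
#' @param window_size,sampling_rate_hz acquisition profile recorded with
#'   the model, checked at classification time.
#' @return An object of class `"rigidity_model"`: `coefficients` (named
#'   `a`, `b`, `c`), `descriptor`, `class_set`, `baseline_regime`,
#'   `window_size`, `sampling_rate_hz`, `class_means`, `residuals`,
#'   `training_error` (filled by [loocv_training_error()] or `NULL`).
#' @examples
#' m <- fit_rigidity_model(means = data.frame(
#'   label = c(0, 40, 80), mean_value = c(1, 5, 7)))
#' classify(m, 5)
#' @export
fit_rigidity_model <- function(values = NULL, labels = NULL, valid = NULL,
                               means = NULL, descriptor = "phi_R",
                               classes = class_set("restricted"),
                               baseline_regime = "single",
                               window_size = 200L, sampling_rate_hz = 50) {
  if (is.null(means)) {
    if (!is.null(labels) && !all(labels %in% classes)) {
      stop(sprintf("labels outside the configured class set {%s}",
                   paste(classes, collapse = ",")))
    }
    means <- class_means(values, labels, valid)
  }
  pts <- means[is.finite(means$mean_value), , drop = FALSE]
  if (nrow(pts) < 3L || length(unique(pts$mean_value)) < 3L) {
    stop("need >= 3 distinct class-mean points to fit a quadratic")
  }
  fit <- stats::lm(label ~ I(mean_value^2) + mean_value, data = pts)
  cf <- stats::coef(fit)
  coefficients <- c(a = unname(cf["I(mean_value^2)"]),
                    b = unname(cf["mean_value"]),
                    c = unname(cf["(Intercept)"]))
  if (any(!is.finite(coefficients))) {
    stop("degenerate design: class means do not identify a quadratic")
  }
  structure(
    list(coefficients = coefficients, descriptor = descriptor,
         class_set = sort(unique(classes)),
         baseline_regime = baseline_regime,
         window_size = as.integer(window_size),
         sampling_rate_hz = sampling_rate_hz,
         class_means = pts, residuals = unname(stats::residuals(fit)),
         training_error = NULL),
    class = "rigidity_model"
  )
}

#' @export
print.rigidity_model <- function(x, ...) {
  cf <- x$coefficients
  cat(sprintf(
    "<rigidity_model> improvement%% = %.4g*phi^2 + %.4g*phi + %.4g\n",
    cf["a"], cf["b"], cf["c"]
  ))
  cat(sprintf("  descriptor %s, regime %s, classes {%s}, %d-sample windows @ %g Hz\n",
              x$descriptor, x$baseline_regime,
              paste(x$class_set, collapse = ","),
              x$window_size, x$sampling_rate_hz))
  if (!is.null(x$training_error)) {
    cat(sprintf("  LOOCV training error %.2f +/- %.2f %%\n",
                x$training_error$mean, x$training_error$sd))
  }
  invisible(x)
}

#' Classify rigidity improvement from a descriptor value
#'
#' Evaluates the fitted quadratic and clamps to the 0-80 % improvement
#' range.  Output is continuous (a discrete expert scale modelled by a
#' continuous function), never snapped to the class grid.  `NA` descriptor
#' values (unclassifiable windows) yield `NA`.
#'
#' @param model a [fit_rigidity_model()] object.
#' @param value numeric descriptor value(s).
#' @return Numeric improvement percentage(s) in `[0, 80]`, `NA` where the
#'   input was `NA`.
#' @export
classify <- function(model, value) {
  stopifnot(inherits(model, "rigidity_model"))
  cf <- model$coefficients
  pred <- cf["a"] * value^2 + cf["b"] * value + cf["c"]
  pmin(pmax(unname(pred), 0), 80)
}

#' @export
predict.rigidity_model <- function(object, newdata, ...) {
  classify(object, newdata)
}

#' Leave-one-out cross-validated training error
#'
#' Holds out one window at a time, recomputes the class means without it,
#' refits the quadratic, and records the absolute prediction error on the
#' held-out window.  `mode = "exhaustive"` visits every window exactly
#' once (n folds); `mode = "montecarlo"` draws `iterations` random
#' holdouts with replacement under `seed`.  A fold whose holdout empties
#' its class (class collapse) or leaves fewer than three classes is
#' skipped and counted.
#'
#' @inheritParams fit_rigidity_model
#' @param mode `"exhaustive"` (default) or `"montecarlo"`.
#' @param iterations Monte-Carlo draws (default 5000).
#' @param seed RNG seed for Monte-Carlo mode.
#' @return List `mean`, `sd`, `n_folds`, `n_skipped`, `errors`.
#' @export
loocv_training_error <- function(values, labels, valid = NULL,
                                 classes = class_set("restricted"),
                                 mode = c("exhaustive", "montecarlo"),
                                 iterations = 5000L, seed = NULL) {
  mode <- match.arg(mode)
  if (is.null(valid)) valid <- rep(TRUE, length(values))
  keep <- which(valid & is.finite(values) & !is.na(labels))
  values <- values[keep]
  labels <- labels[keep]
  n <- length(values)
  if (n < 2L) stop("need >= 2 valid windows for cross-validation")
  holdouts <- if (mode == "exhaustive") {
    seq_len(n)
  } else {
    with_seed(seed, sample.int(n, iterations, replace = TRUE))
  }
  one_fold <- function(i) {
    rest_lab <- labels[-i]
    if (!labels[i] %in% rest_lab) return(NA_real_)      # class collapse
    if (length(unique(rest_lab)) < 3L) return(NA_real_) # cannot refit
    m <- tryCatch(
      fit_rigidity_model(values[-i], rest_lab, classes = classes),
      error = function(e) NULL
    )
    if (is.null(m)) return(NA_real_)
    abs(classify(m, values[i]) - labels[i])
  }
  errors <- vapply(holdouts, one_fold, numeric(1))
  skipped <- sum(is.na(errors))
  errors <- errors[!is.na(errors)]
  list(mean = if (length(errors)) mean(errors) else NA_real_,
       sd = if (length(errors) > 1L) stats::sd(errors) else NA_real_,
       n_folds = length(holdouts), n_skipped = skipped, errors = errors)
}

#' Select the baseline-regime model (multi-model)
#'
#' The multi-model keeps two calibration curves, one per baseline-rigidity
#' cluster measured before stimulation: low baseline (UPDRS rigidity score
#' 1 or 2) and high baseline (UPDRS 3).  No UPDRS-4 patients were observed
#' when the clusters were built, so that regime is unsupported.
#'
#' @param models list with elements `low` and `high`, each a
#'   [fit_rigidity_model()] object.
#' @param baseline_updrs integer UPDRS rigidity sub-score, 1-4.
#' @return The selected `"rigidity_model"`.
#' @export
select_model <- function(models, baseline_updrs) {
  if (!all(c("low", "high") %in% names(models))) {
    stop("`models` must contain both `low` and `high` regime models")
  }
  if (length(baseline_updrs) != 1L || !baseline_updrs %in% 1:4) {
    stop("`baseline_updrs` must be a single score in 1..4")
  }
  if (baseline_updrs == 4) {
    stop("unsupported baseline regime: no calibration exists for UPDRS 4")
  }
  if (baseline_updrs <= 2) models$low else models$high
}

#' Write a rigidity model to JSON
#'
#' @param model a `"rigidity_model"`.
#' @param path output path.
#' @param seed optional seed recorded for provenance.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path, seed = NULL) {
  stopifnot(inherits(model, "rigidity_model"))
  obj <- list(
    descriptor = model$descriptor,
    coefficients = unname(model$coefficients),
    class_set = model$class_set,
    baseline_regime = model$baseline_regime,
    window_size = model$window_size,
    sampling_rate_hz = model$sampling_rate_hz,
    training_error = if (is.null(model$training_error)) NULL else
      list(mean = model$training_error$mean, sd = model$training_error$sd),
    seed = seed
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a rigidity model from JSON
#'
#' @param path path written by [write_model_json()].
#' @return A `"rigidity_model"`.
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cf <- as.numeric(obj$coefficients)
  if (length(cf) != 3L || any(!is.finite(cf))) {
    stop("model file must carry exactly the quadratic coefficients [a,b,c]")
  }
  te <- if (!is.null(obj$training_error) &&
              !is.null(obj$training_error$mean)) {
    list(mean = obj$training_error$mean, sd = obj$training_error$sd)
  } else NULL
  structure(
    list(coefficients = c(a = cf[1], b = cf[2], c = cf[3]),
         descriptor = obj$descriptor,
         class_set = as.numeric(obj$class_set),
         baseline_regime = obj$baseline_regime,
         window_size = as.integer(obj$window_size),
         sampling_rate_hz = as.numeric(obj$sampling_rate_hz),
         class_means = NULL, residuals = NULL, training_error = te),
    class = "rigidity_model"
  )
}
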