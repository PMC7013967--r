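#' The signal-descriptor catalogue
#'
#' Closed catalogue of scalar descriptors combining the window features
#' mu_omega (mean flexion angular velocity), mu_peak (mean peak value) and
#' delta (cogwheel-artefact count).  The core descriptor is the product
#' `phi_y = mu_omega * mu_peak` (units (°/s)^2): mean velocity encodes
#' smoothness of the imposed flexion, mean peak encodes its amplitude, and
#' their product separates improved from unimproved rigidity states.  The
#' remaining entries are the variants explored across the model
#' generations: information-weighted and ratio-penalised single-axis forms
#' (`phi_I` .. `phi_IV`), combined-axis norms (`phi_norm2`, `phi_norm3`)
#' and cross-axis sums (`phi_xy`, `phi_xyz`, `phi_bar`), cogwheel-adjusted
#' forms (`phi_1` .. `phi_8`), and the reduced-window descriptor `phi_R`
#' (identical formula to `phi_y`, extracted from 200-sample windows).
#'
#' @return data.frame with columns `name`, `axes` (comma-separated axis
#'   labels consumed), `uses_delta`, `formula` (display string).
#' @export
descriptor_catalogue <- function() {
  d <- function(name, axes, uses_delta, formula) {
    data.frame(name = name, axes = axes, uses_delta = uses_delta,
               formula = formula, stringsAsFactors = FALSE)
  }
  rbind(
    d("phi_y",     "y",     FALSE, "mu_w * mu_p"),
    d("phi_I",     "y",     FALSE, "phi_y"),
    d("phi_II",    "y",     FALSE, "min(mu_w, mu_p)"),
    d("phi_III",   "y",     FALSE,
      "mu_w^2*log2((mu_w+mu_p)/mu_w) + mu_p^2*log2((mu_w+mu_p)/mu_p)"),
    d("phi_IV",    "y",     FALSE, "phi_y * exp(-log(mu_p/mu_w)^2/(2*sigma^2))"),
    d("phi_norm2", "n2",    FALSE, "mu_w(n2) * mu_p(n2)"),
    d("phi_norm3", "n3",    FALSE, "mu_w(n3) * mu_p(n3)"),
    d("phi_xy",    "x,y",   FALSE, "(mu_w(x) + mu_w(y)) * mu_p(y)"),
    d("phi_xyz",   "x,y,z", FALSE, "(mu_w(x) + mu_w(y) + mu_w(z)) * mu_p(y)"),
    d("phi_bar",   "x,y,z", FALSE, "phi_xyz / 3"),
    d("phi_1",     "y",     TRUE,  "phi_y^2 - delta"),
    d("phi_2",     "y",     TRUE,  "phi_y^2 + delta"),
    d("phi_3",     "y",     TRUE,  "phi_y - delta^2"),
    d("phi_4",     "y",     TRUE,  "phi_y + delta^2"),
    d("phi_5",     "y",     TRUE,  "phi_y - delta"),
    d("phi_6",     "y",     TRUE,  "phi_y + delta"),
    d("phi_7",     "y",     TRUE,  "mu_w * (mu_p - delta)"),
    d("phi_8",     "y",     TRUE,  "mu_w * (mu_p + delta)"),
    d("phi_R",     "y",     FALSE, "phi_y")
  )
}

#' Axes a descriptor consumes
#'
#' @param name a descriptor name from [descriptor_catalogue()].
#' @return Character vector of axis labels (`"x"`, `"y"`, `"z"`, `"n2"`,
#'   `"n3"`).
#' @export
descriptor_axes <- function(name) {
  cat_ <- descriptor_catalogue()
  row <- cat_[cat_$name == name, ]
  if (nrow(row) == 0L) {
    stop(sprintf("unknown descriptor '%s'; available: %s", name,
                 paste(cat_$name, collapse = ", ")))
  }
  strsplit(row$axes, ",", fixed = TRUE)[[1]]
}

#' Evaluate a signal descriptor on window features
#'
#' Computes the named descriptor from a [window_features()] table (one row
#' per axis for a single window).  A window with no detected flexion on
#' the descriptor's primary axis (`mu_omega = 0`) is unclassifiable: the
#' value short-circuits to 0 and `valid` is `FALSE`.  Logarithm-based
#' forms with non-positive inputs return their limiting value 0 with
#' `warning = TRUE`.
#'
#' @param features data.frame with columns `axis`, `mu_omega`, `mu_peak`,
#'   `delta` covering every axis the descriptor requires.
#' @param name descriptor name (see [descriptor_catalogue()]).
#' @param sigma width of the Gaussian ratio penalty in `phi_IV`
#'   (dimensionless, > 0; default 1).
#' @return A list of class `"descriptor_value"`: `name`, `value`, `valid`,
#'   `warning`.
#' @examples
#' f <- data.frame(axis = "y", mu_omega = 3, mu_peak = 12, delta = 0)
#' compute_descriptor(f, "phi_y")$value  # 36
#' @export
compute_descriptor <- function(features, name, sigma = 1) {
  if (!is.numeric(sigma) || sigma <= 0) stop("`sigma` must be > 0")
  axes <- descriptor_axes(name)
  row_for <- function(a) {
    r <- features[features$axis == a, , drop = FALSE]
    if (nrow(r) == 0L) {
      stop(sprintf("descriptor '%s' requires axis '%s' features", name, a))
    }
    r[1, ]
  }
  primary <- row_for(if ("y" %in% axes) "y" else axes[1])  # n2/n3 for norms
  out <- function(value, valid = TRUE, warning = FALSE) {
    structure(list(name = name, value = value, valid = valid,
                   warning = warning),
              class = "descriptor_value")
  }
  if (primary$mu_omega <= 0) return(out(0, valid = FALSE))
  mw <- primary$mu_omega
  mp <- primary$mu_peak
  dl <- primary$delta
  phi_y <- mw * mp
  value <- switch(name,
    phi_y = , phi_I = , phi_R = phi_y,
    phi_II = min(mw, mp),
    phi_III = {
      if (mp <= 0) return(out(0, warning = TRUE))
      mw^2 * log2((mw + mp) / mw) + mp^2 * log2((mw + mp) / mp)
    },
    phi_IV = {
      if (mp <= 0) return(out(0, warning = TRUE))
      phi_y * exp(-log(mp / mw)^2 / (2 * sigma^2))
    },
    phi_norm2 = , phi_norm3 = phi_y,
    phi_xy = (row_for("x")$mu_omega + row_for("y")$mu_omega) * row_for("y")$mu_peak,
    phi_xyz = (row_for("x")$mu_omega + row_for("y")$mu_omega +
                 row_for("z")$mu_omega) * row_for("y")$mu_peak,
    phi_bar = (row_for("x")$mu_omega + row_for("y")$mu_omega +
                 row_for("z")$mu_omega) * row_for("y")$mu_peak / 3,
    phi_1 = phi_y^2 - dl,
    phi_2 = phi_y^2 + dl,
    phi_3 = phi_y - dl^2,
    phi_4 = phi_y + dl^2,
    phi_5 = phi_y - dl,
    phi_6 = phi_y + dl,
    phi_7 = mw * (mp - dl),
    phi_8 = mw * (mp + dl)
  )
  out(value)
}

#' @export
print.descriptor_value <- function(x, ...) {
  cat(sprintf("<descriptor_value> %s = %.6g%s%s\n", x$name, x$value,
              if (!x$valid) " [unclassifiable]" else "",
              if (x$warning) " [limit]" else ""))
  invisible(x)
}

#' Descriptor series for a whole session
#'
#' Extracts the axes the descriptor needs, computes [window_features()]
#' per window and evaluates the descriptor, giving one value per complete
#' window.
#'
#' @inheritParams session_features
#' @inheritParams compute_descriptor
#' @return data.frame `window_index, descriptor, value, valid`.
#' @export
session_descriptors <- function(signal, name = "phi_R", sigma = 1,
                                profile = NULL, window_size = NULL,
                                margin = NULL, dip_threshold = NULL) {
  axes <- descriptor_axes(name)
  feats <- session_features(signal, axes = axes, profile = profile,
                            window_size = window_size, margin = margin,
                            dip_threshold = dip_threshold)
  features_to_descriptors(feats, name = name, sigma = sigma)
}

#' Evaluate a descriptor over a multi-window feature table
#'
#' @param features data.frame as from [session_features()] (must contain a
#'   `window_index` column and the axes the descriptor requires).
#' @inheritParams compute_descriptor
#' @return data.frame `window_index, descriptor, value, valid`.
#' @export
features_to_descriptors <- function(features, name = "phi_R", sigma = 1) {
  if (nrow(features) == 0L) {
    return(data.frame(window_index = integer(0), descriptor = character(0),
                      value = numeric(0), valid = logical(0)))
  }
  idx <- sort(unique(features$window_index))
  rows <- lapply(idx, function(w) {
    dv <- compute_descriptor(features[features$window_index == w, ],
                             name = name, sigma = sigma)
    data.frame(window_index = w, descriptor = name, value = dv$value,
               valid = dv$valid, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
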