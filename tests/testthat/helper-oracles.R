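# Independent brute-force oracles and fixture builders used across tests.

# Brute-force peak finder: enumerate every interior sample, slice the flank
# regions explicitly (up to the first strictly-greater sample on the left /
# first greater-or-equal sample on the right, else the boundary) and demand
# a dip of at least `margin` below the candidate on both sides.
oracle_peaks <- function(x, margin) {
  n <- length(x)
  found <- integer(0)
  if (n < 3L) return(found)
  for (i in 2:(n - 1L)) {
    right <- x[(i + 1L):n]
    stop_r <- which(right >= x[i])
    region_r <- if (length(stop_r)) right[seq_len(stop_r[1] - 1L)] else right
    if (length(region_r) == 0L || min(region_r) > x[i] - margin) next
    left <- x[seq_len(i - 1L)]
    stop_l <- which(left > x[i])
    region_l <- if (length(stop_l)) {
      left[seq((utils::tail(stop_l, 1) + 1L), i - 1L)[seq_len(max(0L, i - 1L - utils::tail(stop_l, 1)))]]
    } else left
    if (length(region_l) == 0L || min(region_l) > x[i] - margin) next
    found <- c(found, i)
  }
  found
}

# Exhaustive LOOCV computed from first principles with lm(): hold out each
# window once, recompute class means with tapply, fit the quadratic
# directly, clamp, record the absolute error.  Folds whose holdout empties
# its class or leaves < 3 usable class means are skipped.
oracle_loocv <- function(values, labels) {
  n <- length(values)
  errors <- numeric(0)
  skipped <- 0L
  for (i in seq_len(n)) {
    v <- values[-i]; l <- labels[-i]
    if (!labels[i] %in% l || length(unique(l)) < 3L) {
      skipped <- skipped + 1L
      next
    }
    mv <- tapply(v, l, mean)
    ml <- as.numeric(names(mv))
    if (length(unique(unname(mv))) < 3L) {
      skipped <- skipped + 1L
      next
    }
    fit <- lm(ml ~ I(mv^2) + mv)
    p <- unname(predict(fit, newdata = data.frame(mv = values[i])))
    p <- min(max(p, 0), 80)
    errors <- c(errors, abs(p - labels[i]))
  }
  list(errors = errors, skipped = skipped)
}

# Rectified half-sine arcade of a given length and amplitude.
make_arcade <- function(len = 40L, amp = 10) {
  amp * sin(pi * seq(0, 1, length.out = len))
}

# A random rectified multi-arcade trace (zeros between arcades), the shape
# peak detection and cogwheel counting operate on.
random_flexion_trace <- function(n_arcades = 3L, max_amp = 20) {
  segs <- lapply(seq_len(n_arcades), function(i) {
    arc <- make_arcade(sample(20:50, 1), runif(1, 0.5, max_amp))
    c(arc, numeric(sample(3:15, 1)))
  })
  c(numeric(sample(0:10, 1)), unlist(segs))
}

# Labelled windows lying exactly on a known quadratic (by class), optionally
# jittered, for model-fitting fixtures.
quadratic_windows <- function(truth = c(-5e-4, 0.5, -10),
                              classes = c(0, 40, 50, 60, 70, 80),
                              n_per_class = 4L, noise_sd = 0,
                              seed = NULL) {
  generate_labelled_windows(truth, classes = classes,
                            n_per_class = n_per_class,
                            noise_sd = noise_sd, seed = seed)
}
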