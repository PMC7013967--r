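test_that("class means average valid windows per label", {
  cm <- class_means(c(2, 4, 6, 8), c(0, 0, 40, 40))
  expect_equal(cm$label, c(0, 40))
  expect_equal(cm$mean_value, c(3, 7))
  expect_equal(cm$n, c(2L, 2L))
  # single window per class
  expect_equal(class_means(5, 60)$mean_value, 5)
  # invalid windows do not move the means
  cm2 <- class_means(c(2, 4, 100, 6, 8), c(0, 0, 0, 40, 40),
                     valid = c(TRUE, TRUE, FALSE, TRUE, TRUE))
  expect_equal(cm2$mean_value, cm$mean_value)
  expect_error(class_means(numeric(0), numeric(0)), "valid")
  expect_error(class_means(1:3, 1:2), "equal length")
})

test_that("three exact points recover their quadratic", {
  phi <- c(1, 5, 9)
  lab <- 0.1 * phi^2 + phi + 5
  m <- fit_rigidity_model(means = data.frame(label = lab, mean_value = phi),
                          classes = lab)
  expect_equal(unname(m$coefficients), c(0.1, 1, 5), tolerance = 1e-9)
  expect_equal(m$residuals, rep(0, 3), tolerance = 1e-9)
})

test_that("six noiseless class means fit with zero residual", {
  phi <- c(20, 90, 130, 160, 200, 235)
  lab <- -5e-4 * phi^2 + 0.5 * phi - 4
  m <- fit_rigidity_model(means = data.frame(label = lab, mean_value = phi),
                          classes = lab)
  expect_equal(max(abs(m$residuals)), 0, tolerance = 1e-8)
})

test_that("least squares matches a normal-equations oracle", {
  set.seed(23)
  phi <- c(20, 90, 130, 160, 200, 235)
  lab <- c(0, 40, 50, 60, 70, 80) + rnorm(6, 0, 3)
  m <- fit_rigidity_model(means = data.frame(label = lab, mean_value = phi),
                          classes = lab)
  X <- cbind(phi^2, phi, 1)
  beta <- solve(t(X) %*% X, t(X) %*% lab)
  expect_equal(unname(m$coefficients), as.numeric(beta), tolerance = 1e-8)
})

test_that("fitting demands three informative points and a known class set", {
  expect_error(fit_rigidity_model(means = data.frame(
    label = c(0, 40), mean_value = c(1, 2))), ">= 3")
  expect_error(fit_rigidity_model(means = data.frame(
    label = c(0, 40, 80), mean_value = c(2, 2, 2))), ">= 3")
  expect_error(
    fit_rigidity_model(c(1, 2, 3), c(0, 40, 45),
                       classes = c(0, 40, 50, 60, 70, 80)),
    "class set"
  )
})

test_that("classification evaluates the quadratic and clamps to [0, 80]", {
  m <- fit_rigidity_model(means = data.frame(label = c(0, 30, 60),
                                             mean_value = c(0, 3, 6)),
                          classes = c(0, 30, 60))
  expect_equal(unname(m$coefficients), c(0, 10, 0), tolerance = 1e-9)
  expect_equal(classify(m, 5), 50)
  expect_equal(classify(m, 100), 80)
  expect_equal(classify(m, -40), 0)
  expect_equal(classify(m, c(1, NA, 3)), c(10, NA, 30))
  expect_equal(predict(m, 5), 50)
})

test_that("a noiseless cohort has zero LOOCV training error", {
  lw <- quadratic_windows(n_per_class = 4L, noise_sd = 0)
  loo <- loocv_training_error(lw$descriptor_value, lw$label,
                              classes = unique(lw$label))
  expect_equal(loo$mean, 0, tolerance = 1e-8)
  expect_equal(loo$sd, 0, tolerance = 1e-8)
  expect_equal(loo$n_skipped, 0L)
})

test_that("exhaustive LOOCV matches the brute-force oracle", {
  set.seed(61)
  for (rep in 1:12) {
    classes <- c(0, 40, 50, 60, 70, 80)[1:sample(3:6, 1)]
    lw <- quadratic_windows(classes = classes,
                            n_per_class = sample(2:4, 1), noise_sd = 8,
                            seed = 1000 + rep)
    loo <- loocv_training_error(lw$descriptor_value, lw$label,
                                classes = classes)
    orc <- oracle_loocv(lw$descriptor_value, lw$label)
    expect_equal(sort(loo$errors), sort(orc$errors), tolerance = 1e-9)
    expect_equal(loo$n_skipped, orc$skipped)
  }
})

test_that("exhaustive LOOCV is invariant under window permutation", {
  lw <- quadratic_windows(n_per_class = 3L, noise_sd = 10, seed = 8)
  loo1 <- loocv_training_error(lw$descriptor_value, lw$label,
                               classes = unique(lw$label))
  p <- sample(nrow(lw))
  loo2 <- loocv_training_error(lw$descriptor_value[p], lw$label[p],
                               classes = unique(lw$label))
  expect_equal(loo1$mean, loo2$mean)
  expect_equal(loo1$sd, loo2$sd)
})

test_that("Monte-Carlo LOOCV is reproducible under a seed", {
  lw <- quadratic_windows(n_per_class = 4L, noise_sd = 10, seed = 9)
  a <- loocv_training_error(lw$descriptor_value, lw$label,
                            classes = unique(lw$label),
                            mode = "montecarlo", iterations = 200L,
                            seed = 42)
  b <- loocv_training_error(lw$descriptor_value, lw$label,
                            classes = unique(lw$label),
                            mode = "montecarlo", iterations = 200L,
                            seed = 42)
  expect_identical(a$errors, b$errors)
  expect_equal(a$n_folds, 200L)
})

test_that("holding out a singleton class skips that fold", {
  lw <- quadratic_windows(classes = c(0, 40, 60, 80),
                          n_per_class = 2L, noise_sd = 2, seed = 4)
  lw <- lw[-1, ]  # class 0 now has a single window
  loo <- loocv_training_error(lw$descriptor_value, lw$label,
                              classes = unique(lw$label))
  expect_equal(loo$n_skipped, 1L)
  expect_equal(length(loo$errors), nrow(lw) - 1L)
})

test_that("refit on scaled descriptors predicts identically", {
  lw <- quadratic_windows(n_per_class = 3L, noise_sd = 6, seed = 31)
  m1 <- fit_rigidity_model(lw$descriptor_value, lw$label,
                           classes = unique(lw$label))
  k <- 7.3
  m2 <- fit_rigidity_model(k * lw$descriptor_value, lw$label,
                           classes = unique(lw$label))
  x <- seq(min(lw$descriptor_value), max(lw$descriptor_value),
           length.out = 11)
  expect_equal(classify(m1, x), classify(m2, k * x), tolerance = 1e-7)
})

test_that("the baseline-regime gate follows the UPDRS score", {
  mk <- function(regime) fit_rigidity_model(
    means = data.frame(label = c(0, 40, 80), mean_value = c(1, 5, 7)),
    classes = c(0, 40, 80), baseline_regime = regime
  )
  models <- list(low = mk("low"), high = mk("high"))
  expect_equal(select_model(models, 1)$baseline_regime, "low")
  expect_equal(select_model(models, 2)$baseline_regime, "low")
  expect_equal(select_model(models, 3)$baseline_regime, "high")
  expect_error(select_model(models, 4), "UPDRS 4")
  expect_error(select_model(models, 0), "1..4")
  expect_error(select_model(list(low = models$low), 2), "both")
})

test_that("models round-trip through JSON", {
  lw <- quadratic_windows(n_per_class = 3L, noise_sd = 4, seed = 77)
  m <- fit_rigidity_model(lw$descriptor_value, lw$label,
                          classes = unique(lw$label),
                          descriptor = "phi_R")
  m$training_error <- loocv_training_error(lw$descriptor_value, lw$label,
                                           classes = unique(lw$label))
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(m, path, seed = 5)
  back <- read_model_json(path)
  expect_equal(back$coefficients, m$coefficients)
  expect_equal(back$class_set, m$class_set)
  expect_equal(back$window_size, m$window_size)
  expect_equal(back$training_error$mean, m$training_error$mean)
  x <- c(30, 120, 210)
  expect_equal(classify(back, x), classify(m, x))
})

test_that("coefficients converge to truth as the cohort grows", {
  truth <- c(-5e-4, 0.5, -10)
  err_at <- function(n) {
    lw <- generate_labelled_windows(truth, n_per_class = n, noise_sd = 5,
                                    seed = 123)
    m <- fit_rigidity_model(lw$descriptor_value, lw$label,
                            classes = unique(lw$label))
    sqrt(sum((m$coefficients - truth)^2))
  }
  expect_lt(err_at(600), err_at(60) + 1e-12)
})
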