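teacher_A <- matrix(c(0.9, -0.05, 0.02, 0.7), 2, 2, byrow = TRUE)
teacher_b <- c(-0.18, -0.02)

test_that("the 70/15/15 split follows the stated rounding rule", {
  s88 <- split_dataset(88, seed = 1)
  expect_equal(lengths(s88), c(train = 62, val = 13, test = 13))
  s10 <- split_dataset(10, seed = 1)
  expect_equal(lengths(s10), c(train = 7, val = 2, test = 1))
  for (n in c(3, 11, 47, 88, 200)) {
    s <- split_dataset(n, seed = n)
    expect_setequal(c(s$train, s$val, s$test), seq_len(n))
    expect_length(intersect(s$train, s$val), 0)
    expect_length(intersect(s$train, s$test), 0)
    expect_length(intersect(s$val, s$test), 0)
  }
  expect_identical(split_dataset(88, seed = 4), split_dataset(88, seed = 4))
  expect_error(split_dataset(2), "at least 3")
})

test_that("mean squared prediction error averages half squared errors", {
  p <- rbind(c(1, 1), c(0, 0))
  o <- rbind(c(1, 1), c(0, 0))
  expect_equal(mean_squared_pe(p, o), 0)
  expect_equal(mean_squared_pe(rbind(c(1, 1)), rbind(c(0, 0))), 1.0)
  expect_equal(mean_squared_pe(rbind(c(1, 0), c(0, 2)),
                               rbind(c(0, 0), c(0, 0))), 1.25)
  expect_error(mean_squared_pe(matrix(0, 0, 2), matrix(0, 0, 2)), "empty")
})

test_that("regression recovers generating coefficients exactly without noise", {
  set.seed(41)
  x <- cbind(rnorm(60, 0.8, 1.5), rnorm(60, 0, 0.9))
  y <- x %*% t(teacher_A) + matrix(teacher_b, 60, 2, byrow = TRUE)
  fit <- fit_pv_regression(x, y)
  expect_equal(unname(fit$matrix), unname(teacher_A), tolerance = 1e-8)
  expect_equal(fit$intercept, teacher_b, tolerance = 1e-8)
  # perfect fit has a degenerate likelihood
  expect_true(is.na(fit$logL))
  expect_error(gaussian_log_likelihood(fit, x, y), "degenerate")
})

test_that("degenerate designs fall back to column means or error", {
  set.seed(42)
  y <- cbind(rnorm(20, 0.5), rnorm(20, -0.2))
  x0 <- matrix(0, 20, 2)
  fit0 <- fit_pv_regression(x0, y)
  expect_equal(fit0$intercept, colMeans(y))
  expect_equal(unname(fit0$matrix), matrix(0, 2, 2))
  # collinear but non-constant predictors are rejected
  xc <- cbind(rnorm(20), 0)
  xc <- cbind(xc[, 1], 2 * xc[, 1])
  expect_error(fit_pv_regression(xc, y), "rank-deficient")
  # the fitted mean response passes through the data centroid
  x <- cbind(rnorm(20), rnorm(20))
  fit <- fit_pv_regression(x, y)
  expect_equal(as.numeric(apply_regression(fit, colMeans(x))), colMeans(y),
               tolerance = 1e-10)
})

test_that("OD/OS mirroring transforms models and predictions consistently", {
  set.seed(43)
  x <- cbind(rnorm(50, 0.8, 1.5), rnorm(50, 0, 0.9))
  y <- x %*% t(teacher_A) + matrix(teacher_b, 50, 2, byrow = TRUE) +
    matrix(rnorm(100, 0, 0.2), 50, 2)
  fit <- fit_pv_regression(x, y)
  mir <- mirror_model_for_eye(fit)
  expect_equal(mir$eye_side, "OS")
  expect_equal(mirror_model_for_eye(mir)$matrix, fit$matrix)
  expect_equal(mirror_model_for_eye(mir)$intercept, fit$intercept)

  # fitting on mirrored data gives exactly the mirrored model
  fit_os <- fit_pv_regression(x %*% diag(c(1, -1)), y %*% diag(c(1, -1)))
  expect_equal(unname(fit_os$matrix), unname(mir$matrix), tolerance = 1e-10)
  expect_equal(fit_os$intercept, mir$intercept, tolerance = 1e-10)

  # equivariance: mirror(model) applied to mirror(x) == mirror(model(x))
  xs <- rbind(c(1.2, 0.4), c(-0.3, -1.1))
  lhs <- apply_regression(mir, xs %*% diag(c(1, -1)))
  rhs <- apply_regression(fit, xs) %*% diag(c(1, -1))
  expect_equal(unname(lhs), unname(rhs), tolerance = 1e-12)
})

test_that("an identity model passes inputs through unchanged", {
  set.seed(44)
  x <- cbind(rnorm(30), rnorm(30))
  y <- x + matrix(rnorm(60, 0, 0.1), 30, 2)
  fit <- fit_pv_regression(x, y)
  fit$matrix <- diag(2)
  fit$intercept <- c(0, 0)
  expect_equal(unname(apply_regression(fit, x)), unname(x))
})

test_that("the Gaussian log-likelihood matches its closed form and is monotone", {
  set.seed(45)
  x <- cbind(rnorm(40), rnorm(40))
  y <- x %*% t(teacher_A) + matrix(rnorm(80, 0, 0.5), 40, 2)
  fit <- fit_pv_regression(x, y)
  res <- y - apply_regression(fit, x)
  n <- nrow(res)
  S <- crossprod(res) / n
  # independent arithmetic path: sum of bivariate normal log-densities
  Sinv <- solve(S)
  manual <- sum(vapply(seq_len(n), function(i) {
    r <- res[i, ]
    -log(2 * pi) - 0.5 * log(det(S)) - 0.5 * as.numeric(r %*% Sinv %*% r)
  }, numeric(1)))
  expect_equal(gaussian_log_likelihood(fit, x, y), manual, tolerance = 1e-10)
  expect_equal(fit$logL, manual, tolerance = 1e-10)
  # scaling residuals up strictly decreases the likelihood
  y10 <- apply_regression(fit, x) + 10 * res
  expect_lt(gaussian_log_likelihood(fit, x, y10), fit$logL)
})

test_that("bundled reference models replay the published coefficients", {
  mods <- reference_models()
  expect_named(mods, c("iolm_od", "iolm_os", "casia_od", "casia_os"))
  od <- mods$iolm_od
  expect_equal(as.numeric(apply_regression(od, c(0, 0))), c(-0.1823, -0.0229))
  expect_equal(as.numeric(apply_regression(od, c(1, 0))),
               c(0.9150 - 0.1823, -0.0018 - 0.0229))
  os <- mirror_model_for_eye(od)
  expect_equal(os$matrix, mods$iolm_os$matrix)
  expect_equal(os$intercept, mods$iolm_os$intercept)
  expect_equal(mods$casia_od$logL, -37.8488)
  expect_equal(mirror_model_for_eye(mods$casia_od)$intercept,
               mods$casia_os$intercept)
})

test_that("robust refit downweights gross outliers", {
  set.seed(46)
  x <- cbind(rnorm(80, 0.8, 1.5), rnorm(80, 0, 0.9))
  y <- x %*% t(teacher_A) + matrix(teacher_b, 80, 2, byrow = TRUE) +
    matrix(rnorm(160, 0, 0.1), 80, 2)
  y[1:4, ] <- y[1:4, ] + 25
  plain <- fit_pv_regression(x, y)
  rob <- fit_pv_regression(x, y, robust = TRUE)
  err <- function(m) max(abs(unname(m$matrix) - unname(teacher_A)))
  expect_lt(err(rob), err(plain))
  expect_lt(err(rob), 0.05)
})

test_that("prediction-error stats summarise per-model error clouds", {
  set.seed(47)
  x <- cbind(rnorm(60, 0.8, 1.5), rnorm(60, 0, 0.9))
  y <- x %*% t(teacher_A) + matrix(teacher_b, 60, 2, byrow = TRUE) +
    matrix(rnorm(120, 0, 0.3), 60, 2)
  fit <- fit_pv_regression(x, y)
  perfect <- fit
  stats <- prediction_error_stats(list(reg = fit), x, y)
  expect_equal(stats$table$model, rep("reg", 2))
  # least-squares residuals have exactly zero mean on the training data
  expect_equal(stats$table$mean, c(0, 0), tolerance = 1e-10)
  expect_s3_class(stats$ellipses$reg, "pv_ellipse")

  # a perfect model yields an all-zero table and a degenerate ellipse
  yhat <- apply_regression(fit, x)
  st2 <- prediction_error_stats(list(reg = fit), x, yhat)
  expect_true(all(abs(st2$table[, c("mean", "sd", "median")]) < 1e-12))
  expect_null(st2$ellipses$reg)
})
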