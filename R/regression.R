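# Multivariate linear prediction of postoperative astigmatism components
# from preoperative keratometry, with OD/OS mirroring and the data split
# shared with the network model.

#' Train/validation/test split
#'
#' Random split of `n` records into training, validation and test sets:
#' the training size is `round(fractions[1] * n)` and the remainder is
#' divided between validation and test as evenly as possible, validation
#' first.  For `n = 88` with the default 70/15/15 fractions this gives
#' 62/13/13.
#'
#' @param n number of records.
#' @param fractions length-3 fractions summing to 1.
#' @param seed integer seed; the split is reproducible and independent of
#'   the caller's RNG state.
#' @return list with integer index vectors `train`, `val`, `test`.
#' @export
split_dataset <- function(n, fractions = c(0.70, 0.15, 0.15), seed = 1) {
  if (n < 3) stop_invalid("need at least 3 records to split")
  if (length(fractions) != 3 || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-8)
    stop_invalid("fractions must be 3 non-negative numbers summing to 1")
  n_train <- round(fractions[1] * n)
  m <- n - n_train
  n_val <- ceiling(m * fractions[2] / (fractions[2] + fractions[3]))
  perm <- with_local_seed(seed, sample.int(n))
  n_test <- n - n_train - n_val
  list(train = sort(perm[seq_len(n_train)]),
       val = sort(perm[n_train + seq_len(n_val)]),
       test = sort(perm[n_train + n_val + seq_len(n_test)]))
}

#' Mean squared prediction error of astigmatism components
#'
#' Per record, half the squared Euclidean error of the two astigmatism
#' components, `0.5 * ((dC0)^2 + (dC45)^2)`, averaged over records.  This is
#' the objective minimised by both the regression and the network model.
#'
#' @param predicted,observed n x 2 matrices of (C0, C45) in dpt.
#' @return mean squared prediction error in dpt^2.
#' @export
mean_squared_pe <- function(predicted, observed) {
  p <- as.matrix(predicted); o <- as.matrix(observed)
  if (nrow(p) == 0) stop_invalid("empty input")
  if (!all(dim(p) == dim(o)) || ncol(p) != 2)
    stop_invalid("predicted and observed must be n x 2 matrices")
  mean(0.5 * rowSums((p - o)^2))
}

#' Fit the multivariate astigmatism regression
#'
#' Least-squares fit of the two postoperative astigmatism components on the
#' two preoperative ones: `y = A x + b` with a 2 x 2 coefficient matrix `A`
#' and intercept `b`, minimising the mean squared prediction error.  Inputs
#' must already be in right-eye (mirrored) orientation; the left-eye
#' counterpart of the fitted model follows from [mirror_model_for_eye()].
#' With `robust = TRUE` the fit is iteratively reweighted with Tukey
#' bisquare weights on the bivariate residual norm.
#'
#' @param x n x 2 matrix of preoperative (C0, C45) in dpt.
#' @param y n x 2 matrix of postoperative (C0, C45) in dpt.
#' @param eye_side orientation the model is expressed in (`"OD"` default).
#' @param robust use bisquare iterative reweighting instead of plain least
#'   squares.
#' @return object of class `pv_regression` with fields `matrix` (2 x 2),
#'   `intercept` (length 2), `eye_side`, `logL`, `n`, `residuals`, `robust`.
#' @examples
#' x <- cbind(rnorm(50), rnorm(50))
#' y <- x %*% t(matrix(c(.9, 0, 0, .7), 2)) + rnorm(100, sd = .1)
#' fit <- fit_pv_regression(x, y)
#' coef(fit)
#' @export
fit_pv_regression <- function(x, y, eye_side = "OD", robust = FALSE) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (ncol(x) != 2 || ncol(y) != 2 || nrow(x) != nrow(y))
    stop_invalid("x and y must be n x 2 matrices of (C0, C45)")
  n <- nrow(x)
  if (n < 4) stop_invalid("need at least 4 records to fit")
  X <- cbind(1, x)
  if (qr(X)$rank < 3) {
    # constant predictors carry no information: intercept-only fit
    if (all(apply(x, 2, stats::sd) == 0)) {
      B <- rbind(colMeans(y), 0, 0)
    } else {
      stop_invalid("rank-deficient design matrix")
    }
  } else {
    B <- qr.coef(qr(X), y)                     # 3 x 2: intercept row first
  }
  if (robust) {
    for (it in 1:30) {
      res <- y - X %*% B
      s <- stats::median(sqrt(rowSums(res^2))) / 0.6745
      if (s <= .Machine$double.eps) break
      u <- sqrt(rowSums(res^2)) / (4.685 * s)
      w <- ifelse(u < 1, (1 - u^2)^2, 0)
      if (all(w == 0)) break
      W <- sqrt(w)
      B_new <- qr.coef(qr(X * W), y * W)
      if (max(abs(B_new - B)) < 1e-10) { B <- B_new; break }
      B <- B_new
    }
  }
  m <- structure(list(matrix = t(B[2:3, , drop = FALSE]),
                      intercept = unname(B[1, ]),
                      eye_side = match.arg(eye_side, c("OD", "OS")),
                      n = n, robust = robust,
                      residuals = y - X %*% B,
                      logL = NA_real_),
                 class = "pv_regression")
  dimnames(m$matrix) <- list(c("C0_post", "C45_post"), c("C0_pre", "C45_pre"))
  m$logL <- tryCatch(gaussian_log_likelihood(m, x, y), error = function(e) NA_real_)
  m
}

#' Evaluate a regression model
#'
#' `A x + b` for each row of `x`; `x` must be in the model's eye
#' orientation (mirror OS inputs first, or mirror the model).
#'
#' @param m a `pv_regression` (fitted or bundled reference model).
#' @param x n x 2 matrix (or length-2 vector) of preoperative (C0, C45).
#' @return n x 2 matrix of predicted (C0, C45).
#' @export
apply_regression <- function(m, x) {
  if (!inherits(m, "pv_regression")) stop_invalid("m must be a pv_regression")
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (ncol(x) != 2) stop_invalid("x must have two columns (C0, C45)")
  out <- x %*% t(m$matrix) + matrix(m$intercept, nrow(x), 2, byrow = TRUE)
  colnames(out) <- c("C0", "C45")
  out
}

#' @export
predict.pv_regression <- function(object, newdata, ...) {
  apply_regression(object, newdata)
}

#' @export
coef.pv_regression <- function(object, ...) {
  cbind(object$matrix, intercept = object$intercept)
}

#' @export
print.pv_regression <- function(x, digits = 4, ...) {
  cat(sprintf("Multivariate astigmatism regression (%s orientation%s, n = %s)\n",
              x$eye_side, if (isTRUE(x$robust)) ", bisquare-robust" else "",
              if (is.na(x$n)) "?" else x$n))
  cat("  [C0_post; C45_post] = A [C0_pre; C45_pre] + b\n")
  print(round(coef(x), digits))
  if (is.finite(x$logL)) cat(sprintf("  logL = %.4f\n", x$logL))
  invisible(x)
}

#' @export
summary.pv_regression <- function(object, ...) {
  out <- list(coefficients = coef(object), eye_side = object$eye_side,
              n = object$n, logL = object$logL)
  if (!is.null(object$residuals)) {
    out$residual_sd <- apply(object$residuals, 2, stats::sd)
    out$mspe <- mean(0.5 * rowSums(object$residuals^2))
  }
  class(out) <- "summary.pv_regression"
  out
}

#' @export
print.summary.pv_regression <- function(x, digits = 4, ...) {
  cat(sprintf("pv_regression (%s), n = %s\n", x$eye_side,
              if (is.na(x$n)) "?" else x$n))
  print(round(x$coefficients, digits))
  if (!is.null(x$mspe))
    cat(sprintf("residual SD (C0, C45): %s; mean squared PE %.4f dpt^2\n",
                paste(round(x$residual_sd, digits), collapse = ", "), x$mspe))
  if (is.finite(x$logL)) cat(sprintf("logL = %.4f\n", x$logL))
  invisible(x)
}

#' @export
logLik.pv_regression <- function(object, ...) {
  structure(object$logL, df = 6 + 3, class = "logLik", nobs = object$n)
}

#' Mirror a regression model between right- and left-eye orientation
#'
#' Because left eyes are pooled by reversing C45, the left-eye version of a
#' fitted model negates both off-diagonal matrix entries and the second
#' intercept component.  The operation is an involution.
#'
#' @param m a `pv_regression`.
#' @return the mirrored `pv_regression` with `eye_side` flipped.
#' @export
mirror_model_for_eye <- function(m) {
  if (!inherits(m, "pv_regression")) stop_invalid("m must be a pv_regression")
  m$matrix[1, 2] <- -m$matrix[1, 2]
  m$matrix[2, 1] <- -m$matrix[2, 1]
  m$intercept[2] <- -m$intercept[2]
  m$eye_side <- if (m$eye_side == "OD") "OS" else "OD"
  m
}

#' Gaussian log-likelihood of a regression model
#'
#' Bivariate Gaussian log-likelihood of the model's residuals on a dataset,
#' with the maximum-likelihood (n denominator) residual covariance:
#' `-(n/2) * (2 log(2 pi) + log det S + 2)`.
#'
#' @param m a `pv_regression`.
#' @param x,y n x 2 matrices of inputs and observed outputs.
#' @return the log-likelihood (scalar).
#' @export
gaussian_log_likelihood <- function(m, x, y) {
  y <- as.matrix(y)
  res <- y - apply_regression(m, x)
  n <- nrow(res)
  if (n <= 2) stop_invalid("need more than 2 records for a likelihood")
  S <- crossprod(res) / n  # ML covariance of the model errors about zero
  dt <- det(S)
  if (!is.finite(dt) || dt <= .Machine$double.eps^2)
    stop_invalid("degenerate residual covariance (perfect or collinear fit)")
  -(n / 2) * (2 * log(2 * pi) + log(dt) + 2)
}

#' Bundled published reference regression models
#'
#' Coefficient sets of the published multivariate regressions predicting
#' postoperative CASIA real-power astigmatism components from preoperative
#' keratometric components (IOLM-based and CASIA-based, each in OD and OS
#' orientation), shipped with the package for replay and cross-checks.
#'
#' @return named list of `pv_regression` objects:
#'   `iolm_od`, `iolm_os`, `casia_od`, `casia_os`.
#' @examples
#' mods <- reference_models()
#' apply_regression(mods$iolm_od, c(0, 0)) # the published intercept
#' @export
reference_models <- function() {
  path <- system.file("extdata", "reference_models.json", package = "cornvec")
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  out <- lapply(raw, function(spec) {
    M <- spec$matrix
    if (!is.matrix(M)) M <- matrix(unlist(M), 2, 2, byrow = TRUE)
    m <- structure(list(matrix = M,
                        intercept = as.numeric(spec$intercept),
                        eye_side = spec$eye_side,
                        n = spec$n %||% NA_integer_,
                        robust = FALSE, residuals = NULL,
                        logL = spec$logL %||% NA_real_),
                   class = "pv_regression")
    dimnames(m$matrix) <- list(c("C0_post", "C45_post"), c("C0_pre", "C45_pre"))
    m
  })
  out
}

#' Fit-error summaries and ellipses for a set of predictors
#'
#' For each model (regression or network), computes the per-eye prediction
#' error `observed - predicted` of the (C0, C45) components, summarises each
#' component with [component_summary()], and fits a confidence ellipse to
#' the error cloud.
#'
#' @param models named list of `pv_regression` and/or `pv_network` objects.
#' @param x n x 2 matrix of preoperative (C0, C45), right-eye orientation.
#' @param y n x 2 matrix of observed postoperative (C0, C45).
#' @param level ellipse coverage level.
#' @return list with `table` (long data frame: model, component, summary
#'   stats), `errors` (named list of n x 2 error matrices) and `ellipses`
#'   (named list of `pv_ellipse`, `NULL` where degenerate).
#' @export
prediction_error_stats <- function(models, x, y, level = 0.90) {
  if (is.null(names(models)) || any(names(models) == ""))
    stop_invalid("models must be a named list")
  y <- as.matrix(y)
  errors <- lapply(models, function(m) {
    e <- y - predict(m, x)
    colnames(e) <- c("C0", "C45")
    e
  })
  tab <- do.call(rbind, lapply(names(errors), function(nm) {
    do.call(rbind, lapply(c("C0", "C45"), function(comp) {
      data.frame(model = nm, component = comp,
                 t(component_summary(errors[[nm]][, comp])),
                 stringsAsFactors = FALSE, check.names = FALSE)
    }))
  }))
  rownames(tab) <- NULL
  ellipses <- lapply(errors, function(e)
    tryCatch(confidence_ellipse(e, level = level), error = function(err) NULL))
  list(table = tab, errors = errors, ellipses = ellipses)
}
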