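# Shallow feedforward network (2 -> 10 -> 8 -> 2) trained with the
# Levenberg-Marquardt algorithm to predict postoperative astigmatism
# components from preoperative ones.
#
# The network is small enough that LM with the full Jacobian over all
# weights is cheap and converges in a handful of epochs, which is why it is
# preferred here over first-order training.  Hidden layers use tanh, the
# output is linear, and inputs are z-scored with training-set statistics.

nn_pack <- function(p) {
  c(as.vector(p$W1), p$b1, as.vector(p$W2), p$b2, as.vector(p$W3), p$b3)
}

nn_unpack <- function(theta, sizes) {
  i <- 0
  take <- function(k) { v <- theta[i + seq_len(k)]; i <<- i + k; v }
  h1 <- sizes[2]; h2 <- sizes[3]
  list(W1 = matrix(take(h1 * sizes[1]), h1, sizes[1]),
       b1 = take(h1),
       W2 = matrix(take(h2 * h1), h2, h1),
       b2 = take(h2),
       W3 = matrix(take(sizes[4] * h2), sizes[4], h2),
       b3 = take(sizes[4]))
}

nn_forward <- function(p, X, keep = FALSE) {
  A1 <- tanh(X %*% t(p$W1) + matrix(p$b1, nrow(X), length(p$b1), byrow = TRUE))
  A2 <- tanh(A1 %*% t(p$W2) + matrix(p$b2, nrow(X), length(p$b2), byrow = TRUE))
  Y <- A2 %*% t(p$W3) + matrix(p$b3, nrow(X), length(p$b3), byrow = TRUE)
  if (keep) list(Y = Y, A1 = A1, A2 = A2) else Y
}

# Jacobian of the stacked residual vector (output 1 rows, then output 2)
# w.r.t. the packed parameter vector; analytic backprop, fully vectorised
# over samples.
nn_jacobian <- function(p, X) {
  fw <- nn_forward(p, X, keep = TRUE)
  n <- nrow(X)
  h1 <- length(p$b1); h2 <- length(p$b2); n_out <- length(p$b3)
  d1 <- 1 - fw$A1^2
  d2 <- 1 - fw$A2^2
  blocks <- vector("list", n_out)
  for (k in seq_len(n_out)) {
    D2 <- d2 * matrix(p$W3[k, ], n, h2, byrow = TRUE)        # n x h2
    D1 <- (D2 %*% p$W2) * d1                                  # n x h1
    JW1 <- D1[, rep(seq_len(h1), times = ncol(X)), drop = FALSE] *
      X[, rep(seq_len(ncol(X)), each = h1), drop = FALSE]
    JW2 <- D2[, rep(seq_len(h2), times = h1), drop = FALSE] *
      fw$A1[, rep(seq_len(h1), each = h2), drop = FALSE]
    JW3 <- matrix(0, n, n_out * h2)
    JW3[, seq(k, by = n_out, length.out = h2)] <- fw$A2
    Jb3 <- matrix(0, n, n_out)
    Jb3[, k] <- 1
    blocks[[k]] <- cbind(JW1, D1, JW2, D2, JW3, Jb3)
  }
  list(J = do.call(rbind, blocks), Y = fw$Y)
}

#' Initialise the shallow prediction network
#'
#' Creates an untrained 2 -> 10 -> 8 -> 2 feedforward network (tanh hidden
#' layers, linear output) with reproducible small random weights
#' (`N(0, 1/fan_in)`) and zero biases.  Input standardisation parameters are
#' set by [train_network_lm()].
#'
#' @param layer_sizes layer widths; input and output must be 2.
#' @param seed integer seed for the weight draw.
#' @return an object of class `pv_network`.
#' @export
init_network <- function(layer_sizes = c(2, 10, 8, 2), seed = 1) {
  if (length(layer_sizes) != 4 || layer_sizes[1] != 2 || layer_sizes[4] != 2)
    stop_invalid("layer_sizes must be c(2, h1, h2, 2)")
  params <- with_local_seed(seed, {
    draw <- function(rows, cols)
      matrix(stats::rnorm(rows * cols, sd = 1 / sqrt(cols)), rows, cols)
    list(W1 = draw(layer_sizes[2], layer_sizes[1]),
         b1 = numeric(layer_sizes[2]),
         W2 = draw(layer_sizes[3], layer_sizes[2]),
         b2 = numeric(layer_sizes[3]),
         W3 = draw(layer_sizes[4], layer_sizes[3]),
         b3 = numeric(layer_sizes[4]))
  })
  structure(list(layer_sizes = layer_sizes, params = params,
                 center = c(0, 0), scale = c(1, 1),
                 history = NULL, best_epoch = NA_integer_,
                 trained = FALSE, seed = seed),
            class = "pv_network")
}

#' Train the network with Levenberg-Marquardt and early stopping
#'
#' Minimises the mean squared prediction error
#' `mean(0.5 * (dC0^2 + dC45^2))` on the training rows by damped
#' Gauss-Newton (Levenberg-Marquardt) steps over the full parameter vector.
#' Each epoch solves `(J'J + lambda diag(J'J)) delta = -J'r`; a step is
#' accepted only if it decreases the training objective (so the training
#' objective is non-increasing over accepted steps), after which `lambda` is
#' divided by `lambda_factor`; rejected proposals multiply `lambda` by
#' `lambda_factor` and retry.  The per-epoch objective on the training,
#' validation and test rows is recorded, training stops when the validation
#' objective has not improved for `patience` consecutive epochs (or at
#' `max_epochs`, or when no damped step is acceptable), and the returned
#' network carries the weights of the epoch with the minimal validation
#' objective.
#'
#' @param net a `pv_network` from [init_network()].
#' @param x n x 2 matrix of inputs (C0, C45), right-eye orientation.
#' @param y n x 2 matrix of targets (C0, C45).
#' @param split list with integer indices `train`, `val`, `test` (see
#'   [split_dataset()]); `val`/`test` may be empty, in which case the
#'   training rows stand in for early stopping.
#' @param max_epochs maximum number of accepted LM steps.
#' @param patience epochs without validation improvement before stopping.
#' @param lambda0 initial damping.
#' @param lambda_factor multiplicative damping update.
#' @param lambda_max damping above which training gives up on an epoch.
#' @return the trained `pv_network`, with `history` (data frame of per-epoch
#'   train/val/test objectives and damping) and `best_epoch`.
#' @export
train_network_lm <- function(net, x, y, split = NULL,
                             max_epochs = 1000, patience = 6,
                             lambda0 = 1e-3, lambda_factor = 10,
                             lambda_max = 1e10) {
  if (!inherits(net, "pv_network")) stop_invalid("net must be a pv_network")
  x <- as.matrix(x); y <- as.matrix(y)
  if (ncol(x) != 2 || ncol(y) != 2 || nrow(x) != nrow(y))
    stop_invalid("x and y must be n x 2 matrices")
  if (is.null(split))
    split <- list(train = seq_len(nrow(x)), val = integer(0), test = integer(0))
  tr <- split$train
  if (!length(tr)) stop_invalid("training set is empty")
  if (length(intersect(tr, split$val)) || length(intersect(tr, split$test)) ||
      length(intersect(split$val, split$test)))
    stop_invalid("train/val/test sets must be disjoint")
  va <- if (length(split$val)) split$val else tr
  te <- split$test

  net$center <- colMeans(x[tr, , drop = FALSE])
  net$scale <- apply(x[tr, , drop = FALSE], 2, stats::sd)
  net$scale[net$scale <= .Machine$double.eps] <- 1
  Z <- sweep(sweep(x, 2, net$center), 2, net$scale, "/")

  obj <- function(p, idx) {
    if (!length(idx)) return(NA_real_)
    mean_squared_pe(nn_forward(p, Z[idx, , drop = FALSE]),
                    y[idx, , drop = FALSE])
  }
  p <- net$params
  lambda <- lambda0
  hist_rows <- list()
  record <- function(epoch, lam) {
    data.frame(epoch = epoch, train = obj(p, tr), val = obj(p, va),
               test = obj(p, te), lambda = lam)
  }
  hist_rows[[1]] <- record(0, lambda)
  if (!is.finite(hist_rows[[1]]$train))
    stop_invalid("non-finite training objective at initialisation")
  best_val <- hist_rows[[1]]$val
  best_p <- p
  best_epoch <- 0
  stall <- 0

  for (epoch in seq_len(max_epochs)) {
    jb <- nn_jacobian(p, Z[tr, , drop = FALSE])
    r <- as.vector(jb$Y - y[tr, , drop = FALSE])
    g <- crossprod(jb$J, r)
    H <- crossprod(jb$J)
    dH <- pmax(diag(H), 1e-12)
    f_old <- sum(r^2)
    accepted <- FALSE
    while (lambda <= lambda_max) {
      delta <- tryCatch(solve(H + lambda * diag(dH), -g),
                        error = function(e) NULL)
      if (!is.null(delta) && all(is.finite(delta))) {
        p_try <- nn_unpack(nn_pack(p) + as.vector(delta), net$layer_sizes)
        r_try <- as.vector(nn_forward(p_try, Z[tr, , drop = FALSE]) -
                             y[tr, , drop = FALSE])
        f_try <- sum(r_try^2)
        if (is.finite(f_try) && f_try < f_old) {
          p <- p_try
          lambda <- lambda / lambda_factor
          accepted <- TRUE
          break
        }
      }
      lambda <- lambda * lambda_factor
    }
    if (!accepted) break  # no acceptable damped step left
    row <- record(epoch, lambda)
    if (!is.finite(row$train))
      stop_invalid("non-finite training objective at epoch %d", epoch)
    hist_rows[[length(hist_rows) + 1]] <- row
    if (is.finite(row$val) && row$val < best_val - 1e-12) {
      best_val <- row$val
      best_p <- p
      best_epoch <- epoch
      stall <- 0
    } else {
      stall <- stall + 1
      if (stall >= patience) break
    }
  }

  net$params <- best_p
  net$history <- do.call(rbind, hist_rows)
  net$best_epoch <- best_epoch
  net$trained <- TRUE
  net
}

#' @export
predict.pv_network <- function(object, newdata, ...) {
  x <- newdata
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (ncol(x) != 2) stop_invalid("newdata must have two columns (C0, C45)")
  Z <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
  out <- nn_forward(object$params, Z)
  colnames(out) <- c("C0", "C45")
  out
}

#' @export
print.pv_network <- function(x, ...) {
  cat(sprintf("Feedforward network %s (tanh hidden, linear output)\n",
              paste(x$layer_sizes, collapse = " -> ")))
  if (x$trained) {
    last <- x$history[nrow(x$history), ]
    at_best <- x$history[x$history$epoch == x$best_epoch, ]
    cat(sprintf("  trained %d epoch(s); best epoch %d (validation MSPE %.5f dpt^2)\n",
                max(x$history$epoch), x$best_epoch, at_best$val))
    if (is.finite(last$test))
      cat(sprintf("  test MSPE at best epoch: %.5f dpt^2\n", at_best$test))
  } else {
    cat("  untrained (seed ", x$seed, ")\n", sep = "")
  }
  invisible(x)
}

#' Performance plot of the network training run
#'
#' Mean squared prediction error per epoch on the training, validation and
#' test rows, with the best (early-stopping) epoch marked — the usual
#' training-curve diagnostic.
#'
#' @param x a trained `pv_network`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.pv_network <- function(x, ...) {
  if (!x$trained) stop_invalid("network is untrained")
  h <- x$history
  cols <- c("blue", "darkgreen", "red")
  graphics::matplot(h$epoch, cbind(h$train, h$val, h$test), type = "b",
                    pch = 1, lty = 1, col = cols, log = "y",
                    xlab = "epoch", ylab = "mean squared prediction error [dpt^2]",
                    main = "Network training performance", ...)
  graphics::abline(v = x$best_epoch, lty = 2, col = "cyan3")
  graphics::legend("topright", c("train", "validation", "test",
                                 sprintf("best epoch (%d)", x$best_epoch)),
                   col = c(cols, "cyan3"), lty = c(1, 1, 1, 2), bty = "n")
  invisible(x)
}
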