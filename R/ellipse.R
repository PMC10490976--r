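# Confidence ellipses in (C0, C45) space and double-angle plots.

#' Confidence ellipse of an astigmatism point cloud
#'
#' Summarises a cloud of (C0, C45) points by its centroid and the ellipse
#' containing a `level` fraction of a bivariate normal distribution with the
#' sample covariance: the sample covariance (n-1 denominator) is
#' eigendecomposed, and the half-axes are `sqrt(eigenvalue * q)` with `q`
#' the chi-square quantile at `level` with 2 degrees of freedom
#' (`-2 * log(1 - level)`).  With `small_sample = TRUE` the F-based factor
#' `2 (n - 1) / (n - 2) * qf(level, 2, n - 2)` is used instead, a sensitivity
#' check for small cohorts.
#'
#' @param points two-column matrix or data frame of (C0, C45) in dpt.
#' @param level coverage probability in (0, 1).
#' @param small_sample use the F-distribution scaling instead of chi-square.
#' @return an object of class `pv_ellipse` with fields `centroid`,
#'   `half_major`, `half_minor`, `orientation` (degrees of the major axis in
#'   `[0, 180)`), `area` (dpt^2), `level`, `n`, `cov`.
#' @examples
#' set.seed(1)
#' e <- confidence_ellipse(matrix(rnorm(400), ncol = 2))
#' e$area # about pi * qchisq(.9, 2) for unit covariance
#' @export
confidence_ellipse <- function(points, level = 0.90, small_sample = FALSE) {
  pts <- as.matrix(points)
  if (ncol(pts) != 2) stop_invalid("points must have two columns (C0, C45)")
  n <- nrow(pts)
  if (n < 3) stop_invalid("at least 3 points are needed for an ellipse")
  if (!is.numeric(level) || level <= 0 || level >= 1)
    stop_invalid("level must be in (0, 1)")
  centroid <- colMeans(pts)
  S <- stats::cov(pts)
  if (!all(is.finite(S)) || det(S) <= .Machine$double.eps^2)
    stop_invalid("degenerate (singular) covariance; ellipse undefined")
  eg <- eigen(S, symmetric = TRUE)
  q <- if (small_sample) {
    if (n < 4) stop_invalid("small-sample scaling needs n >= 4")
    2 * (n - 1) / (n - 2) * stats::qf(level, 2, n - 2)
  } else {
    stats::qchisq(level, df = 2)
  }
  half <- sqrt(eg$values * q)
  orient <- wrap_axis(atan2(eg$vectors[2, 1], eg$vectors[1, 1]) * 180 / pi)
  structure(list(centroid = c(C0 = unname(centroid[1]), C45 = unname(centroid[2])),
                 half_major = half[1], half_minor = half[2],
                 orientation = orient,
                 area = pi * half[1] * half[2],
                 level = level, n = n, cov = S,
                 scaling = if (small_sample) "F" else "chi-square"),
            class = "pv_ellipse")
}

#' @export
print.pv_ellipse <- function(x, digits = 4, ...) {
  cat(sprintf("%.0f%% confidence ellipse (%s scaling, n = %d)\n",
              100 * x$level, x$scaling, x$n))
  cat(sprintf("  centroid    : C0 = %s, C45 = %s dpt\n",
              format(x$centroid[["C0"]], digits = digits),
              format(x$centroid[["C45"]], digits = digits)))
  cat(sprintf("  half axes   : %s / %s dpt at %s deg\n",
              format(x$half_major, digits = digits),
              format(x$half_minor, digits = digits),
              format(x$orientation, digits = digits)))
  cat(sprintf("  area        : %s dpt^2\n", format(x$area, digits = digits)))
  invisible(x)
}

#' Outline coordinates of a fitted ellipse
#'
#' @param e a `pv_ellipse`.
#' @param n_points number of outline points.
#' @return two-column matrix of (C0, C45) outline coordinates.
#' @export
ellipse_outline <- function(e, n_points = 181) {
  th <- seq(0, 2 * pi, length.out = n_points)
  phi <- e$orientation * pi / 180
  R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
  xy <- cbind(e$half_major * cos(th), e$half_minor * sin(th)) %*% t(R)
  sweep(xy, 2, c(e$centroid[["C0"]], e$centroid[["C45"]]), `+`)
}

#' Test points for ellipse membership
#'
#' @param e a `pv_ellipse`.
#' @param points two-column matrix of (C0, C45).
#' @return logical vector: inside (or on) the ellipse.
#' @export
in_ellipse <- function(e, points) {
  pts <- as.matrix(points)
  d <- sweep(pts, 2, c(e$centroid[["C0"]], e$centroid[["C45"]]))
  q <- if (e$scaling == "F") {
    2 * (e$n - 1) / (e$n - 2) * stats::qf(e$level, 2, e$n - 2)
  } else {
    stats::qchisq(e$level, df = 2)
  }
  stats::mahalanobis(d, c(0, 0), e$cov) <= q
}

#' @export
plot.pv_ellipse <- function(x, add = TRUE, col = "black", lwd = 2, ...) {
  if (!add) double_angle_plot(list(), ...)
  graphics::lines(ellipse_outline(x), col = col, lwd = lwd)
  ctr <- c(x$centroid[["C0"]], x$centroid[["C45"]])
  graphics::points(ctr[1], ctr[2], pch = 19, col = col)
  phi <- x$orientation * pi / 180
  graphics::segments(ctr[1], ctr[2],
                     ctr[1] + x$half_major * cos(phi),
                     ctr[2] + x$half_major * sin(phi),
                     col = col, lwd = lwd)
  graphics::segments(ctr[1], ctr[2],
                     ctr[1] - x$half_minor * sin(phi),
                     ctr[2] + x$half_minor * cos(phi),
                     col = col, lwd = 1)
  invisible(x)
}

#' Double-angle plot of astigmatism vectors
#'
#' Scatter of (C0, C45) clouds with reference rings at 0.25, 0.5 and 1.0 dpt,
#' optional confidence ellipses with centroid and axis markers, and
#' with-the-rule (wtr) / against-the-rule (atr) annotations on the C0 axis.
#' If `file` is given a graphics device is opened for it (`.svg`, `.pdf` or
#' `.png` by extension) and closed on exit; otherwise the current device is
#' used.
#'
#' @param points a two-column matrix of (C0, C45), or a named list of such
#'   matrices drawn as separate groups.
#' @param ellipses a `pv_ellipse` or list of them, drawn over the points.
#' @param rings radii (dpt) of the reference rings.
#' @param file optional output path.
#' @param xlim,ylim axis limits (symmetric default from the data and rings).
#' @param cols colours per group.
#' @param main plot title.
#' @return invisibly, the list of ellipses drawn.
#' @export
double_angle_plot <- function(points, ellipses = NULL,
                              rings = c(0.25, 0.5, 1.0), file = NULL,
                              xlim = NULL, ylim = NULL, cols = NULL,
                              main = "Double-angle plot") {
  if (!is.list(points)) points <- list(points)
  points <- Filter(function(p) !is.null(p) && nrow(as.matrix(p)) > 0, points)
  if (inherits(ellipses, "pv_ellipse")) ellipses <- list(ellipses)
  if (!is.null(file)) {
    ext <- tolower(tools::file_ext(file))
    switch(ext,
           svg = grDevices::svg(file, width = 7, height = 7),
           pdf = grDevices::pdf(file, width = 7, height = 7),
           png = grDevices::png(file, width = 700, height = 700),
           stop_invalid("unsupported plot format: .%s", ext))
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  span <- max(c(rings,
                unlist(lapply(points, function(p) abs(as.matrix(p)))),
                unlist(lapply(ellipses, function(e)
                  abs(c(e$centroid)) + e$half_major))), na.rm = TRUE)
  span <- 1.1 * span
  if (is.null(xlim)) xlim <- c(-span, span)
  if (is.null(ylim)) ylim <- c(-span, span)
  graphics::plot(NA, xlim = xlim, ylim = ylim, asp = 1,
                 xlab = "C0 [dpt]", ylab = "C45 [dpt]", main = main)
  graphics::abline(h = 0, v = 0, col = "grey80")
  th <- seq(0, 2 * pi, length.out = 181)
  for (r in rings) {
    graphics::lines(r * cos(th), r * sin(th), col = "goldenrod", lty = 2)
    graphics::text(0, r, sprintf("%.2g dpt", r), col = "goldenrod",
                   cex = 0.7, pos = 3)
  }
  graphics::mtext("atr", side = 1, adj = 0.02, line = -1.5, col = "grey40")
  graphics::mtext("wtr", side = 1, adj = 0.98, line = -1.5, col = "grey40")
  if (is.null(cols)) cols <- grDevices::hcl.colors(max(1, length(points)), "Dark 3")
  for (i in seq_along(points))
    graphics::points(as.matrix(points[[i]]), col = cols[(i - 1) %% length(cols) + 1],
                     pch = 1, cex = 0.7)
  if (length(points) > 1 && !is.null(names(points)))
    graphics::legend("topleft", legend = names(points),
                     col = cols[seq_along(points)], pch = 1, bty = "n", cex = 0.8)
  for (i in seq_along(ellipses)) {
    plot(ellipses[[i]], add = TRUE,
         col = cols[(i - 1) %% length(cols) + 1])
  }
  if (length(ellipses))
    graphics::legend("bottomleft", bty = "n", cex = 0.7,
                     legend = vapply(ellipses, function(e)
                       sprintf("%.0f%% ellipse area %.3f dpt^2",
                               100 * e$level, e$area), character(1)))
  invisible(ellipses)
}
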