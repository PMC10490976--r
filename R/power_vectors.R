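# Meridional notation <-> power vector components.
#
# A power vector is the triple (EQ, C0, C45): equivalent (mean) power and the
# two double-angle projections of the astigmatism onto the 0/90 and 45/135
# degree meridians, all in dioptres.  Unlike the clinical sphere/cylinder/axis
# notation, power vectors add and subtract componentwise, which is what makes
# device comparisons and surgically induced astigmatism well defined.

#' Refractive index steps for corneal surfaces
#'
#' Named presets for the refractive index difference `n2 - n1` across a
#' corneal interface, used to convert radii of curvature into dioptric power.
#' The front (1.376 - 1.000) and back (1.336 - 1.376) steps follow the
#' Liou-Brennan schematic model eye; the keratometric step (1.332 - 1.000)
#' is the classical Zeiss keratometer index, which folds an assumed
#' front-to-back surface ratio into a single fictitious index.
#'
#' @param surface one of `"front"`, `"back"`, `"keratometric"`, or a numeric
#'   index step passed through unchanged (must be non-zero).
#' @return the dimensionless index step `n2 - n1`.
#' @examples
#' refractive_step("front")        # 0.376
#' refractive_step("back")         # -0.040
#' refractive_step("keratometric") # 0.332
#' @export
refractive_step <- function(surface = c("front", "back", "keratometric")) {
  if (is.numeric(surface)) {
    if (length(surface) != 1 || !is.finite(surface) || surface == 0)
      stop_invalid("a numeric index step must be a single non-zero value")
    return(surface)
  }
  surface <- match.arg(surface)
  c(front = 0.376, back = -0.040, keratometric = 0.332)[[surface]]
}

#' Construct a power-vector matrix
#'
#' Power vectors are represented throughout the package as numeric matrices
#' with one row per eye/measurement and columns `EQ`, `C0`, `C45` (dioptres).
#'
#' @param EQ equivalent power (dpt), or an n x 3 matrix/data frame holding all
#'   three components.
#' @param C0,C45 astigmatism projections onto the 0/90 and 45/135 degree
#'   meridians (dpt); recycled against `EQ`.
#' @return an n x 3 numeric matrix with columns `EQ`, `C0`, `C45`.
#' @export
power_vector <- function(EQ, C0 = NULL, C45 = NULL) {
  if (is.null(C0) && is.null(C45)) {
    m <- as.matrix(EQ)
    if (ncol(m) != 3) stop_invalid("expected 3 columns (EQ, C0, C45)")
    colnames(m) <- c("EQ", "C0", "C45")
    storage.mode(m) <- "double"
    return(m)
  }
  n <- max(length(EQ), length(C0), length(C45))
  cbind(EQ = rep_len(as.numeric(EQ), n),
        C0 = rep_len(as.numeric(C0), n),
        C45 = rep_len(as.numeric(C45), n))
}

as_pv <- function(v) {
  if (is.null(dim(v))) v <- matrix(v, nrow = 1)
  v <- as.matrix(v)
  if (ncol(v) != 3) stop_invalid("power vectors have 3 components (EQ, C0, C45)")
  colnames(v) <- c("EQ", "C0", "C45")
  storage.mode(v) <- "double"
  v
}

#' Paraxial power of a single meridian from its radius of curvature
#'
#' `P = 1000 * (n2 - n1) / R` with `R` in millimetres and `P` in dioptres.
#'
#' @param R radius of curvature in mm (vectorised); must be positive.
#' @param media index step: a preset name for [refractive_step()] or a numeric
#'   `n2 - n1`.
#' @return meridional power in dioptres.
#' @examples
#' power_from_radius(7.77, "front") # 48.3912...
#' power_from_radius(6.4, "back")   # -6.25
#' @export
power_from_radius <- function(R, media = "front") {
  dn <- refractive_step(media)
  if (!is.numeric(R) || any(!is.finite(R)) || any(R <= 0))
    stop_invalid("radius must be a positive finite number (mm)")
  1000 * dn / R
}

#' Decompose corneal surface radii into power vector components
#'
#' Converts a surface measured as flat/steep meridional radii with the flat
#' axis into (EQ, C0, C45).  The equivalent power is
#' `EQ = 500 * dn * (1/R_steep + 1/R_flat)` and the cylinder
#' `Cyl = 1000 * dn * (1/R_steep - 1/R_flat)` is projected at twice the flat
#' axis: `C0 = Cyl * cos(2A)`, `C45 = Cyl * sin(2A)`.
#'
#' If a record arrives with `r_flat < r_steep` the meridians are swapped and
#' the stored axis rotated by 90 degrees (with a warning) rather than
#' rejected, so that `r_flat >= r_steep` always holds internally.
#'
#' @param r_flat,r_steep radii of the flat and steep meridian in mm
#'   (vectorised).
#' @param axis_flat axis of the flat meridian in degrees (taken modulo 180).
#' @param media index step (preset name or numeric `n2 - n1`).
#' @param axis_steep optional steep axis; when supplied it must be
#'   perpendicular to `axis_flat` (within `tol` degrees, modulo 180).
#' @param tol perpendicularity tolerance in degrees.
#' @return power-vector matrix (one row per input element).
#' @examples
#' radii_to_power_vector(7.82, 0, 7.72, "front") # 0.6228 dpt, all in C0
#' @export
radii_to_power_vector <- function(r_flat, axis_flat, r_steep,
                                  media = "front", axis_steep = NULL,
                                  tol = 0.5) {
  dn <- refractive_step(media)
  check_numeric(r_flat, "r_flat"); check_numeric(r_steep, "r_steep")
  check_numeric(axis_flat, "axis_flat")
  if (any(r_flat <= 0) || any(r_steep <= 0))
    stop_invalid("radii must be positive (mm)")
  n <- max(length(r_flat), length(r_steep), length(axis_flat))
  r_flat <- rep_len(r_flat, n); r_steep <- rep_len(r_steep, n)
  axis_flat <- rep_len(wrap_axis(axis_flat), n)
  if (!is.null(axis_steep)) {
    d <- abs(wrap_axis(axis_steep) - axis_flat) %% 180
    if (any(pmin(abs(d - 90), abs(d - 90 + 180), abs(d - 90 - 180)) > tol))
      stop_invalid("flat and steep meridians must be perpendicular")
  }
  swap <- r_flat < r_steep
  if (any(swap)) {
    warning("flat/steep meridians mislabelled for ", sum(swap),
            " record(s); swapped and axis rotated by 90 degrees")
    tmp <- r_flat[swap]
    r_flat[swap] <- r_steep[swap]
    r_steep[swap] <- tmp
    axis_flat[swap] <- wrap_axis(axis_flat[swap] + 90)
  }
  EQ <- 500 * dn * (1 / r_steep + 1 / r_flat)
  cyl <- 1000 * dn * (1 / r_steep - 1 / r_flat)
  a2 <- 2 * axis_flat * pi / 180
  power_vector(EQ, cyl * cos(a2), cyl * sin(a2))
}

#' Decompose meridional powers into power vector components
#'
#' For measurements already expressed in dioptres per meridian (tomographic
#' "real power", thin-lens IOL meridians): `EQ = (P_flat + P_steep)/2`, and
#' the cylinder `P_steep - P_flat` is projected at twice the flat axis.
#' Records with `p_flat > p_steep` are normalised by swapping the meridians
#' and rotating the axis by 90 degrees, with a warning.
#'
#' @param p_flat,p_steep meridional powers in dpt (vectorised).
#' @param axis_flat axis of the flat (lower-power) meridian in degrees.
#' @return power-vector matrix.
#' @examples
#' powers_to_power_vector(42, 90, 44) # EQ 43, C0 -2 (against the rule)
#' @export
powers_to_power_vector <- function(p_flat, axis_flat, p_steep) {
  check_numeric(p_flat, "p_flat"); check_numeric(p_steep, "p_steep")
  check_numeric(axis_flat, "axis_flat")
  n <- max(length(p_flat), length(p_steep), length(axis_flat))
  p_flat <- rep_len(p_flat, n); p_steep <- rep_len(p_steep, n)
  axis_flat <- rep_len(wrap_axis(axis_flat), n)
  swap <- p_flat > p_steep
  if (any(swap)) {
    warning("flat/steep powers mislabelled for ", sum(swap),
            " record(s); swapped and axis rotated by 90 degrees")
    tmp <- p_flat[swap]
    p_flat[swap] <- p_steep[swap]
    p_steep[swap] <- tmp
    axis_flat[swap] <- wrap_axis(axis_flat[swap] + 90)
  }
  a2 <- 2 * axis_flat * pi / 180
  cyl <- p_steep - p_flat
  power_vector(0.5 * (p_flat + p_steep), cyl * cos(a2), cyl * sin(a2))
}

#' Spectacle refraction to power vector
#'
#' A refraction `sphere / cylinder x axis` is the pair of meridional powers
#' `sphere` at `axis` and `sphere + cylinder` at `axis + 90`; the result is
#' invariant under cylinder transposition.
#'
#' @param sphere,cylinder refraction in dpt (vectorised).
#' @param axis cylinder axis in degrees.
#' @return power-vector matrix.
#' @export
refraction_to_power_vector <- function(sphere, cylinder, axis) {
  check_numeric(sphere, "sphere"); check_numeric(cylinder, "cylinder")
  check_numeric(axis, "axis")
  n <- max(length(sphere), length(cylinder), length(axis))
  sphere <- rep_len(sphere, n); cylinder <- rep_len(cylinder, n)
  axis <- rep_len(wrap_axis(axis), n)
  p1 <- sphere
  p2 <- sphere + cylinder
  # orient so the stored flat meridian really is the lower-power one
  a1 <- ifelse(p1 <= p2, axis, wrap_axis(axis + 90))
  suppressWarnings(powers_to_power_vector(pmin(p1, p2), a1, pmax(p1, p2)))
}

#' Toric IOL label data to power vector
#'
#' The thin-lens model of a toric IOL with equivalent power `IOLP`, toricity
#' `IOLT` and axis `IOLA` has meridional powers `IOLP - IOLT/2` at `IOLA` and
#' `IOLP + IOLT/2` at `IOLA + 90`.
#'
#' @param power_eq labelled equivalent power IOLP in dpt.
#' @param toricity labelled cylinder IOLT in dpt, must be `>= 0`.
#' @param axis orientation IOLA of the flat meridian in degrees.
#' @return power-vector matrix.
#' @export
tiol_to_power_vector <- function(power_eq, toricity, axis) {
  check_numeric(toricity, "toricity")
  if (any(toricity < 0)) stop_invalid("IOL toricity must be >= 0")
  powers_to_power_vector(power_eq - 0.5 * toricity, axis,
                         power_eq + 0.5 * toricity)
}

#' Mirror power vectors for left eyes
#'
#' Left and right eyes are pooled under a mirror-symmetry assumption: the
#' oblique component C45 is reversed in sign for left (OS) eyes so that all
#' eyes are presented in right-eye orientation.  The operation is an
#' involution and leaves EQ, C0 and the cylinder magnitude unchanged.
#'
#' @param v power-vector matrix (or length-3 vector).
#' @return matrix with `C45` negated.
#' @export
mirror_for_left_eye <- function(v) {
  v <- as_pv(v)
  v[, "C45"] <- -v[, "C45"]
  v
}

#' Power-vector arithmetic
#'
#' Componentwise sum and difference; this is what makes the representation
#' useful for device comparisons and surgically induced astigmatism.
#'
#' @param a,b power-vector matrices of equal shape.
#' @return power-vector matrix.
#' @export
pv_add <- function(a, b) {
  a <- as_pv(a); b <- as_pv(b)
  if (!all(dim(a) == dim(b))) stop_invalid("power-vector shapes differ")
  a + b
}

#' @rdname pv_add
#' @export
pv_subtract <- function(a, b) {
  a <- as_pv(a); b <- as_pv(b)
  if (!all(dim(a) == dim(b))) stop_invalid("power-vector shapes differ")
  a - b
}

#' Convert power vectors back to flat/steep meridional notation
#'
#' Inverse of [powers_to_power_vector()]: the cylinder magnitude is
#' `sqrt(C0^2 + C45^2)`, the flat axis `atan2(C45, C0)/2` mapped into
#' `[0, 180)`, and the meridional powers `EQ -/+ cylinder/2`.  A zero
#' cylinder returns axis 0 by convention and sets `axis_undefined`.
#'
#' @param v power-vector matrix.
#' @return data frame with columns `p_flat`, `axis_flat`, `p_steep`,
#'   `cylinder`, `axis_undefined`.
#' @export
power_vector_to_polar <- function(v) {
  v <- as_pv(v)
  cyl <- sqrt(v[, "C0"]^2 + v[, "C45"]^2)
  ax <- wrap_axis(0.5 * atan2(v[, "C45"], v[, "C0"]) * 180 / pi)
  undef <- cyl == 0
  ax[undef] <- 0
  data.frame(p_flat = v[, "EQ"] - cyl / 2,
             axis_flat = ax,
             p_steep = v[, "EQ"] + cyl / 2,
             cylinder = cyl,
             axis_undefined = undef)
}
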