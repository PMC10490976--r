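test_that("single-meridian power follows the schematic model eye", {
  expect_equal(power_from_radius(7.77, "front"), 1000 * 0.376 / 7.77)
  expect_equal(round(power_from_radius(7.77, "front"), 4), 48.3912)
  expect_equal(power_from_radius(6.4, "back"), -6.25)
  expect_equal(power_from_radius(8.3, "keratometric"), 40.0)
  expect_error(power_from_radius(-1, "front"), "positive")
  expect_error(power_from_radius(0, 0.376), "positive")
  expect_error(power_from_radius(7.7, 0), "non-zero")
})

test_that("surface radii decompose with the mm-to-dioptre cylinder factor", {
  v <- radii_to_power_vector(7.82, 0, 7.72, "front")
  expect_equal(round(sqrt(v[, "C0"]^2 + v[, "C45"]^2), 4), c(C0 = 0.6228),
               ignore_attr = TRUE)
  expect_equal(v[, "C45"], c(C45 = 0))
  expect_gt(v[, "C0"], 0)

  # back surface scaled by the fixed front/back ratio is perpendicular
  rb <- c(7.82, 7.72) / (7.77 / 6.4)
  b <- radii_to_power_vector(rb[1], 0, rb[2], "back")
  expect_equal(round(abs(b[, "C0"]), 4), c(C0 = 0.0804), ignore_attr = TRUE)
  expect_lt(b[, "C0"] * v[, "C0"], 0)

  # equal radii: pure equivalent power, any axis
  z <- radii_to_power_vector(7.77, 123, 7.77, "front")
  expect_equal(z, power_vector(power_from_radius(7.77, "front"), 0, 0))

  # oblique flat axis rotates the astigmatism into C45
  o <- radii_to_power_vector(7.82, 45, 7.72, "front")
  expect_equal(o[, "C0"], c(C0 = 0), tolerance = 1e-12)
  expect_equal(round(o[, "C45"], 4), c(C45 = 0.6228), ignore_attr = TRUE)
})

test_that("mislabelled flat/steep meridians are normalised with a warning", {
  expect_warning(sw <- radii_to_power_vector(7.72, 90, 7.82, "front"),
                 "mislabelled")
  expect_equal(sw, radii_to_power_vector(7.82, 0, 7.72, "front"))
  expect_error(radii_to_power_vector(7.82, 0, 7.72, "front", axis_steep = 45),
               "perpendicular")
  expect_silent(radii_to_power_vector(7.82, 10, 7.72, "front", axis_steep = 100))
})

test_that("meridional powers decompose with the double-angle convention", {
  expect_equal(powers_to_power_vector(42, 90, 44), power_vector(43, -2, 0),
               tolerance = 1e-12)
  expect_equal(powers_to_power_vector(43, 10, 43), power_vector(43, 0, 0),
               tolerance = 1e-12)
  expect_equal(powers_to_power_vector(18.5, 0, 21.5), power_vector(20, 3, 0))
})

test_that("refraction decomposition is transposition-invariant", {
  expect_equal(refraction_to_power_vector(0, 0, 37), power_vector(0, 0, 0))
  expect_equal(refraction_to_power_vector(-1, 2, 0), power_vector(0, 2, 0),
               tolerance = 1e-12)
  expect_equal(refraction_to_power_vector(1, -2, 90), power_vector(0, 2, 0),
               tolerance = 1e-12)
})

test_that("thin-lens toric IOL splits into meridians at the label axis", {
  expect_equal(tiol_to_power_vector(20, 3, 0), power_vector(20, 3, 0))
  expect_equal(tiol_to_power_vector(20, 0, 77), power_vector(20, 0, 0))
  expect_equal(tiol_to_power_vector(20, 3, 45), power_vector(20, 0, 3),
               tolerance = 1e-12)
  expect_error(tiol_to_power_vector(20, -1, 0), "toricity")
})

test_that("left-eye mirroring is an involution preserving EQ, C0 and cylinder", {
  v <- power_vector(43, 1.0, 0.5)
  m <- mirror_for_left_eye(v)
  expect_equal(m, power_vector(43, 1.0, -0.5))
  expect_equal(mirror_for_left_eye(m), v)
  expect_equal(mirror_for_left_eye(power_vector(43, 1, 0)),
               power_vector(43, 1, 0))
  expect_equal(sqrt(rowSums(m[, c("C0", "C45"), drop = FALSE]^2)),
               sqrt(rowSums(v[, c("C0", "C45"), drop = FALSE]^2)))
})

test_that("power vectors add and subtract componentwise", {
  a <- power_vector(48, 1, 0)
  b <- power_vector(47.5, 0.8, -0.1)
  expect_equal(pv_subtract(a, a), power_vector(0, 0, 0))
  expect_equal(pv_subtract(a, b), power_vector(0.5, 0.2, 0.1))
  expect_equal(pv_add(pv_subtract(a, b), b), a)
  expect_error(pv_add(a, power_vector(1:2, 0, 0)), "shapes")
})

test_that("polar conversion round-trips and respects conventions", {
  p <- power_vector_to_polar(power_vector(43, -2, 0))
  expect_equal(p$p_flat, 42)
  expect_equal(p$p_steep, 44)
  expect_equal(p$axis_flat, 90)
  z <- power_vector_to_polar(power_vector(43, 0, 0))
  expect_equal(z$axis_flat, 0)
  expect_true(z$axis_undefined)

  set.seed(31)
  v <- power_vector(rnorm(1000, 43, 2), rnorm(1000, 0, 1.5), rnorm(1000, 0, 1))
  pol <- power_vector_to_polar(v)
  back <- powers_to_power_vector(pol$p_flat, pol$axis_flat, pol$p_steep)
  expect_equal(back, v, tolerance = 1e-9)
})

test_that("decomposition is invariant under axis shifts and transposition", {
  set.seed(8)
  for (i in 1:20) {
    rf <- runif(1, 7.5, 8.2); rs <- rf - runif(1, 0.01, 0.4)
    ax <- runif(1, 0, 180)
    a <- radii_to_power_vector(rf, ax, rs, "front")
    expect_equal(radii_to_power_vector(rf, ax + 180, rs, "front"), a,
                 tolerance = 1e-12)
    p1 <- runif(1, 41, 43); p2 <- p1 + runif(1, 0, 3)
    expect_equal(powers_to_power_vector(p1, ax, p2),
                 suppressWarnings(powers_to_power_vector(p2, ax + 90, p1)),
                 tolerance = 1e-12)
  }
})
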