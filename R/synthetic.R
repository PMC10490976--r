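# Synthetic cohort generator.
#
# Emulates the per-eye CSV of a toric-IOL cataract cohort measured with an
# optical biometer (IOLM, preoperative) and an anterior-segment OCT (CASIA,
# pre- and postoperative).  The ground truth is specified in power-vector
# space — Gaussian (EQ, C0, C45) components for the corneal front surface,
# a front-to-back radius-ratio model with per-meridian jitter plus an extra
# against-the-rule offset for the back surface — and converted to raw
# meridional radii/axes by inverting the decomposition, so that
# decompose_cohort() recovers the configured truth exactly when noise and
# bias are zero.  Device readings are truth plus configurable bias and
# noise; the postoperative truth is the preoperative truth plus a surgically
# induced change; and the postoperative real-power astigmatism can follow a
# configurable linear "teacher" of the preoperative keratometry, which makes
# regression/network recovery tests exact.

# Published cohort summary constants used for the default configuration.
.syn_front_pre <- list(mean = c(EQ = 48.6658, C0 = 0.8114, C45 = 0.0318),
                       sd = c(EQ = 1.7558, C0 = 1.5887, C45 = 0.8311))
.syn_diff_post_iolm <- list(front = list(mean = c(0.1343, -0.0495, -0.0277),
                                         sd = c(0.3062, 0.5316, 0.4777)),
                            back = list(mean = c(-0.3582, 0.0136, 0.0269),
                                        sd = c(0.0718, 0.0920, 0.0920)))
.syn_diff_post_pre <- list(front = list(mean = c(-0.0297, -0.0049, -0.0594),
                                        sd = c(0.2341, 0.3949, 0.3180)),
                           back = list(mean = c(0.0422, 0.0032, 0.0111),
                                       sd = c(0.0678, 0.0672, 0.0712)))
.syn_biometry <- list(AL = c(24.1154, 1.6258), CCT = c(0.5574, 0.0368),
                      ACD = c(3.1882, 0.3936), LT = c(4.6684, 0.5250))

#' Configuration of the synthetic cohort generator
#'
#' Returns the generator configuration with defaults reproducing the
#' marginal statistics of a published toric-IOL cataract cohort: N = 88
#' eyes (39 left), front-surface power-vector distribution from the
#' preoperative OCT marginals, a front-to-back radius ratio of 1.1939
#' (so the mean front/back EQ ratio is about -7.87) with 1.2% per-meridian
#' jitter and an extra -0.20 dpt against-the-rule back-surface C0 offset,
#' device biases and noise levels derived from the published
#' device-difference means/SDs, and a linear teacher (the published OD
#' IOLM-based regression coefficients, residual SD 0.3 dpt) linking
#' preoperative keratometry to the postoperative real-power astigmatism.
#'
#' @param n_eyes number of eyes.
#' @param seed integer seed; the whole cohort is a deterministic function of
#'   the configuration.
#' @param left_eye_fraction fraction of OS eyes.
#' @param teacher `NULL` (postoperative real power = sum of the measured
#'   postoperative surfaces) or a list with `matrix` (2 x 2), `intercept`
#'   (length 2), `residual_sd` (dpt) and `source` (`"IOLM"` or
#'   `"CASIA_pre"`), applied in right-eye orientation.
#' @param rates list of quality-issue rates in `[0, 1]`:
#'   `warning`, `failed`, `missing`, `mydriasis`, `pupil_change`.
#' @param ... overrides for any other configuration element (see the
#'   returned list).
#' @return a list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_eyes = 88, seed = 1,
                             left_eye_fraction = 39 / 88,
                             teacher = list(
                               matrix = matrix(c(0.9150, -0.0018,
                                                 -0.0472, 0.6952), 2, 2),
                               intercept = c(-0.1823, -0.0229),
                               residual_sd = 0.3,
                               source = "IOLM"),
                             rates = list(warning = 0, failed = 0, missing = 0,
                                          mydriasis = 0, pupil_change = 0),
                             ...) {
  # split the published difference SDs into device noise and surgical change:
  # var(post - pre) = var(sia) + 2 var(casia); sia gets half the variance,
  # each CASIA reading a quarter; IOLM noise absorbs the rest of
  # var(post - IOLM).
  casia_noise <- lapply(.syn_diff_post_pre, function(l) l$sd / 2)
  sia_sd <- lapply(.syn_diff_post_pre, function(l) l$sd / sqrt(2))
  iolm_noise <- lapply(names(.syn_diff_post_iolm), function(layer) {
    v <- .syn_diff_post_iolm[[layer]]$sd^2 - 0.75 * .syn_diff_post_pre[[layer]]$sd^2
    sqrt(pmax(v, 1e-6))
  })
  names(iolm_noise) <- names(.syn_diff_post_iolm)
  iolm_bias <- lapply(names(.syn_diff_post_iolm), function(layer)
    .syn_diff_post_pre[[layer]]$mean - .syn_diff_post_iolm[[layer]]$mean)
  names(iolm_bias) <- names(.syn_diff_post_iolm)

  cfg <- list(
    n_eyes = n_eyes, seed = seed, left_eye_fraction = left_eye_fraction,
    age_mean = 74, age_sd = 8,
    biometry = .syn_biometry,
    front_mean = .syn_front_pre$mean, front_sd = .syn_front_pre$sd,
    ratio_mean = 1.1939, ratio_sd = 0.03, back_jitter_sd = 0.012,
    back_extra = c(EQ = 0, C0 = -0.20, C45 = 0),
    sia_bias = list(front = .syn_diff_post_pre$front$mean,
                    back = .syn_diff_post_pre$back$mean),
    sia_sd = sia_sd,
    bias = list(IOLM = iolm_bias,
                CASIA = list(front = c(0, 0, 0), back = c(0, 0, 0))),
    noise = list(IOLM = iolm_noise, CASIA = casia_noise),
    total_offset = list(IOLM = c(0.1143, 0, 0), CASIA = c(0.2018, 0, 0)),
    pupil_mean = 4.3, pupil_sd = 0.4, pupil_change_sd = 0.2,
    teacher = teacher, rates = rates)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop_invalid("unknown configuration element(s): %s",
                 paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  if (any(unlist(cfg$rates) < 0 | unlist(cfg$rates) > 1))
    stop_invalid("issue rates must lie in [0, 1]")
  structure(cfg, class = "synthetic_config")
}

# order-agnostic meridional pair -> power vector (no flat/steep policing)
pv_from_meridians <- function(p1, a1, p2) {
  a2 <- 2 * a1 * pi / 180
  power_vector(0.5 * (p1 + p2), (p2 - p1) * cos(a2), (p2 - p1) * sin(a2))
}

# power vector -> meridional radii, R1 = flat (larger radius) with its axis
pv_to_radii <- function(pv, dn) {
  pol <- power_vector_to_polar(pv)
  pa <- pol$p_flat; pb <- pol$p_steep
  if (any(sign(pa) != sign(dn)) || any(sign(pb) != sign(dn)))
    stop_invalid("meridional power has the wrong sign for this surface")
  ra <- 1000 * dn / pa
  rb <- 1000 * dn / pb
  aa <- pol$axis_flat
  ab <- wrap_axis(pol$axis_flat + 90)
  flat_first <- ra >= rb
  data.frame(R1 = ifelse(flat_first, ra, rb),
             A1 = ifelse(flat_first, aa, ab),
             R2 = ifelse(flat_first, rb, ra),
             A2 = ifelse(flat_first, ab, aa))
}

# draw all per-eye quantities for m eyes; everything in right-eye orientation
syn_draw <- function(cfg, m) {
  draw_pv <- function(mean, sd)
    power_vector(stats::rnorm(m, mean[1], sd[1]),
                 stats::rnorm(m, mean[2], sd[2]),
                 stats::rnorm(m, mean[3], sd[3]))
  front_pre <- draw_pv(cfg$front_mean, cfg$front_sd)
  pol <- power_vector_to_polar(front_pre)
  rf_flat <- 376 / pol$p_flat
  rf_steep <- 376 / pol$p_steep
  rho <- stats::rnorm(m, cfg$ratio_mean, cfg$ratio_sd)
  rb_flat <- rf_flat / rho * exp(stats::rnorm(m, 0, cfg$back_jitter_sd))
  rb_steep <- rf_steep / rho * exp(stats::rnorm(m, 0, cfg$back_jitter_sd))
  back_pre <- pv_from_meridians(-40 / rb_flat, pol$axis_flat, -40 / rb_steep) +
    matrix(cfg$back_extra, m, 3, byrow = TRUE)

  sia <- function(layer)
    power_vector(stats::rnorm(m, cfg$sia_bias[[layer]][1], cfg$sia_sd[[layer]][1]),
                 stats::rnorm(m, cfg$sia_bias[[layer]][2], cfg$sia_sd[[layer]][2]),
                 stats::rnorm(m, cfg$sia_bias[[layer]][3], cfg$sia_sd[[layer]][3]))
  front_post <- front_pre + sia("front")
  back_post <- back_pre + sia("back")

  noise <- function(device, layer)
    power_vector(stats::rnorm(m, 0, cfg$noise[[device]][[layer]][1]),
                 stats::rnorm(m, 0, cfg$noise[[device]][[layer]][2]),
                 stats::rnorm(m, 0, cfg$noise[[device]][[layer]][3]))
  bias_row <- function(device, layer)
    matrix(cfg$bias[[device]][[layer]], m, 3, byrow = TRUE)

  meas <- list(
    IOLM_front = front_pre + bias_row("IOLM", "front") + noise("IOLM", "front"),
    IOLM_back = back_pre + bias_row("IOLM", "back") + noise("IOLM", "back"),
    CASIA_pre_front = front_pre + bias_row("CASIA", "front") + noise("CASIA", "front"),
    CASIA_pre_back = back_pre + bias_row("CASIA", "back") + noise("CASIA", "back"),
    CASIA_post_front = front_post + bias_row("CASIA", "front") + noise("CASIA", "front"),
    CASIA_post_back = back_post + bias_row("CASIA", "back") + noise("CASIA", "back"))

  off <- function(dev) matrix(cfg$total_offset[[dev]], m, 3, byrow = TRUE)
  meas$IOLM_total <- meas$IOLM_front + meas$IOLM_back + off("IOLM")
  meas$CASIA_pre_total <- meas$CASIA_pre_front + meas$CASIA_pre_back + off("CASIA")
  real_post <- meas$CASIA_post_front + meas$CASIA_post_back + off("CASIA")
  teacher_x <- NULL
  if (!is.null(cfg$teacher)) {
    src <- if (identical(cfg$teacher$source, "CASIA_pre"))
      meas$CASIA_pre_front else meas$IOLM_front
    teacher_x <- src[, c("C0", "C45"), drop = FALSE] * (0.332 / 0.376)
    pred <- teacher_x %*% t(cfg$teacher$matrix) +
      matrix(cfg$teacher$intercept, m, 2, byrow = TRUE)
    real_post[, "C0"] <- pred[, 1] + stats::rnorm(m, 0, cfg$teacher$residual_sd)
    real_post[, "C45"] <- pred[, 2] + stats::rnorm(m, 0, cfg$teacher$residual_sd)
  }
  meas$CASIA_post_total <- real_post

  list(front_pre = front_pre, back_pre = back_pre,
       front_post = front_post, back_post = back_post,
       meas = meas, teacher_x = teacher_x,
       age = stats::rnorm(m, cfg$age_mean, cfg$age_sd),
       AL = stats::rnorm(m, cfg$biometry$AL[1], cfg$biometry$AL[2]),
       CCT = stats::rnorm(m, cfg$biometry$CCT[1], cfg$biometry$CCT[2]),
       ACD = stats::rnorm(m, cfg$biometry$ACD[1], cfg$biometry$ACD[2]),
       LT = stats::rnorm(m, cfg$biometry$LT[1], cfg$biometry$LT[2]),
       pupil_pre = stats::rnorm(m, cfg$pupil_mean, cfg$pupil_sd),
       pupil_change = stats::rnorm(m, 0, cfg$pupil_change_sd))
}

syn_feasible <- function(d) {
  ok <- rep(TRUE, nrow(d$front_pre))
  for (nm in names(d$meas)) {
    pv <- d$meas[[nm]]
    pol <- power_vector_to_polar(pv)
    if (grepl("back", nm)) ok <- ok & pol$p_flat < -0.5 & pol$p_steep < -0.5
    else ok <- ok & pol$p_flat > 0.5
  }
  ok & d$pupil_pre > 1.5
}

syn_replace <- function(d, idx, repl) {
  for (nm in c("front_pre", "back_pre", "front_post", "back_post", "teacher_x"))
    if (!is.null(d[[nm]])) d[[nm]][idx, ] <- repl[[nm]]
  for (nm in names(d$meas)) d$meas[[nm]][idx, ] <- repl$meas[[nm]]
  for (nm in c("age", "AL", "CCT", "ACD", "LT", "pupil_pre", "pupil_change"))
    d[[nm]][idx] <- repl[[nm]]
  d
}

#' Generate a synthetic cohort
#'
#' Draws a full per-eye cohort in the canonical CSV schema (see
#' [cohort_columns()]) under the configured ground-truth model, together
#' with a sidecar of the underlying truth for recovery tests.  Left eyes
#' are generated with the mirrored (anatomic) C45 orientation in the raw
#' columns, so that [decompose_cohort()]'s mirroring restores the right-eye
#' oriented truth.  Radii that would be geometrically infeasible are
#' resampled (bounded retries, with a warning).
#'
#' @param cfg a [synthetic_config()].
#' @return list with `records` (data frame in the cohort CSV schema),
#'   `truth` (per-eye ground-truth power vectors, right-eye orientation,
#'   plus teacher inputs when a teacher is configured) and `injected`
#'   (ids of records given quality issues, by issue type).
#' @examples
#' cohort <- generate_cohort(synthetic_config(n_eyes = 20, seed = 42))
#' panel <- decompose_cohort(cohort$records)
#' @export
generate_cohort <- function(cfg) {
  if (!inherits(cfg, "synthetic_config"))
    stop_invalid("cfg must come from synthetic_config()")
  n <- cfg$n_eyes
  out <- with_local_seed(cfg$seed, {
    n_left <- round(cfg$left_eye_fraction * n)
    eye <- sample(c(rep("OS", n_left), rep("OD", n - n_left)))
    d <- syn_draw(cfg, n)
    tries <- 0
    repeat {
      bad <- which(!syn_feasible(d))
      if (!length(bad)) break
      tries <- tries + 1
      if (tries > 10)
        stop_invalid("could not generate feasible radii after 10 retries")
      warning("resampling ", length(bad), " infeasible synthetic record(s)")
      d <- syn_replace(d, bad, syn_draw(cfg, length(bad)))
    }
    list(eye = eye, d = d)
  })
  eye <- out$eye
  d <- out$d
  os <- eye == "OS"

  anat <- function(pv) { pv[os, ] <- mirror_for_left_eye(pv[os, , drop = FALSE]); pv }
  records <- data.frame(patient_id = sprintf("P%04d", seq_len(n)),
                        eye = eye, age = round(d$age, 1),
                        AL = round(d$AL, 4), CCT = round(d$CCT, 4),
                        ACD = round(d$ACD, 4), LT = round(d$LT, 4),
                        pupil_pre = round(d$pupil_pre, 2),
                        pupil_post = round(d$pupil_pre + d$pupil_change, 2),
                        IOLM_quality = "Successful",
                        CASIA_pre_quality = "Successful",
                        CASIA_post_quality = "Successful",
                        stringsAsFactors = FALSE)
  # measurement columns are written at full precision so that decomposition
  # inverts the generator exactly in the zero-noise limit
  put_radii <- function(cols, pv, dn) {
    r <- pv_to_radii(anat(pv), dn)
    records[[cols[1]]] <<- r$R1; records[[cols[2]]] <<- r$A1
    records[[cols[3]]] <<- r$R2; records[[cols[4]]] <<- r$A2
  }
  put_powers <- function(cols, pv) {
    pol <- power_vector_to_polar(anat(pv))
    records[[cols[1]]] <<- pol$p_flat
    records[[cols[2]]] <<- pol$axis_flat
    records[[cols[3]]] <<- pol$p_steep
    records[[cols[4]]] <<- wrap_axis(pol$axis_flat + 90)
  }
  put_radii(iolm_surface_cols("a"), d$meas$IOLM_front, 0.376)
  put_radii(iolm_surface_cols("p"), d$meas$IOLM_back, -0.040)
  put_radii(iolm_surface_cols("t"), d$meas$IOLM_total, 0.332)
  put_radii(casia_surface_cols("a", "pre"), d$meas$CASIA_pre_front, 0.376)
  put_radii(casia_surface_cols("p", "pre"), d$meas$CASIA_pre_back, -0.040)
  put_powers(casia_real_cols("pre"), d$meas$CASIA_pre_total)
  put_radii(casia_surface_cols("a", "post"), d$meas$CASIA_post_front, 0.376)
  put_radii(casia_surface_cols("p", "post"), d$meas$CASIA_post_back, -0.040)
  put_powers(casia_real_cols("post"), d$meas$CASIA_post_total)

  # toric IOL label and postoperative refraction, derived loosely from the
  # preoperative keratometry (optional columns, not used by the predictors)
  kpol <- power_vector_to_polar(anat(d$meas$IOLM_front * (0.332 / 0.376)))
  records$IOLP <- with_local_seed(cfg$seed + 7,
                                  round(stats::rnorm(n, 21, 2.5) * 2) / 2)
  records$IOLT <- pmax(1, round(kpol$cylinder * 1.46 / 0.75) * 0.75)
  records$IOLA <- round(wrap_axis(kpol$axis_flat + 90), 0)
  records$REFS <- with_local_seed(cfg$seed + 8,
                                  round(stats::rnorm(n, -0.25, 0.4) * 4) / 4)
  records$REFC <- with_local_seed(cfg$seed + 9,
                                  -round(abs(stats::rnorm(n, 0, 0.3)) * 4) / 4)
  records$REFA <- with_local_seed(cfg$seed + 10, round(stats::runif(n, 0, 180), 0))

  truth <- data.frame(patient_id = records$patient_id, eye = eye,
                      stringsAsFactors = FALSE)
  for (nm in c("front_pre", "back_pre", "front_post", "back_post"))
    for (comp in c("EQ", "C0", "C45"))
      truth[[paste(nm, comp, sep = "_")]] <- d[[nm]][, comp]
  if (!is.null(d$teacher_x)) {
    truth$teacher_x_C0 <- d$teacher_x[, 1]
    truth$teacher_x_C45 <- d$teacher_x[, 2]
    truth$real_post_C0 <- d$meas$CASIA_post_total[, "C0"]
    truth$real_post_C45 <- d$meas$CASIA_post_total[, "C45"]
  }

  inj <- inject_quality_issues(records, cfg)
  list(records = inj$records, truth = truth, injected = inj$injected,
       config = cfg)
}

#' Inject quality issues into a cohort
#'
#' Marks configured fractions of records with "Warning"/"Failed" flags,
#' missing measurement cells, mydriatic pupils (> 5.5 mm) or large
#' pre-to-post pupil changes (> 1.5 mm), so the exclusion filter can be
#' exercised with known answers.
#'
#' @param records cohort data frame.
#' @param cfg a [synthetic_config()] whose `rates` are used.
#' @param seed seed of the injection draw (independent of the cohort draw).
#' @return list with `records` (modified) and `injected` (named list of
#'   affected `patient_id`s per issue type).
#' @export
inject_quality_issues <- function(records, cfg, seed = cfg$seed + 1) {
  rates <- cfg$rates
  n <- nrow(records)
  injected <- list(warning = character(0), failed = character(0),
                   missing = character(0), mydriasis = character(0),
                   pupil_change = character(0))
  if (all(unlist(rates) == 0) || n == 0)
    return(list(records = records, injected = injected))
  meas_cols <- cohort_columns()$measurement
  qcols <- c("IOLM_quality", "CASIA_pre_quality", "CASIA_post_quality")
  records <- with_local_seed(seed, {
    pick <- function(rate) if (rate <= 0) integer(0) else
      sort(sample.int(n, round(rate * n)))
    i <- pick(rates$warning)
    for (ix in i) records[ix, sample(qcols, 1)] <- "Warning"
    injected$warning <- records$patient_id[i]
    i <- pick(rates$failed)
    records[i, "IOLM_quality"] <- "Failed"
    injected$failed <- records$patient_id[i]
    i <- pick(rates$missing)
    for (ix in i) records[ix, sample(meas_cols, 1)] <- NA_real_
    injected$missing <- records$patient_id[i]
    i <- pick(rates$mydriasis)
    records$pupil_pre[i] <- round(5.6 + abs(stats::rnorm(length(i), 0, 0.5)), 2)
    injected$mydriasis <- records$patient_id[i]
    i <- pick(rates$pupil_change)
    records$pupil_post[i] <- round(records$pupil_pre[i] + 1.6 +
                                     abs(stats::rnorm(length(i), 0, 0.3)), 2)
    injected$pupil_change <- records$patient_id[i]
    records
  })
  list(records = records, injected = injected)
}
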