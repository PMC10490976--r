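test_that("cohort generation is deterministic under its seed", {
  cfg <- synthetic_config(n_eyes = 15, seed = 61)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$records, c2$records)
  expect_identical(c1$truth, c2$truth)
  p1 <- write_cohort_fixture(c1$records)
  p2 <- write_cohort_fixture(c2$records)
  expect_identical(readLines(p1), readLines(p2))  # byte-identical CSV
  c3 <- generate_cohort(synthetic_config(n_eyes = 15, seed = 62))
  expect_false(identical(c1$records$IOLMR1a, c3$records$IOLMR1a))
})

test_that("zero-noise cohorts decompose back to the configured truth", {
  co <- generate_cohort(zero_noise_config(n_eyes = 12, seed = 63))
  panel <- decompose_cohort(co$records)
  for (dev in c("IOLM", "CASIA_pre", "CASIA_post")) {
    for (layer in c("front", "back")) {
      truth_cols <- paste(layer, "pre", c("EQ", "C0", "C45"), sep = "_")
      got <- panel_block(panel, dev, layer)
      expect_equal(unname(got), unname(as.matrix(co$truth[, truth_cols])),
                   tolerance = 1e-9)
    }
    # composite layer is exactly the sum of the two surfaces
    expect_equal(unname(panel_block(panel, dev, "total")),
                 unname(panel_block(panel, dev, "front") +
                          panel_block(panel, dev, "back")),
                 tolerance = 1e-9)
  }
})

test_that("generated marginals match the configured distribution", {
  cfg <- synthetic_config(n_eyes = 2000, seed = 64)
  co <- generate_cohort(cfg)
  panel <- decompose_cohort(co$records)
  front <- panel_block(panel, "IOLM", "front")
  for (i in 1:3) {
    target_mean <- cfg$front_mean[i] + cfg$bias$IOLM$front[i]
    target_sd <- sqrt(cfg$front_sd[i]^2 + cfg$noise$IOLM$front[i]^2)
    expect_lt(abs(mean(front[, i]) - target_mean),
              3 * target_sd / sqrt(2000))
    expect_lt(abs(sd(front[, i]) - target_sd) / target_sd, 0.10)
  }
  # back-surface astigmatism is against the rule and exceeds the fixed-ratio
  # prediction from the front surface
  back <- panel_block(panel, "CASIA_pre", "back")
  expect_lt(mean(back[, "C0"]), -0.15)
  fixed_ratio_pred <- mean(panel_block(panel, "CASIA_pre", "front")[, "C0"]) *
    (-0.040 / 0.376) * cfg$ratio_mean
  expect_gt(abs(mean(back[, "C0"])), 2 * abs(fixed_ratio_pred))
})

test_that("the linear teacher is recovered by the regression", {
  cfg <- synthetic_config(n_eyes = 2000, seed = 65)
  co <- generate_cohort(cfg)
  panel <- decompose_cohort(co$records)
  x <- panel_block(panel, "IOLM", "keratometric", c("C0", "C45"))
  y <- panel_block(panel, "CASIA_post", "total", c("C0", "C45"))
  fit <- fit_pv_regression(x, y)
  expect_lt(max(abs(unname(fit$matrix) - unname(cfg$teacher$matrix))), 0.05)
  expect_lt(max(abs(fit$intercept - cfg$teacher$intercept)), 0.05)
})

test_that("quality issues are injected exactly and excluded exactly", {
  cfg <- synthetic_config(n_eyes = 100, seed = 66,
                          rates = list(warning = 0.10, failed = 0, missing = 0,
                                       mydriasis = 0, pupil_change = 0))
  co <- generate_cohort(cfg)
  expect_length(co$injected$warning, 10)
  res <- apply_exclusions(co$records, seed = 1)
  expect_setequal(res$excluded$patient_id, co$injected$warning)
  expect_equal(nrow(res$retained), 90)

  # rate 0 leaves records untouched
  clean <- generate_cohort(synthetic_config(n_eyes = 30, seed = 67))
  inj0 <- inject_quality_issues(clean$records, synthetic_config(n_eyes = 30, seed = 67))
  expect_identical(inj0$records, clean$records)

  # rate 1 for mydriasis removes every eye
  cfg_all <- synthetic_config(n_eyes = 20, seed = 68,
                              rates = list(warning = 0, failed = 0, missing = 0,
                                           mydriasis = 1, pupil_change = 0))
  co_all <- generate_cohort(cfg_all)
  res_all <- apply_exclusions(co_all$records, seed = 1)
  expect_equal(nrow(res_all$retained), 0)

  # mixed defects are all logged with their ids
  cfg_mix <- synthetic_config(n_eyes = 100, seed = 69,
                              rates = list(warning = 0.05, failed = 0.05,
                                           missing = 0.05, mydriasis = 0.05,
                                           pupil_change = 0.05))
  co_mix <- generate_cohort(cfg_mix)
  res_mix <- apply_exclusions(co_mix$records, seed = 1)
  expect_true(all(unlist(co_mix$injected) %in% res_mix$excluded$patient_id))
})

test_that("decomposition preserves the number of retained eyes", {
  co <- generate_cohort(synthetic_config(n_eyes = 25, seed = 70))
  res <- apply_exclusions(co$records, seed = 2)
  panel <- decompose_cohort(res$retained)
  expect_equal(nrow(panel), nrow(res$retained))
})

test_that("configuration validation rejects nonsense", {
  expect_error(synthetic_config(rates = list(warning = 2, failed = 0,
                                             missing = 0, mydriasis = 0,
                                             pupil_change = 0)), "rates")
  expect_error(synthetic_config(bogus_field = 1), "unknown configuration")
  expect_error(generate_cohort(list()), "synthetic_config")
})
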