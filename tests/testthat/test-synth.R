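test_that("waveform truth carries the closed-form triangle geometry", {
  w <- gen_waveform(theta_up_deg = 16, alpha_deg = 24, h_mm = 3,
                    noise_sd = 0, seed = 1)
  r <- tan(16 * pi / 180) + tan(24 * pi / 180)
  expect_equal(w$truth$beta_deg, 40)
  expect_equal(w$truth$dbt5_ms, 200 * r)
  expect_equal(w$truth$dbtiso_ms, 120 * r)
  expect_equal(w$truth$dbtiso_ms, 87.8369, tolerance = 1e-4)
  expect_equal(w$truth$ratio, r)
  # infeasible geometry: r' wider than the beat period
  expect_error(gen_waveform(theta_up_deg = 45, alpha_deg = 65, h_mm = 8,
                            heart_rate = 120), "too wide")
})

test_that("generators are exactly reproducible under a seed", {
  w1 <- gen_waveform(noise_sd = 0.02, seed = 42)
  w2 <- gen_waveform(noise_sd = 0.02, seed = 42)
  expect_identical(w1$record$signals, w2$record$signals)
  c1 <- gen_cohort("table5", seed = 9)
  c2 <- gen_cohort("table5", seed = 9)
  expect_identical(c1$features, c2$features)
  expect_identical(c1$truth, c2$truth)
  s1 <- binormal_auc_sim(1, 1, 20, 0, 1, 30, reps = 200, seed = 5)
  s2 <- binormal_auc_sim(1, 1, 20, 0, 1, 30, reps = 200, seed = 5)
  expect_identical(s1$aucs, s2$aucs)
})

test_that("noiseless extraction recovers the generator geometry end-to-end", {
  w <- gen_waveform(theta_up_deg = 16, alpha_deg = 24, h_mm = 3,
                    noise_sd = 0)
  pf <- aggregate_patient(extract_rprime(w$record))
  expect_true(pf$any_measurable)
  expect_lt(abs(pf$beta_deg - 40), 1)
  expect_lt(abs(pf$dbt5_ms - w$truth$dbt5_ms), 2)
})

test_that("cohort truth satisfies the geometry identities", {
  co <- gen_cohort("table3", n_pos = 40, n_neg = 40, seed = 17)
  tr <- co$truth
  r <- tan(tr$theta_up_deg * pi / 180) + tan(tr$alpha_deg * pi / 180)
  expect_equal(tr$beta_deg, tr$theta_up_deg + tr$alpha_deg, tolerance = 1e-12)
  expect_equal(tr$dbt5_ms, 200 * r, tolerance = 1e-9)
  expect_equal(tr$dbtiso_ms, 40 * tr$h_mm * r, tolerance = 1e-9)
  expect_equal(tr$ratio, r, tolerance = 1e-9)
  # latent truncation ranges are respected
  expect_true(all(tr$theta_up_deg > 1 & tr$theta_up_deg < 45))
  expect_true(all(tr$alpha_deg > 1 & tr$alpha_deg < 70))
  expect_true(all(tr$h_mm > 0.5 & tr$h_mm < 8))
})

test_that("cohort feature marginals match the latent calibration targets", {
  # closed-form mean of a truncated normal
  tnorm_mean <- function(mu, sd, lo, hi) {
    a <- (lo - mu) / sd; b <- (hi - mu) / sd
    mu + sd * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
  }
  co <- gen_cohort("table5", n_pos = 3000, n_neg = 3000, seed = 33)
  tgt <- co$calibration_targets
  for (cls in c("pos", "neg")) {
    lat <- tgt[[cls]]
    want_beta <- tnorm_mean(lat$theta[1], lat$theta[2], 1, 45) +
      tnorm_mean(lat$alpha[1], lat$alpha[2], 1, 70)
    got <- co$truth$beta_deg[co$truth$scbpt_label == (cls == "pos")]
    se <- sd(got) / sqrt(length(got))
    expect_lt(abs(mean(got) - want_beta), 2 * se + 1e-9)
  }
  # measured features are centred on the truth (noise has mean zero)
  meas <- co$features$beta_deg
  expect_equal(mean(meas, na.rm = TRUE),
               mean(co$truth$beta_deg[!is.na(meas)]), tolerance = 0.02)
  # minimal cohort
  tiny <- gen_cohort("table5", n_pos = 1, n_neg = 1, seed = 2)
  expect_equal(nrow(tiny$features), 2L)
})

test_that("measurability gating follows the class-level frequencies", {
  co <- gen_cohort("table5", n_pos = 2000, n_neg = 2000, seed = 29)
  f <- co$features
  pos <- f$scbpt_label == 1
  pr <- cohort_preset("table5")
  expect_equal(mean(f$measurable_ii[pos]), pr$pos$meas_prob[["II"]],
               tolerance = 0.05)
  expect_equal(mean(f$measurable_iii[!pos]), pr$neg$meas_prob[["III"]],
               tolerance = 0.05)
  none <- !(f$measurable_ii | f$measurable_iii | f$measurable_iv)
  expect_true(all(is.na(f$beta_deg[none])))
  expect_true(all(!is.na(f$beta_deg[!none])))
})

test_that("binormal simulation converges to the closed-form AUC", {
  flat <- binormal_auc_sim(5, 2, 40, 5, 2, 60, reps = 400, seed = 3)
  expect_equal(flat$closed_form, 0.5)
  expect_lt(abs(flat$mean_auc - 0.5), 3 * flat$mc_se)
  unit <- binormal_auc_sim(sqrt(2), 1, 50, 0, 1, 50, reps = 400, seed = 4)
  expect_equal(unit$closed_form, pnorm(1))
  expect_lt(abs(unit$mean_auc - pnorm(1)), 3 * unit$mc_se)
  # validation-cohort beta-angle parameters against the closed form
  p <- cohort_preset("table5")
  beta <- binormal_auc_sim(p$pos$beta[1], p$pos$beta[2], p$n_pos,
                           p$neg$beta[1], p$neg$beta[2], p$n_neg,
                           reps = 400, seed = 6)
  expect_lt(abs(beta$mean_auc - beta$closed_form), 3 * beta$mc_se)
})
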