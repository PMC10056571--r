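# helper: limbs object with chosen angles anchored so the apex sits at
# height h_mm above the isoelectric line
limbs_at <- function(theta_up, alpha, h_mm, apex_x = 10) {
  list(up = list(angle_deg = theta_up, anchor_x_mm = apex_x,
                 anchor_y_mm = h_mm),
       down = list(angle_deg = alpha, anchor_x_mm = apex_x,
                   anchor_y_mm = h_mm))
}

test_that("beat detector finds synthetic beats and their baseline", {
  w <- gen_waveform(heart_rate = 60, n_beats = 5, noise_sd = 0.01, seed = 2)
  beats <- detect_beats(w$record)
  expect_length(beats, 5L)
  expect_true(all(abs(vapply(beats, `[[`, 0L, "r_peak") - w$truth$r_peak) <= 1))
  for (b in beats) {
    expect_lt(b$qrs_onset, b$r_peak)
    expect_gt(b$qrs_offset, b$r_peak)
  }
  # all-zero signal yields an empty list, not an error
  flat <- ecg_record(matrix(0, 2500, 1), 500, list("V1@IV"))
  expect_length(detect_beats(flat), 0L)
  # baseline offset is recovered from the PR segment
  wo <- gen_waveform(baseline_mV = 0.2, noise_sd = 0.01, seed = 4)
  bo <- detect_beats(wo$record)
  bases <- vapply(bo, `[[`, 0, "baseline_mV")
  expect_lt(abs(mean(bases) - 0.2), 0.005)
  expect_true(all(abs(bases - 0.2) < 0.012))
})

test_that("r' candidate location follows the terminal-deflection rule", {
  w <- gen_waveform(theta_up_deg = 16, alpha_deg = 24, h_mm = 3,
                    noise_sd = 0, seed = 1)
  x <- w$record$signals[, 1]
  beats <- detect_beats(w$record)
  for (i in seq_along(beats)) {
    apex <- locate_rprime(beats[[i]], x, 500)
    expect_lte(abs(apex - w$truth$apex[i]), 1)
  }
  # monophasic R beat (no terminal positive deflection) yields no candidate
  t_ms <- (0:2499) / 500 * 1000
  mono <- approx(c(0, 380, 400, 420, 3000), c(0, 0, 1, 0, 0),
                 xout = t_ms, rule = 2)$y
  rec <- ecg_record(matrix(mono, ncol = 1), 500, list("V1@IV"))
  b <- detect_beats(rec)[[1]]
  expect_true(is.na(locate_rprime(b, mono, 500)))
  # r' below the 0.05 mV candidate gate (0.4 mm = 0.04 mV) is ignored
  wl <- gen_waveform(h_mm = 0.4, noise_sd = 0)
  bl <- detect_beats(wl$record)[[1]]
  expect_true(is.na(locate_rprime(bl, wl$record$signals[, 1], 500)))
})

test_that("measurability requires amplitude and descent strictly over 0.1 mV", {
  expect_true(is_measurable(0.15, 0.12))
  expect_false(is_measurable(0.10, 0.30))  # exactly 0.1 mV does not qualify
  expect_false(is_measurable(0.30, 0.08))
  expect_error(is_measurable(-0.1, 0.2))
})

test_that("limb fitting recovers generator angles", {
  w <- gen_waveform(theta_up_deg = 16, alpha_deg = 24, h_mm = 3,
                    noise_sd = 0, seed = 1)
  x <- w$record$signals[, 1]
  b <- detect_beats(w$record)[[1]]
  apex <- locate_rprime(b, x, 500)
  limbs <- fit_limbs(b, apex, x, 500)
  expect_equal(limbs$up$angle_deg, 16, tolerance = 0.5 / 16)
  expect_equal(limbs$down$angle_deg, 24, tolerance = 0.5 / 24)
  # with noise sigma = 0.02 mV the beat-averaged angles stay within 3
  # degrees and most individual beats do too
  wn <- gen_waveform(theta_up_deg = 16, alpha_deg = 24, h_mm = 3,
                     noise_sd = 0.02, seed = 9, n_beats = 8)
  xn <- wn$record$signals[, 1]
  fits <- lapply(detect_beats(wn$record), function(bn) {
    apexn <- locate_rprime(bn, xn, 500)
    if (is.na(apexn)) return(NULL)
    fit_limbs(bn, apexn, xn, 500)
  })
  fits <- fits[!vapply(fits, is.null, TRUE)]
  expect_gte(length(fits), 6L)
  ups <- vapply(fits, function(l) l$up$angle_deg, 0)
  dns <- vapply(fits, function(l) l$down$angle_deg, 0)
  expect_lt(abs(mean(ups) - 16), 3)
  expect_lt(abs(mean(dns) - 24), 3)
  expect_gte(mean(abs(ups - 16) < 3), 0.7)
  expect_gte(mean(abs(dns - 24) < 3), 0.7)
})

test_that("triangle geometry follows the closed-form identities", {
  g <- compute_geometry(limbs_at(16, 24, 3))
  expect_equal(g$beta_deg, 40)
  expect_equal(g$dbt5_ms, 200 * (tan(16 * pi / 180) + tan(24 * pi / 180)))
  expect_equal(g$dbt5_ms, 146.3948, tolerance = 1e-4)
  # vertical upslope, alpha = 45 deg, h = 3 mm
  g2 <- compute_geometry(limbs_at(0, 45, 3))
  expect_equal(g2$dbt5_ms, 200)
  expect_equal(g2$dbtiso_ms, 120)
  expect_equal(g2$ratio, 1)
  # angles from slope ratios: 3 mm rise per 1 mm run and per 2 mm run
  g3 <- compute_geometry(limbs_at(atan(1 / 3) * 180 / pi,
                                  atan(2 / 3) * 180 / pi, 2))
  expect_equal(g3$beta_deg, 52.125, tolerance = 1e-4)
  # apex below the isoelectric line is unmeasurable
  expect_false(compute_geometry(limbs_at(10, 20, -0.5))$measurable)
  # parallel (vertical) limbs have no intersection
  expect_error(compute_geometry(limbs_at(0, 0, 3)), "parallel")
})

test_that("every emitted geometry satisfies the exact identities", {
  for (th in c(5, 15, 25)) for (al in c(10, 30, 50)) for (h in c(1, 3, 5)) {
    g <- compute_geometry(limbs_at(th, al, h))
    expect_equal(g$beta_deg, g$theta_up_deg + g$alpha_deg, tolerance = 1e-12)
    r <- tan(g$theta_up_deg * pi / 180) + tan(g$alpha_deg * pi / 180)
    expect_equal(g$dbt5_ms, 200 * r, tolerance = 1e-9)
    expect_equal(g$dbtiso_ms, 40 * g$h_mm * r, tolerance = 1e-9)
    expect_equal(g$ratio, r, tolerance = 1e-9)
  }
})

test_that("criteria increase strictly with the downslope angle", {
  alphas <- seq(10, 60, by = 5)
  for (th in c(5, 20)) {
    gs <- lapply(alphas, function(a) compute_geometry(limbs_at(th, a, 3)))
    for (f in c("beta_deg", "dbt5_ms", "dbtiso_ms", "ratio")) {
      vals <- vapply(gs, `[[`, 0, f)
      expect_true(all(diff(vals) > 0), info = f)
    }
  }
})

test_that("patient aggregation takes per-lead means then the major value", {
  row <- function(lead, ic, beta, alpha = 20, dbt5 = 100, dbtiso = 60,
                  ratio = 0.8, meas = TRUE)
    data.frame(lead = lead, ic_level = ic, beat_index = 1,
               beta_deg = beta, alpha_deg = alpha, theta_up_deg = beta - alpha,
               h_mm = 2, dbt5_ms = dbt5, dbtiso_ms = dbtiso, ratio = ratio,
               measurable = meas)
  g <- rbind(row("V1", "IV", 40), row("V1", "IV", 44),  # lead mean 42
             row("V1", "III", 50), row("V2", "II", 38))
  pf <- aggregate_patient(g)
  expect_true(pf$any_measurable)
  expect_equal(pf$beta_deg, 50)  # max of per-placement means {42, 50, 38}
  expect_equal(unname(pf$measurable_by_ic), c(TRUE, TRUE, TRUE))
  # order of rows does not matter; adding a smaller lead leaves majors alone
  pf2 <- aggregate_patient(g[sample(nrow(g)), ])
  expect_equal(pf2$beta_deg, pf$beta_deg)
  g3 <- rbind(g, row("V2", "IV", 10, alpha = 5))
  expect_equal(aggregate_patient(g3)$beta_deg, 50)
  # single measurable beat: majors equal that beat
  pf1 <- aggregate_patient(row("V2", "III", 47))
  expect_equal(pf1$beta_deg, 47)
  expect_equal(unname(pf1$measurable_by_ic), c(FALSE, TRUE, FALSE))
  # no measurable beats at all
  pf0 <- aggregate_patient(row("V1", "IV", NA, meas = FALSE))
  expect_false(pf0$any_measurable)
  expect_true(is.na(pf0$beta_deg))
  expect_false(aggregate_patient(g[0, ])$any_measurable)
})

test_that("unmeasurable strips yield NA features through the full pipeline", {
  # 0.8 mm apex (0.08 mV) passes the candidate gate but fails measurability
  w <- gen_waveform(h_mm = 0.8, noise_sd = 0)
  g <- extract_rprime(w$record)
  expect_true(all(!g$measurable))
  expect_false(aggregate_patient(g)$any_measurable)
})
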