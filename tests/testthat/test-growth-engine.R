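test_that("ME to net-energy conversion reproduces the cubic forms", {
  en <- diet_energy(3.2)
  expect_equal(en$nem, 1.37 * 3.2 - 0.138 * 3.2^2 + 0.0105 * 3.2^3 - 1.12,
               tolerance = 1e-12)
  expect_equal(en$neg, 1.42 * 3.2 - 0.174 * 3.2^2 + 0.0122 * 3.2^3 - 1.65,
               tolerance = 1e-12)
  # the default finishing diet lands on the conventional 2.2 / 1.5 Mcal/kg
  expect_equal(round(en$nem, 1), 2.2)
  expect_equal(round(en$neg, 1), 1.5)
  expect_error(diet_energy(1.2), "within")
  expect_error(diet_energy(4.5), "within")
})

test_that("maintenance requirement follows metabolic weight", {
  expect_equal(maintenance_nem(400), 0.077 * 400^0.75, tolerance = 1e-12)
  expect_equal(round(maintenance_nem(400), 3), 6.887)
  expect_equal(round(maintenance_nem(100), 3), 2.435)
  expect_equal(maintenance_nem(0), 0)
  expect_equal(maintenance_nem(400, maintenance_factor = 1.2),
               1.2 * maintenance_nem(400))
})

test_that("retained energy is size-scaled and a power law in gain", {
  expect_equal(retained_energy(478, 478, 0), 0)
  oracle <- 0.0635 * (0.891 * 478)^0.75 * 0.956^1.097
  expect_equal(retained_energy(478, 478, 1.0), oracle, tolerance = 1e-12)
  expect_equal(round(oracle, 3), 5.667)
  # doubling gain multiplies RE by 2^1.097
  expect_equal(retained_energy(400, 550, 2.4) / retained_energy(400, 550, 1.2),
               2^1.097, tolerance = 1e-12)
  # vectorized over weight with scalar gain
  re <- retained_energy(c(314, 400, 500), 566, 1.57)
  expect_length(re, 3)
  expect_true(all(diff(re) > 0))
})

test_that("gain from intake inverts retained energy exactly", {
  diet <- diet_spec()
  expect_equal(round(predict_adg_from_dmi(9, 400, 550, diet), 4), 1.8693)
  # at maintenance intake the gain is zero, with a warning
  maint_dmi <- maintenance_nem(400) / diet$nem
  expect_warning(adg0 <- predict_adg_from_dmi(maint_dmi, 400, 550, diet),
                 "maintenance")
  expect_equal(adg0, 0)
  # round trip: gain -> required intake -> gain, across the plausible range
  for (g in seq(0.2, 2.5, by = 0.23)) {
    dmi <- maint_dmi + retained_energy(400, 550, g) / diet$neg
    expect_equal(predict_adg_from_dmi(dmi, 400, 550, diet), g,
                 tolerance = 1e-6)
  }
})

test_that("forward projection reaches the target and matches the frozen oracle", {
  # immediate attainment
  p1 <- project_days_on_feed(400, 400 + 1e-6)
  expect_equal(p1$dof_pred_d, 1L)
  # frozen from an independent scalar day-loop simulation
  p <- project_days_on_feed(314, 556)
  expect_equal(p$dof_pred_d, 127L)
  expect_equal(p$pdmi_kg_d, 9.644205, tolerance = 1e-5)
  expect_equal(p$padg_kg_d, 1.909442, tolerance = 1e-5)
  expect_true(p$dof_pred_d >= 120 && p$dof_pred_d <= 220)
  # halving the weight to gain less than halves the days (gain slows late)
  half <- project_days_on_feed(314, 314 + (556 - 314) / 2)
  expect_gt(half$dof_pred_d, p$dof_pred_d / 2)
  expect_error(project_days_on_feed(500, 450), "exceed")
  expect_error(project_days_on_feed(314, 5560, max_days = 100), "within")
})

test_that("expected DOF is the gain-scaled weight deficit", {
  expect_equal(round(expected_dof(507.0254, 297, 1.36), 1), 154.4)
  expect_equal(round(expected_dof(566.1473, 314, 1.57), 1), 160.6)
  expect_equal(expected_dof(450, 450, 1.2), 0)
  expect_error(expected_dof(500, 300, 0), "positive")
  expect_warning(expected_dof(280, 300, 1.5), "negative")
})

test_that("backward dry matter required matches day-loop oracles", {
  # zero gain: maintenance-only intake, constant by construction
  expect_equal(dry_matter_required(400, 0, 10, 500),
               maintenance_nem(400) / diet_spec()$nem, tolerance = 1e-12)
  expect_equal(round(dry_matter_required(400, 0, 10, 500), 3), 3.138)
  # frozen independent day-loop value on the steer population means
  expect_equal(dry_matter_required(314, 1.57, 162, 566.147), 8.441533,
               tolerance = 1e-5)
  # strictly increasing in observed gain
  dmr <- dry_matter_required(314, c(0.8, 1.2, 1.6, 2.0), 150, 560)
  expect_true(all(diff(dmr) > 0))
  expect_error(dry_matter_required(314, NA, 150, 560), "required")
})

test_that("forward prediction and backward requirement are mutual inverses", {
  diet <- diet_spec()
  for (sbw in c(320, 420, 520)) {
    for (dmi in c(7.5, 9, 10.5)) {
      adg <- suppressWarnings(predict_adg_from_dmi(dmi, sbw, 566, diet))
      # a one-day backward calculation at that gain must return the intake
      back <- dry_matter_required(sbw, adg, 1, 566, diet)
      expect_equal(back, dmi, tolerance = 1e-6)
    }
  }
})

test_that("daily energy balance partitions exactly into maintenance and gain", {
  diet <- diet_spec()
  sbw <- 380; afsbw <- 560; adg <- 1.4
  dmr_day <- dry_matter_required(sbw, adg, 1, afsbw, diet)
  expect_equal(dmr_day,
               maintenance_nem(sbw) / diet$nem +
                 retained_energy(sbw, afsbw, adg) / diet$neg,
               tolerance = 1e-12)
})

test_that("growth predictions attach per-method columns and flag bad targets", {
  d <- tibble::tibble(
    animal_id = c("a", "b"), sex = c("steer", "heifer"),
    isbw_kg = c(314, 297), adg_kg_d = c(1.57, 1.36), dof_d = c(162, 161),
    afsbw_hh_kg = c(504, 414.4), afsbw_ct_kg = c(566.1, 507.0)
  )
  out <- add_growth_predictions(d)
  expect_true(all(c("pdmi_hh_kg_d", "padg_ct_kg_d", "dof_pred_hh_d",
                    "edof_d", "dmr_kg_d") %in% names(out)))
  expect_true(all(out$dof_pred_ct_d > out$dof_pred_hh_d - 400))
  bad <- d
  bad$afsbw_hh_kg[1] <- 100
  expect_warning(add_growth_predictions(bad), "at or below initial BW")
})

test_that("expected DOF tracks the carcass-route DOF more closely than the hip-height route", {
  co <- quiet_cohort(cohort_spec(n_heifers = 120, n_steers = 120,
                                 truth = "afsbw_mbv"), seed = 42)
  co <- suppressWarnings(add_growth_predictions(co))
  ok <- stats::complete.cases(co[, c("edof_d", "dof_pred_ct_d", "dof_pred_hh_d")])
  r_ct <- cor(co$edof_d[ok], co$dof_pred_ct_d[ok])
  r_hh <- cor(co$edof_d[ok], co$dof_pred_hh_d[ok])
  expect_gt(r_ct, r_hh)
})
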