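test_that("generated marginals match truncated-normal expectations", {
  co <- quiet_cohort(cohort_spec(n_heifers = 10000, n_steers = 0), seed = 99)
  marg <- cohort_defaults()
  marg <- marg[marg$sex == "heifer", ]
  n <- nrow(co)
  for (i in seq_len(nrow(marg))) {
    v <- marg$variable[i]
    if (v == "marbling") next  # discretized; checked separately
    mom <- truncnorm_moments(marg$mean[i], marg$sd[i], marg$min[i], marg$max[i])
    se_mean <- marg$sd[i] / sqrt(n)
    se_sd <- marg$sd[i] / sqrt(2 * n)
    expect_lt(abs(mean(co[[v]]) - mom["mean"]), 3 * se_mean)
    expect_lt(abs(sd(co[[v]]) - mom["sd"]), 4 * se_sd)
  }
  # marbling: whole scores on the observed 3-9 range, mean near target
  expect_true(all(co$marbling == round(co$marbling)))
  expect_true(all(co$marbling >= 3 & co$marbling <= 9))
  expect_lt(abs(mean(co$marbling) - 4.85), 0.2)
})

test_that("range enforcement keeps draws inside the printed ranges", {
  co <- quiet_cohort(cohort_spec(n_heifers = 2000, n_steers = 2000), seed = 17)
  marg <- cohort_defaults()
  for (sx in c("heifer", "steer")) {
    m <- marg[marg$sex == sx, ]
    sub <- co[co$sex == sx, ]
    for (i in seq_len(nrow(m))) {
      v <- m$variable[i]
      expect_true(all(sub[[v]] >= m$min[i] - 1e-9 & sub[[v]] <= m$max[i] + 1e-9),
                  label = paste(sx, v, "within range"))
    }
  }
})

test_that("the configured trait correlations survive generation", {
  co <- quiet_cohort(cohort_spec(n_heifers = 5000, n_steers = 0), seed = 7)
  # copula target 0.370 between ribeye area and its MBV; truncation and the
  # PSD repair attenuate it slightly
  expect_lt(abs(cor(co$rea_cm2, co$mbv_rea) - 0.370), 0.04)
  expect_lt(abs(cor(co$ft_cm, co$mbv_rea) - (-0.335)), 0.05)
  expect_gt(cor(co$final_bw_kg, co$hcw_kg), 0.85)
})

test_that("genotype draws follow the per-sex frequencies", {
  co <- quiet_cohort(cohort_spec(n_heifers = 8000, n_steers = 0), seed = 23)
  gf <- genotype_frequencies()
  for (snp in c("uasms2", "e2fb")) {
    g <- gf[gf$snp == snp & gf$sex == "heifer", ]
    col <- paste0("leptin_", snp)
    p_hat <- mean(co[[col]] == "CC")
    expect_lt(abs(p_hat - g$p_cc), 3 * sqrt(g$p_cc * (1 - g$p_cc) / nrow(co)))
  }
})

test_that("generation is deterministic under a fixed seed", {
  s <- small_spec(100, truth = "afsbw_mbv")
  c1 <- quiet_cohort(s, seed = 12)
  c2 <- quiet_cohort(s, seed = 12)
  expect_identical(as.data.frame(c1), as.data.frame(c2))
  c3 <- quiet_cohort(s, seed = 13)
  expect_false(identical(c1$isbw_kg, c3$isbw_kg))
})

test_that("truth report mirrors the generating parameters", {
  co <- quiet_cohort(small_spec(80, truth = "afsbw_mbv"), seed = 3)
  tr <- truth_report(co)
  expect_equal(tr$value[tr$term == "mbv_rea"], 44.5)
  expect_equal(tr$value[tr$term == "residual_sd"], 51.3)
  expect_true("truth_afsbw_ct_kg" %in% names(co))
  # systematic part is noiseless: regenerating with zero residual matches it
  co0 <- quiet_cohort(small_spec(80, truth = "afsbw_mbv", residual_sd = 0),
                      seed = 3)
  expect_equal(co0$afsbw_ct_kg, co0$truth_afsbw_ct_kg)
  # no truth, empty report
  expect_equal(nrow(truth_report(quiet_cohort(small_spec(20), seed = 1))), 0)
})

test_that("short parameter-recovery study centres on the generating coefficient", {
  est <- vapply(1:20, function(i) {
    co <- quiet_cohort(cohort_spec(n_heifers = 673, n_steers = 826,
                                   truth = "afsbw_mbv"), seed = 3000 + i)
    td <- tidy(fit_adjustment(co, "afsbw_mbv"))
    td$estimate[td$term == "mbv_rea"]
  }, numeric(1))
  expect_lt(abs(mean(est) - 44.5), 2)
})

test_that("calibrating the total response SD rescales only the systematic part", {
  co <- quiet_cohort(cohort_spec(truth = "afsbw_mbv", calibrate_total_sd = 65.7),
                     seed = 31)
  expect_lt(abs(sd(co$afsbw_ct_kg) - 65.7), 3.5)
  tr <- truth_report(co)
  expect_true("systematic_scale" %in% tr$term)
  expect_error(
    quiet_cohort(cohort_spec(truth = "afsbw_mbv", calibrate_total_sd = 40),
                 seed = 1),
    "below residual"
  )
})

test_that("intake-based truths carry their predicted-intake column", {
  co <- quiet_cohort(small_spec(80, truth = "dmr_pdmi"), seed = 5)
  expect_true(all(c("pdmi_kg_d", "dmr_kg_d", "truth_dmr_kg_d") %in% names(co)))
  expect_true(all(co$pdmi_kg_d > 0))
  co2 <- quiet_cohort(small_spec(80, truth = "dmr_endbw"), seed = 5)
  expect_true("pdmi_endbw_kg_d" %in% names(co2))
})

test_that("optional leptin coupling lifts the ribeye MBV of the CC/CC class", {
  co <- quiet_cohort(cohort_spec(n_heifers = 4000, n_steers = 0,
                                 leptin_coupling = TRUE), seed = 41)
  cccc <- co$leptin_uasms2 == "CC" & co$leptin_e2fb == "CC"
  expect_gt(mean(co$mbv_rea[cccc]), mean(co$mbv_rea[!cccc]))
})

test_that("invalid generator specifications are rejected", {
  bad <- cohort_defaults()
  bad$sd[1] <- -1
  expect_error(cohort_spec(marginals = bad), "positive")
  m <- cohort_correlations()
  m[1, 2] <- 0.5  # asymmetric
  expect_error(cohort_spec(correlations = m), "symmetric")
})
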