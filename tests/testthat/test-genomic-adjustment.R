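test_that("reference adjustment equations apply as pure arithmetic", {
  steer <- tibble::tibble(sex = "steer", afsbw_hh_kg = 504.0, mbv_rea = -0.42)
  expect_equal(apply_adjustment(steer, "afsbw_mbv"),
               312.8 + 0.5354 * 504.0 + 44.5 * (-0.42), tolerance = 1e-12)
  expect_equal(round(apply_adjustment(steer, "afsbw_mbv"), 0), 564)

  frame <- tibble::tibble(sex = "steer", hip_height_cm = 120, isbw_kg = 314,
                          mbv_cab_mrb = 52.3, mbv_rea = -0.42)
  expect_equal(round(apply_adjustment(frame, "afsbw_frame"), 1), 589.4)

  dmr <- tibble::tibble(sex = "steer", pdmi_kg_d = 9.0, mbv_rea = -0.42)
  expect_equal(round(apply_adjustment(dmr, "dmr_pdmi", pdmi_col = "pdmi_kg_d"), 2),
               10.16)

  # unit changes in the MBV scores shift predictions by their coefficients
  bump <- function(d, col) { d[[col]] <- d[[col]] + 1; d }
  expect_equal(apply_adjustment(bump(steer, "mbv_rea"), "afsbw_mbv") -
                 apply_adjustment(steer, "afsbw_mbv"), 44.5)
  expect_equal(apply_adjustment(bump(dmr, "mbv_rea"), "dmr_pdmi", pdmi_col = "pdmi_kg_d") -
                 apply_adjustment(dmr, "dmr_pdmi", pdmi_col = "pdmi_kg_d"), -0.606)
  expect_equal(apply_adjustment(bump(dmr, "mbv_rea"), "dmr_endbw", pdmi_col = "pdmi_kg_d") -
                 apply_adjustment(dmr, "dmr_endbw", pdmi_col = "pdmi_kg_d"), -0.45)
  f100 <- frame; f100$mbv_cab_mrb <- f100$mbv_cab_mrb + 100
  expect_equal(apply_adjustment(f100, "afsbw_frame") -
                 apply_adjustment(frame, "afsbw_frame"), -25.7)

  # bit-stable: identical inputs give identical doubles
  expect_identical(apply_adjustment(steer, "afsbw_mbv"),
                   apply_adjustment(steer, "afsbw_mbv"))
})

test_that("difference variables are exact subtractions with missingness propagation", {
  d <- tibble::tibble(
    afsbw_ct_kg = c(566.2, 500, NA), afsbw_hh_kg = c(504.0, 500, 480),
    adg_kg_d = c(1.5, 1.2, 1.3), padg_hh_kg_d = c(1.4, 1.2, 1.1),
    padg_ct_kg_d = c(1.45, 1.2, 1.2),
    edof_d = c(154.4, 120, 130), dof_pred_hh_d = c(140, 120, 125),
    dof_pred_ct_d = c(154.4, 120, 128),
    dmr_kg_d = c(9.1, 8.0, NA), pdmi_hh_kg_d = c(8.8, 8.0, 8.5)
  )
  out <- add_deltas(d)
  expect_equal(out$d_afsbw_kg, c(62.2, 0, NA))
  expect_equal(out$d_dof_ct_d, c(0, 0, 2))
  expect_equal(out$d_dmi_kg_d, c(0.3, 0, NA), tolerance = 1e-12)
  # absent operands: columns simply not created, never zero-filled
  out2 <- add_deltas(d[, c("afsbw_ct_kg", "afsbw_hh_kg")])
  expect_false("d_dmi_kg_d" %in% names(out2))
})

test_that("fitting a noiseless truth recovers coefficients to machine precision", {
  co <- quiet_cohort(small_spec(300, truth = "afsbw_mbv", residual_sd = 0),
                     seed = 21)
  fit <- fit_adjustment(co, "afsbw_mbv")
  est <- tidy(fit)$estimate
  names(est) <- tidy(fit)$term
  truth <- reference_adjustments()$afsbw_mbv$coefs
  expect_equal(unname(est[c("intercept", "a", "afsbw_hh", "a_afsbw_hh", "mbv_rea")]),
               unname(truth), tolerance = 1e-8)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
})

test_that("OLS identity: residuals of a fit on its own training data average zero", {
  co <- quiet_cohort(small_spec(240, truth = "dmr_pdmi"), seed = 8)
  fit <- fit_adjustment(co, "dmr_pdmi", pdmi_col = "pdmi_kg_d")
  res <- co$dmr_kg_d - predict(fit, co, pdmi_col = "pdmi_kg_d")
  expect_lt(abs(mean(res)) / stats::sd(co$dmr_kg_d), 1e-8)
})

test_that("single-sex cohorts drop the sex interaction with a warning", {
  co <- quiet_cohort(cohort_spec(n_heifers = 0, n_steers = 120,
                                 truth = "afsbw_mbv"), seed = 4)
  expect_warning(fit <- fit_adjustment(co, "afsbw_mbv"), "single-sex")
  expect_false(any(tidy(fit)$term %in% c("a", "a_afsbw_hh")))
})

test_that("rank-deficient designs are rejected with the aliased term named", {
  co <- quiet_cohort(small_spec(200, truth = "afsbw_mbv"), seed = 10)
  co$mbv_cab_mrb <- co$hip_height_cm   # force exact collinearity
  co$isbw_kg <- 2 * co$hip_height_cm
  expect_error(fit_adjustment(co, "afsbw_frame"), "aliased|rank")
})

test_that("stepwise selection finds a single strong predictor among noise", {
  set.seed(101)
  n <- 500
  d <- tibble::tibble(
    x = rnorm(n), n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n),
    n4 = rnorm(n), n5 = rnorm(n)
  )
  d$y <- 5 * d$x + rnorm(n)  # effect 5 SD of noise
  # a strict threshold isolates the single true predictor; the default 0.15
  # tolerates ~15 % false entries by design (checked in the all-noise test)
  fit <- stepwise_ols(d, "y", c("n1", "x", "n2", "n3", "n4", "n5"),
                      entry_p = 0.01, stay_p = 0.01)
  expect_equal(sort(fit$selection$terms), "x")
  # exhaustive best-subset oracle agrees on the same data
  expect_equal(best_subset_bic(d, "y", c("x", "n1", "n2", "n3", "n4", "n5")),
               "x")
})

test_that("stepwise is invariant to candidate order without p-value ties", {
  set.seed(77)
  n <- 300
  d <- tibble::tibble(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  d$y <- 2 * d$a - 1.5 * d$b + rnorm(n)
  f1 <- stepwise_ols(d, "y", c("a", "b", "c"))
  f2 <- stepwise_ols(d, "y", c("c", "b", "a"))
  expect_setequal(f1$selection$terms, f2$selection$terms)
})

test_that("an exact linear response enters with r-squared one", {
  d <- tibble::tibble(x = seq_len(40) / 7, z = rnorm(40))
  d$y <- d$x
  fit <- stepwise_ols(d, "y", c("z", "x"))
  expect_equal(fit$selection$terms, "x")
  expect_equal(fit$r2, 1, tolerance = 1e-12)
})

test_that("all-noise candidate pools rarely admit terms at the 0.15 threshold", {
  set.seed(2024)
  sizes <- replicate(300, {
    n <- 50
    d <- data.frame(matrix(rnorm(n * 5), n, 5))
    d$y <- rnorm(n)
    fit <- stepwise_ols(d, "y", paste0("X", 1:5))
    length(fit$selection$terms)
  })
  # expected false entries ~ candidates * alpha; allow a factor-2 margin
  expect_lte(mean(sizes), 5 * 0.15 * 2)
})

test_that("mutually exclusive candidates never co-enter", {
  set.seed(5)
  n <- 400
  d <- tibble::tibble(mbv_rea = rnorm(n))
  d$leptin_cls <- d$mbv_rea + rnorm(n, 0, 0.2)   # strongly associated proxy
  d$y <- 3 * d$mbv_rea + rnorm(n)
  fit <- suppressMessages(
    stepwise_ols(d, "y", c("mbv_rea", "leptin_cls"),
                 exclusive = list(c("mbv_rea", "leptin_cls")))
  )
  expect_length(intersect(c("mbv_rea", "leptin_cls"), fit$selection$terms), 1L)
})

test_that("leptin allele statistics reproduce printed ratios and the chi-square", {
  st <- leptin_allele_stats(c(254, 406), c(416, 349), c(164, 61),
                            snp = c("e2fb", "uasms2"))
  expect_equal(st$c_alleles, c(2 * 254 + 416, 2 * 406 + 349))
  expect_equal(round(st$ct_ratio, 2), c(1.24, 2.46))
  expect_equal(round(st$ct_ratio[2] / st$ct_ratio[1], 2), 1.98)
  # hand-computed Pearson chi-square against 25:50:25
  st2 <- leptin_allele_stats(313, 282, 70)
  o <- c(313, 282, 70); e <- sum(o) * c(0.25, 0.5, 0.25)
  expect_equal(st2$chisq, sum((o - e)^2 / e), tolerance = 1e-10)
  expect_equal(round(st2$chisq, 1), 192.9)
  expect_lt(st2$p_value, 1e-4)
  expect_error(leptin_allele_stats(0, 0, 0), "positive total")
})

test_that("leptin classes form the nine genotype combinations", {
  cls <- leptin_class(c("CC", "CT", "TT"), c("CC", "TT", "CT"))
  expect_s3_class(cls, "factor")
  expect_length(levels(cls), 9)
  expect_equal(as.character(cls), c("CCCC", "CTTT", "TTCT"))
})

test_that("incremental r-squared behaves at its analytic endpoints", {
  set.seed(3)
  n <- 200
  base <- rnorm(n)
  added <- rnorm(n)
  y <- 2 * base + rnorm(n)
  # orthogonalize the added predictor against the response exactly
  added_orth <- stats::residuals(lm(added ~ y + base))
  d <- tibble::tibble(y, base, added_orth)
  ve <- variance_explained(d, "y", "base", "added_orth")
  expect_lt(ve$increment_pct, 1e-8)
  # exact linear combination: the increments add to 100 %
  d2 <- tibble::tibble(y2 = base + 3 * added, base, added)
  ve2 <- variance_explained(d2, "y2", "base", "added")
  expect_equal(ve2$r2_full_pct, 100, tolerance = 1e-10)
})

test_that("group effects recover constructed offsets and reduce to the t-test", {
  set.seed(11)
  n <- 120
  d <- tibble::tibble(
    sex = rep(c("steer", "heifer"), each = n / 2),
    g = sample(c("CCCC", "TTTT"), n, replace = TRUE)
  )
  d$y <- -0.494 + 0.060 * (d$sex == "heifer") + rnorm(n, 0, 0.05)
  eff <- group_effects(d, "y", c("sex", "g"))
  sexeff <- eff[eff$factor == "sex", ]
  off <- sexeff$lsmean[sexeff$level == "heifer"] -
    sexeff$lsmean[sexeff$level == "steer"]
  expect_lt(abs(off - 0.060), 0.03)
  # identical group means: effects near zero
  d0 <- d; d0$y <- rnorm(n)
  eff0 <- group_effects(d0, "y", "sex")
  expect_lt(abs(diff(eff0$lsmean)), 0.1)
  # two-level single factor: F equals t squared
  fit <- lm(y ~ sex, data = d)
  Fv <- anova(fit)[["F value"]][1]
  tv <- stats::t.test(y ~ sex, data = d, var.equal = TRUE)$statistic
  expect_equal(Fv, unname(tv)^2, tolerance = 1e-10)
})
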