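# Default statistical structure of the emulated commercial feedyard cohort:
# per-sex marginal mean/SD/range for each continuous trait, the MBV-phenotype
# correlation block, and the leptin genotype frequencies.

#' Default per-sex marginal distributions of the cohort generator
#'
#' Mean, SD and observed range of every continuous trait the generator draws,
#' per sex, describing a spring-placed commercial feedyard population of 681
#' crossbred heifers and 836 steers. Marbling is on the 2-9 USDA scale (the
#' population range is 3-9); MBV columns are the eleven commercial SNP-panel
#' scores.
#'
#' @return Tibble with columns `variable`, `sex`, `mean`, `sd`, `min`, `max`.
#' @export
cohort_defaults <- function() {
  h <- list( # heifers
    isbw_kg = c(297, 39.7, 182, 427),
    hip_height_cm = c(117, 5.01, 104, 144),
    final_bw_kg = c(507, 54.9, 364, 654),
    dof_d = c(161, 34.9, 91, 262),
    adg_kg_d = c(1.36, 0.312, 0.514, 2.23),
    hcw_kg = c(326, 33.8, 206, 430),
    ft_cm = c(1.25, 0.46, 0, 2.90),
    rea_cm2 = c(85.4, 10.95, 53.6, 137),
    marbling = c(4.85, 1.12, 3, 9),
    mbv_cab_mrb = c(49.1, 16.6, 1.94, 97.7),
    mbv_adg = c(0.15, 0.08, -0.11, 0.37),
    mbv_hcw = c(27.2, 8.49, -16.1, 48.6),
    mbv_rea = c(-0.36, 0.47, -2.01, 0.83),
    mbv_snp50_mrb = c(-30.4, 21.9, -82.9, 38.4),
    mbv_snp50_rea = c(-0.56, 0.67, -2.37, 1.5),
    mbv_all_mrb = c(80.7, 20.4, 25.2, 148),
    mbv_all_rea = c(1.11, 0.31, 0.13, 2.15),
    mbv_all_adg = c(0.38, 0.10, 0.04, 0.64),
    mbv_all_rfi = c(2.18, 1.93, -4.29, 8.53),
    mbv_bt_rfi = c(1.98, 0.60, 0.07, 3.74)
  )
  s <- list( # steers
    isbw_kg = c(314, 45.6, 166, 440),
    hip_height_cm = c(120, 4.99, 104, 147),
    final_bw_kg = c(556, 50.6, 386, 704),
    dof_d = c(162, 42.7, 91, 285),
    adg_kg_d = c(1.57, 0.414, 0.662, 3.04),
    hcw_kg = c(356, 34.1, 248, 441),
    ft_cm = c(1.14, 0.40, 0, 2.41),
    rea_cm2 = c(88.3, 10.4, 58.1, 123),
    marbling = c(4.51, 1.00, 3, 9),
    mbv_cab_mrb = c(52.3, 17.9, 3.17, 101.2),
    mbv_adg = c(0.15, 0.08, -0.09, 0.45),
    mbv_hcw = c(26.3, 9.01, -17.7, 53.1),
    mbv_rea = c(-0.42, 0.47, -1.55, 0.87),
    mbv_snp50_mrb = c(-25.6, 22.7, -96.9, 38.1),
    mbv_snp50_rea = c(-0.62, 0.65, -2.16, 1.64),
    mbv_all_mrb = c(84.1, 22.2, 19.8, 145),
    mbv_all_rea = c(1.11, 0.31, 0.27, 2.09),
    mbv_all_adg = c(0.40, 0.10, 0.04, 0.69),
    mbv_all_rfi = c(2.25, 1.80, -3.62, 9.61),
    mbv_bt_rfi = c(2.05, 0.57, 0.45, 3.73)
  )
  row <- function(lst, sex) {
    tibble::tibble(
      variable = names(lst), sex = sex,
      mean = unname(vapply(lst, `[`, numeric(1), 1)),
      sd = unname(vapply(lst, `[`, numeric(1), 2)),
      min = unname(vapply(lst, `[`, numeric(1), 3)),
      max = unname(vapply(lst, `[`, numeric(1), 4))
    )
  }
  dplyr::bind_rows(row(h, "heifer"), row(s, "steer"))
}

#' Default trait correlation matrix of the cohort generator
#'
#' Pairwise correlations among the generated continuous traits. The
#' MBV-phenotype block carries the observed correlations of each MBV score
#' with hip height, final BW, HCW, fat thickness, marbling score, ribeye area
#' and days on feed; only two phenotype-phenotype pairs are defaulted
#' non-zero (final BW with HCW, 0.95; fat thickness with marbling, 0.35) -
#' the source population's full phenotype correlation matrix is not
#' published. All other pairs default to 0. The matrix is symmetric with unit
#' diagonal; [generate_cohort()] repairs it by eigenvalue clipping if it is
#' not positive semi-definite.
#'
#' @return A 20 x 20 named correlation matrix.
#' @export
cohort_correlations <- function() {
  v <- COHORT_VARS
  m <- diag(length(v))
  dimnames(m) <- list(v, v)
  set <- function(i, j, r) {
    m[i, j] <<- r
    m[j, i] <<- r
  }
  # phenotype-phenotype defaults
  set("final_bw_kg", "hcw_kg", 0.95)
  set("ft_cm", "marbling", 0.35)
  # MBV x phenotype: columns HH, finalBW, HCW, FT, marbling, REA, DOF
  ph <- c("hip_height_cm", "final_bw_kg", "hcw_kg", "ft_cm", "marbling",
          "rea_cm2", "dof_d")
  mb <- list(
    mbv_cab_mrb   = c(-0.060, 0.109, 0.011, 0.261, 0.213, -0.177, 0.016),
    mbv_adg       = c(-0.031, 0.069, 0.032, 0.060, 0.046, -0.069, 0.056),
    mbv_hcw       = c(0.072, 0.162, 0.158, -0.068, 0.063, 0.144, 0.152),
    mbv_rea       = c(0.173, 0.065, 0.138, -0.335, -0.135, 0.370, 0.199),
    mbv_snp50_mrb = c(-0.062, 0.112, 0.020, 0.217, 0.189, -0.148, 0.009),
    mbv_snp50_rea = c(0.097, 0.004, 0.038, -0.152, -0.129, 0.130, 0.061),
    mbv_all_mrb   = c(0.013, 0.163, 0.079, 0.145, 0.129, -0.041, 0.135),
    mbv_all_rea   = c(0.066, 0.100, 0.101, -0.120, -0.071, 0.159, 0.127),
    mbv_all_adg   = c(-0.102, 0.007, -0.044, 0.199, 0.121, -0.144, 0.024),
    mbv_all_rfi   = c(0.091, 0.067, 0.099, -0.056, -0.047, 0.106, 0.025),
    mbv_bt_rfi    = c(-0.036, 0.083, 0.016, 0.215, 0.153, -0.094, 0.111)
  )
  for (nm in names(mb)) {
    for (k in seq_along(ph)) set(nm, ph[k], mb[[nm]][k])
  }
  m
}

#' Default leptin genotype frequencies
#'
#' Per-sex genotype frequencies for the two leptin SNPs, normalized from the
#' source population's printed genotype counts (heifers E2FB 254:416:164 and
#' UASMS2 406:349:61; steers E2FB 233:333:113 and UASMS2 313:282:70). Note
#' the source's internal inconsistency: its descriptive table assigns these
#' count columns to the sexes as above, while its text attributes the
#' resulting C:T ratios of 1.24 (E2FB) and 2.46 (UASMS2) to steers. This
#' package consumes the raw counts as printed and does not resolve the
#' labelling.
#'
#' @return Tibble with `snp`, `sex`, `cc`, `ct`, `tt` (counts) and
#'   `p_cc`, `p_ct`, `p_tt` (frequencies).
#' @export
genotype_frequencies <- function() {
  d <- tibble::tribble(
    ~snp, ~sex, ~cc, ~ct, ~tt,
    "e2fb", "heifer", 254, 416, 164,
    "uasms2", "heifer", 406, 349, 61,
    "e2fb", "steer", 233, 333, 113,
    "uasms2", "steer", 313, 282, 70
  )
  tot <- d$cc + d$ct + d$tt
  d$p_cc <- d$cc / tot
  d$p_ct <- d$ct / tot
  d$p_tt <- d$tt / tot
  d
}
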