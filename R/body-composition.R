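#' Frame score from hip height and age
#'
#' Computes the 1-9 skeletal frame score from hip height using the Beef
#' Improvement Federation polynomials. Steers (and bulls) use the male form,
#' heifers the female form. The score is returned as a continuous value and is
#' deliberately not clamped to the 1-9 scale; the downstream AFSBW lines are
#' linear and tolerate out-of-range scores.
#'
#' @param hip_height_cm Hip height in cm. Must be positive; the equations were
#'   developed for roughly 90-160 cm.
#' @param age_d Age in days when hip height was measured (default 365). The
#'   polynomials are valid between 5 and 21 months (150-640 d); values outside
#'   that window trigger a warning, not an error.
#' @param sex `"steer"` (male form) or `"heifer"` (female form). Vectorized.
#' @return Numeric vector of continuous frame scores.
#' @examples
#' frame_score(120, 365, "steer")
#' frame_score(117, 365, "heifer")
#' @export
frame_score <- function(hip_height_cm, age_d = 365, sex = "steer") {
  if (any(hip_height_cm <= 0, na.rm = TRUE)) {
    abort("hip_height_cm must be positive")
  }
  out_age <- age_d < FS_AGE_RANGE[1] | age_d > FS_AGE_RANGE[2]
  if (any(out_age, na.rm = TRUE)) {
    warn("age_d outside the 150-640 d validity window of the frame-score equations")
  }
  a <- sex_indicator(sex)
  n <- max(length(hip_height_cm), length(age_d), length(a))
  hh <- rep_len(hip_height_cm, n)
  age <- rep_len(age_d, n)
  a <- rep_len(a, n)
  male <- FS_BULL[["intercept"]] + FS_BULL[["hh"]] * hh + FS_BULL[["age"]] * age +
    FS_BULL[["age2"]] * age^2 + FS_BULL[["hh_age"]] * hh * age
  fem <- FS_FEMALE[["intercept"]] + FS_FEMALE[["hh"]] * hh + FS_FEMALE[["age"]] * age +
    FS_FEMALE[["age2"]] * age^2 + FS_FEMALE[["hh_age"]] * hh * age
  fs <- ifelse(a == 1, fem, male)
  if (any(fs < 1 | fs > 9, na.rm = TRUE)) {
    inform("some frame scores fall outside the nominal 1-9 scale; not clamped",
           .frequency = "once", .frequency_id = "mbvgrowth_fs_range")
  }
  fs
}

#' Adjusted final shrunk body weight from frame score
#'
#' Maps a frame score to the shrunk body weight (kg) the animal is expected to
#' reach at the target body-fat endpoint (28 % empty body fat, USDA low
#' Choice), using sex-class-specific linear equations.
#'
#' @param frame_score Continuous frame score (see [frame_score()]).
#' @param sex_class One of `"bull"`, `"steer"`, `"heifer"`. Vectorized.
#' @return AFSBW in kg.
#' @examples
#' afsbw_from_frame(4.113, "steer")
#' @export
afsbw_from_frame <- function(frame_score, sex_class) {
  sex_class <- tolower(as.character(sex_class))
  bad <- !sex_class %in% names(AFSBW_LINES)
  if (any(bad)) {
    abort(paste0("unknown sex_class: ", paste(unique(sex_class[bad]), collapse = ", ")))
  }
  n <- max(length(frame_score), length(sex_class))
  fs <- rep_len(frame_score, n)
  sc <- rep_len(sex_class, n)
  slope <- vapply(sc, function(s) AFSBW_LINES[[s]][["slope"]], numeric(1))
  icpt <- vapply(sc, function(s) AFSBW_LINES[[s]][["intercept"]], numeric(1))
  unname(slope * fs + icpt)
}

#' Empty body fat from carcass traits
#'
#' Predicts empty body fat (% of empty body weight) from fat thickness, hot
#' carcass weight and marbling score, using the richer equation when ribeye
#' area is available and the reduced one otherwise. The equation actually used
#' is recorded per record.
#'
#' @param ft_cm Fat thickness (backfat) in cm.
#' @param hcw_kg Hot carcass weight in kg.
#' @param marbling Marbling score on the 2-9 USDA quality-grade scale.
#' @param rea_cm2 Ribeye area in cm2, or `NA`/`NULL` when not measured.
#' @param validate Reject marbling scores outside \[2, 9\] (default `TRUE`).
#' @return A tibble with columns `ebf_pct` and `ebf_equation_used`
#'   (`"with_rea"` or `"no_rea"`).
#' @examples
#' ebf_from_carcass(1.14, 356, 4.51, 88.3)
#' ebf_from_carcass(1.25, 326, 4.85)
#' @export
ebf_from_carcass <- function(ft_cm, hcw_kg, marbling, rea_cm2 = NULL,
                             validate = TRUE) {
  n <- max(length(ft_cm), length(hcw_kg), length(marbling),
           length(rea_cm2 %||% NA_real_))
  ft <- rep_len(ft_cm, n)
  hcw <- rep_len(hcw_kg, n)
  ms <- rep_len(marbling, n)
  rea <- rep_len(rea_cm2 %||% NA_real_, n)
  if (validate && any(ms < 2 | ms > 9, na.rm = TRUE)) {
    abort("marbling out of [2,9]")
  }
  with_rea <- !is.na(rea)
  ebf <- ifelse(
    with_rea,
    EBF_WITH_REA[["intercept"]] + EBF_WITH_REA[["ft"]] * ft +
      EBF_WITH_REA[["hcw"]] * hcw + EBF_WITH_REA[["ms"]] * ms +
      EBF_WITH_REA[["rea"]] * ifelse(is.na(rea), 0, rea),
    EBF_NO_REA[["intercept"]] + EBF_NO_REA[["ft"]] * ft +
      EBF_NO_REA[["hcw"]] * hcw + EBF_NO_REA[["ms"]] * ms
  )
  tibble::tibble(
    ebf_pct = ebf,
    ebf_equation_used = ifelse(with_rea, "with_rea", "no_rea")
  )
}

#' AFSBW from carcass traits
#'
#' Full carcass-trait route to body composition: empty body fat from
#' [ebf_from_carcass()], empty body weight from hot carcass weight
#' (EBW = 1.316 HCW + 32.39), and the adjusted final shrunk body weight at the
#' target fat endpoint via the 14.26 kg per %-EBF relationship,
#' AFSBW = (EBW + 14.26 (target - EBF)) / 0.891.
#'
#' @inheritParams ebf_from_carcass
#' @param target_ebf Empty-body-fat endpoint in % (default 28, USDA low
#'   Choice). The endpoint is exposed because it can differ by sex and breed
#'   type.
#' @return A tibble with `ebf_pct`, `ebw_kg`, `afsbw_ct_kg`,
#'   `ebf_equation_used`.
#' @examples
#' afsbw_from_carcass(1.25, 326, 4.85)           # reduced EBF equation
#' afsbw_from_carcass(1.14, 356, 4.51, 88.3)     # with ribeye area
#' @export
afsbw_from_carcass <- function(ft_cm, hcw_kg, marbling, rea_cm2 = NULL,
                               target_ebf = TARGET_EBF_DEFAULT,
                               validate = TRUE) {
  ebf <- ebf_from_carcass(ft_cm, hcw_kg, marbling, rea_cm2, validate = validate)
  ebw <- EBW_FROM_HCW[["intercept"]] + EBW_FROM_HCW[["hcw"]] * rep_len(hcw_kg, nrow(ebf))
  afsbw <- (ebw + KG_PER_PCT_EBF * (target_ebf - ebf$ebf_pct)) / EBW_PER_SBW
  tibble::tibble(
    ebf_pct = ebf$ebf_pct,
    ebw_kg = ebw,
    afsbw_ct_kg = afsbw,
    ebf_equation_used = ebf$ebf_equation_used
  )
}

#' Add body-composition columns to a cohort
#'
#' Data-frame-first wrapper over the composition equations. Adds the
#' hip-height route (`frame_score`, `afsbw_hh_kg`) and, when carcass columns
#' are present, the carcass route (`ebf_pct`, `ebw_kg`, `afsbw_ct_kg`,
#' `ebf_equation_used`).
#'
#' @param data A cohort data frame with columns `sex`, `hip_height_cm` and
#'   optionally `age_d`, `hcw_kg`, `ft_cm`, `marbling`, `rea_cm2` (canonical
#'   names, see [cohort_dictionary()]).
#' @param target_ebf Empty-body-fat endpoint in % (default 28).
#' @param default_age_d Age assumed when `age_d` is absent (default 365 d).
#' @return The input as a tibble with composition columns appended.
#' @export
add_body_composition <- function(data, target_ebf = TARGET_EBF_DEFAULT,
                                 default_age_d = 365) {
  data <- tibble::as_tibble(data)
  age <- if ("age_d" %in% names(data)) data$age_d else default_age_d
  data$frame_score <- frame_score(data$hip_height_cm, age, data$sex)
  data$afsbw_hh_kg <- afsbw_from_frame(data$frame_score, data$sex)
  if (all(c("hcw_kg", "ft_cm", "marbling") %in% names(data))) {
    rea <- if ("rea_cm2" %in% names(data)) data$rea_cm2 else NULL
    ct <- afsbw_from_carcass(data$ft_cm, data$hcw_kg, data$marbling, rea,
                             target_ebf = target_ebf)
    data$ebf_pct <- ct$ebf_pct
    data$ebw_kg <- ct$ebw_kg
    data$afsbw_ct_kg <- ct$afsbw_ct_kg
    data$ebf_equation_used <- ct$ebf_equation_used
  }
  data
}
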