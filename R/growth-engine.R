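#' Net energy values of a diet from its metabolizable energy
#'
#' Converts diet metabolizable energy to net energy for maintenance and for
#' gain using the standard cubic conversions. At the default feedlot diet of
#' ME = 3.2 Mcal/kg these give NEg = 1.51 and NEm = 2.19 Mcal/kg, in line with
#' the 1.5 / 2.2 Mcal/kg values typical of finishing diets.
#'
#' @param me Metabolizable energy, Mcal/kg DM. Must lie in (1.5, 4.0).
#' @return A tibble with columns `me`, `nem`, `neg` (Mcal/kg).
#' @examples
#' diet_energy(3.2)
#' @export
diet_energy <- function(me) {
  if (any(me <= 1.5 | me >= 4.0, na.rm = TRUE)) {
    abort("me must be within (1.5, 4.0) Mcal/kg")
  }
  tibble::tibble(
    me = me,
    nem = NEM_FROM_ME[["me"]] * me + NEM_FROM_ME[["me2"]] * me^2 +
      NEM_FROM_ME[["me3"]] * me^3 + NEM_FROM_ME[["intercept"]],
    neg = NEG_FROM_ME[["me"]] * me + NEG_FROM_ME[["me2"]] * me^2 +
      NEG_FROM_ME[["me3"]] * me^3 + NEG_FROM_ME[["intercept"]]
  )
}

#' Diet and engine configuration
#'
#' Bundles the diet energy values and the growth-engine tuning knobs. `nem`
#' and `neg` are derived from `me` unless overridden explicitly.
#'
#' @param me Diet metabolizable energy, Mcal/kg (default 3.2, a typical
#'   high-grain finishing diet).
#' @param nem,neg Optional overrides for the net energy values (Mcal/kg).
#' @param maintenance_factor Multiplicative adjustment on the maintenance
#'   requirement (default 1; environmental stress would raise it).
#' @param srw Standard reference weight, kg shrunk BW at 28 % empty body fat
#'   (default 478).
#' @param target_ebf Empty-body-fat endpoint, % (default 28).
#' @return An object of class `diet_spec`.
#' @examples
#' diet_spec()
#' @export
diet_spec <- function(me = 3.2, nem = NULL, neg = NULL,
                      maintenance_factor = 1, srw = SRW_DEFAULT,
                      target_ebf = TARGET_EBF_DEFAULT) {
  en <- diet_energy(me)
  nem <- nem %||% en$nem
  neg <- neg %||% en$neg
  if (!(nem > neg && neg > 0)) abort("need nem > neg > 0")
  if (maintenance_factor <= 0) abort("maintenance_factor must be positive")
  structure(
    list(me = me, nem = nem, neg = neg,
         maintenance_factor = maintenance_factor,
         srw = srw, target_ebf = target_ebf),
    class = "diet_spec"
  )
}

#' @export
print.diet_spec <- function(x, ...) {
  cat(sprintf(
    "<diet_spec> ME %.2f, NEm %.3f, NEg %.3f Mcal/kg; maint x%.2f; SRW %g kg at %g%% EBF\n",
    x$me, x$nem, x$neg, x$maintenance_factor, x$srw, x$target_ebf))
  invisible(x)
}

#' Maintenance net-energy requirement
#'
#' NEm required (Mcal/d) of a growing animal: `0.077 * SBW^0.75`, optionally
#' scaled by a maintenance adjustment factor.
#'
#' @param sbw Shrunk body weight, kg.
#' @param maintenance_factor Multiplicative adjustment (default 1).
#' @return Mcal/d.
#' @examples
#' maintenance_nem(400)
#' @export
maintenance_nem <- function(sbw, maintenance_factor = 1) {
  if (any(sbw < 0, na.rm = TRUE)) abort("sbw must be non-negative")
  MAINT_COEF * sbw^0.75 * maintenance_factor
}

#' Retained energy of gain
#'
#' Size-scaled retained energy (Mcal/d) of an animal gaining `adg` kg/d of
#' shrunk weight. The animal's weight is first expressed on the scale of a
#' standard reference animal through the equivalent shrunk body weight
#' EQSBW = SBW * SRW / AFSBW, then
#' RE = 0.0635 (0.891 EQSBW)^0.75 (0.956 ADG)^1.097,
#' with 0.891 converting shrunk to empty body weight and 0.956 shrunk gain to
#' empty-body gain.
#'
#' @param sbw Current shrunk body weight, kg.
#' @param afsbw Adjusted final shrunk BW at the fat endpoint, kg.
#' @param adg Shrunk average daily gain, kg/d. Zero gain retains zero energy.
#' @param srw Standard reference weight, kg (default 478).
#' @return Mcal/d.
#' @examples
#' retained_energy(478, 478, 1.0)
#' @export
retained_energy <- function(sbw, afsbw, adg, srw = SRW_DEFAULT) {
  if (any(sbw <= 0 | afsbw <= 0, na.rm = TRUE)) abort("sbw and afsbw must be positive")
  n <- max(length(sbw), length(afsbw), length(adg))
  sbw <- rep_len(sbw, n); afsbw <- rep_len(afsbw, n); adg <- rep_len(adg, n)
  eqsbw <- sbw * srw / afsbw
  re <- RE_COEF * (EBW_PER_SBW * eqsbw)^RE_W_EXP *
    (EBG_PER_SWG * pmax(adg, 0))^RE_G_EXP
  ifelse(adg <= 0, 0, re)
}

#' Gain supported by a dry matter intake
#'
#' Inverts the retained-energy relationship: intake is first split between
#' maintenance and gain (maintenance is fed at NEm, the remainder yields
#' retained energy at NEg), then the retained energy is converted back to
#' shrunk daily gain by the exact algebraic inverse of [retained_energy()].
#' Intake at or below maintenance returns zero gain with a warning (weight
#' loss is not modelled).
#'
#' @param dmi Dry matter intake, kg/d.
#' @param sbw Current shrunk body weight, kg.
#' @param afsbw Adjusted final shrunk BW at the fat endpoint, kg.
#' @param diet A [diet_spec()].
#' @param quiet Suppress the below-maintenance warning (used by the daily
#'   projection loop).
#' @return Shrunk ADG, kg/d.
#' @examples
#' predict_adg_from_dmi(9, 400, 550, diet_spec())
#' @export
predict_adg_from_dmi <- function(dmi, sbw, afsbw, diet = diet_spec(),
                                 quiet = FALSE) {
  maint_dmi <- maintenance_nem(sbw, diet$maintenance_factor) / diet$nem
  re_avail <- (dmi - maint_dmi) * diet$neg
  below <- re_avail <= 0
  if (any(below, na.rm = TRUE) && !quiet) {
    warn("intake at or below maintenance; ADG set to 0")
  }
  eqsbw <- sbw * diet$srw / afsbw
  w_term <- RE_COEF * (EBW_PER_SBW * eqsbw)^RE_W_EXP
  ebg <- (pmax(re_avail, 0) / w_term)^(1 / RE_G_EXP)
  ifelse(below, 0, ebg / EBG_PER_SWG)
}

#' Empirical dry matter intake of growing cattle
#'
#' Default intake predictor for the forward projection:
#' `DMI = SBW^0.75 (0.2435 NEm - 0.0466 NEm^2 - 0.0869) / NEm`.
#'
#' @inheritParams predict_adg_from_dmi
#' @return kg/d.
#' @examples
#' dmi_nrc(400, diet_spec())
#' @export
dmi_nrc <- function(sbw, diet = diet_spec()) {
  nem <- diet$nem
  sbw^0.75 * (DMI_EMP[["nem"]] * nem + DMI_EMP[["nem2"]] * nem^2 +
                DMI_EMP[["intercept"]]) / nem
}

#' End-BW intake stub
#'
#' Stand-in for an alternative empirical intake equation driven by the
#' animal's end body weight: the empirical intake form of [dmi_nrc()]
#' evaluated at the end BW with the diet NEm fixed at 2.2 Mcal/kg. Any
#' function of `(sbw, diet)` can be plugged into [project_days_on_feed()]
#' instead.
#'
#' @param end_bw End (final) body weight, kg.
#' @param nem NEm assumed available for maintenance, Mcal/kg (default 2.2).
#' @return kg/d.
#' @export
dmi_end_bw <- function(end_bw, nem = DMI_ENDBW_NEM) {
  end_bw^0.75 * (DMI_EMP[["nem"]] * nem + DMI_EMP[["nem2"]] * nem^2 +
                   DMI_EMP[["intercept"]]) / nem
}

#' Project days on feed to the target weight
#'
#' Daily forward simulation from the initial shrunk BW: each day intake comes
#' from the pluggable `dmi_model`, gain from [predict_adg_from_dmi()], and the
#' weight is advanced explicitly (Euler, 1-d step). The projection stops on
#' the first day the target AFSBW is met.
#'
#' @param isbw Initial shrunk body weight, kg.
#' @param afsbw Target adjusted final shrunk BW, kg; must exceed `isbw`.
#' @param diet A [diet_spec()].
#' @param dmi_model Function `(sbw, diet) -> kg/d` (default [dmi_nrc()]).
#' @param max_days Give up after this many days (default 1000).
#' @return One-row tibble per animal: `dof_pred_d` (integer days),
#'   `pdmi_kg_d` and `padg_kg_d` (means over the horizon). Vectorized over
#'   `isbw`/`afsbw`.
#' @examples
#' project_days_on_feed(314, 556)
#' @export
project_days_on_feed <- function(isbw, afsbw, diet = diet_spec(),
                                 dmi_model = dmi_nrc, max_days = 1000) {
  n <- max(length(isbw), length(afsbw))
  isbw <- rep_len(isbw, n)
  afsbw <- rep_len(afsbw, n)
  one <- function(w0, wt) {
    if (wt <= w0) abort("afsbw must exceed isbw for a forward projection")
    sbw <- w0
    dmi_sum <- 0
    adg_sum <- 0
    for (d in seq_len(max_days)) {
      dmi <- dmi_model(sbw, diet)
      adg <- predict_adg_from_dmi(dmi, sbw, wt, diet, quiet = TRUE)
      dmi_sum <- dmi_sum + dmi
      adg_sum <- adg_sum + adg
      sbw <- sbw + adg
      if (sbw >= wt) {
        return(tibble::tibble(dof_pred_d = d,
                              pdmi_kg_d = dmi_sum / d,
                              padg_kg_d = adg_sum / d))
      }
    }
    abort(sprintf("projection did not reach %.0f kg within %d days", wt, max_days))
  }
  purrr::map2_dfr(isbw, afsbw, one)
}

#' Expected days on feed from observed gain
#'
#' `eDOF = (AFSBW_CT - iSBW) / oADG`: the days an animal gaining at its
#' observed rate needs to reach the carcass-trait-based target weight. Using
#' the observed ADG removes the intake- and gain-prediction uncertainty from
#' the days-on-feed estimate.
#'
#' @param afsbw_ct Carcass-trait-based AFSBW, kg.
#' @param isbw Initial shrunk BW, kg.
#' @param oadg Observed shrunk ADG, kg/d; must be positive.
#' @return Real-valued days (no rounding). Negative values (target below the
#'   initial weight) are returned but flagged with a warning.
#' @examples
#' expected_dof(507.0, 297, 1.36)
#' @export
expected_dof <- function(afsbw_ct, isbw, oadg) {
  if (any(oadg <= 0, na.rm = TRUE)) abort("oadg must be positive")
  edof <- (afsbw_ct - isbw) / oadg
  if (any(edof < 0, na.rm = TRUE)) {
    warn("afsbw_ct below isbw for some animals; negative eDOF returned")
  }
  edof
}

#' Dry matter required for an observed gain
#'
#' Backward calculation of the feed an individual must have eaten to achieve
#' its observed gain: the weight trajectory is reconstructed day by day from
#' the initial BW and the observed ADG, and each day's requirement is
#' maintenance intake plus the intake that supplies the retained energy of
#' that day's gain, `DMR_day = NEm_req/NEm + RE/NEg`. The mean daily value is
#' returned; it serves as a proxy for intake when individual intake is not
#' recorded (animals fed in groups).
#'
#' @param isbw Initial shrunk BW, kg.
#' @param oadg Observed shrunk ADG, kg/d.
#' @param dof Observed days on feed.
#' @param afsbw Adjusted final shrunk BW used to size-scale retained energy, kg.
#' @param diet A [diet_spec()].
#' @return Mean dry matter required, kg/d. Vectorized over animals.
#' @examples
#' dry_matter_required(314, 1.57, 162, 566.1)
#' @export
dry_matter_required <- function(isbw, oadg, dof, afsbw, diet = diet_spec()) {
  n <- max(length(isbw), length(oadg), length(dof), length(afsbw))
  isbw <- rep_len(isbw, n); oadg <- rep_len(oadg, n)
  dof <- rep_len(dof, n); afsbw <- rep_len(afsbw, n)
  if (any(is.na(oadg) | is.na(dof))) abort("oadg and dof are required")
  if (any(dof < 1)) abort("dof must be at least 1 day")
  one <- function(w0, g, d, wt) {
    day <- seq_len(ceiling(d))
    sbw <- w0 + g * (day - 1)
    dmr <- maintenance_nem(sbw, diet$maintenance_factor) / diet$nem +
      retained_energy(sbw, wt, g, diet$srw) / diet$neg
    mean(dmr)
  }
  purrr::pmap_dbl(list(isbw, oadg, dof, afsbw), one)
}

#' Add growth-engine predictions to a cohort
#'
#' Runs the forward projection to both AFSBW estimates (hip-height and
#' carcass-trait routes), computes the expected days on feed from observed
#' gain, and back-calculates the dry matter required. Appends, per method
#' suffix `_hh` / `_ct`: `pdmi*_kg_d`, `padg*_kg_d`, `dof_pred*_d`, plus
#' `edof_d` and `dmr_kg_d`.
#'
#' @param data Cohort with `isbw_kg`, `adg_kg_d`, `dof_d`, `afsbw_hh_kg`,
#'   `afsbw_ct_kg` (see [add_body_composition()]).
#' @param diet A [diet_spec()].
#' @param dmi_model Intake predictor for the projection (default [dmi_nrc()]).
#' @param max_days Projection horizon per animal.
#' @return The cohort tibble with prediction columns appended.
#' @export
add_growth_predictions <- function(data, diet = diet_spec(),
                                   dmi_model = dmi_nrc, max_days = 1000) {
  data <- tibble::as_tibble(data)
  for (m in c("hh", "ct")) {
    target <- data[[paste0("afsbw_", m, "_kg")]]
    if (is.null(target)) next
    ok <- !is.na(target) & !is.na(data$isbw_kg) & target > data$isbw_kg
    if (!all(ok)) {
      warn(sprintf("%d animal(s) with AFSBW_%s at or below initial BW: projection set to NA",
                   sum(!ok), toupper(m)))
    }
    pr <- tibble::tibble(dof_pred_d = rep(NA_real_, nrow(data)),
                         pdmi_kg_d = NA_real_, padg_kg_d = NA_real_)
    if (any(ok)) {
      pr[ok, ] <- project_days_on_feed(data$isbw_kg[ok], target[ok], diet,
                                       dmi_model, max_days)[, c("dof_pred_d", "pdmi_kg_d", "padg_kg_d")]
    }
    data[[paste0("pdmi_", m, "_kg_d")]] <- pr$pdmi_kg_d
    data[[paste0("padg_", m, "_kg_d")]] <- pr$padg_kg_d
    data[[paste0("dof_pred_", m, "_d")]] <- pr$dof_pred_d
  }
  if (!is.null(data$afsbw_ct_kg)) {
    data$edof_d <- expected_dof(data$afsbw_ct_kg, data$isbw_kg, data$adg_kg_d)
    data$dmr_kg_d <- dry_matter_required(data$isbw_kg, data$adg_kg_d,
                                         data$dof_d, data$afsbw_ct_kg, diet)
  }
  data
}
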