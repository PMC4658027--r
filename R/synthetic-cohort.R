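# truncated-normal quantile via the probability-integral transform
qtruncnorm <- function(p, mean, sd, lo, hi) {
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  qnorm(plo + p * (phi - plo), mean, sd)
}

# clip negative eigenvalues and renormalize to unit diagonal
repair_correlation <- function(m, tol = 1e-8) {
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) >= -tol) return(m)
  warn("default correlation matrix not positive semi-definite; repaired by eigenvalue clipping")
  v <- pmax(e$values, tol)
  r <- e$vectors %*% diag(v) %*% t(e$vectors)
  d <- sqrt(diag(r))
  r <- r / outer(d, d)
  dimnames(r) <- dimnames(m)
  r
}

#' Specification of a synthetic feedlot cohort
#'
#' Collects everything [generate_cohort()] needs: cohort sizes, per-sex
#' marginal distributions, the trait correlation matrix, leptin genotype
#' frequencies, and an optional generating truth so that downstream fitting
#' can be tested against known coefficients.
#'
#' With `truth = "afsbw_mbv"` (or `"afsbw_frame"`) the carcass-trait AFSBW is
#' generated as the corresponding reference mean function plus Normal
#' residual noise of SD `residual_sd`; with `truth = "dmr_pdmi"` /
#' `"dmr_endbw"` the predicted intake is first produced by the growth
#' engine's default (or end-BW) intake model and the dry matter required is
#' generated likewise. `calibrate_total_sd` rescales the systematic part
#' around its mean so the total response SD hits a target value (used to
#' emulate a response whose total SD is known but whose systematic-part
#' variance is not directly published); the rescaled part stays inside the
#' span of the model terms, so fitted r-squared reflects the
#' systematic-to-total variance ratio.
#'
#' @param n_heifers,n_steers Cohort sizes (defaults 681 and 836, the emulated
#'   population).
#' @param marginals Marginal table as from [cohort_defaults()].
#' @param correlations Correlation matrix as from [cohort_correlations()].
#' @param genotypes Genotype frequency table as from
#'   [genotype_frequencies()].
#' @param truth `"none"` or one of the adjustment forms of
#'   [reference_adjustments()].
#' @param truth_coefs Named coefficient vector for the truth mean function
#'   (default: the reference set of the chosen form).
#' @param residual_sd Residual SD of the truth response (default: the
#'   reference RMSE of the chosen form).
#' @param calibrate_total_sd Optional target total SD of the truth response.
#' @param enforce_range Truncate marginals to their printed ranges
#'   (default `TRUE`).
#' @param leptin_coupling Optional additive coupling of `mbv_rea` to the
#'   leptin class (the CC/CC class gets `leptin_coupling_effect` added, then
#'   the score is re-centred); off by default because genotypes and MBVs are
#'   drawn independently.
#' @param leptin_coupling_effect Size of that offset (default 0.25).
#' @param diet [diet_spec()] used when a truth needs predicted intake.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_heifers = 681, n_steers = 836,
                        marginals = cohort_defaults(),
                        correlations = cohort_correlations(),
                        genotypes = genotype_frequencies(),
                        truth = c("none", "afsbw_mbv", "afsbw_frame",
                                  "dmr_pdmi", "dmr_endbw"),
                        truth_coefs = NULL, residual_sd = NULL,
                        calibrate_total_sd = NULL, enforce_range = TRUE,
                        leptin_coupling = FALSE,
                        leptin_coupling_effect = 0.25,
                        diet = diet_spec()) {
  truth <- match.arg(truth)
  if (any(marginals$sd <= 0)) abort("marginal SDs must be positive")
  if (!isSymmetric(unname(correlations)) ||
      any(abs(diag(correlations) - 1) > 1e-12)) {
    abort("correlations must be symmetric with unit diagonal")
  }
  for (col in c("p_cc", "p_ct", "p_tt")) {
    if (any(genotypes[[col]] < 0)) abort("genotype probabilities must be non-negative")
  }
  if (any(abs(genotypes$p_cc + genotypes$p_ct + genotypes$p_tt - 1) > 1e-8)) {
    abort("genotype probabilities must sum to 1")
  }
  if (truth != "none") {
    ref <- reference_adjustments()[[truth]]
    truth_coefs <- truth_coefs %||% ref$coefs
    residual_sd <- residual_sd %||% ref$rmse
  }
  structure(
    list(n_heifers = n_heifers, n_steers = n_steers, marginals = marginals,
         correlations = correlations, genotypes = genotypes, truth = truth,
         truth_coefs = truth_coefs, residual_sd = residual_sd,
         calibrate_total_sd = calibrate_total_sd,
         enforce_range = enforce_range, leptin_coupling = leptin_coupling,
         leptin_coupling_effect = leptin_coupling_effect, diet = diet),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("<cohort_spec> %d heifers + %d steers; truth = %s%s\n",
              x$n_heifers, x$n_steers, x$truth,
              if (x$truth != "none") sprintf(" (residual SD %.3g)", x$residual_sd) else ""))
  invisible(x)
}

draw_sex <- function(spec, sex, n, corr) {
  marg <- spec$marginals[spec$marginals$sex == sex, ]
  marg <- marg[match(COHORT_VARS, marg$variable), ]
  if (any(is.na(marg$variable))) abort("marginals must cover every generated variable")
  L <- chol(corr)
  z <- matrix(rnorm(n * length(COHORT_VARS)), nrow = n) %*% L
  u <- pnorm(z)
  x <- vapply(seq_along(COHORT_VARS), function(j) {
    m <- marg[j, ]
    if (spec$enforce_range) qtruncnorm(u[, j], m$mean, m$sd, m$min, m$max)
    else qnorm(u[, j], m$mean, m$sd)
  }, numeric(n))
  colnames(x) <- COHORT_VARS
  out <- tibble::as_tibble(x)
  # marbling is scored in whole units on the 2-9 scale; population range 3-9
  out$marbling <- pmin(pmax(round(out$marbling), 3), 9)
  out$sex <- sex
  gt <- function(snp) {
    g <- spec$genotypes[spec$genotypes$snp == snp & spec$genotypes$sex == sex, ]
    sample(LEPTIN_GENOTYPES, n, replace = TRUE,
           prob = c(g$p_cc, g$p_ct, g$p_tt))
  }
  out$leptin_uasms2 <- gt("uasms2")
  out$leptin_e2fb <- gt("e2fb")
  out
}

#' Generate a synthetic feedlot cohort
#'
#' Draws a cohort with the configured statistical structure via a Gaussian
#' copula: correlated standard normals are transformed to per-sex
#' truncated-normal marginals; marbling is discretized to whole scores;
#' leptin genotypes are drawn independently per SNP from the per-sex
#' frequencies. The hip-height body-composition route (`frame_score`,
#' `afsbw_hh_kg`, age 365 d) is attached, and when a generating truth is
#' active the truth response is added together with hidden `truth_*` columns
#' holding its noiseless systematic part. Deterministic given `seed`.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed (optional; the current RNG state is used if
#'   absent).
#' @return A tibble of animal records (one row per animal) with attributes
#'   `generator_spec` and `truth_info` (see [truth_report()]).
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_heifers = 50, n_steers = 50), seed = 7)
#' dplyr::count(cohort, sex)
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = NULL) {
  if (!inherits(spec, "cohort_spec")) abort("spec must be a cohort_spec")
  if (!is.null(seed)) set.seed(seed)
  corr <- repair_correlation(spec$correlations[COHORT_VARS, COHORT_VARS])
  parts <- list()
  if (spec$n_heifers > 0) parts$h <- draw_sex(spec, "heifer", spec$n_heifers, corr)
  if (spec$n_steers > 0) parts$s <- draw_sex(spec, "steer", spec$n_steers, corr)
  out <- dplyr::bind_rows(parts)
  out$animal_id <- sprintf("A%05d", seq_len(nrow(out)))
  out$age_d <- 365
  out <- dplyr::relocate(out, "animal_id", "sex", "age_d")

  if (spec$leptin_coupling) {
    cccc <- out$leptin_uasms2 == "CC" & out$leptin_e2fb == "CC"
    shift <- spec$leptin_coupling_effect * (cccc - mean(cccc))
    out$mbv_rea <- out$mbv_rea + shift
  }

  out$frame_score <- frame_score(out$hip_height_cm, out$age_d, out$sex)
  out$afsbw_hh_kg <- afsbw_from_frame(out$frame_score, out$sex)

  truth_info <- NULL
  if (spec$truth != "none") {
    pdmi_col <- NULL
    if (spec$truth == "dmr_pdmi") {
      # intake the engine would predict near the middle of the feeding period
      out$pdmi_kg_d <- dmi_nrc((out$isbw_kg + out$final_bw_kg) / 2, spec$diet)
      pdmi_col <- "pdmi_kg_d"
    } else if (spec$truth == "dmr_endbw") {
      out$pdmi_endbw_kg_d <- dmi_end_bw(out$final_bw_kg)
      pdmi_col <- "pdmi_endbw_kg_d"
    }
    mu <- apply_adjustment(out, spec$truth, coefs = spec$truth_coefs,
                           pdmi_col = pdmi_col %||% "pdmi_kg_d")
    scale_applied <- 1
    if (!is.null(spec$calibrate_total_sd)) {
      sys_target <- sqrt(spec$calibrate_total_sd^2 - spec$residual_sd^2)
      if (is.nan(sys_target)) abort("calibrate_total_sd below residual_sd")
      scale_applied <- sys_target / sd(mu)
      mu <- mean(mu) + (mu - mean(mu)) * scale_applied
    }
    response <- reference_adjustments()[[spec$truth]]$response
    out[[response]] <- mu + rnorm(nrow(out), 0, spec$residual_sd)
    out[[paste0("truth_", response)]] <- mu
    truth_info <- list(form = spec$truth, response = response,
                       coefs = spec$truth_coefs,
                       residual_sd = spec$residual_sd,
                       systematic_scale = scale_applied,
                       pdmi_col = pdmi_col)
  }
  attr(out, "generator_spec") <- spec
  attr(out, "truth_info") <- truth_info
  out
}

#' Report the generating truth of a synthetic cohort
#'
#' Returns the exact coefficients and residual SD used to generate the truth
#' response of a cohort, for parameter-recovery assertions. A cohort
#' generated with `truth = "none"` yields an empty table.
#'
#' @param cohort A tibble from [generate_cohort()].
#' @return Tibble with `form`, `response`, `term`, `value`, plus rows for
#'   `residual_sd` and the systematic scaling factor.
#' @export
truth_report <- function(cohort) {
  ti <- attr(cohort, "truth_info")
  if (is.null(ti)) {
    return(tibble::tibble(form = character(), response = character(),
                          term = character(), value = numeric()))
  }
  tibble::tibble(
    form = ti$form, response = ti$response,
    term = c(names(ti$coefs), "residual_sd", "systematic_scale"),
    value = c(unname(ti$coefs), ti$residual_sd, ti$systematic_scale)
  )
}
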