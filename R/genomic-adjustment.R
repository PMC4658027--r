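#' Reference adjustment coefficient sets
#'
#' Coefficients of the four MBV-augmented adjustment equations calibrated on a
#' commercial feedyard population of 1,517 crossbred heifers and steers (1,499
#' with complete genomic records). The sex indicator `a` is 0 for steers and 1
#' for heifers throughout.
#'
#' * `afsbw_mbv` - carcass-trait AFSBW on the hip-height AFSBW with a sex
#'   interaction and the ribeye-area MBV:
#'   `AFSBW_CT = (312.8 - 175.9 a) + (0.5354 + 0.392 a) AFSBW_HH + 44.5 MBV_REA`.
#' * `afsbw_frame` - carcass-trait AFSBW directly from hip height and initial
#'   BW (sex-interacted, with quadratic hip-height terms) plus the Angus
#'   marbling MBV (-0.257) and ribeye-area MBV (39.04).
#' * `dmr_pdmi` - dry matter required on model-predicted intake:
#'   `DMR = (-3.41 + 6.93 a) + (1.48 - 1.054 a) pDMI - 0.606 MBV_REA`.
#' * `dmr_endbw` - same response with the end-BW intake predictor:
#'   `DMR = (0.71 + 3.01 a) + (0.959 - 0.453 a) pDMI - 0.45 MBV_REA`.
#'
#' @return Named list; each element has `coefs` (named numeric vector),
#'   `response`, `n`, `rmse`, `r2`.
#' @examples
#' reference_adjustments()$afsbw_mbv$coefs
#' @export
reference_adjustments <- function() {
  list(
    afsbw_mbv = list(
      coefs = c(intercept = 312.8, a = -175.9, afsbw_hh = 0.5354,
                a_afsbw_hh = 0.392, mbv_rea = 44.5),
      response = "afsbw_ct_kg", n = 1499, rmse = 51.3, r2 = 0.39
    ),
    afsbw_frame = list(
      coefs = c(intercept = -1184.7, a = 15758, hh = 34.292, a_hh = -270.98,
                isbw = -2.155, a_isbw = -53.347, hh_isbw = 0.00888,
                a_hh_isbw = 0.9126, hh2 = -0.165, a_hh2 = 1.152,
                hh2_isbw = 0.00009, a_hh2_isbw = -0.00387,
                mbv_cab_mrb = -0.257, mbv_rea = 39.04),
      response = "afsbw_ct_kg", n = 1499, rmse = 49, r2 = 0.45
    ),
    dmr_pdmi = list(
      coefs = c(intercept = -3.41, a = 6.93, pdmi = 1.48, a_pdmi = -1.054,
                mbv_rea = -0.606),
      response = "dmr_kg_d", n = 1499, rmse = 1.11, r2 = 0.28
    ),
    dmr_endbw = list(
      coefs = c(intercept = 0.71, a = 3.01, pdmi = 0.959, a_pdmi = -0.453,
                mbv_rea = -0.45),
      response = "dmr_kg_d", n = 1499, rmse = 1.17, r2 = 0.20
    )
  )
}

# Design matrix (named columns) for one adjustment form.
adjustment_design <- function(form, data, pdmi_col = "pdmi_hh_kg_d") {
  a <- sex_indicator(data$sex)
  switch(
    form,
    afsbw_mbv = cbind(
      intercept = 1, a = a, afsbw_hh = data$afsbw_hh_kg,
      a_afsbw_hh = a * data$afsbw_hh_kg, mbv_rea = data$mbv_rea
    ),
    afsbw_frame = {
      hh <- data$hip_height_cm; isbw <- data$isbw_kg
      cbind(intercept = 1, a = a, hh = hh, a_hh = a * hh,
            isbw = isbw, a_isbw = a * isbw,
            hh_isbw = hh * isbw, a_hh_isbw = a * hh * isbw,
            hh2 = hh^2, a_hh2 = a * hh^2,
            hh2_isbw = hh^2 * isbw, a_hh2_isbw = a * hh^2 * isbw,
            mbv_cab_mrb = data$mbv_cab_mrb, mbv_rea = data$mbv_rea)
    },
    dmr_pdmi = ,
    dmr_endbw = {
      pdmi <- data[[pdmi_col]]
      if (is.null(pdmi)) abort(paste0("column ", pdmi_col, " not found"))
      cbind(intercept = 1, a = a, pdmi = pdmi, a_pdmi = a * pdmi,
            mbv_rea = data$mbv_rea)
    },
    abort(paste0("unknown adjustment form: ", form))
  )
}

#' Apply a reference (or fitted) adjustment equation
#'
#' Pure-arithmetic evaluation of an adjustment equation at given covariates;
#' bit-stable across runs. Coefficients default to the reference set for the
#' chosen form but a named vector (e.g. from a fit) can be supplied.
#'
#' @param data Cohort with the columns the form needs (`sex`, `afsbw_hh_kg`,
#'   `mbv_rea`, `hip_height_cm`, `isbw_kg`, `mbv_cab_mrb`, or the intake
#'   column for the DMR forms).
#' @param form One of `"afsbw_mbv"`, `"afsbw_frame"`, `"dmr_pdmi"`,
#'   `"dmr_endbw"`.
#' @param coefs Named coefficient vector (default: [reference_adjustments()]).
#' @param pdmi_col Intake column used by the DMR forms.
#' @return Numeric vector of predictions.
#' @examples
#' d <- tibble::tibble(sex = "steer", afsbw_hh_kg = 504.0, mbv_rea = -0.42)
#' apply_adjustment(d, "afsbw_mbv")
#' @export
apply_adjustment <- function(data, form = c("afsbw_mbv", "afsbw_frame",
                                            "dmr_pdmi", "dmr_endbw"),
                             coefs = NULL, pdmi_col = "pdmi_hh_kg_d") {
  form <- match.arg(form)
  coefs <- coefs %||% reference_adjustments()[[form]]$coefs
  x <- adjustment_design(form, data, pdmi_col)
  miss <- setdiff(names(coefs), colnames(x))
  if (length(miss)) abort(paste0("coefficients without design columns: ",
                                 paste(miss, collapse = ", ")))
  drop(x[, names(coefs), drop = FALSE] %*% coefs)
}

new_mbv_fit <- function(fit, form, response, data_n, selection = NULL) {
  s <- summary(fit)
  structure(
    list(fit = fit, form = form, response = response, n = data_n,
         rmse = s$sigma, r2 = s$r.squared, selection = selection),
    class = "mbv_fit"
  )
}

#' Fit an MBV-augmented adjustment equation
#'
#' Ordinary least squares fit of one of the four adjustment forms (see
#' [reference_adjustments()]) to a cohort. Rows with missing values in the
#' variables of the form are dropped. A single-sex cohort drops the sex terms
#' with a warning (the interaction cannot be estimated); a rank-deficient
#' design is rejected with the offending term named.
#'
#' @inheritParams apply_adjustment
#' @param response Response column; defaults to the form's canonical response
#'   (`afsbw_ct_kg` or `dmr_kg_d`).
#' @return An object of class `mbv_fit` with [tidy()], [glance()],
#'   [predict()][predict.mbv_fit] and [autoplot()] methods.
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_heifers = 150, n_steers = 150,
#'                                       truth = "afsbw_mbv"), seed = 1)
#' fit <- fit_adjustment(cohort, "afsbw_mbv")
#' glance(fit)
#' @export
fit_adjustment <- function(data, form = c("afsbw_mbv", "afsbw_frame",
                                          "dmr_pdmi", "dmr_endbw"),
                           response = NULL, pdmi_col = "pdmi_hh_kg_d") {
  form <- match.arg(form)
  response <- response %||% reference_adjustments()[[form]]$response
  if (!response %in% names(data)) {
    abort(paste0("response column ", response, " not found"))
  }
  x <- adjustment_design(form, data, pdmi_col)
  y <- data[[response]]
  ok <- complete.cases(x, y)
  x <- x[ok, , drop = FALSE]; y <- y[ok]
  if (length(unique(x[, "a"])) < 2) {
    warn("single-sex cohort: sex terms dropped from the adjustment form")
    x <- x[, !grepl("^a(_|$)", colnames(x)), drop = FALSE]
  }
  df <- data.frame(.y = y, x[, -1, drop = FALSE], check.names = FALSE)
  fit <- lm(.y ~ ., data = df)
  if (any(is.na(coef(fit)))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    abort(paste0("rank-deficient design; aliased term(s): ",
                 paste(bad, collapse = ", ")))
  }
  new_mbv_fit(fit, form, response, sum(ok))
}

#' @export
print.mbv_fit <- function(x, ...) {
  cat(sprintf("<mbv_fit: %s> n = %d, RMSE = %.4g, r2 = %.3f\n",
              x$form, x$n, x$rmse, x$r2))
  print(tidy(x), ...)
  invisible(x)
}

#' Predict from a fitted adjustment
#'
#' @param object An `mbv_fit`.
#' @param newdata Optional cohort to predict for (default: training data).
#' @param pdmi_col Intake column for the DMR forms.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.mbv_fit <- function(object, newdata = NULL, pdmi_col = "pdmi_hh_kg_d",
                            ...) {
  if (is.null(newdata)) return(unname(stats::fitted(object$fit)))
  if (identical(object$form, "stepwise")) {
    return(unname(predict(object$fit, newdata = as.data.frame(newdata))))
  }
  x <- adjustment_design(object$form, newdata, pdmi_col)
  keep <- intersect(colnames(x), c("intercept", names(coef(object$fit))[-1]))
  df <- data.frame(x[, setdiff(keep, "intercept"), drop = FALSE],
                   check.names = FALSE)
  unname(predict(object$fit, newdata = df))
}

#' Difference variables between the two prediction routes
#'
#' Forms the per-animal differences the genomic scores are asked to explain:
#' `d_afsbw_kg  = afsbw_ct_kg - afsbw_hh_kg`,
#' `d_adg_hh/ct = adg_kg_d - padg_hh/ct_kg_d` (observed minus predicted gain),
#' `d_dof_hh/ct = edof_d - dof_pred_hh/ct_d`, and
#' `d_dmi_kg_d  = dmr_kg_d - pdmi_hh_kg_d`.
#' Missing operands propagate to missing deltas (never silently zero). Columns
#' whose operands are absent are skipped.
#'
#' @param data Cohort carrying the prediction columns from
#'   [add_body_composition()] and [add_growth_predictions()].
#' @return The cohort with available delta columns appended.
#' @export
add_deltas <- function(data) {
  data <- tibble::as_tibble(data)
  pairs <- list(
    d_afsbw_kg  = c("afsbw_ct_kg", "afsbw_hh_kg"),
    d_adg_hh_kg_d = c("adg_kg_d", "padg_hh_kg_d"),
    d_adg_ct_kg_d = c("adg_kg_d", "padg_ct_kg_d"),
    d_dof_hh_d  = c("edof_d", "dof_pred_hh_d"),
    d_dof_ct_d  = c("edof_d", "dof_pred_ct_d"),
    d_dmi_kg_d  = c("dmr_kg_d", "pdmi_hh_kg_d")
  )
  for (nm in names(pairs)) {
    p <- pairs[[nm]]
    if (all(p %in% names(data))) data[[nm]] <- data[[p[1]]] - data[[p[2]]]
  }
  data
}

#' Stepwise OLS with entry/stay significance thresholds
#'
#' Classic forward-entry / backward-elimination stepwise selection on partial
#' F-test p-values, as implemented in the major statistical packages: at each
#' step the candidate with the smallest entry p-value below `entry_p` is
#' added, then terms whose stay p-value exceeds `stay_p` are removed (worst
#' first). Deterministic given the data and thresholds; ties are broken by
#' candidate list order. Mutually exclusive candidate pairs (e.g. a leptin
#' class factor and an MBV built from the same SNPs) are enforced: once one
#' member is in the model the other is never offered, and the exclusion is
#' recorded in the selection log.
#'
#' @param data Data frame with the response and candidate columns.
#' @param response Response column name.
#' @param candidates Character vector of candidate terms (column names or
#'   formula terms such as `"I(x^2)"` or `"x:sex"`).
#' @param entry_p,stay_p Significance to enter / to stay (defaults 0.15).
#' @param exclusive List of character pairs that must not co-enter.
#' @return An `mbv_fit` whose `selection` element logs each step.
#' @examples
#' d <- tibble::tibble(x = rnorm(50), z = rnorm(50), y = 3 * x + rnorm(50))
#' stepwise_ols(d, "y", c("x", "z"))
#' @export
stepwise_ols <- function(data, response, candidates, entry_p = 0.15,
                         stay_p = 0.15, exclusive = list()) {
  data <- as.data.frame(data)
  if (nrow(data) <= length(candidates) + 5) {
    abort("too few rows for the candidate pool")
  }
  in_model <- character(0)
  log <- list()
  blocked <- function() {
    unlist(lapply(exclusive, function(p) {
      if (any(p %in% in_model)) setdiff(p, in_model) else character(0)
    }))
  }
  fit_terms <- function(terms) {
    f <- if (length(terms)) {
      as.formula(paste(response, "~", paste(terms, collapse = " + ")))
    } else {
      as.formula(paste(response, "~ 1"))
    }
    lm(f, data = data)
  }
  repeat {
    changed <- FALSE
    # forward step
    pool <- setdiff(candidates, c(in_model, blocked()))
    if (length(pool)) {
      cur <- fit_terms(in_model)
      scope <- as.formula(paste("~ . +", paste(pool, collapse = " + ")))
      a1 <- add1(cur, scope = scope, test = "F")
      pv <- a1[["Pr(>F)"]][match(pool, rownames(a1))]
      names(pv) <- pool
      pv <- pv[!is.na(pv)]
      if (length(pv) && min(pv) < entry_p) {
        # first candidate (in list order) attaining the minimum enters
        best <- pool[pool %in% names(pv)[pv == min(pv)]][1]
        in_model <- c(in_model, best)
        excl <- blocked()
        log[[length(log) + 1]] <- list(step = "enter", term = best,
                                       p = unname(min(pv)),
                                       excluded = excl)
        if (length(excl)) {
          inform(paste0("mutual exclusion: ", paste(excl, collapse = ", "),
                        " no longer offered"))
        }
        changed <- TRUE
      }
    }
    # backward step
    if (length(in_model)) {
      cur <- fit_terms(in_model)
      d1 <- drop1(cur, test = "F")
      pv <- d1[["Pr(>F)"]][match(in_model, rownames(d1))]
      names(pv) <- in_model
      pv <- pv[!is.na(pv)]
      if (length(pv) && max(pv) > stay_p) {
        worst <- in_model[in_model %in% names(pv)[pv == max(pv)]][1]
        in_model <- setdiff(in_model, worst)
        log[[length(log) + 1]] <- list(step = "remove", term = worst,
                                       p = unname(max(pv)))
        changed <- TRUE
      }
    }
    # a term re-entering right after removal would cycle; add1/drop1 p-values
    # are deterministic so an unchanged pass terminates the search
    if (!changed) break
    if (length(log) > 10 * length(candidates)) {
      warn("stepwise selection cycled; returning current model")
      break
    }
  }
  fit <- fit_terms(in_model)
  new_mbv_fit(fit, "stepwise", response, nrow(data),
              selection = list(terms = in_model, log = log,
                               entry_p = entry_p, stay_p = stay_p))
}

#' Leptin genotype class
#'
#' Combines the UASMS2 and E2FB genotypes into the nine-level classificatory
#' variable (UASMS2 genotype first: CCCC, CCCT, ..., TTTT).
#'
#' @param uasms2,e2fb Genotype vectors with values CC, CT, TT.
#' @return Factor with the 9 combination levels.
#' @export
leptin_class <- function(uasms2, e2fb) {
  stopifnot(all(uasms2 %in% LEPTIN_GENOTYPES | is.na(uasms2)),
            all(e2fb %in% LEPTIN_GENOTYPES | is.na(e2fb)))
  lv <- as.vector(outer(LEPTIN_GENOTYPES, LEPTIN_GENOTYPES, paste0))
  factor(paste0(uasms2, e2fb), levels = sort(lv))
}

#' Allele statistics for a leptin SNP
#'
#' From genotype counts, computes allele counts (C = 2 CC + CT,
#' T = 2 TT + CT), the C:T ratio, and a Pearson chi-square test of the
#' genotype frequencies against the 25:50:25 (%) expectation.
#'
#' @param cc,ct,tt Genotype counts (non-negative integers; vectorized).
#' @param snp Optional label column.
#' @return Tibble with `snp`, `n`, `c_alleles`, `t_alleles`, `ct_ratio`,
#'   `chisq`, `df`, `p_value`.
#' @examples
#' leptin_allele_stats(406, 349, 61, snp = "UASMS2")
#' @export
leptin_allele_stats <- function(cc, ct, tt, snp = NULL) {
  n <- max(length(cc), length(ct), length(tt))
  cc <- rep_len(cc, n); ct <- rep_len(ct, n); tt <- rep_len(tt, n)
  if (any(c(cc, ct, tt) < 0) || any(cc + ct + tt <= 0)) {
    abort("counts must be non-negative with a positive total")
  }
  stats <- purrr::pmap_dfr(list(cc, ct, tt), function(x1, x2, x3) {
    ch <- suppressWarnings(chisq.test(c(x1, x2, x3), p = c(0.25, 0.5, 0.25)))
    tibble::tibble(chisq = unname(ch$statistic), df = unname(ch$parameter),
                   p_value = unname(ch$p.value))
  })
  tibble::tibble(
    snp = snp %||% NA_character_,
    n = cc + ct + tt,
    c_alleles = 2 * cc + ct,
    t_alleles = 2 * tt + ct,
    ct_ratio = (2 * cc + ct) / (2 * tt + ct),
    chisq = stats$chisq, df = stats$df, p_value = stats$p_value
  )
}

#' Incremental variance explained by an added predictor
#'
#' r-squared of nested OLS models: the base model, the full model with the
#' added predictor(s), and the increment, reported in percent.
#'
#' @param data Data frame.
#' @param response Response column name.
#' @param base Character vector of base predictor terms (may be empty, giving
#'   an intercept-only base).
#' @param added Character vector of added terms.
#' @return One-row tibble: `r2_base_pct`, `r2_full_pct`, `increment_pct`.
#' @export
variance_explained <- function(data, response, base, added) {
  data <- as.data.frame(data)
  f <- function(terms) {
    rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
    summary(lm(as.formula(paste(response, "~", rhs)), data = data))$r.squared
  }
  r2b <- f(base)
  r2f <- f(c(base, added))
  tibble::tibble(r2_base_pct = 100 * r2b, r2_full_pct = 100 * r2f,
                 increment_pct = 100 * (r2f - r2b))
}

#' Group effects of classificatory variables
#'
#' Fixed-effects linear model of a response on one or more factors (additive,
#' no interaction by default) with least-squares means per level: predictions
#' averaged over an equally weighted grid of the other factors' levels. Empty
#' cells are dropped with a warning.
#'
#' @param data Data frame.
#' @param response Response column name.
#' @param factors Character vector of factor column names (e.g. `sex`,
#'   `leptin_class`).
#' @return Tibble with `factor`, `level`, `lsmean`, `n`.
#' @export
group_effects <- function(data, response, factors) {
  data <- as.data.frame(data)
  for (f in factors) data[[f]] <- factor(data[[f]])
  keep <- complete.cases(data[, c(response, factors)])
  if (!all(keep)) warn(sprintf("%d incomplete rows dropped", sum(!keep)))
  data <- data[keep, , drop = FALSE]
  data <- droplevels(data)
  fml <- as.formula(paste(response, "~", paste(factors, collapse = " + ")))
  fit <- lm(fml, data = data)
  grid <- expand.grid(lapply(data[factors], levels),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$.pred <- predict(fit, newdata = grid)
  purrr::map_dfr(factors, function(f) {
    agg <- tapply(grid$.pred, grid[[f]], mean)
    cnt <- table(data[[f]])
    tibble::tibble(factor = f, level = names(agg), lsmean = unname(agg),
                   n = as.integer(cnt[names(agg)]))
  })
}
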