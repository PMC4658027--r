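#' Canonical column dictionary
#'
#' The contract between CSV files and the pipeline stages: canonical column
#' name, semantic type, units, and the first stage that requires it. Units
#' are embedded in the column names (`_kg`, `_cm`, `_d`) to prevent silent
#' unit errors. Unknown columns in an input file are preserved as
#' passthrough.
#'
#' @return Tibble with `column`, `type`, `units`, `required_by`.
#' @export
cohort_dictionary <- function() {
  tibble::tribble(
    ~column, ~type, ~units, ~required_by,
    "animal_id", "character", "", "io",
    "sex", "factor(steer,heifer)", "", "io",
    "isbw_kg", "numeric", "kg", "growth",
    "hip_height_cm", "numeric", "cm", "composition",
    "age_d", "numeric", "d", "composition",
    "adg_kg_d", "numeric", "kg/d", "growth",
    "dof_d", "numeric", "d", "growth",
    "final_bw_kg", "numeric", "kg", "optional",
    "hcw_kg", "numeric", "kg", "composition",
    "ft_cm", "numeric", "cm", "composition",
    "marbling", "numeric", "2-9 scale", "composition",
    "rea_cm2", "numeric", "cm2", "optional",
    "mbv_cab_mrb", "numeric", "", "adjustment",
    "mbv_adg", "numeric", "", "optional",
    "mbv_hcw", "numeric", "", "optional",
    "mbv_rea", "numeric", "", "adjustment",
    "mbv_snp50_mrb", "numeric", "", "optional",
    "mbv_snp50_rea", "numeric", "", "optional",
    "mbv_all_mrb", "numeric", "", "optional",
    "mbv_all_rea", "numeric", "", "optional",
    "mbv_all_adg", "numeric", "", "optional",
    "mbv_all_rfi", "numeric", "", "optional",
    "mbv_bt_rfi", "numeric", "", "optional",
    "leptin_uasms2", "factor(CC,CT,TT)", "", "optional",
    "leptin_e2fb", "factor(CC,CT,TT)", "", "optional"
  )
}

# per-row validation rules; each returns a reason string or NA
cohort_row_checks <- function(data) {
  reasons <- rep(NA_character_, nrow(data))
  flag <- function(bad, reason) {
    bad[is.na(bad)] <- FALSE
    reasons[bad & is.na(reasons)] <<- reason
  }
  if ("marbling" %in% names(data)) {
    flag(data$marbling < 2 | data$marbling > 9, "marbling out of [2,9]")
  }
  if ("isbw_kg" %in% names(data)) flag(data$isbw_kg <= 0, "isbw_kg not positive")
  if ("hip_height_cm" %in% names(data)) {
    flag(data$hip_height_cm < 90 | data$hip_height_cm > 160,
         "hip_height_cm out of [90,160]")
  }
  if ("adg_kg_d" %in% names(data)) flag(data$adg_kg_d <= 0, "adg_kg_d not positive")
  if ("sex" %in% names(data)) {
    flag(!tolower(as.character(data$sex)) %in% c("steer", "heifer"),
         "unknown sex")
  }
  for (g in c("leptin_uasms2", "leptin_e2fb")) {
    if (g %in% names(data)) {
      flag(!is.na(data[[g]]) & !data[[g]] %in% LEPTIN_GENOTYPES,
           paste0(g, " not CC/CT/TT"))
    }
  }
  reasons
}

#' Read and validate a cohort CSV
#'
#' Reads a cohort file against the [cohort_dictionary()]: header matching is
#' case-insensitive, required identity columns (`animal_id`, `sex`) must be
#' present, unknown columns are kept as passthrough, and rows violating the
#' per-row invariants (marbling in \[2, 9\], positive initial BW and ADG,
#' plausible hip height, known sex and genotypes) are quarantined with a
#' reason rather than silently dropped.
#'
#' @param path CSV file path.
#' @param quarantine If `TRUE` (default) invalid rows are removed from the
#'   returned table and attached as `attr(, "quarantine")`; if `FALSE` the
#'   full table is returned with a `quarantine_reason` column.
#' @return Validated tibble of animal records.
#' @export
read_cohort <- function(path, quarantine = TRUE) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_csv(path, show_col_types = FALSE)
  names(raw) <- tolower(names(raw))
  need <- c("animal_id", "sex")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    abort(paste0("missing required column(s): ", paste(miss, collapse = ", ")))
  }
  reasons <- cohort_row_checks(raw)
  if (quarantine) {
    bad <- !is.na(reasons)
    q <- raw[bad, , drop = FALSE]
    q$quarantine_reason <- reasons[bad]
    out <- raw[!bad, , drop = FALSE]
    if (any(bad)) {
      inform(sprintf("%d row(s) quarantined (see attr(x, 'quarantine'))", sum(bad)))
    }
    attr(out, "quarantine") <- q
    out
  } else {
    raw$quarantine_reason <- reasons
    raw
  }
}

#' Write a cohort CSV
#'
#' UTF-8, '.' decimal, header row; the plain-CSV interchange format of the
#' pipeline.
#'
#' @param data Cohort tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(data, path) {
  readr::write_csv(data, path)
  invisible(path)
}

#' Pipeline configuration
#'
#' @param seed Integer seed driving every stochastic stage.
#' @param generator A [cohort_spec()] used when no input file is given.
#' @param input Optional path to a cohort CSV (skips generation).
#' @param diet A [diet_spec()].
#' @param adjustment_forms Adjustment forms to fit (see [fit_adjustment()]).
#' @param crossval_model Form name or formula to cross-validate (`NULL`
#'   disables the stage).
#' @param crossval_reps Cross-validation replicates.
#' @param entry_p,stay_p Stepwise thresholds (kept in the manifest even when
#'   stepwise is not run, so a run is fully described by its config).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1, generator = cohort_spec(),
                            input = NULL, diet = diet_spec(),
                            adjustment_forms = "afsbw_mbv",
                            crossval_model = "afsbw_mbv",
                            crossval_reps = 200,
                            entry_p = 0.15, stay_p = 0.15) {
  structure(
    list(seed = seed, generator = generator, input = input, diet = diet,
         adjustment_forms = adjustment_forms,
         crossval_model = crossval_model, crossval_reps = crossval_reps,
         entry_p = entry_p, stay_p = stay_p),
    class = "pipeline_config"
  )
}

#' Run the full analysis pipeline
#'
#' Chains the stages in order - generate (or read) the cohort, body
#' composition, growth predictions, difference variables, adjustment fits,
#' cross-validation - writing one CSV per stage plus fit reports (JSON), a
#' cross-validation summary CSV, and a run manifest (seed, config hash,
#' package version). No stage mutates an upstream file; two runs with the
#' same config and seed produce identical numeric outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the final cohort tibble, the fits, the
#'   cross-validation summary and the manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  if (!inherits(config, "pipeline_config")) abort("config must be a pipeline_config")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
  }
  cohort <- stage("cohort", {
    if (!is.null(config$input)) read_cohort(config$input)
    else generate_cohort(config$generator, seed = config$seed)
  })
  write_cohort(cohort, file.path(out_dir, "01_cohort.csv"))

  # a generator truth response must survive the recomputing stages
  keep_truth <- function(new, old) {
    for (resp in c("afsbw_ct_kg", "dmr_kg_d")) {
      if (paste0("truth_", resp) %in% names(old) && resp %in% names(old)) {
        new[[resp]] <- old[[resp]]
      }
    }
    new
  }
  cohort <- stage("composition", {
    keep_truth(add_body_composition(cohort, target_ebf = config$diet$target_ebf),
               cohort)
  })
  write_cohort(cohort, file.path(out_dir, "02_composition.csv"))

  cohort <- stage("growth", keep_truth(add_growth_predictions(cohort, config$diet),
                                       cohort))
  cohort <- stage("deltas", add_deltas(cohort))
  write_cohort(cohort, file.path(out_dir, "03_predictions.csv"))

  fits <- stage("adjustment", {
    lapply(setNames(nm = config$adjustment_forms), function(f) {
      fit_adjustment(cohort, f)
    })
  })
  fit_report <- lapply(fits, function(f) {
    list(form = f$form, n = f$n, rmse = f$rmse, r2 = f$r2,
         terms = tidy(f))
  })
  jsonlite::write_json(fit_report, file.path(out_dir, "04_fits.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")

  cv <- NULL
  if (!is.null(config$crossval_model)) {
    cv <- stage("crossval", {
      cross_validate(cohort, config$crossval_model,
                     reps = config$crossval_reps, seed = config$seed)
    })
    readr::write_csv(cv$summary, file.path(out_dir, "05_crossval.csv"))
  }

  manifest <- list(
    seed = config$seed,
    config_hash = rlang::hash(config),
    package_version = as.character(utils::packageVersion("mbvgrowth")),
    n_animals = nrow(cohort),
    stages = c("cohort", "composition", "growth", "deltas", "adjustment",
               if (!is.null(cv)) "crossval")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(list(cohort = cohort, fits = fits, crossval = cv,
                 manifest = manifest))
}
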