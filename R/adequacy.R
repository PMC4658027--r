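# Population (divide-by-n) moments so the MSEP decomposition is an exact
# partition: MSEP = (muP-muO)^2 + (sdP - r sdO)^2 + (1-r^2) sdO^2.
pop_var <- function(x) mean((x - mean(x))^2)
pop_cov <- function(x, y) mean((x - mean(x)) * (y - mean(y)))

#' Model adequacy statistics
#'
#' Precision and accuracy of a set of predictions against observations: mean
#' square error of prediction (MSEP) and its exact three-way decomposition
#' into mean bias `(mean(P)-mean(O))^2`, systematic (slope) bias
#' `(sd_P - r sd_O)^2` and random error `(1-r^2) sd_O^2`; the root of MSEP;
#' Pearson r and r-squared; Lin's concordance correlation coefficient
#' `CCC = 2 cov(O,P) / (var_O + var_P + (mean(O)-mean(P))^2)` and its accuracy
#' component `Cb = CCC / r`. Moments are population (divide-by-n) so the
#' decomposition components sum exactly to MSEP. The signed mean difference
#' `mean(P) - mean(O)` is reported alongside the squared mean-bias component.
#'
#' @param observed,predicted Equal-length finite numeric vectors (n >= 3).
#' @return An object of class `adequacy` (also a list) with elements `n`,
#'   `msep`, `rmsep`, `mean_diff`, `mean_bias`, `systematic_bias`,
#'   `random_err`, their `_pct` shares of MSEP, `r`, `r2`, `ccc`, `cb`, and
#'   the input vectors (for plotting). Zero variance in either vector leaves
#'   the correlation-based statistics `NA` with a warning.
#' @examples
#' adequacy(c(1, 2, 3), c(2, 3, 4))
#' @export
adequacy <- function(observed, predicted) {
  if (length(observed) != length(predicted)) abort("lengths differ")
  if (length(observed) < 3) abort("need at least 3 pairs")
  if (!all(is.finite(observed)) || !all(is.finite(predicted))) {
    abort("inputs must be finite")
  }
  o <- observed; p <- predicted
  n <- length(o)
  vo <- pop_var(o); vp <- pop_var(p)
  msep <- mean((p - o)^2)
  mean_diff <- mean(p) - mean(o)
  mean_bias <- mean_diff^2
  if (vo == 0 || vp == 0) {
    warn("zero variance; correlation-based statistics undefined")
    r <- NA_real_; ccc <- NA_real_; cb <- NA_real_
    # degenerate case: keep the partition exact by assigning the remainder
    sys_bias <- msep - mean_bias
    rand_err <- 0
  } else {
    r <- pop_cov(o, p) / sqrt(vo * vp)
    sys_bias <- (sqrt(vp) - r * sqrt(vo))^2
    rand_err <- (1 - r^2) * vo
    ccc <- 2 * pop_cov(o, p) / (vo + vp + mean_diff^2)
    cb <- if (r == 0) NA_real_ else ccc / r
  }
  pct <- function(x) if (msep > 0) 100 * x / msep else NA_real_
  structure(
    list(n = n, msep = msep, rmsep = sqrt(msep),
         mean_diff = mean_diff,
         mean_bias = mean_bias, mean_bias_pct = pct(mean_bias),
         systematic_bias = sys_bias, systematic_bias_pct = pct(sys_bias),
         random_err = rand_err, random_pct = pct(rand_err),
         r = r, r2 = r^2, ccc = ccc, cb = cb,
         observed = o, predicted = p),
    class = "adequacy"
  )
}

#' @export
print.adequacy <- function(x, ...) {
  cat(sprintf(
    "<adequacy> n = %d  RMSEP = %.4g  mean diff = %.4g\n  MSEP %% (mean/systematic/random): %.2f / %.2f / %.2f\n  r2 = %.3f  CCC = %.3f  Cb = %.3f\n",
    x$n, x$rmsep, x$mean_diff, x$mean_bias_pct, x$systematic_bias_pct,
    x$random_pct, x$r2, x$ccc, x$cb))
  invisible(x)
}

adequacy_row <- function(a) {
  tibble::tibble(
    n = a$n, msep = a$msep, rmsep = a$rmsep, mean_diff = a$mean_diff,
    mean_bias_pct = a$mean_bias_pct,
    systematic_bias_pct = a$systematic_bias_pct,
    random_pct = a$random_pct, r = a$r, r2 = a$r2, ccc = a$ccc, cb = a$cb
  )
}

#' Repeated random 2-fold cross-validation
#'
#' Monte-Carlo cross-validation of a linear model: in each replicate the
#' cohort is split at random (without replacement) into a training half of
#' `train_n` rows and a testing half with the remainder; the model is fitted
#' on each half and evaluated with [adequacy()] on the other, and the two
#' folds' statistics are averaged weighted by test-fold size, giving one
#' value per replicate. The 2.5 % and 97.5 % quantiles (type-7 linear
#' interpolation) over replicates are reported per statistic. Fully
#' reproducible given `seed`. Replicates with a singular fit are skipped and
#' counted (warning if more than 1 % skip).
#'
#' @param data Cohort data frame.
#' @param model Either a formula (fitted by [lm()]) or an `mbv_fit` form name
#'   (`"afsbw_mbv"` etc., refitted via [fit_adjustment()] each replicate).
#' @param reps Number of random splits (default 1000).
#' @param train_n Training rows per split (default `floor(nrow/2)`, e.g.
#'   750 of 1499).
#' @param seed Integer seed for the split stream.
#' @param pdmi_col Intake column for the DMR forms.
#' @param quantiles Reported quantile pair (default `c(0.025, 0.975)`).
#' @return An object of class `crossval_summary`: `summary` (tibble of
#'   per-statistic quantiles), `reps` (per-replicate tibble), `pooled`
#'   (mean over replicates of mean difference and RMSEP), `n_skipped`.
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_heifers = 100, n_steers = 100,
#'                                       truth = "afsbw_mbv"), seed = 1)
#' cross_validate(cohort, "afsbw_mbv", reps = 5, seed = 1)
#' @export
cross_validate <- function(data, model, reps = 1000, train_n = NULL,
                           seed = NULL, pdmi_col = "pdmi_hh_kg_d",
                           quantiles = c(0.025, 0.975)) {
  data <- tibble::as_tibble(data)
  n <- nrow(data)
  train_n <- train_n %||% floor(n / 2)
  if (n < train_n + 3) abort("cohort too small for the requested split")
  if (reps < 2) abort("need at least 2 replicates")
  if (!is.null(seed)) set.seed(seed)

  fit_fun <- if (inherits(model, "formula")) {
    response <- all.vars(model)[1]
    function(train) lm(model, data = train)
  } else {
    form <- match.arg(model, c("afsbw_mbv", "afsbw_frame",
                               "dmr_pdmi", "dmr_endbw"))
    response <- reference_adjustments()[[form]]$response
    function(train) fit_adjustment(train, form, pdmi_col = pdmi_col)
  }
  pred_fun <- function(fit, test) {
    if (inherits(fit, "mbv_fit")) predict(fit, test, pdmi_col = pdmi_col)
    else unname(predict(fit, newdata = test))
  }

  rows <- vector("list", reps)
  skipped <- 0
  for (i in seq_len(reps)) {
    idx <- sample.int(n, train_n)
    halves <- list(list(tr = data[idx, ], te = data[-idx, ]),
                   list(tr = data[-idx, ], te = data[idx, ]))
    stat2 <- lapply(halves, function(h) {
      fit <- tryCatch(suppressWarnings(fit_fun(h$tr)), error = function(e) NULL)
      if (is.null(fit)) return(NULL)
      pr <- pred_fun(fit, h$te)
      ok <- is.finite(pr) & is.finite(h$te[[response]])
      if (sum(ok) < 3) return(NULL)
      adequacy_row(adequacy(h$te[[response]][ok], pr[ok]))
    })
    if (any(vapply(stat2, is.null, logical(1)))) {
      skipped <- skipped + 1
      next
    }
    w <- vapply(stat2, function(s) s$n, numeric(1))
    merged <- (w[1] * unlist(stat2[[1]]) + w[2] * unlist(stat2[[2]])) / sum(w)
    rows[[i]] <- tibble::as_tibble(c(as.list(merged), list(rep = i)))
  }
  reps_tbl <- dplyr::bind_rows(rows)
  if (skipped > 0.01 * reps) {
    warn(sprintf("%d of %d replicates skipped (singular fits)", skipped, reps))
  }
  stat_cols <- c("ccc", "cb", "r2", "mean_bias_pct", "systematic_bias_pct",
                 "random_pct", "rmsep", "mean_diff")
  summ <- purrr::map_dfr(stat_cols, function(s) {
    q <- quantile(reps_tbl[[s]], probs = quantiles, type = 7, na.rm = TRUE)
    tibble::tibble(statistic = s, q_lo = unname(q[1]), q_hi = unname(q[2]),
                   mean = mean(reps_tbl[[s]], na.rm = TRUE))
  })
  structure(
    list(summary = summ, reps = reps_tbl,
         pooled = tibble::tibble(mean_diff = mean(reps_tbl$mean_diff),
                                 rmsep = mean(reps_tbl$rmsep)),
         n_reps = reps, n_skipped = skipped,
         train_n = train_n, quantiles = quantiles),
    class = "crossval_summary"
  )
}

#' @export
print.crossval_summary <- function(x, ...) {
  cat(sprintf("<crossval_summary> %d replicates (%d skipped), train n = %d\n",
              x$n_reps, x$n_skipped, x$train_n))
  print(x$summary, ...)
  invisible(x)
}
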