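#' Tidy an adjustment fit
#'
#' @param x An `mbv_fit`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`.
#' @exportS3Method generics::tidy
tidy.mbv_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  term <- rownames(s)
  term[term == "(Intercept)"] <- "intercept"
  term <- gsub("^`|`$", "", term)
  tibble::tibble(term = term, estimate = s[, 1], std.error = s[, 2],
                 statistic = s[, 3], p.value = s[, 4])
}

#' Glance at an adjustment fit
#'
#' @param x An `mbv_fit`.
#' @param ... Unused.
#' @return One-row tibble: `form`, `n`, `rmse`, `r.squared`,
#'   `adj.r.squared`.
#' @exportS3Method generics::glance
glance.mbv_fit <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(form = x$form, n = x$n, rmse = s$sigma,
                 r.squared = s$r.squared, adj.r.squared = s$adj.r.squared)
}

#' Tidy adequacy statistics
#'
#' @param x An `adequacy` object.
#' @param ... Unused.
#' @return Long tibble with `statistic`, `value`.
#' @exportS3Method generics::tidy
tidy.adequacy <- function(x, ...) {
  keep <- c("n", "msep", "rmsep", "mean_diff", "mean_bias", "mean_bias_pct",
            "systematic_bias", "systematic_bias_pct", "random_err",
            "random_pct", "r", "r2", "ccc", "cb")
  tibble::tibble(statistic = keep,
                 value = vapply(keep, function(k) as.numeric(x[[k]]), numeric(1)))
}

#' Glance at adequacy statistics
#'
#' @param x An `adequacy` object.
#' @param ... Unused.
#' @return One-row wide tibble of the main statistics.
#' @exportS3Method generics::glance
glance.adequacy <- function(x, ...) {
  adequacy_row(x)
}

#' Tidy a cross-validation summary
#'
#' @param x A `crossval_summary`.
#' @param ... Unused.
#' @return Tibble with `statistic`, `q_lo`, `q_hi`, `mean`.
#' @exportS3Method generics::tidy
tidy.crossval_summary <- function(x, ...) x$summary

#' Glance at a cross-validation summary
#'
#' @param x A `crossval_summary`.
#' @param ... Unused.
#' @return One-row tibble: `reps`, `skipped`, `train_n`, pooled `mean_diff`
#'   and `rmsep`.
#' @exportS3Method generics::glance
glance.crossval_summary <- function(x, ...) {
  tibble::tibble(reps = x$n_reps, skipped = x$n_skipped, train_n = x$train_n,
                 mean_diff = x$pooled$mean_diff, rmsep = x$pooled$rmsep)
}

#' Observed-versus-predicted plot of an adequacy evaluation
#'
#' @param object An `adequacy` object.
#' @param ... Unused.
#' @return A ggplot: predictions against observations with the identity
#'   line; the subtitle reports RMSEP, CCC and Cb.
#' @exportS3Method ggplot2::autoplot
autoplot.adequacy <- function(object, ...) {
  d <- tibble::tibble(observed = object$observed, predicted = object$predicted)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$observed, y = .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::labs(
      x = "Observed", y = "Predicted",
      subtitle = sprintf("RMSEP %.3g | CCC %.3f | Cb %.3f | r2 %.3f",
                         object$rmsep, object$ccc, object$cb, object$r2)
    ) +
    ggplot2::theme_minimal()
}

#' Quantile-interval plot of a cross-validation summary
#'
#' @param object A `crossval_summary`.
#' @param statistics Statistics to show (default: concordance, accuracy,
#'   precision).
#' @param ... Unused.
#' @return A ggplot of per-statistic replicate quantile intervals.
#' @exportS3Method ggplot2::autoplot
autoplot.crossval_summary <- function(object,
                                      statistics = c("ccc", "cb", "r2"),
                                      ...) {
  d <- dplyr::filter(object$summary, .data$statistic %in% statistics)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$statistic, y = .data$mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$q_lo, ymax = .data$q_hi)) +
    ggplot2::labs(x = NULL, y = "Replicate quantile interval") +
    ggplot2::theme_minimal()
}

#' Coefficient plot of an adjustment fit
#'
#' @param object An `mbv_fit`.
#' @param ... Unused.
#' @return A ggplot of estimates with approximate 95 % intervals.
#' @exportS3Method ggplot2::autoplot
autoplot.mbv_fit <- function(object, ...) {
  d <- tidy(object)
  d <- d[d$term != "intercept", , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$term, .data$estimate),
                                  y = .data$estimate)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$estimate - 1.96 * .data$std.error,
                                          ymax = .data$estimate + 1.96 * .data$std.error)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Estimate") +
    ggplot2::theme_minimal()
}

#' Stacked MSEP-decomposition plot
#'
#' Shows the share of the mean square error of prediction due to mean bias,
#' systematic (slope) bias and random error, either for a single adequacy
#' evaluation or per replicate-quantile from a cross-validation.
#'
#' @param x An `adequacy` or `crossval_summary` object.
#' @return A ggplot.
#' @export
plot_msep_decomposition <- function(x) {
  if (inherits(x, "adequacy")) {
    d <- tibble::tibble(
      component = factor(c("mean bias", "systematic bias", "random error"),
                         levels = c("mean bias", "systematic bias", "random error")),
      pct = c(x$mean_bias_pct, x$systematic_bias_pct, x$random_pct),
      source = "adequacy"
    )
  } else if (inherits(x, "crossval_summary")) {
    s <- x$summary
    pick <- function(st) s$mean[s$statistic == st]
    d <- tibble::tibble(
      component = factor(c("mean bias", "systematic bias", "random error"),
                         levels = c("mean bias", "systematic bias", "random error")),
      pct = c(pick("mean_bias_pct"), pick("systematic_bias_pct"),
              pick("random_pct")),
      source = "cross-validation mean"
    )
  } else {
    abort("x must be an adequacy or crossval_summary object")
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$source, y = .data$pct,
                                  fill = .data$component)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "% of MSEP", fill = NULL) +
    ggplot2::theme_minimal()
}
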