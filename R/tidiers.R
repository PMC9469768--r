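# broom-style tidiers for fitted objects.

#' Tidy a fitted calibration
#'
#' @param x A `chlorine_calibration`.
#' @param ... Unused.
#' @return Tibble with term, estimate and (for fitted models) std.error,
#'   statistic, p.value.
#' @export
tidy.chlorine_calibration <- function(x, ...) {
  if (is.null(x$fit)) {
    return(tibble::tibble(term = names(x$coefficients),
                          estimate = as.numeric(x$coefficients)))
  }
  s <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(s), estimate = s[, 1],
                 std.error = s[, 2], statistic = s[, 3], p.value = s[, 4])
}

#' Glance at a fitted calibration
#'
#' @inheritParams tidy.chlorine_calibration
#' @return One-row tibble with family, r.squared, adj.r.squared, AIC,
#'   sigma, nobs.
#' @export
glance.chlorine_calibration <- function(x, ...) {
  if (is.null(x$fit)) {
    return(tibble::tibble(family = x$family, r.squared = NA_real_,
                          adj.r.squared = NA_real_, AIC = NA_real_,
                          sigma = NA_real_, nobs = x$n))
  }
  s <- summary(x$fit)
  tibble::tibble(family = x$family, r.squared = s$r.squared,
                 adj.r.squared = s$adj.r.squared, AIC = AIC(x$fit),
                 sigma = s$sigma, nobs = length(stats::fitted(x$fit)))
}

#' Tidy a metrics report
#'
#' @param x A `tier_metrics`.
#' @param ... Unused.
#' @return The per-class tibble with the aggregates appended as attributes
#'   in long form: rows for accuracy, micro and weighted F1 plus one row
#'   per class metric.
#' @export
tidy.tier_metrics <- function(x, ...) {
  agg <- tibble::tibble(
    class = NA_character_,
    metric = c("accuracy", "micro_f1", "weighted_f1"),
    value = c(x$accuracy, x$micro_f1, x$weighted_f1))
  per <- tidyr::pivot_longer(x$per_class, c("precision", "recall", "f1"),
                             names_to = "metric", values_to = "value")
  dplyr::bind_rows(agg, dplyr::select(per, "class", "metric", "value"))
}

#' Tidy a confusion matrix
#'
#' @param x A `tier_confusion`.
#' @param ... Unused.
#' @return Long tibble with predicted, true, n.
#' @export
tidy.tier_confusion <- function(x, ...) {
  df <- as.data.frame(as.table(unclass(x)))
  names(df) <- c("predicted", "true", "n")
  tibble::as_tibble(df)
}
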