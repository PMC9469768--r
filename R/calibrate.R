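# RGB -> concentration calibration.
#
# Three regression families map the free pad's mean (R, G, B) to free
# chlorine in mg/L: a simple linear model on the RGB sum, a multiple linear
# model on R and G (blue dropped for lack of significance), and a polynomial
# with all three channels and their squares. Backward stepwise selection
# minimizes AIC over the polynomial term set. The published coefficient sets
# ship as a built-in model.

calibration_families <- function() {
  list(
    linear_sum    = list(terms = "rgb_sum", min_rows = 3),
    multiple_rg   = list(terms = c("r", "g"), min_rows = 4),
    polynomial_sq = list(terms = c("r", "g", "b", "r2", "g2", "b2"),
                         min_rows = 8)
  )
}

# Derived regressor columns from pad RGB (only when the channels exist).
augment_rgb <- function(rows) {
  if (all(c("r", "g", "b") %in% names(rows))) {
    rows$rgb_sum <- rows$r + rows$g + rows$b
    rows$r2 <- rows$r^2
    rows$g2 <- rows$g^2
    rows$b2 <- rows$b^2
  }
  rows
}

new_calibration <- function(fit, family, terms, data) {
  structure(list(fit = fit, family = family, terms = terms,
                 coefficients = coef(fit),
                 # channel order assumption: x1 -> R, x2 -> G, x3 -> B
                 channel_assignment = c(x1 = "r", x2 = "g", x3 = "b"),
                 n = nrow(data)),
            class = "chlorine_calibration")
}

fit_family <- function(rows, family, terms = NULL) {
  fam <- calibration_families()[[family]]
  terms <- terms %||% fam$terms
  rows <- augment_rgb(tibble::as_tibble(rows))
  if (nrow(rows) < fam$min_rows) {
    stop(sprintf("%s needs at least %d rows", family, fam$min_rows),
         call. = FALSE)
  }
  X <- as.matrix(rows[, terms, drop = FALSE])
  if (qr(cbind(1, X))$rank < ncol(X) + 1) {
    stop("rank-deficient design: collinear or constant regressors",
         call. = FALSE)
  }
  f <- as.formula(paste("concentration ~", paste(terms, collapse = " + ")))
  new_calibration(lm(f, data = rows), family, terms, rows)
}

#' Fit the RGB-sum linear calibration
#'
#' Ordinary least squares of concentration on the sum R + G + B. The DPD
#' pad lightens at low concentrations, so the slope is negative on real and
#' realistic synthetic data.
#'
#' @param rows Tibble with columns `r`, `g`, `b`, `concentration` (and
#'   optionally `group`).
#' @return A `chlorine_calibration` object.
#' @export
fit_linear_sum <- function(rows) fit_family(rows, "linear_sum")

#' Fit the red-green multiple linear calibration
#'
#' OLS of concentration on R and G. Per-term t-test p-values are in
#' [tidy()]; on data without a blue effect the blue exclusion rationale is
#' reproducible by inspecting a full fit.
#'
#' @inheritParams fit_linear_sum
#' @return A `chlorine_calibration` object.
#' @export
fit_multiple_rg <- function(rows) fit_family(rows, "multiple_rg")

#' Fit the squared-channel polynomial calibration
#'
#' OLS of concentration on R, G, B and their squares (seven coefficients
#' with the intercept).
#'
#' @inheritParams fit_linear_sum
#' @return A `chlorine_calibration` object.
#' @export
fit_polynomial_sq <- function(rows) fit_family(rows, "polynomial_sq")

#' Backward stepwise AIC selection over the polynomial term set
#'
#' Starting from the full term set \{R, G, B, R^2, G^2, B^2\}, repeatedly
#' removes the single term whose removal lowers AIC the most, and stops when
#' no removal lowers AIC. The intercept is never removed. AIC is the
#' Gaussian-likelihood form computed by [stats::AIC()].
#'
#' @inheritParams fit_linear_sum
#' @param full_terms Starting term set.
#' @return A `chlorine_calibration` with the surviving terms; the removal
#'   trace (term, AIC after removal) is in attribute `"trace"`.
#' @export
backward_stepwise_aic <- function(rows, full_terms = c("r", "g", "b",
                                                       "r2", "g2", "b2")) {
  rows <- augment_rgb(tibble::as_tibble(rows))
  if (nrow(rows) < 10) stop("need at least 10 rows", call. = FALSE)
  fit_terms <- function(terms) {
    f <- as.formula(paste("concentration ~",
                          if (length(terms)) paste(terms, collapse = " + ")
                          else "1"))
    lm(f, data = rows)
  }
  terms <- full_terms
  current <- fit_terms(terms)
  trace <- tibble::tibble(removed = "<none>", aic = AIC(current),
                          n_terms = length(terms))
  repeat {
    if (length(terms) == 0) break
    aics <- vapply(terms, function(tm) AIC(fit_terms(setdiff(terms, tm))),
                   numeric(1))
    best <- which.min(aics)
    if (aics[best] >= AIC(current)) break
    terms <- setdiff(terms, terms[best])
    current <- fit_terms(terms)
    trace <- dplyr::bind_rows(trace, tibble::tibble(
      removed = names(aics)[best], aic = aics[best], n_terms = length(terms)))
  }
  out <- new_calibration(current, "stepwise", terms, rows)
  attr(out, "trace") <- trace
  out
}

#' Published calibration coefficient sets
#'
#' The three reported coefficient sets, fit to the original photo data:
#' `linear_sum` (slope on the RGB sum), `multiple_rg` (x1 on R, x2 on G),
#' and `polynomial_sq` (x1..x3 on R, G, B and x1^2..x3^2 on their squares,
#' assuming the conventional x1 -> R, x2 -> G, x3 -> B channel order, which
#' the source does not state explicitly for the polynomial).
#'
#' @return Named list of named coefficient vectors.
#' @export
published_coefficients <- function() {
  list(
    linear_sum = c(`(Intercept)` = 3.7360509, rgb_sum = -0.0070353),
    multiple_rg = c(`(Intercept)` = 1.878656, r = 0.015354, g = -0.026582),
    polynomial_sq = c(`(Intercept)` = 1.086e1,
                      r = 6.2720e-2, g = -6.242e-2, b = -1.3970e-1,
                      r2 = 1.297e-4, g2 = 4.526e-4, b2 = -1.626e-4)
  )
}

#' Published calibration as a ready-to-use model
#'
#' Wraps one of the [published_coefficients()] sets as a
#' `chlorine_calibration`. It was fit to the original photographic data, so
#' it is not expected to be accurate on synthetic scenes; synthetic runs
#' should train their own calibration.
#'
#' @param family `"linear_sum"`, `"multiple_rg"` or `"polynomial_sq"`.
#' @return A coefficients-only `chlorine_calibration`.
#' @export
published_model <- function(family = c("polynomial_sq", "linear_sum",
                                       "multiple_rg")) {
  family <- match.arg(family)
  cf <- published_coefficients()[[family]]
  structure(list(fit = NULL, family = family,
                 terms = setdiff(names(cf), "(Intercept)"),
                 coefficients = cf,
                 channel_assignment = c(x1 = "r", x2 = "g", x3 = "b"),
                 n = NA_integer_, published = TRUE),
            class = "chlorine_calibration")
}

#' Predict free-chlorine concentration from a pad sample
#'
#' Evaluates the model's linear predictor. Predictions are not clamped:
#' negative values are legal here and are sent to the lowest tier at the
#' classification stage (see [bin_concentration()]).
#'
#' @param model A `chlorine_calibration`.
#' @param sample Data frame (or one-row tibble) with columns `r`, `g`, `b`
#'   in \[0, 255\].
#' @return Numeric vector of concentrations in mg/L (possibly negative).
#' @export
predict_concentration <- function(model, sample) {
  stopifnot(inherits(model, "chlorine_calibration"))
  sample <- augment_rgb(tibble::as_tibble(sample))
  missing <- setdiff(model$terms, names(sample))
  if (length(missing)) {
    stop("sample lacks regressors: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  X <- cbind(`(Intercept)` = 1,
             as.matrix(sample[, model$terms, drop = FALSE]))
  as.numeric(X %*% model$coefficients[colnames(X)])
}

#' Residual diagnostics for a fitted calibration
#'
#' @param model A fitted (not published-coefficients-only)
#'   `chlorine_calibration`.
#' @return List with `residuals_fitted` (tibble), Shapiro-Wilk statistic and
#'   p-value, adjusted R-squared and AIC. Degenerate (all-zero) residuals
#'   are flagged rather than passed to the normality test.
#' @export
residual_diagnostics <- function(model) {
  stopifnot(inherits(model, "chlorine_calibration"))
  if (is.null(model$fit)) {
    stop("published-coefficients model has no residuals", call. = FALSE)
  }
  res <- stats::residuals(model$fit)
  if (length(res) < 3) stop("too few residuals", call. = FALSE)
  degenerate <- stats::sd(res) < 1e-12
  sw <- if (degenerate) list(statistic = NA_real_, p.value = NA_real_)
        else shapiro.test(res)
  list(
    residuals_fitted = tibble::tibble(fitted = stats::fitted(model$fit),
                                      residual = as.numeric(res)),
    shapiro_statistic = as.numeric(sw$statistic),
    shapiro_p = as.numeric(sw$p.value),
    adj_r_squared = summary(model$fit)$adj.r.squared,
    aic = AIC(model$fit),
    degenerate = degenerate
  )
}

#' @export
print.chlorine_calibration <- function(x, ...) {
  cat("<chlorine_calibration> family =", x$family,
      if (isTRUE(x$published)) "(published coefficients)", "\n")
  print(round(x$coefficients, 7))
  invisible(x)
}

#' Serialize / deserialize a calibration model as JSON
#'
#' @param model A `chlorine_calibration`.
#' @param path File path.
#' @return `read_calibration_json()` returns a coefficients-only
#'   `chlorine_calibration`.
#' @export
write_calibration_json <- function(model, path) {
  obj <- list(family = model$family, terms = model$terms,
              coefficients = as.list(model$coefficients),
              channel_assignment = as.list(model$channel_assignment),
              n = model$n)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration_json
#' @export
read_calibration_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(fit = NULL, family = obj$family, terms = obj$terms,
                 coefficients = unlist(obj$coefficients),
                 channel_assignment = unlist(obj$channel_assignment),
                 n = obj$n),
            class = "chlorine_calibration")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
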