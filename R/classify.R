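# Tier binning, confusion matrices, the classification metric suite,
# stratified splitting and resampled validation, and the two-proportion
# z-test.
#
# Bin boundaries are half-open on the left (a < C <= b), matching the
# concentration-group convention; a negative predicted concentration lands
# in the lowest bin (a zero-chlorine strip can legitimately regress below
# zero).

tier_levels <- function(scheme = c("binary", "multiclass")) {
  scheme <- match.arg(scheme)
  if (scheme == "binary") c("le_0.5", "gt_0.5")
  else c("le_0.2", "mid_0.2_0.5", "gt_0.5")
}

#' Bin a concentration into a tier
#'
#' Binary scheme: `le_0.5` = (-Inf, 0.5\] (the positive class), `gt_0.5`
#' otherwise. Multiclass: `le_0.2` = (-Inf, 0.2\], `mid_0.2_0.5` =
#' (0.2, 0.5\], `gt_0.5` = (0.5, Inf). Negative values (possible regression
#' output for zero-chlorine strips) always map to the lowest bin.
#'
#' @param c Numeric vector of concentrations in mg/L (negatives allowed).
#' @param scheme `"binary"` or `"multiclass"`.
#' @return Factor of tier labels with the scheme's levels.
#' @export
bin_concentration <- function(c, scheme = c("binary", "multiclass")) {
  scheme <- match.arg(scheme)
  if (any(is.na(c) | is.nan(c))) stop("NaN/NA concentration", call. = FALSE)
  lv <- tier_levels(scheme)
  breaks <- if (scheme == "binary") c(-Inf, 0.5, Inf)
            else c(-Inf, 0.2, 0.5, Inf)
  cut(c, breaks = breaks, labels = lv, right = TRUE)
}

#' Confusion matrix of predicted vs true tiers
#'
#' Rows are predicted classes, columns are true classes.
#'
#' @param true_tiers,pred_tiers Equal-length factors/characters with the
#'   scheme's labels.
#' @param scheme `"binary"` or `"multiclass"`.
#' @return A `tier_confusion`: K x K integer matrix (rows = predicted,
#'   columns = true) with attribute `scheme`.
#' @export
confusion <- function(true_tiers, pred_tiers,
                      scheme = c("binary", "multiclass")) {
  scheme <- match.arg(scheme)
  lv <- tier_levels(scheme)
  if (length(true_tiers) != length(pred_tiers)) {
    stop("label sequences differ in length", call. = FALSE)
  }
  bad <- setdiff(unique(c(as.character(true_tiers),
                          as.character(pred_tiers))), lv)
  if (length(bad)) {
    stop("labels not in scheme: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  tt <- factor(as.character(true_tiers), levels = lv)
  pp <- factor(as.character(pred_tiers), levels = lv)
  m <- t(table(true = tt, predicted = pp))  # rows = predicted
  out <- matrix(as.integer(m), nrow(m), ncol(m),
                dimnames = list(predicted = lv, true = lv))
  structure(out, scheme = scheme, class = c("tier_confusion", "matrix",
                                            "array"))
}

#' Build a tier confusion matrix from raw counts
#'
#' @param counts K x K matrix or vector (filled by row), rows = predicted,
#'   columns = true.
#' @param scheme `"binary"` or `"multiclass"`.
#' @return A `tier_confusion`.
#' @export
as_tier_confusion <- function(counts, scheme = c("binary", "multiclass")) {
  scheme <- match.arg(scheme)
  lv <- tier_levels(scheme)
  k <- length(lv)
  m <- matrix(as.integer(counts), k, k, byrow = !is.matrix(counts),
              dimnames = list(predicted = lv, true = lv))
  if (any(m < 0)) stop("negative counts", call. = FALSE)
  structure(m, scheme = scheme, class = c("tier_confusion", "matrix",
                                          "array"))
}

#' Classification metric suite for a tier confusion matrix
#'
#' Accuracy = sum(TP)/total; per-class precision = TP/(TP+FP), recall =
#' TP/(TP+FN), F1 = 2 Pr Re/(Pr+Re); weighted F1 weights each class F1 by
#' its true-class support; micro F1 pools TP/FP/FN over classes (equal to
#' accuracy for single-label classification). Per-class metrics with a zero
#' denominator are treated as 0 with a warning when aggregating.
#'
#' @param cm A `tier_confusion`.
#' @param zero_division Value substituted for 0/0 metrics (default 0).
#' @return A `tier_metrics` list: `accuracy`, `micro_f1`, `weighted_f1`,
#'   `per_class` tibble (precision, recall, f1, support), `total`.
#' @export
metrics <- function(cm, zero_division = 0) {
  stopifnot(inherits(cm, "tier_confusion"))
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix: metrics undefined",
                       call. = FALSE)
  k <- nrow(cm)
  tp <- diag(cm)
  fp <- rowSums(cm) - tp
  fn <- colSums(cm) - tp
  safe_div <- function(num, den) {
    out <- ifelse(den == 0, NA_real_, num / den)
    if (any(is.na(out))) {
      warning("zero-denominator class metric treated as ", zero_division,
              call. = FALSE)
      out[is.na(out)] <- zero_division
    }
    out
  }
  pr <- safe_div(tp, tp + fp)
  re <- safe_div(tp, tp + fn)
  f1 <- ifelse(pr + re == 0, 0, 2 * pr * re / (pr + re))
  support <- colSums(cm)
  micro <- sum(tp) / (sum(tp) + (sum(fp) + sum(fn)) / 2)
  structure(list(
    accuracy = sum(tp) / total,
    micro_f1 = micro,
    weighted_f1 = sum(support * f1) / sum(support),
    per_class = tibble::tibble(class = rownames(cm), precision = pr,
                               recall = re, f1 = f1,
                               support = as.integer(support)),
    total = as.integer(total),
    scheme = attr(cm, "scheme")
  ), class = "tier_metrics")
}

#' @export
print.tier_metrics <- function(x, ...) {
  cat(sprintf("<tier_metrics> %s: accuracy %.3f, weighted F1 %.3f (n = %d)\n",
              x$scheme, x$accuracy, x$weighted_f1, x$total))
  print(x$per_class)
  invisible(x)
}

#' Round a proportion to a whole percent, half away from zero
#'
#' Matches the presentation convention for reported percentages.
#'
#' @param p Proportion in \[0, 1\].
#' @return Integer percent.
#' @export
percent_round <- function(p) floor(p * 100 + 0.5)

#' Stratified train-test split preserving group proportions
#'
#' The total training size is `round(train_fraction * n)`; per-group counts
#' are allocated by largest remainder so relative group proportions are
#' preserved to within rounding, and membership is random within group.
#'
#' @param rows Tibble with a grouping column.
#' @param train_fraction Fraction in (0, 1\]; 1 yields an empty test set
#'   (flagged with a warning).
#' @param seed Integer seed.
#' @param group_col Name of the grouping column.
#' @return List with `train` and `test` tibbles.
#' @export
stratified_split <- function(rows, train_fraction = 0.67, seed = 1L,
                             group_col = "group") {
  stopifnot(train_fraction > 0, train_fraction <= 1)
  rows <- tibble::as_tibble(rows)
  g <- rows[[group_col]]
  if (any(table(g) == 0)) stop("empty group", call. = FALSE)
  n <- nrow(rows)
  groups <- unique(g)
  sizes <- vapply(groups, function(gr) sum(g == gr), integer(1))
  raw <- train_fraction * sizes
  k <- floor(raw)
  target <- round(train_fraction * n)
  extra <- target - sum(k)
  if (extra > 0) {
    ord <- order(raw - k, decreasing = TRUE)
    k[ord[seq_len(extra)]] <- k[ord[seq_len(extra)]] + 1L
  }
  train_idx <- withr::with_seed(as.integer(seed), {
    unlist(lapply(seq_along(groups), function(i) {
      ids <- which(g == groups[i])
      sample(ids, min(k[i], length(ids)))
    }))
  })
  if (length(train_idx) == n) {
    warning("train_fraction leaves an empty test set", call. = FALSE)
  }
  list(train = rows[sort(train_idx), ],
       test = rows[setdiff(seq_len(n), train_idx), ])
}

#' Resampled (repeated random split) validation of a calibration family
#'
#' Repeats stratified split, fit, predict and metric computation
#' `n_repeats` times and summarizes each metric's mean and spread. Fit
#' failures in a repeat are recorded and skipped.
#'
#' @param rows Calibration tibble (`r`, `g`, `b`, `concentration`, group
#'   column).
#' @param n_repeats Number of resampled splits.
#' @param train_fraction Training fraction.
#' @param seed Master seed; repeat i uses `seed + i`.
#' @param family Calibration family name.
#' @param scheme Binning scheme for the metrics.
#' @param group_col Grouping column name.
#' @return List with `per_repeat` tibble (accuracy, weighted F1 per repeat)
#'   and `summary` tibble (mean, sd).
#' @export
resampled_validation <- function(rows, n_repeats = 10, train_fraction = 0.67,
                                 seed = 1L, family = "polynomial_sq",
                                 scheme = "multiclass", group_col = "group") {
  stopifnot(n_repeats >= 1)
  fitter <- switch(family,
                   linear_sum = fit_linear_sum,
                   multiple_rg = fit_multiple_rg,
                   polynomial_sq = fit_polynomial_sq,
                   stop("unknown family", call. = FALSE))
  per <- purrr::map(seq_len(n_repeats), function(i) {
    sp <- stratified_split(rows, train_fraction, seed = seed + i,
                           group_col = group_col)
    res <- tryCatch({
      mod <- fitter(sp$train)
      pred <- predict_concentration(mod, sp$test)
      cm <- confusion(bin_concentration(sp$test$concentration, scheme),
                      bin_concentration(pred, scheme), scheme)
      mt <- metrics(cm)
      tibble::tibble(repeat_id = i, ok = TRUE, accuracy = mt$accuracy,
                     weighted_f1 = mt$weighted_f1, error = NA_character_)
    }, error = function(e) {
      tibble::tibble(repeat_id = i, ok = FALSE, accuracy = NA_real_,
                     weighted_f1 = NA_real_, error = conditionMessage(e))
    })
    res
  })
  per <- dplyr::bind_rows(per)
  ok <- per[per$ok, ]
  summary <- tibble::tibble(
    metric = c("accuracy", "weighted_f1"),
    mean = c(mean(ok$accuracy), mean(ok$weighted_f1)),
    sd = c(stats::sd(ok$accuracy), stats::sd(ok$weighted_f1)),
    n_ok = nrow(ok)
  )
  list(per_repeat = per, summary = summary)
}

#' Two-proportion pooled z-test
#'
#' Pooled two-sided z-test for equality of two proportions. For more than
#' two groups use [proportion_tests()].
#'
#' @param successes1,n1,successes2,n2 Counts.
#' @return List with `z`, `p` (two-sided), and the two proportions.
#' @export
proportion_z_test <- function(successes1, n1, successes2, n2) {
  stopifnot(n1 > 0, n2 > 0, successes1 <= n1, successes2 <= n2,
            successes1 >= 0, successes2 >= 0)
  p1 <- successes1 / n1
  p2 <- successes2 / n2
  pool <- (successes1 + successes2) / (n1 + n2)
  v <- pool * (1 - pool) * (1 / n1 + 1 / n2)
  if (v == 0) stop("zero pooled variance", call. = FALSE)
  z <- (p1 - p2) / sqrt(v)
  list(z = z, p = 2 * pnorm(-abs(z)), p1 = p1, p2 = p2)
}

#' All pairwise two-proportion z-tests plus an overall chi-square
#'
#' @param successes,n Equal-length vectors of per-group counts.
#' @return List with `pairwise` tibble and `chisq` (overall test).
#' @export
proportion_tests <- function(successes, n) {
  stopifnot(length(successes) == length(n), length(n) >= 2)
  k <- length(n)
  idx <- utils::combn(k, 2)
  pairwise <- purrr::map_dfr(seq_len(ncol(idx)), function(j) {
    i1 <- idx[1, j]; i2 <- idx[2, j]
    zt <- proportion_z_test(successes[i1], n[i1], successes[i2], n[i2])
    tibble::tibble(group1 = i1, group2 = i2, z = zt$z, p = zt$p)
  })
  tab <- rbind(successes, n - successes)
  list(pairwise = pairwise,
       chisq = suppressWarnings(chisq.test(tab)))
}
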