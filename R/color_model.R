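# Concentration -> pad color model.
#
# DPD free-chlorine pads darken toward magenta as concentration rises, so the
# sum of the mean R, G, B values of the pad falls monotonically with
# concentration. The model interpolates per-channel anchors linearly in
# concentration and constrains sampled colors to per-tier channel boxes
# (observed min/max per channel within each regulatory tier).

# Observed per-tier channel ranges (min, max) for the free-chlorine pad, by
# tier <=0.2, 0.2-0.5, >0.5 mg/L.
default_tier_bounds <- function() {
  tibble::tibble(
    tier    = rep(c("le_0.2", "mid_0.2_0.5", "gt_0.5"), each = 3),
    channel = rep(c("r", "g", "b"), times = 3),
    min     = c(122, 125, 135, 133, 111, 128, 98, 57, 114),
    max     = c(193, 193, 179, 182, 170, 175, 170, 146, 170)
  )
}

# Channel anchors: mean pad color at reference concentrations. Chosen so the
# anchor of each tier's interior sits at the midpoint of that tier's channel
# box and the RGB sum is strictly decreasing on [0, 4] mg/L.
default_anchors <- function() {
  tibble::tibble(
    concentration = c(0, 0.1, 0.2, 0.35, 0.5, 1, 2, 4),
    r = c(185, 166, 150, 152, 143, 134, 118, 100),
    g = c(185, 163, 143, 135, 122, 102, 80, 60),
    b = c(172, 158, 147, 145, 136, 131, 122, 115)
  )
}

#' Concentration-to-color model for the free-chlorine pad
#'
#' Bundles the per-tier channel bounds, the per-channel interpolation anchors
#' and the pad-to-pad color standard deviation used when sampling pad colors.
#'
#' @param anchors Tibble with columns `concentration`, `r`, `g`, `b`; mean
#'   channel values at reference concentrations (mg/L).
#' @param bounds Tibble of per-tier channel (min, max) boxes.
#' @param pad_sd Standard deviation (color-value units) of pad-to-pad
#'   variability around the anchor color; sampled colors are truncated to the
#'   tier's channel box.
#' @return A `color_model` object.
#' @export
color_model <- function(anchors = default_anchors(),
                        bounds = default_tier_bounds(),
                        pad_sd = 6) {
  stopifnot(all(c("concentration", "r", "g", "b") %in% names(anchors)),
            pad_sd >= 0)
  sums <- anchors$r + anchors$g + anchors$b
  if (any(diff(sums) >= 0)) {
    stop("anchor RGB sums must be strictly decreasing in concentration",
         call. = FALSE)
  }
  structure(list(anchors = anchors, bounds = bounds, pad_sd = pad_sd),
            class = "color_model")
}

#' @export
print.color_model <- function(x, ...) {
  cat("<color_model> ", nrow(x$anchors), " anchors over [",
      min(x$anchors$concentration), ", ", max(x$anchors$concentration),
      "] mg/L, pad_sd = ", x$pad_sd, "\n", sep = "")
  invisible(x)
}

# Mean (noiseless) pad color at concentration c: per-channel linear
# interpolation of the anchors, clamped at the last anchor beyond 4 mg/L.
anchor_color <- function(model, c) {
  a <- model$anchors
  vapply(c("r", "g", "b"), function(ch) {
    stats::approx(a$concentration, a[[ch]], xout = c, rule = 2)$y
  }, numeric(length(c)))
}

tier_bounds_for <- function(model, tier) {
  b <- model$bounds[model$bounds$tier == tier, ]
  stats::setNames(Map(c, b$min, b$max), b$channel)
}

#' Is a pad color inside a tier's channel box?
#'
#' @param rgb Length-3 (R, G, B) vector.
#' @param tier Tier label (`"le_0.2"`, `"mid_0.2_0.5"`, `"gt_0.5"`).
#' @param model A [color_model()].
#' @return Logical scalar.
#' @export
color_in_tier_bounds <- function(rgb, tier, model = color_model()) {
  bb <- tier_bounds_for(model, tier)
  all(vapply(1:3, function(i) {
    rgb[i] >= bb[[i]][1] && rgb[i] <= bb[[i]][2]
  }, logical(1)))
}

#' Sample a pad color for a given concentration
#'
#' Interpolates the model's channel anchors at `c` and adds Gaussian
#' pad-to-pad variability truncated to the channel box of `c`'s tier. With
#' `pad_sd = 0` the anchor color is returned exactly.
#'
#' @param c Concentration in mg/L (scalar, nonnegative).
#' @param model A [color_model()].
#' @param seed Integer seed; the draw is deterministic given `(c, seed)`.
#' @return Named numeric (r, g, b) in \[0, 255\].
#' @export
concentration_to_pad_color <- function(c, model = color_model(), seed = 1L) {
  if (!is.finite(c) || c < 0) {
    stop("concentration must be a nonnegative number", call. = FALSE)
  }
  mu <- as.numeric(anchor_color(model, c))
  tier <- as.character(bin_concentration(c, "multiclass"))
  bb <- tier_bounds_for(model, tier)
  if (model$pad_sd == 0) {
    out <- mu
  } else {
    out <- withr::with_seed(as.integer(seed), {
      vapply(1:3, function(i) {
        lo <- bb[[i]][1]; hi <- bb[[i]][2]
        # rejection-sample the truncated normal; the box always has mass
        for (k in 1:200) {
          v <- rnorm(1, mu[i], model$pad_sd)
          if (v >= lo && v <= hi) return(v)
        }
        min(max(mu[i], lo), hi)
      }, numeric(1))
    })
  }
  stats::setNames(pmin(pmax(out, 0), 255), c("r", "g", "b"))
}
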