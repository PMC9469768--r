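# Two-stage white balancing.
#
# Stage 1 (whole photo): gray-world normalization. The gray-world assumption
# holds that the average color of a scene is achromatic, so each channel is
# rescaled by (Gray/3)/channel_mean where Gray is the sum of the three
# channel means. Stage 2 (cropped strip): white-patch referencing. The mean
# color of the strip's white body is mapped to the theoretical maximum white
# (255, 255, 255) by per-channel gains 255/white_mean.
#
# Arithmetic is done in real numbers; results are clipped to [0, 255] after
# each balance and only rounded when an image is written to disk.

#' Gray-world channel statistics
#'
#' @param img Image array (H x W x 3, values in \[0, 255\]).
#' @return List with `r_avg`, `g_avg`, `b_avg`, and `gray` (their sum).
#' @export
gray_world_stats <- function(img) {
  m <- apply(img, 3, mean)
  list(r_avg = m[1], g_avg = m[2], b_avg = m[3], gray = sum(m))
}

#' Gray-world white balance
#'
#' Applies the per-channel gain `(Gray/3)/channel_mean` so that the three
#' channel means are equal afterwards. Idempotent up to clipping.
#'
#' @inheritParams gray_world_stats
#' @return The balanced image, clipped to \[0, 255\].
#' @export
gray_world_balance <- function(img) {
  st <- gray_world_stats(img)
  means <- c(st$r_avg, st$g_avg, st$b_avg)
  if (any(means <= 0)) {
    stop("a channel mean is zero: image cannot be gray-world balanced",
         call. = FALSE)
  }
  gains <- (st$gray / 3) / means
  for (ch in 1:3) img[, , ch] <- img[, , ch] * gains[ch]
  pmin(pmax(img, 0), 255)
}

#' Select white reference pixels
#'
#' A pixel counts as white when its minimum channel value is at least the
#' threshold, so near-neutral bright pixels (the strip body) qualify while
#' colored pads do not.
#'
#' @inheritParams gray_world_stats
#' @param luminance_threshold Threshold on the minimum channel, in (0, 255).
#' @return Logical H x W mask.
#' @export
select_white_pixels <- function(img, luminance_threshold = 200) {
  stopifnot(luminance_threshold > 0, luminance_threshold < 255)
  mask <- pmin(img[, , 1], img[, , 2], img[, , 3]) >= luminance_threshold
  if (!any(mask)) {
    stop("white-reference failure: no pixel passes the white threshold",
         call. = FALSE)
  }
  mask
}

#' Compute the white reference from a mask
#'
#' @inheritParams gray_world_stats
#' @param mask Logical H x W mask of white pixels.
#' @return List with `r_w`, `g_w`, `b_w` (mean channel values over the mask)
#'   and `count`.
#' @export
white_reference <- function(img, mask) {
  if (!any(mask)) stop("empty white mask", call. = FALSE)
  list(r_w = mean(img[, , 1][mask]),
       g_w = mean(img[, , 2][mask]),
       b_w = mean(img[, , 3][mask]),
       count = sum(mask))
}

#' White-reference (white-patch) balance
#'
#' Default variant applies the gains `255 / white_mean` per channel, mapping
#' the reference region to (255, 255, 255). The literal-reciprocal variant
#' (`variant = "reciprocal"`) multiplies by `white_mean / 255` instead.
#'
#' @inheritParams gray_world_stats
#' @param ref A [white_reference()] list.
#' @param variant `"gain"` (default, brightens toward white) or
#'   `"reciprocal"`.
#' @return The balanced image, clipped to \[0, 255\].
#' @export
white_reference_balance <- function(img, ref, variant = c("gain", "reciprocal")) {
  variant <- match.arg(variant)
  w <- c(ref$r_w, ref$g_w, ref$b_w)
  if (any(w <= 0)) stop("zero white-reference mean", call. = FALSE)
  gains <- if (variant == "gain") 255 / w else w / 255
  for (ch in 1:3) img[, , ch] <- img[, , ch] * gains[ch]
  pmin(pmax(img, 0), 255)
}
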