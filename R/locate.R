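# Geometric processing chain: fiducial detection, perspective alignment,
# black-rectangle detection, strip cropping, pad localization, and
# inscribed-circle color extraction.
#
# Every stage returns a typed `processing_failure` value instead of raising
# when the photo's content defeats it, so a batch run can tally failures by
# stage. Coordinates are 0-based (x, y) pixel centers.

#' Typed processing failure
#'
#' @param stage One of `"fiducial"`, `"rectangle"`, `"strip"`, `"pad"`.
#' @param message Diagnostic message.
#' @return A `processing_failure` object.
#' @export
processing_failure <- function(stage, message = "") {
  stage <- match.arg(stage, c("fiducial", "rectangle", "strip", "pad"))
  structure(list(stage = stage, message = message),
            class = "processing_failure")
}

#' @rdname processing_failure
#' @param x Object to test.
#' @export
is_failure <- function(x) inherits(x, "processing_failure")

#' @export
print.processing_failure <- function(x, ...) {
  cat("<processing_failure> stage =", x$stage, "-", x$message, "\n")
  invisible(x)
}

luminance <- function(img) {
  (img[, , 1] + img[, , 2] + img[, , 3]) / 3
}

otsu_cut <- function(gray) {
  EBImage::otsu(EBImage::Image(gray / 255), range = c(0, 1)) * 255
}

# Connected-component statistics for a logical mask. 0-based coordinates.
component_stats <- function(mask) {
  labels <- EBImage::bwlabel(mask)
  idx <- which(labels > 0)
  if (length(idx) == 0) {
    return(tibble::tibble(label = integer(), area = integer(),
                          cx = numeric(), cy = numeric(),
                          xmin = numeric(), xmax = numeric(),
                          ymin = numeric(), ymax = numeric()))
  }
  h <- nrow(mask)
  lab <- as.integer(labels[idx])
  y <- (idx - 1) %% h
  x <- (idx - 1) %/% h
  st <- tibble::tibble(
    label = sort(unique(lab)),
    area = as.integer(tabulate(lab)[sort(unique(lab))]),
    cx = as.numeric(tapply(x, lab, mean)),
    cy = as.numeric(tapply(y, lab, mean)),
    xmin = as.numeric(tapply(x, lab, min)),
    xmax = as.numeric(tapply(x, lab, max)),
    ymin = as.numeric(tapply(y, lab, min)),
    ymax = as.numeric(tapply(y, lab, max))
  )
  attr(st, "labels") <- labels
  st
}

# Corners of one labeled component as the extreme pixels in the four
# diagonal directions (robust to small residual rotation). TL, TR, BR, BL.
component_corners <- function(labels, lab) {
  idx <- which(labels == lab)
  h <- nrow(labels)
  y <- (idx - 1) %% h
  x <- (idx - 1) %/% h
  s <- x + y; d <- x - y
  rbind(c(x[which.min(s)], y[which.min(s)]),
        c(x[which.max(d)], y[which.max(d)]),
        c(x[which.max(s)], y[which.max(s)]),
        c(x[which.min(d)], y[which.min(d)]))
}

#' Detect the QR-like fiducial
#'
#' Blurs and thresholds the image, then looks for the nested-contour
#' signature of finder patterns: a dark square ring whose bounding box is
#' roughly square, containing a separate dark core concentric with it. The
#' three finder centers define the fiducial quadrilateral; the fourth corner
#' is inferred. Returns a `fiducial_detection` on success and a
#' [processing_failure()] (never an error) otherwise.
#'
#' @param img Image array.
#' @param blur_sigma Gaussian blur sigma (pixels) applied before
#'   thresholding.
#' @param min_long_edge Minimum image long edge in pixels.
#' @return A `fiducial_detection` list (`quad`: 4 x 2 corner-finder-first
#'   canonical quad of finder centers; `finder_corners`: outer-corner points
#'   of each detected finder for alignment refinement) or a
#'   [processing_failure()].
#' @export
detect_fiducial <- function(img, blur_sigma = 1, min_long_edge = 120) {
  if (max(dim(img)[1:2]) < min_long_edge) {
    return(processing_failure("fiducial", "image below minimum resolution"))
  }
  gray <- luminance(img)
  if (blur_sigma > 0) gray <- EBImage::gblur(gray, sigma = blur_sigma)
  if (stats::sd(gray) < 1) {
    return(processing_failure("fiducial", "featureless image"))
  }
  thr <- otsu_cut(gray)
  st <- component_stats(gray < thr)
  labels <- attr(st, "labels")
  if (nrow(st) < 4) {
    return(processing_failure("fiducial", "too few dark contours"))
  }
  st$w <- st$xmax - st$xmin + 1
  st$h <- st$ymax - st$ymin + 1
  st$fill <- st$area / (st$w * st$h)
  long_edge <- max(dim(img)[1:2])

  rings <- st[st$w >= 6 & st$w <= 0.25 * long_edge &
                st$h / st$w > 0.65 & st$h / st$w < 1.55 &
                st$fill > 0.25 & st$fill < 0.8, , drop = FALSE]
  cand <- list()
  for (i in seq_len(nrow(rings))) {
    ring <- rings[i, ]
    near <- st[st$label != ring$label &
                 abs(st$cx - ring$cx) < 0.3 * ring$w &
                 abs(st$cy - ring$cy) < 0.3 * ring$h &
                 st$w < 0.8 * ring$w & st$w > 0.15 * ring$w &
                 st$fill > 0.55, , drop = FALSE]
    if (nrow(near) > 0) {
      cand[[length(cand) + 1]] <-
        list(center = c(ring$cx, ring$cy), size = ring$w, label = ring$label)
    }
  }
  if (length(cand) < 3) {
    return(processing_failure("fiducial",
                              sprintf("found %d finder pattern(s), need 3",
                                      length(cand))))
  }
  # choose the triple of similar size forming the best right isoceles corner
  best <- NULL; best_err <- Inf
  combs <- utils::combn(length(cand), 3)
  for (k in seq_len(ncol(combs))) {
    tri <- cand[combs[, k]]
    P <- do.call(rbind, lapply(tri, `[[`, "center"))
    d2 <- c(sum((P[1, ] - P[2, ])^2), sum((P[1, ] - P[3, ])^2),
            sum((P[2, ] - P[3, ])^2))
    hyp <- which.max(d2)
    legs <- d2[-hyp]
    err <- abs(d2[hyp] - sum(legs)) / d2[hyp] + abs(diff(legs)) / max(legs) +
      stats::sd(vapply(tri, `[[`, numeric(1), "size")) /
      mean(vapply(tri, `[[`, numeric(1), "size"))
    if (err < best_err) { best_err <- err; best <- list(tri = tri, hyp = hyp) }
  }
  if (best_err > 1.5) {
    return(processing_failure("fiducial", "no right-angled finder triple"))
  }
  tri <- best$tri
  # corner finder = vertex opposite the hypotenuse (not on the longest side)
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  corner_i <- setdiff(1:3, pairs[[best$hyp]])
  others <- pairs[[best$hyp]]
  TL <- tri[[corner_i]]$center
  A <- tri[[others[1]]]$center
  B <- tri[[others[2]]]$center
  # right-handed (y down): TL->TR cross TL->BL must be positive
  cr <- (A[1] - TL[1]) * (B[2] - TL[2]) - (A[2] - TL[2]) * (B[1] - TL[1])
  if (cr >= 0) { TR <- A; BL <- B } else { TR <- B; BL <- A }
  BR <- TR + BL - TL
  structure(list(quad = rbind(TL, TR, BR, BL)),
            class = "fiducial_detection")
}

#' Align a photo using the detected fiducial
#'
#' Two-pass (coarse-to-fine) rectification. The coarse pass maps the
#' detected fiducial quad (the three finder-pattern centers plus the
#' inferred fourth corner) onto its nominal position in the base layout.
#' Because the fourth corner is inferred by parallelogram completion, the
#' coarse transform is affine and leaves a perspective residual far from
#' the fiducial under tilt. The fine pass therefore detects the black
#' rectangle in the coarse result and re-estimates the homography from the
#' finder centers plus the rectangle corners against their nominal layout
#' positions, pinning down the perspective across the whole card. If the
#' rectangle cannot be found the coarse alignment is returned.
#'
#' @param img Image array.
#' @param fiducial A `fiducial_detection` or a plain 4 x 2 quad.
#' @param layout The [scene_layout()] defining the target geometry.
#' @param refine Run the rectangle-based refinement pass.
#' @return The aligned image (base canvas size) with the 3 x 3 homography
#'   (input to aligned) in attribute `"homography"`.
#' @export
align_photo <- function(img, fiducial, layout = scene_layout(),
                        refine = TRUE) {
  fo <- layout$fiducial_origin; fs <- layout$fiducial_side
  m <- layout$finder_module
  fc <- 3.5 * m - 0.5
  centers_target <- rbind(
    tl = c(fo[1] + fc, fo[2] + fc),
    tr = c(fo[1] + fs - 7 * m + fc, fo[2] + fc),
    br = c(fo[1] + fs - 7 * m + fc, fo[2] + fs - 7 * m + fc),
    bl = c(fo[1] + fc, fo[2] + fs - 7 * m + fc))
  quad <- if (inherits(fiducial, "fiducial_detection")) fiducial$quad
          else fiducial
  if (abs(polygon_area(quad)) < 1e-6) {
    stop("degenerate fiducial quad: collinear corners", call. = FALSE)
  }
  H <- homography_from_points(quad, centers_target)
  out <- warp_image(img, H, layout$width, layout$height,
                    fill = rep(layout$canvas_value, 3))
  if (refine) {
    rect <- detect_black_rectangle(out)
    if (!is_failure(rect)) {
      ro <- layout$rect_origin; rs <- layout$rect_size
      rect_target <- rbind(c(ro[1], ro[2]),
                           c(ro[1] + rs[1] - 1, ro[2]),
                           c(ro[1] + rs[1] - 1, ro[2] + rs[2] - 1),
                           c(ro[1], ro[2] + rs[2] - 1))
      rect_src <- apply_homography(solve(H), rect)
      H2 <- tryCatch(
        homography_fit_ls(rbind(quad[c(1, 2, 4), , drop = FALSE], rect_src),
                          rbind(centers_target[c("tl", "tr", "bl"), ],
                                rect_target)),
        error = function(e) NULL)
      if (!is.null(H2)) {
        H <- H2
        out <- warp_image(img, H, layout$width, layout$height,
                          fill = rep(layout$canvas_value, 3))
      }
    }
  }
  attr(out, "homography") <- H
  out
}

#' Detect the black background rectangle
#'
#' Thresholds the (aligned) image, labels dark components, gates candidates
#' on bounding-box aspect ratio and area, and returns the largest survivor's
#' corner quad.
#'
#' @param img Aligned image array.
#' @param aspect_bounds Allowed height/width ratio range.
#' @param min_area_frac Minimum component bounding-box area as a fraction of
#'   the image area.
#' @return A 4 x 2 quad (TL, TR, BR, BL) or a [processing_failure()].
#' @export
detect_black_rectangle <- function(img, aspect_bounds = c(1.3, 4),
                                   min_area_frac = 0.03) {
  gray <- luminance(img)
  if (stats::sd(gray) < 1) {
    return(processing_failure("rectangle", "featureless image"))
  }
  thr <- otsu_cut(gray)
  st <- component_stats(gray < thr)
  labels <- attr(st, "labels")
  if (nrow(st) == 0) {
    return(processing_failure("rectangle", "no dark contours"))
  }
  st$w <- st$xmax - st$xmin + 1
  st$h <- st$ymax - st$ymin + 1
  ok <- st[st$h / st$w >= aspect_bounds[1] & st$h / st$w <= aspect_bounds[2] &
             st$w * st$h >= min_area_frac * prod(dim(img)[1:2]), ,
           drop = FALSE]
  if (nrow(ok) == 0) {
    return(processing_failure("rectangle", "no candidate passes the gates"))
  }
  best <- ok[which.max(ok$area), ]
  component_corners(labels, best$label)
}

#' Crop the test strip inside the rectangle
#'
#' Finds the largest bright component inside the detected rectangle and
#' crops to its bounding box; the strip's colorimetric pads are part of the
#' crop whether or not they pass the brightness threshold.
#'
#' @param img Aligned image array.
#' @param rect Rectangle quad from [detect_black_rectangle()].
#' @param aspect_bounds Allowed strip length/width ratio range.
#' @return A `strip_region` list (`image`, `bbox` in aligned coordinates) or
#'   a [processing_failure()].
#' @export
crop_strip <- function(img, rect, aspect_bounds = c(3, 9)) {
  margin <- 4
  x0 <- max(0, min(rect[, 1]) + margin); x1 <- min(dim(img)[2] - 1, max(rect[, 1]) - margin)
  y0 <- max(0, min(rect[, 2]) + margin); y1 <- min(dim(img)[1] - 1, max(rect[, 2]) - margin)
  if (x1 - x0 < 10 || y1 - y0 < 10) {
    return(processing_failure("strip", "rectangle interior too small"))
  }
  region <- img[(y0:y1) + 1, (x0:x1) + 1, , drop = FALSE]
  gray <- luminance(region)
  if (stats::sd(gray) < 1) {
    return(processing_failure("strip", "no bright region inside rectangle"))
  }
  thr <- otsu_cut(gray)
  st <- component_stats(gray > thr)
  if (nrow(st) == 0) {
    return(processing_failure("strip", "no bright region inside rectangle"))
  }
  best <- st[which.max(st$area), ]
  w <- best$xmax - best$xmin + 1
  h <- best$ymax - best$ymin + 1
  if (h / w < aspect_bounds[1] || h / w > aspect_bounds[2]) {
    return(processing_failure("strip", sprintf(
      "bright region aspect %.2f outside [%g, %g]", h / w,
      aspect_bounds[1], aspect_bounds[2])))
  }
  bbox <- c(xmin = x0 + best$xmin, ymin = y0 + best$ymin,
            xmax = x0 + best$xmax, ymax = y0 + best$ymax)
  crop <- img[(bbox["ymin"]:bbox["ymax"]) + 1,
              (bbox["xmin"]:bbox["xmax"]) + 1, , drop = FALSE]
  structure(list(image = crop, bbox = bbox), class = "strip_region")
}

#' Locate the colorimetric pads on the strip
#'
#' Places the total pad near the strip's top end and the free pad mid-strip,
#' at configured fractional positions along the strip axis. The pad polygon
#' is a square slightly smaller than the nominal pad so that the inscribed
#' circle stays inside the pad under small localization error.
#'
#' @param strip A `strip_region` from [crop_strip()].
#' @param layout The [scene_layout()] (pad fractions and nominal pad size).
#' @param min_length Minimum strip length in pixels.
#' @param shrink Pad polygon side as a fraction of the nominal pad side.
#' @return Named list of `pad_region` objects (`total`, `free`), each with
#'   `id`, `center` (aligned coordinates), `polygon` (4 x 2), or a
#'   [processing_failure()].
#' @export
locate_pads <- function(strip, layout = scene_layout(), min_length = 60,
                        shrink = 0.75) {
  bbox <- strip$bbox
  len <- bbox["ymax"] - bbox["ymin"] + 1
  if (len < min_length) {
    return(processing_failure("pad", "strip too short in pixels"))
  }
  cx <- (bbox["xmin"] + bbox["xmax"]) / 2
  side <- layout$pad_side * shrink
  out <- lapply(names(layout$pad_fracs), function(nm) {
    cy <- bbox["ymin"] + layout$pad_fracs[[nm]] * (len - 1)
    poly <- rbind(c(cx - side / 2, cy - side / 2),
                  c(cx + side / 2, cy - side / 2),
                  c(cx + side / 2, cy + side / 2),
                  c(cx - side / 2, cy + side / 2))
    structure(list(id = nm, center = c(cx, cy), polygon = poly),
              class = "pad_region")
  })
  stats::setNames(out, names(layout$pad_fracs))
}

#' Largest circle inscribed in a pad polygon
#'
#' The circle is centered at the polygon centroid with radius equal to the
#' minimum distance from the centroid to the polygon edges, so it always
#' lies inside a convex pad polygon.
#'
#' @param pad A `pad_region` or an n x 2 polygon matrix.
#' @return List with `center` (x, y) and `radius`.
#' @export
inscribe_circle <- function(pad) {
  poly <- if (inherits(pad, "pad_region")) pad$polygon else pad
  ctr <- polygon_centroid(poly)
  n <- nrow(poly)
  r <- min(vapply(seq_len(n), function(i) {
    point_segment_distance(ctr, poly[i, ], poly[i %% n + 1, ])
  }, numeric(1)))
  if (r <= 0) stop("degenerate pad polygon", call. = FALSE)
  list(center = ctr, radius = r)
}

#' Mean pad color over an inscribed circle
#'
#' Averages the channels over pixels whose centers lie strictly inside the
#' circle.
#'
#' @param img Image array.
#' @param circle List with `center` and `radius` (see [inscribe_circle()]).
#' @param min_pixels Minimum acceptable pixel count.
#' @param pad_id,source Provenance recorded in the sample.
#' @return A one-row tibble (`pad`, `r`, `g`, `b`, `n_pixels`, `source`) or
#'   a [processing_failure()].
#' @export
extract_mean_rgb <- function(img, circle, min_pixels = 9, pad_id = NA_character_,
                             source = NA_character_) {
  cx <- circle$center[1]; cy <- circle$center[2]; r <- circle$radius
  h <- dim(img)[1]; w <- dim(img)[2]
  x0 <- max(0, floor(cx - r)); x1 <- min(w - 1, ceiling(cx + r))
  y0 <- max(0, floor(cy - r)); y1 <- min(h - 1, ceiling(cy + r))
  if (x1 < x0 || y1 < y0) {
    return(processing_failure("pad", "circle outside image"))
  }
  xs <- x0:x1; ys <- y0:y1
  d2 <- outer((ys - cy)^2, (xs - cx)^2, "+")
  inside <- d2 < r^2
  n <- sum(inside)
  if (n < min_pixels) {
    return(processing_failure("pad", "too few pixels inside the circle"))
  }
  sub <- img[ys + 1, xs + 1, , drop = FALSE]
  tibble::tibble(
    pad = pad_id,
    r = mean(sub[, , 1][inside]),
    g = mean(sub[, , 2][inside]),
    b = mean(sub[, , 3][inside]),
    n_pixels = as.integer(n),
    source = source
  )
}
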