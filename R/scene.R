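# Synthetic test-strip scene renderer.
#
# A scene is a photo of the standard background: a dark rectangle about three
# strip-widths wide, a white test strip inside it carrying the total-chlorine
# pad near its top end and the free-chlorine pad mid-strip, and a QR-like
# fiducial (three nested-square finder patterns) beside it. The renderer
# applies, in order: perspective tilt, a diagonal lighting cast, Gaussian
# pixel noise, and area downsampling to the resolution level's pixel budget.
# Every scene comes with full ground truth for geometry and pad color.

#' Scene layout configuration
#'
#' All geometry is defined on a base canvas (default 640 x 480) and scaled
#' down with the resolution level. Distances in pixels, 0-based coordinates.
#'
#' @param width,height Base canvas size.
#' @param canvas_value Background gray level (achromatic mid-gray so the
#'   gray-world assumption is neither trivially true nor badly violated).
#' @param paper_white White level of the strip body and fiducial background;
#'   kept below 255/1.2 so a 20% lighting-cast gain does not clip it.
#' @param fiducial_origin,fiducial_side Fiducial square position and size.
#' @param finder_module Side of one fiducial module; finder patterns are
#'   7 x 7 modules.
#' @param rect_origin,rect_size Black rectangle position and (w, h) size.
#' @param strip_size Strip (width, length).
#' @param strip_offset_frac Lateral strip offset as a fraction of the free
#'   slack inside the rectangle (-1 to 1; 0 = centered).
#' @param pad_side Pad square side.
#' @param pad_fracs Fractional centers of the (total, free) pads along the
#'   strip axis, measured from the strip's top end.
#' @param resolution_budgets Long-edge pixel budgets for the low/mid/high
#'   resolution levels (proportional to the square roots of 2, 8 and 12 MP).
#' @param casts Per-cast diagonal (R, G, B) channel gains.
#' @param flip Render the scene rotated 180 degrees (strip upside-down).
#' @return A `scene_layout` list.
#' @export
scene_layout <- function(width = 640, height = 480,
                         canvas_value = 128,
                         paper_white = 210,
                         fiducial_origin = c(60, 90),
                         fiducial_side = 110,
                         finder_module = 5,
                         rect_origin = c(300, 75),
                         rect_size = c(150, 330),
                         strip_size = c(50, 270),
                         strip_offset_frac = 0,
                         pad_side = 34,
                         pad_fracs = c(total = 0.10, free = 0.45),
                         resolution_budgets = c(low = 260, mid = 520, high = 640),
                         casts = list(neutral = c(1, 1, 1),
                                      warm = c(1.2, 1, 0.85),
                                      cool = c(0.85, 1, 1.2)),
                         flip = FALSE) {
  structure(as.list(environment()), class = "scene_layout")
}

#' Specification of one synthetic scene
#'
#' @param concentration Free-chlorine concentration, mg/L (>= 0).
#' @param lighting_cast One of `"neutral"`, `"warm"`, `"cool"`.
#' @param resolution_level One of `"low"`, `"mid"`, `"high"`.
#' @param tilt_deg Perspective tilt about the vertical axis, degrees
#'   (|tilt| <= 10 by default).
#' @param noise_sd Gaussian pixel noise standard deviation, color-value units.
#' @param seed Integer seed; rendering is deterministic given these fields.
#' @param max_tilt_deg Safe tilt range bound.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(concentration, lighting_cast = "neutral",
                       resolution_level = "high", tilt_deg = 0,
                       noise_sd = 0, seed = 1L, max_tilt_deg = 10) {
  if (!is.finite(concentration) || concentration < 0) {
    stop("concentration must be nonnegative", call. = FALSE)
  }
  lighting_cast <- match.arg(lighting_cast, c("neutral", "warm", "cool"))
  resolution_level <- match.arg(resolution_level, c("low", "mid", "high"))
  if (!is.finite(noise_sd) || noise_sd < 0) {
    stop("noise_sd must be nonnegative", call. = FALSE)
  }
  if (abs(tilt_deg) > max_tilt_deg) {
    stop("tilt_deg outside the configured safe range", call. = FALSE)
  }
  structure(list(concentration = concentration,
                 lighting_cast = lighting_cast,
                 resolution_level = resolution_level,
                 tilt_deg = tilt_deg, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

# Draw a filled axis-aligned box [x0, x1] x [y0, y1] (0-based, inclusive).
draw_box <- function(img, x0, y0, x1, y1, rgb) {
  rows <- (max(0, round(y0)):min(dim(img)[1] - 1, round(y1))) + 1
  cols <- (max(0, round(x0)):min(dim(img)[2] - 1, round(x1))) + 1
  for (ch in 1:3) img[rows, cols, ch] <- rgb[ch]
  img
}

# One QR finder pattern: 7x7 dark frame, 5x5 light, 3x3 dark core.
draw_finder <- function(img, x0, y0, m, dark, light) {
  img <- draw_box(img, x0, y0, x0 + 7 * m - 1, y0 + 7 * m - 1, rep(dark, 3))
  img <- draw_box(img, x0 + m, y0 + m, x0 + 6 * m - 1, y0 + 6 * m - 1,
                  rep(light, 3))
  draw_box(img, x0 + 2 * m, y0 + 2 * m, x0 + 5 * m - 1, y0 + 5 * m - 1,
           rep(dark, 3))
}

#' Render a synthetic test-strip scene
#'
#' @param spec A [scene_spec()].
#' @param model A [color_model()].
#' @param layout A [scene_layout()].
#' @return A list of class `scene` with elements `image` (H x W x 3 array in
#'   \[0, 255\]) and `truth` (a `scene_truth` list: pad colors in capture and
#'   white-referenced space, tier, fiducial/rectangle corner quads in
#'   pattern-canonical order, strip bounding box, pad centers, and the
#'   geometry scale).
#' @export
render_scene <- function(spec, model = color_model(), layout = scene_layout()) {
  stopifnot(inherits(spec, "scene_spec"))
  W <- layout$width; H <- layout$height
  pw <- layout$paper_white
  pad_free <- concentration_to_pad_color(spec$concentration, model, spec$seed)
  pad_total <- concentration_to_pad_color(spec$concentration, model,
                                          spec$seed + 1000L)

  img <- array(layout$canvas_value, dim = c(H, W, 3))

  # fiducial: white square carrying three finder patterns (TL, TR, BL)
  fo <- layout$fiducial_origin; fs <- layout$fiducial_side
  m <- layout$finder_module
  img <- draw_box(img, fo[1], fo[2], fo[1] + fs - 1, fo[2] + fs - 1,
                  rep(pw, 3))
  dark <- 15
  img <- draw_finder(img, fo[1], fo[2], m, dark, pw)
  img <- draw_finder(img, fo[1] + fs - 7 * m, fo[2], m, dark, pw)
  img <- draw_finder(img, fo[1], fo[2] + fs - 7 * m, m, dark, pw)
  fc <- 3.5 * m - 0.5  # finder center offset from its box origin
  fid <- rbind(c(fo[1] + fc, fo[2] + fc),
               c(fo[1] + fs - 7 * m + fc, fo[2] + fc),
               c(fo[1] + fs - 7 * m + fc, fo[2] + fs - 7 * m + fc),
               c(fo[1] + fc, fo[2] + fs - 7 * m + fc))

  # black rectangle
  ro <- layout$rect_origin; rs <- layout$rect_size
  if (ro[1] + rs[1] > W || ro[2] + rs[2] > H) {
    stop("rectangle does not fit in the canvas", call. = FALSE)
  }
  img <- draw_box(img, ro[1], ro[2], ro[1] + rs[1] - 1, ro[2] + rs[2] - 1,
                  c(25, 25, 25))
  rect <- rbind(c(ro[1], ro[2]),
                c(ro[1] + rs[1] - 1, ro[2]),
                c(ro[1] + rs[1] - 1, ro[2] + rs[2] - 1),
                c(ro[1], ro[2] + rs[2] - 1))

  # strip, laterally offset within the rectangle's slack
  sw <- layout$strip_size[1]; sl <- layout$strip_size[2]
  slack <- (rs[1] - sw) / 2 - 6
  sx0 <- ro[1] + (rs[1] - sw) / 2 + layout$strip_offset_frac * slack
  sy0 <- ro[2] + (rs[2] - sl) / 2
  img <- draw_box(img, sx0, sy0, sx0 + sw - 1, sy0 + sl - 1, rep(pw, 3))
  strip_bbox <- c(xmin = sx0, ymin = sy0, xmax = sx0 + sw - 1,
                  ymax = sy0 + sl - 1)

  # pads: total near the strip's top end, free mid-strip
  ps <- layout$pad_side
  cx <- sx0 + (sw - 1) / 2
  centers <- lapply(layout$pad_fracs, function(f) c(cx, sy0 + f * (sl - 1)))
  for (nm in names(centers)) {
    cc <- centers[[nm]]
    col <- if (nm == "free") pad_free else pad_total
    img <- draw_box(img, cc[1] - ps / 2, cc[2] - ps / 2,
                    cc[1] + ps / 2 - 1, cc[2] + ps / 2 - 1, col)
  }

  map_pts <- function(p) p
  if (isTRUE(layout$flip)) {
    img <- img[H:1, W:1, , drop = FALSE]
    flip_fun <- function(p) cbind(W - 1 - p[, 1], H - 1 - p[, 2])
    map_pts <- flip_fun
  }

  if (spec$tilt_deg != 0) {
    Ht <- tilt_homography(spec$tilt_deg, W, H)
    img <- warp_image(img, Ht, W, H, fill = rep(layout$canvas_value, 3))
    prev <- map_pts
    map_pts <- function(p) apply_homography(Ht, prev(p))
  }

  gains <- layout$casts[[spec$lighting_cast]]
  for (ch in 1:3) img[, , ch] <- img[, , ch] * gains[ch]

  if (spec$noise_sd > 0) {
    img <- withr::with_seed(spec$seed + 1L, {
      img + array(rnorm(length(img), 0, spec$noise_sd), dim = dim(img))
    })
  }
  img <- pmin(pmax(img, 0), 255)

  budget <- layout$resolution_budgets[[spec$resolution_level]]
  s <- min(1, budget / max(W, H))
  if (s < 1) {
    sigma <- 0.4 / s
    for (ch in 1:3) img[, , ch] <- EBImage::gblur(img[, , ch], sigma = sigma)
    S <- matrix(c(s, 0, (s - 1) / 2, 0, s, (s - 1) / 2, 0, 0, 1),
                3, 3, byrow = TRUE)
    img <- warp_image(img, S, round(W * s), round(H * s),
                      fill = rep(layout$canvas_value, 3))
    img <- pmin(pmax(img, 0), 255)
    prev2 <- map_pts
    map_pts <- function(p) (prev2(p) + 0.5) * s - 0.5
  }

  ref_gain <- 255 / pw
  truth <- structure(list(
    concentration = spec$concentration,
    tier = bin_concentration(spec$concentration, "multiclass"),
    pad_rgb_free = pad_free,
    pad_rgb_total = pad_total,
    pad_rgb_free_ref = pmin(pad_free * ref_gain, 255),
    # geometry in the rendered image's own pixel coordinates
    fiducial_corners = map_pts(fid),
    rectangle_corners = map_pts(rect),
    strip_corners = map_pts(rbind(
      c(strip_bbox["xmin"], strip_bbox["ymin"]),
      c(strip_bbox["xmax"], strip_bbox["ymin"]),
      c(strip_bbox["xmax"], strip_bbox["ymax"]),
      c(strip_bbox["xmin"], strip_bbox["ymax"]))),
    pad_centers = lapply(centers, function(cc) drop(map_pts(rbind(cc)))),
    # geometry in the flat base-layout frame (what alignment restores)
    flat = list(fiducial = fid, rectangle = rect, strip_bbox = strip_bbox,
                pad_centers = centers),
    pad_side = ps * s,
    scale = s,
    spec = spec
  ), class = "scene_truth")

  structure(list(image = img, truth = truth), class = "scene")
}

# Table-1-style concentration group of a known concentration.
table1_group <- function(c) {
  findInterval(c, c(-Inf, 0.125, 0.2, 0.5, 1, 2), left.open = TRUE,
               rightmost.closed = FALSE)
}

table1_counts <- function() c(21L, 27L, 54L, 36L, 46L, 8L)

# Allocate n samples to the six concentration groups by largest remainder,
# proportional to the reference photo counts.
allocate_groups <- function(n) {
  w <- table1_counts() / sum(table1_counts())
  raw <- w * n
  k <- floor(raw)
  extra <- n - sum(k)
  if (extra > 0) {
    ord <- order(raw - k, decreasing = TRUE)
    k[ord[seq_len(extra)]] <- k[ord[seq_len(extra)]] + 1L
  }
  as.integer(k)
}

#' Render a dataset of synthetic scenes with a ground-truth manifest
#'
#' Samples concentrations across the six reference concentration groups in
#' their reference proportions (largest remainder), cycles the requested
#' lighting casts, draws tilts uniformly in the safe range, renders each
#' scene to a PNG and writes a CSV manifest of the full ground truth.
#'
#' @param n Number of scenes (>= 1).
#' @param dir Output directory (created if needed).
#' @param concentration_grid Optional explicit concentrations (length `n`
#'   recycled); by default sampled within each group's range.
#' @param casts Lighting casts to cycle through.
#' @param resolution_levels Resolution levels to cycle through.
#' @param tilt_range Tilt range (degrees) to sample uniformly.
#' @param noise_sd Pixel noise sd for every scene.
#' @param seed Master seed; the dataset is byte-reproducible given it.
#' @param model,layout Color model and layout.
#' @return The manifest as a tibble (invisibly written to
#'   `file.path(dir, "manifest.csv")`).
#' @export
make_dataset <- function(n, dir, concentration_grid = NULL,
                         casts = c("neutral", "warm", "cool"),
                         resolution_levels = c("mid", "high"),
                         tilt_range = c(-8, 8), noise_sd = 3,
                         seed = 1L, model = color_model(),
                         layout = scene_layout()) {
  stopifnot(n >= 1)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  group_sizes <- allocate_groups(n)
  group_lims <- rbind(c(0, 0.125), c(0.125, 0.2), c(0.2, 0.5),
                      c(0.5, 1), c(1, 2), c(2, 4))
  rows <- withr::with_seed(as.integer(seed), {
    conc <- if (is.null(concentration_grid)) {
      cc <- unlist(lapply(1:6, function(g) {
        if (group_sizes[g] == 0) return(numeric(0))
        runif(group_sizes[g], group_lims[g, 1] + 1e-6, group_lims[g, 2])
      }))
      sample(cc)  # decorrelate group from the cast/resolution cycle
    } else {
      rep_len(concentration_grid, n)
    }
    tibble::tibble(
      idx = seq_len(n),
      concentration = conc,
      cast = rep_len(casts, n),
      resolution = rep_len(resolution_levels, n),
      tilt = round(runif(n, tilt_range[1], tilt_range[2]), 3),
      scene_seed = sample.int(.Machine$integer.max %/% 2, n)
    )
  })
  recs <- purrr::pmap(rows, function(idx, concentration, cast, resolution,
                                     tilt, scene_seed) {
    sp <- scene_spec(concentration, cast, resolution, tilt, noise_sd,
                     scene_seed)
    sc <- render_scene(sp, model, layout)
    file <- sprintf("scene_%04d.png", idx)
    write_image(sc$image, file.path(dir, file))
    tr <- sc$truth
    fid <- as.numeric(t(tr$fiducial_corners))
    rect <- as.numeric(t(tr$rectangle_corners))
    tibble::tibble(
      file = file,
      concentration = concentration,
      group = table1_group(concentration),
      tier = as.character(tr$tier),
      pad_r = tr$pad_rgb_free[1], pad_g = tr$pad_rgb_free[2],
      pad_b = tr$pad_rgb_free[3],
      pad_r_ref = tr$pad_rgb_free_ref[1], pad_g_ref = tr$pad_rgb_free_ref[2],
      pad_b_ref = tr$pad_rgb_free_ref[3],
      cast = cast, resolution = resolution, tilt_deg = tilt,
      noise_sd = noise_sd, seed = scene_seed,
      fid_x1 = fid[1], fid_y1 = fid[2], fid_x2 = fid[3], fid_y2 = fid[4],
      fid_x3 = fid[5], fid_y3 = fid[6], fid_x4 = fid[7], fid_y4 = fid[8],
      rect_x1 = rect[1], rect_y1 = rect[2], rect_x2 = rect[3],
      rect_y2 = rect[4], rect_x3 = rect[5], rect_y3 = rect[6],
      rect_x4 = rect[7], rect_y4 = rect[8],
      pad_free_x = tr$pad_centers$free[1], pad_free_y = tr$pad_centers$free[2],
      pad_total_x = tr$pad_centers$total[1],
      pad_total_y = tr$pad_centers$total[2],
      scale = tr$scale
    )
  })
  manifest <- dplyr::bind_rows(recs)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read and write images
#'
#' Images are numeric H x W x 3 arrays with values in \[0, 255\]; on disk
#' they are PNG files.
#'
#' @param path File path.
#' @return `read_image()` returns the array.
#' @export
read_image <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2) a <- array(rep(a, 3), dim = c(dim(a), 3))
  a[, , 1:3, drop = FALSE] * 255
}

#' @rdname read_image
#' @param img Image array.
#' @export
write_image <- function(img, path) {
  png::writePNG(pmin(pmax(img / 255, 0), 1), path)
  invisible(path)
}
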