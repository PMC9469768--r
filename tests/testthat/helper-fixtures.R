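# Shared fixtures, rendered lazily and cached for the whole test run.

.fixture_cache <- new.env(parent = emptyenv())

fixture_scene <- function(key) {
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  sc <- switch(key,
    neutral_hi  = render_scene(scene_spec(1.0, "neutral", "high", 0, 0, 42)),
    warm_hi     = render_scene(scene_spec(1.0, "warm", "high", 0, 0, 42)),
    cool_hi     = render_scene(scene_spec(1.0, "cool", "high", 0, 0, 42)),
    noisy_tilt  = render_scene(scene_spec(0.8, "warm", "high", 8, 3, 7)),
    noisy_mid   = render_scene(scene_spec(0.8, "cool", "mid", -5, 3, 9)),
    low_res     = render_scene(scene_spec(0.4, "neutral", "low", 2, 3, 13)),
    stop("unknown fixture: ", key)
  )
  .fixture_cache[[key]] <- sc
  sc
}

# Synthetic calibration rows in the pipeline's white-referenced color space:
# the noiseless pad color at each concentration scaled by 255/paper_white.
ref_calibration_rows <- function(conc, model = color_model(pad_sd = 0),
                                 paper_white = scene_layout()$paper_white) {
  cols <- t(vapply(conc, function(cc) {
    concentration_to_pad_color(cc, model, 1L) * 255 / paper_white
  }, numeric(3)))
  tibble::tibble(r = cols[, 1], g = cols[, 2], b = cols[, 3],
                 concentration = conc,
                 group = vapply(conc, chlorosnap:::table1_group, numeric(1)))
}

# Generate rows exactly satisfying a named coefficient set (plus optional
# noise) for coefficient-recovery tests.
rows_from_coefficients <- function(cf, n = 60, seed = 2, noise_sd = 0) {
  withr::with_seed(seed, {
    d <- tibble::tibble(r = runif(n, 90, 200), g = runif(n, 60, 200),
                        b = runif(n, 100, 200))
    X <- cbind(`(Intercept)` = 1, rgb_sum = d$r + d$g + d$b, r = d$r,
               g = d$g, b = d$b, r2 = d$r^2, g2 = d$g^2, b2 = d$b^2)
    d$concentration <- as.numeric(X[, names(cf)] %*% cf) +
      rnorm(n, 0, noise_sd)
    d
  })
}

# Brute-force minimum distance from a point to a polygon boundary, by dense
# sampling of every edge (independent of the package's segment-distance
# code).
brute_force_boundary_distance <- function(p, poly, samples = 4000) {
  n <- nrow(poly)
  dmin <- Inf
  for (i in seq_len(n)) {
    a <- poly[i, ]; b <- poly[i %% n + 1, ]
    t <- seq(0, 1, length.out = samples)
    pts <- cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
    dmin <- min(dmin, sqrt((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2))
  }
  dmin
}

iou_boxes <- function(a, b) {
  ix <- max(0, min(a[3], b[3]) - max(a[1], b[1]) + 1)
  iy <- max(0, min(a[4], b[4]) - max(a[2], b[2]) + 1)
  a1 <- (a[3] - a[1] + 1) * (a[4] - a[2] + 1)
  a2 <- (b[3] - b[1] + 1) * (b[4] - b[2] + 1)
  ix * iy / (a1 + a2 - ix * iy)
}
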