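test_that("fiducial detection hits the true finder centers on clean and noisy scenes", {
  for (key in c("neutral_hi", "noisy_tilt", "noisy_mid")) {
    sc <- fixture_scene(key)
    fid <- detect_fiducial(gray_world_balance(sc$image))
    expect_false(is_failure(fid))
    expect_lt(max(abs(fid$quad - sc$truth$fiducial_corners)), 3)
  }
})

test_that("featureless or undersized images yield a typed fiducial failure", {
  blank <- array(128, dim = c(240, 320, 3))
  f <- detect_fiducial(blank)
  expect_true(is_failure(f))
  expect_identical(f$stage, "fiducial")
  tiny <- array(128, dim = c(40, 60, 3))
  expect_identical(detect_fiducial(tiny)$stage, "fiducial")
})

test_that("alignment is a near-similarity for zero tilt and rejects collinear corners", {
  sc <- fixture_scene("neutral_hi")
  fid <- detect_fiducial(sc$image)
  al <- align_photo(sc$image, fid)
  H <- attr(al, "homography")
  H <- H / H[3, 3]
  # no perspective terms, no shear, equal scales
  expect_lt(max(abs(H[3, 1:2])), 1e-4)
  expect_lt(abs(H[1, 2]) + abs(H[2, 1]), 0.02)
  expect_lt(abs(H[1, 1] - H[2, 2]), 0.02)
  bad <- rbind(c(0, 0), c(10, 10), c(20, 20), c(30, 30))
  expect_error(align_photo(sc$image, bad), "degenerate|collinear")
})

test_that("tilted scenes align onto their zero-tilt geometry", {
  sc0 <- fixture_scene("neutral_hi")
  sp8 <- scene_spec(1.0, "neutral", "high", 8, 0, 42)
  sc8 <- render_scene(sp8)
  al8 <- align_photo(sc8$image, detect_fiducial(sc8$image))
  r8 <- detect_black_rectangle(al8)
  expect_false(is_failure(r8))
  # rectangle corners land where the untilted layout puts them
  expect_lt(max(abs(r8 - sc0$truth$rectangle_corners)), 3)
})

test_that("black rectangle is localized within 3 px and gated sensibly", {
  sc <- fixture_scene("noisy_tilt")
  img <- gray_world_balance(sc$image)
  fid <- detect_fiducial(img)
  al <- align_photo(img, fid)
  H <- attr(al, "homography")
  rect <- detect_black_rectangle(al)
  expect_false(is_failure(rect))
  back <- apply_homography(solve(H), rect)
  expect_lt(max(abs(back - sc$truth$rectangle_corners)), 3)
  # no dark rectangle -> typed failure
  flat <- array(200, dim = c(200, 300, 3))
  expect_identical(detect_black_rectangle(flat)$stage, "rectangle")
  # two candidates: the larger wins
  two <- array(200, dim = c(300, 400, 3))
  two[41:100, 41:70, ] <- 20      # 30 x 60
  two[41:280, 201:320, ] <- 20    # 120 x 240, 16x the area
  got <- detect_black_rectangle(two)
  expect_false(is_failure(got))
  expect_equal(got[1, ], c(200, 40), tolerance = 1.5)
})

test_that("strip crop overlaps the true strip and tolerates lateral offset", {
  sc <- fixture_scene("neutral_hi")
  fid <- detect_fiducial(sc$image)
  al <- align_photo(sc$image, fid)
  rect <- detect_black_rectangle(al)
  strip <- crop_strip(al, rect)
  expect_false(is_failure(strip))
  fb <- sc$truth$flat$strip_bbox
  expect_gt(iou_boxes(unname(strip$bbox), unname(fb[c(1, 2, 3, 4)])), 0.9)
  # offset strip still recovered
  lay_off <- scene_layout(strip_offset_frac = 0.8)
  sco <- render_scene(scene_spec(0.6, "neutral", "high", 0, 0, 3),
                      layout = lay_off)
  alo <- align_photo(sco$image, detect_fiducial(sco$image))
  stripo <- crop_strip(alo, detect_black_rectangle(alo))
  expect_false(is_failure(stripo))
  fbo <- sco$truth$flat$strip_bbox
  expect_gt(iou_boxes(unname(stripo$bbox), unname(fbo[c(1, 2, 3, 4)])), 0.9)
  # rectangle with nothing bright inside
  img2 <- array(128, dim = c(480, 640, 3))
  img2[101:380, 301:450, ] <- 25
  rect2 <- detect_black_rectangle(img2)
  expect_false(is_failure(rect2))
  expect_identical(crop_strip(img2, rect2)$stage, "strip")
})

test_that("pad centers sit within 3 px of ground truth; short strips fail", {
  sc <- fixture_scene("noisy_tilt")
  img <- gray_world_balance(sc$image)
  al <- align_photo(img, detect_fiducial(img))
  H <- attr(al, "homography")
  strip <- crop_strip(al, detect_black_rectangle(al))
  pads <- locate_pads(strip)
  expect_named(pads, c("total", "free"))
  for (nm in names(pads)) {
    back <- apply_homography(solve(H), rbind(pads[[nm]]$center))
    expect_lt(max(abs(back - rbind(sc$truth$pad_centers[[nm]]))), 3)
  }
  short <- structure(list(image = array(255, dim = c(30, 20, 3)),
                          bbox = c(xmin = 0, ymin = 0, xmax = 19, ymax = 29)),
                     class = "strip_region")
  expect_identical(locate_pads(short)$stage, "pad")
})

test_that("an upside-down strip keeps its pad identities through alignment", {
  sp <- scene_spec(1.5, "neutral", "high", 4, 3, 11)
  flipped <- render_scene(sp, layout = scene_layout(flip = TRUE))
  r <- process_photo(flipped$image)
  expect_identical(r$status, "ok")
  expect_lt(max(abs(c(r$free_r, r$free_g, r$free_b) -
                      flipped$truth$pad_rgb_free_ref)), 5)
  expect_lt(max(abs(c(r$total_r, r$total_g, r$total_b) -
                      pmin(flipped$truth$pad_rgb_total * 255 / 210, 255))), 5)
})

test_that("inscribed circle radius equals the brute-force boundary distance", {
  sq <- rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10))
  expect_equal(inscribe_circle(sq)$radius, 5)
  rect <- rbind(c(0, 0), c(20, 0), c(20, 10), c(0, 10))
  expect_equal(inscribe_circle(rect)$radius, 5)
  for (seed in 1:5) {
    poly <- withr::with_seed(seed, {
      ang <- sort(runif(6, 0, 2 * pi))
      cbind(8 * cos(ang) + runif(1, -2, 2), 8 * sin(ang) + runif(1, -2, 2))
    })
    circ <- inscribe_circle(poly)
    oracle <- brute_force_boundary_distance(circ$center, poly)
    expect_equal(circ$radius, oracle, tolerance = 1e-4)
  }
})

test_that("mean color extraction matches a pixel-counting oracle", {
  img <- array(0, dim = c(40, 40, 3))
  img[, , 1] <- 150; img[, , 2] <- 60; img[, , 3] <- 120
  s <- extract_mean_rgb(img, list(center = c(20, 20), radius = 8))
  expect_equal(c(s$r, s$g, s$b), c(150, 60, 120))
  # half/half split through the center
  img2 <- array(100, dim = c(40, 40, 3))
  img2[, 21:40, ] <- 200  # right half (x >= 20)
  circ <- list(center = c(19.5, 19.5), radius = 10)
  s2 <- extract_mean_rgb(img2, circ)
  # independent count of pixels on each side
  xs <- 0:39; ys <- 0:39
  d2 <- outer((ys - 19.5)^2, (xs - 19.5)^2, "+")
  inside <- d2 < 100
  val <- matrix(rep(ifelse(xs >= 20, 200, 100), each = 40), 40, 40)
  expect_equal(s2$r, mean(val[inside]))
  expect_equal(s2$n_pixels, sum(inside))
  expect_lt(abs(s2$r - 150), 2)  # near the midpoint up to discretization
  # too small a circle is a typed failure
  expect_identical(extract_mean_rgb(img, list(center = c(5, 5), radius = 1),
                                    min_pixels = 20)$stage, "pad")
})

test_that("geometry detection is invariant to uniform brightness scaling", {
  sc <- fixture_scene("neutral_hi")
  fid1 <- detect_fiducial(sc$image)
  fid2 <- detect_fiducial(sc$image * 0.7)
  expect_lt(max(abs(fid1$quad - fid2$quad)), 0.5)
})
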