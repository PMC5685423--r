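test_that("Landolt geometry keeps the 20% critical-detail ratio", {
  t30 <- landolt_target(6)
  expect_equal(t30$diameter, 30)
  expect_equal(t30$gap_size / t30$diameter, 0.2)
  expect_equal(t30$stroke_width / t30$diameter, 0.2)

  # measure the rendered gap: scan along the gap axis at mid-ring radius
  img <- render_landolt(t30, c(600, 0), DISP,
                        geom = perisr:::window_geom(DISP, c(600, 0), 40))
  geom <- perisr:::window_geom(DISP, c(600, 0), 40)
  xs <- perisr:::geom_x(geom) - 600
  ys <- perisr:::geom_y(geom)
  # upper-right gap axis at 45 deg: sample pixels near the mid-ring circle
  rr <- sqrt(outer(ys^2, xs^2, "+"))
  ang <- atan2(outer(ys, rep(1, length(xs))), outer(rep(1, length(ys)), xs))
  ring <- rr > 0.35 * 30 & rr < 0.45 * 30
  gap_px <- ring & img < 65 # below half-way luminance = carved out
  # angular extent of the gap at mid radius ~ 2*asin(0.1d / 0.4d)
  gap_ang <- range(ang[gap_px])
  expect_equal(diff(gap_ang), 2 * asin(0.25), tolerance = 0.15)
})

test_that("rendered glyph area matches the analytic annulus-minus-slot area", {
  tg <- landolt_target(12) # 60 arcmin diameter
  geom <- perisr:::window_geom(DISP, c(600, 0), 60)
  img <- render_landolt(tg, c(600, 0), DISP, geom = geom)
  area <- sum((img - 45) / 40) * DISP$arcmin_per_pixel^2
  expect_equal(area, perisr:::landolt_area(tg), tolerance = 0.02)
})

test_that("degenerate and out-of-canvas targets are rejected", {
  expect_error(landolt_target(0), "positive")
  expect_error(landolt_target(-3), "positive")
  expect_error(render_landolt(landolt_target(0.1), c(600, 0), DISP),
               "degenerate")
  expect_error(render_landolt(landolt_target(6), c(5000, 0), DISP),
               "clipping")
})

test_that("mask opaque counts are exact for any density", {
  expect_identical(generate_mask(0, 1)$opaque_set, integer(0))
  expect_length(generate_mask(0.5, 1)$opaque_set, 3200)
  expect_length(generate_mask(1, 1)$opaque_set, 6400)
  for (d in c(0.1, 1 / 3, 0.62, 0.987)) {
    m <- generate_mask(d, derive_seed(99, round(d * 1000)))
    expect_length(m$opaque_set, round(d * 6400))
  }
  expect_error(generate_mask(-0.1, 1), "density")
  expect_error(generate_mask(1.2, 1), "density")
  # determinism
  expect_identical(generate_mask(0.5, 7)$opaque_set,
                   generate_mask(0.5, 7)$opaque_set)
  expect_false(identical(generate_mask(0.5, 7)$opaque_set,
                         generate_mask(0.5, 8)$opaque_set))
})

test_that("smooth arc path is isoeccentric at 2 deg/s and meridian-symmetric", {
  p <- smooth_arc_path(25, display = DISP)
  d <- sqrt(rowSums(p$positions^2))
  expect_true(all(abs(d - 600) < DISP$arcmin_per_pixel))
  steps <- vapply(1:24, function(i) {
    a <- p$positions[i, ]; b <- p$positions[i + 1, ]
    600 * acos(min(1, sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))))
  }, numeric(1))
  expect_equal(steps, rep(2 * 60 / 75, 24), tolerance = 1e-9)
  # first and last positions equidistant from the meridian
  expect_equal(abs(p$positions[1, 2]), abs(p$positions[25, 2]))
  expect_equal(unname(p$positions[13, 2]), 0) # midpoint on the meridian
  # speed 0 degenerates to a static path
  p0 <- smooth_arc_path(10, speed = 0, display = DISP)
  expect_true(all(apply(p0$positions, 2, function(v) all(v == v[1]))))
  expect_error(smooth_arc_path(5, eccentricity = -1), "eccentricity")
})

test_that("shuffling conserves the multiset of positions", {
  p <- smooth_arc_path(25, display = DISP)
  for (s in 1:50) {
    q <- shuffle_path(p, s)
    expect_equal(sort(q$positions[, 2]), sort(p$positions[, 2]))
    expect_equal(sort(q$positions[, 1]), sort(p$positions[, 1]))
  }
  expect_identical(shuffle_path(p, 3)$order, shuffle_path(p, 3)$order)
  # single-frame path is its own shuffle
  p1 <- smooth_arc_path(1, display = DISP)
  expect_equal(shuffle_path(p1, 5)$positions, p1$positions)
  expect_error(shuffle_path(static_path(10), 1), "smooth_arc")
})

test_that("sequences have 25 frames and luminances within display range", {
  for (label in conditions()$label) {
    s <- make_seq(label, density = 0.5, gap = 8, seed = 11)
    expect_identical(s$n_frames, 25)
    rng <- range(unlist(lapply(s$frames, range)))
    expect_gte(rng[1], DISP$background_luminance - 1e-9)
    expect_lte(rng[2], DISP$target_luminance + 1e-9)
  }
})

test_that("static condition frames are identical; updating masks differ", {
  s <- make_seq("static_static", 0.5, 10, seed = 2)
  for (f in 2:25) expect_identical(s$frames[[f]], s$frames[[1]])
  u <- make_seq("static_updating", 0.5, 10, seed = 2)
  expect_false(identical(u$masks[[1]]$opaque_set, u$masks[[2]]$opaque_set))
  expect_false(identical(u$frames[[1]], u$frames[[2]]))
})

test_that("full-density masks fully occlude the target", {
  s <- make_seq("static_static", 1, 10, seed = 4)
  for (f in c(1, 13, 25))
    expect_true(all(s$frames[[f]] == DISP$background_luminance))
  # moving target behind a full mask is also invisible
  s2 <- make_seq("smooth_static", 1, 10, seed = 4)
  expect_true(all(s2$frames[[13]] == DISP$background_luminance))
})

test_that("sequence composition is bit-deterministic in the seed", {
  a <- make_seq("smooth_updating", 0.75, 7, seed = 123)
  b <- make_seq("smooth_updating", 0.75, 7, seed = 123)
  expect_identical(a$frames, b$frames)
  expect_identical(a$target_positions, b$target_positions)
  c <- make_seq("smooth_updating", 0.75, 7, seed = 124)
  expect_false(identical(a$frames, c$frames))
})

test_that("windowed rendering agrees with the full-canvas render", {
  s <- make_seq("smooth_static", 0.75, 8, seed = 31)
  full <- make_seq("smooth_static", 0.75, 8, seed = 31, window = "full")
  g <- s$geom
  rows <- (g$row_off + 1):(g$row_off + g$ny)
  cols <- (g$col_off + 1):(g$col_off + g$nx)
  expect_equal(s$frames[[13]], full$frames[[13]][rows, cols])
})

test_that("the fixation cross is drawn at the origin on the full canvas", {
  s <- make_seq("static_static", 0, 10, seed = 1, window = "full")
  g <- s$geom
  r0 <- round((g$y_tl - 0) / DISP$arcmin_per_pixel) + 1
  c0 <- round((0 - g$x_tl) / DISP$arcmin_per_pixel) + 1
  expect_gt(s$frames[[1]][r0, c0], 80) # near target luminance
})

test_that("TIFF export round-trips frames and writes a sidecar", {
  skip_if_not_installed("tiff")
  s <- make_seq("static_static", 0.5, 8, seed = 5)
  path <- tempfile(fileext = ".tif")
  write_stimulus_tiff(s, path)
  pages <- tiff::readTIFF(path, all = TRUE)
  expect_length(pages, 25)
  back <- pages[[1]] * 65535 / 100
  expect_equal(back, s$frames[[1]], tolerance = 0.01)
  sc <- jsonlite::read_json(sub("\\.tif$", ".json", path))
  expect_identical(sc$condition, "static_static")
  expect_equal(sc$n_frames, 25)
  unlink(c(path, sub("\\.tif$", ".json", path)))
})

test_that("invalid conditions and densities are rejected", {
  expect_error(condition_spec("nope", 0.5))
  expect_error(condition_spec("static_static", 2), "density")
})
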