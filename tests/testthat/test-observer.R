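test_that("front end is identity at zero parameters and preserves means", {
  img <- make_seq("static_static", 0.5, 8, seed = 1)$frames[[1]]
  p0 <- observer_params("single_frame", blur_sigma = 0, noise_sd = 0)
  expect_identical(front_end(img, p0), img)
  # a normalized blur kernel preserves the mean of an interior region
  pb <- observer_params("single_frame", blur_sigma = 2.5, noise_sd = 0)
  out <- front_end(img, pb)
  inner <- 12:(nrow(img) - 12)
  expect_equal(mean(out[inner, inner]), mean(img[inner, inner]),
               tolerance = 2e-2)
})

test_that("front-end noise has the requested variance", {
  flat <- matrix(45, 320, 320) # ~1e5 pixels
  pn <- observer_params("single_frame", blur_sigma = 0, noise_sd = 3)
  out <- front_end(flat, pn, seed = 21)
  expect_equal(stats::var(as.vector(out)), 9, tolerance = 0.05)
  expect_error(front_end(flat, pn), "seed")
})

test_that("shift estimation recovers exact and constructed offsets", {
  img <- make_seq("static_static", 0.5, 10, seed = 2)$frames[[1]]
  same <- estimate_shift(img, img)
  expect_equal(same$shift, c(x = 0, y = 0))
  expect_equal(same$confidence, 1, tolerance = 1e-9)
  # integer-pixel translation recovered exactly (noiseless)
  sh <- perisr:::cpp_translate(img, 3, 5, mean(img)) # down 3 rows, right 5
  est <- estimate_shift(img, sh, arcmin_per_pixel = 1.05, max_shift = 20)
  expect_equal(est$shift[["x"]], 5 * 1.05, tolerance = 1e-6)
  expect_equal(est$shift[["y"]], -3 * 1.05, tolerance = 1e-6)
  expect_error(estimate_shift(matrix(1, 10, 10), matrix(1, 10, 10)),
               "zero-variance")
  expect_error(estimate_shift(img, img[-1, ]), "same shape")
})

test_that("independent noise frames correlate weakly", {
  conf <- vapply(1:100, function(s) {
    a <- perisr:::with_seed(derive_seed(1, s), matrix(rnorm(1e4), 100))
    b <- perisr:::with_seed(derive_seed(2, s), matrix(rnorm(1e4), 100))
    estimate_shift(a, b)$confidence
  }, numeric(1))
  expect_lt(max(conf), 0.2)
})

test_that("shift-and-add accumulation averages registered frames", {
  f <- make_seq("static_static", 0.5, 8, seed = 3)$frames[[1]]
  res <- accumulate_sr(list(f, f, f), matrix(0, 3, 2))
  expect_equal(res$composite, f)
  expect_true(all(res$counts == 3))
  res1 <- accumulate_sr(list(f), matrix(0, 1, 2))
  expect_equal(res1$composite, f)
  expect_error(accumulate_sr(list(f, f), matrix(0, 3, 2)), "one shift")
})

test_that("registration uncovers target pixels occluded in single frames", {
  # moving target behind a fixed dense mask: multi-frame registered
  # coverage exceeds any single frame's
  s <- make_seq("smooth_static", 0.75, 10, seed = 8)
  mid <- 13
  tpl <- perisr:::cpp_render_landolt(
    s$geom$ny, s$geom$nx, s$geom$x_tl, s$geom$y_tl, 1.05,
    s$target_positions[mid, 1], s$target_positions[mid, 2],
    s$diameter, cos(pi / 4), sin(pi / 4), 4L)
  target_px <- tpl > 0.5
  occluded_single <- mean(s$frames[[mid]][target_px] < 50)
  shifts <- sweep(s$target_positions, 2, s$target_positions[mid, ])
  comp <- accumulate_sr(s$frames, shifts)$composite
  never_seen <- mean(comp[target_px] < 50)
  expect_lt(never_seen, occluded_single)
  expect_gt(occluded_single, 0.5) # single frames are mostly occluded
})

test_that("noiseless unmasked decisions are perfect for all orientations", {
  p <- observer_params("super_resolution", blur_sigma = 0, noise_sd = 0)
  for (ori in ALL_ORIENTATIONS) {
    s <- make_seq("static_static", 0, 8, orientation = ori, seed = 12)
    r <- simulate_trial(s, p, seed = 99)
    expect_identical(r$chosen_orientation, ori)
    expect_true(r$correct)
  }
})

test_that("tied decision variables are broken uniformly by seed", {
  dv <- c(0.5, 0.5, 0.1, 0.2)
  names(dv) <- ALL_ORIENTATIONS
  picks <- vapply(1:400, function(s) perisr:::choose_max(dv, s), character(1))
  tab <- table(factor(picks, levels = ALL_ORIENTATIONS))
  expect_identical(sum(tab[3:4]), 0L)
  expect_gt(min(tab[1:2]), 120) # both tied options chosen often
})

test_that("a fully occluded stimulus yields chance 4AFC performance", {
  p <- observer_params("single_frame", noise_sd = 8)
  correct <- vapply(1:800, function(i) {
    s <- derive_seed(31, i)
    ori <- ALL_ORIENTATIONS[1 + (s %% 4)]
    sq <- make_seq("static_static", 1, 8, ori, seed = derive_seed(s, 1))
    simulate_trial(sq, p, seed = derive_seed(s, 2))$correct
  }, logical(1))
  expect_lt(abs(mean(correct) - 0.25), 0.045)
})

test_that("probability summation equals single frame for static noiseless input", {
  s <- make_seq("static_static", 0.5, 6, seed = 14)
  ps <- observer_params("prob_summation", noise_sd = 0)
  sf <- observer_params("single_frame", noise_sd = 0)
  r1 <- simulate_trial(s, ps, seed = 5)
  r2 <- simulate_trial(s, sf, seed = 5)
  expect_identical(r1$chosen_orientation, r2$chosen_orientation)
  expect_equal(r1$decision_variables, r2$decision_variables)
})

test_that("oracle registration is at least as good as no registration", {
  ora <- observer_params("super_resolution", noise_sd = 8,
                         motion_knowledge = "oracle")
  non <- observer_params("super_resolution", noise_sd = 8,
                         motion_knowledge = "none")
  acc_o <- observer_accuracy("smooth_static", 0.75, 8, ora, 120, seed0 = 3)
  acc_n <- observer_accuracy("smooth_static", 0.75, 8, non, 120, seed0 = 3)
  expect_gte(acc_o, acc_n)
  expect_gt(acc_o, acc_n + 0.1) # misregistration costs real accuracy here
})

test_that("responses are deterministic given sequence, params and seed", {
  s <- make_seq("smooth_updating", 0.75, 6, seed = 77)
  p <- observer_params("super_resolution", noise_sd = 8)
  r1 <- simulate_trial(s, p, seed = 1234)
  r2 <- simulate_trial(s, p, seed = 1234)
  expect_identical(r1$chosen_orientation, r2$chosen_orientation)
  expect_identical(r1$decision_variables, r2$decision_variables)
})

test_that("decision variables permute with 90-degree stimulus relabeling", {
  # the four templates are rotations of one another; relabeling the gap
  # orientation of an otherwise identical noiseless stimulus must permute
  # the winning decision variable accordingly
  p <- observer_params("single_frame", blur_sigma = 1, noise_sd = 0)
  dv <- sapply(ALL_ORIENTATIONS, function(ori) {
    s <- make_seq("static_static", 0, 8, orientation = ori, seed = 3)
    simulate_trial(s, p, seed = 9)$decision_variables
  })
  for (i in seq_along(ALL_ORIENTATIONS))
    expect_identical(names(which.max(dv[, i])), ALL_ORIENTATIONS[i])
})
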