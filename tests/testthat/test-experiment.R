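test_that("experiment designs have the published cell structure", {
  d1 <- perisr:::EXPERIMENT_DESIGNS[["1"]]
  expect_length(d1$conditions, 2)
  expect_equal(d1$densities, c(0, 0.5, 0.75))
  for (e in c("2", "3", "4")) {
    d <- perisr:::EXPERIMENT_DESIGNS[[e]]
    expect_length(d$conditions, 2)
    expect_equal(d$densities, c(0.5, 0.75))
  }
  expect_error(run_experiment(9), "unknown experiment")
  expect_error(run_experiment(1, subjects = list()), "empty subject")
})

test_that("subject jitter perturbs parameters reproducibly", {
  subs <- subject_models(8, seed = 4)
  expect_length(subs, 8)
  blurs <- vapply(subs, function(s) s$params$blur_sigma, numeric(1))
  expect_gt(stats::sd(blurs), 0)
  expect_true(all(blurs > 0))
  subs2 <- subject_models(8, seed = 4)
  expect_identical(blurs,
                   vapply(subs2, function(s) s$params$blur_sigma, numeric(1)))
})

test_that("run_condition pools runs, caps trials, and is seed-stable", {
  expect_error(run_condition(subject_models(1)[[1]], "static_static", 0.5,
                             n_runs = 0), "n_runs")
  sub <- subject_models(1, base = observer_params("single_frame",
                                                  noise_sd = 8))[[1]]
  res <- run_condition(sub, "static_static", 1, n_runs = 2, seed = 3,
                       fit = FALSE)
  expect_lte(nrow(res$trials), 2 * 50) # 50-trial cap per run
  expect_identical(sort(unique(res$trials$run)), 1:2)
  res2 <- run_condition(sub, "static_static", 1, n_runs = 2, seed = 3,
                        fit = FALSE)
  expect_identical(res$trials$gap_arcmin, res2$trials$gap_arcmin)
})

test_that("repeated-measures ANOVA matches stats::aov on a toy table", {
  # 2 conditions x 2 densities x 3 subjects with arbitrary fixed numbers
  tab <- tibble::tibble(
    subject = rep(c("s1", "s2", "s3"), each = 4),
    condition = rep(rep(c("a", "b"), each = 2), 3),
    density = rep(c(0.5, 0.75), 6),
    mu = c(10.2, 15.1, 7.9, 12.3,
           11.5, 16.8, 8.4, 13.9,
           9.7, 14.2, 7.1, 11.8))
  res <- rm_anova_2way(tab)
  # independent route: aov with within-subject error strata
  tab$fs <- factor(tab$subject); tab$fa <- factor(tab$condition)
  tab$fb <- factor(tab$density)
  fit <- summary(stats::aov(mu ~ fa * fb + Error(fs / (fa * fb)), data = tab))
  f_a <- fit[["Error: fs:fa"]][[1]]["fa", "F value"]
  f_b <- fit[["Error: fs:fb"]][[1]]["fb", "F value"]
  f_ab <- fit[["Error: fs:fa:fb"]][[1]]["fa:fb", "F value"]
  eff <- res$effects
  expect_equal(eff$F[eff$source == "A"], f_a, tolerance = 1e-10)
  expect_equal(eff$F[eff$source == "B"], f_b, tolerance = 1e-10)
  expect_equal(eff$F[eff$source == "A:B"], f_ab, tolerance = 1e-10)
  # sums of squares are conserved
  expect_equal(sum(eff$ss), res$ss_total, tolerance = 1e-9)
  expect_equal(eff$df[eff$source == "A"], 1)
  expect_equal(eff$df[eff$source == "B"], 1)
})

test_that("ANOVA degenerate cases behave", {
  tab <- expand.grid(subject = c("s1", "s2", "s3"),
                     condition = c("a", "b"),
                     density = c(0.5, 0.75))
  tab$mu <- 5
  res <- rm_anova_2way(tab)
  expect_true(all(res$effects$ss < 1e-20))
  one <- tab[tab$subject == "s1", ]
  expect_error(rm_anova_2way(one), "2 subjects")
  expect_error(rm_anova_2way(tab[-1, ]), "balanced")
})

test_that("motion benefit contrasts are zero for identical conditions and antisymmetric", {
  tab <- expand.grid(subject = sprintf("s%d", 1:5),
                     condition = c("static_static", "smooth_static"),
                     density = c(0, 0.5, 0.75), stringsAsFactors = FALSE)
  # identical threshold per (subject, density) in both conditions
  key <- interaction(tab$subject, tab$density)
  base <- perisr:::with_seed(8, rnorm(nlevels(key), 10, 2))
  tab$mu <- base[as.integer(key)]
  mb <- motion_benefit(tab)
  expect_equal(mb$difference, rep(0, 3))
  # antisymmetry
  tab2 <- tab
  tab2$mu[tab2$condition == "smooth_static"] <-
    tab2$mu[tab2$condition == "smooth_static"] - 2
  m1 <- motion_benefit(tab2, c("static_static", "smooth_static"))
  m2 <- motion_benefit(tab2, c("smooth_static", "static_static"))
  expect_equal(m1$difference, -m2$difference)
  expect_equal(m1$difference, rep(2, 3))
  expect_error(motion_benefit(tab2[-1, ]), "missing cells")
})

test_that("trial records and fits round-trip through their file formats", {
  resp <- make_logistic_responder(8, 2)
  tr <- run_staircase(condition_spec("static_static", 0.5),
                      observer_params("single_frame", noise_sd = 8),
                      seed = 3, display = DISP)
  path <- tempfile(fileext = ".csv")
  write_trials_csv(tr, path)
  back <- utils::read.csv(path)
  expect_identical(names(back), names(tr))
  expect_equal(back$gap_arcmin, tr$gap_arcmin)

  fit <- fit_ml(simulate_logistic_trials(rep(seq(4, 12, 2), each = 40),
                                         8, 2, seed = 5))
  jp <- tempfile(fileext = ".json")
  write_fit_json(fit, jp, subject = "s1", condition = "static_static",
                 density = 0.5)
  j <- jsonlite::read_json(jp)
  expect_equal(j$mu, fit$mu)
  expect_identical(j$condition, "static_static")
  unlink(c(path, jp))
})

test_that("configuration files merge over defaults", {
  cfg <- default_config()
  expect_equal(cfg$staircase$initial_gap, 17.8)
  expect_equal(cfg$display$frame_rate, 75)
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(list(observer = list(noise_sd = 9),
                            experiment = list(n_runs = 3)),
                       path, auto_unbox = TRUE)
  over <- read_config(path)
  expect_equal(over$observer$noise_sd, 9)
  expect_equal(over$experiment$n_runs, 3)
  expect_equal(over$observer$blur_sigma, cfg$observer$blur_sigma)
  ypath <- tempfile(fileext = ".yaml")
  writeLines("staircase:\n  max_trials: 20", ypath)
  overy <- read_config(ypath)
  expect_equal(overy$staircase$max_trials, 20)
  unlink(c(path, ypath))
})
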