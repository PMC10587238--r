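test_that("the Arrhenius transform converts units and drops arrhythmic points", {
  cs <- make_cardiac_series(temps = c(16, 17, 27), fh = c(100, 110, 90))
  xy <- arrhenius_transform(cs)
  expect_equal(nrow(xy), 2)      # 27 degC point is the arrhythmic one
  expect_equal(xy$x[1], 1000 / 289.15, tolerance = 1e-10)
  expect_equal(xy$y[1], log(100), tolerance = 1e-10)
  expect_true(all(diff(xy$x) < 0))
  bad <- make_cardiac_series(temps = c(16, 17, 18, 19), fh = c(100, -5, 90, 80))
  expect_error(arrhenius_transform(bad), "positive")
})

test_that("an exact broken line is recovered with a tight interval", {
  x <- 1000 / (seq(16, 25) + 273.15)
  x0 <- 1000 / (20.5 + 273.15)
  y <- ifelse(x >= x0, 4.4 - 5.8 * (x - x0), 4.4 - 2.5 * (x - x0))
  fit <- fit_breakpoint(data.frame(x = x, y = y), seed = 1)
  expect_true(fit$identified)
  expect_false(fit$excluded)
  expect_equal(fit$breakpoint_x, x0, tolerance = 1e-6)
  expect_equal(fit$t_ab, 20.5, tolerance = 1e-4)
  expect_lt(fit$ci_halfwidth_c, 0.01)
  expect_equal(unname(fit$slopes["below"]), -5.8, tolerance = 1e-6)
  expect_equal(unname(fit$slopes["above"]), -2.5, tolerance = 1e-6)
})

test_that("a single straight line yields no identified breakpoint", {
  x <- 1000 / (seq(16, 25) + 273.15)
  y <- 4.4 - 5.8 * (x - x[1])
  fit <- fit_breakpoint(data.frame(x = x, y = y), seed = 2)
  expect_false(fit$identified)
  expect_true(fit$excluded)
  expect_identical(fit$reason, "not_identified")
  # and so does a series too short to split
  few <- data.frame(x = x[1:3], y = y[1:3])
  expect_identical(fit_breakpoint(few, seed = 2)$reason, "too_few_points")
})

test_that("the fitted breakpoint matches the exhaustive grid-search oracle", {
  cfg <- small_config()
  coh <- generate_cohort(study_config(n_fish = 10, seed = 31))
  set.seed(33)
  for (i in 1:10) {
    cs <- simulate_cardiac_series(coh[i, ], cfg)
    xy <- arrhenius_transform(cs)
    rising <- xy[xy$temp_c <= summarize_cardiac(cs)$t_peak, ]
    if (nrow(rising) < 6) next
    fit <- fit_breakpoint(rising, seed = 100 + i)
    oracle <- oracle_breakpoint_grid(rising$x, rising$y)
    # the refined knot can only improve on the best grid candidate, and must
    # stay within one grid step of it
    step <- max(diff(oracle$candidates))
    expect_lte(allometherm:::breakstick_rss(sort(rising$x),
                                            rising$y[order(rising$x)],
                                            fit$breakpoint_x),
               oracle$rss + 1e-12)
    expect_lt(abs(fit$breakpoint_x - oracle$psi), step + 1e-12)
  }
})

test_that("zero-noise series return their latent thermal limits", {
  cfg <- zero_noise_config(n_fish = 6)
  coh <- generate_cohort(study_config(n_fish = 6, seed = 41))
  coh$u_fh <- 0
  for (i in c(1, 4, 6)) {
    set.seed(50 + i)
    cs <- simulate_cardiac_series(coh[i, ], cfg)
    out <- analyze_cardiac_series(cs, seed = 60 + i)
    fit <- attr(out, "fit")
    expect_true(fit$identified)
    expect_equal(fit$t_ab, cs$truth$t_ab, tolerance = 1e-3)
    expect_equal(out$t_peak, cs$truth$t_peak_obs)
    expect_equal(out$t_arr, cs$truth$t_arr_obs)
    expect_equal(out$t_ab, fit$t_ab)
  }
})

test_that("cardiac summaries apply the peak and tie-break rules", {
  cs <- make_cardiac_series(temps = 20:27,
                            fh = c(100, 110, 120, 150, 140, 130, 120, 60))
  s <- summarize_cardiac(cs)
  expect_equal(s$peak_fhmax, 150)
  expect_equal(s$t_peak, 23)
  expect_equal(s$t_arr, 27)
  # tie: the lowest temperature attaining the maximum wins
  tie <- make_cardiac_series(temps = 20:26,
                             fh = c(100, 110, 120, 150, 140, 150, 70))
  expect_equal(summarize_cardiac(tie)$t_peak, 23)
  # monotonically rising series peaks at the last pre-arrhythmia step
  mono <- make_cardiac_series(temps = 20:25,
                              fh = c(100, 105, 110, 115, 120, 80))
  expect_equal(summarize_cardiac(mono)$t_peak, 24)
  # no arrhythmia observed: T_ARR absent
  none <- make_cardiac_series(temps = 20:24,
                              fh = c(100, 110, 120, 115, 105),
                              arr_last = FALSE)
  expect_true(is.na(summarize_cardiac(none)$t_arr))
})

test_that("summary invariants hold across generated series", {
  cfg <- small_config()
  coh <- generate_cohort(study_config(n_fish = 12, seed = 71))
  set.seed(72)
  for (i in seq_len(nrow(coh))) {
    cs <- simulate_cardiac_series(coh[i, ], cfg)
    s <- summarize_cardiac(cs)
    expect_lte(s$t_peak, s$t_arr)
    pre <- cs$observations[!cs$observations$arrhythmia_flag, ]
    expect_true(all(s$peak_fhmax >= pre$fhmax_bpm))
  }
})

test_that("tightening the CI limit never un-excludes a fit", {
  cfg <- small_config()
  coh <- generate_cohort(study_config(n_fish = 8, seed = 81))
  set.seed(82)
  for (i in seq_len(nrow(coh))) {
    cs <- simulate_cardiac_series(coh[i, ], cfg)
    xy <- arrhenius_transform(cs)
    rising <- xy[xy$temp_c <= summarize_cardiac(cs)$t_peak, ]
    if (nrow(rising) < 6) next
    wide <- fit_breakpoint(rising, ci_limit_c = 1.5, seed = 90 + i)
    narrow <- fit_breakpoint(rising, ci_limit_c = 0.3, seed = 90 + i)
    if (wide$excluded) expect_true(narrow$excluded)
  }
})

test_that("bootstrap breakpoint intervals achieve near-nominal coverage", {
  # 200 series at default noise; the 95% interval should cover the latent
  # T_AB in 90-99% of identified fits
  cfg <- study_config(n_fish = 200, seed = 300)
  coh <- generate_cohort(cfg)
  set.seed(301)
  covered <- 0L; total <- 0L
  for (i in seq_len(nrow(coh))) {
    cs <- simulate_cardiac_series(coh[i, ], cfg)
    xy <- arrhenius_transform(cs)
    rising <- xy[xy$temp_c <= summarize_cardiac(cs)$t_peak, ]
    if (nrow(rising) < 6) next
    fit <- fit_breakpoint(rising, seed = 400 + i)
    if (!fit$identified || anyNA(fit$ci_c)) next
    total <- total + 1L
    if (cs$truth$t_ab >= fit$ci_c[1] && cs$truth$t_ab <= fit$ci_c[2])
      covered <- covered + 1L
  }
  expect_gte(total, 100)
  coverage <- covered / total
  expect_gte(coverage, 0.90)
  expect_lte(coverage, 0.99)
})
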