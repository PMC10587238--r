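table1_mmr <- list(slope = 0.810,
                   intercepts = c("12" = 1.011, "16" = 1.235,
                                  "20" = 1.436, "22" = 1.497))

noiseless_mixed_data <- function(n_fish = 30, pars = table1_mmr, seed = 1) {
  cfg <- study_config(n_fish = n_fish, seed = seed, individual_sd = 0,
                      residual_sd = 0, mmr_slope = pars$slope,
                      mmr_intercepts = pars$intercepts)
  simulate_scaling_data(cfg, "mmr")
}

test_that("the mixed model recovers noiseless generating coefficients", {
  d <- noiseless_mixed_data()
  fit <- suppressWarnings(fit_scaling_mixed(d))
  expect_equal(fit$slope, 0.810, tolerance = 1e-6)
  ints <- fit$intercepts
  expect_equal(ints$estimate[match(c(12, 16, 20, 22), ints$temperature)],
               c(1.011, 1.235, 1.436, 1.497), tolerance = 1e-6)
  expect_equal(fit$n_individuals, 30)
  expect_equal(fit$n_observations, 120)
})

test_that("rescaling mass units shifts intercepts by b*ln(scale) only", {
  d <- noiseless_mixed_data(seed = 2)
  d_g <- d
  d_g$ln_mass <- log(exp(d$ln_mass) * 1000)      # grams instead of kg
  f1 <- suppressWarnings(fit_scaling_mixed(d))
  f2 <- suppressWarnings(fit_scaling_mixed(d_g))
  expect_equal(f2$slope, f1$slope, tolerance = 1e-6)
  expect_equal(f2$intercepts$estimate,
               f1$intercepts$estimate - f1$slope * log(1000),
               tolerance = 1e-5)
})

test_that("a single temperature level degenerates to one intercept", {
  d <- noiseless_mixed_data(seed = 3)
  d1 <- d[d$temperature == "16", ]
  fit <- suppressWarnings(fit_scaling_mixed(d1))
  expect_equal(nrow(fit$intercepts), 1)
  expect_equal(fit$intercepts$temperature, 16)
  expect_equal(fit$slope, 0.810, tolerance = 1e-6)
  expect_equal(fit$intercepts$estimate, 1.235, tolerance = 1e-6)
})

test_that("simple regressions interpolate exact lines and recover noisy truth", {
  x <- c(-5, -4, -3, -2, -1)
  d <- data.frame(ln_mass = x, ln_response = 3.359 + 0.030 * x)
  fit <- fit_scaling_simple(d)
  expect_equal(fit$slope, 0.030, tolerance = 1e-10)
  expect_equal(fit$intercepts$estimate, 3.359, tolerance = 1e-10)
  # two points plus their midpoint still interpolate exactly
  d3 <- data.frame(ln_mass = c(-5, -3, -4), ln_response = 2 + 0.5 * c(-5, -3, -4))
  expect_equal(fit_scaling_simple(d3)$slope, 0.5, tolerance = 1e-10)
  expect_error(fit_scaling_simple(d3[1:2, ]), "at least 3")
  expect_error(fit_scaling_simple(data.frame(ln_mass = rep(1, 5),
                                             ln_response = rnorm(5))),
               "degenerate")
  # ventricle-mass recovery at n = 30 lands within 2 SE of truth
  cfg <- study_config(n_fish = 30, seed = 4)
  dv <- simulate_scaling_data(cfg, "vm")
  fv <- fit_scaling_simple(dv)
  expect_lt(abs(fv$slope - 0.855), 2 * fv$slope_se)
})

test_that("BIC selection prefers the generating fixed-effect structure", {
  cfg <- study_config(seed = 5)
  d <- simulate_scaling_data(cfg, "mmr", n_obs = 238)
  cmp <- compare_models_bic(d)
  expect_identical(cmp$selected, "additive")
  expect_true(all(cmp$table$delta_bic >= 0))
  expect_equal(cmp$table$delta_bic[cmp$table$model == "additive"], 0)
  # a strong mass-by-temperature interaction flips the choice
  d2 <- d
  shift <- (as.numeric(as.character(d2$temperature)) - 12) / 10 * 0.15
  d2$ln_response <- d2$ln_response + shift * d2$ln_mass
  cmp2 <- compare_models_bic(d2)
  expect_identical(cmp2$selected, "interaction")
  # duplicated candidates tie and the first wins
  cmp3 <- compare_models_bic(d, candidates = list(
    a = list(interaction = FALSE), b = list(interaction = FALSE)))
  expect_identical(cmp3$selected, "a")
  expect_equal(cmp3$table$bic[1], cmp3$table$bic[2])
})

test_that("effect tests separate real temperature structure from none", {
  cfg <- study_config(seed = 6)
  d <- simulate_scaling_data(cfg, "mmr", n_obs = 238)
  fit <- fit_scaling_mixed(d)
  et <- test_effects(fit)
  expect_true(all(c("ln_mass", "temperature") %in% et$anova$term))
  expect_lt(et$anova$p_value[et$anova$term == "temperature"], 0.001)
  expect_equal(nrow(et$contrasts), choose(4, 2))
  expect_true(all(et$contrasts$p_value >= 0 & et$contrasts$p_value <= 1))
  # flat intercepts: no temperature signal to find
  flat <- study_config(seed = 7,
                       mmr_intercepts = c("12" = 1.2, "16" = 1.2,
                                          "20" = 1.2, "22" = 1.2))
  d0 <- simulate_scaling_data(flat, "mmr")
  et0 <- test_effects(fit_scaling_mixed(d0))
  expect_gt(et0$anova$p_value[et0$anova$term == "temperature"], 0.05)
  expect_true(all(et0$contrasts$p_value > 0.05))
  # terms not in the model are not tested
  expect_false("origin" %in% et$anova$term)
  fit_cov <- fit_scaling_mixed(d, covariates = "origin")
  expect_true("origin" %in% test_effects(fit_cov)$anova$term)
})

test_that("mass normalization obeys its defining identities", {
  expect_equal(mass_normalize(0.5, 0.065, 0.81), 0.5 / 0.065)
  expect_equal(mass_normalize(0.5, 0.3, 0), 0.5 / 0.065)
  v <- exp(1.011 + 0.810 * log(0.065))
  expect_equal(mass_normalize(v, 0.065, 0.810), 4.62, tolerance = 1e-2)
  expect_error(mass_normalize(-1, 0.1, 0.8), "domain")
  expect_error(mass_normalize(1, 0, 0.8), "domain")
  # normalize-then-fit: the exponent is fully removed on noiseless data
  d <- noiseless_mixed_data(seed = 8)
  d16 <- d[d$temperature == "16", ]
  norm <- mass_normalize(exp(d16$ln_response), exp(d16$ln_mass), 0.810)
  refit <- fit_scaling_simple(data.frame(ln_mass = d16$ln_mass,
                                         ln_response = log(norm)))
  expect_lt(abs(refit$slope), 1e-6)
})

test_that("singular fits are flagged but still returned", {
  # residual noise but literally zero between-individual variance
  cfg <- study_config(n_fish = 25, seed = 9, individual_sd = 0,
                      residual_sd = 0.1)
  d <- simulate_scaling_data(cfg, "mmr")
  expect_warning(fit <- fit_scaling_mixed(d), "singular")
  expect_true(fit$singular)
  expect_equal(fit$slope, 0.810, tolerance = 0.05)
  # non-positive responses are a data error before logging
  d$ln_response[1] <- NaN
  expect_error(suppressWarnings(fit_scaling_mixed(d)), "non-finite")
})
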