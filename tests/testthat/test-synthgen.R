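test_that("cohorts respect size, mass range and the seed contract", {
  cfg <- study_config(n_fish = 83, mass_range = c(0.005, 0.700), seed = 1)
  coh <- generate_cohort(cfg)
  expect_equal(nrow(coh), 83)
  expect_true(all(coh$body_mass_kg >= 0.005 & coh$body_mass_kg <= 0.700))
  expect_identical(coh, generate_cohort(cfg))
  expect_equal(nrow(generate_cohort(study_config(n_fish = 0))), 0)
  expect_setequal(unique(coh$size_class[coh$body_mass_kg < 0.050]),
                  "juvenile")
  # lab-born fish only occur among juveniles
  expect_true(all(coh$size_class[coh$origin == "lab_born"] == "juvenile"))
})

test_that("invalid generator configurations are rejected", {
  expect_error(study_config(mass_range = c(0.7, 0.005)), "mass_range")
  expect_error(study_config(mass_range = c(-1, 0.7)), "mass_range")
  expect_error(study_config(temperatures = c(12, 12, 20)), "distinct")
  expect_error(study_config(residual_sd = -0.1), "SDs")
  expect_error(study_config(cardiac = cardiac_config(tab_intercept = 3.4)),
               "T_AB >= T_ARR")
})

test_that("zero-noise traces decline at exactly the model-implied slope", {
  cfg <- zero_noise_config()
  coh <- generate_cohort(cfg)
  fish <- coh[1, ]
  set.seed(1)
  tr <- simulate_o2_trace(fish, 16, cfg)
  v_net <- tr$truth$net_volume
  # resting cycles: MO2 = exp(ln a(16) + b ln m), background 10% on top
  rmr <- exp(cfg$rmr_intercepts[["16"]] + cfg$rmr_slope * log(fish$body_mass_kg))
  expected_slope <- -(rmr + 0.10 * rmr) / v_net
  mid <- tr$samples[tr$samples$phase == "measure" &
                      tr$samples$cycle_index == 30, ]
  obs_slope <- stats::coef(lm(o2_mg_per_l ~ I(time_s / 60), data = mid))[2]
  expect_equal(unname(obs_slope), expected_slope, tolerance = 1e-10)
  # the injected maximum episode makes a true MMR exist
  expect_equal(tr$truth$mmr,
               exp(cfg$mmr_intercepts[["16"]] + cfg$mmr_slope *
                     log(fish$body_mass_kg)))
})

test_that("traces obey the intermittent-flow protocol by construction", {
  cfg <- small_config(seed = 5)
  coh <- generate_cohort(cfg)
  set.seed(2)
  tr <- simulate_o2_trace(coh[2, ], 22, cfg)
  s <- tr$samples
  expect_gte(max(s$cycle_index), 60)
  expect_true(all(diff(s$time_s) > 0))
  for (cyc in c(1, 31, 62)) {
    m <- s[s$phase == "measure" & s$cycle_index == cyc, ]
    expect_gte(diff(range(m$time_s)), 240)
  }
  sat <- allometherm:::o2_air_saturation(22, cfg$salinity)
  expect_true(all(s$o2_mg_per_l > 0.70 * sat - 0.1))
  ratio <- tr$truth$net_volume / tr$fish_mass
  expect_true(ratio >= 19.2 && ratio <= 93.9)
  expect_error(simulate_o2_trace(coh[1, ], 14, cfg), "not simulated")
})

test_that("fish of equal mass but different random intercepts yield different slopes", {
  cfg <- zero_noise_config()
  cfg$individual_sd <- 0.2  # latents drawn below, traces still noise-free
  fish <- data.frame(fish_id = c("a", "b"), body_mass_kg = 0.065,
                     origin = "wild", sex = "F", size_class = "adult",
                     u_mmr = c(0.2, -0.2), u_rmr = c(0.2, -0.2),
                     u_fh = 0, stringsAsFactors = FALSE)
  set.seed(3)
  tr_a <- simulate_o2_trace(fish[1, ], 16, cfg)
  set.seed(3)
  tr_b <- simulate_o2_trace(fish[2, ], 16, cfg)
  slope_of <- function(tr) {
    m <- tr$samples[tr$samples$phase == "measure" & tr$samples$cycle_index == 30, ]
    unname(coef(lm(o2_mg_per_l ~ I(time_s / 60), data = m))[2])
  }
  # slope ratio should equal exp(u_a - u_b) because volumes match by mass
  expect_equal(slope_of(tr_a) / slope_of(tr_b) *
                 (tr_a$truth$net_volume / tr_b$truth$net_volume),
               exp(0.4), tolerance = 1e-6)
  expect_false(isTRUE(all.equal(tr_a$truth$rmr, tr_b$truth$rmr)))
})

test_that("cardiac series reproduce the configured power laws at zero noise", {
  cfg <- zero_noise_config()
  fish <- data.frame(fish_id = "f", body_mass_kg = 0.065, origin = "wild",
                     sex = "F", size_class = "adult", u_mmr = 0, u_rmr = 0,
                     u_fh = 0, stringsAsFactors = FALSE)
  set.seed(4)
  cs <- simulate_cardiac_series(fish, cfg)
  cc <- cfg$cardiac
  lnm <- log(0.065)
  expect_equal(cs$truth$t_ab, exp(cc$tab_intercept + cc$tab_slope * lnm))
  expect_equal(cs$truth$t_peak, exp(cc$tpeak_intercept + cc$tpeak_slope * lnm))
  expect_equal(cs$truth$t_arr, exp(cc$tarr_intercept + cc$tarr_slope * lnm))
  # 65-g fish arrests near 26.5 degC under the default coefficients
  expect_equal(cs$truth$t_arr, 26.47, tolerance = 0.01)
  obs <- cs$observations
  expect_equal(obs$temp_c, seq(16, ceiling(cs$truth$t_arr)))
  expect_identical(which(obs$arrhythmia_flag), nrow(obs))
  # fHmax at 16 degC follows the configured scaling law
  expect_equal(log(obs$fhmax_bpm[1]),
               cc$intercept_fh_16 + cc$slope_fh * lnm)
})

test_that("latent cardiac limits increase with body mass for positive slopes", {
  cfg <- zero_noise_config()
  masses <- c(0.005, 0.020, 0.065, 0.250, 0.700)
  traits <- t(sapply(masses, function(m)
    allometherm:::cardiac_traits(m, cfg$cardiac, trait_sd = 0)))
  expect_true(all(diff(traits[, "tab"]) > 0))
  expect_true(all(diff(traits[, "tpeak"]) > 0))
  expect_true(all(diff(traits[, "tarr"]) > 0))
  expect_true(all(traits[, "tab"] < traits[, "tpeak"]))
  expect_true(all(traits[, "tpeak"] < traits[, "tarr"]))
})

test_that("generate_study assembles repeated measures with a truth sidecar", {
  cfg <- small_config(seed = 9)
  study <- generate_study(cfg)
  expect_s3_class(study, "study_dataset")
  expect_equal(length(study$traces), 4 * 4)
  for (f in study$cohort$fish_id)
    for (tp in cfg$temperatures)
      expect_true(paste(f, tp, sep = "_") %in% names(study$traces))
  expect_equal(length(study$cardiac), 3)
  expect_equal(nrow(study$ventricles), 3)
  expect_equal(nrow(study$truth$trials), 16)
  expect_true(all(c("u_mmr", "u_rmr", "u_fh") %in% names(study$truth$latents)))
  # same config -> bit-identical; different seed -> same shape, new values
  study2 <- generate_study(cfg)
  expect_identical(study$truth$trials, study2$truth$trials)
  study3 <- generate_study(small_config(seed = 10))
  expect_equal(dim(study3$truth$trials), dim(study$truth$trials))
  expect_false(isTRUE(all.equal(study3$truth$trials$mmr_true,
                                study$truth$trials$mmr_true)))
})

test_that("study files round-trip through CSV", {
  cfg <- study_config(n_fish = 2, n_cardiac = 1, seed = 13)
  study <- generate_study(cfg)
  dir <- withr::local_tempdir()
  files <- write_study(study, dir)
  expect_true(file.exists(file.path(dir, "cohort.csv")))
  expect_true(file.exists(file.path(dir, "truth.json")))
  tr0 <- study$traces[[1]]
  tf <- file.path(dir, sprintf("trace_%s_%s.csv", tr0$fish_id, tr0$temperature))
  tr1 <- read_o2_trace(tf, chamber_volume = tr0$chamber_volume,
                       fish_mass = tr0$fish_mass)
  expect_equal(tr1$fish_id, tr0$fish_id)
  expect_equal(tr1$temperature, tr0$temperature)
  expect_equal(tr1$samples$o2_mg_per_l, tr0$samples$o2_mg_per_l,
               tolerance = 1e-12)
  cs0 <- study$cardiac[[1]]
  cs1 <- read_cardiac_series(file.path(dir, sprintf("cardiac_%s.csv",
                                                    cs0$fish_id)))
  expect_equal(cs1$observations$fhmax_bpm, cs0$observations$fhmax_bpm,
               tolerance = 1e-12)
})
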