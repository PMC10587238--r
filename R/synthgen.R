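# Synthetic-data generator: seeded cohorts, intermittent-flow respirometry
# traces, per-degree maximum heart-rate series and ventricle masses with the
# statistical structure the downstream analysis assumes (power-law mass
# scaling with temperature-specific intercepts, individual random intercepts,
# lognormal residuals, mass-dependent cardiac thermal-tolerance limits).

#' Configuration for the synthetic study generator
#'
#' Builds the parameter set that defines a simulated respirometry + cardiac
#' thermal-tolerance study. The defaults encode the study conditions the
#' package is designed around: 83 fish spanning 5--700 g tested at four acute
#' temperatures (12, 16, 20, 22 degC), whole-animal metabolic rates following
#' ln(rate) = ln(a_T) + b ln(BM) with a common slope and temperature-specific
#' intercepts, normal individual random intercepts and lognormal residuals on
#' the ln scale, microbial background respiration averaging 10% of the fish's
#' resting rate, and cardiac thermal-tolerance limits (T_AB, T_PEAK, T_ARR)
#' that are power laws of body mass.
#'
#' @param n_fish Number of fish in the cohort.
#' @param mass_range Body-mass range in kg; masses are drawn log-uniformly.
#' @param temperatures Acute test temperatures (degC) for respirometry.
#' @param mmr_slope,rmr_slope Common mass-scaling exponents of maximum and
#'   resting metabolic rate (dimensionless).
#' @param mmr_intercepts,rmr_intercepts Named numeric vectors of ln(a) per
#'   temperature, in ln(mg O2 min^-1); names are the temperatures.
#' @param individual_sd SD of per-fish random intercepts on the ln scale.
#' @param residual_sd SD of per-trial lognormal residuals on the ln scale.
#' @param cycle_sd SD of per-cycle lognormal jitter around the trial level.
#' @param background_fraction Background (microbial) respiration as a
#'   fraction of the fish's resting rate (target mean 0.10).
#' @param o2_noise_sd Additive sensor noise on dissolved O2 samples (mg/L).
#' @param n_cycles Flush/measure cycles per overnight trial (> 60).
#' @param flush_s,measure_s Flush and measure phase durations (s); the
#'   default 600/300 split is one of the protocol's 15-min cycles.
#' @param dt_measure,dt_flush Sampling intervals (s) within each phase.
#' @param volume_ratio Target net-chamber-volume-to-body-mass ratio (L/kg);
#'   raised automatically (up to 93.9) when needed to keep oxygen above 70%
#'   of air saturation within a measure phase.
#' @param salinity Salinity (ppt) used for the air-saturation O2 level.
#' @param cardiac Cardiac generator parameters; see [cardiac_config()].
#' @param n_cardiac Number of fish (from the head of the cohort) given a
#'   cardiac series and a ventricle mass.
#' @param vm_slope,vm_intercept,vm_sd Ventricle-mass power law
#'   ln(VM) = vm_intercept + vm_slope * ln(BM) + N(0, vm_sd), VM in kg.
#' @param seed Root integer seed; every stochastic stage derives its own
#'   stream from it, so one seed reproduces the whole study.
#' @return An object of class `"study_config"` (a validated list).
#' @seealso [generate_study()], [generate_cohort()]
#' @export
study_config <- function(n_fish = 83,
                         mass_range = c(0.005, 0.700),
                         temperatures = c(12, 16, 20, 22),
                         mmr_slope = 0.810,
                         mmr_intercepts = c("12" = 1.011, "16" = 1.235,
                                            "20" = 1.436, "22" = 1.497),
                         rmr_slope = 0.809,
                         rmr_intercepts = c("12" = 0.235, "16" = 0.590,
                                            "20" = 0.845, "22" = 0.970),
                         individual_sd = 0.10,
                         residual_sd = 0.10,
                         cycle_sd = 0.02,
                         background_fraction = 0.10,
                         o2_noise_sd = 0.005,
                         n_cycles = 62,
                         flush_s = 600,
                         measure_s = 300,
                         dt_measure = 5,
                         dt_flush = 30,
                         volume_ratio = 40,
                         salinity = 33,
                         cardiac = cardiac_config(),
                         n_cardiac = 30,
                         vm_slope = 0.855,
                         vm_intercept = -7.639,
                         vm_sd = 0.05,
                         seed = 1L) {
  cfg <- list(n_fish = n_fish, mass_range = mass_range,
              temperatures = temperatures,
              mmr_slope = mmr_slope, mmr_intercepts = mmr_intercepts,
              rmr_slope = rmr_slope, rmr_intercepts = rmr_intercepts,
              individual_sd = individual_sd, residual_sd = residual_sd,
              cycle_sd = cycle_sd, background_fraction = background_fraction,
              o2_noise_sd = o2_noise_sd, n_cycles = n_cycles,
              flush_s = flush_s, measure_s = measure_s,
              dt_measure = dt_measure, dt_flush = dt_flush,
              volume_ratio = volume_ratio, salinity = salinity,
              cardiac = cardiac, n_cardiac = n_cardiac,
              vm_slope = vm_slope, vm_intercept = vm_intercept, vm_sd = vm_sd,
              seed = seed)
  class(cfg) <- "study_config"
  validate_study_config(cfg)
}

#' Cardiac generator parameters
#'
#' Parameters of the latent maximum heart-rate (fHmax) thermal performance
#' curve. In Arrhenius coordinates (x = 1000/T_K, y = ln fHmax) the curve is
#' piecewise linear: a steep rising limb up to the breakpoint temperature
#' T_AB, a shallower rise from T_AB to T_PEAK, and a linear decline (per degC)
#' from T_PEAK until arrhythmia at T_ARR. T_AB, T_PEAK and T_ARR are power
#' laws of body mass, ln(T) = intercept + slope * ln(BM). The default limb
#' slopes correspond to fHmax thermal sensitivities of Q10 = 2.0 below T_AB
#' and Q10 = 1.35 above it (evaluated at 16 degC).
#'
#' @param slope_fh Mass-scaling exponent of fHmax (dimensionless).
#' @param intercept_fh_16 ln(fHmax) intercept at 16 degC, ln(beats min^-1).
#' @param tab_slope,tab_intercept,tpeak_slope,tpeak_intercept,tarr_slope,tarr_intercept
#'   Power-law coefficients of T_AB, T_PEAK, T_ARR (temperatures in degC on
#'   the ln scale).
#' @param q10_cold,q10_warm fHmax Q10 below and above T_AB, which set the two
#'   Arrhenius limb slopes.
#' @param post_peak_decline Decline of ln(fHmax) per degC above T_PEAK.
#' @param trait_sd Lognormal SD of individual T_AB/T_PEAK/T_ARR around their
#'   power laws.
#' @param individual_sd SD of per-fish random intercepts on ln(fHmax).
#' @param obs_sd Additive SD on ln(fHmax) per 1-degC observation.
#' @param start_temp First test temperature (degC) of the warming ramp.
#' @return A list of class `"cardiac_config"`.
#' @export
cardiac_config <- function(slope_fh = -0.052,
                           intercept_fh_16 = 4.325,
                           tab_slope = 0.030, tab_intercept = 3.144,
                           tpeak_slope = 0.034, tpeak_intercept = 3.304,
                           tarr_slope = 0.030, tarr_intercept = 3.359,
                           q10_cold = 2.0, q10_warm = 1.35,
                           post_peak_decline = 0.05,
                           trait_sd = 0.02,
                           individual_sd = 0.05,
                           obs_sd = 0.02,
                           start_temp = 16) {
  cc <- list(slope_fh = slope_fh, intercept_fh_16 = intercept_fh_16,
             tab_slope = tab_slope, tab_intercept = tab_intercept,
             tpeak_slope = tpeak_slope, tpeak_intercept = tpeak_intercept,
             tarr_slope = tarr_slope, tarr_intercept = tarr_intercept,
             q10_cold = q10_cold, q10_warm = q10_warm,
             post_peak_decline = post_peak_decline,
             trait_sd = trait_sd, individual_sd = individual_sd,
             obs_sd = obs_sd, start_temp = start_temp)
  class(cc) <- "cardiac_config"
  cc
}

#' @noRd
validate_study_config <- function(cfg) {
  if (length(cfg$mass_range) != 2 || any(cfg$mass_range <= 0) ||
      diff(cfg$mass_range) < 0)
    stopf("configuration error: mass_range must be positive and increasing")
  if (anyDuplicated(cfg$temperatures))
    stopf("configuration error: temperatures must be distinct")
  sds <- c(cfg$individual_sd, cfg$residual_sd, cfg$cycle_sd, cfg$o2_noise_sd,
           cfg$vm_sd, cfg$cardiac$trait_sd, cfg$cardiac$individual_sd,
           cfg$cardiac$obs_sd)
  if (any(sds < 0)) stopf("configuration error: all SDs must be >= 0")
  tkey <- as.character(cfg$temperatures)
  for (nm in c("mmr_intercepts", "rmr_intercepts")) {
    missing <- setdiff(tkey, names(cfg[[nm]]))
    if (length(missing))
      stopf("configuration error: %s lacks temperature(s) %s", nm,
            paste(missing, collapse = ", "))
  }
  # the cardiac power laws must keep T_AB below T_ARR across the mass range
  cc <- cfg$cardiac
  for (m in cfg$mass_range) {
    if (exp(cc$tab_intercept + cc$tab_slope * log(m)) >=
        exp(cc$tarr_intercept + cc$tarr_slope * log(m)))
      stopf("configuration error: T_AB >= T_ARR at body mass %g kg", m)
  }
  if (cfg$n_cycles < 1 || cfg$measure_s <= 60)
    stopf("configuration error: need n_cycles >= 1 and measure_s > 60 s")
  cfg
}

#' Generate a synthetic fish cohort
#'
#' Draws `n_fish` body masses log-uniformly over the configured range and
#' assigns origin (lab-born only among juveniles < 50 g), sex (unknown below
#' 7 g, where the species is not yet dimorphic) and the latent per-fish
#' random intercepts (`u_mmr`, `u_rmr`, `u_fh`) used by the trace and series
#' generators. The latent columns belong to the generator's truth sidecar,
#' not to analysis-facing files.
#'
#' @param config A [study_config()].
#' @return A data.frame with one row per fish: `fish_id`, `body_mass_kg`,
#'   `origin`, `sex`, `size_class` and latent intercepts.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "study_config"))
  n <- config$n_fish
  if (n == 0) {
    return(data.frame(fish_id = character(), body_mass_kg = numeric(),
                      origin = character(), sex = character(),
                      size_class = character(), u_mmr = numeric(),
                      u_rmr = numeric(), u_fh = numeric(),
                      stringsAsFactors = FALSE))
  }
  local_seed(stage_seed(config$seed, "cohort"), {
    lm_rng <- log(config$mass_range)
    mass <- exp(stats::runif(n, lm_rng[1], lm_rng[2]))
    juvenile <- mass < 0.050
    origin <- ifelse(juvenile & stats::runif(n) < 0.5, "lab_born", "wild")
    sex <- ifelse(mass < 0.007, "unknown",
                  ifelse(stats::runif(n) < 0.5, "F", "M"))
    data.frame(
      fish_id = sprintf("fish%03d", seq_len(n)),
      body_mass_kg = mass,
      origin = origin,
      sex = sex,
      size_class = ifelse(juvenile, "juvenile", "adult"),
      u_mmr = stats::rnorm(n, 0, config$individual_sd),
      u_rmr = stats::rnorm(n, 0, config$individual_sd),
      u_fh = stats::rnorm(n, 0, config$cardiac$individual_sd),
      stringsAsFactors = FALSE
    )
  })
}

# Latent cardiac thermal-tolerance traits (degC) for one body mass.
# With trait_sd > 0 the three traits get correlated-free lognormal noise;
# draws violating T_AB < T_PEAK < T_ARR are redrawn.
#' @noRd
cardiac_traits <- function(mass, cc, trait_sd = cc$trait_sd) {
  mu <- c(tab = cc$tab_intercept + cc$tab_slope * log(mass),
          tpeak = cc$tpeak_intercept + cc$tpeak_slope * log(mass),
          tarr = cc$tarr_intercept + cc$tarr_slope * log(mass))
  for (i in 1:100) {
    tr <- exp(mu + stats::rnorm(3, 0, trait_sd))
    if (tr[1] < tr[2] && tr[2] < tr[3]) return(tr)
  }
  stopf("configuration error: cannot order T_AB < T_PEAK < T_ARR at mass %g",
        mass)
}

# Latent ln(fHmax) at temperature temp_c for a fish with given traits.
# Piecewise linear in x = 1000/T_K up to T_PEAK, then linear decline in degC.
#' @noRd
latent_ln_fh <- function(temp_c, mass, u_fh, traits, cc) {
  tk_ref <- cc$start_temp + 273.15
  s_cold <- -(log(cc$q10_cold) / 10) * tk_ref^2 / 1000
  s_warm <- -(log(cc$q10_warm) / 10) * tk_ref^2 / 1000
  xs <- 1000 / (cc$start_temp + 273.15)
  x_ab <- 1000 / (traits[["tab"]] + 273.15)
  x_pk <- 1000 / (traits[["tpeak"]] + 273.15)
  y16 <- cc$intercept_fh_16 + cc$slope_fh * log(mass) + u_fh
  y_ab <- y16 + s_cold * (x_ab - xs)
  y_pk <- y_ab + s_warm * (x_pk - x_ab)
  x <- 1000 / (temp_c + 273.15)
  y <- ifelse(temp_c <= traits[["tab"]], y16 + s_cold * (x - xs),
        ifelse(temp_c <= traits[["tpeak"]], y_ab + s_warm * (x - x_ab),
               y_pk - cc$post_peak_decline * (temp_c - traits[["tpeak"]])))
  y
}

#' Simulate one intermittent-flow respirometry trace
#'
#' Builds the dissolved-O2 time series of one overnight trial: alternating
#' flush/measure cycles in which O2 declines linearly at the rate implied by
#' the fish's oxygen uptake plus microbial background respiration, with a
#' maximum-metabolic-rate episode in the first post-chase cycle and once
#' overnight so a true MMR exists, early-recovery cycles decaying toward the
#' resting level, and additive sensor noise. Oxygen never falls below 70% of
#' air saturation: the chamber volume is enlarged (within the protocol's
#' 19.2--93.9 L/kg net-volume-to-mass band) when necessary.
#'
#' @param fish One row of a [generate_cohort()] data.frame.
#' @param temperature Test temperature (degC); must be in
#'   `config$temperatures`.
#' @param config A [study_config()].
#' @return An object of class `"o2_trace"`: fish metadata, chamber volume,
#'   a `samples` data.frame (`time_s`, `o2_mg_per_l`, `phase`,
#'   `cycle_index`, `temp_c`), the background slopes used, and a `truth`
#'   list (trial MMR/RMR levels and realized per-cycle MO2).
#' @export
simulate_o2_trace <- function(fish, temperature, config) {
  stopifnot(inherits(config, "study_config"))
  tkey <- as.character(temperature)
  if (!temperature %in% config$temperatures)
    stopf("domain error: temperature %s degC is not simulated", tkey)
  mass <- fish$body_mass_kg
  lnm <- log(mass)

  mmr_trial <- exp(config$mmr_intercepts[[tkey]] + config$mmr_slope * lnm +
                     fish$u_mmr + stats::rnorm(1, 0, config$residual_sd))
  rmr_trial <- exp(config$rmr_intercepts[[tkey]] + config$rmr_slope * lnm +
                     fish$u_rmr + stats::rnorm(1, 0, config$residual_sd))
  mmr_trial <- max(mmr_trial, rmr_trial * 1.05)

  n_cyc <- config$n_cycles
  level <- rep(rmr_trial, n_cyc)
  level[1] <- mmr_trial
  decay <- 2:min(6, n_cyc)                       # post-chase recovery
  level[decay] <- rmr_trial + (mmr_trial - rmr_trial) * 0.5^(decay - 1)
  overnight <- max(2L, floor(0.7 * n_cyc))       # spontaneous activity burst
  level[overnight] <- mmr_trial
  mo2_cycle <- level * exp(stats::rnorm(n_cyc, 0, config$cycle_sd))

  o2_sat <- o2_air_saturation(temperature, config$salinity)
  bg_rate <- config$background_fraction * rmr_trial     # mg O2 / min
  # choose net volume: target ratio, enlarged to keep O2 >= 70% saturation
  need <- max(mo2_cycle + bg_rate) * (config$measure_s / 60) /
    (0.30 * o2_sat * mass)
  ratio <- min(93.9, max(config$volume_ratio, need))
  if (need > 93.9)
    stopf("configuration error: cannot keep O2 above 70%%%s",
          " saturation within the allowed chamber volumes")
  v_net <- ratio * mass
  chamber <- v_net + mass                        # fish density 1 kg / L
  bg_slope <- -bg_rate / v_net                   # mg / L / min

  # flush sampling starts one step in so cycle boundaries never collide
  t_flush <- seq(config$dt_flush, config$flush_s - config$dt_flush,
                 by = config$dt_flush)
  t_meas <- seq(0, config$measure_s, by = config$dt_measure)
  cyc_len <- config$flush_s + config$measure_s
  samples <- do.call(rbind, lapply(seq_len(n_cyc), function(i) {
    t0 <- (i - 1) * cyc_len
    slope <- -(mo2_cycle[i] + bg_rate) / v_net   # mg / L / min
    data.frame(
      time_s = c(t0 + t_flush, t0 + config$flush_s + t_meas),
      o2_mg_per_l = c(rep(o2_sat, length(t_flush)),
                      o2_sat + slope * t_meas / 60),
      phase = c(rep("flush", length(t_flush)),
                rep("measure", length(t_meas))),
      cycle_index = i,
      stringsAsFactors = FALSE
    )
  }))
  samples$o2_mg_per_l <- samples$o2_mg_per_l +
    stats::rnorm(nrow(samples), 0, config$o2_noise_sd)
  samples$temp_c <- temperature

  structure(list(
    fish_id = fish$fish_id,
    temperature = temperature,
    chamber_volume = chamber,
    fish_mass = mass,
    samples = samples,
    background_slope_pre = bg_slope,
    background_slope_post = bg_slope,
    truth = list(mmr = mmr_trial, rmr = rmr_trial, cycle_mo2 = mo2_cycle,
                 background_rate = bg_rate, net_volume = v_net)
  ), class = "o2_trace")
}

#' Simulate a per-degree maximum heart-rate series
#'
#' Generates one fHmax observation (plus a within-window SD) per 1 degC from
#' the ramp start up to the fish's mass-dependent arrhythmia temperature.
#' ln(fHmax) follows the latent piecewise-linear Arrhenius curve (slope
#' change at T_AB, decline after T_PEAK) with additive observation noise;
#' only the final observation carries the arrhythmia flag.
#'
#' @inheritParams simulate_o2_trace
#' @return An object of class `"cardiac_series"` with an `observations`
#'   data.frame (`temp_c`, `fhmax_bpm`, `fhmax_sd`, `arrhythmia_flag`) and a
#'   `truth` list holding the latent T_AB/T_PEAK/T_ARR.
#' @export
simulate_cardiac_series <- function(fish, config) {
  stopifnot(inherits(config, "study_config"))
  cc <- config$cardiac
  mass <- fish$body_mass_kg
  traits <- cardiac_traits(mass, cc)
  temps <- seq(cc$start_temp, ceiling(traits[["tarr"]]))
  if (length(temps) < 4)
    stopf("configuration error: fewer than 4 ramp steps before T_ARR at mass %g kg",
          mass)
  # rising limbs evaluated on the latent curve; the post-peak decline is
  # anchored at the last rising ramp step, so the observed series turns over
  # exactly once on the observation grid
  y0 <- latent_ln_fh(temps, mass, fish$u_fh, traits, cc)
  rising <- temps <= traits[["tpeak"]]
  if (any(!rising)) {
    t_anchor <- max(temps[rising])
    y_anchor <- y0[temps == t_anchor]
    y0[!rising] <- y_anchor - cc$post_peak_decline * (temps[!rising] - t_anchor)
  }
  y <- y0 + stats::rnorm(length(temps), 0, cc$obs_sd)
  fh <- exp(y)
  obs <- data.frame(
    temp_c = temps,
    fhmax_bpm = fh,
    fhmax_sd = round(abs(stats::rnorm(length(temps), 2, 0.5)), 2),
    arrhythmia_flag = seq_along(temps) == length(temps),
    stringsAsFactors = FALSE
  )
  # observed (grid-level) truths implied by the noise-free curve
  pre <- temps[-length(temps)]
  t_peak_obs <- pre[which.max(y0[-length(temps)])]
  structure(list(
    fish_id = fish$fish_id,
    observations = obs,
    truth = list(t_ab = unname(traits[["tab"]]),
                 t_peak = unname(traits[["tpeak"]]),
                 t_arr = unname(traits[["tarr"]]),
                 t_peak_obs = t_peak_obs,
                 t_arr_obs = temps[length(temps)])
  ), class = "cardiac_series")
}

#' Simulate directly at the trait/summary level
#'
#' Fast path used for parameter-recovery work: generates ln-scale
#' observations of a response from its generating scaling law without
#' synthesizing raw traces. `"mmr"` and `"rmr"` give repeated measures at
#' every configured temperature (optionally subsampled to `n_obs` total
#' observations, each fish keeping at least one); `"fhmax"` gives per-degree
#' observations from the ramp start up to each fish's latent arrhythmia
#' temperature under the additive model ln fH = a_T + b ln(BM) + u + e;
#' `"vm"`, `"tab"`, `"tpeak"`, `"tarr"` give one observation per fish.
#'
#' @param config A [study_config()].
#' @param response One of `"mmr"`, `"rmr"`, `"fhmax"`, `"vm"`, `"tab"`,
#'   `"tpeak"`, `"tarr"`.
#' @param n_obs Optional total observation count for repeated-measures
#'   responses (random fish-by-temperature subsample).
#' @param cohort Optional pre-generated cohort (defaults to
#'   [generate_cohort()] under the config seed).
#' @return A data.frame with `fish_id`, `body_mass_kg`, `ln_mass`,
#'   `temperature` (factor, where applicable), `ln_response`, `origin`,
#'   `sex`, plus attribute `"truth"` holding the generating slope.
#' @export
simulate_scaling_data <- function(config, response = "mmr", n_obs = NULL,
                                  cohort = NULL) {
  stopifnot(inherits(config, "study_config"))
  response <- match.arg(response,
                        c("mmr", "rmr", "fhmax", "vm", "tab", "tpeak", "tarr"))
  if (is.null(cohort)) cohort <- generate_cohort(config)
  n <- nrow(cohort)
  # every response draws from its own sub-stream of the root seed
  resp_seed <- function() {
    s <- stage_seed(config$seed, "scaling")
    if (is.null(s)) NULL else
      (s + 131L * match(response, c("mmr", "rmr", "fhmax", "vm", "tab",
                                    "tpeak", "tarr"))) %% 2147483647L
  }
  lnm <- log(cohort$body_mass_kg)
  cc <- config$cardiac

  if (response %in% c("mmr", "rmr")) {
    slope <- if (response == "mmr") config$mmr_slope else config$rmr_slope
    ints <- if (response == "mmr") config$mmr_intercepts else
      config$rmr_intercepts
    u <- if (response == "mmr") cohort$u_mmr else cohort$u_rmr
    out <- local_seed(resp_seed(), {
      d <- expand.grid(i = seq_len(n), temperature = config$temperatures)
      d <- d[order(d$i, d$temperature), ]
      d$ln_response <- ints[as.character(d$temperature)] + slope * lnm[d$i] +
        u[d$i] + stats::rnorm(nrow(d), 0, config$residual_sd)
      if (!is.null(n_obs) && n_obs < nrow(d)) {
        # drop random fish-by-temperature combinations, keeping >= 1 per fish
        keep_first <- !duplicated(d$i)
        pool <- which(!keep_first)
        drop <- sample(pool, nrow(d) - n_obs)
        d <- d[-drop, ]
      }
      d
    })
    res <- data.frame(fish_id = cohort$fish_id[out$i],
                      body_mass_kg = cohort$body_mass_kg[out$i],
                      ln_mass = lnm[out$i],
                      temperature = factor(out$temperature),
                      ln_response = out$ln_response,
                      origin = cohort$origin[out$i],
                      sex = cohort$sex[out$i],
                      stringsAsFactors = FALSE)
    attr(res, "truth") <- list(slope = slope, intercepts = ints)
    return(res)
  }

  if (response == "fhmax") {
    # additive per-degree model: a_T taken from the reference-mass latent
    # curve so that mass enters only through slope_fh
    ref_mass <- 0.065
    out <- local_seed(resp_seed(), {
      rows <- lapply(seq_len(n), function(i) {
        tr <- exp(c(cc$tab_intercept + cc$tab_slope * lnm[i],
                    cc$tpeak_intercept + cc$tpeak_slope * lnm[i],
                    cc$tarr_intercept + cc$tarr_slope * lnm[i]))
        temps <- seq(cc$start_temp, ceiling(tr[3]) - 1)
        ref_traits <- c(tab = exp(cc$tab_intercept + cc$tab_slope * log(ref_mass)),
                        tpeak = exp(cc$tpeak_intercept + cc$tpeak_slope * log(ref_mass)),
                        tarr = exp(cc$tarr_intercept + cc$tarr_slope * log(ref_mass)))
        a_t <- latent_ln_fh(temps, ref_mass, 0, ref_traits, cc) -
          cc$slope_fh * log(ref_mass)
        data.frame(i = i, temperature = temps,
                   ln_response = a_t + cc$slope_fh * lnm[i] + cohort$u_fh[i] +
                     stats::rnorm(length(temps), 0, cc$obs_sd))
      })
      do.call(rbind, rows)
    })
    res <- data.frame(fish_id = cohort$fish_id[out$i],
                      body_mass_kg = cohort$body_mass_kg[out$i],
                      ln_mass = lnm[out$i],
                      temperature = factor(out$temperature),
                      ln_response = out$ln_response,
                      origin = cohort$origin[out$i],
                      sex = cohort$sex[out$i],
                      stringsAsFactors = FALSE)
    attr(res, "truth") <- list(slope = cc$slope_fh)
    return(res)
  }

  pars <- switch(response,
    vm = c(config$vm_slope, config$vm_intercept, config$vm_sd),
    tab = c(cc$tab_slope, cc$tab_intercept, cc$trait_sd),
    tpeak = c(cc$tpeak_slope, cc$tpeak_intercept, cc$trait_sd),
    tarr = c(cc$tarr_slope, cc$tarr_intercept, cc$trait_sd))
  ln_resp <- local_seed(resp_seed(),
    pars[2] + pars[1] * lnm + stats::rnorm(n, 0, pars[3]))
  res <- data.frame(fish_id = cohort$fish_id,
                    body_mass_kg = cohort$body_mass_kg,
                    ln_mass = lnm,
                    ln_response = ln_resp,
                    origin = cohort$origin,
                    sex = cohort$sex,
                    stringsAsFactors = FALSE)
  attr(res, "truth") <- list(slope = pars[1], intercept = pars[2])
  res
}

#' Generate a complete synthetic study
#'
#' Cohort plus per-fish O2 traces at every configured temperature (the
#' repeated-measures design), cardiac series and ventricle masses for the
#' first `n_cardiac` fish, and a truth sidecar holding every latent quantity
#' (random intercepts, trial MMR/RMR levels, cardiac limits, generating
#' parameters) for parameter-recovery testing. Deterministic under the
#' config seed.
#'
#' @param config A [study_config()].
#' @return An object of class `"study_dataset"` with elements `cohort`,
#'   `traces` (named list, `<fish>_<temp>`), `cardiac` (named list),
#'   `ventricles` (data.frame) and `truth`.
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  cohort <- generate_cohort(config)
  traces <- local_seed(stage_seed(config$seed, "traces"), {
    out <- list()
    for (i in seq_len(nrow(cohort))) {
      for (tp in config$temperatures) {
        out[[paste(cohort$fish_id[i], tp, sep = "_")]] <-
          simulate_o2_trace(cohort[i, ], tp, config)
      }
    }
    out
  })
  idx_cardiac <- seq_len(min(config$n_cardiac, nrow(cohort)))
  cardiac <- local_seed(stage_seed(config$seed, "cardiac"), {
    out <- list()
    for (i in idx_cardiac)
      out[[cohort$fish_id[i]]] <- simulate_cardiac_series(cohort[i, ], config)
    out
  })
  ventricles <- local_seed(stage_seed(config$seed, "ventricles"), {
    m <- cohort$body_mass_kg[idx_cardiac]
    data.frame(
      fish_id = cohort$fish_id[idx_cardiac],
      body_mass_kg = m,
      ventricle_mass_kg = exp(config$vm_intercept +
                                config$vm_slope * log(m) +
                                stats::rnorm(length(m), 0, config$vm_sd)),
      stringsAsFactors = FALSE
    )
  })
  cfg_plain <- unclass(config)
  cfg_plain$cardiac <- unclass(cfg_plain$cardiac)
  truth <- list(
    config = cfg_plain,
    latents = cohort[, c("fish_id", "u_mmr", "u_rmr", "u_fh")],
    trials = do.call(rbind, lapply(names(traces), function(k) {
      tr <- traces[[k]]
      data.frame(fish_id = tr$fish_id, temp_c = tr$temperature,
                 mmr_true = tr$truth$mmr, rmr_true = tr$truth$rmr,
                 stringsAsFactors = FALSE)
    })),
    cardiac = do.call(rbind, lapply(cardiac, function(cs) {
      data.frame(fish_id = cs$fish_id, t_ab = cs$truth$t_ab,
                 t_peak = cs$truth$t_peak, t_arr = cs$truth$t_arr,
                 t_peak_obs = cs$truth$t_peak_obs,
                 t_arr_obs = cs$truth$t_arr_obs,
                 stringsAsFactors = FALSE)
    }))
  )
  structure(list(cohort = cohort, traces = traces, cardiac = cardiac,
                 ventricles = ventricles, truth = truth),
            class = "study_dataset")
}

#' Write a synthetic study to CSV files
#'
#' Emits the analysis-facing files (`cohort.csv`, `trace_<fish>_<temp>.csv`,
#' `background.csv`, `cardiac_<fish>.csv`, `ventricles.csv`) and the latent
#' `truth.json` sidecar.
#'
#' @param study A [generate_study()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "study_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  w <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    files <<- c(files, p)
  }
  coh <- study$cohort[, c("fish_id", "body_mass_kg", "origin", "sex")]
  w(coh, "cohort.csv")
  bg <- do.call(rbind, lapply(study$traces, function(tr) {
    data.frame(fish_id = tr$fish_id, temp_c = tr$temperature,
               chamber_volume_l = tr$chamber_volume,
               slope_pre = tr$background_slope_pre,
               slope_post = tr$background_slope_post,
               stringsAsFactors = FALSE)
  }))
  w(bg, "background.csv")
  for (k in names(study$traces)) {
    tr <- study$traces[[k]]
    w(tr$samples, sprintf("trace_%s_%s.csv", tr$fish_id, tr$temperature))
  }
  for (k in names(study$cardiac)) {
    cs <- study$cardiac[[k]]
    w(cs$observations, sprintf("cardiac_%s.csv", cs$fish_id))
  }
  w(study$ventricles, "ventricles.csv")
  tj <- file.path(dir, "truth.json")
  jsonlite::write_json(study$truth, tj, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  files <- c(files, tj)
  invisible(files)
}

#' Read a trace CSV back into an `o2_trace`
#'
#' @param path Path to a `trace_<fish>_<temp>.csv` file.
#' @param fish_id,temperature Trace identity (parsed from the filename when
#'   omitted).
#' @param chamber_volume Chamber volume in L.
#' @param fish_mass Fish body mass in kg.
#' @return An `"o2_trace"` object (without generator truth).
#' @export
read_o2_trace <- function(path, chamber_volume, fish_mass,
                          fish_id = NULL, temperature = NULL) {
  samples <- utils::read.csv(path, stringsAsFactors = FALSE)
  assert_cols(samples, c("time_s", "o2_mg_per_l", "phase", "cycle_index"),
              sprintf("trace file '%s'", basename(path)))
  if (is.null(fish_id) || is.null(temperature)) {
    m <- regmatches(basename(path),
                    regexec("^trace_(.+)_([0-9.]+)\\.csv$", basename(path)))[[1]]
    if (length(m) == 3) {
      fish_id <- fish_id %||% m[2]
      temperature <- temperature %||% as.numeric(m[3])
    }
  }
  structure(list(fish_id = fish_id, temperature = temperature,
                 chamber_volume = chamber_volume, fish_mass = fish_mass,
                 samples = samples,
                 background_slope_pre = NA_real_,
                 background_slope_post = NA_real_,
                 truth = NULL),
            class = "o2_trace")
}

#' Read a cardiac CSV back into a `cardiac_series`
#'
#' @param path Path to a `cardiac_<fish>.csv` file.
#' @param fish_id Fish identifier (parsed from the filename when omitted).
#' @return A `"cardiac_series"` object (without generator truth).
#' @export
read_cardiac_series <- function(path, fish_id = NULL) {
  obs <- utils::read.csv(path, stringsAsFactors = FALSE)
  assert_cols(obs, c("temp_c", "fhmax_bpm", "fhmax_sd", "arrhythmia_flag"),
              sprintf("cardiac file '%s'", basename(path)))
  obs$arrhythmia_flag <- as.logical(obs$arrhythmia_flag)
  if (is.null(fish_id)) {
    m <- regmatches(basename(path),
                    regexec("^cardiac_(.+)\\.csv$", basename(path)))[[1]]
    if (length(m) == 2) fish_id <- m[2]
  }
  structure(list(fish_id = fish_id, observations = obs, truth = NULL),
            class = "cardiac_series")
}

#' @export
print.study_dataset <- function(x, ...) {
  cat(sprintf("Synthetic study: %d fish, %d O2 traces, %d cardiac series\n",
              nrow(x$cohort), length(x$traces), length(x$cardiac)))
  invisible(x)
}
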