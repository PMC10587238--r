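# Shared fixtures: small configurations and hand-built objects.

small_config <- function(seed = 1, ...) {
  study_config(n_fish = 4, n_cardiac = 3, seed = seed, ...)
}

zero_noise_config <- function(seed = 1, n_fish = 4, n_cardiac = 3, ...) {
  study_config(n_fish = n_fish, n_cardiac = n_cardiac, seed = seed,
               individual_sd = 0, residual_sd = 0, cycle_sd = 0,
               o2_noise_sd = 0, vm_sd = 0,
               cardiac = cardiac_config(trait_sd = 0, obs_sd = 0), ...)
}

# An o2_trace built from explicit per-cycle slopes (mg/L/min, negative),
# with ideal flush plateaus; no noise.
make_trace <- function(slopes, chamber_volume = 2.1, fish_mass = 0.1,
                       o2_start = 8, measure_s = 300, flush_s = 120,
                       dt = 5, temperature = 16, fish_id = "t1") {
  cyc_len <- flush_s + measure_s
  t_f <- seq(0, flush_s - dt, by = dt)
  t_m <- seq(0, measure_s, by = dt)
  samples <- do.call(rbind, lapply(seq_along(slopes), function(i) {
    t0 <- (i - 1) * cyc_len
    data.frame(time_s = c(t0 + t_f, t0 + flush_s + t_m),
               o2_mg_per_l = c(rep(o2_start, length(t_f)),
                               o2_start + slopes[i] * t_m / 60),
               phase = c(rep("flush", length(t_f)),
                         rep("measure", length(t_m))),
               cycle_index = i, temp_c = temperature,
               stringsAsFactors = FALSE)
  }))
  structure(list(fish_id = fish_id, temperature = temperature,
                 chamber_volume = chamber_volume, fish_mass = fish_mass,
                 samples = samples, background_slope_pre = 0,
                 background_slope_post = 0, truth = NULL),
            class = "o2_trace")
}

# An mo2_series with given accepted MO2 values (all cycles 300 s long).
make_mo2_series <- function(mo2, duration = 300, accepted = TRUE) {
  n <- length(mo2)
  structure(list(
    fish_id = "m1", temperature = 16,
    cycles = data.frame(cycle_index = seq_len(n), t_mid_s = seq_len(n) * 900,
                        slope = -mo2 / 2, r_squared = 0.999,
                        duration_s = duration, n_points = 49,
                        accepted = rep_len(accepted, n),
                        reason = NA_character_, mo2 = mo2,
                        stringsAsFactors = FALSE),
    net_volume = 2, background_slope_pre = 0, background_slope_post = 0),
    class = "mo2_series")
}

# A cardiac_series from explicit temperatures and heart rates.
make_cardiac_series <- function(temps, fh, arr_last = TRUE, fish_id = "c1") {
  n <- length(temps)
  structure(list(
    fish_id = fish_id,
    observations = data.frame(temp_c = temps, fhmax_bpm = fh,
                              fhmax_sd = 2, arrhythmia_flag =
                                seq_len(n) == n & arr_last,
                              stringsAsFactors = FALSE),
    truth = NULL), class = "cardiac_series")
}

# Independent exhaustive-grid oracle for the broken-stick knot: for every
# candidate, RSS from a plain lm() fit; returns the argmin candidate.
oracle_breakpoint_grid <- function(x, y, m = 2, per_interval = 50) {
  xs <- sort(x)
  n <- length(xs)
  lo <- xs[m]; hi <- xs[n - m + 1]
  inner <- xs[xs >= lo & xs <= hi]
  cands <- c()
  for (i in seq_len(length(inner) - 1)) {
    a <- inner[i]; b <- inner[i + 1]
    cands <- c(cands, (a + b) / 2,
               seq(a, b, length.out = per_interval + 2)[-c(1, per_interval + 2)])
  }
  cands <- sort(unique(cands[cands > lo & cands < hi]))
  rss <- sapply(cands, function(p) {
    sum(resid(stats::lm(y ~ x + pmax(x - p, 0)))^2)
  })
  list(psi = cands[which.min(rss)], rss = min(rss), candidates = cands)
}
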