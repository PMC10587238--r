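# Orchestration: one reproducible run tying together simulate -> respiro ->
# cardiac -> scaling -> report, with a YAML-config surface, per-stage seeds
# derived from one root seed, CSV outputs and a JSON run manifest.

#' Pipeline run configuration
#'
#' @param out_dir Output directory for all stage products.
#' @param stages Character vector of stages to run, in order, from
#'   `c("simulate", "respiro", "cardiac", "scaling", "report")`.
#' @param seed Root integer seed for the whole run.
#' @param study A [study_config()] for the simulate stage (its seed is
#'   overridden by `seed`).
#' @param r2_threshold,min_duration Respirometry quality thresholds.
#' @param n_boot,ci_limit_c Cardiac breakpoint settings.
#' @param ref_mass Reference body mass (kg) for normalization and means.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(out_dir, stages = c("simulate", "respiro", "cardiac",
                                           "scaling", "report"),
                       seed = 1L, study = study_config(seed = seed),
                       r2_threshold = 0.96, min_duration = 180,
                       n_boot = 100, ci_limit_c = 1.5, ref_mass = 0.065) {
  study$seed <- seed
  structure(list(out_dir = out_dir, stages = stages, seed = seed,
                 study = study, r2_threshold = r2_threshold,
                 min_duration = min_duration, n_boot = n_boot,
                 ci_limit_c = ci_limit_c, ref_mass = ref_mass),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors [run_config()]; unknown study keys are rejected. Nested
#' `study:` keys override [study_config()] defaults and `study.cardiac:`
#' keys override [cardiac_config()] defaults.
#'
#' @param path YAML file path.
#' @return A `"run_config"`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("config file '%s' does not exist", path)
  raw <- yaml::read_yaml(path)
  study_args <- raw$study %||% list()
  if (!is.null(study_args$cardiac))
    study_args$cardiac <- do.call(cardiac_config, study_args$cardiac)
  if (!is.null(study_args$mass_range))
    study_args$mass_range <- as.numeric(study_args$mass_range)
  if (!is.null(study_args$temperatures))
    study_args$temperatures <- as.numeric(study_args$temperatures)
  for (nm in c("mmr_intercepts", "rmr_intercepts"))
    if (!is.null(study_args[[nm]]))
      study_args[[nm]] <- unlist(study_args[[nm]])
  bad <- setdiff(names(study_args), names(formals(study_config)))
  if (length(bad))
    stopf("config error: unknown study key(s): %s", paste(bad, collapse = ", "))
  study <- do.call(study_config, study_args)
  args <- raw[setdiff(names(raw), "study")]
  bad <- setdiff(names(args), names(formals(run_config)))
  if (length(bad))
    stopf("config error: unknown key(s): %s", paste(bad, collapse = ", "))
  do.call(run_config, c(args, list(study = study)))
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in order, writing each stage's CSV products
#' under `config$out_dir` and a `manifest.json` describing inputs, outputs,
#' parameters, seeds and per-stage record counts. A failing stage aborts the
#' run with a descriptive error.
#'
#' Stage products: `simulate` writes the synthetic study (see
#' [write_study()]); `respiro` writes `mo2_<fish>_<temp>.csv` and
#' `metabolic_summary.csv`; `cardiac` writes `cardiac_summary.csv`;
#' `scaling` writes `scaling_fits.csv` and `effect_tests.csv`; `report`
#' writes `tpc_table.csv`, `q10_table.csv`, `fick.json` and
#' `run_summary.txt`.
#'
#' @param config A `"run_config"` (or path to a YAML file).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir <- config$out_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$seed,
                   parameters = list(r2_threshold = config$r2_threshold,
                                     min_duration = config$min_duration,
                                     n_boot = config$n_boot,
                                     ci_limit_c = config$ci_limit_c,
                                     ref_mass = config$ref_mass),
                   stages = list())
  note <- function(stage, files, n_records) {
    manifest$stages[[stage]] <<- list(outputs = basename(files),
                                      n_records = n_records)
  }

  if ("simulate" %in% config$stages) {
    study <- generate_study(config$study)
    files <- write_study(study, dir)
    note("simulate", files, length(study$traces))
  }

  if ("respiro" %in% config$stages) {
    files <- run_respiro_stage(dir, r2_threshold = config$r2_threshold,
                               min_duration = config$min_duration)
    note("respiro", files, nrow(utils::read.csv(
      file.path(dir, "metabolic_summary.csv"))))
  }

  if ("cardiac" %in% config$stages) {
    f <- run_cardiac_stage(dir, n_boot = config$n_boot,
                           ci_limit_c = config$ci_limit_c,
                           seed = stage_seed(config$seed, "breakpoint"))
    note("cardiac", f, nrow(utils::read.csv(
      file.path(dir, "cardiac_summary.csv"))))
  }

  if ("scaling" %in% config$stages) {
    f <- run_scaling_stage(dir)
    note("scaling", f, nrow(utils::read.csv(
      file.path(dir, "scaling_fits.csv"))))
  }

  if ("report" %in% config$stages) {
    f <- run_report_stage(dir, ref_mass = config$ref_mass,
                          seed = config$seed)
    note("report", f, NA)
  }

  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

#' @noRd
run_respiro_stage <- function(dir, r2_threshold = 0.96, min_duration = 180) {
  cohort_file <- file.path(dir, "cohort.csv")
  bg_file <- file.path(dir, "background.csv")
  if (!file.exists(cohort_file)) stopf("missing input file '%s'", cohort_file)
  cohort <- utils::read.csv(cohort_file, stringsAsFactors = FALSE)
  assert_cols(cohort, c("fish_id", "body_mass_kg"), "cohort.csv")
  bg <- utils::read.csv(bg_file, stringsAsFactors = FALSE)
  assert_cols(bg, c("fish_id", "temp_c", "chamber_volume_l", "slope_pre",
                    "slope_post"), "background.csv")
  files <- character()
  rows <- list()
  trace_files <- list.files(dir, "^trace_.*\\.csv$", full.names = TRUE)
  if (!length(trace_files)) stopf("no trace_*.csv files found in '%s'", dir)
  for (tf in trace_files) {
    m <- regmatches(basename(tf),
                    regexec("^trace_(.+)_([0-9.]+)\\.csv$", basename(tf)))[[1]]
    fish <- m[2]; temp <- as.numeric(m[3])
    meta <- bg[bg$fish_id == fish & bg$temp_c == temp, ]
    if (!nrow(meta))
      stopf("background.csv has no row for fish %s at %s degC", fish, temp)
    mass <- cohort$body_mass_kg[cohort$fish_id == fish]
    if (!length(mass)) stopf("cohort.csv has no row for fish %s", fish)
    trace <- read_o2_trace(tf, chamber_volume = meta$chamber_volume_l[1],
                           fish_mass = mass[1])
    series <- extract_mo2_series(trace, meta$slope_pre[1], meta$slope_post[1],
                                 r2_threshold = r2_threshold,
                                 min_duration = min_duration)
    out <- series$cycles[, c("cycle_index", "t_mid_s", "mo2", "r_squared",
                             "duration_s", "accepted", "reason")]
    names(out)[names(out) == "r_squared"] <- "r2"
    p <- file.path(dir, sprintf("mo2_%s_%s.csv", fish, temp))
    utils::write.csv(out, p, row.names = FALSE)
    files <- c(files, p)
    # trials with too few acceptable cycles are dropped (with notice), not
    # fatal: incomplete individuals are a normal feature of these studies
    summ <- tryCatch(summarize_metabolism(series), error = function(e) {
      message(sprintf("skipping %s at %s degC: %s", fish, temp,
                      conditionMessage(e)))
      NULL
    })
    if (is.null(summ)) next
    rows[[length(rows) + 1]] <- data.frame(
      fish_id = fish, temp_c = temp, mmr = summ$mmr, rmr = summ$rmr,
      aas = summ$aas, fas = summ$fas, n_cycles = summ$n_accepted_cycles,
      warning_flag = summ$warning_flag, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    stopf("no trial in '%s' yielded a metabolic summary", dir)
  ms <- do.call(rbind, rows)
  ms <- ms[order(ms$fish_id, ms$temp_c), ]
  p <- file.path(dir, "metabolic_summary.csv")
  utils::write.csv(ms, p, row.names = FALSE)
  c(files, p)
}

#' @noRd
run_cardiac_stage <- function(dir, n_boot = 100, ci_limit_c = 1.5,
                              seed = NULL) {
  cfiles <- list.files(dir, "^cardiac_[^s].*\\.csv$", full.names = TRUE)
  cfiles <- cfiles[!grepl("cardiac_summary", cfiles)]
  if (!length(cfiles)) stopf("no cardiac_*.csv files found in '%s'", dir)
  rows <- lapply(seq_along(cfiles), function(i) {
    series <- read_cardiac_series(cfiles[i])
    s <- analyze_cardiac_series(series, n_boot = n_boot,
                                ci_limit_c = ci_limit_c,
                                seed = if (is.null(seed)) NULL else seed + i)
    data.frame(fish_id = s$fish_id, t_ab = s$t_ab,
               t_ab_ci_halfwidth = s$t_ab_ci_halfwidth,
               t_ab_excluded_reason = s$t_ab_excluded_reason %||% NA_character_,
               t_peak = s$t_peak, peak_fhmax = s$peak_fhmax, t_arr = s$t_arr,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$fish_id), ]
  p <- file.path(dir, "cardiac_summary.csv")
  utils::write.csv(out, p, row.names = FALSE)
  p
}

#' @noRd
run_scaling_stage <- function(dir) {
  ms_file <- file.path(dir, "metabolic_summary.csv")
  if (!file.exists(ms_file)) stopf("missing input file '%s'", ms_file)
  ms <- utils::read.csv(ms_file, stringsAsFactors = FALSE)
  assert_cols(ms, c("fish_id", "temp_c", "mmr", "rmr", "aas", "fas"),
              "metabolic_summary.csv")
  cohort <- utils::read.csv(file.path(dir, "cohort.csv"),
                            stringsAsFactors = FALSE)
  ms <- merge(ms, cohort, by = "fish_id")
  ms$ln_mass <- log(ms$body_mass_kg)
  ms$temperature <- ms$temp_c

  fit_rows <- list()
  add_fit <- function(name, fit) {
    ints <- fit$intercepts
    term <- ifelse(is.na(ints$temperature), "ln_a",
                   paste0("ln_a_", ints$temperature))
    fit_rows[[length(fit_rows) + 1]] <<- rbind(
      data.frame(response = name, term = "slope", estimate = fit$slope,
                 se = fit$slope_se, ci_lo = fit$slope_ci[1],
                 ci_hi = fit$slope_ci[2], bic = fit$bic,
                 stringsAsFactors = FALSE),
      data.frame(response = name, term = term, estimate = ints$estimate,
                 se = ints$se, ci_lo = NA_real_, ci_hi = NA_real_,
                 bic = fit$bic, stringsAsFactors = FALSE))
  }

  fits <- list()
  tests <- list()
  for (resp in c("mmr", "rmr", "aas", "fas")) {
    d <- ms[is.finite(ms[[resp]]) & ms[[resp]] > 0, ]
    d$ln_response <- log(d[[resp]])
    fit <- fit_scaling_mixed(d)
    fits[[resp]] <- fit
    add_fit(resp, fit)
    et <- test_effects(fit)
    et$anova$response <- resp
    tests[[resp]] <- et$anova
  }

  cfiles <- list.files(dir, "^cardiac_.*\\.csv$", full.names = TRUE)
  cfiles <- cfiles[!grepl("cardiac_summary", cfiles)]
  if (length(cfiles) >= 2) {
    fh <- do.call(rbind, lapply(cfiles, function(p) {
      series <- read_cardiac_series(p)
      xy <- arrhenius_transform(series)
      data.frame(fish_id = series$fish_id, temperature = xy$temp_c,
                 ln_response = xy$y, stringsAsFactors = FALSE)
    }))
    fh <- merge(fh, cohort, by = "fish_id")
    fh$ln_mass <- log(fh$body_mass_kg)
    fit <- fit_scaling_mixed(fh)
    fits[["fhmax"]] <- fit
    add_fit("fhmax", fit)
  }

  cs_file <- file.path(dir, "cardiac_summary.csv")
  if (file.exists(cs_file)) {
    cs <- utils::read.csv(cs_file, stringsAsFactors = FALSE)
    cs <- merge(cs, cohort, by = "fish_id")
    cs$ln_mass <- log(cs$body_mass_kg)
    for (resp in c("t_ab", "t_peak", "t_arr", "peak_fhmax")) {
      d <- cs[is.finite(cs[[resp]]) & cs[[resp]] > 0, ]
      if (nrow(d) < 3) next
      d$ln_response <- log(d[[resp]])
      fit <- fit_scaling_simple(d)
      fits[[resp]] <- fit
      add_fit(resp, fit)
    }
  }
  vm_file <- file.path(dir, "ventricles.csv")
  if (file.exists(vm_file)) {
    vm <- utils::read.csv(vm_file, stringsAsFactors = FALSE)
    assert_cols(vm, c("fish_id", "body_mass_kg", "ventricle_mass_kg"),
                "ventricles.csv")
    vm$ln_mass <- log(vm$body_mass_kg)
    vm$ln_response <- log(vm$ventricle_mass_kg)
    fit <- fit_scaling_simple(vm)
    fits[["vm"]] <- fit
    add_fit("vm", fit)
  }

  p1 <- file.path(dir, "scaling_fits.csv")
  utils::write.csv(do.call(rbind, fit_rows), p1, row.names = FALSE)
  p2 <- file.path(dir, "effect_tests.csv")
  utils::write.csv(do.call(rbind, tests), p2, row.names = FALSE)
  c(p1, p2)
}

#' @noRd
run_report_stage <- function(dir, ref_mass = 0.065, seed = NULL) {
  sf_file <- file.path(dir, "scaling_fits.csv")
  if (!file.exists(sf_file)) stopf("missing input file '%s'", sf_file)
  sf <- utils::read.csv(sf_file, stringsAsFactors = FALSE)
  assert_cols(sf, c("response", "term", "estimate"), "scaling_fits.csv")
  rebuild <- function(resp) {
    rows <- sf[sf$response == resp, ]
    if (!nrow(rows)) return(NULL)
    ints <- rows[rows$term != "slope", ]
    list(slope = rows$estimate[rows$term == "slope"],
         intercepts = data.frame(
           temperature = suppressWarnings(
             as.numeric(sub("^ln_a_?", "", ints$term))),
           estimate = ints$estimate))
  }
  fits <- Filter(Negate(is.null),
                 lapply(stats::setNames(nm = c("mmr", "rmr", "aas", "fas")),
                        rebuild))
  cs_file <- file.path(dir, "cardiac_summary.csv")
  summaries <- NULL
  if (file.exists(cs_file)) {
    cs <- utils::read.csv(cs_file, stringsAsFactors = FALSE)
    summaries <- lapply(seq_len(nrow(cs)), function(i) as.list(cs[i, ]))
  }
  temps <- sort(unique(stats::na.omit(suppressWarnings(as.numeric(
    sub("^ln_a_", "", sf$term[grepl("^ln_a_", sf$term)]))))))
  tab <- build_tpc_table(fits, summaries, temperatures = temps,
                         ref_mass = ref_mass)
  p1 <- file.path(dir, "tpc_table.csv")
  utils::write.csv(tab$means, p1, row.names = FALSE)
  p2 <- file.path(dir, "q10_table.csv")
  utils::write.csv(tab$q10, p2, row.names = FALSE)
  b_mr <- sf$estimate[sf$response == "mmr" & sf$term == "slope"]
  fh_slope <- sf$estimate[sf$response == "fhmax" & sf$term == "slope"]
  fick <- if (length(b_mr) && length(fh_slope))
    fick_decompose(b_mr, fh_slope) else NULL
  p3 <- file.path(dir, "fick.json")
  jsonlite::write_json(
    if (is.null(fick)) list() else unclass(fick), p3,
    auto_unbox = TRUE, digits = NA)
  p4 <- file.path(dir, "run_summary.txt")
  writeLines(c(
    sprintf("allometherm %s run summary",
            as.character(utils::packageVersion("allometherm"))),
    sprintf("R version: %s", R.version.string),
    sprintf("seed: %s", seed %||% "none"),
    sprintf("reference mass: %g kg", ref_mass),
    sprintf("temperatures: %s", paste(temps, collapse = ", ")),
    sprintf("responses tabulated: %s", paste(names(fits), collapse = ", "))
  ), p4)
  c(p1, p2, p3, p4)
}
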