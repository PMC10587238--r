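# Internal helpers shared across modules.

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards. seed = NULL runs in the ambient stream.
#' @noRd
local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Draw a sub-seed for a named stage from a root seed, so that one root seed
# reproduces the whole pipeline while stages stay independent.
#' @noRd
stage_seed <- function(root_seed, stage) {
  if (is.null(root_seed)) return(NULL)
  offsets <- c(cohort = 11L, traces = 23L, cardiac = 37L, ventricles = 53L,
               respiro = 67L, breakpoint = 79L, scaling = 97L, report = 113L)
  off <- offsets[[stage]] %||% 1L
  (as.integer(root_seed) * 1009L + off) %% 2147483647L
}

# Dissolved-oxygen air-saturation concentration (mg O2 per L) after
# Benson & Krause (1984), with their salinity correction. Used only to set
# plausible starting oxygen levels in simulated respirometry traces.
#' @noRd
o2_air_saturation <- function(temp_c, salinity = 33) {
  tk <- temp_c + 273.15
  ln_c <- -139.34411 + 1.575701e5 / tk - 6.642308e7 / tk^2 +
    1.2438e10 / tk^3 - 8.621949e11 / tk^4
  fs <- exp(-salinity * (0.017674 - 10.754 / tk + 2140.7 / tk^2))
  exp(ln_c) * fs
}

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
assert_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stopf("%s is missing required column(s): %s", what,
          paste(missing, collapse = ", "))
  invisible(df)
}
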