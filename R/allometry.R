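# Allometric scaling: ln-ln power-law fits. Repeated-measures responses use
# linear mixed models (lme4, ML) with a per-individual random intercept and
# temperature as a categorical fixed effect coded as absolute per-level
# intercepts; one-off traits use ordinary least squares. Candidate fixed
# structures are compared by BIC; effects tested with Type II Wald
# chi-square and Tukey-adjusted pairwise temperature contrasts.

#' Fit a mixed-effects mass-scaling model
#'
#' Maximum-likelihood fit of
#' `ln_response ~ 0 + temperature + ln_mass (+ covariates) + (1 | fish_id)`,
#' giving a common scaling exponent and one absolute intercept per
#' temperature level. Estimation is ML (not REML) so that BIC comparisons
#' across fixed-effect structures are valid.
#'
#' @param data Data.frame with columns `fish_id`, `ln_mass`, `temperature`,
#'   and the response column; optionally `origin` and `sex`.
#' @param response Name of the ln-scale response column.
#' @param covariates Character vector of extra fixed effects (e.g.
#'   `c("origin", "sex")`).
#' @param interaction Include a `ln_mass:temperature` interaction
#'   (temperature-specific slopes; used for model comparison).
#' @return An object of class `"scaling_fit"`: `slope` (with `se` and 95%
#'   Wald `ci`), `intercepts` data.frame (temperature, estimate, se),
#'   `random_intercept_sd`, `residual_sd`, `bic`, `n_individuals`,
#'   `n_observations`, `singular` flag and the fitted `model`.
#' @export
fit_scaling_mixed <- function(data, response = "ln_response",
                              covariates = NULL, interaction = FALSE) {
  assert_cols(data, c("fish_id", "ln_mass", "temperature", response),
              "scaling data")
  if (any(!is.finite(data[[response]])))
    stopf("data error: non-finite ln response (responses must be positive before logging)")
  data$temperature <- factor(data$temperature)
  one_level <- nlevels(data$temperature) == 1
  rhs <- if (one_level) "ln_mass" else "0 + temperature + ln_mass"
  if (interaction && !one_level) rhs <- paste(rhs, "+ ln_mass:temperature")
  if (length(covariates)) {
    usable <- covariates[vapply(covariates, function(v)
      length(unique(data[[v]])) > 1, logical(1))]
    if (length(usable)) rhs <- paste(rhs, "+", paste(usable, collapse = " + "))
  }
  replicated <- anyDuplicated(data$fish_id) > 0
  if (replicated) {
    fml <- stats::as.formula(paste(response, "~", rhs, "+ (1 | fish_id)"))
    # boundary fits are re-reported below as a structured warning
    model <- withCallingHandlers(
      lme4::lmer(fml, data = data, REML = FALSE,
                 control = lme4::lmerControl(calc.derivs = FALSE)),
      message = function(m) {
        if (grepl("boundary \\(singular\\) fit", conditionMessage(m)))
          invokeRestart("muffleMessage")
      })
    singular <- lme4::isSingular(model)
    if (singular)
      warning("singular mixed fit: random-intercept variance estimated at zero",
              call. = FALSE)
    fe <- lme4::fixef(model)
  } else {
    # one observation per individual: the random intercept is not
    # identifiable and the model reduces to ordinary least squares
    warning("no within-individual replication; random intercept dropped",
            call. = FALSE)
    model <- stats::lm(stats::as.formula(paste(response, "~", rhs)),
                       data = data)
    singular <- TRUE
    fe <- stats::coef(model)
  }
  se <- sqrt(diag(as.matrix(stats::vcov(model))))
  b <- unname(fe["ln_mass"])
  b_se <- unname(se["ln_mass"])
  int_idx <- if (one_level) which(names(fe) == "(Intercept)") else
    grep("^temperature[0-9.]+$", names(fe))
  ints <- data.frame(
    temperature = if (one_level) as.numeric(levels(data$temperature)) else
      as.numeric(sub("^temperature", "", names(fe)[int_idx])),
    estimate = unname(fe[int_idx]),
    se = unname(se[int_idx])
  )
  if (replicated) {
    vc <- as.data.frame(lme4::VarCorr(model))
  } else {
    vc <- data.frame(grp = c("fish_id", "Residual"),
                     sdcor = c(NA_real_, summary(model)$sigma))
  }
  out <- list(
    response = response,
    slope = b, slope_se = b_se,
    slope_ci = b + c(-1, 1) * stats::qnorm(0.975) * b_se,
    intercepts = ints,
    fixed_effects = data.frame(term = names(fe), estimate = unname(fe),
                               se = unname(se)),
    random_intercept_sd = vc$sdcor[vc$grp == "fish_id"][1],
    residual_sd = vc$sdcor[vc$grp == "Residual"][1],
    bic = stats::BIC(model),
    n_individuals = length(unique(data$fish_id)),
    n_observations = nrow(data),
    estimation = "ML",
    kind = "mixed",
    singular = singular,
    interaction = interaction,
    model = model,
    data = data
  )
  class(out) <- "scaling_fit"
  out
}

#' Fit a simple (OLS) mass-scaling model
#'
#' Ordinary least squares of an ln-scale trait on ln body mass, for
#' independent one-off responses (cardiac thermal-tolerance metrics,
#' ventricle mass).
#'
#' @param data Data.frame with columns `ln_mass` and the response column.
#' @param response Name of the ln-scale response column.
#' @return A `"scaling_fit"` with a single intercept row
#'   (`temperature = NA`).
#' @export
fit_scaling_simple <- function(data, response = "ln_response") {
  assert_cols(data, c("ln_mass", response), "scaling data")
  data <- data[is.finite(data[[response]]) & is.finite(data$ln_mass), ]
  if (nrow(data) < 3)
    stopf("data error: need at least 3 points for a scaling regression")
  if (stats::var(data$ln_mass) == 0)
    stopf("degenerate design: ln_mass has zero variance")
  fml <- stats::as.formula(paste(response, "~ ln_mass"))
  model <- stats::lm(fml, data = data)
  # exact interpolations trip summary.lm's perfect-fit caution; harmless here
  quiet <- function(expr) withCallingHandlers(expr, warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
  sm <- quiet(summary(model))
  cf <- sm$coefficients
  ci <- quiet(stats::confint(model))
  out <- list(
    response = response,
    slope = cf["ln_mass", "Estimate"], slope_se = cf["ln_mass", "Std. Error"],
    slope_ci = unname(ci["ln_mass", ]),
    intercepts = data.frame(temperature = NA_real_,
                            estimate = cf["(Intercept)", "Estimate"],
                            se = cf["(Intercept)", "Std. Error"]),
    fixed_effects = data.frame(term = rownames(cf),
                               estimate = unname(cf[, "Estimate"]),
                               se = unname(cf[, "Std. Error"])),
    random_intercept_sd = NA_real_,
    residual_sd = sm$sigma,
    bic = stats::BIC(model),
    n_individuals = nrow(data),
    n_observations = nrow(data),
    estimation = "ML",
    kind = "simple",
    singular = FALSE,
    interaction = FALSE,
    model = model,
    data = data
  )
  class(out) <- "scaling_fit"
  out
}

#' Compare candidate scaling-model structures by BIC
#'
#' Fits every candidate on the same data by maximum likelihood and selects
#' the lowest BIC (ties broken by candidate order). Candidates that fail to
#' fit are recorded with their error message and do not compete.
#'
#' @param data As for [fit_scaling_mixed()].
#' @param candidates Named list; each element is a list of arguments for
#'   [fit_scaling_mixed()] (`covariates`, `interaction`). A sensible default
#'   compares additive vs mass-by-temperature interaction structures.
#' @param response Name of the ln-scale response column.
#' @return A list of class `"model_comparison"`: `table` (model, bic,
#'   delta_bic, status), `selected` (model id) and `fits`.
#' @export
compare_models_bic <- function(data, candidates = NULL,
                               response = "ln_response") {
  if (is.null(candidates))
    candidates <- list(additive = list(interaction = FALSE),
                       interaction = list(interaction = TRUE))
  if (length(candidates) < 2)
    stopf("need at least 2 candidate models")
  fits <- lapply(candidates, function(args) {
    tryCatch(
      do.call(fit_scaling_mixed,
              c(list(data = data, response = response), args)),
      error = function(e) conditionMessage(e))
  })
  ok <- vapply(fits, inherits, logical(1), what = "scaling_fit")
  bics <- ifelse(ok, vapply(fits, function(f)
    if (inherits(f, "scaling_fit")) f$bic else NA_real_, numeric(1)), NA_real_)
  if (!any(ok)) stopf("no candidate model could be fitted")
  best <- which(bics == min(bics, na.rm = TRUE))[1]   # first-minimum tie rule
  tab <- data.frame(
    model = names(candidates),
    bic = bics,
    delta_bic = round(bics - bics[best], 1),
    status = ifelse(ok, "ok", vapply(fits, function(f)
      if (is.character(f)) f else "", character(1))),
    stringsAsFactors = FALSE
  )
  structure(list(table = tab, selected = names(candidates)[best],
                 fits = fits),
            class = "model_comparison")
}

#' Type II tests and temperature contrasts for a scaling fit
#'
#' Type II Wald chi-square tests per fixed term (car::Anova) and, for mixed
#' fits with several temperature levels, Tukey-adjusted pairwise contrasts
#' of the temperature intercepts (emmeans, asymptotic degrees of freedom).
#' For the tests the model is refit with reference-level contrast coding
#' (the cell-means coding used for reporting absolute intercepts is not
#' suitable for marginality-respecting tests).
#'
#' @param fit A `"scaling_fit"` from [fit_scaling_mixed()] or
#'   [fit_scaling_simple()].
#' @return A list of class `"effect_tests"`: `anova` data.frame (term,
#'   statistic, df, p_value) and `contrasts` data.frame (all temperature
#'   pairs with adjusted p), the latter NULL for simple fits.
#' @export
test_effects <- function(fit) {
  stopifnot(inherits(fit, "scaling_fit"))
  if (fit$kind == "simple") {
    a <- car::Anova(fit$model, type = 2)
    tab <- data.frame(term = rownames(a)[rownames(a) != "Residuals"],
                      statistic = a$`F value`[rownames(a) != "Residuals"],
                      df = a$Df[rownames(a) != "Residuals"],
                      p_value = a$`Pr(>F)`[rownames(a) != "Residuals"],
                      stringsAsFactors = FALSE)
    return(structure(list(anova = tab, contrasts = NULL),
                     class = "effect_tests"))
  }
  data <- fit$data
  rhs <- "ln_mass"
  if (nlevels(data$temperature) > 1) rhs <- paste(rhs, "+ temperature")
  if (fit$interaction && nlevels(data$temperature) > 1)
    rhs <- paste(rhs, "+ ln_mass:temperature")
  extra <- setdiff(fit$fixed_effects$term,
                   c("(Intercept)", "ln_mass",
                     grep("^temperature|:", fit$fixed_effects$term,
                          value = TRUE)))
  for (v in c("origin", "sex"))
    if (any(startsWith(extra, v))) rhs <- paste(rhs, "+", v)
  fml <- stats::as.formula(paste(fit$response, "~", rhs, "+ (1 | fish_id)"))
  model <- withCallingHandlers(
    lme4::lmer(fml, data = data, REML = FALSE,
               control = lme4::lmerControl(calc.derivs = FALSE)),
    message = function(m) {
      if (grepl("boundary \\(singular\\) fit", conditionMessage(m)))
        invokeRestart("muffleMessage")
    })
  a <- car::Anova(model, type = 2)
  tab <- data.frame(term = rownames(a), statistic = a$Chisq, df = a$Df,
                    p_value = a$`Pr(>Chisq)`, stringsAsFactors = FALSE)
  contrasts <- NULL
  if (nlevels(data$temperature) > 1) {
    emm <- emmeans::emmeans(model, "temperature", lmer.df = "asymptotic")
    prs <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                           adjust = "tukey"))
    contrasts <- data.frame(contrast = as.character(prs$contrast),
                            estimate = prs$estimate, se = prs$SE,
                            statistic = prs$z.ratio %||% prs$t.ratio,
                            p_value = prs$p.value, stringsAsFactors = FALSE)
  }
  structure(list(anova = tab, contrasts = contrasts), class = "effect_tests")
}

#' Mass-normalize a whole-animal rate to a reference body mass
#'
#' Rescales a whole-animal rate along the fitted scaling exponent to the
#' reference mass and expresses it in mass-specific units:
#' `value * (ref_mass / mass)^b / ref_mass`. With the defaults the result is
#' in (rate units) per 65 g of fish.
#'
#' @param value Whole-animal rate(s), > 0.
#' @param mass Body mass(es) in kg, > 0.
#' @param b Scaling exponent.
#' @param ref_mass Reference body mass in kg (default 0.065, the study's
#'   mean fish size).
#' @return Mass-specific value(s) at the reference size.
#' @export
mass_normalize <- function(value, mass, b, ref_mass = 0.065) {
  if (any(value <= 0) || any(mass <= 0) || ref_mass <= 0)
    stopf("domain error: value, mass and ref_mass must be positive")
  value * (ref_mass / mass)^b / ref_mass
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("Scaling fit (%s, %s): b = %.3f (SE %.3f) [%.3f, %.3f], BIC %.1f\n",
              x$response, x$kind, x$slope, x$slope_se, x$slope_ci[1],
              x$slope_ci[2], x$bic))
  if (nrow(x$intercepts) && !all(is.na(x$intercepts$temperature))) {
    cat("  ln(a) per temperature:\n")
    for (i in seq_len(nrow(x$intercepts)))
      cat(sprintf("    %g degC: %.3f (SE %.3f)\n",
                  x$intercepts$temperature[i], x$intercepts$estimate[i],
                  x$intercepts$se[i]))
  } else {
    cat(sprintf("  ln(a) = %.3f (SE %.3f)\n", x$intercepts$estimate[1],
                x$intercepts$se[1]))
  }
  invisible(x)
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("BIC model comparison (selected:", x$selected, ")\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}
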