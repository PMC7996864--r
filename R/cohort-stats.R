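#' Dichotomize Pfirrmann grades into degeneration classes
#'
#' Grades 1-2 are non-degenerated, grades 3-5 degenerated.
#'
#' @param grade Integer Pfirrmann grades in 1-5.
#' @return Factor with levels `non-degenerated`, `degenerated`.
#' @examples
#' dichotomize_pfirrmann(c(2, 3))
#' @export
dichotomize_pfirrmann <- function(grade) {
  if (anyNA(grade) || any(grade < 1 | grade > 5 | grade != round(grade))) {
    abort("Pfirrmann grades must be integers in 1-5.")
  }
  factor(
    ifelse(grade <= 2, "non-degenerated", "degenerated"),
    levels = c("non-degenerated", "degenerated")
  )
}

# build the fixed-effects formula from the columns that actually vary,
# following the default interaction structure (cohort x segment); age enters
# centred at the sample mean
build_fixed_formula <- function(obs, group_var, interactions) {
  terms <- character(0)
  n_levels <- function(v) length(unique(obs[[v]]))
  if (n_levels(group_var) < 2) {
    abort(paste0("`", group_var, "` must have at least 2 levels."))
  }
  terms <- c(terms, group_var)
  # the adjacency model mirrors its reported specification: adjacency class,
  # age, gender and Pfirrmann grading only (segment is confounded with the
  # extrusion site and is not part of that model)
  if ("segment" %in% names(obs) && !group_var %in% c("segment", "adjacency") &&
    n_levels("segment") > 1) {
    terms <- c(terms, "segment")
    if (interactions && group_var == "cohort") {
      terms <- c(terms, "cohort:segment")
    }
  }
  if ("region" %in% names(obs) && group_var != "region" &&
    n_levels("region") > 1) {
    terms <- c(terms, "region")
    if (interactions && group_var == "cohort") {
      terms <- c(terms, "cohort:region")
    }
  }
  if ("age" %in% names(obs)) terms <- c(terms, "age_c")
  if ("gender" %in% names(obs) && n_levels("gender") > 1) {
    terms <- c(terms, "gender")
  }
  if ("pfirrmann" %in% names(obs) && group_var != "degeneration" &&
    n_levels("pfirrmann") > 1) {
    terms <- c(terms, "degeneration")
  }
  as.formula(paste(
    "gagcest_value ~", paste(terms, collapse = " + "), "+ (1 | subject_id)"
  ))
}

#' Fit the cohort linear mixed model
#'
#' REML linear mixed model of the gagCEST response with a subject-specific
#' random intercept. The default fixed-effects structure follows the study's
#' cohort model: cohort, segment, their interaction, region (when per-region
#' rows are present), mean-centred age, gender, and the dichotomized
#' Pfirrmann grade as confounder. Singular fits (random-intercept variance
#' estimated at zero) are returned with a warning, not an error;
#' rank-deficient fixed designs are an error naming the aliased terms.
#'
#' @param obs An observation tibble as from [generate_cohort()].
#' @param group_var The factor of interest: `"cohort"`, `"region"`,
#'   `"degeneration"`, or `"adjacency"`.
#' @param formula Optional explicit `lme4` formula overriding the default
#'   structure.
#' @param interactions Include the default cohort x segment / cohort x region
#'   interactions.
#' @param ci_level Confidence level for downstream intervals.
#' @return An object of class `gagcest_lmm` wrapping the `lmerMod` fit.
#' @examples
#' m <- fit_cohort_lmm(generate_cohort(scenario_cohort(), seed = 1))
#' marginal_means(m, "cohort")
#' @export
fit_cohort_lmm <- function(obs, group_var = "cohort", formula = NULL,
                           interactions = TRUE, ci_level = 0.99) {
  if (!is.data.frame(obs) || !"gagcest_value" %in% names(obs)) {
    abort("`obs` must contain a `gagcest_value` column.")
  }
  if (anyNA(obs$gagcest_value)) abort("Missing gagCEST responses.")
  if (ci_level <= 0 || ci_level >= 1) abort("`ci_level` must be in (0, 1).")
  dat <- dplyr::mutate(obs, dplyr::across(
    dplyr::any_of(c("cohort", "segment", "region", "gender", "adjacency")),
    ~ droplevels(factor(.x))
  ))
  if (dplyr::n_distinct(dat$subject_id) < 2) {
    abort("At least 2 subjects are required to estimate a random intercept.")
  }
  if ("age" %in% names(dat)) dat$age_c <- dat$age - mean(dat$age)
  if ("pfirrmann" %in% names(dat)) {
    dat$degeneration <- dichotomize_pfirrmann(dat$pfirrmann)
  }
  if (is.null(formula)) {
    formula <- build_fixed_formula(dat, group_var, interactions)
  }

  fixed <- lme4::nobars(formula)
  X <- model.matrix(fixed, dat)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort(paste0(
      "Fixed-effects design is rank deficient; aliased terms: ",
      paste(aliased, collapse = ", "), "."
    ))
  }

  fit <- withCallingHandlers(
    lme4::lmer(formula, data = dat, REML = TRUE),
    message = function(m) invokeRestart("muffleMessage")
  )
  singular <- lme4::isSingular(fit, tol = 1e-5)
  if (singular) {
    warn("Random-intercept variance estimated at zero (singular fit).")
  }
  structure(
    list(
      fit = fit, data = dat, group_var = group_var, formula = formula,
      ci_level = ci_level, singular = singular,
      converged = length(fit@optinfo$conv$lme4$messages) == 0
    ),
    class = "gagcest_lmm"
  )
}

#' Fit the adjacency linear mixed model
#'
#' The study's second model, restricted to radiculopathy subjects: adjacency
#' class (extruded / adjacent / non-adjacent) replaces cohort as the factor
#' of interest, with age, gender, and Pfirrmann degeneration as confounders
#' and the subject random intercept retained.
#'
#' @param obs Observation tibble; non-radiculopathy rows are dropped.
#' @inheritParams fit_cohort_lmm
#' @return A `gagcest_lmm`.
#' @export
fit_adjacency_lmm <- function(obs, formula = NULL, ci_level = 0.99) {
  dat <- dplyr::filter(obs, .data$cohort == "radiculopathy")
  if (nrow(dat) == 0) abort("No radiculopathy observations present.")
  if (!any(dat$extruded)) abort("No extruded disks present.")
  dat$adjacency <- droplevels(dat$adjacency)
  fit_cohort_lmm(dat,
    group_var = "adjacency", formula = formula,
    interactions = FALSE, ci_level = ci_level
  )
}

#' Estimated marginal means with confidence intervals
#'
#' Model-based stratum means from the fitted mixed model, averaging over the
#' other factors' observed level distributions (proportional weights) with
#' numeric covariates at their means. Intervals use the normal approximation
#' on the fixed-effect covariance (an approximation, flagged in the `df`
#' column as `Inf`); the default level is 99%.
#'
#' @param model A [fit_cohort_lmm()] / [fit_adjacency_lmm()] result.
#' @param by Stratifying factor; defaults to the model's factor of interest.
#' @param ci_level Confidence level; defaults to the model's.
#' @return A tibble with columns `stratum`, `mean`, `se`, `df`, `ci_low`,
#'   `ci_high`.
#' @export
marginal_means <- function(model, by = model$group_var,
                           ci_level = model$ci_level) {
  if (!inherits(model, "gagcest_lmm")) {
    abort("`model` must come from fit_cohort_lmm().")
  }
  if (!by %in% names(model$data)) {
    abort(paste0("Stratifying factor `", by, "` not present in the data."))
  }
  # emmeans notes that factors involved in interactions are being averaged
  # over; that proportional averaging is exactly the estimand here
  emm <- suppressMessages(emmeans::emmeans(
    model$fit,
    specs = by, weights = "proportional",
    lmer.df = "asymptotic",
    data = model$data
  ))
  s <- summary(emm, level = ci_level)
  tibble::tibble(
    stratum = as.character(s[[1]]),
    mean = s$emmean,
    se = s$SE,
    df = s$df,
    ci_low = s$asymp.LCL,
    ci_high = s$asymp.UCL
  )
}

#' @export
print.gagcest_lmm <- function(x, ...) {
  cat("gagCEST linear mixed model (REML)\n")
  cat("  factor of interest:", x$group_var, "\n")
  cat(
    "  observations:", nrow(x$data), " subjects:",
    dplyr::n_distinct(x$data$subject_id), "\n"
  )
  vc <- as.data.frame(lme4::VarCorr(x$fit))
  cat(sprintf(
    "  random-intercept sd: %.3f  residual sd: %.3f%s\n",
    vc$sdcor[vc$grp == "subject_id"], vc$sdcor[vc$grp == "Residual"],
    if (x$singular) "  (singular)" else ""
  ))
  invisible(x)
}

#' Tidy a fitted gagCEST mixed model
#'
#' @param x A `gagcest_lmm`.
#' @param ... Unused.
#' @return Fixed-effect estimates with normal-approximation confidence
#'   intervals at the model's level.
#' @export
tidy.gagcest_lmm <- function(x, ...) {
  co <- lme4::fixef(x$fit)
  se <- sqrt(diag(as.matrix(stats::vcov(x$fit))))
  zcrit <- qnorm(1 - (1 - x$ci_level) / 2)
  tibble::tibble(
    term = names(co),
    estimate = unname(co),
    std.error = unname(se),
    ci_low = unname(co - zcrit * se),
    ci_high = unname(co + zcrit * se)
  )
}

#' Model-level summary of a fitted gagCEST mixed model
#'
#' @param x A `gagcest_lmm`.
#' @param ... Unused.
#' @return One-row tibble: variance components, convergence and singularity
#'   flags, observation and subject counts.
#' @export
glance.gagcest_lmm <- function(x, ...) {
  vc <- as.data.frame(lme4::VarCorr(x$fit))
  tibble::tibble(
    random_intercept_sd = vc$sdcor[vc$grp == "subject_id"],
    residual_sd = vc$sdcor[vc$grp == "Residual"],
    converged = x$converged,
    singular = x$singular,
    n_obs = nrow(x$data),
    n_subjects = dplyr::n_distinct(x$data$subject_id),
    REML_criterion = as.numeric(lme4::REMLcrit(x$fit))
  )
}
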