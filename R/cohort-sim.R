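#' Study cohorts
#' @return Cohort factor levels used throughout the package.
#' @export
cohort_levels <- function() {
  c("nsLBP", "radiculopathy", "volunteer")
}

# per-cohort Pfirrmann grade probabilities (grades 1-5), from the reported
# per-cohort grade counts; their means reproduce the reported per-cohort
# mean grades (nsLBP 2.7, radiculopathy 2.6, volunteers 2.4)
pfirrmann_probabilities <- function() {
  list(
    nsLBP = c(0, 37, 30, 11, 2) / 80,
    radiculopathy = c(0, 48, 31, 11, 0) / 90,
    volunteer = c(0, 70, 19, 7, 0) / 96
  )
}

# cohort demographics: sizes, age ranges (years), female counts
cohort_demographics <- function() {
  tibble::tibble(
    cohort = cohort_levels(),
    n = c(16L, 18L, 20L),
    age_min = c(22.5, 14, 39.5),
    age_max = c(83.5, 96, 76.5),
    n_female = c(10L, 10L, 11L)
  )
}

#' Cohort simulation scenario
#'
#' Defines the ground truth of a statistics-level simulated study: the
#' stratum structure of the mean gagCEST response, subject-level random
#' intercept and residual standard deviations (percent units), cohort sizes,
#' and the Pfirrmann/extrusion/demographic generators. Four packaged
#' scenarios ([scenario_cohort()], [scenario_region()],
#' [scenario_degeneration()], [scenario_adjacency()]) are each calibrated to
#' one reported results stratification.
#'
#' @param name Scenario identifier.
#' @param means_by How the ground-truth mean is assigned: by
#'   `cohort_segment` cell, by `region` (NP/AF), by `degeneration`
#'   (dichotomized Pfirrmann), or by `adjacency` class.
#' @param means Ground-truth means in percent: a cohort x segment matrix for
#'   `cohort_segment`, otherwise a named vector over the stratifying levels.
#' @param cohorts Cohorts to simulate.
#' @param regions `"whole"` for one whole-disk row per (subject, segment), or
#'   `c("NP", "AF")` for per-region rows.
#' @param random_intercept_sd,residual_sd Between-subject and residual SDs,
#'   percent.
#' @param extrusion_levels Lumbar levels at which radiculopathy extrusions
#'   may be placed; restricted to L4/5 and L5/S1, where all reported
#'   extrusions occurred.
#' @param seed Default seed used by [generate_cohort()].
#' @return A list of class `cohort_scenario`.
#' @export
cohort_scenario <- function(name, means_by, means,
                            cohorts = cohort_levels(),
                            regions = "whole",
                            random_intercept_sd = 0.5,
                            residual_sd = 0.8,
                            extrusion_levels = c("L4/5", "L5/S1"),
                            seed = 1L) {
  if (!all(extrusion_levels %in% c("L4/5", "L5/S1"))) {
    abort("Extrusions may only be placed at L4/5 or L5/S1.")
  }
  means_by <- match.arg(
    means_by,
    c("cohort_segment", "region", "degeneration", "adjacency")
  )
  if (random_intercept_sd <= 0 || residual_sd <= 0) {
    abort("Scenario standard deviations must be positive.")
  }
  if (!all(cohorts %in% cohort_levels())) abort("Unknown cohort name.")
  if (means_by == "adjacency" && !identical(cohorts, "radiculopathy")) {
    abort("Adjacency scenarios must simulate the radiculopathy cohort only.")
  }
  if (means_by == "cohort_segment") {
    if (!is.matrix(means) ||
      !setequal(rownames(means), cohorts) ||
      !identical(colnames(means), lumbar_levels())) {
      abort("`means` must be a cohort x segment matrix with lumbar level columns.")
    }
  } else {
    required <- switch(means_by,
      region = c("NP", "AF"),
      degeneration = c("non-degenerated", "degenerated"),
      adjacency = c("extruded", "adjacent", "non-adjacent")
    )
    if (!setequal(names(means), required)) {
      abort(paste0(
        "`means` must be named: ", paste(required, collapse = ", "), "."
      ))
    }
  }
  structure(
    list(
      name = name, means_by = means_by, means = means, cohorts = cohorts,
      regions = regions, random_intercept_sd = random_intercept_sd,
      residual_sd = residual_sd, extrusion_levels = extrusion_levels,
      seed = as.integer(seed)
    ),
    class = "cohort_scenario"
  )
}

#' @rdname packaged_scenarios
#' @name packaged_scenarios
#' @title Packaged cohort scenarios
#'
#' @description
#' Each packaged scenario fixes its ground-truth means to one reported
#' stratification of the study results, so parameter recovery on simulated
#' cohorts can be compared against those printed values.
#'
#' `scenario_cohort()`: cohort x segment cell means. The reported
#' segment-level cells are covariate-adjusted and their per-cohort averages
#' do not exactly match the reported cohort overalls (nsLBP 1.3, radiculopathy
#' 1.8, volunteers 1.9); the cells are therefore recentred by a per-cohort
#' constant so each cohort's balanced segment average equals its overall,
#' keeping the overall cohort contrast — the headline result — exact.
#'
#' `scenario_region()`: NP 2.1 vs AF 1.2.
#'
#' `scenario_degeneration()`: Pfirrmann <= 2 (non-degenerated) 2.0 vs >= 3
#' (degenerated) 1.3, with the response driven by the dichotomized grade.
#'
#' `scenario_adjacency()`: radiculopathy only; extruded 1.0, adjacent 0.9,
#' non-adjacent 2.1.
#'
#' @param ... Overrides passed to [cohort_scenario()] (e.g. `seed`,
#'   `residual_sd`).
#' @return A `cohort_scenario`.
NULL

#' @rdname packaged_scenarios
#' @export
scenario_cohort <- function(...) {
  cells <- rbind(
    nsLBP = c(1.3, 1.1, 1.2, 1.1, 2.3),
    radiculopathy = c(2.5, 2.1, 1.7, 1.2, 1.5),
    volunteer = c(2.5, 2.0, 1.5, 1.7, 2.1)
  )
  colnames(cells) <- lumbar_levels()
  overall <- c(nsLBP = 1.3, radiculopathy = 1.8, volunteer = 1.9)
  cells <- cells + (overall - rowMeans(cells))[rownames(cells)]
  cohort_scenario("scenario_cohort", "cohort_segment", cells, ...)
}

#' @rdname packaged_scenarios
#' @export
scenario_region <- function(...) {
  cohort_scenario("scenario_region", "region",
    c(NP = 2.1, AF = 1.2),
    regions = c("NP", "AF"), ...
  )
}

#' @rdname packaged_scenarios
#' @export
scenario_degeneration <- function(...) {
  cohort_scenario("scenario_degeneration", "degeneration",
    c("non-degenerated" = 2.0, "degenerated" = 1.3), ...
  )
}

#' @rdname packaged_scenarios
#' @export
scenario_adjacency <- function(...) {
  cohort_scenario("scenario_adjacency", "adjacency",
    c(extruded = 1.0, adjacent = 0.9, "non-adjacent" = 2.1),
    cohorts = "radiculopathy", ...
  )
}

# adjacency class of each lumbar level given the extruded level: adjacent
# disks share a vertebra with the extruded disk's segment
adjacency_classes <- function(extruded_level) {
  lv <- lumbar_levels()
  i <- match(extruded_level, lv)
  if (is.na(i)) abort("Unknown lumbar level.")
  out <- rep("non-adjacent", 5)
  out[i] <- "extruded"
  if (i > 1) out[i - 1] <- "adjacent"
  if (i < 5) out[i + 1] <- "adjacent"
  setNames(out, lv)
}

#' Simulate a cohort observation table
#'
#' Draws one gagCEST observation per (subject, segment, region):
#' `y = stratum_mean + b_subject + e`, with `b ~ N(0, random_intercept_sd^2)`
#' and `e ~ N(0, residual_sd^2)`. Subject covariates follow the study's
#' demographics: cohort sizes 16/18/20, ages uniform over each cohort's
#' reported range, genders per the reported counts, per-disk Pfirrmann
#' grades from per-cohort grade probabilities, and — in the radiculopathy
#' cohort — exactly one disk extrusion per subject, at L4/5 or L5/S1 (nine
#' subjects each), from which adjacency classes are derived. Output is
#' bit-reproducible for a fixed seed.
#'
#' @param scenario A [cohort_scenario()].
#' @param seed Integer seed; defaults to the scenario's.
#' @return A tibble with columns `subject_id`, `cohort`, `age`, `gender`,
#'   `segment`, `region`, `pfirrmann`, `extruded`, `adjacency`,
#'   `gagcest_value`.
#' @examples
#' obs <- generate_cohort(scenario_cohort(), seed = 7)
#' dplyr::count(obs, cohort)
#' @export
generate_cohort <- function(scenario, seed = scenario$seed) {
  if (!inherits(scenario, "cohort_scenario")) {
    abort("`scenario` must be a cohort_scenario.")
  }
  withr::with_seed(seed, generate_cohort_impl(scenario))
}

generate_cohort_impl <- function(scenario) {
  demo <- dplyr::filter(cohort_demographics(), .data$cohort %in% scenario$cohorts)
  pprob <- pfirrmann_probabilities()
  lv <- lumbar_levels()

  subjects <- purrr::pmap_dfr(demo, function(cohort, n, age_min, age_max,
                                             n_female) {
    extruded_at <- rep(NA_character_, n)
    if (cohort == "radiculopathy") {
      # one extrusion per subject, split evenly over the allowed levels
      extruded_at <- sample(rep(scenario$extrusion_levels, length.out = n))
    }
    tibble::tibble(
      subject_id = sprintf("%s_%02d", cohort, seq_len(n)),
      cohort = cohort,
      age = round(runif(n, age_min, age_max), 1),
      gender = sample(rep(c("female", "male"), c(n_female, n - n_female))),
      extruded_level = extruded_at,
      b_subject = rnorm(n, sd = scenario$random_intercept_sd)
    )
  })

  obs <- tidyr::expand_grid(
    subjects,
    segment = factor(lv, levels = lv),
    region = factor(scenario$regions,
      levels = union(scenario$regions, c("whole", "NP", "AF"))
    )
  )
  obs <- dplyr::arrange(obs, .data$subject_id, .data$segment, .data$region)

  # per-disk grades are a subject x segment property shared across regions
  disks <- dplyr::distinct(obs, .data$subject_id, .data$cohort, .data$segment)
  disks$pfirrmann <- purrr::map_int(
    as.character(disks$cohort),
    ~ sample(1:5, 1, prob = pprob[[.x]])
  )
  obs <- dplyr::left_join(
    obs, disks,
    by = c("subject_id", "cohort", "segment")
  )

  obs <- dplyr::mutate(obs,
    extruded = !is.na(.data$extruded_level) &
      as.character(.data$segment) == .data$extruded_level,
    adjacency = purrr::map2_chr(
      .data$extruded_level, as.character(.data$segment),
      function(e, s) if (is.na(e)) "not-applicable" else adjacency_classes(e)[[s]]
    ),
    adjacency = factor(
      .data$adjacency,
      levels = c("extruded", "adjacent", "non-adjacent", "not-applicable")
    )
  )

  mu <- switch(scenario$means_by,
    cohort_segment = scenario$means[cbind(
      as.character(obs$cohort), as.character(obs$segment)
    )],
    region = unname(scenario$means[as.character(obs$region)]),
    degeneration = unname(
      scenario$means[as.character(dichotomize_pfirrmann(obs$pfirrmann))]
    ),
    adjacency = unname(scenario$means[as.character(obs$adjacency)])
  )

  obs$gagcest_value <- mu + obs$b_subject +
    rnorm(nrow(obs), sd = scenario$residual_sd)

  dplyr::select(
    dplyr::mutate(obs, cohort = factor(.data$cohort, levels = cohort_levels())),
    "subject_id", "cohort", "age", "gender", "segment", "region",
    "pfirrmann", "extruded", "adjacency", "gagcest_value"
  )
}
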