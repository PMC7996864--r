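#' Replicate-averaged marginal-mean recovery for a scenario
#'
#' Runs the full statistics-level simulation loop: generates `n_reps`
#' independently seeded cohorts from a scenario, fits the appropriate REML
#' mixed model to each (the adjacency model for adjacency scenarios, the
#' cohort model otherwise), extracts estimated marginal means for the
#' scenario's stratifying factor, and averages them across replicates. This
#' is the parameter-recovery surface on which simulated cohorts are compared
#' with the study's printed stratum means.
#'
#' @param scenario A [cohort_scenario()].
#' @param n_reps Number of replicates.
#' @param seed Master seed; per-replicate seeds are drawn from it.
#' @param by Stratifying factor; defaults to the scenario's own.
#' @return A list with `per_replicate` (tibble: `replicate`, `stratum`,
#'   `mean`, ...) and `summary` (tibble: `stratum`, `mean` averaged across
#'   replicates, `sd_across_reps`, `n_reps`).
#' @examples
#' \donttest{
#' replicate_marginal_means(scenario_region(), n_reps = 3, seed = 1)$summary
#' }
#' @export
replicate_marginal_means <- function(scenario, n_reps = 25, seed = 1L,
                                     by = NULL) {
  if (!inherits(scenario, "cohort_scenario")) {
    abort("`scenario` must be a cohort_scenario.")
  }
  by <- by %||% switch(scenario$means_by,
    cohort_segment = "cohort",
    region = "region",
    degeneration = "degeneration",
    adjacency = "adjacency"
  )
  rep_seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max - 1, n_reps))
  per_rep <- purrr::map_dfr(seq_len(n_reps), function(i) {
    obs <- generate_cohort(scenario, seed = rep_seeds[i])
    model <- suppressWarnings(
      if (scenario$means_by == "adjacency") {
        fit_adjacency_lmm(obs)
      } else {
        fit_cohort_lmm(obs, group_var = by)
      }
    )
    dplyr::mutate(marginal_means(model, by = by), replicate = i, .before = 1)
  })
  summary <- dplyr::summarise(
    dplyr::group_by(per_rep, .data$stratum),
    sd_across_reps = sd(.data$mean),
    mean = mean(.data$mean),
    n_reps = dplyr::n(),
    .groups = "drop"
  )
  summary <- dplyr::relocate(summary, "stratum", "mean")
  list(per_replicate = per_rep, summary = summary)
}

#' Ground-truth marginal means of a scenario
#'
#' The stratum means a perfectly recovered analysis would return: for
#' cohort x segment scenarios the balanced per-cohort average of the cell
#' means; otherwise the scenario's stratum means directly.
#'
#' @param scenario A [cohort_scenario()].
#' @return Tibble with `stratum` and `truth` (percent).
#' @export
scenario_truth <- function(scenario) {
  if (scenario$means_by == "cohort_segment") {
    tibble::tibble(
      stratum = rownames(scenario$means),
      truth = rowMeans(scenario$means)
    )
  } else {
    tibble::tibble(
      stratum = names(scenario$means),
      truth = unname(scenario$means)
    )
  }
}
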