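test_that("REML recovers the variance components across seeds", {
  sc <- scenario_cohort()
  est <- purrr::map_dfr(1:20, function(s) {
    m <- suppressWarnings(fit_cohort_lmm(generate_cohort(sc, seed = 400 + s)))
    glance(m)[, c("random_intercept_sd", "residual_sd")]
  })
  expect_lt(abs(mean(est$random_intercept_sd) - 0.5) / 0.5, 0.15)
  expect_lt(abs(mean(est$residual_sd) - 0.8) / 0.8, 0.15)
})

test_that("constant responses collapse to zero effects and variances", {
  obs <- generate_cohort(scenario_cohort(), seed = 2)
  obs$gagcest_value <- 1.5
  m <- suppressWarnings(fit_cohort_lmm(obs))
  td <- tidy(m)
  expect_equal(td$estimate[td$term == "(Intercept)"], 1.5, tolerance = 1e-6)
  expect_equal(max(abs(td$estimate[td$term != "(Intercept)"])), 0,
    tolerance = 1e-6
  )
  g <- glance(m)
  expect_equal(g$random_intercept_sd, 0, tolerance = 1e-6)
  expect_equal(g$residual_sd, 0, tolerance = 1e-6)
})

test_that("rank-deficient fixed designs fail loudly, naming aliased terms", {
  obs <- generate_cohort(scenario_cohort(), seed = 2)
  obs$cohort_copy <- obs$cohort
  expect_error(
    fit_cohort_lmm(obs,
      formula = gagcest_value ~ cohort + cohort_copy + (1 | subject_id)
    ),
    "aliased"
  )
})

test_that("marginal means equal raw stratum means in balanced one-factor data", {
  set.seed(60)
  obs <- tibble::tibble(
    subject_id = rep(sprintf("s%02d", 1:30), each = 5),
    cohort = factor(rep(cohort_levels(), each = 50),
      levels = cohort_levels()
    ),
    segment = factor(rep(lumbar_levels(), 30), levels = lumbar_levels()),
    gagcest_value = rnorm(150, rep(c(1.3, 1.8, 1.9), each = 50), 0.5)
  )
  m <- suppressWarnings(fit_cohort_lmm(obs,
    formula = gagcest_value ~ cohort + (1 | subject_id)
  ))
  mm <- marginal_means(m, "cohort")
  raw <- tapply(obs$gagcest_value, obs$cohort, mean)
  expect_equal(mm$mean, as.numeric(raw[mm$stratum]), tolerance = 1e-6)
  expect_true(all(mm$ci_low <= mm$mean & mm$mean <= mm$ci_high))
})

test_that("intervals widen with the confidence level and recoding is neutral", {
  obs <- generate_cohort(scenario_cohort(), seed = 9)
  m <- suppressWarnings(fit_cohort_lmm(obs))
  mm95 <- marginal_means(m, ci_level = 0.95)
  mm99 <- marginal_means(m, ci_level = 0.99)
  expect_true(all(
    mm99$ci_high - mm99$ci_low > mm95$ci_high - mm95$ci_low
  ))

  releveled <- dplyr::mutate(obs,
    cohort = stats::relevel(factor(cohort), ref = "volunteer")
  )
  m2 <- suppressWarnings(fit_cohort_lmm(releveled))
  mm1 <- dplyr::arrange(marginal_means(m), stratum)
  mm2 <- dplyr::arrange(marginal_means(m2), stratum)
  expect_equal(mm1$mean, mm2$mean, tolerance = 1e-6)
})

test_that("a null cohort effect is covered by the 99% CI almost always", {
  null_sc <- cohort_scenario(
    "null", "cohort_segment",
    matrix(1.5, 3, 5, dimnames = list(cohort_levels(), lumbar_levels()))
  )
  covered <- vapply(1:30, function(s) {
    m <- suppressWarnings(fit_cohort_lmm(generate_cohort(null_sc, seed = 500 + s)))
    td <- tidy(m)
    ix <- grepl("^cohort", td$term) & !grepl(":", td$term)
    all(td$ci_low[ix] <= 0 & td$ci_high[ix] >= 0)
  }, logical(1))
  expect_gte(mean(covered), 0.9)
})

test_that("the adjacency model needs radiculopathy data with extrusions", {
  obs <- generate_cohort(scenario_adjacency(), seed = 4)
  m <- suppressWarnings(fit_adjacency_lmm(obs))
  mm <- marginal_means(m)
  expect_setequal(mm$stratum, c("extruded", "adjacent", "non-adjacent"))

  vol_only <- dplyr::filter(generate_cohort(scenario_cohort(), seed = 4),
    cohort == "volunteer"
  )
  expect_error(fit_adjacency_lmm(vol_only), "radiculopathy")
  no_ext <- dplyr::mutate(obs, extruded = FALSE)
  expect_error(fit_adjacency_lmm(no_ext), "extruded")
  single <- dplyr::filter(obs, subject_id == obs$subject_id[1])
  expect_error(fit_adjacency_lmm(single), "2 subjects")
})

test_that("permuting adjacency labels destroys the class contrast", {
  sc <- scenario_adjacency()
  contrast <- function(obs) {
    mm <- marginal_means(suppressWarnings(fit_adjacency_lmm(obs)))
    mm$mean[mm$stratum == "non-adjacent"] - mm$mean[mm$stratum == "adjacent"]
  }
  real <- numeric(6)
  permuted <- numeric(6)
  for (s in 1:6) {
    obs <- generate_cohort(sc, seed = 700 + s)
    real[s] <- contrast(obs)
    shuffled <- withr::with_seed(
      800 + s,
      dplyr::mutate(obs, adjacency = sample(adjacency))
    )
    permuted[s] <- contrast(shuffled)
  }
  expect_gt(mean(real), 0.8)
  expect_lt(abs(mean(permuted)), 0.4)
})

test_that("Kruskal-Wallis H matches a first-principles rank computation", {
  groups <- list(c(1, 1, 2), c(2, 3, 3), c(4, 5, 5))
  df <- data.frame(
    value = unlist(groups),
    grp = rep(letters[1:3], lengths(groups))
  )
  res <- kruskal_dunn(df, "value", "grp")
  expect_equal(res$statistic, brute_force_kw_h(groups), tolerance = 1e-12)
  expect_equal(res$df, 2)

  # identical groups: H = 0 and no post-hoc
  same <- data.frame(value = rep(c(1, 2, 3), 2), grp = rep(c("a", "b"), each = 3))
  res0 <- kruskal_dunn(same, "value", "grp")
  expect_equal(res0$statistic, 0)
  expect_null(res0$pairwise)

  # degenerate all-identical data short-circuits
  const <- data.frame(value = rep(2, 6), grp = rep(c("a", "b"), each = 3))
  expect_equal(kruskal_dunn(const, "value", "grp")$statistic, 0)
  expect_error(kruskal_dunn(df[1:3, ], "value", "grp"), "2 groups")
})

test_that("Dunn post-hoc runs only on rejection, with adjusted p-values", {
  set.seed(70)
  df <- data.frame(
    value = c(rnorm(20, 0), rnorm(20, 0), rnorm(20, 4)),
    grp = rep(c("a", "b", "c"), each = 20)
  )
  res <- kruskal_dunn(df, "value", "grp")
  expect_false(is.null(res$pairwise))
  pw <- tidy(res)
  expect_equal(nrow(pw), 3)
  expect_true(all(pw$p.adjusted >= pw$p.value - 1e-15))
  # the separated pair is the significant one
  sig <- pw[pw$p.adjusted < 0.01, ]
  expect_true(all(sig$group2 == "c" | sig$group1 == "c"))
  expect_true(glance(res)$posthoc_performed)
})
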