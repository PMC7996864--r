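#' Kruskal-Wallis test with Dunn's post-hoc comparisons
#'
#' Compares a value (here: Pfirrmann grades) across groups (here: study
#' cohorts) without assuming normality. The omnibus Kruskal-Wallis H uses
#' the tie-corrected statistic; when it rejects at `alpha`, Dunn's pairwise
#' rank-based z statistics are computed with the tie-corrected variance and
#' the p-values adjusted for multiplicity (Bonferroni by default).
#'
#' @param data Data frame.
#' @param value,group Column names (strings) of the value and grouping
#'   variables.
#' @param alpha Omnibus rejection level gating the post-hoc tests.
#' @param p_adjust Multiplicity adjustment method for the pairwise p-values
#'   (see [stats::p.adjust()]).
#' @return An object of class `kruskal_dunn`: omnibus `statistic`, `df`,
#'   `p.value`, and — when the omnibus rejects — a `pairwise` tibble of Dunn
#'   z statistics with adjusted p-values.
#' @examples
#' obs <- generate_cohort(scenario_cohort(), seed = 1)
#' disks <- dplyr::distinct(obs, subject_id, cohort, segment, pfirrmann)
#' kruskal_dunn(disks, "pfirrmann", "cohort")
#' @export
kruskal_dunn <- function(data, value = "gagcest_value", group = "cohort",
                         alpha = 0.05, p_adjust = "bonferroni") {
  x <- data[[value]]
  g <- droplevels(factor(data[[group]]))
  if (nlevels(g) < 2) abort("Need at least 2 groups.")
  if (any(table(g) < 2)) abort("Each group needs at least 2 observations.")
  if (length(unique(x)) == 1) {
    out <- list(
      statistic = 0, df = nlevels(g) - 1L, p.value = 1,
      pairwise = NULL, alpha = alpha, groups = levels(g)
    )
    class(out) <- "kruskal_dunn"
    return(out)
  }
  kw <- kruskal.test(x, g)
  pairwise <- NULL
  if (kw$p.value < alpha) {
    pairwise <- dunn_pairwise(x, g, p_adjust)
  }
  structure(
    list(
      statistic = unname(kw$statistic), df = unname(kw$parameter),
      p.value = kw$p.value, pairwise = pairwise, alpha = alpha,
      groups = levels(g)
    ),
    class = "kruskal_dunn"
  )
}

# Dunn's z for all group pairs: difference of mean ranks over the pooled
# tie-corrected standard error
dunn_pairwise <- function(x, g, p_adjust) {
  n <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  ni <- tapply(r, g, length)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  v0 <- n * (n + 1) / 12 - tie_term
  lv <- levels(g)
  pairs <- utils::combn(lv, 2)
  z <- apply(pairs, 2, function(p) {
    (rbar[[p[1]]] - rbar[[p[2]]]) /
      sqrt(v0 * (1 / ni[[p[1]]] + 1 / ni[[p[2]]]))
  })
  p <- 2 * pnorm(-abs(z))
  tibble::tibble(
    group1 = pairs[1, ], group2 = pairs[2, ],
    z = unname(z),
    p.value = unname(p),
    p.adjusted = p.adjust(p, method = p_adjust)
  )
}

#' @export
print.kruskal_dunn <- function(x, ...) {
  cat(sprintf(
    "Kruskal-Wallis: H = %.4f, df = %d, p = %.4g\n",
    x$statistic, x$df, x$p.value
  ))
  if (is.null(x$pairwise)) {
    cat("No post-hoc comparisons (omnibus not significant at alpha =",
      x$alpha, "or degenerate data).\n")
  } else {
    cat("Dunn post-hoc comparisons:\n")
    print(as.data.frame(x$pairwise), row.names = FALSE)
  }
  invisible(x)
}

#' @rdname kruskal_dunn
#' @param x A `kruskal_dunn` object.
#' @param ... Unused.
#' @export
tidy.kruskal_dunn <- function(x, ...) {
  if (is.null(x$pairwise)) {
    return(tibble::tibble(
      group1 = character(), group2 = character(),
      z = numeric(), p.value = numeric(), p.adjusted = numeric()
    ))
  }
  x$pairwise
}

#' @rdname kruskal_dunn
#' @export
glance.kruskal_dunn <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic, df = x$df, p.value = x$p.value,
    n_groups = length(x$groups),
    posthoc_performed = !is.null(x$pairwise)
  )
}
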