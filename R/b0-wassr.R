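#' Mirror-symmetry cost of a z-spectrum about a candidate centre
#'
#' The maximum-symmetry B0 estimator scores each candidate water-centre
#' frequency `delta` by the summed squared difference between the spectrum
#' interpolated at `delta + w` and at `delta - w`, over the sampled offset
#' magnitudes `w` for which both reflected points lie inside the sampled
#' sweep (no extrapolation). A noiseless spectrum exactly symmetric about the
#' candidate has cost 0.
#'
#' @param spectrum A [z_spectrum()] with at least 5 sampled offsets.
#' @param candidate_center Candidate centre frequency, ppm, inside the
#'   sampled range.
#' @return Non-negative cost (dimensionless).
#' @export
symmetry_cost <- function(spectrum, candidate_center) {
  spectrum <- as_zspectrum(spectrum)
  if (nrow(spectrum) < 5) {
    abort("Need at least 5 sampled offsets for a reliable interpolant.")
  }
  rng <- range(spectrum$offset_ppm)
  if (candidate_center < rng[1] || candidate_center > rng[2]) {
    abort("`candidate_center` must lie inside the sampled range.")
  }
  fz <- zspec_interpolant(spectrum)
  w <- unique(abs(spectrum$offset_ppm))
  w <- w[w > 0]
  .symmetry_cost(fz, rng, w, candidate_center)
}

# vectorized over candidate centres; fz/rng/w precomputed by callers in loops
.symmetry_cost <- function(fz, rng, w, centers) {
  vapply(centers, function(d) {
    keep <- (d + w) <= rng[2] & (d - w) >= rng[1]
    if (!any(keep)) {
      return(Inf)
    }
    ww <- w[keep]
    sum((fz(d + ww) - fz(d - ww))^2)
  }, numeric(1))
}

#' Maximum-symmetry B0 estimate for one voxel
#'
#' Locates the centre frequency about which the WASSR spectrum is most
#' mirror-symmetric: a coarse grid search (step 0.01 ppm) over
#' `±search_halfwidth` followed by bounded scalar minimization around the
#' best grid point. Flat, low-signal spectra (dynamic range below the
#' validity threshold: minimum not below `0.8 x` maximum) are flagged invalid
#' rather than estimated.
#'
#' @param spectrum A [z_spectrum()], typically a WASSR acquisition.
#' @param search_halfwidth Half-width of the candidate search interval, ppm.
#' @param coarse_step Grid step of the coarse search, ppm.
#' @param validity_ratio A spectrum is estimable when `min(z) <
#'   validity_ratio * max(z)`.
#' @return A one-row tibble with columns `delta_ppm`, `valid`, `cost`.
#' @export
estimate_b0_voxel <- function(spectrum, search_halfwidth = 0.5,
                              coarse_step = 0.01, validity_ratio = 0.8) {
  spectrum <- as_zspectrum(spectrum)
  if (nrow(spectrum) < 5) {
    abort("Need at least 5 sampled offsets.")
  }
  est <- .estimate_b0(
    spectrum$offset_ppm, spectrum$z,
    search_halfwidth, coarse_step, validity_ratio
  )
  tibble::tibble(delta_ppm = est[1], valid = as.logical(est[2]), cost = est[3])
}

# fast path shared with estimate_b0_map(); returns c(delta, valid, cost)
.estimate_b0 <- function(offsets, z, search_halfwidth, coarse_step,
                         validity_ratio) {
  if (min(z) >= validity_ratio * max(z)) {
    return(c(NA_real_, 0, NA_real_))
  }
  rng <- range(offsets)
  half <- min(search_halfwidth, abs(rng[1]), abs(rng[2]))
  fz <- splinefun(offsets, z, method = "natural")
  w <- unique(abs(offsets))
  w <- w[w > 0]
  grid <- seq(-half, half, by = coarse_step)
  costs <- .symmetry_cost(fz, rng, w, grid)
  i <- which.min(costs)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(length(grid), i + 1)]
  if (lo < hi) {
    opt <- optimize(function(d) .symmetry_cost(fz, rng, w, d),
      interval = c(lo, hi), tol = 1e-5
    )
    c(opt$minimum, 1, opt$objective)
  } else {
    c(grid[i], 1, costs[i])
  }
}

#' Per-pixel B0 map from a WASSR stack
#'
#' Applies the maximum-symmetry estimator to every masked pixel of a WASSR
#' acquisition. The stack is normalized by the unsaturated reference image
#' before estimation; pixels outside the mask, with non-positive S0, or with
#' too little spectral dynamic range are flagged invalid.
#'
#' @param wassr_stack Numeric array `H x W x n_offsets` of saturation-weighted
#'   signal.
#' @param offsets WASSR frequency offsets, ppm, length matching the stack's
#'   third dimension.
#' @param s0_image `H x W` unsaturated reference image; `NULL` if the stack is
#'   already normalized.
#' @param mask Logical `H x W` matrix of pixels to estimate; default all.
#' @param ... Passed to [estimate_b0_voxel()].
#' @return A list of class `b0_map` with matrices `delta` (ppm, `NA` where
#'   invalid) and `valid`.
#' @export
estimate_b0_map <- function(wassr_stack, offsets, s0_image = NULL, mask = NULL,
                            ...) {
  dm <- dim(wassr_stack)
  if (length(dm) != 3 || dm[3] != length(offsets)) {
    abort("`wassr_stack` must be H x W x n_offsets matching `offsets`.")
  }
  args <- modifyList(
    list(search_halfwidth = 0.5, coarse_step = 0.01, validity_ratio = 0.8),
    list(...)
  )
  if (is.null(mask)) mask <- matrix(TRUE, dm[1], dm[2])
  delta <- matrix(NA_real_, dm[1], dm[2])
  valid <- matrix(FALSE, dm[1], dm[2])
  idx <- which(mask, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1]
    j <- idx[k, 2]
    z <- wassr_stack[i, j, ]
    if (!is.null(s0_image)) {
      s0 <- s0_image[i, j]
      if (!is.finite(s0) || s0 <= 0) next
      z <- z / s0
    }
    if (any(!is.finite(z))) next
    est <- .estimate_b0(
      offsets, z,
      args$search_halfwidth, args$coarse_step, args$validity_ratio
    )
    if (est[2] == 1) {
      delta[i, j] <- est[1]
      valid[i, j] <- TRUE
    }
  }
  structure(list(delta = delta, valid = valid), class = "b0_map")
}
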