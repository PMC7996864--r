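#' Lorentzian line shape
#'
#' Saturation profile of a single exchanging pool: an amplitude-scaled
#' Lorentzian with full width at half maximum `width`, centred at zero.
#'
#' @param x Offset from the pool centre, ppm.
#' @param amplitude Peak saturation depth (dimensionless, 0-1).
#' @param width Full width at half maximum, ppm.
#' @return Numeric vector of saturation depths.
#' @export
lorentzian <- function(x, amplitude, width) {
  hw2 <- (width / 2)^2
  amplitude * hw2 / (hw2 + x^2)
}

#' Two-pool (plus optional MT) saturation model
#'
#' Analytic forward model for a z-spectrum: direct water saturation, a GAG
#' hydroxyl pool resonating at a positive offset inside the GAG-specific
#' 0.9-1.9 ppm band, and an optional broad symmetric magnetization-transfer
#' pool. Amplitudes are saturation depths; their sum must stay below 1 so the
#' simulated spectrum remains in (0, 1].
#'
#' @param water_amplitude,water_width Direct water saturation depth and FWHM
#'   (ppm).
#' @param gag_amplitude,gag_center,gag_width GAG pool depth (scales with GAG
#'   concentration), centre (ppm, within the GAG band), and FWHM (ppm).
#' @param mt_amplitude,mt_width Optional broad symmetric MT pool.
#' @return A list of class `pool_model`.
#' @examples
#' pool_model(gag_amplitude = 0.03)
#' @export
pool_model <- function(water_amplitude = 0.9, water_width = 1.4,
                       gag_amplitude = 0, gag_center = 1.3, gag_width = 0.8,
                       mt_amplitude = 0, mt_width = 6) {
  amps <- c(water_amplitude, gag_amplitude, mt_amplitude)
  pars <- c(amps, water_width, gag_center, gag_width, mt_width)
  if (anyNA(pars) || any(!is.finite(pars))) {
    abort("Pool parameters must be finite.")
  }
  if (any(amps < 0) || any(amps > 1)) {
    abort("Pool amplitudes must lie in [0, 1].")
  }
  if (sum(amps) >= 1) {
    abort("Pool amplitudes must sum to less than 1 so Z stays in (0, 1].")
  }
  if (gag_center < 0.9 || gag_center > 1.9) {
    abort("`gag_center` must lie inside the GAG band [0.9, 1.9] ppm.")
  }
  if (water_width <= 0 || gag_width <= 0 || mt_width <= 0) {
    abort("Pool widths must be positive.")
  }
  structure(
    list(
      water_amplitude = water_amplitude, water_width = water_width,
      gag_amplitude = gag_amplitude, gag_center = gag_center,
      gag_width = gag_width,
      mt_amplitude = mt_amplitude, mt_width = mt_width
    ),
    class = "pool_model"
  )
}

# noiseless forward model, vectorized over offsets
pool_z <- function(pool, offsets, b0_offset = 0) {
  x <- offsets - b0_offset
  1 -
    lorentzian(x, pool$water_amplitude, pool$water_width) -
    lorentzian(x - pool$gag_center, pool$gag_amplitude, pool$gag_width) -
    lorentzian(x, pool$mt_amplitude, pool$mt_width)
}

#' Closed-form MTRasym of a pool model
#'
#' For the Lorentzian forward model at zero B0 offset, the water and MT pools
#' are symmetric about 0 and cancel in `Z(-dw) - Z(dw)`; the asymmetry is the
#' GAG pool's Lorentzian evaluated at `dw - gag_center` minus its mirror at
#' `-dw - gag_center`. Used as the analytic oracle for the sampled pipeline.
#'
#' @param pool A [pool_model()].
#' @param delta_ppm Positive offsets at which to evaluate, ppm.
#' @return MTRasym values (dimensionless).
#' @export
pool_mtr_asym <- function(pool, delta_ppm) {
  lorentzian(delta_ppm - pool$gag_center, pool$gag_amplitude, pool$gag_width) -
    lorentzian(-delta_ppm - pool$gag_center, pool$gag_amplitude, pool$gag_width)
}

#' Expected band-averaged gagCEST effect of a pool model
#'
#' Mean of the closed-form MTRasym over the sampled offsets that fall inside
#' the GAG band, in percent. This is the mapping from `gag_amplitude` to the
#' observable gagCEST effect size under a given sampling scheme, and serves as
#' per-region ground truth for phantoms.
#'
#' @param pool A [pool_model()].
#' @param offsets Sampled frequency offsets, ppm.
#' @param band A [gag_band()].
#' @return Expected gagCEST effect in percent.
#' @export
pool_band_gagcest <- function(pool, offsets, band = gag_band()) {
  dw <- offsets[offsets >= band$lower & offsets <= band$upper]
  if (length(dw) == 0) {
    abort("No sampled offsets fall inside the GAG band.")
  }
  100 * mean(pool_mtr_asym(pool, dw))
}
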