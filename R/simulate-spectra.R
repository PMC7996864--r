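#' Acquisition specification for CEST/WASSR sampling
#'
#' Sampling scheme of the synthetic acquisition: a symmetric CEST sweep out to
#' 3 ppm, a narrow symmetric WASSR sweep out to 1 ppm, single midsagittal
#' slice, 1.6 x 1.6 mm pixels, and the noise level expressed as a fraction of
#' the unsaturated signal.
#'
#' @param cest_offsets CEST frequency offsets, ppm; symmetric about 0, default
#'   33 evenly spaced points on \[-3, 3\].
#' @param wassr_offsets WASSR offsets, ppm; default 21 points on \[-1, 1\].
#' @param pixel_size In-plane pixel size, mm.
#' @param slice_count Number of slices (midsagittal acquisition: 1).
#' @param noise_sd Noise standard deviation as a fraction of S0.
#' @return A list of class `acquisition_spec`.
#' @export
acquisition_spec <- function(cest_offsets = seq(-3, 3, length.out = 33),
                             wassr_offsets = seq(-1, 1, length.out = 21),
                             pixel_size = c(1.6, 1.6),
                             slice_count = 1,
                             noise_sd = 0.01) {
  check_offsets <- function(x, max_abs, what) {
    if (any(diff(x) <= 0)) {
      abort(paste0("`", what, "` must be strictly increasing."))
    }
    if (max(abs(x)) > max_abs + 1e-9) {
      abort(paste0("`", what, "` must lie within ±", max_abs, " ppm."))
    }
    # need 0 or a symmetric pair bracketing it so the sweep covers water
    if (!any(abs(x) < 1e-9) && !(any(x < 0) && any(x > 0))) {
      abort(paste0("`", what, "` must contain 0 or bracket it symmetrically."))
    }
    invisible(x)
  }
  check_offsets(cest_offsets, 3, "cest_offsets")
  check_offsets(wassr_offsets, 1, "wassr_offsets")
  if (noise_sd < 0) abort("`noise_sd` must be non-negative.")
  structure(
    list(
      cest_offsets = cest_offsets, wassr_offsets = wassr_offsets,
      pixel_size = pixel_size, slice_count = slice_count, noise_sd = noise_sd
    ),
    class = "acquisition_spec"
  )
}

#' GAG-specific frequency band
#'
#' The band of saturation offsets attributed to glycosaminoglycan hydroxyl
#' protons, 0.9-1.9 ppm downfield of water.
#'
#' @param lower,upper Band edges, ppm.
#' @return A list of class `gag_band`.
#' @export
gag_band <- function(lower = 0.9, upper = 1.9) {
  if (!(lower > 0 && lower < upper && upper <= 3)) {
    abort("Require 0 < lower < upper <= 3 ppm.")
  }
  structure(list(lower = lower, upper = upper), class = "gag_band")
}

#' Simulate a CEST z-spectrum
#'
#' Evaluates the sum-of-Lorentzians forward model at the requested offsets,
#' shifted by a B0 offset, with additive Gaussian noise on Z (an adequate
#' approximation to Rician noise at the high SNR of normalized spectra).
#' Values are clipped to \[0, 1\].
#'
#' @param pool A [pool_model()].
#' @param offsets Sampling offsets, ppm, within ±3.
#' @param b0_offset Water centre-frequency shift, ppm.
#' @param noise_sd Gaussian noise SD on Z.
#' @param seed Optional integer seed for reproducible noise.
#' @return A [z_spectrum()].
#' @examples
#' sp <- simulate_z_spectrum(pool_model(gag_amplitude = 0.03), seq(-3, 3, 0.25))
#' band_gagcest(sp)
#' @export
simulate_z_spectrum <- function(pool, offsets, b0_offset = 0, noise_sd = 0,
                                seed = NULL) {
  if (!inherits(pool, "pool_model")) abort("`pool` must be a pool_model.")
  if (length(offsets) == 0) abort("`offsets` must not be empty.")
  if (!all(is.finite(offsets)) || !is.finite(b0_offset) ||
      !is.finite(noise_sd)) {
    abort("Offsets, b0_offset and noise_sd must be finite.")
  }
  if (max(abs(offsets)) > 3 + 1e-9) {
    abort("CEST offsets must lie within ±3 ppm.")
  }
  z <- pool_z(pool, offsets, b0_offset)
  if (noise_sd > 0) {
    noise <- with_optional_seed(seed, rnorm(length(offsets), sd = noise_sd))
    z <- z + noise
  }
  z_spectrum(offsets, pmin(pmax(z, 0), 1))
}

#' Simulate a WASSR z-spectrum
#'
#' Direct-saturation-only narrow sweep: a single symmetric water dip centred
#' at the voxel's B0 offset, used to locate the water frequency.
#'
#' @param b0_offset Water centre-frequency shift, ppm.
#' @param offsets Sampling offsets, ppm, within ±1.
#' @param noise_sd Gaussian noise SD on Z.
#' @param seed Optional integer seed.
#' @param amplitude,width Water dip depth and FWHM (ppm) of the low-power
#'   WASSR saturation.
#' @return A [z_spectrum()].
#' @export
simulate_wassr_spectrum <- function(b0_offset, offsets = seq(-1, 1, length.out = 21),
                                    noise_sd = 0, seed = NULL,
                                    amplitude = 0.85, width = 0.3) {
  if (length(offsets) == 0) abort("`offsets` must not be empty.")
  if (!all(is.finite(offsets)) || !is.finite(b0_offset) ||
      !is.finite(noise_sd)) {
    abort("Offsets, b0_offset and noise_sd must be finite.")
  }
  if (max(abs(offsets)) > 1 + 1e-9) {
    abort("WASSR offsets must lie within ±1 ppm.")
  }
  z <- 1 - lorentzian(offsets - b0_offset, amplitude, width)
  if (noise_sd > 0) {
    z <- z + with_optional_seed(seed, rnorm(length(offsets), sd = noise_sd))
  }
  z_spectrum(offsets, pmin(pmax(z, 0), 1))
}

# run expr under a temporary seed when one is given, without disturbing the
# caller's RNG stream otherwise
with_optional_seed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}
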