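#' Z-spectrum objects
#'
#' A z-spectrum is the saturation-weighted signal divided by the unsaturated
#' reference signal `S0`, sampled as a function of the saturation frequency
#' offset from water (in ppm). It is represented as a tibble with columns
#' `offset_ppm` and `z`, so z-spectra compose directly with dplyr verbs.
#'
#' @param offsets Numeric vector of frequency offsets in ppm, strictly
#'   increasing.
#' @param values Numeric vector of normalized signal values `Z = S_sat / S0`,
#'   same length as `offsets`, finite and non-negative.
#'
#' @return A tibble of class `zspectrum` with columns `offset_ppm` and `z`.
#' @examples
#' z_spectrum(c(-1, 0, 1), c(0.9, 0.2, 0.85))
#' @export
z_spectrum <- function(offsets, values) {
  offsets <- as.numeric(offsets)
  values <- as.numeric(values)
  if (length(offsets) == 0) {
    abort("`offsets` must not be empty.")
  }
  if (length(offsets) != length(values)) {
    abort("`offsets` and `values` must have the same length.")
  }
  if (anyNA(offsets) || any(!is.finite(offsets))) {
    abort("`offsets` must be finite.")
  }
  if (any(diff(offsets) <= 0)) {
    abort("`offsets` must be strictly increasing.")
  }
  if (anyNA(values) || any(!is.finite(values)) || any(values < 0)) {
    abort("`values` must be finite and non-negative.")
  }
  out <- tibble::tibble(offset_ppm = offsets, z = values)
  class(out) <- c("zspectrum", class(out))
  out
}

is_zspectrum <- function(x) {
  is.data.frame(x) && all(c("offset_ppm", "z") %in% names(x))
}

as_zspectrum <- function(x) {
  if (!is_zspectrum(x)) {
    abort("Expected a z-spectrum (data frame with columns `offset_ppm`, `z`).")
  }
  x
}

# cubic-spline interpolant of a z-spectrum; natural boundary conditions keep
# the interpolant tame at the sweep edges
zspec_interpolant <- function(spectrum) {
  spectrum <- as_zspectrum(spectrum)
  splinefun(spectrum$offset_ppm, spectrum$z, method = "natural")
}

#' Plot a z-spectrum
#'
#' @param object A `zspectrum` tibble.
#' @param ... Unused.
#' @return A ggplot object with the conventional reversed frequency axis.
#' @export
autoplot.zspectrum <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$offset_ppm, y = .data$z)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(
      x = "frequency offset from water (ppm)",
      y = expression(Z(omega) == S[sat] / S[0])
    ) +
    ggplot2::theme_minimal()
}
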