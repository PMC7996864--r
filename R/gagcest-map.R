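#' Per-pixel gagCEST (band-averaged MTRasym) map
#'
#' For every masked pixel: normalize the CEST stack by the unsaturated
#' reference S0, correct the z-spectrum by the pixel's B0 offset from the
#' WASSR-derived map, and average MTRasym over the GAG-specific band. Pixels
#' outside the mask, with non-positive S0, or with an invalid B0 estimate are
#' flagged invalid. Map values are not clipped: negative gagCEST values are
#' physically possible under noise and asymmetric magnetization transfer and
#' are retained.
#'
#' @param cest_stack Numeric array `H x W x n_offsets` of saturation-weighted
#'   signal.
#' @param offsets CEST frequency offsets, ppm.
#' @param s0_image `H x W` unsaturated reference image.
#' @param b0map A [estimate_b0_map()] result, or `NULL` to skip B0
#'   correction.
#' @param mask Logical `H x W` analysis mask; default all pixels.
#' @param band A [gag_band()].
#' @return A list of class `gagcest_map` with matrices `value` (percent, `NA`
#'   where invalid) and `valid`.
#' @export
gagcest_map <- function(cest_stack, offsets, s0_image, b0map = NULL,
                        mask = NULL, band = gag_band()) {
  dm <- dim(cest_stack)
  if (length(dm) != 3 || dm[3] != length(offsets)) {
    abort("`cest_stack` must be H x W x n_offsets matching `offsets`.")
  }
  if (!all(dim(s0_image) == dm[1:2])) {
    abort("`s0_image` dimensions must match the stack.")
  }
  if (!is.null(b0map) && !inherits(b0map, "b0_map")) {
    abort("`b0map` must be an estimate_b0_map() result or NULL.")
  }
  if (is.null(mask)) mask <- matrix(TRUE, dm[1], dm[2])

  band_idx <- which(offsets >= band$lower - 1e-9 & offsets <= band$upper + 1e-9)
  if (length(band_idx) == 0) {
    abort("No sampled offsets fall inside the GAG band.")
  }
  band_w <- offsets[band_idx]
  mirror_idx <- match_mirror(offsets, band_w)

  value <- matrix(NA_real_, dm[1], dm[2])
  valid <- matrix(FALSE, dm[1], dm[2])
  idx <- which(mask, arr.ind = TRUE)
  plane <- dm[1] * dm[2]
  koff <- (seq_len(dm[3]) - 1L) * plane
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1]
    j <- idx[k, 2]
    s0 <- s0_image[i, j]
    if (!is.finite(s0) || s0 <= 0) next
    delta <- 0
    if (!is.null(b0map)) {
      if (!isTRUE(b0map$valid[i, j])) next
      delta <- b0map$delta[i, j]
    }
    z <- cest_stack[(j - 1L) * dm[1] + i + koff] / s0
    if (any(!is.finite(z))) next
    if (delta != 0) {
      fz <- splinefun(offsets, z, method = "natural")
      rng <- range(offsets)
      z <- fz(pmin(pmax(offsets + delta, rng[1]), rng[2]))
    }
    asym <- if (anyNA(mirror_idx)) {
      fz2 <- splinefun(offsets, z, method = "natural")
      fz2(-band_w) - z[band_idx]
    } else {
      z[mirror_idx] - z[band_idx]
    }
    value[i, j] <- 100 * mean(asym)
    valid[i, j] <- TRUE
  }
  structure(list(value = value, valid = valid, band = band),
    class = "gagcest_map"
  )
}

# indices of the sampled offsets mirroring `band_w` about 0, NA where the
# mirror is not itself a sample point
match_mirror <- function(offsets, band_w) {
  vapply(band_w, function(w) {
    i <- match(TRUE, abs(offsets + w) < 1e-9)
    if (is.na(i)) NA_integer_ else i
  }, integer(1))
}

#' ROI-level gagCEST values for labeled disks
#'
#' Means of valid map pixels over each disk ROI and its NP/AF partition. A
#' partition with no valid pixels is reported as missing (`NA`), never as
#' zero.
#'
#' @param map A [gagcest_map()] result.
#' @param disks A disk ROI tibble as returned by [assign_levels()] /
#'   [split_np_af()] (columns `level`, `pixels`, optionally `np_pixels`,
#'   `af_pixels`).
#' @return A tibble with columns `level`, `region` (`whole`, `NP`, `AF`),
#'   `gagcest`, `n_pixels`.
#' @export
roi_gagcest <- function(map, disks) {
  if (!inherits(map, "gagcest_map")) abort("`map` must be a gagcest_map.")
  if (!is.data.frame(disks) || !all(c("level", "pixels") %in% names(disks))) {
    abort("`disks` must be a disk ROI tibble with `level` and `pixels`.")
  }
  dmap <- dim(map$value)
  roi_mean <- function(pix) {
    if (is.null(pix) || nrow(pix) == 0) {
      return(c(NA_real_, 0))
    }
    if (any(pix[, 1] < 1 | pix[, 1] > dmap[1] |
      pix[, 2] < 1 | pix[, 2] > dmap[2])) {
      abort("ROI pixels fall outside the map bounds.")
    }
    lin <- (pix[, 2] - 1L) * dmap[1] + pix[, 1]
    ok <- map$valid[lin]
    if (!any(ok)) {
      return(c(NA_real_, 0))
    }
    c(mean(map$value[lin][ok]), sum(ok))
  }
  purrr::map_dfr(seq_len(nrow(disks)), function(r) {
    parts <- list(whole = disks$pixels[[r]])
    parts$NP <- if ("np_pixels" %in% names(disks)) disks$np_pixels[[r]]
    parts$AF <- if ("af_pixels" %in% names(disks)) disks$af_pixels[[r]]
    purrr::imap_dfr(parts, function(pix, region) {
      m <- roi_mean(pix)
      tibble::tibble(
        level = disks$level[r], region = region,
        gagcest = m[1], n_pixels = as.integer(m[2])
      )
    })
  })
}

#' Plot a gagCEST map as a colour overlay
#'
#' Renders the valid map pixels with the conventional blue-low to red-high
#' colour scale over a grey S0 underlay.
#'
#' @param map A [gagcest_map()] result.
#' @param s0 Optional underlay image.
#' @param limits Colour scale limits in percent.
#' @return A ggplot object.
#' @export
plot_gagcest_map <- function(map, s0 = NULL, limits = c(-1, 4)) {
  df <- tibble::tibble(
    row = as.vector(row(map$value)),
    col = as.vector(col(map$value)),
    gagcest = as.vector(map$value)
  )
  p <- ggplot2::ggplot()
  if (!is.null(s0)) {
    bg <- tibble::tibble(
      row = as.vector(row(s0)), col = as.vector(col(s0)),
      s0 = as.vector(s0)
    )
    p <- p + ggplot2::geom_raster(
      data = bg, ggplot2::aes(x = .data$col, y = .data$row, alpha = .data$s0),
      fill = "grey30", show.legend = FALSE
    )
  }
  p +
    ggplot2::geom_raster(
      data = dplyr::filter(df, !is.na(.data$gagcest)),
      ggplot2::aes(x = .data$col, y = .data$row, fill = .data$gagcest)
    ) +
    ggplot2::scale_fill_gradientn(
      colours = c("blue", "cyan", "yellow", "red"),
      limits = limits, oob = scales_squish, name = "gagCEST (%)"
    ) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}

# minimal squish so we do not depend on scales directly at runtime
scales_squish <- function(x, range = c(0, 1)) {
  pmin(pmax(x, range[1]), range[2])
}
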