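#' Midsagittal lumbar phantom scene
#'
#' Geometry and ground truth for a synthetic midsagittal lumbar spine: six
#' stacked vertebral bodies with the five lumbar disks (L1/2-L5/S1) between
#' them, each disk split into a nucleus pulposus (NP) core and an annulus
#' fibrosus (AF) rim, over a smooth B0 inhomogeneity field. GAG pool
#' amplitudes may be given per region (length 1) or per disk (length 5,
#' cranial to caudal).
#'
#' @param height,width Image dimensions in pixels. Must be large enough that
#'   no disk touches the image border.
#' @param np_gag_amplitude,af_gag_amplitude GAG saturation depths for NP and
#'   AF tissue; length 1 or 5.
#' @param vertebra_mt_amplitude Broad symmetric MT pool depth in vertebral
#'   bone.
#' @param s0_disk,s0_vertebra,s0_background Unsaturated signal levels.
#' @param b0_field `"ramp"` (linear craniocaudal ramp over
#'   `±b0_range`), `"none"`, or a user-supplied `height x width` matrix of
#'   offsets in ppm.
#' @param b0_range Half-range of the built-in ramp field, ppm.
#' @param seed Integer seed recorded in the scene and used by
#'   [generate_phantom()] unless overridden.
#' @return A list of class `phantom_scene` including the label geometry:
#'   `labels` (0 background, 1 vertebra, 2 disk), `level` (1-5 cranial to
#'   caudal, 0 elsewhere), `np` (logical NP mask), and `b0` (ppm).
#' @export
phantom_scene <- function(height = 120, width = 48,
                          np_gag_amplitude = 0.0323,
                          af_gag_amplitude = 0.0185,
                          vertebra_mt_amplitude = 0.15,
                          s0_disk = 1, s0_vertebra = 0.6,
                          s0_background = 0.03,
                          b0_field = c("ramp", "none"),
                          b0_range = 0.3,
                          seed = 1L) {
  vert_h <- 12L
  disk_h <- 6L
  margin_r <- 9L
  margin_c <- 12L
  need_h <- 2L * margin_r + 6L * vert_h + 5L * disk_h
  if (height < need_h || width < 2L * margin_c + 24L) {
    abort(sprintf(
      "Scene too small: need at least %d x %d pixels so disks clear the border.",
      need_h, 2L * margin_c + 24L
    ))
  }
  np_gag <- rep_len(np_gag_amplitude, 5)
  af_gag <- rep_len(af_gag_amplitude, 5)
  if (any(np_gag < 0) || any(af_gag < 0)) abort("GAG amplitudes must be >= 0.")

  labels <- matrix(0L, height, width)
  level <- matrix(0L, height, width)
  np <- matrix(FALSE, height, width)
  vert_cols <- (margin_c + 1L):(margin_c + 24L)
  disk_cols <- (margin_c + 3L):(margin_c + 22L)
  np_cols <- (margin_c + 8L):(margin_c + 17L)
  for (k in 1:6) {
    r0 <- margin_r + (k - 1L) * (vert_h + disk_h)
    labels[(r0 + 1L):(r0 + vert_h), vert_cols] <- 1L
    if (k <= 5) {
      d0 <- r0 + vert_h
      rows <- (d0 + 1L):(d0 + disk_h)
      labels[rows, disk_cols] <- 2L
      level[rows, disk_cols] <- k
      np[rows[2:5], np_cols] <- TRUE
    }
  }

  if (is.matrix(b0_field)) {
    if (!all(dim(b0_field) == c(height, width))) {
      abort("`b0_field` matrix must be height x width.")
    }
    b0 <- b0_field
  } else {
    b0_field <- match.arg(b0_field)
    b0 <- switch(b0_field,
      none = matrix(0, height, width),
      ramp = matrix(seq(-b0_range, b0_range, length.out = height),
        height, width,
        byrow = FALSE
      )
    )
  }

  structure(
    list(
      height = height, width = width,
      labels = labels, level = level, np = np, b0 = b0,
      np_gag_amplitude = np_gag, af_gag_amplitude = af_gag,
      vertebra_mt_amplitude = vertebra_mt_amplitude,
      s0_disk = s0_disk, s0_vertebra = s0_vertebra,
      s0_background = s0_background,
      seed = as.integer(seed)
    ),
    class = "phantom_scene"
  )
}

# forward model for a vector of pixels sharing a pool but with per-pixel b0:
# returns length(b0) x length(offsets) matrix
pool_z_matrix <- function(pool, offsets, b0) {
  n <- length(offsets)
  m <- length(b0)
  W <- matrix(offsets, m, n, byrow = TRUE)
  X <- W - b0
  lor <- function(x, a, w) {
    hw2 <- (w / 2)^2
    a * hw2 / (hw2 + x^2)
  }
  1 - lor(X, pool$water_amplitude, pool$water_width) -
    lor(X - pool$gag_center, pool$gag_amplitude, pool$gag_width) -
    lor(X, pool$mt_amplitude, pool$mt_width)
}

#' Generate a synthetic CEST/WASSR acquisition of a lumbar phantom
#'
#' Evaluates the sum-of-Lorentzians forward model per pixel under the scene's
#' B0 field, for both the CEST sweep and the narrow WASSR sweep, and adds
#' Gaussian noise (as a fraction of S0) in the signal domain:
#' `S = S0 * (Z + noise)`. Ground truth (labels, disk levels, NP mask, B0
#' field, expected per-pixel gagCEST in percent) is returned aligned
#' pixelwise.
#'
#' @param scene A [phantom_scene()].
#' @param acq An [acquisition_spec()]; its `noise_sd` sets the noise level.
#' @param seed Integer seed; defaults to the scene's.
#' @return A list of class `cest_phantom` with elements `cest`, `wassr`
#'   (arrays `H x W x n`), `s0` (matrix), `cest_offsets`, `wassr_offsets`,
#'   `truth` (list: `labels`, `level`, `np`, `b0`, `gagcest`), `scene`, `acq`.
#' @examples
#' ph <- generate_phantom(phantom_scene(), acquisition_spec(noise_sd = 0))
#' table(ph$truth$labels)
#' @export
generate_phantom <- function(scene = phantom_scene(),
                             acq = acquisition_spec(),
                             seed = scene$seed) {
  if (!inherits(scene, "phantom_scene")) abort("`scene` must be a phantom_scene.")
  if (!inherits(acq, "acquisition_spec")) abort("`acq` must be an acquisition_spec.")
  h <- scene$height
  w <- scene$width
  ncest <- length(acq$cest_offsets)
  nwassr <- length(acq$wassr_offsets)

  s0 <- matrix(scene$s0_background, h, w)
  s0[scene$labels == 1L] <- scene$s0_vertebra
  s0[scene$labels == 2L] <- scene$s0_disk

  cest <- array(1, dim = c(h, w, ncest)) # background: no saturation
  wassr <- array(1, dim = c(h, w, nwassr))
  gag_truth <- matrix(0, h, w)

  fill <- function(pix, pool) {
    if (length(pix) == 0) {
      return()
    }
    b0 <- scene$b0[pix]
    zc <- pool_z_matrix(pool, acq$cest_offsets, b0)
    zw <- 1 - lorentzian(
      outer(b0, acq$wassr_offsets, function(b, o) o - b), 0.85, 0.3
    )
    for (k in seq_len(ncest)) cest[pix + (k - 1L) * h * w] <<- zc[, k]
    for (k in seq_len(nwassr)) wassr[pix + (k - 1L) * h * w] <<- zw[, k]
    gag_truth[pix] <<- pool_band_gagcest(pool, acq$cest_offsets)
  }

  vert_pool <- pool_model(
    water_amplitude = 0.75, water_width = 1.4,
    mt_amplitude = scene$vertebra_mt_amplitude, mt_width = 6
  )
  fill(which(scene$labels == 1L), vert_pool)
  for (k in 1:5) {
    disk <- scene$level == k
    for (region in c("np", "af")) {
      pix <- which(disk & (if (region == "np") scene$np else !scene$np))
      amp <- if (region == "np") {
        scene$np_gag_amplitude[k]
      } else {
        scene$af_gag_amplitude[k]
      }
      fill(pix, pool_model(gag_amplitude = amp))
    }
  }

  if (acq$noise_sd > 0) {
    noise <- with_optional_seed(
      seed,
      rnorm(length(cest) + length(wassr) + length(s0), sd = acq$noise_sd)
    )
    cest <- cest + array(noise[seq_along(cest)], dim = dim(cest))
    wassr <- wassr +
      array(noise[length(cest) + seq_along(wassr)], dim = dim(wassr))
    # the unsaturated reference is acquired with the same noise floor
    s0 <- pmax(
      s0 + matrix(noise[length(cest) + length(wassr) + seq_along(s0)], h, w) *
        max(s0),
      1e-6
    )
  }
  cest <- pmax(cest, 0)
  wassr <- pmax(wassr, 0)

  # to signal domain
  for (k in seq_len(ncest)) cest[, , k] <- cest[, , k] * s0
  for (k in seq_len(nwassr)) wassr[, , k] <- wassr[, , k] * s0

  structure(
    list(
      cest = cest, wassr = wassr, s0 = s0,
      cest_offsets = acq$cest_offsets, wassr_offsets = acq$wassr_offsets,
      truth = list(
        labels = scene$labels, level = scene$level, np = scene$np,
        b0 = scene$b0, gagcest = gag_truth
      ),
      scene = scene, acq = acq, seed = as.integer(seed)
    ),
    class = "cest_phantom"
  )
}

#' Foreground mask of a phantom acquisition
#'
#' Pixels whose unsaturated signal exceeds a fraction of the image maximum;
#' the analysis mask used by the pipeline stages.
#'
#' @param s0 Unsaturated reference image.
#' @param threshold Fraction of `max(s0)`.
#' @return Logical matrix.
#' @export
foreground_mask <- function(s0, threshold = 0.2) {
  s0 > threshold * max(s0)
}
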