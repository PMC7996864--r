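#' Write an image stack as NIfTI with a JSON offsets sidecar
#'
#' Stacks are stored `H x W x n_offsets` in a single NIfTI volume; the
#' per-volume saturation offsets go to a JSON sidecar
#' `{"offsets_ppm": [...]}` next to it.
#'
#' @param stack Numeric array `H x W x n_offsets` (or a matrix for a single
#'   volume such as S0).
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @param offsets_ppm Frequency offsets, ppm; omit for offset-free volumes.
#' @param pixel_size In-plane pixel size, mm.
#' @return `path`, invisibly.
#' @export
write_cest_stack <- function(stack, path, offsets_ppm = NULL,
                             pixel_size = c(1.6, 1.6)) {
  img <- RNifti::asNifti(stack, pixdim = c(pixel_size, 1)[1:min(3, length(dim(stack)))])
  RNifti::writeNifti(img, path)
  if (!is.null(offsets_ppm)) {
    jsonlite::write_json(
      list(offsets_ppm = offsets_ppm),
      sidecar_path(path),
      auto_unbox = FALSE, digits = NA
    )
  }
  invisible(path)
}

#' Read an image stack and its offsets sidecar
#'
#' @param path NIfTI path written by [write_cest_stack()].
#' @return List with `stack` (array) and `offsets_ppm` (numeric or `NULL` if
#'   no sidecar exists).
#' @export
read_cest_stack <- function(path) {
  stack <- as.array(RNifti::readNifti(path))
  sc <- sidecar_path(path)
  offsets <- NULL
  if (file.exists(sc)) {
    offsets <- as.numeric(jsonlite::read_json(sc, simplifyVector = TRUE)$offsets_ppm)
  }
  list(stack = stack, offsets_ppm = offsets)
}

sidecar_path <- function(path) {
  paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")
}

#' Write / read cohort observation tables
#'
#' Observation tables are plain CSV with the standard column set; factors
#' are restored on read.
#'
#' @param obs Observation tibble as from [generate_cohort()].
#' @param path CSV path.
#' @return `write_observations()`: `path`, invisibly; `read_observations()`:
#'   a tibble.
#' @export
write_observations <- function(obs, path) {
  readr::write_csv(obs, path)
  invisible(path)
}

#' @rdname write_observations
#' @export
read_observations <- function(path) {
  obs <- readr::read_csv(path, show_col_types = FALSE)
  dplyr::mutate(obs,
    cohort = factor(.data$cohort, levels = cohort_levels()),
    segment = factor(.data$segment, levels = lumbar_levels()),
    region = factor(.data$region),
    adjacency = factor(
      .data$adjacency,
      levels = c("extruded", "adjacent", "non-adjacent", "not-applicable")
    )
  )
}
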