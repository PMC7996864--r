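#' Pixel features for disk/non-disk classification
#'
#' Default feature set for the Bayes classifier: unsaturated signal intensity
#' (normalized to the image maximum), mean normalized z-spectrum value over
#' the weakly saturated far offsets (|offset| >= `far_ppm`), and the pixel
#' row coordinate normalized to \[0, 1\].
#'
#' @param cest_stack `H x W x n_offsets` signal array.
#' @param offsets CEST offsets, ppm.
#' @param s0 Unsaturated reference image.
#' @param far_ppm Offsets at or beyond this magnitude count as weakly
#'   saturated.
#' @return `H x W x 3` feature array (dimnames on the third axis).
#' @export
pixel_features <- function(cest_stack, offsets, s0, far_ppm = 2.5) {
  dm <- dim(cest_stack)
  far <- which(abs(offsets) >= far_ppm)
  if (length(far) == 0) abort("No offsets at |offset| >= far_ppm.")
  zfar <- apply(cest_stack[, , far, drop = FALSE], c(1, 2), mean)
  zfar <- ifelse(s0 > 0, zfar / s0, 0)
  rowpos <- matrix(
    (seq_len(dm[1]) - 1) / max(1, dm[1] - 1), dm[1], dm[2]
  )
  out <- array(c(s0 / max(s0), zfar, rowpos), dim = c(dm[1], dm[2], 3))
  dimnames(out) <- list(NULL, NULL, c("s0_norm", "z_far", "row_norm"))
  out
}

#' Fit a Gaussian Bayes pixel classifier
#'
#' Class-conditional multivariate Gaussian model with class priors: each
#' class gets a feature mean vector and covariance matrix; posteriors follow
#' from Bayes' rule. Zero-variance (degenerate) features are handled by
#' ridge-regularizing the covariance, with a warning.
#'
#' @param features Numeric matrix or data frame, one row per labeled pixel.
#' @param labels Class labels, length `nrow(features)`; at least 2 classes,
#'   each with more than one example.
#' @param priors Named class prior probabilities summing to 1; default the
#'   empirical class frequencies.
#' @param reg Ridge added to a covariance diagonal when it is not positive
#'   definite.
#' @return A list of class `bayes_classifier` with per-class `means`,
#'   `covariances`, `priors`, and the training accuracy.
#' @examples
#' x <- matrix(c(rnorm(50), rnorm(50, 3)), ncol = 1)
#' fit_bayes(x, rep(c("a", "b"), each = 50))
#' @export
fit_bayes <- function(features, labels, priors = NULL, reg = 1e-6) {
  x <- as.matrix(features)
  storage.mode(x) <- "double"
  if (any(!is.finite(x))) abort("Features must be finite.")
  labels <- as.character(labels)
  if (nrow(x) != length(labels)) abort("One label per feature row required.")
  classes <- sort(unique(labels))
  if (length(classes) < 2) abort("At least 2 classes required.")
  counts <- table(labels)
  if (any(counts < 2)) {
    abort(paste0(
      "Each class needs at least 2 training examples; too few for: ",
      paste(names(counts)[counts < 2], collapse = ", ")
    ))
  }
  if (is.null(priors)) {
    priors <- as.numeric(counts[classes]) / nrow(x)
    names(priors) <- classes
  } else {
    if (is.null(names(priors)) || !setequal(names(priors), classes)) {
      abort("`priors` must be named with the class labels.")
    }
    priors <- priors[classes]
    if (abs(sum(priors) - 1) > 1e-8) abort("`priors` must sum to 1.")
  }
  means <- list()
  covs <- list()
  for (cl in classes) {
    xc <- x[labels == cl, , drop = FALSE]
    means[[cl]] <- colMeans(xc)
    S <- stats::cov(xc)
    if (any(!is.finite(S)) || min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) < reg) {
      warn(paste0("Degenerate covariance for class '", cl, "'; regularizing."))
      S <- S + diag(reg, ncol(x))
    }
    covs[[cl]] <- S
  }
  obj <- structure(
    list(
      classes = classes, means = means, covariances = covs, priors = priors,
      features = colnames(x) %||% paste0("f", seq_len(ncol(x)))
    ),
    class = "bayes_classifier"
  )
  obj$training_accuracy <-
    mean(predict_class(obj, x) == labels)
  obj
}

# log multivariate normal density, rows of x
log_dmvnorm <- function(x, mu, sigma) {
  p <- length(mu)
  ch <- chol(sigma)
  xc <- sweep(x, 2, mu)
  q <- backsolve(ch, t(xc), transpose = TRUE)
  -0.5 * colSums(q^2) - sum(log(diag(ch))) - 0.5 * p * log(2 * pi)
}

#' Posterior class probabilities from a Bayes classifier
#'
#' @param object A [fit_bayes()] classifier.
#' @param newdata Feature matrix, columns in training order.
#' @param ... Unused.
#' @return Matrix of posteriors, one column per class, rows summing to 1.
#' @export
predict.bayes_classifier <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  storage.mode(x) <- "double"
  ll <- vapply(
    object$classes,
    function(cl) {
      log(object$priors[[cl]]) +
        log_dmvnorm(x, object$means[[cl]], object$covariances[[cl]])
    },
    numeric(nrow(x))
  )
  ll <- matrix(ll, nrow = nrow(x), dimnames = list(NULL, object$classes))
  m <- apply(ll, 1, max)
  post <- exp(ll - m)
  post / rowSums(post)
}

predict_class <- function(object, x) {
  post <- predict.bayes_classifier(object, x)
  object$classes[max.col(post, ties.method = "first")]
}

#' Classify pixels into disk / non-disk
#'
#' Applies a fitted Bayes classifier to a feature image; a pixel joins the
#' binary disk mask iff its posterior probability of the disk class exceeds
#' 0.5. Pixels with non-finite features or outside the mask are excluded.
#'
#' @param classifier A [fit_bayes()] model containing a `disk` class.
#' @param feature_image `H x W x p` feature array as from [pixel_features()].
#' @param mask Logical analysis mask; default all pixels.
#' @param disk_class Name of the disk class in the classifier.
#' @return List with `posterior` (`H x W` matrix of disk posteriors, `NA`
#'   outside mask) and `disk_mask` (logical matrix).
#' @export
classify_pixels <- function(classifier, feature_image, mask = NULL,
                            disk_class = "disk") {
  if (!inherits(classifier, "bayes_classifier")) {
    abort("`classifier` must come from fit_bayes().")
  }
  if (!disk_class %in% classifier$classes) {
    abort(paste0("Classifier has no class '", disk_class, "'."))
  }
  dm <- dim(feature_image)
  if (length(dm) != 3) abort("`feature_image` must be H x W x p.")
  if (is.null(mask)) mask <- matrix(TRUE, dm[1], dm[2])
  x <- matrix(feature_image, nrow = dm[1] * dm[2], ncol = dm[3])
  use <- as.vector(mask) & apply(is.finite(x), 1, all)
  posterior <- matrix(NA_real_, dm[1], dm[2])
  if (any(use)) {
    post <- predict.bayes_classifier(classifier, x[use, , drop = FALSE])
    posterior[use] <- post[, disk_class]
  }
  disk_mask <- !is.na(posterior) & posterior > 0.5
  list(posterior = posterior, disk_mask = disk_mask)
}

#' Label connected components of a binary mask
#'
#' Breadth-first labelling under 4- or 8-connectivity.
#'
#' @param mask Logical matrix.
#' @param connectivity 4 (edge-sharing neighbours) or 8.
#' @return Integer matrix of component labels (0 = background).
#' @export
label_components <- function(mask, connectivity = 4) {
  if (!connectivity %in% c(4, 8)) abort("`connectivity` must be 4 or 8.")
  h <- nrow(mask)
  w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nbr_dr <- if (connectivity == 4) {
    c(-1L, 1L, 0L, 0L)
  } else {
    c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L)
  }
  nbr_dc <- if (connectivity == 4) {
    c(0L, 0L, -1L, 1L)
  } else {
    c(0L, 0L, -1L, 1L, -1L, 1L, -1L, 1L)
  }
  current <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    current <- current + 1L
    queue <- start
    lab[start] <- current
    while (length(queue) > 0) {
      p <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- ((p - 1L) %% h) + 1L
      c <- ((p - 1L) %/% h) + 1L
      for (k in seq_along(nbr_dr)) {
        rr <- r + nbr_dr[k]
        cc <- c + nbr_dc[k]
        if (rr >= 1L && rr <= h && cc >= 1L && cc <= w) {
          q <- (cc - 1L) * h + rr
          if (mask[q] && lab[q] == 0L) {
            lab[q] <- current
            queue <- c(queue, q)
          }
        }
      }
    }
  }
  lab
}

#' Extract candidate disk ROIs from a binary disk mask
#'
#' Connected components filtered by pixel area and bounding-box elongation,
#' sorted by centroid craniocaudal (row) position. By default exactly five
#' surviving components are required — the five lumbar disks — and any other
#' count is an error listing the candidates, mirroring the need for visual
#' confirmation when automatic identification fails.
#'
#' @param mask Logical disk mask.
#' @param min_area,max_area Component area bounds in pixels.
#' @param max_elongation Maximum bounding-box aspect ratio (long/short side).
#' @param connectivity Passed to [label_components()].
#' @param expect_n Required component count after filtering, or `NULL` to
#'   return whatever survives.
#' @return Tibble with one row per component: `area`, `centroid_row`,
#'   `centroid_col`, `pixels` (list of `n x 2` row/col matrices), sorted
#'   cranial to caudal.
#' @export
extract_disks <- function(mask, min_area = 20, max_area = 2000,
                          max_elongation = 8, connectivity = 4,
                          expect_n = 5) {
  lab <- label_components(mask, connectivity)
  n <- max(lab)
  comps <- purrr::map_dfr(seq_len(n), function(k) {
    pix <- which(lab == k, arr.ind = TRUE)
    colnames(pix) <- c("row", "col")
    bbox <- c(diff(range(pix[, 1])) + 1, diff(range(pix[, 2])) + 1)
    tibble::tibble(
      area = nrow(pix),
      centroid_row = mean(pix[, 1]),
      centroid_col = mean(pix[, 2]),
      elongation = max(bbox) / min(bbox),
      pixels = list(pix)
    )
  })
  kept <- dplyr::filter(
    comps,
    .data$area >= min_area, .data$area <= max_area,
    .data$elongation <= max_elongation
  )
  kept <- dplyr::arrange(kept, .data$centroid_row)
  if (!is.null(expect_n) && nrow(kept) != expect_n) {
    abort(paste0(
      "Automatic disk identification found ", nrow(kept), " candidate",
      if (nrow(kept) == 1) "" else "s", " (expected ", expect_n, "). ",
      "Candidate areas: ",
      paste(kept$area, collapse = ", "), "."
    ))
  }
  dplyr::select(kept, -"elongation")
}

#' Lumbar level labels
#' @return Character vector `L1/2` ... `L5/S1`, cranial to caudal.
#' @export
lumbar_levels <- function() {
  c("L1/2", "L2/3", "L3/4", "L4/5", "L5/S1")
}

#' Assign lumbar segment labels to extracted disks
#'
#' Labels the five disks L1/2 through L5/S1 in cranial-to-caudal order of
#' their centroid rows (increasing row = caudal).
#'
#' @param disks Tibble from [extract_disks()]; must have exactly 5 rows.
#' @return The tibble with a `level` factor column, sorted cranially.
#' @export
assign_levels <- function(disks) {
  if (nrow(disks) != 5) {
    abort(paste0("Expected exactly 5 disks, got ", nrow(disks), "."))
  }
  disks <- dplyr::arrange(disks, .data$centroid_row)
  disks$level <- factor(lumbar_levels(), levels = lumbar_levels())
  dplyr::relocate(disks, "level")
}

#' Partition disk ROIs into nucleus pulposus and annulus fibrosus
#'
#' Within each pixel row of a disk, the central fraction `fraction` of that
#' row's anteroposterior (column) extent becomes NP; the remainder is AF. A
#' disk too narrow to partition (< 4 pixels wide) keeps whole-disk pixels
#' only, with the partitions flagged missing; an empty AF (e.g. `fraction =
#' 1`) is likewise flagged.
#'
#' @param disks Disk ROI tibble with a `pixels` list-column.
#' @param fraction Central AP fraction assigned to the NP.
#' @return The tibble with `np_pixels`, `af_pixels` list-columns and a
#'   logical `partition_ok` flag.
#' @export
split_np_af <- function(disks, fraction = 0.5) {
  if (fraction <= 0 || fraction > 1) abort("`fraction` must be in (0, 1].")
  parts <- purrr::map(disks$pixels, function(pix) {
    if (diff(range(pix[, 2])) + 1 < 4) {
      return(list(np = NULL, af = NULL, ok = FALSE))
    }
    is_np <- logical(nrow(pix))
    for (r in unique(pix[, 1])) {
      sel <- which(pix[, 1] == r)
      cols <- pix[sel, 2]
      m <- length(cols)
      n_np <- round(fraction * m)
      if (n_np == 0) next
      skip <- floor((m - n_np) / 2)
      is_np[sel[order(cols)][(skip + 1):(skip + n_np)]] <- TRUE
    }
    np <- pix[is_np, , drop = FALSE]
    af <- pix[!is_np, , drop = FALSE]
    list(np = np, af = af, ok = nrow(np) > 0 && nrow(af) > 0)
  })
  disks$np_pixels <- purrr::map(parts, "np")
  disks$af_pixels <- purrr::map(parts, "af")
  disks$partition_ok <- purrr::map_lgl(parts, "ok")
  if (!all(disks$partition_ok)) {
    warn("Some disks could not be partitioned into NP/AF; flagged missing.")
  }
  disks
}

#' Dice overlap coefficient between two pixel sets
#'
#' @param a,b Logical matrices of equal dimension, or `n x 2` pixel index
#'   matrices.
#' @return Dice coefficient in \[0, 1\].
#' @export
dice <- function(a, b) {
  as_set <- function(x) {
    if (is.matrix(x) && ncol(x) == 2 && !is.logical(x)) {
      paste(x[, 1], x[, 2])
    } else {
      which(as.vector(x))
    }
  }
  sa <- as_set(a)
  sb <- as_set(b)
  if (length(sa) + length(sb) == 0) {
    return(NA_real_)
  }
  2 * length(intersect(sa, sb)) / (length(sa) + length(sb))
}
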