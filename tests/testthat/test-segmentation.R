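test_that("fitted 1-D boundary sits at the analytic equal-posterior point", {
  set.seed(31)
  x <- matrix(c(rnorm(400, 0, 1), rnorm(400, 4, 1)), ncol = 1)
  lab <- rep(c("a", "b"), each = 400)
  cl <- fit_bayes(x, lab)
  post_diff <- function(v) {
    p <- predict(cl, matrix(v, 1, 1))
    p[1, "a"] - p[1, "b"]
  }
  boundary <- stats::uniroot(post_diff, c(0, 4))$root
  # analytic point for equal variances and priors: midpoint of class means
  midpoint <- (cl$means$a + cl$means$b) / 2
  expect_lt(abs(boundary - midpoint) / 4, 0.02)
  expect_gt(cl$training_accuracy, 0.95)
})

test_that("degenerate training sets are rejected or regularized", {
  expect_error(
    fit_bayes(matrix(c(0, 1), ncol = 1), c("a", "b")),
    "at least 2 training examples"
  )
  expect_error(fit_bayes(matrix(rnorm(4), ncol = 1), rep("a", 4)), "2 classes")
  set.seed(30)
  expect_warning(
    fit_bayes(matrix(c(rep(0, 5), rnorm(5)), ncol = 1),
      rep(c("a", "b"), each = 5)),
    "regulariz"
  )
})

test_that("identical class distributions return the priors as posteriors", {
  x <- matrix(rep(c(1, 2, 1, 2), 2), ncol = 1)
  lab <- rep(c("a", "b"), each = 4)
  cl <- suppressWarnings(fit_bayes(x, lab, priors = c(a = 0.7, b = 0.3)))
  post <- predict(cl, matrix(c(1, 1.5, 2), ncol = 1))
  expect_equal(post[, "a"], rep(0.7, 3), tolerance = 1e-9)
})

test_that("raising a class prior moves the boundary toward the other class", {
  set.seed(32)
  x <- matrix(c(rnorm(300, 0), rnorm(300, 3)), ncol = 1)
  lab <- rep(c("disk", "other"), each = 300)
  boundary_at <- function(p_disk) {
    cl <- fit_bayes(x, lab, priors = c(disk = p_disk, other = 1 - p_disk))
    stats::uniroot(function(v) {
      pr <- predict(cl, matrix(v, 1, 1))
      pr[1, "disk"] - 0.5
    }, c(-2, 5))$root
  }
  bounds <- vapply(c(0.1, 0.5, 0.9), boundary_at, numeric(1))
  # growing disk prior pushes the threshold toward the other class's mean
  expect_true(all(diff(bounds) > 0))
})

test_that("classifier agrees with an independent quadratic discriminant", {
  skip_if_not_installed("MASS")
  set.seed(33)
  x <- cbind(
    c(rnorm(200, 0, 1), rnorm(200, 2.5, 1.5)),
    c(rnorm(200, 1, 0.5), rnorm(200, -1, 1))
  )
  lab <- rep(c("a", "b"), each = 200)
  cl <- fit_bayes(x, lab)
  q <- MASS::qda(x, grouping = lab)
  new <- cbind(seq(-2, 4, length.out = 50), seq(2, -2, length.out = 50))
  expect_equal(
    unname(predict(cl, new)[, "a"]),
    unname(stats::predict(q, new)$posterior[, "a"]),
    tolerance = 1e-6
  )
})

test_that("phantom pixels classify to >= 95 % accuracy and the mask is clean", {
  ph <- noiseless_phantom()
  mask <- foreground_mask(ph$s0)
  feat <- pixel_features(ph$cest, ph$cest_offsets, ph$s0)
  train <- generate_phantom(phantom_scene(), acquisition_spec(noise_sd = 0.01),
    seed = 77
  )
  feat_tr <- pixel_features(train$cest, train$cest_offsets, train$s0)
  idx <- which(foreground_mask(train$s0))
  cl <- fit_bayes(
    matrix(feat_tr, ncol = 3)[idx, ],
    ifelse(train$truth$labels[idx] == 2L, "disk", "other")
  )
  seg <- classify_pixels(cl, feat, mask)
  truth <- ph$truth$labels == 2
  acc <- mean((seg$disk_mask == truth)[mask])
  expect_gte(acc, 0.95)
  expect_true(all(seg$posterior[mask] >= 0 & seg$posterior[mask] <= 1))
  # all-background image yields an empty mask
  empty <- classify_pixels(cl, feat, mask = matrix(FALSE, nrow(mask), ncol(mask)))
  expect_equal(sum(empty$disk_mask), 0)
})

test_that("connected components respect the chosen connectivity", {
  m <- matrix(FALSE, 4, 4)
  m[1, 1] <- TRUE
  m[2, 2] <- TRUE # diagonal touch only
  expect_equal(max(label_components(m, 4)), 2)
  expect_equal(max(label_components(m, 8)), 1)
})

test_that("disk extraction finds exactly five ordered disks on the phantom", {
  ph <- noiseless_phantom()
  disks <- extract_disks(ph$truth$labels == 2)
  expect_equal(nrow(disks), 5)
  expect_true(all(diff(disks$centroid_row) > 0))
  labeled <- assign_levels(disks)
  expect_equal(as.character(labeled$level), lumbar_levels())

  # merging two disks breaks automatic identification loudly
  merged <- ph$truth$labels == 2
  bridge_rows <- range(which(apply(merged, 1, any)))
  cols <- which(merged[bridge_rows[1], ])
  merged[bridge_rows[1]:bridge_rows[2], cols[1]] <- TRUE
  expect_error(extract_disks(merged), "candidate")

  # widening the area filter on a speckled mask admits extra components
  speckled <- ph$truth$labels == 2
  speckled[1, c(2, 10, 20)] <- TRUE
  comps <- extract_disks(speckled,
    min_area = 0, max_area = Inf,
    max_elongation = Inf, expect_n = NULL
  )
  expect_gte(nrow(comps), 5)
})

test_that("level assignment re-sorts shuffled and jittered inputs", {
  ph <- noiseless_phantom()
  disks <- extract_disks(ph$truth$labels == 2)
  shuffled <- disks[c(3, 1, 5, 2, 4), ]
  expect_equal(
    as.character(assign_levels(shuffled)$level),
    lumbar_levels()
  )
  jittered <- shuffled
  jittered$centroid_row <- jittered$centroid_row + runif(5, -1, 1)
  relab <- assign_levels(jittered)
  expect_equal(order(relab$centroid_row), 1:5)
  expect_error(assign_levels(disks[1:4, ]), "5")
})

test_that("NP/AF split takes the central AP fraction row by row", {
  pix <- as.matrix(expand.grid(row = 1:3, col = 1:10))
  colnames(pix) <- c("row", "col")
  disks <- tibble::tibble(level = "L1/2", pixels = list(pix))
  split <- split_np_af(disks, fraction = 0.5)
  np_cols <- sort(unique(split$np_pixels[[1]][, 2]))
  expect_equal(np_cols, 3:7) # central 5 of 10 columns (left-biased centring)
  expect_equal(nrow(split$np_pixels[[1]]) + nrow(split$af_pixels[[1]]), 30)

  # fraction 1 leaves no AF and is flagged
  expect_warning(all_np <- split_np_af(disks, fraction = 1), "flagged")
  expect_false(all_np$partition_ok[1])

  # too-narrow disks cannot be partitioned
  narrow <- tibble::tibble(
    level = "L1/2",
    pixels = list(cbind(row = 1:5, col = rep(2, 5)))
  )
  expect_warning(out <- split_np_af(narrow), "flagged")
  expect_false(out$partition_ok[1])
})

test_that("automatic NP/AF partition overlaps the phantom truth (Dice >= 0.7)", {
  ph <- noiseless_phantom()
  disks <- split_np_af(assign_levels(extract_disks(ph$truth$labels == 2)))
  for (r in 1:5) {
    lv_mask <- ph$truth$level == r
    np_truth <- which(lv_mask & ph$truth$np, arr.ind = TRUE)
    af_truth <- which(lv_mask & !ph$truth$np, arr.ind = TRUE)
    expect_gte(dice(disks$np_pixels[[r]], np_truth), 0.7)
    expect_gte(dice(disks$af_pixels[[r]], af_truth), 0.7)
  }
})

test_that("dichotomized Pfirrmann grades follow the 2/3 boundary", {
  expect_equal(
    as.character(dichotomize_pfirrmann(c(1, 2, 3, 5))),
    c("non-degenerated", "non-degenerated", "degenerated", "degenerated")
  )
  expect_error(dichotomize_pfirrmann(6), "1-5")
  expect_error(dichotomize_pfirrmann(2.5), "1-5")
})
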