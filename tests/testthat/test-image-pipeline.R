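test_that("top-hat preprocessing zeroes flat images and keeps small bright features", {
  expect_true(all(preprocess(matrix(0.5, 40, 40), 10) == 0))
  img <- matrix(0.1, 60, 60)
  d <- sqrt(outer((1:60 - 30)^2, (1:60 - 30)^2, `+`))
  img[d <= 3] <- 0.8
  ph <- preprocess(img, structuring_radius = 10)
  expect_gt(max(ph[d <= 2]), 0.9)      # feature survives (rescaled to ~1)
  expect_lt(max(ph[d > 15]), 0.05)     # background suppressed
  expect_error(preprocess(matrix(numeric(0), 0, 0)), "empty")
  expect_error(preprocess(img, 0.5), "structuring_radius")
})

test_that("top-hat suppresses a smooth illumination gradient under the dots", {
  h <- 80; w <- 80
  grad <- matrix(rep(seq(0, 0.3, length.out = w), each = h), h, w)
  img <- grad
  centers <- rbind(c(20, 20), c(20, 60), c(60, 20), c(60, 60), c(40, 40))
  d_all <- matrix(Inf, h, w)
  for (k in 1:5) {
    d <- sqrt(outer((1:h - centers[k, 1])^2, (1:w - centers[k, 2])^2, `+`))
    img[d <= 4] <- img[d <= 4] + 0.5
    d_all <- pmin(d_all, d)
  }
  ph <- preprocess(img, structuring_radius = 8)
  # oracle: white top-hat is the image minus its morphological opening
  kern <- EBImage::makeBrush(17, "disc")
  oracle <- img - EBImage::opening(img, kern)
  expect_equal(ph, oracle / max(oracle), tolerance = 1e-12)
  bg <- ph[d_all > 12]
  dot <- ph[d_all <= 2]
  expect_lt(max(bg), 0.1 * max(dot))
})

test_that("bright-pixel detection matches foreground and flags flat images", {
  bin <- matrix(0, 20, 20); bin[5:8, 5:8] <- 1
  px <- detect_bright_pixels(bin)
  expect_equal(nrow(px$coords), 16L)
  expect_true(all(px$coords[, 1] %in% 5:8 & px$coords[, 2] %in% 5:8))
  expect_warning(px0 <- detect_bright_pixels(matrix(0, 10, 10)), "flat")
  expect_equal(length(px0), 0L)
})

test_that("bright pixels on a synthetic lattice fall inside true dot masks", {
  eye <- generate_eye_image(lattice_spec(7, 7), degeneration_spec(seed = 5))
  ph <- preprocess(eye$image, 8)
  px <- detect_bright_pixels(ph)
  cent <- eye$truth$true_centroids
  in_dot <- vapply(seq_len(nrow(px$coords)), function(i) {
    any(sqrt((cent[, 1] - px$coords[i, 1])^2 +
               (cent[, 2] - px$coords[i, 2])^2) <= eye$truth$lattice$dot_radius + 0.5)
  }, logical(1))
  expect_gt(mean(in_dot), 0.95)
})

test_that("centroid-distance pruning uses the interpolated quantile and keeps ties", {
  # 10 collinear pixels: distances {4.5, 3.5, 2.5, 1.5, 0.5} x 2,
  # 0.8 quantile (type 7) = 3.7, so the two pixels at 4.5 are discarded
  px <- pixel_set(cbind(rep(3L, 10), 1:10), c(5L, 12L))
  kept <- prune_by_centroid_distance(px, 0.8)
  expect_equal(nrow(kept$coords), 8L)
  expect_equal(sort(kept$coords[, 2]), 2:9)

  # ring: all pixels equidistant, all retained
  theta <- seq(0, 2 * pi, length.out = 13)[-13]
  ring <- unique(cbind(round(25 + 10 * sin(theta)), round(25 + 10 * cos(theta))))
  pr <- pixel_set(ring, c(50L, 50L))
  expect_equal(length(prune_by_centroid_distance(pr, 0.8)), nrow(ring))

  single <- pixel_set(cbind(5L, 5L), c(10L, 10L))
  expect_equal(length(prune_by_centroid_distance(single, 0.8)), 1L)
  expect_error(prune_by_centroid_distance(pixel_set(matrix(integer(0), ncol = 2),
                                                    c(5L, 5L))), "empty")
})

test_that("pruning retains a fraction within 1/n of q for distinct distances", {
  set.seed(7)
  for (rep in 1:5) {
    coords <- unique(cbind(sample(1:200, 400, TRUE), sample(1:200, 400, TRUE)))
    px <- pixel_set(coords, c(200L, 200L))
    for (q in c(0.5, 0.8, 0.9)) {
      kept <- prune_by_centroid_distance(px, q)
      expect_lt(abs(length(kept) / length(px) - q), 1 / length(px) + 1e-9)
    }
  }
})

test_that("confidence ellipse recovers shape, is equivariant, and rejects degenerate input", {
  set.seed(11)
  # uniform disk -> near-unit axis ratio
  n <- 8000
  r <- sqrt(runif(n)); a <- runif(n, 0, 2 * pi)
  disk <- unique(cbind(as.integer(round(100 + 60 * r * sin(a))),
                       as.integer(round(100 + 60 * r * cos(a)))))
  e_disk <- fit_confidence_ellipse(pixel_set(disk, c(220L, 220L)))
  expect_lt(e_disk$semi_axes[1] / e_disk$semi_axes[2], 1.05)

  # Gaussian cloud with coordinate variances (4, 1) -> ratio ~ 2
  g <- unique(cbind(as.integer(round(rnorm(10000, 60, 2) * 4)) ,
                    as.integer(round(rnorm(10000, 60, 1) * 4))))
  # scale x4 to reduce integer-rounding distortion, ratio is scale free
  e_g <- fit_confidence_ellipse(pixel_set(g, c(1000L, 1000L)))
  expect_lt(abs(e_g$semi_axes[1] / e_g$semi_axes[2] - 2), 0.1)

  # translation equivariance
  shift <- fit_confidence_ellipse(pixel_set(g + 17L, c(1000L, 1000L)))
  expect_equal(unname(shift$center - e_g$center), c(17, 17), tolerance = 1e-9)
  expect_equal(shift$semi_axes, e_g$semi_axes, tolerance = 1e-9)

  # 90-degree rotation permutes the axes' orientation but not their lengths
  rot <- cbind(g[, 2], max(g[, 1]) + 1L - g[, 1])
  e_rot <- fit_confidence_ellipse(pixel_set(rot, c(1000L, 1000L)))
  expect_equal(e_rot$semi_axes, e_g$semi_axes, tolerance = 1e-9)

  expect_error(fit_confidence_ellipse(pixel_set(cbind(1:10, 1:10), c(20L, 20L))),
               "rank-deficient")
})

test_that("ROI masking matches per-pixel membership and is idempotent", {
  eye <- generate_eye_image(lattice_spec(6, 6), degeneration_spec(seed = 8))
  ph <- preprocess(eye$image, 8)
  px <- prune_by_centroid_distance(detect_bright_pixels(ph), 0.8)
  roi <- fit_confidence_ellipse(px)
  masked <- mask_to_roi(ph, roi)

  # membership oracle: direct ellipse inequality per pixel
  ct <- cos(roi$orientation); st <- sin(roi$orientation)
  outside_zeroed <- TRUE; inside_kept <- TRUE
  for (i in seq(1, nrow(ph), by = 3)) for (j in seq(1, ncol(ph), by = 3)) {
    u <- ct * (j - roi$center[2]) + st * (i - roi$center[1])
    v <- -st * (j - roi$center[2]) + ct * (i - roi$center[1])
    inside <- (u / roi$semi_axes[1])^2 + (v / roi$semi_axes[2])^2 <= 1
    if (!inside && masked[i, j] != 0) outside_zeroed <- FALSE
    if (inside && masked[i, j] != ph[i, j]) inside_kept <- FALSE
  }
  expect_true(outside_zeroed)
  expect_true(inside_kept)
  expect_identical(mask_to_roi(masked, roi), masked)

  # ellipse covering the whole image acts as identity
  big <- roi; big$semi_axes <- c(a = 1e4, b = 1e4)
  expect_identical(mask_to_roi(ph, big), ph)
})
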