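test_that("search downscaling hits 500 px with the right scale factor", {
  set.seed(1)
  big <- array(runif(1500 * 1500 * 3, 0, 255), dim = c(1500, 1500, 3))
  ds <- downscale_for_search(big)
  expect_equal(dim(ds$image), c(500L, 500L))
  expect_equal(ds$scale, 3)

  same <- array(runif(500 * 500 * 3, 0, 255), dim = c(500, 500, 3))
  ds2 <- downscale_for_search(same)
  expect_equal(dim(ds2$image), c(500L, 500L))
  expect_equal(ds2$scale, 1)
  expect_equal(ds2$image, to_grayscale(same))   # untouched, just grayscale

  rect <- array(runif(1000 * 800 * 3, 0, 255), dim = c(1000, 800, 3))
  ds3 <- downscale_for_search(rect)
  expect_equal(dim(ds3$image), c(500L, 400L))   # aspect preserved
  expect_equal(ds3$scale, 2)
})

test_that("template extraction centers on the largest dark object and pads", {
  img <- matrix(220, 500, 500)
  rr <- outer(seq_len(500) - 200, rep(1, 500))
  cc <- t(outer(seq_len(500) - 300, rep(1, 500)))
  img[rr^2 + cc^2 <= 40^2] <- 60       # dark disk centered at (200, 300)
  res <- extract_template(img)
  expect_equal(dim(res$template), c(150L, 150L))
  expect_equal(res$centroid, c(200, 300), tolerance = 0.51)

  # disk near the border: output still 150x150, padded with background
  img2 <- matrix(220, 500, 500)
  rr2 <- outer(seq_len(500) - 20, rep(1, 500))
  img2[rr2^2 + cc^2 <= 15^2] <- 60
  res2 <- extract_template(img2)
  expect_equal(dim(res2$template), c(150L, 150L))
  expect_equal(res2$template[1, 1], 220)        # padded corner

  expect_error(extract_template(matrix(128, 50, 50)),
               class = "cribra3d_empty_section")
})

test_that("NCC surface matches the double-summation oracle", {
  set.seed(31)
  for (i in 1:15) {
    M <- sample(8:16, 1); N <- sample(8:16, 1)
    P <- sample(2:5, 1); Q <- sample(2:5, 1)
    f <- matrix(sample(0:255, M * N, replace = TRUE), M, N)
    t <- matrix(sample(0:255, P * Q, replace = TRUE), P, Q)
    s <- normalized_cross_correlation(f, t)
    expect_lt(max(abs(s$gamma - ncc_oracle(f, t))), 1e-10)
    expect_true(all(s$gamma >= -1 & s$gamma <= 1))
    expect_equal(s$best_value, max(s$gamma))
  }
})

test_that("NCC is 1 at a perfect match and invariant to affine intensity maps", {
  set.seed(8)
  f <- matrix(runif(20 * 20, 0, 255), 20, 20)
  t <- f[3:8, 5:10]
  s <- normalized_cross_correlation(f, t)
  expect_equal(s$best_offset, c(3, 5))
  expect_equal(s$best_value, 1, tolerance = 1e-10)

  s2 <- normalized_cross_correlation(f, 0.4 * t + 31)   # a*t + b, a > 0
  expect_equal(s2$best_offset, c(3, 5))
  expect_equal(s2$best_value, 1, tolerance = 1e-10)
  expect_equal(s$gamma, s2$gamma, tolerance = 1e-9)

  s3 <- normalized_cross_correlation(2.5 * f - 10, t)   # and of the image
  expect_equal(s$gamma, s3$gamma, tolerance = 1e-9)

  expect_error(normalized_cross_correlation(f, matrix(5, 3, 3)), "variance")
})

test_that("registering an image to itself gives the identity transform", {
  ph <- cached_phantom("bubble")
  g <- to_grayscale(ph$stack$images[[10]])
  tf <- find_rigid_transform(g, g, angle_range = 4)
  expect_equal(tf$angle_deg, 0)
  expect_equal(c(tf$dr, tf$dc), c(0, 0))
  expect_gt(tf$gamma, 0.999)
  expect_false(tf$failed)
})

test_that("a known rotation + shift is recovered as its inverse", {
  ph <- cached_phantom("bubble")
  g <- to_grayscale(ph$stack$images[[12]])
  ctr <- c(160.5, 160.5)
  moved <- rotate_bilinear(g, 7, center = ctr, shift = c(12, -5))
  tf <- find_rigid_transform(g, moved, angle_range = 10)
  expect_false(tf$failed)
  expect_lt(abs(tf$angle_deg + 7), 1 + 1e-9)
  # compare as maps: recovered transform must undo the known one at the center
  th <- tf$angle_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  fwd_known <- function(p) {
    th0 <- 7 * pi / 180
    R0 <- matrix(c(cos(th0), sin(th0), -sin(th0), cos(th0)), 2)
    as.numeric(R0 %*% (p - ctr)) + ctr + c(12, -5)
  }
  p2 <- as.numeric(R %*% (fwd_known(ctr) - tf$center)) + tf$center + c(tf$dr, tf$dc)
  expect_lt(sqrt(sum((p2 - ctr)^2)), 1.5)
})

test_that("the translation search never exceeds 20% of the image side", {
  ph <- cached_phantom("bubble")
  g <- to_grayscale(ph$stack$images[[15]])
  n <- nrow(g)
  shifted <- rotate_bilinear(g, 0, shift = c(round(0.3 * n), 0), fill = 220)
  tf <- find_rigid_transform(g, shifted, angle_range = 2, failure_floor = 0)
  expect_lte(abs(tf$dr), 0.2 * n)
  expect_lte(abs(tf$dc), 0.2 * n)
})

test_that("aligning a stack of identical slices yields identity transforms", {
  ph <- cached_phantom("bubble")
  img <- ph$stack$images[[10]]
  stack <- section_stack(list(img, img, img))
  res <- align_stack(stack, angle_range = 3)
  expect_false(any(res$failures))
  for (tf in res$transforms[-1]) {
    expect_equal(tf$angle_deg, 0)
    expect_equal(c(tf$dr, tf$dc), c(0, 0))
    expect_gt(tf$gamma, 0.999)
  }
  expect_equal(res$stack$images[[2]], img, tolerance = 1e-8)
})

test_that("an empty section is flagged, not fatal", {
  ph <- cached_phantom("bubble")
  img <- ph$stack$images[[10]]
  blank <- array(180, dim = dim(img))
  res <- align_stack(section_stack(list(img, blank, img)), angle_range = 2)
  expect_true(res$failures[2])
  expect_equal(length(res$stack$images), 3L)
})
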