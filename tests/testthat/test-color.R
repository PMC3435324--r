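test_that("contrast stretch maps the typical 100-255 range onto 0-255", {
  # heavy mass at both limits so the percentile limits equal them exactly
  vals <- c(rep(100, 60), 177.5, rep(255, 60))
  img <- array(rep(vals, 3), dim = c(11, 11, 3))
  st <- stretch_contrast(img)
  expect_equal(st[, , 1][img[, , 1] == 100][1], 0)
  expect_equal(st[, , 1][img[, , 1] == 255][1], 255)
  # linear midpoint of [100, 255] lands mid-range
  expect_equal(st[, , 2][img[, , 2] == 177.5][1], 127.5, tolerance = 1e-10)
})

test_that("contrast stretch leaves full-range and constant channels unchanged", {
  full <- c(rep(0, 60), 120, rep(255, 60))
  img <- array(c(full, full, rep(42, 121)), dim = c(11, 11, 3))
  st <- stretch_contrast(img)
  expect_equal(st[, , 1], img[, , 1])
  expect_equal(st[, , 3], img[, , 3])   # constant channel: stretch undefined
})

test_that("custom HSV planes follow the defining arithmetic", {
  # gray pixels carry no chroma
  g <- array(200, dim = c(2, 2, 3))
  h <- rgb_to_custom_hsv(g)
  expect_equal(h$V, matrix(200, 2, 2))
  expect_equal(h$Cr, matrix(0, 2, 2))
  expect_equal(h$Cb, matrix(0, 2, 2))
  expect_equal(h$S, matrix(0, 2, 2))

  px <- array(c(100, 50, 200), dim = c(1, 1, 3))
  h2 <- rgb_to_custom_hsv(px)
  expect_equal(h2$V[1], 81.5)
  expect_equal(h2$Cr[1], 18.5)
  expect_equal(h2$Cb[1], 118.5)
  expect_equal(h2$H[1], atan2(118.5, 18.5), tolerance = 1e-12)

  red <- rgb_to_custom_hsv(array(c(255, 0, 0), dim = c(1, 1, 3)))
  expect_equal(red$V[1], 76.5)
  expect_equal(red$Cr[1], 178.5)
  expect_equal(red$Cb[1], -76.5)
  expect_lt(red$H[1], 0)
})

test_that("custom HSV matches the direct-arithmetic oracle on random pixels", {
  set.seed(421)
  rgb <- array(sample(0:255, 3 * 50, replace = TRUE), dim = c(50, 1, 3))
  h <- rgb_to_custom_hsv(rgb)
  V <- 0.3 * rgb[, , 1] + 0.59 * rgb[, , 2] + 0.11 * rgb[, , 3]
  expect_equal(as.vector(h$V), as.vector(V), tolerance = 1e-12)
  expect_equal(as.vector(h$H),
               as.vector(atan2(rgb[, , 3] - V, rgb[, , 1] - V)), tolerance = 1e-12)
  expect_equal(as.vector(h$S),
               as.vector(sqrt((rgb[, , 1] - V)^2 + (rgb[, , 3] - V)^2)),
               tolerance = 1e-12)
})

test_that("otsu threshold equals the exhaustive between-class-variance maximizer", {
  set.seed(77)
  for (i in 1:30) {
    n <- sample(20:400, 1)
    v <- switch(1 + i %% 3,
                sample(0:255, n, replace = TRUE),
                c(rnorm(n, 60, 12), rnorm(n, 190, 20)),
                rpois(n, 90))
    expect_identical(otsu_threshold(v), otsu_oracle(v))
  }
  # small forced case: same class partition as the oracle
  s <- c(10, 10, 10, 200, 200)
  expect_identical(otsu_threshold(s), otsu_oracle(s))
  expect_true(otsu_threshold(s) >= 10 && otsu_threshold(s) < 200)
})

test_that("otsu rejects degenerate input", {
  expect_error(otsu_threshold(rep(7, 10)), "distinct")
  expect_error(otsu_threshold(numeric(0)))
})
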