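test_that("in-plane downsampling reaches ~4 um voxels", {
  masks <- list(matrix(FALSE, 1000, 1000))
  ds <- downsample_stack(masks, 0.9, 4)
  expect_equal(dim(ds$volume)[1:2], c(225L, 225L))   # 1000 * 0.9 / 4
  expect_equal(ds$voxel_size_um, 4)
  expect_false(any(ds$volume))

  expect_error(downsample_stack(masks, 5, 4), "factor")
})

test_that("block-mean downsampling conserves the area of a solid disk", {
  size <- 900
  rr <- outer(seq_len(size) - 450, rep(1, size)); cc <- t(rr)
  disk <- rr^2 + cc^2 <= 100^2
  ds <- downsample_stack(list(disk), 0.9, 4)
  scale2 <- (4 / 0.9)^2
  expect_lt(abs(sum(ds$volume) - sum(disk) / scale2) / (sum(disk) / scale2), 0.05)
})

test_that("3D labelling agrees with a flood-fill oracle on random volumes", {
  set.seed(12)
  for (i in 1:8) {
    conn <- if (i %% 2 == 0) 6L else 26L
    v <- array(runif(8 * 8 * 5) < 0.35, dim = c(8, 8, 5))
    res <- label_components(mask_stack(v), connectivity = conn)
    oracle <- flood_fill_oracle(v, conn)
    expect_identical(partition_signature(res$labels), partition_signature(oracle))
    # voxel conservation across labelling
    expect_equal(sum(res$components$voxels), sum(v))
  }
})

test_that("component heights count occupied sections", {
  v <- array(FALSE, c(6, 6, 10))
  v[3, 3, ] <- TRUE                      # 1-voxel column through all slices
  res <- label_components(mask_stack(v))
  expect_equal(nrow(res$components), 1L)
  expect_equal(res$components$height_sections, 10L)

  v2 <- array(FALSE, c(12, 12, 8))
  v2[2:4, 2:4, 2:3] <- TRUE
  v2[8:10, 8:10, 5:7] <- TRUE            # two disjoint blocks
  res2 <- label_components(mask_stack(v2))
  expect_equal(nrow(res2$components), 2L)
  expect_equal(sort(res2$components$height_sections), c(2L, 3L))

  v3 <- array(FALSE, c(3, 3, 3)); v3[2, 2, 2] <- TRUE
  res3 <- label_components(mask_stack(v3))
  expect_equal(res3$components$voxels, 1L)
  expect_equal(res3$components$height_sections, 1L)
})

test_that("architecture thresholds are <25 bubble, >35 tube, else unclear", {
  mk <- function(h) data.frame(id = 1L, voxels = h, height_sections = h)
  expect_equal(classify_architecture(mk(20), 60)$label, "bubble")
  expect_equal(classify_architecture(mk(30), 60)$label, "unclear")
  expect_equal(classify_architecture(mk(40), 60)$label, "tube")
  expect_equal(classify_architecture(mk(25), 60)$label, "unclear")
  expect_equal(classify_architecture(mk(35), 60)$label, "unclear")

  expect_warning(e <- classify_architecture(mk(10)[0, ], 60), "unclear")
  expect_equal(e$label, "unclear")
  expect_equal(e$max_height_sections, 0L)
  expect_warning(classify_architecture(mk(40), 30), "40 sections")
})

test_that("classification is unchanged by in-plane downsampling", {
  ph <- cached_phantom("tube")
  tr <- ph$truth
  full <- mask_stack(tr$volume_mask, voxel_size_um = tr$spec$pixel_size_um)
  ds <- downsample_stack(tr$cribra_masks, tr$spec$pixel_size_um,
                         tr$spec$slice_thickness_um)
  c1 <- suppressWarnings(classify_architecture(label_components(full), tr$spec$n_sections))
  c2 <- suppressWarnings(classify_architecture(label_components(ds), tr$spec$n_sections))
  expect_equal(c1$label, c2$label)
})

test_that("run lengths through a voxel follow the box geometry", {
  v <- array(FALSE, c(8, 6, 14))
  v[2:4, 2:3, 3:12] <- TRUE              # 3 x 2 x 10 solid box
  ms <- mask_stack(v)
  ext <- voxel_run_lengths(ms, c(3, 2, 7))
  expect_equal(ext$length, 3L)
  expect_equal(ext$width, 2L)
  expect_equal(ext$height, 10L)
  expect_equal(ext$aspect_ratio, 10 / 3)

  # runs are maximal through the voxel, not one-sided
  v2 <- array(FALSE, c(3, 3, 5)); v2[2, 2, ] <- TRUE
  expect_equal(voxel_run_lengths(mask_stack(v2), c(2, 2, 1))$height, 5L)
  expect_equal(voxel_run_lengths(mask_stack(v2), c(2, 2, 1))$length, 1L)

  expect_error(voxel_run_lengths(ms, c(1, 1, 1)), "luminal")
})

test_that("aspect sampling is seeded, consistent and self-checking", {
  ph <- cached_phantom("tube")
  ds <- downsample_stack(ph$truth$cribra_masks, 0.9, 4)
  s1 <- sample_aspect_ratios(ds, n = 500, seed = 11)
  s2 <- sample_aspect_ratios(ds, n = 500, seed = 11)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 500L)
  # aspect * length = height for every sampled voxel
  expect_lt(max(abs(s1$aspect_ratio * s1$length - s1$height)), 1e-9)
  expect_true(all(s1$length >= 1 & s1$width >= 1 & s1$height >= 1))
  expect_error(sample_aspect_ratios(mask_stack(array(FALSE, c(2, 2, 2)))), "empty")
})

test_that("least-squares line fitting matches the closed form", {
  f <- fit_line(1:10, 2 * (1:10) + 1)
  expect_equal(f$slope, 2, tolerance = 1e-12)
  expect_equal(f$intercept, 1, tolerance = 1e-12)
  expect_equal(f$norm_of_residuals, 0, tolerance = 1e-10)

  set.seed(3)
  x <- runif(5); y <- runif(5)
  f2 <- fit_line(x, y)
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(f2$intercept, beta[1], tolerance = 1e-10)
  expect_equal(f2$slope, beta[2], tolerance = 1e-10)
  expect_equal(f2$norm_of_residuals, sqrt(sum((y - X %*% beta)^2)), tolerance = 1e-10)

  expect_error(fit_line(rep(2, 5), 1:5), "identical")
})

test_that("surface meshes are watertight with exact voxel volumes", {
  v <- array(FALSE, c(3, 3, 3)); v[2, 2, 2] <- TRUE
  m <- extract_surface(mask_stack(v, 4))
  expect_equal(mesh_volume(m), 64, tolerance = 1e-9)

  v2 <- array(FALSE, c(12, 12, 12)); v2[2:11, 2:11, 2:11] <- TRUE
  m2 <- extract_surface(mask_stack(v2, 4))
  expect_lt(abs(mesh_volume(m2) - 1000 * 64) / (1000 * 64), 0.1)
  expect_equal(diff(range(m2$vertices[, 3])), 10 * 4)   # height * voxel size
  # watertight: every undirected edge is shared by exactly two triangles
  e <- rbind(m2$faces[, 1:2], m2$faces[, 2:3], m2$faces[, c(3, 1)])
  ek <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  expect_true(all(table(ek) == 2))

  expect_error(extract_surface(mask_stack(array(FALSE, c(2, 2, 2)))), "empty")

  td <- withr::local_tempdir()
  write_mesh_obj(m, file.path(td, "m.obj"))
  write_mesh_ply(m, file.path(td, "m.ply"))
  obj <- readLines(file.path(td, "m.obj"))
  expect_equal(sum(grepl("^v ", obj)), nrow(m$vertices))
  expect_equal(sum(grepl("^f ", obj)), nrow(m$faces))
  ply <- readLines(file.path(td, "m.ply"))
  expect_equal(ply[1], "ply")
})
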