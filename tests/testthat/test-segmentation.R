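test_that("object-area filters cut exactly at the published thresholds", {
  # duct filter: < 2290 px^2 removed (21*109 = 2289), >= kept (29*79 = 2291)
  m <- matrix(FALSE, 200, 400)
  m[30:50, 40:148] <- TRUE              # 2289 px^2
  m[100:128, 250:328] <- TRUE           # 2291 px^2
  out <- cribra3d:::remove_small_objects(m, 2290)
  expect_equal(sum(out[30:50, 40:148]), 0)
  expect_equal(sum(out[100:128, 250:328]), 2291)

  # cribra filter: < 100 px^2 removed (9*11 = 99), 101 px^2 kept
  m2 <- matrix(FALSE, 60, 60)
  m2[5:13, 5:15] <- TRUE                # 99
  m2[30:39, 30:39] <- TRUE; m2[40, 30] <- TRUE   # 101, connected
  out2 <- cribra3d:::remove_small_objects(m2, 100)
  expect_equal(sum(out2[5:13, 5:15]), 0)
  expect_equal(sum(out2), 101)
})

test_that("border-touching objects are cleared, interior ones kept", {
  m <- matrix(FALSE, 50, 50)
  m[1:5, 10:20] <- TRUE       # touches top border
  m[20:30, 20:30] <- TRUE     # interior
  out <- cribra3d:::clear_border_objects(m)
  expect_equal(sum(out[1:5, ]), 0)
  expect_equal(sum(out), 11 * 11)
})

test_that("an all-white slice yields an empty duct mask", {
  img <- array(250, dim = c(80, 80, 3))
  img[1, 1, ] <- c(249, 249, 249)   # minimal spread so the stretch is defined
  expect_warning(m <- segment_duct(img), "empty")
  expect_false(any(m))
})

test_that("duct segmentation finds a solid disk in a synthetic H&E image", {
  img <- flat_he_image()
  duct <- segment_duct(img)
  expect_gt(dice_masks(duct, attr(img, "duct")), 0.95)
  # lumina are filled into the duct mask
  img2 <- flat_he_image(lumen_radius = 30)
  duct2 <- segment_duct(img2)
  expect_gt(mean(duct2[attr(img2, "lumen")]), 0.95)
})

test_that("the duct morphology chain is idempotent on its own output", {
  ph <- cached_phantom("bubble")
  duct <- segment_duct(ph$stack$images[[18]])
  rerun <- cribra3d:::mask_fill_holes(
    cribra3d:::mask_close(
      cribra3d:::remove_small_objects(
        cribra3d:::mask_fill_holes(
          cribra3d:::mask_close(cribra3d:::mask_open(duct, 1), 3)), 2290), 9))
  expect_identical(rerun, duct)
})

test_that("cribra segmentation recovers a clean circular lumen", {
  img <- flat_he_image(lumen_radius = 40)
  duct <- segment_duct(img)
  cri <- segment_cribra(img, duct)
  lum <- attr(img, "lumen")
  s <- precision_recall(cri, lum)
  expect_gt(s$precision, 85)
  expect_gt(s$recall, 70)     # the deliberate erosion shrinks a 40 px lumen
  # retained objects are interior and above the area floor
  lab <- cribra3d:::label_mask_2d(cri)
  expect_true(all(tabulate(lab[lab > 0]) >= 100))
  expect_equal(sum(cri[c(1, nrow(cri)), ]) + sum(cri[, c(1, ncol(cri))]), 0)
})

test_that("the closing step repairs a crescent-shaped lumen", {
  # a C-shaped segmentation with a narrow mouth, as left by debris at the
  # lumen rim: closing (disc r=3) bridges the mouth and the subsequent hole
  # fill restores the solid lumen
  size <- 120; ctr <- (size + 1) / 2
  rr <- outer(seq_len(size) - ctr, rep(1, size)); cc <- t(rr)
  rad <- sqrt(rr^2 + cc^2)
  disk <- rad <= 30
  mouth <- abs(cc) <= 2 & rr < 0 & rad > 12      # 5 px wide radial slit
  crescent <- disk & !mouth
  fixed <- cribra3d:::mask_fill_holes(cribra3d:::mask_close(crescent, 3))
  expect_gt(mean(fixed[disk]), 0.98)              # slit closed and filled
  # without the closing, filling alone cannot repair the open mouth
  unfixed <- cribra3d:::mask_fill_holes(crescent)
  expect_lt(mean(unfixed[disk]), 0.98)
})

test_that("the restricted-range Otsu threshold is capped at exactly 242", {
  set.seed(2042)
  # bright plateau split into two populations well above the cap: the
  # unrestricted choice would land between them, the cap forces 242
  vals <- c(runif(4000, 60, 120),
            runif(400, 246, 249), runif(400, 252.5, 255))
  expect_gt(otsu_oracle(vals[vals > mean(vals) + sd(vals)]), 242)
  expect_identical(cribra3d:::restricted_otsu(vals, cap = 242), 242)
  # when the restricted Otsu is below the cap it is used untouched
  vals2 <- c(runif(4000, 60, 120), runif(500, 180, 200), runif(500, 230, 250))
  hi2 <- vals2[vals2 > mean(vals2) + sd(vals2)]
  expect_identical(cribra3d:::restricted_otsu(vals2, cap = 242),
                   min(otsu_threshold(hi2), 242))
})

test_that("cribra segmentation respects an empty duct mask", {
  img <- flat_he_image(lumen_radius = 30)
  empty <- matrix(FALSE, dim(img)[1], dim(img)[2])
  expect_false(any(segment_cribra(img, empty)))
})

test_that("segment_stack collects per-slice statistics", {
  ph <- cached_phantom("bubble")
  stack <- section_stack(ph$stack$images[10:11])
  seg <- segment_stack(stack)
  expect_length(seg$duct_masks, 2L)
  expect_equal(nrow(seg$per_slice), 2L)
  expect_true(all(seg$per_slice$duct_area_px > 0))
  expect_equal(seg$per_slice$cribra_area_px[1], sum(seg$cribra_masks[[1]]))
  expect_error(segment_stack(stack, bogus_arg = 1), "unknown")
})
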