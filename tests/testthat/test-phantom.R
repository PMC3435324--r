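test_that("phantom specs are validated", {
  expect_error(phantom_spec("bubble", n_sections = 30), "40")
  expect_error(phantom_spec("tube", max_perturb_shift_frac = 0.25), "0.20")
  expect_error(phantom_spec("bubble", image_size = 300, duct_radius_px = 200), "fit")
  expect_error(phantom_spec("bubble", image_size = 300, duct_radius_px = 100,
                            cribrum_size_range_px = c(60, 90)), "55%")
})

test_that("phantom generation is deterministic given the spec", {
  a <- generate_phantom(small_phantom_spec("bubble", seed = 42))
  b <- generate_phantom(small_phantom_spec("bubble", seed = 42))
  expect_identical(a$truth$volume_mask, b$truth$volume_mask)
  expect_identical(a$truth$transforms[[5]], b$truth$transforms[[5]])
  expect_identical(a$stack$images[[7]], b$stack$images[[7]])
})

test_that("generated truth obeys the architecture height rule it is labelled with", {
  for (arch in c("bubble", "tube", "unclear")) {
    ph <- cached_phantom(arch)
    tr <- ph$truth
    ds <- downsample_stack(tr$cribra_masks, tr$spec$pixel_size_um,
                           tr$spec$slice_thickness_um)
    comp <- label_components(ds)
    heights <- comp$components$height_sections
    if (arch == "bubble") expect_true(all(heights < 25))
    if (arch == "tube") expect_true(any(heights > 35))
    if (arch == "unclear") expect_true(max(heights) >= 25 && max(heights) <= 35)
    call <- suppressWarnings(classify_architecture(comp, tr$spec$n_sections))
    expect_equal(call$label, arch)
  }
})

test_that("cribra masks are subsets of the duct masks on every slice", {
  ph <- cached_phantom("tube")
  for (z in seq_along(ph$truth$cribra_masks)) {
    expect_true(all(ph$truth$duct_masks[[z]][ph$truth$cribra_masks[[z]]]))
  }
})

test_that("recorded perturbations respect the spec amplitudes", {
  ph <- cached_phantom("bubble", apply_transforms = TRUE)
  sp <- ph$truth$spec
  tf1 <- ph$truth$transforms[[1]]
  expect_equal(c(tf1$angle_deg, tf1$dr, tf1$dc), c(0, 0, 0))
  for (tf in ph$truth$transforms[-1]) {
    expect_lte(abs(tf$angle_deg), sp$max_perturb_angle_deg)
    expect_lte(max(abs(c(tf$dr, tf$dc))), sp$max_perturb_shift_frac * sp$image_size)
    expect_equal(tf$dr, round(tf$dr))    # integer pixel shifts
    expect_equal(tf$dc, round(tf$dc))
  }
})

test_that("rendered duct tissue passes the custom hue gate after stretching", {
  ph <- cached_phantom("bubble")
  img <- ph$stack$images[[20]]
  st <- stretch_contrast(img)
  hsv <- rgb_to_custom_hsv(st)
  interior <- ph$truth$duct_masks[[20]] & !ph$truth$cribra_masks[[20]]
  interior <- EBImage::erode(interior * 1, EBImage::makeBrush(9, "disc")) > 0.5
  expect_gt(mean(hsv$H[interior] >= 0.7 & st[, , 1][interior] <= 150), 0.9)
  # lumen pixels are excluded by the red rule
  lum <- ph$truth$cribra_masks[[20]]
  lum_core <- EBImage::erode(lum * 1, EBImage::makeBrush(9, "disc")) > 0.5
  if (any(lum_core)) expect_gt(mean(st[, , 1][lum_core] > 150), 0.9)
})

test_that("palette colors satisfy the segmentation constraints programmatically", {
  pal <- phantom_palette()
  h <- rgb_to_custom_hsv(array(pal$duct, dim = c(1, 1, 3)))
  expect_gte(h$H[1], 0.7)
  expect_lte(pal$duct[1], 150)
  expect_gt(pal$lumen[1], 150)
})

test_that("noise-free, perturbation-free rendering is reproducible and clean", {
  sp <- small_phantom_spec("bubble", seed = 9, noise_sd = 0, stain_variation = 0,
                           max_perturb_angle_deg = 0, max_perturb_shift_frac = 0,
                           debris_fraction = 0)
  tr <- generate_phantom_volume(sp)
  s1 <- render_serial_sections(tr, sp)
  s2 <- render_serial_sections(tr, sp)
  expect_identical(s1$images[[3]], s2$images[[3]])
  # slices with identical truth masks differ only through slice-local texture;
  # with all stochastic per-slice amplitudes at zero the rendering pipeline is
  # a pure function of the masks and fields, so rerendering is bit-identical
  expect_identical(s1$images[[sp$n_sections]], s2$images[[sp$n_sections]])
})

test_that("the renderer and duct segmentation agree on a noise-free phantom", {
  sp <- small_phantom_spec("bubble", seed = 5, noise_sd = 0, stain_variation = 0)
  ph <- generate_phantom(sp, apply_transforms = FALSE)
  duct <- suppressWarnings(segment_duct(ph$stack$images[[20]]))
  expect_gt(dice_masks(duct, ph$truth$duct_masks[[20]]), 0.95)
})

test_that("phantoms round-trip to disk with full truth", {
  ph <- cached_phantom("bubble")
  td <- withr::local_tempdir()
  sub <- list(truth = ph$truth, stack = ph$stack)
  write_phantom(sub, td)
  expect_true(file.exists(file.path(td, "slice_000.tif")))
  truth <- jsonlite::read_json(file.path(td, "truth.json"), simplifyVector = TRUE)
  expect_equal(truth$architecture, "bubble")
  expect_equal(length(truth$transforms$angle_deg), ph$truth$spec$n_sections)
  rt <- read_section_stack(td)
  expect_equal(rt$images[[1]], ph$stack$images[[1]], ignore_attr = TRUE)
})
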