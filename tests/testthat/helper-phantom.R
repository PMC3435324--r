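# Shared phantom fixtures, generated once per test run. Small geometry keeps
# the unit tests fast; the acceptance tests use the generator defaults.

.phantom_cache <- new.env(parent = emptyenv())

small_phantom_spec <- function(architecture, seed = 1L, n_sections = 40L, ...) {
  phantom_spec(architecture, n_sections = n_sections, image_size = 320L,
               duct_radius_px = 109, cribrum_size_range_px = c(30, 46),
               seed = seed, ...)
}

cached_phantom <- function(architecture, seed = 1L, apply_transforms = FALSE) {
  key <- paste(architecture, seed, apply_transforms)
  if (!exists(key, envir = .phantom_cache)) {
    assign(key,
           generate_phantom(small_phantom_spec(architecture, seed),
                            apply_transforms = apply_transforms),
           envir = .phantom_cache)
  }
  get(key, envir = .phantom_cache)
}

# A simple synthetic H&E-like test image: pale background, purple duct disk,
# optional white lumen disk. Deliberately independent of the phantom module.
flat_he_image <- function(size = 260, duct_radius = 90, lumen_radius = 0,
                          lumen_center = NULL, purple = c(120, 70, 150),
                          lumen_col = c(252, 253, 254),
                          bg = c(230, 205, 215)) {
  ctr <- (size + 1) / 2
  if (is.null(lumen_center)) lumen_center <- c(ctr, ctr)
  rr <- outer(seq_len(size) - ctr, rep(1, size))
  cc <- t(rr)
  duct <- rr^2 + cc^2 <= duct_radius^2
  img <- array(0, dim = c(size, size, 3))
  # mild deterministic shading so every channel spans a range and the
  # contrast stretch is well defined
  shade <- 0.9 + 0.2 * (outer(seq_len(size), seq_len(size), `+`) %% 7) / 7
  for (ch in 1:3) {
    plane <- matrix(bg[ch], size, size) * shade
    plane[duct] <- purple[ch] * shade[duct]
    img[, , ch] <- plane
  }
  if (lumen_radius > 0) {
    rr2 <- outer(seq_len(size) - lumen_center[1], rep(1, size))
    cc2 <- t(outer(seq_len(size) - lumen_center[2], rep(1, size)))
    lum <- rr2^2 + cc2^2 <= lumen_radius^2
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[lum] <- lumen_col[ch] * shade[lum]
      img[, , ch] <- plane
    }
    attr(img, "lumen") <- lum
  }
  attr(img, "duct") <- duct
  clamp_img(img)
}

clamp_img <- function(img) {
  a <- attributes(img)
  img <- pmin(pmax(img, 0), 255)
  attributes(img) <- a
  img
}

dice_masks <- function(a, b) {
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}
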