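#' Segment the duct (cellular region) in an aligned section
#'
#' H&E-stained nuclear tissue is purple, which after the custom hue transform
#' falls at `H >= hue_threshold` (0.7 rad). The pipeline is: per-channel
#' contrast stretch; custom HSV; keep `H >= 0.7`; drop near-white pixels whose
#' stretched red intensity exceeds `red_cap` (150); opening with a disc of
#' radius 1 and closing with a disc of radius 3 (remove false connections and
#' close small gaps); fill holes so segmented regions are solid; remove
#' objects smaller than `min_area` (2290 px^2, about six nuclei -- too small
#' to be ducts); a large closing with a disc of radius 9 to improve convexity;
#' and a final hole fill. An empty result (a slice without tissue) yields an
#' empty mask with a warning.
#'
#' @param image HxWx3 aligned section, values in \[0, 255\].
#' @param hue_threshold hue cut in radians on `arctan2(Cb, Cr)` (default 0.7).
#' @param red_cap maximum stretched red intensity for duct pixels (default 150).
#' @param min_area minimum object area in px^2 (default 2290).
#' @param open_radius,close_radius,final_close_radius disc radii of the
#'   morphology chain (defaults 1, 3, 9).
#' @return logical duct mask.
#' @export
segment_duct <- function(image, hue_threshold = 0.7, red_cap = 150,
                         min_area = 2290, open_radius = 1, close_radius = 3,
                         final_close_radius = 9) {
  assert_color_image(image)
  st <- stretch_contrast(image)
  hsv <- rgb_to_custom_hsv(st)
  mask <- hsv$H >= hue_threshold
  mask <- mask & (st[, , 1] <= red_cap)
  mask <- mask_open(mask, open_radius)
  mask <- mask_close(mask, close_radius)
  mask <- mask_fill_holes(mask)
  mask <- remove_small_objects(mask, min_area)
  mask <- mask_close(mask, final_close_radius)
  mask <- mask_fill_holes(mask)
  if (!any(mask)) warning("segment_duct: empty mask (slice may lack tissue)")
  mask
}

# Otsu threshold computed within the high-intensity range (values more than
# one standard deviation above the mean), capped at `cap`: whenever the
# restricted-range Otsu exceeds the cap, the cap itself is the threshold.
restricted_otsu <- function(values, cap = 242) {
  hi_floor <- mean(values) + stats::sd(values)
  hi <- values[values > hi_floor]
  if (length(hi) >= 2L && min(hi) < max(hi)) {
    min(otsu_threshold(hi), cap)
  } else {
    min(hi_floor, cap)
  }
}

# Tiled (4x4) contrast-limited adaptive histogram equalization of one
# channel, on the 0--255 scale, with bilinear blending between tiles. The
# clip limit (histogram bins clipped at `clip_limit` times the mean bin
# count) keeps near-uniform regions -- empty lumina in particular -- from
# being rank-spread across the full range, which is the defining property of
# the contrast-limited variant of adaptive equalization.
equalize_tiled <- function(plane, tiles = 4L, clip_limit = 1.5) {
  eq <- EBImage::clahe(plane / 255, nx = tiles, ny = tiles,
                       bins = 256L, limit = clip_limit)
  matrix(as.numeric(eq), nrow(plane), ncol(plane)) * 255
}

#' Segment intraductal cribra (microlumina) in an aligned section
#'
#' Two candidate maps are built and combined. "White" lumina: the green channel
#' of the original image is adaptively equalized over a 4x4 tile grid; pixels
#' more than one standard deviation above the mean of the equalized plane form
#' a restricted high-intensity range, within which an Otsu threshold is
#' computed (capped at `otsu_cap` = 242, beyond which a fixed 242 is more
#' reliable); pixels above the threshold are lumen candidates. "Pink" debris:
#' the saturation plane of the contrast-stretched image is rescaled to
#' \[0, 255\] and Otsu-binarized, catching eosin-stained cellular debris that
#' the green channel misses. The union is restricted to the duct, holes are
#' filled, and a morphology chain corrects the known artifacts: erosion (disc
#' radius 4) compensating threshold-induced enlargement; closing (disc radius
#' 3) repairing crescent-shaped gaps left by edge debris; hole fill; opening
#' (disc radius 4) smoothing ragged boundaries; a second hole fill;
#' border-touching (incompletely imaged) objects are cleared; and objects
#' below `min_area` (100 px^2) are removed.
#'
#' @param image HxWx3 aligned section, values in \[0, 255\].
#' @param duct logical duct mask from [segment_duct()] for the same slice.
#' @param hue_threshold hue cut separating purple tissue from pink debris:
#'   debris candidates must be high-saturation AND non-purple
#'   (`H < hue_threshold`), since hematoxylin-stained tissue also carries
#'   chroma (default 0.7, the duct hue gate).
#' @param otsu_cap maximum allowed Otsu threshold on the equalized green
#'   channel (default 242).
#' @param min_area minimum retained object area in px^2 (default 100).
#' @param erode_radius,close_radius,open_radius disc radii of the morphology
#'   chain (defaults 4, 3, 4).
#' @param tiles tiles per side for the adaptive equalization (default 4).
#' @param clahe_limit clip limit of the adaptive equalization (histogram bins
#'   clipped at this multiple of the mean bin count; 1 is equivalent to no
#'   equalization).
#' @return logical cribra mask (a subset of `duct`).
#' @export
segment_cribra <- function(image, duct, hue_threshold = 0.7, otsu_cap = 242,
                           min_area = 100,
                           erode_radius = 4, close_radius = 3, open_radius = 4,
                           tiles = 4L, clahe_limit = 1.5) {
  assert_color_image(image)
  stopifnot(is.logical(duct), all(dim(duct) == dim(image)[1:2]))
  if (!any(duct)) return(duct)

  # (a,b) white lumen candidate from the equalized green channel
  eq_green <- equalize_tiled(image[, , 2], tiles = tiles, clip_limit = clahe_limit)
  white <- eq_green > restricted_otsu(eq_green, cap = otsu_cap)

  # (c) pink debris candidate: high saturation at a non-purple hue
  st <- stretch_contrast(image)
  hsv <- rgb_to_custom_hsv(st)
  S <- hsv$S
  s_rng <- range(S)
  pink <- if (s_rng[2] > s_rng[1]) {
    s_norm <- (S - s_rng[1]) * (255 / (s_rng[2] - s_rng[1]))
    (s_norm > otsu_threshold(s_norm)) & (hsv$H < hue_threshold)
  } else {
    matrix(FALSE, nrow(S), ncol(S))
  }

  # (d) combine, restrict to the duct, fill debris holes
  mask <- (white | pink) & duct
  mask <- mask_fill_holes(mask)
  # (e)-(i) artifact-correcting morphology
  mask <- mask_erode(mask, erode_radius)
  mask <- mask_close(mask, close_radius)
  mask <- mask_fill_holes(mask)
  mask <- mask_open(mask, open_radius)
  mask <- mask_fill_holes(mask)
  # (j,k) incomplete and too-small objects
  mask <- clear_border_objects(mask)
  remove_small_objects(mask, min_area)
}

#' Segment every slice of an aligned stack
#'
#' Convenience wrapper running [segment_duct()] and [segment_cribra()] on each
#' section and collecting per-slice statistics.
#'
#' @param stack an aligned [section_stack()].
#' @param ... passed on to [segment_duct()] and [segment_cribra()] (matched by
#'   name; unknown names are an error).
#' @return list with `duct_masks`, `cribra_masks` (lists of logical matrices)
#'   and `per_slice` (data.frame: slice, duct_area_px, cribra_count,
#'   cribra_area_px).
#' @export
segment_stack <- function(stack, ...) {
  stopifnot(inherits(stack, "section_stack"))
  dots <- list(...)
  duct_args <- dots[names(dots) %in% names(formals(segment_duct))]
  cribra_args <- dots[names(dots) %in% names(formals(segment_cribra))]
  unknown <- setdiff(names(dots), c(names(formals(segment_duct)),
                                    names(formals(segment_cribra))))
  if (length(unknown)) stop("unknown arguments: ", paste(unknown, collapse = ", "))

  n <- length(stack$images)
  duct_masks <- vector("list", n)
  cribra_masks <- vector("list", n)
  stats <- data.frame(slice = seq_len(n), duct_area_px = NA_real_,
                      cribra_count = NA_integer_, cribra_area_px = NA_real_)
  for (i in seq_len(n)) {
    duct_masks[[i]] <- suppressWarnings(
      do.call(segment_duct, c(list(stack$images[[i]]), duct_args)))
    cribra_masks[[i]] <- do.call(
      segment_cribra, c(list(stack$images[[i]], duct_masks[[i]]), cribra_args))
    lab <- label_mask_2d(cribra_masks[[i]])
    stats$duct_area_px[i] <- sum(duct_masks[[i]])
    stats$cribra_count[i] <- max(lab)
    stats$cribra_area_px[i] <- sum(cribra_masks[[i]])
  }
  list(duct_masks = duct_masks, cribra_masks = cribra_masks, per_slice = stats)
}
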