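#' Specification of a synthetic DCIS phantom
#'
#' Describes a synthetic serial-section specimen: a single cribriform duct
#' whose microlumina are laid out to realize a requested 3D architecture.
#' Defaults emulate the imaging conditions of the real material: ~0.9 um
#' pixels, 4 um sections, at least 40 sections, pre-cropped fields of
#' 500--1500 px. Cribra sizes default to 27--42% of the duct radius
#' (65--100 px at the default geometry, about 115--180 um diameter -- the
#' upper part of the range typical of cribriform microlumina, where
#' boundary-scale segmentation effects stay small relative to the object).
#' Bubble phantoms scatter rounded lumina
#' through the duct interior with z-extents well below 25 sections; tube
#' phantoms run near-vertical channels close to the duct border through the
#' whole specimen; unclear phantoms contain one channel of intermediate
#' (25--35 section) height.
#'
#' @param architecture one of "bubble", "tube", "unclear".
#' @param n_sections number of serial sections (>= 40, the inclusion
#'   criterion).
#' @param image_size image side in pixels.
#' @param pixel_size_um in-plane pixel size, microns (default 0.9).
#' @param slice_thickness_um section thickness, microns (default 4).
#' @param duct_radius_px duct radius; defaults to 34% of the image side.
#' @param n_cribra number of cribra; defaults to 8 (bubble), 3 (tube),
#'   3 (unclear: one channel plus two bubbles).
#' @param cribrum_size_range_px in-plane cribrum radius range (px); defaults
#'   to 27--42% of the duct radius.
#' @param max_perturb_angle_deg per-slice rigid rotation amplitude (degrees).
#' @param max_perturb_shift_frac per-slice translation amplitude as a fraction
#'   of the image side; must stay below 0.20 so the truth is recoverable
#'   within the registration's translation bound.
#' @param stain_variation per-slice multiplicative brightness jitter amplitude.
#' @param noise_sd per-pixel Gaussian channel noise (8-bit units).
#' @param debris_fraction fraction of cribra containing pink debris.
#' @param blur_sigma optical blur (Gaussian sigma, px) applied to each
#'   rendered slice.
#' @param seed random seed; the phantom is fully deterministic given the spec.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(architecture = c("bubble", "tube", "unclear"),
                         n_sections = 60L,
                         image_size = 700L,
                         pixel_size_um = 0.9,
                         slice_thickness_um = 4,
                         duct_radius_px = NULL,
                         n_cribra = NULL,
                         cribrum_size_range_px = NULL,
                         max_perturb_angle_deg = 4,
                         max_perturb_shift_frac = 0.05,
                         stain_variation = 0.08,
                         noise_sd = 3,
                         debris_fraction = 0.3,
                         blur_sigma = 1,
                         seed = 1L) {
  architecture <- match.arg(architecture)
  if (is.null(duct_radius_px)) duct_radius_px <- round(0.34 * image_size)
  if (is.null(cribrum_size_range_px)) {
    cribrum_size_range_px <- round(c(0.27, 0.42) * duct_radius_px)
  }
  if (is.null(n_cribra)) {
    n_cribra <- switch(architecture, bubble = 8L, tube = 3L, unclear = 3L)
  }
  if (n_sections < 40L) {
    stop("n_sections must be at least 40 (specimen inclusion criterion)", call. = FALSE)
  }
  if (max_perturb_shift_frac >= 0.20) {
    stop("max_perturb_shift_frac must stay below 0.20 (the registration's translation bound)",
         call. = FALSE)
  }
  if (image_size <= 0 || duct_radius_px <= 0 || any(cribrum_size_range_px <= 0) ||
      pixel_size_um <= 0 || slice_thickness_um <= 0) {
    stop("all sizes must be positive", call. = FALSE)
  }
  if (duct_radius_px >= image_size / 2) {
    stop("duct radius must fit inside the image", call. = FALSE)
  }
  if (max(cribrum_size_range_px) > 0.55 * duct_radius_px) {
    stop("cribra too large for the duct: max cribrum radius must not exceed 55% of the duct radius",
         call. = FALSE)
  }
  if (architecture == "unclear" && n_sections < 40L) {
    stop("unclear phantoms need at least 40 sections", call. = FALSE)
  }
  structure(list(architecture = architecture,
                 n_sections = as.integer(n_sections),
                 image_size = as.integer(image_size),
                 pixel_size_um = pixel_size_um,
                 slice_thickness_um = slice_thickness_um,
                 duct_radius_px = duct_radius_px,
                 n_cribra = as.integer(n_cribra),
                 cribrum_size_range_px = cribrum_size_range_px,
                 max_perturb_angle_deg = max_perturb_angle_deg,
                 max_perturb_shift_frac = max_perturb_shift_frac,
                 stain_variation = stain_variation,
                 noise_sd = noise_sd,
                 debris_fraction = debris_fraction,
                 blur_sigma = blur_sigma,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' H&E-like phantom palette
#'
#' Nominal 8-bit RGB colors for the four tissue classes, chosen so the
#' segmentation thresholds apply: the duct purple must satisfy the custom hue
#' gate (H >= 0.7 with margin) at red <= 150, lumina must be near-white
#' (red > 150), debris must carry high chroma. The constraints are verified
#' programmatically through [rgb_to_custom_hsv()]; violations are an error,
#' so the palette can be adjusted without silently breaking the contract.
#'
#' @return list with numeric RGB triplets `duct`, `lumen`, `background`,
#'   `debris`.
#' @export
phantom_palette <- function() {
  # empty lumina are blank glass: microscope exposure/white balance puts them
  # at the top of the 8-bit range
  pal <- list(duct = c(120, 70, 150),
              lumen = c(252, 253, 254),
              background = c(230, 205, 215),
              debris = c(240, 120, 170))
  hsv_of <- function(rgb) rgb_to_custom_hsv(array(rgb, dim = c(1, 1, 3)))
  duct <- hsv_of(pal$duct)
  stopifnot(duct$H[1] >= 0.75,                 # hue gate with margin
            pal$duct[1] <= 140,                # red cap with margin
            pal$lumen[1] > 160,                # white exclusion rule
            pal$background[1] > 160,
            hsv_of(pal$debris)$S[1] > 2 * hsv_of(pal$lumen)$S[1])
  pal
}

# Per-slice (center, radius) profile of one cribrum; rows are sections,
# columns cx, cy, r (NA where the cribrum is absent).
cribrum_profile <- function(kind, n, center, r, z0 = NULL, cz = NULL,
                            zspan = NULL, wander = NULL) {
  prof <- matrix(NA_real_, n, 3)
  if (kind == "bubble") {
    # rounded but flat-topped z-profile (punched-out holes are closer to
    # capped cylinders than to ellipsoids)
    for (z in seq_len(n)) {
      u <- (z - z0) / cz
      if (abs(u) < 1) {
        s <- sqrt(1 - u^4)
        prof[z, ] <- c(center, r * s)
      }
    }
  } else {                              # channel
    for (z in zspan[1]:zspan[2]) {
      w <- if (is.null(wander)) c(0, 0) else {
        c(wander$ax * sin(2 * pi * wander$kx * z / n + wander$px),
          wander$ay * sin(2 * pi * wander$ky * z / n + wander$py))
      }
      prof[z, ] <- c(center + w, r)
    }
  }
  prof
}

place_bubbles <- function(n_bubbles, n, r_safe, size_range, z_margin = 2,
                          cz_range = c(6, 10), max_tries = 300L,
                          avoid = list()) {
  placed <- list()
  for (b in seq_len(n_bubbles)) {
    for (try in seq_len(max_tries)) {
      r <- stats::runif(1, size_range[1], size_range[2])
      cz <- stats::runif(1, cz_range[1], cz_range[2])
      rho_max <- r_safe - r - 12
      if (rho_max <= 0) break
      ang <- stats::runif(1, 0, 2 * pi)
      rho <- sqrt(stats::runif(1)) * rho_max
      center <- rho * c(cos(ang), sin(ang))
      z0 <- stats::runif(1, cz + z_margin, n - cz - z_margin)
      ok <- TRUE
      for (av in avoid) {       # stay clear of channels (any z overlaps them)
        if (sqrt(sum((center - av$center)^2)) < r + av$r + 18) {
          ok <- FALSE; break
        }
      }
      if (ok) for (p in placed) {
        dxy <- sqrt(sum((center - p$center)^2))
        dz <- abs(z0 - p$z0)
        # flat-topped profiles are near-cylindrical: disjoint only if
        # separated in-plane or along z
        if (dxy < r + p$r + 6 && dz < cz + p$cz + 2) {
          ok <- FALSE; break
        }
      }
      if (ok) {
        placed[[length(placed) + 1L]] <-
          list(kind = "bubble", center = center, r = r, z0 = z0, cz = cz)
        break
      }
    }
  }
  placed
}

place_channels <- function(n_channels, n, r_safe, size_range, zspans) {
  placed <- list()
  base_ang <- stats::runif(1, 0, 2 * pi)
  for (ch in seq_len(n_channels)) {
    r <- stats::runif(1, size_range[1], size_range[2])
    ang <- base_ang + 2 * pi * (ch - 1) / n_channels + stats::runif(1, -0.2, 0.2)
    rho <- r_safe - r - 12
    if (rho <= 0) next
    wander <- list(ax = stats::runif(1, 2, 5), ay = stats::runif(1, 2, 5),
                   kx = sample(1:2, 1), ky = sample(1:2, 1),
                   px = stats::runif(1, 0, 2 * pi), py = stats::runif(1, 0, 2 * pi))
    placed[[length(placed) + 1L]] <-
      list(kind = "channel", center = rho * c(cos(ang), sin(ang)), r = r,
           zspan = zspans[[ch]], wander = wander)
  }
  placed
}

#' Generate a phantom ground-truth volume
#'
#' Builds, deterministically from the spec's seed, a duct of roughly circular
#' cross-section (low-order harmonic boundary irregularity, slow axial
#' modulation) containing cribra laid out for the requested architecture, and
#' draws the per-slice rigid perturbations later applied by the renderer. The
#' generated truth is verified against its own label: the <25 / >35 section
#' height rule applied to the generated lumen volume must reproduce the
#' requested architecture, otherwise the spec is rejected as inconsistent.
#'
#' @param spec a [phantom_spec()].
#' @return an object of class `phantom_truth`: list with `volume_mask` (3D
#'   logical lumen volume, unperturbed frame), `duct_masks`, `cribra_masks`
#'   (per-slice logical), `transforms` (per-slice [rigid_transform()] applied
#'   by the renderer; element 1 is the identity), `architecture`, `cribra`
#'   (geometry of each placed cribrum), and `spec`.
#' @export
generate_phantom_volume <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$n_sections
  sz <- spec$image_size
  with_seed(spec$seed, {
    # duct boundary: R(phi, z) = R0 * (0.95 + sum_k a_k cos(k phi + p_k))
    #                          * (1 + 0.03 sin(2 pi z / n + p_z))
    R0 <- spec$duct_radius_px
    a <- stats::runif(3, 0.01, 0.04)
    ph <- stats::runif(3, 0, 2 * pi)
    pz <- stats::runif(1, 0, 2 * pi)
    center <- (sz + 1) / 2
    xs <- rep(seq_len(sz), times = sz) - center     # rows
    ys <- rep(seq_len(sz), each = sz) - center      # cols
    rr <- sqrt(xs^2 + ys^2)
    phi <- atan2(ys, xs)
    radius_phi <- R0 * (0.95 + a[1] * cos(phi + ph[1]) +
                        a[2] * cos(2 * phi + ph[2]) + a[3] * cos(3 * phi + ph[3]))
    # worst-case duct radius is R0*(0.95 - 0.12)*0.97 ~ 0.805*R0; keep every
    # cribrum behind a solid tissue ring so lumina stay enclosed holes
    r_safe <- 0.76 * R0

    cribra <- switch(spec$architecture,
      bubble = place_bubbles(spec$n_cribra, n, r_safe, spec$cribrum_size_range_px),
      tube = place_channels(spec$n_cribra, n, r_safe, spec$cribrum_size_range_px,
                            zspans = replicate(spec$n_cribra, {
                              z0 <- sample(1:3, 1)
                              c(z0, n - sample(0:2, 1))
                            }, simplify = FALSE)),
      unclear = {
        span30 <- {
          z0 <- sample(seq_len(n - 29L), 1)
          c(z0, z0 + 29L)
        }
        chan <- place_channels(1L, n, r_safe, spec$cribrum_size_range_px,
                               zspans = list(span30))
        c(chan,
          place_bubbles(2L, n, r_safe,
                        pmin(spec$cribrum_size_range_px, 0.8 * r_safe),
                        cz_range = c(5, 8),
                        avoid = lapply(chan, function(ch) {
                          list(center = ch$center, r = ch$r)
                        })))
      })
    if (length(cribra) < 1L) {
      stop("inconsistent phantom spec: no cribrum could be placed inside the duct",
           call. = FALSE)
    }
    # debris assignment and per-slice profiles
    for (i in seq_along(cribra)) {
      cr <- cribra[[i]]
      cr$debris <- stats::runif(1) < spec$debris_fraction
      cr$debris_angle <- stats::runif(1, 0, 2 * pi)
      cr$profile <- if (cr$kind == "bubble") {
        cribrum_profile("bubble", n, cr$center, cr$r, z0 = cr$z0, cz = cr$cz)
      } else {
        cribrum_profile("channel", n, cr$center, cr$r, zspan = cr$zspan,
                        wander = cr$wander)
      }
      cribra[[i]] <- cr
    }

    duct_masks <- vector("list", n)
    cribra_masks <- vector("list", n)
    for (z in seq_len(n)) {
      sz_scale <- 1 + 0.03 * sin(2 * pi * z / n + pz)
      duct <- matrix(rr <= radius_phi * sz_scale, sz, sz)
      lum <- matrix(FALSE, sz, sz)
      for (cr in cribra) {
        p <- cr$profile[z, ]
        if (is.na(p[3])) next
        cx <- center + p[1]; cy <- center + p[2]; r <- p[3]
        rws <- max(1, floor(cx - r)):min(sz, ceiling(cx + r))
        cls <- max(1, floor(cy - r)):min(sz, ceiling(cy + r))
        sub <- outer((rws - cx)^2, (cls - cy)^2, `+`) <= r^2
        lum[rws, cls] <- lum[rws, cls] | sub
      }
      lum <- lum & duct
      duct_masks[[z]] <- duct
      cribra_masks[[z]] <- lum
    }
    volume <- array(FALSE, dim = c(sz, sz, n))
    for (z in seq_len(n)) volume[, , z] <- cribra_masks[[z]]

    # per-slice rigid perturbations (continuous angle, integer shift)
    max_shift <- round(spec$max_perturb_shift_frac * sz)
    transforms <- vector("list", n)
    transforms[[1]] <- rigid_transform(center = c(center, center))
    for (z in 2:n) {
      angle <- stats::runif(1, -spec$max_perturb_angle_deg, spec$max_perturb_angle_deg)
      shift <- if (max_shift > 0) sample(-max_shift:max_shift, 2, replace = TRUE)
               else c(0L, 0L)
      transforms[[z]] <- rigid_transform(angle_deg = angle, dr = shift[1],
                                         dc = shift[2], center = c(center, center))
    }

    truth <- structure(list(volume_mask = volume,
                            duct_masks = duct_masks,
                            cribra_masks = cribra_masks,
                            transforms = transforms,
                            architecture = spec$architecture,
                            cribra = cribra,
                            spec = spec),
                       class = "phantom_truth")
    # label-consistency invariant: the height rule applied to the generated
    # volume must reproduce the requested architecture
    ds <- downsample_stack(cribra_masks, spec$pixel_size_um, spec$slice_thickness_um)
    call <- suppressWarnings(classify_architecture(label_components(ds), n))
    if (call$label != spec$architecture) {
      stop(sprintf(paste0("inconsistent phantom spec: requested '%s' but the ",
                          "generated volume classifies as '%s' ",
                          "(largest cribrum %d sections)"),
                   spec$architecture, call$label, call$max_height_sections),
           call. = FALSE)
    }
    truth
  })
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("phantom_truth: %s, %d sections of %dx%d px, %d cribra\n",
              x$architecture, x$spec$n_sections, x$spec$image_size,
              x$spec$image_size, length(x$cribra)))
  invisible(x)
}

#' Render a phantom as an H&E-like serial-section stack
#'
#' Each slice is composed from the four-class palette (purple duct tissue,
#' near-white lumina, pale stroma/fat background, pink high-saturation debris
#' in a fraction of cribra), modulated by a smooth multiplicative texture
#' field (nuclear density / stain take-up), optically blurred, degraded with
#' per-pixel Gaussian channel noise and per-slice multiplicative brightness
#' jitter (stain variability), and finally rigidly perturbed by the recorded
#' per-slice transform, with exposed areas filled with the background color.
#' Rendering is deterministic given the spec.
#'
#' @param truth a `phantom_truth` from [generate_phantom_volume()].
#' @param spec the matching [phantom_spec()] (defaults to `truth$spec`).
#' @param apply_transforms if FALSE, the per-slice rigid perturbations are
#'   skipped (used to obtain the geometrically clean reference rendering).
#' @return a [section_stack()].
#' @export
render_serial_sections <- function(truth, spec = truth$spec,
                                   apply_transforms = TRUE) {
  stopifnot(inherits(truth, "phantom_truth"))
  n <- spec$n_sections
  sz <- spec$image_size
  pal <- phantom_palette()
  center <- (sz + 1) / 2
  with_seed(spec$seed + 1L, {
    tex_shared <- smooth_random_field(sz, sz, grid = 24L, amplitude = 0.15)
    # stain density inside the duct is strongly mottled (nuclear crowding);
    # its dark tail is what anchors the per-slice contrast stretch
    deep_shared <- smooth_random_field(sz, sz, grid = 32L, amplitude = 0.45)
    # cell-scale stain granularity: partially persists between adjacent
    # sections (nuclei span 2-3 sections) and gives the rotation search
    # sharp structure everywhere in the duct
    fine_grid <- max(8L, as.integer(sz / 4))
    fine_shared <- smooth_random_field(sz, sz, grid = fine_grid, amplitude = 0.25)
    images <- vector("list", n)
    for (z in seq_len(n)) {
      duct <- truth$duct_masks[[z]]
      lum <- truth$cribra_masks[[z]]
      # debris regions for this slice
      deb <- matrix(FALSE, sz, sz)
      for (cr in truth$cribra) {
        if (!cr$debris) next
        p <- cr$profile[z, ]
        if (is.na(p[3]) || p[3] < 6) next
        dcx <- center + p[1] + 0.45 * p[3] * cos(cr$debris_angle)
        dcy <- center + p[2] + 0.45 * p[3] * sin(cr$debris_angle)
        dr <- 0.4 * p[3]
        rws <- max(1, floor(dcx - dr)):min(sz, ceiling(dcx + dr))
        cls <- max(1, floor(dcy - dr)):min(sz, ceiling(dcy + dr))
        deb[rws, cls] <- deb[rws, cls] |
          (outer((rws - dcx)^2, (cls - dcy)^2, `+`) <= dr^2)
      }
      deb <- deb & lum

      tex <- 0.7 * tex_shared +
        0.3 * smooth_random_field(sz, sz, grid = 24L, amplitude = 0.15)
      t_duct <- (0.7 * deep_shared +
        0.3 * smooth_random_field(sz, sz, grid = 32L, amplitude = 0.45)) *
        (0.5 * fine_shared +
         0.5 * smooth_random_field(sz, sz, grid = fine_grid, amplitude = 0.25))
      t_lum <- 1 + 0.05 * (tex - 1)       # empty lumina carry no stain texture
      t_bg <- 1 + 0.5 * (tex - 1)
      beta <- 1 + stats::runif(1, -spec$stain_variation, spec$stain_variation)

      tissue <- duct & !lum
      lumen_only <- lum & !deb
      img <- array(0, dim = c(sz, sz, 3))
      # stain jitter applies to stained material; empty lumina are glass and
      # follow the illumination, which varies far less
      beta_lum <- 1 + 0.25 * (beta - 1)
      for (chn in 1:3) {
        plane <- pal$background[chn] * t_bg * beta
        plane[tissue] <- pal$duct[chn] * t_duct[tissue] * beta
        plane[lumen_only] <- pal$lumen[chn] * t_lum[lumen_only] * beta_lum
        plane[deb] <- pal$debris[chn] * t_bg[deb] * beta
        if (spec$blur_sigma > 0) {
          plane <- matrix(as.numeric(EBImage::gblur(plane, sigma = spec$blur_sigma)),
                          sz, sz)
        }
        if (spec$noise_sd > 0) {
          plane <- plane + stats::rnorm(sz * sz, 0, spec$noise_sd)
        }
        img[, , chn] <- clamp(plane, 0, 255)
      }
      tf <- truth$transforms[[z]]
      if (apply_transforms && (tf$angle_deg != 0 || tf$dr != 0 || tf$dc != 0)) {
        for (chn in 1:3) {
          img[, , chn] <- rotate_bilinear(img[, , chn], tf$angle_deg,
                                          center = tf$center,
                                          shift = c(tf$dr, tf$dc),
                                          fill = pal$background[chn] * beta)
        }
      }
      a <- round(clamp(img, 0, 255))
      storage.mode(a) <- "integer"      # 8-bit payload; halves stack memory
      images[[z]] <- a
    }
    section_stack(images, spec$pixel_size_um, spec$slice_thickness_um)
  })
}

#' Generate a complete phantom (truth plus rendered stack)
#'
#' @param spec a [phantom_spec()].
#' @param apply_transforms passed to [render_serial_sections()].
#' @return list with `truth` and `stack`.
#' @export
generate_phantom <- function(spec, apply_transforms = TRUE) {
  truth <- generate_phantom_volume(spec)
  list(truth = truth,
       stack = render_serial_sections(truth, spec, apply_transforms))
}

#' Write a phantom to disk
#'
#' Writes the rendered stack as numbered TIFFs plus a `truth.json` carrying
#' the architecture label, the per-slice rigid perturbations, and the duct and
#' cribra masks (run-length encoded).
#'
#' @param phantom list with `truth` and `stack` from [generate_phantom()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_section_stack(phantom$stack, dir)
  truth <- phantom$truth
  payload <- list(
    architecture = truth$architecture,
    n_sections = truth$spec$n_sections,
    image_size = truth$spec$image_size,
    pixel_size_um = truth$spec$pixel_size_um,
    slice_thickness_um = truth$spec$slice_thickness_um,
    seed = truth$spec$seed,
    transforms = lapply(truth$transforms, function(tf) {
      list(angle_deg = tf$angle_deg, dr = tf$dr, dc = tf$dc, center = tf$center)
    }),
    duct_masks = lapply(truth$duct_masks, rle_encode_mask),
    cribra_masks = lapply(truth$cribra_masks, rle_encode_mask))
  jsonlite::write_json(payload, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
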