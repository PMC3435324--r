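#' Rigid transform between consecutive sections
#'
#' A rotation about a stated center followed by a translation, in the frame in
#' which the registration search ran (a `scale` factor links that frame to the
#' full-resolution frame). Coordinates are row-major and 1-based: the first
#' component of `center` and the translation is the row (y), the second the
#' column (x). A positive angle rotates counter-clockwise in (row, col) space.
#'
#' @param angle_deg rotation angle in degrees.
#' @param dr,dc translation in pixels (rows, columns).
#' @param center rotation center, c(row, col).
#' @param scale factor mapping search-frame displacements to full resolution.
#' @param gamma best normalized cross-correlation achieved (NA if unknown).
#' @param failed logical; TRUE when the pair was flagged as an alignment
#'   failure and the identity transform substituted.
#' @return an object of class `rigid_transform`.
#' @export
rigid_transform <- function(angle_deg = 0, dr = 0, dc = 0,
                            center = c(0, 0), scale = 1,
                            gamma = NA_real_, failed = FALSE) {
  structure(list(angle_deg = angle_deg, dr = dr, dc = dc,
                 center = center, scale = scale,
                 gamma = gamma, failed = failed),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("rigid_transform: angle %.2f deg, shift (%.2f, %.2f) px, gamma %.3f%s\n",
              x$angle_deg, x$dr, x$dc, x$gamma,
              if (isTRUE(x$failed)) " [FAILED]" else ""))
  invisible(x)
}

# Rotate a matrix about `center` by `angle_deg` (bilinear interpolation), then
# translate by `shift` = c(dr, dc), in one resampling pass. Exposed areas get
# `fill`.
rotate_bilinear <- function(mat, angle_deg, center = NULL, shift = c(0, 0),
                            fill = 0) {
  nr <- nrow(mat); nc <- ncol(mat)
  if (is.null(center)) center <- c((nr + 1) / 2, (nc + 1) / 2)
  th <- angle_deg * pi / 180
  co <- cos(th); si <- sin(th)
  rr <- rep(seq_len(nr), times = nc)
  cc <- rep(seq_len(nc), each = nr)
  qr <- rr - shift[1] - center[1]
  qc <- cc - shift[2] - center[2]
  sr <- co * qr + si * qc + center[1]
  sc <- -si * qr + co * qc + center[2]
  matrix(sample_bilinear(mat, sr, sc, fill = fill), nr, nc)
}

#' Apply a rigid transform to an image
#'
#' Rotates about `tf$center` by `tf$angle_deg` and translates by
#' `(tf$dr, tf$dc)` in a single bilinear resampling pass; newly exposed areas
#' are filled with `fill` (black by default, which correlates poorly with
#' tissue).
#'
#' @param image HxW matrix or HxWx3 array.
#' @param tf a [rigid_transform()] expressed in the frame of `image`.
#' @param fill fill value for exposed areas.
#' @return transformed image of the same shape.
#' @export
apply_rigid_transform <- function(image, tf, fill = 0) {
  if (is.matrix(image)) {
    return(rotate_bilinear(image, tf$angle_deg, tf$center, c(tf$dr, tf$dc), fill))
  }
  assert_color_image(image)
  out <- image
  fill <- rep_len(fill, 3)
  for (ch in 1:3) {
    out[, , ch] <- rotate_bilinear(image[, , ch], tf$angle_deg, tf$center,
                                   c(tf$dr, tf$dc), fill[ch])
  }
  out
}

#' Downscale an image for the registration search
#'
#' The search runs at low resolution: the longest side is scaled to
#' `target` (500) pixels, preserving aspect ratio, and the image is converted
#' to grayscale with luminance weights 0.3/0.59/0.11. Images already at or
#' below the target are left unchanged. The returned scale factor maps
#' low-resolution displacements back to full resolution.
#'
#' @param image HxW matrix or HxWx3 array.
#' @param target longest side of the search image in pixels (default 500).
#' @return list with `image` (grayscale matrix) and `scale` (>= 1).
#' @export
downscale_for_search <- function(image, target = 500L) {
  gray <- to_grayscale(image)
  side <- max(dim(gray))
  if (side <= target) return(list(image = gray, scale = 1))
  scale <- side / target
  new_dims <- as.integer(round(dim(gray) / scale))
  small <- EBImage::resize(gray, w = new_dims[1], h = new_dims[2], antialias = TRUE)
  list(image = matrix(as.numeric(small), new_dims[1], new_dims[2]), scale = scale)
}

# Condition signalled when a section contains no foreground object.
empty_section_error <- function(msg = "empty section: no foreground object found") {
  structure(class = c("cribra3d_empty_section", "error", "condition"),
            list(message = msg, call = NULL))
}

#' Extract a centroid-anchored template
#'
#' Otsu-thresholds the red channel (tissue is dark in red for H&E), takes the
#' largest 8-connected foreground object, and crops a `size` x `size` window
#' centered on its centroid. Crops reaching past the image border are padded
#' with the background intensity (median of non-foreground pixels) so the
#' output is always `size` x `size`.
#'
#' @param image HxWx3 array (red channel used) or HxW grayscale matrix.
#' @param size template side in pixels (default 150).
#' @return list with `template` (size x size matrix), `centroid` c(row, col),
#'   and `threshold` (the Otsu cut used).
#' @export
extract_template <- function(image, size = 150L) {
  plane <- if (is.matrix(image)) image else image[, , 1]
  if (min(plane) == max(plane)) stop(empty_section_error())
  thr <- otsu_threshold(plane)
  fg <- plane <= thr                    # stained tissue is the dark class
  if (!any(fg)) stop(empty_section_error())
  lab <- label_mask_2d(fg)
  sizes <- tabulate(lab[lab > 0L])
  big <- which.max(sizes)
  idx <- which(lab == big, arr.ind = TRUE)
  centroid <- c(mean(idx[, 1]), mean(idx[, 2]))
  bg <- stats::median(plane[!fg])
  half <- floor((size - 1) / 2)
  r0 <- round(centroid[1]) - half
  c0 <- round(centroid[2]) - half
  templ <- matrix(bg, size, size)
  rows <- r0:(r0 + size - 1L); cols <- c0:(c0 + size - 1L)
  rin <- rows >= 1 & rows <= nrow(plane)
  cin <- cols >= 1 & cols <= ncol(plane)
  templ[rin, cin] <- plane[rows[rin], cols[cin]]
  list(template = templ, centroid = centroid, threshold = thr, origin = c(r0, c0))
}

# Sliding-window sums of `m` over all P x Q windows, via integral images.
window_sums <- function(m, P, Q) {
  I <- apply(apply(m, 2, cumsum), 1, cumsum)   # transposed integral image
  I <- t(I)
  I <- rbind(0, cbind(0, I))
  M <- nrow(m); N <- ncol(m)
  u <- 1:(M - P + 1); v <- 1:(N - Q + 1)
  I[u + P, v + Q, drop = FALSE] - I[u, v + Q, drop = FALSE] -
    I[u + P, v, drop = FALSE] + I[u, v, drop = FALSE]
}

# Raw cross-correlation sums S(u,v) = sum_xy f(u+x-1, v+y-1) * t(x, y) for all
# valid offsets, computed either with FFTs (large inputs) or directly.
cross_corr_sums <- function(f, t) {
  M <- nrow(f); N <- ncol(f); P <- nrow(t); Q <- ncol(t)
  M2 <- stats::nextn(M, c(2, 3, 5)); N2 <- stats::nextn(N, c(2, 3, 5))
  fp <- matrix(0, M2, N2); fp[1:M, 1:N] <- f
  tp <- matrix(0, M2, N2); tp[1:P, 1:Q] <- t
  cc <- Re(stats::fft(Conj(stats::fft(tp)) * stats::fft(fp), inverse = TRUE)) / (M2 * N2)
  cc[1:(M - P + 1), 1:(N - Q + 1), drop = FALSE]
}

# Internal NCC core working from precomputed base-image statistics, so the
# rotation search can reuse them across candidate angles.
ncc_surface_core <- function(num, win_var, sst, var_floor = 1e-6) {
  denom2 <- win_var * sst
  gamma <- matrix(0, nrow(num), ncol(num))
  ok <- win_var > var_floor & denom2 > 0
  gamma[ok] <- num[ok] / sqrt(denom2[ok])
  clamp(gamma, -1, 1)
}

ncc_precompute_base <- function(f, P, Q) {
  fc <- f - mean(f)                     # conditioning; gamma is shift-invariant
  s1 <- window_sums(fc, P, Q)
  s2 <- window_sums(fc^2, P, Q)
  n <- P * Q
  list(fc = fc, win_var = pmax(s2 - s1^2 / n, 0), n = n)
}

#' Normalized cross-correlation surface
#'
#' Computes `gamma(u, v)`, the normalized cross-correlation between template
#' `t` and image `f` at every valid placement, where `(u, v)` is the 1-based
#' top-left position of the template within `f`:
#' `gamma = sum[(f - fbar_uv)(t - tbar)] / sqrt(sum(f - fbar_uv)^2 * sum(t - tbar)^2)`
#' with `fbar_uv` the mean of `f` under the template at offset `(u, v)`.
#' Values lie in \[-1, 1\] and are invariant to positive affine intensity
#' transforms of either input. Windows with (numerically) zero variance are
#' assigned gamma = 0 so flat background can never win the search.
#'
#' @param f image matrix.
#' @param t template matrix, strictly smaller than `f` in both dimensions and
#'   with nonzero intensity variance.
#' @return an object of class `correlation_surface`: list with `gamma` matrix,
#'   `best_offset` c(u, v), and `best_value`.
#' @export
normalized_cross_correlation <- function(f, t) {
  stopifnot(is.matrix(f), is.matrix(t))
  if (nrow(t) >= nrow(f) || ncol(t) >= ncol(f)) {
    stop("template must be strictly smaller than the image in both dimensions",
         call. = FALSE)
  }
  tc <- t - mean(t)
  sst <- sum(tc^2)
  if (sst <= 0) stop("zero-variance template", call. = FALSE)
  pre <- ncc_precompute_base(f, nrow(t), ncol(t))
  num <- cross_corr_sums(pre$fc, tc)
  gamma <- ncc_surface_core(num, pre$win_var, sst)
  best <- best_offset_of(gamma)
  structure(list(gamma = gamma, best_offset = best$offset, best_value = best$value),
            class = "correlation_surface")
}

# Deterministic argmax: among exact maxima, pick the offset with the smallest
# displacement from `ref` (Euclidean), then smallest row, then column.
best_offset_of <- function(gamma, ref = c(1, 1)) {
  mx <- max(gamma)
  idx <- which(gamma == mx, arr.ind = TRUE)
  if (nrow(idx) > 1L) {
    d <- (idx[, 1] - ref[1])^2 + (idx[, 2] - ref[2])^2
    idx <- idx[order(d, idx[, 1], idx[, 2]), , drop = FALSE]
  }
  list(offset = as.numeric(idx[1, ]), value = mx)
}

# Sample the `size` x `size` template of `img` rotated by `angle` about
# `centroid`, without rotating the whole image.
rotated_template <- function(img, centroid, angle_deg, size, origin, fill) {
  th <- angle_deg * pi / 180
  co <- cos(th); si <- sin(th)
  rows <- origin[1]:(origin[1] + size - 1L)
  cols <- origin[2]:(origin[2] + size - 1L)
  rr <- rep(rows, times = size); cc <- rep(cols, each = size)
  qr <- rr - centroid[1]; qc <- cc - centroid[2]
  sr <- co * qr + si * qc + centroid[1]
  sc <- -si * qr + co * qc + centroid[2]
  matrix(sample_bilinear(img, sr, sc, fill = fill), size, size)
}

#' Find the rigid transform aligning one section to its predecessor
#'
#' Searches rotation first (coarse sweep in `angle_step` degree increments over
#' \code{[-angle_range, angle_range]}, then refinement in `refine_step`
#' increments within one coarse step of the best angle), rotating the
#' unregistered image about the centroid of its largest tissue object, and for
#' each candidate angle finds the translation maximizing the normalized
#' cross-correlation of the centroid-anchored template against the base image.
#' The translation is constrained to at most `max_shift_frac` (20%) of the
#' image side along each axis. If the best correlation falls below
#' `failure_floor` the pair is flagged as an alignment failure and the identity
#' transform is returned so the stack stays complete.
#'
#' Ties in the correlation maximum are broken toward the smallest `|angle|`,
#' then the smallest shift, so the result is deterministic.
#'
#' @param base grayscale matrix: the previously aligned reference section.
#' @param unregistered grayscale matrix of the same size: the section to align.
#' @param template_size template side in pixels (default 150).
#' @param max_shift_frac maximum translation as a fraction of the image side.
#' @param angle_range,angle_step coarse rotation sweep (degrees).
#' @param refine_step refinement step (degrees).
#' @param failure_floor minimum acceptable correlation.
#' @return a [rigid_transform()] (scale = 1, i.e. in the search frame).
#' @export
find_rigid_transform <- function(base, unregistered,
                                 template_size = 150L,
                                 max_shift_frac = 0.20,
                                 angle_range = 20,
                                 angle_step = 1,
                                 refine_step = 0.1,
                                 failure_floor = 0.2) {
  stopifnot(is.matrix(base), is.matrix(unregistered),
            all(dim(base) == dim(unregistered)))
  info <- extract_template(unregistered, size = template_size)
  centroid <- info$centroid
  origin <- info$origin
  bg <- stats::median(unregistered)   # pad value for off-image template samples
  M <- nrow(base); N <- ncol(base)
  P <- Q <- template_size
  if (P >= M || Q >= N) stop("template does not fit inside the image", call. = FALSE)

  pre <- ncc_precompute_base(base, P, Q)

  # offsets allowed by the translation bound
  max_dr <- floor(max_shift_frac * M)
  max_dc <- floor(max_shift_frac * N)
  u <- seq_len(M - P + 1); v <- seq_len(N - Q + 1)
  allowed <- outer(abs(u - origin[1]) <= max_dr, abs(v - origin[2]) <= max_dc)

  eval_angle <- function(angle) {
    t_rot <- rotated_template(unregistered, centroid, angle, template_size,
                              origin, fill = bg)
    tc <- t_rot - mean(t_rot)
    sst <- sum(tc^2)
    if (sst <= 0) return(list(value = -Inf))
    num <- cross_corr_sums(pre$fc, tc)
    gamma <- ncc_surface_core(num, pre$win_var, sst)
    gamma[!allowed] <- -Inf
    best <- best_offset_of(gamma, ref = origin)
    list(value = best$value, offset = best$offset)
  }

  search <- function(angles, best) {
    for (a in angles) {
      res <- eval_angle(a)
      if (res$value > best$value + 1e-12) {
        best <- list(value = res$value, offset = res$offset, angle = a)
      }
    }
    best
  }

  coarse <- seq(-angle_range, angle_range, by = angle_step)
  coarse <- coarse[order(abs(coarse), -sign(coarse))]   # 0 first, ties +ve first
  best <- search(coarse, list(value = -Inf, offset = origin, angle = 0))
  fine <- best$angle + seq(-angle_step, angle_step, by = refine_step)
  fine <- setdiff(fine, best$angle)
  fine <- fine[abs(fine) <= angle_range + angle_step]
  fine <- fine[order(abs(fine - best$angle), -sign(fine - best$angle))]
  best <- search(fine, best)

  if (!is.finite(best$value) || best$value < failure_floor) {
    return(rigid_transform(center = centroid, gamma = max(best$value, -1),
                           failed = TRUE))
  }
  rigid_transform(angle_deg = best$angle,
                  dr = best$offset[1] - origin[1],
                  dc = best$offset[2] - origin[2],
                  center = centroid, scale = 1,
                  gamma = best$value, failed = FALSE)
}

# Map a point from the low-resolution search frame to full resolution
# (pixel centers convention).
map_point_up <- function(p, scale) (p - 0.5) * scale + 0.5

#' Align a serial-section stack
#'
#' The first section is left unchanged; each subsequent section is rigidly
#' registered to its already-aligned predecessor. The search runs at low
#' resolution (longest side `search_size` pixels, grayscale); the optimal
#' rotation and translation are then rescaled (translation multiplied by the
#' scale factor, angle unchanged) and applied to the full-resolution image.
#' Newly exposed areas are filled with black. Per-pair failures (correlation
#' below `failure_floor`, or an empty section) are flagged and the identity
#' transform used; the stack is never aborted.
#'
#' @param stack a [section_stack()] with at least 2 sections.
#' @param search_size longest side of the low-resolution search frame.
#' @inheritParams find_rigid_transform
#' @return list with `stack` (aligned [section_stack()]), `transforms` (list of
#'   [rigid_transform()] in the full-resolution frame; element 1 is the
#'   identity), and `failures` (logical vector per section).
#' @export
align_stack <- function(stack, search_size = 500L,
                        template_size = 150L, max_shift_frac = 0.20,
                        angle_range = 20, angle_step = 1,
                        refine_step = 0.1, failure_floor = 0.2) {
  stopifnot(inherits(stack, "section_stack"), length(stack$images) >= 2L)
  n <- length(stack$images)
  aligned <- vector("list", n)
  transforms <- vector("list", n)
  failures <- logical(n)
  aligned[[1]] <- stack$images[[1]]
  transforms[[1]] <- rigid_transform(gamma = 1)

  for (i in 2:n) {
    ds_base <- downscale_for_search(aligned[[i - 1]], target = search_size)
    ds_un <- downscale_for_search(stack$images[[i]], target = search_size)
    tf_low <- tryCatch(
      find_rigid_transform(ds_base$image, ds_un$image,
                           template_size = template_size,
                           max_shift_frac = max_shift_frac,
                           angle_range = angle_range, angle_step = angle_step,
                           refine_step = refine_step,
                           failure_floor = failure_floor),
      cribra3d_empty_section = function(e) {
        rigid_transform(failed = TRUE, gamma = NA_real_)
      })
    scale <- ds_un$scale
    tf_full <- rigid_transform(angle_deg = tf_low$angle_deg,
                               dr = tf_low$dr * scale,
                               dc = tf_low$dc * scale,
                               center = map_point_up(tf_low$center, scale),
                               scale = scale,
                               gamma = tf_low$gamma,
                               failed = tf_low$failed)
    failures[i] <- tf_full$failed
    aligned[[i]] <- if (tf_full$failed) {
      stack$images[[i]]
    } else {
      # interpolation weights sum to 1 only up to rounding; keep 8-bit range
      clamp(apply_rigid_transform(stack$images[[i]], tf_full, fill = 0), 0, 255)
    }
    transforms[[i]] <- tf_full
  }

  list(stack = section_stack(aligned, stack$pixel_size_um, stack$slice_thickness_um),
       transforms = transforms, failures = failures)
}

#' Write alignment transforms to a JSON file
#'
#' Records, per section pair, the rotation angle (degrees, positive
#' counter-clockwise in row/col space), the translation (rows and columns,
#' full-resolution pixels), the rotation center, the search-frame scale, the
#' best correlation, and the failure flag.
#'
#' @param transforms list of [rigid_transform()] from [align_stack()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_transforms_json <- function(transforms, path) {
  payload <- lapply(transforms, function(tf) {
    list(angle_deg = tf$angle_deg, dr = tf$dr, dc = tf$dc,
         center = tf$center, scale = tf$scale,
         gamma = tf$gamma, failed = tf$failed)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
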