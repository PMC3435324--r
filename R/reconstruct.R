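#' Stack binary cribra masks into an isotropic voxel volume
#'
#' In-plane, masks are downsampled by the factor
#' `slice_thickness_um / pixel_size_um` (about 4.44 for 0.9 um pixels) so that
#' one voxel is approximately `slice_thickness_um` (4 um) on every side; the z
#' axis (one voxel per section) is untouched. Downsampling is by block mean: a
#' voxel is lumen iff at least half of its source pixel block is lumen, which
#' preserves thin but real lumina while suppressing single-pixel noise.
#'
#' @param masks list of logical matrices (per-slice cribra masks), all the
#'   same dimensions.
#' @param pixel_size_um in-plane pixel size (microns); must not exceed
#'   `slice_thickness_um`.
#' @param slice_thickness_um section thickness (microns).
#' @return an object of class `mask_stack`: list with `volume` (3D logical
#'   array, dims x/y/z), `voxel_size_um`, and `n_sections`.
#' @export
downsample_stack <- function(masks, pixel_size_um = 0.9, slice_thickness_um = 4) {
  stopifnot(is.list(masks), length(masks) >= 1L)
  f <- slice_thickness_um / pixel_size_um
  if (f < 1) stop("downsampling factor below 1 (pixel size exceeds slice thickness)",
                  call. = FALSE)
  d <- dim(masks[[1]])
  rbin <- floor((seq_len(d[1]) - 1L) / f) + 1L
  cbin <- floor((seq_len(d[2]) - 1L) / f) + 1L
  nr <- max(rbin); nc <- max(cbin)
  counts <- outer(tabulate(rbin, nr), tabulate(cbin, nc))
  vol <- array(FALSE, dim = c(nr, nc, length(masks)))
  for (k in seq_along(masks)) {
    m <- masks[[k]]
    stopifnot(all(dim(m) == d))
    sums <- rowsum(t(rowsum(m * 1, rbin, reorder = TRUE)), cbin, reorder = TRUE)
    vol[, , k] <- t(sums) / counts >= 0.5
  }
  structure(list(volume = vol, voxel_size_um = slice_thickness_um,
                 n_sections = length(masks)),
            class = "mask_stack")
}

#' Construct a mask_stack directly from a voxel volume
#'
#' Used for phantom ground-truth volumes that are already on the voxel grid.
#'
#' @param volume 3D logical array.
#' @param voxel_size_um voxel edge length in microns.
#' @return a `mask_stack`.
#' @export
mask_stack <- function(volume, voxel_size_um = 4) {
  stopifnot(is.array(volume), length(dim(volume)) == 3L)
  structure(list(volume = volume, voxel_size_um = voxel_size_um,
                 n_sections = dim(volume)[3]),
            class = "mask_stack")
}

#' Label connected luminal components in 3D
#'
#' Components are maximal under face (6-) connectivity by default: in-plane
#' 4-neighbours plus overlap between successive sections, which matches the
#' overlap-based notion of inter-slice connection. 26-connectivity is
#' available via `connectivity`. Each component's voxel count and height (the
#' number of distinct z-sections it occupies) are reported.
#'
#' @param stack a `mask_stack`.
#' @param connectivity 6 (default) or 26.
#' @return list with `components` (data.frame: id, voxels, height_sections,
#'   ordered by decreasing voxel count), `labels` (3D integer array), and
#'   `n_sections`.
#' @export
label_components <- function(stack, connectivity = 6L) {
  stopifnot(inherits(stack, "mask_stack"))
  dims <- dim(stack$volume)
  lab <- label_components_cpp(as.logical(stack$volume), dims, as.integer(connectivity))
  lab <- array(lab, dims)
  idx <- which(lab > 0L)
  if (length(idx) == 0L) {
    return(list(components = data.frame(id = integer(), voxels = integer(),
                                        height_sections = integer()),
                labels = lab, n_sections = stack$n_sections))
  }
  labs <- lab[idx]
  nlab <- max(labs)
  voxels <- tabulate(labs, nbins = nlab)
  z <- (idx - 1L) %/% (dims[1] * dims[2]) + 1L
  key <- unique((as.numeric(labs) - 1) * (dims[3] + 1) + z)
  heights <- tabulate(key %/% (dims[3] + 1) + 1, nbins = nlab)
  comp <- data.frame(id = seq_len(nlab), voxels = voxels,
                     height_sections = heights)
  comp <- comp[order(-comp$voxels, comp$id), ]
  rownames(comp) <- NULL
  list(components = comp, labels = lab, n_sections = stack$n_sections)
}

#' Classify the 3D luminal architecture
#'
#' The specimen is called "bubble" if the largest cribrum (3D luminal
#' component) spans fewer than `bounds[1]` = 25 sections (100 um) in height,
#' "tube" if it spans more than `bounds[2]` = 35 sections (140 um), and
#' "unclear" in between. Stacks shorter than 40 sections are processed but
#' flagged against the inclusion criterion.
#'
#' @param components data.frame from [label_components()] (or the list it
#'   returns), with a `height_sections` column.
#' @param n_sections number of sections in the stack.
#' @param bounds the two height thresholds in sections (default c(25, 35)).
#' @return an object of class `architecture_call`: list with `label`,
#'   `max_height_sections`, `heights`, `bounds`, and `flagged_short`.
#' @export
classify_architecture <- function(components, n_sections, bounds = c(25, 35)) {
  if (is.list(components) && !is.data.frame(components) &&
      !is.null(components$components)) {
    components <- components$components
  }
  heights <- components$height_sections
  if (length(heights) == 0L) {
    warning("no luminal components: architecture is unclear")
    max_h <- 0L
  } else {
    max_h <- max(heights)
  }
  label <- if (length(heights) == 0L) "unclear"
           else if (max_h < bounds[1]) "bubble"
           else if (max_h > bounds[2]) "tube"
           else "unclear"
  flagged <- n_sections < 40L
  if (flagged) warning("stack has fewer than 40 sections (inclusion criterion)")
  structure(list(label = label, max_height_sections = max_h,
                 heights = heights, bounds = bounds, flagged_short = flagged),
            class = "architecture_call")
}

#' @export
print.architecture_call <- function(x, ...) {
  cat(sprintf("architecture: %s (largest cribrum %d sections; bounds %d/%d)\n",
              x$label, x$max_height_sections, x$bounds[1], x$bounds[2]))
  invisible(x)
}

# Maximal contiguous-run length arrays along one axis (1 = x, 2 = y, 3 = z):
# each lumen voxel receives the length of the maximal run of lumen voxels
# through it along that axis; non-lumen voxels get 0.
run_lengths_axis <- function(volume, axis) {
  p <- switch(axis, `1` = c(1L, 2L, 3L), `2` = c(2L, 1L, 3L), `3` = c(3L, 1L, 2L))
  v <- if (axis == 1L) volume else aperm(volume, p)
  d1 <- dim(v)[1]
  vec <- as.logical(v)
  pos <- which(vec)
  out <- integer(length(vec))
  if (length(pos)) {
    line_id <- (pos - 1L) %/% d1
    new_run <- c(TRUE, diff(pos) != 1L | diff(line_id) != 0L)
    run_id <- cumsum(new_run)
    lens <- tabulate(run_id)
    out[pos] <- lens[run_id]
  }
  res <- array(out, dim(v))
  if (axis == 1L) res else aperm(res, order(p))
}

#' Contiguous-run extents through one lumen voxel
#'
#' For a voxel inside the luminal space, returns the maximal contiguous runs
#' of lumen voxels through it along x (length), y (width) and z (height, the
#' section axis), and the aspect ratio height/length. Runs are maximal through
#' the voxel, not one-sided. Voxels outside the luminal space are rejected.
#'
#' @param stack a `mask_stack`.
#' @param voxel integer vector c(x, y, z) (array indices).
#' @return list with `length`, `width`, `height`, `aspect_ratio`.
#' @export
voxel_run_lengths <- function(stack, voxel) {
  stopifnot(inherits(stack, "mask_stack"), length(voxel) == 3L)
  vol <- stack$volume
  if (!vol[voxel[1], voxel[2], voxel[3]]) {
    stop("voxel is not inside the luminal space", call. = FALSE)
  }
  run1d <- function(line, pos) {
    lo <- pos; while (lo > 1L && line[lo - 1L]) lo <- lo - 1L
    hi <- pos; while (hi < length(line) && line[hi + 1L]) hi <- hi + 1L
    hi - lo + 1L
  }
  len <- run1d(vol[, voxel[2], voxel[3]], voxel[1])
  wid <- run1d(vol[voxel[1], , voxel[3]], voxel[2])
  hei <- run1d(vol[voxel[1], voxel[2], ], voxel[3])
  list(length = len, width = wid, height = hei, aspect_ratio = hei / len)
}

#' Sample per-voxel aspect ratios from a reconstruction
#'
#' Samples `n` lumen voxels uniformly with replacement (deterministic given
#' `seed`) and returns, for each, the contiguous-run extents along x/y/z and
#' the aspect ratio height/length, as plotted against height to contrast
#' bubble-like and tube-like reconstructions.
#'
#' @param stack a `mask_stack` with at least one lumen voxel.
#' @param n number of voxels to sample (default 10000).
#' @param seed random seed.
#' @return data.frame with columns `length`, `width`, `height`,
#'   `aspect_ratio`.
#' @export
sample_aspect_ratios <- function(stack, n = 10000L, seed = 1L) {
  stopifnot(inherits(stack, "mask_stack"))
  lumen <- which(stack$volume)
  if (length(lumen) == 0L) stop("empty lumen: nothing to sample", call. = FALSE)
  lx <- run_lengths_axis(stack$volume, 1L)
  ly <- run_lengths_axis(stack$volume, 2L)
  lz <- run_lengths_axis(stack$volume, 3L)
  picks <- with_seed(seed, sample(lumen, size = n, replace = TRUE))
  data.frame(length = lx[picks], width = ly[picks], height = lz[picks],
             aspect_ratio = lz[picks] / lx[picks])
}

#' Least-squares line fit
#'
#' Ordinary least squares of y on x, reported as slope, intercept and the
#' Euclidean norm of the residuals (the fit-quality figure quoted with the
#' aspect-ratio-vs-height fits).
#'
#' @param x,y numeric vectors; at least two distinct x values.
#' @return an object of class `linear_fit`: list with `slope`, `intercept`,
#'   `norm_of_residuals`.
#' @export
fit_line <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  if (length(unique(x)) < 2L) stop("all x values identical: fit undefined", call. = FALSE)
  fit <- stats::lm(y ~ x)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 norm_of_residuals = sqrt(sum(stats::residuals(fit)^2))),
            class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("y = %.2fx+%.2f, norm of residuals %.1f\n",
              x$slope, x$intercept, x$norm_of_residuals))
  invisible(x)
}

#' Plot aspect ratio against height
#'
#' Scatter of the per-voxel aspect ratio (height/length) as a function of
#' height, optionally with a least-squares line.
#'
#' @param samples data.frame from [sample_aspect_ratios()].
#' @param fit optional `linear_fit` to overlay.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `samples`.
#' @export
plot_aspect_ratios <- function(samples, fit = NULL, ...) {
  graphics::plot(samples$height, samples$aspect_ratio,
                 xlab = "height (voxels)", ylab = "aspect ratio (height/length)",
                 pch = 16, cex = 0.4, col = grDevices::rgb(0, 0, 0.6, 0.3), ...)
  if (!is.null(fit)) graphics::abline(fit$intercept, fit$slope, col = "red", lwd = 2)
  invisible(samples)
}

# ---- surface meshing -------------------------------------------------------

#' Extract a closed triangulated surface of the lumen volume
#'
#' Builds the boundary surface of the binary volume (the 0.5 isosurface of the
#' voxel indicator function realized as voxel faces), triangulated with
#' consistent outward orientation, vertices in micron coordinates
#' (z = section index x voxel size), and area-weighted smoothed vertex
#' normals. The mesh is watertight for interior components.
#'
#' @param stack a `mask_stack` with a nonempty volume.
#' @return an object of class `voxel_mesh`: list with `vertices` (N x 3,
#'   microns, columns x/y/z), `faces` (M x 3, 1-based, outward-oriented),
#'   `normals` (N x 3), and `voxel_size_um`.
#' @export
extract_surface <- function(stack) {
  stopifnot(inherits(stack, "mask_stack"))
  vol <- stack$volume
  if (!any(vol)) stop("empty volume: no surface to extract", call. = FALSE)
  d <- dim(vol)
  vs <- stack$voxel_size_um

  shift_neighbor <- function(axis, step) {
    out <- array(FALSE, d)
    if (axis == 1L) {
      if (step == 1L) out[1:(d[1] - 1), , ] <- vol[2:d[1], , ]
      else out[2:d[1], , ] <- vol[1:(d[1] - 1), , ]
    } else if (axis == 2L) {
      if (step == 1L) out[, 1:(d[2] - 1), ] <- vol[, 2:d[2], ]
      else out[, 2:d[2], ] <- vol[, 1:(d[2] - 1), ]
    } else {
      if (step == 1L) out[, , 1:(d[3] - 1)] <- vol[, , 2:d[3]]
      else out[, , 2:d[3]] <- vol[, , 1:(d[3] - 1)]
    }
    out
  }

  quads <- list()
  for (spec in list(list(1L, 1L), list(1L, -1L), list(2L, 1L), list(2L, -1L),
                    list(3L, 1L), list(3L, -1L))) {
    axis <- spec[[1]]; step <- spec[[2]]
    face <- vol & !shift_neighbor(axis, step)
    idx <- which(face, arr.ind = TRUE)
    if (nrow(idx) == 0L) next
    i <- idx[, 1]; j <- idx[, 2]; k <- idx[, 3]
    # corner coordinates on the lattice (voxel (i,j,k) spans [i-1,i] etc.)
    corners <- switch(paste0(axis, step > 0),
      "1TRUE"  = list(cbind(i, j - 1, k - 1), cbind(i, j, k - 1),
                      cbind(i, j, k),         cbind(i, j - 1, k)),
      "1FALSE" = list(cbind(i - 1, j - 1, k), cbind(i - 1, j, k),
                      cbind(i - 1, j, k - 1), cbind(i - 1, j - 1, k - 1)),
      "2TRUE"  = list(cbind(i - 1, j, k - 1), cbind(i - 1, j, k),
                      cbind(i, j, k),         cbind(i, j, k - 1)),
      "2FALSE" = list(cbind(i - 1, j - 1, k), cbind(i - 1, j - 1, k - 1),
                      cbind(i, j - 1, k - 1), cbind(i, j - 1, k)),
      "3TRUE"  = list(cbind(i - 1, j - 1, k), cbind(i, j - 1, k),
                      cbind(i, j, k),         cbind(i - 1, j, k)),
      "3FALSE" = list(cbind(i - 1, j - 1, k - 1), cbind(i - 1, j, k - 1),
                      cbind(i, j, k - 1),         cbind(i, j - 1, k - 1)))
    key_of <- function(m) m[, 1] + (d[1] + 1) * (m[, 2] + (d[2] + 1) * m[, 3])
    quads[[length(quads) + 1L]] <- cbind(key_of(corners[[1]]), key_of(corners[[2]]),
                                         key_of(corners[[3]]), key_of(corners[[4]]))
  }

  qk <- do.call(rbind, quads)             # one row of 4 corner keys per quad
  ukeys <- unique(as.vector(qk))
  vz <- floor(ukeys / ((d[1] + 1) * (d[2] + 1)))
  rem <- ukeys - vz * (d[1] + 1) * (d[2] + 1)
  vy <- floor(rem / (d[1] + 1))
  vx <- rem - vy * (d[1] + 1)
  vertices <- cbind(x = vx, y = vy, z = vz) * vs

  # quads -> 2 triangles each, preserving winding
  q1 <- match(qk[, 1], ukeys); q2 <- match(qk[, 2], ukeys)
  q3 <- match(qk[, 3], ukeys); q4 <- match(qk[, 4], ukeys)
  faces <- rbind(cbind(q1, q2, q3), cbind(q1, q3, q4))
  colnames(faces) <- NULL

  # area-weighted vertex normals, normalized (smoothed normals)
  v1 <- vertices[faces[, 1], , drop = FALSE]
  v2 <- vertices[faces[, 2], , drop = FALSE]
  v3 <- vertices[faces[, 3], , drop = FALSE]
  e1 <- v2 - v1; e2 <- v3 - v1
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  normals <- matrix(0, nrow(vertices), 3)
  for (s in 1:3) {
    acc <- rowsum(fn, faces[, s])
    ids <- as.integer(rownames(acc))
    normals[ids, ] <- normals[ids, ] + acc
  }
  nrm <- sqrt(rowSums(normals^2))
  nrm[nrm == 0] <- 1
  normals <- normals / nrm

  structure(list(vertices = vertices, faces = faces, normals = normals,
                 voxel_size_um = vs),
            class = "voxel_mesh")
}

#' Enclosed volume of a closed mesh
#'
#' Signed volume by the divergence theorem; positive for outward-oriented
#' closed surfaces. Units are cubic microns when the mesh came from
#' [extract_surface()].
#'
#' @param mesh a `voxel_mesh`.
#' @return volume in um^3.
#' @export
mesh_volume <- function(mesh) {
  v1 <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  v2 <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  v3 <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  cross <- cbind(v2[, 2] * v3[, 3] - v2[, 3] * v3[, 2],
                 v2[, 3] * v3[, 1] - v2[, 1] * v3[, 3],
                 v2[, 1] * v3[, 2] - v2[, 2] * v3[, 1])
  sum(rowSums(v1 * cross)) / 6
}

#' Write a mesh as Wavefront OBJ
#' @param mesh a `voxel_mesh`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mesh_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# cribra lumen surface (microns)", con)
  writeLines(sprintf("v %g %g %g", mesh$vertices[, 1], mesh$vertices[, 2],
                     mesh$vertices[, 3]), con)
  writeLines(sprintf("vn %g %g %g", mesh$normals[, 1], mesh$normals[, 2],
                     mesh$normals[, 3]), con)
  writeLines(sprintf("f %d//%d %d//%d %d//%d",
                     mesh$faces[, 1], mesh$faces[, 1],
                     mesh$faces[, 2], mesh$faces[, 2],
                     mesh$faces[, 3], mesh$faces[, 3]), con)
  invisible(path)
}

#' Write a mesh as ASCII PLY
#' @inheritParams write_mesh_obj
#' @export
write_mesh_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property float x", "property float y", "property float z",
               "property float nx", "property float ny", "property float nz",
               sprintf("element face %d", nrow(mesh$faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%g %g %g %g %g %g",
                     mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3],
                     mesh$normals[, 1], mesh$normals[, 2], mesh$normals[, 3]), con)
  writeLines(sprintf("3 %d %d %d", mesh$faces[, 1] - 1L,
                     mesh$faces[, 2] - 1L, mesh$faces[, 3] - 1L), con)
  invisible(path)
}
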