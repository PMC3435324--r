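#' @useDynLib cribra3d, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Run `code` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Luminance weights shared by the grayscale conversion and the V plane.
LUMA_WEIGHTS <- c(r = 0.3, g = 0.59, b = 0.11)

is_color_image <- function(x) is.array(x) && length(dim(x)) == 3L && dim(x)[3] == 3L

assert_color_image <- function(x, what = "image") {
  if (!is_color_image(x)) {
    stop(sprintf("`%s` must be an HxWx3 array (8-bit RGB, values in [0,255])", what),
         call. = FALSE)
  }
  invisible(x)
}

#' Convert an RGB image to grayscale
#'
#' Luminance-weighted conversion with weights 0.3/0.59/0.11 on the red, green
#' and blue channels, matching the V plane of [rgb_to_custom_hsv()] so that the
#' registration search and the segmentation operate on the same intensity scale.
#'
#' @param image an HxWx3 numeric array with values in \[0, 255\], or an HxW
#'   matrix (returned unchanged).
#' @return an HxW numeric matrix in \[0, 255\].
#' @export
to_grayscale <- function(image) {
  if (is.matrix(image)) return(image)
  assert_color_image(image)
  LUMA_WEIGHTS[["r"]] * image[, , 1] +
    LUMA_WEIGHTS[["g"]] * image[, , 2] +
    LUMA_WEIGHTS[["b"]] * image[, , 3]
}

# Dice coefficient between two logical masks.
dice <- function(a, b) {
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}

# Disc structuring element of the given radius (odd-sized EBImage brush).
disc_kernel <- function(radius) EBImage::makeBrush(2L * radius + 1L, shape = "disc")

as_mask <- function(x) {
  m <- x > 0.5
  storage.mode(m) <- "logical"
  if (!is.matrix(m)) m <- matrix(m, nrow = dim(x)[1])
  m
}

# Binary morphology wrappers; EBImage works on numeric 0/1 matrices.
mask_open <- function(mask, radius) {
  if (radius <= 0) return(mask)
  as_mask(EBImage::opening(mask * 1, disc_kernel(radius)))
}

mask_close <- function(mask, radius) {
  if (radius <= 0) return(mask)
  as_mask(EBImage::closing(mask * 1, disc_kernel(radius)))
}

mask_erode <- function(mask, radius) {
  if (radius <= 0) return(mask)
  as_mask(EBImage::erode(mask * 1, disc_kernel(radius)))
}

mask_fill_holes <- function(mask) {
  as_mask(EBImage::fillHull(mask * 1))
}

# 2D connected-component labels (8-connectivity) via the 3D labeller.
label_mask_2d <- function(mask) {
  dims <- dim(mask)
  lab <- label_components_cpp(as.logical(mask), c(dims, 1L), 26L)
  matrix(lab, dims[1], dims[2])
}

# Remove connected objects with pixel area strictly below `min_area`.
remove_small_objects <- function(mask, min_area) {
  if (!any(mask)) return(mask)
  lab <- label_mask_2d(mask)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_area)
  mask & matrix(lab %in% keep, nrow(mask), ncol(mask))
}

# Remove connected objects that touch the image border.
clear_border_objects <- function(mask) {
  if (!any(mask)) return(mask)
  lab <- label_mask_2d(mask)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border <- border[border > 0L]
  if (length(border) == 0L) return(mask)
  mask & !matrix(lab %in% border, nrow(mask), ncol(mask))
}

# Bilinear sampling of matrix `img` at continuous (row, col) positions.
# Positions outside the image return `fill`.
sample_bilinear <- function(img, r, c, fill = 0) {
  nr <- nrow(img); nc <- ncol(img)
  out <- rep(fill, length(r))
  inside <- r >= 1 & r <= nr & c >= 1 & c <= nc
  if (!any(inside)) return(out)
  r <- r[inside]; c <- c[inside]
  r0 <- clamp(floor(r), 1, nr); c0 <- clamp(floor(c), 1, nc)
  r1 <- pmin(r0 + 1, nr);       c1 <- pmin(c0 + 1, nc)
  fr <- r - r0; fc <- c - c0
  v <- img[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
       img[cbind(r1, c0)] * fr       * (1 - fc) +
       img[cbind(r0, c1)] * (1 - fr) * fc +
       img[cbind(r1, c1)] * fr       * fc
  out[inside] <- v
  out
}

# Smooth multiplicative random field: coarse uniform grid, bilinearly upsampled.
smooth_random_field <- function(nr, nc, grid = 24L, amplitude = 0.15) {
  g <- matrix(stats::runif(grid * grid, 1 - amplitude, 1 + amplitude), grid, grid)
  rr <- seq(1, grid, length.out = nr)
  cc <- seq(1, grid, length.out = nc)
  pts <- expand.grid(r = rr, c = cc)
  matrix(sample_bilinear(g, pts$r, pts$c, fill = 1), nr, nc)
}
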