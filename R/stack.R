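#' Construct a serial-section stack
#'
#' An ordered list of 8-bit RGB section images of one pre-cropped ductal region
#' of interest, with the physical metadata needed downstream: in-plane pixel
#' size (microns) and section thickness (microns).
#'
#' @param images list of HxWx3 numeric arrays with values in \[0, 255\]; all
#'   the same dimensions.
#' @param pixel_size_um in-plane pixel size in microns (default 0.9).
#' @param slice_thickness_um section thickness in microns (default 4).
#' @return an object of class `section_stack`.
#' @export
section_stack <- function(images, pixel_size_um = 0.9, slice_thickness_um = 4) {
  stopifnot(is.list(images), length(images) >= 1L)
  dims <- lapply(images, dim)
  for (i in seq_along(images)) {
    assert_color_image(images[[i]], sprintf("images[[%d]]", i))
    if (!identical(dims[[i]], dims[[1]])) {
      stop("all section images must have identical dimensions", call. = FALSE)
    }
    rng <- range(images[[i]])
    if (rng[1] < 0 || rng[2] > 255) {
      stop("section images must have values in [0, 255]", call. = FALSE)
    }
  }
  stopifnot(pixel_size_um > 0, slice_thickness_um > 0)
  structure(list(images = images,
                 pixel_size_um = pixel_size_um,
                 slice_thickness_um = slice_thickness_um),
            class = "section_stack")
}

#' @export
print.section_stack <- function(x, ...) {
  d <- dim(x$images[[1]])
  cat(sprintf("section_stack: %d sections of %dx%d px (%.2f um/px, %.1f um thick)\n",
              length(x$images), d[1], d[2], x$pixel_size_um, x$slice_thickness_um))
  invisible(x)
}

#' @export
length.section_stack <- function(x) length(x$images)

read_image_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image format: ", ext, call. = FALSE))
  if (length(dim(img)) == 2L) {
    img <- array(rep(img, 3), dim = c(dim(img), 3L))
  }
  img[, , 1:3, drop = FALSE] * 255
}

write_image_file <- function(img, path) {
  ext <- tolower(tools::file_ext(path))
  img01 <- clamp(img / 255, 0, 1)
  switch(ext,
    tif = , tiff = tiff::writeTIFF(img01, path, bits.per.sample = 8L),
    png = png::writePNG(img01, path),
    stop("unsupported image format: ", ext, call. = FALSE))
  invisible(path)
}

#' Read a serial-section stack from a directory
#'
#' Reads all TIFF/PNG files in `dir` in lexicographic order (the numbered
#' `slice_000.tif`, `slice_001.tif`, ... convention sorts correctly).
#'
#' @param dir directory containing the slice images.
#' @inheritParams section_stack
#' @return a [section_stack()].
#' @export
read_section_stack <- function(dir, pixel_size_um = 0.9, slice_thickness_um = 4) {
  files <- sort(list.files(dir, pattern = "\\.(tif|tiff|png)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (length(files) == 0L) stop("no TIFF/PNG images found in ", dir, call. = FALSE)
  section_stack(lapply(files, read_image_file),
                pixel_size_um = pixel_size_um,
                slice_thickness_um = slice_thickness_um)
}

#' Write a serial-section stack as numbered TIFF files
#'
#' @param stack a [section_stack()].
#' @param dir output directory (created if missing).
#' @param format "tif" or "png".
#' @return the vector of files written, invisibly.
#' @export
write_section_stack <- function(stack, dir, format = "tif") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- file.path(dir, sprintf("slice_%03d.%s", seq_along(stack$images) - 1L, format))
  for (i in seq_along(stack$images)) write_image_file(stack$images[[i]], files[i])
  invisible(files)
}

#' Write binary masks as 1-bit-style PNG files
#'
#' @param masks list of logical matrices.
#' @param dir output directory.
#' @param prefix filename prefix.
#' @return files written, invisibly.
#' @export
write_mask_stack <- function(masks, dir, prefix = "mask") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- file.path(dir, sprintf("%s_%03d.png", prefix, seq_along(masks) - 1L))
  for (i in seq_along(masks)) png::writePNG(masks[[i]] * 1, files[i])
  invisible(files)
}

#' Read binary masks written by [write_mask_stack()]
#' @param dir directory of mask PNGs.
#' @param prefix filename prefix used when writing.
#' @return list of logical matrices.
#' @export
read_mask_stack <- function(dir, prefix = "mask") {
  files <- sort(list.files(dir, pattern = paste0("^", prefix, "_\\d+\\.png$"),
                           full.names = TRUE))
  if (length(files) == 0L) stop("no mask PNGs found in ", dir, call. = FALSE)
  lapply(files, function(f) {
    m <- png::readPNG(f)
    if (length(dim(m)) == 3L) m <- m[, , 1]
    m > 0.5
  })
}

# Run-length encoding of a logical mask for compact JSON truth files.
rle_encode_mask <- function(mask) {
  r <- rle(as.vector(mask))
  list(dim = dim(mask), lengths = r$lengths, values = as.integer(r$values))
}

rle_decode_mask <- function(enc) {
  v <- inverse.rle(list(lengths = as.integer(enc$lengths),
                        values = as.logical(enc$values)))
  matrix(v, enc$dim[1], enc$dim[2])
}
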