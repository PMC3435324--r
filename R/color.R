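#' Per-channel linear contrast stretch
#'
#' H&E photomicrograph intensities typically occupy only the upper part of the
#' 8-bit range (about 100--255). Each channel's observed \[min, max\] is mapped
#' linearly onto \[0, 255\], clipping values outside the limits, to restore
#' the full dynamic range before the hue transform is applied. The limits are
#' the 1st and 99th intensity percentiles rather than the literal extremes:
#' single-pixel noise deviates would otherwise dictate the map (the common
#' saturated-limits convention, e.g. MATLAB's `stretchlim` default). A channel
#' with no spread between the limits is left unchanged, since its stretch is
#' undefined.
#'
#' @param image HxWx3 numeric array, values in \[0, 255\].
#' @param probs lower/upper percentile limits (default c(0.01, 0.99)).
#' @return HxWx3 numeric array spanning \[0, 255\] per non-constant channel.
#' @export
stretch_contrast <- function(image, probs = c(0.01, 0.99)) {
  assert_color_image(image)
  out <- image
  for (ch in 1:3) {
    plane <- image[, , ch]
    lim <- stats::quantile(plane, probs, names = FALSE, type = 7)
    if (lim[2] > lim[1]) {
      out[, , ch] <- clamp((plane - lim[1]) * (255 / (lim[2] - lim[1])), 0, 255)
    }
  }
  out
}

#' Custom HSV decomposition for H&E images
#'
#' Computes the value plane `V = 0.3*Ir + 0.59*Ig + 0.11*Ib`, the chroma planes
#' `Cr = Ir - V` and `Cb = Ib - V`, the hue `H = arctan2(Cb, Cr)` (radians, in
#' (-pi, pi\]) and the saturation `S = sqrt(Cr^2 + Cb^2)` (chroma magnitude,
#' the natural companion of the arctan2 hue). Purple nuclear tissue falls in
#' the quadrant where both Cr and Cb are positive, i.e. H above roughly 0.7.
#' All planes are returned in floating point; nothing is truncated before
#' thresholding.
#'
#' @param image HxWx3 numeric array, values in \[0, 255\].
#' @return a list of class `custom_hsv` with matrices `V`, `Cr`, `Cb`, `H`, `S`.
#' @export
rgb_to_custom_hsv <- function(image) {
  assert_color_image(image)
  V <- LUMA_WEIGHTS[["r"]] * image[, , 1] +
       LUMA_WEIGHTS[["g"]] * image[, , 2] +
       LUMA_WEIGHTS[["b"]] * image[, , 3]
  Cr <- image[, , 1] - V
  Cb <- image[, , 3] - V
  structure(list(V = V, Cr = Cr, Cb = Cb,
                 H = atan2(Cb, Cr), S = sqrt(Cr^2 + Cb^2)),
            class = "custom_hsv")
}

#' Otsu threshold over a 256-bin histogram
#'
#' Returns the cut value `k` (in 0..254) maximizing the between-class variance
#' of the two populations `x <= k` and `x > k`, computed over the 256-bin
#' histogram of the (clamped, floored) 8-bit values. Ties are broken toward the
#' smallest cut so the result is deterministic.
#'
#' @param values numeric vector or matrix of intensities on the 0--255 scale.
#' @return the threshold `k`; foreground is conventionally `values > k`.
#' @export
otsu_threshold <- function(values) {
  v <- as.numeric(values)
  v <- v[is.finite(v)]
  if (length(v) < 2L || min(v) == max(v)) {
    stop("otsu_threshold() needs at least two distinct finite values", call. = FALSE)
  }
  bins <- floor(clamp(v, 0, 255))
  h <- tabulate(bins + 1L, nbins = 256L)
  n <- sum(h)
  lv <- 0:255
  w0 <- cumsum(as.numeric(h))           # counts in class {<= k}
  m0 <- cumsum(as.numeric(h) * lv)      # intensity sums in class {<= k}
  mu_total <- m0[256]
  w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, 256)
  mean0 <- m0[valid] / w0[valid]
  mean1 <- (mu_total - m0[valid]) / w1[valid]
  bcv[valid] <- w0[valid] * w1[valid] * (mean0 - mean1)^2
  which.max(bcv) - 1L                   # which.max takes the first (smallest) maximizer
}
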