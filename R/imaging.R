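#' Fluorescence image container
#'
#' A single-channel non-negative intensity image, optionally calibrated
#' (pixel size) and tagged with the acquisition day.
#'
#' @param pixels numeric matrix of intensities, all `>= 0`.
#' @param pixel_size optional pixel edge length (mm/pixel).
#' @param day optional acquisition-day tag.
#' @return object of class `fluor_image`.
#' @export
fluor_image <- function(pixels, pixel_size = NULL, day = NULL) {
  pixels <- as.matrix(pixels)
  if (length(pixels) == 0L) stop("'pixels' must be non-empty")
  if (!is.numeric(pixels) || any(pixels < 0))
    stop("intensities must be numeric and non-negative")
  structure(list(pixels = pixels, pixel_size = pixel_size, day = day),
            class = "fluor_image")
}

#' Read a fluorescence image from TIFF or PNG
#'
#' Multi-channel images are reduced to one channel (default: green, the
#' EGFP emission channel).
#'
#' @param path image file path (`.tif`, `.tiff` or `.png`).
#' @param channel channel index for multi-channel images (default 2 = green),
#'   or `"mean"` to average channels.
#' @param pixel_size,day passed to [fluor_image()].
#' @return a [fluor_image()].
#' @export
read_fluor_image <- function(path, channel = 2L, pixel_size = NULL,
                             day = NULL) {
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    tif = , tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("reading TIFF requires the 'tiff' package")
      tiff::readTIFF(path)
    },
    png = {
      if (!requireNamespace("png", quietly = TRUE))
        stop("reading PNG requires the 'png' package")
      png::readPNG(path)
    },
    stop("unsupported image format: ", ext))
  if (length(dim(px)) == 3L) {
    px <- if (identical(channel, "mean")) apply(px, c(1, 2), mean)
          else px[, , min(channel, dim(px)[3])]
  }
  fluor_image(px, pixel_size = pixel_size, day = day)
}

#' Quantify transfection from a fluorescence image
#'
#' The transfected region is the set of pixels with intensity strictly above
#' the threshold; the same threshold must be applied to every image of a
#' comparison. Reported are the transfected area (pixel count, or mm^2 when
#' the image is calibrated), the mean fluorescence intensity over that
#' region (0 when empty), and the integrated density — the product of area
#' and mean intensity.
#'
#' @param image a [fluor_image()].
#' @param threshold intensity threshold, `>= 0`.
#' @return object of class `transfection_metrics`: `area_px`, `area`
#'   (calibrated, `NA` without `pixel_size`), `mean_intensity`,
#'   `integrated_density`, `day`.
#' @export
quantify <- function(image, threshold) {
  stopifnot(inherits(image, "fluor_image"), threshold >= 0)
  sel <- image$pixels > threshold
  area_px <- sum(sel)
  mean_int <- if (area_px > 0) mean(image$pixels[sel]) else 0
  area <- if (!is.null(image$pixel_size)) area_px * image$pixel_size^2
          else NA_real_
  structure(list(area_px = area_px, area = area, mean_intensity = mean_int,
                 integrated_density = area_px * mean_int, day = image$day),
            class = "transfection_metrics")
}

#' @export
print.transfection_metrics <- function(x, ...) {
  cat(sprintf(
    "<transfection_metrics> area %d px, mean intensity %.4g, ID %.5g\n",
    x$area_px, x$mean_intensity, x$integrated_density))
  invisible(x)
}

#' Generate a synthetic fluorescence image
#'
#' Gaussian expression blobs plus non-negative background noise, for testing
#' the quantification pipeline. Deterministic for a given seed.
#'
#' @param width,height image dimensions (pixels).
#' @param centers 2-column matrix of blob centers (x, y in pixels), or
#'   `NULL` for none.
#' @param radii blob Gaussian radii (pixels), recycled over blobs.
#' @param amplitudes blob peak intensities, `>= 0`, recycled.
#' @param noise background noise scale (half-normal, i.e. `|N(0, noise)|`);
#'   0 for none.
#' @param seed optional RNG seed fixing the noise.
#' @param pixel_size,day passed to [fluor_image()].
#' @return a [fluor_image()].
#' @export
synth_image <- function(width, height, centers = NULL, radii = 1,
                        amplitudes = 1, noise = 0, seed = NULL,
                        pixel_size = NULL, day = NULL) {
  stopifnot(width >= 1, height >= 1, all(amplitudes >= 0), noise >= 0)
  px <- matrix(0, nrow = height, ncol = width)
  xs <- matrix(rep(seq_len(width), each = height), nrow = height)
  ys <- matrix(rep(seq_len(height), width), nrow = height)
  if (!is.null(centers)) {
    centers <- matrix(centers, ncol = 2)
    nb <- nrow(centers)
    radii <- rep_len(radii, nb)
    amplitudes <- rep_len(amplitudes, nb)
    for (b in seq_len(nb)) {
      d2 <- (xs - centers[b, 1])^2 + (ys - centers[b, 2])^2
      px <- px + amplitudes[b] * exp(-d2 / (2 * radii[b]^2))
    }
  }
  if (noise > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                          globalenv())
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
    }
    px <- px + abs(matrix(stats::rnorm(width * height, sd = noise),
                          nrow = height))
  }
  fluor_image(px, pixel_size = pixel_size, day = day)
}
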