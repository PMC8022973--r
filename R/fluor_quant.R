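# Pixel-threshold scoring of per-worm fluorescence micrographs: crop,
# invert, brightness/contrast/intensity adjustment, then counting pixels
# whose deviation from a reference background gray exceeds an integer
# "shades of variance" threshold.

#' 8-bit grayscale image container
#'
#' Wraps an integer matrix of pixel values in \[0, 255\], origin top-left,
#' row-major (rows are image rows). All image operations in the package
#' consume and produce this class.
#'
#' @param mat Numeric matrix; values must be whole numbers in \[0, 255\].
#' @return A `gray_image` (integer matrix subclass).
#' @export
gray_image <- function(mat) {
  if (!is.matrix(mat) || nrow(mat) < 1L || ncol(mat) < 1L)
    stop("mat must be a matrix with dimensions >= 1x1", call. = FALSE)
  if (any(!is.finite(mat)) || any(mat < 0) || any(mat > 255) ||
      any(mat != round(mat)))
    stop("pixel values must be integers in [0, 255]", call. = FALSE)
  structure(matrix(as.integer(mat), nrow(mat), ncol(mat)),
            class = c("gray_image", "matrix", "array"))
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("gray_image %d x %d, range [%d, %d]\n",
              nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}

#' Rectangular region of interest, 0-based and half-open
#'
#' Pixel coordinates follow the convention `[x0, x1) x [y0, y1)` with `x`
#' the column axis, `y` the row axis, and the origin at the top-left pixel
#' having `(x, y) = (0, 0)`.
#'
#' @param x0,y0,x1,y1 Integer corners with `x1 > x0`, `y1 > y0`.
#' @return A `bounding_box`.
#' @export
bounding_box <- function(x0, y0, x1, y1) {
  v <- c(x0 = x0, y0 = y0, x1 = x1, y1 = y1)
  if (any(!is.finite(v)) || any(v != round(v)))
    stop("box coordinates must be finite integers", call. = FALSE)
  if (x1 <= x0 || y1 <= y0 || x0 < 0 || y0 < 0)
    stop("box must satisfy 0 <= x0 < x1 and 0 <= y0 < y1", call. = FALSE)
  structure(as.list(as.integer(v)), names = names(v), class = "bounding_box")
}

#' Scoring parameters for the pixel-threshold statistic
#'
#' @param brightness_pct,contrast_pct,intensity_pct Signed percentages in
#'   \[-100, 500\]. Defaults are the adjustment used for the processed
#'   micrographs: brightness -17, contrast +71, intensity -27.
#' @param background_gray Reference background gray value in \[0, 255\];
#'   default 209 (hex D1).
#' @param variance Integer threshold in \[0, 255\]: a pixel is counted when
#'   its absolute deviation from `background_gray` strictly exceeds it.
#' @return A `quant_config` list.
#' @export
quant_config <- function(brightness_pct = -17, contrast_pct = 71,
                         intensity_pct = -27, background_gray = 209,
                         variance = 40) {
  pcts <- c(brightness_pct, contrast_pct, intensity_pct)
  if (any(!is.finite(pcts)) || any(pcts < -100) || any(pcts > 500))
    stop("percentages must lie in [-100, 500]", call. = FALSE)
  if (!is.finite(background_gray) || background_gray < 0 || background_gray > 255)
    stop("background_gray must lie in [0, 255]", call. = FALSE)
  if (!is.finite(variance) || variance != round(variance) ||
      variance < 0 || variance > 255)
    stop("variance must be an integer in [0, 255]", call. = FALSE)
  structure(list(brightness_pct = brightness_pct, contrast_pct = contrast_pct,
                 intensity_pct = intensity_pct,
                 background_gray = background_gray,
                 variance = as.integer(variance)),
            class = "quant_config")
}

# round half away from zero (base round() rounds half to even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

clamp8 <- function(x) pmin(pmax(x, 0), 255)

#' Crop a sub-image
#'
#' Extracts the pixels of `box` (0-based, half-open) without resampling.
#'
#' @param img A [gray_image()].
#' @param box A [bounding_box()] fully inside the image.
#' @return The cropped `gray_image`.
#' @export
crop <- function(img, box) {
  stopifnot(inherits(img, "gray_image"), inherits(box, "bounding_box"))
  if (box$x1 > ncol(img) || box$y1 > nrow(img))
    stop("bounding box extends outside the image", call. = FALSE)
  gray_image(unclass(img)[(box$y0 + 1):box$y1, (box$x0 + 1):box$x1,
                          drop = FALSE])
}

#' Invert a grayscale image
#'
#' Maps every pixel p to 255 - p, so fluorescence rendered bright on dark
#' becomes dark on a light background (and vice versa).
#'
#' @param img A [gray_image()].
#' @return The inverted `gray_image`.
#' @export
invert <- function(img) {
  stopifnot(inherits(img, "gray_image"))
  gray_image(255L - unclass(img))
}

#' Brightness, contrast and intensity adjustment
#'
#' Applies, in order: brightness `p' = p + 255 B/100` (additive, scaled to
#' the full 8-bit range); contrast `p'' = 127.5 + (p' - 127.5)(1 + C/100)`
#' (linear about mid-gray); intensity `p''' = p'' (1 + I/100)`
#' (multiplicative). Each stage rounds half away from zero and clamps to
#' \[0, 255\] before the next, so results are bit-exact and reproducible.
#'
#' @param img A [gray_image()].
#' @param cfg A [quant_config()] supplying the three percentages.
#' @return The adjusted `gray_image`.
#' @export
adjust_bci <- function(img, cfg) {
  stopifnot(inherits(img, "gray_image"), inherits(cfg, "quant_config"))
  p <- unclass(img)
  p <- clamp8(round_half_away(p + 255 * cfg$brightness_pct / 100))
  p <- clamp8(round_half_away(127.5 + (p - 127.5) * (1 + cfg$contrast_pct / 100)))
  p <- clamp8(round_half_away(p * (1 + cfg$intensity_pct / 100)))
  gray_image(p)
}

#' Modal background gray of an image
#'
#' Returns the most frequent pixel value; ties are broken toward the lighter
#' (larger) value. Useful when the processed-image background differs from
#' the nominal reference.
#'
#' @param img A [gray_image()].
#' @return Integer gray value in \[0, 255\].
#' @export
estimate_background <- function(img) {
  stopifnot(inherits(img, "gray_image"))
  counts <- tabulate(unclass(img) + 1L, nbins = 256L)
  candidates <- which(counts == max(counts)) - 1L
  max(candidates)
}

#' Count pixels deviating from the background gray
#'
#' Counts pixels whose absolute deviation from `background_gray` strictly
#' exceeds `variance` shades -- the grayscale specialisation of per-channel
#' colour matching with a shade tolerance.
#'
#' @param img A processed (inverted and adjusted) [gray_image()].
#' @param background_gray Reference gray in \[0, 255\].
#' @param variance Integer shade threshold in \[0, 255\].
#' @return Integer count of above-threshold pixels.
#' @export
count_bright_pixels <- function(img, background_gray, variance) {
  stopifnot(inherits(img, "gray_image"))
  sum(abs(unclass(img) - background_gray) > variance)
}

#' Score one worm image
#'
#' The full per-worm statistic: crop the worm's bounding box, invert,
#' apply the brightness/contrast/intensity adjustment, then count pixels
#' deviating from the background gray by more than the variance threshold.
#'
#' @param img A [gray_image()] micrograph.
#' @param box The worm's [bounding_box()].
#' @param cfg A [quant_config()].
#' @param worm_id Optional identifier carried into the score.
#' @return A `fluorescence_score`: list with `worm_id`,
#'   `bright_pixel_count`, `total_pixels` and the `config` snapshot.
#' @export
score_worm <- function(img, box, cfg, worm_id = NA_character_) {
  processed <- adjust_bci(invert(crop(img, box)), cfg)
  n_bright <- count_bright_pixels(processed, cfg$background_gray, cfg$variance)
  structure(list(worm_id = worm_id,
                 bright_pixel_count = as.integer(n_bright),
                 total_pixels = length(processed),
                 config = cfg),
            class = "fluorescence_score")
}

#' @export
print.fluorescence_score <- function(x, ...) {
  cat(sprintf("fluorescence score%s: %d / %d pixels above threshold\n",
              if (is.na(x$worm_id)) "" else paste0(" [", x$worm_id, "]"),
              x$bright_pixel_count, x$total_pixels))
  invisible(x)
}

#' Calibrate the shade-variance threshold from control images
#'
#' Finds the smallest integer variance `v` in \[0, 255\] such that the
#' `target_quantile` of the control images' bright-pixel fractions is at
#' most `target_fraction`. The deposited analyses never print the threshold
#' they used, so this calibration is the package's operational substitute:
#' it pins the false-positive pixel rate on reporter-free controls.
#'
#' @param control_imgs List of at least 3 processed (inverted + adjusted)
#'   control [gray_image()]s.
#' @param background_gray Reference gray the deviations are measured from.
#' @param target_quantile Quantile of the per-image fractions to control
#'   (default 0.5, the median).
#' @param target_fraction Maximum allowed bright-pixel fraction at that
#'   quantile (default 0.01).
#' @return The calibrated integer variance; 255 with a warning if no value
#'   attains the target.
#' @export
calibrate_variance <- function(control_imgs, background_gray = 209,
                               target_quantile = 0.5, target_fraction = 0.01) {
  if (!is.list(control_imgs) || length(control_imgs) < 3L)
    stop("at least 3 processed control images are required", call. = FALSE)
  stopifnot(all(vapply(control_imgs, inherits, logical(1), "gray_image")))
  # fraction of pixels with deviation > v, for all v at once per image
  frac <- vapply(control_imgs, function(im) {
    dev <- abs(unclass(im) - background_gray)
    counts <- tabulate(dev + 1L, nbins = 256L)
    # exceed[v + 1] = #pixels with dev > v
    exceed <- rev(cumsum(rev(counts)))[-1]
    c(exceed, 0) / length(im)
  }, numeric(256))
  qs <- apply(frac, 1, stats::quantile, probs = target_quantile, type = 7)
  ok <- which(qs <= target_fraction)
  if (length(ok) == 0L) {
    warning("target fraction unattainable; returning variance 255")
    return(255L)
  }
  as.integer(ok[1] - 1L)
}

#' Compare fluorescence scores between treated and control worms
#'
#' Two-sided Mann-Whitney U test on per-worm bright-pixel counts plus a
#' fold change of treated over control. The fold change is the ratio of
#' arithmetic means by default; the ratio of medians is also reported.
#'
#' @param treated,control Non-empty lists of `fluorescence_score` objects.
#' @return A `group_comparison` with `fold_change` = mean(treated)/
#'   mean(control), plus `fold_change_median` and a `control_mean_zero`
#'   flag when the ratio is undefined.
#' @export
compare_fluorescence <- function(treated, control) {
  tc <- vapply(treated, function(s) as.numeric(s$bright_pixel_count), numeric(1))
  cc <- vapply(control, function(s) as.numeric(s$bright_pixel_count), numeric(1))
  if (length(tc) == 0L || length(cc) == 0L)
    stop("both groups must be non-empty", call. = FALSE)
  cmp <- mann_whitney_u(tc, cc, "two_sided")
  cmp$control_mean_zero <- mean(cc) == 0
  cmp$fold_change <- if (cmp$control_mean_zero) NA_real_ else mean(tc) / mean(cc)
  cmp$fold_change_median <-
    if (stats::median(cc) == 0) NA_real_ else stats::median(tc) / stats::median(cc)
  cmp
}
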