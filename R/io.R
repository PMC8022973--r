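# Readers and writers for the plain-text formats the pipelines exchange:
# PNG/TIFF grayscale images, the worm-image manifest, long-format plate
# CSVs, and morphometry CSVs. All CSV writers use fixed column orders and
# RFC-4180 quoting via write.csv.

#' Read an 8-bit grayscale image
#'
#' Reads PNG (or TIFF, if the tiff package is installed) into a
#' [gray_image()]. Multi-channel images are converted to grayscale by
#' averaging the colour channels (luminance average) with a warning;
#' higher bit depths are rescaled to 0-255 with a warning.
#'
#' @param path Image file; format chosen by extension.
#' @return A [gray_image()].
#' @export
read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("the tiff package is required to read TIFF files", call. = FALSE)
      tiff::readTIFF(path)
    },
    stop("unsupported image format: .", ext, call. = FALSE))
  if (length(dim(arr)) == 3L) {
    warning("multi-channel image converted to grayscale by channel average")
    arr <- apply(arr[, , seq_len(min(3, dim(arr)[3])), drop = FALSE],
                 c(1, 2), mean)
  }
  # readPNG/readTIFF normalise to [0, 1] regardless of stored bit depth;
  # values that are not multiples of 1/255 (e.g. 16-bit sources) are
  # rescaled to the 8-bit range
  px <- round_half_away(arr * 255)
  if (max(abs(px - arr * 255)) > 1e-6)
    warning("image rescaled to 8-bit range")
  gray_image(clamp8(px))
}

#' Write a grayscale image as 8-bit PNG
#'
#' @param img A [gray_image()].
#' @param path Output file path (.png).
#' @export
write_gray_png <- function(img, path) {
  stopifnot(inherits(img, "gray_image"))
  png::writePNG(unclass(img) / 255, path)
  invisible(path)
}

#' Read a worm-image manifest
#'
#' The manifest is a CSV with columns `worm_id`, `file`, `group`, `x0`,
#' `y0`, `x1`, `y1` (bounding boxes 0-based, half-open). Image paths are
#' resolved relative to the manifest's directory. Boxes are validated
#' against image dimensions lazily, at crop time.
#'
#' @param path Manifest CSV.
#' @return Data frame of validated records with a `box` list-column of
#'   [bounding_box()] objects.
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("worm_id", "file", "group", "x0", "y0", "x1", "y1")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("manifest is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (col in c("x0", "y0", "x1", "y1"))
    if (!is.numeric(df[[col]]))
      stop("manifest column ", col, " must be numeric (row ",
           which(!is.finite(suppressWarnings(as.numeric(df[[col]]))))[1],
           ")", call. = FALSE)
  dup <- df$worm_id[duplicated(df$worm_id)]
  if (length(dup))
    stop("duplicate worm_id in manifest: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  df$box <- lapply(seq_len(nrow(df)), function(i)
    bounding_box(df$x0[i], df$y0[i], df$x1[i], df$y1[i]))
  df$file <- file.path(dirname(path), df$file)
  df
}

#' Write a worm-image manifest
#'
#' @param df Data frame with columns `worm_id`, `file`, `group`, `x0`,
#'   `y0`, `x1`, `y1`.
#' @param path Output CSV path.
#' @export
write_manifest <- function(df, path) {
  cols <- c("worm_id", "file", "group", "x0", "y0", "x1", "y1")
  utils::write.csv(df[, cols], path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a long-format plate CSV into luminescence series
#'
#' Expected columns: `well`, `group`, `time_s`, `intensity`.
#'
#' @param path Plate CSV.
#' @return List of [luminescence_series()], one per well, in first-seen
#'   well order.
#' @export
read_plate_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("well", "group", "time_s", "intensity")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("plate CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  wells <- unique(df$well)
  lapply(wells, function(w) {
    sub <- df[df$well == w, ]
    sub <- sub[order(sub$time_s), ]
    luminescence_series(w, sub$group[1], sub$time_s, sub$intensity)
  })
}

#' Write luminescence series as a long-format plate CSV
#'
#' @param series_list List of [luminescence_series()].
#' @param path Output CSV path.
#' @export
write_plate_csv <- function(series_list, path) {
  df <- do.call(rbind, lapply(series_list, function(s)
    data.frame(well = s$well_id, group = s$group,
               time_s = s$times, intensity = s$intensities)))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a morphometry CSV
#'
#' Expected columns: `worm_id`, `dpe_group`, `body_length_um`,
#' `gonad_length_um`.
#'
#' @param path Morphometry CSV.
#' @return A validated [morphometry_table()].
#' @export
read_morphometry_csv <- function(path) {
  morphometry_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write a morphometry table as CSV
#'
#' @param df Morphometry data frame.
#' @param path Output CSV path.
#' @export
write_morphometry_csv <- function(df, path) {
  cols <- c("worm_id", "dpe_group", "body_length_um", "gonad_length_um")
  utils::write.csv(as.data.frame(df)[, cols], path, row.names = FALSE,
                   quote = TRUE)
  invisible(path)
}

#' Write per-well decay fits as CSV
#'
#' @param fits List of `decay_fit` objects.
#' @param path Output CSV path.
#' @export
write_fits_csv <- function(fits, path) {
  df <- do.call(rbind, lapply(fits, function(f)
    data.frame(well = f$well_id, group = f$group, a = f$a, b = f$b, c = f$c,
               half_life_s = f$half_life, rss = f$rss,
               converged = f$converged)))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Write per-worm fluorescence scores as CSV
#'
#' @param scores List of `fluorescence_score` objects.
#' @param groups Character vector of group labels, one per score.
#' @param path Output CSV path.
#' @export
write_scores_csv <- function(scores, groups, path) {
  df <- do.call(rbind, lapply(seq_along(scores), function(i) {
    s <- scores[[i]]
    data.frame(worm_id = s$worm_id, group = groups[i],
               bright_pixel_count = s$bright_pixel_count,
               total_pixels = s$total_pixels,
               variance = s$config$variance,
               background_gray = s$config$background_gray)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Serialise a group comparison to JSON
#'
#' @param cmp A `group_comparison`.
#' @param path Output JSON path.
#' @param extra Named list of extra fields to include.
#' @export
write_comparison_json <- function(cmp, path, extra = list()) {
  payload <- c(unclass(cmp), extra)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
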