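# Synthetic-data generators emulating the three assay readouts: worm
# micrographs with gut autofluorescence, plate-reader luminescence series,
# and per-group morphometry tables. All generators are pure functions of
# (parameters, seed); per-entity substreams are derived from the master
# seed and the entity index, so adding wells or worms never perturbs the
# ones already generated.

# derive a reproducible 32-bit substream seed from (seed, index)
substream_seed <- function(seed, index) {
  (as.numeric(seed) * 48271 + as.numeric(index) * 69621) %% 2147483647
}

with_substream <- function(seed, index, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, index))
  expr
}

#' Parameters of the synthetic worm image
#'
#' The simulated micrograph is a dark canvas with a stylised worm: a tube
#' of width `body_width` around a sinusoidal midline with random phase.
#' The tube interior sits at `body_level + reporter_extra` (the diffuse
#' body-wide reporter signal; 0 for controls), and a central stripe of half
#' the tube width additionally carries `gut_extra`, emulating the gut
#' autofluorescence concentrated in the intestine. Gaussian noise of sd
#' `noise_sd` is added per pixel, rounded and clamped to \[0, 255\].
#'
#' @param height,width Canvas size in pixels.
#' @param background_level Dark background gray (default 10).
#' @param body_level Worm body gray above background (default 40).
#' @param gut_extra Autofluorescence increment on the gut stripe
#'   (default 60).
#' @param reporter_extra Body-wide reporter increment, 0 for controls.
#' @param noise_sd Gaussian noise standard deviation in gray levels.
#' @param body_width Tube width in pixels.
#' @param amplitude,frequency Midline sine amplitude (pixels) and number of
#'   periods along the worm.
#' @return An `image_sim_params` list.
#' @export
image_sim_params <- function(height = 80, width = 200, background_level = 10,
                             body_level = 40, gut_extra = 60,
                             reporter_extra = 0, noise_sd = 2,
                             body_width = 12, amplitude = 15,
                             frequency = 1.5) {
  levels <- c(background_level, body_level, gut_extra, reporter_extra)
  if (any(!is.finite(levels)) || any(levels < 0) || any(levels > 255))
    stop("all gray levels must lie in [0, 255]", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(height = height, width = width,
                 background_level = background_level, body_level = body_level,
                 gut_extra = gut_extra, reporter_extra = reporter_extra,
                 noise_sd = noise_sd, body_width = body_width,
                 amplitude = amplitude, frequency = frequency),
            class = "image_sim_params")
}

#' Generate one synthetic worm micrograph with ground truth
#'
#' @param params An [image_sim_params()].
#' @param seed Master seed; the image is a deterministic function of
#'   `(params, seed)`.
#' @param index Entity index used to derive the substream, so batches can
#'   share one master seed.
#' @return A `worm_image_truth`: `image` ([gray_image()]), logical
#'   `body_mask` and `gut_mask` (gut inside body), `params` and `seed`.
#' @export
generate_worm_image <- function(params = image_sim_params(), seed = 1L,
                                index = 1L) {
  stopifnot(inherits(params, "image_sim_params"))
  h <- params$height; w <- params$width
  half <- params$body_width / 2
  cy <- (h + 1) / 2
  if (cy - params$amplitude - half < 1 || cy + params$amplitude + half > h)
    stop("worm does not fit the canvas; reduce amplitude or body_width",
         call. = FALSE)
  with_substream(seed, index, {
    phase <- stats::runif(1, 0, 2 * pi)
    xs <- seq_len(w)
    mid <- cy + params$amplitude *
      sin(2 * pi * params$frequency * (xs - 1) / (w - 1) + phase)
    rows <- matrix(seq_len(h), h, w)
    mids <- matrix(mid, h, w, byrow = TRUE)
    body <- abs(rows - mids) <= half
    gut <- abs(rows - mids) <= half / 2
    px <- matrix(params$background_level, h, w)
    px[body] <- params$body_level + params$reporter_extra
    px[gut] <- params$body_level + params$reporter_extra + params$gut_extra
    if (params$noise_sd > 0)
      px <- px + stats::rnorm(h * w, 0, params$noise_sd)
    img <- gray_image(clamp8(round_half_away(px)))
    structure(list(image = img, body_mask = body, gut_mask = gut,
                   params = params, seed = seed, index = index),
              class = "worm_image_truth")
  })
}

#' Generate a batch of synthetic worm images
#'
#' @param n Number of worms.
#' @param params An [image_sim_params()] shared by the batch.
#' @param seed Master seed; worm `i` uses substream `(seed, offset + i)`.
#' @param offset Index offset so treated and control batches drawn from the
#'   same master seed use disjoint substreams.
#' @return List of `worm_image_truth`.
#' @export
generate_worm_batch <- function(n, params = image_sim_params(), seed = 1L,
                                offset = 0L) {
  lapply(seq_len(n), function(i)
    generate_worm_image(params, seed, index = offset + i))
}

#' Generate plate-reader luminescence series
#'
#' Intensities follow `a + b * 2^(c t)` plus independent Gaussian noise per
#' well, clamped at 0. Default sampling matches the plate-reader protocol:
#' one read every 176 s for 48.84 h (1000 time points per well).
#'
#' @param a,b,c Model parameters (time unit: seconds).
#' @param noise_sd Gaussian noise sd in luminescence units.
#' @param interval_s Sampling interval in seconds (default 176).
#' @param duration_h Total span in hours (default 48.84).
#' @param n_wells Number of wells (default 8 per group).
#' @param group_label Group label stored in each series.
#' @param seed Master seed.
#' @param offset Substream index offset (use different offsets for treated
#'   and control batches sharing a master seed).
#' @param well_prefix Prefix for well ids.
#' @return List of [luminescence_series()].
#' @export
generate_luminescence <- function(a = 1000, b = 1000, c = -0.0001,
                                  noise_sd = 0, interval_s = 176,
                                  duration_h = 48.84, n_wells = 8,
                                  group_label = "treated", seed = 1L,
                                  offset = 0L, well_prefix = group_label) {
  stopifnot(interval_s > 0, duration_h > 0, n_wells >= 1)
  times <- seq(0, duration_h * 3600, by = interval_s)
  mu <- model_intensity(times, a, b, c)
  lapply(seq_len(n_wells), function(i) {
    y <- with_substream(seed, offset + i, {
      if (noise_sd > 0) mu + stats::rnorm(length(mu), 0, noise_sd) else mu
    })
    luminescence_series(sprintf("%s_%02d", well_prefix, i), group_label,
                        times, pmax(y, 0))
  })
}

#' Default morphometry group specification
#'
#' Three age groups of virgin males at 0-1, 2-3 and 5-6 days
#' post-emergence, n = 8 each. Gonad proportions centre on 65% and 45% for
#' the youngest and oldest groups; the middle group's 55% is an
#' interpolation (no reference central value exists for it). Body lengths
#' rise modestly (1150 to 1230 um) against a large between-worm sd of
#' 150 um, so individual body-length comparisons are usually not
#' significant at these group sizes while the proportion contrast is.
#'
#' @return Data frame with columns `label`, `mean_body`, `sd_body`,
#'   `mean_prop`, `sd_prop`, `n`.
#' @export
default_morphometry_specs <- function() {
  data.frame(label = c("0-1", "2-3", "5-6"),
             mean_body = c(1150, 1190, 1230),
             sd_body = c(150, 150, 150),
             mean_prop = c(65, 55, 45),
             sd_prop = c(5, 5, 5),
             n = c(8L, 8L, 8L))
}

# normal truncated to (lo, hi) by rejection
rnorm_trunc <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rnorm(n, mean, sd)
    out <- c(out, draw[draw > lo & draw <= hi])
  }
  out[seq_len(n)]
}

#' Generate a synthetic morphometry table
#'
#' Body lengths are Normal(mean_body, sd_body) truncated positive; gonad
#' proportions are Normal(mean_prop, sd_prop) truncated to (0, 100\];
#' gonad length is body x proportion / 100, so the proportion statistic has
#' exactly the specified distribution.
#'
#' @param group_specs Data frame as returned by
#'   [default_morphometry_specs()].
#' @param seed Master seed; group `i` draws from substream `(seed, i)`.
#' @return A [morphometry_table()] data frame.
#' @export
generate_morphometry <- function(group_specs = default_morphometry_specs(),
                                 seed = 1L) {
  stopifnot(all(group_specs$n >= 1),
            all(group_specs$mean_prop > 0 & group_specs$mean_prop < 100))
  rows <- lapply(seq_len(nrow(group_specs)), function(i) {
    sp <- group_specs[i, ]
    with_substream(seed, i, {
      body <- rnorm_trunc(sp$n, sp$mean_body, sp$sd_body, 0, Inf)
      prop <- rnorm_trunc(sp$n, sp$mean_prop, sp$sd_prop, 0, 100)
      data.frame(worm_id = sprintf("%s_w%02d", sp$label, seq_len(sp$n)),
                 dpe_group = sp$label,
                 body_length_um = body,
                 gonad_length_um = body * prop / 100)
    })
  })
  morphometry_table(do.call(rbind, rows))
}
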