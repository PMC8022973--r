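# End-to-end pipeline plumbing: high-level analysis entry points over the
# on-disk formats, and a reproducible multi-stage runner that archives its
# resolved configuration next to its outputs.

#' Quantify fluorescence for every worm in a manifest
#'
#' Reads each image, scores the worm inside its bounding box with
#' [score_worm()], and compares the treated group against the control
#' group. When `variance` is `NULL`, the threshold is calibrated on the
#' processed control images with [calibrate_variance()].
#'
#' @param manifest_path Manifest CSV (see [read_manifest()]).
#' @param cfg A [quant_config()]; its `variance` is replaced by the
#'   calibrated value when `variance = NULL` is requested.
#' @param control_group Label identifying control worms in the manifest.
#' @param variance Integer threshold, or `NULL` to calibrate from controls.
#' @param estimate_bg Replace `cfg$background_gray` by the modal gray of
#'   the processed control images ([estimate_background()]). The nominal
#'   reference (209, hex D1) describes externally processed micrographs;
#'   for images processed by this pipeline the background depends on the
#'   brightness/contrast/intensity settings and is better estimated.
#' @return List with `scores` (per-worm `fluorescence_score`s), `groups`,
#'   `comparison` (a `group_comparison`), and the resolved `config`.
#' @export
quantify_manifest <- function(manifest_path, cfg = quant_config(),
                              control_group = "control",
                              variance = cfg$variance, estimate_bg = FALSE) {
  records <- read_manifest(manifest_path)
  images <- lapply(records$file, read_gray_image)
  is_ctrl <- records$group == control_group
  if (estimate_bg || is.null(variance)) {
    processed <- lapply(which(is_ctrl), function(i)
      adjust_bci(invert(crop(images[[i]], records$box[[i]])), cfg))
  }
  if (estimate_bg) {
    pooled <- do.call(rbind, lapply(processed, unclass))
    cfg$background_gray <- estimate_background(gray_image(pooled))
  }
  if (is.null(variance))
    variance <- calibrate_variance(processed, cfg$background_gray)
  cfg$variance <- as.integer(variance)
  scores <- lapply(seq_len(nrow(records)), function(i)
    score_worm(images[[i]], records$box[[i]], cfg, records$worm_id[i]))
  treated <- scores[records$group != control_group]
  control <- scores[records$group == control_group]
  comparison <- compare_fluorescence(treated, control)
  list(scores = scores, groups = records$group, comparison = comparison,
       config = cfg)
}

#' Fit the decay model to every well of a plate
#'
#' @param series_list List of [luminescence_series()] (e.g. from
#'   [read_plate_csv()]).
#' @param start Optimiser starts passed to [fit_decay()].
#' @return List of `decay_fit` objects in well order.
#' @export
fit_plate <- function(series_list, start = c(a = 1000, b = 1000, c = -0.0001)) {
  lapply(series_list, fit_decay, start = start)
}

#' Assemble a pipeline run configuration
#'
#' @param seed Master seed used by every simulation stage.
#' @param outdir Output directory (created if absent).
#' @param stages Character vector of stages to run, in order, from
#'   `simulate-images`, `simulate-plate`, `simulate-morphometry`,
#'   `quantify`, `fit-decay`, `morphometry`.
#' @param params Named list of per-stage parameter overrides.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L, outdir = "nemaquant-run",
                       stages = c("simulate-images", "simulate-plate",
                                  "simulate-morphometry", "quantify",
                                  "fit-decay", "morphometry"),
                       params = list()) {
  known <- c("simulate-images", "simulate-plate", "simulate-morphometry",
             "quantify", "fit-decay", "morphometry")
  bad <- setdiff(stages, known)
  if (length(bad))
    stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  bad_keys <- setdiff(names(params), known)
  if (length(bad_keys))
    stop("unknown config key(s): ", paste(bad_keys, collapse = ", "),
         call. = FALSE)
  structure(list(seed = as.integer(seed), outdir = outdir, stages = stages,
                 params = params),
            class = "run_config")
}

# write `payload` (a writer closure taking a path) atomically: temp file in
# the same directory, then rename
atomic_write <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = paste0(".", basename(path)))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path))
    stop("could not move temporary file onto ", path, call. = FALSE)
  invisible(path)
}

#' Run a multi-stage reproducible pipeline
#'
#' Executes the configured stages in order, writing every output
#' atomically (temp-then-rename) under `config$outdir` together with the
#' resolved configuration (`run_config.json`), so any output is
#' reproducible from the archived config alone. Simulation stages feed the
#' matching analysis stages through the same on-disk formats external data
#' would use.
#'
#' @param config A [run_config()].
#' @return Invisibly, a named list of the files written.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  written <- list()
  note <- function(name, path) written[[name]] <<- path

  p <- function(stage, key, default) {
    v <- config$params[[stage]][[key]]
    if (is.null(v)) default else v
  }

  for (stage in config$stages) {
    switch(stage,
      "simulate-images" = {
        n_per_group <- p(stage, "n_per_group", 20L)
        reporter_extra <- p(stage, "reporter_extra", 50)
        base <- image_sim_params()
        treated_params <- image_sim_params(reporter_extra = reporter_extra,
                                           noise_sd = base$noise_sd)
        img_dir <- file.path(config$outdir, "images")
        dir.create(img_dir, showWarnings = FALSE)
        worms <- c(generate_worm_batch(n_per_group, treated_params,
                                       config$seed, offset = 0L),
                   generate_worm_batch(n_per_group, base, config$seed,
                                       offset = n_per_group))
        groups <- rep(c("treated", "control"), each = n_per_group)
        ids <- sprintf("%s_%02d", groups, c(seq_len(n_per_group),
                                            seq_len(n_per_group)))
        files <- paste0(ids, ".png")
        for (i in seq_along(worms))
          atomic_write(file.path(img_dir, files[i]),
                       function(tmp) write_gray_png(worms[[i]]$image, tmp))
        manifest <- data.frame(worm_id = ids, file = file.path("images", files),
                               group = groups, x0 = 0, y0 = 0,
                               x1 = base$width, y1 = base$height)
        path <- file.path(config$outdir, "manifest.csv")
        atomic_write(path, function(tmp) write_manifest(manifest, tmp))
        note("manifest", path)
      },
      "simulate-plate" = {
        series <- c(
          generate_luminescence(
            a = p(stage, "a", 1000), b = p(stage, "b", 1000),
            c = p(stage, "c", -0.0001), noise_sd = p(stage, "noise_sd", 20),
            n_wells = p(stage, "n_wells", 8L), group_label = "treated",
            seed = config$seed, offset = 0L),
          generate_luminescence(
            a = p(stage, "a", 1000), b = 0, c = p(stage, "c", -0.0001),
            noise_sd = p(stage, "noise_sd", 20),
            n_wells = p(stage, "n_wells", 8L), group_label = "control",
            seed = config$seed, offset = p(stage, "n_wells", 8L)))
        path <- file.path(config$outdir, "plate.csv")
        atomic_write(path, function(tmp) write_plate_csv(series, tmp))
        note("plate", path)
      },
      "simulate-morphometry" = {
        tbl <- generate_morphometry(seed = config$seed)
        path <- file.path(config$outdir, "morphometry.csv")
        atomic_write(path, function(tmp) write_morphometry_csv(tbl, tmp))
        note("morphometry_table", path)
      },
      "quantify" = {
        res <- quantify_manifest(
          written$manifest %||% file.path(config$outdir, "manifest.csv"),
          quant_config(), variance = p(stage, "variance", 60L),
          estimate_bg = p(stage, "estimate_bg", TRUE))
        spath <- file.path(config$outdir, "scores.csv")
        atomic_write(spath, function(tmp)
          write_scores_csv(res$scores, res$groups, tmp))
        jpath <- file.path(config$outdir, "fluorescence_comparison.json")
        atomic_write(jpath, function(tmp)
          write_comparison_json(res$comparison, tmp,
                                extra = list(config = unclass(res$config))))
        note("scores", spath); note("fluorescence_comparison", jpath)
      },
      "fit-decay" = {
        series <- read_plate_csv(
          written$plate %||% file.path(config$outdir, "plate.csv"))
        fits <- fit_plate(series)
        groups <- vapply(fits, function(f) f$group, character(1))
        fpath <- file.path(config$outdir, "fits.csv")
        atomic_write(fpath, function(tmp) write_fits_csv(fits, tmp))
        cmp <- compare_half_lives(fits[groups == "treated"],
                                  fits[groups == "control"])
        jpath <- file.path(config$outdir, "half_life_comparison.json")
        atomic_write(jpath, function(tmp) write_comparison_json(cmp, tmp))
        dw <- detection_window(series[groups == "treated"],
                               series[groups == "control"],
                               alpha = p(stage, "alpha", 0.05))
        wpath <- file.path(config$outdir, "detection_window.json")
        atomic_write(wpath, function(tmp)
          jsonlite::write_json(
            list(conservative_end_s = dw$conservative_end,
                 liberal_end_s = dw$liberal_end, alpha = dw$alpha),
            tmp, auto_unbox = TRUE, digits = NA))
        note("fits", fpath); note("half_life_comparison", jpath)
        note("detection_window", wpath)
      },
      "morphometry" = {
        tbl <- read_morphometry_csv(
          written$morphometry_table %||%
            file.path(config$outdir, "morphometry.csv"))
        ana <- analyze_groups(tbl, metric = p(stage, "metric", "proportion"),
                              alpha = p(stage, "alpha", 0.05))
        path <- file.path(config$outdir, "morphometry_summary.csv")
        atomic_write(path, function(tmp) {
          df <- do.call(rbind, lapply(names(ana$box_summaries), function(g) {
            bs <- ana$box_summaries[[g]]
            data.frame(dpe_group = g, n = ana$group_sizes[[g]],
                       median = bs$median, q1 = bs$q1, q3 = bs$q3,
                       lower_whisker = bs$lower_whisker,
                       upper_whisker = bs$upper_whisker,
                       letter = ana$letters[[g]])
          }))
          utils::write.csv(df, tmp, row.names = FALSE, quote = TRUE)
        })
        ppath <- file.path(config$outdir, "morphometry_pvalues.csv")
        atomic_write(ppath, function(tmp)
          utils::write.csv(ana$p_matrix, tmp, quote = TRUE))
        note("morphometry_summary", path)
        note("morphometry_pvalues", ppath)
      })
  }

  cfg_path <- file.path(config$outdir, "run_config.json")
  atomic_write(cfg_path, function(tmp)
    jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE))
  note("run_config", cfg_path)
  invisible(written)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
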