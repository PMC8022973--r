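# Luminescence decay kinetics: per-well fit of Intensity = a + b * 2^(c t),
# half-life extraction (-1/c), treated-vs-control comparison, and the
# above-background detection window.

#' One well's luminescence time series
#'
#' @param well_id Well identifier.
#' @param group Group label, typically `"treated"` or `"control"`.
#' @param times Numeric vector of times in seconds from the first read;
#'   strictly increasing, starting at 0, length >= 4.
#' @param intensities Non-negative luminescence readings, same length.
#' @return A `luminescence_series`.
#' @export
luminescence_series <- function(well_id, group, times, intensities) {
  if (length(times) != length(intensities) || length(times) < 4L)
    stop("need >= 4 paired (time, intensity) readings", call. = FALSE)
  if (times[1] != 0 || any(diff(times) <= 0))
    stop("times must start at 0 and be strictly increasing", call. = FALSE)
  if (any(!is.finite(intensities)) || any(intensities < 0))
    stop("intensities must be finite and >= 0", call. = FALSE)
  structure(list(well_id = well_id, group = group,
                 times = as.numeric(times),
                 intensities = as.numeric(intensities)),
            class = "luminescence_series")
}

#' Luminescence decay model
#'
#' Evaluates `a + b * 2^(c * t)`: a constant background `a` plus a
#' component of amplitude `b` that halves every `-1/c` time units when
#' `c < 0`.
#'
#' @param t Time(s), same unit as `1/c`.
#' @param a Baseline intensity.
#' @param b Decaying amplitude.
#' @param c Rate per time unit (negative for decay).
#' @return Model intensity at `t`.
#' @export
model_intensity <- function(t, a, b, c) a + b * 2^(c * t)

#' Fit the decay model to one well by damped least squares
#'
#' Minimises the residual sum of squares of `a + b * 2^(c t)` with a
#' Levenberg-Marquardt optimiser from the given starts (defaults
#' `a = 1000, b = 1000, c = -0.0001`, with time in seconds). If the first
#' attempt does not converge, the fit is restarted with `c` one decade up
#' and down. Degenerate series yield a non-converged fit (flag set), not an
#' error. A fitted amplitude numerically indistinguishable from zero leaves
#' `c` unidentifiable and is also flagged as non-converged.
#'
#' @param series A [luminescence_series()].
#' @param start Named numeric vector or list with entries `a`, `b`, `c`.
#' @return A `decay_fit`: `a`, `b`, `c`, `half_life` (seconds, `-1/c`),
#'   `rss`, `converged`, plus the series' `well_id` and `group`.
#' @export
fit_decay <- function(series, start = c(a = 1000, b = 1000, c = -0.0001)) {
  stopifnot(inherits(series, "luminescence_series"))
  start <- as.list(start)[c("a", "b", "c")]
  if (any(vapply(start, is.null, logical(1))))
    stop("start must provide a, b and c", call. = FALSE)
  df <- data.frame(time = series$times, y = series$intensities)

  attempt <- function(st) {
    tryCatch(
      minpack.lm::nlsLM(
        y ~ a + b * 2^(c * time), data = df, start = st,
        control = minpack.lm::nls.lm.control(
          ftol = 1e-10, ptol = 1e-12, maxiter = 500)),
      error = function(e) NULL)
  }
  fit <- attempt(start)
  if (is.null(fit)) {
    for (scale in c(10, 0.1)) {
      st <- start; st$c <- st$c * scale
      fit <- attempt(st)
      if (!is.null(fit)) break
    }
  }

  if (is.null(fit)) {
    rss0 <- sum((df$y - model_intensity(df$time, start$a, start$b, start$c))^2)
    return(new_decay_fit(start$a, start$b, start$c, rss0, FALSE,
                         series$well_id, series$group))
  }
  cf <- stats::coef(fit)
  rss <- sum(stats::resid(fit)^2)
  scale_y <- max(abs(df$y), 1)
  identifiable <- abs(cf[["b"]]) > 1e-8 * scale_y
  new_decay_fit(cf[["a"]], cf[["b"]], cf[["c"]], rss,
                converged = identifiable && all(is.finite(cf)),
                series$well_id, series$group)
}

new_decay_fit <- function(a, b, c, rss, converged, well_id = NA, group = NA) {
  hl <- if (c != 0) -1 / c else NA_real_
  structure(list(a = a, b = b, c = c, half_life = hl, rss = rss,
                 converged = converged, well_id = well_id, group = group),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("decay fit%s: a = %.4g, b = %.4g, c = %.4g /s (%s)\n",
              if (is.na(x$well_id)) "" else paste0(" [well ", x$well_id, "]"),
              x$a, x$b, x$c,
              if (x$converged) "converged" else "NOT converged"))
  if (is.finite(x$half_life))
    cat(sprintf("  half-life = %.6g s (%.4g h), rss = %.4g\n",
                x$half_life, x$half_life / 3600, x$rss))
  invisible(x)
}

#' Half-life of a decay fit
#'
#' Returns `-1/c` in the time unit of the fit (seconds by convention). A
#' positive `c` gives a negative value and a `non_decaying` attribute;
#' `c = 0` gives `NA` with the same flag.
#'
#' @param fit A `decay_fit`.
#' @return Numeric half-life with attribute `non_decaying` (logical).
#' @export
half_life <- function(fit) {
  stopifnot(inherits(fit, "decay_fit"))
  if (fit$c == 0)
    return(structure(NA_real_, non_decaying = TRUE))
  structure(-1 / fit$c, non_decaying = fit$c > 0)
}

#' Compare treated and control half-lives
#'
#' Two-sided Mann-Whitney U test on per-well half-lives. Wells with
#' non-converged fits or non-decaying estimates (`c >= 0`) are excluded
#' with a warning; both the used and excluded counts are reported.
#'
#' @param treated_fits,control_fits Lists of `decay_fit` objects, each with
#'   at least 2 usable fits.
#' @return A `group_comparison` with extra fields `n_excluded_treated` and
#'   `n_excluded_control`.
#' @export
compare_half_lives <- function(treated_fits, control_fits) {
  usable <- function(fits) {
    keep <- vapply(fits, function(f) isTRUE(f$converged) && f$c < 0, logical(1))
    list(hl = vapply(fits[keep], function(f) f$half_life, numeric(1)),
         n_excluded = sum(!keep))
  }
  tr <- usable(treated_fits)
  ct <- usable(control_fits)
  if (tr$n_excluded + ct$n_excluded > 0)
    warning(sprintf("excluded %d treated and %d control well(s) (non-converged or non-decaying)",
                    tr$n_excluded, ct$n_excluded))
  if (length(tr$hl) < 2L || length(ct$hl) < 2L)
    stop("need >= 2 usable fits per group", call. = FALSE)
  cmp <- mann_whitney_u(tr$hl, ct$hl, "two_sided")
  cmp$n_excluded_treated <- tr$n_excluded
  cmp$n_excluded_control <- ct$n_excluded
  cmp
}

#' Detection window of above-background luminescence
#'
#' At each shared time point, tests one-sided (treated > control) across
#' wells with the Mann-Whitney U test. Two endpoints summarise how long the
#' treated signal stays distinguishable from background: `conservative_end`
#' is the last time of the contiguous significant run starting at t = 0;
#' `liberal_end` is the last significant time anywhere. Both are 0 when no
#' time point is significant.
#'
#' @param treated,control Lists of [luminescence_series()] on an identical
#'   time grid, at least 3 wells per group.
#' @param alpha Per-time-point significance level (default 0.05).
#' @return A `detection_window`: `conservative_end`, `liberal_end` (seconds),
#'   `alpha`, and the per-time-point `p_values` with their `times`.
#' @export
detection_window <- function(treated, control, alpha = 0.05) {
  stopifnot(length(treated) >= 3L, length(control) >= 3L)
  grid <- treated[[1]]$times
  same_grid <- function(s) length(s$times) == length(grid) &&
    all(s$times == grid)
  if (!all(vapply(c(treated, control), same_grid, logical(1))))
    stop("all series must share the same time grid", call. = FALSE)

  tmat <- vapply(treated, function(s) s$intensities, numeric(length(grid)))
  cmat <- vapply(control, function(s) s$intensities, numeric(length(grid)))
  pvals <- vapply(seq_along(grid), function(i) {
    mann_whitney_u(cmat[i, ], tmat[i, ], alternative = "greater")$p_value
  }, numeric(1))

  sig <- pvals < alpha
  liberal <- if (any(sig)) grid[max(which(sig))] else 0
  conservative <- if (sig[1]) {
    run_end <- which(!sig)[1]
    grid[if (is.na(run_end)) length(grid) else run_end - 1L]
  } else 0
  structure(list(conservative_end = conservative, liberal_end = liberal,
                 alpha = alpha, p_values = pvals, times = grid),
            class = "detection_window")
}

#' @export
print.detection_window <- function(x, ...) {
  cat(sprintf("detection window (alpha = %g): contiguous to %.3g h, last significant at %.3g h\n",
              x$alpha, x$conservative_end / 3600, x$liberal_end / 3600))
  invisible(x)
}
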