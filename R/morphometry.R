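# Male gonad morphometry: gonad length as a percentage of body length per
# age group, pairwise Mann-Whitney comparisons, letter groups, box summaries.

#' Validate a morphometry table
#'
#' Checks a data frame of per-worm measurements: columns `worm_id`,
#' `dpe_group` (days post-emergence label, e.g. "0-1", "2-3", "5-6"),
#' `body_length_um` and `gonad_length_um`, with
#' `0 < gonad_length <= body_length`.
#'
#' @param df Data frame of measurements.
#' @return The validated data frame (invisibly classed `morphometry_table`).
#' @export
morphometry_table <- function(df) {
  required <- c("worm_id", "dpe_group", "body_length_um", "gonad_length_um")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (any(!nzchar(as.character(df$dpe_group))))
    stop("dpe_group labels must be non-empty", call. = FALSE)
  bad <- !is.finite(df$body_length_um) | !is.finite(df$gonad_length_um) |
    df$gonad_length_um <= 0 | df$gonad_length_um > df$body_length_um
  if (any(bad))
    stop("rows violate 0 < gonad_length <= body_length: ",
         paste(df$worm_id[bad], collapse = ", "), call. = FALSE)
  class(df) <- unique(c("morphometry_table", class(df)))
  df
}

#' Gonad length as a percentage of body length
#'
#' @param body_length_um,gonad_length_um Lengths in micrometres with
#'   `0 < gonad <= body`.
#' @return Percentage in (0, 100\].
#' @examples
#' gonad_proportion(1000, 450)  # 45
#' @export
gonad_proportion <- function(body_length_um, gonad_length_um) {
  if (any(gonad_length_um <= 0) || any(gonad_length_um > body_length_um))
    stop("require 0 < gonad_length <= body_length", call. = FALSE)
  100 * gonad_length_um / body_length_um
}

#' Group-wise morphometry analysis
#'
#' For the chosen metric -- the gonad/body percentage (default), body
#' length, or gonad length -- computes per-group box summaries, all
#' pairwise two-sided Mann-Whitney p-values (exact at typical group sizes
#' of 7-9), and a compact letter display at level `alpha`. Pairwise
#' p-values are uncorrected by default, matching the convention of
#' reporting raw P < 0.05 letters; set `bonferroni = TRUE` to adjust.
#'
#' @param df Data frame accepted by [morphometry_table()].
#' @param metric `"proportion"`, `"body_length"` or `"gonad_length"`.
#' @param alpha Significance level for the letter display.
#' @param bonferroni Apply Bonferroni correction to the pairwise p-values.
#' @return A `morphometry_analysis`: list with `metric`, per-group
#'   `box_summaries`, the symmetric `p_matrix`, `letters`, `group_sizes`
#'   and `alpha`. Groups with fewer than 2 records are excluded with a
#'   warning.
#' @export
analyze_groups <- function(df, metric = c("proportion", "body_length",
                                          "gonad_length"),
                           alpha = 0.05, bonferroni = FALSE) {
  metric <- match.arg(metric)
  df <- morphometry_table(as.data.frame(df))
  values <- switch(metric,
    proportion = gonad_proportion(df$body_length_um, df$gonad_length_um),
    body_length = df$body_length_um,
    gonad_length = df$gonad_length_um)
  groups <- split(values, factor(df$dpe_group, levels = unique(df$dpe_group)))

  small <- names(groups)[vapply(groups, length, integer(1)) < 2L]
  if (length(small)) {
    warning("excluding group(s) with < 2 records: ",
            paste(small, collapse = ", "))
    groups <- groups[setdiff(names(groups), small)]
  }
  k <- length(groups)
  if (k < 2L) stop("need at least 2 groups with >= 2 records", call. = FALSE)

  pm <- matrix(1, k, k, dimnames = list(names(groups), names(groups)))
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      p <- mann_whitney_u(groups[[i]], groups[[j]], "two_sided")$p_value
      pm[i, j] <- pm[j, i] <- p
    }
  }
  if (bonferroni) {
    m <- k * (k - 1) / 2
    pm[row(pm) != col(pm)] <- pmin(1, pm[row(pm) != col(pm)] * m)
  }
  structure(list(metric = metric,
                 box_summaries = lapply(groups, box_summary),
                 p_matrix = pm,
                 letters = compact_letter_display(pm, alpha),
                 group_sizes = vapply(groups, length, integer(1)),
                 alpha = alpha),
            class = "morphometry_analysis")
}

#' @export
print.morphometry_analysis <- function(x, ...) {
  cat("Morphometry analysis of", x$metric, "by age group\n")
  for (g in names(x$box_summaries)) {
    bs <- x$box_summaries[[g]]
    cat(sprintf("  %s dpe (n = %d, letter %s): median %.4g [Q1 %.4g, Q3 %.4g]\n",
                g, x$group_sizes[[g]], x$letters[[g]],
                bs$median, bs$q1, bs$q3))
  }
  cat("pairwise two-sided Mann-Whitney p-values:\n")
  print(signif(x$p_matrix, 4))
  invisible(x)
}
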