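# Nonparametric statistics shared by every analysis module: Mann-Whitney U
# with exact small-sample enumeration, compact letter displays, and box-plot
# summaries using 1.5 x IQR whiskers.

# cache of exact tie-free null U distributions, keyed "n1_n2"
.mw_null_cache <- new.env(parent = emptyenv())

#' Mann-Whitney U test with exact enumeration for small samples
#'
#' Computes the Mann-Whitney U statistic for two independent samples, using
#' midranks for ties. The p-value is exact -- obtained by full enumeration of
#' all \eqn{\binom{n_1+n_2}{n_1}} rank arrangements -- whenever
#' \eqn{n_1+n_2 \le 20} and the arrangement count does not exceed
#' \eqn{10^6}; otherwise a normal approximation with tie correction and a 0.5
#' continuity correction is used.
#'
#' The U statistic reported is the number of "rank wins" of `x` over `y`
#' (pairs with \eqn{x_i > y_j}, ties counted 1/2), i.e.
#' \eqn{U = R_x - n_1(n_1+1)/2} with \eqn{R_x} the midrank sum of `x`.
#'
#' @param x,y Numeric vectors, non-empty and finite.
#' @param alternative `"two_sided"` (default) or `"greater"`. `"greater"`
#'   tests the one-sided alternative that values in `y` are stochastically
#'   greater than values in `x` (the lower tail of U).
#' @param exact Force (`TRUE`) or forbid (`FALSE`) the exact path;
#'   `NULL` (default) decides by sample size as described above.
#' @return A `group_comparison` object: list with `u_statistic`, `p_value`,
#'   `n1`, `n2`, `fold_change` (mean of `x` over mean of `y`, `NA` when the
#'   latter is not positive), and `method` (`"exact"` or
#'   `"normal_approximation"`).
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))            # U = 0, p = 1/3
#' mann_whitney_u(1:3, 4:6, "greater")         # one-sided p = 1/20
#' @export
mann_whitney_u <- function(x, y, alternative = c("two_sided", "greater"),
                           exact = NULL) {
  alternative <- match.arg(alternative)
  if (length(x) == 0L || length(y) == 0L)
    stop("both samples must be non-empty", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("samples must contain only finite values", call. = FALSE)

  n1 <- length(x)
  n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)                       # midranks
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2

  fold <- if (mean(y) > 0) mean(x) / mean(y) else NA_real_

  if (length(unique(pooled)) == 1L) {
    warning("all values identical across both groups; p = 1")
    return(new_group_comparison(u, 1, n1, n2, fold, "exact"))
  }

  feasible <- (n1 + n2) <= 20 && choose(n1 + n2, n1) <= 1e6
  use_exact <- if (is.null(exact)) feasible else isTRUE(exact)
  if (use_exact && !feasible)
    stop("exact enumeration infeasible for these sample sizes", call. = FALSE)

  if (use_exact) {
    ustar <- mw_exact_null(r, n1)
    eps <- 1e-9
    p_lo <- mean(ustar <= u + eps)
    p_hi <- mean(ustar >= u - eps)
    p <- switch(alternative,
      two_sided = min(1, 2 * min(p_lo, p_hi)),
      greater = p_lo)
    method <- "exact"
  } else {
    n <- n1 + n2
    mu <- n1 * n2 / 2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    sigma <- sqrt(sigma2)
    p <- switch(alternative,
      two_sided = min(1, 2 * stats::pnorm(-(max(abs(u - mu) - 0.5, 0)) / sigma)),
      greater = stats::pnorm((u - mu + 0.5) / sigma))
    method <- "normal_approximation"
  }
  new_group_comparison(u, p, n1, n2, fold, method)
}

# Exact null distribution of U given the pooled midranks `r` and group size
# n1: U for every choice of n1 ranks out of the pool. Tie-free pools depend
# only on (n1, n2) and are cached.
mw_exact_null <- function(r, n1) {
  n <- length(r)
  tie_free <- !any(duplicated(r))
  key <- paste0(n1, "_", n - n1)
  if (tie_free && !is.null(.mw_null_cache[[key]]))
    return(.mw_null_cache[[key]])
  sel <- utils::combn(n, n1)
  ustar <- colSums(matrix(r[sel], nrow = n1)) - n1 * (n1 + 1) / 2
  if (tie_free) .mw_null_cache[[key]] <- ustar
  ustar
}

new_group_comparison <- function(u, p, n1, n2, fold, method) {
  structure(
    list(u_statistic = u, p_value = p, n1 = n1, n2 = n2,
         fold_change = fold, method = method),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Mann-Whitney U comparison (", x$method, ")\n", sep = "")
  cat(sprintf("  U = %g, p = %.4g (n1 = %d, n2 = %d)\n",
              x$u_statistic, x$p_value, x$n1, x$n2))
  if (!is.na(x$fold_change))
    cat(sprintf("  fold change (mean ratio) = %.4g\n", x$fold_change))
  invisible(x)
}

#' Compact letter display for pairwise comparisons
#'
#' Assigns lowercase letters to groups from a symmetric matrix of pairwise
#' p-values so that two groups share at least one letter if and only if their
#' pairwise p-value is at least `alpha`. Uses the insert-and-absorb
#' algorithm: start with a single letter containing every group; for each
#' significant pair still sharing a letter, duplicate that letter column,
#' delete one group from each copy, then absorb columns that are subsets of
#' another.
#'
#' @param pairwise_p Symmetric k x k numeric matrix of p-values (diagonal
#'   ignored), optionally with dimnames giving group labels.
#' @param alpha Significance level; a pair with `p < alpha` is significant.
#' @return A `letter_assignment`: named character vector of letter strings
#'   (letters are consecutive lowercase starting at "a"), with attribute
#'   `alpha`.
#' @examples
#' p <- matrix(1, 3, 3); p[1, 3] <- p[3, 1] <- 0.01
#' compact_letter_display(p, 0.05)  # "a", "ab", "b"
#' @export
compact_letter_display <- function(pairwise_p, alpha = 0.05) {
  if (!is.matrix(pairwise_p) || nrow(pairwise_p) != ncol(pairwise_p))
    stop("pairwise_p must be a square matrix", call. = FALSE)
  k <- nrow(pairwise_p)
  if (k < 2) stop("at least 2 groups required", call. = FALSE)
  offdiag <- pairwise_p[row(pairwise_p) != col(pairwise_p)]
  if (any(!is.finite(offdiag)) || any(offdiag < 0) || any(offdiag > 1))
    stop("off-diagonal p-values must lie in [0, 1]", call. = FALSE)
  if (!isTRUE(all.equal(pairwise_p[row(pairwise_p) != col(pairwise_p)],
                        t(pairwise_p)[row(pairwise_p) != col(pairwise_p)])))
    stop("pairwise_p must be symmetric", call. = FALSE)

  labels <- rownames(pairwise_p)
  if (is.null(labels)) labels <- paste0("g", seq_len(k))

  cols <- list(rep(TRUE, k))
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      if (pairwise_p[i, j] >= alpha) next
      newcols <- list()
      for (col in cols) {
        if (col[i] && col[j]) {
          c1 <- col; c1[i] <- FALSE
          c2 <- col; c2[j] <- FALSE
          newcols <- c(newcols, list(c1, c2))
        } else {
          newcols <- c(newcols, list(col))
        }
      }
      cols <- absorb_columns(newcols)
    }
  }
  # canonical order: by first group present in the column
  first <- vapply(cols, function(cc) which(cc)[1], integer(1))
  cols <- cols[order(first)]
  letters_used <- letters[seq_along(cols)]
  out <- vapply(seq_len(k), function(g) {
    paste0(letters_used[vapply(cols, function(cc) cc[g], logical(1))],
           collapse = "")
  }, character(1))
  names(out) <- labels
  structure(out, alpha = alpha, class = c("letter_assignment", "character"))
}

# drop columns that are subsets of (or duplicate) another column
absorb_columns <- function(cols) {
  m <- length(cols)
  keep <- rep(TRUE, m)
  for (a in seq_len(m)) {
    if (!keep[a]) next
    for (b in seq_len(m)) {
      if (a == b || !keep[b]) next
      if (all(cols[[a]] <= cols[[b]])) {
        identical_col <- all(cols[[a]] == cols[[b]])
        if (!identical_col || a > b) { keep[a] <- FALSE; break }
      }
    }
  }
  cols[keep]
}

#' @export
print.letter_assignment <- function(x, ...) {
  cat("Compact letter display (alpha = ", attr(x, "alpha"), ")\n", sep = "")
  print(stats::setNames(as.character(x), names(x)))
  invisible(x)
}

#' Five-number box-plot summary with 1.5 x IQR whiskers
#'
#' Quartiles are computed by linear interpolation of the sorted order
#' statistics (`quantile()` type 7). Whiskers extend to the most extreme data
#' points within 1.5 x IQR of the first/third quartile; all points beyond the
#' whiskers are reported as outliers.
#'
#' @param x Numeric vector with at least one finite value.
#' @return A `box_summary` list: `median`, `q1`, `q3`, `iqr`,
#'   `lower_whisker`, `upper_whisker`, `outliers`, `n`.
#' @examples
#' box_summary(1:9)
#' @export
box_summary <- function(x) {
  if (length(x) < 1L || !all(is.finite(x)))
    stop("x must contain at least one finite value and no NA", call. = FALSE)
  q <- unname(stats::quantile(x, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- x >= lo_fence & x <= hi_fence
  structure(
    list(median = q[2], q1 = q[1], q3 = q[3], iqr = iqr,
         lower_whisker = min(x[inside]), upper_whisker = max(x[inside]),
         outliers = sort(x[!inside]), n = length(x)),
    class = "box_summary")
}

#' @export
print.box_summary <- function(x, ...) {
  cat(sprintf("box summary (n = %d): median %g [Q1 %g, Q3 %g], whiskers [%g, %g]\n",
              x$n, x$median, x$q1, x$q3, x$lower_whisker, x$upper_whisker))
  if (length(x$outliers))
    cat("  outliers:", paste(x$outliers, collapse = ", "), "\n")
  invisible(x)
}
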