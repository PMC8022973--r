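# Independent oracles used across the suite. These deliberately take the
# naive route (scalar loops, per-arrangement recomputation) so they share
# no code path with the package implementation.

# Mann-Whitney U by direct pairwise comparison (no ranks)
oracle_u_pairwise <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y) u <- u + (xi > yj) + 0.5 * (xi == yj)
  u
}

# exact p by enumerating every assignment of pooled values to group 1,
# recomputing U per arrangement with the pairwise oracle
oracle_mw_exact <- function(x, y, alternative = "two_sided") {
  pooled <- c(x, y)
  n1 <- length(x)
  u_obs <- oracle_u_pairwise(x, y)
  sel <- utils::combn(length(pooled), n1)
  ustar <- apply(sel, 2, function(idx)
    oracle_u_pairwise(pooled[idx], pooled[-idx]))
  eps <- 1e-9
  p_lo <- mean(ustar <= u_obs + eps)
  p_hi <- mean(ustar >= u_obs - eps)
  if (alternative == "greater") p_lo else min(1, 2 * min(p_lo, p_hi))
}

# single-pass scalar reimplementation of the worm scoring statistic:
# crop, invert, brightness -> contrast -> intensity (round half away from
# zero, clamp per stage), threshold on deviation from background
oracle_score_worm <- function(img, box, cfg) {
  m <- unclass(img)
  rha <- function(v) sign(v) * floor(abs(v) + 0.5)
  cl <- function(v) min(max(v, 0), 255)
  count <- 0
  for (row in (box$y0 + 1):box$y1) {
    for (col in (box$x0 + 1):box$x1) {
      p <- 255 - m[row, col]
      p <- cl(rha(p + 255 * cfg$brightness_pct / 100))
      p <- cl(rha(127.5 + (p - 127.5) * (1 + cfg$contrast_pct / 100)))
      p <- cl(rha(p * (1 + cfg$intensity_pct / 100)))
      if (abs(p - cfg$background_gray) > cfg$variance) count <- count + 1
    }
  }
  count
}

# second rasterizer for the synthetic worm body: per-pixel distance check
# against the midline recomputed from the stored parameters and phase
oracle_body_pixels <- function(truth) {
  pr <- truth$params
  img <- truth$image
  cy <- (pr$height + 1) / 2
  # recover the phase by regenerating the substream draw
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed((truth$seed * 48271 + truth$index * 69621) %% 2147483647)
  phase <- stats::runif(1, 0, 2 * pi)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  count <- 0
  for (col in seq_len(pr$width)) {
    mid <- cy + pr$amplitude *
      sin(2 * pi * pr$frequency * (col - 1) / (pr$width - 1) + phase)
    for (row in seq_len(pr$height)) {
      if (abs(row - mid) <= pr$body_width / 2) count <- count + 1
    }
  }
  count
}
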