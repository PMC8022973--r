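# Pixel-threshold scoring pipeline

make_img <- function(h, w, fill = 0) gray_image(matrix(fill, h, w))

test_that("crop uses 0-based half-open boxes and preserves pixels", {
  set.seed(1)
  m <- matrix(sample(0:255, 100, replace = TRUE), 10, 10)
  img <- gray_image(m)

  full <- crop(img, bounding_box(0, 0, 10, 10))
  expect_identical(unclass(full), unclass(img))

  sub <- crop(img, bounding_box(2, 2, 5, 5))
  expect_identical(dim(sub), c(3L, 3L))
  expect_identical(unclass(sub), unclass(img)[3:5, 3:5])

  # crop-then-crop equals a single composed crop
  once <- crop(img, bounding_box(3, 4, 8, 9))
  twice <- crop(crop(img, bounding_box(1, 2, 9, 10)),
                bounding_box(2, 2, 7, 7))
  expect_identical(unclass(once), unclass(twice))

  expect_error(crop(img, bounding_box(5, 5, 11, 11)), "outside")
})

test_that("invert is the 255-complement and an involution", {
  img <- gray_image(matrix(c(0, 209, 255, 100), 2, 2))
  inv <- invert(img)
  expect_identical(unclass(inv), matrix(c(255L, 46L, 0L, 155L), 2, 2))
  expect_identical(unclass(invert(inv)), unclass(img))
})

test_that("brightness/contrast/intensity stages follow the documented formulas", {
  expect_identical(unclass(adjust_bci(make_img(1, 1, 100),
                                      quant_config(0, 0, 0)))[1, 1], 100L)
  # brightness -17%: 100 - 43.35 -> 57
  expect_identical(unclass(adjust_bci(make_img(1, 1, 100),
                                      quant_config(-17, 0, 0)))[1, 1], 57L)
  # contrast +71% pushes 0 to the lower clamp
  expect_identical(unclass(adjust_bci(make_img(1, 1, 0),
                                      quant_config(0, 71, 0)))[1, 1], 0L)
  # stages compose in order with per-stage rounding
  img <- make_img(1, 1, 200)
  cfg <- quant_config(-17, 71, -27)
  s1 <- min(max(round(200 - 43.35), 0), 255)                     # 157
  s2 <- min(max(sign(127.5 + (s1 - 127.5) * 1.71) *
                  floor(abs(127.5 + (s1 - 127.5) * 1.71) + 0.5), 0), 255)
  s3 <- min(max(floor(s2 * 0.73 + 0.5), 0), 255)
  expect_identical(unclass(adjust_bci(img, cfg))[1, 1], as.integer(s3))
})

test_that("background estimation takes the mode, ties toward lighter", {
  expect_equal(estimate_background(make_img(5, 5, 209)), 209)
  m <- matrix(209, 10, 10); m[1, 1] <- 255
  expect_equal(estimate_background(gray_image(m)), 209)
  bim <- gray_image(matrix(rep(c(100, 200), each = 50), 10, 10))
  expect_equal(estimate_background(bim), 200)
})

test_that("bright-pixel counting uses a strict threshold", {
  expect_equal(count_bright_pixels(make_img(4, 4, 209), 209, 0), 0)
  m <- matrix(209, 4, 4); m[2, 2] <- 255
  expect_equal(count_bright_pixels(gray_image(m), 209, 40), 1)   # |46| > 40
  expect_equal(count_bright_pixels(gray_image(m), 209, 46), 0)   # strict
})

test_that("score_worm equals the brute-force scalar oracle", {
  set.seed(202)
  for (rep in 1:10) {
    truth <- generate_worm_image(
      image_sim_params(height = 40, width = 80, reporter_extra = 50,
                       amplitude = 8, noise_sd = 3),
      seed = rep, index = 1)
    box <- bounding_box(5, 3, 75, 38)
    cfg <- quant_config(variance = 60, background_gray = 186)
    got <- score_worm(truth$image, box, cfg, "w")
    expect_identical(got$bright_pixel_count,
                     as.integer(oracle_score_worm(truth$image, box, cfg)))
    expect_equal(got$total_pixels, 70 * 35)
    # determinism
    expect_identical(score_worm(truth$image, box, cfg, "w")$bright_pixel_count,
                     got$bright_pixel_count)
  }
})

test_that("uniform signal increments never decrease the count", {
  truth <- generate_worm_image(
    image_sim_params(height = 40, width = 80, amplitude = 8, noise_sd = 0,
                     reporter_extra = 0),
    seed = 4)
  cfg <- quant_config(variance = 60, background_gray = 186)
  box <- bounding_box(0, 0, 80, 40)
  counts <- vapply(c(0, 10, 20, 40, 60), function(extra) {
    m <- unclass(truth$image)
    m[truth$body_mask] <- pmin(m[truth$body_mask] + extra, 255)
    score_worm(gray_image(m), box, cfg)$bright_pixel_count
  }, integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("variance calibration pins the control bright-pixel fraction", {
  flat <- replicate(3, make_img(10, 10, 186), simplify = FALSE)
  expect_equal(calibrate_variance(flat, 186, target_fraction = 0), 0)

  # max deviation 30: strict > means v = 30 already excludes everything
  m <- matrix(186, 10, 10); m[1, 1:5] <- 216
  devs <- replicate(3, gray_image(m), simplify = FALSE)
  expect_equal(calibrate_variance(devs, 186, target_fraction = 0), 30)

  # returned v is monotone non-increasing in target_fraction
  set.seed(9)
  imgs <- replicate(5, gray_image(matrix(
    pmin(pmax(round(186 + rnorm(400, 0, 15)), 0), 255), 20, 20)),
    simplify = FALSE)
  fracs <- c(0.5, 0.2, 0.1, 0.02, 0)
  vs <- vapply(fracs, function(tf)
    calibrate_variance(imgs, 186, target_fraction = tf), integer(1))
  expect_true(all(diff(vs) >= 0))

  expect_error(calibrate_variance(list(), 186), "at least 3")
  # maximal deviation everywhere: only v = 255 empties the count
  v <- calibrate_variance(replicate(3, make_img(2, 2, 0), simplify = FALSE),
                          255, target_fraction = 0)
  expect_equal(v, 255)
})

test_that("fluorescence comparison reports fold change and exact p", {
  mk <- function(counts) lapply(counts, function(k)
    structure(list(worm_id = NA, bright_pixel_count = k, total_pixels = 100,
                   config = quant_config()), class = "fluorescence_score"))
  same <- suppressWarnings(compare_fluorescence(mk(c(5, 5)), mk(c(5, 5))))
  expect_equal(same$fold_change, 1)
  expect_equal(same$p_value, 1)

  cmp <- compare_fluorescence(mk(c(39, 39)), mk(c(10, 10)))
  expect_equal(cmp$fold_change, 3.9)

  tr <- c(8, 12, 30); ct <- c(1, 2, 3)
  cmp2 <- compare_fluorescence(mk(tr), mk(ct))
  expect_equal(cmp2$p_value, oracle_mw_exact(tr, ct), tolerance = 1e-12)

  zero <- suppressWarnings(compare_fluorescence(mk(c(1, 2)), mk(c(0, 0))))
  expect_true(zero$control_mean_zero)
  expect_true(is.na(zero$fold_change))
})
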