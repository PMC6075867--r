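# ROI intensity quantification, bright-AZ classification, dF, correlation.

test_that("ROI quantification: uniform image, impulse arithmetic, borders", {
  az <- data.frame(az_id = 1:2, x_um = c(1.0, 2.0), y_um = 1.0)
  img <- matrix(5, 30, 30)
  it <- quantify_intensity(img, az, 0.138)
  expect_true(all(it$mean_f == 5))

  img2 <- matrix(0, 30, 30)
  r <- round(1.0 / 0.138 + 0.5); c <- r
  img2[r, c] <- 9
  it2 <- quantify_intensity(img2, az, 0.138)
  expect_equal(it2$mean_f[1], 1.0)
  expect_equal(it2$sum_f[1], 9)

  near_edge <- data.frame(az_id = 1L, x_um = 0.05, y_um = 0.05)
  it3 <- quantify_intensity(img, near_edge, 0.138)
  expect_true(it3$border[1])
  expect_error(quantify_intensity(img, az[0, ], 0.138), "empty")
})

test_that("quantification is translation-equivariant and rank-faithful", {
  # adequately sampled puncta (sigma ~2.2 px) with known amplitudes
  cfg <- synth_config(n_az = 200, min_sep_um = 1, close_pair_frac = 0,
                      seed = 5, field_size_um = c(25, 25),
                      psf_sigma_um = 0.3)
  az <- sample_pr_population(cfg)
  res <- render_channel_image(az, "cac", cfg, noise_sd = 0)
  it <- quantify_intensity(res$image, az, cfg$pixel_size_um,
                           subpixel = TRUE)
  ok <- !it$border
  expect_gte(cor(it$mean_f[ok], res$az$intensity_cac[ok],
                 method = "spearman"), 0.99)
  # shift image and AZ table together by 5 px: integer ROIs are identical
  it_int <- quantify_intensity(res$image, az, cfg$pixel_size_um)
  sh <- azquant:::shift_frame_int(res$image, 5, 5)
  az2 <- az
  az2$x_um <- az$x_um + 5 * cfg$pixel_size_um
  az2$y_um <- az$y_um + 5 * cfg$pixel_size_um
  it2 <- quantify_intensity(sh, az2, cfg$pixel_size_um)
  ok2 <- !it_int$border & !it2$border
  expect_equal(it2$mean_f[ok2], it_int$mean_f[ok2], tolerance = 1e-12)
})

test_that("bright classification: degenerate and hand-checked thresholds", {
  az <- data.frame(az_id = 1:5, x_um = 1:5, y_um = 1)
  mk <- function(v) {
    out <- data.frame(az_id = seq_along(v), channel = "c", mean_f = v,
                      sum_f = v, norm_f = 0, border = FALSE)
    class(out) <- c("intensity_table", "data.frame")
    out
  }
  eq <- bright_az_classify(mk(rep(4, 5)))
  expect_equal(sum(eq$bright), 0)

  t1 <- bright_az_classify(mk(c(1, 1, 1, 1, 10)))
  expect_equal(attr(t1, "threshold"), 10, tolerance = 1e-9)
  expect_equal(sum(t1$bright), 0)              # strict inequality

  # note: for x = (1,1,1,1,B) the threshold equals B exactly (mean + 2
  # population SDs of a single outlier among four equal values), so the
  # strict rule needs n != 5 to flag an outlier
  x <- c(1, 1, 1, 1, 1, 12)
  t2 <- bright_az_classify(mk(x))
  thr_oracle <- mean(x) + 2 * sqrt(mean((x - mean(x))^2))
  expect_equal(sum(t2$bright), sum(x > thr_oracle))
  expect_equal(sum(t2$bright), 1)
})

test_that("calibrated Cac channel reproduces the bright tail and fold", {
  cfg <- synth_config(n_az = 4000, seed = 21, field_size_um = c(90, 90))
  az <- sample_pr_population(cfg)
  res <- render_channel_image(az, "cac", cfg)
  it <- bright_az_classify(quantify_intensity(res$image, az,
                                              cfg$pixel_size_um))
  expect_lt(abs(attr(it, "bright_fraction") - 0.0572), 0.012)
  expect_equal(attr(it, "bright_fold"), 2.1, tolerance = 0.15)

  brp <- render_channel_image(az, "brp", cfg)
  itb <- bright_az_classify(quantify_intensity(brp$image, az,
                                               cfg$pixel_size_um))
  expect_equal(attr(itb, "bright_fold"), 1.7, tolerance = 1.7 * 0.15)
})

test_that("dF: constant stack, square pulse, epoch stability", {
  az <- data.frame(az_id = 1:2, x_um = c(1, 2), y_um = 1)
  arr <- array(3, c(30, 30, 12))
  st <- movie_stack(arr, 0.13, 0.138)
  d0 <- delta_f(st, 4:6, 1:3, az)
  expect_true(all(d0$dF == 0))

  arr2 <- arr
  arr2[, , 4:6] <- 3 + 2.5
  st2 <- movie_stack(arr2, 0.13, 0.138)
  d1 <- delta_f(st2, 4:6, 1:3, az)
  expect_equal(d1$dF, c(2.5, 2.5), tolerance = 1e-12)

  # three epochs with fixed amplitude: CoV < 10%
  arr3 <- arr
  for (ep in list(4:6, 7:9, 10:12)) arr3[, , ep] <- 3 + 2.5
  st3 <- movie_stack(arr3, 0.13, 0.138)
  d3 <- delta_f(st3, list(4:6, 7:9, 10:12), 1:3, az)
  expect_true(all(d3$cv < 0.10))
  expect_error(delta_f(st, 3:5, 1:3, az), "overlap")
})

test_that("saturation control flags sensor-limited recordings", {
  same <- rnorm(100, 1000, 10)
  s0 <- saturation_control(same, same)
  expect_equal(s0$shift, 0)
  expect_true(s0$sensor_limited)

  set.seed(4)
  stim <- rnorm(200, 1924, 63 * sqrt(200) / 10)
  iono <- rnorm(200, 6105, 175 * sqrt(200) / 10)
  s1 <- saturation_control(stim, iono)
  expect_equal(s1$mean_ratio, 1924 / 6105, tolerance = 0.02)
  expect_false(s1$sensor_limited)

  wide <- rnorm(200, 1000, 400)
  narrow <- rnorm(200, 3000, 150)
  s2 <- saturation_control(wide, narrow)
  expect_gt(s2$rcv_stim, s2$rcv_iono)
})

test_that("grouped correlation: exact lines and the textbook example", {
  x <- data.frame(az_id = 1:20, value = 1:20)
  y <- data.frame(az_id = 1:20, value = 2 * (1:20) + 1)
  expect_equal(correlate_az(x, y)$pooled$r, 1)
  yn <- data.frame(az_id = 1:20, value = -(1:20))
  expect_equal(correlate_az(x, yn)$pooled$r, -1)

  xs <- data.frame(az_id = 1:10, value = rep(c(1, 2, 3, 4, 5), 2))
  ys <- data.frame(az_id = 1:10, value = rep(c(2, 1, 4, 3, 5), 2))
  res <- correlate_az(xs, ys)
  expect_equal(res$pooled$r, 0.8, tolerance = 1e-12)

  gx <- data.frame(az_id = 1:40, value = rnorm(40))
  expect_error(correlate_az(gx, data.frame(az_id = 1:40, value = 1)),
               "zero variance")
})
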