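# Spot detection, event detection, and centroid-proximity assignment.

gauss_punctum <- function(nr, nc, r0, c0, amp = 100, sig = 1.5) {
  outer(seq_len(nr), seq_len(nc), function(r, c)
    amp * exp(-((r - r0)^2 + (c - c0)^2) / (2 * sig^2)))
}

test_that("find_spots localises puncta and suppresses close maxima", {
  img <- gauss_punctum(41, 41, 21, 21)
  sp <- find_spots(img, 0.138, min_separation_um = 0.4, threshold = 10)
  expect_equal(nrow(sp), 1)
  expect_lt(abs(sp$x_um - (21 - 0.5) * 0.138), 0.2 * 0.138)
  expect_lt(abs(sp$y_um - (21 - 0.5) * 0.138), 0.2 * 0.138)

  two <- gauss_punctum(41, 41, 21, 18, amp = 100) +
         gauss_punctum(41, 41, 21, 23, amp = 80)      # 5 px apart
  sp2 <- find_spots(two, 0.138, min_separation_um = 3 * 0.138,
                    threshold = 10)
  expect_equal(nrow(sp2), 2)
  sp1 <- find_spots(two, 0.138, min_separation_um = 7 * 0.138,
                    threshold = 10)
  expect_equal(nrow(sp1), 1)
  expect_lt(abs(sp1$x_um - (18 - 0.5) * 0.138), 0.15)  # brighter kept

  empty <- find_spots(matrix(0, 20, 20), 0.138, threshold = 5)
  expect_equal(nrow(empty), 0)
})

test_that("find_spots recovers a synthetic layout nearly perfectly", {
  cfg <- synth_config(n_az = 300, close_pair_frac = 0, seed = 17)
  az <- sample_pr_population(cfg)
  res <- render_channel_image(az, "glurIIA", cfg)
  sp <- suppressWarnings(find_spots(res$image, cfg$pixel_size_um))
  d <- azquant:::pairwise_dist(cbind(sp$x_um, sp$y_um),
                               cbind(az$x_um, az$y_um))
  hit <- apply(d, 2, min) < 0.3          # AZ recovered
  fp <- apply(d, 1, min) > 0.3           # spot without an AZ
  expect_gte(mean(hit), 0.98)
  expect_lte(mean(fp), 0.02)
})

test_that("event detection on constructed stacks", {
  cfg <- one_az_cfg()
  az <- one_az_table(cfg)
  ev <- data.frame(az_id = 1L, time_s = 0.5, kind = "evoked",
                   stimulus_index = 1L)
  mv <- render_movie(az, ev, cfg)
  st <- subtract_baseline(mv, "auto", 5)
  expect_warning(detect_events(st), "noise SD is 0")
  det <- suppressWarnings(detect_events(st))
  expect_equal(nrow(det), 1)
  expect_equal(det$frame, floor(0.5 / 0.13) + 1)
  expect_lt(abs(det$x_um - az$x_um), 0.2 * cfg$pixel_size_um)
  expect_lt(abs(det$y_um - az$y_um), 0.2 * cfg$pixel_size_um)

  # two simultaneous flashes 3 um apart -> two events
  cfg2 <- clean_cfg(n_az = 2)
  cfg2$field_size_um <- c(8, 8)
  az2 <- data.frame(az_id = 1:2, x_um = c(2.0, 5.0), y_um = 4.0)
  ev2 <- data.frame(az_id = 1:2, time_s = c(0.5, 0.5), kind = "evoked",
                    stimulus_index = 1L)
  mv2 <- render_movie(az2, ev2, cfg2)
  st2 <- subtract_baseline(mv2, "auto", 5)
  det2 <- suppressWarnings(detect_events(st2))
  expect_equal(nrow(det2), 2)
  a2 <- assign_events(det2, az2, 0.5)
  expect_setequal(a2$az_id, 1:2)
})

test_that("noise-only stacks yield at most 1 spurious event per 1000 frames", {
  cfg <- synth_config(n_az = 5, n_stimuli = 0, movie_duration_s = 130,
                      silent_frac = 1, spont_only_frac = 0, seed = 31,
                      field_size_um = c(20, 20))
  sim <- simulate_experiment(cfg)
  pp <- preprocess_stack(sim$movie, apply_mode = "integer", crop_px = 128)
  nf <- dim(sim$movie$data)[3]
  for (ts in c(3, 5)) {
    ev <- detect_events(pp$stack, threshold_sd = ts)
    expect_lte(nrow(ev), ceiling(nf / 1000))
  }
})

test_that("detected event counts track ground truth on a default movie", {
  cfg <- tiny_cfg(n_az = 150, n_stimuli = 30, seed = 4)
  sim <- simulate_experiment(cfg)
  ana <- suppressWarnings(analyze_movie(sim$movie, sim$images$glurIIA))
  expect_lt(abs(ana$summary$n_events - nrow(sim$events)) / nrow(sim$events),
            0.05)
})

test_that("assignment follows nearest-centroid with tie-break to lower id", {
  az <- data.frame(az_id = c(3L, 7L), x_um = c(1, 3), y_um = 1)
  ev <- data.frame(event_id = 1:2, frame = 1L, time_s = 0.13,
                   x_um = c(1, 2), y_um = 1, peak_dF = 5, n_frames = 1L)
  class(ev) <- c("event_list", "data.frame")
  out <- assign_events(ev, az, max_dist_um = 1.5)
  expect_equal(out$az_id[1], 3L)       # exactly at AZ 3
  expect_equal(out$az_id[2], 3L)       # equidistant -> lower az_id
  far <- ev; far$x_um <- 10
  outf <- assign_events(far, az, max_dist_um = 0.5)
  expect_true(all(is.na(outf$az_id)))
  expect_true(all(outf$unassigned_reason == "no AZ in range"))
})

test_that("assignment equals brute-force nearest neighbour and is order
           invariant", {
  set.seed(8)
  az <- generate_az_layout(200, c(25, 25), 0.6, 0, seed = 8)
  idx <- sample.int(200, 5000, replace = TRUE)
  ev <- data.frame(event_id = seq_len(5000), frame = 1L, time_s = 0.13,
                   x_um = az$x_um[idx] + rnorm(5000, sd = 0.1),
                   y_um = az$y_um[idx] + rnorm(5000, sd = 0.1),
                   peak_dF = 5, n_frames = 1L)
  class(ev) <- c("event_list", "data.frame")
  out <- assign_events(ev, az, max_dist_um = 0.5)
  # brute-force per-event oracle
  oracle <- vapply(seq_len(nrow(ev)), function(i) {
    d <- sqrt((az$x_um - ev$x_um[i])^2 + (az$y_um - ev$y_um[i])^2)
    j <- which.min(d)
    if (d[j] <= 0.5) az$az_id[j] else NA_integer_
  }, integer(1))
  expect_identical(out$az_id, oracle)
  # >= 99% of events assigned to their true AZ
  ok <- !is.na(out$az_id)
  expect_gte(mean(out$az_id[ok] == az$az_id[idx][ok]), 0.99)
  # permuting event order never changes the mapping
  perm <- sample.int(nrow(ev))
  out2 <- assign_events(ev[perm, ], az, max_dist_um = 0.5)
  expect_identical(out2$az_id, out$az_id[perm])
})
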