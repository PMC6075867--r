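# Synthetic generator: layouts, Pr population, event times, rendering.

test_that("layout places the requested AZs and honours min separation", {
  az1 <- generate_az_layout(1, c(5, 5), 0.6, 0, seed = 1)
  expect_equal(nrow(az1), 1)
  expect_equal(unresolvable_fraction(az1), 0)

  az <- generate_az_layout(50, c(12, 12), min_sep_um = 0.6,
                           close_pair_frac = 0, seed = 7)
  # exhaustive all-pairs distance oracle
  d <- as.matrix(stats::dist(cbind(az$x_um, az$y_um)))
  diag(d) <- Inf
  expect_true(min(d) >= 0.6)
  expect_error(generate_az_layout(500, c(5, 5), 0.6),
               "density")
})

test_that("planted close pairs set the unresolvable fraction", {
  az <- generate_az_layout(300, c(25, 25), 0.6, close_pair_frac = 0.0245,
                           seed = 3)
  # planting granularity: round(0.0245 * 300 / 2) = 4 pairs -> 8/300
  expect_equal(attr(az, "n_close_pairs"), 4)
  expect_equal(unresolvable_fraction(az, 0.28), 8 / 300)
})

test_that("unresolvable fraction matches hand-checked collinear case", {
  az <- data.frame(az_id = 1:3, x_um = c(0, 0.2, 1.0), y_um = 0)
  expect_equal(unresolvable_fraction(az, 0.28), 2 / 3)
  expect_equal(unresolvable_fraction(az[1, , drop = FALSE], 0.28), 0)
})

test_that("degenerate mixture: silent_frac = 1 gives all-zero Pr", {
  cfg <- tiny_cfg(n_az = 100, silent_frac = 1, spont_only_frac = 0)
  az <- sample_pr_population(cfg)
  expect_true(all(az$true_pr == 0))
  expect_true(all(az$true_class == "silent"))
})

test_that("calibrated population mean, tail and skewness match design", {
  cfg <- synth_config(n_az = 2000, seed = 42)
  az <- sample_pr_population(cfg)
  # mean within 3 SEM of 0.073
  sem <- sd(az$true_pr) / sqrt(nrow(az))
  expect_lt(abs(mean(az$true_pr) - 0.073), 3 * sem)
  expect_true(all(az$true_pr >= 0 & az$true_pr <= cfg$pr_cap))
  expect_true(all(az$true_pr[az$true_class != "active"] == 0))

  # large-sample Monte-Carlo oracle of the mixture: fraction above
  # mean + 2 * population SD ~ 9.9%, skewness right of 2
  cfg2 <- synth_config(n_az = 200000, seed = 9,
                       field_size_um = c(650, 650))
  big <- sample_pr_population(cfg2)
  p <- big$true_pr
  thr <- mean(p) + 2 * sd(p) * sqrt((length(p) - 1) / length(p))
  expect_equal(mean(p > thr), 0.099, tolerance = 0.05)
  sk <- mean((p - mean(p))^3) / (mean((p - mean(p))^2))^1.5
  expect_gt(sk, 1.9)
  expect_lt(sk, 2.6)
})

test_that("configs whose cap truncation discards >5% of mass are rejected", {
  expect_error(synth_config(pr_high_mean = 1.4, pr_high_shape = 4),
               "truncation")
})

test_that("event simulation follows the Bernoulli/Poisson model", {
  az <- data.frame(az_id = 1:3, x_um = 1:3, y_um = 1,
                   true_pr = c(0, 1, 0),
                   true_class = factor(c("active", "active", "silent"),
                                       c("silent", "spont_only", "active")))
  stim <- seq(1, 54)
  ev <- simulate_event_times(az, stim, 60, spont_rate_hz = 0, seed = 2)
  expect_equal(sum(ev$az_id == 1), 0)               # p = 0
  expect_equal(sum(ev$az_id == 2 & ev$kind == "evoked"), 54)  # p = 1
  # at most one evoked event per (az, stimulus)
  expect_false(any(duplicated(ev[ev$kind == "evoked",
                                 c("az_id", "stimulus_index")])))

  # Poisson bound: 1000 AZs x 0.011 Hz x 300 s -> lambda = 3300
  azp <- data.frame(az_id = 1:1000, x_um = 1, y_um = 1, true_pr = 0,
                    true_class = factor(rep("spont_only", 1000),
                                        c("silent", "spont_only", "active")))
  evs <- simulate_event_times(azp, numeric(0), 300, 0.011, seed = 5)
  expect_lt(abs(nrow(evs) - 3300), 4 * sqrt(3300))
  expect_true(all(is.na(evs$stimulus_index)))
})

test_that("evoked counts are Binomial(S, p) and spontaneous counts Poisson", {
  # 10^4 replicate AZs at p = 0.3, S = 20
  n <- 10000; S <- 20; p <- 0.3
  az <- data.frame(az_id = seq_len(n), x_um = 1, y_um = 1, true_pr = p,
                   true_class = factor(rep("active", n),
                                       c("silent", "spont_only", "active")))
  ev <- simulate_event_times(az, seq_len(S), S + 1, 0, seed = 11)
  cnt <- tabulate(ev$az_id, n)
  expect_lt(abs(mean(cnt) - S * p), 3 * sqrt(S * p * (1 - p) / n))
  v <- S * p * (1 - p)
  # SE of the sample variance of a binomial is ~ sqrt(2/(n-1)) * v
  expect_lt(abs(var(cnt) - v), 3 * sqrt(2 / (n - 1)) * v * 1.5)

  # index of dispersion of spontaneous counts at lambda >= 1000
  azs <- data.frame(az_id = seq_len(2000), x_um = 1, y_um = 1, true_pr = 0,
                    true_class = factor(rep("spont_only", 2000),
                                        c("silent", "spont_only", "active")))
  evs <- simulate_event_times(azs, numeric(0), 100, 0.011, seed = 12)
  cs <- tabulate(evs$az_id, 2000)
  expect_gt(var(cs) / mean(cs), 0.9)
  expect_lt(var(cs) / mean(cs), 1.1)
})

test_that("generator output is bit-identical under a fixed seed", {
  cfg <- tiny_cfg(n_az = 30, n_stimuli = 5, seed = 99)
  s1 <- simulate_experiment(cfg)
  s2 <- simulate_experiment(cfg)
  expect_identical(s1$az, s2$az)
  expect_identical(s1$events, s2$events)
  expect_identical(s1$movie$data, s2$movie$data)
})

test_that("rendered flash follows the closed-form kernel and decay", {
  cfg <- one_az_cfg()
  az <- one_az_table(cfg)
  # no events: constant stack at the baseline
  ev0 <- simulate_event_times(az[az$true_pr < 0, ], numeric(0), 2, 0, 1)
  mv0 <- render_movie(az, ev0, cfg)
  expect_true(all(mv0$data == cfg$baseline_f))

  # one event: peak pixel = baseline + amplitude, then exponential decay
  ev <- data.frame(az_id = 1L, time_s = 0.50, kind = "evoked",
                   stimulus_index = 1L)
  class(ev) <- c("event_truth", "data.frame")
  mv <- render_movie(az, ev, cfg)
  f0 <- floor(0.50 / cfg$frame_interval_s) + 1
  expect_equal(max(mv$data[, , f0]), cfg$baseline_f + cfg$flash_amplitude,
               tolerance = 1e-12)
  for (k in 1:4) {
    expected <- cfg$flash_amplitude * exp(-0.13 * k / 0.26)
    expect_equal(max(mv$data[, , f0 + k]) - cfg$baseline_f, expected,
                 tolerance = 1e-9)
  }
})

test_that("channel rendering hits the requested Pr correlation", {
  cfg <- synth_config(n_az = 1000, seed = 7)
  az <- sample_pr_population(cfg)

  res <- render_channel_image(az, "cac", cfg)          # r = 0.61
  expect_equal(cor(res$az$intensity_cac, az$true_pr), 0.61,
               tolerance = 0.013)

  cfg$channels$cac$r <- 0
  res0 <- render_channel_image(az, "cac", cfg)
  expect_lt(abs(cor(res0$az$intensity_cac, az$true_pr)), 0.1)

  cfg$channels$cac$r <- 1                              # comonotone
  res1 <- render_channel_image(az, "cac", cfg)
  act <- az$true_pr > 0
  expect_equal(order(res1$az$intensity_cac[act]), order(az$true_pr[act]))

  expect_error(channel_amplitudes(az$true_pr, 1.2, 0), "0.999")
})

test_that("rendered PSD pair matches its ground-truth geometry", {
  # dip 0: unimodal channel B
  p0 <- render_psd_pair(0.59, 1.01, dip_frac = 0)
  pr0 <- detect_ring(extract_profile(p0$a, p0$b, p0$center_um, 2.0))
  expect_equal(pr0$dip_frac, 0)
  expect_false(pr0$has_ring)

  # fine-grid render: radial minimum / flank ratio = 1 - dip within 0.01
  p <- render_psd_pair(0.59, 1.01, dip_frac = 0.15, pixel_size_um = 0.04)
  prof <- extract_profile(p$a, p$b, p$center_um, 2.0,
                          pixel_size_um = 0.04)
  prof <- detect_ring(prof)
  expect_equal(prof$dip_frac, 0.15, tolerance = 0.01)

  expect_error(render_psd_pair(0.2, 0.25, pixel_size_um = 0.138),
               "unresolvable")
  expect_error(render_psd_pair(1.0, 0.5), "ring_outer")
})
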