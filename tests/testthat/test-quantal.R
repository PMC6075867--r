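# Pr estimation, classification, distribution shape, session stability.

test_that("evoked/spontaneous split follows the stimulus-window rule", {
  ev <- data.frame(event_id = 1:3, frame = 1:3,
                   time_s = c(2.05, 3.6, 10.0),
                   x_um = 1, y_um = 1, peak_dF = 5, n_frames = 1L,
                   az_id = c(1L, 1L, 2L))
  class(ev) <- c("event_list", "data.frame")
  stim <- c(2, 5, 8)                      # 0.33 Hz
  out <- split_evoked_spontaneous(ev, stim, window_s = 0.3)
  expect_equal(out$kind, c("evoked", "spontaneous", "spontaneous"))
  expect_equal(out$stimulus_index, c(1L, NA, NA))
  expect_error(split_evoked_spontaneous(ev, stim, window_s = 4),
               "inter-stimulus")
})

test_that("extra same-AZ events in one window relabel to spontaneous", {
  ev <- data.frame(event_id = 1:3, frame = 1:3,
                   time_s = c(2.05, 2.15, 2.2),
                   x_um = 1, y_um = 1, peak_dF = 5, n_frames = 1L,
                   az_id = c(1L, 1L, 2L))
  class(ev) <- c("event_list", "data.frame")
  out <- split_evoked_spontaneous(ev, 2, window_s = 0.3)
  expect_equal(out$kind, c("evoked", "spontaneous", "evoked"))
  # exhaustive enumeration oracle: one evoked per (az, stimulus)
  key <- paste(out$az_id, out$stimulus_index)[out$kind == "evoked"]
  expect_false(any(duplicated(key)))
})

test_that("compute_pr divides events by stimuli", {
  ev <- data.frame(az_id = integer(0), kind = character(0))
  pm <- compute_pr(ev, az_ids = 1:3, n_stimuli = 100, duration_s = 300)
  expect_true(all(pm$pr_hat == 0))

  ev2 <- data.frame(az_id = rep(1L, 20),
                    kind = c(rep("evoked", 15), rep("spontaneous", 5)))
  pm2 <- compute_pr(ev2, az_ids = 1:2, n_stimuli = 54, duration_s = 250)
  expect_equal(pm2$pr_hat[1], 15 / 54, tolerance = 1e-12)
  expect_equal(round(pm2$pr_hat[1], 4), 0.2778)
  expect_equal(pm2$spont_rate_hz[1], 5 / 250)
  expect_equal(pm2$pr_hat[2], 0)
})

test_that("pr_hat lands in the binomial interval at S = 1000", {
  az <- data.frame(az_id = 1L, x_um = 1, y_um = 1, true_pr = 0.3,
                   true_class = factor("active",
                                       c("silent", "spont_only", "active")))
  ev <- simulate_event_times(az, seq_len(1000), 1001, 0, seed = 3)
  pm <- compute_pr(data.frame(az_id = ev$az_id, kind = ev$kind),
                   1L, 1000, 1001)
  # 99% binomial interval
  expect_gte(pm$pr_hat, qbinom(0.005, 1000, 0.3) / 1000)
  expect_lte(pm$pr_hat, qbinom(0.995, 1000, 0.3) / 1000)
})

test_that("estimator is consistent as stimuli grow", {
  az <- sample_pr_population(tiny_cfg(n_az = 200, seed = 6))
  med_err <- vapply(c(100, 1000, 10000), function(S) {
    ev <- simulate_event_times(az, seq_len(S), S + 1, 0, seed = S)
    pm <- compute_pr(data.frame(az_id = ev$az_id, kind = ev$kind),
                     az$az_id, S, S + 1)
    median(abs(pm$pr_hat - az$true_pr))
  }, numeric(1))
  expect_true(all(diff(med_err) < 0))
})

test_that("classification matches the hand-computed example", {
  pm <- make_prmap(c(0, 0, 0.05, 0.05, 0.05, 0.5))
  out <- classify_azs(pm)
  expect_equal(attr(out, "threshold"), 0.4615, tolerance = 1e-4)
  expect_equal(sum(out$class == "high"), 1)
  expect_equal(sum(out$class == "low"), 3)      # evoked releasers below thr
  expect_equal(sum(out$class == "spont_only"), 2)
  expect_equal(mean(pm$pr_hat), 0.1083, tolerance = 1e-3)
  # population SD oracle
  expect_equal(sd(pm$pr_hat) * sqrt(5 / 6), 0.1766, tolerance = 1e-3)
})

test_that("degenerate classification: equal pr gives no high AZs", {
  pm <- make_prmap(rep(0.2, 8))
  out <- classify_azs(pm)
  expect_equal(sum(out$class == "high"), 0)
  expect_true(all(out$class == "low"))
})

test_that("classes always partition the population", {
  for (seed in 1:3) {
    az <- sample_pr_population(tiny_cfg(n_az = 150, seed = seed))
    ev <- simulate_event_times(az, seq_len(40), 120, 0.011, seed = seed)
    ev$kind <- as.character(ev$kind)
    pm <- compute_pr(data.frame(az_id = ev$az_id, kind = ev$kind),
                     az$az_id, 40, 120)
    pm <- classify_azs(pm)
    expect_equal(sum(table(pm$class)), nrow(az))
    expect_false(any(is.na(pm$class)))
  }
})

test_that("distribution summary: symmetric, formula oracle, calibrated", {
  set.seed(10)
  g <- make_prmap(pmin(pmax(rnorm(10000, 0.5, 0.1), 0), 1))
  s <- distribution_summary(g)
  expect_lt(abs(s$skewness), 0.05)

  x <- c(1, 2, 3, 4, 100)
  # brute-force adjusted Fisher-Pearson formula
  n <- 5; m <- mean(x)
  g1 <- mean((x - m)^3) / mean((x - m)^2)^1.5
  expect_equal(distribution_summary(make_prmap(x))$skewness,
               g1 * sqrt(n * (n - 1)) / (n - 2), tolerance = 1e-12)
  if (requireNamespace("e1071", quietly = TRUE))
    expect_equal(distribution_summary(make_prmap(x))$skewness,
                 e1071::skewness(x, type = 2), tolerance = 1e-10)

  big <- sample_pr_population(synth_config(n_az = 20000, seed = 2,
                                           field_size_um = c(210, 210)))
  sk <- distribution_summary(make_prmap(big$true_pr))$skewness
  expect_gt(sk, 1.9)
  expect_lt(sk, 2.6)
})

test_that("session stability: identity, shuffled, and attenuation law", {
  az <- sample_pr_population(tiny_cfg(n_az = 500, seed = 12,
                                      field_size_um = c(34, 34)))
  S <- 54
  sim_map <- function(seed) {
    cnt <- rbinom(nrow(az), S, az$true_pr)
    make_prmap(cnt / S, n_stimuli = S)
  }
  m1 <- sim_map(1)
  expect_equal(session_stability(m1, m1)$r, 1)

  set.seed(99)
  shuf <- m1
  shuf$pr_hat <- sample(shuf$pr_hat)
  expect_lt(abs(session_stability(m1, shuf)$r), 0.1)

  # analytic attenuation vs Monte-Carlo over 100 replicate session pairs
  set.seed(7)
  rs <- replicate(100, {
    a <- rbinom(nrow(az), S, az$true_pr) / S
    b <- rbinom(nrow(az), S, az$true_pr) / S
    cor(a, b)
  })
  pred <- session_stability(m1, sim_map(2), true_pr = az$true_pr,
                            n_stimuli = S)$r_predicted
  expect_lt(abs(mean(rs) - pred), 0.05)
  expect_error(session_stability(m1[1:5, ], m1[1:5, ]), ">= 10")
})

test_that("high/low class-mean contrast matches the calibrated population", {
  az <- sample_pr_population(synth_config(n_az = 20000, seed = 3,
                                          field_size_um = c(210, 210)))
  pm <- make_prmap(az$true_pr, n_stimuli = 1e6)
  pm$n_evoked <- as.integer(az$true_pr > 0)   # exact classes
  pm <- classify_azs(pm)
  hi <- mean(pm$pr_hat[pm$class == "high"])
  lo <- mean(pm$pr_hat[pm$class == "low"])
  expect_equal(hi / lo, 5.7, tolerance = 0.15)
})
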