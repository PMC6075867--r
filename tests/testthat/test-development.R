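# Developmental simulation, session matching, birth-dating, growth.

test_that("session matching: identity, known shift, and planted new AZs", {
  az <- generate_az_layout(80, c(15, 15), 0.6, 0, seed = 2)
  m <- match_sessions(az, az)
  expect_equal(m$az_id_a, m$az_id_b)
  expect_equal(length(attr(m, "new_ids")), 0)

  sh <- az
  sh$x_um <- az$x_um + 2.0
  sh$y_um <- az$y_um - 1.5
  m2 <- match_sessions(az, sh)
  expect_equal(m2$az_id_a, m2$az_id_b)
  expect_lt(max(abs(attr(m2, "shift_um") - c(2.0, -1.5))), 0.1)

  extra <- data.frame(az_id = 81:85,
                      x_um = c(2.3, 5.1, 8.7, 11.2, 13.9) + 20,
                      y_um = c(3.1, 6.4, 9.9, 12.5, 14.1))
  b <- rbind(az, extra)
  m3 <- match_sessions(az, b)
  expect_setequal(attr(m3, "new_ids"), 81:85)
  expect_error(match_sessions(az[1:2, ], sh[70:75, ]), "mutual pairs")
})

test_that("development: geometric growth and constant-count degenerate", {
  cfg <- synth_config(n_az = 50)
  s1 <- simulate_development(3, growth_fold_per_day = 1, cfg = cfg,
                             seed = 1)
  cnt <- vapply(s1$sessions, function(s) nrow(s$az), numeric(1))
  expect_true(all(cnt == 50))
  expect_equal(growth_fold(s1)$mean_fold, 1.0)

  s2 <- simulate_development(4, growth_fold_per_day = 2, cfg = cfg,
                             seed = 2)
  cnt2 <- vapply(s2$sessions, function(s) nrow(s$az), numeric(1))
  expect_equal(cnt2[4] / cnt2[1], 8, tolerance = 0.02)
  expect_equal(growth_fold(s2)$first_fraction, 0.125, tolerance = 0.01)
})

test_that("identity chaining recovers the true birth schedule", {
  cfg <- synth_config(n_az = 60)
  ser <- simulate_development(5, growth_fold_per_day = 1.6, cfg = cfg,
                              seed = 4)
  tk <- birthdate(ser)
  # no AZ maps to two targets within any session (collision-free)
  for (s in unique(tk$tracks$session)) {
    sub <- tk$tracks[tk$tracks$session == s, ]
    expect_false(any(duplicated(sub$az_id)))
    expect_false(any(duplicated(sub$track_id)))
  }
  # uncensored birth days match ground truth exactly: an AZ born at
  # continuous time b first appears at session ceiling(b)
  first <- ser$sessions[[1]]$az$az_id
  last <- ser$sessions[[length(ser$sessions)]]$az
  truth_birth <- ceiling(ser$truth$birth_time)
  # map tracks back to generator ids via final-session positions
  m <- match_sessions(last, last)  # identity; ensures api stability
  final_tracks <- tk$tracks[tk$tracks$session == length(ser$sessions), ]
  ids <- final_tracks$az_id
  bd <- tk$birth$birth_day[match(final_tracks$track_id,
                                 tk$birth$track_id)]
  cens <- tk$birth$censored[match(final_tracks$track_id,
                                  tk$birth$track_id)]
  tb <- truth_birth[match(ids, ser$truth$az_id)]
  ok <- !cens
  expect_equal(bd[ok], tb[ok])
  expect_true(all(tb[cens] <= 0))
})

test_that("maturation time: censoring rules and arithmetic", {
  # constructed series: five anchor AZs present throughout (censored),
  # AZ 6 born day 1 with its ring first seen day 4
  anchors <- data.frame(az_id = 1:5, x_um = c(1, 4, 7, 2, 6),
                        y_um = c(1, 2, 5, 6, 3))
  ser <- list(sessions = lapply(0:5, function(d) {
    az <- if (d >= 1)
      rbind(anchors, data.frame(az_id = 6L, x_um = 4.5, y_um = 4.5))
    else anchors
    list(day = d, az = az)
  }))
  class(ser) <- "session_series"
  rings <- lapply(0:5, function(d) {
    ids <- if (d >= 1) 1:6 else 1:5
    data.frame(az_id = ids,
               has_ring = c(d >= 2, rep(FALSE, 4), d >= 4)[seq_along(ids)])
  })
  mt <- maturation_time(ser, rings)
  # anchor 1 present at day 0 -> censored, excluded despite ring at day 2
  # AZ 6 born day 1, ring day 4 -> 3 days
  expect_equal(mt$n, 1)
  expect_equal(mt$mean_days, 3)
  expect_equal(sum(mt$per_az$censored), 5)
})

test_that("default developmental simulation matures rings at ~3.2 days,
           never before 2", {
  cfg <- synth_config(n_az = 60)
  ser <- simulate_development(6, cfg = cfg, seed = 9)
  rings <- call_rings(ser)
  mt <- maturation_time(ser, rings)
  expect_gt(mt$n, 50)
  expect_equal(mt$mean_days, 3.2, tolerance = 0.3 / 3.2)
  use <- !mt$per_az$censored & !is.na(mt$per_az$days_to_ring)
  expect_true(all(mt$per_az$days_to_ring[use] >= 2))
})

test_that("growth matches the configured fold within counting error", {
  cfg <- synth_config(n_az = 100)
  ser <- simulate_development(4, growth_fold_per_day = 1.9, cfg = cfg,
                              seed = 11)
  gf <- growth_fold(ser)
  expect_equal(gf$mean_fold, 1.9, tolerance = 0.05)
  # day-1 count as a fraction of day-4 count ~ 1.9^-3
  expect_equal(gf$first_fraction, 1.9^-3, tolerance = 0.1 * 1.9^-3)
})

test_that("apposition ratio and rab3-like presynaptically silent regime", {
  az <- generate_az_layout(20, c(10, 10), 0.8, 0, seed = 5)
  expect_equal(apposition_ratio(az, az)$ratio, 1.0)
  expect_true(all(apposition_ratio(az, az)$apposed))

  pre <- az[1:10, ]
  ap <- apposition_ratio(az, pre)
  expect_equal(ap$ratio, 2.0)
  expect_equal(ap$n_apposed, 10)

  cfg <- synth_config(n_az = 80)
  ser <- simulate_development(6, cfg = cfg, seed = 12,
                              rab3_silent_frac = 0.5)
  last <- ser$sessions[[length(ser$sessions)]]$az
  pre <- last[last$intensity_presyn > 0, ]
  ap2 <- apposition_ratio(last, pre)
  expect_equal(ap2$ratio, 2.0, tolerance = 0.15)
  # rings only among presynaptically apposed PSDs
  rings <- call_rings(ser)
  rc <- rings[[length(rings)]]
  ringed <- rc$az_id[rc$has_ring]
  expect_true(all(!last$presyn_silent[match(ringed, last$az_id)]))
})

test_that("lower activity slows ring acquisition (direction control)", {
  cfg <- synth_config(n_az = 120)
  ctrl <- simulate_development(6, cfg = cfg, seed = 14,
                               activity_factor = 1)
  low <- simulate_development(6, cfg = cfg, seed = 14,
                              activity_factor = 0.5)
  pct_ring <- function(ser) {
    rc <- call_rings(ser)[[6]]
    100 * mean(rc$has_ring)
  }
  expect_gt(pct_ring(ctrl), pct_ring(low))
})
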