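# Calibrated-recovery benchmarks: run the full imaging + analysis chain on
# generator defaults and report the recovered headline statistics. These
# are the package's validation harness: the generator is parameterised at
# the study conditions and the pipeline must recover them through the
# image-analysis chain.

#' End-to-end Pr-mapping benchmark
#'
#' Simulates `n_az` AZs from the default calibrated mixture split across
#' `n_fields` fields of view (movies are rendered and analysed
#' independently, like separate NMJ recordings), runs the full chain
#' (render, preprocess, detect, assign, estimate), pools the per-AZ
#' estimates, and classifies with the strict mean+2SD rule.
#'
#' @param seed integer seed (controls every random draw).
#' @param n_az total AZ count (default 2000).
#' @param n_fields number of fields of view the population is split into.
#' @param n_stimuli stimuli per recording (default 100).
#' @return list with `high_pct` (percentage of AZs classified high-Pr),
#'   `mean_pr` (mean estimated Pr over all AZs), `class_pct`, `n_az`,
#'   `prmap`.
#' @export
benchmark_pr_mapping <- function(seed, n_az = 2000, n_fields = 4,
                                 n_stimuli = 100) {
  per <- round(n_az / n_fields)
  maps <- vector("list", n_fields)
  for (f in seq_len(n_fields)) {
    cfg <- synth_config(n_az = per, n_stimuli = n_stimuli,
                        seed = seed * 100L + f)
    sim <- simulate_experiment(cfg)
    ana <- suppressWarnings(analyze_movie(sim$movie, sim$images$glurIIA))
    maps[[f]] <- as.data.frame(ana$prmap)
    rm(sim, ana); gc(FALSE)
  }
  pm <- do.call(rbind, maps)
  pm$az_id <- seq_len(nrow(pm))
  class(pm) <- c("pr_map", "data.frame")
  pm <- classify_azs(pm)
  cf <- attr(pm, "class_fractions")
  list(high_pct = 100 * unname(cf["high"]),
       mean_pr = mean(pm$pr_hat),
       class_pct = 100 * cf,
       n_az = nrow(pm),
       prmap = pm)
}

#' Spontaneous-rate recovery benchmark
#'
#' Simulates stimulus-free recordings of non-silent AZs releasing
#' spontaneously at `rate_hz`, renders and analyses them, and reports the
#' mean per-AZ spontaneous rate recovered by the pipeline.
#'
#' @param seed integer seed.
#' @param n_az total AZ count (default 1000).
#' @param duration_s recording length (default 300 s).
#' @param rate_hz ground-truth rate per AZ (default 0.011 events/s).
#' @param n_fields fields of view.
#' @return list with `rate_hz` (recovered mean), `true_rate_hz`, `n_az`.
#' @export
benchmark_spont_rate <- function(seed, n_az = 1000, duration_s = 300,
                                 rate_hz = 0.011, n_fields = 5) {
  per <- round(n_az / n_fields)
  rates <- numeric(0)
  for (f in seq_len(n_fields)) {
    cfg <- synth_config(n_az = per, n_stimuli = 0,
                        movie_duration_s = duration_s,
                        silent_frac = 0, spont_only_frac = 1,
                        spont_rate_hz = rate_hz, seed = seed * 100L + f)
    sim <- simulate_experiment(cfg)
    ana <- suppressWarnings(analyze_movie(sim$movie, sim$images$glurIIA))
    rates <- c(rates, ana$prmap$spont_rate_hz)
    rm(sim, ana); gc(FALSE)
  }
  list(rate_hz = mean(rates), true_rate_hz = rate_hz, n_az = length(rates))
}

#' Asynchronous-release (syt1-like) total-rate benchmark
#'
#' Simulates the high-spontaneous, weak-evoked release regime of a
#' synaptotagmin-null synapse: a 5 Hz stimulus train with a small per-
#' stimulus fusion probability on top of an elevated spontaneous rate, so
#' the total per-AZ release rate equals `total_rate_hz`. The pipeline
#' detects and assigns events and reports recovered events/AZ/s.
#'
#' @param seed integer seed.
#' @param n_az AZ count (default 700).
#' @param duration_s recording length (default 120 s).
#' @param stim_hz train frequency (default 5).
#' @param total_rate_hz target total rate (default 0.03 /AZ/s).
#' @param spont_rate_hz spontaneous component (default 0.018 /AZ/s).
#' @param n_fields fields of view.
#' @return list with `rate_hz` (recovered), `true_rate_hz`, `n_az`.
#' @export
benchmark_syt1_rate <- function(seed, n_az = 700, duration_s = 120,
                                stim_hz = 5, total_rate_hz = 0.03,
                                spont_rate_hz = 0.018, n_fields = 3) {
  pr_per_stim <- (total_rate_hz - spont_rate_hz) / stim_hz
  per <- round(n_az / n_fields)
  tot_events <- 0; tot_az <- 0; tot_dur <- 0
  for (f in seq_len(n_fields)) {
    cfg <- synth_config(n_az = per,
                        n_stimuli = round((duration_s - 4) * stim_hz),
                        stim_period_s = 1 / stim_hz, stim_start_s = 2,
                        movie_duration_s = duration_s,
                        silent_frac = 0, spont_only_frac = 0,
                        spont_rate_hz = spont_rate_hz,
                        seed = seed * 100L + f)
    az <- sample_pr_population(cfg)
    az$true_pr <- pr_per_stim
    ev <- simulate_event_times(az, cfg$stim_times_s, cfg$movie_duration_s,
                               cfg$spont_rate_hz, seed = cfg$seed + 10L,
                               evoked_latency_s = 0.15)
    res <- render_channel_image(az, "glurIIA", cfg)
    mv <- render_movie(az, ev, cfg)
    ana_az <- suppressWarnings({
      spots <- find_spots(res$image, cfg$pixel_size_um)
      data.frame(az_id = spots$spot_id, x_um = spots$x_um,
                 y_um = spots$y_um)
    })
    pp <- preprocess_stack(mv, apply_mode = "integer", crop_px = 128L)
    det <- detect_events(pp$stack)
    det <- assign_events(det, ana_az)
    dur <- dim(mv$data)[3] * cfg$frame_interval_s
    tot_events <- tot_events + sum(!is.na(det$az_id))
    tot_az <- tot_az + nrow(ana_az)
    tot_dur <- dur
    rm(mv, pp, det); gc(FALSE)
  }
  list(rate_hz = tot_events / tot_az / tot_dur,
       true_rate_hz = total_rate_hz, n_az = tot_az)
}

#' Maturation-timing benchmark
#'
#' Runs the default developmental simulation (daily imaging, ring
#' acquisition clocked at 3.2 days with a 2-day floor), calls rings per
#' session from rendered PSDs, tracks identities across sessions, and
#' reports the mean time from PSD emergence to the first ring-positive
#' session over uncensored AZs.
#'
#' @param seed integer seed.
#' @param days daily sessions (default 6).
#' @param n_az_initial AZ count in the first session (default 120).
#' @return list with `mean_days`, `n`, `min_days`.
#' @export
benchmark_maturation <- function(seed, days = 6, n_az_initial = 120) {
  cfg <- synth_config(n_az = n_az_initial)
  ser <- simulate_development(days, cfg = cfg, seed = seed)
  rings <- call_rings(ser)
  mt <- maturation_time(ser, rings)
  use <- !mt$per_az$censored & !is.na(mt$per_az$days_to_ring)
  list(mean_days = mt$mean_days, n = mt$n,
       min_days = if (any(use)) min(mt$per_az$days_to_ring[use])
                  else NA_real_)
}

#' Receptor-field morphometry benchmark
#'
#' Renders a noise-free mature PSD at the printed 72-hour geometry
#' (0.59 um core, 1.01 um ring outer FWHM at 0.138 um/px) and recovers
#' both diameters with the profile module.
#'
#' @param dip_frac rendered ring dip (default 0.3).
#' @return list with `diam_a_um`, `diam_b_um`.
#' @export
benchmark_morphometry <- function(dip_frac = 0.3) {
  p <- render_psd_pair(0.59, 1.01, dip_frac = dip_frac,
                       pixel_size_um = 0.138, noise_sd = 0)
  prof <- extract_profile(p$a, p$b, p$center_um, 2.2)
  list(diam_a_um = measure_diameter(prof, "A")$fwhm_um,
       diam_b_um = measure_diameter(prof, "B")$fwhm_um)
}
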