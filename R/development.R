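# Multi-day developmental simulation: AZ addition, maturation trajectories,
# and ring acquisition.

#' Simulate a multi-day developmental imaging series
#'
#' Grows an NMJ-like AZ population over daily imaging sessions. The AZ
#' count multiplies by `growth_fold_per_day * activity_factor^growth_gamma`
#' per day (new AZs are born at continuous times; AZs are never deleted).
#' Each AZ follows saturating maturation trajectories for Pr, channel
#' intensity, and receptor-field geometry with time constant
#' `maturation_days / activity_factor`. Newborn AZs start with Pr <= 0.14
#' and an unsegregated (ringless) receptor field; the central dip of the
#' GluRIIB-like channel starts growing only after a 2-day refractory age
#' and crosses the 10% ring criterion at a per-AZ time whose population
#' mean is `maturation_days / activity_factor` (SD ~0.3 d), so rings are
#' never acquired faster than 2 days.
#'
#' A `rab3_silent_frac > 0` emulates a presynaptically concentrated regime:
#' that fraction of AZs gets zero presynaptic intensity and Pr = 0, and
#' their PSDs never mature (ring formation requires an apposed, active
#' presynaptic terminal).
#'
#' @param days number of daily sessions (>= 1; sessions at day 0, 1, ...).
#' @param growth_fold_per_day AZ-count fold increase per day (>= 1;
#'   default 1.9, i.e. roughly doubling).
#' @param maturation_days mean age at ring acquisition under unit activity
#'   (> 2; default 3.2 d).
#' @param activity_factor presynaptic activity scale (> 0); multiplies both
#'   maturation rate and (through `growth_gamma`) AZ addition.
#' @param cfg a [synth_config()]; supplies the initial AZ count, Pr
#'   mixture, pixel size and channel definitions.
#' @param seed RNG seed.
#' @param growth_gamma exponent coupling activity to growth (default 1).
#' @param session_jitter_um per-AZ localisation jitter SD between sessions.
#' @param session_shift_um scale of the random global field translation per
#'   session.
#' @param rab3_silent_frac fraction of presynaptically empty AZs
#'   (default 0).
#' @param mature_diam_a_um,mature_diam_b_um asymptotic receptor-field FWHM
#'   diameters (um).
#' @param newborn_diam_a_um,newborn_diam_b_um diameters at birth (um).
#' @return object of class `session_series`: list with `sessions` (each
#'   `day` and an `az_table` with per-session geometry columns `diam_a_um`,
#'   `diam_b_um`, `dip_frac`, `true_pr`, `age_days`) and `truth`
#'   (per-AZ `birth_time`, `t_ring_days`, `pr_mature`, `presyn_silent`).
#' @export
simulate_development <- function(days, growth_fold_per_day = 1.9,
                                 maturation_days = 3.2,
                                 activity_factor = 1,
                                 cfg = synth_config(),
                                 seed = 1L,
                                 growth_gamma = 1,
                                 session_jitter_um = 0.04,
                                 session_shift_um = 1.0,
                                 rab3_silent_frac = 0,
                                 mature_diam_a_um = 0.59,
                                 mature_diam_b_um = 1.01,
                                 newborn_diam_a_um = 0.40,
                                 newborn_diam_b_um = 0.36) {
  if (days < 1) stopf("days must be >= 1")
  if (growth_fold_per_day < 1) stopf("growth_fold_per_day must be >= 1")
  if (maturation_days <= 0) stopf("maturation_days must be > 0")
  if (activity_factor <= 0) stopf("activity_factor must be > 0")
  g <- growth_fold_per_day * activity_factor^growth_gamma
  n0 <- cfg$n_az
  span <- days - 1
  n_final <- max(n0, round(n0 * g^span))

  set.seed(seed)
  # birth times: first n0 AZs predate the series (left-censored at day 0);
  # later births follow the exponential growth density on (0, span]
  birth <- numeric(n_final)
  if (n_final > n0 && span > 0 && g > 1) {
    u <- stats::runif(n_final - n0)
    birth[(n0 + 1):n_final] <- log(1 + u * (g^span - 1)) / log(g)
  }
  birth <- sort(birth)

  side <- ceiling(sqrt(n_final / 0.5)) + 2
  az <- generate_az_layout(n_final, c(side, side), cfg$min_sep_um,
                           close_pair_frac = 0, seed = seed + 1L)

  # mature (asymptotic) per-AZ release parameters from the calibrated mixture
  cfg_pop <- cfg
  cfg_pop$n_az <- n_final
  cfg_pop$seed <- seed + 2L
  azp <- sample_pr_population(cfg_pop, az = az)
  pr_mature <- azp$true_pr
  presyn_silent <- rep(FALSE, n_final)
  if (rab3_silent_frac > 0) {
    presyn_silent <- stats::runif(n_final) < rab3_silent_frac
    pr_mature[presyn_silent] <- 0
  }

  tau <- maturation_days / activity_factor
  # per-AZ ring-acquisition age: 2 d refractory + gamma remainder with
  # mean (tau - 2) and SD (tau - 2)/4  (tau <= 2 pins rings at 2 d)
  rem <- max(tau - 2, 0.01)
  t_ring <- 2 + stats::rgamma(n_final, shape = 16, scale = rem / 16)
  t_ring[presyn_silent] <- Inf
  dip_max <- 0.35
  # dip trajectory time constant solving dip(t_ring) = 0.10
  tau_dip <- (t_ring - 2) / (-log(1 - 0.10 / dip_max))

  # presynaptic intensity: calibrated marginal coupled to mature Pr
  amp_mature <- channel_amplitudes(pr_mature, cfg$channels$cac$r,
                                   cfg$channels$cac$offset,
                                   seed = seed + 3L)
  amp_mature[presyn_silent] <- 0

  sessions <- vector("list", days)
  shift_xy <- c(0, 0)
  for (s in seq_len(days)) {
    day <- s - 1
    if (s > 1)
      shift_xy <- shift_xy + stats::runif(2, -session_shift_um,
                                          session_shift_um)
    present <- which(birth <= day)
    age <- day - birth[present]
    mat <- 1 - exp(-age / tau)
    pr_now <- pr_mature[present] * mat
    pr_now[age < 1] <- pmin(pr_now[age < 1], 0.14)
    dip_now <- ifelse(age > 2 & is.finite(t_ring[present]),
                      dip_max * (1 - exp(-(age - 2) / tau_dip[present])),
                      0)
    tab <- data.frame(
      az_id = az$az_id[present],
      x_um = az$x_um[present] + shift_xy[1] +
        stats::rnorm(length(present), sd = session_jitter_um),
      y_um = az$y_um[present] + shift_xy[2] +
        stats::rnorm(length(present), sd = session_jitter_um),
      age_days = age,
      true_pr = pr_now,
      dip_frac = dip_now,
      diam_a_um = newborn_diam_a_um +
        (mature_diam_a_um - newborn_diam_a_um) * (1 - exp(-age / 0.5)),
      diam_b_um = newborn_diam_b_um +
        (mature_diam_b_um - newborn_diam_b_um) * (1 - exp(-age / 0.8)),
      intensity_presyn = amp_mature[present] * mat,
      presyn_silent = presyn_silent[present])
    class(tab) <- c("az_table", "data.frame")
    sessions[[s]] <- list(day = day, az = tab)
  }
  structure(list(
    sessions = sessions,
    truth = data.frame(az_id = az$az_id, birth_time = birth,
                       t_ring_days = t_ring, pr_mature = pr_mature,
                       presyn_silent = presyn_silent,
                       censored = birth <= 0)),
    class = "session_series")
}

#' @export
print.session_series <- function(x, ...) {
  cat("session_series:", length(x$sessions), "sessions, final AZ count",
      nrow(x$sessions[[length(x$sessions)]]$az), "\n")
  invisible(x)
}

#' Call receptor rings for every AZ of every session
#'
#' Renders each AZ's two-channel PSD at its current session geometry
#' (core/ring diameters and central dip) and applies [extract_profile()] +
#' [detect_ring()], yielding the measured (not ground-truth) ring calls a
#' live-imaging analysis would produce.
#'
#' @param series a `session_series`.
#' @param pixel_size_um render pixel size (default 0.138).
#' @param noise_sd render noise (default 0).
#' @param ring_threshold dip criterion (default 0.10).
#' @return list (one per session) of data.frames with `az_id`, `dip_meas`,
#'   `has_ring`.
#' @export
call_rings <- function(series, pixel_size_um = 0.138, noise_sd = 0,
                       ring_threshold = 0.10) {
  lapply(seq_along(series$sessions), function(s) {
    tab <- series$sessions[[s]]$az
    n <- nrow(tab)
    dip <- logical(n)
    dipv <- numeric(n)
    for (i in seq_len(n)) {
      psd <- render_psd_pair(tab$diam_a_um[i],
                             max(tab$diam_b_um[i], tab$diam_a_um[i]),
                             dip_frac = tab$dip_frac[i],
                             pixel_size_um = pixel_size_um,
                             noise_sd = noise_sd, seed = s * 100000L + i)
      prof <- extract_profile(psd$a, psd$b, psd$center_um,
                              length_um = 2.2 * max(tab$diam_b_um[i],
                                                    tab$diam_a_um[i]),
                              pixel_size_um = pixel_size_um,
                              n_angles = 12L)
      prof <- detect_ring(prof, ring_threshold)
      dip[i] <- prof$has_ring
      dipv[i] <- prof$dip_frac
    }
    data.frame(az_id = tab$az_id, dip_meas = dipv, has_ring = dip)
  })
}
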