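#' Assign release classes and ground-truth Pr to an AZ layout
#'
#' Draws each AZ's true release class (silent / spontaneous-only / active)
#' from the configured fractions and, for active AZs, a ground-truth evoked
#' release probability from the calibrated two-component gamma mixture,
#' right-truncated at `pr_cap`. With the default calibration the full
#' population (zeros included) has mean Pr ~0.073, ~9.9% of AZs above its
#' mean + 2 SD, and skewness ~2 - the summary statistics of the measured AZ
#' population this generator emulates.
#'
#' @param cfg a [synth_config()].
#' @param az optional `az_table` from [generate_az_layout()]; generated from
#'   `cfg` when omitted.
#' @return the `az_table` with added columns `true_class` (factor: silent,
#'   spont_only, active) and `true_pr`.
#' @examples
#' az <- sample_pr_population(synth_config(n_az = 200, seed = 2))
#' mean(az$true_pr)
#' @export
sample_pr_population <- function(cfg, az = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  validate_synth_config(cfg)
  if (is.null(az))
    az <- generate_az_layout(cfg$n_az, cfg$field_size_um, cfg$min_sep_um,
                             cfg$close_pair_frac, seed = cfg$seed)
  n <- nrow(az)
  set.seed(cfg$seed + 1L)
  u <- stats::runif(n)
  cls <- ifelse(u < cfg$silent_frac, "silent",
         ifelse(u < cfg$silent_frac + cfg$spont_only_frac, "spont_only",
                "active"))
  pr <- numeric(n)
  act <- cls == "active"
  n_act <- sum(act)
  if (n_act > 0) {
    hi <- stats::runif(n_act) < cfg$pr_q_high
    draw <- numeric(n_act)
    draw[!hi] <- stats::rgamma(sum(!hi), cfg$pr_low_shape,
                               scale = cfg$pr_low_mean / cfg$pr_low_shape)
    draw[hi] <- stats::rgamma(sum(hi), cfg$pr_high_shape,
                              scale = cfg$pr_high_mean / cfg$pr_high_shape)
    pr[act] <- pmin(draw, cfg$pr_cap)
  }
  az$true_class <- factor(cls, levels = c("silent", "spont_only", "active"))
  az$true_pr <- pr
  az
}

#' Simulate ground-truth fusion-event times
#'
#' Evoked release is Bernoulli per (active AZ, stimulus): each stimulus
#' triggers at most one fusion at an AZ, with probability `true_pr`,
#' independently across AZs and stimuli (multivesicular release is out of
#' scope of quantal imaging). Spontaneous release is a homogeneous Poisson
#' process at `spont_rate_hz` per non-silent AZ over the whole recording.
#' Silent AZs emit nothing.
#'
#' @param az `az_table` with `true_pr` and `true_class`.
#' @param stim_times_s stimulus onset times (seconds, within the recording).
#' @param duration_s recording duration in seconds (> 0).
#' @param spont_rate_hz spontaneous rate per non-silent AZ (events/s, >= 0).
#' @param seed integer RNG seed.
#' @param evoked_latency_s evoked events occur uniformly within this window
#'   after their stimulus.
#' @return data.frame (class `event_truth`) with columns `az_id`, `time_s`,
#'   `kind` ("evoked"/"spontaneous") and `stimulus_index` (NA for
#'   spontaneous events).
#' @export
simulate_event_times <- function(az, stim_times_s, duration_s,
                                 spont_rate_hz, seed = 1L,
                                 evoked_latency_s = 0.05) {
  if (duration_s <= 0) stopf("duration_s must be > 0")
  if (spont_rate_hz < 0) stopf("spont_rate_hz must be >= 0")
  if (length(stim_times_s) &&
      (min(stim_times_s) < 0 || max(stim_times_s) > duration_s))
    stopf("stimulus times must lie within [0, duration_s]")
  set.seed(seed)
  n_stim <- length(stim_times_s)

  ev <- list()
  if (n_stim > 0) {
    # Bernoulli trials for every (AZ, stimulus) pair at once
    p <- rep(az$true_pr, times = n_stim)
    hit <- stats::runif(length(p)) < p
    if (any(hit)) {
      az_i <- rep(seq_len(nrow(az)), times = n_stim)[hit]
      st_i <- rep(seq_len(n_stim), each = nrow(az))[hit]
      t_ev <- stim_times_s[st_i] +
        stats::runif(sum(hit), 0, evoked_latency_s)
      ev$evoked <- data.frame(az_id = az$az_id[az_i], time_s = t_ev,
                              kind = "evoked", stimulus_index = st_i)
    }
  }
  non_silent <- which(az$true_class != "silent")
  if (spont_rate_hz > 0 && length(non_silent)) {
    counts <- stats::rpois(length(non_silent), spont_rate_hz * duration_s)
    tot <- sum(counts)
    if (tot > 0) {
      az_i <- rep(non_silent, counts)
      ev$spont <- data.frame(az_id = az$az_id[az_i],
                             time_s = stats::runif(tot, 0, duration_s),
                             kind = "spontaneous",
                             stimulus_index = NA_integer_)
    }
  }
  out <- if (length(ev)) do.call(rbind, ev) else
    data.frame(az_id = integer(0), time_s = numeric(0),
               kind = character(0), stimulus_index = integer(0))
  out <- out[order(out$time_s), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("event_truth", "data.frame")
  out
}
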