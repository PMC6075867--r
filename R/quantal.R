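# Per-AZ release probability estimation and classification.

#' Label events as evoked or spontaneous by stimulus windows
#'
#' An event whose onset lies in `(t_stim, t_stim + window_s]` is labelled
#' evoked and tagged with that stimulus; everything else is spontaneous. At
#' most one evoked event per (AZ, stimulus) is allowed - extra same-AZ
#' events inside one window are relabelled spontaneous (quantal imaging
#' counts at most one fusion per stimulus per site).
#'
#' @param events an `event_list` with `az_id` assigned.
#' @param stim_times_s stimulus onset times (seconds).
#' @param window_s evoked window in seconds; must be smaller than the
#'   minimum inter-stimulus interval (default 0.3, two to three frames at
#'   7-8 Hz).
#' @return the event list with columns `kind` ("evoked"/"spontaneous") and
#'   `stimulus_index` (NA for spontaneous).
#' @export
split_evoked_spontaneous <- function(events, stim_times_s, window_s = 0.3) {
  if (length(stim_times_s) > 1) {
    isi <- min(diff(sort(stim_times_s)))
    if (window_s >= isi)
      stopf("window_s (%.3g) must be below the inter-stimulus interval (%.3g)",
            window_s, isi)
  }
  events$kind <- rep("spontaneous", nrow(events))
  events$stimulus_index <- rep(NA_integer_, nrow(events))
  if (nrow(events) == 0 || !length(stim_times_s)) return(events)
  st <- sort(stim_times_s)
  # index of the latest stimulus at or before each event time
  idx <- findInterval(events$time_s, st + 1e-12)
  inwin <- idx >= 1
  dt <- events$time_s - ifelse(inwin, st[pmax(idx, 1L)], Inf)
  evoked <- inwin & dt > 0 & dt <= window_s
  events$kind[evoked] <- "evoked"
  events$stimulus_index[evoked] <- idx[evoked]
  # enforce one evoked event per (AZ, stimulus): keep the earliest
  ev <- which(evoked & !is.na(events$az_id))
  if (length(ev) > 1) {
    key <- paste(events$az_id[ev], events$stimulus_index[ev])
    ord <- ev[order(events$time_s[ev])]
    keyo <- paste(events$az_id[ord], events$stimulus_index[ord])
    dup <- ord[duplicated(keyo)]
    events$kind[dup] <- "spontaneous"
    events$stimulus_index[dup] <- NA_integer_
  }
  events
}

#' Per-AZ release probability and spontaneous rate
#'
#' The evoked release probability estimate is the number of observed evoked
#' events at an AZ divided by the number of delivered stimuli; the
#' spontaneous rate is the spontaneous event count divided by the recording
#' duration. AZs with no events get zero for both.
#'
#' @param events an `event_list` with `az_id` and `kind`.
#' @param az_ids integer vector of all AZ ids (zero-event AZs included).
#' @param n_stimuli number of delivered stimuli (>= 1).
#' @param duration_s recording duration in seconds (> 0).
#' @return data.frame (class `pr_map`) with `az_id`, `n_evoked`,
#'   `n_stimuli`, `pr_hat`, `spont_count`, `spont_rate_hz`.
#' @export
compute_pr <- function(events, az_ids, n_stimuli, duration_s) {
  if (n_stimuli < 1) stopf("n_stimuli must be >= 1")
  if (duration_s <= 0) stopf("duration_s must be > 0")
  az_ids <- sort(unique(as.integer(az_ids)))
  assigned <- events[!is.na(events$az_id), , drop = FALSE]
  n_ev <- table(factor(assigned$az_id[assigned$kind == "evoked"],
                       levels = az_ids))
  n_sp <- table(factor(assigned$az_id[assigned$kind == "spontaneous"],
                       levels = az_ids))
  out <- data.frame(az_id = az_ids,
                    n_evoked = as.integer(n_ev),
                    n_stimuli = as.integer(n_stimuli),
                    pr_hat = as.numeric(n_ev) / n_stimuli,
                    spont_count = as.integer(n_sp),
                    spont_rate_hz = as.numeric(n_sp) / duration_s)
  class(out) <- c("pr_map", "data.frame")
  out
}

#' Classify AZs by release behaviour
#'
#' High-Pr AZs are those whose estimated Pr exceeds the population mean
#' plus `sd_mult` standard deviations (strict inequality; an all-equal
#' population yields none). The mean and SD are taken over all AZs,
#' including silent and spontaneous-only sites at Pr = 0, since real AZ
#' populations are defined by their apposed receptor fields, not by
#' activity. Remaining AZs with evoked release are "low"; AZs with only
#' spontaneous events are "spont_only"; AZs with no events are "silent".
#' The four classes partition the population.
#'
#' @param prmap a `pr_map` from [compute_pr()].
#' @param sd_mult SD multiplier (> 0; default 2).
#' @param sd_type "population" (divide by n; default) or "sample" (n - 1).
#' @return the `pr_map` with a `class` factor column and attributes
#'   `threshold`, `class_fractions`.
#' @export
classify_azs <- function(prmap, sd_mult = 2,
                         sd_type = c("population", "sample")) {
  if (sd_mult <= 0) stopf("sd_mult must be > 0")
  sd_type <- match.arg(sd_type)
  p <- prmap$pr_hat
  n <- length(p)
  s <- stats::sd(p)
  if (sd_type == "population") s <- s * sqrt((n - 1) / n)
  if (!is.finite(s)) s <- 0
  thr <- mean(p) + sd_mult * s
  cls <- ifelse(s > 0 & p > thr, "high",
         ifelse(prmap$n_evoked > 0, "low",
         ifelse(prmap$spont_count > 0, "spont_only", "silent")))
  prmap$class <- factor(cls, levels = c("high", "low", "spont_only",
                                        "silent"))
  attr(prmap, "threshold") <- thr
  attr(prmap, "class_fractions") <- prop.table(table(prmap$class))
  prmap
}

#' Summarise the shape of a Pr distribution
#'
#' Returns the moments and shape descriptors used to characterise AZ
#' release heterogeneity: mean, SEM, SD, adjusted Fisher-Pearson skewness,
#' percentiles, a histogram, the distribution normalised to its maximum,
#' and the empirical CDF.
#'
#' @param prmap a `pr_map` (or any data.frame with `pr_hat`).
#' @param breaks histogram break specification (passed to [hist()]).
#' @param probs percentile probabilities.
#' @return list with `n`, `mean`, `sem`, `sd`, `skewness`, `percentiles`,
#'   `histogram` (counts/mids), `normalized` (pr/max), and `ecdf`.
#' @export
distribution_summary <- function(prmap, breaks = "Sturges",
                                 probs = c(0.25, 0.5, 0.75, 0.9, 0.95)) {
  p <- prmap$pr_hat
  if (length(p) < 3) stopf("need >= 3 AZs")
  h <- graphics::hist(p, breaks = breaks, plot = FALSE)
  list(n = length(p),
       mean = mean(p),
       sem = stats::sd(p) / sqrt(length(p)),
       sd = stats::sd(p),
       skewness = skewness_adj(p),
       percentiles = stats::quantile(p, probs),
       histogram = list(counts = h$counts, mids = h$mids,
                        breaks = h$breaks),
       normalized = if (max(p) > 0) p / max(p) else p,
       ecdf = stats::ecdf(p))
}

#' Session-to-session stability of per-AZ release probability
#'
#' Correlates Pr estimates for the same AZs measured in two sessions
#' (inner join on `az_id`). When ground-truth Pr values are supplied, also
#' reports the analytic attenuation prediction for the correlation of two
#' independent binomial estimates of the same underlying population:
#' `r_pred = Var(p) / (Var(p) + E[p(1-p)]/S)` at `S` stimuli.
#'
#' @param map1,map2 `pr_map` objects sharing >= 10 AZ ids.
#' @param true_pr optional ground-truth Pr vector (one per AZ of the
#'   underlying population) for the attenuation prediction.
#' @param n_stimuli stimulus count for the prediction (defaults to
#'   `map1$n_stimuli`).
#' @return list with `r`, `r_squared`, `p_value`, `n`, `pairs` (joined
#'   table), and `r_predicted` (NA without ground truth).
#' @export
session_stability <- function(map1, map2, true_pr = NULL,
                              n_stimuli = NULL) {
  j <- merge(map1[, c("az_id", "pr_hat")], map2[, c("az_id", "pr_hat")],
             by = "az_id", suffixes = c("_1", "_2"))
  if (nrow(j) < 10) stopf("need >= 10 shared AZs, got %d", nrow(j))
  ct <- stats::cor.test(j$pr_hat_1, j$pr_hat_2)
  r_pred <- NA_real_
  if (!is.null(true_pr)) {
    S <- n_stimuli %||% map1$n_stimuli[1]
    vp <- stats::var(true_pr) * (length(true_pr) - 1) / length(true_pr)
    r_pred <- vp / (vp + mean(true_pr * (1 - true_pr)) / S)
  }
  list(r = unname(ct$estimate), r_squared = unname(ct$estimate)^2,
       p_value = ct$p.value, n = nrow(j), pairs = j,
       r_predicted = r_pred)
}
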