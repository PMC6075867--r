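# Cross-session AZ identity tracking, birth-dating, and growth metrics.

#' Match AZ tables between two imaging sessions
#'
#' Estimates a global translation between two sessions from the mode of the
#' pairwise displacement histogram (refined by the median of inlier
#' displacements), then matches AZs by mutual nearest neighbour within
#' `max_match_um` after registration. Unmatched entries of `tableB` are
#' "new" AZs; unmatched entries of `tableA` are "lost" (flagged for QC -
#' the synthetic generator never deletes AZs, so lost entries indicate
#' matching failures).
#'
#' @param tableA,tableB nonempty `az_table`s (need `az_id`, `x_um`,
#'   `y_um`).
#' @param max_match_um mutual-NN acceptance radius (default 1.0 um).
#' @param bin_um displacement histogram bin (default 0.5 um).
#' @param max_points subsample size per table for translation estimation.
#' @return data.frame `matches` (`az_id_a`, `az_id_b`, `dist_um`) with
#'   attributes `shift_um` (estimated B-relative-to-A translation),
#'   `new_ids`, `lost_ids`.
#' @export
match_sessions <- function(tableA, tableB, max_match_um = 1.0,
                           bin_um = 0.5, max_points = 600L) {
  if (!nrow(tableA) || !nrow(tableB)) stopf("both tables must be nonempty")
  pa <- cbind(tableA$x_um, tableA$y_um)
  pb <- cbind(tableB$x_um, tableB$y_um)
  ia <- if (nrow(pa) > max_points)
    sort(sample.int(nrow(pa), max_points)) else seq_len(nrow(pa))
  ib <- if (nrow(pb) > max_points)
    sort(sample.int(nrow(pb), max_points)) else seq_len(nrow(pb))
  dx <- outer(pb[ib, 1], pa[ia, 1], "-")
  dy <- outer(pb[ib, 2], pa[ia, 2], "-")
  # modal displacement bin
  kx <- round(dx / bin_um); ky <- round(dy / bin_um)
  key <- paste(kx, ky)
  mode_key <- names(which.max(table(key)))
  sel <- key == mode_key
  shift <- c(x = stats::median(dx[sel]), y = stats::median(dy[sel]))
  # refine with inliers of the first estimate
  inl <- abs(dx - shift[1]) < bin_um & abs(dy - shift[2]) < bin_um
  shift <- c(x = stats::median(dx[inl]), y = stats::median(dy[inl]))

  pb_reg <- sweep(pb, 2, shift)
  d <- pairwise_dist(pa, pb_reg)
  nn_ab <- apply(d, 1, which.min)   # for each A, closest B
  nn_ba <- apply(d, 2, which.min)   # for each B, closest A
  ia_m <- which(nn_ba[nn_ab] == seq_len(nrow(pa)))
  ib_m <- nn_ab[ia_m]
  dist_m <- d[cbind(ia_m, ib_m)]
  ok <- dist_m <= max_match_um
  ia_m <- ia_m[ok]; ib_m <- ib_m[ok]; dist_m <- dist_m[ok]
  if (length(ia_m) < 3)
    stopf("ambiguous registration: only %d mutual pairs", length(ia_m))
  matches <- data.frame(az_id_a = tableA$az_id[ia_m],
                        az_id_b = tableB$az_id[ib_m],
                        dist_um = dist_m)
  attr(matches, "shift_um") <- shift
  attr(matches, "new_ids") <- setdiff(tableB$az_id, matches$az_id_b)
  attr(matches, "lost_ids") <- setdiff(tableA$az_id, matches$az_id_a)
  matches
}

#' Chain session correspondences into persistent identities and birth-date
#' AZs
#'
#' Matches consecutive sessions of a series, chains the pairwise
#' correspondences into persistent track identities, and assigns each track
#' a birth day: the timestamp of the first session in which it appears.
#' Tracks already present in the first session are left-censored (their
#' true birth predates the series). Chains are consecutive-only: an AZ that
#' drops out and reappears starts a new track (reported via the per-pair
#' lost counts), it is never silently bridged.
#'
#' @param series a `session_series` (or a list with `sessions`, each
#'   having `day` and `az`).
#' @param max_match_um matching radius passed to [match_sessions()].
#' @return list with `tracks` (data.frame: `track_id`, `session`, `day`,
#'   `az_id`), `birth` (data.frame: `track_id`, `birth_day`, `censored`),
#'   and `lost_per_pair` (count of lost AZs at each session transition).
#' @export
birthdate <- function(series, max_match_um = 1.0) {
  ss <- series$sessions
  n_s <- length(ss)
  # track id bookkeeping: map (session, az_id) -> track
  tr_of <- stats::setNames(seq_len(nrow(ss[[1]]$az)),
                           ss[[1]]$az$az_id)
  next_track <- length(tr_of) + 1L
  tracks <- data.frame(track_id = unname(tr_of), session = 1L,
                       day = ss[[1]]$day, az_id = ss[[1]]$az$az_id)
  birth <- data.frame(track_id = unname(tr_of),
                      birth_day = ss[[1]]$day,
                      censored = TRUE)
  lost <- integer(0)
  for (s in seq_len(n_s - 1L)) {
    m <- match_sessions(ss[[s]]$az, ss[[s + 1L]]$az, max_match_um)
    lost <- c(lost, length(attr(m, "lost_ids")))
    new_tr <- stats::setNames(integer(0), character(0))
    # continue matched tracks
    cont <- tr_of[as.character(m$az_id_a)]
    new_tr[as.character(m$az_id_b)] <- unname(cont)
    # open tracks for new AZs
    new_ids <- attr(m, "new_ids")
    if (length(new_ids)) {
      ids <- next_track:(next_track + length(new_ids) - 1L)
      new_tr[as.character(new_ids)] <- ids
      next_track <- next_track + length(new_ids)
      birth <- rbind(birth,
                     data.frame(track_id = ids,
                                birth_day = ss[[s + 1L]]$day,
                                censored = FALSE))
    }
    tr_of <- new_tr
    tracks <- rbind(tracks,
                    data.frame(track_id = unname(tr_of), session = s + 1L,
                               day = ss[[s + 1L]]$day,
                               az_id = as.integer(names(tr_of))))
  }
  list(tracks = tracks, birth = birth, lost_per_pair = lost)
}

#' Time from PSD emergence to ring acquisition
#'
#' For each track born during the series (AZs present in the first session
#' are excluded as left-censored, exactly as in live birth-dating
#' analyses), the maturation time is the timestamp of the first
#' ring-positive session minus the birth day. The estimate is interval-
#' censored by the session spacing. Tracks ringed already at their birth
#' session are flagged as inconsistent (rings are never acquired within
#' the same session an AZ first appears, given the >= 2-day minimum).
#'
#' @param series a `session_series`.
#' @param ring_calls per-session ring calls as returned by [call_rings()]
#'   (data.frames with `az_id`, `has_ring`).
#' @param tracking optional precomputed result of [birthdate()].
#' @param max_match_um matching radius if `tracking` is computed here.
#' @return list with `per_az` (track_id, birth_day, ring_day,
#'   days_to_ring, flagged), `mean_days`, `sd_days`, `n`.
#' @export
maturation_time <- function(series, ring_calls, tracking = NULL,
                            max_match_um = 1.0) {
  tk <- tracking %||% birthdate(series, max_match_um)
  # attach ring calls to tracks
  ring_day <- rep(NA_real_, max(tk$tracks$track_id))
  for (s in seq_along(series$sessions)) {
    rc <- ring_calls[[s]]
    sub <- tk$tracks[tk$tracks$session == s, ]
    hr <- rc$has_ring[match(sub$az_id, rc$az_id)]
    pos <- sub$track_id[which(hr)]
    upd <- pos[is.na(ring_day[pos])]
    ring_day[upd] <- series$sessions[[s]]$day
  }
  per <- tk$birth
  per$ring_day <- ring_day[per$track_id]
  per$days_to_ring <- per$ring_day - per$birth_day
  per$flagged <- !per$censored & !is.na(per$days_to_ring) &
    per$days_to_ring <= 0
  use <- !per$censored & !is.na(per$days_to_ring) & !per$flagged
  list(per_az = per,
       mean_days = if (any(use)) mean(per$days_to_ring[use]) else NA_real_,
       sd_days = if (sum(use) > 1) stats::sd(per$days_to_ring[use])
                 else NA_real_,
       n = sum(use))
}

#' AZ-count growth across sessions
#'
#' Ratio of AZ counts across each interval of `interval_days`, plus the
#' first-session count as a fraction of the final count (the "day-1
#' fraction" used to relate AZ addition rate to the proportion of mature
#' synapses).
#'
#' @param series a `session_series`.
#' @param interval_days interval for fold computation (default 1).
#' @return list with `counts` (per session), `folds` (per interval),
#'   `mean_fold`, and `first_fraction` (first / final count).
#' @export
growth_fold <- function(series, interval_days = 1) {
  dys <- vapply(series$sessions, function(s) s$day, numeric(1))
  cnt <- vapply(series$sessions, function(s) nrow(s$az), numeric(1))
  if (length(cnt) < 2) stopf("need >= 2 sessions")
  folds <- numeric(0)
  for (i in seq_along(dys)) {
    j <- which(abs(dys - (dys[i] + interval_days)) < 1e-9)
    if (length(j) == 1) folds <- c(folds, cnt[j] / cnt[i])
  }
  list(counts = data.frame(day = dys, n_az = cnt),
       folds = folds,
       mean_fold = if (length(folds)) mean(folds) else NA_real_,
       first_fraction = cnt[1] / cnt[length(cnt)])
}

#' Postsynaptic-to-presynaptic apposition ratio
#'
#' Matches presynaptic puncta to postsynaptic densities by mutual nearest
#' neighbour (no global registration: both tables come from one field of
#' view) and reports the PSD:presynaptic count ratio together with per-PSD
#' apposed flags, for ring-versus-apposition contingency analyses.
#'
#' @param psd_table,presyn_table `az_table`s from the same field.
#' @param max_match_um acceptance radius (default 0.5 um).
#' @return list with `ratio` (n_PSD / n_presyn), `apposed` (logical per
#'   PSD row), `n_psd`, `n_presyn`, `n_apposed`.
#' @export
apposition_ratio <- function(psd_table, presyn_table, max_match_um = 0.5) {
  if (!nrow(psd_table) || !nrow(presyn_table))
    stopf("both tables must be nonempty")
  d <- pairwise_dist(cbind(psd_table$x_um, psd_table$y_um),
                     cbind(presyn_table$x_um, presyn_table$y_um))
  nn_pp <- apply(d, 1, which.min)
  nn_pr <- apply(d, 2, which.min)
  mutual <- nn_pr[nn_pp] == seq_len(nrow(psd_table))
  apposed <- mutual & d[cbind(seq_len(nrow(psd_table)), nn_pp)] <=
    max_match_um
  list(ratio = nrow(psd_table) / nrow(presyn_table),
       apposed = apposed,
       n_psd = nrow(psd_table), n_presyn = nrow(presyn_table),
       n_apposed = sum(apposed))
}
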