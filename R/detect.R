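# Spot and event detection: structural puncta, quantal flashes, and
# centroid-proximity assignment of flashes to AZs.

# Logical matrix of 8-neighbourhood local maxima (strict against at least
# one neighbour, >= against the rest, to keep plateau centres).
#' @noRd
local_maxima <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  pad <- matrix(-Inf, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- img
  ok <- matrix(TRUE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    ok <- ok & img >= pad[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc]
  }
  ok
}

# Local-maximum test restricted to the linear indices `pix` (out-of-image
# neighbours count as -Inf, so edge pixels can be maxima).
#' @noRd
masked_maxima <- function(fr, pix, ny, nx) {
  r <- (pix - 1L) %% ny + 1L
  c <- (pix - 1L) %/% ny + 1L
  v <- fr[pix]
  ge <- rep(TRUE, length(pix))
  gt <- rep(FALSE, length(pix))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    rr <- r + dr; cc <- c + dc
    ok <- rr >= 1 & rr <= ny & cc >= 1 & cc <= nx
    nb <- rep(-Inf, length(pix))
    nb[ok] <- fr[cbind(rr[ok], cc[ok])]
    ge <- ge & v >= nb
    gt <- gt | v > nb
  }
  ge & gt
}

# Intensity-weighted subpixel centroid in a 3x3 neighbourhood around
# integer peak (r, c); values below zero are ignored.
#' @noRd
refine_centroid <- function(img, r, c) {
  rr <- max(1L, r - 1L):min(nrow(img), r + 1L)
  cc <- max(1L, c - 1L):min(ncol(img), c + 1L)
  w <- pmax(img[rr, cc, drop = FALSE], 0)
  s <- sum(w)
  if (s <= 0) return(c(r, c))
  c(sum(rr * rowSums(w)) / s, sum(cc * colSums(w)) / s)
}

#' Detect fluorescent puncta in a structural image
#'
#' Finds local intensity maxima above a threshold ("find spot" style peak
#' detection), suppresses maxima closer than `min_separation_um` (keeping
#' the brighter), and refines each kept peak to a subpixel centroid by
#' intensity weighting in its 3x3 neighbourhood. The automatic threshold is
#' the image median plus `auto_mult` robust SDs (median absolute
#' deviation).
#'
#' @param image 2D numeric matrix.
#' @param pixel_size_um pixel size in um.
#' @param min_separation_um minimum peak separation in um (> 0).
#' @param threshold `"auto"` or an absolute intensity value.
#' @param auto_mult robust-SD multiplier for the automatic threshold
#'   (default 4).
#' @return data.frame with `spot_id`, `x_um`, `y_um`, `peak` (intensity);
#'   empty when nothing exceeds threshold. Warns when >10% of pixels are
#'   suprathreshold (saturated or low-contrast input).
#' @export
find_spots <- function(image, pixel_size_um, min_separation_um = 0.4,
                       threshold = "auto", auto_mult = 4) {
  if (!is.matrix(image)) stopf("image must be a 2D matrix")
  if (min_separation_um <= 0) stopf("min_separation_um must be > 0")
  thr <- if (identical(threshold, "auto"))
    stats::median(image) + auto_mult * mad_sd(as.vector(image))
  else as.numeric(threshold)
  above <- image > thr
  if (mean(above) > 0.10)
    warnf("%.0f%% of pixels exceed threshold: saturated or low-contrast image",
          100 * mean(above))
  cand <- which(above & local_maxima(image), arr.ind = TRUE)
  if (nrow(cand) == 0)
    return(data.frame(spot_id = integer(0), x_um = numeric(0),
                      y_um = numeric(0), peak = numeric(0)))
  vals <- image[cand]
  ord <- order(vals, decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  vals <- vals[ord]
  # greedy non-maximum suppression, brightest first
  min_sep_px <- min_separation_um / pixel_size_um
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (i == 1L) { keep[1L] <- TRUE; next }
    kept <- which(keep)
    d2 <- (cand[kept, 1] - cand[i, 1])^2 + (cand[kept, 2] - cand[i, 2])^2
    keep[i] <- all(d2 >= min_sep_px^2)
  }
  cand <- cand[keep, , drop = FALSE]
  vals <- vals[keep]
  ctr <- t(vapply(seq_len(nrow(cand)),
                  function(i) refine_centroid(image, cand[i, 1], cand[i, 2]),
                  numeric(2)))
  data.frame(spot_id = seq_len(nrow(cand)),
             x_um = px_to_um(ctr[, 2], pixel_size_um),
             y_um = px_to_um(ctr[, 1], pixel_size_um),
             peak = vals)
}

#' Detect quantal fusion events in a conditioned movie
#'
#' Per frame, pixels exceeding `threshold_sd` times the per-pixel noise SD
#' (estimated by the temporal median absolute deviation, robust to sparse
#' flashes) are grouped into connected components; components of at least
#' `min_area_px` pixels become candidate events with intensity-weighted
#' centroids and peak dF. Components containing several well-separated
#' local maxima (simultaneous flashes at neighbouring AZs) are split among
#' the maxima. A flash persisting across consecutive frames at the same
#' location (< `merge_dist_um`) is merged and reported once at its onset
#' frame; a gap of one frame or more starts a new event.
#'
#' @param stack a baseline-subtracted [movie_stack()].
#' @param threshold_sd noise-SD multiplier (> 0; default 5).
#' @param min_area_px minimum component area in pixels (default 4).
#' @param merge_dist_um distance for splitting simultaneous flashes and for
#'   merging a flash across frames (default 0.5 um).
#' @param peak_sd secondary acceptance criterion: an event's peak pixel
#'   must also exceed `peak_sd` x noise SD (default `threshold_sd + 4`).
#'   Spatially smoothed noise forms connected suprathreshold clusters whose
#'   peaks stay near the threshold, while genuine indicator flashes peak
#'   far above it; the peak criterion rejects the former without touching
#'   the latter.
#' @param abs_threshold absolute dF threshold used when the estimated noise
#'   SD is zero (noise-free synthetic input; a warning is raised and half
#'   the maximal dF is used unless given).
#' @return data.frame (class `event_list`) with `event_id`, `frame`,
#'   `time_s`, `x_um`, `y_um`, `peak_dF`, `n_frames` (merged length);
#'   `kind` and `az_id` are filled downstream.
#' @export
detect_events <- function(stack, threshold_sd = 5, min_area_px = 4L,
                          merge_dist_um = 0.5, peak_sd = NULL,
                          abs_threshold = NULL) {
  stopifnot(inherits(stack, "movie_stack"))
  if (threshold_sd <= 0) stopf("threshold_sd must be > 0")
  peak_sd <- peak_sd %||% (threshold_sd + 4)
  d <- dim(stack$data)
  px <- stack$pixel_size_um
  npix <- d[1] * d[2]
  # per-pixel noise level from the temporal MAD, estimated on at most 64
  # evenly spaced frames (robust to sparse flashes; subsampling costs ~12%
  # precision on the SD, immaterial for a 5-sigma threshold)
  sub <- if (d[3] > 64L) round(seq(1, d[3], length.out = 64L)) else
    seq_len(d[3])
  flat <- matrix(stack$data[, , sub], npix, length(sub))
  mm <- .temporal_mad_cpp(flat)
  med <- mm[, 1]
  sdmap <- mm[, 2]
  if (all(sdmap == 0)) {
    warnf("estimated noise SD is 0; using absolute threshold")
    thr_vec <- rep(abs_threshold %||% (max(stack$data) / 2), npix)
    pk_vec <- thr_vec
  } else {
    # guard against dead pixels: floor at the field's median noise level
    sdmap <- pmax(sdmap, stats::median(sdmap[sdmap > 0]))
    thr_vec <- med + threshold_sd * sdmap
    pk_vec <- med + peak_sd * sdmap
  }
  thr_mat <- matrix(thr_vec, d[1], d[2])
  pk_mat <- matrix(pk_vec, d[1], d[2])

  min_sep_px <- merge_dist_um / px
  per_frame <- vector("list", d[3])
  for (f in seq_len(d[3])) {
    fr <- stack$data[, , f]
    mask <- fr > thr_mat
    if (!any(mask)) next
    lab <- EBImage::bwlabel(mask)
    pix <- which(lab > 0)
    labs <- lab[pix]
    sizes <- tabulate(labs)
    keep_lab <- which(sizes >= min_area_px)
    if (!length(keep_lab)) next
    # local maxima evaluated only at suprathreshold pixels
    lm_at <- masked_maxima(fr, pix, d[1], d[2])
    by_lab <- split(seq_along(pix), labs)
    evs <- list()
    for (l in keep_lab) {
      sel <- by_lab[[l]]
      pidx <- pix[sel]
      idx <- cbind((pidx - 1L) %% d[1] + 1L, (pidx - 1L) %/% d[1] + 1L)
      vals <- fr[pidx]
      # local maxima inside the component, brightest-first suppression
      is_max <- lm_at[sel]
      mx <- idx[is_max, , drop = FALSE]
      mv <- vals[is_max]
      if (nrow(mx) > 1) {
        ord <- order(mv, decreasing = TRUE)
        mx <- mx[ord, , drop = FALSE]; mv <- mv[ord]
        keep <- logical(nrow(mx)); keep[1] <- TRUE
        for (i in 2:nrow(mx)) {
          kept <- which(keep)
          d2 <- (mx[kept, 1] - mx[i, 1])^2 + (mx[kept, 2] - mx[i, 2])^2
          keep[i] <- all(d2 >= min_sep_px^2)
        }
        mx <- mx[keep, , drop = FALSE]; mv <- mv[keep]
      }
      if (nrow(mx) == 0) {  # flat component: single event at weighted centre
        ipk <- idx[which.max(vals), , drop = FALSE]
        if (max(vals) < pk_mat[ipk]) next
        w <- vals - min(vals) + 1e-9
        evs[[length(evs) + 1L]] <-
          c(sum(idx[, 1] * w) / sum(w), sum(idx[, 2] * w) / sum(w),
            max(vals))
        next
      }
      if (nrow(mx) == 1) {
        if (mv[1] < pk_mat[mx[1, , drop = FALSE]]) next
        w <- pmax(vals, 0)
        if (sum(w) == 0) w <- w + 1e-9
        evs[[length(evs) + 1L]] <-
          c(sum(idx[, 1] * w) / sum(w), sum(idx[, 2] * w) / sum(w),
            max(vals))
      } else {
        # assign component pixels to the nearest kept maximum
        d2m <- outer(idx[, 1], mx[, 1], "-")^2 +
          outer(idx[, 2], mx[, 2], "-")^2
        grp <- max.col(-d2m)
        for (g in seq_len(nrow(mx))) {
          if (mv[g] < pk_mat[mx[g, , drop = FALSE]]) next
          sel <- grp == g
          w <- pmax(vals[sel], 0)
          if (sum(w) == 0) w <- w + 1e-9
          evs[[length(evs) + 1L]] <-
            c(sum(idx[sel, 1] * w) / sum(w),
              sum(idx[sel, 2] * w) / sum(w), max(vals[sel]))
        }
      }
    }
    if (length(evs)) {
      m <- do.call(rbind, evs)
      per_frame[[f]] <- data.frame(frame = f, r = m[, 1], c = m[, 2],
                                   peak = m[, 3])
    }
  }
  det <- do.call(rbind, per_frame)
  if (is.null(det) || nrow(det) == 0) {
    out <- data.frame(event_id = integer(0), frame = integer(0),
                      time_s = numeric(0), x_um = numeric(0),
                      y_um = numeric(0), peak_dF = numeric(0),
                      n_frames = integer(0))
    class(out) <- c("event_list", "data.frame")
    return(out)
  }

  # merge detections persisting across consecutive frames at one site
  det <- det[order(det$frame), , drop = FALSE]
  ev_open <- list()   # active chains: list(r, c, frame0, last, peak)
  done <- list()
  for (f in sort(unique(det$frame))) {
    rows <- det[det$frame == f, , drop = FALSE]
    # retire chains not seen in the previous frame
    if (length(ev_open)) {
      last <- vapply(ev_open, function(e) e$last, numeric(1))
      retire <- last < f - 1L
      done <- c(done, ev_open[retire])
      ev_open <- ev_open[!retire]
    }
    used <- rep(FALSE, nrow(rows))
    if (length(ev_open)) {
      er <- vapply(ev_open, function(e) e$r, numeric(1))
      ec <- vapply(ev_open, function(e) e$c, numeric(1))
      for (i in seq_len(nrow(rows))) {
        d2 <- (er - rows$r[i])^2 + (ec - rows$c[i])^2
        j <- which.min(d2)
        if (length(j) && d2[j] < min_sep_px^2 && ev_open[[j]]$last == f - 1L) {
          ev_open[[j]]$last <- f
          ev_open[[j]]$peak <- max(ev_open[[j]]$peak, rows$peak[i])
          er[j] <- Inf  # one continuation per chain per frame
          used[i] <- TRUE
        }
      }
    }
    for (i in which(!used))
      ev_open[[length(ev_open) + 1L]] <-
        list(r = rows$r[i], c = rows$c[i], frame0 = f, last = f,
             peak = rows$peak[i])
  }
  done <- c(done, ev_open)
  out <- data.frame(
    frame = vapply(done, function(e) e$frame0, numeric(1)),
    x_um = px_to_um(vapply(done, function(e) e$c, numeric(1)), px),
    y_um = px_to_um(vapply(done, function(e) e$r, numeric(1)), px),
    peak_dF = vapply(done, function(e) e$peak, numeric(1)),
    n_frames = vapply(done, function(e) e$last - e$frame0 + 1, numeric(1)))
  out <- out[order(out$frame, out$x_um), , drop = FALSE]
  out$event_id <- seq_len(nrow(out))
  # an event in frame f occurred somewhere in ((f-1), f] * dt; report the
  # frame-end time so stimulus-window labelling sees it after its stimulus
  out$time_s <- out$frame * stack$frame_interval_s
  out <- out[, c("event_id", "frame", "time_s", "x_um", "y_um",
                 "peak_dF", "n_frames")]
  rownames(out) <- NULL
  class(out) <- c("event_list", "data.frame")
  out
}

#' Assign detected events to AZs by centroid proximity
#'
#' Maps each event to the nearest AZ centroid within `max_dist_um`
#' (nearest-centroid reformulation of fixed-size ROI capture: identical for
#' well-separated AZs, well defined for overlaps). Distance ties within
#' 1e-9 um break to the lower `az_id`. Events with no AZ in range stay
#' unassigned with a recorded reason.
#'
#' @param events an `event_list`.
#' @param az `az_table` (nonempty).
#' @param max_dist_um assignment radius in um (default 0.5, about the
#'   half-width of a 5-pixel ROI at 0.138 um/px plus margin).
#' @return the event list with `az_id` (NA when unassigned) and
#'   `unassigned_reason` columns.
#' @export
assign_events <- function(events, az, max_dist_um = 0.5) {
  if (nrow(az) == 0) stopf("AZ table is empty")
  if (max_dist_um <= 0) stopf("max_dist_um must be > 0")
  events$az_id <- rep(NA_integer_, nrow(events))
  events$unassigned_reason <- rep(NA_character_, nrow(events))
  if (nrow(events) == 0) return(events)
  ord <- order(az$az_id)  # tie-break: lower az_id wins via which.min
  azo <- az[ord, , drop = FALSE]
  d <- pairwise_dist(cbind(events$x_um, events$y_um),
                     cbind(azo$x_um, azo$y_um))
  # quantize ties: distances within 1e-9 compare equal
  dq <- round(d / 1e-9) * 1e-9
  j <- apply(dq, 1, which.min)
  best <- d[cbind(seq_len(nrow(events)), j)]
  ok <- best <= max_dist_um
  events$az_id[ok] <- azo$az_id[j[ok]]
  events$unassigned_reason[!ok] <- "no AZ in range"
  events
}
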