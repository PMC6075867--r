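# Structural-channel fluorescence quantification at AZs.

#' Quantify per-AZ fluorescence in a square ROI
#'
#' Measures mean and summed intensity in a `roi_px` x `roi_px` square
#' centred on each AZ's nearest pixel (3-pixel square ROIs around each
#' fluorescence peak are the standard for AZ channel quantification). AZs
#' whose ROI would leave the image are flagged `border = TRUE` and carry NA
#' intensities.
#'
#' @param image 2D numeric matrix.
#' @param az `az_table` (nonempty) with `x_um`, `y_um`.
#' @param pixel_size_um pixel size in um.
#' @param roi_px odd ROI side length in pixels (default 3).
#' @param channel channel name used for the output column label.
#' @param subpixel when `TRUE`, the ROI grid is centred on the exact
#'   (fractional) AZ position and sampled by bilinear interpolation,
#'   removing the pixel-phase jitter of integer ROI placement; the default
#'   `FALSE` centres on the nearest pixel, as in standard ROI analysis.
#' @return data.frame (class `intensity_table`) with `az_id`, `channel`,
#'   `mean_f`, `sum_f`, `norm_f` (per-image min-max normalised mean,
#'   border AZs excluded), `border`.
#' @export
quantify_intensity <- function(image, az, pixel_size_um, roi_px = 3L,
                               channel = "channel", subpixel = FALSE) {
  if (nrow(az) == 0) stopf("AZ table is empty")
  if (roi_px %% 2 != 1) stopf("roi_px must be odd")
  hw <- (roi_px - 1L) %/% 2L
  rf <- um_to_px(az$y_um, pixel_size_um)
  cf <- um_to_px(az$x_um, pixel_size_um)
  r <- round(rf); c <- round(cf)
  border <- r - hw < 1 | r + hw > nrow(image) |
            c - hw < 1 | c + hw > ncol(image)
  mean_f <- sum_f <- rep(NA_real_, nrow(az))
  off <- -hw:hw
  for (i in which(!border)) {
    roi <- if (subpixel) {
      g <- expand.grid(r = rf[i] + off, c = cf[i] + off)
      interp_bilinear(image, g$r, g$c)
    } else {
      image[r[i] + off, c[i] + off]
    }
    sum_f[i] <- sum(roi)
    mean_f[i] <- sum_f[i] / length(roi)
  }
  ok <- !border
  norm_f <- rep(NA_real_, nrow(az))
  if (any(ok)) {
    rng <- range(mean_f[ok])
    norm_f[ok] <- if (diff(rng) > 0) (mean_f[ok] - rng[1]) / diff(rng)
                  else 0
  }
  out <- data.frame(az_id = az$az_id, channel = channel, mean_f = mean_f,
                    sum_f = sum_f, norm_f = norm_f, border = border)
  class(out) <- c("intensity_table", "data.frame")
  out
}

#' Flag unusually bright AZs
#'
#' Marks AZs whose mean ROI fluorescence exceeds the population mean plus
#' `sd_mult` standard deviations (strict inequality; SD = 0 yields none),
#' and reports the bright fraction and the fold-difference between bright
#' and remaining AZs.
#'
#' @param table an `intensity_table` with >= 3 non-border AZs.
#' @param sd_mult SD multiplier (default 2).
#' @param sd_type "population" or "sample" SD.
#' @return the table with a logical `bright` column and attributes
#'   `threshold`, `bright_fraction`, `bright_fold`.
#' @export
bright_az_classify <- function(table, sd_mult = 2,
                               sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  ok <- !table$border & is.finite(table$mean_f)
  x <- table$mean_f[ok]
  if (length(x) < 3) stopf("need >= 3 quantified AZs")
  s <- stats::sd(x)
  if (sd_type == "population") s <- s * sqrt((length(x) - 1) / length(x))
  thr <- mean(x) + sd_mult * s
  bright <- rep(NA, nrow(table))
  bright[ok] <- s > 0 & x > thr
  table$bright <- bright
  attr(table, "threshold") <- thr
  attr(table, "bright_fraction") <- mean(bright[ok])
  attr(table, "bright_fold") <-
    if (any(bright[ok])) mean(x[x > thr]) / mean(x[x <= thr]) else NA_real_
  table
}

#' Stimulus-epoch fluorescence increase (dF) per AZ
#'
#' dF is the mean ROI intensity over a stimulation epoch minus the mean
#' over a rest epoch, per AZ - the operational proxy for local Ca(2+)
#' influx at an AZ during train stimulation. With several stimulation
#' epochs, per-AZ stability is reported as the coefficient of variation of
#' dF across epochs.
#'
#' @param stack a [movie_stack()].
#' @param stim_epoch frame indices of the stimulation epoch (or a list of
#'   several epochs, each >= 3 frames).
#' @param rest_epoch frame indices of the rest epoch (>= 3 frames,
#'   disjoint from every stimulation epoch).
#' @param az `az_table`.
#' @param roi_px ROI side (odd; default 3).
#' @return data.frame with `az_id`, `dF` (first/only epoch mean minus
#'   rest), per-epoch columns `dF_epoch<k>` when several epochs are given,
#'   and `cv` (across-epoch coefficient of variation, NA for one epoch).
#' @export
delta_f <- function(stack, stim_epoch, rest_epoch, az, roi_px = 3L) {
  stopifnot(inherits(stack, "movie_stack"))
  epochs <- if (is.list(stim_epoch)) stim_epoch else list(stim_epoch)
  if (any(vapply(epochs, length, 1L) < 3) || length(rest_epoch) < 3)
    stopf("each epoch needs >= 3 frames")
  if (any(unlist(epochs) %in% rest_epoch))
    stopf("stimulation and rest epochs overlap")
  mean_img <- function(frames)
    apply(stack$data[, , frames, drop = FALSE], c(1, 2), mean)
  rest <- quantify_intensity(mean_img(rest_epoch), az,
                             stack$pixel_size_um, roi_px)$mean_f
  dfs <- vapply(epochs, function(ep)
    quantify_intensity(mean_img(ep), az, stack$pixel_size_um,
                       roi_px)$mean_f - rest,
    numeric(nrow(az)))
  dfs <- matrix(dfs, nrow = nrow(az))
  out <- data.frame(az_id = az$az_id, dF = dfs[, 1])
  if (ncol(dfs) > 1) {
    colnames(dfs) <- paste0("dF_epoch", seq_len(ncol(dfs)))
    out <- cbind(out, dfs)
    m <- rowMeans(dfs)
    s <- apply(dfs, 1, stats::sd)
    out$cv <- ifelse(m != 0, s / abs(m), NA_real_)
  } else {
    out$cv <- NA_real_
  }
  out
}

#' Indicator-saturation control
#'
#' Compares the per-AZ fluorescence reached during stimulation with that
#' after a Ca(2+) ionophore saturates the indicator. If stimulation already
#' drives the sensor to >= `limit` of its ionophore ceiling, dF differences
#' between AZs could reflect sensor saturation rather than Ca(2+) influx,
#' and the recording is flagged sensor-limited.
#'
#' @param df_stim,df_iono per-AZ fluorescence (same AZ order/set).
#' @param limit sensor-limited flag threshold on the mean ratio
#'   (default 0.8).
#' @return list with the two means, mean ratio, robust CVs (IQR/median),
#'   a location-shift statistic (difference of means), and
#'   `sensor_limited`.
#' @export
saturation_control <- function(df_stim, df_iono, limit = 0.8) {
  if (length(df_stim) != length(df_iono))
    stopf("inputs must cover the same AZ set")
  rcv <- function(x) stats::IQR(x) / abs(stats::median(x))
  m_s <- mean(df_stim); m_i <- mean(df_iono)
  list(mean_stim = m_s, mean_iono = m_i,
       mean_ratio = m_s / m_i,
       shift = m_i - m_s,
       rcv_stim = rcv(df_stim), rcv_iono = rcv(df_iono),
       sensor_limited = m_s >= limit * m_i)
}

#' Grouped Pearson correlation of per-AZ measures
#'
#' Computes the Pearson correlation per recording (group) between two
#' per-AZ quantities paired on `az_id`, then the across-group mean r - the
#' headline statistic for, e.g., Ca(2+)-channel intensity versus Pr - plus
#' pooled statistics over all AZs.
#'
#' @param x,y data.frames with `az_id` and `value`.
#' @param group vector of recording ids, one per row of the joined table;
#'   a single id gives one group.
#' @return list with `per_group` (data.frame: group, n, r, r_squared,
#'   p_value, conf_low, conf_high), `mean_r`, `mean_r_squared`, and
#'   `pooled` (r/p over all AZs).
#' @export
correlate_az <- function(x, y, group = NULL) {
  j <- merge(x, y, by = "az_id", suffixes = c("_x", "_y"))
  if (is.null(group)) group <- rep(1L, nrow(j))
  if (length(group) != nrow(j)) stopf("group must match the joined rows")
  res <- lapply(split(seq_len(nrow(j)), group), function(idx) {
    if (length(idx) < 10) stopf("each group needs >= 10 AZs")
    xs <- j$value_x[idx]; ys <- j$value_y[idx]
    if (stats::sd(xs) == 0 || stats::sd(ys) == 0)
      stopf("zero variance within a group")
    ct <- stats::cor.test(xs, ys)
    data.frame(n = length(idx), r = unname(ct$estimate),
               r_squared = unname(ct$estimate)^2, p_value = ct$p.value,
               conf_low = ct$conf.int[1], conf_high = ct$conf.int[2])
  })
  per_group <- cbind(group = names(res), do.call(rbind, res))
  rownames(per_group) <- NULL
  pooled <- stats::cor.test(j$value_x, j$value_y)
  list(per_group = per_group,
       mean_r = mean(per_group$r),
       mean_r_squared = mean(per_group$r_squared),
       pooled = list(r = unname(pooled$estimate),
                     p_value = pooled$p.value, n = nrow(j)))
}
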