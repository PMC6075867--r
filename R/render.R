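#' Render a synthetic functional movie
#'
#' Turns ground-truth fusion events into a time-lapse stack mimicking a
#' postsynaptic Ca(2+)-indicator recording. Each event stamps an isotropic
#' Gaussian flash (sigma `psf_sigma_um`) at its AZ position with a
#' single-frame rise to `flash_amplitude` and exponential decay
#' (`flash_decay_s`). Baseline fluorescence `baseline_f` bleaches with time
#' constant `bleach_tau_s`; a global translation accumulates at
#' `drift_px_per_frame` (random direction, drawn once per movie); i.i.d.
#' Gaussian noise of SD `noise_sd` is added per pixel per frame. A fixed
#' seed yields a bit-identical stack.
#'
#' @param az `az_table` with positions.
#' @param events `event_truth` from [simulate_event_times()].
#' @param cfg a [synth_config()].
#' @return a [movie_stack()]; the per-frame ground-truth drift is attached
#'   as attribute `drift_px` (frames x 2 matrix, dy/dx in pixels).
#' @export
render_movie <- function(az, events, cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  if (nrow(events) && !all(events$az_id %in% az$az_id))
    stopf("events reference AZs missing from the table")
  if (cfg$flash_decay_s < cfg$frame_interval_s)
    warnf("flash_decay_s < frame_interval_s: events may span a single frame")
  px <- cfg$pixel_size_um
  dt <- cfg$frame_interval_s
  nx <- ceiling(cfg$field_size_um[1] / px)
  ny <- ceiling(cfg$field_size_um[2] / px)
  nf <- max(1L, ceiling(cfg$movie_duration_s / dt))

  set.seed(cfg$seed + 2L)
  th <- stats::runif(1, 0, 2 * pi)
  drift_step <- cfg$drift_px_per_frame * c(sin(th), cos(th))  # (dy, dx) px
  # generative drift path, quantised to 1/4 pixel (lets the renderer reuse
  # shifted baseline textures; the quantised path IS the ground truth)
  drift_px <- round(4 * outer(0:(nf - 1L), drift_step)) / 4

  # per-frame bleach factor of the baseline
  t_fr <- (seq_len(nf) - 1) * dt
  bleach <- if (is.finite(cfg$bleach_tau_s))
    exp(-t_fr / cfg$bleach_tau_s) else rep(1, nf)

  stack <- array(0, c(ny, nx, nf))
  if (cfg$baseline_structure > 0) {
    # static membrane-like baseline texture on a padded canvas; it drifts
    # together with the puncta so movement correction has structure to
    # lock onto
    pad <- ceiling(max(abs(drift_px))) + 2L
    big <- matrix(stats::rnorm((ny + 2 * pad) * (nx + 2 * pad)),
                  ny + 2 * pad, nx + 2 * pad)
    # diffraction-limited speckle: membrane-bound indicator structure is
    # sharp at the PSF scale, which is what registration locks onto
    big <- gauss_filter_frame(big, sigma_px = cfg$psf_sigma_um / px)
    big <- big / stats::sd(big) * cfg$baseline_structure + 1
    big <- pmax(big, 0.1) * cfg$baseline_f
    g <- expand.grid(r = seq_len(ny) + pad, c = seq_len(nx) + pad)
    # cache the shifted texture per distinct quantised offset
    key <- paste(drift_px[, 1], drift_px[, 2])
    cache <- new.env(parent = emptyenv())
    for (f in seq_len(nf)) {
      if (is.null(cache[[key[f]]]))
        cache[[key[f]]] <- matrix(
          interp_bilinear(big, g$r - drift_px[f, 1],
                          g$c - drift_px[f, 2]), ny, nx)
      stack[, , f] <- bleach[f] * cache[[key[f]]]
    }
  } else {
    for (f in seq_len(nf)) stack[, , f] <- cfg$baseline_f * bleach[f]
  }

  if (nrow(events)) {
    pos <- az[match(events$az_id, az$az_id), c("x_um", "y_um")]
    onset_frame <- pmin(floor(events$time_s / dt) + 1L, nf)
    # each flash persists until it decays below 2% of its amplitude
    k_max <- ceiling(cfg$flash_decay_s / dt * log(50))
    ks <- 0:k_max
    n_ev <- nrow(events)
    f_all <- rep(onset_frame, each = length(ks)) + ks
    i_all <- rep(seq_len(n_ev), each = length(ks))
    amp_all <- cfg$flash_amplitude *
      exp(-rep(ks, n_ev) * dt / cfg$flash_decay_s)
    keep <- f_all <= nf
    f_all <- f_all[keep]; i_all <- i_all[keep]; amp_all <- amp_all[keep]
    cy <- um_to_px(pos$y_um[i_all], px) + drift_px[f_all, 1]
    cx <- um_to_px(pos$x_um[i_all], px) + drift_px[f_all, 2]
    .stamp_flashes_cpp(stack, ny, nx, nf, cy, cx, as.integer(f_all),
                       amp_all, cfg$psf_sigma_um / px)
  }
  if (cfg$noise_sd > 0)
    stack <- stack + stats::rnorm(length(stack), sd = cfg$noise_sd)

  out <- movie_stack(stack, dt, px, cfg$stim_times_s)
  attr(out, "drift_px") <- drift_px
  out
}

# Draw channel amplitudes from the calibrated two-gamma marginal and couple
# them to true_pr so that the sample Pearson correlation equals `r`.
#' @noRd
channel_amplitudes <- function(true_pr, r, offset, seed = 1L,
                               mode = c("copula", "linear"),
                               body_shape = 3, bright_mean = 2.8,
                               bright_shape = 40, q_bright = 0.045458) {
  mode <- match.arg(mode)
  if (abs(r) > 0.999) stopf("|intensity_pr_r| > 0.999 is not supported")
  n <- length(true_pr)
  set.seed(seed)
  if (mode == "linear") {
    e <- stats::rnorm(n)
    if (stats::sd(true_pr) == 0) return(offset + e - min(e) + 0.05)
    xs <- (true_pr - mean(true_pr)) / stats::sd(true_pr)
    if (n > 2) {  # orthogonalize so the sample correlation is exact
      e <- e - xs * sum(e * xs) / sum(xs * xs)
      e <- (e - mean(e)) / stats::sd(e)
    }
    y <- r * xs + sqrt(1 - r^2) * e
    return(y - min(y) + 0.05 + offset)
  }
  # copula mode: fixed marginal draw, coupling strength root-solved so the
  # realised Pearson correlation with true_pr matches the request
  b <- stats::runif(n) < q_bright
  marg <- ifelse(b,
                 stats::rgamma(n, bright_shape, scale = bright_mean / bright_shape),
                 stats::rgamma(n, body_shape, scale = 1 / body_shape))
  marg <- offset + sort(marg)
  z_x <- stats::qnorm((rank(true_pr, ties.method = "random") - 0.5) / n)
  eps <- stats::rnorm(n)
  amp_for <- function(rho) {
    z <- rho * z_x + sqrt(max(0, 1 - rho^2)) * eps
    marg[rank(z, ties.method = "first")]
  }
  if (stats::sd(true_pr) == 0) return(amp_for(0))
  cor_for <- function(rho) stats::cor(amp_for(rho), true_pr)
  s <- sign(r)
  if (abs(r) < 1e-12) return(amp_for(0))
  cmax <- cor_for(s)
  if (abs(cmax) < abs(r)) {
    if (abs(cmax) > abs(r) - 0.05) return(amp_for(s))
    stopf("target correlation %.2f beyond the %.2f reachable under this marginal; use mode='linear'",
          r, cmax)
  }
  rho <- stats::uniroot(function(p) cor_for(s * p) - r, c(0, 1),
                        tol = 1e-4)$root
  amp_for(s * rho)
}

#' Render a structural channel image
#'
#' Renders one Gaussian punctum per AZ whose amplitude is drawn from a
#' calibrated fluorescence marginal and coupled to the AZ's ground-truth Pr
#' so that the sample Pearson correlation between amplitude and `true_pr`
#' equals the channel's configured `intensity_pr_r` (a Gaussian-copula
#' coupling whose strength is root-solved on the realised sample; an exact
#' additive "linear" mode is also available). `r = 1` returns the comonotone
#' coupling: amplitude rank order equal to Pr rank order.
#'
#' @param az `az_table` with `true_pr`.
#' @param channel channel name; must exist in `cfg$channels`.
#' @param cfg a [synth_config()].
#' @param seed RNG seed (defaults to `cfg$seed` + a channel hash).
#' @param mode "copula" (calibrated marginal, default) or "linear".
#' @param amp_scale multiplier from marginal units to fluorescence counts.
#' @param noise_sd additive Gaussian image noise (defaults to
#'   `cfg$noise_sd`).
#' @return list with `image` (matrix) and `az` (the table with an added
#'   `intensity_<channel>` column holding each AZ's rendered amplitude).
#' @export
render_channel_image <- function(az, channel, cfg, seed = NULL,
                                 mode = c("copula", "linear"),
                                 amp_scale = 1000, noise_sd = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  ch <- cfg$channels[[channel]]
  if (is.null(ch)) stopf("channel '%s' not configured", channel)
  mode <- match.arg(mode)
  if (is.null(seed))
    seed <- cfg$seed + 100L + match(channel, names(cfg$channels))
  r <- ch$r
  if (abs(r - 1) < 1e-12) {  # perfect coupling: comonotone
    set.seed(seed)
    b <- stats::runif(nrow(az)) < 0.045458
    marg <- ifelse(b, stats::rgamma(nrow(az), 40, scale = 2.8 / 40),
                   stats::rgamma(nrow(az), 3, scale = 1 / 3))
    amp <- ch$offset + sort(marg)[rank(az$true_pr, ties.method = "first")]
  } else {
    amp <- channel_amplitudes(az$true_pr, r, ch$offset, seed = seed,
                              mode = mode)
  }
  amp <- amp * amp_scale
  px <- cfg$pixel_size_um
  nx <- ceiling(cfg$field_size_um[1] / px)
  ny <- ceiling(cfg$field_size_um[2] / px)
  img <- matrix(0, ny, nx)
  for (i in seq_len(nrow(az)))
    img <- stamp_gaussian(img, az$x_um[i], az$y_um[i], amp[i],
                          cfg$psf_sigma_um, px)
  nz <- noise_sd %||% cfg$noise_sd
  if (nz > 0) img <- img + stats::rnorm(length(img), sd = nz)
  az[[paste0("intensity_", channel)]] <- amp
  list(image = img, az = az)
}

#' Render a two-channel synthetic postsynaptic density
#'
#' Channel A is a Gaussian-edged disk (flat core, Gaussian shoulder) whose
#' full width at half maximum equals `core_diam_um`; channel B is an annulus
#' whose radial profile peaks at a ring radius and dips at the centre to
#' `(1 - dip_frac)` of the flank maximum, with outer FWHM
#' `ring_outer_diam_um`. This is the idealised geometry of a mature
#' receptor field: a GluRIIA-like core surrounded by a GluRIIB-like ring.
#' Ground truth is attached for recovery tests.
#'
#' @param core_diam_um FWHM of channel A (um).
#' @param ring_outer_diam_um outer FWHM of channel B (um,
#'   >= `core_diam_um`).
#' @param dip_frac central dip of channel B as a fraction of the flank
#'   maximum, in \[0, 1).
#' @param pixel_size_um pixel size (um).
#' @param noise_sd additive Gaussian noise SD (image peak is 1).
#' @param seed RNG seed for the noise.
#' @param window_um rendered window side length; defaults to 2.4x the ring
#'   outer diameter.
#' @return list with matrices `a`, `b`, the micron coordinates `center_um`,
#'   `pixel_size_um`, and `truth` (the requested geometry).
#' @export
render_psd_pair <- function(core_diam_um, ring_outer_diam_um, dip_frac = 0,
                            pixel_size_um = 0.138, noise_sd = 0, seed = 1L,
                            window_um = NULL) {
  if (ring_outer_diam_um < core_diam_um)
    stopf("ring_outer_diam_um must be >= core_diam_um")
  if (dip_frac < 0 || dip_frac >= 1) stopf("dip_frac must lie in [0, 1)")
  if (core_diam_um < 2 * pixel_size_um ||
      ring_outer_diam_um < 2 * pixel_size_um)
    stopf("unresolvable: a diameter is below 2 pixels (%.3f um)",
          2 * pixel_size_um)
  win <- window_um %||% (2.4 * ring_outer_diam_um)
  n <- ceiling(win / pixel_size_um)
  if (n %% 2 == 0) n <- n + 1L  # odd so a pixel centre sits at the middle
  ctr <- (n / 2) * pixel_size_um  # centre in um
  xs <- px_to_um(seq_len(n), pixel_size_um)
  rr <- sqrt(outer((xs - ctr)^2, (xs - ctr)^2, "+"))

  # channel A: flat core + Gaussian shoulder, FWHM = core_diam_um
  R <- core_diam_um / 2
  r_flat <- 0.3 * R
  sig_e <- (R - r_flat) / sqrt(2 * log(2))
  a <- exp(-pmax(rr - r_flat, 0)^2 / (2 * sig_e^2))

  # channel B: Gaussian ring; centre value (1 - dip_frac) x flank maximum,
  # outer half-maximum crossing at ring_outer_diam_um / 2
  r_half <- ring_outer_diam_um / 2
  aa <- sqrt(-log(1 - dip_frac))
  bb <- sqrt(log(2))
  sig_b <- r_half / (sqrt(2) * (aa + bb))
  r_pk <- r_half * aa / (aa + bb)
  b <- exp(-(rr - r_pk)^2 / (2 * sig_b^2))

  if (noise_sd > 0) {
    set.seed(seed)
    a <- a + stats::rnorm(length(a), sd = noise_sd)
    b <- b + stats::rnorm(length(b), sd = noise_sd)
  }
  list(a = a, b = b, center_um = c(x = ctr, y = ctr),
       pixel_size_um = pixel_size_um,
       truth = list(core_diam_um = core_diam_um,
                    ring_outer_diam_um = ring_outer_diam_um,
                    dip_frac = dip_frac, ring_radius_um = r_pk))
}
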