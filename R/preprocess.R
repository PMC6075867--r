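#' Gaussian-filter every frame of a movie
#'
#' Convolves each frame with an isotropic Gaussian ("fine" spatial filter)
#' to reduce shot noise before event detection. `sigma_px = 0` returns the
#' input unchanged. Total frame intensity is conserved up to boundary
#' handling.
#'
#' @param stack a [movie_stack()] (or a plain matrix, filtered directly).
#' @param sigma_px Gaussian sigma in pixels (>= 0); default 1.
#' @return filtered stack of the same class and dimensions.
#' @export
gaussian_filter_stack <- function(stack, sigma_px = 1) {
  if (sigma_px < 0) stopf("sigma_px must be >= 0")
  if (sigma_px == 0) return(stack)
  if (is.matrix(stack)) return(gauss_filter_frame(stack, sigma_px))
  stopifnot(inherits(stack, "movie_stack"))
  out <- stack
  # EBImage applies the 2D kernel to each frame of a 3D array
  out$data <- gauss_filter_frame(stack$data, sigma_px)
  out
}

# Gaussian convolution per frame with replicated (edge-value) boundaries;
# separable kernel evaluated in compiled code.
#' @noRd
gauss_filter_frame <- function(img, sigma_px) {
  d <- if (is.matrix(img)) c(dim(img), 1L) else dim(img)
  res <- .gauss3d_cpp(as.numeric(img), d[1], d[2], d[3], sigma_px)
  if (is.matrix(img)) matrix(res, d[1], d[2]) else array(res, d)
}

# FFT cross-correlation between two equally sized matrices; returns the
# correlation surface with zero shift at index (1, 1) (wrap-around layout).
#' @noRd
xcorr_fft <- function(ref, img) {
  Re(stats::fft(stats::fft(ref) * Conj(stats::fft(img)), inverse = TRUE))
}

#' Estimate and correct global frame-to-frame drift
#'
#' Registers every frame to a reference frame by FFT cross-correlation with
#' subpixel refinement (upsampled local discrete Fourier transform, as in
#' standard single-step DFT registration), then re-aligns the stack by
#' bilinear interpolation. Only rigid translation is modelled, matching the
#' translational movement correction applied to the recordings this package
#' emulates.
#'
#' @param stack a [movie_stack()] with >= 2 frames.
#' @param reference frame index used as the registration target (default 1).
#' @param upsample subpixel upsampling factor (default 10; 1 = integer
#'   shifts).
#' @param crop_px registration is estimated on a centred square crop of at
#'   most this many pixels per side (speed); the full frame is shifted.
#' @param apply_mode how the correction is applied: "bilinear" (subpixel
#'   interpolation, default), "integer" (shifts rounded to whole pixels -
#'   an order of magnitude faster, residual misalignment < 0.5 px), or
#'   "none" (estimate only).
#' @return list with `stack` (re-aligned movie), `shifts` (data.frame:
#'   `frame`, `dy_px`, `dx_px` - the estimated drift of each frame relative
#'   to the reference; the applied correction is its negation) and
#'   `ambiguous` (frames whose correlation peak was not unique).
#' @export
correct_drift <- function(stack, reference = 1L, upsample = 10L,
                          crop_px = 256L,
                          apply_mode = c("bilinear", "integer", "none")) {
  apply_mode <- match.arg(apply_mode)
  stopifnot(inherits(stack, "movie_stack"))
  nf <- n_frames(stack)
  if (nf < 2) stopf("need >= 2 frames to register")
  d <- dim(stack$data)
  # centred crop for estimation
  side <- min(d[1], d[2], crop_px)
  r0 <- floor((d[1] - side) / 2)
  c0 <- floor((d[2] - side) / 2)
  rows <- (r0 + 1):(r0 + side)
  cols <- (c0 + 1):(c0 + side)
  # Hann window suppresses the spurious spectral content of non-periodic
  # frames (edges), which otherwise biases the subpixel peak
  h <- 0.5 - 0.5 * cos(2 * pi * (seq_len(side) - 1) / (side - 1))
  win <- h %o% h
  ref <- stack$data[rows, cols, reference] * win
  ref_f <- stats::fft(ref)

  shifts <- matrix(0, nf, 2)
  ambiguous <- logical(nf)
  for (f in seq_len(nf)) {
    if (f == reference) next
    img <- stack$data[rows, cols, f] * win
    img_f <- stats::fft(img)
    cp <- ref_f * Conj(img_f)
    # regularised phase correlation: normalising the cross-power spectrum
    # removes the spectral-leakage bias of raw cross-correlation on
    # non-periodic content, while the additive floor keeps noise-dominated
    # high frequencies (negligible magnitude) from being amplified
    m <- Mod(cp)
    cp <- cp / (m + 0.05 * mean(m))
    cc <- Re(stats::fft(cp, inverse = TRUE))
    pk <- which.max(cc)
    pr <- (pk - 1L) %% side + 1L
    pc <- (pk - 1L) %/% side + 1L
    # second peak far from the first -> ambiguous registration
    cc2 <- cc
    rr_sup <- ((pr - 2):(pr + 2) - 1L) %% side + 1L
    cc_sup <- ((pc - 2):(pc + 2) - 1L) %% side + 1L
    cc2[rr_sup, cc_sup] <- -Inf
    if (max(cc2) > 0.99 * cc[pr, pc]) ambiguous[f] <- TRUE
    dy <- if (pr - 1L > side / 2) pr - 1L - side else pr - 1L
    dx <- if (pc - 1L > side / 2) pc - 1L - side else pc - 1L
    if (upsample > 1) {
      us <- upsample_dft_peak(cp, dy, dx, upsample)
      dy <- us[1]; dx <- us[2]
    }
    # cc peak at (dy, dx) means frame content moved by (-dy, -dx) relative
    # to the reference under the conjugate convention used here; store the
    # frame's displacement
    shifts[f, ] <- c(-dy, -dx)
  }
  out <- stack
  if (apply_mode != "none") {
    for (f in seq_len(nf)) {
      s <- shifts[f, ]
      if (apply_mode == "integer") s <- round(s)
      if (all(s == 0)) next
      out$data[, , f] <-
        if (apply_mode == "integer")
          shift_frame_int(stack$data[, , f], -s[1], -s[2])
        else shift_frame(stack$data[, , f], -s[1], -s[2])
    }
  }
  list(stack = out,
       shifts = data.frame(frame = seq_len(nf),
                           dy_px = shifts[, 1], dx_px = shifts[, 2]),
       ambiguous = which(ambiguous))
}

# Refine a cross-power-spectrum peak on an upsampled local grid via an
# explicit (matrix-product) inverse DFT evaluated around (dy0, dx0).
#' @noRd
upsample_dft_peak <- function(cp, dy0, dx0, upsample) {
  n <- nrow(cp); m <- ncol(cp)
  span <- 1.5                      # +/- 1.5 px around the integer peak
  steps <- seq(-span, span, by = 1 / upsample)
  ky <- c(0:(floor(n / 2)), -((ceiling(n / 2) - 1):1)) / n
  kx <- c(0:(floor(m / 2)), -((ceiling(m / 2) - 1):1)) / m
  Ey <- exp(2i * pi * outer(dy0 + steps, ky))         # |steps| x n
  Ex <- exp(2i * pi * outer(kx, dx0 + steps))         # m x |steps|
  cc <- Re(Ey %*% cp %*% Ex)
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  c(dy0 + steps[pk[1]], dx0 + steps[pk[2]])
}

# Shift a frame by (dy, dx) pixels with bilinear interpolation and edge
# clamping.
#' @noRd
shift_frame <- function(img, dy, dx) {
  nr <- nrow(img); nc <- ncol(img)
  g <- expand.grid(r = seq_len(nr), c = seq_len(nc))
  matrix(interp_bilinear(img, g$r - dy, g$c - dx), nr, nc)
}

# Whole-pixel shift by index relocation with edge clamping (fast path).
#' @noRd
shift_frame_int <- function(img, dy, dx) {
  nr <- nrow(img); nc <- ncol(img)
  r_src <- pmin(pmax(seq_len(nr) - dy, 1L), nr)
  c_src <- pmin(pmax(seq_len(nc) - dx, 1L), nc)
  img[r_src, c_src, drop = FALSE]
}

#' Normalise photobleaching
#'
#' Divides each frame by its total-intensity ratio to the first frame,
#' flattening the multiplicative decay that photobleaching imposes on the
#' whole field. Without this, the slow trend inflates the temporal noise
#' estimate and detection thresholds drift over long recordings. Sparse
#' flashes perturb frame means by well under a percent, so the plain mean
#' is an adequate bleach tracer.
#'
#' @param stack a [movie_stack()].
#' @return the normalised stack; the per-frame scale factors are attached
#'   as attribute `bleach_scale`.
#' @export
correct_bleach <- function(stack) {
  stopifnot(inherits(stack, "movie_stack"))
  m <- apply(stack$data, 3, mean)
  scale <- m / m[1]
  scale[scale <= 0] <- 1
  out <- stack
  out$data <- sweep(stack$data, 3, scale, "/")
  attr(out, "bleach_scale") <- scale
  out
}

#' Subtract an event-free composite baseline
#'
#' Builds a per-pixel baseline from a composite of quiet frames (frames with
#' no synaptic release) and subtracts it from every frame, leaving only the
#' event-driven fluorescence transients. Output may be negative (kept, not
#' clipped). With `quiet_frames = "auto"` the `k_frames` frames of lowest
#' total intensity are used, after excluding dropout frames whose total
#' intensity falls below half the median frame's.
#'
#' @param stack a [movie_stack()].
#' @param quiet_frames frame indices to average, or `"auto"`.
#' @param k_frames number of frames in the composite under `"auto"`
#'   (default 5, matching the 5-6 image composites used in practice).
#' @return the baseline-subtracted stack; chosen frames are recorded in
#'   attribute `quiet_frames` and the composite in attribute `baseline`.
#' @export
subtract_baseline <- function(stack, quiet_frames = "auto", k_frames = 5L) {
  stopifnot(inherits(stack, "movie_stack"))
  nf <- n_frames(stack)
  if (identical(quiet_frames, "auto")) {
    if (k_frames < 1) stopf("k_frames must be >= 1")
    tot <- apply(stack$data, 3, sum)
    floor_ok <- tot >= 0.5 * stats::median(tot)
    cand <- which(floor_ok)
    if (length(cand) < k_frames)
      stopf("only %d usable quiet frames available, need %d",
            length(cand), k_frames)
    quiet_frames <- cand[order(tot[cand])][seq_len(k_frames)]
  } else {
    quiet_frames <- as.integer(quiet_frames)
    if (!length(quiet_frames) || any(quiet_frames < 1 | quiet_frames > nf))
      stopf("quiet_frames out of range")
  }
  comp <- apply(stack$data[, , quiet_frames, drop = FALSE], c(1, 2), mean)
  out <- stack
  out$data <- sweep(stack$data, c(1, 2), comp, "-")
  attr(out, "quiet_frames") <- quiet_frames
  attr(out, "baseline") <- comp
  out
}

#' Run the standard preprocessing chain
#'
#' Applies, in order: Gaussian filtering, drift correction, bleach
#' normalisation, and quiet-frame baseline subtraction - the conditioning
#' applied to raw quantal-imaging stacks before event detection.
#'
#' @param stack a [movie_stack()].
#' @param sigma_px filter sigma (0 disables).
#' @param register logical; estimate and correct drift.
#' @param upsample subpixel factor for registration.
#' @param k_frames quiet-frame composite size.
#' @param debleach logical; normalise photobleaching (default TRUE).
#' @param apply_mode,crop_px registration controls (see [correct_drift()]).
#' @return list with `stack` (conditioned movie), `shifts` (or NULL), and
#'   `quiet_frames`.
#' @export
preprocess_stack <- function(stack, sigma_px = 1, register = TRUE,
                             upsample = 10L, k_frames = 5L,
                             debleach = TRUE,
                             apply_mode = "bilinear", crop_px = 256L) {
  stopifnot(inherits(stack, "movie_stack"))
  st <- gaussian_filter_stack(stack, sigma_px)
  shifts <- NULL
  if (register && n_frames(st) >= 2) {
    reg <- correct_drift(st, upsample = upsample, crop_px = crop_px,
                         apply_mode = apply_mode)
    st <- reg$stack
    shifts <- reg$shifts
    rm(reg)
  }
  gc(FALSE)   # large stacks: release superseded copies promptly
  if (debleach) st <- correct_bleach(st)
  gc(FALSE)
  st <- subtract_baseline(st, "auto", k_frames = k_frames)
  list(stack = st, shifts = shifts,
       quiet_frames = attr(st, "quiet_frames"))
}
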