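# Internal helpers shared across modules.

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Squared Euclidean distance matrix between two 2-column position matrices.
#' @noRd
pairwise_dist <- function(a, b = a) {
  da <- outer(a[, 1], b[, 1], "-")
  db <- outer(a[, 2], b[, 2], "-")
  sqrt(da * da + db * db)
}

# Adjusted Fisher-Pearson skewness (the b1 estimator with the small-sample
# correction factor sqrt(n(n-1))/(n-2)).
#' @noRd
skewness_adj <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3) return(NA_real_)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  g1 <- m3 / m2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

# Bilinear interpolation of matrix `img` at (row, col) positions given in
# pixel units where (1, 1) is the centre of the top-left pixel. Out-of-range
# samples are clamped to the edge.
#' @noRd
interp_bilinear <- function(img, r, c) {
  nr <- nrow(img); nc <- ncol(img)
  r <- pmin(pmax(r, 1), nr)
  c <- pmin(pmax(c, 1), nc)
  r0 <- pmin(floor(r), nr - 1L); c0 <- pmin(floor(c), nc - 1L)
  fr <- r - r0; fc <- c - c0
  img[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    img[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    img[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    img[cbind(r0 + 1, c0 + 1)] * fr * fc
}

# Micron position -> pixel index (centre of pixel i is at (i - 0.5) * px).
#' @noRd
um_to_px <- function(u, pixel_size_um) u / pixel_size_um + 0.5

#' @noRd
px_to_um <- function(p, pixel_size_um) (p - 0.5) * pixel_size_um

# Draw an isotropic Gaussian punctum of peak `amp` at micron position
# (x_um, y_um) onto matrix `img` (rows = y, cols = x), in place via return.
# Stamps only a local window of +/- 4 sigma for speed.
#' @noRd
stamp_gaussian <- function(img, x_um, y_um, amp, sigma_um, pixel_size_um) {
  sig_px <- sigma_um / pixel_size_um
  cx <- um_to_px(x_um, pixel_size_um)
  cy <- um_to_px(y_um, pixel_size_um)
  hw <- ceiling(4 * sig_px)
  r0 <- max(1L, floor(cy) - hw); r1 <- min(nrow(img), floor(cy) + hw)
  c0 <- max(1L, floor(cx) - hw); c1 <- min(ncol(img), floor(cx) + hw)
  if (r0 > r1 || c0 > c1) return(img)
  rr <- r0:r1; cc <- c0:c1
  ky <- exp(-((rr - cy)^2) / (2 * sig_px^2))
  kx <- exp(-((cc - cx)^2) / (2 * sig_px^2))
  img[rr, cc] <- img[rr, cc] + amp * (ky %o% kx)
  img
}

# Robust SD via the median absolute deviation, scaled for the normal.
#' @noRd
mad_sd <- function(x) stats::median(abs(x - stats::median(x))) * 1.4826

#' @noRd
stopf <- function(...) stop(sprintf(...), call. = FALSE)

#' @noRd
warnf <- function(...) warning(sprintf(...), call. = FALSE)
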