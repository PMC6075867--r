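#' Construct a movie stack
#'
#' Lightweight container for a time-lapse fluorescence recording: a numeric
#' array of dimension rows x cols x frames plus its frame interval, pixel
#' size, and optional stimulus train.
#'
#' @param data numeric array (rows x cols x frames) or a matrix (one frame).
#' @param frame_interval_s frame interval in seconds (> 0).
#' @param pixel_size_um pixel size in um (> 0).
#' @param stim_times_s optional stimulus onset times (seconds); must lie
#'   within the recording.
#' @return object of class `movie_stack`.
#' @export
movie_stack <- function(data, frame_interval_s, pixel_size_um,
                        stim_times_s = NULL) {
  if (is.matrix(data)) data <- array(data, c(dim(data), 1L))
  if (length(dim(data)) != 3L) stopf("data must be rows x cols x frames")
  if (dim(data)[3] < 1L) stopf("movie must have >= 1 frame")
  if (frame_interval_s <= 0 || pixel_size_um <= 0)
    stopf("frame interval and pixel size must be positive")
  dur <- dim(data)[3] * frame_interval_s
  if (!is.null(stim_times_s) && length(stim_times_s) &&
      (min(stim_times_s) < 0 || max(stim_times_s) > dur))
    stopf("stimulus times must lie within the recording (0..%.2f s)", dur)
  structure(list(data = data, frame_interval_s = frame_interval_s,
                 pixel_size_um = pixel_size_um,
                 stim_times_s = stim_times_s),
            class = "movie_stack")
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("movie_stack: %d x %d px, %d frames (%.2f s at %.3f s/frame, %.3f um/px)\n",
              d[1], d[2], d[3], d[3] * x$frame_interval_s,
              x$frame_interval_s, x$pixel_size_um))
  if (length(x$stim_times_s))
    cat("  stimuli:", length(x$stim_times_s), "\n")
  invisible(x)
}

#' @export
dim.movie_stack <- function(x) dim(x$data)

#' Number of frames in a movie stack
#' @param stack a `movie_stack`.
#' @return integer frame count.
#' @export
n_frames <- function(stack) dim(stack$data)[3]

#' Frame mid-exposure times
#' @param stack a `movie_stack`.
#' @return numeric vector: frame f covers `[(f-1), f] * frame_interval_s`;
#'   returned times are the interval starts, so an event at time t falls in
#'   frame `floor(t / frame_interval_s) + 1`.
#' @export
frame_times <- function(stack)
  (seq_len(n_frames(stack)) - 1) * stack$frame_interval_s

#' Read / write multi-page grayscale TIFF movies
#'
#' Frame order is time. Intensities are stored as 32-bit float TIFF scaled
#' to \[0, 1\]; the affine scale, frame interval, pixel size and stimulus
#' train are kept in a JSON sidecar (`<path>.json`) so the round trip
#' reproduces the stack to single-float precision with full metadata.
#'
#' @param stack a `movie_stack`.
#' @param path file path (`.tif`).
#' @rdname movie_tiff
#' @return `write_movie_tiff` returns `path` invisibly; `read_movie_tiff`
#'   returns a `movie_stack`.
#' @export
write_movie_tiff <- function(stack, path) {
  lo <- min(stack$data)
  hi <- max(stack$data)
  scale <- if (hi > lo) hi - lo else 1
  frames <- lapply(seq_len(n_frames(stack)),
                   function(f) (stack$data[, , f] - lo) / scale)
  tiff::writeTIFF(frames, path, bits.per.sample = 32L,
                  reduce = FALSE, compression = "none")
  jsonlite::write_json(
    list(offset = lo, scale = scale,
         frame_interval_s = stack$frame_interval_s,
         pixel_size_um = stack$pixel_size_um,
         stim_times_s = stack$stim_times_s),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @param frame_interval_s,pixel_size_um,stim_times_s metadata overrides;
#'   taken from the JSON sidecar when present.
#' @rdname movie_tiff
#' @export
read_movie_tiff <- function(path, frame_interval_s = NULL,
                            pixel_size_um = NULL, stim_times_s = NULL) {
  meta <- list(offset = 0, scale = 1)
  side <- paste0(path, ".json")
  if (file.exists(side))
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  frame_interval_s <- frame_interval_s %||% meta$frame_interval_s
  pixel_size_um <- pixel_size_um %||% meta$pixel_size_um
  stim_times_s <- stim_times_s %||% meta$stim_times_s
  if (is.null(frame_interval_s) || is.null(pixel_size_um))
    stopf("no sidecar metadata: frame_interval_s and pixel_size_um required")
  frames <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(frames)) frames <- list(frames)
  arr <- array(0, c(dim(frames[[1]])[1:2], length(frames)))
  for (f in seq_along(frames)) {
    fr <- frames[[f]]
    if (length(dim(fr)) == 3L) fr <- fr[, , 1]
    arr[, , f] <- fr * meta$scale + meta$offset
  }
  movie_stack(arr, frame_interval_s, pixel_size_um, stim_times_s)
}
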