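# Coarse rPPG extraction: ROI green-channel spatial mean.

#' Green-channel spatial mean over an ROI
#'
#' Computes, for every frame, the arithmetic mean of the green-channel
#' intensities of the pixels selected by `mask`:
#' `trace[t] = (1/N) * sum_i I_i(t)` with `N` the (time-constant) number of
#' masked pixels.  This is the coarse rPPG signal every later stage refines.
#'
#' @param frames numeric array `(h, w, 3, n_frames)` (see
#'   [render_palm_video()] / [read_frame_dir()]), or `(h, w, 3)` for a single
#'   frame.
#' @param mask logical matrix `(h, w)`; `TRUE` marks ROI pixels.  A list of
#'   `n_frames` masks is accepted for per-frame ROIs, though a static mask is
#'   the default analysis path.
#' @param fs sampling rate attached to the returned trace (default 100 Hz).
#' @return a `raw_trace` of length `n_frames`.
#' @export
green_channel_mean <- function(frames, mask, fs = 100) {
  if (length(dim(frames)) == 3L) {
    frames <- array(frames, dim = c(dim(frames), 1L))
  }
  d <- dim(frames)
  if (length(d) != 4L || d[3] < 2L) {
    stopf("`frames` must be an (h, w, 3, n) array with a green channel")
  }
  n <- d[4]
  per_frame <- is.list(mask)
  if (per_frame) {
    if (length(mask) != n) stopf("need one mask per frame (%d)", n)
    masks <- mask
  } else {
    masks <- NULL
  }
  check_mask <- function(m) {
    if (!is.logical(m)) m <- m != 0
    if (!identical(dim(m), d[1:2])) {
      stopf("mask shape (%s) does not match frames (%s)",
            paste(dim(m), collapse = "x"), paste(d[1:2], collapse = "x"))
    }
    if (!any(m)) stopf("empty ROI mask: no pixels selected")
    m
  }
  green <- matrix(frames[, , 2, ], nrow = d[1] * d[2], ncol = n)
  if (per_frame) {
    out <- vapply(seq_len(n), function(t) {
      m <- check_mask(masks[[t]])
      mean(green[as.vector(m), t])
    }, numeric(1))
  } else {
    m <- check_mask(mask)
    out <- colMeans(green[as.vector(m), , drop = FALSE])
  }
  new_raw_trace(out, fs)
}

#' Threshold-based palm ROI mask
#'
#' Selects the pixels whose green intensity strictly exceeds the given
#' quantile of the frame's green-channel values.  This is a deliberately
#' simple stand-in for a learned palm-segmentation model: under the package's
#' recording geometry the palm is the bright region of the scene.
#'
#' @param frame numeric array `(h, w, 3)` (or `(h, w, 3, 1)`).
#' @param percentile quantile in (0, 1); default 0.5.
#' @return logical matrix `(h, w)`.
#' @export
threshold_mask <- function(frame, percentile = 0.5) {
  if (length(dim(frame)) == 4L) frame <- frame[, , , 1]
  if (length(dim(frame)) != 3L) stopf("`frame` must be an (h, w, 3) array")
  check_scalar(percentile, "percentile")
  if (percentile <= 0 || percentile >= 1) {
    stopf("percentile must lie strictly inside (0, 1)")
  }
  g <- frame[, , 2]
  thr <- quantile(as.vector(g), percentile, names = FALSE)
  mask <- g > thr
  if (!any(mask)) {
    stopf("threshold_mask produced an empty mask (flat frame?)")
  }
  mask
}

#' Read an ROI mask image
#'
#' Nonzero pixels mark the ROI.  Accepts ASCII PGM/PPM, or PNG when the
#' `png` package is installed.
#'
#' @param path image file path.
#' @return logical matrix.
#' @export
read_mask <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (!requireNamespace("png", quietly = TRUE)) {
      stopf("reading PNG masks requires the 'png' package")
    }
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) img <- img[, , 1]
    return(img > 0)
  }
  fr <- read_ppm_frame(path)
  fr[, , 1] > 0
}
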