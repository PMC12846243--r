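# Palm-like video synthesis and frame-stack I/O.
#
# Frames are held as a numeric array of dimension (height, width, 3, n_frames)
# with values on the 0-255 sensor scale (channel order R, G, B).  Only the
# green channel is pulse-modulated, matching how the camera sees pulsatile
# blood volume under 532 nm illumination.

#' Video rendering parameters
#'
#' @param height,width frame size in pixels.
#' @param fps frame rate, Hz; must equal the paired PPG sampling rate.
#' @param base_green mean green intensity of the palm region (0-255).
#' @param modulation_depth fractional green-channel modulation per unit of
#'   normalized pulse amplitude, in \[0, 0.2\].
#' @param pixel_noise_sigma per-pixel additive Gaussian noise std.
#' @param jitter_px maximum integer translational jitter per frame, pixels.
#' @return an object of class `video_render_params`.
#' @export
video_render_params <- function(height = 24, width = 24, fps = 100,
                                base_green = 120, modulation_depth = 0.05,
                                pixel_noise_sigma = 0, jitter_px = 0) {
  check_scalar(height, "height", 2)
  check_scalar(width, "width", 2)
  check_scalar(fps, "fps", 1)
  check_scalar(base_green, "base_green", 1, 255)
  check_scalar(modulation_depth, "modulation_depth", 0, 0.2)
  check_scalar(pixel_noise_sigma, "pixel_noise_sigma", 0)
  check_scalar(jitter_px, "jitter_px", 0)
  structure(list(height = as.integer(height), width = as.integer(width),
                 fps = fps, base_green = base_green,
                 modulation_depth = modulation_depth,
                 pixel_noise_sigma = pixel_noise_sigma,
                 jitter_px = as.integer(jitter_px)),
            class = "video_render_params")
}

#' Render a palm-like video from a clean pulse
#'
#' The green channel of every frame is `base_green * (1 + modulation_depth *
#' s(t))` plus optional per-pixel noise, where `s(t)` is the pulse normalized
#' to \[-1, 1\]; a smooth radial palm-brightness profile modulates the scene
#' spatially, and optional integer jitter translates it frame to frame.  Red
#' and blue channels are static.
#'
#' @param clean an `annotated_pulse`.
#' @param vparams a [video_render_params()]; `fps` must equal `clean$fs`.
#' @param seed integer RNG seed.
#' @return numeric array `(height, width, 3, n_frames)` on the 0-255 scale.
#' @export
render_palm_video <- function(clean, vparams = video_render_params(),
                              seed = 1) {
  stopifnot(inherits(clean, "annotated_pulse"),
            inherits(vparams, "video_render_params"))
  if (abs(vparams$fps - clean$fs) > 1e-9) {
    stopf("vparams$fps (%g) must equal the pulse sampling rate (%g)",
          vparams$fps, clean$fs)
  }
  n <- length(clean$samples)
  h <- vparams$height
  w <- vparams$width
  s <- minmax01(clean$samples) * 2 - 1        # normalized to [-1, 1]
  # static radial profile: brighter palm center, dimmer edges (+-10%)
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  r2 <- ((yy - (h + 1) / 2) / h)^2 + ((xx - (w + 1) / 2) / w)^2
  profile <- 1 + 0.1 * (1 - 2 * r2 / max(r2))
  frames <- array(0, dim = c(h, w, 3, n))
  with_local_seed(seed, {
    jit <- if (vparams$jitter_px > 0) {
      cbind(sample(-vparams$jitter_px:vparams$jitter_px, n, replace = TRUE),
            sample(-vparams$jitter_px:vparams$jitter_px, n, replace = TRUE))
    } else {
      matrix(0L, n, 2)
    }
    red <- pmin(255, pmax(0, 0.6 * vparams$base_green * profile))
    blue <- pmin(255, pmax(0, 0.4 * vparams$base_green * profile))
    for (t in seq_len(n)) {
      prof_t <- if (any(jit[t, ] != 0)) {
        shift_matrix(profile, jit[t, 1], jit[t, 2])
      } else {
        profile
      }
      g <- vparams$base_green * (1 + vparams$modulation_depth * s[t]) * prof_t
      if (vparams$pixel_noise_sigma > 0) {
        g <- g + matrix(rnorm(h * w, 0, vparams$pixel_noise_sigma), h, w)
      }
      frames[, , 1, t] <- red
      frames[, , 2, t] <- pmin(255, pmax(0, g))
      frames[, , 3, t] <- blue
    }
  })
  frames
}

# integer circular shift of a matrix (edge wrap keeps the mean stable)
shift_matrix <- function(m, dy, dx) {
  h <- nrow(m); w <- ncol(m)
  m[((seq_len(h) - 1 - dy) %% h) + 1, ((seq_len(w) - 1 - dx) %% w) + 1]
}

#' Write a frame stack as ASCII PPM (P3) files
#'
#' One file per frame, `frame_000001.ppm` etc.  ASCII PPM is plain text and
#' needs no image library; [read_frame_dir()] reads it back.
#'
#' @param frames array `(h, w, 3, n)` on the 0-255 scale.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_frame_dir <- function(frames, dir) {
  stopifnot(length(dim(frames)) == 4L, dim(frames)[3] == 3L)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  n <- dim(frames)[4]
  h <- dim(frames)[1]; w <- dim(frames)[2]
  for (t in seq_len(n)) {
    path <- file.path(dir, sprintf("frame_%06d.ppm", t))
    fr <- round(frames[, , , t])
    # PPM is row-major: R G B per pixel, rows top to bottom
    inter <- rbind(as.vector(t(fr[, , 1])), as.vector(t(fr[, , 2])),
                   as.vector(t(fr[, , 3])))
    writeLines(c("P3", sprintf("%d %d", w, h), "255",
                 paste(as.integer(inter), collapse = " ")), path)
  }
  invisible(dir)
}

read_ppm_frame <- function(path) {
  toks <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  if (toks[1] != "P3" && toks[1] != "P2") {
    stopf("'%s' is not an ASCII PPM/PGM (P3/P2) file", path)
  }
  w <- as.integer(toks[2]); h <- as.integer(toks[3])
  vals <- as.numeric(toks[-(1:4)])
  if (toks[1] == "P2") {
    g <- matrix(vals, h, w, byrow = TRUE)
    fr <- array(0, c(h, w, 3))
    fr[, , 1] <- g; fr[, , 2] <- g; fr[, , 3] <- g
    return(fr)
  }
  m <- matrix(vals, nrow = 3)
  fr <- array(0, c(h, w, 3))
  for (ch in 1:3) fr[, , ch] <- matrix(m[ch, ], h, w, byrow = TRUE)
  fr
}

#' Read a directory of frames into a frame stack
#'
#' Supports ASCII PPM/PGM (`.ppm`/`.pgm`) always, and PNG when the `png`
#' package is installed.  Files are read in lexicographic order.
#'
#' @param dir directory of frame files.
#' @return numeric array `(h, w, 3, n)` on the 0-255 scale.
#' @export
read_frame_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.(ppm|pgm|png)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (length(files) == 0L) stopf("no frame files found in '%s'", dir)
  read_one <- function(f) {
    if (grepl("\\.png$", f, ignore.case = TRUE)) {
      if (!requireNamespace("png", quietly = TRUE)) {
        stopf("reading PNG frames requires the 'png' package")
      }
      img <- png::readPNG(f) * 255
      if (length(dim(img)) == 2L) {
        fr <- array(0, c(dim(img), 3))
        for (ch in 1:3) fr[, , ch] <- img
        fr
      } else {
        img[, , 1:3, drop = FALSE]
      }
    } else {
      read_ppm_frame(f)
    }
  }
  first <- read_one(files[1])
  frames <- array(0, dim = c(dim(first)[1:2], 3, length(files)))
  frames[, , , 1] <- first
  if (length(files) > 1L) {
    for (i in 2:length(files)) frames[, , , i] <- read_one(files[i])
  }
  frames
}
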