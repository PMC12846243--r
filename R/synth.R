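# Synthetic paired palm-video / PPG generator.
#
# The generator states a small "world": 20 s records sampled at 100 Hz,
# quasi-periodic pulse waves carrying the five classical morphology fiducials
# (cycle-start valley, systolic peak, dicrotic notch, second peak), beat-to-
# beat interval variability, and the nuisance terms a palm recording picks up
# (white sensor noise, slow baseline drift, illumination flicker, mild
# motion-induced amplitude modulation).

#' Pulse-shape model parameters
#'
#' Describes one cardiac-cycle template.  The beat is built from monotone
#' cubic segments through five knots: the cycle-start valley (amplitude 0),
#' the systolic peak (`systolic_amp`), the dicrotic notch
#' (`second_peak_amp - notch_depth`, floored at 0), the second (diastolic)
#' peak (`second_peak_amp`) and the end-of-cycle valley (0).  Monotone
#' (Fritsch-Carlson) interpolation guarantees the knots are the only local
#' extrema, so the fiducials are exact by construction.
#'
#' @param heart_rate_bpm mean heart rate, beats/min, in \[40, 180\].
#' @param hrv_cv coefficient of variation of the beat-to-beat interval
#'   (dimensionless, >= 0).  Intervals are i.i.d. lognormal.
#' @param systolic_amp main (systolic) peak amplitude; the waveform's
#'   amplitude unit (default 1).
#' @param notch_depth drop of the dicrotic notch below the second peak, in
#'   amplitude units.  0 gives a notch-free shoulder.
#' @param second_peak_amp second (diastolic) peak amplitude; must satisfy
#'   `0 <= second_peak_amp < systolic_amp`.
#' @param systolic_width_s time from the cycle-start valley to the systolic
#'   peak (the rise time), seconds.
#' @param diastolic_width_s time from the dicrotic notch to the second peak,
#'   seconds.
#' @param notch_delay_s time from the systolic peak to the dicrotic notch,
#'   seconds.
#' @return an object of class `pulse_model_params`.
#' @export
pulse_model_params <- function(heart_rate_bpm = 72,
                               hrv_cv = 0.04,
                               systolic_amp = 1,
                               notch_depth = 0.15,
                               second_peak_amp = 0.5,
                               systolic_width_s = 0.18,
                               diastolic_width_s = 0.12,
                               notch_delay_s = 0.22) {
  check_scalar(heart_rate_bpm, "heart_rate_bpm", 40, 180)
  check_scalar(hrv_cv, "hrv_cv", 0)
  check_scalar(systolic_amp, "systolic_amp", 1e-9)
  check_scalar(notch_depth, "notch_depth", 0)
  check_scalar(second_peak_amp, "second_peak_amp", 0)
  if (second_peak_amp >= systolic_amp) {
    stopf("second_peak_amp must be < systolic_amp")
  }
  check_scalar(systolic_width_s, "systolic_width_s", 1e-6)
  check_scalar(diastolic_width_s, "diastolic_width_s", 1e-6)
  check_scalar(notch_delay_s, "notch_delay_s", 1e-6)
  structure(list(heart_rate_bpm = heart_rate_bpm, hrv_cv = hrv_cv,
                 systolic_amp = systolic_amp, notch_depth = notch_depth,
                 second_peak_amp = second_peak_amp,
                 systolic_width_s = systolic_width_s,
                 diastolic_width_s = diastolic_width_s,
                 notch_delay_s = notch_delay_s),
            class = "pulse_model_params")
}

#' Nuisance/noise model parameters
#'
#' Additive and multiplicative corruptions applied by [corrupt_signal()]:
#' `out = clean * (1 + AM) + sinusoidal drift + random-walk drift +
#' illumination flicker + white noise`.
#'
#' @param white_sigma additive Gaussian noise std, signal units.
#' @param drift_amp,drift_freq_hz baseline-drift sinusoid amplitude and
#'   frequency; `drift_freq_hz` must stay below 0.5 Hz (sub-cardiac).
#' @param drift_walk_sigma per-sample std of a Gaussian random-walk drift.
#' @param flicker_amp,flicker_freq_hz illumination flicker sinusoid; the
#'   frequency must lie outside the 0.7-3 Hz cardiac band.
#' @param am_depth depth of a slow (0.05 Hz) amplitude modulation emulating
#'   mild motion, dimensionless.
#' @return an object of class `noise_params`.
#' @export
noise_params <- function(white_sigma = 0.15,
                         drift_amp = 0.5,
                         drift_freq_hz = 0.1,
                         drift_walk_sigma = 0,
                         flicker_amp = 0.1,
                         flicker_freq_hz = 4,
                         am_depth = 0.1) {
  for (nm in c("white_sigma", "drift_amp", "drift_freq_hz",
               "drift_walk_sigma", "flicker_amp", "flicker_freq_hz",
               "am_depth")) {
    check_scalar(get(nm), nm, 0)
  }
  if (drift_freq_hz >= 0.5) stopf("drift_freq_hz must be < 0.5 Hz")
  if (flicker_amp > 0 && flicker_freq_hz >= 0.7 && flicker_freq_hz <= 3.0) {
    stopf("flicker_freq_hz must lie outside the cardiac band [0.7, 3] Hz")
  }
  structure(list(white_sigma = white_sigma, drift_amp = drift_amp,
                 drift_freq_hz = drift_freq_hz,
                 drift_walk_sigma = drift_walk_sigma,
                 flicker_amp = flicker_amp, flicker_freq_hz = flicker_freq_hz,
                 am_depth = am_depth),
            class = "noise_params")
}

#' Zero-noise parameter set
#' @return a `noise_params` with every term 0.
#' @export
noise_params_none <- function() {
  noise_params(white_sigma = 0, drift_amp = 0, drift_freq_hz = 0,
               drift_walk_sigma = 0, flicker_amp = 0, flicker_freq_hz = 0,
               am_depth = 0)
}

# Knot times/values of one beat of length T_beat.  Times are compressed
# proportionally when the template is too long for a short beat (the decay
# back to the valley must keep at least 10% of the beat).
beat_knots <- function(p, T_beat) {
  t_sys <- p$systolic_width_s
  t_notch <- t_sys + p$notch_delay_s
  t_sp <- t_notch + p$diastolic_width_s
  scale <- min(1, 0.9 * T_beat / t_sp)
  tt <- c(0, t_sys, t_notch, t_sp) * scale
  h_notch <- max(0, p$second_peak_amp - p$notch_depth)
  vv <- c(0, p$systolic_amp, h_notch, p$second_peak_amp)
  # collapse duplicate times (degenerate widths after scaling)
  keep <- c(TRUE, diff(tt) > 1e-9)
  list(t = c(tt[keep], T_beat), v = c(vv[keep], 0))
}

# Evaluate one beat: piecewise cubic Hermite with zero derivative at every
# knot (smoothstep segments).  Monotone between knots, so the knots are the
# beat's only extrema — the recorded fiducials are exact by construction.
beat_eval <- function(kn, tl) {
  seg <- findInterval(tl, kn$t, rightmost.closed = TRUE)
  seg[seg < 1L] <- 1L
  seg[seg >= length(kn$t)] <- length(kn$t) - 1L
  t0 <- kn$t[seg]
  t1 <- kn$t[seg + 1L]
  y0 <- kn$v[seg]
  y1 <- kn$v[seg + 1L]
  s <- (tl - t0) / (t1 - t0)
  s[s < 0] <- 0
  s[s > 1] <- 1
  y0 + (y1 - y0) * s * s * (3 - 2 * s)
}

#' Generate a clean annotated PPG signal
#'
#' Builds a quasi-periodic pulse wave beat by beat.  Beat intervals are drawn
#' i.i.d. lognormal with mean `60/heart_rate_bpm` seconds and coefficient of
#' variation `params$hrv_cv`; each beat is a monotone-cubic curve through the
#' template knots of [pulse_model_params()].  Fiducials (cycle-start valley,
#' systolic peak, dicrotic notch, second peak) are recorded from the knots as
#' generated, not re-detected from the samples.
#'
#' @param params a [pulse_model_params()].
#' @param duration_s record length in seconds; must cover at least one full
#'   cycle at the stated heart rate (the spec demands >= 2 cycles for
#'   meaningful downstream use; 20 s is the stated world).
#' @param fs sampling rate in Hz, >= 25.
#' @param seed integer RNG seed; the output is a pure function of
#'   `(params, duration_s, fs, seed)`.
#' @return an object of class `annotated_pulse`: list with `samples`, `fs`,
#'   and `fiducials`, a data.frame with columns `cycle`, `valley`, `systolic`,
#'   `notch`, `second_peak` (1-based sample indices; `NA` when the shape has
#'   no notch/second peak, and for truncated trailing cycles).
#' @export
generate_clean_ppg <- function(params = pulse_model_params(),
                               duration_s = 20, fs = 100, seed = 1) {
  stopifnot(inherits(params, "pulse_model_params"))
  check_scalar(fs, "fs", 25)
  mean_T <- 60 / params$heart_rate_bpm
  if (duration_s < 2 * mean_T) {
    stopf("duration_s = %g covers fewer than two cycles at %g bpm",
          duration_s, params$heart_rate_bpm)
  }
  n <- round(duration_s * fs)
  with_local_seed(seed, {
    # beat intervals: lognormal with stated mean and CV
    n_beats_max <- ceiling(duration_s / mean_T * (1 + 6 * params$hrv_cv)) + 3L
    if (params$hrv_cv > 0) {
      sdlog <- sqrt(log(1 + params$hrv_cv^2))
      meanlog <- log(mean_T) - sdlog^2 / 2
      intervals <- rlnorm(n_beats_max, meanlog, sdlog)
    } else {
      intervals <- rep(mean_T, n_beats_max)
    }
    starts <- cumsum(c(0, intervals))
    starts <- starts[starts < duration_s]
    x <- numeric(n)
    tgrid <- (seq_len(n) - 1) / fs
    has_notch <- params$notch_depth > 0 && params$second_peak_amp > 0 &&
      params$second_peak_amp - params$notch_depth < params$second_peak_amp
    fid <- vector("list", length(starts))
    for (b in seq_along(starts)) {
      t0 <- starts[b]
      T_beat <- if (b < length(starts)) starts[b + 1] - t0 else
        intervals[length(starts)]
      kn <- beat_knots(params, T_beat)
      i0 <- ceiling(t0 * fs - 1e-9) + 1L        # first sample index in beat
      i1 <- min(n, floor((t0 + T_beat) * fs - 1e-9) + 1L)
      if (i0 > n) break
      idx <- i0:i1
      tl <- tgrid[idx] - t0
      tl[tl < 0] <- 0
      tl[tl > T_beat] <- T_beat
      x[idx] <- beat_eval(kn, tl)
      complete <- (t0 + T_beat) * fs <= n - 1 + 1e-9
      knot_idx <- function(tk) {
        j <- round((t0 + tk) * fs) + 1L
        if (j < 1L || j > n) NA_integer_ else j
      }
      sys_i <- knot_idx(kn$t[2])
      # snap the systolic fiducial to the larger of the two samples
      # bracketing the analytic peak, so it is a local max of the samples
      if (!is.na(sys_i)) {
        cand <- intersect((sys_i - 1L):(sys_i + 1L), idx)
        sys_i <- cand[which.max(x[cand])]
      }
      nn <- length(kn$t)
      fid[[b]] <- data.frame(
        cycle = b,
        valley = knot_idx(0),
        systolic = if (complete || (t0 + kn$t[2]) * fs <= n - 1) sys_i
                   else NA_integer_,
        notch = if (has_notch && nn >= 5L) knot_idx(kn$t[3]) else NA_integer_,
        second_peak = if (has_notch && nn >= 5L) knot_idx(kn$t[4])
                      else NA_integer_)
      if (!complete) {
        fid[[b]]$notch <- NA_integer_
        fid[[b]]$second_peak <- NA_integer_
      }
    }
    fiducials <- do.call(rbind, fid)
    structure(list(samples = x, fs = fs, fiducials = fiducials,
                   params = params, duration_s = duration_s, seed = seed),
              class = "annotated_pulse")
  })
}

#' @export
print.annotated_pulse <- function(x, ...) {
  cat(sprintf("<annotated_pulse> %d samples @ %g Hz, %d cycles\n",
              length(x$samples), x$fs, nrow(x$fiducials)))
  invisible(x)
}

#' Corrupt a clean pulse into a coarse rPPG-like trace
#'
#' Applies `out = clean * (1 + AM) + drift + flicker + white noise`, the
#' degradations a palm-video green-channel trace accumulates from
#' illumination fluctuation and mild physiological motion.  Length and
#' sampling rate are preserved.
#'
#' @param clean an `annotated_pulse` (or `raw_trace`).
#' @param noise a [noise_params()].
#' @param seed integer RNG seed.
#' @return a `raw_trace`.
#' @export
corrupt_signal <- function(clean, noise = noise_params(), seed = 1) {
  stopifnot(inherits(noise, "noise_params"))
  x <- trace_samples(clean)
  fs <- trace_fs(clean)
  if (length(x) == 0L) stopf("`clean` is empty")
  n <- length(x)
  t <- (seq_len(n) - 1) / fs
  with_local_seed(seed, {
    am <- if (noise$am_depth > 0) {
      noise$am_depth * sin(2 * pi * 0.05 * t + runif(1, 0, 2 * pi))
    } else 0
    drift <- 0
    if (noise$drift_amp > 0) {
      drift <- drift + noise$drift_amp *
        sin(2 * pi * noise$drift_freq_hz * t + runif(1, 0, 2 * pi))
    }
    if (noise$drift_walk_sigma > 0) {
      drift <- drift + cumsum(rnorm(n, 0, noise$drift_walk_sigma))
    }
    flicker <- if (noise$flicker_amp > 0) {
      noise$flicker_amp *
        sin(2 * pi * noise$flicker_freq_hz * t + runif(1, 0, 2 * pi))
    } else 0
    white <- if (noise$white_sigma > 0) rnorm(n, 0, noise$white_sigma) else 0
    new_raw_trace(x * (1 + am) + drift + flicker + white, fs)
  })
}
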