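# Fiducial-point detection: cycle-start valleys, systolic peaks, dicrotic
# notch and second (diastolic) peak.

#' Detect cycle-start valleys
#'
#' Finds local minima, ranks them by topographic prominence (of the inverted
#' signal) and greedily keeps the most prominent ones subject to a 0.4 s
#' refractory separation — one valley per cardiac cycle for heart rates up
#' to 150 bpm.  Minima with prominence below 10% of the signal range, or
#' below half the largest candidate prominence, are ignored: the latter rule
#' separates true cycle-start valleys (full-swing prominence) from dicrotic
#' notches (whose prominence is only the notch depth).
#'
#' @param signal numeric vector (or a trace object), >= 2 s long.
#' @param fs sampling rate, Hz.
#' @param refractory_s minimum valley separation in seconds (default 0.4).
#' @param min_prominence_frac prominence floor as a fraction of the signal
#'   range (default 0.1).
#' @return increasing integer vector of valley indices (possibly empty).
#' @export
detect_valleys <- function(signal, fs = NULL, refractory_s = 0.4,
                           min_prominence_frac = 0.1) {
  x <- trace_samples(signal)
  fs <- trace_fs(signal, fs)
  if (length(x) < 2 * fs) stopf("signal must be at least 2 s long")
  rng <- diff(range(x))
  if (rng <= 0) return(integer(0))
  cand <- local_extrema(x)$minima
  if (length(cand) == 0L) return(integer(0))
  neg <- -x
  prom <- vapply(cand, function(i) peak_prominence(neg, i), numeric(1))
  keep_cand <- prom >= min_prominence_frac * rng &
    prom >= 0.5 * max(prom)
  cand <- cand[keep_cand]
  prom <- prom[keep_cand]
  if (length(cand) == 0L) return(integer(0))
  ord <- order(prom, decreasing = TRUE)
  sep <- refractory_s * fs
  accepted <- integer(0)
  for (i in cand[ord]) {
    if (all(abs(accepted - i) >= sep)) accepted <- c(accepted, i)
  }
  sort(accepted)
}

#' Annotate key peaks of a PPG window
#'
#' Detects, per cardiac cycle (between consecutive valleys): the systolic
#' peak (global maximum of the cycle), the dicrotic notch (most prominent
#' local minimum within a physiologic window after the systolic peak) and
#' the second peak (first local maximum after the notch).  Cycles without a
#' detectable notch carry systolic-only annotations.  Windows with no
#' quasi-periodic structure — the maximum normalized autocorrelation over
#' cardiac-plausible lags (0.33-1.5 s) below 0.3 — yield an empty
#' annotation, as do flat windows.
#'
#' @param window numeric vector (or trace object), at least one expected
#'   cycle long (>= 1 s).
#' @param fs sampling rate, Hz.
#' @param notch_window_s how far after the systolic peak the notch may lie
#'   (default 0.45 s).
#' @param acf_gate autocorrelation threshold below which the window is
#'   treated as structureless (default 0.3).
#' @return an object of class `peak_annotation`: list with `cycles` (a
#'   data.frame `cycle`, `valley`, `systolic`, `notch`, `second_peak`) and
#'   `fs`.  Empty annotation has zero rows.
#' @export
annotate_peaks <- function(window, fs = NULL, notch_window_s = 0.45,
                           acf_gate = 0.3) {
  x <- trace_samples(window)
  fs <- trace_fs(window, fs)
  if (length(x) < fs) stopf("window shorter than one expected cycle")
  empty <- structure(list(
    cycles = data.frame(cycle = integer(0), valley = integer(0),
                        systolic = integer(0), notch = integer(0),
                        second_peak = integer(0)),
    fs = fs), class = "peak_annotation")
  if (sd(x) == 0) return(empty)
  # periodicity gate: normalized autocorrelation over cardiac-scale lags
  xc <- x - mean(x)
  lags <- seq.int(max(2L, round(0.33 * fs)), min(length(x) - 2L,
                                                 round(1.5 * fs)))
  denom <- sum(xc^2)
  ac <- vapply(lags, function(l) {
    sum(xc[seq_len(length(xc) - l)] * xc[-seq_len(l)]) / denom
  }, numeric(1))
  if (max(ac) < acf_gate) return(empty)
  valleys <- detect_valleys(x, fs)
  if (length(valleys) < 2L) return(empty)
  rows <- vector("list", length(valleys) - 1L)
  for (ci in seq_len(length(valleys) - 1L)) {
    v0 <- valleys[ci]
    v1 <- valleys[ci + 1L]
    seg <- v0:v1
    sys_i <- seg[which.max(x[seg])]
    notch_i <- NA_integer_
    sp_i <- NA_integer_
    hi <- min(v1 - 1L, sys_i + round(notch_window_s * fs))
    if (hi - sys_i >= 3L) {
      sub <- x[sys_i:hi]
      mins <- local_extrema(sub)$minima
      if (length(mins)) {
        promv <- vapply(mins, function(i) peak_prominence(-sub, i),
                        numeric(1))
        notch_i <- sys_i - 1L + mins[which.max(promv)]
        # second peak: first local max after the notch, before next valley
        sub2 <- x[notch_i:(v1 - 1L)]
        maxs <- local_extrema(sub2)$maxima
        if (length(maxs)) {
          sp_i <- notch_i - 1L + maxs[1L]
        } else {
          notch_i <- NA_integer_  # a notch needs a bounding second peak
        }
      }
    }
    rows[[ci]] <- data.frame(cycle = ci, valley = v0, systolic = sys_i,
                             notch = notch_i, second_peak = sp_i)
  }
  structure(list(cycles = do.call(rbind, rows), fs = fs),
            class = "peak_annotation")
}

#' @export
print.peak_annotation <- function(x, ...) {
  cat(sprintf("<peak_annotation> %d cycles (%d with dicrotic notch)\n",
              nrow(x$cycles), sum(!is.na(x$cycles$notch))))
  invisible(x)
}
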