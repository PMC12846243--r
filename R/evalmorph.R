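# Waveform evaluation: pointwise metrics and the cycle-morphology pipeline
# (valley detection -> cycle segmentation -> quality screen -> normalization
# -> template averaging -> fiducial indices -> two-site comparison).

#' Pointwise reconstruction metrics
#'
#' MAPE is computed on signals min-max normalized to \[0, 1\] with the
#' denominator floored at `eps` (a percentage error is meaningless on raw
#' near-zero samples); RMSE, Pearson correlation and cosine similarity use
#' the signals as given.
#'
#' @param reconstructed,reference numeric vectors (or trace objects) of
#'   equal length >= 2.
#' @param eps denominator floor for MAPE (default 1e-3).
#' @return an object of class `metric_report`: list with `mape`, `rmse`,
#'   `pearson_rho`, `cosine_similarity`.
#' @export
compute_metrics <- function(reconstructed, reference, eps = 1e-3) {
  rec <- trace_samples(reconstructed)
  ref <- trace_samples(reference)
  if (length(rec) != length(ref)) {
    stopf("lengths differ (%d vs %d)", length(rec), length(ref))
  }
  if (length(ref) < 2L) stopf("need at least 2 samples")
  if (sd(ref) == 0) {
    stopf("constant reference: Pearson correlation undefined")
  }
  recn <- minmax01(rec)
  refn <- minmax01(ref)
  mape <- mean(abs(refn - recn) / pmax(abs(refn), eps))
  rmse <- sqrt(mean((ref - rec)^2))
  rho <- cor(rec, ref)
  cossim <- sum(rec * ref) / sqrt(sum(rec^2) * sum(ref^2))
  structure(list(mape = mape, rmse = rmse, pearson_rho = rho,
                 cosine_similarity = cossim),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(
    "<metric_report> MAPE %.4f | RMSE %.4f | rho %.4f | cosine %.4f\n",
    x$mape, x$rmse, x$pearson_rho, x$cosine_similarity))
  invisible(x)
}

#' Segment, screen, normalize and resample cardiac cycles
#'
#' Cycles run between consecutive valleys.  An automated quality screen
#' replaces manual inspection: a cycle is rejected when its duration
#' deviates more than `max_duration_dev` from the record's median cycle
#' duration, or when its peak-to-valley amplitude falls outside
#' `[min_amp_frac, 1/min_amp_frac]` times the median cycle amplitude (weak
#' cycles and large transients alike).  Survivors are min-max normalized to
#' \[0, 1\] and linearly resampled to `resample_len` points.
#'
#' @param signal numeric vector or trace object.
#' @param valleys valley indices from [detect_valleys()]; detected
#'   automatically when `NULL`.
#' @param fs sampling rate, Hz.
#' @param resample_len common cycle length after resampling (default 100).
#' @param max_duration_dev relative duration deviation limit (default 0.3).
#' @param min_amp_frac amplitude floor relative to the median (default 0.3).
#' @return an object of class `cycle_set`: `valleys`, `cycles` (list of
#'   normalized resampled cycles), `durations_s` (of survivors), `kept`,
#'   `rejected` (indices with reasons), `fs`, `resample_len`.
#' @export
build_cycle_set <- function(signal, valleys = NULL, fs = NULL,
                            resample_len = 100,
                            max_duration_dev = 0.3, min_amp_frac = 0.3) {
  x <- trace_samples(signal)
  fs <- trace_fs(signal, fs)
  if (is.null(valleys)) valleys <- detect_valleys(x, fs)
  if (length(valleys) < 2L) {
    stopf("need at least 2 valleys to segment cycles (got %d)",
          length(valleys))
  }
  n_cyc <- length(valleys) - 1L
  dur <- diff(valleys) / fs
  amp <- vapply(seq_len(n_cyc), function(i) {
    seg <- x[valleys[i]:valleys[i + 1L]]
    diff(range(seg))
  }, numeric(1))
  med_dur <- median(dur)
  med_amp <- median(amp)
  reasons <- character(n_cyc)
  reasons[abs(dur - med_dur) > max_duration_dev * med_dur] <- "duration"
  bad_amp <- amp < min_amp_frac * med_amp | amp > med_amp / min_amp_frac
  reasons[bad_amp] <- ifelse(nzchar(reasons[bad_amp]),
                             paste0(reasons[bad_amp], "+amplitude"),
                             "amplitude")
  keep <- !nzchar(reasons)
  if (!any(keep)) {
    stopf("all %d cycles rejected (%s)", n_cyc,
          paste(sprintf("cycle %d: %s", which(!keep), reasons[!keep]),
                collapse = "; "))
  }
  grid <- seq(0, 1, length.out = resample_len)
  cycles <- lapply(which(keep), function(i) {
    seg <- x[valleys[i]:valleys[i + 1L]]
    res <- approx(seq(0, 1, length.out = length(seg)), seg, xout = grid)$y
    minmax01(res)   # normalize after resampling so the span is exact
  })
  structure(list(valleys = valleys, cycles = cycles,
                 durations_s = dur[keep], kept = which(keep),
                 rejected = data.frame(cycle = which(!keep),
                                       reason = reasons[!keep]),
                 fs = fs, resample_len = resample_len),
            class = "cycle_set")
}

#' @export
print.cycle_set <- function(x, ...) {
  cat(sprintf("<cycle_set> %d cycles kept (%d rejected), %d points each\n",
              length(x$cycles), nrow(x$rejected), x$resample_len))
  invisible(x)
}

#' Average normalized cycle template
#'
#' Pointwise mean of the normalized, resampled cycles.
#'
#' @param cycles a `cycle_set` from [build_cycle_set()].
#' @return numeric vector of length `resample_len`, with attributes
#'   `fs_effective` (points per second of the average cycle) and
#'   `mean_duration_s`.
#' @export
average_waveform <- function(cycles) {
  stopifnot(inherits(cycles, "cycle_set"))
  if (length(cycles$cycles) == 0L) stopf("empty cycle set")
  avg <- Reduce(`+`, cycles$cycles) / length(cycles$cycles)
  attr(avg, "fs_effective") <- cycles$resample_len /
    mean(cycles$durations_s)
  attr(avg, "mean_duration_s") <- mean(cycles$durations_s)
  avg
}

#' Morphology indices of an averaged cycle
#'
#' Measures, on a \[0, 1\]-normalized cycle: rise time `t1` (cycle start to
#' main peak), fall time `t2` (main peak to cycle end), main peak amplitude
#' `h1`, dicrotic notch amplitude `h2` (most prominent local minimum after
#' the main peak) and second peak amplitude `h3` (first local maximum after
#' the notch).  `h2`/`h3` are `NA` when the shape has no notch.
#'
#' @param avg_cycle numeric vector normalized to \[0, 1\] (e.g. from
#'   [average_waveform()]).
#' @param fs_effective effective sampling rate of the cycle in points per
#'   second; taken from the `fs_effective` attribute when missing.
#' @return an object of class `morphology_indices`: `t1`, `t2` (seconds),
#'   `h1`, `h2`, `h3` (normalized amplitude units), plus `physiologic`
#'   (TRUE when `0 <= h2 <= h3 <= h1`).
#' @export
morphology_indices <- function(avg_cycle, fs_effective = NULL) {
  x <- as.numeric(avg_cycle)
  if (is.null(fs_effective)) fs_effective <- attr(avg_cycle, "fs_effective")
  if (is.null(fs_effective)) stopf("fs_effective is required")
  if (min(x) < -1e-6 || max(x) > 1 + 1e-6) {
    stopf("avg_cycle must be normalized to [0, 1]")
  }
  n <- length(x)
  pk <- which.max(x)
  t1 <- (pk - 1) / fs_effective
  t2 <- (n - pk) / fs_effective
  h1 <- x[pk]
  h2 <- NA_real_
  h3 <- NA_real_
  if (n - pk >= 3L) {
    sub <- x[pk:n]
    mins <- local_extrema(sub)$minima
    if (length(mins)) {
      promv <- vapply(mins, function(i) peak_prominence(-sub, i), numeric(1))
      notch_rel <- mins[which.max(promv)]
      sub2 <- sub[notch_rel:length(sub)]
      maxs <- local_extrema(sub2)$maxima
      if (length(maxs)) {
        h2 <- sub[notch_rel]
        h3 <- sub2[maxs[1L]]
      }
    }
  }
  physiologic <- !is.na(h2) && !is.na(h3) && h2 >= 0 && h2 <= h3 && h3 <= h1
  structure(list(t1 = t1, t2 = t2, h1 = h1, h2 = h2, h3 = h3,
                 physiologic = physiologic, fs_effective = fs_effective),
            class = "morphology_indices")
}

#' @export
print.morphology_indices <- function(x, ...) {
  cat(sprintf(
    "<morphology_indices> t1 %.3f s | t2 %.3f s | h1 %.3f | h2 %s | h3 %s\n",
    x$t1, x$t2, x$h1,
    ifelse(is.na(x$h2), "NA", sprintf("%.3f", x$h2)),
    ifelse(is.na(x$h3), "NA", sprintf("%.3f", x$h3))))
  invisible(x)
}

#' Compare averaged waveforms from two measurement sites
#'
#' Absolute differences of the morphology indices (times in ms, amplitudes
#' in normalized units) plus the Pearson correlation between the two
#' averaged cycles.
#'
#' @param avg_a,avg_b averaged cycles of equal resample length (from
#'   [average_waveform()]).
#' @param fs_effective effective rate in points per second; per-site
#'   attributes are used when missing.
#' @return an object of class `site_comparison`: `delta_t1`, `delta_t2`
#'   (ms), `delta_h1`, `delta_h2`, `delta_h3`, `rho`.  Deltas involving a
#'   missing fiducial are `NA`.
#' @export
compare_sites <- function(avg_a, avg_b, fs_effective = NULL) {
  if (length(avg_a) != length(avg_b)) {
    stopf("averaged cycles must share the resample length")
  }
  fa <- if (is.null(fs_effective)) attr(avg_a, "fs_effective") else
    fs_effective
  fb <- if (is.null(fs_effective)) attr(avg_b, "fs_effective") else
    fs_effective
  ma <- morphology_indices(avg_a, fa)
  mb <- morphology_indices(avg_b, fb)
  structure(list(
    delta_t1 = abs(ma$t1 - mb$t1) * 1000,
    delta_t2 = abs(ma$t2 - mb$t2) * 1000,
    delta_h1 = abs(ma$h1 - mb$h1),
    delta_h2 = abs(ma$h2 - mb$h2),
    delta_h3 = abs(ma$h3 - mb$h3),
    rho = cor(as.numeric(avg_a), as.numeric(avg_b)),
    site_a = ma, site_b = mb),
    class = "site_comparison")
}

#' @export
print.site_comparison <- function(x, ...) {
  cat(sprintf(paste0(
    "<site_comparison> dt1 %.2f ms | dt2 %.2f ms | dh1 %.3f | dh2 %s | ",
    "dh3 %s | rho %.3f\n"),
    x$delta_t1, x$delta_t2, x$delta_h1,
    ifelse(is.na(x$delta_h2), "NA", sprintf("%.3f", x$delta_h2)),
    ifelse(is.na(x$delta_h3), "NA", sprintf("%.3f", x$delta_h3)),
    x$rho))
  invisible(x)
}
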