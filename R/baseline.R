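# EEMD-based baseline-drift removal.
#
# Empirical mode decomposition (EMD) splits a signal into intrinsic mode
# functions (IMFs) by iterative sifting with cubic-spline envelopes; the
# ensemble variant (EEMD) averages decompositions over noise-perturbed
# copies to suppress mode mixing.  Baseline components are recognized by
# their extrema density: an oscillation slower than the cardiac rhythm has
# too few local extrema to be pulse.

#' EEMD configuration
#'
#' Defaults restate the reference protocol: 50 ensemble trials, noise width
#' 0.01 (interpreted as noise std = 0.01 x input std, the common EEMD
#' convention), at most 8 IMFs, and a baseline-selection extrema ratio of
#' 0.7.
#'
#' @param n_trials number of ensemble trials (>= 1; 1 = plain EMD).
#' @param noise_width std of the added white noise as a fraction of the
#'   input signal's std, in (0, 1).
#' @param max_imfs maximum number of IMFs, in \[1, 16\].
#' @param extrema_ratio baseline-selection ratio in (0, 1): an IMF is
#'   baseline when its extrema count falls below
#'   `extrema_ratio * length / fs`.
#' @param seed integer RNG seed for the ensemble noise.
#' @return an object of class `eemd_config`.
#' @export
eemd_config <- function(n_trials = 50, noise_width = 0.01, max_imfs = 8,
                        extrema_ratio = 0.7, seed = 1) {
  check_scalar(n_trials, "n_trials", 1)
  check_scalar(noise_width, "noise_width")
  if (noise_width <= 0 || noise_width >= 1) {
    stopf("noise_width must lie strictly inside (0, 1)")
  }
  check_scalar(max_imfs, "max_imfs", 1, 16)
  check_scalar(extrema_ratio, "extrema_ratio")
  if (extrema_ratio <= 0 || extrema_ratio >= 1) {
    stopf("extrema_ratio must lie strictly inside (0, 1)")
  }
  structure(list(n_trials = as.integer(n_trials), noise_width = noise_width,
                 max_imfs = as.integer(max_imfs),
                 extrema_ratio = extrema_ratio, seed = seed),
            class = "eemd_config")
}

# Upper/lower envelope through extrema, with the two outermost extrema
# mirrored beyond each end to tame boundary splines.
emd_envelope <- function(x, idx) {
  n <- length(x)
  if (length(idx) < 2L) return(NULL)
  ti <- idx
  vi <- x[idx]
  # mirror up to two extrema about each endpoint
  kL <- seq_len(min(2L, length(idx)))
  kR <- seq.int(length(idx), by = -1L, length.out = min(2L, length(idx)))
  ti <- c(2 - rev(ti[kL]), ti, 2 * n - ti[kR])
  vi <- c(rev(vi[kL]), vi, vi[kR])
  keep <- !duplicated(ti)
  spline(ti[keep], vi[keep], xout = seq_len(n), method = "fmm")$y
}

# Sift one IMF out of r.  Returns NULL when r is a residual (fewer than two
# maxima or minima).
emd_sift <- function(r, max_sift = 50, sd_tol = 0.2) {
  h <- r
  for (it in seq_len(max_sift)) {
    e <- local_extrema(h)
    if (length(e$maxima) < 2L || length(e$minima) < 2L) {
      if (it == 1L) return(NULL)
      break
    }
    up <- emd_envelope(h, e$maxima)
    lo <- emd_envelope(h, e$minima)
    m <- (up + lo) / 2
    h_new <- h - m
    denom <- sum(h^2)
    sd_it <- if (denom > 0) sum((h - h_new)^2) / denom else 0
    h <- h_new
    if (sd_it < sd_tol) break
  }
  h
}

# Plain EMD: list(components = list of IMFs, residual)
emd_decompose_once <- function(x, max_imfs) {
  comps <- list()
  r <- x
  for (k in seq_len(max_imfs)) {
    imf <- emd_sift(r)
    if (is.null(imf)) break
    comps[[k]] <- imf
    r <- r - imf
  }
  list(components = comps, residual = r)
}

#' Ensemble empirical mode decomposition
#'
#' Decomposes the trace into IMFs, averaging over `cfg$n_trials`
#' noise-perturbed copies (noise std = `cfg$noise_width` x signal std).
#' With `n_trials = 1` this is plain EMD and the components plus residual
#' reconstruct the input exactly (up to float tolerance); the ensemble
#' average is only approximately complete.
#'
#' @param trace a `raw_trace` (or numeric vector).
#' @param cfg an [eemd_config()].
#' @param fs sampling rate when `trace` is a bare vector.
#' @return an object of class `imf_set`: list with `components` (IMF 1 =
#'   highest frequency), `residual`, `fs`.  A constant input yields an empty
#'   component list with `residual = input`.
#' @export
eemd_decompose <- function(trace, cfg = eemd_config(), fs = NULL) {
  stopifnot(inherits(cfg, "eemd_config"))
  x <- trace_samples(trace)
  fs <- trace_fs(trace, fs)
  n <- length(x)
  if (n < 4L) stopf("trace too short for decomposition (need >= 4 samples)")
  if (!all(is.finite(x))) stopf("trace contains non-finite values")
  s <- sd(x)
  if (s == 0 || cfg$n_trials == 1L) {
    dec <- if (s == 0) {
      list(components = list(), residual = x)
    } else {
      emd_decompose_once(x, cfg$max_imfs)
    }
    return(structure(c(dec, list(fs = fs, cfg = cfg)), class = "imf_set"))
  }
  with_local_seed(cfg$seed, {
    sigma <- cfg$noise_width * s
    acc <- list()
    res_acc <- numeric(n)
    n_max <- 0L
    for (tr in seq_len(cfg$n_trials)) {
      xt <- x + rnorm(n, 0, sigma)
      dec <- emd_decompose_once(xt, cfg$max_imfs)
      kk <- length(dec$components)
      n_max <- max(n_max, kk)
      for (k in seq_len(kk)) {
        if (length(acc) < k) acc[[k]] <- numeric(n)
        acc[[k]] <- acc[[k]] + dec$components[[k]]
      }
      res_acc <- res_acc + dec$residual
    }
    comps <- lapply(acc, function(a) a / cfg$n_trials)
    structure(list(components = comps, residual = res_acc / cfg$n_trials,
                   fs = fs, cfg = cfg),
              class = "imf_set")
  })
}

#' @export
print.imf_set <- function(x, ...) {
  cat(sprintf("<imf_set> %d IMFs + residual, %d samples @ %g Hz\n",
              length(x$components),
              length(x$residual), x$fs))
  invisible(x)
}

#' Extrema-count threshold for baseline classification
#'
#' `ratio * n / fs`: the expected cardiac-cycle count of the record scaled by
#' the selection ratio (a 20 s record at ratio 0.7 gives 14).
#'
#' @param n signal length in samples.
#' @param fs sampling rate, Hz.
#' @param ratio selection ratio (default 0.7).
#' @return numeric threshold.
#' @export
baseline_extrema_threshold <- function(n, fs, ratio = 0.7) {
  ratio * n / fs
}

#' Classify baseline IMFs by extrema density
#'
#' Component `i` is flagged for removal iff its number of strict local
#' extrema is below `ratio * length / fs`.  The residual trend is always
#' baseline by construction (it carries no oscillation) and is reported via
#' the `"residual"` attribute rather than an index.
#'
#' @param imfs an `imf_set`.
#' @param fs sampling rate, Hz (defaults to `imfs$fs`).
#' @param ratio selection ratio (default from the decomposition config).
#' @return integer vector of component indices to remove, with attribute
#'   `threshold` (the extrema-count cutoff).
#' @export
classify_baseline_imfs <- function(imfs, fs = NULL, ratio = NULL) {
  stopifnot(inherits(imfs, "imf_set"))
  fs <- if (is.null(fs)) imfs$fs else fs
  if (is.null(ratio)) {
    ratio <- if (!is.null(imfs$cfg)) imfs$cfg$extrema_ratio else 0.7
  }
  if (length(imfs$components) == 0L) {
    out <- integer(0)
    attr(out, "threshold") <- baseline_extrema_threshold(
      length(imfs$residual), fs, ratio)
    return(out)
  }
  thr <- baseline_extrema_threshold(length(imfs$components[[1]]), fs, ratio)
  counts <- vapply(imfs$components, count_extrema, integer(1))
  out <- which(counts < thr)
  attr(out, "threshold") <- thr
  attr(out, "extrema_counts") <- counts
  out
}

#' Remove baseline drift from a coarse rPPG trace
#'
#' EEMD-decomposes the trace, drops the low-extrema (baseline) IMFs and the
#' residual trend, sums the surviving IMFs, and adds back the mean offset so
#' that `mean(output) == mean(input)` exactly.
#'
#' @param trace a `raw_trace` (or numeric vector).
#' @param cfg an [eemd_config()].
#' @param fs sampling rate when `trace` is a bare vector.
#' @return an object of class `corrected_trace`: `samples`, `fs`,
#'   `removed_indices` (IMF indices dropped; the residual is always dropped
#'   and is not indexed), `imfs` (the decomposition).
#' @export
remove_baseline <- function(trace, cfg = eemd_config(), fs = NULL) {
  x <- trace_samples(trace)
  fs <- trace_fs(trace, fs)
  imfs <- eemd_decompose(x, cfg, fs = fs)
  removed <- classify_baseline_imfs(imfs, fs = fs, ratio = cfg$extrema_ratio)
  kept <- setdiff(seq_along(imfs$components), removed)
  if (length(kept) == 0L) {
    warning("all IMFs classified as baseline; returning the constant mean ",
            "trace", call. = FALSE)
    recon <- numeric(length(x))
  } else {
    recon <- Reduce(`+`, imfs$components[kept])
  }
  out <- recon + (mean(x) - mean(recon))
  structure(list(samples = out, fs = fs,
                 removed_indices = as.integer(removed),
                 threshold = attr(removed, "threshold"),
                 imfs = imfs),
            class = "corrected_trace")
}
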