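#' @useDynLib palmppg, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif rlnorm spline approx fft sd var
#'   cor median quantile coef lm
#' @importFrom utils read.csv write.csv modifyList
NULL

# Run expr with a locally seeded RNG, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stopf("`%s` must be a finite numeric scalar", name)
  }
  if (x < lower || x > upper) {
    stopf("`%s` = %g outside [%g, %g]", name, x, lower, upper)
  }
  invisible(x)
}

# Strict local extrema of a numeric vector with plateaus broken by the
# first-occurrence rule: a run of equal values counts once, at its start.
# Returns list(maxima = idx, minima = idx) of interior extrema.
local_extrema <- function(x) {
  n <- length(x)
  if (n < 3L) return(list(maxima = integer(0), minima = integer(0)))
  d <- diff(x)
  s <- sign(d)
  nz <- which(s != 0)
  if (length(nz) < 2L) return(list(maxima = integer(0), minima = integer(0)))
  sc <- s[nz]                       # compressed slope signs
  chg <- which(diff(sc) != 0)       # slope sign changes
  idx <- nz[chg] + 1L               # first sample after the rising/falling run
  kind <- sc[chg]                   # +1 -> maximum, -1 -> minimum
  list(maxima = idx[kind > 0], minima = idx[kind < 0])
}

# Number of strict local extrema (maxima + minima), plateau-compressed.
count_extrema <- function(x) {
  e <- local_extrema(x)
  length(e$maxima) + length(e$minima)
}

# Topographic prominence of peak `idx` of signal x (idx must be a local max).
peak_prominence <- function(x, idx) {
  n <- length(x)
  h <- x[idx]
  left_min <- Inf
  i <- idx - 1L
  lm <- h
  while (i >= 1L) {
    lm <- min(lm, x[i])
    if (x[i] > h) break
    i <- i - 1L
  }
  left_base <- lm
  i <- idx + 1L
  rm_ <- h
  while (i <= n) {
    rm_ <- min(rm_, x[i])
    if (x[i] > h) break
    i <- i + 1L
  }
  right_base <- rm_
  h - max(left_base, right_base)
}

# Min-max normalize to [0, 1]; constant input maps to all zeros.
minmax01 <- function(x) {
  r <- range(x)
  if (r[2] - r[1] <= 0) return(rep(0, length(x)))
  (x - r[1]) / (r[2] - r[1])
}

# Min-max normalize to [-1, 1]; returns list(x, lo, hi) for de-normalization.
minmax_pm1 <- function(x) {
  r <- range(x)
  if (r[2] - r[1] <= 0) {
    return(list(x = rep(0, length(x)), lo = r[1], hi = r[2]))
  }
  list(x = 2 * (x - r[1]) / (r[2] - r[1]) - 1, lo = r[1], hi = r[2])
}

denorm_pm1 <- function(x, lo, hi) {
  if (hi - lo <= 0) return(rep(lo, length(x)))
  (x + 1) / 2 * (hi - lo) + lo
}

new_raw_trace <- function(samples, fs) {
  stopifnot(is.numeric(samples), all(is.finite(samples)))
  check_scalar(fs, "fs", lower = 1e-9)
  structure(list(samples = as.numeric(samples), fs = fs),
            class = "raw_trace")
}

trace_samples <- function(x) {
  if (inherits(x, c("raw_trace", "corrected_trace", "annotated_pulse"))) {
    return(x$samples)
  }
  if (is.numeric(x)) return(as.numeric(x))
  stopf("cannot interpret object of class '%s' as a signal", class(x)[1])
}

trace_fs <- function(x, fs = NULL) {
  if (!is.null(fs)) return(fs)
  if (is.list(x) && !is.null(x$fs)) return(x$fs)
  stopf("sampling rate `fs` is required")
}

#' Write a signal trace as a two-column CSV (time_s, amplitude)
#'
#' @param trace a `raw_trace`, `corrected_trace`, `annotated_pulse` or
#'   numeric vector.
#' @param path output file path.
#' @param fs sampling rate in Hz; taken from `trace` when it carries one.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path, fs = NULL) {
  x <- trace_samples(trace)
  fs <- trace_fs(trace, fs)
  df <- data.frame(time_s = (seq_along(x) - 1) / fs, amplitude = x)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a two-column (time_s, amplitude) CSV trace
#'
#' The sampling rate is inferred from the median time step.
#'
#' @param path file written by [write_trace_csv()] (or any CSV whose first two
#'   columns are time in seconds and amplitude).
#' @return a `raw_trace`.
#' @export
read_trace_csv <- function(path) {
  df <- read.csv(path)
  if (ncol(df) < 2L) stopf("expected at least two columns in '%s'", path)
  t <- df[[1]]
  x <- df[[2]]
  if (length(t) < 2L) stopf("trace in '%s' too short", path)
  fs <- 1 / median(diff(t))
  new_raw_trace(x, fs)
}

#' @export
print.raw_trace <- function(x, ...) {
  cat(sprintf("<raw_trace> %d samples @ %g Hz (%.2f s)\n",
              length(x$samples), x$fs, length(x$samples) / x$fs))
  invisible(x)
}

#' @export
print.corrected_trace <- function(x, ...) {
  cat(sprintf(
    "<corrected_trace> %d samples @ %g Hz; removed components: %s\n",
    length(x$samples), x$fs,
    if (length(x$removed_indices)) {
      paste(x$removed_indices, collapse = ", ")
    } else "none"))
  invisible(x)
}
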