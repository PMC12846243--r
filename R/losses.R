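# Loss terms of the adversarial reconstruction objective.
#
# Generator loss:  L_G = 1/2 (D(gen, rough) - 1)^2
#                      + alpha * L1(ref, gen)              (time domain)
#                      + beta  * L1(|FFT ref|, |FFT gen|)  (1024-point FFT)
#                      + gamma * L1 at annotated peaks     (peak-aware)
# Discriminator (LSGAN):  L_D = 1/2 D(gen)^2 + 1/2 (D(real) - 1)^2
#
# L1 terms are means; the spectral term uses the one-sided half (bins
# 0..512) of the 1024-bin magnitude spectrum, which for real signals carries
# the full information.

FFT_N <- 1024L
SPEC_BINS <- 513L   # one-sided half of a 1024-point FFT (0..Nyquist)

#' 1024-point FFT magnitude spectrum
#'
#' The window is zero-padded (or truncated) to 1024 samples before the
#' discrete Fourier transform.
#'
#' @param window numeric vector.
#' @param n_fft transform size (default 1024).
#' @return numeric vector of `n_fft` magnitudes.
#' @export
spectral_magnitude <- function(window, n_fft = FFT_N) {
  x <- as.numeric(window)
  if (length(x) >= n_fft) x <- x[seq_len(n_fft)] else
    x <- c(x, numeric(n_fft - length(x)))
  Mod(fft(x))
}

# mean one-sided spectral L1 between two windows
spectral_l1 <- function(ref, gen, n_fft = FFT_N) {
  mr <- spectral_magnitude(ref, n_fft)[seq_len(SPEC_BINS)]
  mg <- spectral_magnitude(gen, n_fft)[seq_len(SPEC_BINS)]
  mean(abs(mr - mg))
}

# gradient of spectral_l1 w.r.t. gen (length(gen) entries)
spectral_l1_grad <- function(ref, gen, n_fft = FFT_N) {
  L <- length(gen)
  xg <- c(as.numeric(gen), numeric(max(0, n_fft - L)))[seq_len(n_fft)]
  xr <- c(as.numeric(ref), numeric(max(0, n_fft - length(ref))))[
    seq_len(n_fft)]
  G <- fft(xg)
  R <- fft(xr)
  q <- numeric(n_fft)
  ks <- seq_len(SPEC_BINS)
  q[ks] <- sign(Mod(G)[ks] - Mod(R)[ks]) / SPEC_BINS
  mag <- Mod(G)
  cvec <- complex(real = q, imaginary = 0)
  nz <- mag > 0
  cvec[nz] <- q[nz] * Conj(G[nz]) / mag[nz]
  cvec[!nz] <- 0
  Re(fft(cvec))[seq_len(L)]
}

peak_indices <- function(peaks) {
  if (is.null(peaks)) return(integer(0))
  if (inherits(peaks, "peak_annotation")) {
    idx <- c(peaks$cycles$systolic, peaks$cycles$notch,
             peaks$cycles$second_peak)
    return(sort(unique(idx[!is.na(idx)])))
  }
  sort(unique(as.integer(peaks)))
}

#' Generator loss (single window)
#'
#' @param d_score discriminator realness score of the generated window.
#' @param generated,reference numeric vectors of equal length.
#' @param peaks peak locations on the *reference* waveform: a
#'   `peak_annotation` from [annotate_peaks()] or an integer index vector;
#'   `NULL`/empty drops the peak term.
#' @param w a [loss_weights()].
#' @return scalar loss, with attribute `terms` (the four components).
#' @export
generator_loss <- function(d_score, generated, reference, peaks = NULL,
                           w = loss_weights()) {
  stopifnot(inherits(w, "loss_weights"))
  gen <- as.numeric(generated)
  ref <- as.numeric(reference)
  if (length(gen) != length(ref)) {
    stopf("generated and reference lengths differ (%d vs %d)",
          length(gen), length(ref))
  }
  idx <- peak_indices(peaks)
  if (length(idx) && (min(idx) < 1L || max(idx) > length(ref))) {
    stopf("peak indices out of window bounds")
  }
  adv <- 0.5 * mean((d_score - 1)^2)
  time_l1 <- mean(abs(ref - gen))
  spec <- spectral_l1(ref, gen)
  peak <- if (length(idx) == 0L) 0 else if (w$peak_norm == "l1") {
    mean(abs(ref[idx] - gen[idx]))
  } else {
    sqrt(mean((ref[idx] - gen[idx])^2))
  }
  terms <- c(adversarial = adv, time = w$alpha * time_l1,
             spectral = w$beta * spec, peak = w$gamma * peak)
  structure(sum(terms), terms = terms)
}

#' Discriminator loss (LSGAN)
#'
#' `L_D = 1/2 mean(d_fake^2) + 1/2 mean((d_real - 1)^2)`.
#'
#' @param d_fake_score,d_real_score scores (scalars or vectors).
#' @return scalar loss.
#' @export
discriminator_loss <- function(d_fake_score, d_real_score) {
  0.5 * mean(d_fake_score^2) + 0.5 * mean((d_real_score - 1)^2)
}

# Batch generator loss (non-adversarial terms) and gradient w.r.t. gen.
# gen/ref: (1, L, B) arrays; peaks: list of B integer vectors.  The loss is
# the batch mean of per-window losses.  Ablation switches zero out terms.
gen_direct_loss_grad <- function(gen, ref, peaks, w, use_peak_loss = TRUE) {
  d <- dim(gen)
  L <- d[2]; B <- d[3]
  gg <- array(0, dim = d)
  total <- 0
  for (b in seq_len(B)) {
    gb <- gen[1, , b]
    rb <- ref[1, , b]
    total <- total + w$alpha * mean(abs(rb - gb)) + w$beta *
      spectral_l1(rb, gb)
    gvec <- w$alpha * sign(gb - rb) / L + w$beta * spectral_l1_grad(rb, gb)
    if (use_peak_loss && w$gamma > 0 && length(peaks[[b]])) {
      idx <- peaks[[b]]
      total <- total + w$gamma * mean(abs(rb[idx] - gb[idx]))
      gvec[idx] <- gvec[idx] + w$gamma * sign(gb[idx] - rb[idx]) /
        length(idx)
    }
    gg[1, , b] <- gvec / B
  }
  list(loss = total / B, ggen = gg)
}
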