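# Shared fixtures, built in code.

# white-sensor-noise-only corruption (the GAN benchmark world)
noise_white <- function(sigma = 0.15) {
  noise_params(white_sigma = sigma, drift_amp = 0, drift_freq_hz = 0,
               drift_walk_sigma = 0, flicker_amp = 0, flicker_freq_hz = 0,
               am_depth = 0)
}

# tiny architectures for fast structural/gradient tests
tiny_gcfg <- function(gated = TRUE) {
  generator_config(depth = 3, base_channels = 2, gated_skips = gated)
}

tiny_dcfg <- function() discriminator_config(n_layers = 3, base_channels = 2)

# reduced-scale architectures used by the training-based acceptance tests
# (the package default depth 5 / base 16 exceeds the single-CPU test budget)
accept_gcfg <- function() generator_config(depth = 4, base_channels = 8)
accept_dcfg <- function() discriminator_config(n_layers = 3,
                                               base_channels = 8)

# brute-force per-pixel green-mean oracle (explicit double loop)
green_mean_oracle <- function(frames, mask) {
  d <- dim(frames)
  out <- numeric(d[4])
  for (t in seq_len(d[4])) {
    s <- 0
    n <- 0
    for (i in seq_len(d[1])) {
      for (j in seq_len(d[2])) {
        if (mask[i, j]) {
          s <- s + frames[i, j, 2, t]
          n <- n + 1
        }
      }
    }
    out[t] <- s / n
  }
  out
}

# independent DFT-magnitude oracle: explicit transform matrix
dft_mag_oracle <- function(x, n_fft = 1024L) {
  xx <- c(x, numeric(max(0, n_fft - length(x))))[seq_len(n_fft)]
  if (is.null(.GlobalEnv$.palmppg_dft_mat) ||
      nrow(.GlobalEnv$.palmppg_dft_mat) != n_fft) {
    kk <- 0:(n_fft - 1)
    .GlobalEnv$.palmppg_dft_mat <-
      exp(-2i * pi * outer(kk, kk) / n_fft)
  }
  Mod(as.vector(.GlobalEnv$.palmppg_dft_mat %*% xx))
}

# hand-coded generator loss (independent of the package implementation)
gen_loss_oracle <- function(d_score, gen, ref, peaks, alpha, beta, gamma) {
  adv <- 0.5 * mean((d_score - 1)^2)
  time_l1 <- mean(abs(ref - gen))
  mr <- dft_mag_oracle(ref)[1:513]
  mg <- dft_mag_oracle(gen)[1:513]
  spec <- mean(abs(mr - mg))
  peak <- if (length(peaks)) mean(abs(ref[peaks] - gen[peaks])) else 0
  adv + alpha * time_l1 + beta * spec + gamma * peak
}

# fiducials of complete interior cycles: rows whose cycle lies strictly
# between the first and last ground-truth valley (record-edge cycles cannot
# be segmented by any valley-based method)
interior_fiducials <- function(pulse) {
  fid <- pulse$fiducials
  fid[-c(1L, nrow(fid)), , drop = FALSE]
}

# match each true fiducial to the nearest detected one; returns the fraction
# recovered within tol samples
recovery_rate <- function(truth, detected, tol = 3) {
  truth <- truth[!is.na(truth)]
  if (length(truth) == 0L) return(NA_real_)
  if (length(detected) == 0L) return(0)
  hits <- vapply(truth, function(i) min(abs(detected - i)) <= tol,
                 logical(1))
  mean(hits)
}
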