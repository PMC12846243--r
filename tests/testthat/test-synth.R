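test_that("degenerate single-lobe pulse is strictly periodic", {
  p <- pulse_model_params(heart_rate_bpm = 60, hrv_cv = 0, notch_depth = 0,
                          second_peak_amp = 0)
  cp <- generate_clean_ppg(p, duration_s = 20, fs = 100, seed = 1)
  expect_length(cp$samples, 2000L)
  # period exactly 100 samples
  for (b in 1:19) {
    expect_equal(cp$samples[(b * 100 + 1):(b * 100 + 100)],
                 cp$samples[1:100], tolerance = 1e-12)
  }
  expect_identical(sum(!is.na(cp$fiducials$systolic)), 20L)
  # single lobe: no notch/second-peak fiducials
  expect_true(all(is.na(cp$fiducials$notch)))
  expect_true(all(is.na(cp$fiducials$second_peak)))
})

test_that("annotated valleys agree with a brute-force local-minimum scan", {
  # notch-free shape with a strictly decaying tail: the cycle-start valleys
  # are the only interior local minima
  cp <- generate_clean_ppg(pulse_model_params(heart_rate_bpm = 60,
                                              hrv_cv = 0, notch_depth = 0,
                                              second_peak_amp = 0.5,
                                              diastolic_width_s = 0.005),
                           duration_s = 20, fs = 100, seed = 4)
  x <- cp$samples
  # independent oracle: interior strict local minima by explicit scan
  oracle <- integer(0)
  for (i in 2:(length(x) - 1)) {
    if (x[i] < x[i - 1] && x[i] <= x[i + 1]) oracle <- c(oracle, i)
  }
  ann <- cp$fiducials$valley
  # the first annotated valley sits at the record boundary (not interior)
  expect_identical(length(oracle), length(ann) - 1L)
  expect_true(all(abs(sort(oracle) - sort(ann[-1])) <= 1))
})

test_that("pulse generation is a pure function of (params, seed)", {
  p <- pulse_model_params()
  a <- generate_clean_ppg(p, 20, 100, seed = 42)
  b <- generate_clean_ppg(p, 20, 100, seed = 42)
  expect_identical(a, b)
  c <- generate_clean_ppg(p, 20, 100, seed = 43)
  expect_false(identical(a$samples, c$samples))
})

test_that("systolic-peak samples are local maxima and fiducials increase", {
  for (seed in 1:3) {
    cp <- generate_clean_ppg(pulse_model_params(heart_rate_bpm = 75,
                                                hrv_cv = 0.06),
                             20, 100, seed = seed)
    x <- cp$samples
    sys <- cp$fiducials$systolic
    sys <- sys[!is.na(sys) & sys > 1 & sys < length(x)]
    expect_true(all(x[sys] >= x[sys - 1] & x[sys] >= x[sys + 1]))
    comp <- cp$fiducials[stats::complete.cases(cp$fiducials), ]
    if (nrow(comp)) {
      expect_true(all(comp$valley < comp$systolic &
                        comp$systolic < comp$notch &
                        comp$notch <= comp$second_peak))
    }
  }
})

test_that("dominant spectral peak sits at the stated heart rate", {
  for (hr in c(50, 72, 110)) {
    cp <- generate_clean_ppg(pulse_model_params(heart_rate_bpm = hr),
                             20, 100, seed = 5)
    sp <- Mod(stats::fft(cp$samples - mean(cp$samples)))
    n <- length(cp$samples)
    f <- (seq_len(n) - 1) * cp$fs / n
    keep <- f > 0 & f <= 50
    fpeak <- f[keep][which.max(sp[keep])]
    expect_lt(abs(fpeak - hr / 60), cp$fs / n + 1e-9)  # within one FFT bin
  }
})

test_that("too-short records are rejected", {
  expect_error(generate_clean_ppg(pulse_model_params(heart_rate_bpm = 40),
                                  duration_s = 2, fs = 100),
               "fewer than two cycles")
  expect_error(pulse_model_params(second_peak_amp = 1.2),
               "second_peak_amp")
  expect_error(pulse_model_params(heart_rate_bpm = 20), "heart_rate_bpm")
})

test_that("zero noise leaves the signal untouched", {
  cp <- generate_clean_ppg(seed = 2)
  out <- corrupt_signal(cp, noise_params_none(), seed = 9)
  expect_identical(out$samples, cp$samples)
  expect_identical(out$fs, cp$fs)
})

test_that("white-noise corruption has the configured variance", {
  cp <- generate_clean_ppg(duration_s = 60, seed = 3)
  sigma <- 0.2
  out <- corrupt_signal(cp, noise_white(sigma), seed = 11)
  v <- stats::var(out$samples - cp$samples)
  expect_lt(abs(v - sigma^2) / sigma^2, 0.10)
})

test_that("pure sinusoidal drift is a bounded perturbation", {
  cp <- generate_clean_ppg(seed = 6)
  A <- 0.7
  np <- noise_params(white_sigma = 0, drift_amp = A, drift_freq_hz = 0.1,
                     drift_walk_sigma = 0, flicker_amp = 0,
                     flicker_freq_hz = 0, am_depth = 0)
  out <- corrupt_signal(cp, np, seed = 1)
  expect_lte(max(abs(out$samples - cp$samples)), A + 1e-9)
})

test_that("noise parameter invariants are enforced", {
  expect_error(noise_params(drift_freq_hz = 0.6), "drift_freq_hz")
  expect_error(noise_params(flicker_freq_hz = 1.2, flicker_amp = 0.1),
               "cardiac band")
  expect_error(noise_params(white_sigma = -1), "white_sigma")
})

test_that("paired dataset honors the 240-segment 9:1 split", {
  ds <- make_paired_dataset(noise = noise_white(), n_records = 240,
                            duration_s = 4, fs = 100, seed = 1)
  expect_length(ds$split$train, 216L)
  expect_length(ds$split$val, 24L)
  expect_identical(sort(c(ds$split$train, ds$split$val)), 1:240)
  expect_length(intersect(ds$split$train, ds$split$val), 0L)
})

test_that("dataset splits are reproducible and subject-wise split works", {
  a <- make_paired_dataset(noise = noise_white(), n_records = 20,
                           duration_s = 4, seed = 5)
  b <- make_paired_dataset(noise = noise_white(), n_records = 20,
                           duration_s = 4, seed = 5)
  expect_identical(a$split, b$split)
  expect_identical(a$records[[3]]$rough$samples,
                   b$records[[3]]$rough$samples)
  s <- make_paired_dataset(noise = noise_white(), n_records = 24,
                           duration_s = 4, seed = 2,
                           split_by = "subject")
  val_subj <- unique(vapply(s$records[s$split$val],
                            function(r) r$subject, numeric(1)))
  train_subj <- unique(vapply(s$records[s$split$train],
                              function(r) r$subject, numeric(1)))
  expect_length(intersect(val_subj, train_subj), 0L)
  expect_error(make_paired_dataset(n_records = 9), ">= 10")
})

test_that("dataset manifest serializes the stated world", {
  ds <- make_paired_dataset(noise = noise_white(), n_records = 10,
                            duration_s = 4, seed = 3)
  path <- tempfile(fileext = ".json")
  write_dataset_manifest(ds, path)
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_identical(m$n_records, 10L)
  expect_identical(m$seed, 3L)
  expect_equal(m$noise_params$white_sigma, 0.15)
})
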