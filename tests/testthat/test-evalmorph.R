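test_that("identity reconstruction scores perfectly", {
  x <- sin(seq(0, 20, length.out = 500)) + 2
  m <- compute_metrics(x, x)
  expect_equal(m$mape, 0)
  expect_equal(m$rmse, 0)
  expect_equal(m$pearson_rho, 1)
  expect_equal(m$cosine_similarity, 1)
})

test_that("sign flip of a zero-mean signal inverts rho and cosine", {
  set.seed(1)
  x <- stats::rnorm(200)
  x <- x - mean(x)
  m <- compute_metrics(-x, x)
  expect_equal(m$pearson_rho, -1)
  expect_equal(m$cosine_similarity, -1)
})

test_that("metrics match hand arithmetic on 4-vectors", {
  ref <- c(1, 2, 3, 4)
  rec <- c(1, 2, 3, 5)
  m <- compute_metrics(rec, ref)
  expect_equal(m$rmse, 0.5)
  rho_hand <- sum((rec - mean(rec)) * (ref - mean(ref))) /
    sqrt(sum((rec - mean(rec))^2) * sum((ref - mean(ref))^2))
  expect_equal(m$pearson_rho, rho_hand, tolerance = 1e-12)
  expect_error(compute_metrics(c(1, 2), c(3, 3)), "constant reference")
  expect_error(compute_metrics(c(1, 2), c(1, 2, 3)), "lengths differ")
})

test_that("metrics agree with textbook formulas on random vectors", {
  set.seed(21)
  for (rep in 1:25) {
    n <- sample(20:200, 1)
    ref <- stats::rnorm(n, sd = stats::runif(1, 0.5, 3))
    rec <- ref + stats::rnorm(n, sd = 0.4)
    m <- compute_metrics(rec, ref)
    expect_equal(m$rmse, sqrt(mean((ref - rec)^2)), tolerance = 1e-10)
    expect_equal(m$pearson_rho, stats::cor(rec, ref), tolerance = 1e-10)
    expect_equal(m$cosine_similarity,
                 sum(rec * ref) / sqrt(sum(rec^2) * sum(ref^2)),
                 tolerance = 1e-10)
    rn <- (rec - min(rec)) / diff(range(rec))
    fn <- (ref - min(ref)) / diff(range(ref))
    expect_equal(m$mape, mean(abs(fn - rn) / pmax(abs(fn), 1e-3)),
                 tolerance = 1e-10)
  }
})

test_that("clean periodic records segment into clean cycle sets", {
  cp <- generate_clean_ppg(pulse_model_params(heart_rate_bpm = 70,
                                              hrv_cv = 0.02),
                           20, 100, seed = 5)
  cs <- build_cycle_set(cp$samples, fs = 100)
  expect_identical(nrow(cs$rejected), 0L)
  expect_identical(length(cs$cycles),
                   length(detect_valleys(cp$samples, 100)) - 1L)
  for (cyc in cs$cycles) {
    expect_equal(min(cyc), 0)
    expect_equal(max(cyc), 1)
    expect_length(cyc, 100L)
  }
})

test_that("a cycle corrupted by a large transient is screened out", {
  cp <- generate_clean_ppg(pulse_model_params(heart_rate_bpm = 60,
                                              hrv_cv = 0),
                           20, 100, seed = 7)
  x <- cp$samples
  x[520:530] <- x[520:530] + 5   # large transient inside one cycle
  cs <- build_cycle_set(x, fs = 100)
  expect_true(any(grepl("amplitude", cs$rejected$reason)))
  hit <- findInterval(520L, cs$valleys)   # the cycle holding the transient
  expect_false(hit %in% cs$kept)
  expect_gte(length(cs$cycles), 15L)
})

test_that("degenerate cycle sets raise informative errors", {
  expect_error(build_cycle_set(sin(1:300 / 10), valleys = c(50L), fs = 100),
               "2 valleys")
  # two cycles with wildly different amplitudes, strict screen
  t <- seq(0, 2, by = 0.01)
  x <- c(1 - cos(2 * pi * t[t < 1]), 0.2 * (1 - cos(2 * pi * t[t >= 1])))
  expect_error(build_cycle_set(x, valleys = c(1L, 101L, 201L), fs = 100,
                               min_amp_frac = 1),
               "rejected")
})

test_that("template averaging is idempotent and noise-reducing", {
  # 60 bpm keeps every beat sample-aligned, so all cycles are identical
  cs_template <- build_cycle_set(
    generate_clean_ppg(pulse_model_params(heart_rate_bpm = 60, hrv_cv = 0),
                       20, 100, seed = 2)$samples, fs = 100)
  avg <- average_waveform(cs_template)
  # identical cycles: the average equals any single cycle
  expect_equal(avg, cs_template$cycles[[1]], tolerance = 1e-9,
               ignore_attr = TRUE)
  # single-cycle set
  cs1 <- cs_template
  cs1$cycles <- cs_template$cycles[1]
  cs1$durations_s <- cs_template$durations_s[1]
  expect_equal(average_waveform(cs1), cs_template$cycles[[1]],
               ignore_attr = TRUE)
  # noisy copies of a template: the average is closer (L2) than the worst
  set.seed(14)
  template <- avg
  noisy <- lapply(1:12, function(i) template + stats::rnorm(100, 0, 0.08))
  cs_noisy <- cs_template
  cs_noisy$cycles <- noisy
  cs_noisy$durations_s <- rep(1, 12)
  avg_noisy <- average_waveform(cs_noisy)
  dists <- vapply(noisy, function(c) sqrt(sum((c - template)^2)),
                  numeric(1))
  expect_lt(sqrt(sum((avg_noisy - template)^2)), max(dists))
})

test_that("morphology indices read the constructed geometry", {
  # peak at 30% of the cycle
  n <- 100
  x <- numeric(n)
  up <- 1:30; x[up] <- (up - 1) / 29
  down <- 31:100; x[down] <- 1 - (down - 30) / 70
  fs_eff <- 100   # 1 s cycle; peak at sample 30 -> t1 = 29/100 s
  mi <- morphology_indices(x, fs_eff)
  expect_lt(abs(mi$t1 - 0.3), 1.5 / fs_eff)
  expect_lt(abs(mi$t2 - 0.7), 1.5 / fs_eff)
  expect_equal(mi$h1, 1)
  expect_true(is.na(mi$h2) && is.na(mi$h3))   # single lobe
  expect_error(morphology_indices(x * 3, fs_eff), "normalized")
})

test_that("morphology indices find the notch of a full pulse template", {
  cp <- generate_clean_ppg(pulse_model_params(hrv_cv = 0.02), 20, 100,
                           seed = 9)
  avg <- average_waveform(build_cycle_set(cp$samples, fs = 100))
  mi <- morphology_indices(avg)
  expect_equal(mi$h1, max(avg))
  expect_false(is.na(mi$h2))
  expect_false(is.na(mi$h3))
  expect_true(mi$h2 <= mi$h3 && mi$h3 <= mi$h1)
  expect_true(mi$physiologic)
})

test_that("site comparison is zero for identical sites", {
  cp <- generate_clean_ppg(seed = 4)
  avg <- average_waveform(build_cycle_set(cp$samples, fs = 100))
  sc <- compare_sites(avg, avg)
  expect_equal(sc$delta_t1, 0)
  expect_equal(sc$delta_h2, 0)
  expect_equal(sc$rho, 1)
})

test_that("correlation decreases under growing time shifts", {
  cp <- generate_clean_ppg(seed = 4)
  avg <- average_waveform(build_cycle_set(cp$samples, fs = 100))
  rhos <- vapply(c(1L, 2L, 5L), function(k) {
    shifted <- c(avg[(k + 1):length(avg)], avg[seq_len(k)])
    attr(shifted, "fs_effective") <- attr(avg, "fs_effective")
    compare_sites(avg, shifted)$rho
  }, numeric(1))
  expect_true(all(rhos < 1))
  expect_true(all(diff(rhos) < 0))
})
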