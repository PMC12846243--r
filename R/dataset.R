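# Paired synthetic dataset assembly and train/validation splitting.

#' Generate a paired (rough, reference) dataset with a 9:1 split
#'
#' Emulates the acquisition campaign the pipeline targets: `n_records`
#' independent 20 s segments at 100 Hz from `n_subjects` subjects (each
#' subject gets a stable resting heart rate drawn once from 55-95 bpm),
#' each segment paired as (corrupted rough trace, clean reference pulse)
#' with ground-truth fiducials.  Records are split into train/validation at
#' 9:1, either at record granularity (the reference protocol) or by subject
#' (leakage-safe alternative).
#'
#' @param params a [pulse_model_params()] template; each subject's
#'   `heart_rate_bpm` is redrawn.
#' @param noise a [noise_params()].
#' @param n_records number of segments (>= 10, so the 9:1 split is exact at
#'   record granularity).
#' @param duration_s,fs segment length (s) and sampling rate (Hz).
#' @param seed integer RNG seed; every record derives its own sub-seed.
#' @param n_subjects number of synthetic subjects (default 12).
#' @param split_by `"record"` (default) or `"subject"`.
#' @param apply_eemd run [remove_baseline()] on each rough trace (slow; only
#'   needed when the noise model includes drift).
#' @param eemd_cfg an [eemd_config()] used when `apply_eemd = TRUE`.
#' @return an object of class `paired_dataset`: `records` (list with
#'   `clean`, `rough`, `subject`, `seed`), `split` (list `train`, `val` of
#'   record indices), `fs`, `manifest`.
#' @export
make_paired_dataset <- function(params = pulse_model_params(),
                                noise = noise_params(),
                                n_records = 240, duration_s = 20, fs = 100,
                                seed = 1, n_subjects = 12,
                                split_by = c("record", "subject"),
                                apply_eemd = FALSE,
                                eemd_cfg = eemd_config()) {
  split_by <- match.arg(split_by)
  if (n_records < 10) {
    stopf("n_records must be >= 10 to honor the 9:1 split (got %d)",
          n_records)
  }
  with_local_seed(seed, {
    subj_hr <- runif(n_subjects, 55, 95)
    subject <- rep(seq_len(n_subjects), length.out = n_records)
    rec_seed <- sample.int(2^30, n_records)
    records <- vector("list", n_records)
    for (r in seq_len(n_records)) {
      p_r <- params
      p_r$heart_rate_bpm <- subj_hr[subject[r]]
      clean <- generate_clean_ppg(p_r, duration_s, fs, seed = rec_seed[r])
      rough <- corrupt_signal(clean, noise, seed = rec_seed[r] + 1L)
      if (apply_eemd) {
        cfg_r <- eemd_cfg
        cfg_r$seed <- rec_seed[r] + 2L
        rough <- remove_baseline(rough, cfg_r)
      }
      records[[r]] <- list(clean = clean, rough = rough,
                           subject = subject[r], seed = rec_seed[r])
    }
    n_val <- max(1L, round(n_records / 10))
    if (split_by == "record") {
      val <- sort(sample.int(n_records, n_val))
    } else {
      n_val_subj <- max(1L, round(n_subjects / 10))
      val_subj <- sample.int(n_subjects, n_val_subj)
      val <- which(subject %in% val_subj)
    }
    train <- setdiff(seq_len(n_records), val)
    manifest <- list(n_records = n_records, duration_s = duration_s,
                     fs = fs, seed = seed, n_subjects = n_subjects,
                     split_by = split_by, apply_eemd = apply_eemd,
                     pulse_params = unclass(params),
                     noise_params = unclass(noise))
    structure(list(records = records, split = list(train = train, val = val),
                   fs = fs, manifest = manifest),
              class = "paired_dataset")
  })
}

#' @export
print.paired_dataset <- function(x, ...) {
  cat(sprintf(
    "<paired_dataset> %d records (%d train / %d val) @ %g Hz\n",
    length(x$records), length(x$split$train), length(x$split$val), x$fs))
  invisible(x)
}

#' Write a dataset manifest as JSON
#'
#' Records the generator parameters and seed so a dataset can be rebuilt
#' bit-identically.
#'
#' @param dataset a `paired_dataset`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_dataset_manifest <- function(dataset, path) {
  jsonlite::write_json(dataset$manifest, path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

# Cut one record into (rough, reference) training windows with 50% overlap.
# Returns list of windows: each has rough/ref in [-1, 1], de-norm ranges,
# and peak indices (window coordinates) carried from ground truth.
record_windows <- function(record, window = 1024L, hop = window %/% 2L) {
  rough <- trace_samples(record$rough)
  ref <- record$clean$samples
  n <- length(ref)
  if (n < window) {
    stopf("record length %d shorter than window %d", n, window)
  }
  starts <- unique(c(seq.int(1L, n - window + 1L, by = hop),
                     n - window + 1L))
  fid <- record$clean$fiducials
  pk_all <- sort(unique(stats::na.omit(
    c(fid$systolic, fid$notch, fid$second_peak))))
  lapply(starts, function(s0) {
    idx <- s0:(s0 + window - 1L)
    rg <- minmax_pm1(rough[idx])
    rf <- minmax_pm1(ref[idx])
    pk <- pk_all[pk_all >= s0 & pk_all <= s0 + window - 1L] - s0 + 1L
    list(rough = rg$x, ref = rf$x, peaks = as.integer(pk),
         rough_lo = rg$lo, rough_hi = rg$hi,
         ref_lo = rf$lo, ref_hi = rf$hi, start = s0, record = NA_integer_)
  })
}

# All windows of the given record indices, tagged with their record id.
dataset_windows <- function(dataset, which_records, window = 1024L,
                            hop = window %/% 2L) {
  out <- list()
  for (r in which_records) {
    ws <- record_windows(dataset$records[[r]], window, hop)
    for (w in ws) {
      w$record <- r
      out[[length(out) + 1L]] <- w
    }
  }
  out
}

# Stack a list of windows into (1, L, B) arrays + peak index list.
windows_to_batch <- function(ws) {
  L <- length(ws[[1]]$rough)
  B <- length(ws)
  rough <- array(0, dim = c(1L, L, B))
  ref <- array(0, dim = c(1L, L, B))
  peaks <- vector("list", B)
  for (b in seq_len(B)) {
    rough[1, , b] <- ws[[b]]$rough
    ref[1, , b] <- ws[[b]]$ref
    peaks[[b]] <- ws[[b]]$peaks
  }
  list(rough = rough, ref = ref, peaks = peaks)
}
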