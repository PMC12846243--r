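# Adversarial training loop and full-record reconstruction.

#' Training configuration
#'
#' Defaults are desk-scale (200 epochs, batch 32); the reference protocol
#' (1000 epochs, batch 192) is available by configuration.  The 3:1 D:G
#' schedule is realized inside the alternating loop: each iteration performs
#' `d_steps_per_g` discriminator updates (each on its own batch) followed by
#' one generator update.
#'
#' @param epochs training epochs.
#' @param batch_size windows per batch.
#' @param d_steps_per_g discriminator updates per generator update
#'   (default 3).
#' @param lr,beta1,beta2 Adam hyperparameters (2e-4, 0.5, 0.999).
#' @param init_std weight-initialization std (default 0.02).
#' @param seed integer RNG seed (initialization + shuffling).
#' @param window window length fed to the generator; 1024 samples so the
#'   spectral loss needs no padding.
#' @param use_peak_loss,use_gated_skips,use_adversarial ablation switches;
#'   disabling adversarial training drops the discriminator entirely and
#'   trains the generator on the remaining terms.
#' @return an object of class `train_config`.
#' @export
train_config <- function(epochs = 200, batch_size = 32, d_steps_per_g = 3,
                         lr = 2e-4, beta1 = 0.5, beta2 = 0.999,
                         init_std = 0.02, seed = 1, window = 1024,
                         use_peak_loss = TRUE, use_gated_skips = TRUE,
                         use_adversarial = TRUE) {
  check_scalar(epochs, "epochs", 0)
  check_scalar(batch_size, "batch_size", 1)
  check_scalar(d_steps_per_g, "d_steps_per_g", 1)
  check_scalar(init_std, "init_std", 1e-9)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 d_steps_per_g = as.integer(d_steps_per_g),
                 lr = lr, beta1 = beta1, beta2 = beta2,
                 init_std = init_std, seed = seed,
                 window = as.integer(window),
                 use_peak_loss = isTRUE(use_peak_loss),
                 use_gated_skips = isTRUE(use_gated_skips),
                 use_adversarial = isTRUE(use_adversarial)),
            class = "train_config")
}

val_metrics <- function(gparams, gcfg, val_batch) {
  out <- gen_forward(gparams, val_batch$rough, gcfg)
  B <- dim(out)[3]
  m <- vapply(seq_len(B), function(b) {
    rep_ <- compute_metrics(out[1, , b], val_batch$ref[1, , b])
    c(rep_$mape, rep_$rmse, rep_$pearson_rho, rep_$cosine_similarity)
  }, numeric(4))
  rowMeans(m)
}

#' Train the conditional GAN
#'
#' Alternating LSGAN training on (rough, reference) windows cut from the
#' dataset records with 50% overlap.  Weights start N(0, `init_std`^2);
#' every iteration runs `d_steps_per_g` discriminator updates then one
#' generator update; validation metrics are computed each epoch on the
#' held-out records.  Seeded and fully reproducible.
#'
#' @param dataset a `paired_dataset` (needs non-empty train and val splits).
#' @param gcfg a [generator_config()] (its `gated_skips` flag is overridden
#'   by `tcfg$use_gated_skips`).
#' @param dcfg a [discriminator_config()].
#' @param w a [loss_weights()].
#' @param tcfg a [train_config()].
#' @param verbose print a progress line every 10 epochs.
#' @return an object of class `gan_checkpoint`: `gen_params`,
#'   `disc_params`, `gcfg`, `dcfg`, `w`, `tcfg`, `history` (one row per
#'   epoch: `epoch`, `loss_g`, `loss_d`, `val_mape`, `val_rmse`, `val_rho`,
#'   `val_cosine`).
#' @export
train_gan <- function(dataset, gcfg = generator_config(),
                      dcfg = discriminator_config(), w = loss_weights(),
                      tcfg = train_config(), verbose = FALSE) {
  stopifnot(inherits(dataset, "paired_dataset"),
            inherits(tcfg, "train_config"))
  if (length(dataset$split$train) == 0L || length(dataset$split$val) == 0L) {
    stopf("dataset must have non-empty train and validation splits")
  }
  gcfg$gated_skips <- tcfg$use_gated_skips
  train_ws <- dataset_windows(dataset, dataset$split$train, tcfg$window)
  val_ws <- dataset_windows(dataset, dataset$split$val, tcfg$window)
  if (length(train_ws) == 0L) stopf("no training windows")
  val_batch <- windows_to_batch(val_ws)
  n_tr <- length(train_ws)
  bs <- min(tcfg$batch_size, n_tr)
  group <- if (tcfg$use_adversarial) tcfg$d_steps_per_g + 1L else 1L
  with_local_seed(tcfg$seed, {
    gparams <- gen_init(gcfg, seed = NULL, init_std = tcfg$init_std)
    gstate <- adam_init(gparams)
    if (tcfg$use_adversarial) {
      dparams <- disc_init(dcfg, seed = NULL, init_std = tcfg$init_std)
      dstate <- adam_init(dparams)
    } else {
      dparams <- NULL
      dstate <- NULL
    }
    history <- vector("list", tcfg$epochs)
    n_d_updates <- 0L
    n_g_updates <- 0L
    for (ep in seq_len(tcfg$epochs)) {
      ord <- sample.int(n_tr)
      n_batches <- max(1L, floor(n_tr / bs))
      batch_idx <- lapply(seq_len(n_batches), function(i) {
        ord[((i - 1L) * bs + 1L):(i * bs)]
      })
      # cycle batches so every iteration gets d_steps_per_g + 1 of them
      n_iter <- max(1L, ceiling(n_batches / group))
      bpos <- 0L
      next_batch <- function() {
        bpos <<- bpos %% n_batches + 1L
        windows_to_batch(train_ws[batch_idx[[bpos]]])
      }
      lg_acc <- 0
      ld_acc <- 0
      for (it in seq_len(n_iter)) {
        if (tcfg$use_adversarial) {
          for (dstep in seq_len(tcfg$d_steps_per_g)) {
            ba <- next_batch()
            gen_out <- gen_forward(gparams, ba$rough, gcfg)
            B <- dim(gen_out)[3]
            fake_in <- stack_two_channel(gen_out, ba$rough)
            real_in <- stack_two_channel(ba$ref, ba$rough)
            ff <- disc_fw(dparams, fake_in, dcfg, keep_cache = TRUE)
            fr <- disc_fw(dparams, real_in, dcfg, keep_cache = TRUE)
            ld <- discriminator_loss(ff$score, fr$score)
            if (!is.finite(ld)) {
              stopf("NaN/Inf discriminator loss at epoch %d", ep)
            }
            bf <- disc_bw(dparams, ff$cache, ff$score / B, dcfg)
            br <- disc_bw(dparams, fr$cache, (fr$score - 1) / B, dcfg)
            dgrads <- add_params(bf$grads, br$grads)
            up <- adam_step(dparams, dgrads, dstate, tcfg$lr, tcfg$beta1,
                            tcfg$beta2)
            dparams <- up$params
            dstate <- up$state
            n_d_updates <- n_d_updates + 1L
            ld_acc <- ld_acc + ld
          }
        }
        bg <- next_batch()
        gf <- gen_forward(gparams, bg$rough, gcfg, keep_cache = TRUE)
        B <- dim(gf$out)[3]
        direct <- gen_direct_loss_grad(gf$out, bg$ref, bg$peaks, w,
                                       tcfg$use_peak_loss)
        ggen <- direct$ggen
        lg <- direct$loss
        if (tcfg$use_adversarial) {
          fake_in <- stack_two_channel(gf$out, bg$rough)
          ff <- disc_fw(dparams, fake_in, dcfg, keep_cache = TRUE)
          lg <- lg + 0.5 * mean((ff$score - 1)^2)
          db <- disc_bw(dparams, ff$cache, (ff$score - 1) / B, dcfg)
          ggen <- ggen + db$gx[1L, , , drop = FALSE]
        }
        if (!is.finite(lg)) stopf("NaN/Inf generator loss at epoch %d", ep)
        gb <- gen_backward(gparams, gf$cache, ggen, gcfg)
        up <- adam_step(gparams, gb$grads, gstate, tcfg$lr, tcfg$beta1,
                        tcfg$beta2)
        gparams <- up$params
        gstate <- up$state
        n_g_updates <- n_g_updates + 1L
        lg_acc <- lg_acc + lg
      }
      vm <- val_metrics(gparams, gcfg, val_batch)
      history[[ep]] <- data.frame(
        epoch = ep, loss_g = lg_acc / n_iter,
        loss_d = if (tcfg$use_adversarial) {
          ld_acc / (n_iter * tcfg$d_steps_per_g)
        } else NA_real_,
        val_mape = vm[1], val_rmse = vm[2], val_rho = vm[3],
        val_cosine = vm[4])
      if (verbose && (ep %% 10L == 0L || ep == 1L)) {
        cat(sprintf("epoch %4d | L_G %.4f | L_D %s | val rho %.4f\n",
                    ep, lg_acc / n_iter,
                    if (tcfg$use_adversarial) {
                      sprintf("%.4f", ld_acc / (n_iter * tcfg$d_steps_per_g))
                    } else "--",
                    vm[3]))
      }
    }
    structure(list(gen_params = gparams, disc_params = dparams,
                   gcfg = gcfg, dcfg = dcfg, w = w, tcfg = tcfg,
                   history = do.call(rbind, history),
                   n_d_updates = n_d_updates, n_g_updates = n_g_updates),
              class = "gan_checkpoint")
  })
}

add_params <- function(a, b) {
  if (is.null(a)) return(NULL)
  if (is.list(a)) {
    for (i in seq_along(a)) a[[i]] <- add_params(a[[i]], b[[i]])
    a
  } else {
    a + b
  }
}

#' @export
print.gan_checkpoint <- function(x, ...) {
  h <- x$history
  cat(sprintf(
    "<gan_checkpoint> %d epochs trained; final val rho %.4f (MAPE %.4f)\n",
    nrow(h), h$val_rho[nrow(h)], h$val_mape[nrow(h)]))
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' Single-file archive holding weights plus every configuration object.
#'
#' @param checkpoint a `gan_checkpoint`.
#' @param path file path (`.rds`).
#' @return `path` invisibly / the checkpoint.
#' @export
save_checkpoint <- function(checkpoint, path) {
  stopifnot(inherits(checkpoint, "gan_checkpoint"))
  saveRDS(checkpoint, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  stopifnot(inherits(ck, "gan_checkpoint"))
  ck
}

#' Reconstruct a full record with a trained generator
#'
#' The rough trace is cut into windows with 50% overlap, each window is
#' min-max normalized to \[-1, 1\], passed through the generator,
#' de-normalized back to that window's rough amplitude range, and the
#' overlapping windows are averaged.  Output length equals input length.
#'
#' @param checkpoint a `gan_checkpoint` (or a list with `gen_params`,
#'   `gcfg`, `tcfg`).
#' @param rough a `corrected_trace`, `raw_trace` or numeric vector.
#' @param fs sampling rate when `rough` is a bare vector (informational).
#' @return numeric vector, the reconstructed rPPG signal.
#' @export
reconstruct <- function(checkpoint, rough, fs = NULL) {
  x <- trace_samples(rough)
  window <- checkpoint$tcfg$window
  n <- length(x)
  if (n < window) {
    stopf(paste0("record length %d is shorter than one window (%d); ",
                 "pad the record or retrain with a smaller window"),
          n, window)
  }
  hop <- window %/% 2L
  starts <- unique(c(seq.int(1L, n - window + 1L, by = hop),
                     n - window + 1L))
  B <- length(starts)
  batch <- array(0, dim = c(1L, window, B))
  los <- numeric(B)
  his <- numeric(B)
  for (b in seq_len(B)) {
    seg <- x[starts[b]:(starts[b] + window - 1L)]
    nm <- minmax_pm1(seg)
    batch[1, , b] <- nm$x
    los[b] <- nm$lo
    his[b] <- nm$hi
  }
  out <- gen_forward(checkpoint$gen_params, batch, checkpoint$gcfg)
  acc <- numeric(n)
  cnt <- numeric(n)
  for (b in seq_len(B)) {
    idx <- starts[b]:(starts[b] + window - 1L)
    acc[idx] <- acc[idx] + denorm_pm1(out[1, , b], los[b], his[b])
    cnt[idx] <- cnt[idx] + 1
  }
  acc / cnt
}
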