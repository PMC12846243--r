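# Fast structural tests of the training loop use a tiny world: 12 s records
# (one 1024-sample window plus change), 10 records, a depth-3 generator and
# very few epochs.

tiny_world <- function(seed = 1, n_records = 10) {
  make_paired_dataset(noise = noise_white(0.1), n_records = n_records,
                      duration_s = 12, fs = 100, seed = seed)
}

tiny_tcfg <- function(...) {
  train_config(epochs = 2, batch_size = 8, seed = 7, ...)
}

test_that("training is bit-reproducible from the seed", {
  ds <- tiny_world()
  a <- train_gan(ds, tiny_gcfg(), tiny_dcfg(), tcfg = tiny_tcfg())
  b <- train_gan(ds, tiny_gcfg(), tiny_dcfg(), tcfg = tiny_tcfg())
  expect_identical(a$history, b$history)
  expect_identical(a$gen_params, b$gen_params)
})

test_that("the D:G update schedule is 3:1", {
  ds <- tiny_world()
  ck <- train_gan(ds, tiny_gcfg(), tiny_dcfg(), tcfg = tiny_tcfg())
  expect_identical(ck$n_d_updates, 3L * ck$n_g_updates)
})

test_that("disabling the peak term equals setting gamma to zero", {
  ds <- tiny_world()
  a <- train_gan(ds, tiny_gcfg(), tiny_dcfg(),
                 w = loss_weights(gamma = 0),
                 tcfg = tiny_tcfg())
  b <- train_gan(ds, tiny_gcfg(), tiny_dcfg(),
                 w = loss_weights(gamma = 0.5),
                 tcfg = tiny_tcfg(use_peak_loss = FALSE))
  expect_identical(a$history$loss_g, b$history$loss_g)
})

test_that("non-adversarial training skips the discriminator", {
  ds <- tiny_world()
  ck <- train_gan(ds, tiny_gcfg(), tiny_dcfg(),
                  tcfg = tiny_tcfg(use_adversarial = FALSE))
  expect_null(ck$disc_params)
  expect_true(all(is.na(ck$history$loss_d)))
  expect_identical(ck$n_d_updates, 0L)
})

test_that("gated-skip ablation switches the architecture", {
  ds <- tiny_world()
  ck <- train_gan(ds, tiny_gcfg(), tiny_dcfg(),
                  tcfg = tiny_tcfg(use_gated_skips = FALSE))
  expect_null(ck$gen_params$gates)
  expect_false(ck$gcfg$gated_skips)
})

test_that("history records finite losses and validation metrics", {
  ds <- tiny_world()
  ck <- train_gan(ds, tiny_gcfg(), tiny_dcfg(), tcfg = tiny_tcfg())
  h <- ck$history
  expect_identical(nrow(h), 2L)
  expect_true(all(is.finite(h$loss_g)))
  expect_true(all(is.finite(h$loss_d)))
  expect_true(all(is.finite(h$val_rho)))
})

test_that("reconstruction preserves length and is deterministic", {
  ds <- tiny_world()
  ck <- train_gan(ds, tiny_gcfg(), tiny_dcfg(), tcfg = tiny_tcfg())
  rough <- ds$records[[1]]$rough
  y1 <- reconstruct(ck, rough)
  y2 <- reconstruct(ck, rough)
  expect_length(y1, length(rough$samples))
  expect_identical(y1, y2)
  expect_true(all(is.finite(y1)))
  # de-normalized output stays within the rough window amplitude range
  expect_gte(min(y1), min(rough$samples) - 1e-9)
  expect_lte(max(y1), max(rough$samples) + 1e-9)
  expect_error(reconstruct(ck, numeric(500)), "shorter than one window")
})

test_that("an untrained generator still yields finite reconstructions", {
  gcfg <- tiny_gcfg()
  ck <- structure(list(gen_params = gen_init(gcfg, seed = 5),
                       gcfg = gcfg, tcfg = train_config(epochs = 0)),
                  class = "gan_checkpoint")
  y <- reconstruct(ck, sin(1:2000 / 10) + 2)
  expect_length(y, 2000L)
  expect_true(all(is.finite(y)))
})

test_that("checkpoints survive a save/load round trip", {
  ds <- tiny_world()
  ck <- train_gan(ds, tiny_gcfg(), tiny_dcfg(), tcfg = tiny_tcfg())
  path <- tempfile(fileext = ".rds")
  save_checkpoint(ck, path)
  back <- load_checkpoint(path)
  expect_identical(back$gen_params, ck$gen_params)
  rough <- ds$records[[2]]$rough
  expect_identical(reconstruct(back, rough), reconstruct(ck, rough))
  unlink(path)
})

test_that("empty splits and windows are rejected", {
  ds <- tiny_world()
  ds$split$val <- integer(0)
  expect_error(train_gan(ds, tiny_gcfg(), tiny_dcfg(),
                         tcfg = tiny_tcfg()),
               "non-empty")
  ds2 <- make_paired_dataset(noise = noise_white(), n_records = 10,
                             duration_s = 4, seed = 1)
  expect_error(train_gan(ds2, tiny_gcfg(), tiny_dcfg(),
                         tcfg = tiny_tcfg()),
               "shorter than window")
})
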