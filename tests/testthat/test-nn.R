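# Gradient correctness (vs central finite differences) and architecture
# contracts of the hand-written network.

fd_rel_err <- function(fd, an) abs(fd - an) / max(1e-7, abs(fd), abs(an))

test_that("generator backprop matches finite differences", {
  set.seed(42)
  gcfg <- tiny_gcfg()
  L <- 32L; B <- 2L
  gp <- gen_init(gcfg, seed = 7, init_std = 0.2)
  x <- array(stats::runif(L * B, -1, 1), dim = c(1, L, B))
  ref <- array(stats::runif(L * B, -1, 1), dim = c(1, L, B))
  peaks <- list(c(3L, 10L), c(5L, 20L, 22L))
  w <- loss_weights()
  loss_fn <- function(params) {
    out <- gen_forward(params, x, gcfg)
    palmppg:::gen_direct_loss_grad(out, ref, peaks, w)$loss
  }
  fw <- gen_forward(gp, x, gcfg, keep_cache = TRUE)
  direct <- palmppg:::gen_direct_loss_grad(fw$out, ref, peaks, w)
  gb <- palmppg:::gen_backward(gp, fw$cache, direct$ggen, gcfg)
  eps <- 1e-6
  paths <- list(list("enc", 1L, "W"), list("enc", 2L, "gamma"),
                list("enc", 3L, "a"), list("dec", 1L, "V"),
                list("dec", 2L, "beta"), list("gates", 1L, "We"),
                list("gates", 2L, "bg"))
  for (pth in paths) {
    leaf <- gp[[pth[[1]]]][[pth[[2]]]][[pth[[3]]]]
    for (i in sample(length(leaf), min(2, length(leaf)))) {
      pp <- gp; pp[[pth[[1]]]][[pth[[2]]]][[pth[[3]]]][i] <- leaf[i] + eps
      pm <- gp; pm[[pth[[1]]]][[pth[[2]]]][[pth[[3]]]][i] <- leaf[i] - eps
      fd <- (loss_fn(pp) - loss_fn(pm)) / (2 * eps)
      an <- gb$grads[[pth[[1]]]][[pth[[2]]]][[pth[[3]]]][i]
      expect_lt(fd_rel_err(fd, an), 1e-4)
    }
  }
  for (i in c(1L, 5L)) {
    pp <- gp; pp$fin$V[i] <- gp$fin$V[i] + eps
    pm <- gp; pm$fin$V[i] <- gp$fin$V[i] - eps
    fd <- (loss_fn(pp) - loss_fn(pm)) / (2 * eps)
    expect_lt(fd_rel_err(fd, gb$grads$fin$V[i]), 1e-4)
  }
})

test_that("discriminator backprop matches finite differences", {
  set.seed(1)
  dcfg <- tiny_dcfg()
  L <- 45L; B <- 2L
  dp <- disc_init(dcfg, seed = 3, init_std = 0.2)
  x <- array(stats::runif(2 * L * B, -1, 1), dim = c(2, L, B))
  wts <- c(0.3, -0.2)
  loss_fn <- function(params, xx = x) {
    s <- palmppg:::disc_fw(params, xx, dcfg)
    0.5 * mean(s^2) + sum(s * wts)
  }
  fw <- palmppg:::disc_fw(dp, x, dcfg, keep_cache = TRUE)
  bw <- palmppg:::disc_bw(dp, fw$cache, fw$score / B + wts, dcfg)
  eps <- 1e-6
  for (li in seq_along(dp$layers)) {
    for (nm in names(dp$layers[[li]])) {
      leaf <- dp$layers[[li]][[nm]]
      i <- sample(length(leaf), 1)
      pp <- dp; pp$layers[[li]][[nm]][i] <- leaf[i] + eps
      pm <- dp; pm$layers[[li]][[nm]][i] <- leaf[i] - eps
      fd <- (loss_fn(pp) - loss_fn(pm)) / (2 * eps)
      an <- bw$grads$layers[[li]][[nm]][i]
      if (abs(fd) > 1e-10 || abs(an) > 1e-10) {
        expect_lt(fd_rel_err(fd, an), 1e-4)
      }
    }
  }
  # gradient w.r.t. the candidate input channel
  for (i in c(5L, 17L)) {
    xp <- x; xp[1, i, 1] <- x[1, i, 1] + eps
    xm <- x; xm[1, i, 1] <- x[1, i, 1] - eps
    fd <- (loss_fn(dp, xp) - loss_fn(dp, xm)) / (2 * eps)
    expect_lt(fd_rel_err(fd, bw$gx[1, i, 1]), 1e-4)
  }
})

test_that("spectral L1 gradient matches finite differences", {
  set.seed(9)
  ref <- stats::rnorm(64)
  gen <- stats::rnorm(64)
  an <- palmppg:::spectral_l1_grad(ref, gen)
  eps <- 1e-6
  for (i in c(1L, 17L, 64L)) {
    gp <- gen; gp[i] <- gen[i] + eps
    gm <- gen; gm[i] <- gen[i] - eps
    fd <- (palmppg:::spectral_l1(ref, gp) - palmppg:::spectral_l1(ref, gm)) /
      (2 * eps)
    expect_lt(fd_rel_err(fd, an[i]), 1e-4)
  }
})

test_that("generator preserves length and range for supported windows", {
  gcfg <- generator_config()   # default depth 5 / base 16
  gp <- gen_init(gcfg, seed = 1)
  for (L in c(256L, 512L, 1024L)) {
    out <- generator_forward(numeric(L), gp, gcfg)
    expect_length(out, L)
    expect_true(all(is.finite(out)) && all(abs(out) <= 1))
  }
  expect_error(generator_forward(numeric(100), gp, gcfg), "multiple")
})

test_that("instance norm makes batch members independent", {
  gcfg <- tiny_gcfg()
  gp <- gen_init(gcfg, seed = 4)
  set.seed(11)
  w1 <- stats::runif(64, -1, 1)
  w2 <- stats::runif(64, -1, 1)
  joint <- gen_forward(gp, cbind(w1, w2), gcfg)
  solo1 <- gen_forward(gp, matrix(w1, ncol = 1), gcfg)
  solo2 <- gen_forward(gp, matrix(w2, ncol = 1), gcfg)
  expect_equal(joint[1, , 1], solo1[1, , 1], tolerance = 1e-12)
  expect_equal(joint[1, , 2], solo2[1, , 1], tolerance = 1e-12)
})

test_that("gated skip saturates to the plain skip and respects (0,1)", {
  set.seed(5)
  C <- 3L; L <- 8L; B <- 2L
  e <- array(stats::rnorm(C * L * B), dim = c(C, L, B))
  d <- array(stats::rnorm(C * L * B), dim = c(C, L, B))
  gate_open <- list(We = matrix(0, C, C), Wd = matrix(0, C, C),
                    bg = rep(40, C))
  fo <- gated_skip(e, d, gate_open)
  expect_equal(fo$fused[1:C, , ], e, tolerance = 1e-12)
  expect_equal(fo$fused[C + 1:C, , ], d, tolerance = 1e-12)
  gate_shut <- list(We = matrix(0, C, C), Wd = matrix(0, C, C),
                    bg = rep(-40, C))
  fs_ <- gated_skip(e, d, gate_shut)
  expect_lt(max(abs(fs_$fused[1:C, , ])), 1e-10)
  gate_rand <- list(We = matrix(stats::rnorm(C * C), C, C),
                    Wd = matrix(stats::rnorm(C * C), C, C),
                    bg = stats::rnorm(C))
  fr <- gated_skip(e, d, gate_rand)
  expect_true(all(fr$gate_values > 0 & fr$gate_values < 1))
  expect_error(gated_skip(e, d[, 1:4, , drop = FALSE], gate_rand),
               "shapes differ")
})

test_that("discriminator is channel-asymmetric, deterministic and batched", {
  dcfg <- tiny_dcfg()
  dp <- disc_init(dcfg, seed = 2)
  set.seed(8)
  a <- stats::runif(60, -1, 1)
  b <- stats::runif(60, -1, 1)
  s_ab <- discriminator_forward(a, b, dp, dcfg)
  s_ba <- discriminator_forward(b, a, dp, dcfg)
  expect_false(isTRUE(all.equal(s_ab, s_ba)))
  expect_identical(s_ab, discriminator_forward(a, b, dp, dcfg))
  joint <- discriminator_forward(cbind(a, b), cbind(b, a), dp, dcfg)
  expect_equal(joint, c(s_ab, s_ba), tolerance = 1e-12)
  expect_error(discriminator_forward(a, b[1:10], dp, dcfg), "equal")
})

test_that("zero input through a fresh generator stays in range", {
  gcfg <- tiny_gcfg()
  gp <- gen_init(gcfg, seed = 3)
  out <- generator_forward(numeric(64), gp, gcfg)
  expect_true(all(is.finite(out)))
  expect_true(all(abs(out) <= 1))
})
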