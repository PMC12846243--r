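# Conditional 1-D U-Net generator and convolutional discriminator.
#
# Generator: encoder of strided convolutions (kernel 4, stride 2, padding 1),
# PReLU + instance norm everywhere except the final layer, transposed-conv
# decoder with gated skip connections, Tanh output.  Discriminator: stacked
# convolutions (kernel 5, stride 3, padding 2) with LeakyReLU + instance
# norm, final stride-1 linear layer, two-channel input (candidate, rough
# conditioning signal), patch scores averaged to one scalar per sample.

#' Generator architecture configuration
#'
#' @param depth number of down-sampling stages (default 5).
#' @param base_channels channels of the first stage, doubling per stage.
#' @param kernel,stride fixed at 4 and 2 by the architecture.
#' @param gated_skips use gated (sigmoid-modulated) skip connections;
#'   `FALSE` gives plain concatenation skips (the ablation variant).
#' @param in_channels input channels (1 for a single rough trace).
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(depth = 5, base_channels = 16, kernel = 4,
                             stride = 2, gated_skips = TRUE,
                             in_channels = 1) {
  if (kernel != 4 || stride != 2) {
    stopf("the generator uses kernel 4 / stride 2 by construction")
  }
  check_scalar(depth, "depth", 2, 8)
  check_scalar(base_channels, "base_channels", 1)
  structure(list(depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 kernel = 4L, stride = 2L, pad = 1L,
                 gated_skips = isTRUE(gated_skips),
                 in_channels = as.integer(in_channels)),
            class = "generator_config")
}

#' Discriminator architecture configuration
#'
#' @param n_layers total conv layers including the final stride-1 linear one.
#' @param base_channels channels of the first layer, doubling per layer.
#' @param kernel,stride fixed at 5 and 3 (final layer stride 1).
#' @param in_channels input channels (2: candidate + conditioning rough).
#' @return an object of class `discriminator_config`.
#' @export
discriminator_config <- function(n_layers = 4, base_channels = 16,
                                 kernel = 5, stride = 3, in_channels = 2) {
  if (kernel != 5 || stride != 3) {
    stopf("the discriminator uses kernel 5 / stride 3 (final stride 1)")
  }
  check_scalar(n_layers, "n_layers", 2, 8)
  structure(list(n_layers = as.integer(n_layers),
                 base_channels = as.integer(base_channels),
                 kernel = 5L, stride = 3L, pad = 2L,
                 in_channels = as.integer(in_channels)),
            class = "discriminator_config")
}

#' Loss weights for the generator objective
#'
#' Defaults restate the reference protocol: alpha = 1.0 (time-domain L1),
#' beta = 0.3 (spectral L1), gamma = 0.5 (peak-aware term).
#'
#' @param alpha,beta,gamma non-negative term weights.
#' @param peak_norm `"l1"` (default) or `"l2"` norm for the peak term.
#' @return an object of class `loss_weights`.
#' @export
loss_weights <- function(alpha = 1.0, beta = 0.3, gamma = 0.5,
                         peak_norm = c("l1", "l2")) {
  check_scalar(alpha, "alpha", 0)
  check_scalar(beta, "beta", 0)
  check_scalar(gamma, "gamma", 0)
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 peak_norm = match.arg(peak_norm)),
            class = "loss_weights")
}

gen_channels <- function(gcfg) gcfg$base_channels * 2^(seq_len(gcfg$depth) - 1)

#' Initialize generator parameters
#'
#' All weights drawn N(0, `init_std`^2), biases 0, instance-norm affine
#' parameters (1, 0), PReLU slopes 0.25.
#'
#' @param gcfg a [generator_config()].
#' @param seed integer RNG seed.
#' @param init_std weight-init std (default 0.02).
#' @return nested parameter list.
#' @export
gen_init <- function(gcfg = generator_config(), seed = 1, init_std = 0.02) {
  ch <- gen_channels(gcfg)
  D <- gcfg$depth
  k <- gcfg$kernel
  with_local_seed(seed, {
    enc <- vector("list", D)
    cin <- gcfg$in_channels
    for (i in seq_len(D)) {
      enc[[i]] <- list(W = gauss_mat(ch[i], cin * k, init_std),
                       b = numeric(ch[i]), gamma = rep(1, ch[i]),
                       beta = numeric(ch[i]), a = rep(0.25, ch[i]))
      cin <- ch[i]
    }
    dec <- vector("list", D - 1L)
    din <- ch[D]
    for (j in seq_len(D - 1L)) {
      cout <- ch[D - j]
      # tconv weight: conv-style matrix of the reverse map (din, cout * k)
      dec[[j]] <- list(V = gauss_mat(din, cout * k, init_std),
                       b = numeric(cout), gamma = rep(1, cout),
                       beta = numeric(cout), a = rep(0.25, cout))
      din <- 2L * cout
    }
    fin <- list(V = gauss_mat(din, 1L * k, init_std), b = numeric(1))
    gates <- NULL
    if (gcfg$gated_skips) {
      gates <- lapply(seq_len(D - 1L), function(j) {
        cg <- ch[D - j]
        list(We = gauss_mat(cg, cg, init_std),
             Wd = gauss_mat(cg, cg, init_std), bg = numeric(cg))
      })
    }
    list(enc = enc, dec = dec, fin = fin, gates = gates)
  })
}

#' Gated skip-connection fusion
#'
#' Computes `g = sigmoid(We x enc + Wd x dec + b)` (1x1 convolutions over
#' channels) and returns the fused features `concat(g * enc, dec)` along the
#' channel axis.  With the gate saturated at 1 this reduces to the plain
#' concatenation skip.
#'
#' @param encoder_features,decoder_features arrays `(C, L, B)` of matching
#'   temporal length and channel count.
#' @param gate list with `We`, `Wd` (`C x C` matrices) and `bg` (length-C
#'   bias), e.g. one element of `gen_init()$gates`.
#' @return list with `fused` (`(2C, L, B)`) and `gate_values` (`(C, L, B)`,
#'   each strictly inside (0, 1)).
#' @export
gated_skip <- function(encoder_features, decoder_features, gate) {
  de <- dim(encoder_features)
  dd <- dim(decoder_features)
  if (!identical(de, dd)) {
    stopf("encoder (%s) and decoder (%s) feature shapes differ",
          paste(de, collapse = "x"), paste(dd, collapse = "x"))
  }
  pre <- chanmix(encoder_features, gate$We) +
    chanmix(decoder_features, gate$Wd) + as.numeric(gate$bg)
  g <- sigmoid(pre)
  fused <- array(0, dim = c(2L * de[1], de[2], de[3]))
  fused[seq_len(de[1]), , ] <- g * encoder_features
  fused[de[1] + seq_len(de[1]), , ] <- decoder_features
  list(fused = fused, gate_values = g)
}

#' Generator forward pass
#'
#' @param params parameters from [gen_init()] (or a checkpoint).
#' @param x input windows: array `(1, L, B)`, matrix `(L, B)` or vector;
#'   values expected in \[-1, 1\]; `L` must be a multiple of `2^depth`.
#' @param gcfg the matching [generator_config()].
#' @param keep_cache keep intermediate activations for backprop.
#' @return array `(1, L, B)` in \[-1, 1\]; with `keep_cache = TRUE`, a list
#'   `(out, cache)`.
#' @export
gen_forward <- function(params, x, gcfg = generator_config(),
                        keep_cache = FALSE) {
  x <- as_clb(x, gcfg$in_channels)
  L <- dim(x)[2]
  D <- gcfg$depth
  if (L %% 2^D != 0) {
    stopf(paste0("input length %d is not a multiple of 2^depth = %d; ",
                 "pad the window (e.g. to %d) before calling the generator"),
          L, 2^D, ceiling(L / 2^D) * 2^D)
  }
  k <- gcfg$kernel; s <- gcfg$stride; p <- gcfg$pad
  enc_in <- vector("list", D)
  enc_z <- vector("list", D)
  enc_ic <- vector("list", D)
  enc_n <- vector("list", D)
  e <- vector("list", D)
  h <- x
  for (i in seq_len(D)) {
    enc_in[[i]] <- h
    z <- conv_fw(h, params$enc[[i]]$W, params$enc[[i]]$b, k, s, p)
    enc_z[[i]] <- z
    nf <- inorm_fw(z, params$enc[[i]]$gamma, params$enc[[i]]$beta)
    enc_ic[[i]] <- nf$cache
    enc_n[[i]] <- nf$y
    h <- prelu_fw(nf$y, params$enc[[i]]$a)
    e[[i]] <- h
  }
  dec_in <- vector("list", D - 1L)
  dec_u <- vector("list", D - 1L)
  dec_ic <- vector("list", D - 1L)
  dec_n <- vector("list", D - 1L)
  dec_p <- vector("list", D - 1L)
  gate_g <- vector("list", D - 1L)
  d <- e[[D]]
  for (j in seq_len(D - 1L)) {
    lvl <- D - j
    dec_in[[j]] <- d
    u <- tconv_fw(d, params$dec[[j]]$V, params$dec[[j]]$b, k, s, p)
    dec_u[[j]] <- u
    nf <- inorm_fw(u, params$dec[[j]]$gamma, params$dec[[j]]$beta)
    dec_ic[[j]] <- nf$cache
    dec_n[[j]] <- nf$y
    pp <- prelu_fw(nf$y, params$dec[[j]]$a)
    dec_p[[j]] <- pp
    if (gcfg$gated_skips) {
      gs <- gated_skip(e[[lvl]], pp, params$gates[[j]])
      gate_g[[j]] <- gs$gate_values
      d <- gs$fused
    } else {
      C <- dim(pp)[1]
      d <- array(0, dim = c(2L * C, dim(pp)[2], dim(pp)[3]))
      d[seq_len(C), , ] <- e[[lvl]]
      d[C + seq_len(C), , ] <- pp
    }
  }
  fin_in <- d
  y <- tconv_fw(d, params$fin$V, params$fin$b, k, s, p)
  out <- tanh(y)
  if (!keep_cache) return(out)
  list(out = out,
       cache = list(enc_in = enc_in, enc_z = enc_z, enc_ic = enc_ic,
                    enc_n = enc_n, e = e, dec_in = dec_in, dec_u = dec_u,
                    dec_ic = dec_ic, dec_n = dec_n, dec_p = dec_p,
                    gate_g = gate_g, fin_in = fin_in, out = out))
}

# Backward pass: gout has the shape of the generator output.
gen_backward <- function(params, cache, gout, gcfg = generator_config()) {
  D <- gcfg$depth
  k <- gcfg$kernel; s <- gcfg$stride; p <- gcfg$pad
  grads <- list(enc = vector("list", D), dec = vector("list", D - 1L),
                fin = NULL,
                gates = if (gcfg$gated_skips) vector("list", D - 1L)
                        else NULL)
  gy <- gout * (1 - cache$out^2)
  tb <- tconv_bw(cache$fin_in, params$fin$V, gy, k, s, p)
  grads$fin <- list(V = tb$gV, b = tb$gb)
  gd <- tb$gx
  ge_skip <- vector("list", D)
  for (j in rev(seq_len(D - 1L))) {
    lvl <- D - j
    C <- dim(cache$dec_p[[j]])[1]
    gge <- gd[seq_len(C), , , drop = FALSE]
    gp <- gd[C + seq_len(C), , , drop = FALSE]
    if (gcfg$gated_skips) {
      g <- cache$gate_g[[j]]
      e_feat <- cache$e[[lvl]]
      ge <- gge * g
      gpre <- gge * e_feat * g * (1 - g)
      dm <- dim(gpre)
      gpre_m <- matrix(gpre, nrow = dm[1])
      em <- matrix(e_feat, nrow = dm[1])
      pm <- matrix(cache$dec_p[[j]], nrow = dm[1])
      grads$gates[[j]] <- list(We = gpre_m %*% t(em),
                               Wd = gpre_m %*% t(pm),
                               bg = rowSums(gpre_m))
      ge <- ge + chanmix(gpre, t(params$gates[[j]]$We))
      gp <- gp + chanmix(gpre, t(params$gates[[j]]$Wd))
    } else {
      ge <- gge
    }
    ge_skip[[lvl]] <- ge
    pb <- prelu_bw(cache$dec_n[[j]], params$dec[[j]]$a, gp)
    ib <- inorm_bw(cache$dec_ic[[j]], params$dec[[j]]$gamma, pb$gx)
    tb <- tconv_bw(cache$dec_in[[j]], params$dec[[j]]$V, ib$gx, k, s, p)
    grads$dec[[j]] <- list(V = tb$gV, b = tb$gb, gamma = ib$ggamma,
                           beta = ib$gbeta, a = pb$ga)
    gd <- tb$gx
  }
  ge_tot <- gd            # gradient at the bottleneck activation e[[D]]
  gx <- NULL
  for (i in rev(seq_len(D))) {
    if (!is.null(ge_skip[[i]])) ge_tot <- ge_tot + ge_skip[[i]]
    pb <- prelu_bw(cache$enc_n[[i]], params$enc[[i]]$a, ge_tot)
    ib <- inorm_bw(cache$enc_ic[[i]], params$enc[[i]]$gamma, pb$gx)
    cb <- conv_bw(cache$enc_in[[i]], params$enc[[i]]$W, ib$gx, k, s, p)
    grads$enc[[i]] <- list(W = cb$gW, b = cb$gb, gamma = ib$ggamma,
                           beta = ib$gbeta, a = pb$ga)
    if (i > 1L) ge_tot <- cb$gx else gx <- cb$gx
  }
  list(grads = grads, gx = gx)
}

#' Generator forward on normalized windows (user-facing)
#'
#' Convenience wrapper around [gen_forward()]: accepts a vector or `(L, B)`
#' matrix of windows already normalized to \[-1, 1\] and returns the
#' generated windows with the same shape.  Instance normalization makes every
#' sample's output independent of the rest of the batch.
#'
#' @param rough_window numeric vector, `(L, B)` matrix, or `(1, L, B)` array.
#' @param params generator parameters ([gen_init()]); freshly initialized
#'   from seed 1 when omitted.
#' @param cfg a [generator_config()].
#' @return object with the same shape as the input.
#' @export
generator_forward <- function(rough_window, params = NULL,
                              cfg = generator_config()) {
  if (is.null(params)) params <- gen_init(cfg, seed = 1)
  out <- gen_forward(params, rough_window, cfg)
  reshape_like(out, rough_window)
}

as_clb <- function(x, channels = 1L) {
  if (is.array(x) && length(dim(x)) == 3L) return(x)
  if (is.matrix(x)) return(array(x, dim = c(1L, nrow(x), ncol(x))))
  array(as.numeric(x), dim = c(1L, length(x), 1L))
}

reshape_like <- function(out, x) {
  if (is.array(x) && length(dim(x)) == 3L) return(out)
  if (is.matrix(x)) return(matrix(out, nrow = dim(out)[2]))
  as.numeric(out)
}

# ---- discriminator ---------------------------------------------------------

disc_channels <- function(dcfg) {
  dcfg$base_channels * 2^(seq_len(dcfg$n_layers - 1L) - 1L)
}

#' Initialize discriminator parameters
#'
#' @param dcfg a [discriminator_config()].
#' @param seed integer RNG seed.
#' @param init_std weight-init std (default 0.02).
#' @return nested parameter list.
#' @export
disc_init <- function(dcfg = discriminator_config(), seed = 1,
                      init_std = 0.02) {
  ch <- disc_channels(dcfg)
  k <- dcfg$kernel
  with_local_seed(seed, {
    layers <- vector("list", dcfg$n_layers)
    cin <- dcfg$in_channels
    for (i in seq_along(ch)) {
      layers[[i]] <- list(W = gauss_mat(ch[i], cin * k, init_std),
                          b = numeric(ch[i]), gamma = rep(1, ch[i]),
                          beta = numeric(ch[i]))
      cin <- ch[i]
    }
    layers[[dcfg$n_layers]] <- list(W = gauss_mat(1L, cin * k, init_std),
                                    b = numeric(1))
    list(layers = layers)
  })
}

disc_fw <- function(params, x, dcfg = discriminator_config(),
                    keep_cache = FALSE) {
  k <- dcfg$kernel; p <- dcfg$pad
  nl <- dcfg$n_layers
  ins <- vector("list", nl)
  zs <- vector("list", nl)
  ics <- vector("list", nl)
  ns <- vector("list", nl)
  h <- x
  for (i in seq_len(nl - 1L)) {
    ins[[i]] <- h
    z <- conv_fw(h, params$layers[[i]]$W, params$layers[[i]]$b, k,
                 dcfg$stride, p)
    zs[[i]] <- z
    nf <- inorm_fw(z, params$layers[[i]]$gamma, params$layers[[i]]$beta)
    ics[[i]] <- nf$cache
    ns[[i]] <- nf$y
    h <- lrelu_fw(nf$y)
  }
  ins[[nl]] <- h
  patch <- conv_fw(h, params$layers[[nl]]$W, params$layers[[nl]]$b, k, 1L, p)
  score <- colMeans(matrix(patch, nrow = dim(patch)[1] * dim(patch)[2]))
  if (!keep_cache) return(score)
  list(score = score,
       cache = list(ins = ins, zs = zs, ics = ics, ns = ns, patch = patch))
}

# gscore: vector of dL/d(score_b); returns grads and gx (grad wrt input)
disc_bw <- function(params, cache, gscore, dcfg = discriminator_config()) {
  k <- dcfg$kernel; p <- dcfg$pad
  nl <- dcfg$n_layers
  dp <- dim(cache$patch)
  npatch <- dp[1] * dp[2]
  gpatch <- array(rep(gscore / npatch, each = npatch), dim = dp)
  grads <- list(layers = vector("list", nl))
  cb <- conv_bw(cache$ins[[nl]], params$layers[[nl]]$W, gpatch, k, 1L, p)
  grads$layers[[nl]] <- list(W = cb$gW, b = cb$gb)
  gh <- cb$gx
  for (i in rev(seq_len(nl - 1L))) {
    gn <- lrelu_bw(cache$ns[[i]], gh)
    ib <- inorm_bw(cache$ics[[i]], params$layers[[i]]$gamma, gn)
    cb <- conv_bw(cache$ins[[i]], params$layers[[i]]$W, ib$gx, k,
                  dcfg$stride, p)
    grads$layers[[i]] <- list(W = cb$gW, b = cb$gb, gamma = ib$ggamma,
                              beta = ib$gbeta)
    gh <- cb$gx
  }
  list(grads = grads, gx = gh)
}

#' Discriminator forward (user-facing)
#'
#' Stacks the candidate and conditioning signals as a two-channel input and
#' returns one realness score per sample (patch scores averaged; final layer
#' linear).
#'
#' @param candidate,condition numeric vectors or `(L, B)` matrices of equal
#'   shape.
#' @param params parameters from [disc_init()]; freshly initialized from
#'   seed 1 when omitted.
#' @param cfg a [discriminator_config()].
#' @return numeric vector of per-sample scores.
#' @export
discriminator_forward <- function(candidate, condition, params = NULL,
                                  cfg = discriminator_config()) {
  if (is.null(params)) params <- disc_init(cfg, seed = 1)
  cand <- if (is.matrix(candidate)) candidate else
    matrix(candidate, ncol = 1)
  cond <- if (is.matrix(condition)) condition else matrix(condition, ncol = 1)
  if (!identical(dim(cand), dim(cond))) {
    stopf("candidate and condition must have equal length/shape")
  }
  x <- array(0, dim = c(2L, nrow(cand), ncol(cand)))
  x[1L, , ] <- cand
  x[2L, , ] <- cond
  disc_fw(params, x, cfg)
}

stack_two_channel <- function(cand, cond) {
  d <- dim(cand)
  x <- array(0, dim = c(2L, d[2], d[3]))
  x[1L, , ] <- cand[1L, , ]
  x[2L, , ] <- cond[1L, , ]
  x
}
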