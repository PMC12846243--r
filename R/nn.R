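# Minimal neural-network primitives with hand-derived backpropagation.
#
# Activations are numeric arrays of dimension (channels, length, batch).
# Convolutions run through the RcppArmadillo kernels in src/conv1d.cpp; the
# element-wise pieces (instance norm, PReLU, LeakyReLU, sigmoid gates, tanh)
# are vectorized R.  Gradients are verified against central finite
# differences in the test suite.

IN_EPS <- 1e-5

conv_fw <- function(x, W, b, k, stride, pad) {
  conv1d_fw_cpp(x, W, b, as.integer(k), as.integer(stride), as.integer(pad))
}

conv_bw <- function(x, W, gout, k, stride, pad) {
  gx <- conv1d_bw_input_cpp(W, gout, dim(x)[2], as.integer(k),
                            as.integer(stride), as.integer(pad))
  gW <- conv1d_bw_weight_cpp(x, gout, as.integer(k), as.integer(stride),
                             as.integer(pad))
  gb <- rowSums(matrix(gout, nrow = dim(gout)[1]))
  list(gx = gx, gW = gW, gb = gb)
}

# transposed conv: weight V is the conv-style matrix of the reverse map
# (rows = in-channels of the tconv, cols = out-channels * k)
tconv_fw <- function(x, V, b, k, stride, pad) {
  Lout <- (dim(x)[2] - 1L) * stride - 2L * pad + k
  y <- conv1d_bw_input_cpp(V, x, as.integer(Lout), as.integer(k),
                           as.integer(stride), as.integer(pad))
  y + b   # bias recycles along the channel (first) dimension
}

tconv_bw <- function(x, V, gout, k, stride, pad) {
  gx <- conv1d_fw_cpp(gout, V, numeric(nrow(V)), as.integer(k),
                      as.integer(stride), as.integer(pad))
  gV <- conv1d_bw_weight_cpp(gout, x, as.integer(k), as.integer(stride),
                             as.integer(pad))
  gb <- rowSums(matrix(gout, nrow = dim(gout)[1]))
  list(gx = gx, gV = gV, gb = gb)
}

# ---- instance normalization (affine, per channel and sample over length) --

inorm_fw <- function(x, gamma, beta) {
  r <- inorm_fw_cpp(x, gamma, beta)
  list(y = r$y, cache = list(xhat = r$xhat, istd = r$istd))
}

inorm_bw <- function(cache, gamma, gout) {
  r <- inorm_bw_cpp(cache$xhat, cache$istd, gamma, gout)
  list(gx = r$gx, ggamma = as.numeric(r$ggamma),
       gbeta = as.numeric(r$gbeta))
}

# ---- activations -----------------------------------------------------------

prelu_fw <- function(x, a) prelu_fw_cpp(x, a)

prelu_bw <- function(x, a, gout) {
  r <- prelu_bw_cpp(x, a, gout)
  list(gx = r$gx, ga = as.numeric(r$ga))
}

lrelu_fw <- function(x, slope = 0.2) lrelu_fw_cpp(x, slope)

lrelu_bw <- function(x, gout, slope = 0.2) lrelu_bw_cpp(x, gout, slope)

sigmoid <- function(x) 1 / (1 + exp(-x))

# 1x1 channel-mixing convolution used by the skip gates
chanmix <- function(x, M) {
  d <- dim(x)
  out <- M %*% matrix(x, nrow = d[1])
  dim(out) <- c(nrow(M), d[2], d[3])
  out
}

# ---- Adam ------------------------------------------------------------------

zeros_like <- function(p) {
  if (is.null(p)) return(NULL)
  if (is.list(p)) lapply(p, zeros_like) else p * 0
}

adam_init <- function(params) {
  list(m = zeros_like(params), v = zeros_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr = 2e-4, beta1 = 0.5,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  rec <- function(p, g, m, v) {
    if (is.null(p)) return(list(NULL, NULL, NULL))
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (i in seq_along(p)) {
        r <- rec(p[[i]], g[[i]], m[[i]], v[[i]])
        out_p[[i]] <- r[[1]]; out_m[[i]] <- r[[2]]; out_v[[i]] <- r[[3]]
      }
      list(out_p, out_m, out_v)
    } else {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g * g
      list(p - lr * (m / bc1) / (sqrt(v / bc2) + eps), m, v)
    }
  }
  r <- rec(params, grads, state$m, state$v)
  list(params = r[[1]], state = list(m = r[[2]], v = r[[3]], t = state$t))
}

# Gaussian N(0, sd^2) weight init, matching the training protocol
gauss_mat <- function(nr, nc, sd = 0.02) matrix(rnorm(nr * nc, 0, sd), nr, nc)
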