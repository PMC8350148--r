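# Minimal neural-network primitives used by the connectivity model.
#
# Conventions:
#   * dense inputs are (n_samples x n_features) matrices; weights are
#     (n_in x n_out); biases length n_out.
#   * 1-D convolution operates on arrays with dim (channels, length, batch);
#     kernels are stored as (c_out, c_in * k) with the input channel running
#     fastest, so row o, column c + c_in*(kk-1) holds the weight connecting
#     input channel c at kernel offset kk to output channel o.
#   * every *_fwd returns list(out, <cache fields>); *_bwd consumes the
#     gradient of the loss w.r.t. `out` and returns dX plus parameter grads.
# All parameters live in nested lists with leaves W / b so that a single
# recursive Adam update covers the whole model.

nn_linear_init <- function(n_in, n_out) {
  bound <- 1 / sqrt(n_in)
  list(W = matrix(stats::runif(n_in * n_out, -bound, bound), n_in, n_out),
       b = stats::runif(n_out, -bound, bound))
}

nn_conv_init <- function(c_in, c_out, k) {
  fan_in <- c_in * k
  bound <- 1 / sqrt(fan_in)
  list(W = matrix(stats::runif(c_out * fan_in, -bound, bound), c_out, fan_in),
       b = stats::runif(c_out, -bound, bound))
}

nn_linear_fwd <- function(X, par) {
  Y <- X %*% par$W
  Y <- Y + rep(par$b, each = nrow(Y))
  list(out = Y, X = X)
}

nn_linear_bwd <- function(dY, par, cache) {
  list(dX = dY %*% t(par$W),
       dW = crossprod(cache$X, dY),
       db = colSums(dY))
}

nn_relu_fwd <- function(X) {
  pos <- X > 0
  list(out = X * pos, pos = pos)
}

nn_relu_bwd <- function(dY, cache) dY * cache$pos

nn_sigmoid <- function(x) 1 / (1 + exp(-x))

# inverted dropout; draws from the current RNG stream
nn_dropout_fwd <- function(X, rate) {
  if (rate <= 0) return(list(out = X, mask = NULL, rate = rate))
  keep <- (stats::runif(length(X)) >= rate) / (1 - rate)
  dim(keep) <- dim(X)
  list(out = X * keep, mask = keep, rate = rate)
}

nn_dropout_bwd <- function(dY, cache) {
  if (is.null(cache$mask)) dY else dY * cache$mask
}

# 'same' 1-D convolution, stride 1, odd kernel, pad = (k-1)/2;
# compiled kernels in src/nn_kernels.cpp do the im2col work
nn_conv_fwd <- function(A, par, k, pad) {
  list(out = .conv1d_fwd(A, par$W, par$b, k, pad), A = A)
}

nn_conv_bwd <- function(dY, par, cache, k, pad) {
  .conv1d_bwd(dY, cache$A, par$W, k, pad)
}

# max pooling, kernel 2 stride 2; ties resolved to the earlier position
nn_pool_fwd <- function(A) {
  out <- .pool2_fwd(A)
  out$dimA <- dim(A)
  out
}

nn_pool_bwd <- function(dY, cache) {
  .pool2_bwd(dY, cache$take1, cache$dimA[2L])
}

# ---- nested parameter-list algebra ----------------------------------------

par_map <- function(f, x, ...) {
  if (is.list(x)) {
    out <- x
    rest <- list(...)
    for (i in seq_along(x)) {
      out[[i]] <- do.call(par_map, c(list(f, x[[i]]), lapply(rest, `[[`, i)))
    }
    out
  } else {
    f(x, ...)
  }
}

par_zeros <- function(p) par_map(function(x) x * 0, p)
par_add <- function(a, b) par_map(`+`, a, b)
par_scale <- function(p, s) par_map(function(x) x * s, p)

# flatten all leaves into one numeric vector (fixed traversal order) and back;
# used by the finite-difference gradient checks and the optimizer state dump
par_unlist <- function(p) unlist(p, use.names = FALSE)

par_relist <- function(values, skeleton) {
  i <- 0L
  rec <- function(x) {
    if (is.list(x)) {
      for (k in seq_along(x)) x[[k]] <- rec(x[[k]])
      x
    } else {
      v <- values[(i + 1L):(i + length(x))]
      i <<- i + length(x)
      dim(v) <- dim(x)
      v
    }
  }
  rec(skeleton)
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = par_zeros(params), v = par_zeros(params), t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.5, beta2 = 0.999, eps = 1e-8,
                      weight_decay = 0) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    # decoupled weight decay (AdamW): shrinkage applied outside the moments
    list(p = p * (1 - lr * weight_decay) - lr * mhat / (sqrt(vhat) + eps),
         m = m, v = v)
  }
  rec <- function(p, g, m, v) {
    if (is.list(p)) {
      for (i in seq_along(p)) {
        r <- rec(p[[i]], g[[i]], m[[i]], v[[i]])
        p[[i]] <- r$p; m[[i]] <- r$m; v[[i]] <- r$v
      }
      list(p = p, m = m, v = v)
    } else {
      upd(p, g, m, v)
    }
  }
  r <- rec(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = t))
}
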