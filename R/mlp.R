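## Multilayer perceptrons in plain matrix algebra, with explicit
## reverse-mode gradients. Each MLP is N_layer hidden blocks (affine + ReLU,
## with inverted dropout after the rectifier during training) followed by an
## affine output layer. Parameters use the uniform fan-in initialization
## W, b ~ U(-1/sqrt(d_in), 1/sqrt(d_in)).

mlp_init <- function(d_in, d_hidden, d_out, n_layer) {
  dims <- c(d_in, rep(d_hidden, n_layer), d_out)
  W <- vector("list", n_layer + 1L)
  b <- vector("list", n_layer + 1L)
  for (j in seq_len(n_layer + 1L)) {
    s <- 1 / sqrt(dims[j])
    W[[j]] <- matrix(stats::runif(dims[j] * dims[j + 1L], -s, s), dims[j], dims[j + 1L])
    b[[j]] <- stats::runif(dims[j + 1L], -s, s)
  }
  list(W = W, b = b)
}

# Forward through one MLP (compiled kernel). Returns the output and (if
# keep) the cache needed for the backward sweep: the input of every affine
# layer and the combined ReLU x dropout multiplier of every hidden block.
mlp_fwd <- function(m, X, p = 0, training = FALSE, keep = TRUE) {
  mlp_fwd_cpp(m$W, m$b, X, p, training, keep)
}

# Backward through one MLP given the gradient of the loss in its output.
# Returns the gradient in the input plus per-layer parameter gradients.
mlp_bwd <- function(m, cache, gout) {
  r <- mlp_bwd_cpp(m$W, cache$ins, cache$mask, gout)
  r$gb <- lapply(r$gb, as.vector)
  r
}

# Gradient accumulator across the repeated MLP applications of one model
# pass: nested structure mirroring model$params.
grad_acc_new <- function(params) {
  rapply(params, function(x) x * 0, how = "replace")
}

acc_mlp_grad <- function(acc, name, bk) {
  for (j in seq_along(bk$gW)) {
    acc[[name]]$W[[j]] <- acc[[name]]$W[[j]] + bk$gW[[j]]
    acc[[name]]$b[[j]] <- acc[[name]]$b[[j]] + bk$gb[[j]]
  }
  acc
}

## ---- Adam --------------------------------------------------------------

adam_new <- function(params, lr = 1e-4, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(m = rapply(params, function(x) x * 0, how = "replace"),
       v = rapply(params, function(x) x * 0, how = "replace"),
       t = 0L, lr = lr, beta1 = beta1, beta2 = beta2, eps = eps)
}

adam_step <- function(params, grads, st) {
  st$t <- st$t + 1L
  out <- adam_step_cpp(params, grads, st$m, st$v, st$lr, st$beta1, st$beta2,
                       st$eps, st$t)
  st$m <- out$m; st$v <- out$v
  list(params = out$p, state = st)
}
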