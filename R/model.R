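## The message-passing model family.
##
## One forward pass over an Nt-frame window (or a batch of per-target
## subgraphs) composes up to three stages, each a synchronous edge-model /
## node-model update:
##
##   backward temporal  A = Phi^B,edge(a[dst], a[src]); B = sum over the
##                      daughter set D; a <- Phi^B,node(B, a)  (Nt-1 times,
##                      future -> past, final frame frozen, B = 0 for tracks
##                      that end)
##   spatial            H = phi^edge(b[dst], b[src]) over directed contact
##                      edges; I = AGG (sum or mean) over in-neighbors;
##                      b <- phi^node(I, b)  (Ns times)
##   forward temporal   U = Phi^F,edge(c[dst], c[src]) over parent edges;
##                      V = U of the (unique) parent edge, 0 for cells that
##                      enter the field of view; c <- Phi^F,node(V, c)
##                      (Nt-1 times, past -> future)
##
## and decodes each target's final-frame state through psi^dec into three
## fate logits. Variants: "bidirectional" (all stages), "unidirectional"
## (no backward stage, b initialized from the raw features),
## "cell_external" (unidirectional with the target's own ancestor-chain
## features nulled at spatial initialization), "no_spatial" (unidirectional
## without the contact stage). Every edge model takes
## concat(state[receiver], state[sender]).

#' Model configuration
#'
#' @param variant One of `"bidirectional"`, `"unidirectional"`,
#'   `"cell_external"`, `"no_spatial"`.
#' @param aggregation Spatial neighbor aggregation, `"sum"` or `"mean"`.
#'   Mean over an empty neighbor set is defined as the zero vector.
#' @param Nt Frames per window (>= 2).
#' @param Ns Spatial message-passing iterations (>= 0).
#' @param n_layer,n_node,dropout MLP hyperparameters: number of hidden
#'   blocks, hidden width, and dropout probability applied after each hidden
#'   rectifier during training.
#' @param forward_freeze Which frame the forward temporal stage leaves
#'   untouched: `"first"` (no parent exists there; the default) or
#'   `"final"`.
#' @return A `model_config` list.
#' @export
model_config <- function(variant = c("bidirectional", "unidirectional", "cell_external", "no_spatial"),
                         aggregation = c("sum", "mean"),
                         Nt = 4L, Ns = 1L, n_layer = 1L, n_node = 50L, dropout = 0.1,
                         forward_freeze = c("first", "final")) {
  variant <- match.arg(variant)
  aggregation <- match.arg(aggregation)
  forward_freeze <- match.arg(forward_freeze)
  stopifnot(Nt >= 2, Ns >= 0, n_layer >= 1, n_node >= 1, dropout >= 0, dropout < 1)
  structure(list(variant = variant, aggregation = aggregation, Nt = as.integer(Nt),
                 Ns = as.integer(Ns), n = 6L, n_layer = as.integer(n_layer),
                 n_node = as.integer(n_node), dropout = dropout,
                 forward_freeze = forward_freeze),
            class = "model_config")
}

mlp_names_for <- function(config) {
  switch(config$variant,
         bidirectional = c("bedge", "bnode", "sedge", "snode", "fedge", "fnode", "dec"),
         unidirectional = c("sedge", "snode", "fedge", "fnode", "dec"),
         cell_external = c("sedge", "snode", "fedge", "fnode", "dec"),
         no_spatial = c("fedge", "fnode", "dec"))
}

#' Initialize a model
#'
#' Creates the MLP collection required by the configured variant (up to
#' seven networks: backward temporal edge/node, spatial edge/node, forward
#' temporal edge/node, decoder), with reproducible uniform fan-in weights.
#'
#' @param config A [model_config()].
#' @param seed Integer seed for weight initialization.
#' @return An `fc_model`.
#' @export
init_model <- function(config, seed = 1L) {
  n <- config$n
  params <- with_local_seed(seed, {
    p <- list()
    for (nm in mlp_names_for(config)) {
      p[[nm]] <- if (nm == "dec") mlp_init(n, config$n_node, 3L, config$n_layer)
                 else mlp_init(2L * n, config$n_node, n, config$n_layer)
    }
    p
  })
  structure(list(config = config, params = params, seed = seed), class = "fc_model")
}

#' @export
print.fc_model <- function(x, ...) {
  np <- sum(rapply(x$params, length, how = "unlist"))
  cat(sprintf("Cell-fate model: variant=%s agg=%s Nt=%d Ns=%d (%d parameters)\n",
              x$config$variant, x$config$aggregation, x$config$Nt, x$config$Ns, np))
  invisible(x)
}

scatter_sum <- function(E, dst, n) {
  out <- matrix(0, n, ncol(E))
  if (nrow(E)) {
    rs <- rowsum(E, group = dst)
    out[as.integer(rownames(rs)), ] <- rs
  }
  out
}

softmax_rows <- function(Z) {
  m <- Z[, 1]
  for (j in 2:ncol(Z)) m <- pmax(m, Z[, j])
  E <- exp(Z - m)
  E / rowSums(E)
}

## ---- generic engine ----------------------------------------------------

# Forward over a tensor set (window_tensors / subgraph_batch_tensors).
# Returns logits, softmax scores, and (if keep_cache) everything needed for
# engine_backward.
engine_forward <- function(model, tens, training = FALSE, keep_cache = FALSE) {
  cfg <- model$config
  p <- cfg$dropout
  n <- cfg$n
  N <- tens$n_nodes
  X <- tens$X
  if (ncol(X) != n) stop("feature dimension mismatch")
  kc <- keep_cache
  cache <- list()

  a <- X
  if (cfg$variant == "bidirectional") {
    upd <- which(tens$rel < 0L)
    cache$back <- vector("list", cfg$Nt - 1L)
    for (k in seq_len(cfg$Nt - 1L)) {
      ce <- mlp_fwd(model$params$bedge, cbind(a[tens$back_dst, , drop = FALSE],
                                              a[tens$back_src, , drop = FALSE]),
                    p, training, kc)
      B <- scatter_sum(ce$out, tens$back_dst, N)
      cn <- mlp_fwd(model$params$bnode, cbind(B[upd, , drop = FALSE], a[upd, , drop = FALSE]),
                    p, training, kc)
      a[upd, ] <- cn$out
      if (kc) cache$back[[k]] <- list(edge = ce, node = cn)
    }
    b <- a
  } else {
    b <- X
  }
  if (cfg$variant == "cell_external") {
    if (is.null(tens$zero_mask))
      stop("cell_external generic evaluation needs per-target subgraph tensors (zero_mask)")
    b[tens$zero_mask, ] <- 0
  }

  if (cfg$variant != "no_spatial" && cfg$Ns > 0L) {
    cache$sp <- vector("list", cfg$Ns)
    dval <- pmax(tens$sp_deg, 1L)
    for (l in seq_len(cfg$Ns)) {
      ce <- mlp_fwd(model$params$sedge, cbind(b[tens$sp_dst, , drop = FALSE],
                                              b[tens$sp_src, , drop = FALSE]),
                    p, training, kc)
      I <- scatter_sum(ce$out, tens$sp_dst, N)
      if (cfg$aggregation == "mean") I <- I / dval
      cn <- mlp_fwd(model$params$snode, cbind(I, b), p, training, kc)
      b <- cn$out
      if (kc) cache$sp[[l]] <- list(edge = ce, node = cn)
    }
  }

  cc <- b
  first_rel <- -(cfg$Nt - 1L)
  upd <- if (cfg$forward_freeze == "first") which(tens$rel > first_rel) else which(tens$rel < 0L)
  updm <- logical(N); updm[upd] <- TRUE
  eu <- which(updm[tens$fwd_dst])
  vpos <- match(tens$fwd_dst[eu], upd)
  cache$fwd <- vector("list", cfg$Nt - 1L)
  for (m in seq_len(cfg$Nt - 1L)) {
    ce <- mlp_fwd(model$params$fedge, cbind(cc[tens$fwd_dst[eu], , drop = FALSE],
                                            cc[tens$fwd_src[eu], , drop = FALSE]),
                  p, training, kc)
    V <- matrix(0, length(upd), n)
    V[vpos, ] <- ce$out
    cn <- mlp_fwd(model$params$fnode, cbind(V, cc[upd, , drop = FALSE]), p, training, kc)
    cc[upd, ] <- cn$out
    if (kc) cache$fwd[[m]] <- list(edge = ce, node = cn)
  }

  dec <- mlp_fwd(model$params$dec, cc[tens$targets, , drop = FALSE], p, training, kc)
  logits <- dec$out
  out <- list(logits = logits, probs = softmax_rows(logits))
  if (kc) {
    cache$dec <- dec
    cache$fwd_idx <- list(upd = upd, eu = eu, vpos = vpos)
    out$cache <- cache
  }
  out
}

# Reverse sweep of engine_forward. glogits is the loss gradient in the
# decoder output (one row per target). Returns parameter gradients and,
# optionally, the gradient in the input feature matrix.
engine_backward <- function(model, tens, cache, glogits, want_gx = FALSE) {
  cfg <- model$config
  n <- cfg$n
  N <- tens$n_nodes
  acc <- grad_acc_new(model$params)

  bk <- mlp_bwd(model$params$dec, cache$dec, glogits)
  acc <- acc_mlp_grad(acc, "dec", bk)
  gc_ <- matrix(0, N, n)
  gc_[tens$targets, ] <- gc_[tens$targets, ] + bk$gin

  upd <- cache$fwd_idx$upd; eu <- cache$fwd_idx$eu; vpos <- cache$fwd_idx$vpos
  for (m in rev(seq_len(cfg$Nt - 1L))) {
    st <- cache$fwd[[m]]
    bn <- mlp_bwd(model$params$fnode, st$node, gc_[upd, , drop = FALSE])
    acc <- acc_mlp_grad(acc, "fnode", bn)
    gV <- bn$gin[, 1:n, drop = FALSE]
    gc_[upd, ] <- bn$gin[, (n + 1):(2 * n), drop = FALSE]
    if (length(eu)) {
      be <- mlp_bwd(model$params$fedge, st$edge, gV[vpos, , drop = FALSE])
      acc <- acc_mlp_grad(acc, "fedge", be)
      gc_ <- gc_ + scatter_sum(be$gin[, 1:n, drop = FALSE], tens$fwd_dst[eu], N)
      gc_ <- gc_ + scatter_sum(be$gin[, (n + 1):(2 * n), drop = FALSE], tens$fwd_src[eu], N)
    }
  }

  if (cfg$variant != "no_spatial" && cfg$Ns > 0L) {
    dval <- pmax(tens$sp_deg, 1L)
    for (l in rev(seq_len(cfg$Ns))) {
      st <- cache$sp[[l]]
      bn <- mlp_bwd(model$params$snode, st$node, gc_)
      acc <- acc_mlp_grad(acc, "snode", bn)
      gI <- bn$gin[, 1:n, drop = FALSE]
      gc_ <- bn$gin[, (n + 1):(2 * n), drop = FALSE]
      if (length(tens$sp_dst)) {
        if (cfg$aggregation == "mean") gI <- gI / dval
        be <- mlp_bwd(model$params$sedge, st$edge, gI[tens$sp_dst, , drop = FALSE])
        acc <- acc_mlp_grad(acc, "sedge", be)
        gc_ <- gc_ + scatter_sum(be$gin[, 1:n, drop = FALSE], tens$sp_dst, N)
        gc_ <- gc_ + scatter_sum(be$gin[, (n + 1):(2 * n), drop = FALSE], tens$sp_src, N)
      }
    }
  }

  if (cfg$variant == "cell_external") gc_[tens$zero_mask, ] <- 0

  if (cfg$variant == "bidirectional") {
    updb <- which(tens$rel < 0L)
    for (k in rev(seq_len(cfg$Nt - 1L))) {
      st <- cache$back[[k]]
      bn <- mlp_bwd(model$params$bnode, st$node, gc_[updb, , drop = FALSE])
      acc <- acc_mlp_grad(acc, "bnode", bn)
      gB <- bn$gin[, 1:n, drop = FALSE]
      gc_[updb, ] <- bn$gin[, (n + 1):(2 * n), drop = FALSE]
      if (length(tens$back_dst)) {
        pos <- match(tens$back_dst, updb)
        be <- mlp_bwd(model$params$bedge, st$edge, gB[pos, , drop = FALSE])
        acc <- acc_mlp_grad(acc, "bedge", be)
        gc_ <- gc_ + scatter_sum(be$gin[, 1:n, drop = FALSE], tens$back_dst, N)
        gc_ <- gc_ + scatter_sum(be$gin[, (n + 1):(2 * n), drop = FALSE], tens$back_src, N)
      }
    }
  }

  list(grads = acc, gX = if (want_gx) gc_)
}

## ---- exported stage wrappers (operate on tensor sets) ------------------

#' Run the model on a window or subgraph batch
#'
#' Evaluates the configured message-passing composition and returns the
#' decoder logits and softmax fate scores for every target. Dropout is
#' disabled (evaluation mode).
#'
#' @param model An `fc_model`.
#' @param x An `stg_window`, a `target_subgraph`, or a prebuilt tensor set.
#' @param fconfig A [feature_config()] (ignored when `x` is already a tensor
#'   set).
#' @return `list(logits, probs)`, one row per target, columns NB/Del/Div.
#' @export
predict_fates <- function(model, x, fconfig = feature_config()) {
  tens <- as_tensors(x, model$config, fconfig)
  out <- engine_forward(model, tens, training = FALSE, keep_cache = FALSE)
  colnames(out$logits) <- colnames(out$probs) <- c("NB", "Del", "Div")
  out$y <- tens$y
  out
}

as_tensors <- function(x, mconfig, fconfig) {
  if (inherits(x, "stg_window")) {
    if (mconfig$variant == "cell_external")
      subgraph_batch_tensors(x, fconfig, Ns = max(mconfig$Ns, 1L))
    else window_tensors(x, fconfig)
  } else if (inherits(x, "target_subgraph")) {
    subgraph_tensors(x, fconfig)
  } else x
}
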