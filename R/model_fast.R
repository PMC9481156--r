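## Exact fast evaluation paths used by the training loop.
##
## Cell-external fast path (valid at Ns = 1): with the target's ancestor
## chain nulled at spatial initialization, the decoded state depends only on
## the chain's post-spatial states, and those are target-independent --
## a chain has exactly one node per frame and contact edges are within-frame,
## so no chain node is a spatial neighbor of another. Hence one shared
## spatial sweep with a zero receiver state, phi^node(AGG phi^edge(0, x_u), 0),
## yields every target's chain states at once; the forward temporal stage
## then runs on a batch of independent Nt-slot chains. This reproduces the
## per-target subgraph evaluation exactly (verified in the test suite).
##
## Null-graph fast path (uni/cell-external/no-spatial variants): with all
## features zero, every spatial message equals phi^edge(0, 0), so a node's
## state depends only on its contact degree (sum aggregation) or on whether
## it has any contact (mean). Targets collapse to the distinct
## (existence, parent, degree) signatures of their chains, weighted by
## multiplicity; expectations of the stochastic dropout updates are
## unchanged by the collapse.

# Precomputed arrays for the cell-external fast path on one window. Because
# the receiver state of every spatial edge is the null vector, the edge
# model output depends only on the source node: it is evaluated once per
# distinct source (src_nodes) and gathered per edge.
fast_tensors <- function(window, fconfig) {
  wt <- window_tensors(window, fconfig)
  slot <- chain_layout(window)
  rows_used <- sort(unique(slot[!is.na(slot)]))
  ei <- which(wt$sp_dst %in% rows_used)
  dstm <- match(wt$sp_dst[ei], rows_used)
  src_nodes <- sort(unique(wt$sp_src[ei]))
  smap <- matrix(match(slot, rows_used), nrow(slot), ncol(slot))
  list(X = wt$X, n_nodes = wt$n_nodes, Nt = wt$Nt, y = wt$y,
       src_nodes = src_nodes, src_map = match(wt$sp_src[ei], src_nodes),
       dstm = dstm,
       n_used = length(rows_used), rows_used = rows_used,
       deg_used = wt$sp_deg[rows_used],
       slot = smap, exists = !is.na(smap),
       n_targets = nrow(slot))
}

# Shared forward: returns logits per target plus cache.
fast_forward <- function(model, ft, training = FALSE, keep_cache = FALSE) {
  cfg <- model$config
  if (cfg$variant != "cell_external" || cfg$Ns != 1L)
    stop("fast path applies to the cell_external variant with Ns = 1")
  p <- cfg$dropout; n <- cfg$n
  Tn <- ft$n_targets; Nt <- ft$Nt
  kc <- keep_cache
  cache <- list()

  ce <- mlp_fwd(model$params$sedge,
                cbind(matrix(0, length(ft$src_nodes), n),
                      ft$X[ft$src_nodes, , drop = FALSE]),
                p, training, kc)
  I <- scatter_sum(ce$out[ft$src_map, , drop = FALSE], ft$dstm, ft$n_used)
  if (cfg$aggregation == "mean") I <- I / pmax(ft$deg_used, 1L)
  cn <- mlp_fwd(model$params$snode, cbind(I, matrix(0, ft$n_used, n)), p, training, kc)
  btilde <- cn$out
  if (kc) cache$sp <- list(edge = ce, node = cn)

  ## chain batch: row (t, tau) = (tau - 1) * Tn + t
  C <- matrix(0, Tn * Nt, n)
  sl <- as.vector(ft$slot)
  ex <- as.vector(ft$exists)
  C[which(ex), ] <- btilde[sl[ex], ]

  taus <- rep(seq_len(Nt), each = Tn)
  upd_tau <- if (cfg$forward_freeze == "first") taus > 1L else taus < Nt
  u <- which(ex & upd_tau)
  par_exists <- c(rep(FALSE, Tn), ex[seq_len(Tn * (Nt - 1L))])
  wp <- which(ex & upd_tau & par_exists)
  vrow <- match(wp, u)
  cache$fwd <- vector("list", Nt - 1L)
  for (m in seq_len(Nt - 1L)) {
    cef <- mlp_fwd(model$params$fedge, cbind(C[wp, , drop = FALSE], C[wp - Tn, , drop = FALSE]),
                   p, training, kc)
    V <- matrix(0, length(u), n)
    V[vrow, ] <- cef$out
    cnf <- mlp_fwd(model$params$fnode, cbind(V, C[u, , drop = FALSE]), p, training, kc)
    C[u, ] <- cnf$out
    if (kc) cache$fwd[[m]] <- list(edge = cef, node = cnf)
  }

  trows <- (Nt - 1L) * Tn + seq_len(Tn)
  dec <- mlp_fwd(model$params$dec, C[trows, , drop = FALSE], p, training, kc)
  out <- list(logits = dec$out, probs = softmax_rows(dec$out))
  if (kc) {
    cache$dec <- dec
    cache$idx <- list(u = u, wp = wp, vrow = vrow, trows = trows, ex = ex)
    out$cache <- cache
  }
  out
}

fast_backward <- function(model, ft, cache, glogits) {
  cfg <- model$config; n <- cfg$n
  Tn <- ft$n_targets; Nt <- ft$Nt
  acc <- grad_acc_new(model$params)
  idx <- cache$idx

  bk <- mlp_bwd(model$params$dec, cache$dec, glogits)
  acc <- acc_mlp_grad(acc, "dec", bk)
  gC <- matrix(0, Tn * Nt, n)
  gC[idx$trows, ] <- bk$gin

  for (m in rev(seq_len(Nt - 1L))) {
    st <- cache$fwd[[m]]
    bn <- mlp_bwd(model$params$fnode, st$node, gC[idx$u, , drop = FALSE])
    acc <- acc_mlp_grad(acc, "fnode", bn)
    gV <- bn$gin[, 1:n, drop = FALSE]
    gC[idx$u, ] <- bn$gin[, (n + 1):(2 * n), drop = FALSE]
    if (length(idx$wp)) {
      be <- mlp_bwd(model$params$fedge, st$edge, gV[idx$vrow, , drop = FALSE])
      acc <- acc_mlp_grad(acc, "fedge", be)
      gC[idx$wp, ] <- gC[idx$wp, ] + be$gin[, 1:n, drop = FALSE]
      gC[idx$wp - Tn, ] <- gC[idx$wp - Tn, ] + be$gin[, (n + 1):(2 * n), drop = FALSE]
    }
  }

  ## gradient into btilde rows, then through the shared spatial sweep
  gbt <- matrix(0, ft$n_used, n)
  ex <- idx$ex
  sl <- as.vector(ft$slot)
  gex <- rowsum(gC[which(ex), , drop = FALSE], group = sl[ex])
  gbt[as.integer(rownames(gex)), ] <- gex

  bn <- mlp_bwd(model$params$snode, cache$sp$node, gbt)
  acc <- acc_mlp_grad(acc, "snode", bn)
  gI <- bn$gin[, 1:n, drop = FALSE]
  if (cfg$aggregation == "mean") gI <- gI / pmax(ft$deg_used, 1L)
  gmsg <- scatter_sum(gI[ft$dstm, , drop = FALSE], ft$src_map, length(ft$src_nodes))
  be <- mlp_bwd(model$params$sedge, cache$sp$edge, gmsg)
  acc <- acc_mlp_grad(acc, "sedge", be)
  acc
}

## ---- collapsed null-graph pass -----------------------------------------

# Signature-collapsed representation of a window's null graph for the
# uni/cell-external/no-spatial variants.
null_tensors <- function(ft, mconfig) {
  sig <- matrix(0L, ft$n_targets, ft$Nt)
  sig[!ft$exists] <- -1L
  if (mconfig$variant != "no_spatial") {
    d <- matrix(0L, ft$n_targets, ft$Nt)
    d[ft$exists] <- ft$deg_used[ft$slot[ft$exists]]
    if (mconfig$aggregation == "mean") d <- (d > 0L) * 1L
    sig[ft$exists] <- d[ft$exists]
  }
  key <- apply(sig, 1L, paste, collapse = ",")
  uk <- unique(key)
  ii <- match(uk, key)
  list(sig = sig[ii, , drop = FALSE], counts = as.vector(table(key)[uk]),
       n_sub = ft$n_targets, Nt = ft$Nt)
}

# Forward + backward of the neutral-baseline MSE update on a collapsed null
# graph. Returns the loss and parameter gradients.
null_pass <- function(model, nt, training = FALSE) {
  cfg <- model$config; n <- cfg$n
  U <- nrow(nt$sig); Nt <- nt$Nt
  ex <- nt$sig >= 0L
  has_sp <- cfg$variant != "no_spatial"

  if (has_sp) {
    ce <- mlp_fwd(model$params$sedge, matrix(0, 1L, 2L * n), cfg$dropout, training, TRUE)
    m0 <- ce$out
    dmat <- pmax(nt$sig, 0L)
    Iall <- matrix(as.vector(dmat)[as.vector(ex)], ncol = 1) %*% m0
    cn <- mlp_fwd(model$params$snode, cbind(Iall, matrix(0, nrow(Iall), n)),
                  cfg$dropout, training, TRUE)
    bt <- cn$out
  }

  C <- matrix(0, U * Nt, n)
  if (has_sp) C[which(as.vector(ex)), ] <- bt
  taus <- rep(seq_len(Nt), each = U)
  exv <- as.vector(ex)
  upd_tau <- if (cfg$forward_freeze == "first") taus > 1L else taus < Nt
  u <- which(exv & upd_tau)
  par_exists <- c(rep(FALSE, U), exv[seq_len(U * (Nt - 1L))])
  wp <- which(exv & upd_tau & par_exists)
  vrow <- match(wp, u)
  fcache <- vector("list", Nt - 1L)
  for (m in seq_len(Nt - 1L)) {
    cef <- mlp_fwd(model$params$fedge, cbind(C[wp, , drop = FALSE], C[wp - U, , drop = FALSE]),
                   cfg$dropout, training, TRUE)
    V <- matrix(0, length(u), n)
    V[vrow, ] <- cef$out
    cnf <- mlp_fwd(model$params$fnode, cbind(V, C[u, , drop = FALSE]), cfg$dropout, training, TRUE)
    C[u, ] <- cnf$out
    fcache[[m]] <- list(edge = cef, node = cnf)
  }
  trows <- (Nt - 1L) * U + seq_len(U)
  dec <- mlp_fwd(model$params$dec, C[trows, , drop = FALSE], cfg$dropout, training, TRUE)
  probs <- softmax_rows(dec$out)

  w <- nt$counts
  loss <- sum(w * rowSums((probs - 1 / 3)^2)) / nt$n_sub

  ## backward
  gp <- (2 / nt$n_sub) * w * (probs - 1 / 3)
  gz <- probs * (gp - rowSums(gp * probs))
  acc <- grad_acc_new(model$params)
  bk <- mlp_bwd(model$params$dec, dec, gz)
  acc <- acc_mlp_grad(acc, "dec", bk)
  gC <- matrix(0, U * Nt, n)
  gC[trows, ] <- bk$gin
  for (m in rev(seq_len(Nt - 1L))) {
    st <- fcache[[m]]
    bn <- mlp_bwd(model$params$fnode, st$node, gC[u, , drop = FALSE])
    acc <- acc_mlp_grad(acc, "fnode", bn)
    gV <- bn$gin[, 1:n, drop = FALSE]
    gC[u, ] <- bn$gin[, (n + 1):(2 * n), drop = FALSE]
    if (length(wp)) {
      be <- mlp_bwd(model$params$fedge, st$edge, gV[vrow, , drop = FALSE])
      acc <- acc_mlp_grad(acc, "fedge", be)
      gC[wp, ] <- gC[wp, ] + be$gin[, 1:n, drop = FALSE]
      gC[wp - U, ] <- gC[wp - U, ] + be$gin[, (n + 1):(2 * n), drop = FALSE]
    }
  }
  if (has_sp) {
    gbt <- gC[which(exv), , drop = FALSE]
    bn <- mlp_bwd(model$params$snode, cn, gbt)
    acc <- acc_mlp_grad(acc, "snode", bn)
    gI <- bn$gin[, 1:n, drop = FALSE]
    gm0 <- matrix(colSums(gI * as.vector(dmat)[as.vector(ex)]), 1L, n)
    be <- mlp_bwd(model$params$sedge, ce, gm0)
    acc <- acc_mlp_grad(acc, "sedge", be)
  }
  list(loss = loss, grads = acc)
}
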