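# Independent reference implementation of the message-passing model:
# explicit per-node loops over the update equations, sharing only the
# weight values with the package implementation. Evaluation mode (no
# dropout).

ref_mlp <- function(m, x) {
  a <- x
  nl <- length(m$W) - 1L
  for (j in seq_len(nl)) a <- pmax(as.vector(a %*% m$W[[j]]) + m$b[[j]], 0)
  as.vector(a %*% m$W[[nl + 1L]]) + m$b[[nl + 1L]]
}

# Forward pass over a tensor set (window_tensors or subgraph batch),
# returning softmax scores per target.
ref_forward <- function(model, tens) {
  cfg <- model$config
  n <- cfg$n
  N <- tens$n_nodes
  getrow <- function(S, i) S[i, ]
  a <- tens$X

  if (cfg$variant == "bidirectional") {
    for (k in seq_len(cfg$Nt - 1L)) {
      a2 <- a
      for (v in seq_len(N)) {
        if (tens$rel[v] == 0L) next                       # final frame frozen
        B <- rep(0, n)
        es <- which(tens$back_dst == v)
        for (e in es)
          B <- B + ref_mlp(model$params$bedge, c(a[v, ], a[tens$back_src[e], ]))
        a2[v, ] <- ref_mlp(model$params$bnode, c(B, a[v, ]))
      }
      a <- a2
    }
    b <- a
  } else b <- tens$X
  if (cfg$variant == "cell_external") b[tens$zero_mask, ] <- 0

  if (cfg$variant != "no_spatial") {
    for (l in seq_len(cfg$Ns)) {
      b2 <- b
      for (v in seq_len(N)) {
        es <- which(tens$sp_dst == v)
        I <- rep(0, n)
        for (e in es)
          I <- I + ref_mlp(model$params$sedge, c(b[v, ], b[tens$sp_src[e], ]))
        if (cfg$aggregation == "mean" && length(es)) I <- I / length(es)
        b2[v, ] <- ref_mlp(model$params$snode, c(I, b[v, ]))
      }
      b <- b2
    }
  }

  cc <- b
  first_rel <- -(cfg$Nt - 1L)
  for (m in seq_len(cfg$Nt - 1L)) {
    c2 <- cc
    for (v in seq_len(N)) {
      frozen <- if (cfg$forward_freeze == "first") tens$rel[v] == first_rel
                else tens$rel[v] == 0L
      if (frozen) next
      e <- which(tens$fwd_dst == v)
      V <- if (length(e) == 1L)
        ref_mlp(model$params$fedge, c(cc[v, ], cc[tens$fwd_src[e], ]))
      else rep(0, n)
      c2[v, ] <- ref_mlp(model$params$fnode, c(V, cc[v, ]))
    }
    cc <- c2
  }

  probs <- t(vapply(tens$targets, function(v) {
    z <- ref_mlp(model$params$dec, cc[v, ])
    e <- exp(z - max(z)); e / sum(e)
  }, numeric(3)))
  probs
}

# O(n^2) pairwise-comparison AUC with half credit for ties.
ref_auc <- function(scores, positive) {
  pos <- scores[positive]
  neg <- scores[!positive]
  if (!length(pos) || !length(neg)) return(NA_real_)
  s <- 0
  for (p in pos) s <- s + sum(p > neg) + 0.5 * sum(p == neg)
  s / (length(pos) * length(neg))
}

# Brute-force periodic Delaunay adjacency: (i, j) are neighbors iff some
# triangle through them has an empty circumcircle (3x3 tiling for
# periodicity). O(n^3)-ish; for tiny n only.
brute_delaunay <- function(pos, L) {
  n <- nrow(pos)
  sh <- as.matrix(expand.grid(c(-L, 0, L), c(-L, 0, L)))
  tiled <- pos[rep(1:n, 9), ] + sh[rep(1:9, each = n), ]
  orig <- rep(1:n, 9)
  edges <- NULL
  for (i in 1:n) for (jt in seq_len(9 * n)) {
    if (jt == 4 * n + i) next
    p <- pos[i, ]; q <- tiled[jt, ]
    if (sum((p - q)^2) > (0.8 * L)^2) next
    for (kt in seq_len(9 * n)) {
      if (kt == jt || kt == 4 * n + i) next
      r <- tiled[kt, ]
      ax <- p[1]; ay <- p[2]; bx <- q[1]; by <- q[2]; cx <- r[1]; cy <- r[2]
      D <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
      if (abs(D) < 1e-12) next
      ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) + (cx^2 + cy^2) * (ay - by)) / D
      uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) + (cx^2 + cy^2) * (bx - ax)) / D
      rad2 <- (ax - ux)^2 + (ay - uy)^2
      d2 <- (tiled[, 1] - ux)^2 + (tiled[, 2] - uy)^2
      d2[c(jt, kt, 4 * n + i)] <- Inf
      if (min(d2) > rad2 + 1e-12) { edges <- rbind(edges, sort(c(i, orig[jt]))); break }
    }
  }
  unique(edges[edges[, 1] != edges[, 2], , drop = FALSE])
}
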