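## Prediction windows and per-target subgraphs.
##
## A window is a run of Nt consecutive frames re-indexed t = -(Nt-1) .. 0.
## Prediction targets are the cells in the final frame (t = 0) whose fate is
## one of NB/Del/Div; censored cells are never targets. A target's subgraph
## is its ancestor chain, the Ns-step contact neighborhoods of every
## ancestor (at the ancestor's own frame), and the within-window descendant
## closure of those neighbors, with all induced contact and lineage edges --
## exactly the receptive field of the message-passing model.

#' Extract all Nt-frame prediction windows from a graph
#'
#' @param graph An `stg`.
#' @param Nt Number of frames per window (>= 2).
#' @return A list of `stg_window` objects, one per contiguous `Nt`-frame run,
#'   each holding the node rows of the window and its eligible targets.
#' @export
extract_windows <- function(graph, Nt) {
  if (Nt < 2) stop("Nt must be at least 2")
  nf <- length(graph$frames)
  if (nf < Nt) stop(sprintf("graph has %d frames; need at least Nt = %d", nf, Nt))
  fpos <- match(graph$nodes$frame, graph$frames)
  lapply(seq_len(nf - Nt + 1L), function(s) {
    span <- s:(s + Nt - 1L)
    idx <- which(fpos %in% span)
    final <- which(fpos == span[Nt])
    targets <- final[graph$nodes$fate[final] %in% c("NB", "Del", "Div")]
    structure(list(graph = graph, frames = graph$frames[span], Nt = Nt,
                   idx = idx, target_idx = targets),
              class = "stg_window")
  })
}

#' @export
print.stg_window <- function(x, ...) {
  cat(sprintf("Prediction window: frames %s..%s (Nt = %d), %d nodes, %d targets\n",
              x$frames[1], x$frames[x$Nt], x$Nt, length(x$idx), length(x$target_idx)))
  invisible(x)
}

# Ancestor chain of a node within a window: global row indices ordered from
# the earliest present ancestor to the node itself. The walk stops at cells
# that appear without a parent (entered the field of view).
ancestor_chain <- function(window, node) {
  g <- window$graph
  par_of <- integer(nrow(g$nodes))
  par_of[g$lineage$hi] <- g$lineage$lo
  lo_f <- window$frames[1]
  chain <- node
  cur <- node
  while (g$nodes$frame[cur] > lo_f && par_of[cur] > 0L) {
    cur <- par_of[cur]
    chain <- c(cur, chain)
  }
  chain
}

#' Extract the subgraph feeding one target's prediction
#'
#' @param window An `stg_window`.
#' @param target Either a global node row index of `window$graph` or a
#'   length-2 vector `c(frame, cell_id)`; must lie in the window's final
#'   frame and be an eligible target.
#' @param Ns Number of spatial message-passing steps (contact-graph radius
#'   around each ancestor).
#' @return A `target_subgraph`: an induced `stg` plus the target's local row,
#'   its ancestor chain, and per-node relative frame and role
#'   (`lineage` / `neighbor`).
#' @export
extract_target_subgraph <- function(window, target, Ns = 1L) {
  g <- window$graph
  if (length(target) == 2L) {
    tg <- which(g$nodes$frame == target[1] & g$nodes$cell_id == target[2])
    if (!length(tg)) stop("target (frame, cell_id) not found")
    target <- tg
  }
  if (!target %in% window$target_idx) stop("target is not an eligible frame-0 target of this window")

  chain <- ancestor_chain(window, target)
  win_set <- rep(FALSE, nrow(g$nodes))
  win_set[window$idx] <- TRUE

  ## adjacency within the window's frames
  adj_a <- g$contacts$a[win_set[g$contacts$a] & win_set[g$contacts$b]]
  adj_b <- g$contacts$b[win_set[g$contacts$a] & win_set[g$contacts$b]]
  nb_of <- split(c(adj_b, adj_a), c(adj_a, adj_b))

  neigh <- integer(0)
  for (v in chain) {
    frontier <- v
    seen <- v
    if (Ns > 0) for (s in seq_len(Ns)) {
      nxt <- unique(unlist(nb_of[as.character(frontier)], use.names = FALSE))
      nxt <- setdiff(nxt, seen)
      if (!length(nxt)) break
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    neigh <- union(neigh, setdiff(seen, v))
  }

  ## descendant closure of the ancestor-neighbors, inside the window
  clos <- neigh
  frontier <- neigh
  while (length(frontier)) {
    kids <- g$lineage$hi[g$lineage$lo %in% frontier & win_set[g$lineage$hi]]
    kids <- setdiff(kids, clos)
    clos <- c(clos, kids)
    frontier <- kids
  }

  keep <- sort(unique(c(chain, clos)))
  g2l <- integer(nrow(g$nodes)); g2l[keep] <- seq_along(keep)

  csel <- win_set[g$contacts$a] & win_set[g$contacts$b] &
    g$contacts$a %in% keep & g$contacts$b %in% keep
  lsel <- g$lineage$lo %in% keep & g$lineage$hi %in% keep & win_set[g$lineage$hi] & win_set[g$lineage$lo]

  sub <- structure(list(
    nodes = g$nodes[keep],
    contacts = data.table::data.table(a = g2l[g$contacts$a[csel]], b = g2l[g$contacts$b[csel]]),
    lineage = data.table::data.table(lo = g2l[g$lineage$lo[lsel]], hi = g2l[g$lineage$hi[lsel]]),
    frames = window$frames
  ), class = "stg")

  role <- rep("neighbor", length(keep))
  role[g2l[chain]] <- "lineage"
  structure(list(
    graph = sub,
    target = g2l[target],
    chain = g2l[chain],
    rel = match(g$nodes$frame[keep], window$frames) - window$Nt,
    role = role,
    orig = keep,
    Nt = window$Nt
  ), class = "target_subgraph")
}

#' @export
print.target_subgraph <- function(x, ...) {
  cat(sprintf("Target subgraph: %d nodes (%d lineage, %d neighborhood), Nt = %d\n",
              nrow(x$graph$nodes), sum(x$role == "lineage"), sum(x$role == "neighbor"), x$Nt))
  invisible(x)
}

## ---- numeric tensor assembly -------------------------------------------

# Canonical feature matrix for a set of node rows. Inactive features are
# zeroed (dimension kept); NFB is nulled in the final frame of the window,
# since it is the prediction target there.
feature_matrix <- function(nodes, rel, fconfig) {
  n <- nrow(nodes)
  X <- matrix(0, n, 6,
              dimnames = list(NULL, c("area", "g1", "nfb_nb", "nfb_del", "nfb_div", "random")))
  if ("area" %in% fconfig$features) X[, 1] <- nodes$area
  if ("g1" %in% fconfig$features) X[, 2] <- nodes$g1
  if ("nfb" %in% fconfig$features) {
    X[, 3] <- nodes$nfb_nb
    X[, 4] <- nodes$nfb_del
    X[, 5] <- nodes$nfb_div
    X[rel == 0L, 3:5] <- 0
  }
  if ("random" %in% fconfig$features) {
    if (anyNA(nodes$random)) stop("random feature requested but not drawn; call add_random_feature()")
    X[, 6] <- nodes$random
  }
  X
}

# Numeric arrays for running the model on a whole window: features, relative
# frames, directed contact edges, temporal edge lists in both orientations,
# spatial in-degrees, and target rows with labels.
window_tensors <- function(window, fconfig) {
  g <- window$graph
  keep <- window$idx
  g2l <- integer(nrow(g$nodes)); g2l[keep] <- seq_along(keep)
  nodes <- g$nodes[keep]
  rel <- match(nodes$frame, window$frames) - window$Nt
  X <- feature_matrix(nodes, rel, fconfig)

  csel <- g2l[g$contacts$a] > 0L & g2l[g$contacts$b] > 0L
  la <- g2l[g$contacts$a[csel]]; lb <- g2l[g$contacts$b[csel]]
  lsel <- g2l[g$lineage$lo] > 0L & g2l[g$lineage$hi] > 0L
  lo <- g2l[g$lineage$lo[lsel]]; hi <- g2l[g$lineage$hi[lsel]]

  y <- match(g$nodes$fate[window$target_idx], c("NB", "Del", "Div"))
  list(
    X = X, rel = rel, Nt = window$Nt, n_nodes = length(keep),
    sp_dst = c(la, lb), sp_src = c(lb, la),
    back_dst = lo, back_src = hi,
    fwd_dst = hi, fwd_src = lo,
    sp_deg = tabulate(c(la, lb), nbins = length(keep)),
    targets = g2l[window$target_idx], y = y,
    zero_mask = NULL
  )
}

# Tensors for one target subgraph (or, via subgraph_batch_tensors, the
# disjoint union of many). zero_mask marks the target's ancestor chain for
# the cell-external variant; meta carries pooling information per node.
subgraph_tensors <- function(sg, fconfig) {
  g <- sg$graph
  nodes <- g$nodes
  X <- feature_matrix(nodes, sg$rel, fconfig)
  la <- g$contacts$a; lb <- g$contacts$b
  zm <- rep(FALSE, nrow(nodes)); zm[sg$chain] <- TRUE
  y <- match(nodes$fate[sg$target], c("NB", "Del", "Div"))
  list(
    X = X, rel = sg$rel, Nt = sg$Nt, n_nodes = nrow(nodes),
    sp_dst = c(la, lb), sp_src = c(lb, la),
    back_dst = g$lineage$lo, back_src = g$lineage$hi,
    fwd_dst = g$lineage$hi, fwd_src = g$lineage$lo,
    sp_deg = tabulate(c(la, lb), nbins = nrow(nodes)),
    targets = sg$target, y = y,
    zero_mask = zm,
    meta = data.table::data.table(target_row = 1L, rel = sg$rel, role = sg$role,
                                  nfb_nb = nodes$nfb_nb, nfb_del = nodes$nfb_del,
                                  nfb_div = nodes$nfb_div)
  )
}

# Disjoint-union batch of per-target subgraph tensors for a window.
subgraph_batch_tensors <- function(window, fconfig, Ns = 1L, targets = window$target_idx) {
  parts <- lapply(targets, function(tg)
    subgraph_tensors(extract_target_subgraph(window, tg, Ns), fconfig))
  off <- cumsum(c(0L, vapply(parts, `[[`, 0L, "n_nodes")))
  comb <- function(field) unlist(lapply(seq_along(parts), function(i) parts[[i]][[field]] + off[i]))
  meta <- data.table::rbindlist(lapply(seq_along(parts), function(i) {
    m <- data.table::copy(parts[[i]]$meta); m$target_row <- i; m
  }))
  list(
    X = do.call(rbind, lapply(parts, `[[`, "X")),
    rel = unlist(lapply(parts, `[[`, "rel")),
    Nt = window$Nt, n_nodes = off[length(off)],
    sp_dst = comb("sp_dst"), sp_src = comb("sp_src"),
    back_dst = comb("back_dst"), back_src = comb("back_src"),
    fwd_dst = comb("fwd_dst"), fwd_src = comb("fwd_src"),
    sp_deg = unlist(lapply(parts, `[[`, "sp_deg")),
    targets = comb("targets"), y = vapply(parts, `[[`, 0L, "y"),
    zero_mask = unlist(lapply(parts, `[[`, "zero_mask")),
    meta = meta
  )
}

# Ancestor-chain layout of all targets of a window, for the exact fast path
# of the cell-external variant at Ns = 1 (see model.R). slot[t, tau] is the
# local node row of target t's ancestor at relative frame tau (NA before the
# ancestor entered the window).
chain_layout <- function(window) {
  g <- window$graph
  keep <- window$idx
  g2l <- integer(nrow(g$nodes)); g2l[keep] <- seq_along(keep)
  Tn <- length(window$target_idx); Nt <- window$Nt
  slot <- matrix(NA_integer_, Tn, Nt)
  for (t in seq_len(Tn)) {
    ch <- ancestor_chain(window, window$target_idx[t])
    slot[t, (Nt - length(ch) + 1L):Nt] <- g2l[ch]
  }
  slot
}
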