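## Spatiotemporal cell graphs: cells as nodes over sampled frames, same-frame
## contact edges, and lineage edges across consecutive frames (division forks,
## continuations, terminals).
##
## A graph (`stg`) stores:
##   nodes    - one row per (frame, cell_id): parent_id, fate, area, g1,
##              nfb_nb/nfb_del/nfb_div, random, optional x/y centroids
##   contacts - same-frame unordered pairs (a < b), as node row indices
##   lineage  - temporal edges (lo = row at frame i, hi = row at frame i+1),
##              covering both continuations and daughters; the daughter set
##              D(i, cell) and the parent P(i+1, cell) are the two readings
##              of the same edge list
##   frames   - ordered frame values; adjacency is positional

#' Build a spatiotemporal cell graph from track and contact tables
#'
#' Assembles the package's central graph structure and derives fate labels
#' from the lineage structure: a cell with two children in the next frame
#' divides (`Div`), one child persists (`NB`), none and the track ends before
#' the last frame delaminates (`Del`) unless flagged `CENSOR`, and cells in
#' the last frame (or flagged) are `Censored`. A provided `fate` column is
#' validated against the derived labels; any inconsistency, dangling parent
#' reference or contact referencing a missing cell is an error naming the
#' offending row.
#'
#' @param tracks Track table (see [read_track_table()]); `fate` optional.
#' @param contacts Contact table with columns `frame`, `cell_id_a`,
#'   `cell_id_b`; may be `NULL` for a contact-free graph.
#' @return An object of class `stg`.
#' @export
build_graph <- function(tracks, contacts = NULL) {
  nodes <- data.table::as.data.table(tracks)
  need <- c("frame", "cell_id", "parent_id")
  miss <- setdiff(need, names(nodes))
  if (length(miss)) stop("track table missing column(s): ", paste(miss, collapse = ", "))
  if (!"area" %in% names(nodes)) nodes$area <- 0
  if (!"g1" %in% names(nodes)) nodes$g1 <- 0
  data.table::setorderv(nodes, c("frame", "cell_id"))
  code <- node_code(nodes$frame, nodes$cell_id)
  if (anyDuplicated(code)) {
    d <- nodes[duplicated(code)][1L]
    stop(sprintf("duplicate (frame, cell_id): frame=%d cell_id=%d", d$frame, d$cell_id))
  }
  frames <- sort(unique(nodes$frame))
  fpos <- match(nodes$frame, frames)
  n <- nrow(nodes)

  ## Resolve parent references (newborn daughters only; parent_id < 0 = none).
  parent_idx <- rep(NA_integer_, n)
  has_par <- !is.na(nodes$parent_id) & nodes$parent_id >= 0
  if (any(has_par)) {
    w <- which(has_par)
    if (any(fpos[w] == 1L)) {
      b <- nodes[w[fpos[w] == 1L][1L]]
      stop(sprintf("dangling parent reference in first frame: frame=%d cell_id=%d parent_id=%d",
                   b$frame, b$cell_id, b$parent_id))
    }
    pcode <- node_code(frames[fpos[w] - 1L], nodes$parent_id[w])
    parent_idx[w] <- match(pcode, code)
    if (anyNA(parent_idx[w])) {
      b <- nodes[w[is.na(parent_idx[w])][1L]]
      stop(sprintf("dangling parent reference: frame=%d cell_id=%d parent_id=%d",
                   b$frame, b$cell_id, b$parent_id))
    }
  }

  ## Continuations: same cell_id present in the next frame without a parent_id.
  next_code <- node_code(frames[pmin(fpos + 1L, length(frames))], nodes$cell_id)
  cont_idx <- ifelse(fpos < length(frames), match(next_code, code), NA_integer_)
  cont_idx[!is.na(cont_idx) & has_par[pmax(cont_idx, 1L)]] <- NA_integer_

  ## Temporal lineage edges lo (frame i) -> hi (frame i+1).
  lo <- c(which(!is.na(cont_idx)), parent_idx[has_par])
  hi <- c(cont_idx[!is.na(cont_idx)], which(has_par))
  nchild <- tabulate(lo, nbins = n)
  if (any(nchild > 2L)) {
    b <- nodes[which(nchild > 2L)[1L]]
    stop(sprintf("more than two daughters: frame=%d cell_id=%d", b$frame, b$cell_id))
  }

  derived <- character(n)
  derived[nchild == 2L] <- "Div"
  derived[nchild == 1L] <- "NB"
  ends <- nchild == 0L
  last <- fpos == length(frames)
  flagged <- if ("fate" %in% names(nodes)) nodes$fate %in% "Censored" else rep(FALSE, n)
  derived[ends & (last | flagged)] <- "Censored"
  derived[ends & !last & !flagged] <- "Del"
  if ("fate" %in% names(nodes)) {
    bad <- which(!is.na(nodes$fate) & nodes$fate != derived &
                   !(derived == "Censored"))
    if (length(bad)) {
      b <- nodes[bad[1L]]
      stop(sprintf("fate label inconsistent with lineage: frame=%d cell_id=%d given=%s derived=%s",
                   b$frame, b$cell_id, b$fate, derived[bad[1L]]))
    }
  }
  nodes$fate <- derived
  nodes$nfb_nb <- 0
  nodes$nfb_del <- 0
  nodes$nfb_div <- 0
  if (!"random" %in% names(nodes)) nodes$random <- NA_real_

  ## Contacts: resolve to row indices, enforce same-frame existing endpoints.
  ctab <- data.table::data.table(a = integer(), b = integer())
  if (!is.null(contacts) && nrow(contacts)) {
    cdt <- data.table::as.data.table(contacts)
    ia <- match(node_code(cdt$frame, cdt$cell_id_a), code)
    ib <- match(node_code(cdt$frame, cdt$cell_id_b), code)
    bad <- which(is.na(ia) | is.na(ib))
    if (length(bad)) {
      b <- cdt[bad[1L]]
      stop(sprintf("contact references a cell missing from its frame: frame=%d cell_id_a=%d cell_id_b=%d",
                   b$frame, b$cell_id_a, b$cell_id_b))
    }
    if (any(ia == ib)) stop("contact pairs a cell with itself")
    ctab <- unique(data.table::data.table(a = pmin(ia, ib), b = pmax(ia, ib)))
  }

  structure(list(
    nodes = nodes,
    contacts = ctab,
    lineage = data.table::data.table(lo = lo, hi = hi),
    frames = frames
  ), class = "stg")
}

#' @export
print.stg <- function(x, ...) {
  cat(sprintf("Spatiotemporal cell graph: %d nodes over %d frames, %d contact pairs, %d lineage edges\n",
              nrow(x$nodes), length(x$frames), nrow(x$contacts), nrow(x$lineage)))
  print(table(fate = x$nodes$fate))
  invisible(x)
}

#' Set the next-frame-behavior (NFB) one-hot feature from fate labels
#'
#' Encodes each cell's behavior in the following frame as a one-hot vector:
#' `NB` = (1,0,0), `Del` = (0,1,0), `Div` = (0,0,1). Censored cells get the
#' null vector. Nulling of the final frame of a prediction window (whose NFB
#' is the prediction target) happens at window assembly, not here.
#'
#' @param graph An `stg`.
#' @return The graph with `nfb_*` columns filled.
#' @export
set_nfb <- function(graph) {
  stopifnot(inherits(graph, "stg"))
  graph$nodes$nfb_nb <- as.numeric(graph$nodes$fate == "NB")
  graph$nodes$nfb_del <- as.numeric(graph$nodes$fate == "Del")
  graph$nodes$nfb_div <- as.numeric(graph$nodes$fate == "Div")
  graph
}

#' Attach the uninformative uniform-random feature
#'
#' Draws one U(0,1) value per node, once at graph-construction time, so that
#' training and attribution are reproducible. The feature carries no fate
#' information by construction and anchors the attribution significance band.
#'
#' @param graph An `stg`.
#' @param seed Integer seed for the draws.
#' @return The graph with the `random` column filled.
#' @export
add_random_feature <- function(graph, seed) {
  stopifnot(inherits(graph, "stg"))
  graph$nodes$random <- with_local_seed(seed, stats::runif(nrow(graph$nodes)))
  graph
}

#' Feature configuration
#'
#' Declares which of the canonical node features
#' `[area, g1, nfb (3 slots), random]` are active. Inactive features are held
#' at zero in every node; the feature vector keeps its fixed length 6 so that
#' model shapes are constant across feature ablations.
#'
#' @param features Character subset of `c("area", "g1", "nfb", "random")`.
#' @return A `feature_config` list (normalization maxima are filled in by
#'   [normalize_features()]).
#' @export
feature_config <- function(features = c("area", "g1", "nfb", "random")) {
  stopifnot(all(features %in% c("area", "g1", "nfb", "random")))
  structure(list(features = features, norm = c(area = NA_real_, g1 = NA_real_)),
            class = "feature_config")
}

#' Normalize scalar features by their global maximum
#'
#' Divides each active scalar feature (area, g1) by its maximum over the
#' union of the supplied graphs -- training and test data together -- so that
#' the largest observed value maps to exactly 1. The divisors are recorded in
#' the returned configuration.
#'
#' @param graphs A list of `stg` objects (train and test).
#' @param config A [feature_config()].
#' @return `list(graphs = <rescaled graphs>, config = <config with norm>)`.
#' @export
normalize_features <- function(graphs, config) {
  stopifnot(all(vapply(graphs, inherits, TRUE, "stg")))
  for (feat in intersect(config$features, c("area", "g1"))) {
    m <- max(vapply(graphs, function(g) {
      v <- g$nodes[[feat]]
      if (length(v)) max(v) else -Inf
    }, 0))
    if (!is.finite(m) || m <= 0)
      stop(sprintf("feature '%s' is zero everywhere; cannot normalize", feat))
    graphs <- lapply(graphs, function(g) { g$nodes[[feat]] <- g$nodes[[feat]] / m; g })
    config$norm[[feat]] <- m
  }
  list(graphs = graphs, config = config)
}

#' Validate the structural invariants of a spatiotemporal graph
#'
#' Checks lineage consistency (every lineage edge's parent/daughter relations
#' are mutual, no node has more than one parent), fate/child-count
#' consistency, same-frame contacts and NFB one-hot structure. Errors on the
#' first violation; returns the graph invisibly when clean.
#'
#' @param graph An `stg`.
#' @export
validate_stg <- function(graph) {
  nodes <- graph$nodes
  n <- nrow(nodes)
  fpos <- match(nodes$frame, graph$frames)
  if (nrow(graph$lineage)) {
    if (any(fpos[graph$lineage$hi] - fpos[graph$lineage$lo] != 1L))
      stop("lineage edge does not connect consecutive frames")
    if (anyDuplicated(graph$lineage$hi)) stop("a node has more than one parent")
  }
  nchild <- tabulate(graph$lineage$lo, nbins = n)
  expected <- c(NB = 1L, Div = 2L, Del = 0L, Censored = 0L)[nodes$fate]
  if (any(nchild != expected)) {
    b <- nodes[which(nchild != expected)[1L]]
    stop(sprintf("fate/child-count mismatch: frame=%d cell_id=%d fate=%s", b$frame, b$cell_id, b$fate))
  }
  if (nrow(graph$contacts)) {
    if (any(nodes$frame[graph$contacts$a] != nodes$frame[graph$contacts$b]))
      stop("contact edge connects different frames")
  }
  s <- nodes$nfb_nb + nodes$nfb_del + nodes$nfb_div
  if (!all(s %in% c(0, 1))) stop("NFB is not one-hot")
  invisible(graph)
}

#' Export a spatiotemporal graph back to track-table form
#'
#' Inverse of [build_graph()] for the tabular content: one row per node with
#' the canonical columns (plus centroids when present). Together with
#' [build_graph()] this round-trips losslessly for non-censored content.
#'
#' @param graph An `stg`.
#' @return A `data.table` in track-table format (canonical fate labels).
#' @export
graph_to_tracktable <- function(graph) {
  cols <- c("frame", "cell_id", "parent_id", "fate", "area", "g1",
            intersect(c("x", "y"), names(graph$nodes)))
  out <- graph$nodes[, cols, with = FALSE]
  out$parent_id[is.na(out$parent_id)] <- -1L
  out
}

#' Zero out every feature of a graph or subgraph
#'
#' Returns an object with identical topology (nodes, contacts, lineage) but
#' all feature values -- area, g1, NFB and the random feature -- set to zero.
#' This is the baseline input for integrated-gradients attribution and the
#' input of the neutral-baseline training loss.
#'
#' @param x An `stg` or `target_subgraph`.
#' @return An object of the same class with zeroed features.
#' @export
null_graph <- function(x) {
  g <- if (inherits(x, "target_subgraph")) x$graph else x
  g$nodes$area <- 0
  g$nodes$g1 <- 0
  g$nodes$nfb_nb <- 0
  g$nodes$nfb_del <- 0
  g$nodes$nfb_div <- 0
  g$nodes$random <- 0
  if (inherits(x, "target_subgraph")) { x$graph <- g; x } else g
}
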