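## Periodic Voronoi tessellation by direct cell construction.
##
## Each site's Voronoi cell is obtained by successively clipping a bounding
## square (side L, centered on the site -- the periodic cell always fits in
## the half-box) with the perpendicular-bisector half-planes of candidate
## sites taken in order of increasing distance from a 3x3 tiling of the box.
## Clipping stops once the next candidate is farther than twice the current
## maximum vertex distance, which cannot alter the cell; two sites are
## neighbors when the final polygon has an edge of positive length on their
## bisector. Polygon areas come from the shoelace formula.

# Sutherland-Hodgman clip of polygon V (counterclockwise vertex matrix) by
# the half-plane {x : (x - m) . d <= 0}.
clip_halfplane <- function(V, m, d) {
  s <- (V[, 1] - m[1]) * d[1] + (V[, 2] - m[2]) * d[2]
  inside <- s <= 0
  if (all(inside)) return(V)
  if (!any(inside)) return(V[0, , drop = FALSE])
  n <- nrow(V)
  nx <- c(2:n, 1L)
  out <- matrix(NA_real_, 2L * n, 2L)
  out[2L * seq_len(n) - 1L, ][inside, ] <- V[inside, ]
  cr <- which(inside != inside[nx])
  tt <- s[cr] / (s[cr] - s[nx[cr]])
  out[2L * cr, ] <- V[cr, , drop = FALSE] + tt * (V[nx[cr], , drop = FALSE] - V[cr, , drop = FALSE])
  out[!is.na(out[, 1]), , drop = FALSE]
}

shoelace <- function(V) {
  n <- nrow(V)
  nx <- c(2:n, 1L)
  abs(sum(V[, 1] * V[nx, 2] - V[nx, 1] * V[, 2])) / 2
}

#' Contact network (and cell areas) from a periodic Voronoi tessellation
#'
#' Two cells are in contact when their Voronoi cells share a ridge of
#' positive length; the tessellation is computed with periodic boundary
#' conditions via a 3x3 tiling of the box. Zero-length ridges (cocircular
#' degeneracies, e.g. the diagonals of a perfect square lattice) are not
#' contacts.
#'
#' @param positions N x 2 matrix of points in `[0, L)^2`, N >= 3, not all
#'   collinear.
#' @param L Box side.
#' @return A list with `edges` (two-column matrix of row-index pairs,
#'   `a < b`, each once) and `areas` (per-point Voronoi cell area).
#' @export
voronoi_contacts <- function(positions, L = 1) {
  pos <- as.matrix(positions)
  n <- nrow(pos)
  if (n < 3L) stop("need at least 3 points")
  cc <- scale(pos, scale = FALSE)
  if (svd(cc)$d[2] < 1e-12 * L) stop("degenerate input: all points are collinear")

  shifts <- as.matrix(expand.grid(sx = c(-L, 0, L), sy = c(-L, 0, L)))
  tiled <- pos[rep(seq_len(n), times = 9L), , drop = FALSE] +
    shifts[rep(seq_len(9L), each = n), c("sx", "sy")]
  tiled_orig <- rep(seq_len(n), times = 9L)
  self0 <- 4L * n + seq_len(n)  # index of each point's own central copy

  eps <- 1e-9 * L
  edges_a <- edges_b <- integer(0)
  areas <- numeric(n)
  for (i in seq_len(n)) {
    p <- pos[i, ]
    d2 <- (tiled[, 1] - p[1])^2 + (tiled[, 2] - p[2])^2
    d2[self0[i]] <- Inf
    ord <- order(d2)
    V <- cbind(p[1] + c(-L, L, L, -L) / 2, p[2] + c(-L, -L, L, L) / 2)
    used <- integer(0)
    for (j in ord) {
      rmax2 <- max((V[, 1] - p[1])^2 + (V[, 2] - p[2])^2)
      if (d2[j] > 4 * rmax2 + eps) break
      q <- tiled[j, ]
      V <- clip_halfplane(V, (p + q) / 2, q - p)
      if (nrow(V) < 3L) stop("empty Voronoi cell (coincident points?)")
      used <- c(used, j)
    }
    areas[i] <- shoelace(V)
    ## neighbors: candidates whose bisector supports a polygon edge
    nv <- nrow(V)
    nx <- c(2:nv, 1L)
    elen <- sqrt((V[nx, 1] - V[, 1])^2 + (V[nx, 2] - V[, 2])^2)
    for (j in used) {
      q <- tiled[j, ]
      d <- q - p; m <- (p + q) / 2
      nd <- sqrt(sum(d^2))
      s <- abs((V[, 1] - m[1]) * d[1] + (V[, 2] - m[2]) * d[2]) / nd
      on_line <- s < 1e-7 * L
      if (any(on_line & on_line[nx] & elen > eps)) {
        edges_a <- c(edges_a, i)
        edges_b <- c(edges_b, tiled_orig[j])
      }
    }
  }
  ed <- unique(cbind(pmin(edges_a, edges_b), pmax(edges_a, edges_b)))
  ed <- ed[ed[, 1] != ed[, 2], , drop = FALSE]
  list(edges = ed, areas = areas)
}
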