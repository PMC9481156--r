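## Export of a simulated trajectory to track/contact tables.
##
## Only particles inside the centered crop_fraction*L square are emitted.
## Fate labels are derived from the event log between consecutive sampled
## frames: delamination inside the crop is Del, a division whose two
## daughters are both inside the crop at the next frame is Div (the
## daughters start fresh tracks pointing at the parent), and anything that
## cannot be followed -- crop-boundary crossings, divisions with a daughter
## outside, presence in the last sampled frame -- is Censored rather than
## being turned into a fabricated fate event. Cell areas are the periodic
## Voronoi cell areas; contacts are Voronoi ridges between two in-crop
## cells.

#' Convert a simulated trajectory into track and contact tables
#'
#' @param traj A `sim_traj` from [run_sim()].
#' @param config Optional [sim_config()] override (defaults to
#'   `traj$config`).
#' @return `list(tracks, contacts)` of `data.table`s in the package's track
#'   table format (with `x`, `y` centroid columns; `g1` is 0: the simulator
#'   has no cell-cycle reporter).
#' @export
crop_to_tracktable <- function(traj, config = traj$config) {
  L <- config$L
  half <- config$crop_fraction * L / 2
  nf <- length(traj$frames)
  if (!nf) stop("trajectory has no sampled frames")

  vor <- lapply(traj$frames, function(fr) voronoi_contacts(fr$pos, L))
  in_crop <- lapply(traj$frames, function(fr)
    abs(fr$pos[, 1] - L / 2) <= half & abs(fr$pos[, 2] - L / 2) <= half)

  ev <- traj$events
  li <- traj$lineage
  rows <- list()
  crows <- list()
  next_track <- 1L
  cur <- list()   # sim id (character) -> active track id at previous frame

  for (f in seq_len(nf)) {
    fr <- traj$frames[[f]]
    sel <- which(in_crop[[f]])
    ids <- fr$ids[sel]

    ## assign track ids for this frame: continuations keep their track, new
    ## appearances open one (daughters of a clean division carry parent_id)
    tr <- integer(length(ids))
    par <- rep(-1L, length(ids))
    for (k in seq_along(ids)) {
      key <- as.character(ids[k])
      hit <- cur[[key]]
      if (!is.null(hit)) {
        tr[k] <- hit
      } else {
        tr[k] <- next_track; next_track <- next_track + 1L
        pk <- cur[[paste0("d:", key)]]
        par[k] <- if (!is.null(pk)) pk else -1L
      }
    }

    ## fate of each emitted cell, decided by events before the next frame
    fate <- rep("Censored", length(ids))
    nxtmap <- list()
    if (f < nf) {
      t0 <- fr$time
      t1 <- traj$frames[[f + 1L]]$time
      nxt_ids <- traj$frames[[f + 1L]]$ids
      nxt_in <- in_crop[[f + 1L]]
      evf <- ev[ev$time > t0 & ev$time <= t1, ]
      lif <- li[li$time > t0 & li$time <= t1, ]
      for (k in seq_along(ids)) {
        id <- ids[k]
        if (id %in% evf$cell[evf$type == "del"]) {
          fate[k] <- "Del"
        } else if (id %in% lif$parent) {
          ds <- lif[lif$parent == id, ]
          d_ids <- c(ds$d1[1], ds$d2[1])
          pos_d <- match(d_ids, nxt_ids)
          ok <- !is.na(pos_d) & nxt_in[pos_d]
          if (all(ok)) {
            fate[k] <- "Div"
            for (dd in d_ids) nxtmap[[paste0("d:", dd)]] <- tr[k]
          } else fate[k] <- "Censored"
        } else {
          pos_n <- match(id, nxt_ids)
          if (!is.na(pos_n) && nxt_in[pos_n]) {
            fate[k] <- "NB"
            nxtmap[[as.character(id)]] <- tr[k]
          } else fate[k] <- "Censored"
        }
      }
    }

    rows[[f]] <- data.table::data.table(
      frame = f - 1L, cell_id = tr, parent_id = par, fate = fate,
      area = vor[[f]]$areas[sel], g1 = 0,
      x = fr$pos[sel, 1], y = fr$pos[sel, 2])

    ## contacts among in-crop cells, as track ids
    edg <- vor[[f]]$edges
    keep <- in_crop[[f]][edg[, 1]] & in_crop[[f]][edg[, 2]]
    if (any(keep)) {
      e <- edg[keep, , drop = FALSE]
      ta <- tr[match(fr$ids[e[, 1]], ids)]
      tb <- tr[match(fr$ids[e[, 2]], ids)]
      crows[[f]] <- data.table::data.table(
        frame = f - 1L, cell_id_a = pmin(ta, tb), cell_id_b = pmax(ta, tb))
    }
    cur <- nxtmap
  }

  list(tracks = data.table::rbindlist(rows),
       contacts = data.table::rbindlist(crows))
}

#' Simulate one data set end to end
#'
#' Convenience wrapper: calibrate the commitment rate if unset, run the
#' simulation, crop, and build the validated spatiotemporal graph with NFB
#' and the random feature attached.
#'
#' @param config A [sim_config()].
#' @param target_fraction Per-fate event-fraction target for
#'   [calibrate_rate()] when `lambda_rate` is `NULL`.
#' @return `list(graph, tracks, contacts, traj, lambda)`.
#' @export
simulate_dataset <- function(config, target_fraction = 0.07) {
  lam <- config$lambda_rate
  if (is.null(lam)) {
    lam <- calibrate_rate(config, target_fraction)
    config$lambda_rate <- as.numeric(lam)
  }
  traj <- run_sim(config)
  tabs <- crop_to_tracktable(traj)
  graph <- build_graph(tabs$tracks, tabs$contacts)
  graph <- set_nfb(graph)
  graph <- add_random_feature(graph, seed = derive_seeds(config$seed, 2L)[2])
  validate_stg(graph)
  list(graph = graph, tracks = tabs$tracks, contacts = tabs$contacts,
       traj = traj, lambda = as.numeric(lam))
}
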