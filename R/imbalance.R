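## Neighbor fate net imbalance.
##
## For each cell that divides (or delaminates) at frame t, take its six
## nearest cells by centroid distance at frame t and follow them -- and, for
## dividing neighbors, their descendants -- forward in time. The net
## imbalance at lag tau is the cumulative number of divisions minus
## delaminations among the tracked set in (t, t + tau], averaged over
## events. Under uncoordinated homeostasis the curve stays near zero; an
## implanted delamination-induced-division rule makes the curve around
## delaminated cells rise at the lag matching the induced delay. An
## optional background mode subtracts the population-wide expected net
## imbalance accumulated by the tracked cells.

#' Neighbor fate net-imbalance curve
#'
#' @param tracks Track table with centroid columns `x`, `y` (canonical fate
#'   labels, e.g. from [crop_to_tracktable()] or [read_track_table()]).
#' @param event_type `"Div"` or `"Del"`: which focal events to follow.
#' @param max_lag Maximum lag in frames.
#' @param background_correct Subtract the population-wide expected net
#'   imbalance per tracked cell per frame.
#' @return A `data.table` with `lag`, `mean`, `se`, and the number of
#'   events `n` contributing at each lag. Events with fewer than six
#'   neighbors in the field are skipped (count in attribute
#'   `"skipped"`).
#' @export
neighbor_fate_imbalance <- function(tracks, event_type = c("Div", "Del"),
                                    max_lag = 6L, background_correct = FALSE) {
  event_type <- match.arg(event_type)
  dt <- data.table::as.data.table(tracks)
  if (!all(c("x", "y") %in% names(dt))) stop("track table needs x/y centroid columns")
  frames <- sort(unique(dt$frame))
  byf <- split(dt, dt$frame)
  names(byf) <- as.character(frames)

  ## per-frame net fate rate for the background mode
  bg <- vapply(byf, function(b) (sum(b$fate == "Div") - sum(b$fate == "Del")) / nrow(b), 0)

  ## daughters of track id p at next frame; continuation = same id
  kids <- function(fr_next, id_set) {
    b <- byf[[as.character(fr_next)]]
    if (is.null(b)) return(data.table::data.table(cell_id = integer(), src = integer()))
    cont <- b[b$cell_id %in% id_set & b$parent_id < 0, ]
    dgt <- b[b$parent_id %in% id_set, ]
    rbind(data.table::data.table(cell_id = cont$cell_id, src = cont$cell_id),
          data.table::data.table(cell_id = dgt$cell_id, src = dgt$parent_id))
  }

  events <- dt[dt$fate == event_type, ]
  curves <- matrix(NA_real_, nrow(events), max_lag + 1L)
  skipped <- 0L
  for (e in seq_len(nrow(events))) {
    f0 <- events$frame[e]
    b0 <- byf[[as.character(f0)]]
    others <- b0[b0$cell_id != events$cell_id[e], ]
    if (nrow(others) < 6L) { skipped <- skipped + 1L; next }
    d2 <- (others$x - events$x[e])^2 + (others$y - events$y[e])^2
    tracked <- others$cell_id[order(d2, others$cell_id)[1:6]]
    cum <- 0
    curves[e, 1L] <- 0
    for (tau in seq_len(max_lag)) {
      fr <- f0 + tau - 1L
      b <- byf[[as.character(fr)]]
      if (is.null(b) || !(fr + 1L) %in% frames) break
      cur <- b[b$cell_id %in% tracked, ]
      cum <- cum + sum(cur$fate == "Div") - sum(cur$fate == "Del")
      if (background_correct) cum <- cum - nrow(cur) * bg[[as.character(fr)]]
      ## advance the tracked set: NB continues, Div is replaced by its
      ## daughters, Del and Censored stop contributing
      keep <- cur$cell_id[cur$fate %in% c("NB", "Div")]
      tracked <- kids(fr + 1L, keep)$cell_id
      curves[e, tau + 1L] <- cum
    }
  }
  res <- data.table::data.table(
    lag = 0:max_lag,
    mean = colMeans(curves, na.rm = TRUE),
    se = apply(curves, 2L, function(v) {
      v <- v[!is.na(v)]
      if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else NA_real_
    }),
    n = colSums(!is.na(curves)))
  attr(res, "skipped") <- skipped
  res
}

#' Permute fate labels within frames (control for the imbalance analysis)
#'
#' Shuffles the NB/Del/Div labels among the non-censored cells of each
#' frame, preserving per-frame fate counts but destroying any spatial
#' coordination. Lineage columns are left untouched: the shuffled table is
#' a control for [neighbor_fate_imbalance()] only, not a valid graph.
#'
#' @param tracks Track table.
#' @param seed Integer seed.
#' @return The shuffled table.
#' @export
shuffle_fates <- function(tracks, seed = 1L) {
  dt <- data.table::copy(data.table::as.data.table(tracks))
  with_local_seed(seed, {
    for (f in unique(dt$frame)) {
      i <- which(dt$frame == f & dt$fate != "Censored")
      dt$fate[i] <- dt$fate[sample(i)]
    }
  })
  dt
}
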