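# Small deterministic graphs used across tests.

# Ring of cells over n_frames frames with a delamination (cell 3 after
# frame 1) and a division (cell 5 -> 11, 12 after frame 1); for graphs of
# five or more frames a second event pair follows frame 3 (cell 7
# delaminates, cell 9 -> 13, 14), so that Nt = 4 windows have targets of
# every fate.
toy_tracks <- function(n_frames = 6L, n_cells = 10L, seed = 1L) {
  withr::local_seed(seed)
  mkframe <- function(f, ids, parents = rep(-1L, length(ids)))
    data.table::data.table(frame = f, cell_id = ids, parent_id = parents,
                           area = stats::runif(length(ids), .5, 1),
                           g1 = stats::runif(length(ids)))
  tr <- list(mkframe(0L, seq_len(n_cells)), mkframe(1L, seq_len(n_cells)))
  after <- c(setdiff(seq_len(n_cells), c(3L, 5L)), 11L, 12L)
  tr[[3]] <- mkframe(2L, after, c(rep(-1L, n_cells - 2L), 5L, 5L))
  tr[[4]] <- mkframe(3L, after)
  if (n_frames >= 5L) {
    after2 <- c(setdiff(after, c(7L, 9L)), 13L, 14L)
    tr[[5]] <- mkframe(4L, after2, c(rep(-1L, length(after) - 2L), 9L, 9L))
    for (f in seq_len(max(0L, n_frames - 5L)) + 4L) tr[[f + 1L]] <- mkframe(f, after2)
  }
  data.table::rbindlist(tr[seq_len(n_frames)])
}

toy_contacts <- function(tracks) {
  ring <- function(f, ids) data.table::data.table(frame = f, cell_id_a = ids,
                                                  cell_id_b = c(ids[-1], ids[1]))
  data.table::rbindlist(lapply(split(tracks, tracks$frame), function(b)
    ring(b$frame[1], sort(b$cell_id))))
}

toy_graph <- function(n_frames = 6L, seed = 1L) {
  tracks <- toy_tracks(n_frames, seed = seed)
  g <- build_graph(tracks, toy_contacts(tracks))
  g <- set_nfb(g)
  g <- add_random_feature(g, seed + 1L)
  validate_stg(g)
  g
}

# Normalized toy graph + its windows and feature config.
toy_setup <- function(n_frames = 6L, seed = 1L,
                      features = c("area", "g1", "nfb", "random")) {
  g <- toy_graph(n_frames, seed)
  fc <- feature_config(features)
  nf <- normalize_features(list(g), fc)
  list(graph = nf$graphs[[1]], fconfig = nf$config,
       windows = extract_windows(nf$graphs[[1]], 4L))
}
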