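## Deterministic fixtures: a tiny hand-built track/contact pair with one
## division and one delamination, and a seeded miniature simulation for
## fast tests.

#' Hand-built track table fixture
#'
#' Ten tracks over four frames: cells 1-8 in frame 0 on a ring, cell 3
#' delaminates after frame 0, cell 2 divides after frame 1 into cells 9 and
#' 10, everything else persists; frame-3 cells are censored by construction.
#'
#' @return A `data.table` in track-table format (with toy area/g1 values).
#' @export
fixture_tracks <- function() {
  mk <- function(frame, id, parent = -1L, area = 1 + id / 10, g1 = id / 10)
    data.table::data.table(frame = frame, cell_id = id, parent_id = parent,
                           fate = NA_character_, area = area, g1 = g1)
  data.table::rbindlist(list(
    mk(0L, 1:8),
    mk(1L, c(1:2, 4:8)),
    mk(2L, c(1L, 4:8)), mk(2L, 9:10, parent = 2L),
    mk(3L, c(1L, 4:10))
  ))
}

#' Contact table accompanying [fixture_tracks()]
#'
#' A ring of contacts among the cells present in each frame.
#'
#' @return A `data.table` in contact-table format.
#' @export
fixture_contacts <- function() {
  ring <- function(frame, ids)
    data.table::data.table(frame = frame, cell_id_a = ids,
                           cell_id_b = c(ids[-1], ids[1]))
  data.table::rbindlist(list(
    ring(0L, 1:8),
    ring(1L, c(1:2, 4:8)),
    ring(2L, c(1L, 9:10, 4:8)),
    ring(3L, c(1L, 9:10, 4:8))
  ))
}

#' Assembled fixture graph
#'
#' @param seed Seed for the random feature.
#' @return A validated `stg` with NFB and random feature attached.
#' @export
fixture_graph <- function(seed = 7L) {
  g <- build_graph(fixture_tracks(), fixture_contacts())
  g <- set_nfb(g)
  g <- add_random_feature(g, seed)
  validate_stg(g)
  g
}

#' Miniature simulated data set for fast tests
#'
#' A scaled-down homeostasis simulation (around 200 cells, shortened burn-in
#' and production) with a fixed commitment rate of the calibrated magnitude;
#' unit-test material, not the study conditions.
#'
#' @param setup Coordination setup.
#' @param seed Simulation seed.
#' @param N0 Initial cells.
#' @param production_steps,burnin_steps Shortened phases (steps).
#' @return As [simulate_dataset()].
#' @export
mini_dataset <- function(setup = "del_induced_div", seed = 1L, N0 = 240L,
                         production_steps = 160L, burnin_steps = 200L) {
  cfg <- sim_config(setup = setup, N0 = N0, seed = seed,
                    lambda_rate = 0.0036,
                    burnin_steps = burnin_steps,
                    production_steps = production_steps)
  simulate_dataset(cfg)
}

#' Write the committed fixtures
#'
#' Writes the hand fixture and (optionally) a miniature simulated data set
#' (tracks, contacts) to `out_dir`. Regeneration is deterministic.
#'
#' @param out_dir Output directory (created if needed).
#' @param include_mini Also write the seeded miniature simulation (slower).
#' @return Invisibly, the written paths.
#' @export
make_fixtures <- function(out_dir, include_mini = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p1 <- file.path(out_dir, "fixture_tracks.tsv")
  p2 <- file.path(out_dir, "fixture_contacts.tsv")
  g <- build_graph(fixture_tracks(), fixture_contacts())
  tt <- fixture_tracks(); tt$fate <- g$nodes$fate
  write_track_table(tt, p1)
  write_contact_table(fixture_contacts(), p2)
  paths <- c(p1, p2)
  if (include_mini) {
    mini <- mini_dataset(seed = 11L)
    p3 <- file.path(out_dir, "mini_tracks.tsv")
    p4 <- file.path(out_dir, "mini_contacts.tsv")
    write_track_table(mini$tracks, p3)
    write_contact_table(mini$contacts, p4)
    paths <- c(paths, p3, p4)
  }
  invisible(paths)
}
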