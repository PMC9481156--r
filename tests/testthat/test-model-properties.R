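test_that("softmax scores are a distribution and eval mode is deterministic", {
  st <- toy_setup()
  for (v in c("bidirectional", "unidirectional", "cell_external", "no_spatial")) {
    m <- init_model(model_config(v, "sum"), seed = 3)
    o1 <- predict_fates(m, st$windows[[1]], st$fconfig)
    o2 <- predict_fates(m, st$windows[[1]], st$fconfig)
    expect_equal(rowSums(o1$probs), rep(1, nrow(o1$probs)), tolerance = 1e-12)
    expect_identical(o1$probs, o2$probs)
  }
})

test_that("outputs are invariant under cell relabeling", {
  tracks <- toy_tracks()
  perm <- c(101L, 45L, 7L, 88L, 3L, 60L, 21L, 99L, 14L, 50L, 72L, 36L, 81L, 15L)
  tracks2 <- data.table::copy(tracks)
  tracks2$cell_id <- perm[tracks$cell_id]
  tracks2$parent_id <- ifelse(tracks$parent_id > 0, perm[pmax(tracks$parent_id, 1L)], -1L)
  ct <- toy_contacts(tracks)
  ct2 <- data.table::copy(ct)
  ct2$cell_id_a <- perm[ct$cell_id_a]; ct2$cell_id_b <- perm[ct$cell_id_b]

  g1 <- set_nfb(build_graph(tracks, ct))
  g2 <- set_nfb(build_graph(tracks2, ct2))
  # same random values attached per corresponding node
  g1 <- add_random_feature(g1, 5)
  g2$nodes$random <- g1$nodes$random[match(
    fatecoord:::node_code(g2$nodes$frame, match(g2$nodes$cell_id, perm)),
    fatecoord:::node_code(g1$nodes$frame, g1$nodes$cell_id))]
  fc <- feature_config()
  for (v in c("bidirectional", "unidirectional")) {
    m <- init_model(model_config(v, "sum"), seed = 4)
    w1 <- extract_windows(g1, 4)[[1]]
    w2 <- extract_windows(g2, 4)[[1]]
    o1 <- predict_fates(m, w1, fc)
    o2 <- predict_fates(m, w2, fc)
    ord1 <- order(g1$nodes$cell_id[w1$target_idx])
    ord2 <- order(match(g2$nodes$cell_id[w2$target_idx], perm))
    expect_equal(o1$probs[ord1, ], o2$probs[ord2, ], tolerance = 1e-12)
  }
})

# Minimal 3-frame line: target cell 1 contacts neighbor 2 (and optionally
# its duplicate 3 with identical features).
line_graph <- function(duplicate = FALSE, nb_area = 0.8) {
  ids <- if (duplicate) 1:3 else 1:2
  tr <- data.table::rbindlist(lapply(0:2, function(f)
    data.table::data.table(frame = f, cell_id = ids, parent_id = -1L,
                           area = c(0.5, rep(nb_area, length(ids) - 1L)),
                           g1 = 0.3)))
  ct <- data.table::rbindlist(lapply(0:2, function(f)
    data.table::data.table(frame = f, cell_id_a = 1L,
                           cell_id_b = setdiff(ids, 1L))))
  g <- set_nfb(build_graph(tr, ct))
  g$nodes$random <- 0.5
  g
}

test_that("mean aggregation ignores duplicated neighbors; sum does not", {
  fc <- feature_config()
  for (agg in c("mean", "sum")) {
    m <- init_model(model_config("cell_external", agg, Nt = 2), seed = 6)
    w1 <- extract_windows(line_graph(FALSE), 2)[[1]]
    w2 <- extract_windows(line_graph(TRUE), 2)[[1]]
    t1 <- which(line_graph(FALSE)$nodes$cell_id[w1$target_idx] == 1L)
    t2 <- which(line_graph(TRUE)$nodes$cell_id[w2$target_idx] == 1L)
    p1 <- predict_fates(m, w1, fc)$probs[t1, ]
    p2 <- predict_fates(m, w2, fc)$probs[t2, ]
    if (agg == "mean") expect_equal(p1, p2, tolerance = 1e-12)
    else expect_gt(max(abs(p1 - p2)), 1e-6)
  }
})

test_that("isolated targets aggregate zero messages under both modes", {
  tr <- data.table::rbindlist(lapply(0:2, function(f)
    data.table::data.table(frame = f, cell_id = 1:2, parent_id = -1L,
                           area = c(0.5, 0.9), g1 = 0.1)))
  g <- set_nfb(build_graph(tr, NULL))   # no contacts at all
  g$nodes$random <- 0.2
  fc <- feature_config()
  w <- extract_windows(g, 2)[[1]]
  msum <- init_model(model_config("unidirectional", "sum", Nt = 2), seed = 8)
  mmean <- msum
  mmean$config <- model_config("unidirectional", "mean", Nt = 2)
  expect_equal(predict_fates(msum, w, fc)$probs,
               predict_fates(mmean, w, fc)$probs, tolerance = 1e-14)
})

test_that("the cell-external model ignores the target's own lineage features", {
  st <- toy_setup()
  g2 <- st$graph
  w <- st$windows[[1]]
  tg <- w$target_idx[1]
  # perturb the target's own area/g1/random along its whole ancestor chain
  chain <- fatecoord:::ancestor_chain(w, tg)
  g2$nodes$area[chain] <- 0.123
  g2$nodes$g1[chain] <- 0.999
  g2$nodes$random[chain] <- 0.001
  w2 <- extract_windows(g2, 4)[[1]]
  m <- init_model(model_config("cell_external", "mean"), seed = 2)
  p1 <- predict_fates(m, w, st$fconfig)$probs
  p2 <- predict_fates(m, w2, st$fconfig)$probs
  k <- match(tg, w$target_idx)
  expect_equal(p1[k, ], p2[k, ], tolerance = 1e-12)
  # a non-external model does react to the same perturbation
  mu <- init_model(model_config("unidirectional", "mean"), seed = 2)
  q1 <- predict_fates(mu, w, st$fconfig)$probs
  q2 <- predict_fates(mu, w2, st$fconfig)$probs
  expect_gt(max(abs(q1[k, ] - q2[k, ])), 1e-8)
})

test_that("freezing the final frame disables the forward temporal models", {
  st <- toy_setup()
  cfgf <- model_config("unidirectional", "sum", forward_freeze = "final")
  m1 <- init_model(cfgf, seed = 3)
  m2 <- m1
  # different forward temporal weights must not matter when the decoded
  # frame is never updated
  m2$params$fedge <- fatecoord:::mlp_init(12, 50, 6, 1)
  m2$params$fnode <- fatecoord:::mlp_init(12, 50, 6, 1)
  expect_equal(predict_fates(m1, st$windows[[1]], st$fconfig)$probs,
               predict_fates(m2, st$windows[[1]], st$fconfig)$probs,
               tolerance = 1e-12)
  # with the default first-frame freeze they do matter
  m1$config$forward_freeze <- m2$config$forward_freeze <- "first"
  expect_gt(max(abs(predict_fates(m1, st$windows[[1]], st$fconfig)$probs -
                    predict_fates(m2, st$windows[[1]], st$fconfig)$probs)), 1e-8)
})

test_that("the cell-external fast path equals per-target subgraph evaluation", {
  st <- toy_setup()
  for (agg in c("mean", "sum")) {
    m <- init_model(model_config("cell_external", agg), seed = 9)
    gen <- predict_fates(m, st$windows[[1]], st$fconfig)$probs
    ft <- fatecoord:::fast_tensors(st$windows[[1]], st$fconfig)
    expect_equal(fatecoord:::fast_forward(m, ft)$probs, unname(gen),
                 tolerance = 1e-12)
  }
})
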