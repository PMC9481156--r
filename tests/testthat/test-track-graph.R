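test_that("fates are derived from lineage structure", {
  tr <- data.table::data.table(
    frame = c(0L, 1L, 1L), cell_id = c(1L, 2L, 3L), parent_id = c(-1L, 1L, 1L),
    area = 1, g1 = 0)
  g <- build_graph(tr)
  expect_equal(g$nodes$fate[g$nodes$frame == 0L], "Div")
  expect_equal(sum(g$lineage$lo == 1L), 2L)

  tr2 <- data.table::data.table(
    frame = c(0L, 0L, 1L), cell_id = c(1L, 2L, 2L), parent_id = -1L,
    area = 1, g1 = 0)
  g2 <- build_graph(tr2)
  expect_equal(g2$nodes$fate[g2$nodes$frame == 0L & g2$nodes$cell_id == 1L], "Del")
  expect_equal(g2$nodes$fate[g2$nodes$frame == 1L], "Censored")
})

test_that("fixture graph matches its hand enumeration", {
  g <- fixture_graph()
  expect_equal(nrow(g$nodes), 31L)             # 8 + 7 + 8 + 8
  expect_equal(length(g$frames), 4L)
  expect_equal(as.vector(table(g$nodes$fate)[c("Div", "Del")]), c(1L, 1L))
  expect_equal(nrow(g$contacts), 8L + 7L + 8L + 8L)
  # lineage: 7 continuations 0->1 (cell 3 delaminates), 6 continuations +
  # 2 daughters 1->2, 8 continuations 2->3
  expect_equal(nrow(g$lineage), 7L + 8L + 8L)
  div <- which(g$nodes$fate == "Div")
  expect_equal(sort(g$nodes$cell_id[g$lineage$hi[g$lineage$lo == div]]), c(9L, 10L))
})

test_that("validation errors name the offending rows", {
  tr <- data.table::data.table(frame = c(0L, 1L), cell_id = c(1L, 2L),
                               parent_id = c(-1L, 9L), area = 1, g1 = 0)
  expect_error(build_graph(tr), "dangling parent.*parent_id=9")

  tr3 <- data.table::data.table(frame = c(0L, 1L, 1L, 1L), cell_id = c(1L, 2L, 3L, 4L),
                                parent_id = c(-1L, 1L, 1L, 1L), area = 1, g1 = 0)
  expect_error(build_graph(tr3), "more than two daughters.*cell_id=1")

  tr4 <- toy_tracks()
  ct <- data.table::data.table(frame = 0L, cell_id_a = 1L, cell_id_b = 99L)
  expect_error(build_graph(tr4, ct), "missing from its frame")
})

test_that("NFB one-hot encodes the fate and is null for censored cells", {
  g <- toy_graph()
  nb <- g$nodes[g$nodes$fate == "NB"][1]
  expect_equal(c(nb$nfb_nb, nb$nfb_del, nb$nfb_div), c(1, 0, 0))
  del <- g$nodes[g$nodes$fate == "Del"][1]
  expect_equal(c(del$nfb_nb, del$nfb_del, del$nfb_div), c(0, 1, 0))
  div <- g$nodes[g$nodes$fate == "Div"][1]
  expect_equal(c(div$nfb_nb, div$nfb_del, div$nfb_div), c(0, 0, 1))
  cen <- g$nodes[g$nodes$fate == "Censored"][1]
  expect_equal(c(cen$nfb_nb, cen$nfb_del, cen$nfb_div), c(0, 0, 0))
})

test_that("final-frame NFB is nulled in window features only", {
  st <- toy_setup()
  wt <- fatecoord:::window_tensors(st$windows[[1]], st$fconfig)
  s <- rowSums(wt$X[, 3:5])
  expect_true(all(s[wt$rel == 0L] == 0))
  expect_true(all(s[wt$rel < 0L] %in% c(0, 1)))
  # non-final frames: one-hot exactly for non-censored cells
  fates <- st$graph$nodes$fate[st$windows[[1]]$idx]
  expect_true(all(s[wt$rel < 0L & fates != "Censored"] == 1))
})

test_that("feature normalization divides by the global max over all graphs", {
  g1 <- toy_graph(seed = 1)
  g2 <- toy_graph(seed = 2)
  g1$nodes$area <- g1$nodes$area * 4 / max(g1$nodes$area)   # train max 4
  g2$nodes$area <- g2$nodes$area * 8 / max(g2$nodes$area)   # test max 8
  nf <- normalize_features(list(g1, g2), feature_config())
  expect_equal(nf$config$norm[["area"]], 8)
  expect_equal(max(nf$graphs[[2]]$nodes$area), 1)
  expect_equal(max(nf$graphs[[1]]$nodes$area), 0.5)

  g3 <- toy_graph()
  g3$nodes$g1 <- 0
  expect_error(normalize_features(list(g3), feature_config()), "zero everywhere")
})

test_that("the random feature is reproducible, uniform and uninformative", {
  g <- toy_graph()
  a <- add_random_feature(g, 42)$nodes$random
  b <- add_random_feature(g, 42)$nodes$random
  expect_identical(a, b)
  expect_true(all(a >= 0 & a <= 1))

  # correlation with fate over many nodes is within Monte-Carlo error
  big <- do.call(rbind, lapply(1:40, function(i) toy_tracks(seed = i)))
  big$frame <- big$frame + rep(seq(0, 39 * 10, by = 10), each = nrow(big) / 40)
  gb <- add_random_feature(set_nfb(build_graph(big)), 7)
  r <- gb$nodes$random
  is_div <- as.numeric(gb$nodes$fate == "Div")
  n <- length(r)
  expect_gt(n, 1000)
  expect_lt(abs(cor(r, is_div)), 4 / sqrt(n))
})

test_that("lineage consistency: parent and daughter relations are mutual", {
  g <- toy_graph()
  for (e in seq_len(nrow(g$lineage))) {
    lo <- g$lineage$lo[e]; hi <- g$lineage$hi[e]
    expect_equal(g$nodes$frame[hi], g$nodes$frame[lo] + 1L)
  }
  expect_false(anyDuplicated(g$lineage$hi) > 0)
})

test_that("null_graph zeroes features, preserves topology, and is idempotent", {
  g <- toy_graph()
  ng <- null_graph(g)
  expect_equal(nrow(ng$nodes), nrow(g$nodes))
  expect_equal(ng$contacts, g$contacts)
  expect_true(all(ng$nodes$area == 0) && all(ng$nodes$random == 0))
  expect_identical(null_graph(ng)$nodes$area, ng$nodes$area)
  w <- extract_windows(set_nfb(g), 4)[[1]]
  sg <- extract_target_subgraph(w, w$target_idx[1])
  nsg <- null_graph(sg)
  expect_equal(nrow(nsg$graph$nodes), nrow(sg$graph$nodes))
  expect_true(all(nsg$graph$nodes$g1 == 0))
})
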