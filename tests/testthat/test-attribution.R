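test_that("integrated gradients: zero-baseline features get zero attribution", {
  st <- toy_setup()
  w <- st$windows[[1]]
  sg <- extract_target_subgraph(w, w$target_idx[2])
  m <- init_model(model_config("cell_external", "mean"), seed = 5)
  ig <- integrated_gradients(m, sg, st$fconfig, M = 20)
  X <- attr(ig, "X")
  for (f in 1:3) expect_true(all(ig[[f]][X == 0] == 0))

  # inactive features are zero in the input, hence zero attribution
  fc2 <- feature_config(c("nfb", "random"))
  ig2 <- integrated_gradients(m, sg, fc2, M = 10)
  expect_true(all(ig2$Div[, 1:2] == 0))
})

test_that("attributions over the three fates sum to zero feature-wise", {
  st <- toy_setup()
  w <- st$windows[[1]]
  m <- init_model(model_config("unidirectional", "sum"), seed = 7)
  sg <- extract_target_subgraph(w, w$target_idx[1])
  ig <- integrated_gradients(m, sg, st$fconfig, M = 30)
  s <- ig$NB + ig$Del + ig$Div
  expect_lt(max(abs(s)), 1e-10)
})

test_that("completeness: attributions add up to the score difference", {
  st <- toy_setup()
  w <- st$windows[[1]]
  m <- init_model(model_config("cell_external", "mean"), seed = 11)
  sg <- extract_target_subgraph(w, w$target_idx[1])
  tens <- fatecoord:::subgraph_tensors(sg, st$fconfig)
  ig <- fatecoord:::ig_batch(m, tens, M = 200)
  pX <- fatecoord:::engine_forward(m, tens)$probs
  t0 <- tens; t0$X <- tens$X * 0
  p0 <- fatecoord:::engine_forward(m, t0)$probs
  for (f in 1:3) {
    diff <- pX[1, f] - p0[1, f]
    expect_lt(abs(sum(ig[[f]]) - diff), max(0.01 * abs(diff), 1e-6))
  }
})

test_that("pooling averages within categories and filters NFB by value", {
  # hand-built: 2 nodes in the same (feature, frame, role) category
  meta <- data.table::data.table(target_row = 1L, rel = c(-1L, -1L, 0L),
                                 role = c("neighbor", "neighbor", "lineage"))
  X <- matrix(0, 3, 6); X[, 1] <- c(1, 1, 1)
  ig <- list(NB = matrix(0, 3, 6), Del = matrix(0, 3, 6), Div = matrix(0, 3, 6))
  ig$NB[, 1] <- c(0.2, 0.4, 0.7)
  pooled <- pool_attributions(ig, X, meta)
  row <- pooled[pooled$feature == "area" & pooled$rel == -1L & pooled$role == "neighbor", ]
  expect_equal(row$NB, 0.3)

  # NFB rows average only over cells carrying that NFB value
  X2 <- matrix(0, 3, 6); X2[, 4] <- c(1, 0, 0)   # only node 1 has NFB = Del
  ig$NB[, 4] <- c(0.5, 9, 9)                      # others must be ignored
  pooled2 <- pool_attributions(ig, X2, meta)
  r2 <- pooled2[pooled2$feature == "nfb_del" & pooled2$rel == -1L, ]
  expect_equal(r2$NB, 0.5)
  expect_equal(nrow(pooled2[pooled2$feature == "nfb_div", ]), 0L)  # empty category missing
})

test_that("pooled attributions keep the zero fate-sum and match a filtered mean", {
  st <- toy_setup()
  w <- st$windows[[1]]
  m <- init_model(model_config("cell_external", "mean"), seed = 2)
  tab <- attribution_table(m, list(w), st$fconfig, M = 20)
  expect_lt(max(abs(tab$NB + tab$Del + tab$Div)), 1e-9)

  # cross-check one NFB row against a brute-force filtered mean
  tens <- fatecoord:::subgraph_batch_tensors(w, st$fconfig, Ns = 1L)
  ig <- fatecoord:::ig_batch(m, tens, M = 20)
  pp <- pool_attributions(ig, tens$X, tens$meta)
  sel <- tens$X[, 4] == 1 & tens$meta$rel == -1L & tens$meta$role == "neighbor"
  if (any(sel)) {
    manual <- tapply(ig$Div[sel, 4], tens$meta$target_row[sel], mean)
    got <- pp[pp$feature == "nfb_del" & pp$rel == -1L & pp$role == "neighbor", ]
    expect_equal(mean(manual), mean(got$Div), tolerance = 1e-12)
  }
})

test_that("replicate aggregation: mean, standard error, and the random band", {
  base <- data.table::data.table(feature = c("random", "area"), rel = -1L,
                                 role = "neighbor", NB = 0, Del = 0, Div = 0, n = 5L)
  vals <- c(0.011, 0.008, 0.013, 0.009, 0.010, 0.009)
  tabs <- lapply(vals, function(v) {
    t <- data.table::copy(base); t$NB <- c(v, 0.5); t$Del <- -c(v, 0.5) / 2
    t$Div <- -c(v, 0.5) / 2; t
  })
  agg <- aggregate_attributions(tabs)
  rr <- agg[agg$feature == "random", ]
  expect_equal(rr$NB, mean(vals))
  expect_equal(rr$NB_se, stats::sd(vals) / sqrt(6))
  expect_equal(agg[agg$feature == "area", ]$NB_se, 0)

  # identical tables give zero SE
  agg2 <- aggregate_attributions(tabs[c(1, 1)])
  expect_true(all(agg2$NB_se == 0))

  # band arithmetic on a single random row with symmetric values
  one <- data.table::data.table(feature = "random", rel = 0L, role = "lineage",
                                NB = 0.01, NB_se = 0.002, Del = 0.01, Del_se = 0.002,
                                Div = 0.01, Div_se = 0.002, n_models = 6L)
  expect_equal(unname(random_baseline_band(one)), c(0.008, 0.012))
  expect_error(random_baseline_band(one[0, ]), "random")
})

test_that("without coordination, pooled attributions stay inside the band", {
  # uncoordinated control: mixed commitments with induction off, small scale
  cfg <- sim_config("mixed", N0 = 240L, seed = 31L, lambda_rate = 0.006,
                    induction = FALSE, burnin_steps = 200L,
                    production_steps = 160L)
  res <- simulate_dataset(cfg)
  fc <- heavy_fconfig()
  w <- extract_windows(res$graph, 4L)
  mcfg <- model_config("cell_external", "mean")
  tcfg <- train_config(epochs = 120L, eval_every = 30L, seed = 51L)
  rt <- replicate_train(w[1:3], w[4:5], mcfg, tcfg, fc, n_replicates = 2L)
  tabs <- lapply(rt$fits, function(f)
    attribution_table(f$model, w[4:5], fc, M = 12L, max_targets_per_window = 50L))
  agg <- aggregate_attributions(tabs)
  band <- random_baseline_band(agg)
  vals <- c(agg$NB, agg$Del, agg$Div)
  inside <- vals >= band["lo"] & vals <= band["hi"]
  expect_gte(mean(inside), 0.9)
})
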