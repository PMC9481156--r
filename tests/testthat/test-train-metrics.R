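test_that("class weights are inverse proportions", {
  y <- c(rep(1L, 8), 2L, 3L)
  expect_equal(unname(class_weights(y)), c(1.25, 10, 10))
  expect_error(class_weights(c(1L, 1L, 2L)), "absent")
})

test_that("weighted cross-entropy has its closed-form landmarks", {
  w <- c(NB = 1, Del = 1, Div = 1)
  uni <- matrix(1 / 3, 4, 3)
  expect_equal(weighted_ce_loss(uni, c(1L, 2L, 3L, 1L), w), log(3))
  perfect <- matrix(c(1 - 2e-12, 1e-12, 1e-12), 1, 3)
  expect_lt(weighted_ce_loss(perfect, 1L, w), 1e-10)
  # weighting scales each target's term by its label weight
  w2 <- c(NB = 2, Del = 1, Div = 1)
  expect_equal(weighted_ce_loss(uni[1, , drop = FALSE], 1L, w2), 2 * log(3))
})

test_that("baseline MSE loss matches its definition and landmarks", {
  st <- toy_setup()
  m <- init_model(model_config("unidirectional", "mean"), seed = 3)
  w <- st$windows[[1]]
  sgs <- lapply(w$target_idx[1:3], function(tg)
    null_graph(extract_target_subgraph(w, tg)))
  l <- baseline_mse_loss(m, sgs, st$fconfig)
  # by-hand recomputation from the predicted null scores
  probs <- do.call(rbind, lapply(sgs, function(sg)
    predict_fates(m, sg, st$fconfig)$probs))
  expect_equal(l, sum((probs - 1 / 3)^2) / 3, tolerance = 1e-12)
  expect_gte(l, 0)
  # hand arithmetic: scores (1,0,0) on one subgraph -> (2/3)^2 + 2*(1/3)^2
  expect_equal(sum((c(1, 0, 0) - 1 / 3)^2), 2 / 3)
})

test_that("loss gradients agree with finite differences on a 2-target toy", {
  st <- toy_setup()
  mcfg <- model_config("unidirectional", "sum", dropout = 0)
  m <- init_model(mcfg, seed = 2)
  tens <- fatecoord:::window_tensors(st$windows[[1]], st$fconfig)
  tens$targets <- tens$targets[1:2]
  tens$y <- tens$y[1:2]
  w <- c(NB = 1.5, Del = 4, Div = 3)
  out <- fatecoord:::engine_forward(m, tens, keep_cache = TRUE)
  bk <- fatecoord:::engine_backward(m, tens, out$cache,
                                    fatecoord:::ce_grad(out$probs, tens$y, w))
  flat <- function(x) unlist(x, use.names = FALSE)
  p0 <- flat(m$params); gr <- flat(bk$grads)
  withr::local_seed(9)
  d <- stats::rnorm(length(p0)); d <- d / sqrt(sum(d^2))
  lossp <- function(pv) {
    m2 <- m; m2$params <- utils::relist(pv, m$params)
    weighted_ce_loss(fatecoord:::engine_forward(m2, tens)$probs, tens$y, w)
  }
  eps <- 1e-5
  fd <- (lossp(p0 + eps * d) - lossp(p0 - eps * d)) / (2 * eps)
  expect_equal(sum(gr * d), fd, tolerance = 1e-6)
})

test_that("AUC equals the pairwise-comparison oracle, including ties", {
  withr::local_seed(31)
  for (rep in 1:5) {
    y <- sample(1:3, 40, replace = TRUE, prob = c(.6, .2, .2))
    scores <- matrix(stats::runif(120), 40, 3)
    scores[sample(40, 10), ] <- 0.5          # force ties
    r <- fate_metrics(scores, y)
    for (k in 1:3)
      expect_equal(unname(r$auc[k]), ref_auc(scores[, k], y == k), tolerance = 1e-12)
  }
  # perfect separation
  y <- c(1L, 1L, 2L, 3L)
  s <- matrix(c(.9, .8, .1, .2,  .05, .1, .9, .1,  .05, .1, 0, .7), 4, 3)
  expect_equal(unname(fate_metrics(s, y)$auc), c(1, 1, 1))
  # a fate absent from the labels has undefined AUC
  expect_true(is.na(fate_metrics(s[1:3, ], c(1L, 1L, 2L))$auc["Div"]))
})

test_that("confusion matrix rows sum to the class counts", {
  withr::local_seed(2)
  y <- sample(1:3, 60, replace = TRUE)
  scores <- matrix(stats::runif(180), 60, 3)
  r <- fate_metrics(scores, y)
  expect_equal(unname(rowSums(r$confusion)), unname(tabulate(y, 3)))
})

test_that("training is deterministic given the seed and its loss falls", {
  st <- toy_setup()
  mcfg <- model_config("cell_external", "mean")
  # small lr-raised smoke problem: the machinery must fit a strong signal
  tc <- train_config(lr = 1e-3, epochs = 40L, eval_every = 10L, seed = 3L)
  f1 <- train(st$windows[1:2], st$windows[3], mcfg, tc, st$fconfig)
  f2 <- train(st$windows[1:2], st$windows[3], mcfg, tc, st$fconfig)
  expect_identical(f1$final$params, f2$final$params)
  expect_identical(f1$history, f2$history)
  expect_lt(f1$history$train_loss[nrow(f1$history)], f1$history$train_loss[1])
})

test_that("training on permuted labels stays at chance level", {
  res <- heavy_mini()
  fc <- heavy_fconfig()
  w <- extract_windows(res$graph, 4L)
  mcfg <- model_config("cell_external", "mean")
  items <- fatecoord:::prep_windows(w[1:3], mcfg, fc)
  test_items <- fatecoord:::prep_windows(w[4:5], mcfg, fc)
  withr::local_seed(13)
  for (i in seq_along(items)) items[[i]]$y <- sample(items[[i]]$y)
  for (i in seq_along(test_items)) test_items[[i]]$y <- sample(test_items[[i]]$y)
  wts <- class_weights(unlist(lapply(items, `[[`, "y")))
  m <- init_model(mcfg, seed = 4)
  ad <- fatecoord:::adam_new(m$params, lr = 1e-3)
  best <- -Inf
  for (ep in 1:60) {
    for (it in items) {
      out <- fatecoord:::item_forward(m, it, training = TRUE, keep_cache = TRUE)
      gr <- fatecoord:::item_backward(m, it, out$cache,
                                      fatecoord:::ce_grad(out$probs, it$y, wts))
      st <- fatecoord:::adam_step(m$params, gr, ad)
      m$params <- st$params; ad <- st$state
    }
    if (ep %% 15 == 0) best <- max(best, evaluate(m, test_items)$macro_f1)
  }
  expect_lt(best, 0.5)
})
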