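## Training: class-weighted softmax cross-entropy on the window's targets,
## optionally interleaved with a neutral-baseline MSE update on the
## corresponding null graph (one CE step then one null step per window,
## every epoch), Adam throughout. Model selection keeps the epoch with the
## best test-set macro-F1.

#' Training configuration
#'
#' @param lr Adam learning rate.
#' @param epochs Number of passes over the training windows.
#' @param baseline_loss Whether to interleave the neutral-baseline MSE
#'   update (required for attribution with a null-graph baseline).
#' @param eval_every Evaluate test metrics every this many epochs; model
#'   selection picks the best evaluated epoch.
#' @param seed Seed controlling weight initialization, dropout and any
#'   target subsampling.
#' @param max_targets_train,max_targets_eval Optional per-window caps on the
#'   number of targets (seeded subsample), to bound runtime on large data.
#' @return A `train_config` list.
#' @export
train_config <- function(lr = 1e-4, epochs = 2000L, baseline_loss = TRUE,
                         eval_every = 1L, seed = 1L,
                         max_targets_train = Inf, max_targets_eval = Inf) {
  stopifnot(lr > 0, epochs >= 1)
  structure(list(lr = lr, epochs = as.integer(epochs), baseline_loss = baseline_loss,
                 eval_every = as.integer(eval_every), seed = as.integer(seed),
                 max_targets_train = max_targets_train,
                 max_targets_eval = max_targets_eval),
            class = "train_config")
}

#' Inverse-proportion class weights
#'
#' @param y Integer fate labels (1 = NB, 2 = Del, 3 = Div).
#' @return Weights `1 / proportion` per class.
#' @export
class_weights <- function(y) {
  tab <- tabulate(y, nbins = 3L)
  if (any(tab == 0L))
    stop("fate class absent from training data: ", paste(c("NB", "Del", "Div")[tab == 0L], collapse = ", "))
  prop <- tab / sum(tab)
  stats::setNames(1 / prop, c("NB", "Del", "Div"))
}

#' Class-weighted softmax cross-entropy
#'
#' Mean over targets of `-w[label] * log(score of the true label)`.
#'
#' @param probs Matrix of softmax scores (targets x 3).
#' @param y Integer labels (1..3).
#' @param w Length-3 class weights.
#' @return The scalar loss.
#' @export
weighted_ce_loss <- function(probs, y, w) {
  mean(-w[y] * log(pmax(probs[cbind(seq_along(y), y)], 1e-300)))
}

ce_grad <- function(probs, y, w) {
  Tn <- length(y)
  G <- probs
  G[cbind(seq_len(Tn), y)] <- G[cbind(seq_len(Tn), y)] - 1
  G * (w[y] / Tn)
}

mse_grad <- function(probs) {
  Tn <- nrow(probs)
  gp <- 2 * (probs - 1 / 3) / Tn
  probs * (gp - rowSums(gp * probs))
}

#' Neutral-baseline MSE loss on null graphs
#'
#' The mean over subgraphs and fates of the squared deviation of the
#' null-graph softmax scores from the neutral value 1/3.
#'
#' @param model An `fc_model`.
#' @param null_subgraphs A list of (nulled) `target_subgraph` objects, or a
#'   prebuilt tensor batch.
#' @param fconfig A [feature_config()].
#' @return The scalar loss.
#' @export
baseline_mse_loss <- function(model, null_subgraphs, fconfig = feature_config()) {
  probs <- if (is.list(null_subgraphs) && !is.null(null_subgraphs$X)) {
    engine_forward(model, null_subgraphs)$probs
  } else {
    do.call(rbind, lapply(null_subgraphs, function(sg)
      engine_forward(model, subgraph_tensors(sg, fconfig))$probs))
  }
  sum((probs - 1 / 3)^2) / nrow(probs)
}

## ---- per-window training items ----------------------------------------

prep_window <- function(window, mconfig, fconfig, max_targets = Inf) {
  if (!length(window$target_idx)) return(NULL)
  if (is.finite(max_targets) && length(window$target_idx) > max_targets) {
    keep <- sort(sample(seq_along(window$target_idx), max_targets))
    window$target_idx <- window$target_idx[keep]
  }
  if (mconfig$variant == "cell_external" && mconfig$Ns == 1L) {
    ft <- fast_tensors(window, fconfig)
    list(type = "fast", ft = ft, nt = null_tensors(ft, mconfig), y = ft$y,
         n_targets = ft$n_targets)
  } else if (mconfig$variant == "cell_external") {
    tens <- subgraph_batch_tensors(window, fconfig, Ns = mconfig$Ns)
    ntens <- tens; ntens$X <- tens$X * 0
    list(type = "generic", tens = tens, ntens = ntens, y = tens$y,
         n_targets = length(tens$y))
  } else {
    tens <- window_tensors(window, fconfig)
    it <- list(type = "generic", tens = tens, y = tens$y, n_targets = length(tens$y))
    if (mconfig$variant == "bidirectional") {
      ntens <- tens; ntens$X <- tens$X * 0
      it$ntens <- ntens
    } else {
      ft <- fast_tensors(window, fconfig)
      it$nt <- null_tensors(ft, mconfig)
    }
    it
  }
}

prep_windows <- function(windows, mconfig, fconfig, max_targets = Inf) {
  items <- lapply(windows, prep_window, mconfig = mconfig, fconfig = fconfig,
                  max_targets = max_targets)
  items[!vapply(items, is.null, TRUE)]
}

item_forward <- function(model, item, training = FALSE, keep_cache = FALSE) {
  if (item$type == "fast") fast_forward(model, item$ft, training, keep_cache)
  else engine_forward(model, item$tens, training, keep_cache)
}

item_backward <- function(model, item, cache, glogits) {
  if (item$type == "fast") fast_backward(model, item$ft, cache, glogits)
  else engine_backward(model, item$tens, cache, glogits)$grads
}

collect_predictions <- function(model, items) {
  probs <- do.call(rbind, lapply(items, function(it) item_forward(model, it)$probs))
  colnames(probs) <- c("NB", "Del", "Div")
  list(probs = probs, y = unlist(lapply(items, `[[`, "y")))
}

## ---- metrics -----------------------------------------------------------

#' One-vs-rest AUC, macro-F1, per-class recall/precision and confusion matrix
#'
#' AUC uses the rank-based estimator (via pROC) of the probability that a
#' random positive outscores a random negative, ties counting one half. A
#' fate absent from `y` gets `NA` AUC and is excluded from averages.
#'
#' @param probs Softmax score matrix (targets x 3, columns NB/Del/Div).
#' @param y Integer labels (1..3).
#' @return An `eval_report` list.
#' @export
fate_metrics <- function(probs, y) {
  lev <- c("NB", "Del", "Div")
  pred <- max.col(probs, ties.method = "first")
  conf <- table(factor(lev[y], levels = lev), factor(lev[pred], levels = lev))
  f1 <- recall <- precision <- stats::setNames(rep(NA_real_, 3L), lev)
  for (k in 1:3) {
    tp <- conf[k, k]; fn <- sum(conf[k, ]) - tp; fp <- sum(conf[, k]) - tp
    recall[k] <- if (tp + fn > 0) tp / (tp + fn) else NA
    precision[k] <- if (tp + fp > 0) tp / (tp + fp) else 0
    f1[k] <- if (is.na(recall[k])) NA
             else if (tp == 0) 0 else 2 * precision[k] * recall[k] / (precision[k] + recall[k])
  }
  auc <- stats::setNames(rep(NA_real_, 3L), lev)
  for (k in 1:3) {
    resp <- y == k
    if (any(resp) && !all(resp))
      auc[k] <- as.numeric(pROC::roc(response = resp, predictor = probs[, k],
                                     levels = c(FALSE, TRUE), direction = "<",
                                     quiet = TRUE)$auc)
  }
  structure(list(auc = auc, macro_f1 = mean(f1, na.rm = TRUE),
                 recall = recall, precision = precision,
                 confusion = conf, n = length(y)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Evaluation over %d targets: macro-F1 = %.3f\n", x$n, x$macro_f1))
  cat("AUC: ", paste(sprintf("%s=%.3f", names(x$auc), x$auc), collapse = "  "), "\n")
  print(x$confusion)
  invisible(x)
}

#' Evaluate a trained model on test windows
#'
#' @param model An `fc_model`.
#' @param windows A list of `stg_window` (or prepped items from training).
#' @param fconfig A [feature_config()].
#' @return An `eval_report` (see [fate_metrics()]).
#' @export
evaluate <- function(model, windows, fconfig = feature_config()) {
  items <- if (length(windows) && inherits(windows[[1]], "stg_window"))
    prep_windows(windows, model$config, fconfig) else windows
  pr <- collect_predictions(model, items)
  fate_metrics(pr$probs, pr$y)
}

## ---- the training loop -------------------------------------------------

#' Train a cell-fate model
#'
#' Runs the per-window update schedule: for every training window, one Adam
#' step on the class-weighted cross-entropy over the window's targets,
#' then (if enabled) one Adam step on the neutral-baseline MSE loss of the
#' window's null graph. Test metrics are recorded every `eval_every` epochs
#' and the parameters with the best test macro-F1 are returned.
#'
#' @param windows_train,windows_test Lists of `stg_window` (disjoint data).
#' @param mconfig A [model_config()].
#' @param tconfig A [train_config()].
#' @param fconfig A [feature_config()].
#' @param verbose Print progress every 100 epochs.
#' @return A list with the selected `model`, the `final` epoch's model, the
#'   per-evaluation `history`, `best_epoch`, the class `weights` used and
#'   the test `report` at the selected epoch.
#' @export
train <- function(windows_train, windows_test, mconfig, tconfig,
                  fconfig = feature_config(), verbose = FALSE) {
  set.seed(tconfig$seed)
  items <- prep_windows(windows_train, mconfig, fconfig, tconfig$max_targets_train)
  if (!length(items)) stop("no training windows with eligible targets")
  test_items <- prep_windows(windows_test, mconfig, fconfig, tconfig$max_targets_eval)
  w <- class_weights(unlist(lapply(items, `[[`, "y")))

  model <- init_model(mconfig, seed = derive_seeds(tconfig$seed, 1L))
  ad <- adam_new(model$params, lr = tconfig$lr)

  hist <- vector("list", 0L)
  best <- list(f1 = -Inf, params = model$params, epoch = 0L, report = NULL)
  for (ep in seq_len(tconfig$epochs)) {
    tot <- 0
    for (it in items) {
      out <- item_forward(model, it, training = TRUE, keep_cache = TRUE)
      tot <- tot + weighted_ce_loss(out$probs, it$y, w) * it$n_targets
      grads <- item_backward(model, it, out$cache, ce_grad(out$probs, it$y, w))
      st <- adam_step(model$params, grads, ad)
      model$params <- st$params; ad <- st$state
      if (tconfig$baseline_loss) {
        if (!is.null(it$nt)) {
          np <- null_pass(model, it$nt, training = TRUE)
          st <- adam_step(model$params, np$grads, ad)
        } else {
          nout <- engine_forward(model, it$ntens, training = TRUE, keep_cache = TRUE)
          ngr <- engine_backward(model, it$ntens, nout$cache, mse_grad(nout$probs))$grads
          st <- adam_step(model$params, ngr, ad)
        }
        model$params <- st$params; ad <- st$state
      }
    }
    if (ep %% tconfig$eval_every == 0L || ep == tconfig$epochs) {
      rep_ <- if (length(test_items)) evaluate(model, test_items) else NULL
      f1 <- if (is.null(rep_)) NA_real_ else rep_$macro_f1
      hist[[length(hist) + 1L]] <- data.table::data.table(
        epoch = ep, train_loss = tot / sum(vapply(items, `[[`, 0L, "n_targets")),
        test_macro_f1 = f1)
      if (!is.null(rep_) && f1 > best$f1) {
        best <- list(f1 = f1, params = model$params, epoch = ep, report = rep_)
      }
      if (verbose && ep %% 100L == 0L)
        message(sprintf("epoch %d: train CE %.4f, test macro-F1 %.3f", ep,
                        tot / sum(vapply(items, `[[`, 0L, "n_targets")), f1))
    }
  }
  sel <- model; sel$params <- best$params
  list(model = sel, final = model, history = data.table::rbindlist(hist),
       best_epoch = best$epoch, weights = w, report = best$report)
}

#' Train several replicate models and aggregate their metrics
#'
#' @inheritParams train
#' @param n_replicates Number of models trained from distinct seeds.
#' @param seeds Optional explicit seeds (length `n_replicates`).
#' @return A list with per-replicate `fits`, the per-replicate selected-epoch
#'   reports, and `summary` (mean and sd of AUC and macro-F1 across
#'   replicates).
#' @export
replicate_train <- function(windows_train, windows_test, mconfig, tconfig,
                            fconfig = feature_config(), n_replicates = 6L,
                            seeds = NULL, verbose = FALSE) {
  seeds <- seeds %||% derive_seeds(tconfig$seed, n_replicates)
  stopifnot(length(seeds) == n_replicates)
  fits <- lapply(seq_len(n_replicates), function(i) {
    tc <- tconfig; tc$seed <- seeds[i]
    train(windows_train, windows_test, mconfig, tc, fconfig, verbose = verbose)
  })
  aucs <- do.call(rbind, lapply(fits, function(f) f$report$auc))
  f1s <- vapply(fits, function(f) f$report$macro_f1, 0)
  list(fits = fits, seeds = seeds,
       summary = list(auc_mean = colMeans(aucs), auc_sd = apply(aucs, 2L, stats::sd),
                      macro_f1_mean = mean(f1s), macro_f1_sd = stats::sd(f1s)))
}
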