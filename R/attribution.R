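## Integrated-gradients attribution.
##
## For a target's subgraph with concatenated features X and the null graph
## X' = 0 as baseline, the attribution of feature k to the softmax score of
## fate f is IG_k^f = (X_k - X'_k) * mean over a midpoint discretization of
## the path integral of dF^f/dX_k along the straight line from X' to X.
## Because the three softmax scores sum to one, the three attributions of
## any feature sum to zero, and this survives pooling. Pooled categories
## are (feature type x relative frame x role), role being the target's own
## ancestor lineage versus the surrounding cells; NFB categories average
## only over the cells carrying that NFB value. A significance band is
## spanned by the pooled attributions of the uninformative random feature.

feature_names <- c("area", "g1", "nfb_nb", "nfb_del", "nfb_div", "random")

# Per-fate input-gradient averages over the integration path for a tensor
# batch; returns list (NB, Del, Div) of N x 6 IG matrices.
ig_batch <- function(model, tens, M = 50L) {
  X0 <- tens$X
  acc <- rep(list(X0 * 0), 3L)
  for (j in seq_len(M)) {
    tj <- tens
    tj$X <- X0 * ((j - 0.5) / M)
    out <- engine_forward(model, tj, training = FALSE, keep_cache = TRUE)
    p <- out$probs
    for (f in 1:3) {
      gl <- -p * p[, f]
      gl[, f] <- gl[, f] + p[, f]
      acc[[f]] <- acc[[f]] + engine_backward(model, tj, out$cache, gl, want_gx = TRUE)$gX
    }
  }
  stats::setNames(lapply(acc, function(A) X0 * (A / M)), c("NB", "Del", "Div"))
}

#' Integrated gradients for one target subgraph
#'
#' @param model A trained `fc_model` (evaluated with dropout off).
#' @param subgraph A `target_subgraph`.
#' @param fconfig A [feature_config()].
#' @param M Number of midpoint steps discretizing the path integral.
#' @return A list of three N x 6 matrices (one per fate) of per-node,
#'   per-feature attributions, with the subgraph's `meta` attached as
#'   attribute.
#' @export
integrated_gradients <- function(model, subgraph, fconfig = feature_config(), M = 50L) {
  tens <- subgraph_tensors(subgraph, fconfig)
  ig <- ig_batch(model, tens, M)
  attr(ig, "meta") <- tens$meta
  attr(ig, "X") <- tens$X
  ig
}

#' Pool per-feature attributions into spatiotemporal categories
#'
#' Averages attributions within (feature type, relative frame, role)
#' categories per subgraph; NFB categories are averaged only over the cells
#' whose NFB input equals the category (the fate-sum-zero identity is
#' preserved by this pooling).
#'
#' @param ig List of three N x 6 IG matrices (per fate).
#' @param X The N x 6 input feature matrix (for NFB category membership).
#' @param meta `data.table` with per-node `target_row`, `rel`, `role`.
#' @return A `data.table` with one row per (subgraph, category).
#' @export
pool_attributions <- function(ig, X, meta) {
  parts <- lapply(seq_along(feature_names), function(k) {
    member <- if (k %in% 3:5) X[, k] == 1 else rep(TRUE, nrow(X))
    if (!any(member)) return(NULL)
    data.table::data.table(
      target_row = meta$target_row[member], feature = feature_names[k],
      rel = meta$rel[member], role = meta$role[member],
      NB = ig$NB[member, k], Del = ig$Del[member, k], Div = ig$Div[member, k])
  })
  long <- data.table::rbindlist(parts)
  long[, list(NB = mean(NB), Del = mean(Del), Div = mean(Div)),
       by = c("target_row", "feature", "rel", "role")]
}

#' Attribution table for one trained model
#'
#' Computes integrated gradients on the targets of the supplied (test)
#' windows via per-target subgraph batches and pools them over subgraphs.
#'
#' @param model A trained `fc_model`.
#' @param windows List of `stg_window`.
#' @param fconfig A [feature_config()].
#' @param M Path-integral steps.
#' @param max_targets_per_window Optional seeded subsample cap per window.
#' @param seed Seed for the subsample.
#' @return `data.table` keyed by (feature, rel, role) with mean attribution
#'   per fate and the number of contributing subgraphs.
#' @export
attribution_table <- function(model, windows, fconfig = feature_config(), M = 50L,
                              max_targets_per_window = Inf, seed = 1L) {
  Ns <- max(model$config$Ns, 1L)
  pooled <- list()
  for (wi in seq_along(windows)) {
    w <- windows[[wi]]
    if (!length(w$target_idx)) next
    if (is.finite(max_targets_per_window) && length(w$target_idx) > max_targets_per_window) {
      keep <- with_local_seed(seed + wi, sort(sample(seq_along(w$target_idx),
                                                     max_targets_per_window)))
      w$target_idx <- w$target_idx[keep]
    }
    tens <- subgraph_batch_tensors(w, fconfig, Ns = Ns)
    ig <- ig_batch(model, tens, M)
    pp <- pool_attributions(ig, tens$X, tens$meta)
    pp$target_row <- pp$target_row + wi * 1e6   # keep subgraphs distinct across windows
    pooled[[length(pooled) + 1L]] <- pp
  }
  long <- data.table::rbindlist(pooled)
  long[, list(NB = mean(NB), Del = mean(Del), Div = mean(Div), n = .N),
       by = c("feature", "rel", "role")]
}

#' Aggregate attribution tables over model replicates
#'
#' @param tables List of per-model tables from [attribution_table()].
#' @return `data.table` with per-category mean and standard error (over
#'   models) for each fate, plus the number of models contributing.
#' @export
aggregate_attributions <- function(tables) {
  all_ <- data.table::rbindlist(tables, idcol = "model")
  se <- function(x) if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else 0
  all_[, list(NB = mean(NB), NB_se = se(NB),
              Del = mean(Del), Del_se = se(Del),
              Div = mean(Div), Div_se = se(Div),
              n_models = .N),
       by = c("feature", "rel", "role")]
}

#' Significance band from the pooled random-feature attributions
#'
#' The band spans from the minimum of (model-mean - SE) to the maximum of
#' (model-mean + SE) over all pooled random-feature categories and fates.
#' Pooled attributions inside the band are indistinguishable from those of
#' a feature known to carry no information.
#'
#' @param agg Output of [aggregate_attributions()].
#' @return `c(lo, hi)`.
#' @export
random_baseline_band <- function(agg) {
  rr <- agg[agg$feature == "random", ]
  if (!nrow(rr)) stop("no pooled random-feature rows; was the random feature active?")
  c(lo = min(rr$NB - rr$NB_se, rr$Del - rr$Del_se, rr$Div - rr$Div_se),
    hi = max(rr$NB + rr$NB_se, rr$Del + rr$Del_se, rr$Div + rr$Div_se))
}
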