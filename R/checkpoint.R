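## Model checkpoints as portable JSON array archives: every MLP weight
## matrix with its dimensions, the model configuration, and the
## initialization seed.

#' Save a model checkpoint
#'
#' @param model An `fc_model`.
#' @param path Output path (JSON).
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  pack <- function(x) {
    if (is.list(x)) lapply(x, pack)
    else list(dim = dim(x) %||% length(x), v = as.vector(x))
  }
  obj <- list(config = unclass(model$config), seed = model$seed,
              params = pack(model$params))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path Path written by [save_model()].
#' @return An `fc_model`.
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  unpack <- function(x) {
    if (is.list(x) && !is.null(x$v)) {
      v <- as.numeric(unlist(x$v))
      d <- as.integer(unlist(x$dim))
      if (length(d) == 2L) matrix(v, d[1], d[2]) else v
    } else lapply(x, unpack)
  }
  cfg <- obj$config
  config <- model_config(variant = cfg$variant, aggregation = cfg$aggregation,
                         Nt = cfg$Nt, Ns = cfg$Ns, n_layer = cfg$n_layer,
                         n_node = cfg$n_node, dropout = cfg$dropout,
                         forward_freeze = cfg$forward_freeze)
  structure(list(config = config, params = unpack(obj$params),
                 seed = obj$seed), class = "fc_model")
}
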