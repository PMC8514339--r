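#' Save a model checkpoint
#'
#' Serializes masks, weights, biases, head parameters, head loss weights,
#' activation, node lists and training history into a single
#' self-describing JSON file (full numeric precision).
#'
#' @param model A `pnet_model`.
#' @param path Output file path (`.json`).
#' @return `path`, invisibly.
#' @export
save_pnet <- function(model, path) {
  payload <- list(
    format = "pnet-checkpoint-1",
    activation = model$activation,
    head_loss_weights = model$head_loss_weights,
    layer_names = model$layer_names,
    nodes = model$nodes,
    display_names = as.list(model$display_names),
    trained = isTRUE(model$trained),
    layers = lapply(model$layers, function(l) {
      list(M = l$M, W = l$W, b = l$b)
    }),
    heads = lapply(model$heads, function(h) list(v = h$v, c = h$c)),
    history = if (!is.null(model$history)) as.list(model$history) else NULL
  )
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       na = "null")
  invisible(path)
}

#' Load a model checkpoint written by [save_pnet()]
#'
#' @param path Checkpoint JSON path.
#' @return A `pnet_model`.
#' @export
load_pnet <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  if (!identical(p$format, "pnet-checkpoint-1")) {
    stop("not a recognized checkpoint: ", path)
  }
  layers <- lapply(p$layers, function(l) {
    list(M = as.matrix(l$M), W = as.matrix(l$W), b = as.numeric(l$b))
  })
  heads <- lapply(p$heads, function(h) {
    list(v = as.numeric(h$v), c = as.numeric(h$c))
  })
  nodes <- lapply(p$nodes, as.character)
  structure(list(layers = unname(layers), heads = unname(heads),
                 head_loss_weights = as.numeric(p$head_loss_weights),
                 activation = p$activation,
                 nodes = nodes,
                 layer_names = as.character(p$layer_names),
                 display_names = unlist(p$display_names),
                 trained = isTRUE(p$trained),
                 history = if (!is.null(p$history))
                   as.data.frame(lapply(p$history, unlist)) else NULL),
            class = "pnet_model")
}
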