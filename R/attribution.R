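# rescale-rule multiplier of a nonlinearity: (f(z) - f(z0)) / (z - z0),
# falling back to the derivative f'(z0) where the denominator is tiny
rescale_mult <- function(d_out, d_in, deriv0, eps = 1e-7) {
  small <- abs(d_in) < eps
  out <- d_out / d_in
  out[small] <- deriv0[small]
  out
}

#' Sample-level DeepLIFT contributions (rescale rule) for every layer
#'
#' Propagates multipliers backward from a scalar target through the masked
#' layers and the sigmoid heads. Linear (masked) operations pass multipliers
#' through the effective weights `M * W`; each nonlinearity contributes the
#' rescale multiplier `(f(z) - f(z0)) / (z - z0)`, falling back to the
#' derivative `f'(z0)` when `|z - z0| < 1e-7`. The contribution of node i in
#' layer l for sample s is `C_i^{l,s} = m_i * (h_i(x_s) - h_i(x0))`, and per
#' layer the contributions sum to the target difference
#' `delta_t = t(x_s) - t(x0)` (completeness).
#'
#' @param model A trained `pnet_model`.
#' @param x Samples to explain: `profile_tensor` or input matrix.
#' @param x0 Reference input; default the all-zeros profile (no genomic
#'   alteration).
#' @param target `"mean"` (the averaged outcome, default) or an integer head
#'   index to explain a single layer's head.
#' @return Object of class `deeplift_scores`: list with `layers` (one
#'   samples x nodes contribution matrix per network layer, including the
#'   feature layer), `delta_t` (samples x layers matrix of the explained
#'   target difference per layer: heads attached below a layer are not
#'   functions of it and are held fixed when that layer is explained, so
#'   each column is the summed probability change of the heads at or above
#'   the layer; the feature-layer column is the full outcome difference),
#'   `outcome_delta` (per-sample difference of the averaged outcome) and
#'   `layer_names`.
#' @export
deeplift_scores <- function(model, x, x0 = NULL, target = "mean") {
  X <- if (inherits(x, "profile_tensor")) as_input_matrix(x) else {
    if (is.vector(x)) matrix(x, nrow = 1) else as.matrix(x)
  }
  L <- length(model$layers)
  for (l in seq_len(L)) {
    if (any(!is.finite(model$layers[[l]]$W))) {
      stop("model has non-finite weights; train it before attribution")
    }
  }
  if (is.null(x0)) x0 <- rep(0, ncol(X))
  fw <- model_forward(model, X)
  fw0 <- model_forward(model, matrix(x0, nrow = 1))

  n <- nrow(X)
  rescale <- rescale_mult
  act_deriv0 <- function(h0) {
    if (model$activation == "tanh") 1 - h0^2 else rep(1, length(h0))
  }

  # multiplier of the target w.r.t. each head pre-activation (n x L)
  heads_used <- if (identical(target, "mean")) seq_len(L) else as.integer(target)
  stopifnot(all(heads_used %in% seq_len(L)))
  scale <- if (identical(target, "mean")) 1 / L else 1
  t_val <- if (identical(target, "mean")) fw$score else fw$head_p[, heads_used]
  t0_val <- if (identical(target, "mean")) fw0$score else fw0$head_p[, heads_used]

  mH <- vector("list", L + 1)      # multipliers w.r.t. H[[l]] (input is l = 1)
  for (l in seq_len(L + 1)) mH[[l]] <- matrix(0, n, ncol(fw$H[[l]]))

  identity_heads <- identical(model$head_activation, "identity")
  for (h in heads_used) {
    dz <- sweep(fw$head_z[, h, drop = FALSE], 2, fw0$head_z[, h], "-")
    dp <- sweep(fw$head_p[, h, drop = FALSE], 2, fw0$head_p[, h], "-")
    s0 <- fw0$head_p[, h]
    deriv0 <- if (identity_heads) matrix(1, n, 1) else
      matrix(s0 * (1 - s0), n, 1)
    m_sig <- rescale(dp, dz, deriv0) * scale
    mH[[h + 1]] <- mH[[h + 1]] + tcrossprod(drop(m_sig), model$heads[[h]]$v)
  }

  for (l in L:1) {
    dZ <- sweep(fw$Z[[l]], 2, drop(fw0$Z[[l]]), "-")
    dH <- sweep(fw$H[[l + 1]], 2, drop(fw0$H[[l + 1]]), "-")
    deriv0 <- matrix(act_deriv0(drop(fw0$H[[l + 1]])), n, ncol(dH), byrow = TRUE)
    mZ <- mH[[l + 1]] * rescale(dH, dZ, deriv0)
    Wm <- model$layers[[l]]$M * model$layers[[l]]$W
    mH[[l]] <- mH[[l]] + mZ %*% t(Wm)
  }

  layers <- vector("list", L + 1)
  for (l in seq_len(L + 1)) {
    dH <- sweep(fw$H[[l]], 2, drop(fw0$H[[l]]), "-")
    C <- mH[[l]] * dH
    colnames(C) <- model$nodes[[l]]
    rownames(C) <- rownames(X)
    layers[[l]] <- C
  }
  names(layers) <- model$layer_names
  # explained target difference per layer: explaining layer l holds paths
  # that bypass it (heads attached below l) fixed at their sample values,
  # so the decomposable difference is the summed change of the heads at or
  # above l; for the feature layer this is the full outcome difference
  dp <- sweep(fw$head_p, 2, drop(fw0$head_p), "-") * scale
  delta_t <- matrix(0, n, L + 1,
                    dimnames = list(rownames(X), model$layer_names))
  for (l in seq_len(L + 1)) {
    reach <- intersect(heads_used, seq(max(1, l - 1), L))
    if (length(reach) > 0) {
      delta_t[, l] <- rowSums(dp[, reach, drop = FALSE])
    }
  }
  structure(list(layers = layers,
                 delta_t = delta_t,
                 outcome_delta = unname(t_val - t0_val),
                 layer_names = model$layer_names,
                 target = target),
            class = "deeplift_scores")
}

#' Aggregate sample-level contributions into node importance
#'
#' `C_i^l = |sum_s C_i^{l,s}|`: the absolute value of the signed sum over
#' samples (not the sum of absolute values), so contributions of opposite
#' sign cancel.
#'
#' @param scores A `deeplift_scores` object, or a single samples x nodes
#'   contribution matrix.
#' @return Named numeric vector per layer (list when given the full object).
#' @export
aggregate_importance <- function(scores) {
  agg <- function(m) abs(colSums(m))
  if (inherits(scores, "deeplift_scores")) lapply(scores$layers, agg) else
    agg(as.matrix(scores))
}

#' Degree-adjust aggregate importance scores
#'
#' Within a layer, a node whose degree exceeds the layer's mean degree plus
#' five (population) standard deviations has its score divided by its
#' degree; all other scores are unchanged. This counters over-annotation
#' bias of hub nodes.
#'
#' @param C Named numeric vector of aggregate importance for one layer.
#' @param degrees Numeric vector of node degrees (fan-in + fan-out), same
#'   length/order as `C`.
#' @return Adjusted scores, same names as `C`.
#' @export
adjust_importance <- function(C, degrees) {
  stopifnot(length(C) == length(degrees), all(degrees >= 0))
  mu <- mean(degrees)
  sigma <- sqrt(mean((degrees - mu)^2))   # population standard deviation
  hub <- degrees > mu + 5 * sigma
  out <- C
  out[hub] <- C[hub] / degrees[hub]
  out
}

# degrees per layer computed from the model's own masks (heads excluded)
model_degrees <- function(model) {
  L <- length(model$layers)
  out <- vector("list", L + 1)
  for (l in seq_len(L + 1)) {
    fan_in <- if (l == 1) rep(0, length(model$nodes[[1]])) else
      colSums(model$layers[[l - 1]]$M)
    fan_out <- if (l == L + 1) rep(0, length(model$nodes[[L + 1]])) else
      rowSums(model$layers[[l]]$M)
    out[[l]] <- stats::setNames(fan_in + fan_out, model$nodes[[l]])
  }
  names(out) <- model$layer_names
  out
}

#' Full interpretation of a trained model over an evaluation set
#'
#' Runs [deeplift_scores()], aggregates over samples, degree-adjusts, and
#' ranks nodes per layer (rank 1 = largest adjusted score; ties broken
#' lexicographically by node id).
#'
#' @param model A trained `pnet_model`.
#' @param x Evaluation samples (`profile_tensor` or matrix); the testing set
#'   by default in the surrounding workflow.
#' @param x0,target Passed to [deeplift_scores()].
#' @return Object of class `pnet_importance`: `table` (data.frame with
#'   node_id, display_name, layer, degree, C, adjusted_C, rank) plus the
#'   underlying `scores`.
#' @export
pnet_importance <- function(model, x, x0 = NULL, target = "mean") {
  n_eval <- if (inherits(x, "profile_tensor")) dim(x)[1] else nrow(as.matrix(x))
  if (is.null(n_eval) || n_eval == 0) stop("empty evaluation set")
  dl <- deeplift_scores(model, x, x0 = x0, target = target)
  C <- aggregate_importance(dl)
  degs <- model_degrees(model)
  rows <- list()
  for (ln in names(C)) {
    adj <- adjust_importance(C[[ln]], unname(degs[[ln]]))
    ord <- order(-adj, names(C[[ln]]))
    rk <- integer(length(adj)); rk[ord] <- seq_along(adj)
    dn <- model$display_names
    ids <- names(C[[ln]])
    rows[[ln]] <- data.frame(
      node_id = ids,
      display_name = unname(ifelse(ids %in% names(dn), dn[ids], ids)),
      layer = ln,
      degree = unname(degs[[ln]]),
      C = unname(C[[ln]]),
      adjusted_C = unname(adj),
      rank = rk,
      stringsAsFactors = FALSE)
  }
  structure(list(table = do.call(rbind, c(rows, make.row.names = FALSE)),
                 scores = dl),
            class = "pnet_importance")
}

#' @exportS3Method base::print
print.pnet_importance <- function(x, n = 5, ...) {
  for (ln in unique(x$table$layer)) {
    sub <- x$table[x$table$layer == ln, ]
    sub <- sub[order(sub$rank), ]
    cat("--", ln, "(top", min(n, nrow(sub)), "of", nrow(sub), ")\n")
    print(utils::head(sub[, c("node_id", "degree", "C", "adjusted_C", "rank")], n),
          row.names = FALSE)
  }
  invisible(x)
}

#' Class-difference analysis of node activations
#'
#' For every node in every layer, compares the activation distribution
#' between the two sample classes with a Welch t statistic. Nodes with zero
#' variance in both classes (for example zero fan-in nodes whose activation
#' is the constant `tanh(b)`) are flagged degenerate with statistic 0.
#'
#' @param model A trained `pnet_model`.
#' @param x Samples (`profile_tensor` or matrix).
#' @param y 0/1 labels aligned with `x`.
#' @return data.frame with `layer`, `node`, `mean_class0`, `mean_class1`,
#'   `statistic`, `p_value`, `degenerate`.
#' @export
node_activation_analysis <- function(model, x, y) {
  X <- if (inherits(x, "profile_tensor")) as_input_matrix(x) else as.matrix(x)
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("both classes must be present")
  fw <- model_forward(model, X)
  out <- list()
  for (l in seq_along(fw$H)) {
    A <- fw$H[[l]]
    a0 <- A[y == 0, , drop = FALSE]
    a1 <- A[y == 1, , drop = FALSE]
    n0 <- nrow(a0); n1 <- nrow(a1)
    m0 <- colMeans(a0); m1 <- colMeans(a1)
    v0 <- apply(a0, 2, stats::var); v1 <- apply(a1, 2, stats::var)
    se2 <- v0 / n0 + v1 / n1
    degenerate <- se2 == 0
    stat <- ifelse(degenerate, 0, (m1 - m0) / sqrt(se2))
    df <- ifelse(degenerate, NA_real_,
                 se2^2 / ((v0 / n0)^2 / (n0 - 1) + (v1 / n1)^2 / (n1 - 1)))
    pv <- ifelse(degenerate, NA_real_, 2 * stats::pt(-abs(stat), df))
    out[[l]] <- data.frame(layer = model$layer_names[l],
                           node = model$nodes[[l]],
                           mean_class0 = unname(m0), mean_class1 = unname(m1),
                           statistic = unname(stat), p_value = unname(pv),
                           degenerate = unname(degenerate),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Export importance tables and a Sankey-ready link table
#'
#' Writes one CSV per layer (`importance_<layer>.csv`: node_id,
#' display_name, layer, degree, C, adjusted_C, rank) and `links.csv`
#' apportioning each node's aggregate importance over its outgoing
#' (parent-ward) connections in proportion to `|M * W|`, so the shares out
#' of a node sum to the node's own importance.
#'
#' @param importance A `pnet_importance`.
#' @param model The `pnet_model` the importance was computed from.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
export_importance_report <- function(importance, model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- importance$table
  for (ln in unique(tab$layer)) {
    sub <- tab[tab$layer == ln, ]
    sub <- sub[order(sub$rank), ]
    utils::write.csv(sub, file.path(dir, paste0("importance_", ln, ".csv")),
                     row.names = FALSE)
  }
  links <- list()
  for (l in seq_along(model$layers)) {
    Wm <- abs(model$layers[[l]]$M * model$layers[[l]]$W)
    ln <- model$layer_names[l]
    Cl <- tab$C[tab$layer == ln][match(model$nodes[[l]],
                                       tab$node_id[tab$layer == ln])]
    rs <- rowSums(Wm)
    idx <- which(model$layers[[l]]$M == 1, arr.ind = TRUE)
    if (nrow(idx) == 0) next
    share <- Cl[idx[, 1]] * Wm[idx] / rs[idx[, 1]]
    # nodes with outgoing mask edges but all-zero weights: split evenly
    zero_rows <- rs == 0
    if (any(zero_rows[idx[, 1]])) {
      fo <- rowSums(model$layers[[l]]$M)
      z <- zero_rows[idx[, 1]]
      share[z] <- Cl[idx[z, 1]] / fo[idx[z, 1]]
    }
    links[[l]] <- data.frame(
      source_node = model$nodes[[l]][idx[, 1]],
      target_node = model$nodes[[l + 1]][idx[, 2]],
      source_layer = ln,
      share = share,
      stringsAsFactors = FALSE)
  }
  links <- do.call(rbind, c(links, make.row.names = FALSE))
  links <- links[order(links$source_layer, links$source_node, links$target_node), ]
  utils::write.csv(links, file.path(dir, "links.csv"), row.names = FALSE)
  invisible(dir)
}
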