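# Independent oracles used across test files. These deliberately avoid the
# package's own code paths: BFS on edge lists, pair counting for AUC,
# explicit edge-by-edge network evaluation, finite differences.

# shortest child->parent distance from `node` up to `root` by BFS
bfs_depth <- function(edges, node, root) {
  frontier <- node
  d <- 0
  seen <- character(0)
  while (length(frontier) > 0) {
    if (root %in% frontier) return(d)
    seen <- c(seen, frontier)
    frontier <- setdiff(edges$parent[edges$child %in% frontier], seen)
    d <- d + 1
  }
  NA_integer_
}

# AUC by exhaustive positive-negative pair counting (ties count 1/2)
pair_count_auc <- function(y, s) {
  pos <- s[y == 1]
  neg <- s[y == 0]
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}

# evaluate a masked model sample-by-sample, edge-by-edge, from its explicit
# edge list only (no matrix algebra): oracle for masked_forward
edgewise_forward <- function(model, x) {
  h <- x
  for (l in seq_along(model$layers)) {
    ly <- model$layers[[l]]
    out <- numeric(ncol(ly$M))
    for (j in seq_len(ncol(ly$M))) {
      acc <- ly$b[j]
      for (i in seq_len(nrow(ly$M))) {
        if (ly$M[i, j] == 1) acc <- acc + ly$W[i, j] * h[i]
      }
      out[j] <- if (model$activation == "tanh") tanh(acc) else acc
    }
    h <- out
  }
  h
}

# numerical gradient of a scalar function by central differences
num_grad <- function(f, x, h = 1e-5) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

# small random masked model for property tests; every unit keeps >= 1
# incoming mask edge so no layer is dead
random_small_model <- function(seed, max_width = 6, n_hidden = NULL) {
  set.seed(seed)
  if (is.null(n_hidden)) n_hidden <- sample(2:4, 1)
  widths <- c(sample(2:max_width, 1), sample(2:max_width, n_hidden, replace = TRUE))
  net <- build_dense_network(widths)
  for (l in seq_along(net$masks)) {
    m <- net$masks[[l]]
    keep <- matrix(runif(length(m)) < 0.6, nrow(m), ncol(m))
    for (j in seq_len(ncol(m))) {
      if (!any(keep[, j])) keep[sample(nrow(m), 1), j] <- TRUE
    }
    net$masks[[l]] <- m * keep
  }
  mdl <- pnet_model(net, seed = seed)
  # random nonzero weights on masked-in entries
  for (l in seq_along(mdl$layers)) {
    M <- mdl$layers[[l]]$M
    mdl$layers[[l]]$W <- matrix(rnorm(length(M), sd = 0.8), nrow(M)) * M
    mdl$layers[[l]]$b <- rnorm(ncol(M), sd = 0.3)
    mdl$heads[[l]]$v <- rnorm(ncol(M), sd = 0.8)
    mdl$heads[[l]]$c <- rnorm(1, sd = 0.3)
  }
  mdl
}

# compact simulated cohort used by several files
tiny_cohort <- function(seed = 1, n = 200, p1 = 0.6, p0 = 0.05,
                        widths = c(6, 2), genes_per_leaf = 4, n_drivers = 1) {
  generate_cohort(sim_config(layer_widths = widths,
                             genes_per_leaf_pathway = genes_per_leaf,
                             n_samples = n, n_drivers = n_drivers,
                             p1 = p1, p0 = p0, seed = seed))
}
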