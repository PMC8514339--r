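#' Training configuration
#'
#' Defaults follow the training protocol: Adam with learning rate 0.001
#' dropped by `lr_drop_factor` every `lr_drop_every` epochs, class-weighted
#' binary cross-entropy summed over per-layer heads, and a geometric ramp of
#' head loss weights (doubling per layer) so later, narrower layers weigh
#' more in the loss.
#'
#' @param epochs Number of passes over the training data (default 300).
#' @param batch_size Mini-batch size (default 10; small batches keep the
#'   Adam step count high enough for the sparse parameterization to
#'   converge on cohorts of a few hundred samples).
#' @param lr_init Initial learning rate (default 0.001).
#' @param lr_drop_every Epoch interval between learning-rate drops (50).
#' @param lr_drop_factor Multiplier applied at each drop, in (0,1) (0.75).
#' @param head_loss_weights Optional numeric vector, one per hidden layer,
#'   non-decreasing; `NULL` means `2^(0:(heads-1))`.
#' @param class_weight_mode `"balanced"` (w_c = N / (2 n_c)) or `"none"`.
#' @param l2 Optional L2 penalty on masked-in weights (default 0).
#' @param seed RNG seed used for initialization and batch shuffling.
#' @return List of class `pnet_config`.
#' @export
pnet_config <- function(epochs = 300, batch_size = 10, lr_init = 0.001,
                        lr_drop_every = 50, lr_drop_factor = 0.75,
                        head_loss_weights = NULL,
                        class_weight_mode = c("balanced", "none"),
                        l2 = 0, seed = 1) {
  class_weight_mode <- match.arg(class_weight_mode)
  stopifnot(epochs >= 0, batch_size >= 1, lr_init > 0,
            lr_drop_every >= 1, lr_drop_factor > 0, lr_drop_factor < 1,
            l2 >= 0)
  if (!is.null(head_loss_weights)) {
    stopifnot(all(head_loss_weights > 0),
              !is.unsorted(head_loss_weights))
  }
  structure(list(epochs = epochs, batch_size = batch_size, lr_init = lr_init,
                 lr_drop_every = lr_drop_every, lr_drop_factor = lr_drop_factor,
                 head_loss_weights = head_loss_weights,
                 class_weight_mode = class_weight_mode,
                 l2 = l2, seed = seed),
            class = "pnet_config")
}

#' Construct an untrained masked network model
#'
#' One masked linear layer per consecutive layer pair of the topology, tanh
#' hidden activations, and a 1-unit sigmoid prediction head after every
#' hidden layer. Weights are initialized Glorot-style uniform with the
#' fan-in taken from the mask (the effective, sparse fan-in), so units with
#' few biological inputs start with proportionally larger weights.
#'
#' @param net A `layered_network` (from [build_layered_network()] or
#'   [build_dense_network()]).
#' @param head_loss_weights Optional per-head loss weights (see
#'   [pnet_config()]).
#' @param activation Hidden activation, `"tanh"` (default) or `"identity"`
#'   (used by analytic attribution checks).
#' @param head_activation `"sigmoid"` (default) or `"identity"`; identity
#'   heads make the whole network linear for analytic oracles and cannot be
#'   trained.
#' @param seed RNG seed for initialization.
#' @return Object of class `pnet_model`.
#' @export
pnet_model <- function(net, head_loss_weights = NULL, activation = c("tanh", "identity"),
                       head_activation = c("sigmoid", "identity"), seed = 1) {
  activation <- match.arg(activation)
  head_activation <- match.arg(head_activation)
  validate_layered_network(net)
  set.seed(seed)
  L <- length(net$masks)
  layers <- vector("list", L)
  heads <- vector("list", L)
  for (l in seq_len(L)) {
    M <- unname(net$masks[[l]])
    fan_in <- pmax(colSums(M), 1)
    lim <- sqrt(6 / fan_in)                # mask-derived fan-in
    W <- matrix(stats::runif(length(M), -1, 1), nrow(M), ncol(M)) *
      matrix(lim, nrow(M), ncol(M), byrow = TRUE)
    layers[[l]] <- list(M = M, W = W * M, b = rep(0, ncol(M)))
    vlim <- sqrt(6 / ncol(M))
    heads[[l]] <- list(v = stats::runif(ncol(M), -vlim, vlim), c = 0)
  }
  if (is.null(head_loss_weights)) head_loss_weights <- 2^(0:(L - 1))
  stopifnot(length(head_loss_weights) == L, all(head_loss_weights > 0))
  structure(list(layers = layers, heads = heads,
                 head_loss_weights = head_loss_weights,
                 activation = activation,
                 head_activation = head_activation,
                 nodes = net$layers,
                 layer_names = names(net$layers),
                 display_names = net$display_names,
                 trained = FALSE),
            class = "pnet_model")
}

#' @exportS3Method base::print
print.pnet_model <- function(x, ...) {
  n <- vapply(x$nodes, length, integer(1))
  cat("masked network model:",
      paste(sprintf("%s(%d)", names(n), n), collapse = " -> "),
      "|", length(x$heads), "sigmoid heads\n")
  cat(if (isTRUE(x$trained)) "trained" else "untrained",
      "| activation:", x$activation, "\n")
  invisible(x)
}

act_fun <- function(z, activation) {
  if (activation == "tanh") tanh(z) else z
}
act_deriv_from_output <- function(h, activation) {
  if (activation == "tanh") 1 - h^2 else matrix(1, nrow(h), ncol(h))
}
sigmoid <- function(z) 1 / (1 + exp(-z))

#' Forward pass through one masked layer
#'
#' Computes `y = f((M * W)^T x + b)` where `*` is the Hadamard product, so
#' weights at masked-out positions can never influence the output.
#'
#' @param x Input vector (length `n_in`) or matrix (samples x `n_in`).
#' @param W Weight matrix `n_in x n_out`.
#' @param b Bias vector length `n_out`.
#' @param M Binary mask, same shape as `W`.
#' @param activation `"tanh"` (default) or `"identity"`.
#' @return Activation vector/matrix with `n_out` columns.
#' @export
masked_forward <- function(x, W, b, M, activation = "tanh") {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  if (ncol(x) != nrow(W) || !all(dim(W) == dim(M)) || length(b) != ncol(W)) {
    stop("shape mismatch in masked_forward")
  }
  z <- x %*% (M * W)
  z <- sweep(z, 2, b, "+")
  out <- act_fun(z, activation)
  if (nrow(out) == 1) drop(out) else out
}

#' Sigmoid prediction head
#' @param z Pre-activation value(s).
#' @return `1 / (1 + exp(-z))`.
#' @export
head_predict <- function(z) sigmoid(z)

#' Average per-head probabilities into the final network score
#' @param head_probs Vector of per-head probabilities for one sample, or a
#'   samples x heads matrix.
#' @return The arithmetic mean across heads (per sample).
#' @export
average_heads <- function(head_probs) {
  if (is.matrix(head_probs)) rowMeans(head_probs) else mean(head_probs)
}

# batch gradient of the head-weighted, class-weighted mean BCE w.r.t. all
# trainable tensors; masked entries get exactly zero gradient
bce_gradients <- function(model, Xb, yb, wb, lw, l2 = 0) {
  nb <- nrow(Xb)
  L <- length(model$layers)
  fw <- model_forward(model, Xb)
  grads <- list()
  dH_next <- NULL     # gradient flowing into H[[l+1]] from layer l+1
  for (l in L:1) {
    Hl <- fw$H[[l + 1]]
    dA <- lw[l] * wb * (fw$head_p[, l] - yb) / nb
    grads[[paste0("v", l)]] <- drop(crossprod(Hl, dA))
    grads[[paste0("c", l)]] <- sum(dA)
    dH <- tcrossprod(dA, model$heads[[l]]$v)
    if (!is.null(dH_next)) dH <- dH + dH_next
    dZ <- dH * act_deriv_from_output(Hl, model$activation)
    Wm <- model$layers[[l]]$M * model$layers[[l]]$W
    gW <- crossprod(fw$H[[l]], dZ) * model$layers[[l]]$M
    if (l2 > 0) gW <- gW + 2 * l2 * Wm
    grads[[paste0("W", l)]] <- gW
    grads[[paste0("b", l)]] <- colSums(dZ)
    dH_next <- dZ %*% t(Wm)
  }
  grads
}

# full forward pass; returns hidden activations, head pre-activations and
# probabilities, and the averaged score
model_forward <- function(model, X) {
  if (is.vector(X)) X <- matrix(X, nrow = 1)
  L <- length(model$layers)
  H <- vector("list", L + 1)
  Z <- vector("list", L)
  H[[1]] <- X
  head_z <- matrix(0, nrow(X), L)
  for (l in seq_len(L)) {
    ly <- model$layers[[l]]
    Z[[l]] <- sweep(H[[l]] %*% (ly$M * ly$W), 2, ly$b, "+")
    H[[l + 1]] <- act_fun(Z[[l]], model$activation)
    hd <- model$heads[[l]]
    head_z[, l] <- H[[l + 1]] %*% hd$v + hd$c
  }
  head_p <- if (identical(model$head_activation, "identity")) head_z else
    sigmoid(head_z)
  list(H = H, Z = Z, head_z = head_z, head_p = head_p,
       score = rowMeans(head_p))
}

#' Predict scores from a trained masked network
#'
#' @param object A `pnet_model`.
#' @param newdata A `profile_tensor` or a samples x features input matrix.
#' @param type `"score"` for the averaged outcome (default), `"heads"` for
#'   the per-head probability matrix, `"all"` for both.
#' @param ... Unused.
#' @return Numeric vector of scores in \[0, 1\], or matrix/list per `type`.
#' @export
predict.pnet_model <- function(object, newdata, type = c("score", "heads", "all"),
                               ...) {
  type <- match.arg(type)
  X <- if (inherits(newdata, "profile_tensor")) as_input_matrix(newdata) else
    as.matrix(newdata)
  fw <- model_forward(object, X)
  switch(type,
         score = stats::setNames(fw$score, rownames(X)),
         heads = fw$head_p,
         all = fw)
}

#' Balanced inverse-frequency class weights
#'
#' `w_c = N / (2 * n_c)`: the minority class receives proportionally more
#' weight so the loss is not dominated by the majority class.
#'
#' @param train_labels 0/1 vector.
#' @return Named numeric vector `c("0" = w0, "1" = w1)`.
#' @export
class_weights <- function(train_labels) {
  n0 <- sum(train_labels == 0)
  n1 <- sum(train_labels == 1)
  if (n0 == 0 || n1 == 0) stop("both classes must be present to weight them")
  N <- n0 + n1
  c("0" = N / (2 * n0), "1" = N / (2 * n1))
}

#' Class-weighted multi-head binary cross-entropy
#'
#' Per head h: `H_h = -(1/N) sum_i w_i [y_i log p_i + (1-y_i) log(1-p_i)]`
#' with probabilities clipped to `[eps, 1-eps]`; the total is
#' `sum_h head_loss_weights[h] * H_h`.
#'
#' @param y 0/1 labels (length N).
#' @param p Probability vector (one head) or N x heads matrix.
#' @param class_weights Named weights as from [class_weights()]; default
#'   unit weights.
#' @param head_loss_weights One positive weight per head; default 1.
#' @param eps Clipping constant (1e-7).
#' @return Scalar loss.
#' @export
weighted_bce <- function(y, p, class_weights = c("0" = 1, "1" = 1),
                         head_loss_weights = NULL, eps = 1e-7) {
  if (!is.matrix(p)) p <- matrix(p, ncol = 1)
  if (is.null(head_loss_weights)) head_loss_weights <- rep(1, ncol(p))
  stopifnot(length(head_loss_weights) == ncol(p), nrow(p) == length(y))
  p <- pmin(pmax(p, eps), 1 - eps)
  w <- ifelse(y == 1, class_weights[["1"]], class_weights[["0"]])
  per_head <- vapply(seq_len(ncol(p)), function(h) {
    -mean(w * (y * log(p[, h]) + (1 - y) * log(1 - p[, h])))
  }, numeric(1))
  sum(head_loss_weights * per_head)
}

#' Train a masked network with Adam
#'
#' Mini-batch Adam on the class-weighted multi-head cross-entropy. The
#' learning rate at epoch e is `lr_init * lr_drop_factor^floor((e-1)/lr_drop_every)`.
#' Gradients are masked, so weights at masked-out positions never move.
#' When validation data are given, the weights from the epoch with the best
#' validation AUC are restored at the end.
#'
#' @param model An untrained (or previously trained) `pnet_model`.
#' @param x Input matrix (samples x features) or `profile_tensor`.
#' @param y 0/1 labels.
#' @param config A `pnet_config`.
#' @param x_val,y_val Optional validation data for best-epoch restoration.
#' @return The trained model, with a `history` data frame attached
#'   (`epoch`, `lr`, `loss`, `val_loss`, `val_auc`).
#' @export
train_pnet <- function(model, x, y, config = pnet_config(),
                       x_val = NULL, y_val = NULL) {
  X <- if (inherits(x, "profile_tensor")) as_input_matrix(x) else as.matrix(x)
  y <- as.integer(y)
  stopifnot(nrow(X) == length(y))
  if (identical(model$head_activation, "identity")) {
    stop("identity-head models are analysis-only and cannot be trained")
  }
  Xv <- if (!is.null(x_val)) {
    if (inherits(x_val, "profile_tensor")) as_input_matrix(x_val) else as.matrix(x_val)
  } else NULL

  L <- length(model$layers)
  lw <- if (!is.null(config$head_loss_weights)) config$head_loss_weights else
    model$head_loss_weights
  stopifnot(length(lw) == L)
  model$head_loss_weights <- lw
  cw <- if (config$class_weight_mode == "balanced") class_weights(y) else
    c("0" = 1, "1" = 1)
  wvec <- ifelse(y == 1, cw[["1"]], cw[["0"]])

  if (config$epochs == 0) {
    model$history <- data.frame(epoch = integer(0), lr = numeric(0),
                                loss = numeric(0), val_loss = numeric(0),
                                val_auc = numeric(0))
    return(model)
  }

  set.seed(config$seed)
  # Adam state, one slot per tensor (W, b per layer; v, c per head)
  zero_like <- function(p) lapply(p, function(q) q * 0)
  params <- list()
  for (l in seq_len(L)) {
    params[[paste0("W", l)]] <- model$layers[[l]]$W
    params[[paste0("b", l)]] <- model$layers[[l]]$b
    params[[paste0("v", l)]] <- model$heads[[l]]$v
    params[[paste0("c", l)]] <- model$heads[[l]]$c
  }
  m_state <- zero_like(params)
  v_state <- zero_like(params)
  beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-8
  tstep <- 0
  n <- nrow(X)

  hist_rows <- vector("list", config$epochs)
  best <- list(auc = -Inf, params = NULL, loss = Inf)

  sync_model <- function(model, params) {
    for (l in seq_len(L)) {
      model$layers[[l]]$W <- params[[paste0("W", l)]]
      model$layers[[l]]$b <- params[[paste0("b", l)]]
      model$heads[[l]]$v <- params[[paste0("v", l)]]
      model$heads[[l]]$c <- params[[paste0("c", l)]]
    }
    model
  }

  for (epoch in seq_len(config$epochs)) {
    lr <- config$lr_init *
      config$lr_drop_factor^floor((epoch - 1) / config$lr_drop_every)
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    for (idx in batches) {
      model <- sync_model(model, params)
      grads <- bce_gradients(model, X[idx, , drop = FALSE], y[idx],
                             wvec[idx], lw, l2 = config$l2)

      tstep <- tstep + 1
      for (nm in names(params)) {
        g <- grads[[nm]]
        m_state[[nm]] <- beta1 * m_state[[nm]] + (1 - beta1) * g
        v_state[[nm]] <- beta2 * v_state[[nm]] + (1 - beta2) * g^2
        mhat <- m_state[[nm]] / (1 - beta1^tstep)
        vhat <- v_state[[nm]] / (1 - beta2^tstep)
        params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + adam_eps)
      }
    }

    model <- sync_model(model, params)
    fw_all <- model_forward(model, X)
    loss <- weighted_bce(y, fw_all$head_p, cw, lw)
    if (!is.finite(loss)) {
      stop("training aborted: non-finite loss at epoch ", epoch,
           " (learning rate ", lr, "); inspect inputs or lower lr_init")
    }
    val_loss <- NA_real_; val_auc <- NA_real_
    if (!is.null(Xv)) {
      fw_val <- model_forward(model, Xv)
      val_loss <- weighted_bce(as.integer(y_val), fw_val$head_p, cw, lw)
      val_auc <- rank_auc(as.integer(y_val), fw_val$score)
      if (val_auc > best$auc ||
          (val_auc == best$auc && val_loss < best$loss)) {
        best <- list(auc = val_auc, params = params, loss = val_loss)
      }
    }
    hist_rows[[epoch]] <- data.frame(epoch = epoch, lr = lr, loss = loss,
                                     val_loss = val_loss, val_auc = val_auc)
  }

  if (!is.null(Xv) && !is.null(best$params)) {
    params <- best$params
    model <- sync_model(model, params)
  }
  model$trained <- TRUE
  model$class_weights <- cw
  model$history <- do.call(rbind, hist_rows)
  model
}

#' Build a fully connected layered topology
#'
#' All-ones masks over the given layer widths; useful for dense comparator
#' models. Node names are generated.
#'
#' @param widths Integer vector of layer sizes, input first.
#' @param layer_names Optional names, defaults to `input`, `h1`, `h2`, ...
#' @return A `layered_network` whose masks are all ones.
#' @export
build_dense_network <- function(widths, layer_names = NULL) {
  stopifnot(length(widths) >= 2, all(widths >= 1))
  if (is.null(layer_names)) {
    layer_names <- c("input", paste0("h", seq_len(length(widths) - 1)))
  }
  layers <- lapply(seq_along(widths), function(i) {
    sprintf("%s_%04d", layer_names[i], seq_len(widths[i]))
  })
  names(layers) <- layer_names
  masks <- lapply(seq_len(length(widths) - 1), function(l) {
    matrix(1, widths[l], widths[l + 1],
           dimnames = list(layers[[l]], layers[[l + 1]]))
  })
  structure(list(layers = layers, masks = masks,
                 display_names = stats::setNames(unlist(layers), unlist(layers))),
            class = "layered_network")
}

#' Dense topology with (approximately) the parameter count of a sparse one
#'
#' Keeps the input width and the number of hidden layers of `net` and
#' shrinks hidden widths by a common factor until the dense parameter count
#' (including heads) is as close as possible to, without exceeding by more
#' than one layer's rounding, the sparse count of `net`.
#'
#' @param net A `layered_network`.
#' @return A dense `layered_network` of matched size.
#' @export
build_dense_equivalent <- function(net) {
  n <- layer_sizes(net)
  target <- count_params(net, include_heads = TRUE)$sparse_total
  widths_for <- function(s) {
    c(n[1], pmax(1, round(n[-1] * s)))
  }
  pcount <- function(s) {
    w <- widths_for(s)
    sum(w[-1] * (w[-length(w)] + 1)) + sum(w[-1] + 1)
  }
  lo <- 1e-4; hi <- 1
  if (pcount(hi) <= target) {
    s <- hi
  } else {
    for (it in 1:60) {
      mid <- (lo + hi) / 2
      if (pcount(mid) > target) hi <- mid else lo <- mid
    }
    s <- lo
  }
  build_dense_network(unname(widths_for(s)))
}

#' Train an ensemble of models on balanced subsamples
#'
#' Each member is trained on all minority-class samples plus an
#' equally sized draw from the majority class; draws are disjoint across
#' members when the majority class is large enough. Prediction is the mean
#' of the members' averaged-head scores. This mirrors the external
#' validation protocol of training two balanced models and averaging.
#'
#' @param net A `layered_network` defining the architecture.
#' @param x Input matrix or `profile_tensor`.
#' @param y 0/1 labels.
#' @param config A `pnet_config`.
#' @param n_members Number of ensemble members (default 2).
#' @return Object of class `pnet_ensemble` (list of trained models plus the
#'   subsample indices used).
#' @export
train_balanced_ensemble <- function(net, x, y, config = pnet_config(),
                                    n_members = 2) {
  X <- if (inherits(x, "profile_tensor")) as_input_matrix(x) else as.matrix(x)
  y <- as.integer(y)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (min(n0, n1) < 2) stop("minority class must have at least 2 samples")
  minority <- if (n1 <= n0) 1L else 0L
  min_idx <- which(y == minority)
  maj_idx <- which(y != minority)
  set.seed(config$seed)
  maj_pool <- sample(maj_idx)
  need <- length(min_idx)
  members <- vector("list", n_members)
  draws <- vector("list", n_members)
  for (k in seq_len(n_members)) {
    if (length(maj_pool) >= need) {
      take <- maj_pool[seq_len(need)]
      maj_pool <- maj_pool[-seq_len(need)]
    } else {
      take <- sample(maj_idx, need, replace = length(maj_idx) < need)
    }
    idx <- sort(c(min_idx, take))
    draws[[k]] <- idx
    cfg_k <- config
    cfg_k$seed <- config$seed + k
    mdl <- pnet_model(net, head_loss_weights = config$head_loss_weights,
                      seed = cfg_k$seed)
    members[[k]] <- train_pnet(mdl, X[idx, , drop = FALSE], y[idx], cfg_k)
  }
  structure(list(members = members, draws = draws),
            class = "pnet_ensemble")
}

#' @export
predict.pnet_ensemble <- function(object, newdata, ...) {
  scores <- vapply(object$members, function(m) predict(m, newdata),
                   numeric(if (inherits(newdata, "profile_tensor"))
                     dim(newdata)[1] else nrow(as.matrix(newdata))))
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  rowMeans(scores)
}
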