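#' Parse a child-parent pathway relation table
#'
#' Reads a headerless two-column tab-separated file (or data frame) of
#' directed child -> parent pathway relations, in the dialect of Reactome's
#' `ReactomePathwaysRelation.txt`, and compiles it into a validated acyclic
#' hierarchy graph.
#'
#' @param source Path to a headerless two-column TSV, or a data frame whose
#'   first two columns are child and parent identifiers.
#' @param species_prefix Keep only relations where both endpoints start with
#'   this prefix (default `"R-HSA"`, human Reactome). Use `NULL` to keep all.
#' @return An object of class `pnet_hierarchy`: a list with `pathway_ids`
#'   (character), `edges` (data.frame with columns `child`, `parent`),
#'   `roots` (pathways that never appear as a child) and `display_names`
#'   (named character, filled by [read_pathway_names()] or left as ids).
#' @seealso [parse_gmt()], [build_layered_network()]
#' @export
parse_relations <- function(source, species_prefix = "R-HSA") {
  if (is.character(source)) {
    if (!file.exists(source)) stop("relations file not found: ", source)
    df <- utils::read.table(source, sep = "\t", header = FALSE,
                            colClasses = "character", quote = "",
                            comment.char = "", blank.lines.skip = FALSE)
  } else {
    df <- as.data.frame(source, stringsAsFactors = FALSE)
  }
  if (nrow(df) > 0) {
    if (ncol(df) < 2) stop("relations input must have two columns")
    child <- trimws(as.character(df[[1]]))
    parent <- trimws(as.character(df[[2]]))
    bad <- which(child == "" | parent == "" | is.na(child) | is.na(parent))
    if (length(bad) > 0) {
      stop("malformed relation row (empty identifier) at line ", bad[1])
    }
  } else {
    child <- character(0)
    parent <- character(0)
  }
  if (!is.null(species_prefix) && length(child) > 0) {
    keep <- startsWith(child, species_prefix) & startsWith(parent, species_prefix)
    child <- child[keep]
    parent <- parent[keep]
  }
  edges <- unique(data.frame(child = child, parent = parent,
                             stringsAsFactors = FALSE))
  ids <- sort(unique(c(edges$child, edges$parent)))
  if (nrow(edges) > 0) {
    # child -> parent arrows; an acyclic relation is required for layering
    g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                       vertices = data.frame(name = ids))
    if (!igraph::is_dag(g)) {
      cyc <- igraph::girth(g, circle = TRUE)$circle
      cyc_names <- if (length(cyc) > 0) igraph::V(g)$name[cyc] else
        find_cycle_nodes(edges)
      stop("cycle detected in pathway relations: ",
           paste(cyc_names, collapse = " -> "))
    }
  }
  roots <- setdiff(ids, edges$child)
  structure(list(
    pathway_ids = ids,
    edges = edges,
    roots = sort(roots),
    display_names = stats::setNames(ids, ids)
  ), class = "pnet_hierarchy")
}

# fallback cycle reporter for directed graphs (DFS)
find_cycle_nodes <- function(edges) {
  adj <- split(edges$parent, edges$child)
  state <- new.env(parent = emptyenv())
  path <- character(0)
  res <- NULL
  visit <- function(v) {
    if (!is.null(res)) return(invisible(NULL))
    st <- get0(v, envir = state, ifnotfound = 0L)
    if (st == 1L) {
      res <<- c(path[which(path == v)[1]:length(path)], v)
      return(invisible(NULL))
    }
    if (st == 2L) return(invisible(NULL))
    assign(v, 1L, envir = state)
    path <<- c(path, v)
    for (w in adj[[v]]) visit(w)
    path <<- path[-length(path)]
    assign(v, 2L, envir = state)
  }
  for (v in unique(edges$child)) visit(v)
  res
}

#' @exportS3Method base::print
print.pnet_hierarchy <- function(x, ...) {
  cat("pathway hierarchy:", length(x$pathway_ids), "pathways,",
      nrow(x$edges), "child->parent relations,",
      length(x$roots), "roots\n")
  invisible(x)
}

#' Read a pathway display-name table
#'
#' @param source Path to a two-column TSV (id, display name) or a data frame.
#' @return Named character vector mapping id to display name.
#' @export
read_pathway_names <- function(source) {
  if (is.character(source)) {
    df <- utils::read.table(source, sep = "\t", header = FALSE,
                            colClasses = "character", quote = "",
                            comment.char = "")
  } else {
    df <- as.data.frame(source, stringsAsFactors = FALSE)
  }
  stats::setNames(as.character(df[[2]]), as.character(df[[1]]))
}

#' Parse a GMT gene-set file
#'
#' One gene set per tab-separated line: set name, description, then one or
#' more gene symbols. Gene symbols are upper-cased and whitespace-stripped;
#' duplicates within a line are removed.
#'
#' @param source Path to a GMT file, or a character vector of GMT lines.
#' @return A named list of character vectors (class `pnet_genesets`).
#' @export
parse_gmt <- function(source) {
  lines <- if (length(source) == 1 && file.exists(source)) {
    readLines(source, warn = FALSE)
  } else {
    as.character(source)
  }
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop("GMT line ", i, " has fewer than 3 fields")
    }
    genes <- normalize_gene_symbols(fields[-(1:2)])
    genes <- unique(genes[nzchar(genes)])
    if (length(genes) == 0) stop("GMT line ", i, " has no gene symbols")
    sets[[fields[1]]] <- genes
  }
  structure(sets, class = "pnet_genesets")
}

normalize_gene_symbols <- function(x) toupper(trimws(x))

#' Compile hierarchy and gene sets into a layered masked network topology
#'
#' Stratifies pathways by their shortest child -> parent distance to any
#' root, keeps `n_pathway_layers` strata (most specific stratum adjacent to
#' the gene layer), and emits one binary mask per consecutive layer pair.
#' Pathways deeper than the retained strata are collapsed onto their
#' shallowest retained ancestor and their gene annotations propagate with
#' them. Relations that skip strata are re-routed through one-to-one "copy"
#' nodes so that every mask connects adjacent layers only. Each gene feeds
#' from exactly 3 feature nodes (mutation, amplification, deletion).
#'
#' @param graph A `pnet_hierarchy` from [parse_relations()].
#' @param genesets A `pnet_genesets` from [parse_gmt()]; set names must be
#'   pathway ids of `graph` (sets naming unknown pathways are ignored with a
#'   warning).
#' @param n_pathway_layers Number of pathway strata to retain (default 5).
#' @param gene_universe Optional gene symbols; the gene layer is restricted
#'   to `gene_universe` intersected with annotated genes.
#' @return A `layered_network`: list with `layers` (named list of ordered
#'   node-id vectors: `features`, `genes`, `pathway1` ... ), `masks` (list of
#'   0/1 matrices, `masks[[l]]` of dim `n_l x n_{l+1}` with dimnames), and
#'   `display_names`.
#' @export
build_layered_network <- function(graph, genesets, n_pathway_layers = 5,
                                  gene_universe = NULL) {
  stopifnot(inherits(graph, "pnet_hierarchy"), n_pathway_layers >= 1)
  membership <- genesets[names(genesets) %in% graph$pathway_ids]
  if (length(membership) < length(genesets)) {
    warning(length(genesets) - length(membership),
            " gene set(s) name pathways absent from the hierarchy; ignored")
  }

  # Depth = shortest child->parent distance to the layering origin. With a
  # single root that root is the origin (it is not a mask node); with
  # several roots an implicit origin sits above them all, so the top-level
  # pathways themselves occupy the last mask layer and feed the outcome.
  depth <- pathway_depths(graph)
  if (length(graph$roots) != 1) depth <- depth + 1L
  K <- n_pathway_layers

  # collapse pathways deeper than K onto their ancestor at depth K
  parent_of <- split(graph$edges$parent, graph$edges$child)
  representative <- function(p) {
    while (depth[[p]] > K) {
      pars <- parent_of[[p]]
      pars <- pars[order(depth[pars], pars)]   # shallowest, then lexicographic
      p <- pars[1]
    }
    p
  }
  reps <- vapply(names(depth), function(p) {
    if (depth[[p]] < 1) NA_character_ else representative(p)
  }, character(1))

  # propagated membership on retained pathways (depth 1..K)
  eff_membership <- list()
  for (pw in names(membership)) {
    if (!pw %in% names(depth)) {
      # pathway absent from the relation table: place it at the most
      # specific stratum so its genes still enter the network
      depth[pw] <- K
      reps[pw] <- pw
    }
    r <- reps[[pw]]
    if (is.na(r)) next   # annotation on the excluded origin root
    eff_membership[[r]] <- sort(unique(c(eff_membership[[r]], membership[[pw]])))
  }

  genes <- sort(unique(unlist(eff_membership)))
  if (!is.null(gene_universe)) {
    genes <- intersect(genes, normalize_gene_symbols(gene_universe))
  }
  if (length(genes) == 0) stop("empty gene layer: no gene overlaps any gene set")

  # overall layers: 1 features, 2 genes, 2+i = pathway stratum at depth K+1-i
  # (layer "pathway1", adjacent to genes, holds the deepest retained stratum)
  retained <- names(depth)[depth >= 1 & depth <= K]
  strata <- lapply(seq_len(K), function(i) sort(names(depth)[depth == K + 1 - i]))

  copy_name <- function(id, d) paste0(id, "..copy", d)
  pair_edges <- vector("list", K + 1)  # pair_edges[[j]] feeds mask j (layers j -> j+1)
  for (i in seq_along(pair_edges)) {
    pair_edges[[i]] <- list(from = character(0), to = character(0))
  }
  add_edge <- function(pair, from, to) {
    pair_edges[[pair]]$from <<- c(pair_edges[[pair]]$from, from)
    pair_edges[[pair]]$to <<- c(pair_edges[[pair]]$to, to)
  }
  copies <- lapply(seq_len(K), function(i) character(0))
  add_copy <- function(d, cn) {
    i <- K + 1 - d
    copies[[i]] <<- c(copies[[i]], cn)
  }

  # gene -> pathway connections; annotations held above the deepest stratum
  # are routed through one-to-one copy nodes so masks stay layer-adjacent
  for (pw in names(eff_membership)) {
    gs <- intersect(eff_membership[[pw]], genes)
    if (length(gs) == 0) next
    d <- depth[[pw]]
    if (d == K) {
      add_edge(2, gs, rep(pw, length(gs)))
    } else {
      prev <- NULL
      for (dd in K:(d + 1)) {
        cn <- copy_name(pw, dd)
        add_copy(dd, cn)
        if (dd == K) add_edge(2, gs, rep(cn, length(gs)))
        else add_edge(K + 2 - dd, prev, cn)     # from copy@(dd+1) in layer K+2-dd
        prev <- cn
      }
      add_edge(K + 2 - d, prev, pw)
    }
  }

  # pathway -> pathway edges among retained nodes; depth-skipping relations
  # are re-routed through copies of the parent
  dropped_backward <- 0L
  if (nrow(graph$edges) > 0) {
    for (r in seq_len(nrow(graph$edges))) {
      ch <- graph$edges$child[r]; pa <- graph$edges$parent[r]
      if (!(ch %in% retained) || !(pa %in% retained)) next
      dc <- depth[[ch]]; dp <- depth[[pa]]
      if (dp >= dc) { dropped_backward <- dropped_backward + 1L; next }
      if (dp == dc - 1) {
        add_edge(K + 3 - dc, ch, pa)
      } else {
        prev <- ch
        for (dd in (dc - 1):(dp + 1)) {
          cn <- copy_name(pa, dd)
          add_copy(dd, cn)
          add_edge(K + 2 - dd, prev, cn)
          prev <- cn
        }
        add_edge(K + 2 - dp, prev, pa)
      }
    }
  }
  if (dropped_backward > 0) {
    warning(dropped_backward, " relation(s) point to a parent at the same or ",
            "greater depth than the child and cannot be stratified; dropped")
  }

  layers <- c(
    list(features = as.vector(t(outer(genes, c("_mut", "_amp", "_del"), paste0)))),
    list(genes = genes),
    lapply(seq_len(K), function(i) sort(unique(c(strata[[i]], copies[[i]]))))
  )
  names(layers) <- c("features", "genes", paste0("pathway", seq_len(K)))

  masks <- vector("list", length(layers) - 1)
  m1 <- matrix(0, nrow = length(layers$features), ncol = length(genes),
               dimnames = list(layers$features, genes))
  for (j in seq_along(genes)) m1[(3 * j - 2):(3 * j), j] <- 1
  masks[[1]] <- m1
  for (l in 3:length(layers)) {
    from <- layers[[l - 1]]; to <- layers[[l]]
    m <- matrix(0, nrow = length(from), ncol = length(to),
                dimnames = list(from, to))
    pe <- pair_edges[[l - 1]]
    if (length(pe$from) > 0) {
      m[cbind(pe$from, pe$to)] <- 1
    }
    masks[[l - 1]] <- m
  }

  dn <- graph$display_names
  cp <- unlist(copies)
  if (length(cp) > 0) {
    base <- sub("\\.\\.copy[0-9]+$", "", cp)
    dn[cp] <- paste0(ifelse(base %in% names(dn), dn[base], base), " (copy)")
  }
  net <- structure(list(
    layers = layers,
    masks = masks,
    display_names = dn
  ), class = "layered_network")
  validate_layered_network(net)
  net
}

# shortest child->parent distance to any root (roots have depth 0)
pathway_depths <- function(graph) {
  ids <- graph$pathway_ids
  if (length(ids) == 0) return(stats::setNames(integer(0), character(0)))
  d <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  d[graph$roots] <- 0L
  children_of <- split(graph$edges$child, graph$edges$parent)
  frontier <- graph$roots
  depth <- 0L
  while (length(frontier) > 0) {
    depth <- depth + 1L
    nxt <- unique(unlist(children_of[frontier], use.names = FALSE))
    nxt <- nxt[!is.na(nxt)]
    nxt <- nxt[is.na(d[nxt])]
    d[nxt] <- depth
    frontier <- nxt
  }
  d
}

validate_layered_network <- function(net) {
  stopifnot(length(net$masks) == length(net$layers) - 1)
  for (l in seq_along(net$masks)) {
    m <- net$masks[[l]]
    stopifnot(nrow(m) == length(net$layers[[l]]),
              ncol(m) == length(net$layers[[l + 1]]),
              all(m %in% c(0, 1)))
  }
  invisible(net)
}

#' @exportS3Method base::print
print.layered_network <- function(x, ...) {
  n <- layer_sizes(x)
  cat("layered network:",
      paste(sprintf("%s(%d)", names(n), n), collapse = " -> "), "\n")
  pc <- count_params(x)
  cat("sparse parameters:", pc$sparse_total,
      "| dense equivalent:", pc$dense_total, "\n")
  invisible(x)
}

#' Layer sizes of a layered network
#' @param net A `layered_network`.
#' @return Named integer vector of node counts per layer.
#' @export
layer_sizes <- function(net) {
  vapply(net$layers, length, integer(1))
}

#' Count trainable parameters of the masked model and its dense counterpart
#'
#' Dense weights per layer follow `w_l = n_l * (n_{l-1} + 1)`; sparse weights
#' per layer are the number of mask ones plus `n_l` biases. When
#' `include_heads` is TRUE each hidden layer contributes an extra `n_l + 1`
#' parameters for its sigmoid prediction head (both totals).
#'
#' @param net A `layered_network` (or any list with `layers` and `masks`).
#' @param include_bias Count bias terms in the sparse totals (default TRUE).
#' @param include_heads Count per-layer prediction heads (default FALSE).
#' @return List of class `param_count`: `per_layer` data.frame, plus
#'   `sparse_total` and `dense_total`.
#' @export
count_params <- function(net, include_bias = TRUE, include_heads = FALSE) {
  n <- layer_sizes(net)
  per <- data.frame(layer = names(n)[-1],
                    sparse = NA_real_, dense = NA_real_)
  for (l in seq_along(net$masks)) {
    nl <- n[l + 1]
    per$dense[l] <- nl * (n[l] + 1)
    per$sparse[l] <- sum(net$masks[[l]]) + if (include_bias) nl else 0
    if (include_heads) {
      per$dense[l] <- per$dense[l] + nl + 1
      per$sparse[l] <- per$sparse[l] + nl + 1
    }
  }
  structure(list(per_layer = per,
                 sparse_total = sum(per$sparse),
                 dense_total = sum(per$dense)),
            class = "param_count")
}

#' @exportS3Method base::print
print.param_count <- function(x, ...) {
  print(x$per_layer, row.names = FALSE)
  cat("total sparse:", x$sparse_total, " total dense:", x$dense_total, "\n")
  invisible(x)
}

#' Node degrees (fan-in + fan-out) of every node in a layered network
#'
#' Feature nodes have fan-in 0 and the top pathway layer has fan-out 0;
#' prediction heads never count toward degree.
#'
#' @param net A `layered_network`.
#' @return data.frame with columns `node`, `layer`, `fan_in`, `fan_out`,
#'   `degree`, ordered as the network's layers.
#' @export
node_degrees <- function(net) {
  out <- list()
  L <- length(net$layers)
  for (l in seq_len(L)) {
    nodes <- net$layers[[l]]
    fan_in <- if (l == 1) rep(0, length(nodes)) else colSums(net$masks[[l - 1]])
    fan_out <- if (l == L) rep(0, length(nodes)) else rowSums(net$masks[[l]])
    out[[l]] <- data.frame(node = nodes, layer = names(net$layers)[l],
                           fan_in = as.numeric(fan_in),
                           fan_out = as.numeric(fan_out),
                           degree = as.numeric(fan_in) + as.numeric(fan_out),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Export a compiled network to plain-text files
#'
#' Writes `nodes.csv` (node_id, layer, display_name) and one sparse triplet
#' CSV per mask (`mask_<from>_<to>.csv`: row_node, col_node, value).
#'
#' @param net A `layered_network`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
export_network <- function(net, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  deg <- node_degrees(net)
  nodes <- data.frame(node_id = deg$node, layer = deg$layer,
                      display_name = display_name_of(net, deg$node))
  utils::write.csv(nodes, file.path(dir, "nodes.csv"), row.names = FALSE)
  for (l in seq_along(net$masks)) {
    m <- net$masks[[l]]
    idx <- which(m == 1, arr.ind = TRUE)
    trip <- data.frame(row_node = rownames(m)[idx[, 1]],
                       col_node = colnames(m)[idx[, 2]],
                       value = 1)
    trip <- trip[order(trip$row_node, trip$col_node), ]
    utils::write.csv(trip, file.path(dir, sprintf(
      "mask_%s_%s.csv", names(net$layers)[l], names(net$layers)[l + 1])),
      row.names = FALSE)
  }
  invisible(dir)
}

display_name_of <- function(net, ids) {
  dn <- net$display_names
  out <- ifelse(ids %in% names(dn), dn[ids], ids)
  unname(out)
}
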