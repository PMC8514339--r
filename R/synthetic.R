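#' Configuration for synthetic hierarchy and cohort generation
#'
#' The generator emulates the structure of the real study inputs: a rooted
#' pathway hierarchy with a configurable number of strata, disjoint gene
#' sets on the most specific pathways, and a cohort in which class-1
#' (metastatic-like) samples carry alterations in genes under designated
#' driver pathways at rate `p1` against a background rate `p0`. Alteration
#' channels are drawn from `channel_mix` (mutation, amplification,
#' deletion), so amplification and deletion are never both set for the same
#' gene and sample.
#'
#' @param layer_widths Pathway counts per stratum, ordered from the most
#'   specific (gene-adjacent, leaf) stratum proceeding root-ward (default
#'   `c(18, 6, 2)`: 18 leaf pathways up to 2 top-level processes under a
#'   single origin root).
#' @param children_per_parent Maximum branching factor (default 3).
#' @param genes_per_leaf_pathway Genes annotated to each leaf pathway (6).
#' @param n_samples Cohort size (default 1000, near the real cohort size).
#' @param n_drivers Number of driver (leaf) pathways (default 3).
#' @param p1 Alteration probability of driver-pathway genes in class-1
#'   samples (default 0.3).
#' @param p0 Background alteration probability (default 0.05).
#' @param channel_mix Probabilities of (mutation, amplification, deletion)
#'   given an alteration; must sum to 1 (default 0.5/0.3/0.2).
#' @param class_balance Fraction of class-1 samples (default 0.33, the
#'   metastatic fraction of the real cohort).
#' @param cross_edge_rate Probability of adding a second parent to a
#'   pathway (default 0: a tree).
#' @param seed RNG seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(layer_widths = c(18, 6, 2), children_per_parent = 3,
                       genes_per_leaf_pathway = 6, n_samples = 1000,
                       n_drivers = 3, p1 = 0.3, p0 = 0.05,
                       channel_mix = c(mut = 0.5, amp = 0.3, del = 0.2),
                       class_balance = 0.33, cross_edge_rate = 0,
                       seed = 1) {
  stopifnot(length(layer_widths) >= 1, all(layer_widths >= 1),
            children_per_parent >= 1, genes_per_leaf_pathway >= 1,
            n_samples >= 1, n_drivers >= 0,
            p0 >= 0, p1 >= p0, p1 <= 1,
            length(channel_mix) == 3, abs(sum(channel_mix) - 1) < 1e-8,
            class_balance > 0, class_balance < 1,
            cross_edge_rate >= 0, cross_edge_rate <= 1)
  for (i in seq_along(layer_widths)[-1]) {
    if (layer_widths[i - 1] > layer_widths[i] * children_per_parent) {
      stop("stratum ", i - 1, " is wider than children_per_parent allows ",
           "given stratum ", i)
    }
  }
  structure(as.list(environment()), class = "sim_config")
}

#' Generate a synthetic pathway hierarchy and gene sets
#'
#' Builds a rooted layered DAG: a single origin root `SP_ROOT`, then the
#' requested strata of pathways; each pathway's parent is assigned
#' round-robin in the stratum above (plus optional random cross-edges).
#' Leaf pathways receive disjoint gene sets `G00001 ...`.
#'
#' @param config A `sim_config`.
#' @return List with `graph` (a `pnet_hierarchy`), `genesets`
#'   (`pnet_genesets`) and `names` (display names).
#' @export
generate_hierarchy <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  W <- rev(config$layer_widths)   # build top-down; config is leaf-first
  L <- length(W)
  ids <- lapply(seq_len(L), function(l) sprintf("SP%d_%04d", l, seq_len(W[l])))
  child <- character(0); parent <- character(0)
  # stratum 1 hangs off the single origin root
  child <- c(child, ids[[1]])
  parent <- c(parent, rep("SP_ROOT", W[1]))
  for (l in seq_len(L)[-1]) {
    # round-robin keeps every parent under the branching cap
    pars <- rep_len(ids[[l - 1]], W[l])
    child <- c(child, ids[[l]])
    parent <- c(parent, pars)
    if (config$cross_edge_rate > 0) {
      extra <- which(stats::runif(W[l]) < config$cross_edge_rate)
      for (i in extra) {
        cand <- setdiff(ids[[l - 1]], pars[i])
        if (length(cand) > 0) {
          child <- c(child, ids[[l]][i])
          parent <- c(parent, sample(cand, 1))
        }
      }
    }
  }
  edges <- data.frame(child = child, parent = parent, stringsAsFactors = FALSE)
  graph <- parse_relations(edges, species_prefix = NULL)
  leaves <- ids[[L]]
  g_per <- config$genes_per_leaf_pathway
  genes <- sprintf("G%05d", seq_len(g_per * length(leaves)))
  sets <- lapply(seq_along(leaves), function(i) {
    genes[((i - 1) * g_per + 1):(i * g_per)]
  })
  names(sets) <- leaves
  display <- stats::setNames(
    c("synthetic origin", paste("synthetic pathway", unlist(ids))),
    c("SP_ROOT", unlist(ids)))
  graph$display_names <- display
  list(graph = graph, genesets = structure(sets, class = "pnet_genesets"),
       names = display)
}

#' Generate a synthetic cohort with planted driver pathways
#'
#' Class labels are assigned by `class_balance` (fixed counts, shuffled).
#' `n_drivers` leaf pathways are designated drivers; in class-1 samples
#' each driver gene is altered independently with probability `p1`, every
#' other (gene, sample) pair with `p0`. An altered pair receives exactly
#' one channel drawn from `channel_mix`.
#'
#' @param hierarchy Output of [generate_hierarchy()] (regenerated from
#'   `config` when omitted).
#' @param config A `sim_config`.
#' @return List of class `synthetic_cohort`: `graph`, `genesets`, `names`,
#'   `net` (compiled `layered_network`), `tensor` (`profile_tensor`),
#'   `labels` (named 0/1 vector), `truth` (driver pathway ids and gene
#'   symbols), `config`.
#' @export
generate_cohort <- function(config, hierarchy = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(hierarchy)) hierarchy <- generate_hierarchy(config)
  leaves <- names(hierarchy$genesets)
  if (config$n_drivers > length(leaves)) {
    stop("n_drivers exceeds the number of leaf pathways")
  }
  set.seed(config$seed + 1)
  n <- config$n_samples
  samples <- sprintf("S%05d", seq_len(n))
  n1 <- max(1, round(n * config$class_balance))
  y <- stats::setNames(sample(c(rep(1L, n1), rep(0L, n - n1))), samples)

  drivers <- sort(sample(leaves, config$n_drivers))
  driver_genes <- sort(unique(unlist(hierarchy$genesets[drivers])))

  net <- build_layered_network(hierarchy$graph, hierarchy$genesets,
                               n_pathway_layers = length(config$layer_widths))
  net$display_names <- hierarchy$names
  genes <- net$layers$genes
  G <- length(genes)
  prob <- matrix(config$p0, n, G, dimnames = list(samples, genes))
  if (length(driver_genes) > 0) {
    prob[y == 1, genes %in% driver_genes] <- config$p1
  }
  altered <- matrix(stats::rbinom(n * G, 1, prob), n, G) == 1
  channel <- matrix(0L, n, G)
  k <- sum(altered)
  if (k > 0) {
    channel[altered] <- sample.int(3, k, replace = TRUE,
                                   prob = config$channel_mix)
  }
  x <- array(0, dim = c(n, G, 3),
             dimnames = list(samples, genes, c("mut", "amp", "del")))
  x[, , "mut"] <- (channel == 1L) * 1
  x[, , "amp"] <- (channel == 2L) * 1
  x[, , "del"] <- (channel == 3L) * 1
  structure(list(graph = hierarchy$graph, genesets = hierarchy$genesets,
                 names = hierarchy$names, net = net,
                 tensor = structure(x, class = c("profile_tensor", "array")),
                 labels = y,
                 truth = list(driver_pathways = drivers,
                              driver_genes = driver_genes),
                 config = config),
            class = "synthetic_cohort")
}

#' @exportS3Method base::print
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic cohort:", length(x$labels), "samples (",
      sum(x$labels == 1), "class 1 /", sum(x$labels == 0), "class 0 ),",
      dim(x$tensor)[2], "genes,",
      length(x$truth$driver_pathways), "driver pathways\n")
  invisible(x)
}

#' Write a synthetic cohort as the flat-file fixture set
#'
#' Emits exactly the dialects the ingestion functions read: `relations.tsv`
#' (headerless child/parent), `pathway_names.tsv`, `genesets.gmt`,
#' `mutations.csv` and `cnv.csv` (genes x samples; CNV uses +2/-2 for the
#' amplification/deletion indicators), and `labels.csv`.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(cohort$graph$edges, file.path(dir, "relations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  nm <- cohort$names
  utils::write.table(data.frame(id = names(nm), name = unname(nm)),
                     file.path(dir, "pathway_names.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  gmt <- vapply(names(cohort$genesets), function(s) {
    paste(c(s, "synthetic gene set", cohort$genesets[[s]]), collapse = "\t")
  }, character(1))
  writeLines(gmt, file.path(dir, "genesets.gmt"))
  mut <- t(cohort$tensor[, , "mut"])
  utils::write.csv(mut, file.path(dir, "mutations.csv"))
  cnv <- t(cohort$tensor[, , "amp"] * 2 - cohort$tensor[, , "del"] * 2)
  utils::write.csv(cnv, file.path(dir, "cnv.csv"))
  utils::write.csv(data.frame(sample_id = names(cohort$labels),
                              response = unname(cohort$labels)),
                   file.path(dir, "labels.csv"), row.names = FALSE)
  invisible(dir)
}
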