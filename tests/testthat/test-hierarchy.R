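test_that("parse_relations handles empty input, dedup, filtering and depth", {
  g0 <- parse_relations(data.frame(child = character(0), parent = character(0)),
                        species_prefix = NULL)
  expect_length(g0$pathway_ids, 0)
  expect_identical(nrow(g0$edges), 0L)

  df <- data.frame(child = c("A", "B", "A"), parent = c("root", "A", "root"))
  g <- parse_relations(df, species_prefix = NULL)
  expect_identical(g$roots, "root")
  expect_identical(nrow(g$edges), 2L)  # duplicate (A, root) removed
  # child->parent BFS oracle: B is two hops from the root
  expect_identical(bfs_depth(g$edges, "B", "root"), 2)
  expect_identical(bfs_depth(g$edges, "A", "root"), 1)

  # species prefix keeps only matching identifiers
  mixed <- data.frame(child = c("R-HSA-2", "R-MMU-2"),
                      parent = c("R-HSA-1", "R-MMU-1"))
  gh <- parse_relations(mixed)
  expect_identical(gh$pathway_ids, c("R-HSA-1", "R-HSA-2"))
})

test_that("parse_relations rejects cycles and malformed rows", {
  expect_error(parse_relations(data.frame(child = c("A", "B"),
                                          parent = c("B", "A")),
                               species_prefix = NULL),
               "cycle")
  expect_error(parse_relations(data.frame(child = c("A", ""),
                                          parent = c("B", "C")),
                               species_prefix = NULL),
               "line 2")
})

test_that("parse_gmt implements set semantics per line", {
  sets <- parse_gmt(c("P1\tdesc\tTP53\tAR", "P2\td\tG1\tG1", "P3\td\tG1\tG2"))
  expect_setequal(sets$P1, c("TP53", "AR"))
  expect_identical(sets$P2, "G1")               # duplicates collapse
  expect_true("G1" %in% sets$P2 && "G1" %in% sets$P3)  # sets independent
  expect_error(parse_gmt("P1\tonly_desc"), "line 1")
  # symbols normalized to upper case
  expect_identical(parse_gmt("P\td\t tp53 ")$P, "TP53")
})

test_that("build_layered_network matches the hand-built chain example", {
  g <- parse_relations(data.frame(child = c("P1", "P2"),
                                  parent = c("root", "P1")),
                       species_prefix = NULL)
  gs <- parse_gmt("P2\td\tG1\tG2")
  net <- build_layered_network(g, gs, n_pathway_layers = 2)
  expect_identical(unname(layer_sizes(net)), c(6L, 2L, 1L, 1L))
  expect_identical(net$layers$genes, c("G1", "G2"))
  expect_identical(net$layers$pathway1, "P2")
  expect_identical(net$layers$pathway2, "P1")
  expect_true(all(net$masks[[2]] == 1))   # gene->P2 mask all ones, 2x1
  expect_identical(dim(net$masks[[2]]), c(2L, 1L))

  # feature->gene mask: exactly 3 features per gene, none shared
  expect_identical(unname(colSums(net$masks[[1]])), c(3, 3))
  expect_identical(unname(rowSums(net$masks[[1]])), rep(1, 6))

  # restriction to a gene universe
  net1 <- build_layered_network(g, gs, n_pathway_layers = 2,
                                gene_universe = "G1")
  expect_identical(net1$layers$genes, "G1")
  expect_length(net1$layers$features, 3)

  # membership naming only unknown pathways -> empty gene layer
  expect_error(
    suppressWarnings(build_layered_network(g, parse_gmt("NOPE\td\tG1"),
                                           n_pathway_layers = 2)),
    "empty gene layer")
})

test_that("pathways deeper than the retained strata collapse onto ancestors", {
  # root -> A -> B -> C, annotations on C only; with 2 pathway layers C
  # collapses into B and its genes connect through B
  g <- parse_relations(data.frame(child = c("A", "B", "C"),
                                  parent = c("root", "A", "B")),
                       species_prefix = NULL)
  gs <- parse_gmt("C\td\tG1\tG2\tG3")
  net <- build_layered_network(g, gs, n_pathway_layers = 2)
  expect_identical(net$layers$pathway1, "B")
  expect_identical(net$layers$pathway2, "A")
  expect_identical(unname(colSums(net$masks[[2]])), 3)  # all genes reach B
})

test_that("annotations above the deepest stratum route through copy nodes", {
  # A is a leaf pathway at depth 1 while the hierarchy is two strata deep:
  # its genes enter at the gene-adjacent layer via an identity copy of A
  # and flow one-to-one up to A itself
  g <- parse_relations(data.frame(child = c("A", "B", "C"),
                                  parent = c("root", "root", "B")),
                       species_prefix = NULL)
  gs <- parse_gmt(c("C\td\tG1\tG2", "A\td\tG3"))
  net <- build_layered_network(g, gs, n_pathway_layers = 2)
  expect_setequal(net$layers$pathway1, c("C", "A..copy2"))
  expect_setequal(net$layers$pathway2, c("A", "B"))
  # G3 feeds only the copy; the copy feeds only A, one-to-one
  expect_identical(unname(net$masks[[2]]["G3", c("A..copy2", "C")]), c(1, 0))
  expect_identical(unname(net$masks[[3]]["A..copy2", "A"]), 1)
  expect_identical(sum(net$masks[[3]]["A..copy2", ]), 1)
  # a parent at the same or greater depth than its child is dropped
  g2 <- parse_relations(data.frame(child = c("A", "B", "C", "C"),
                                   parent = c("root", "A", "root", "B")),
                        species_prefix = NULL)
  expect_warning(
    net2 <- build_layered_network(g2, parse_gmt("C\td\tG1"),
                                  n_pathway_layers = 2),
    "dropped")
  # the backward C -> B relation leaves B with no inputs at all
  expect_identical(sum(net2$masks[[2]][, "B"]), 0)
})

test_that("network compilation is deterministic and masks are stratified", {
  co <- tiny_cohort(seed = 7, n = 10)
  net_a <- build_layered_network(co$graph, co$genesets, n_pathway_layers = 2)
  net_b <- build_layered_network(co$graph, co$genesets, n_pathway_layers = 2)
  expect_identical(net_a, net_b)
  for (m in net_a$masks) expect_true(all(m %in% c(0, 1)))
  # every non-top pathway node keeps an outgoing connection
  L <- length(net_a$layers)
  for (l in seq(3, L - 1)) {
    expect_true(all(rowSums(net_a$masks[[l]]) >= 1),
                label = paste("fan-out at layer", l))
  }
})

test_that("gene membership is recoverable from the masks (oracle)", {
  for (seed in 1:5) {
    cfg <- sim_config(layer_widths = c(9, 3), genes_per_leaf_pathway = 3,
                      seed = seed)
    hier <- generate_hierarchy(cfg)
    # truncate to a single pathway layer: leaves collapse onto their parents
    net <- build_layered_network(hier$graph, hier$genesets,
                                 n_pathway_layers = 1)
    # oracle: propagated membership of a retained pathway is the union of
    # its (tree) descendants' gene sets, straight from the edge list
    kids <- split(hier$graph$edges$child, hier$graph$edges$parent)
    for (pw in net$layers$pathway1) {
      want <- sort(unique(unlist(hier$genesets[kids[[pw]]])))
      got <- rownames(net$masks[[2]])[net$masks[[2]][, pw] == 1]
      expect_identical(got, want, label = paste(pw, "seed", seed))
    }
  }
})

test_that("count_params follows the dense-weight formula and bounds", {
  # single layer: n = [3, 2] -> dense 2 * (3 + 1) = 8
  d1 <- build_dense_network(c(3, 2))
  expect_identical(count_params(d1, include_bias = FALSE)$dense_total, 8)
  # n = [6, 4, 2, 1]: 4x7 + 2x5 + 1x3 = 41
  d2 <- build_dense_network(c(6, 4, 2, 1))
  expect_identical(count_params(d2, include_bias = FALSE)$dense_total, 41)
  # sparse = mask ones + biases
  net <- build_dense_network(c(4, 3))
  net$masks[[1]][] <- 0
  net$masks[[1]][cbind(c(1, 2, 3, 4, 1, 2), c(1, 1, 2, 2, 3, 3))] <- 1
  expect_identical(count_params(net)$sparse_total, 6 + 3)

  # property: sparse <= dense always; equality iff masks all ones
  for (seed in 1:10) {
    mdl_net <- random_small_model(seed)
    fake <- list(layers = mdl_net$nodes,
                 masks = lapply(mdl_net$layers, `[[`, "M"))
    pc <- count_params(fake)
    expect_lte(pc$sparse_total, pc$dense_total)
    all_ones <- all(vapply(fake$masks, function(m) all(m == 1), logical(1)))
    expect_identical(pc$sparse_total == pc$dense_total, all_ones)
  }
  dense_pc <- count_params(d2)
  expect_identical(dense_pc$sparse_total, dense_pc$dense_total)
})

test_that("node degrees count mask fan-in plus fan-out, heads excluded", {
  g <- parse_relations(data.frame(child = c("P1", "P2"),
                                  parent = c("root", "P1")),
                       species_prefix = NULL)
  net <- build_layered_network(g, parse_gmt("P2\td\tG1\tG2"),
                               n_pathway_layers = 2)
  deg <- node_degrees(net)
  expect_identical(deg$degree[deg$node == "P2"], 3)   # 2 genes in, P1 out
  expect_identical(deg$degree[deg$node == "G1"], 4)   # 3 features in, 1 out
  expect_true(all(deg$fan_in[deg$layer == "features"] == 0))
  expect_identical(deg$fan_out[deg$node == "P1"], 0)

  # isolated node: all-zero mask row/col
  dn <- build_dense_network(c(2, 2))
  dn$masks[[1]][, 1] <- 0
  dn$masks[[1]][1, ] <- 0
  dg <- node_degrees(dn)
  expect_identical(dg$degree[dg$node == "h1_0001"], 0)
})

test_that("export_network writes node and sparse-mask tables", {
  net <- build_layered_network(
    parse_relations(data.frame(child = "P1", parent = "root"),
                    species_prefix = NULL),
    parse_gmt("P1\td\tG1\tG2"), n_pathway_layers = 1)
  dir <- withr::local_tempdir()
  export_network(net, dir)
  nodes <- read.csv(file.path(dir, "nodes.csv"))
  expect_setequal(nodes$node_id, unlist(net$layers))
  trip <- read.csv(file.path(dir, "mask_genes_pathway1.csv"))
  expect_equal(nrow(trip), sum(net$masks[[2]]))
  expect_true(all(trip$value == 1))
})
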