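core5 <- c("KLF4", "MITF", "NR3C1", "NR3C2", "SOX2")

test_that("regulatory edges follow target-set membership and collapse experiments", {
  lib <- make_library(list(`A E1 x` = c("B", "C", "G1"),
                           `A E2 x` = c("B", "G2"),
                           `B E1 x` = c("G3")),
                      background_size = 100L, tf_names = c("A", "A", "B"))
  net <- build_regulatory_network(c("A", "B"), lib)
  expect_equal(nrow(net$regulatory_edges), 1)  # only A -> B lands inside the node set
  e <- net$regulatory_edges
  expect_equal(e$regulator, "A")
  expect_equal(e$target, "B")
  expect_equal(e$n_experiments, 2L)            # two experiments collapsed
  expect_equal(net$node_stats$out_degree, c(1L, 0L))

  # TFs with no library sets give a node-only network
  bare <- build_regulatory_network(c("X", "Y"), lib)
  expect_equal(nrow(bare$regulatory_edges), 0)
  expect_equal(bare$node_stats$out_degree, c(0L, 0L))
})

test_that("SOX2 has maximal out-degree on the packaged synthetic core fixture", {
  lib <- read_gmt(extdata("core_tf_targets_synthetic.gmt"), "core_fixture",
                  background_size = 22000L, parse_tf_names = TRUE)
  net <- build_regulatory_network(core5, lib)
  st <- net$node_stats
  sox2 <- st$out_degree[st$tf == "SOX2"]
  expect_equal(sox2, 4L)
  expect_true(all(sox2 > st$out_degree[st$tf != "SOX2"]))
})

test_that("PPI overlay counts distinct partners per reference list (self-pair once)", {
  lib <- make_library(list(`SOX2 E x` = "MITF"), background_size = 100L,
                      tf_names = "SOX2")
  net <- build_regulatory_network(core5, lib)
  inter <- interaction_table(
    a = c("SOX2", "SOX2", "SOX2", "SOX2", "MITF"),
    b = c("ARID3B", "ARID3B", "SOX2", "CTCF", "SOX2"))
  refs <- list(selected = c("ARID3B", "SOX2", "MITF"),
               enriched = c("CTCF", "SOX2", "MITF"))
  net <- add_ppi_overlay(net, inter, refs)
  st <- net$node_stats
  sox2 <- st[st$tf == "SOX2", ]
  # distinct partners: ARID3B (dup collapsed), SOX2 (self), CTCF, MITF
  expect_equal(sox2$partners_selected, 3L)  # ARID3B, SOX2, MITF
  expect_equal(sox2$partners_enriched, 3L)  # CTCF, SOX2, MITF
  # idempotence for a fixed interaction table
  again <- add_ppi_overlay(net, inter, refs)
  expect_equal(again$node_stats, net$node_stats)
  expect_equal(again$ppi_edges, net$ppi_edges)
  # empty interaction table -> zero partner counts
  none <- add_ppi_overlay(build_regulatory_network(core5, lib),
                          interaction_table(character(0), character(0)), refs)
  expect_true(all(none$node_stats$partners_total == 0))
})

test_that("node stats always equal independent recomputation from the edges", {
  scen <- generate_scenario(scenario_parameters(
    universe_size = 2000L, n_tfs = 25L, n_planted = 4L,
    target_set_size = c(60L, 60L), selected_list_size = 100L,
    n_pathways = 5L, enrichment_strength = 5), seed = 13)
  net <- build_regulatory_network(scen$catalog$symbols, scen$tf_library)
  net <- add_ppi_overlay(net, scen$interactions,
                         list(all_tfs = scen$catalog$symbols))
  recount <- compute_node_stats(net)
  expect_equal(net$node_stats, recount)
  # direct counting oracle for one node
  u <- net$nodes[1]
  reg <- net$regulatory_edges
  expect_equal(recount$out_degree[recount$tf == u],
               length(unique(reg$target[reg$regulator == u])))
  ppi <- net$ppi_edges
  expect_equal(recount$partners_all_tfs[recount$tf == u],
               length(unique(c(ppi$b[ppi$a == u], ppi$a[ppi$b == u]))))
})

test_that("hub ranking is deterministic: partners, then out-degree, then name", {
  lib <- make_library(list(`B E x` = c("A", "C"), `A E x` = "B"),
                      background_size = 50L, tf_names = c("B", "A"))
  net <- build_regulatory_network(c("A", "B", "C"), lib)
  inter <- interaction_table(c("A", "B", "C"), c("B", "C", "A"))
  net <- add_ppi_overlay(net, inter, list(ref = c("A", "B", "C")))
  hubs <- rank_hubs(net)
  # all partner counts equal (cycle); B wins on out-degree 2, then A before C
  expect_equal(hubs$tf, c("B", "A", "C"))
  expect_equal(hubs$rank, 1:3)
  # single-node network ranks itself with zero score
  solo <- build_regulatory_network("A", lib)
  h1 <- rank_hubs(solo)
  expect_equal(h1$tf, "A")
  expect_equal(h1$partners_total, 0L)
})

test_that("SOX2 out-ranks every other core TF on the Table 4 fixture", {
  lib <- read_gmt(extdata("core_tf_targets_synthetic.gmt"), "core_fixture",
                  background_size = 22000L, parse_tf_names = TRUE)
  inter <- read_interactions(extdata("table4_core_tf_interactions.tsv"))
  l1 <- read_gene_list(extdata("table1_selected_tfs.txt"))$symbols
  l2 <- read_gene_list(extdata("table1_target_enriched_tfs.txt"))$symbols
  net <- build_regulatory_network(core5, lib)
  net <- add_ppi_overlay(net, inter, list(selected = l1, enriched = l2))
  st <- net$node_stats
  sox2 <- st[st$tf == "SOX2", ]
  expect_equal(sox2$partners_selected, 7L)
  expect_equal(sox2$partners_enriched, 21L)
  expect_true(all(sox2$partners_selected > st$partners_selected[st$tf != "SOX2"]))
  expect_true(all(sox2$partners_enriched > st$partners_enriched[st$tf != "SOX2"]))
  expect_equal(rank_hubs(net)$tf[1], "SOX2")
})

test_that("removing a node removes exactly its incident edges", {
  lib <- make_library(list(`A E x` = c("B", "C"), `B E x` = "C"),
                      background_size = 50L, tf_names = c("A", "B"))
  net <- build_regulatory_network(c("A", "B", "C"), lib)
  net <- add_ppi_overlay(net, interaction_table(c("A", "B"), c("B", "C")),
                         list(ref = c("A", "B", "C")))
  cut <- remove_node(net, "A")
  expect_false("A" %in% cut$nodes)
  expect_false(any(cut$regulatory_edges$regulator == "A" |
                   cut$regulatory_edges$target == "A"))
  expect_false(any(cut$ppi_edges$a == "A" | cut$ppi_edges$b == "A"))
  # stats of the non-adjacent relation B->C unchanged
  expect_equal(cut$node_stats$out_degree[cut$node_stats$tf == "B"],
               net$node_stats$out_degree[net$node_stats$tf == "B"])
})

test_that("network export writes edge TSV, GraphML and node stats", {
  lib <- make_library(list(`A E x` = "B"), background_size = 50L, tf_names = "A")
  net <- build_regulatory_network(c("A", "B"), lib)
  net <- add_ppi_overlay(net, interaction_table("A", "B"), list(ref = c("A", "B")))
  edge_path <- withr::local_tempfile(fileext = ".tsv")
  gml_path <- withr::local_tempfile(fileext = ".graphml")
  stats_path <- withr::local_tempfile(fileext = ".tsv")
  export_network(net, edge_path, gml_path, stats_path)
  edges <- read.delim(edge_path)
  expect_setequal(edges$type, c("regulatory", "ppi"))
  g <- igraph::read_graph(gml_path, format = "graphml")
  expect_equal(sort(igraph::V(g)$name), c("A", "B"))
  expect_equal(igraph::ecount(g), 2)
  expect_equal(read.delim(stats_path)$tf, c("A", "B"))
})
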