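test_that("select_tfs crosses a gene list with the catalog", {
  cat <- tf_catalog(c("SOX2", "KLF4", "POU5F1"), aliases = c(OCT4 = "POU5F1"))
  gl <- gene_list(c("Sox2", "G1", "OCT4", "G2"), "sel")
  expect_equal(suppressMessages(select_tfs(gl, cat)), c("POU5F1", "SOX2"))
  # disjoint -> empty; containment -> the full catalog
  expect_equal(suppressMessages(select_tfs(gene_list(c("G1", "G2"), "x"), cat)),
               character(0))
  expect_equal(suppressMessages(
    select_tfs(gene_list(c("SOX2", "KLF4", "POU5F1", "G9"), "y"), cat)),
    sort(cat$symbols))
})

test_that("tf_target_enrichment collapses experiments and thresholds list 2", {
  set.seed(5)
  universe <- sprintf("G%04d", 1:2000)
  query_genes <- universe[1:100]
  # planted TF: two experiments heavily overlapping the query; decoys random
  sets <- list(
    list(name = "TFP E1 x", description = "", members = c(universe[1:40], universe[500:519]), tf_symbol = "TFP"),
    list(name = "TFP E2 x", description = "", members = c(universe[1:25], universe[700:734]), tf_symbol = "TFP"),
    list(name = "TFD1 E1 x", description = "", members = sample(universe, 60), tf_symbol = "TFD1"),
    list(name = "TFD2 E1 x", description = "", members = sample(universe, 60), tf_symbol = "TFD2"))
  lib <- gene_set_library(sets, "chea-like", background_universe = universe)
  res <- suppressMessages(tf_target_enrichment(gene_list(query_genes, "q"), lib, 0.01))
  expect_equal(res$list2, "TFP")
  ev <- res$evidence
  expect_equal(nrow(ev), 3)                       # one row per TF
  expect_equal(ev$n_experiments[ev$tf == "TFP"], 2L)
  # collapsing keeps the minimum adjusted p over the TF's experiments
  full <- as.data.frame(res$table)
  expect_equal(ev$p_adj[ev$tf == "TFP"],
               min(full$p_adj[full$tf_symbol == "TFP"]))
  # a library without TF annotations is rejected with guidance
  plain <- make_library(list(S = universe[1:10]), background_size = 2000L)
  expect_error(suppressMessages(tf_target_enrichment(gene_list(query_genes, "q"), plain)),
               "parse_tf_names")
})

test_that("list 2 grows monotonically with the threshold", {
  scen <- generate_scenario(scenario_parameters(
    universe_size = 3000L, n_tfs = 20L, n_planted = 3L,
    target_set_size = c(80L, 80L), selected_list_size = 120L,
    n_pathways = 5L, enrichment_strength = 4), seed = 9)
  gl <- scen$selected
  alphas <- c(0.001, 0.01, 0.1, 0.5)
  lists <- lapply(alphas, function(a)
    suppressMessages(tf_target_enrichment(gl, scen$tf_library, a))$list2)
  for (i in seq_len(length(alphas) - 1))
    expect_true(all(lists[[i]] %in% lists[[i + 1]]))
})

test_that("core calling is the normalized intersection, commutative and idempotent", {
  l1 <- c("klf4", "MITF", "ZNF1")
  l2 <- c("KLF4", "mitf", "TP53")
  rep12 <- call_core_tfs(l1, l2)
  expect_equal(rep12$core, c("KLF4", "MITF"))
  expect_equal(call_core_tfs(l2, l1)$core, rep12$core)      # commutative
  expect_equal(call_core_tfs(l1, l1)$core, sort(rep12$list1))  # idempotent
  expect_lte(length(rep12$core), min(length(rep12$list1), length(rep12$list2)))
  expect_warning(call_core_tfs("A", "B"), "no overlap")
  expect_silent(validate_core_tfs <- validate_core_tf_report(rep12))
})

test_that("the Table 1 fixture lists intersect in exactly the five core TFs", {
  l1 <- read_gene_list(extdata("table1_selected_tfs.txt"))$symbols
  l2 <- read_gene_list(extdata("table1_target_enriched_tfs.txt"))$symbols
  rep <- call_core_tfs(l1, l2)
  expect_length(rep$list1, 53)
  expect_length(rep$list2, 66)
  expect_equal(rep$core, c("KLF4", "MITF", "NR3C1", "NR3C2", "SOX2"))
  validate_core_tf_report(rep)
})

test_that("shared_enrichments intersects per-TF pathway calls case-insensitively", {
  universe <- sprintf("G%04d", 1:3000)
  targA <- gene_list(universe[1:150], "A_targets")
  targB <- gene_list(universe[101:250], "B_targets")
  lib1 <- make_library(list(`Axon Guidance` = universe[100:160],
                            `other pw` = universe[2000:2100]),
                       library_id = "L1", background_universe = universe)
  lib2 <- make_library(list(`AXON GUIDANCE` = universe[95:155],
                            `B only pw` = universe[200:260]),
                       library_id = "L2", background_universe = universe)
  res <- suppressMessages(shared_enrichments(list(A = targA, B = targB, C = NULL),
                                             list(lib1, lib2), threshold = 0.01))
  expect_equal(res$tfs_excluded, "C")
  expect_equal(res$shared, "axon guidance")
  for (tf in res$tfs_considered)
    expect_true(all(res$shared %in% tolower(res$per_tf_enriched[[tf]]$set_name)))
  expect_error(suppressMessages(shared_enrichments(list(A = targA, C = NULL), list(lib1))),
               "at least two")
})

test_that("identical target lists share everything; disjoint signals share nothing", {
  universe <- sprintf("G%04d", 1:3000)
  targ <- gene_list(universe[1:120], "t")
  lib <- make_library(list(pw1 = universe[1:80], pw2 = universe[2500:2600]),
                      library_id = "L", background_universe = universe)
  same <- suppressMessages(shared_enrichments(list(A = targ, B = targ), list(lib)))
  expect_equal(sort(same$shared),
               sort(unique(tolower(same$per_tf_enriched$A$set_name))))

  # two TFs enriched for non-overlapping pathway blocks
  tA <- gene_list(universe[1:100], "tA"); tB <- gene_list(universe[1001:1100], "tB")
  lib2 <- make_library(list(pwA = universe[1:90], pwB = universe[1001:1090]),
                       library_id = "L2", background_universe = universe)
  disj <- suppressMessages(shared_enrichments(list(A = tA, B = tB), list(lib2)))
  expect_length(disj$shared, 0)
})

test_that("shared pathways shrink weakly as TFs are added", {
  scen <- generate_scenario(scenario_preset("strong"), seed = 21)
  core <- scen$ground_truth$planted_core_tfs
  targets <- lapply(core, function(tf) {
    members <- unique(unlist(lapply(scen$tf_library$sets, function(s)
      if (identical(s$tf_symbol, tf)) s$members else NULL)))
    gene_list(members, paste0(tf, "_targets"))
  })
  names(targets) <- core
  libs <- list(scen$pathway_library)
  prev <- NULL
  for (m in 2:length(core)) {
    res <- suppressMessages(shared_enrichments(targets[seq_len(m)], libs))
    if (!is.null(prev)) expect_true(all(res$shared %in% prev))
    prev <- res$shared
  }
})
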