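# Seeded synthetic scenario generator: gene universe, TF catalog, TF-target
# and pathway GMT libraries, selected-gene list with planted core-TF signal,
# and an interaction table with a planted hub. Symbols are G000001... /
# TF0001... so nothing collides with real gene semantics.

#' Parameters of a synthetic scenario
#'
#' Defaults describe a study-scale condition: a ~22,000-gene universe (the
#' rough protein-coding complement of a mammalian genome), a catalog of 60
#' TFs of which 5 are planted core TFs, ChIP-seq-style target sets of a few
#' hundred genes with 1-3 experiments per TF, and a 200-gene selected list
#' in which the planted TFs' targets are over-represented tenfold.
#'
#' `enrichment_strength` is the sampling-weight fold-change of planted-TF
#' target genes when the selected list is drawn; at strength 1 the list is
#' drawn uniformly from the universe (the null condition).
#'
#' @param universe_size total gene universe size.
#' @param n_tfs number of catalog TFs (planted + decoys).
#' @param n_planted number of planted core TFs (always placed in the
#'   selected list; the first one is the planted interaction hub).
#' @param n_experiments_per_tf inclusive integer range, experiments per TF.
#' @param target_set_size inclusive integer range of target-set sizes.
#' @param experiment_pool_factor each TF's experiments are drawn from a
#'   TF-specific target pool of `experiment_pool_factor * max(target_set_size)`
#'   genes, so replicate experiments overlap heavily (as ChIP-seq
#'   experiments for one TF do) rather than being independent draws.
#' @param n_pathways number of pathway sets (including planted ones).
#' @param pathway_size inclusive integer range of pathway sizes.
#' @param n_planted_pathways pathways constructed to overlap every planted
#'   TF's target list (ground truth for shared-pathway recovery).
#' @param planted_pathway_fraction fraction of a planted pathway drawn from
#'   planted-TF targets (round-robin across TFs).
#' @param selected_list_size size of the selected-gene list.
#' @param enrichment_strength sampling-weight fold for planted targets
#'   (>= 1; 1 = null).
#' @param ppi_density Erdos-Renyi edge probability among catalog TFs.
#' @param hub_connectivity probability that the planted hub interacts with
#'   any given other catalog TF.
#' @return named list of parameters.
#' @export
scenario_parameters <- function(universe_size = 22000L, n_tfs = 60L,
                                n_planted = 5L,
                                n_experiments_per_tf = c(1L, 3L),
                                target_set_size = c(200L, 400L),
                                experiment_pool_factor = 1.2,
                                n_pathways = 150L,
                                pathway_size = c(40L, 150L),
                                n_planted_pathways = 2L,
                                planted_pathway_fraction = 0.7,
                                selected_list_size = 200L,
                                enrichment_strength = 10,
                                ppi_density = 0.02,
                                hub_connectivity = 0.75) {
  p <- list(universe_size = as.integer(universe_size),
            n_tfs = as.integer(n_tfs), n_planted = as.integer(n_planted),
            n_experiments_per_tf = as.integer(n_experiments_per_tf),
            target_set_size = as.integer(target_set_size),
            experiment_pool_factor = experiment_pool_factor,
            n_pathways = as.integer(n_pathways),
            pathway_size = as.integer(pathway_size),
            n_planted_pathways = as.integer(n_planted_pathways),
            planted_pathway_fraction = planted_pathway_fraction,
            selected_list_size = as.integer(selected_list_size),
            enrichment_strength = enrichment_strength,
            ppi_density = ppi_density, hub_connectivity = hub_connectivity)
  if (p$n_planted > p$n_tfs) stop("n_planted exceeds n_tfs")
  if (p$n_tfs >= p$universe_size) stop("n_tfs must be below universe_size")
  if (p$selected_list_size > p$universe_size)
    stop("selected_list_size exceeds universe_size")
  if (max(p$target_set_size) >= p$universe_size)
    stop("target sets must be smaller than the universe")
  if (p$experiment_pool_factor < 1)
    stop("experiment_pool_factor must be >= 1")
  if (p$enrichment_strength < 1) stop("enrichment_strength must be >= 1")
  p
}

#' Preset scenario parameter sets
#'
#' * `"strong"` — the planted-recovery condition: 22,000-gene universe,
#'   60 TFs with 5 planted core TFs, 300-gene target sets, 200-gene selected
#'   list, enrichment strength 10, hub connectivity 0.75.
#' * `"null"` — the calibration condition: 2,000-gene universe, 50 decoy
#'   TFs (none planted), single 50-gene target set per TF, 100-gene selected
#'   list drawn uniformly (strength 1).
#'
#' @param name preset name.
#' @return parameter list as from [scenario_parameters()].
#' @export
scenario_preset <- function(name = c("strong", "null")) {
  name <- match.arg(name)
  switch(name,
    strong = scenario_parameters(universe_size = 22000L, n_tfs = 60L,
                                 n_planted = 5L,
                                 n_experiments_per_tf = c(1L, 3L),
                                 target_set_size = c(300L, 300L),
                                 n_pathways = 150L,
                                 pathway_size = c(40L, 150L),
                                 n_planted_pathways = 2L,
                                 selected_list_size = 200L,
                                 enrichment_strength = 10,
                                 ppi_density = 0.02,
                                 hub_connectivity = 0.75),
    null = scenario_parameters(universe_size = 2000L, n_tfs = 50L,
                               n_planted = 0L,
                               n_experiments_per_tf = c(1L, 1L),
                               target_set_size = c(50L, 50L),
                               n_pathways = 20L,
                               pathway_size = c(30L, 80L),
                               n_planted_pathways = 0L,
                               selected_list_size = 100L,
                               enrichment_strength = 1,
                               ppi_density = 0.02,
                               hub_connectivity = 0.75))
}

.sample_range <- function(range) {
  if (range[1] == range[2]) range[1] else sample(range[1]:range[2], 1L)
}

#' Generate a complete synthetic scenario
#'
#' Deterministic given `(parameters, seed)`; the sampling order is fixed
#' (universe, per-TF target sets, pathways, selected list, interactions) so
#' the same seed reproduces byte-identical artifacts. The selected list is
#' composed of (a) the planted core TFs themselves, (b) genes from the union
#' of the planted TFs' targets, each included at rate `enrichment_strength`
#' times the base rate `selected_list_size / universe_size`, and (c) uniform
#' background genes filling the remaining slots; at strength 1 the list
#' after (a) is a single uniform draw from the universe. Decoy TFs receive
#' target sets with no preferential overlap.
#' Interactions are Erdos-Renyi at `ppi_density` among catalog TFs except
#' the planted hub, which connects to each other TF with probability
#' `hub_connectivity`.
#'
#' @param parameters list from [scenario_parameters()]/[scenario_preset()].
#' @param seed integer RNG seed.
#' @param dir optional directory; when given, all five input artifacts plus
#'   a ground-truth JSON are written there in the formats the readers
#'   expect.
#' @return object of class `synthetic_scenario`: `parameters`, `seed`,
#'   `universe`, `catalog` ([tf_catalog()]), `tf_library`,
#'   `pathway_library` ([gene_set_library()]), `selected` ([gene_list()]),
#'   `interactions` (`interaction_table`), `ground_truth`, and `files`
#'   (paths, when written).
#' @export
generate_scenario <- function(parameters = scenario_parameters(), seed = 1L,
                              dir = NULL) {
  p <- parameters
  set.seed(as.integer(seed))
  tf_syms <- sprintf("TF%04d", seq_len(p$n_tfs))
  gene_syms <- sprintf("G%06d", seq_len(p$universe_size - p$n_tfs))
  universe <- c(tf_syms, gene_syms)
  planted <- tf_syms[seq_len(p$n_planted)]
  hub <- if (p$n_planted > 0) planted[1] else tf_syms[1]

  # per-TF experiment-level target sets (planted hub's first set regulates
  # the other planted TFs, giving the network stage known regulatory edges)
  sets <- list()
  target_union <- character(0)
  tf_targets <- vector("list", p$n_tfs); names(tf_targets) <- tf_syms
  for (tf in tf_syms) {
    n_exp <- .sample_range(p$n_experiments_per_tf)
    pool_size <- min(ceiling(p$experiment_pool_factor * max(p$target_set_size)),
                     p$universe_size - 1L)
    pool <- sample(universe[universe != tf], pool_size)
    if (tf == hub && p$n_planted > 1L)
      pool <- unique(c(setdiff(planted, tf), pool))
    for (e in seq_len(n_exp)) {
      size <- .sample_range(p$target_set_size)
      members <- sample(pool, min(size, length(pool)))
      if (tf == hub && e == 1L && p$n_planted > 1L) {
        others <- setdiff(planted, tf)
        members <- c(others, setdiff(members, others))[seq_len(size)]
      }
      sets[[length(sets) + 1L]] <- list(
        name = sprintf("%s E%d synthetic", tf, e),
        description = "synthetic ChIP-seq experiment",
        members = members, tf_symbol = tf)
      tf_targets[[tf]] <- union(tf_targets[[tf]], members)
    }
    if (tf %in% planted) target_union <- union(target_union, tf_targets[[tf]])
  }
  tf_library <- gene_set_library(sets, "synthetic_tf_targets",
                                 background_universe = universe)

  # pathway library: planted pathways overlap every planted TF's targets
  pw_sets <- list()
  planted_pw <- character(0)
  n_pw_planted <- if (p$n_planted > 0) p$n_planted_pathways else 0L
  for (j in seq_len(p$n_pathways)) {
    size <- .sample_range(p$pathway_size)
    if (j <= n_pw_planted) {
      n_target <- ceiling(size * p$planted_pathway_fraction)
      per_tf <- ceiling(n_target / p$n_planted)
      members <- character(0)
      for (tf in planted)
        members <- union(members, sample(tf_targets[[tf]],
                                         min(per_tf, length(tf_targets[[tf]]))))
      fill <- sample(setdiff(universe, members), max(0L, size - length(members)))
      members <- c(members, fill)
      name <- sprintf("PW%04d synthetic pathway", j)
      planted_pw <- c(planted_pw, name)
    } else {
      members <- sample(universe, size)
      name <- sprintf("PW%04d synthetic pathway", j)
    }
    pw_sets[[j]] <- list(name = name, description = "synthetic pathway",
                         members = members, tf_symbol = NULL)
  }
  pathway_library <- gene_set_library(pw_sets, "synthetic_pathways",
                                      background_universe = universe)

  # selected list: planted TFs forced in; at strength 1 the remainder is a
  # uniform draw from the universe; above 1, each planted-target gene enters
  # at rate strength * (S/U) and the rest is uniform background from
  # non-target genes
  rest <- setdiff(universe, planted)
  n_pick <- p$selected_list_size - length(planted)
  if (p$enrichment_strength == 1 || length(target_union) == 0L) {
    picks <- sample(rest, n_pick)
  } else {
    base_rate <- p$selected_list_size / p$universe_size
    union_rest <- intersect(rest, target_union)
    inc <- union_rest[stats::runif(length(union_rest)) <
                        min(1, p$enrichment_strength * base_rate)]
    if (length(inc) > n_pick) inc <- inc[seq_len(n_pick)]
    fill <- sample(setdiff(rest, union_rest), n_pick - length(inc))
    picks <- c(inc, fill)
  }
  selected <- gene_list(c(planted, picks), label = "synthetic_selected")

  # interactions: ER among TFs, hub preferentially connected
  pairs <- utils::combn(tf_syms, 2L)
  is_hub_pair <- pairs[1, ] == hub | pairs[2, ] == hub
  prob <- ifelse(is_hub_pair, p$hub_connectivity, p$ppi_density)
  keep <- stats::runif(ncol(pairs)) < prob
  interactions <- interaction_table(pairs[1, keep], pairs[2, keep],
                                    rep("synthetic", sum(keep)))

  ground_truth <- list(planted_core_tfs = planted, planted_hub = hub,
                       planted_pathways = planted_pw,
                       planted_target_union_size = length(target_union))
  scen <- structure(list(parameters = p, seed = as.integer(seed),
                         universe = universe,
                         catalog = tf_catalog(tf_syms),
                         tf_library = tf_library,
                         pathway_library = pathway_library,
                         selected = selected, interactions = interactions,
                         ground_truth = ground_truth, files = NULL),
                    class = "synthetic_scenario")
  if (!is.null(dir)) scen$files <- write_scenario(scen, dir)
  scen
}

#' Write a synthetic scenario's artifacts to disk
#'
#' Emits exactly the formats the readers expect: `selected_genes.txt`,
#' `tf_catalog.txt`, `universe.txt` (gene lists), `tf_targets.gmt`,
#' `pathways.gmt`, `interactions.tsv`, and `ground_truth.json`.
#'
#' @param scenario a `synthetic_scenario`.
#' @param dir output directory (created if needed).
#' @return named character vector of file paths, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(selected = file.path(dir, "selected_genes.txt"),
             catalog = file.path(dir, "tf_catalog.txt"),
             universe = file.path(dir, "universe.txt"),
             tf_targets = file.path(dir, "tf_targets.gmt"),
             pathways = file.path(dir, "pathways.gmt"),
             interactions = file.path(dir, "interactions.tsv"),
             ground_truth = file.path(dir, "ground_truth.json"))
  write_gene_list(scenario$selected, paths["selected"])
  writeLines(scenario$catalog$symbols, paths["catalog"])
  writeLines(scenario$universe, paths["universe"])
  write_gmt(scenario$tf_library, paths["tf_targets"])
  write_gmt(scenario$pathway_library, paths["pathways"])
  it <- as.data.frame(scenario$interactions)
  utils::write.table(
    data.frame(symbol_a = it$a, symbol_b = it$b, source = it$source),
    paths["interactions"], sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(scenario$ground_truth, paths["ground_truth"],
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cat(sprintf(
    "<synthetic_scenario> seed %d: universe %d, %d TFs (%d planted), %d selected genes\n",
    x$seed, x$parameters$universe_size, x$parameters$n_tfs,
    x$parameters$n_planted, length(x$selected$symbols)))
  invisible(x)
}
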