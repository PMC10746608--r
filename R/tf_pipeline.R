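# The four inference stages: list 1 (selected TFs), list 2 (target-enriched
# TFs), core calling by intersection, and shared-pathway profiling of the
# core TFs' target sets.

#' List 1: TFs present in the selected-gene list
#'
#' Crosses a selected-gene list (e.g. genes under selection in domesticated
#' mammals) with a TF catalog. When the catalog carries an alias map, query
#' symbols are alias-resolved before matching; by default no renaming
#' occurs.
#'
#' @param selected_genes a [gene_list()].
#' @param catalog a [tf_catalog()].
#' @return sorted character vector of TF symbols found in the list.
#' @export
select_tfs <- function(selected_genes, catalog) {
  stopifnot(inherits(selected_genes, "gene_list"), inherits(catalog, "tf_catalog"))
  if (length(selected_genes$symbols) == 0L) stop("empty selected-gene list")
  syms <- resolve_aliases(selected_genes$symbols, catalog)
  hits <- sort(unique(syms[syms %in% catalog$symbols]))
  message(sprintf("select_tfs: %d of %d selected genes are catalog TFs",
                  length(hits), length(selected_genes$symbols)))
  hits
}

#' List 2: TFs whose targets are over-represented in the selected list
#'
#' Runs [enrich()] over every experiment-level set of a TF-target library
#' (ChEA-style: several ChIP-seq experiments per TF), with BH adjustment
#' across all experiment-level records, then collapses to one record per TF.
#' The default collapse keeps the experiment with the minimal adjusted p
#' (ties: larger overlap `k`, then set name); `collapse = "bonferroni"`
#' additionally multiplies each TF's best adjusted p by its number of
#' experiments (capped at 1) before thresholding, a conservative
#' alternative. List 2 contains the TFs whose collapsed `p_adj` is strictly
#' below `threshold`.
#'
#' @param selected_genes a [gene_list()].
#' @param tf_library a [gene_set_library()] whose sets carry `tf_symbol`
#'   (read with `parse_tf_names = TRUE`).
#' @param threshold adjusted-p cutoff, default 0.01.
#' @param collapse experiment-to-TF collapse rule.
#' @return list with elements `list2` (sorted TF symbols), `evidence`
#'   (data.frame, one row per TF in the library: `tf`, `best_set_name`, `k`,
#'   `K`, `n`, `N`, `odds_ratio`, `p_raw`, `p_adj`, `n_experiments`), and
#'   `table` (the full experiment-level `enrich_table`).
#' @export
tf_target_enrichment <- function(selected_genes, tf_library, threshold = 0.01,
                                 collapse = c("min_padj", "bonferroni")) {
  collapse <- match.arg(collapse)
  stopifnot(inherits(tf_library, "gene_set_library"))
  has_tf <- vapply(tf_library$sets, function(s) !is.null(s$tf_symbol), logical(1))
  if (!all(has_tf))
    stop("library sets lack tf_symbol annotations; re-read the GMT with parse_tf_names = TRUE")
  tab <- enrich(selected_genes, tf_library, threshold = threshold)
  df <- as.data.frame(tab)
  # collapse experiments per TF: best adjusted p, tie-break larger k, then name
  df <- df[order(df$p_adj, -df$k, df$set_name), , drop = FALSE]
  n_exp <- table(df$tf_symbol)
  best <- df[!duplicated(df$tf_symbol), , drop = FALSE]
  best$n_experiments <- as.integer(n_exp[best$tf_symbol])
  if (collapse == "bonferroni")
    best$p_adj <- pmin(1, best$p_adj * best$n_experiments)
  evidence <- data.frame(tf = best$tf_symbol, best_set_name = best$set_name,
                         k = best$k, K = best$K, n = best$n, N = best$N,
                         odds_ratio = best$odds_ratio, p_raw = best$p_raw,
                         p_adj = best$p_adj,
                         n_experiments = best$n_experiments,
                         stringsAsFactors = FALSE)
  evidence <- evidence[order(evidence$p_adj, -evidence$k, evidence$tf), , drop = FALSE]
  rownames(evidence) <- NULL
  list2 <- sort(evidence$tf[evidence$p_adj < threshold])
  message(sprintf(
    "tf_target_enrichment: %d set(s), %d TF(s); %d TF(s) below adjusted p < %g",
    nrow(df), nrow(evidence), length(list2), threshold))
  list(list2 = list2, evidence = evidence, table = tab)
}

#' Call core TFs as the intersection of the two evidence channels
#'
#' Core TFs are those both present in the selected-gene list (list 1) and
#' exhibiting significant target over-representation in it (list 2). The
#' intersection is taken on normalized symbols; dialect variants are never
#' merged automatically. An empty intersection raises a warning, not an
#' error.
#'
#' @param list1 character vector, TFs selected in the gene list.
#' @param list2 character vector, target-enriched TFs.
#' @param evidence optional per-TF evidence data.frame (see
#'   [tf_target_enrichment()]); rows gain an `in_selected_list` flag.
#' @param parameters named list of run parameters recorded verbatim.
#' @return object of class `core_tf_report` with elements `list1`, `list2`,
#'   `core`, `evidence`, `parameters`.
#' @export
call_core_tfs <- function(list1, list2, evidence = NULL, parameters = list()) {
  l1 <- sort(unique(normalize_symbols(list1)))
  l2 <- sort(unique(normalize_symbols(list2)))
  l1 <- l1[!is.na(l1)]; l2 <- l2[!is.na(l2)]
  core <- sort(intersect(l1, l2))
  if (length(core) == 0L)
    warning("no overlap between the two TF lists")
  if (!is.null(evidence)) {
    evidence$in_selected_list <- evidence$tf %in% l1
  } else if (length(l1) || length(l2)) {
    evidence <- data.frame(tf = sort(union(l1, l2)), stringsAsFactors = FALSE)
    evidence$in_selected_list <- evidence$tf %in% l1
    evidence$in_enriched_list <- evidence$tf %in% l2
  }
  structure(list(list1 = l1, list2 = l2, core = core,
                 evidence = evidence, parameters = parameters),
            class = "core_tf_report")
}

#' @export
print.core_tf_report <- function(x, ...) {
  cat(sprintf("<core_tf_report> list1: %d TFs, list2: %d TFs, core: %d TFs\n",
              length(x$list1), length(x$list2), length(x$core)))
  if (length(x$core)) cat("  core:", paste(x$core, collapse = ", "), "\n")
  invisible(x)
}

#' Check internal consistency of a core-TF report
#'
#' Verifies `core == intersect(list1, list2)` and `core` is contained in
#' both lists.
#'
#' @param report a `core_tf_report`.
#' @return `TRUE` invisibly, or an error.
#' @export
validate_core_tf_report <- function(report) {
  stopifnot(inherits(report, "core_tf_report"))
  expected <- sort(intersect(report$list1, report$list2))
  if (!identical(sort(report$core), expected))
    stop("core is not the intersection of list1 and list2")
  if (!all(report$core %in% report$list1) || !all(report$core %in% report$list2))
    stop("core must be contained in both lists")
  invisible(TRUE)
}

#' Shared pathway enrichments across core-TF target lists
#'
#' For each TF's target gene list, runs [enrich()] against every pathway
#' library and combines them with [combine_libraries()]; pathways with
#' `p_adj` strictly below `threshold` form that TF's enriched set. The
#' shared result is the intersection of enriched pathway names across all
#' TFs that have target data, matched case-insensitively on `set_name`
#' across libraries. TFs with no (or empty) target list are excluded from
#' the intersection and reported separately.
#'
#' @param tf_target_sets named list mapping TF symbol to a [gene_list()] of
#'   its known targets (entries may be `NULL` for TFs lacking data).
#' @param pathway_libraries list of [gene_set_library()] objects.
#' @param threshold adjusted-p cutoff, default 0.01.
#' @return object of class `shared_pathway_result`: list with
#'   `per_tf_enriched` (named list of data.frames with `library_id`,
#'   `set_name`, `p_adj`), `shared` (character vector of shared pathway
#'   names, lower-cased canonical form), `shared_detail` (rows of every
#'   TF's table matching a shared name), `tfs_considered`, `tfs_excluded`.
#' @export
shared_enrichments <- function(tf_target_sets, pathway_libraries,
                               threshold = 0.01) {
  stopifnot(is.list(tf_target_sets), length(names(tf_target_sets)) == length(tf_target_sets))
  usable <- vapply(tf_target_sets, function(g)
    !is.null(g) && inherits(g, "gene_list") && length(g$symbols) > 0, logical(1))
  excluded <- names(tf_target_sets)[!usable]
  considered <- names(tf_target_sets)[usable]
  if (length(considered) < 2L)
    stop("need at least two TFs with non-empty target sets (",
         length(considered), " usable)")
  if (length(excluded))
    message("shared_enrichments: no target data for ",
            paste(excluded, collapse = ", "), "; excluded from the intersection")
  per_tf <- lapply(considered, function(tf) {
    tabs <- lapply(pathway_libraries, function(lib)
      enrich(tf_target_sets[[tf]], lib, threshold = threshold))
    comb <- combine_libraries(tabs)
    df <- as.data.frame(comb)
    df <- df[df$p_adj < threshold, c("library_id", "set_name", "p_adj"), drop = FALSE]
    rownames(df) <- NULL
    df
  })
  names(per_tf) <- considered
  keys <- lapply(per_tf, function(df) unique(tolower(df$set_name)))
  shared <- sort(Reduce(intersect, keys))
  shared_detail <- do.call(rbind, lapply(considered, function(tf) {
    df <- per_tf[[tf]]
    df <- df[tolower(df$set_name) %in% shared, , drop = FALSE]
    if (nrow(df)) cbind(tf = tf, df, stringsAsFactors = FALSE) else NULL
  }))
  structure(list(per_tf_enriched = per_tf, shared = shared,
                 shared_detail = shared_detail,
                 tfs_considered = considered, tfs_excluded = excluded,
                 threshold = threshold),
            class = "shared_pathway_result")
}

#' @export
print.shared_pathway_result <- function(x, ...) {
  cat(sprintf("<shared_pathway_result> %d TF(s) considered, %d shared pathway(s)\n",
              length(x$tfs_considered), length(x$shared)))
  if (length(x$shared)) cat("  ", paste(x$shared, collapse = "; "), "\n")
  invisible(x)
}
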