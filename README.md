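# coreTF

Identify candidate **core transcription factors (TFs)** behind a
selection-signature gene list — such as the curated lists of genes under
selection in domesticated mammals — by requiring two independent lines of
evidence per TF:

* **List 1 — selected TFs**: the TF is itself a member of the
  selected-gene list (found by crossing the list with a TF census);
* **List 2 — target-enriched TFs**: the TF's experimentally demonstrated
  targets (ChIP-seq-derived gene-set libraries in GMT format) are
  over-represented in the selected-gene list.

The **core TFs** are the intersection: regulators that are both under
selection and upstream of a significant share of the other selected genes.
Around that call, the package provides per-TF pathway profiling with a
cross-TF shared-pathway intersection, a regulatory/protein-interaction
network stage with hub ranking, strict readers/writers for the standard
formats (gene lists, GMT, interaction TSV), and a fully seeded synthetic
data generator with planted signal for end-to-end verification.

## The statistic

Over-representation of a query list of effective size $n$ in a gene set of
size $K$, with overlap $k$, against a universe of $N$ genes (default
$N = 22{,}000$, the approximate protein-coding complement of a mammalian
genome) is the one-sided hypergeometric tail

$$p = P(X \ge k), \quad X \sim \mathrm{Hypergeom}(N, K, n),$$

equivalently a one-sided Fisher exact test on
$[[k,\,n-k],[K-k,\,N-K-n+k]]$. P-values are Benjamini–Hochberg adjusted
within each library across all of its sets; significance is adjusted
$p < 0.01$ (strict) by default. ChIP-seq libraries carrying several
experiments per TF are adjusted at the experiment level and then collapsed
to each TF's best adjusted p. Cross-library combination preserves each
library's own adjustment and re-ranks; nothing is re-adjusted across
libraries.

## Worked example

Precomputed-list mode intersects two published TF list transcriptions
shipped with the package:

```r
library(coreTF)
l1 <- read_gene_list(system.file("extdata", "table1_selected_tfs.txt", package = "coreTF"))$symbols
l2 <- read_gene_list(system.file("extdata", "table1_target_enriched_tfs.txt", package = "coreTF"))$symbols
call_core_tfs(l1, l2)
#> <core_tf_report> list1: 53 TFs, list2: 66 TFs, core: 5 TFs
#>   core: KLF4, MITF, NR3C1, NR3C2, SOX2
```

53 TFs sit in the selected-gene list, 66 TFs have target enrichment in it,
and exactly five TFs carry both marks — the core candidates.

The full pipeline on a seeded synthetic scenario with five planted core
TFs (universe 22,000; 60-TF catalog; 300-gene target sets; 200-gene
selected list; tenfold planted over-representation):

```r
scen <- generate_scenario(scenario_preset("strong"), seed = 7)
res <- run_stages(selected = scen$selected, catalog = scen$catalog,
                  tf_library = scen$tf_library,
                  pathway_libraries = list(scen$pathway_library),
                  interactions = scen$interactions)
res$report
#> <core_tf_report> list1: 5 TFs, list2: 5 TFs, core: 5 TFs
#>   core: TF0001, TF0002, TF0003, TF0004, TF0005
head(as.data.frame(res$evidence_table)[, c("set_name", "k", "K", "n", "N", "p_adj")], 3)
#>              set_name  k   K   n     N        p_adj
#> 1 TF0004 E1 synthetic 32 300 200 22000 7.157010e-23
#> 2 TF0003 E1 synthetic 30 300 200 22000 7.932421e-21
#> 3 TF0001 E2 synthetic 28 300 200 22000 7.426092e-19
head(res$hubs[, c("rank", "tf", "partners_total", "out_degree")], 3)
#>   rank     tf partners_total out_degree
#> 1    1 TF0001              4          4
#> 2    2 TF0003              2          0
#> 3    3 TF0005              2          0
```

All five planted TFs are recovered (overlaps of ~30 of their 300 targets
in the 200-gene list, against a null expectation of 2.7), and the planted
hub `TF0001` ranks first on interaction partners with its regulatory
out-degree as tie-break.

File-based runs use `run_pipeline(pipeline_config(...))` (or a YAML
config; see `?pipeline_config`), which persists the report (JSON + TSV),
enrichment tables, network exports (edge TSV, GraphML, node stats) and a
run log with input checksums and the stage-by-stage funnel counts. A thin
CLI wrapper with `run` / `core` / `simulate` subcommands is installed at
`system.file("scripts", "coretf.R", package = "coreTF")`.

## Scope notes

Adjusted p-values printed by web enrichment platforms depend on the exact
library versions behind them and are treated as provenance, not as
reproduction targets; precomputed-list mode exists precisely so published
tables can drive the downstream stages. Symbol normalization never
resolves dialect variants (OCT4 vs POU5F1) unless an explicit alias map
is supplied. See the methods vignette
(`vignettes/core-tf-discovery.Rmd`) for the model, parameter rationale,
generator design, and known limitations.
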