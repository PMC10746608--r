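---
title: "Core TF discovery: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Core TF discovery: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coreTF)
```

## The problem

Selection scans in domesticated mammals (dog, pig, cattle, fox, rabbit, and
others, each compared with wild conspecifics) yield long lists of candidate
genes — several hundred symbols — with no indication of which regulators
orchestrate them. `coreTF` implements a dual-evidence screen for "core"
transcription factors (TFs) behind such a list:

1. **List 1 — selected TFs.** TFs that are themselves members of the
   selected-gene list, found by crossing the list with a TF census.
2. **List 2 — target-enriched TFs.** TFs whose experimentally demonstrated
   targets (ChIP-seq-derived gene-set libraries, one set per experiment)
   are over-represented in the selected-gene list.
3. **Core TFs.** The intersection of the two lists: TFs that are both
   under selection and upstream of a significant share of the other
   selected genes — the signature expected of a regulator coupled to the
   phenotype rather than a passenger.

Two downstream stages characterize the core set: pathway profiling of each
core TF's known targets with a cross-TF intersection of enriched pathways,
and a network stage that assembles TF→TF regulatory edges from target-set
membership, overlays protein–protein interactions, and ranks hub
candidates by partner counts.

## The statistic

Over-representation is tested one-sided. For a query of effective size $n$
drawn from a universe of $N$ genes, and a gene set of size $K$ with overlap
$k$, the p-value is the hypergeometric upper tail

$$p = P(X \ge k), \qquad X \sim \mathrm{Hypergeom}(N, K, n),$$

identical to a one-sided Fisher exact test of the table
$[[k, n-k], [K-k, N-K-n+k]]$. Within each library, p-values are adjusted
across *all* sets (significant or not) by Benjamini–Hochberg step-up, and
significance means adjusted $p$ strictly below the threshold (default
0.01). Odds ratios use the cross-product, with the Haldane–Anscombe +0.5
correction on any zero cell; they are reported and used only as a
deterministic tie-break (sorting is by adjusted p ascending, odds ratio
descending, set name ascending).

Cross-library combination concatenates per-library tables and re-sorts;
adjusted p-values are **not** recomputed across libraries. Each library is
corrected on its own — mirroring a workflow in which four pathway
libraries are queried separately and the most significant enrichments are
then ranked together — so combined rankings compare values that were
adjusted in their own context.

## Parameters that matter

* **Background size $N$** (default 22,000): the assumed number of
  protein-coding genes in a mammalian genome. Public libraries rarely ship
  an explicit universe, so $N$ is taken as a size; when an explicit
  universe is supplied, members outside it are dropped with a warning
  (libraries routinely contain retired symbols) and the effective query
  size $n$ counts only query genes inside the universe. With only $N$
  known, $n$ is the full query size and a message notes the approximation.
* **Threshold** (default 0.01, strict `<`): applied to adjusted p-values,
  per library.
* **Experiment→TF collapse**: ChIP-seq libraries carry several experiment
  sets per TF. Adjustment happens at the experiment level first; each TF
  then keeps its minimum adjusted p (ties: larger overlap, then set name).
  This mirrors reading the best row of a per-TF query result. A
  conservative alternative (`collapse = "bonferroni"`, multiplying the
  best adjusted p by the TF's experiment count) is available but off by
  default.
* **Symbol handling**: trim, uppercase, strip internal whitespace — and
  nothing else. Historical dialect variants (OCT4/POU5F1, P300/EP300) are
  *not* merged unless an explicit alias map is supplied, because silent
  renaming would manufacture or destroy overlaps between published lists
  and a census. All fixture lists are kept verbatim.

## Numerical and degenerate-input choices

* `overlap_pvalue` delegates to the exact hypergeometric tail; tests hold
  it to within $10^{-12}$ relative error of an independent log-binomial
  pmf summation on an exhaustive grid of all $(K, n, k)$ for $N \le 50$
  (even $n$) plus randomized instances up to $N = 200$, with pmf mass
  conservation checked on the same grid.
* An empty overlap gives $p = 1$; a set identical to the query attains the
  minimal attainable p for its geometry, $1/\binom{N}{n}$.
* Empty queries and empty libraries are errors; an empty intersection of
  the two TF lists is a warning (an empty core is a legitimate negative
  finding).
* A threshold of 1 is accepted at the function level as a degenerate
  screen (every set with adjusted $p < 1$ passes); the file-based config
  requires a threshold in $(0, 1)$.
* Because the test is discrete and exact, its achieved size sits *below*
  the nominal level: at the calibration geometry used in the tests
  ($N = 2000$, $K = 50$, $n = 100$) the largest attainable tail value
  under 0.01 is $\approx 2.8 \times 10^{-3}$. Calibration tests therefore
  compare the empirical decoy rate against this enumerated exact size
  (and check it never exceeds nominal), not against 0.01 itself — a
  two-sided check centered on the nominal level would fail for any exact
  discrete test, which is a property of Fisher-style tests, not a defect
  of the pipeline.

## Shared-pathway intersection

Per-TF pathway profiles are computed on each TF's known target list (the
union of its experiment sets). A pathway counts as shared when its *name*
(case-insensitive) is enriched for every TF considered; names are matched
across libraries because published shared-pathway tables list pathway
names without library attribution. TFs with no target data are excluded
from the intersection and reported separately rather than imputed — in
the motivating study, one of five core TFs (NR3C2) lacked ChIP-seq data
and was handled exactly this way. The intersection shrinks weakly as TFs
are added; fewer than two usable TFs is an error.

## Network stage

Regulatory edges are directed regulator→target and exist when the target
TF appears in any of the regulator's experiment sets; parallel edges
collapse with the experiment count retained. PPI edges are undirected,
restricted to pairs touching the network nodes, and partner counts are per
distinct partner symbol (a self-interaction counts once). Hubs are ranked
by total partner count across the supplied reference lists (descending),
with regulatory out-degree and then name as tie-breaks — partner and
degree counts are always reported raw so users can re-rank on any single
column. Degree-type counts are the only centrality notion used; the
published comparison is an informal "most targets / most partners" one,
and anything fancier would overfit that claim.

## What the synthetic generator emulates

`generate_scenario()` builds a complete, seeded input bundle: universe
(`G000001…` plus `TF0001…` symbols, avoiding real-gene semantics), TF
catalog, ChIP-seq-style target library, pathway library, selected list,
and interaction table, with ground truth recorded. Key design points:

* **Planted signal.** Planted core TFs are placed in the selected list
  (they are "selected TFs") and the rest of the list includes each gene of
  the planted TFs' target union at `enrichment_strength` times the base
  rate $S/U$, topped up with uniform background. At strength 1 the list
  is one uniform draw — the exact null.
* **Correlated experiments.** A TF's experiments are sampled from a
  TF-specific target pool (1.2× the set size by default) rather than
  independently, reflecting how replicate ChIP-seq experiments for one TF
  overlap heavily; independent draws would dilute the per-experiment
  planted signal in a way real libraries do not.
* **Planted hub.** The first planted TF interacts with each other catalog
  TF with probability `hub_connectivity` (0.75), against an Erdős–Rényi
  background (0.02); its first experiment set contains the other planted
  TFs, planting known regulatory edges.
* **Presets.** `"strong"` (universe 22,000; 60 TFs, 5 planted; 300-gene
  sets; 200-gene list; strength 10) is the recovery condition;
  `"null"` (universe 2,000; 50 decoy TFs; 50-gene sets; 100-gene list;
  strength 1) is the calibration condition.

What it does **not** emulate: realistic ChEA set-size distributions
(beyond the configured ranges), overlapping biology between decoy TFs,
annotation noise, or any sequence-level signal. Passing recovery tests
therefore demonstrates that the pipeline's statistics and plumbing behave
as designed under a known signal model — not that real selection scans
will yield clean five-TF cores.

## Problem sizes used by the test suite

The suite runs the funnel fixture instantly; oracle equivalence on the
grid above; null calibration on 150–500 replicates of the null preset;
planted recovery on 100 replicates of the strong preset; and assorted
reduced scenarios (universes 1,500–3,000) for property checks. These sizes
were chosen so each property is measured with meaningful Monte-Carlo
resolution while the whole suite stays comfortably interactive.

## Known limitations

* Printed adjusted p-values from web-based enrichment platforms are not
  reproducible without the exact library versions behind them; the
  package treats such values as provenance, never as test targets, and
  ships precomputed-list mode so published table transcriptions can
  drive the downstream stages.
* The intersection logic treats a TF symbol as an identity; if two lists
  use different dialects for the same protein the overlap is missed
  unless an alias map says otherwise. This is deliberate (see above) but
  means results inherit the source lists' nomenclature hygiene.
* One published shared-pathway table prints seven rows while its text
  counts six; whether one row is a super-heading is not decidable from
  the source, so fixture-level documentation accepts either count rather
  than asserting one.
* A TF-target library cited under two successive release names is treated
  as a single library input.
* BH adjustment is applied within one library at a time by design;
  nothing corrects across libraries, so combined rankings are orderings,
  not jointly FDR-controlled calls.
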