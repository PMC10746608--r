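# Over-representation statistics: one-sided Fisher exact (hypergeometric
# upper tail), Haldane-Anscombe odds ratios, BH adjustment, per-library
# enrichment and cross-library combination.

.check_table_geometry <- function(k, K, n, N) {
  if (any(N <= 0)) stop("N must be positive")
  if (any(K < 0) || any(n < 0) || any(k < 0)) stop("negative counts")
  if (any(K > N) || any(n > N)) stop("K and n must not exceed N")
  if (any(k > pmin(K, n))) stop("k must not exceed min(K, n)")
}

#' One-sided over-representation p-value
#'
#' Probability of observing an overlap of at least `k` between a query of
#' size `n` and a set of size `K` drawn from a universe of `N` genes:
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`. Identical to the one-sided
#' (`greater`) Fisher exact p-value of the 2x2 table
#' `[[k, n-k], [K-k, N-K-n+k]]`. Vectorized over all four arguments.
#'
#' @param k overlap count(s).
#' @param K set size(s).
#' @param n query size(s).
#' @param N background universe size(s).
#' @return numeric vector of upper-tail probabilities in `[0, 1]`.
#' @examples
#' overlap_pvalue(3, 3, 3, 10)  # 1/choose(10,3)
#' @export
overlap_pvalue <- function(k, K, n, N) {
  .check_table_geometry(k, K, n, N)
  # P(X >= k) = P(X > k - 1)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  pmin(pmax(p, 0), 1)
}

#' Odds ratio of a 2x2 overlap table
#'
#' `(k * (N-K-n+k)) / ((K-k) * (n-k))`; when any cell is zero, 0.5 is added
#' to all four cells first (Haldane-Anscombe correction) so complete
#' containment yields a finite value. Used for reporting and deterministic
#' tie-breaking only.
#'
#' @inheritParams overlap_pvalue
#' @return numeric vector of non-negative odds ratios.
#' @export
overlap_odds_ratio <- function(k, K, n, N) {
  .check_table_geometry(k, K, n, N)
  a <- k; b <- n - k; c <- K - k; d <- N - K - n + k
  zero <- a == 0 | b == 0 | c == 0 | d == 0
  a[zero] <- a[zero] + 0.5; b[zero] <- b[zero] + 0.5
  c[zero] <- c[zero] + 0.5; d[zero] <- d[zero] + 0.5
  (a * d) / (b * c)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: sort ascending, `q_i = p_(i) * m / i`, enforce
#' monotonicity from the largest rank down, cap at 1, return in the original
#' input order. Thresholding the output at `alpha` selects exactly the BH
#' rejection set.
#'
#' @param p_values numeric vector of probabilities in `[0, 1]`.
#' @return adjusted p-values, same length and order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (anyNA(p_values) || any(p_values < 0) || any(p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

new_enrich_table <- function(df, query_label, threshold) {
  rownames(df) <- NULL
  structure(df, class = c("enrich_table", "data.frame"),
            query_label = query_label, threshold = threshold)
}

.sort_enrich <- function(df) {
  df[order(df$p_adj, -df$odds_ratio, df$set_name), , drop = FALSE]
}

#' @export
print.enrich_table <- function(x, ...) {
  cat(sprintf("<enrich_table> query '%s', %d record(s), threshold %g\n",
              attr(x, "query_label"), nrow(x), attr(x, "threshold")))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  invisible(x)
}

#' Over-representation analysis of a gene list against a library
#'
#' For every set in the library, counts the overlap `k` with the query,
#' computes the one-sided hypergeometric p-value against the library's
#' background, and adjusts across *all* sets of this library (significant or
#' not) with Benjamini-Hochberg. When the library carries an explicit
#' background universe, the effective query size `n` counts only query genes
#' inside that universe; otherwise `n` is the full query size (an
#' approximation noted once per call).
#'
#' Records are sorted by (`p_adj` ascending, `odds_ratio` descending,
#' `set_name` ascending), which makes every ranking deterministic. With
#' `filter = TRUE` only records with `p_adj` strictly below `threshold` are
#' kept; otherwise the full table is returned with the threshold recorded.
#'
#' @param query a [gene_list()].
#' @param library a [gene_set_library()].
#' @param threshold adjusted-p cutoff recorded on (and optionally applied
#'   to) the table; default 0.01.
#' @param filter keep only records with `p_adj < threshold`.
#' @return an `enrich_table`: data.frame with columns `library_id`,
#'   `set_name`, `tf_symbol` (NA unless the library is TF-annotated), `k`,
#'   `K`, `n`, `N`, `odds_ratio`, `p_raw`, `p_adj`, `overlap_members`.
#' @export
enrich <- function(query, library, threshold = 0.01, filter = FALSE) {
  stopifnot(inherits(query, "gene_list"), inherits(library, "gene_set_library"))
  if (length(query$symbols) == 0L) stop("empty query")
  if (length(library$sets) == 0L) stop("empty library")
  if (!(threshold > 0 && threshold <= 1)) stop("threshold must be in (0, 1]")
  q <- query$symbols
  if (!is.null(library$background_universe)) {
    q <- q[q %in% library$background_universe]
    if (length(q) == 0L)
      stop("no query gene lies in the library's background universe")
  } else {
    message(sprintf(
      "enrich: no explicit universe for '%s'; using n = %d (full query) against N = %d",
      library$library_id, length(q), library$background_size))
  }
  n <- length(q)
  N <- library$background_size
  recs <- lapply(library$sets, function(s) {
    ov <- intersect(q, s$members)
    list(k = length(ov), K = length(s$members), ov = ov,
         tf = if (is.null(s$tf_symbol)) NA_character_ else s$tf_symbol)
  })
  k <- vapply(recs, `[[`, integer(1), "k")
  K <- vapply(recs, `[[`, integer(1), "K")
  df <- data.frame(
    library_id = library$library_id,
    set_name = vapply(library$sets, `[[`, character(1), "name"),
    tf_symbol = vapply(recs, `[[`, character(1), "tf"),
    k = k, K = K, n = n, N = N,
    odds_ratio = overlap_odds_ratio(k, K, n, N),
    p_raw = overlap_pvalue(k, K, n, N),
    stringsAsFactors = FALSE
  )
  df$p_adj <- bh_adjust(df$p_raw)
  df$overlap_members <- vapply(recs, function(r) paste(r$ov, collapse = ";"),
                               character(1))
  df <- .sort_enrich(df)
  if (filter) df <- df[df$p_adj < threshold, , drop = FALSE]
  new_enrich_table(df, query_label = query$label, threshold = threshold)
}

#' Combine enrichment tables from several libraries
#'
#' Concatenates per-library tables for the *same* query, preserving each
#' record's library provenance and adjusted p-value (adjustment is never
#' recomputed across libraries; each library was corrected on its own), and
#' re-sorts by (`p_adj`, descending `odds_ratio`, `set_name`) so the most
#' significant enrichments across libraries rank first. Identical set names
#' from different libraries remain distinct records.
#'
#' @param tables list of `enrich_table` objects for one query.
#' @return a single combined `enrich_table`.
#' @export
combine_libraries <- function(tables) {
  stopifnot(length(tables) >= 1L,
            all(vapply(tables, inherits, logical(1), "enrich_table")))
  labels <- unique(vapply(tables, attr, character(1), "query_label"))
  if (length(labels) != 1L)
    stop("tables derive from different queries: ", paste(labels, collapse = ", "))
  thresholds <- vapply(tables, attr, numeric(1), "threshold")
  df <- do.call(rbind, lapply(tables, as.data.frame))
  df <- .sort_enrich(df)
  new_enrich_table(df, query_label = labels, threshold = max(thresholds))
}
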