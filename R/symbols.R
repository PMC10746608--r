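#' Normalize gene symbols
#'
#' Canonicalizes gene/TF symbols: trims surrounding whitespace, removes any
#' internal whitespace, and uppercases. No alias resolution is performed here;
#' dialect variants (e.g. `OCT4` vs `POU5F1`) are only merged when an explicit
#' alias map is supplied to the functions that accept one. Empty strings and
#' `NA` are returned as `NA`.
#'
#' Normalization is idempotent: `normalize_symbols(normalize_symbols(x))`
#' equals `normalize_symbols(x)`.
#'
#' @param x character vector of raw symbols.
#' @return character vector of the same length, normalized.
#' @examples
#' normalize_symbols(c(" Sox2", "nr3c1 ", "K LF4"))
#' @export
normalize_symbols <- function(x) {
  if (length(x) == 0L) return(character(0))
  x <- as.character(x)
  x <- gsub("[[:space:]]+", "", x)
  x <- toupper(x)
  x[!nzchar(x) | is.na(x)] <- NA_character_
  x
}

#' Construct a gene list
#'
#' A `gene_list` is an ordered, duplicate-free collection of normalized gene
#' symbols with a free-text label. Order of first appearance is preserved so
#' reports can mirror the source file.
#'
#' @param symbols character vector of raw symbols.
#' @param label free-text label for provenance.
#' @return an object of class `gene_list` with elements `label`, `symbols`,
#'   and `n_duplicates_removed`.
#' @export
gene_list <- function(symbols, label = "gene list") {
  syms <- normalize_symbols(symbols)
  syms <- syms[!is.na(syms)]
  n_before <- length(syms)
  syms <- unique(syms)
  structure(
    list(label = as.character(label)[1], symbols = syms,
         n_duplicates_removed = n_before - length(syms)),
    class = "gene_list"
  )
}

#' @export
print.gene_list <- function(x, ...) {
  cat(sprintf("<gene_list> '%s': %d symbols\n", x$label, length(x$symbols)))
  invisible(x)
}

#' @export
length.gene_list <- function(x) length(x$symbols)

#' Construct a TF catalog
#'
#' A census of transcription-factor symbols (a local stand-in for the human TF
#' catalog) with an optional alias map. Alias targets must be catalog members;
#' an alias may not shadow a canonical symbol of a different entry.
#'
#' @param symbols character vector of TF symbols.
#' @param aliases optional named character vector, `names` = alias,
#'   value = canonical symbol.
#' @return object of class `tf_catalog` with elements `symbols`, `aliases`.
#' @export
tf_catalog <- function(symbols, aliases = NULL) {
  syms <- unique(normalize_symbols(symbols))
  syms <- syms[!is.na(syms)]
  if (length(syms) == 0L) stop("TF catalog contains zero symbols")
  al <- character(0)
  if (!is.null(aliases) && length(aliases)) {
    al <- normalize_symbols(unname(aliases))
    names(al) <- normalize_symbols(names(aliases))
    keep <- !is.na(al) & !is.na(names(al))
    al <- al[keep]
    bad <- setdiff(al, syms)
    if (length(bad))
      stop("alias targets not in catalog: ", paste(bad, collapse = ", "))
    shadow <- names(al)[names(al) %in% syms & unname(al) != names(al)]
    if (length(shadow))
      stop("alias shadows a different canonical symbol: ",
           paste(shadow, collapse = ", "))
    al <- al[unname(al) != names(al)]
  }
  structure(list(symbols = syms, aliases = al), class = "tf_catalog")
}

#' @export
print.tf_catalog <- function(x, ...) {
  cat(sprintf("<tf_catalog> %d TFs, %d aliases\n",
              length(x$symbols), length(x$aliases)))
  invisible(x)
}

#' Resolve symbols through a catalog alias map
#'
#' Replaces any symbol that is a known alias by its canonical catalog symbol.
#' Symbols that are not aliases pass through unchanged. Used opt-in; by
#' default no renaming happens anywhere in the pipeline.
#'
#' @param symbols character vector (already normalized or not).
#' @param catalog a [tf_catalog()].
#' @return character vector of the same length.
#' @export
resolve_aliases <- function(symbols, catalog) {
  syms <- normalize_symbols(symbols)
  if (length(catalog$aliases) == 0L) return(syms)
  hit <- match(syms, names(catalog$aliases))
  syms[!is.na(hit)] <- unname(catalog$aliases[hit[!is.na(hit)]])
  syms
}
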