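# File readers/writers for every artifact the pipeline touches. All dialects
# are strict and documented; symbols are normalized on the way in, never
# silently renamed.

.header_tokens <- c("GENE", "GENES", "SYMBOL", "SYMBOLS", "GENE_SYMBOL",
                    "GENESYMBOL", "ID", "NAME", "TF", "TFS",
                    "SYMBOL_A", "SYMBOLA", "INTERACTOR_A", "GENE_A", "GENEA",
                    "PROTEIN_A", "OFFICIAL_SYMBOL_A")

.is_header <- function(first_field) {
  toupper(gsub("[[:space:]]+", "", first_field)) %in% .header_tokens
}

.read_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  readLines(path, warn = FALSE)
}

#' Read a gene list from plain text or single-column TSV
#'
#' One symbol per line (further tab-separated columns are ignored). Blank
#' lines and lines starting with `#` are skipped. A single header line is
#' skipped when its first token is a common column label (`gene`, `symbol`,
#' `id`, ...) rather than a gene symbol. Symbols are normalized
#' (trimmed, uppercased) and deduplicated; the number of duplicates removed
#' is reported via [message()] and stored on the result.
#'
#' @param path file path.
#' @param label free-text label; defaults to the file name.
#' @return a [gene_list()].
#' @export
read_gene_list <- function(path, label = basename(path)) {
  lines <- .read_lines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) && .is_header(strsplit(lines[1], "\t")[[1]][1]))
    lines <- lines[-1]
  syms <- vapply(strsplit(lines, "\t"), function(f) f[1], character(1))
  gl <- gene_list(syms, label = label)
  if (length(gl$symbols) == 0L)
    stop("zero symbols in '", path, "' after filtering")
  if (gl$n_duplicates_removed > 0)
    message(sprintf("read_gene_list: %d duplicate symbol(s) removed from '%s'",
                    gl$n_duplicates_removed, path))
  gl
}

#' Write a gene list as plain text
#'
#' @param x a [gene_list()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_list <- function(x, path) {
  writeLines(x$symbols, path)
  invisible(path)
}

#' Read a TF catalog (with optional alias map)
#'
#' The catalog file is a gene-list file of TF symbols. The optional alias
#' file is a two-column TSV `alias<TAB>canonical`; alias resolution is always
#' opt-in downstream.
#'
#' @param path catalog file path.
#' @param alias_path optional alias TSV path.
#' @return a [tf_catalog()].
#' @export
read_tf_catalog <- function(path, alias_path = NULL) {
  syms <- read_gene_list(path, label = "tf_catalog")$symbols
  aliases <- NULL
  if (!is.null(alias_path)) {
    lines <- .read_lines(alias_path)
    lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
    fields <- strsplit(lines, "\t")
    ok <- lengths(fields) >= 2L
    if (any(!ok))
      message(sprintf("read_tf_catalog: %d malformed alias row(s) skipped",
                      sum(!ok)))
    fields <- fields[ok]
    aliases <- vapply(fields, `[`, character(1), 2L)
    names(aliases) <- vapply(fields, `[`, character(1), 1L)
  }
  tf_catalog(syms, aliases)
}

#' Construct a gene-set library
#'
#' Container for a named collection of gene sets (GMT-style) together with
#' the assumed background universe: either just its size `N` (the default
#' 22000 mirrors the roughly 22,000 protein-coding genes of a mammalian
#' genome) or an explicit symbol universe.
#'
#' @param sets list of sets, each a list with `name`, `description`,
#'   `members`, optional `tf_symbol`.
#' @param library_id free-text identifier.
#' @param background_size positive integer `N`.
#' @param background_universe optional character vector; when supplied its
#'   cardinality defines `background_size` and set members outside it are
#'   dropped with a warning.
#' @return object of class `gene_set_library`.
#' @export
gene_set_library <- function(sets, library_id,
                             background_size = 22000L,
                             background_universe = NULL) {
  nm <- vapply(sets, function(s) s$name, character(1))
  dup <- nm[duplicated(nm)]
  if (length(dup))
    stop("duplicate set name(s): ", paste(unique(dup), collapse = ", "))
  if (!is.null(background_universe)) {
    background_universe <- unique(normalize_symbols(background_universe))
    background_universe <- background_universe[!is.na(background_universe)]
    background_size <- length(background_universe)
    dropped <- 0L
    sets <- lapply(sets, function(s) {
      keep <- s$members %in% background_universe
      dropped <<- dropped + sum(!keep)
      s$members <- s$members[keep]
      s
    })
    if (dropped > 0)
      warning(sprintf("%d set member(s) outside the supplied universe dropped",
                      dropped))
  }
  background_size <- as.integer(background_size)
  if (is.na(background_size) || background_size <= 0L)
    stop("background_size must be a positive integer")
  max_set <- if (length(sets)) max(vapply(sets, function(s) length(s$members), integer(1))) else 0L
  if (background_size < max_set)
    stop("background_size (", background_size,
         ") smaller than the largest set (", max_set, ")")
  names(sets) <- nm
  structure(list(library_id = as.character(library_id)[1], sets = sets,
                 background_size = background_size,
                 background_universe = background_universe),
            class = "gene_set_library")
}

#' @export
print.gene_set_library <- function(x, ...) {
  cat(sprintf("<gene_set_library> '%s': %d sets, background N = %d\n",
              x$library_id, length(x$sets), x$background_size))
  invisible(x)
}

#' Read a GMT gene-set library
#'
#' Enrichr/MSigDB dialect: tab-separated lines `name<TAB>description<TAB>`
#' `member1<TAB>member2...`; the description field is never a member;
#' trailing empty fields are tolerated. Duplicate members within a line are
#' deduplicated; duplicate set names across lines are an error (never a
#' silent overwrite).
#'
#' For ChIP-seq TF-target libraries whose set names embed experiment
#' metadata (`"SOX2 12345 ChIP-seq ESC Mouse"`), `parse_tf_names = TRUE`
#' annotates each set with `tf_symbol`, the uppercased first token of the
#' name, split on whitespace (default) or underscores.
#'
#' @param path GMT file path.
#' @param library_id identifier recorded on every result row.
#' @param background_size assumed universe size `N` (default 22000).
#' @param parse_tf_names annotate sets with a TF symbol parsed from the name.
#' @param tf_name_sep token separator for TF-name parsing.
#' @param background_universe optional explicit universe (see
#'   [gene_set_library()]).
#' @return a [gene_set_library()].
#' @export
read_gmt <- function(path, library_id = basename(path),
                     background_size = 22000L,
                     parse_tf_names = FALSE,
                     tf_name_sep = c("whitespace", "underscore"),
                     background_universe = NULL) {
  tf_name_sep <- match.arg(tf_name_sep)
  lines <- .read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop(sprintf("GMT line %d has %d field(s); need name, description, >=1 member",
                   i, length(f)))
    members <- normalize_symbols(f[-(1:2)])
    members <- unique(members[!is.na(members)])
    if (length(members) == 0L)
      stop(sprintf("GMT line %d has no non-empty members", i))
    tf <- NULL
    if (parse_tf_names) {
      splitter <- if (tf_name_sep == "whitespace") "[[:space:]]+" else "_"
      tf <- toupper(strsplit(trimws(f[1]), splitter)[[1]][1])
      if (!nzchar(tf)) stop(sprintf("GMT line %d: empty TF token in name", i))
    }
    list(name = f[1], description = f[2], members = members, tf_symbol = tf)
  })
  gene_set_library(sets, library_id, background_size, background_universe)
}

#' Write a gene-set library as GMT
#'
#' @param library a [gene_set_library()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(library, path) {
  lines <- vapply(library$sets, function(s) {
    paste(c(s$name, s$description, s$members), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a protein-interaction edge table
#'
#' TSV with at least two symbol columns (BioGRID-export-like); a third
#' column, when present, is kept as a source tag. Pairs are canonicalized to
#' unordered form (lexicographically sorted endpoints) so the result is
#' independent of row order and of within-row column order; duplicates are
#' collapsed with their multiplicity recorded. Self-pairs are permitted.
#' Rows with a missing symbol are skipped with a reported count.
#'
#' @param path TSV path.
#' @return object of class `interaction_table`: a data.frame with columns
#'   `a`, `b` (sorted so `a <= b`), `source`, `multiplicity`.
#' @export
read_interactions <- function(path) {
  lines <- .read_lines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) && .is_header(strsplit(lines[1], "\t")[[1]][1]))
    lines <- lines[-1]
  if (length(lines) == 0L) return(interaction_table(character(0), character(0)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  a <- normalize_symbols(vapply(fields, function(f) if (length(f) >= 1) f[1] else NA_character_, character(1)))
  b <- normalize_symbols(vapply(fields, function(f) if (length(f) >= 2) f[2] else NA_character_, character(1)))
  src <- vapply(fields, function(f) if (length(f) >= 3) f[3] else NA_character_, character(1))
  ok <- !is.na(a) & !is.na(b)
  if (any(!ok))
    message(sprintf("read_interactions: %d row(s) with missing symbols skipped",
                    sum(!ok)))
  interaction_table(a[ok], b[ok], src[ok])
}

#' Construct an interaction table from endpoint vectors
#'
#' @param a,b character vectors of endpoints (parallel).
#' @param source optional source tags (first tag kept per unique pair).
#' @return an `interaction_table` data.frame.
#' @export
interaction_table <- function(a, b, source = NULL) {
  a <- normalize_symbols(a); b <- normalize_symbols(b)
  if (length(a) != length(b)) stop("endpoint vectors differ in length")
  if (is.null(source)) source <- rep(NA_character_, length(a))
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  first <- !duplicated(key)
  tab <- data.frame(a = lo[first], b = hi[first],
                    source = as.character(source)[first],
                    multiplicity = as.integer(table(key)[key[first]]),
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$a, tab$b), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("interaction_table", "data.frame")
  tab
}

#' Write an enrichment table as TSV
#'
#' Deterministic column order `library_id, set_name, k, K, n, N, odds_ratio,
#' p_raw, p_adj, overlap_members` (members semicolon-joined); floats are
#' serialized at 10 significant digits. An empty table yields a header-only
#' file.
#'
#' @param table an `enrich_table` (see [enrich()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_enrichment_table <- function(table, path) {
  cols <- c("library_id", "set_name", "k", "K", "n", "N",
            "odds_ratio", "p_raw", "p_adj", "overlap_members")
  out <- as.data.frame(table)[, cols, drop = FALSE]
  for (col in c("odds_ratio", "p_raw", "p_adj"))
    out[[col]] <- sprintf("%.10g", out[[col]])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read back a TSV written by [write_enrichment_table()]
#'
#' @param path TSV path.
#' @param query_label,threshold metadata to restore on the object.
#' @return an `enrich_table`.
#' @export
read_enrichment_table <- function(path, query_label = NA_character_,
                                  threshold = 0.01) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(library_id = "character",
                                         set_name = "character",
                                         overlap_members = "character"))
  new_enrich_table(df, query_label = query_label, threshold = threshold)
}

#' Write a core-TF report as JSON (with TSV mirrors)
#'
#' JSON schema: `{parameters, list1[], list2[], core[], evidence[...]}`.
#' When `tsv_dir` is given, `list1.tsv`, `list2.tsv` and `evidence.tsv`
#' mirrors are written alongside.
#'
#' @param report a `core_tf_report` (see [call_core_tfs()]).
#' @param path JSON output path.
#' @param tsv_dir optional directory for TSV mirrors.
#' @return `path`, invisibly.
#' @export
write_core_tf_report <- function(report, path, tsv_dir = NULL) {
  payload <- list(parameters = report$parameters,
                  list1 = report$list1, list2 = report$list2,
                  core = report$core, evidence = report$evidence)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = 10,
                       dataframe = "rows", na = "null", pretty = TRUE)
  if (!is.null(tsv_dir)) {
    dir.create(tsv_dir, showWarnings = FALSE, recursive = TRUE)
    writeLines(report$list1, file.path(tsv_dir, "list1.tsv"))
    writeLines(report$list2, file.path(tsv_dir, "list2.tsv"))
    if (!is.null(report$evidence) && nrow(report$evidence))
      utils::write.table(report$evidence, file.path(tsv_dir, "evidence.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read back a JSON core-TF report
#'
#' @param path JSON path.
#' @return a `core_tf_report`.
#' @export
read_core_tf_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  call_core_tfs(x$list1, x$list2,
                evidence = if (is.data.frame(x$evidence)) x$evidence else NULL,
                parameters = x$parameters)
}
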