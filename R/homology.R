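outfmt6_cols <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                  "gapopen", "qstart", "qend", "sstart", "send",
                  "evalue", "bitscore")

#' Read a BLAST tabular (outfmt 6) homology hit table
#'
#' Parses the 12-column tab-separated layout
#' (`qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore`). Files are assumed to contain only the hits of the
#' final PSI-BLAST iteration; if a file concatenates iterations separated
#' by `# Iteration:` sentinel lines, set `split_iterations = TRUE` to keep
#' only the block after the last sentinel. Comment lines starting with `#`
#' are skipped; otherwise-malformed rows are dropped and counted, and more
#' than 10% malformed rows is an error.
#'
#' @param path Path to the hit table.
#' @param taxon Taxon (genus) label attached to every row.
#' @param split_iterations Keep only rows after the last `# Iteration:`
#'   sentinel; default `FALSE`.
#' @return A tibble with a `taxon` column followed by the 12 outfmt-6
#'   columns (numeric fields typed), with attributes `n_malformed` and
#'   `n_metaproteins` (distinct query proteins).
#' @export
read_hit_table <- function(path, taxon, split_iterations = FALSE) {
  stopifnot(is.character(taxon), nchar(taxon) > 0)
  lines <- readr::read_lines(path)
  if (split_iterations) {
    sent <- which(stringr::str_detect(lines, "^#\\s*Iteration:"))
    if (length(sent) > 0) lines <- lines[seq.int(max(sent) + 1L, length(lines))]
  }
  lines <- lines[!stringr::str_detect(lines, "^#") & lines != ""]
  if (length(lines) == 0) {
    out <- tibble(taxon = character())
    for (cn in outfmt6_cols) out[[cn]] <- character(0)
    out <- dplyr::mutate(out, dplyr::across(
      dplyr::all_of(c("pident", "evalue", "bitscore")), as.numeric))
    attr(out, "n_malformed") <- 0L
    attr(out, "n_metaproteins") <- 0L
    return(out)
  }
  fields <- stringr::str_split(lines, "\t")
  ok <- lengths(fields) == 12L
  parsed <- NULL
  if (any(ok)) {
    mat <- do.call(rbind, fields[ok])
    colnames(mat) <- outfmt6_cols
    parsed <- as_tibble(mat) %>%
      dplyr::mutate(dplyr::across(dplyr::all_of(
        c("pident", "length", "mismatch", "gapopen", "qstart", "qend",
          "sstart", "send", "evalue", "bitscore")),
        function(v) suppressWarnings(as.numeric(v))))
    bad_num <- !stats::complete.cases(parsed[, c("evalue", "bitscore", "pident")])
    ok[ok][bad_num] <- FALSE
    parsed <- parsed[!bad_num, , drop = FALSE]
  }
  n_bad <- sum(!ok)
  if (n_bad > 0.1 * length(lines)) {
    stop("more than 10% malformed rows in ", path, " (", n_bad, " of ",
         length(lines), ")")
  }
  if (is.null(parsed)) parsed <- tibble()
  if (nrow(parsed) > 0 && any(parsed$evalue < 0)) {
    stop("negative e-values in ", path)
  }
  out <- dplyr::bind_cols(tibble(taxon = rep(taxon, nrow(parsed))), parsed)
  attr(out, "n_malformed") <- n_bad
  attr(out, "n_metaproteins") <- dplyr::n_distinct(parsed$qseqid)
  out
}

#' Merge species/strain hit tables at the genus level
#'
#' Concatenates the hit tables of all species belonging to one genus into a
#' single table per genus, collapsing duplicate rows so that the merged
#' metaproteome is non-redundant; the metaprotein count of a genus is the
#' number of distinct query proteins after the merge.
#'
#' @param tables List of hit tables from [read_hit_table()].
#' @param genus Character vector, one genus label per table; defaults to
#'   each table's `taxon` column, i.e. tables already keyed by genus.
#' @return Named list of merged tables, one per genus, each carrying the
#'   `n_metaproteins` attribute.
#' @export
merge_taxa_at_genus <- function(tables, genus = NULL) {
  if (is.null(genus)) {
    genus <- vapply(tables, function(t) {
      g <- unique(t$taxon)
      if (length(g) != 1) stop("table without a single genus label")
      g
    }, character(1))
  }
  if (anyNA(genus) || any(!nzchar(genus))) stop("missing genus label")
  stopifnot(length(genus) == length(tables))
  purrr::imap(split(tables, genus), function(tabs, g) {
    out <- dplyr::bind_rows(tabs)
    out$taxon <- rep(g, nrow(out))
    out <- dplyr::distinct(out)
    attr(out, "n_metaproteins") <- dplyr::n_distinct(out$qseqid)
    out
  })
}

#' Resolve a hit table to a non-redundant human gene set
#'
#' Keeps hits with e-value at or below the threshold, maps subject
#' accessions to gene ids (version suffixes such as `.1` stripped by
#' default) and deduplicates. Accessions missing from the mapping are
#' reported via the `unmapped` attribute, not an error.
#'
#' @param hits Hit table from [read_hit_table()] or
#'   [merge_taxa_at_genus()].
#' @param mapping Tibble with columns `accession`, `gene_id`.
#' @param e_threshold Inclusive e-value cut-off, default 0.05.
#' @param strip_version Strip a trailing `.N` accession version before the
#'   lookup; default `TRUE`.
#' @return A tibble with columns `taxon`, `gene_id` (one row per gene,
#'   sorted), attributes `n_metaproteins`, `n_hits` (rows passing the
#'   threshold) and `unmapped` (accessions without a gene id).
#' @export
hits_to_gene_set <- function(hits, mapping, e_threshold = 0.05,
                             strip_version = TRUE) {
  stopifnot(nrow(mapping) > 0,
            all(c("accession", "gene_id") %in% names(mapping)))
  taxon <- unique(hits$taxon)
  kept <- dplyr::filter(hits, .data$evalue <= e_threshold)
  acc <- kept$sseqid
  if (strip_version) acc <- stringr::str_remove(acc, "\\.\\d+$")
  gene <- mapping$gene_id[match(acc, mapping$accession)]
  unmapped <- sort(unique(acc[is.na(gene)]))
  genes <- sort(unique(gene[!is.na(gene)]))
  out <- tibble(taxon = rep(if (length(taxon)) taxon else NA_character_,
                            length(genes)),
                gene_id = genes)
  attr(out, "n_metaproteins") <- attr(hits, "n_metaproteins") %||%
    dplyr::n_distinct(hits$qseqid)
  attr(out, "n_hits") <- nrow(kept)
  attr(out, "unmapped") <- unmapped
  out
}

#' Per-taxon gene sets and summary for a collection of hit tables
#'
#' @param tables Named list of genus-level hit tables.
#' @param mapping Accession-to-gene tibble (see [hits_to_gene_set()]).
#' @param e_threshold Inclusive e-value cut-off, default 0.05.
#' @return List with `gene_sets` (named list taxon -> gene id vector) and
#'   `summary` (tibble `taxon`, `n_metaproteins`, `n_hits`, `n_genes`).
#' @export
taxon_gene_sets <- function(tables, mapping, e_threshold = 0.05) {
  sets <- purrr::map(tables, hits_to_gene_set, mapping = mapping,
                     e_threshold = e_threshold)
  summary <- purrr::imap_dfr(sets, function(s, nm) {
    tibble(taxon = nm,
           n_metaproteins = attr(s, "n_metaproteins"),
           n_hits = attr(s, "n_hits"),
           n_genes = nrow(s))
  })
  list(gene_sets = purrr::map(sets, "gene_id"), summary = summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
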