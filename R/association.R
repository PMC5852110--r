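#' Sorensen-Dice similarity of two sets
#'
#' `2|A∩B| / (|A| + |B|)`; two empty sets have similarity 0 by convention.
#'
#' @param a,b Vectors treated as sets (duplicates ignored).
#' @return Similarity in `[0, 1]`.
#' @export
sorensen_dice <- function(a, b) {
  a <- unique(a); b <- unique(b)
  denom <- length(a) + length(b)
  if (denom == 0) return(0)
  2 * length(intersect(a, b)) / denom
}

#' Taxon-by-substructure Sorensen-Dice matrix
#'
#' One coefficient per (taxon, substructure) pair, comparing the items
#' (shared GO terms, or genes) attributed to each side. Average-linkage
#' hierarchical clustering orders rows and columns for heatmap rendering;
#' labels are sorted lexicographically before clustering so the ordering is
#' reproducible.
#'
#' @param items_by_taxon Named list: taxon -> character vector of items.
#' @param items_by_substructure Named list: substructure -> items.
#' @param item_kind Label recording what the items are (`"GOs"` or
#'   `"genes"`).
#' @return An `sd_matrix` object: list with `matrix` (taxa x
#'   substructures), `row_order`, `col_order` (labels in dendrogram order)
#'   and `item_kind`.
#' @export
sd_matrix <- function(items_by_taxon, items_by_substructure,
                      item_kind = c("GOs", "genes")) {
  item_kind <- match.arg(item_kind)
  stopifnot(length(items_by_taxon) > 0, length(items_by_substructure) > 0)
  taxa <- sort(names(items_by_taxon))
  subs <- sort(names(items_by_substructure))
  m <- matrix(0, length(taxa), length(subs), dimnames = list(taxa, subs))
  for (t in taxa) {
    for (s in subs) {
      m[t, s] <- sorensen_dice(items_by_taxon[[t]], items_by_substructure[[s]])
    }
  }
  cluster_order <- function(x) {
    if (nrow(x) < 3) return(rownames(x))
    rownames(x)[hclust(stats::dist(1 - x), method = "average")$order]
  }
  structure(list(matrix = m,
                 row_order = cluster_order(m),
                 col_order = cluster_order(t(m)),
                 item_kind = item_kind),
            class = "sd_matrix")
}

#' @export
print.sd_matrix <- function(x, ...) {
  cat("<sd_matrix> ", nrow(x$matrix), " taxa x ", ncol(x$matrix),
      " substructures (", x$item_kind, ")\n", sep = "")
  invisible(x)
}

#' @rdname sd_matrix
#' @param x An `sd_matrix`.
#' @param ... Unused.
#' @return `tidy()`: a long tibble `taxon`, `substructure`, `sd`.
#' @export
tidy.sd_matrix <- function(x, ...) {
  as_tibble(x$matrix, rownames = "taxon") %>%
    tidyr::pivot_longer(-"taxon", names_to = "substructure", values_to = "sd")
}

#' Intersect enriched GO sets into taxon-to-brain-substructure records
#'
#' A record is emitted for every (taxon, substructure, GO) triple whose GO
#' term is significant in both the taxon's and the substructure's
#' enrichment results (both post-significance and post-direction-filter).
#' Each record carries the supporting genes: the genes annotated
#' (propagated) to the term that lie in the substructure's differentially
#' expressed set, and alongside them the taxon's hit genes annotated to the
#' term.
#'
#' @param taxon_records Tibble with columns `taxon`, `go_id` (one row per
#'   significant term per taxon), e.g. stacked [enrich()] outputs.
#' @param substructure_records Tibble with columns `substructure`, `go_id`.
#' @param annotations A `go_annotations` object.
#' @param taxon_genes Named list: taxon -> gene id vector (from
#'   [taxon_gene_sets()]).
#' @param substructure_genes Named list: substructure -> DE gene id vector
#'   (from [de_gene_sets()]).
#' @param propagate Count genes through propagated annotations (default
#'   `TRUE`).
#' @return A tibble with columns `taxon`, `substructure`, `go_id`,
#'   `genes` and `taxon_genes` (list-columns of gene ids) and
#'   `empty_support` (flag: the shared GO has no substructure gene at the
#'   gene level).
#' @export
common_gos <- function(taxon_records, substructure_records, annotations,
                       taxon_genes, substructure_genes, propagate = TRUE) {
  pairs <- annotation_pairs(annotations, propagate = propagate)
  genes_by_term <- split(pairs$gene_id, pairs$go_id)
  out <- dplyr::inner_join(
    dplyr::distinct(taxon_records[, c("taxon", "go_id")]),
    dplyr::distinct(substructure_records[, c("substructure", "go_id")]),
    by = "go_id", relationship = "many-to-many"
  ) %>%
    dplyr::arrange(.data$taxon, .data$substructure, .data$go_id)
  out$genes <- purrr::map2(out$go_id, out$substructure, function(g, s) {
    sort(intersect(genes_by_term[[g]], substructure_genes[[s]]))
  })
  out$taxon_genes <- purrr::map2(out$go_id, out$taxon, function(g, t) {
    sort(intersect(genes_by_term[[g]], taxon_genes[[t]]))
  })
  out$empty_support <- lengths(out$genes) == 0
  out[, c("taxon", "substructure", "go_id", "genes", "taxon_genes",
          "empty_support")]
}

#' Pearson diagnostic: metaproteome size versus matched GO count
#'
#' Checks whether the number of GO terms matched per taxon is driven by the
#' size of the taxon's metaproteome; a value near zero (or negative)
#' indicates the association counts are not a trivial artefact of
#' metaproteome size.
#'
#' @param summary Tibble with columns `taxon`, `n_metaproteins` (e.g. from
#'   [taxon_gene_sets()]).
#' @param go_counts Tibble with columns `taxon`, `n_gos` (matched GO terms
#'   per taxon).
#' @return Pearson correlation coefficient; `NA` with a warning when
#'   either vector has zero variance.
#' @export
metaprotein_go_correlation <- function(summary, go_counts) {
  joined <- dplyr::inner_join(summary[, c("taxon", "n_metaproteins")],
                              go_counts[, c("taxon", "n_gos")], by = "taxon")
  if (nrow(joined) < 3) stop("need at least 3 taxa")
  if (stats::sd(joined$n_metaproteins) == 0 || stats::sd(joined$n_gos) == 0) {
    warning("zero variance; correlation undefined")
    return(NA_real_)
  }
  cor(joined$n_metaproteins, joined$n_gos, method = "pearson")
}

#' Per-slim summary of association records
#'
#' @param records Tibble from [common_gos()].
#' @param slims Tibble from [cluster_slims()] labelling every `go_id` in
#'   `records`.
#' @return A tibble, one row per slim: `slim`, `n_gos` (distinct GO
#'   terms), `n_taxa` (distinct taxa), `substructures`
#'   (comma-separated sorted labels).
#' @export
slim_summary <- function(records, slims) {
  if (nrow(records) == 0) {
    return(tibble(slim = character(), n_gos = integer(),
                  n_taxa = integer(), substructures = character()))
  }
  unlabeled <- setdiff(unique(records$go_id), slims$go_id)
  if (length(unlabeled) > 0) {
    stop("GO id(s) without a slim label: ", paste(unlabeled, collapse = ", "))
  }
  records %>%
    dplyr::inner_join(slims[, c("go_id", "slim")], by = "go_id") %>%
    dplyr::group_by(.data$slim) %>%
    dplyr::summarise(
      n_gos = dplyr::n_distinct(.data$go_id),
      n_taxa = dplyr::n_distinct(.data$taxon),
      substructures = paste(sort(unique(.data$substructure)), collapse = ", "),
      .groups = "drop") %>%
    dplyr::arrange(.data$slim)
}

#' Stacked per-substructure, per-taxon slim counts
#'
#' The data behind stacked-bar renderings: how many shared GO terms each
#' (substructure, taxon) pair contributes to each slim.
#'
#' @inheritParams slim_summary
#' @return Tibble `substructure`, `taxon`, `slim`, `n_gos`.
#' @export
slim_stacked_counts <- function(records, slims) {
  if (nrow(records) == 0) {
    return(tibble(substructure = character(), taxon = character(),
                  slim = character(), n_gos = integer()))
  }
  records %>%
    dplyr::inner_join(slims[, c("go_id", "slim")], by = "go_id") %>%
    dplyr::group_by(.data$substructure, .data$taxon, .data$slim) %>%
    dplyr::summarise(n_gos = dplyr::n_distinct(.data$go_id),
                     .groups = "drop") %>%
    dplyr::arrange(.data$substructure, .data$taxon, .data$slim)
}

#' Default psychobiotic genus list
#'
#' Genera with reported mental-health influence or
#' neurotransmitter-producing capability, used as the default focus set of
#' [psychobiotic_report()]. `Enterobacteriaceae` is a family-level label
#' kept verbatim. Editable: pass your own vector to the report.
#'
#' @return Character vector of 12 taxon labels.
#' @export
default_psychobiotics <- function() {
  c("Actinomyces", "Bacillus", "Bacteroides", "Bifidobacterium",
    "Enterobacteriaceae", "Enterococcus", "Escherichia", "Faecalibacterium",
    "Lactobacillus", "Prevotella", "Staphylococcus", "Streptococcus")
}

#' Psychobiotic subset report
#'
#' Restricts the association records to a focus list of taxa
#' (psychobiotics by default) and, optionally, to slims of interest, then
#' ranks the shared GO terms by how many records mention them and reports
#' the share of the top-`k` terms.
#'
#' @param records Tibble from [common_gos()].
#' @param slims Optional [cluster_slims()] tibble; required when
#'   `slims_of_interest` is given.
#' @param psychobiotics Taxa to keep; default [default_psychobiotics()].
#' @param slims_of_interest Slim labels to keep; `NULL` keeps all slims.
#' @param top_k Number of top-ranked GO terms for the share statistic,
#'   default 7.
#' @return A list of class `psychobiotic_report`: `records` (the filtered
#'   records), `n_records`, `go_ranking` (tibble `go_id`, `n`, `share`),
#'   `top_k`, `top_k_share`, `substructure_shares` (tibble).
#' @export
psychobiotic_report <- function(records, slims = NULL,
                                psychobiotics = default_psychobiotics(),
                                slims_of_interest = NULL, top_k = 7) {
  stopifnot(length(psychobiotics) > 0)
  kept <- dplyr::filter(records, .data$taxon %in% psychobiotics)
  if (!is.null(slims_of_interest)) {
    if (is.null(slims)) stop("slims_of_interest given without a slim table")
    kept <- kept %>%
      dplyr::inner_join(slims[, c("go_id", "slim")], by = "go_id") %>%
      dplyr::filter(.data$slim %in% slims_of_interest)
  }
  ranking <- kept %>%
    dplyr::count(.data$go_id, sort = TRUE, name = "n") %>%
    dplyr::mutate(share = .data$n / sum(.data$n))
  sub_shares <- kept %>%
    dplyr::count(.data$substructure, sort = TRUE, name = "n") %>%
    dplyr::mutate(share = .data$n / sum(.data$n))
  structure(list(records = kept,
                 n_records = nrow(kept),
                 go_ranking = ranking,
                 top_k = top_k,
                 top_k_share = if (nrow(ranking)) {
                   sum(head(ranking$n, top_k)) / sum(ranking$n)
                 } else NA_real_,
                 substructure_shares = sub_shares),
            class = "psychobiotic_report")
}

#' @export
print.psychobiotic_report <- function(x, ...) {
  cat("<psychobiotic_report> ", x$n_records, " records; top ", x$top_k,
      " GOs hold ", if (is.na(x$top_k_share)) "NA" else
        sprintf("%.1f%%", 100 * x$top_k_share),
      " of mentions\n", sep = "")
  invisible(x)
}
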