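#' Run the full taxa-to-brain-substructure association pipeline
#'
#' Chains every stage: annotation propagation, count-matrix filtering,
#' negative-binomial quasi-likelihood differential expression of each
#' substructure against the grand mean, per-taxon homology-hit resolution,
#' GO enrichment of both gene-list families with Bonferroni control
#' (underrepresented terms discarded on the taxon side), intersection into
#' association records, Sorensen-Dice matrices, the metaproteome-size
#' Pearson diagnostic, and slim construction by clustering semantic
#' distances of the shared terms.
#'
#' @param ontology A [go_ontology()].
#' @param annotations Long `gene_id`/`go_id` tibble or `go_annotations`.
#' @param counts Count tibble (first column `gene_id`).
#' @param samples Sample metadata tibble (`sample_id`, `substructure`).
#' @param hits Named list of taxon hit tables (genus level).
#' @param accession_map Tibble `accession`, `gene_id`.
#' @param alpha Significance level for both the DE and enrichment
#'   Bonferroni-adjusted p-values, default 0.05.
#' @param lfc_threshold Minimum absolute DE log2 fold change, default 1.5.
#' @param cpm_threshold,min_replicates,filter_rule Passed to
#'   [filter_genes()].
#' @param e_threshold Homology e-value cut-off, default 0.05.
#' @param propagate Propagate annotation counts to ancestors, default
#'   `TRUE`.
#' @param substructure_direction Direction filter for substructure
#'   enrichments (`"both"` by default; taxon lists always keep `"over"`
#'   only).
#' @param n_slims Requested slim count, default 14 (clamped to the number
#'   of unique shared terms).
#' @param compute_mds Also compute leading-fold-change sample distances
#'   (slower); default `FALSE`.
#' @return A `t2bs_result` list: `filtered_counts`, `de`, `de_sets`,
#'   `taxon_sets` (with `summary`), `taxon_enrichment`,
#'   `substructure_enrichment`, `records`, `sd_gos`, `sd_genes`,
#'   `pearson`, `slims`, `slim_summary`, `slim_stacked`, `sample_distances`
#'   (optional), and the thresholds used (`params`).
#' @export
run_t2bs_pipeline <- function(ontology, annotations, counts, samples, hits,
                              accession_map,
                              alpha = 0.05, lfc_threshold = 1.5,
                              cpm_threshold = 0.5, min_replicates = 2,
                              filter_rule = "standard",
                              e_threshold = 0.05, propagate = TRUE,
                              substructure_direction = "both",
                              n_slims = 14, compute_mds = FALSE) {
  if (!inherits(annotations, "go_annotations")) {
    annotations <- propagate_annotations(ontology, annotations)
  }
  universe <- sort(unique(annotations$direct$gene_id))

  filtered <- filter_genes(counts, samples, annotated = universe,
                           cpm_threshold = cpm_threshold,
                           min_replicates = min_replicates,
                           rule = filter_rule)
  fit <- fit_nbql(filtered, samples)
  de <- de_test(fit, alpha = alpha, lfc_threshold = lfc_threshold)
  de_sets <- de_gene_sets(de)

  sub_pop <- filtered$gene_id
  substructure_enrichment <- purrr::imap_dfr(de_sets, function(set, s) {
    res <- enrich(set, sub_pop, annotations, alpha = alpha,
                  propagate = propagate)
    res <- filter_direction(res, keep = substructure_direction)
    if (nrow(res)) dplyr::bind_cols(tibble(substructure = s), res) else NULL
  })

  tgs <- taxon_gene_sets(hits, accession_map, e_threshold = e_threshold)
  taxon_enrichment <- purrr::imap_dfr(tgs$gene_sets, function(set, tx) {
    set <- intersect(set, universe)
    if (length(set) == 0) return(NULL)
    res <- enrich(set, universe, annotations, alpha = alpha,
                  propagate = propagate)
    res <- filter_direction(res, keep = "over")
    if (nrow(res)) dplyr::bind_cols(tibble(taxon = tx), res) else NULL
  })

  empty_enr <- nrow(taxon_enrichment) == 0 || nrow(substructure_enrichment) == 0
  records <- if (empty_enr) {
    tibble(taxon = character(), substructure = character(),
           go_id = character(), genes = list(), taxon_genes = list(),
           empty_support = logical())
  } else {
    common_gos(taxon_enrichment, substructure_enrichment, annotations,
               taxon_genes = tgs$gene_sets, substructure_genes = de_sets,
               propagate = propagate)
  }

  # GOs matched per taxon = its significant (overrepresented) enriched terms
  tx_go_n <- if (nrow(taxon_enrichment)) {
    taxon_enrichment %>%
      dplyr::group_by(.data$taxon) %>%
      dplyr::summarise(n_gos = dplyr::n_distinct(.data$go_id), .groups = "drop")
  } else tibble(taxon = character(), n_gos = integer())
  go_counts <- tibble(taxon = names(tgs$gene_sets)) %>%
    dplyr::left_join(tx_go_n, by = "taxon") %>%
    dplyr::mutate(n_gos = dplyr::coalesce(.data$n_gos, 0L))
  pearson <- if (nrow(tgs$summary) >= 3) {
    tryCatch(metaprotein_go_correlation(tgs$summary, go_counts),
             warning = function(w) NA_real_)
  } else NA_real_

  sd_gos <- sd_genes <- NULL
  if (!empty_enr) {
    gos_by_taxon <- split(taxon_enrichment$go_id, taxon_enrichment$taxon)
    gos_by_sub <- split(substructure_enrichment$go_id,
                        substructure_enrichment$substructure)
    sd_gos <- sd_matrix(gos_by_taxon, gos_by_sub, item_kind = "GOs")
    genes_by_taxon <- tgs$gene_sets[names(gos_by_taxon)]
    sd_genes <- sd_matrix(genes_by_taxon, de_sets[names(gos_by_sub)],
                          item_kind = "genes")
  }

  slims <- slim_tab <- slim_stack <- NULL
  uniq <- sort(unique(records$go_id))
  if (length(uniq) >= 2) {
    dmat <- semantic_distance_matrix(ontology, uniq)
    slims <- cluster_slims(dmat, n_slims = min(n_slims, length(uniq)))
    slim_tab <- slim_summary(records, slims)
    slim_stack <- slim_stacked_counts(records, slims)
  }

  sample_distances <- if (compute_mds) {
    leading_fc_distances(filtered, samples)
  } else NULL

  structure(list(filtered_counts = filtered, fit = fit, de = de,
                 de_sets = de_sets, taxon_sets = tgs,
                 taxon_enrichment = taxon_enrichment,
                 substructure_enrichment = substructure_enrichment,
                 records = records, sd_gos = sd_gos, sd_genes = sd_genes,
                 pearson = pearson, slims = slims,
                 slim_summary = slim_tab, slim_stacked = slim_stack,
                 sample_distances = sample_distances,
                 params = list(alpha = alpha, lfc_threshold = lfc_threshold,
                               cpm_threshold = cpm_threshold,
                               min_replicates = min_replicates,
                               filter_rule = filter_rule,
                               e_threshold = e_threshold,
                               propagate = propagate, n_slims = n_slims)),
            class = "t2bs_result")
}

#' @export
print.t2bs_result <- function(x, ...) {
  cat("<t2bs_result> ", nrow(x$records), " association records (",
      dplyr::n_distinct(x$records$go_id), " unique GOs, ",
      dplyr::n_distinct(x$records$taxon), " taxa, ",
      dplyr::n_distinct(x$records$substructure), " substructures)\n",
      sep = "")
  invisible(x)
}

#' Score pipeline output against the planted truth of a synthetic study
#'
#' Recall is the fraction of planted (taxon, substructure, GO) triples
#' present among the association records. The false-association rate is
#' computed over (taxon, substructure) pairs: among pairs with no planted
#' association, the fraction that nonetheless produced at least one
#' record.
#'
#' @param records Tibble from [common_gos()] / `t2bs_result$records`.
#' @param planted Planted-truth tibble (`taxon`, `substructure`, `go_id`).
#' @param taxa,substructures All labels in the study (defaults: those seen
#'   in `planted` and `records`).
#' @return List with `recall`, `false_rate`, `n_records`, `n_planted`,
#'   `n_recovered`, `n_false_pairs`, `n_unplanted_pairs`.
#' @export
association_recovery <- function(records, planted,
                                 taxa = NULL, substructures = NULL) {
  key <- function(d) paste(d$taxon, d$substructure, sep = "\r")
  triple <- function(d) paste(d$taxon, d$substructure, d$go_id, sep = "\r")
  recovered <- triple(planted) %in% triple(records)
  if (is.null(taxa)) taxa <- unique(c(planted$taxon, records$taxon))
  if (is.null(substructures)) {
    substructures <- unique(c(planted$substructure, records$substructure))
  }
  all_pairs <- as_tibble(expand.grid(taxon = taxa,
                                     substructure = substructures,
                                     stringsAsFactors = FALSE))
  unplanted <- all_pairs[!key(all_pairs) %in% key(planted), ]
  false_pairs <- unique(key(records)[!key(records) %in% key(planted)])
  list(recall = mean(recovered),
       false_rate = if (nrow(unplanted)) {
         length(false_pairs) / nrow(unplanted)
       } else 0,
       n_records = nrow(records),
       n_planted = nrow(planted),
       n_recovered = sum(recovered),
       n_false_pairs = length(false_pairs),
       n_unplanted_pairs = nrow(unplanted))
}
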