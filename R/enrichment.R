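#' GO term enrichment of a gene list by Fisher's exact test
#'
#' For every GO term annotating at least one study gene, builds the 2x2
#' table (study / non-study genes crossed with carrying / not carrying the
#' term, counts over propagated annotations by default) and computes the
#' two-sided Fisher's exact p-value. Bonferroni correction is applied over
#' the terms tested for this study list, and only terms with adjusted
#' p at most `alpha` are returned. The direction label compares the study
#' term frequency with the population frequency: `over` when the study
#' ratio exceeds the population ratio, `under` otherwise.
#'
#' @param study Character vector of study gene ids; must be a subset of
#'   `population`.
#' @param population Character vector of population (universe) gene ids.
#' @param annotations A `go_annotations` object (or long `gene_id`/`go_id`
#'   tibble).
#' @param alpha Significance level on the Bonferroni-adjusted p, default
#'   0.05.
#' @param propagate Use ancestor-propagated annotations (default `TRUE`);
#'   `FALSE` counts direct annotations only.
#' @param ontology Optional [go_ontology()]; when supplied, term names and
#'   namespaces are joined onto the result.
#' @return A tibble of significant terms with columns `go_id`,
#'   `study_count`, `study_n`, `pop_count`, `pop_n`, `fold`, `direction`,
#'   `p`, `p_adj` (plus `name`, `namespace` when `ontology` is given),
#'   sorted by `p`; attribute `n_tested` records the Bonferroni family
#'   size.
#' @export
enrich <- function(study, population, annotations, alpha = 0.05,
                   propagate = TRUE, ontology = NULL) {
  study <- unique(study)
  population <- unique(population)
  extra <- setdiff(study, population)
  if (length(extra) > 0) {
    stop("study genes outside the population: ", paste(extra, collapse = ", "))
  }
  pairs <- annotation_pairs(annotations, propagate = propagate)
  pairs <- dplyr::filter(pairs, .data$gene_id %in% population)
  study_n <- length(study)
  pop_n <- length(population)

  counts <- pairs %>%
    dplyr::group_by(.data$go_id) %>%
    dplyr::summarise(pop_count = dplyr::n_distinct(.data$gene_id),
                     study_count = dplyr::n_distinct(
                       .data$gene_id[.data$gene_id %in% study]),
                     .groups = "drop") %>%
    dplyr::filter(.data$study_count > 0)

  if (nrow(counts) == 0) {
    out <- tibble(go_id = character(), study_count = integer(),
                  study_n = integer(), pop_count = integer(),
                  pop_n = integer(), fold = double(),
                  direction = character(), p = double(), p_adj = double())
    attr(out, "n_tested") <- 0L
    return(out)
  }

  p <- vapply(seq_len(nrow(counts)), function(i) {
    fisher_two_sided(counts$study_count[i], study_n,
                     counts$pop_count[i], pop_n)
  }, double(1))

  out <- counts %>%
    dplyr::mutate(study_n = study_n, pop_n = pop_n,
                  fold = (.data$study_count / study_n) /
                         (.data$pop_count / pop_n),
                  direction = ifelse(.data$study_count / study_n >
                                       .data$pop_count / pop_n,
                                     "over", "under"),
                  p = p,
                  p_adj = pmin(1, p * dplyr::n())) %>%
    dplyr::filter(.data$p_adj <= alpha) %>%
    dplyr::arrange(.data$p, .data$go_id) %>%
    dplyr::select("go_id", "study_count", "study_n", "pop_count", "pop_n",
                  "fold", "direction", "p", "p_adj")
  if (!is.null(ontology)) {
    out <- out %>%
      dplyr::left_join(dplyr::select(ontology$terms, go_id = "id",
                                     "name", "namespace"),
                       by = "go_id") %>%
      dplyr::relocate("name", "namespace", .after = "go_id")
  }
  attr(out, "n_tested") <- nrow(counts)
  out
}

# two-sided Fisher's exact p for the 2x2 table
# (study/non-study genes x carrying/not carrying the term)
fisher_two_sided <- function(study_count, study_n, pop_count, pop_n) {
  tab <- matrix(c(study_count, pop_count - study_count,
                  study_n - study_count,
                  (pop_n - pop_count) - (study_n - study_count)), 2, 2)
  fisher.test(tab, conf.int = FALSE)$p.value
}

#' Drop underrepresented terms from an enrichment result
#'
#' Significant underrepresented GOs are discarded from taxon-associated
#' gene lists; substructure lists keep both directions by default.
#'
#' @param records Tibble from [enrich()].
#' @param keep `"over"` to retain overrepresented terms only, `"both"` for
#'   the identity.
#' @return The filtered tibble.
#' @export
filter_direction <- function(records, keep = c("over", "both")) {
  keep <- match.arg(keep)
  if (keep == "both") records else
    dplyr::filter(records, .data$direction == "over")
}
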