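#' Read a gene-to-GO annotation table
#'
#' Reads the two-column "id2gos" dialect: tab-separated, first column a gene
#' id, second column a semicolon-separated list of GO ids.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `gene_id`, `go_id` (one row per pair).
#' @export
read_annotations <- function(path) {
  raw <- readr::read_tsv(path, col_names = c("gene_id", "go_ids"),
                         col_types = "cc", progress = FALSE)
  raw %>%
    dplyr::mutate(go_id = stringr::str_split(.data$go_ids, ";")) %>%
    tidyr::unnest("go_id") %>%
    dplyr::mutate(go_id = stringr::str_trim(.data$go_id)) %>%
    dplyr::filter(.data$go_id != "") %>%
    dplyr::select("gene_id", "go_id") %>%
    dplyr::distinct()
}

#' Write annotations in the two-column id2gos dialect
#'
#' @param annotations Long tibble with columns `gene_id`, `go_id`, or a
#'   `go_annotations` object (its direct annotations are written).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  if (inherits(annotations, "go_annotations")) annotations <- annotations$direct
  annotations %>%
    dplyr::group_by(.data$gene_id) %>%
    dplyr::summarise(go_ids = paste(sort(unique(.data$go_id)), collapse = ";"),
                     .groups = "drop") %>%
    dplyr::arrange(.data$gene_id) %>%
    readr::write_tsv(path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Propagate direct annotations to all `is_a` ancestors
#'
#' Builds the ancestor-closed annotation set used for enrichment counting:
#' each gene inherits, in addition to its directly annotated terms, every
#' ancestor of those terms along `is_a` edges. GO ids that do not resolve in
#' the ontology (after `alt_id` mapping) are dropped and reported in the
#' `skipped` element rather than raising an error, matching how annotation
#' files routinely lag the ontology release.
#'
#' @param ontology A [go_ontology()].
#' @param direct Long tibble with columns `gene_id`, `go_id`.
#' @return A `go_annotations` object: list with tibbles `direct` and
#'   `propagated` (columns `gene_id`, `go_id`) and a character vector
#'   `skipped` of unresolvable or obsolete GO ids.
#' @export
propagate_annotations <- function(ontology, direct) {
  if (inherits(direct, "go_annotations")) direct <- direct$direct
  direct <- dplyr::distinct(as_tibble(direct)[, c("gene_id", "go_id")])

  alt <- setNames(ontology$alt_ids$id, ontology$alt_ids$alt_id)
  mapped <- ifelse(direct$go_id %in% names(alt),
                   unname(alt[direct$go_id]), direct$go_id)
  live <- ontology$terms$id[!ontology$terms$obsolete]
  ok <- mapped %in% live
  skipped <- sort(unique(direct$go_id[!ok]))
  direct <- dplyr::distinct(tibble(gene_id = direct$gene_id[ok], go_id = mapped[ok]))

  anc <- term_ancestors(ontology)
  closure <- tibble(
    go_id = names(anc),
    ancestor = lapply(anc, function(a) c(NA_character_, a))
  ) %>% tidyr::unnest("ancestor")
  propagated <- direct %>%
    dplyr::inner_join(closure, by = "go_id", relationship = "many-to-many") %>%
    dplyr::transmute(gene_id = .data$gene_id,
                     go_id = dplyr::coalesce(.data$ancestor, .data$go_id)) %>%
    dplyr::distinct()

  structure(list(direct = direct, propagated = propagated, skipped = skipped),
            class = "go_annotations")
}

#' @export
print.go_annotations <- function(x, ...) {
  cat("<go_annotations> ", dplyr::n_distinct(x$direct$gene_id), " genes, ",
      dplyr::n_distinct(x$direct$go_id), " direct terms -> ",
      dplyr::n_distinct(x$propagated$go_id), " propagated terms",
      if (length(x$skipped)) paste0(" (", length(x$skipped), " ids skipped)"),
      "\n", sep = "")
  invisible(x)
}

# term -> genes map as a long tibble, using propagated or direct annotations
annotation_pairs <- function(annotations, propagate = TRUE) {
  if (inherits(annotations, "go_annotations")) {
    if (propagate) annotations$propagated else annotations$direct
  } else {
    as_tibble(annotations)[, c("gene_id", "go_id")]
  }
}
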