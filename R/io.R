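#' Write association records as a flat TSV
#'
#' Gene list-columns are semicolon-joined; term names and slim labels are
#' added when available.
#'
#' @param records Tibble from [common_gos()].
#' @param path Output TSV path.
#' @param ontology Optional [go_ontology()] for term names.
#' @param slims Optional [cluster_slims()] tibble for slim labels.
#' @return `path`, invisibly.
#' @export
write_t2bs_records <- function(records, path, ontology = NULL, slims = NULL) {
  out <- records %>%
    dplyr::mutate(genes = purrr::map_chr(.data$genes, paste, collapse = ";"),
                  taxon_genes = purrr::map_chr(.data$taxon_genes, paste,
                                               collapse = ";"))
  if (!is.null(ontology)) {
    out <- out %>%
      dplyr::left_join(dplyr::select(ontology$terms, go_id = "id",
                                     go_name = "name"), by = "go_id") %>%
      dplyr::relocate("go_name", .after = "go_id")
  }
  if (!is.null(slims)) {
    out <- out %>%
      dplyr::left_join(slims[, c("go_id", "slim")], by = "go_id")
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Write a Sorensen-Dice matrix as TSV
#'
#' @param x An `sd_matrix`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_sd_matrix <- function(x, path) {
  as_tibble(x$matrix, rownames = "taxon") %>%
    readr::write_tsv(path, progress = FALSE)
  invisible(path)
}

#' Write differential-expression results as TSV
#'
#' Columns: gene, substructure, log2fc, F, p, p_adj, selected.
#'
#' @param de Tibble from [de_test()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_de_results <- function(de, path) {
  readr::write_tsv(de, path, progress = FALSE)
  invisible(path)
}

#' Read a counts TSV (first column gene id) and a sample metadata CSV
#'
#' @param counts_path TSV with `gene_id` then one column per sample.
#' @param samples_path CSV with `sample_id`, `substructure` (and
#'   optionally `replicate`).
#' @return List with `counts` and `samples` tibbles.
#' @export
read_count_study <- function(counts_path, samples_path) {
  counts <- readr::read_tsv(counts_path, show_col_types = FALSE,
                            progress = FALSE)
  names(counts)[1] <- "gene_id"
  samples <- readr::read_csv(samples_path, show_col_types = FALSE,
                             progress = FALSE)
  list(counts = counts, samples = samples)
}

#' Read an accession-to-gene mapping TSV
#'
#' @param path Two-column TSV (`accession`, `gene_id`), with or without a
#'   header line.
#' @return Tibble with columns `accession`, `gene_id`.
#' @export
read_accession_map <- function(path) {
  first <- readr::read_lines(path, n_max = 1)
  has_header <- grepl("accession", first, fixed = TRUE)
  readr::read_tsv(path,
                  col_names = if (has_header) TRUE else c("accession", "gene_id"),
                  skip = 0, col_types = "cc", progress = FALSE)
}
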