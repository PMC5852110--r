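#' Counts-per-million normalisation
#'
#' @param counts Tibble whose first column is `gene_id` and remaining
#'   columns are per-sample integer counts.
#' @return A tibble of the same shape with counts replaced by CPM; each
#'   sample column sums to one million.
#' @export
compute_cpm <- function(counts) {
  m <- as_count_matrix(counts)
  libs <- colSums(m)
  if (any(libs <= 0)) {
    stop("zero library size in sample(s): ",
         paste(colnames(m)[libs <= 0], collapse = ", "))
  }
  cpm <- sweep(m, 2, libs, "/") * 1e6
  dplyr::bind_cols(tibble(gene_id = rownames(m)), as_tibble(cpm))
}

# counts tibble -> integer matrix with gene_id rownames
as_count_matrix <- function(counts) {
  stopifnot(names(counts)[1] == "gene_id")
  if (anyDuplicated(counts$gene_id)) stop("duplicate gene ids in count table")
  m <- as.matrix(counts[, -1])
  if (anyDuplicated(colnames(m))) stop("duplicate sample ids in count table")
  rownames(m) <- counts$gene_id
  storage.mode(m) <- "double"
  m
}

# sample metadata -> factor of substructure labels aligned to matrix columns
sample_groups <- function(samples, sample_ids) {
  stopifnot(all(c("sample_id", "substructure") %in% names(samples)))
  miss <- setdiff(sample_ids, samples$sample_id)
  if (length(miss)) stop("samples missing from metadata: ", paste(miss, collapse = ", "))
  factor(samples$substructure[match(sample_ids, samples$sample_id)])
}

#' Filter a brain count matrix prior to differential expression
#'
#' Removes, in order: genes absent from the annotated universe; genes with
#' zero counts in every sample; and genes failing the low-expression CPM
#' rule. Two readings of the CPM rule are available:
#'
#' * `rule = "standard"` (default): keep a gene only if it has
#'   CPM > `cpm_threshold` in at least `min_replicates` samples of at least
#'   one substructure — the keep-rule of the negative-binomial DE
#'   toolchains, which preserves genes expressed in only a few tissues.
#' * `rule = "literal"`: eliminate a gene if any substructure has at least
#'   `min_replicates` replicates with CPM <= `cpm_threshold`, i.e. drop
#'   genes lowly expressed anywhere.
#'
#' @param counts Tibble, first column `gene_id`, remaining columns samples.
#' @param samples Tibble with columns `sample_id`, `substructure`.
#' @param annotated Character vector of annotated gene ids (the Entrez-like
#'   universe); genes outside it are dropped.
#' @param cpm_threshold CPM cut-off, default 0.5.
#' @param min_replicates Replicate count in the rule, default 2.
#' @param rule `"standard"` or `"literal"` (see Details).
#' @return The filtered counts tibble, row order preserved, with attribute
#'   `filter_log` (a tibble of per-step removal counts).
#' @export
filter_genes <- function(counts, samples, annotated,
                         cpm_threshold = 0.5, min_replicates = 2,
                         rule = c("standard", "literal")) {
  rule <- match.arg(rule)
  stopifnot(length(annotated) > 0)
  m <- as_count_matrix(counts)
  grp <- sample_groups(samples, colnames(m))

  keep_ann <- rownames(m) %in% annotated
  keep_nz <- rowSums(m) > 0
  cpm <- sweep(m, 2, colSums(m), "/") * 1e6
  by_sub <- lapply(split(seq_along(grp), grp), function(idx) {
    cpm[, idx, drop = FALSE]
  })
  keep_cpm <- if (rule == "standard") {
    Reduce(`|`, lapply(by_sub, function(x) {
      rowSums(x > cpm_threshold) >= min_replicates
    }))
  } else {
    !Reduce(`|`, lapply(by_sub, function(x) {
      rowSums(x <= cpm_threshold) >= min_replicates
    }))
  }
  keep <- keep_ann & keep_nz & keep_cpm
  if (!any(keep)) {
    stop("no genes pass the filters; review cpm_threshold (",
         cpm_threshold, ") and the annotated universe")
  }
  out <- counts[keep, , drop = FALSE]
  attr(out, "filter_log") <- tibble(
    step = c("input", "unannotated", "all_zero", "low_cpm", "retained"),
    n = c(nrow(m), sum(!keep_ann), sum(keep_ann & !keep_nz),
          sum(keep_ann & keep_nz & !keep_cpm), sum(keep))
  )
  out
}

#' Leading log-fold-change distances and MDS embedding
#'
#' For every sample pair the distance is the root-mean-square of the
#' `n_top` largest absolute log2-CPM differences between the two samples
#' (the "leading fold change" convention of MDS plots for count data),
#' followed by classical metric multidimensional scaling to two dimensions.
#' Log-CPM uses a prior count (default 2) to avoid taking logs of zero.
#'
#' @param counts Tibble, first column `gene_id`.
#' @param samples Tibble with `sample_id`, `substructure`.
#' @param n_top Number of top genes per pair, default 500; clamped with a
#'   warning when it exceeds the gene count.
#' @param prior_count Prior count added before the log, default 2.
#' @return A `sample_distances` object: list with `dist` (symmetric
#'   matrix), `mds` (tibble `sample_id`, `substructure`, `dim1`, `dim2`)
#'   and `n_top`.
#' @export
leading_fc_distances <- function(counts, samples, n_top = 500, prior_count = 2) {
  m <- as_count_matrix(counts)
  stopifnot(ncol(m) >= 3)
  if (n_top > nrow(m)) {
    warning("n_top (", n_top, ") exceeds gene count (", nrow(m), "); clamped")
    n_top <- nrow(m)
  }
  grp <- sample_groups(samples, colnames(m))
  logcpm <- edgeR::cpm(m, log = TRUE, prior.count = prior_count)
  ns <- ncol(m)
  d <- matrix(0, ns, ns, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(ns - 1)) {
    for (j in (i + 1):ns) {
      diffs <- sort((logcpm[, i] - logcpm[, j])^2, decreasing = TRUE)
      d[i, j] <- d[j, i] <- sqrt(mean(diffs[seq_len(n_top)]))
    }
  }
  coords <- cmdscale(as.dist(d), k = 2)
  mds <- tibble(sample_id = colnames(m),
                substructure = as.character(grp),
                dim1 = coords[, 1], dim2 = coords[, 2])
  structure(list(dist = d, mds = mds, n_top = n_top),
            class = "sample_distances")
}

#' @export
print.sample_distances <- function(x, ...) {
  cat("<sample_distances> ", nrow(x$dist), " samples, leading-FC top ",
      x$n_top, " genes\n", sep = "")
  invisible(x)
}
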