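#' Fit per-gene negative-binomial quasi-likelihood models
#'
#' Fits, for every gene, a log-link negative-binomial generalised linear
#' model with one coefficient per substructure and an offset for library
#' size, with quasi-likelihood dispersion estimation (the
#' `estimateDisp`/`glmQLFit` machinery of edgeR, the toolchain this
#' pipeline is built around). The returned object is the substrate for
#' [de_test()].
#'
#' @param counts Tibble, first column `gene_id`, remaining columns samples
#'   (typically the output of [filter_genes()]).
#' @param samples Tibble with `sample_id`, `substructure`; every
#'   substructure needs at least two replicates.
#' @param robust Passed to [edgeR::glmQLFit()]; default `FALSE`.
#' @return An `nbql_fit` object wrapping the edgeR fit, the design matrix
#'   and the substructure levels.
#' @export
fit_nbql <- function(counts, samples, robust = FALSE) {
  m <- as_count_matrix(counts)
  grp <- sample_groups(samples, colnames(m))
  if (nlevels(grp) < 2) stop("need at least two substructures")
  reps <- table(grp)
  if (any(reps < 2)) {
    stop("substructure(s) with fewer than two replicates: ",
         paste(names(reps)[reps < 2], collapse = ", "))
  }
  design <- stats::model.matrix(~ 0 + grp)
  colnames(design) <- levels(grp)
  y <- edgeR::DGEList(counts = m, group = grp)
  y <- edgeR::estimateDisp(y, design)
  fit <- edgeR::glmQLFit(y, design, robust = robust)
  structure(list(fit = fit, dge = y, design = design,
                 substructures = levels(grp),
                 genes = rownames(m)),
            class = "nbql_fit")
}

#' @export
print.nbql_fit <- function(x, ...) {
  cat("<nbql_fit> ", length(x$genes), " genes, ",
      length(x$substructures), " substructures, common dispersion ",
      signif(x$dge$common.dispersion, 3), "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-gene summaries of a quasi-likelihood fit
#'
#' @param x An `nbql_fit`.
#' @param ... Unused.
#' @return A tibble with one row per gene: tagwise negative-binomial
#'   dispersion, average log2-CPM and the quasi-likelihood residual df.
#' @export
tidy.nbql_fit <- function(x, ...) {
  tibble(gene_id = x$genes,
         dispersion = x$dge$tagwise.dispersion,
         ave_log2cpm = x$dge$AveLogCPM,
         df_residual = x$fit$df.residual.zeros)
}

#' One-row summary of a quasi-likelihood fit
#'
#' @param x An `nbql_fit`.
#' @param ... Unused.
#' @return A tibble with gene/sample/substructure counts, the common
#'   dispersion and the prior df of the quasi-dispersion shrinkage.
#' @export
glance.nbql_fit <- function(x, ...) {
  tibble(n_genes = length(x$genes),
         n_samples = ncol(x$dge$counts),
         n_substructures = length(x$substructures),
         common_dispersion = x$dge$common.dispersion,
         df_prior = median(x$fit$df.prior))
}

#' Quasi-likelihood F-test of each substructure against the grand mean
#'
#' Tests, for every gene and every requested substructure, the contrast
#' "this substructure's expression versus the mean over all
#' substructures" with the quasi-likelihood F-test, then applies Bonferroni
#' correction. A gene is `selected` for a substructure when the adjusted
#' p-value is at most `alpha` and the absolute log2 fold change is at least
#' `lfc_threshold`.
#'
#' @param fit An `nbql_fit` from [fit_nbql()].
#' @param substructure Substructure label(s) to test; default all.
#' @param alpha Significance level on the Bonferroni-adjusted p, default
#'   0.05.
#' @param lfc_threshold Minimum absolute log2 fold change, default 1.5.
#' @param family Bonferroni family: `"global"` (default; all genes times
#'   all tested substructures) or `"per_substructure"`.
#' @return A tibble with columns `gene_id`, `substructure`, `log2fc`,
#'   `f_stat`, `p`, `p_adj`, `selected`.
#' @export
de_test <- function(fit, substructure = NULL, alpha = 0.05,
                    lfc_threshold = 1.5,
                    family = c("global", "per_substructure")) {
  family <- match.arg(family)
  stopifnot(inherits(fit, "nbql_fit"))
  subs <- fit$substructures
  if (is.null(substructure)) substructure <- subs
  unknown <- setdiff(substructure, subs)
  if (length(unknown)) {
    stop("unknown substructure label(s): ", paste(unknown, collapse = ", "))
  }
  k <- length(subs)
  res <- purrr::map_dfr(substructure, function(s) {
    ctr <- rep(-1 / k, k)
    ctr[match(s, subs)] <- 1 - 1 / k
    qlf <- edgeR::glmQLFTest(fit$fit, contrast = ctr)
    tab <- qlf$table
    tibble(gene_id = rownames(tab),
           substructure = s,
           log2fc = tab$logFC,
           f_stat = tab$F,
           p = tab$PValue)
  })
  if (family == "global") {
    res$p_adj <- pmin(1, res$p * nrow(res))
  } else {
    res <- res %>%
      dplyr::group_by(.data$substructure) %>%
      dplyr::mutate(p_adj = pmin(1, .data$p * dplyr::n())) %>%
      dplyr::ungroup()
  }
  res$selected <- res$p_adj <= alpha & abs(res$log2fc) >= lfc_threshold
  res
}

#' Differentially expressed gene sets per substructure
#'
#' @param de Tibble from [de_test()].
#' @return Named list: substructure -> character vector of selected genes.
#' @export
de_gene_sets <- function(de) {
  sel <- dplyr::filter(de, .data$selected)
  sets <- split(sel$gene_id, sel$substructure)
  lapply(sets, unique)
}
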