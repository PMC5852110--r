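#' Shortest-path semantic similarity between two GO terms
#'
#' The similarity between two terms is the reciprocal of the minimal number
#' of `is_a` edges (branches) separating them in the ontology graph, with
#' edges treated as undirected by default so that sibling terms are at
#' finite distance through their shared parent. By convention the
#' similarity of a term with itself is 1 (the supremum of the measure) and
#' the similarity of terms with no connecting path (e.g. different
#' namespaces) is 0.
#'
#' @param ontology A [go_ontology()].
#' @param a,b Term ids (alternate ids are resolved).
#' @param directed If `TRUE`, paths must follow `is_a` direction (one term
#'   an ancestor of the other); the default `FALSE` measures paths on the
#'   undirected view of the DAG.
#' @return Similarity in `[0, 1]`.
#' @export
#'
#' @examples
#' ont <- go_ontology(
#'   tibble::tibble(id = c("GO:1", "GO:2", "GO:3"),
#'                  name = c("a", "b", "c"),
#'                  namespace = "biological_process", obsolete = FALSE),
#'   tibble::tibble(child = c("GO:2", "GO:3"), parent = c("GO:1", "GO:2")))
#' semantic_similarity(ont, "GO:3", "GO:1")  # 2 edges apart -> 0.5
semantic_similarity <- function(ontology, a, b, directed = FALSE) {
  a <- resolve_term_ids(ontology, a)
  b <- resolve_term_ids(ontology, b)
  if (a == b) return(1)
  g <- ontology_igraph(ontology, directed = directed)
  d <- igraph::distances(g, v = a, to = b,
                         mode = if (directed) "out" else "all")[1, 1]
  if (directed) {
    d2 <- igraph::distances(g, v = b, to = a, mode = "out")[1, 1]
    d <- min(d, d2)
  }
  if (!is.finite(d)) 0 else 1 / d
}

#' All-pairs branch-distance matrix for a set of GO terms
#'
#' Shortest undirected `is_a` path lengths between every pair of the given
#' terms; the substrate for slim clustering. Pairs with no connecting path
#' receive a finite penalty distance so that hierarchical clustering stays
#' well defined.
#'
#' @param ontology A [go_ontology()].
#' @param ids Character vector of at least two term ids.
#' @param penalty Distance assigned to disconnected pairs; default is the
#'   graph diameter plus one.
#' @return A symmetric numeric matrix with zero diagonal, dimnames `ids`.
#' @export
semantic_distance_matrix <- function(ontology, ids, penalty = NULL) {
  stopifnot(length(ids) >= 2)
  ids <- resolve_term_ids(ontology, ids)
  g <- ontology_igraph(ontology, directed = FALSE)
  d <- igraph::distances(g, v = ids, to = ids, mode = "all")
  if (any(!is.finite(d))) {
    if (is.null(penalty)) {
      penalty <- igraph::diameter(g, directed = FALSE, unconnected = TRUE) + 1
    }
    d[!is.finite(d)] <- penalty
  }
  dimnames(d) <- list(ids, ids)
  d
}

#' Cluster GO terms into a-posteriori slims
#'
#' Agglomerative hierarchical clustering of the branch-distance matrix, cut
#' at a requested number of groups. This replaces the manual curation of
#' dendrogram clusters with a parameterised cut: the grouping that the
#' curated analysis produced by hand is approximated by choosing
#' `n_slims`. Term ids are canonically sorted before clustering so the
#' result does not depend on input order.
#'
#' @param dist Symmetric nonnegative distance matrix with term ids as
#'   dimnames (e.g. from [semantic_distance_matrix()]).
#' @param n_slims Number of slims to cut the dendrogram into; default 14.
#' @param linkage Agglomeration method passed to [stats::hclust()];
#'   default `"average"`.
#' @return A tibble with columns `go_id`, `slim` (labels `slim_01`, ...,
#'   numbered by first dendrogram appearance after canonical sorting), with
#'   attributes `linkage_method`, `n_slims` and `hclust` (the tree).
#' @export
cluster_slims <- function(dist, n_slims = 14, linkage = "average") {
  ids <- rownames(dist)
  stopifnot(!is.null(ids), isTRUE(all.equal(dist, t(dist))), all(dist >= 0))
  if (n_slims < 1 || n_slims > length(ids)) {
    stop("n_slims must be between 1 and the number of terms (", length(ids), ")")
  }
  ord <- order(ids)
  dist <- dist[ord, ord, drop = FALSE]
  ids <- ids[ord]
  if (n_slims == length(ids)) {
    labels <- seq_along(ids)
    tree <- NULL
  } else {
    tree <- hclust(as.dist(dist), method = linkage)
    labels <- cutree(tree, k = n_slims)
  }
  # relabel by order of first appearance over sorted ids, for stability
  labels <- match(labels, unique(labels))
  out <- tibble(go_id = ids,
                slim = sprintf("slim_%02d", labels))
  attr(out, "linkage_method") <- linkage
  attr(out, "n_slims") <- n_slims
  attr(out, "hclust") <- tree
  out
}

#' Write a slim assignment table
#'
#' @param slims Tibble from [cluster_slims()].
#' @param ontology Optional [go_ontology()] used to add term names.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_slims <- function(slims, path, ontology = NULL) {
  out <- slims
  if (!is.null(ontology)) {
    out <- dplyr::left_join(out,
                            dplyr::select(ontology$terms, go_id = "id",
                                          go_name = "name"),
                            by = "go_id")
    out <- dplyr::select(out, "go_id", "go_name", "slim")
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
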