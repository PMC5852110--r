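# Independent oracles and small fixture builders used across the suite.
# Everything here is deliberately brute-force and shares no code with the
# package's own computation paths.

# ---- ontology fixtures -------------------------------------------------

# chain: ids[k] is_a ids[k-1] is_a ... is_a ids[1]
chain_ontology <- function(ids = c("GO:0000001", "GO:0000002", "GO:0000003"),
                           namespace = "biological_process") {
  go_ontology(
    tibble::tibble(id = ids, name = paste0("term ", seq_along(ids)),
                   namespace = namespace, obsolete = FALSE),
    tibble::tibble(child = ids[-1], parent = ids[-length(ids)]))
}

# random connected-ish DAG over n terms: term i (>1) gets 1-2 parents among
# earlier terms, uniformly. Independent of the package's generator.
random_dag_ontology <- function(n, seed) {
  set.seed(seed)
  ids <- sprintf("GO:%07d", seq_len(n))
  edges <- list()
  for (i in 2:n) {
    np <- if (i > 2 && runif(1) < 0.3) 2 else 1
    par <- sample(ids[seq_len(i - 1)], np)
    edges[[i]] <- tibble::tibble(child = ids[i], parent = par)
  }
  go_ontology(
    tibble::tibble(id = ids, name = ids, namespace = "biological_process",
                   obsolete = FALSE),
    dplyr::bind_rows(edges))
}

# ---- graph oracles -----------------------------------------------------

# undirected adjacency matrix of an ontology's live terms
adjacency_oracle <- function(ontology) {
  ids <- ontology$terms$id[!ontology$terms$obsolete]
  a <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (r in seq_len(nrow(ontology$edges))) {
    c1 <- ontology$edges$child[r]; p1 <- ontology$edges$parent[r]
    a[c1, p1] <- a[p1, c1] <- 1
  }
  a
}

# Floyd-Warshall all-pairs shortest paths on the undirected view
floyd_warshall_oracle <- function(ontology) {
  a <- adjacency_oracle(ontology)
  n <- nrow(a)
  d <- matrix(Inf, n, n, dimnames = dimnames(a))
  diag(d) <- 0
  d[a == 1] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

# transitive ancestor closure by repeated squaring of the (directed)
# child->parent reachability matrix
reachability_oracle <- function(ontology) {
  ids <- ontology$terms$id[!ontology$terms$obsolete]
  a <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (r in seq_len(nrow(ontology$edges))) {
    a[ontology$edges$child[r], ontology$edges$parent[r]] <- 1
  }
  reach <- a
  repeat {
    nxt <- ((reach + reach %*% reach) > 0) * 1
    if (all(nxt == reach)) break
    reach <- nxt
  }
  reach  # reach[i, j] == 1 iff j is a strict ancestor of i
}

# ---- enrichment oracle -------------------------------------------------

# two-sided Fisher p by exhaustive enumeration: sum the hypergeometric
# probabilities of all tables (same margins) no more probable than observed
hypergeom_enum_oracle <- function(study_count, study_n, pop_count, pop_n) {
  ks <- max(0, study_n + pop_count - pop_n):min(study_n, pop_count)
  probs <- vapply(ks, function(k) {
    exp(lchoose(pop_count, k) + lchoose(pop_n - pop_count, study_n - k) -
          lchoose(pop_n, study_n))
  }, double(1))
  p_obs <- probs[ks == study_count]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# ---- misc --------------------------------------------------------------

# random non-empty subset of a pool (possibly empty when allow_empty)
random_set <- function(pool, allow_empty = FALSE) {
  n <- sample.int(length(pool), 1) - as.integer(allow_empty)
  if (n <= 0) character(0) else sample(pool, n)
}

pearson_formula_oracle <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# reduced-size synthetic configuration for fast tests
small_config <- function(seed = 20180308, ...) {
  synthetic_config(seed = seed, n_terms = 60, n_genes = 300,
                   n_substructures = 4, replicates_per_substructure = 3,
                   n_taxa = 5, n_planted = 3, n_signal_genes = 10,
                   n_branches = 4, ...)
}
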