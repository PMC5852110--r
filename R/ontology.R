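#' Gene Ontology graph objects
#'
#' A `go_ontology` holds the term table and the `is_a` edge list of a Gene
#' Ontology (or any OBO-format ontology restricted to `is_a` relations).
#' Only `[Term]` stanzas are consumed; `part_of`, `regulates` and other
#' relationship types are ignored so that the graph is the minimal "GO
#' topology" over which shortest-path semantic distances are measured.
#'
#' @param terms Tibble with columns `id`, `name`, `namespace`, `obsolete`.
#' @param edges Tibble with columns `child`, `parent` (both term ids);
#'   directed child-to-parent `is_a` pairs.
#' @param alt_ids Tibble with columns `alt_id`, `id` mapping secondary ids
#'   to their primary term.
#'
#' @return A `go_ontology` object (list with elements `terms`, `edges`,
#'   `alt_ids`).
#' @export
go_ontology <- function(terms, edges, alt_ids = NULL) {
  terms <- as_tibble(terms)
  edges <- as_tibble(edges)
  if (is.null(alt_ids)) alt_ids <- tibble(alt_id = character(), id = character())
  stopifnot(all(c("id", "name", "namespace", "obsolete") %in% names(terms)),
            all(c("child", "parent") %in% names(edges)))
  if (anyDuplicated(terms$id)) {
    stop("duplicate term ids: ",
         paste(unique(terms$id[duplicated(terms$id)]), collapse = ", "))
  }
  # obsolete terms are excluded from the graph entirely
  obs <- terms$id[terms$obsolete]
  edges <- dplyr::filter(edges, !.data$child %in% obs, !.data$parent %in% obs)
  unknown <- setdiff(c(edges$child, edges$parent), terms$id)
  if (length(unknown) > 0) {
    stop("edges reference unknown term ids: ", paste(unknown, collapse = ", "))
  }
  ont <- structure(list(terms = terms, edges = edges, alt_ids = as_tibble(alt_ids)),
                   class = "go_ontology")
  validate_acyclic(ont)
  ont
}

validate_acyclic <- function(ontology) {
  g <- ontology_igraph(ontology, directed = TRUE)
  if (!igraph::is_dag(g)) {
    cyc <- igraph::feedback_arc_set(g)
    ends <- igraph::ends(g, cyc[1])
    stop("ontology contains a cycle involving edge ",
         ends[1], " -> ", ends[2])
  }
  invisible(ontology)
}

#' @export
print.go_ontology <- function(x, ...) {
  cat("<go_ontology> ", nrow(x$terms), " terms (",
      sum(x$terms$obsolete), " obsolete), ", nrow(x$edges),
      " is_a edges, namespaces: ",
      paste(sort(unique(x$terms$namespace)), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# igraph view of the non-obsolete terms (vertices named by term id)
ontology_igraph <- function(ontology, directed = TRUE) {
  live <- ontology$terms$id[!ontology$terms$obsolete]
  igraph::graph_from_data_frame(
    ontology$edges[, c("child", "parent")],
    directed = directed,
    vertices = data.frame(name = live)
  )
}

#' Resolve term ids, mapping alternate ids to their primary id
#'
#' @param ontology A [go_ontology()].
#' @param ids Character vector of term ids (primary or `alt_id`).
#' @return Character vector of primary ids; unknown ids raise an error.
#' @export
resolve_term_ids <- function(ontology, ids) {
  alt <- setNames(ontology$alt_ids$id, ontology$alt_ids$alt_id)
  out <- ifelse(ids %in% names(alt), unname(alt[ids]), ids)
  unknown <- setdiff(out, ontology$terms$id)
  if (length(unknown) > 0) {
    stop("unknown term id(s): ", paste(unknown, collapse = ", "))
  }
  out
}

#' Parse an OBO 1.2/1.4 file into a `go_ontology`
#'
#' Consumes `[Term]` stanzas only; within a stanza the `id`, `name`,
#' `namespace`, `is_a`, `alt_id` and `is_obsolete` tags are read and all
#' other tags are ignored. Obsolete terms are kept in the term table,
#' flagged, and stripped of any edges.
#'
#' @param path Path to an OBO file.
#' @return A [go_ontology()].
#' @export
#'
#' @examples
#' obo <- tempfile(fileext = ".obo")
#' writeLines(c("[Term]", "id: GO:0000001", "name: root",
#'              "namespace: biological_process", "",
#'              "[Term]", "id: GO:0000002", "name: child",
#'              "namespace: biological_process", "is_a: GO:0000001 ! root"),
#'            obo)
#' parse_obo(obo)
parse_obo <- function(path) {
  stopifnot(file.exists(path))
  lines <- readr::read_lines(path)
  stanza_starts <- which(lines == "[Term]")
  other_starts <- which(stringr::str_detect(lines, "^\\[") & lines != "[Term]")
  bounds <- sort(c(stanza_starts, other_starts, length(lines) + 1L))

  terms <- list(); edges <- list(); alts <- list()
  for (s in stanza_starts) {
    end <- min(bounds[bounds > s]) - 1L
    block <- lines[s:end]
    tag <- function(name) {
      hit <- stringr::str_match(block, paste0("^", name, ":\\s*(.*?)\\s*$"))[, 2]
      hit[!is.na(hit)]
    }
    id <- tag("id")
    if (length(id) != 1) {
      stop("malformed [Term] stanza at line ", s,
           ": expected exactly one id, found ", length(id))
    }
    name <- tag("name")
    ns <- tag("namespace")
    obsolete <- any(tag("is_obsolete") == "true")
    isa_raw <- tag("is_a")
    parents <- stringr::str_trim(stringr::str_remove(isa_raw, "\\s*!.*$"))
    terms[[id]] <- tibble(
      id = id,
      name = if (length(name)) name[1] else id,
      namespace = if (length(ns)) ns[1] else NA_character_,
      obsolete = obsolete
    )
    if (!obsolete && length(parents) > 0) {
      edges[[id]] <- tibble(child = id, parent = parents)
    }
    alt <- tag("alt_id")
    if (length(alt) > 0) alts[[id]] <- tibble(alt_id = alt, id = id)
  }
  if (length(terms) == 0) stop("no [Term] stanzas found in ", path)
  terms <- dplyr::bind_rows(terms)
  edges <- if (length(edges)) dplyr::bind_rows(edges) else
    tibble(child = character(), parent = character())
  alts <- if (length(alts)) dplyr::bind_rows(alts) else NULL
  go_ontology(terms, edges, alts)
}

#' Write a `go_ontology` to an OBO 1.2 file
#'
#' Inverse of [parse_obo()] for the tag subset it consumes; parsing the
#' written file reproduces the ontology.
#'
#' @param ontology A [go_ontology()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(ontology, path) {
  parents <- split(ontology$edges$parent, ontology$edges$child)
  alts <- split(ontology$alt_ids$alt_id, ontology$alt_ids$id)
  out <- c("format-version: 1.2", "")
  for (i in seq_len(nrow(ontology$terms))) {
    tm <- ontology$terms[i, ]
    block <- c("[Term]",
               paste0("id: ", tm$id),
               paste0("name: ", tm$name),
               paste0("namespace: ", tm$namespace))
    for (a in alts[[tm$id]]) block <- c(block, paste0("alt_id: ", a))
    if (tm$obsolete) block <- c(block, "is_obsolete: true")
    for (p in sort(parents[[tm$id]])) block <- c(block, paste0("is_a: ", p))
    out <- c(out, block, "")
  }
  readr::write_lines(out, path)
  invisible(path)
}

# named list: term id -> character vector of strict is_a ancestors.
# Computed once per ontology by dynamic programming over a topological order.
term_ancestors <- function(ontology) {
  g <- ontology_igraph(ontology, directed = TRUE)
  # with child->parent edges, topo_sort(mode = "out") puts children before
  # parents; walk it reversed so each vertex sees its parents' ancestors
  ord <- igraph::topo_sort(g, mode = "out")$name
  parents <- split(ontology$edges$parent, ontology$edges$child)
  anc <- setNames(vector("list", length(ord)), ord)
  for (v in rev(ord)) {
    ps <- parents[[v]]
    if (is.null(ps)) {
      anc[[v]] <- character(0)
    } else {
      anc[[v]] <- unique(c(ps, unlist(anc[ps], use.names = FALSE)))
    }
  }
  anc
}
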