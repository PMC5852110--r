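#' Configuration of the synthetic taxa-to-brain study
#'
#' Bundles every knob of the synthetic-data generator. The defaults define
#' the reference study the test-suite exercises: a 300-term single-root
#' ontology, 2000 annotated genes, six substructures with four replicates,
#' ten taxa, and five planted (taxon, substructure, GO term) associations
#' of effect `log2FC = 3` carried by 20 dedicated signal genes each, with
#' negative-binomial counts (variance `mu + dispersion * mu^2`,
#' dispersion 0.05) and 10% off-target homology-hit noise.
#'
#' @param seed Integer seed; every generator derives its stream from it.
#' @param n_terms Number of ontology terms (including root and obsolete
#'   terms), at least 5.
#' @param n_branches Number of top-level branches under the root; planted
#'   terms are drawn from distinct branches so the planted associations are
#'   functionally separated modules.
#' @param n_genes Number of genes.
#' @param n_substructures,replicates_per_substructure Design of the count
#'   matrix.
#' @param n_taxa Number of taxa (genus labels `taxon_01`, ...).
#' @param n_planted,effect_log2fc,n_signal_genes Planted-association count,
#'   per-association log2 effect size and dedicated signal genes; used only
#'   when `planted_associations` is `NULL`.
#' @param planted_associations Optional tibble with columns `taxon`,
#'   `substructure`, `go_id`, `effect_log2fc`, `n_signal_genes` overriding
#'   the default planting.
#' @param nb_dispersion Negative-binomial dispersion of the counts.
#' @param baseline_mean Median of the log-normal per-gene baseline means.
#' @param library_size Optional target expected library size; `NULL` keeps
#'   the unscaled per-gene means (expected library about
#'   `n_genes * baseline_mean * exp(0.5)`). Library sizes are additionally
#'   jittered by +/-20% to exercise CPM normalisation.
#' @param annotation_mean_terms Mean number of direct terms per background
#'   gene (geometric, leaf-biased).
#' @param frac_silent Fraction of background genes rendered (near-)silent
#'   (baseline mean scaled by 1/1000), so the CPM filter has genuine work
#'   to do; signal genes are never silenced.
#' @param hit_noise Fraction of off-target homology hits.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 20180308,
                             n_terms = 300, n_branches = 6,
                             n_genes = 2000,
                             n_substructures = 6,
                             replicates_per_substructure = 4,
                             n_taxa = 10,
                             n_planted = 5,
                             effect_log2fc = 3,
                             n_signal_genes = 20,
                             planted_associations = NULL,
                             nb_dispersion = 0.05,
                             baseline_mean = 100,
                             library_size = NULL,
                             annotation_mean_terms = 3,
                             frac_silent = 0.05,
                             hit_noise = 0.1) {
  cfg <- list(seed = as.integer(seed), n_terms = n_terms,
              n_branches = n_branches, n_genes = n_genes,
              n_substructures = n_substructures,
              replicates_per_substructure = replicates_per_substructure,
              n_taxa = n_taxa, n_planted = n_planted,
              effect_log2fc = effect_log2fc,
              n_signal_genes = n_signal_genes,
              planted_associations = planted_associations,
              nb_dispersion = nb_dispersion,
              baseline_mean = baseline_mean, library_size = library_size,
              annotation_mean_terms = annotation_mean_terms,
              frac_silent = frac_silent,
              hit_noise = hit_noise)
  with(cfg, stopifnot(
    n_terms >= 5, n_genes > 0, n_substructures > 0,
    replicates_per_substructure >= 2, n_taxa > 0,
    effect_log2fc >= 0, nb_dispersion > 0, baseline_mean > 0,
    frac_silent >= 0, frac_silent < 1,
    hit_noise >= 0, hit_noise <= 1))
  structure(cfg, class = "synthetic_config")
}

#' Generate a synthetic rooted ontology
#'
#' Grows an acyclic single-root (per namespace) DAG: a fixed number of
#' top-level branches hang from the root and every later term attaches
#' with one or two `is_a` parents chosen inside one branch, biased toward
#' recently added terms so branches deepen (depth at least 3 for 20+
#' terms). Keeping multi-parent links within a branch means terms of
#' different branches share only the root as common ancestor — planted
#' terms drawn from distinct branches are functionally disjoint modules.
#' A small tail of obsolete terms and a couple of `alt_id`s are included
#' to exercise the parser.
#'
#' @param cfg A [synthetic_config()].
#' @return A [go_ontology()] with attribute `branches` (tibble `id`,
#'   `branch` for live non-root terms).
#' @export
gen_ontology <- function(cfg) {
  set.seed(cfg$seed)
  n <- cfg$n_terms
  n_obs <- if (n >= 100) floor(n / 100) else 0L
  n_live <- n - n_obs
  nb <- max(1L, min(cfg$n_branches, (n_live - 1L) %/% 3L))
  ids <- sprintf("GO:%07d", seq_len(n))
  root <- ids[1]
  heads <- ids[1 + seq_len(nb)]
  edges <- tibble(child = heads, parent = root)
  branch_of <- setNames(seq_len(nb), heads)
  members <- as.list(heads)  # per-branch term ids, in creation order

  rest <- if (n_live > nb + 1) ids[(nb + 2):n_live] else character(0)
  # seed each branch with a 2-chain so every branch reaches depth >= 3
  chain_needed <- rep(seq_len(nb), 2)
  for (i in seq_along(rest)) {
    id <- rest[i]
    if (i <= length(chain_needed)) {
      b <- chain_needed[i]
      par <- members[[b]][length(members[[b]])]
      edges <- dplyr::bind_rows(edges, tibble(child = id, parent = par))
    } else {
      b <- sample.int(nb, 1)
      pool <- members[[b]]
      w <- seq_along(pool)  # recency bias -> deeper branches
      np <- if (length(pool) >= 2 && runif(1) < 0.25) 2L else 1L
      par <- sample(pool, np, prob = w)
      edges <- dplyr::bind_rows(edges, tibble(child = id, parent = par))
    }
    branch_of[id] <- b
    members[[b]] <- c(members[[b]], id)
  }

  obsolete <- c(rep(FALSE, n_live), rep(TRUE, n_obs))
  terms <- tibble(
    id = ids,
    name = c("biological process root",
             sprintf("synthetic process %03d", seq_len(n - 1))),
    namespace = "biological_process",
    obsolete = obsolete)
  alt_ids <- tibble(alt_id = sprintf("GO:%07d", 9000001:9000002),
                    id = heads[c(1, min(2, nb))])
  ont <- go_ontology(terms, edges, alt_ids)
  attr(ont, "branches") <- tibble(id = names(branch_of),
                                  branch = unname(branch_of))
  ont
}

# default planting: one leaf per distinct branch, taxa/substructures cycled
plant_associations <- function(cfg, ontology) {
  if (!is.null(cfg$planted_associations)) {
    return(as_tibble(cfg$planted_associations))
  }
  branches <- attr(ontology, "branches")
  if (is.null(branches)) stop("ontology carries no branch map; supply planted_associations")
  nb <- max(branches$branch)
  if (cfg$n_planted > nb) {
    stop("n_planted (", cfg$n_planted, ") exceeds branch count (", nb, ")")
  }
  has_child <- unique(ontology$edges$parent)
  leaves <- branches[!branches$id %in% has_child, ]
  # deepest leaf of each branch, lexicographic tie-break
  depth <- term_depths(ontology)
  leaves$depth <- depth[leaves$id]
  picks <- leaves %>%
    dplyr::arrange(.data$branch, dplyr::desc(.data$depth), .data$id) %>%
    dplyr::distinct(.data$branch, .keep_all = TRUE) %>%
    head(cfg$n_planted)
  tibble(
    taxon = sprintf("taxon_%02d", seq_len(cfg$n_planted)),
    substructure = sprintf("sub_%d",
                           ((seq_len(cfg$n_planted) - 1) %% cfg$n_substructures) + 1),
    go_id = picks$id,
    effect_log2fc = cfg$effect_log2fc,
    n_signal_genes = cfg$n_signal_genes)
}

# depth (shortest is_a path from the root) of every live term
term_depths <- function(ontology) {
  g <- ontology_igraph(ontology, directed = TRUE)
  roots <- setdiff(ontology$terms$id[!ontology$terms$obsolete],
                   ontology$edges$child)
  d <- igraph::distances(g, to = roots, mode = "out")
  apply(d, 1, min)
}

#' Generate synthetic gene-to-GO annotations with planted signal genes
#'
#' Every planted association receives `n_signal_genes` dedicated genes
#' annotated directly to the planted term (plus two background terms
#' each); the remaining genes draw a geometric number of terms (mean
#' `annotation_mean_terms`) biased toward leaves and deep terms, which
#' yields heavy-tailed propagated term sizes.
#'
#' @param cfg A [synthetic_config()].
#' @param ontology Output of [gen_ontology()].
#' @return A `go_annotations` object with attributes `planted` (tibble
#'   including a `signal_genes` list-column) and `genes` (all gene ids).
#' @export
gen_annotations <- function(cfg, ontology) {
  set.seed(cfg$seed + 1L)
  planted <- plant_associations(cfg, ontology)
  bad <- setdiff(planted$go_id,
                 ontology$terms$id[!ontology$terms$obsolete])
  if (length(bad)) stop("planted term(s) not in ontology: ",
                        paste(bad, collapse = ", "))
  genes <- sprintf("gene_%04d", seq_len(cfg$n_genes))
  n_sig_total <- sum(planted$n_signal_genes)
  if (n_sig_total > cfg$n_genes) stop("more signal genes than genes")
  planted$signal_genes <- split(
    genes[seq_len(n_sig_total)],
    rep(seq_len(nrow(planted)), planted$n_signal_genes))

  depth <- term_depths(ontology)
  live <- names(depth)
  root <- live[depth == 0]
  candidates <- setdiff(live, root)
  is_leaf <- !(candidates %in% ontology$edges$parent)
  w <- (1 + depth[candidates]) * ifelse(is_leaf, 3, 1)

  draw_terms <- function(k, exclude = character(0)) {
    pool <- setdiff(candidates, exclude)
    sample(pool, min(k, length(pool)), prob = w[match(pool, candidates)])
  }
  direct <- vector("list", cfg$n_genes)
  sig_term <- setNames(rep(NA_character_, cfg$n_genes), genes)
  for (i in seq_len(nrow(planted))) {
    sig_term[planted$signal_genes[[i]]] <- planted$go_id[i]
  }
  p_geom <- 1 / cfg$annotation_mean_terms
  for (i in seq_len(cfg$n_genes)) {
    g <- genes[i]
    if (!is.na(sig_term[g])) {
      direct[[i]] <- tibble(gene_id = g,
                            go_id = c(sig_term[g],
                                      draw_terms(2, exclude = planted$go_id)))
    } else {
      k <- 1 + stats::rgeom(1, p_geom)
      direct[[i]] <- tibble(gene_id = g, go_id = draw_terms(k))
    }
  }
  ann <- propagate_annotations(ontology, dplyr::bind_rows(direct))
  attr(ann, "planted") <- planted
  attr(ann, "genes") <- genes
  ann
}

#' Generate a synthetic brain count matrix with planted expression effects
#'
#' Counts are negative-binomial with per-gene log-normal baseline means,
#' per-sample library factors jittered uniformly by +/-20%, and the signal
#' genes of every planted association multiplied by `2^effect_log2fc` in
#' the replicates of the planted substructure.
#'
#' @param cfg A [synthetic_config()].
#' @param annotations Output of [gen_annotations()] (carries the planting).
#' @return List with `counts` (tibble, first column `gene_id`) and
#'   `samples` (tibble `sample_id`, `substructure`, `replicate`).
#' @export
gen_counts <- function(cfg, annotations) {
  set.seed(cfg$seed + 2L)
  planted <- attr(annotations, "planted")
  genes <- attr(annotations, "genes") %||% sort(unique(annotations$direct$gene_id))
  ng <- length(genes)
  samples <- tidyr::expand_grid(
    substructure = sprintf("sub_%d", seq_len(cfg$n_substructures)),
    replicate = seq_len(cfg$replicates_per_substructure)) %>%
    dplyr::mutate(sample_id = sprintf("%s_r%d", .data$substructure,
                                      .data$replicate)) %>%
    dplyr::select("sample_id", "substructure", "replicate")

  lambda <- rlnorm(ng, meanlog = log(cfg$baseline_mean), sdlog = 1)
  signal <- if (is.null(planted)) character(0) else
    unlist(planted$signal_genes, use.names = FALSE)
  n_silent <- floor(cfg$frac_silent * ng)
  if (n_silent > 0) {
    silent <- sample(setdiff(genes, signal), min(n_silent, ng - length(signal)))
    lambda[match(silent, genes)] <- lambda[match(silent, genes)] / 1000
  }
  if (!is.null(cfg$library_size)) {
    lambda <- lambda * cfg$library_size / sum(lambda)
  }
  u <- runif(nrow(samples), 0.8, 1.2)
  mu <- outer(lambda, u)
  if (!is.null(planted) && nrow(planted) > 0) {
    for (i in seq_len(nrow(planted))) {
      gi <- match(planted$signal_genes[[i]], genes)
      si <- which(samples$substructure == planted$substructure[i])
      mu[gi, si] <- mu[gi, si] * 2^planted$effect_log2fc[i]
    }
  }
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / cfg$nb_dispersion),
                   nrow = ng,
                   dimnames = list(genes, samples$sample_id))
  list(counts = dplyr::bind_cols(tibble(gene_id = genes), as_tibble(counts)),
       samples = samples)
}

#' Generate synthetic per-taxon homology hit tables
#'
#' Every planted (taxon, term) pair contributes one confident hit
#' (e-value well below 0.05) per signal gene. All taxa additionally
#' receive off-target noise hits to random genes (the `hit_noise`
#' fraction) and a few rows with e-values just above 0.05 that exercise
#' the threshold. An accession-to-gene map is emitted alongside; subject
#' accessions carry a `.1` version suffix.
#'
#' @param cfg A [synthetic_config()].
#' @param annotations Output of [gen_annotations()].
#' @return List with `hits` (named list taxon -> outfmt-6-shaped tibble)
#'   and `accession_map` (tibble `accession`, `gene_id`).
#' @export
gen_hits <- function(cfg, annotations) {
  set.seed(cfg$seed + 3L)
  planted <- attr(annotations, "planted")
  genes <- attr(annotations, "genes") %||% sort(unique(annotations$direct$gene_id))
  accession_map <- tibble(accession = sprintf("NP_%06d", seq_along(genes)),
                          gene_id = genes)
  acc_of <- setNames(accession_map$accession, genes)
  taxa <- sprintf("taxon_%02d", seq_len(cfg$n_taxa))

  make_rows <- function(taxon, target_genes, evalues, q_offset) {
    n <- length(target_genes)
    if (n == 0) return(NULL)
    tibble(taxon = taxon,
           qseqid = sprintf("%s_meta_%04d", taxon, q_offset + seq_len(n)),
           sseqid = paste0(acc_of[target_genes], ".1"),
           pident = round(runif(n, 35, 95), 2),
           length = sample(80:400, n, replace = TRUE),
           mismatch = sample(0:50, n, replace = TRUE),
           gapopen = sample(0:5, n, replace = TRUE),
           qstart = sample(1:50, n, replace = TRUE),
           qend = sample(100:400, n, replace = TRUE),
           sstart = sample(1:50, n, replace = TRUE),
           send = sample(100:400, n, replace = TRUE),
           evalue = evalues,
           bitscore = round(runif(n, 50, 300), 1))
  }

  hits <- lapply(taxa, function(tx) {
    rows <- list()
    mine <- planted[planted$taxon == tx, , drop = FALSE]
    n_signal <- 0L
    if (nrow(mine) > 0) {
      sig <- unlist(mine$signal_genes, use.names = FALSE)
      n_signal <- length(sig)
      rows$signal <- make_rows(tx, sig, 10^runif(n_signal, -30, -4), 0L)
    }
    n_noise <- if (cfg$hit_noise == 0) 0L else {
      max(3L, round(cfg$hit_noise * max(n_signal, cfg$n_signal_genes)))
    }
    noise_genes <- sample(genes, n_noise)
    rows$noise <- make_rows(tx, noise_genes, 10^runif(n_noise, -6, -2),
                            n_signal)
    n_above <- max(2L, round(0.1 * (n_signal + n_noise)))
    above_genes <- sample(genes, n_above)
    rows$above <- make_rows(tx, above_genes, runif(n_above, 0.051, 0.5),
                            n_signal + n_noise)
    dplyr::bind_rows(rows)
  })
  names(hits) <- taxa
  list(hits = hits, accession_map = accession_map)
}

#' Generate the full synthetic study
#'
#' Runs [gen_ontology()], [gen_annotations()], [gen_counts()] and
#' [gen_hits()] for one configuration and bundles the results with the
#' planted truth. Identical configurations (including the seed) produce
#' identical studies.
#'
#' @param cfg A [synthetic_config()].
#' @return A `t2bs_study` list: `config`, `ontology`, `annotations`,
#'   `counts`, `samples`, `hits`, `accession_map`, `planted`.
#' @export
simulate_t2bs_study <- function(cfg = synthetic_config()) {
  ontology <- gen_ontology(cfg)
  annotations <- gen_annotations(cfg, ontology)
  cs <- gen_counts(cfg, annotations)
  hm <- gen_hits(cfg, annotations)
  structure(list(config = cfg,
                 ontology = ontology,
                 annotations = annotations,
                 counts = cs$counts,
                 samples = cs$samples,
                 hits = hm$hits,
                 accession_map = hm$accession_map,
                 planted = attr(annotations, "planted")),
            class = "t2bs_study")
}

#' @export
print.t2bs_study <- function(x, ...) {
  cat("<t2bs_study> ", nrow(x$counts), " genes x ", nrow(x$samples),
      " samples, ", length(x$hits), " taxa, ", nrow(x$planted),
      " planted associations (seed ", x$config$seed, ")\n", sep = "")
  invisible(x)
}

#' Write every synthetic input to disk in its standard text format
#'
#' OBO ontology, id2gos annotation TSV, counts TSV, sample metadata CSV,
#' per-taxon outfmt-6 hit tables, accession map TSV and a JSON manifest of
#' the planted truth. Output is byte-deterministic for a given study.
#'
#' @param study Output of [simulate_t2bs_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_inputs <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "hits"), showWarnings = FALSE)
  write_obo(study$ontology, file.path(dir, "ontology.obo"))
  write_annotations(study$annotations, file.path(dir, "annotations.tsv"))
  readr::write_tsv(study$counts, file.path(dir, "counts.tsv"), progress = FALSE)
  readr::write_csv(study$samples, file.path(dir, "samples.csv"), progress = FALSE)
  readr::write_tsv(study$accession_map, file.path(dir, "accession_map.tsv"),
                   progress = FALSE)
  for (tx in names(study$hits)) {
    readr::write_tsv(study$hits[[tx]][, outfmt6_cols],
                     file.path(dir, "hits", paste0(tx, ".tsv")),
                     col_names = FALSE, progress = FALSE)
  }
  manifest <- list(
    seed = study$config$seed,
    n_terms = study$config$n_terms,
    n_genes = study$config$n_genes,
    planted = lapply(seq_len(nrow(study$planted)), function(i) {
      p <- study$planted[i, ]
      list(taxon = p$taxon, substructure = p$substructure, go_id = p$go_id,
           effect_log2fc = p$effect_log2fc,
           signal_genes = p$signal_genes[[1]])
    }))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
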