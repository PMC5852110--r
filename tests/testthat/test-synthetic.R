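test_that("generated ontologies are rooted, acyclic, deep and deterministic", {
  tiny <- gen_ontology(synthetic_config(seed = 1, n_terms = 5))
  expect_equal(nrow(tiny$terms), 5)
  live <- tiny$terms$id[!tiny$terms$obsolete]
  roots <- setdiff(live, tiny$edges$child)
  expect_equal(length(roots), 1)

  cfg <- synthetic_config(seed = 2, n_terms = 80)
  ont <- gen_ontology(cfg)
  # acyclicity is enforced by the constructor; depth >= 3 for 20+ terms
  g <- igraph::graph_from_data_frame(ont$edges)
  expect_true(igraph::is_dag(g))
  depths <- igraph::distances(
    g, v = setdiff(ont$terms$id[!ont$terms$obsolete], ont$edges$child),
    mode = "in")
  expect_gte(max(depths[is.finite(depths)]), 3)

  again <- gen_ontology(synthetic_config(seed = 2, n_terms = 80))
  expect_equal(ont$terms, again$terms)
  expect_equal(ont$edges, again$edges)
})

test_that("planted terms come from distinct branches sharing only the root", {
  cfg <- synthetic_config(seed = 3)
  ont <- gen_ontology(cfg)
  ann <- gen_annotations(cfg, ont)
  planted <- attr(ann, "planted")
  expect_equal(nrow(planted), cfg$n_planted)
  anc <- t2bsgo:::term_ancestors(ont)
  root <- setdiff(ont$terms$id[!ont$terms$obsolete], ont$edges$child)
  combos <- utils::combn(planted$go_id, 2)
  for (i in seq_len(ncol(combos))) {
    shared <- intersect(anc[[combos[1, i]]], anc[[combos[2, i]]])
    expect_equal(shared, root)
  }
})

test_that("annotations cover every gene and plant countable signal genes", {
  cfg <- small_config(seed = 4)
  ont <- gen_ontology(cfg)
  ann <- gen_annotations(cfg, ont)
  genes <- attr(ann, "genes")
  expect_setequal(unique(ann$direct$gene_id), genes)

  planted <- attr(ann, "planted")
  for (i in seq_len(nrow(planted))) {
    carriers <- ann$direct$gene_id[ann$direct$go_id == planted$go_id[i]]
    sig <- planted$signal_genes[[i]]
    expect_equal(length(sig), planted$n_signal_genes[i])
    expect_true(all(sig %in% carriers))
    # non-signal carriers are background draws; count them by brute force
    expect_equal(sum(carriers %in% sig), length(sig))
  }

  ann2 <- gen_annotations(cfg, ont)
  expect_equal(ann$direct, ann2$direct)
})

test_that("counts are nonnegative integers with the planted effect visible", {
  cfg <- small_config(seed = 5)
  st <- simulate_t2bs_study(cfg)
  m <- as.matrix(st$counts[, -1])
  expect_true(all(m >= 0))
  expect_true(all(m == round(m)))

  # empirical log2FC of planted genes near the planted effect (mean over
  # several seeds stays within +/-1 of 3.0)
  lfcs <- unlist(lapply(c(11, 12, 13, 14, 15), function(seed) {
    stx <- simulate_t2bs_study(small_config(seed = seed))
    mx <- as.matrix(stx$counts[, -1])
    rownames(mx) <- stx$counts$gene_id
    cpm <- sweep(mx, 2, colSums(mx), "/") * 1e6
    sapply(seq_len(nrow(stx$planted)), function(i) {
      p <- stx$planted[i, ]
      insub <- stx$samples$substructure == p$substructure
      sig <- p$signal_genes[[1]]
      log2(rowMeans(cpm[sig, insub, drop = FALSE]) /
             rowMeans(cpm[sig, !insub, drop = FALSE]))
    })
  }))
  expect_lt(abs(mean(lfcs) - 3), 1)
})

test_that("null configuration plants nothing and triggers few selections", {
  cfg <- synthetic_config(seed = 6, n_planted = 0, n_genes = 400,
                          n_terms = 50)
  st <- simulate_t2bs_study(cfg)
  expect_equal(nrow(st$planted), 0)
  filt <- filter_genes(st$counts, st$samples, annotated = st$counts$gene_id)
  de <- de_test(fit_nbql(filt, st$samples))
  expect_lte(sum(de$p_adj <= 0.05), 2)
})

test_that("hit tables isolate planted genes when noise is off", {
  cfg <- small_config(seed = 7, hit_noise = 0)
  ont <- gen_ontology(cfg)
  ann <- gen_annotations(cfg, ont)
  hm <- gen_hits(cfg, ann)
  planted <- attr(ann, "planted")
  tx <- planted$taxon[1]
  gs <- hits_to_gene_set(hm$hits[[tx]], hm$accession_map)
  sig <- sort(unname(unlist(planted$signal_genes[planted$taxon == tx])))
  # with no off-target noise the post-threshold set is exactly the signal
  expect_equal(gs$gene_id, sig)

  # rows above the e-value threshold exist and are excluded
  expect_true(any(hm$hits[[tx]]$evalue > 0.05))
  expect_true(all(gs$gene_id %in%
                    hm$accession_map$gene_id[
                      match(sub("\\.\\d+$", "",
                                hm$hits[[tx]]$sseqid[hm$hits[[tx]]$evalue <= 0.05]),
                            hm$accession_map$accession)]))
})

test_that("identical configurations write byte-identical input files", {
  cfg <- small_config(seed = 8)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_synthetic_inputs(simulate_t2bs_study(cfg), d1)
  write_synthetic_inputs(simulate_t2bs_study(cfg), d2)
  f1 <- list.files(d1, recursive = TRUE)
  f2 <- list.files(d2, recursive = TRUE)
  expect_equal(f1, f2)
  for (f in f1) {
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))),
                 label = f)
  }
})

test_that("written inputs parse back into an equivalent study", {
  cfg <- small_config(seed = 9)
  st <- simulate_t2bs_study(cfg)
  dir <- withr::local_tempdir()
  write_synthetic_inputs(st, dir)
  ont <- parse_obo(file.path(dir, "ontology.obo"))
  expect_equal(ont$terms, st$ontology$terms)
  ann <- read_annotations(file.path(dir, "annotations.tsv"))
  expect_equal(dplyr::arrange(ann, gene_id, go_id),
               dplyr::arrange(st$annotations$direct, gene_id, go_id))
  study <- read_count_study(file.path(dir, "counts.tsv"),
                            file.path(dir, "samples.csv"))
  expect_equal(study$counts, st$counts, ignore_attr = TRUE)
  amap <- read_accession_map(file.path(dir, "accession_map.tsv"))
  expect_equal(amap, st$accession_map, ignore_attr = TRUE)
})
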