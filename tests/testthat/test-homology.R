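write_hits <- function(rows, path) {
  readr::write_tsv(rows, path, col_names = FALSE, progress = FALSE)
  path
}

hit_row <- function(q, s, e, bits = 100) {
  tibble::tibble(qseqid = q, sseqid = s, pident = 90, length = 100,
                 mismatch = 5, gapopen = 0, qstart = 1, qend = 100,
                 sstart = 1, send = 100, evalue = e, bitscore = bits)
}

test_that("outfmt-6 parsing: empty files, typed fields, malformed rows", {
  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(0), empty)
  t0 <- read_hit_table(empty, "Escherichia")
  expect_equal(nrow(t0), 0)

  path <- withr::local_tempfile(fileext = ".tsv")
  write_hits(dplyr::bind_rows(hit_row("q1", "NP_1.1", 1e-10),
                              hit_row("q2", "NP_2.1", 0.04),
                              hit_row("q2", "NP_3.1", 0.2)), path)
  t3 <- read_hit_table(path, "Escherichia")
  expect_equal(nrow(t3), 3)
  expect_type(t3$evalue, "double")
  expect_type(t3$bitscore, "double")
  expect_equal(attr(t3, "n_metaproteins"), 2)

  # > 10% malformed rows is a hard error
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(readr::format_tsv(hit_row("q1", "NP_1.1", 1e-5),
                                 col_names = FALSE),
               "only\tthree\tcols"), bad)
  expect_error(read_hit_table(bad, "Escherichia"), "malformed")
})

test_that("iteration sentinels select the last PSI-BLAST block", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# Iteration: 1",
               readr::format_tsv(hit_row("q1", "NP_1.1", 1e-5),
                                 col_names = FALSE),
               "# Iteration: 2",
               readr::format_tsv(hit_row("q2", "NP_2.1", 1e-6),
                                 col_names = FALSE)), path)
  last <- read_hit_table(path, "Bacillus", split_iterations = TRUE)
  expect_equal(last$qseqid, "q2")
  both <- read_hit_table(path, "Bacillus")
  expect_equal(nrow(both), 2)  # comments skipped, all rows kept
})

test_that("gene-set resolution: threshold boundary, dedup, version stripping", {
  mapping <- tibble::tibble(accession = c("NP_1", "NP_2", "NP_3"),
                            gene_id = c("gA", "gA", "gB"))
  hits <- dplyr::bind_cols(
    tibble::tibble(taxon = rep("Escherichia", 4)),
    dplyr::bind_rows(hit_row("q1", "NP_1.1", 0.05),   # kept: inclusive <=
                     hit_row("q2", "NP_2.2", 0.001),  # same gene -> dedup
                     hit_row("q3", "NP_3.1", 0.06),   # excluded
                     hit_row("q4", "NP_9.1", 0.001))) # unmapped
  gs <- hits_to_gene_set(hits, mapping)
  expect_equal(gs$gene_id, "gA")
  expect_equal(attr(gs, "unmapped"), "NP_9")
  expect_equal(attr(gs, "n_hits"), 3)
})

test_that("gene-set resolution matches a brute-force oracle and is stable", {
  set.seed(20)
  accs <- sprintf("NP_%03d", 1:40)
  mapping <- tibble::tibble(accession = accs,
                            gene_id = sprintf("g%02d", sample(1:25, 40,
                                                              replace = TRUE)))
  rows <- dplyr::bind_cols(
    tibble::tibble(taxon = rep("Prevotella", 100)),
    dplyr::bind_rows(lapply(1:100, function(i) {
      hit_row(sprintf("q%03d", sample(1:50, 1)),
              paste0(sample(c(accs, "NP_999"), 1), ".1"),
              10^runif(1, -8, 0.3))
    })))
  gs <- hits_to_gene_set(rows, mapping)
  # oracle: filter, map, dedup by hand
  kept <- rows[rows$evalue <= 0.05, ]
  acc <- sub("\\.\\d+$", "", kept$sseqid)
  expected <- sort(unique(mapping$gene_id[match(acc, mapping$accession)]))
  expected <- expected[!is.na(expected)]
  expect_equal(gs$gene_id, expected)

  # row order invariance
  gs2 <- hits_to_gene_set(rows[sample(nrow(rows)), ], mapping)
  expect_equal(gs2$gene_id, gs$gene_id)

  # monotonicity: a looser threshold never shrinks the set
  for (thr in c(0.001, 0.01, 0.05, 0.5)) {
    lo <- hits_to_gene_set(rows, mapping, e_threshold = thr)$gene_id
    hi <- hits_to_gene_set(rows, mapping, e_threshold = thr * 2)$gene_id
    expect_true(all(lo %in% hi))
  }
})

test_that("genus merge dedups queries and commutes with gene mapping", {
  sp1 <- dplyr::bind_cols(tibble::tibble(taxon = rep("Lactobacillus", 2)),
                          dplyr::bind_rows(hit_row("q1", "NP_1.1", 1e-4),
                                           hit_row("q2", "NP_2.1", 1e-4)))
  sp2 <- dplyr::bind_cols(tibble::tibble(taxon = rep("Lactobacillus", 2)),
                          dplyr::bind_rows(hit_row("q3", "NP_3.1", 1e-4),
                                           hit_row("q4", "NP_1.1", 1e-4)))
  merged <- merge_taxa_at_genus(list(sp1, sp2))
  expect_equal(names(merged), "Lactobacillus")
  expect_equal(attr(merged$Lactobacillus, "n_metaproteins"), 4)

  dup <- merge_taxa_at_genus(list(sp1, sp1))
  expect_equal(attr(dup$Lactobacillus, "n_metaproteins"), 2)
  expect_equal(nrow(dup$Lactobacillus), 2)

  mapping <- tibble::tibble(accession = c("NP_1", "NP_2", "NP_3"),
                            gene_id = c("gA", "gB", "gC"))
  merged_set <- hits_to_gene_set(merged$Lactobacillus, mapping)$gene_id
  split_sets <- union(hits_to_gene_set(sp1, mapping)$gene_id,
                      hits_to_gene_set(sp2, mapping)$gene_id)
  expect_setequal(merged_set, split_sets)

  expect_error(merge_taxa_at_genus(list(sp1), genus = ""), "genus")
})

test_that("generated hit tables round-trip through the parser", {
  cfg <- small_config(seed = 77)
  st <- simulate_t2bs_study(cfg)
  dir <- withr::local_tempdir()
  write_synthetic_inputs(st, dir)
  for (tx in names(st$hits)) {
    back <- read_hit_table(file.path(dir, "hits", paste0(tx, ".tsv")), tx)
    expect_equal(attr(back, "n_malformed"), 0)
    expect_equal(nrow(back), nrow(st$hits[[tx]]))
    expect_equal(back$evalue, st$hits[[tx]]$evalue, tolerance = 1e-12)
  }
})
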