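test_that("Sorensen-Dice follows its closed form", {
  expect_equal(sorensen_dice(c("a", "b"), c("a", "b")), 1)
  expect_equal(sorensen_dice(c("a"), c("b")), 0)
  expect_equal(sorensen_dice(character(0), character(0)), 0)
  expect_equal(sorensen_dice(c("a", "b", "c"), c("b", "c", "d")), 2 * 2 / 6)
  # symmetric; 1 only for identical non-empty sets
  set.seed(60)
  pool <- letters
  for (i in 1:100) {
    a <- random_set(pool, allow_empty = TRUE)
    b <- random_set(pool, allow_empty = TRUE)
    sab <- sorensen_dice(a, b)
    expect_equal(sab, sorensen_dice(b, a))
    expect_true(sab >= 0 && sab <= 1)
    if (sab == 1) expect_setequal(a, b)
    # oracle: direct formula on deduplicated sets
    expect_equal(sab, {
      au <- unique(a); bu <- unique(b)
      if (length(au) + length(bu) == 0) 0 else
        2 * sum(au %in% bu) / (length(au) + length(bu))
    })
  }
})

test_that("SD matrices match per-pair brute force and stay in [0, 1]", {
  expect_equal(sd_matrix(list(t1 = "x"), list(s1 = "x"))$matrix,
               matrix(1, 1, 1, dimnames = list("t1", "s1")))
  set.seed(61)
  pool <- sprintf("GO:%04d", 1:30)
  taxa <- setNames(lapply(1:5, function(i) random_set(pool, TRUE)),
                   sprintf("t%d", 1:5))
  subs <- setNames(lapply(1:4, function(i) random_set(pool, TRUE)),
                   sprintf("s%d", 1:4))
  m <- sd_matrix(taxa, subs)$matrix
  expect_true(all(m >= 0 & m <= 1))
  for (t in names(taxa)) {
    for (s in names(subs)) {
      a <- unique(taxa[[t]]); b <- unique(subs[[s]])
      expect_equal(m[t, s], if (length(a) + length(b) == 0) 0 else
        2 * length(intersect(a, b)) / (length(a) + length(b)))
    }
  }
  long <- tidy(sd_matrix(taxa, subs))
  expect_equal(nrow(long), 20)
})

test_that("common GOs are the pairwise intersections of significant sets", {
  tx <- tibble::tibble(taxon = c("t1", "t1"), go_id = c("G1", "G2"))
  sb <- tibble::tibble(substructure = c("s1", "s1"), go_id = c("G2", "G3"))
  ann <- tibble::tibble(gene_id = c("a", "b", "c"),
                        go_id = c("G2", "G2", "G3"))
  rec <- common_gos(tx, sb, ann, taxon_genes = list(t1 = c("a")),
                    substructure_genes = list(s1 = c("b")),
                    propagate = FALSE)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$go_id, "G2")
  expect_equal(rec$genes[[1]], "b")
  expect_equal(rec$taxon_genes[[1]], "a")
  expect_false(rec$empty_support)

  disjoint <- common_gos(tx, dplyr::mutate(sb, go_id = c("G8", "G9")),
                         ann, list(t1 = "a"), list(s1 = "b"),
                         propagate = FALSE)
  expect_equal(nrow(disjoint), 0)
})

test_that("a term shared by 3 taxa and 2 substructures yields all 6 records", {
  tx <- tibble::tibble(taxon = rep(c("t1", "t2", "t3"), each = 1),
                       go_id = "G0")
  sb <- tibble::tibble(substructure = c("s1", "s2"), go_id = "G0")
  ann <- tibble::tibble(gene_id = sprintf("g%d", 1:4), go_id = "G0")
  rec <- common_gos(tx, sb, ann,
                    taxon_genes = list(t1 = "g1", t2 = "g2", t3 = "g3"),
                    substructure_genes = list(s1 = c("g1", "g4"), s2 = "g2"),
                    propagate = FALSE)
  expect_equal(nrow(rec), 6)
  # brute-force double loop over the two significant collections
  expected <- 0
  for (t in unique(tx$taxon)) {
    for (s in unique(sb$substructure)) {
      expected <- expected +
        length(intersect(tx$go_id[tx$taxon == t], sb$go_id[sb$substructure == s]))
    }
  }
  expect_equal(nrow(rec), expected)
})

test_that("record count equals summed pairwise intersections on random input", {
  set.seed(62)
  for (i in 1:20) {
    pool <- sprintf("GO:%03d", 1:15)
    tx <- tidyr::expand_grid(taxon = sprintf("t%d", 1:4), go_id = pool) |>
      dplyr::slice_sample(prop = 0.3)
    sb <- tidyr::expand_grid(substructure = sprintf("s%d", 1:3),
                             go_id = pool) |>
      dplyr::slice_sample(prop = 0.4)
    ann <- tibble::tibble(gene_id = "g1", go_id = pool)
    rec <- common_gos(tx, sb, ann,
                      taxon_genes = sapply(sprintf("t%d", 1:4),
                                           function(x) "g1", simplify = FALSE),
                      substructure_genes = sapply(sprintf("s%d", 1:3),
                                                  function(x) "g1",
                                                  simplify = FALSE),
                      propagate = FALSE)
    expected <- 0
    for (t in sprintf("t%d", 1:4)) {
      for (s in sprintf("s%d", 1:3)) {
        expected <- expected + length(
          intersect(tx$go_id[tx$taxon == t], sb$go_id[sb$substructure == s]))
      }
    }
    expect_equal(nrow(rec), expected)
  }
})

test_that("the Pearson diagnostic matches the textbook formula", {
  s <- tibble::tibble(taxon = sprintf("t%d", 1:5),
                      n_metaproteins = c(10, 20, 30, 40, 50))
  g_prop <- tibble::tibble(taxon = s$taxon, n_gos = s$n_metaproteins * 3)
  expect_equal(metaprotein_go_correlation(s, g_prop), 1)
  g_neg <- tibble::tibble(taxon = s$taxon, n_gos = 100 - s$n_metaproteins)
  expect_equal(metaprotein_go_correlation(s, g_neg), -1)

  set.seed(63)
  for (i in 1:10) {
    x <- rpois(8, 50); y <- rpois(8, 20)
    if (sd(x) == 0 || sd(y) == 0) next
    s2 <- tibble::tibble(taxon = sprintf("t%d", 1:8), n_metaproteins = x)
    g2 <- tibble::tibble(taxon = sprintf("t%d", 1:8), n_gos = y)
    expect_equal(metaprotein_go_correlation(s2, g2),
                 pearson_formula_oracle(x, y), tolerance = 1e-12)
  }
  flat <- tibble::tibble(taxon = sprintf("t%d", 1:4), n_metaproteins = 5)
  gflat <- tibble::tibble(taxon = flat$taxon, n_gos = 1:4)
  expect_warning(out <- metaprotein_go_correlation(flat, gflat), "variance")
  expect_true(is.na(out))
})

test_that("slim summaries match a brute-force group-by and permutation", {
  recs <- tibble::tibble(
    taxon = c("t1", "t2", "t1", "t3"),
    substructure = c("s1", "s1", "s2", "s1"),
    go_id = c("G1", "G1", "G2", "G3"),
    genes = list("a", "a", "b", "c"),
    taxon_genes = list("a", "a", "b", "c"),
    empty_support = FALSE)
  slims <- tibble::tibble(go_id = c("G1", "G2", "G3"),
                          slim = c("slim_01", "slim_01", "slim_02"))
  s <- slim_summary(recs, slims)
  expect_equal(s$n_gos, c(2, 1))
  expect_equal(s$n_taxa, c(2, 1))  # slim_01 spans taxa t1, t2
  expect_equal(s$substructures, c("s1, s2", "s1"))

  expect_equal(slim_summary(recs[sample(4), ], slims), s)
  expect_equal(nrow(slim_summary(recs[0, ], slims)), 0)
  expect_error(slim_summary(recs, slims[-1, ]), "G1")

  stacked <- slim_stacked_counts(recs, slims)
  # oracle: count distinct GOs by hand for one cell
  expect_equal(stacked$n_gos[stacked$substructure == "s1" &
                               stacked$taxon == "t1" &
                               stacked$slim == "slim_01"], 1)
  expect_equal(sum(stacked$n_gos), 4)
})

test_that("psychobiotic report filters and ranks with verifiable shares", {
  recs <- tibble::tibble(
    taxon = c("Lactobacillus", "Lactobacillus", "Escherichia", "OtherGenus"),
    substructure = c("s1", "s2", "s1", "s1"),
    go_id = c("G1", "G1", "G2", "G3"),
    genes = list("a", "b", "c", "d"),
    taxon_genes = list("a", "b", "c", "d"),
    empty_support = FALSE)
  rep1 <- psychobiotic_report(recs, top_k = 1)
  expect_equal(rep1$n_records, 3)  # OtherGenus dropped
  expect_equal(rep1$go_ranking$go_id[1], "G1")
  expect_equal(rep1$top_k_share, 2 / 3)

  none <- psychobiotic_report(recs, psychobiotics = "Akkermansia")
  expect_equal(none$n_records, 0)
  expect_true(is.na(none$top_k_share))

  all_kept <- psychobiotic_report(recs,
                                  psychobiotics = unique(recs$taxon))
  expect_equal(all_kept$n_records, nrow(recs))

  slims <- tibble::tibble(go_id = c("G1", "G2", "G3"),
                          slim = c("Ion transport", "Synapse", "Other"))
  focus <- psychobiotic_report(recs, slims = slims,
                               slims_of_interest = "Ion transport")
  expect_equal(focus$n_records, 2)
  expect_equal(focus$substructure_shares$share,
               c(0.5, 0.5))
})
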