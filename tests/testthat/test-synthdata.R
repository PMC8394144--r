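test_that("ancestor generation is deterministic and ancestors are unrelated", {
  a1 <- generate_ancestors(1, 10000, seed = 7)
  expect_length(a1, 1)
  expect_equal(nchar(a1), 10000)
  expect_identical(a1, generate_ancestors(1, 10000, seed = 7))

  pair <- fix_ancestors()
  expect_lt(exact_kmer_jaccard(pair[1], pair[2]), 0.01)

  expect_error(generate_ancestors(0, 10000), "n must be")
  expect_error(generate_ancestors(1, 500), "length must be")
})

test_that("gc content is respected", {
  a <- generate_ancestors(1, 50000, gc = 0.3, seed = 5)
  gc <- sum(strsplit(a, "")[[1]] %in% c("G", "C")) / 50000
  expect_equal(gc, 0.3, tolerance = 0.05)
})

test_that("evolve_genome plants substitutions at the stated rate", {
  anc <- substr(fix_ancestors()[1], 1, 10000)
  same <- evolve_genome(anc, 0, seed = 1)
  expect_identical(same$sequence, anc)
  expect_length(same$sub_positions, 0)

  anc_long <- paste(rep(fix_ancestors()[1], 2), collapse = "")
  ev <- evolve_genome(anc_long, 0.05, seed = 2)
  n <- nchar(anc_long)
  frac <- length(ev$sub_positions) / n
  sigma <- sqrt(0.05 * 0.95 / n)
  expect_lt(abs(frac - 0.05), 3 * sigma)
  # planted positions actually differ (original coordinates, no indels)
  pos <- ev$sub_positions
  expect_true(all(substring(ev$sequence, pos, pos) !=
                  substring(anc_long, pos, pos)))
  # untouched positions unchanged
  keep <- setdiff(seq_len(n), pos)[1:2000]
  expect_true(all(substring(ev$sequence, keep, keep) ==
                  substring(anc_long, keep, keep)))
  expect_error(evolve_genome("", 0.01), "non-empty")
  expect_error(evolve_genome(anc, 0.3, indel_rate = 0.25), "< 0.5")
})

test_that("degrade_to_bin realizes target completeness and contamination", {
  g <- fix_ancestors()[1]
  full <- degrade_to_bin(g, completeness = 1, contamination = 0,
                         n_contigs = 4, seed = 3)
  expect_identical(paste(sort(strsplit(paste(sort(full$contigs),
                                             collapse = ""), "")[[1]]),
                         collapse = ""),
                   paste(sort(strsplit(g, "")[[1]]), collapse = ""))
  one <- degrade_to_bin(g, completeness = 1, n_contigs = 1, seed = 4)
  expect_equal(compute_n50(one$contigs), nchar(g))

  part <- degrade_to_bin(g, completeness = 0.6, n_contigs = 12, seed = 5)
  expect_equal(sum(nchar(part$contigs)) / nchar(g), 0.6, tolerance = 0.02)
  expect_equal(part$completeness / 100, 0.6, tolerance = 0.02)

  cont <- degrade_to_bin(g, completeness = 0.8, contamination = 0.1,
                         contaminant = fix_ancestors()[2], n_contigs = 8,
                         seed = 6)
  expect_equal(cont$contamination / 100, 0.1, tolerance = 0.03)
  expect_error(degrade_to_bin(g, completeness = 0.5, contamination = 0.1,
                              n_contigs = 4), "contaminant")
})

test_that("generate_proteome plants epitopes exactly where the truth says", {
  eps <- c(e1 = "MKTAYIAKQR")
  none <- generate_proteome(20, c(50, 120), eps, planted = NULL, seed = 9)
  expect_length(oracle_ecg_genes(none$proteins, eps), 0)
  expect_identical(none$proteins,
                   generate_proteome(20, c(50, 120), eps, seed = 9)$proteins)

  pl <- generate_proteome(5, c(60, 80), eps,
                          planted = data.frame(gene = c(1, 4),
                                               epitope_id = c("e1", "e1")),
                          seed = 10)
  expect_setequal(oracle_ecg_genes(pl$proteins, eps), c("gene_1", "gene_4"))
  expect_equal(pl$truth$gene, c(1, 4))
  expect_error(generate_proteome(3, c(5, 8), eps,
                                 planted = data.frame(gene = 1,
                                                      epitope_id = "e1"),
                                 seed = 1),
               "longer than")
})

test_that("disease table generation matches its planted 2x2 counts", {
  empty <- generate_disease_table(10, 10, 0, 0, seed = 1)
  expect_equal(nrow(empty$table), 0)
  expect_equal(sum(empty$counts), 20)

  dt <- generate_disease_table(200, 300, 0.6, 0.3, 0.8, 0.4, seed = 2)
  expect_equal(sum(dt$counts), 500)
  expect_equal(nrow(dt$table), sum(dt$counts[, "annotated"]))
  exp_ann <- 200 * 0.6 + 300 * 0.3
  sigma <- sqrt(200 * 0.6 * 0.4 + 300 * 0.3 * 0.7)
  expect_lt(abs(nrow(dt$table) - exp_ann), 3 * sigma)
  # table rows agree with the counts matrix by group
  expect_equal(sum(dt$table$taxon %in% dt$high_taxa),
               unname(dt$counts["high", "annotated"]))
})

test_that("community counts are multinomial draws summing to depth", {
  single <- generate_community_counts(c(only = 1), 100, seed = 1)
  expect_equal(unname(single), 100)

  comp <- random_composition(500, seed = 3)
  comp["taxon_1"] <- 1e-3
  comp <- comp / sum(comp)
  counts <- generate_community_counts(comp, 1e6, seed = 4)
  expect_equal(sum(counts), 1e6)
  expected <- 1e6 * comp[["taxon_1"]]
  sigma <- sqrt(expected * (1 - comp[["taxon_1"]]))
  expect_lt(abs(counts[["taxon_1"]] - expected), 3 * sigma)
  expect_error(generate_community_counts(c(a = 0.5, b = 0.4), 10), "sum to 1")
})

test_that("bin FASTA/TSV round trip preserves sequences and metadata", {
  sc <- simulate_catalog_scenario(n_species = 1, bins_per_species = 2,
                                  genome_length = 10000, sub_rate = 0.01,
                                  seed = 5)
  dir <- withr::local_tempdir()
  write_bins(sc$bins, dir)
  write_bin_metadata(sc$bins, file.path(dir, "meta.tsv"))
  back <- read_bins(dir, file.path(dir, "meta.tsv"))
  expect_equal(length(back), 2)
  expect_identical(unname(back[[1]]$contigs), unname(sc$bins[[1]]$contigs))
  expect_equal(back[[2]]$completeness, sc$bins[[2]]$completeness)
  expect_equal(back[[1]]$trna_count, 20L)
})
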