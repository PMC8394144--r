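test_that("coverage cutoff is min(0.8, product of completeness fractions)", {
  expect_equal(coverage_cutoff(1, 1), 0.8)
  expect_equal(coverage_cutoff(0.5, 0.5), 0.25)
  expect_equal(coverage_cutoff(0.9, 1), 0.8)
  expect_error(coverage_cutoff(0, 1), "> 0")
  expect_error(coverage_cutoff(50, 100), "fraction")
})

test_that("fragment ANI recovers planted identity and gates unrelated pairs", {
  anc <- fix_ancestors()
  b1 <- genome_bin("q", anc[1], 100, 0)
  self <- fragment_ani(b1, b1)
  expect_equal(self$ani, 1)
  expect_equal(self$coverage, 1)
  expect_true(self$passed_coverage)

  ev <- evolve_genome(anc[1], 0.03, seed = 9)
  b2 <- genome_bin("g", ev$sequence, 100, 0)
  res <- fragment_ani(b1, b2)
  realized <- 1 - length(ev$sub_positions) / nchar(anc[1])
  expect_equal(res$ani, realized, tolerance = 0.003)
  expect_true(res$passed_coverage)

  far <- fragment_ani(b1, genome_bin("u", anc[2], 100, 0))
  expect_true(is.na(far$ani))
  expect_false(far$passed_coverage)
})

test_that("coverage gating splits conspecific bins with disjoint halves", {
  g <- fix_ancestors()[1]
  half1 <- substr(g, 1, nchar(g) / 2)
  half2 <- substr(g, nchar(g) / 2 + 1, nchar(g))
  b1 <- genome_bin("h1", half1, 50, 0)
  b2 <- genome_bin("h2", half2, 50, 0)
  res <- fragment_ani(b1, b2)
  expect_false(res$passed_coverage) # no shared sequence at cutoff 0.25
})

test_that("average linkage matches brute force on a 3-item instance", {
  d <- matrix(c(0, 0.01, 0.9,
                0.01, 0, 0.9,
                0.9, 0.9, 0), 3, byrow = TRUE,
              dimnames = list(letters[1:3], letters[1:3]))
  cl <- average_linkage_cluster(d, 0.2)
  expect_equal(cl[["a"]], cl[["b"]])
  expect_false(cl[["a"]] == cl[["c"]])

  expect_length(unique(average_linkage_cluster(d * 0, 0.2)), 1)
  expect_length(unique(average_linkage_cluster(d, 0.005)), 3)
  d[1, 2] <- NA
  expect_error(average_linkage_cluster(d, 0.2), "NA")
})

test_that("two-step clustering recovers the planted species exactly", {
  sc <- fix_scenario()
  cl <- two_step_species_clustering(sc$bins, s = 1000)
  expect_length(cl$clusters, 6)
  got <- sort(vapply(cl$clusters, function(x) paste(x$members, collapse = ","),
                     character(1)))
  want <- sort(vapply(split(sc$truth$bin_id, sc$truth$species),
                      function(x) paste(sort(x), collapse = ","), character(1)))
  expect_identical(got, unname(want))
  # within-cluster ANI >= 0.95 (brute-force check of the species criterion)
  ids <- vapply(sc$bins, function(b) b$bin_id, character(1))
  one <- cl$clusters[[1]]$members
  for (pair in utils::combn(one[1:3], 2, simplify = FALSE)) {
    ani <- fragment_ani(sc$bins[[match(pair[1], ids)]],
                        sc$bins[[match(pair[2], ids)]])$ani
    expect_gte(ani, 0.95)
  }
})

test_that("clustering is a fixpoint on its own representatives", {
  sc <- fix_scenario()
  cl <- two_step_species_clustering(sc$bins, s = 1000)
  ids <- vapply(sc$bins, function(b) b$bin_id, character(1))
  reps <- vapply(cl$clusters, function(x) x$representative, character(1))
  again <- two_step_species_clustering(sc$bins[match(reps, ids)], s = 1000)
  expect_length(again$clusters, length(cl$clusters))
  expect_setequal(vapply(again$clusters, function(x) x$representative,
                         character(1)), reps)
})

test_that("single bin and degraded-copy representative selection", {
  b <- genome_bin("solo", fix_ancestors()[1], 95, 1)
  cl <- two_step_species_clustering(list(b), s = 500)
  expect_length(cl$clusters, 1)
  expect_equal(cl$clusters[[1]]$representative, "solo")

  # same sequence content, one copy fragmented to a lower N50
  g <- fix_ancestors()[1]
  intact <- genome_bin("intact", g, 95, 1)
  cuts <- seq(1, nchar(g), by = 2000)
  shattered <- genome_bin("shatter",
                          substring(g, cuts, c(cuts[-1] - 1, nchar(g))),
                          95, 1)
  expect_gt(intactness_score(95, 1, compute_n50(intact$contigs)),
            intactness_score(95, 1, compute_n50(shattered$contigs)))
  cl2 <- two_step_species_clustering(list(shattered, intact), s = 500)
  expect_length(cl2$clusters, 1)
  expect_equal(cl2$clusters[[1]]$representative, "intact")
})

test_that("representative choice is invariant to input order", {
  sc <- fix_scenario()
  sub <- sc$bins[1:5] # one planted species
  cl_f <- two_step_species_clustering(sub, s = 500)
  cl_r <- two_step_species_clustering(rev(sub), s = 500)
  expect_equal(cl_f$clusters[[1]]$representative,
               cl_r$clusters[[1]]$representative)
})

test_that("merge_catalog labels novel, replaced, and inherited clusters", {
  anc <- fix_ancestors()
  base <- list(genome_bin("base1", anc[1], 90, 1),
               genome_bin("base2", anc[2], 100, 0))
  # no new bins: everything inherited
  ev <- evolve_genome(anc[1], 0.01, seed = 31)
  third <- generate_ancestors(1, 50000, seed = 302)
  newb <- list(genome_bin("new1", ev$sequence, 100, 0),
               genome_bin("new2", third, 80, 0))
  mc <- merge_catalog(base, newb, s = 1000)
  prov <- setNames(vapply(mc$clusters, function(x) x$provenance, character(1)),
                   vapply(mc$clusters, function(x) x$representative, character(1)))
  expect_equal(unname(prov["new1"]), "replaced")  # higher S than base1
  expect_equal(unname(prov["base2"]), "inherited")
  expect_equal(unname(prov["new2"]), "novel")
  expect_error(merge_catalog(base, list(genome_bin("base1", anc[1], 90, 1))),
               "collision")
})

test_that("non-redundant counting collapses redundant and same-sample genomes", {
  a <- fix_ancestors()[1]
  sp <- setNames(rep("sp1", 3), c("g1", "g2", "g3"))
  identicals <- lapply(1:3, function(i) {
    genome_bin(paste0("g", i), a, 100, 0, sample_id = paste0("s", i))
  })
  expect_equal(count_nonredundant(identicals, sp, s = 1000), 1L)

  ev <- evolve_genome(a, 0.045, seed = 12)
  same_sample <- list(genome_bin("g1", a, 100, 0, sample_id = "sA"),
                      genome_bin("g2", ev$sequence, 100, 0, sample_id = "sA"))
  expect_equal(count_nonredundant(same_sample, sp, s = 1000), 1L)
  diff_sample <- list(genome_bin("g1", a, 100, 0, sample_id = "sA"),
                      genome_bin("g2", ev$sequence, 100, 0, sample_id = "sB"))
  expect_equal(count_nonredundant(diff_sample, sp, s = 1000), 2L)
})

test_that("country-specific species and family enrichment", {
  sc <- fix_scenario()
  cl <- two_step_species_clustering(sc$bins, s = 1000)
  ids <- vapply(sc$bins, function(b) b$bin_id, character(1))
  # force each species' bins to one country; species 1-4 family F, 5-6 family G
  country_of <- setNames(
    paste0("country_", sc$truth$species[match(ids, sc$truth$bin_id)] %% 2),
    ids)
  reps <- vapply(cl$clusters, function(x) x$representative, character(1))
  fam <- setNames(ifelse(as.integer(sub("sp(\\d+).*", "\\1", reps)) <= 4,
                         "F", "G"), reps)
  res <- country_specific_species(cl, country_of, base_ids = character(0),
                                  family_of = fam)
  expect_setequal(names(res$specific), c("country_0", "country_1"))
  expect_equal(sum(lengths(res$specific)), 6)
  expect_true(all(c("odds_ratio", "p") %in% names(res$enrichment)))
  # a species with members from two countries is not specific
  country_mixed <- country_of
  country_mixed[cl$clusters[[1]]$members[1]] <- "elsewhere"
  res2 <- country_specific_species(cl, country_mixed, base_ids = character(0))
  expect_equal(sum(lengths(res2$specific)), 5)
  # base membership disqualifies
  res3 <- country_specific_species(cl, country_of,
                                   base_ids = cl$clusters[[1]]$members[1])
  expect_equal(sum(lengths(res3$specific)), 5)
})

test_that("family enrichment detects a planted overrepresentation", {
  # 50 specific species (80% family X) vs 150 background (20% family X):
  # hypergeometric oracle via fisher_exact on the 2x2
  tab <- matrix(c(40, 10, 30, 120), 2, byrow = TRUE)
  ft <- fisher_exact(tab)
  expect_gt(ft$odds_ratio, 1)
  expect_lt(ft$p, 0.05)
  expect_equal(ft$p, oracle_fisher_p(40, 10, 30, 120), tolerance = 1e-9)
})

test_that("depth pairing rejects ambiguous clusters and detects quality shifts", {
  set.seed(88)
  anc <- generate_ancestors(8, 20000, seed = 303)
  low <- list(); high <- list()
  for (i in 1:8) {
    ev <- evolve_genome(anc[i], 0.02, seed = 500 + i)
    low[[i]] <- degrade_to_bin(anc[i], completeness = 0.7, n_contigs = 10,
                               seed = 600 + i, bin_id = paste0("low", i),
                               sample_id = "L")
    high[[i]] <- degrade_to_bin(ev$sequence, completeness = 0.9, n_contigs = 4,
                                seed = 700 + i, bin_id = paste0("high", i),
                                sample_id = "H")
  }
  res <- pair_conspecific_across_depths(low, high, s = 500)
  expect_equal(nrow(res$pairs), 8)
  expect_true(all(res$pairs$high_completeness > res$pairs$low_completeness))
  p_comp <- res$tests$p[res$tests$metric == "completeness"]
  expect_lt(p_comp, 0.05)

  # a cluster with two low-depth bins is excluded
  low2 <- c(low, list(degrade_to_bin(anc[1], completeness = 0.75,
                                     n_contigs = 10, seed = 99,
                                     bin_id = "low_dup", sample_id = "L")))
  res2 <- pair_conspecific_across_depths(low2, high, s = 500)
  expect_equal(nrow(res2$pairs), 7)

  # identical inputs pair each bin with its copy; all differences zero
  copies <- lapply(low, function(b) genome_bin(paste0(b$bin_id, "_c"),
                                               b$contigs, b$completeness,
                                               b$contamination,
                                               sample_id = "H"))
  res3 <- pair_conspecific_across_depths(low, copies, s = 500)
  expect_equal(res3$pairs$low_n50, res3$pairs$high_n50)
  expect_error(pair_conspecific_across_depths(low[1:2],
                                              list(genome_bin("x", fix_ancestors()[2], 90, 0)),
                                              s = 500),
               "no conspecific pairs")
})
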