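test_that("conspecific alignment covers the genome and finds planted SNVs", {
  g <- substr(fix_ancestors()[1], 1, 30000)
  self <- call_snvs(align_conspecific(g, g))
  expect_equal(self$aligned_length, nchar(g))
  expect_equal(nrow(self$snvs), 0)

  ev <- evolve_genome(g, 10 / nchar(g), seed = 41) # ~10 substitutions
  res <- call_snvs(align_conspecific(g, ev$sequence))
  expect_gte(res$aligned_length, 0.99 * nchar(g))
  expect_setequal(res$snvs$pos, ev$sub_positions)
  ref_at <- substring(g, res$snvs$pos, res$snvs$pos)
  expect_identical(res$snvs$ref, ref_at)
  expect_true(all(res$snvs$ref != res$snvs$alt))

  far <- call_snvs(align_conspecific(g, fix_ancestors()[2]))
  expect_lte(far$aligned_length, 0.01 * nchar(g))
})

test_that("snv calling tracks a planted 1% divergence within 5%", {
  g <- fix_ancestors()[1] # 50 kb
  ev <- evolve_genome(g, 0.01, seed = 42)
  res <- call_snvs(align_conspecific(g, ev$sequence))
  expect_equal(nrow(res$snvs), length(ev$sub_positions), tolerance = 0.05)
  expect_gt(mean(ev$sub_positions %in% res$snvs$pos), 0.95)
})

test_that("alignment handles indels without mistaking them for SNVs", {
  g <- substr(fix_ancestors()[1], 1, 30000)
  ev <- evolve_genome(g, 0.005, indel_rate = 1e-4, seed = 43)
  res <- call_snvs(align_conspecific(g, ev$sequence))
  recovered <- mean(ev$sub_positions %in% res$snvs$pos)
  expect_gt(recovered, 0.95)
  # called positions are almost exclusively planted ones
  expect_gt(mean(res$snvs$pos %in% ev$sub_positions), 0.95)
})

test_that("snv_per_kb implements the per-pair-normalized mean", {
  ps <- data.frame(genome_id = c("g1", "g2"),
                   n_snv = c(10, 10), aligned_length = c(10000, 10000))
  expect_equal(snv_per_kb(ps)$snv_per_kb, 1)
  one <- data.frame(genome_id = "g1", n_snv = 5, aligned_length = 1000)
  expect_equal(snv_per_kb(one)$snv_per_kb, 5)
  zero <- data.frame(genome_id = c("g1", "g2"),
                     n_snv = c(0, 0), aligned_length = c(9000, 11000))
  expect_equal(snv_per_kb(zero)$snv_per_kb, 0)
  # zero-aligned pairs contribute 0 and are flagged
  mix <- data.frame(genome_id = c("g1", "g2"),
                    n_snv = c(8, 0), aligned_length = c(8000, 0))
  res <- snv_per_kb(mix)
  expect_equal(res$snv_per_kb, 0.5)
  expect_equal(res$zero_aligned, "g2")
  expect_false(snv_per_kb(mix, min_genomes = 10)$eligible)
  expect_true(snv_per_kb(rbind(mix, mix, mix, mix, mix), min_genomes = 10)$eligible)
  expect_error(snv_per_kb(mix[0, ]), "fewer than 2")
})

test_that("snv_per_kb is invariant to member order", {
  g <- substr(fix_ancestors()[1], 1, 20000)
  members <- lapply(1:3, function(i) {
    genome_bin(paste0("m", i),
               evolve_genome(g, 0.002, seed = 50 + i)$sequence, 100, 0)
  })
  rep_bin <- genome_bin("rep", g, 100, 0)
  d1 <- snv_catalog(rep_bin, members)$summary$snv_per_kb
  d2 <- snv_catalog(rep_bin, rev(members))$summary$snv_per_kb
  expect_equal(d1, d2)
})

test_that("chunk size follows the 5-per-kb rule and counts sum to total", {
  blocks <- data.frame(rep_start = 1, g_start = 1, len = 600000)
  set.seed(123)
  pos <- sort(sample.int(600000, 1200))
  over5 <- chunk_normality(pos, blocks, species_snv_per_kb = 6)
  expect_equal(over5$chunk_size, 50000L)
  at5 <- chunk_normality(pos, blocks, species_snv_per_kb = 5)
  expect_equal(at5$chunk_size, 100000L)
  expect_equal(sum(at5$counts),
               sum(pos <= at5$n_chunks * at5$chunk_size))

  short <- chunk_normality(pos[pos <= 3e5],
                           data.frame(rep_start = 1, g_start = 1, len = 3e5),
                           species_snv_per_kb = 5)
  expect_false(short$tested) # only 3 chunks of 100 kb
})

test_that("uniform SNVs pass the normality screen; a hot chunk fails it", {
  region <- 2e6
  blocks <- data.frame(rep_start = 1, g_start = 1, len = region)
  set.seed(7)
  pairs <- lapply(1:40, function(i) {
    pos <- sort(sample.int(region, 4000))
    list(snv_pos = pos, blocks = blocks, species_snv_per_kb = 2)
  })
  hot_pos <- sort(c(sample.int(region, 4000), sample.int(100000, 3000)))
  pairs$hot <- list(snv_pos = hot_pos, blocks = blocks,
                    species_snv_per_kb = 2)
  screen <- chunk_normality_screen(pairs)
  expect_true(all(screen$tested))
  uniform <- screen[rownames(screen) != "hot" & screen$pair != "hot", ]
  expect_gte(mean(uniform$normal), 0.95)
  expect_lt(screen$q[screen$pair == "hot"], 0.05)
})

test_that("nearest-species distances match brute-force path sums", {
  star <- ape::read.tree(text = "(A:2,B:2,C:2,D:2,E:2,F:2);")
  expect_equal(nearest_species_distance(star, "A", 5), 4)

  tr <- ape::read.tree(text = "((A:1,B:2):3,(C:4,D:5):6);")
  # brute force: dist(A,B)=3, dist(A,C)=1+3+6+4=14, dist(A,D)=15
  expect_equal(nearest_species_distance(tr, "A", 2), (3 + 14) / 2)
  expect_error(nearest_species_distance(tr, "Z", 2), "not in tree")
  expect_error(nearest_species_distance(tr, "A", 5), "fewer than")
})

test_that("density-distance association detects a planted inverse relation", {
  n <- 100
  dens_eq <- setNames(seq_len(n) / 10, paste0("s", seq_len(n)))
  self <- density_speciation_association(dens_eq, dens_eq)
  expect_equal(self$spearman, 1)

  inv <- with(list(), {
    set.seed(11)
    dist <- runif(n, 0.1, 2)
    dens <- 1 / dist + rnorm(n, 0, 0.2)
    list(dist = setNames(dist, names(dens_eq)),
         dens = setNames(dens, names(dens_eq)))
  })
  res <- density_speciation_association(inv$dens, inv$dist)
  expect_lt(res$spearman, -0.5)
  expect_equal(res$top_decile_n, 10)
  expect_lt(res$top_decile_p, 0.05)

  # null: independent values give small correlation
  nullres <- with(list(), {
    set.seed(12)
    density_speciation_association(
      setNames(runif(n), names(dens_eq)), setNames(runif(n), names(dens_eq)))
  })
  expect_lt(abs(nullres$spearman), 0.3)
  expect_error(density_speciation_association(dens_eq[1:5], dens_eq[1:5]),
               "at least 20")
})

test_that("planted SNV densities are recovered by the full per-cluster path", {
  g <- fix_ancestors()[1] # 50 kb, 4 members for speed; deeper run in acceptance
  for (d in c(2, 10)) {
    members <- lapply(1:4, function(i) {
      genome_bin(paste0("m", i),
                 evolve_genome(g, d / 1000, seed = 60 * d + i)$sequence,
                 100, 0)
    })
    truth <- vapply(1:4, function(i) {
      length(evolve_genome(g, d / 1000, seed = 60 * d + i)$sub_positions) /
        (nchar(g) / 1000)
    }, numeric(1))
    cat_res <- snv_catalog(genome_bin("rep", g, 100, 0), members)
    expect_equal(cat_res$summary$snv_per_kb, mean(truth), tolerance = 0.05)
  }
})
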