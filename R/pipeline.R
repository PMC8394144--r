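#' Default run configuration
#'
#' All catalog-construction thresholds in one place: sketch parameters,
#' the Mash linkage cutoffs (0.2 preliminary clustering, 0.1 connected
#' components and depth pairing, 0.001 redundancy), the 0.05 ANI species
#' cutoff with the 0.8 coverage cap, the minimum-quality bin filter
#' (completeness 50, contamination 5, QS 50), the SNV chunking rule
#' (50 kb above 5 SNV/kb, else 100 kb), the 1e-05 clade-enrichment
#' threshold, the 40-taxon disease floor, and the eight abundance-stratum
#' bounds.
#'
#' @param seed Root seed; every stochastic stage derives its own seed
#'   from it.
#' @return Named list of configuration values.
#' @export
default_config <- function(seed = 1L) {
  list(seed = as.integer(seed),
       k = 21L, s = 10000L, hash_seed = 42L,
       mash_cutoff = 0.2, component_cutoff = 0.1, redundancy_cutoff = 0.001,
       ani_cutoff = 0.05, coverage_cap = 0.8,
       min_completeness = 50, max_contamination = 5, min_qs = 50,
       frag_len = 1000L, min_frag = 500L, min_ident = 0.7,
       anchor_min = 31L, max_gap = 5000L,
       snv_min_genomes = 10L, snv_chunk_rule = 5,
       ecg_p_cutoff = 1e-5, disease_min_taxa = 40L,
       strata_bounds = 10^seq(-7, 0))
}

#' Simulate a default catalog scenario with planted ground truth
#'
#' Generates `n_species` unrelated ancestors and derives
#' `bins_per_species` conspecific bins from each (independent planted
#' substitutions per bin, optional MAG-style degradation), so the true
#' species partition is known exactly.
#'
#' @param n_species Number of planted species. Default 6.
#' @param bins_per_species Bins per species. Default 5.
#' @param genome_length Ancestor length in bp.
#' @param sub_rate Per-bin substitution rate (conspecific divergence).
#' @param completeness Retained fraction for degraded bins (1 = intact).
#' @param n_contigs Contigs per bin after degradation.
#' @param seed Root seed.
#' @return List with `bins` (list of `genome_bin`) and `truth` (data
#'   frame: bin_id, species, sample_id, sub_rate).
#' @export
simulate_catalog_scenario <- function(n_species = 6L, bins_per_species = 5L,
                                      genome_length = 100000L,
                                      sub_rate = 0.02, completeness = 1,
                                      n_contigs = 5L, seed = 1L) {
  ancestors <- generate_ancestors(n_species, genome_length,
                                  seed = derive_seed(seed, "ancestors"))
  bins <- list(); truth <- NULL
  for (sp in seq_len(n_species)) {
    for (b in seq_len(bins_per_species)) {
      sd_b <- derive_seed(seed, paste0("bin", sp, "_", b))
      ev <- evolve_genome(ancestors[sp], sub_rate, seed = sd_b)
      id <- sprintf("sp%02d_bin%02d", sp, b)
      bin <- degrade_to_bin(ev$sequence, completeness = completeness,
                            n_contigs = n_contigs, seed = sd_b,
                            bin_id = id, sample_id = paste0("sample_", b),
                            country = c("Korea", "India", "Japan")[1 + (b %% 3)],
                            has_5S = TRUE, has_16S = TRUE, has_23S = TRUE,
                            trna_count = 20L)
      # degradation keeps the realized completeness; contamination is 0
      bins[[id]] <- bin
      truth <- rbind(truth, data.frame(
        bin_id = id, species = sp, sample_id = paste0("sample_", b),
        sub_rate = sub_rate, stringsAsFactors = FALSE))
    }
  }
  list(bins = unname(bins), truth = truth)
}

#' Run the catalog-construction pipeline
#'
#' QC report, minimum-quality filter, two-step iterative species
#' clustering, and the non-redundant genome count, from a list of genome
#' bins.
#'
#' @param bins List of `genome_bin` objects.
#' @param config Configuration from [default_config()].
#' @return List with `qc`, `kept` (bin ids passing the filter),
#'   `clustering`, `species_of`, `nonredundant`, and the echoed `config`.
#' @export
run_catalog <- function(bins, config = default_config()) {
  if (length(bins) == 0) stop("no input bins")
  qc <- qc_report(bins)
  kept <- qc$bin_id[qc$passes_filter]
  if (length(kept) == 0) stop("no bins pass the minimum-quality filter")
  fbins <- bins[match(kept, qc$bin_id)]
  clustering <- two_step_species_clustering(
    fbins, mash_cutoff = config$mash_cutoff, ani_cutoff = config$ani_cutoff,
    k = config$k, s = config$s, hash_seed = config$hash_seed,
    frag_len = config$frag_len, min_frag = config$min_frag,
    min_ident = config$min_ident)
  species_of <- unlist(lapply(seq_along(clustering$clusters), function(i) {
    setNames(rep(paste0("species_", i),
                 length(clustering$clusters[[i]]$members)),
             clustering$clusters[[i]]$members)
  }))
  nonredundant <- count_nonredundant(
    fbins, species_of, component_cutoff = config$component_cutoff,
    redundancy_cutoff = config$redundancy_cutoff, k = config$k,
    s = config$s, hash_seed = config$hash_seed)
  list(qc = qc, kept = kept, clustering = clustering,
       species_of = species_of, nonredundant = nonredundant,
       config = config)
}

#' Run the SNV stage over a species clustering
#'
#' For every cluster with at least `min_members` genomes, aligns members
#' to the representative, calls SNVs, and computes SNV-per-kb; clusters
#' below `config$snv_min_genomes` members are flagged ineligible for
#' density analyses.
#'
#' @param catalog Result of [run_catalog()].
#' @param bins The same bins passed to [run_catalog()].
#' @param min_members Smallest cluster size to process. Default 3.
#' @param config Configuration list.
#' @return List of per-cluster [snv_catalog()] results (named by species
#'   id) plus a `summary` data frame.
#' @export
run_snv <- function(catalog, bins, min_members = 3L,
                    config = default_config()) {
  ids <- vapply(bins, function(b) b$bin_id, character(1))
  out <- list()
  for (i in seq_along(catalog$clustering$clusters)) {
    cl <- catalog$clustering$clusters[[i]]
    if (length(cl$members) < min_members) next
    rep_bin <- bins[[match(cl$representative, ids)]]
    members <- bins[match(setdiff(cl$members, cl$representative), ids)]
    out[[paste0("species_", i)]] <- snv_catalog(
      rep_bin, members, min_genomes = config$snv_min_genomes,
      anchor_min = config$anchor_min, max_gap = config$max_gap)
  }
  summary <- do.call(rbind, lapply(names(out), function(nm) {
    s <- out[[nm]]$summary
    data.frame(species = nm, n_genomes = s$n_genomes,
               snv_per_kb = s$snv_per_kb, eligible = s$eligible,
               stringsAsFactors = FALSE)
  }))
  list(clusters = out, summary = summary)
}

#' Run the cross-reactivity stage
#'
#' ECG profiles per species proteome, optional clade enrichment, and the
#' high/low cross-reactivity partition.
#'
#' @param proteomes Named list (species id -> named character vector of
#'   proteins).
#' @param epitopes Filtered epitopes from [filter_epitopes()].
#' @param clades Optional named list (clade -> member species ids) to
#'   test for enrichment.
#' @param taxonomy Optional taxonomy (parent -> children) for the
#'   partition.
#' @param config Configuration list.
#' @return List with `profiles` (data frame), `enrichment`, and
#'   `partition` (NULL when no clades given).
#' @export
run_mimicry <- function(proteomes, epitopes, clades = NULL, taxonomy = list(),
                        config = default_config()) {
  profiles <- do.call(rbind, lapply(names(proteomes), function(sp) {
    e <- count_ecgs(proteomes[[sp]], epitopes)
    data.frame(species = sp, ecg_count = e$ecg_count,
               gene_count = e$gene_count, density = e$density,
               stringsAsFactors = FALSE)
  }))
  enrichment <- NULL; partition <- NULL
  if (!is.null(clades)) {
    dens <- setNames(profiles$density, profiles$species)
    enrichment <- do.call(rbind, lapply(names(clades), function(cl) {
      e <- clade_enrichment(dens, clades[[cl]])
      data.frame(taxon = cl, fold_change = e$fold_change, p = e$p,
                 n_clade = e$n_clade, stringsAsFactors = FALSE)
    }))
    partition <- partition_cross_reactivity(
      enrichment, taxonomy, all_taxa = unique(c(names(clades),
                                                profiles$species)),
      p_cutoff = config$ecg_p_cutoff)
  }
  list(profiles = profiles, enrichment = enrichment, partition = partition)
}

#' Run the sequencing-depth profiling stage
#'
#' @param reference_counts Named count vector (deepest profile).
#' @param depths Depths to subsample to.
#' @param config Configuration list.
#' @param mode Subsampling mode, see [subsample_profile()].
#' @return The [depth_curve()] data frame.
#' @export
run_depth <- function(reference_counts, depths, config = default_config(),
                      mode = "multinomial") {
  depth_curve(reference_counts, depths, seed = config$seed, mode = mode)
}
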