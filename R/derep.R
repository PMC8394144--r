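#' Pairwise alignment-coverage cutoff
#'
#' The minimum aligned fraction required before an ANI value between two
#' genomes is trusted: `min(0.8, comp_a * comp_b)` with completeness as
#' fractions. Incomplete bins cannot align over regions they lack, so the
#' required coverage scales with the product of completeness estimates,
#' capped at 0.8.
#'
#' @param comp_a,comp_b Completeness fractions in (0, 1].
#' @return Coverage cutoff fraction.
#' @export
coverage_cutoff <- function(comp_a, comp_b) {
  if (any(comp_a <= 0) || any(comp_b <= 0)) stop("completeness must be > 0")
  if (any(comp_a > 1) || any(comp_b > 1)) {
    stop("completeness must be a fraction in (0, 1]")
  }
  pmin(0.8, comp_a * comp_b)
}

#' Fragment-mapping average nucleotide identity
#'
#' The query is cut into non-overlapping `frag_len` windows (terminal
#' fragments shorter than `min_frag` dropped); each window is located on
#' the reference by exact 21-mer seeds and scored by banded alignment.
#' Windows reaching identity >= `min_ident` count as mapped. ANI is the
#' length-weighted mean identity of mapped windows pooled over both
#' mapping directions; per-genome aligned fractions are computed in both
#' directions and their minimum is the pair's coverage, gated by
#' [coverage_cutoff()].
#'
#' @param query,ref `genome_bin` objects.
#' @param frag_len Window length in bp (>= 200). Default 1000.
#' @param min_frag Minimum terminal window length kept. Default 500.
#' @param min_ident Identity floor for a window to count as mapped.
#' @param band Alignment band half-width in bp.
#' @return List with `ani` (NA when no window maps), `coverage`,
#'   `coverage_cutoff`, and `passed_coverage`.
#' @export
fragment_ani <- function(query, ref, frag_len = 1000L, min_frag = 500L,
                         min_ident = 0.7, band = 40L) {
  if (frag_len < 200) stop("frag_len must be >= 200")
  map_qr <- cpp_fragment_map(query$contigs, ref$contigs, as.integer(frag_len),
                             as.integer(min_frag), 21L, min_ident,
                             as.integer(band), 8L)
  map_rq <- cpp_fragment_map(ref$contigs, query$contigs, as.integer(frag_len),
                             as.integer(min_frag), 21L, min_ident,
                             as.integer(band), 8L)
  frac <- function(mp, total_len) {
    sum(mp$wlen[mp$mapped == 1]) / total_len
  }
  cov_q <- frac(map_qr, genome_length(query))
  cov_r <- frac(map_rq, genome_length(ref))
  wl <- c(map_qr$wlen[map_qr$mapped == 1], map_rq$wlen[map_rq$mapped == 1])
  id <- c(map_qr$identity[map_qr$mapped == 1],
          map_rq$identity[map_rq$mapped == 1])
  ani <- if (length(wl) == 0) NA_real_ else sum(wl * id) / sum(wl)
  cutoff <- coverage_cutoff(query$completeness / 100, ref$completeness / 100)
  coverage <- min(cov_q, cov_r)
  list(ani = ani, coverage = coverage, coverage_cutoff = cutoff,
       passed_coverage = !is.na(ani) && coverage >= cutoff)
}

#' Average-linkage clustering of a distance matrix at a cutoff
#'
#' Standard agglomerative average-linkage (UPGMA); merges with linkage
#' distance <= `cutoff` are applied.
#'
#' @param dist Symmetric distance matrix with zero diagonal and dimnames.
#' @param cutoff Linkage-distance cutoff.
#' @return Named integer vector of cluster labels.
#' @export
average_linkage_cluster <- function(dist, cutoff) {
  if (any(is.na(dist))) stop("distance matrix contains NA/NaN entries")
  n <- nrow(dist)
  ids <- rownames(dist)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (n == 1) return(setNames(1L, ids))
  hc <- hclust(as.dist(dist), method = "average")
  cutree(hc, h = cutoff)
}

# ANI distance matrix for one preliminary cluster, with coverage gating:
# pairs failing coverage get distance 1 (regarded as different genomes).
ani_distance_submatrix <- function(bins, cache = NULL, ...) {
  n <- length(bins)
  ids <- vapply(bins, function(b) b$bin_id, character(1))
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      key <- paste(sort(c(ids[i], ids[j])), collapse = "\r")
      res <- if (!is.null(cache) && !is.null(cache[[key]])) {
        cache[[key]]
      } else {
        r <- fragment_ani(bins[[i]], bins[[j]], ...)
        if (!is.null(cache)) cache[[key]] <- r
        r
      }
      d <- if (!res$passed_coverage) 1 else 1 - res$ani
      m[i, j] <- d
      m[j, i] <- d
    }
  }
  m
}

# One pass of the two-step procedure over a list of bins: Mash preliminary
# clusters cut at mash_cutoff, then ANI average-linkage within each at
# ani_cutoff. Returns a list of bin-id character vectors.
cluster_once <- function(bins, mash_cutoff, ani_cutoff, k, s, hash_seed,
                         cache, ...) {
  ids <- vapply(bins, function(b) b$bin_id, character(1))
  if (length(bins) == 1) return(list(ids))
  dm <- distance_matrix(bins, k = k, s = s, hash_seed = hash_seed)
  prelim <- average_linkage_cluster(dm, mash_cutoff)
  out <- list()
  for (cl in sort(unique(prelim))) {
    members <- ids[prelim == cl]
    if (length(members) == 1) {
      out[[length(out) + 1]] <- members
      next
    }
    sub <- bins[match(members, ids)]
    am <- ani_distance_submatrix(sub, cache = cache, ...)
    fine <- average_linkage_cluster(am, ani_cutoff)
    for (fc in sort(unique(fine))) {
      out[[length(out) + 1]] <- members[fine == fc]
    }
  }
  out
}

choose_representative <- function(member_ids, bin_index) {
  s <- vapply(member_ids, function(id) bin_intactness(bin_index[[id]]),
              numeric(1))
  best <- member_ids[s == max(s)]
  sort(best)[1] # ties broken by lexicographically smallest bin id
}

canonical_partition <- function(partition) {
  p <- lapply(partition, sort)
  p[order(vapply(p, `[`, character(1), 1))]
}

#' Two-step iterative species clustering
#'
#' Step 1: all-pairs Mash distances, average-linkage cut at `mash_cutoff`
#' (preliminary clusters). Step 2: within each preliminary cluster,
#' pairwise fragment ANI with coverage gating (pairs failing coverage get
#' distance 1), average-linkage cut at `ani_cutoff`; each cluster's
#' representative is the member with the highest intactness score. The two
#' steps are then re-run on the representatives alone, clusters whose
#' representatives co-cluster are merged, and this is repeated until the
#' partition stops changing.
#'
#' @param bins List of `genome_bin` objects that pass the bin filter.
#' @param mash_cutoff Preliminary Mash linkage cutoff. Default 0.2.
#' @param ani_cutoff ANI-distance linkage cutoff. Default 0.05 (95%
#'   identity, the conventional species boundary).
#' @param k,s,hash_seed Sketch parameters (see [build_sketch()]).
#' @param max_iter Iteration cap; exceeded iteration is an error.
#' @param ... Passed to [fragment_ani()].
#' @return Object of class `species_clustering`: list with `clusters`
#'   (each with `members`, `representative`, `iteration_found`) and
#'   `n_iterations`.
#' @export
two_step_species_clustering <- function(bins, mash_cutoff = 0.2,
                                        ani_cutoff = 0.05, k = 21L,
                                        s = 10000L, hash_seed = 42L,
                                        max_iter = 25L, ...) {
  ids <- vapply(bins, function(b) b$bin_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate bin ids")
  bin_index <- setNames(bins, ids)
  cache <- new.env(parent = emptyenv())
  partition <- canonical_partition(
    cluster_once(bins, mash_cutoff, ani_cutoff, k, s, hash_seed, cache, ...))
  found_at <- setNames(rep(1L, length(partition)),
                       vapply(partition, paste, character(1), collapse = ","))
  iter <- 1L
  repeat {
    if (iter >= max_iter) {
      stop("species clustering did not converge after ", max_iter,
           " iterations (", length(partition), " clusters at exit)")
    }
    reps <- vapply(partition, choose_representative, character(1),
                   bin_index = bin_index)
    rep_partition <- cluster_once(bin_index[reps], mash_cutoff, ani_cutoff,
                                  k, s, hash_seed, cache, ...)
    merged <- lapply(rep_partition, function(rep_group) {
      sort(unlist(partition[match(rep_group, reps)]))
    })
    merged <- canonical_partition(merged)
    iter <- iter + 1L
    keys <- vapply(merged, paste, character(1), collapse = ",")
    new_keys <- setdiff(keys, names(found_at))
    found_at[new_keys] <- iter
    if (identical(merged, partition)) break
    partition <- merged
  }
  clusters <- lapply(partition, function(members) {
    list(members = members,
         representative = choose_representative(members, bin_index),
         iteration_found = unname(
           found_at[[paste(members, collapse = ",")]]))
  })
  structure(list(clusters = clusters, n_iterations = iter),
            class = "species_clustering")
}

#' @export
print.species_clustering <- function(x, ...) {
  cat(sprintf("<species_clustering> %d clusters, %d bins, %d iteration(s)\n",
              length(x$clusters),
              sum(vapply(x$clusters, function(cl) length(cl$members),
                         integer(1))),
              x$n_iterations))
  invisible(x)
}

#' Merge new genome bins into an existing catalog of representatives
#'
#' Runs the two-step clustering on the union of the base representatives
#' and the new bins, and labels every resulting cluster: `novel` (no base
#' member), `replaced` (contains a base member but a new bin became the
#' representative), or `inherited` (representative is a base genome).
#'
#' @param base_reps List of `genome_bin` representatives of the base
#'   catalog.
#' @param new_bins List of new `genome_bin` objects; ids must not collide
#'   with the base.
#' @param ... Passed to [two_step_species_clustering()].
#' @return A `species_clustering` whose clusters additionally carry a
#'   `provenance` label.
#' @export
merge_catalog <- function(base_reps, new_bins, ...) {
  base_ids <- vapply(base_reps, function(b) b$bin_id, character(1))
  new_ids <- vapply(new_bins, function(b) b$bin_id, character(1))
  if (length(intersect(base_ids, new_ids)) > 0) {
    stop("bin id collision between base catalog and new bins")
  }
  res <- two_step_species_clustering(c(base_reps, new_bins), ...)
  res$clusters <- lapply(res$clusters, function(cl) {
    has_base <- any(cl$members %in% base_ids)
    cl$provenance <- if (!has_base) "novel"
      else if (cl$representative %in% base_ids) "inherited"
      else "replaced"
    cl
  })
  res
}

#' Count non-redundant genomes
#'
#' Redundancy is resolved at Mash distance 0.001 (99.9% identity):
#' average-linkage clustering at 0.001 is run within each connected
#' component of the graph linking pairs at distance <= 0.1 (genomes
#' further apart cannot end up in one 0.001-cluster). Genomes from the
#' same sample assigned to the same species cluster are counted only once.
#'
#' @param bins List of `genome_bin` objects.
#' @param species_of Named character vector mapping bin id to species
#'   cluster id.
#' @param component_cutoff Mash distance bounding the connected
#'   components. Default 0.1.
#' @param redundancy_cutoff Average-linkage cutoff defining redundancy.
#'   Default 0.001.
#' @inheritParams build_sketch
#' @return Integer count of non-redundant genomes.
#' @export
count_nonredundant <- function(bins, species_of, component_cutoff = 0.1,
                               redundancy_cutoff = 0.001, k = 21L,
                               s = 10000L, hash_seed = 42L) {
  ids <- vapply(bins, function(b) b$bin_id, character(1))
  if (any(!ids %in% names(species_of))) {
    stop("species assignment missing for some bins")
  }
  if (length(bins) == 1) return(1L)
  dm <- distance_matrix(bins, k = k, s = s, hash_seed = hash_seed)
  adj <- dm <= component_cutoff
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  unit <- integer(length(ids))
  next_unit <- 0L
  for (cmp in sort(unique(comp))) {
    members <- which(comp == cmp)
    if (length(members) == 1) {
      unit[members] <- next_unit + 1L
      next_unit <- next_unit + 1L
    } else {
      sub <- dm[members, members, drop = FALSE]
      cl <- average_linkage_cluster(sub, redundancy_cutoff)
      unit[members] <- next_unit + cl
      next_unit <- next_unit + max(cl)
    }
  }
  # same-sample rule: one genome per (sample, species cluster), keeping the
  # lexicographically first bin id for determinism
  key <- paste(vapply(bins, function(b) b$sample_id, character(1)),
               unname(species_of[ids]), sep = "\r")
  ord <- order(ids)
  keep <- logical(length(ids))
  keep[ord] <- !duplicated(key[ord])
  length(unique(unit[keep]))
}

#' Country-specific species and per-family enrichment
#'
#' A species is specific to a country when all member bins come from that
#' country and none of the members belongs to the base catalog. Per family
#' and country, a two-sided Fisher's exact test on the 2x2 table
#' (country-specific vs rest) x (in family vs not) quantifies family
#' enrichment among the country-specific species.
#'
#' @param clustering A `species_clustering`.
#' @param country_of Named character vector mapping bin id to country.
#' @param base_ids Character vector of base-catalog bin ids.
#' @param family_of Named character vector mapping species representative
#'   id to family label; species without a label are excluded from the
#'   enrichment test with a warning.
#' @return List with `specific` (country -> representative ids) and
#'   `enrichment` (data frame: country, family, odds_ratio, p).
#' @export
country_specific_species <- function(clustering, country_of, base_ids,
                                     family_of = NULL) {
  reps <- vapply(clustering$clusters, function(cl) cl$representative,
                 character(1))
  spec_country <- vapply(clustering$clusters, function(cl) {
    if (any(cl$members %in% base_ids)) return(NA_character_)
    countries <- unique(unname(country_of[cl$members]))
    if (length(countries) == 1 && !is.na(countries)) countries else NA_character_
  }, character(1))
  countries <- sort(unique(spec_country[!is.na(spec_country)]))
  specific <- lapply(setNames(countries, countries), function(co) {
    reps[!is.na(spec_country) & spec_country == co]
  })
  enrichment <- NULL
  if (!is.null(family_of)) {
    fam <- unname(family_of[reps])
    if (any(is.na(fam))) {
      warning(sum(is.na(fam)), " species without family label excluded")
    }
    ok <- !is.na(fam)
    for (co in countries) {
      is_spec <- !is.na(spec_country) & spec_country == co
      for (f in sort(unique(fam[ok]))) {
        in_fam <- ok & fam == f
        tab <- matrix(c(sum(is_spec & in_fam), sum(is_spec & ok & !in_fam),
                        sum(!is_spec & in_fam), sum(!is_spec & ok & !in_fam)),
                      nrow = 2, byrow = TRUE)
        ft <- fisher_exact(tab)
        enrichment <- rbind(enrichment, data.frame(
          country = co, family = f, odds_ratio = ft$odds_ratio, p = ft$p,
          stringsAsFactors = FALSE))
      }
    }
  }
  list(specific = specific, enrichment = enrichment)
}

#' Pair conspecific genomes assembled at two sequencing depths
#'
#' Bins from a lower- and a higher-depth assembly of the same community
#' are clustered by Mash average linkage at 0.1 (90% identity); clusters
#' with exactly one bin per depth condition yield a conspecific pair
#' (clusters with more than one bin from the same depth are rejected).
#' Completeness, contamination, N50, and genome size of the paired bins
#' are compared by two-sided Mann-Whitney U tests.
#'
#' @param bins_low,bins_high Bins from the lower/higher sequencing depth.
#' @param pairing_cutoff Mash linkage cutoff for pairing. Default 0.1.
#' @inheritParams build_sketch
#' @return List with `pairs` (data frame of per-pair metrics) and `tests`
#'   (data frame: metric, U, p).
#' @export
pair_conspecific_across_depths <- function(bins_low, bins_high,
                                           pairing_cutoff = 0.1, k = 21L,
                                           s = 10000L, hash_seed = 42L) {
  all_bins <- c(bins_low, bins_high)
  depth <- c(rep("low", length(bins_low)), rep("high", length(bins_high)))
  ids <- vapply(all_bins, function(b) b$bin_id, character(1))
  dm <- distance_matrix(all_bins, k = k, s = s, hash_seed = hash_seed)
  cl <- average_linkage_cluster(dm, pairing_cutoff)
  metrics <- function(b) {
    c(completeness = b$completeness, contamination = b$contamination,
      n50 = compute_n50(b$contigs), genome_size = genome_length(b))
  }
  pairs <- NULL
  for (g in unique(cl)) {
    members <- which(cl == g)
    if (sum(depth[members] == "low") != 1 ||
        sum(depth[members] == "high") != 1) next
    lo <- all_bins[[members[depth[members] == "low"]]]
    hi <- all_bins[[members[depth[members] == "high"]]]
    pairs <- rbind(pairs, data.frame(
      low_id = lo$bin_id, high_id = hi$bin_id,
      t(setNames(metrics(lo), paste0("low_", names(metrics(lo))))),
      t(setNames(metrics(hi), paste0("high_", names(metrics(hi))))),
      stringsAsFactors = FALSE))
  }
  if (is.null(pairs)) stop("no conspecific pairs formed at cutoff ",
                           pairing_cutoff)
  tests <- do.call(rbind, lapply(
    c("completeness", "contamination", "n50", "genome_size"),
    function(mname) {
      mw <- mann_whitney_u(pairs[[paste0("low_", mname)]],
                           pairs[[paste0("high_", mname)]])
      data.frame(metric = mname, U = mw$U, p = mw$p, stringsAsFactors = FALSE)
    }))
  list(pairs = pairs, tests = tests)
}
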