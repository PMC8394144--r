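#' Align a conspecific genome to its species representative
#'
#' Whole-genome alignment specialized for genomes at >= ~95% identity:
#' maximal exact matches anchored by k-mers that are unique in both
#' genomes are chained collinearly (weighted longest-increasing-
#' subsequence on the second genome's coordinates), and inter-anchor gaps
#' up to `max_gap` bp are closed by global alignment, yielding a set of
#' gapless blocks. Each representative position is covered by at most one
#' block (one-to-one contract). Coordinates are 1-based and global over
#' the concatenation of each genome's contigs; both genomes are assumed
#' to be on the same strand.
#'
#' @param rep,g `genome_bin` objects (or bare character sequences).
#' @param anchor_min Minimum exact-anchor length. Default 31.
#' @param max_gap Largest inter-anchor gap closed by alignment (bp).
#' @return Object of class `conspecific_alignment`: data frame of blocks
#'   (`rep_start`, `g_start`, `len`, 1-based) plus the two concatenated
#'   sequences as attributes. Zero rows when no anchors exist.
#' @export
align_conspecific <- function(rep, g, anchor_min = 31L, max_gap = 5000L) {
  rep_contigs <- if (inherits(rep, "genome_bin")) rep$contigs else as.character(rep)
  g_contigs <- if (inherits(g, "genome_bin")) g$contigs else as.character(g)
  if (sum(nchar(rep_contigs)) == 0 || sum(nchar(g_contigs)) == 0) {
    stop("both genomes must be non-empty")
  }
  blocks <- cpp_anchor_blocks(rep_contigs, g_contigs, as.integer(anchor_min))
  rep_seq <- paste(rep_contigs, collapse = "")
  g_seq <- paste(g_contigs, collapse = "")
  out <- data.frame(rep_start = integer(0), g_start = integer(0),
                    len = integer(0))
  if (nrow(blocks) > 0) {
    # close inter-anchor gaps <= max_gap; equal-length gaps are compared
    # column-wise, unequal ones aligned globally and split into gapless runs
    res <- list(data.frame(rep_start = blocks[1, 1] + 1L,
                           g_start = blocks[1, 2] + 1L, len = blocks[1, 3]))
    if (nrow(blocks) > 1) {
      for (i in 2:nrow(blocks)) {
        prev <- res[[length(res)]]
        prev_rend <- prev$rep_start[nrow(prev)] + prev$len[nrow(prev)] - 1L
        prev_gend <- prev$g_start[nrow(prev)] + prev$len[nrow(prev)] - 1L
        rs <- blocks[i, 1] + 1L; gs <- blocks[i, 2] + 1L
        gap_r <- rs - prev_rend - 1L
        gap_g <- gs - prev_gend - 1L
        if (gap_r > 0 && gap_g > 0 && gap_r <= max_gap && gap_g <= max_gap) {
          if (gap_r == gap_g) {
            res[[length(res) + 1]] <- data.frame(
              rep_start = prev_rend + 1L, g_start = prev_gend + 1L,
              len = gap_r)
          } else {
            sub_r <- substr(rep_seq, prev_rend + 1L, rs - 1L)
            sub_g <- substr(g_seq, prev_gend + 1L, gs - 1L)
            aln <- Biostrings::pairwiseAlignment(sub_g, sub_r,
                                                 type = "global")
            res[[length(res) + 1]] <- gapless_runs(aln, prev_rend, prev_gend)
          }
        }
        res[[length(res) + 1]] <- data.frame(rep_start = rs, g_start = gs,
                                             len = blocks[i, 3])
      }
    }
    out <- do.call(rbind, res)
    out <- out[out$len > 0, , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "rep_seq") <- rep_seq
  attr(out, "g_seq") <- g_seq
  class(out) <- c("conspecific_alignment", "data.frame")
  out
}

# decompose a Biostrings global alignment into gapless blocks with
# coordinates offset to the two genomes
gapless_runs <- function(aln, rep_offset, g_offset) {
  pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  rp <- g_offset; sp <- rep_offset # pattern = g, subject = rep
  runs <- data.frame(rep_start = integer(0), g_start = integer(0),
                     len = integer(0))
  cur_r <- cur_g <- NA_integer_; cur_len <- 0L
  flush <- function() {
    if (cur_len > 0L) {
      runs[nrow(runs) + 1L, ] <<- c(cur_r, cur_g, cur_len)
    }
    cur_len <<- 0L
  }
  for (i in seq_along(pat)) {
    pg <- pat[i] != "-"; sg <- sub[i] != "-"
    if (pg) rp <- rp + 1L
    if (sg) sp <- sp + 1L
    if (pg && sg) {
      if (cur_len == 0L) { cur_r <- sp; cur_g <- rp }
      cur_len <- cur_len + 1L
    } else flush()
  }
  flush()
  runs
}

#' Call SNVs from a conspecific alignment
#'
#' Substitution columns inside gapless alignment blocks are reported as
#' SNVs (1-based positions on the representative); indel columns never
#' enter the blocks and are not SNVs. The aligned length is the total
#' block length on the representative.
#'
#' @param alignment A `conspecific_alignment` from [align_conspecific()].
#' @return List with `snvs` (data frame: pos, ref, alt), `aligned_length`
#'   (bp on the representative), and `blocks`.
#' @export
call_snvs <- function(alignment) {
  rep_seq <- attr(alignment, "rep_seq")
  g_seq <- attr(alignment, "g_seq")
  pos <- integer(0); refb <- character(0); altb <- character(0)
  if (nrow(alignment) > 0) {
    rep_raw <- charToRaw(rep_seq)
    g_raw <- charToRaw(g_seq)
    for (i in seq_len(nrow(alignment))) {
      rs <- alignment$rep_start[i]; gs <- alignment$g_start[i]
      len <- alignment$len[i]
      a <- rep_raw[rs:(rs + len - 1L)]
      b <- g_raw[gs:(gs + len - 1L)]
      mism <- which(a != b)
      if (length(mism) > 0) {
        pos <- c(pos, rs + mism - 1L)
        refb <- c(refb, rawToChar(a[mism], multiple = TRUE))
        altb <- c(altb, rawToChar(b[mism], multiple = TRUE))
      }
    }
  }
  list(snvs = data.frame(pos = pos, ref = refb, alt = altb,
                         stringsAsFactors = FALSE),
       aligned_length = sum(alignment$len), blocks = alignment)
}

#' Per-species SNV density (SNV per kb)
#'
#' For a species cluster G with representative r, the density is the mean
#' over non-representative members g of the per-pair SNV count divided by
#' the aligned length in kb:
#' `snv_per_kb = sum_g( n_snv[r,g] / (aligned_len[r,g]/1000) ) / (n(G)-1)`.
#' Pairs with zero aligned length contribute 0 and are flagged.
#'
#' @param pair_stats Data frame with one row per non-representative
#'   member: columns `genome_id`, `n_snv`, `aligned_length` (bp).
#' @param min_genomes Minimum cluster size n(G) for the density to be
#'   reported in downstream analyses; the statistic itself requires
#'   n(G) >= 2. Default 10, matching the sampling-bias guard used for
#'   catalog-wide density analyses.
#' @return List with `snv_per_kb`, `n_genomes`, `eligible` (n(G) >=
#'   `min_genomes`), and `zero_aligned` (genome ids with no alignment).
#' @export
snv_per_kb <- function(pair_stats, min_genomes = 10L) {
  n_g <- nrow(pair_stats) + 1L # members plus the representative
  if (n_g < 2L) stop("snv_per_kb undefined for clusters with fewer than 2 genomes")
  per_pair <- ifelse(pair_stats$aligned_length > 0,
                     pair_stats$n_snv / (pair_stats$aligned_length / 1000),
                     0)
  list(snv_per_kb = sum(per_pair) / (n_g - 1L), n_genomes = n_g,
       eligible = n_g >= min_genomes,
       zero_aligned = pair_stats$genome_id[pair_stats$aligned_length == 0])
}

#' SNV catalog for a species cluster
#'
#' Aligns every non-representative member to the representative, calls
#' SNVs, and computes the cluster's SNV-per-kb density.
#'
#' @param rep_bin Representative `genome_bin`.
#' @param member_bins List of the other member bins.
#' @param min_genomes Passed to [snv_per_kb()].
#' @param ... Passed to [align_conspecific()].
#' @return List with `pairs` (per-pair list of `snvs`, `aligned_length`,
#'   `blocks`), `pair_stats`, and `summary` (the [snv_per_kb()] result).
#' @export
snv_catalog <- function(rep_bin, member_bins, min_genomes = 10L, ...) {
  pairs <- lapply(member_bins, function(g) {
    call_snvs(align_conspecific(rep_bin, g, ...))
  })
  ids <- vapply(member_bins, function(b) b$bin_id, character(1))
  names(pairs) <- ids
  pair_stats <- data.frame(
    genome_id = ids,
    n_snv = vapply(pairs, function(p) nrow(p$snvs), integer(1)),
    aligned_length = vapply(pairs, function(p) p$aligned_length, numeric(1)),
    stringsAsFactors = FALSE)
  list(pairs = pairs, pair_stats = pair_stats,
       summary = snv_per_kb(pair_stats, min_genomes = min_genomes))
}

#' Chunked SNV-count normality screen for one r-g pair
#'
#' The aligned region on the representative is concatenated and cut into
#' consecutive non-overlapping chunks (trailing partial chunk dropped):
#' 50-kb chunks when the species' SNV density exceeds 5 per kb, 100-kb
#' chunks otherwise. Pairs with at least 5 chunks are tested by a
#' one-sample Kolmogorov-Smirnov test against a normal with the sample
#' mean and SD of the per-chunk counts; chimeric regions inflate local
#' counts and break normality.
#'
#' @param snv_pos SNV positions (1-based, representative coordinates).
#' @param blocks Alignment blocks (`rep_start`, `len`) defining the
#'   aligned region.
#' @param species_snv_per_kb The cluster's SNV density, selecting the
#'   chunk size.
#' @return List with `chunk_size`, `counts`, `n_chunks`, `D`, `p`, and
#'   `tested` (FALSE when fewer than 5 chunks).
#' @export
chunk_normality <- function(snv_pos, blocks, species_snv_per_kb) {
  chunk_size <- if (species_snv_per_kb > 5) 50000L else 100000L
  # map representative positions into the concatenated aligned region
  ord <- order(blocks$rep_start)
  starts <- blocks$rep_start[ord]; lens <- blocks$len[ord]
  offsets <- cumsum(c(0, lens[-length(lens)]))
  aligned_total <- sum(lens)
  n_chunks <- aligned_total %/% chunk_size
  if (n_chunks < 5L) {
    return(list(chunk_size = chunk_size, counts = integer(0),
                n_chunks = as.integer(n_chunks), D = NA_real_, p = NA_real_,
                tested = FALSE))
  }
  idx <- findInterval(snv_pos, starts)
  ok <- idx >= 1 & snv_pos <= starts[pmax(idx, 1)] + lens[pmax(idx, 1)] - 1
  aligned_pos <- offsets[idx[ok]] + (snv_pos[ok] - starts[idx[ok]]) + 1
  chunk_of <- ceiling(aligned_pos / chunk_size)
  counts <- tabulate(chunk_of[chunk_of <= n_chunks], nbins = n_chunks)
  ks <- ks_normal(counts)
  list(chunk_size = chunk_size, counts = counts,
       n_chunks = as.integer(n_chunks), D = ks$D, p = ks$p, tested = TRUE)
}

#' Chunk-normality screen across many r-g pairs with BH correction
#'
#' @param pair_list List of lists, each with `snv_pos`, `blocks`, and
#'   `species_snv_per_kb` (see [chunk_normality()]).
#' @param q_cutoff Pairs with BH q above this are labeled normal.
#' @return Data frame with one row per pair: n_chunks, D, p, q, tested,
#'   and `normal` (q > `q_cutoff`).
#' @export
chunk_normality_screen <- function(pair_list, q_cutoff = 0.05) {
  res <- lapply(pair_list, function(pp) {
    chunk_normality(pp$snv_pos, pp$blocks, pp$species_snv_per_kb)
  })
  out <- data.frame(
    pair = if (is.null(names(pair_list))) seq_along(pair_list)
           else names(pair_list),
    n_chunks = vapply(res, function(r) r$n_chunks, integer(1)),
    D = vapply(res, function(r) r$D, numeric(1)),
    p = vapply(res, function(r) r$p, numeric(1)),
    tested = vapply(res, function(r) r$tested, logical(1)),
    stringsAsFactors = FALSE)
  out$q <- NA_real_
  out$q[out$tested] <- bh_qvalues(out$p[out$tested])
  out$normal <- out$q > q_cutoff
  out
}

#' Mean patristic distance to the k nearest species
#'
#' Branch-length path distances from one leaf of a phylogeny to all other
#' leaves; the mean of the `k_nearest` smallest measures how recently the
#' species' neighborhood diversified (short distances = rapid
#' speciation).
#'
#' @param tree An `ape::phylo` tree or a path to a newick file.
#' @param species Leaf label.
#' @param k_nearest Number of nearest species to average. Default 5.
#' @return Mean patristic distance.
#' @export
nearest_species_distance <- function(tree, species, k_nearest = 5L) {
  if (is.character(tree)) tree <- ape::read.tree(tree)
  if (!species %in% tree$tip.label) stop("leaf not in tree: ", species)
  if (length(tree$tip.label) - 1L < k_nearest) {
    stop("tree has fewer than k_nearest other leaves")
  }
  d <- ape::cophenetic.phylo(tree)[species, ]
  d <- d[names(d) != species]
  mean(sort(d)[seq_len(k_nearest)])
}

#' Association between SNV density and speciation proximity
#'
#' Spearman correlation between per-species SNV density and mean nearest-
#' species patristic distance, plus a two-sided Mann-Whitney U test
#' comparing the densities of the decile of species with the smallest
#' distances (`floor(0.1 * n)` species, distance ties broken by species
#' id) against all remaining species.
#'
#' @param densities Named numeric vector of per-species SNV-per-kb
#'   values.
#' @param distances Named numeric vector of nearest-species distances
#'   (same species ids).
#' @return List with `spearman` (NA when degenerate), `top_decile_p`,
#'   `top_decile_n`, and the top-decile species ids.
#' @export
density_speciation_association <- function(densities, distances) {
  common <- intersect(names(densities), names(distances))
  if (length(common) < 20) stop("need at least 20 species with both values")
  x <- densities[common]; y <- distances[common]
  rho <- if (length(unique(x)) == 1 || length(unique(y)) == 1) NA_real_
         else suppressWarnings(cor(x, y, method = "spearman"))
  ord <- order(y, names(y))
  n_top <- floor(0.1 * length(common))
  top <- names(y)[ord][seq_len(n_top)]
  mw <- mann_whitney_u(x[top], x[setdiff(common, top)])
  list(spearman = rho, top_decile_p = mw$p, top_decile_n = n_top,
       top_decile_species = top)
}
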