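#' Generate unrelated ancestor genomes
#'
#' Draws `n` i.i.d. random DNA sequences. Unrelated random sequences share
#' essentially no 21-mers, so ancestors behave as distinct species for
#' sketching, ANI, and clustering tests.
#'
#' @param n Number of ancestors (>= 1).
#' @param length Genome length in bp (>= 10000).
#' @param gc GC content in (0, 1).
#' @param seed Integer seed; the same seed reproduces the same sequences.
#' @return Character vector of `n` genome sequences.
#' @export
generate_ancestors <- function(n, length, gc = 0.5, seed = 1L) {
  stopifnot_scalar_number(n, "n"); stopifnot_scalar_number(length, "length")
  if (n < 1) stop("n must be >= 1")
  if (length < 10000) stop("length must be >= 10000")
  if (gc <= 0 || gc >= 1) stop("gc must be in (0, 1)")
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  with_seed(seed, {
    vapply(seq_len(n), function(i) {
      paste(sample(names(probs), length, replace = TRUE, prob = probs),
            collapse = "")
    }, character(1))
  })
}

#' Evolve a genome by planted substitutions and short indels
#'
#' Each site is independently substituted with probability `sub_rate`,
#' uniformly to one of the three alternative bases. Short indels (1-5 bp)
#' are planted at rate `indel_rate` per site. Substituted positions are
#' returned in the coordinates of the ancestor, which is the planted truth
#' that SNV calling must recover.
#'
#' @param ancestor Ancestor sequence (non-empty).
#' @param sub_rate Per-site substitution probability.
#' @param indel_rate Per-site indel initiation probability.
#' @param seed Integer seed.
#' @return List with `sequence` (evolved genome) and `sub_positions`
#'   (1-based positions on the ancestor).
#' @export
evolve_genome <- function(ancestor, sub_rate, indel_rate = 0, seed = 1L) {
  if (!is.character(ancestor) || length(ancestor) != 1L || nchar(ancestor) == 0) {
    stop("ancestor must be a single non-empty sequence")
  }
  if (sub_rate + indel_rate >= 0.5) stop("sub_rate + indel_rate must be < 0.5")
  if (sub_rate < 0 || indel_rate < 0) stop("rates must be non-negative")
  with_seed(seed, {
    bases <- strsplit(toupper(ancestor), "")[[1]]
    n <- length(bases)
    sub_pos <- which(runif(n) < sub_rate)
    alphabet <- c("A", "C", "G", "T")
    for (p in sub_pos) {
      bases[p] <- sample(setdiff(alphabet, bases[p]), 1L)
    }
    if (indel_rate > 0) {
      indel_pos <- which(runif(n) < indel_rate)
      # apply right-to-left so earlier coordinates stay valid
      pieces <- as.list(bases)
      for (p in rev(indel_pos)) {
        len <- sample.int(5L, 1L)
        if (runif(1) < 0.5) { # insertion after p
          pieces[[p]] <- paste0(pieces[[p]],
                                paste(sample(alphabet, len, TRUE), collapse = ""))
        } else { # deletion of up to len bases starting at p
          for (q in p:min(n, p + len - 1L)) pieces[[q]] <- ""
        }
      }
      seqout <- paste(unlist(pieces), collapse = "")
    } else {
      seqout <- paste(bases, collapse = "")
    }
    list(sequence = seqout, sub_positions = sub_pos)
  })
}

#' Degrade a genome into a MAG-like bin
#'
#' Emulates the quality range of real MAGs: the genome is fragmented at
#' random breakpoints, a random subset of fragments totaling about
#' `completeness` of the genome is retained, and foreign fragments from a
#' designated contaminant genome totaling about `contamination` of the
#' retained length are appended. Stored completeness/contamination metadata
#' are set to the realized values (as percent), so the bin's QC metadata is
#' truthful by construction.
#'
#' @param genome Source genome sequence.
#' @param completeness Target retained fraction in (0, 1].
#' @param contamination Target contaminant fraction in `[0, 0.2]` of the
#'   retained length.
#' @param contaminant Foreign genome sequence (required when
#'   `contamination > 0`).
#' @param n_contigs Number of fragments to cut the genome into.
#' @param seed Integer seed.
#' @param bin_id,sample_id,country Metadata labels for the resulting bin.
#' @param ... Further arguments passed to [genome_bin()] (rRNA flags etc.).
#' @return A `genome_bin`.
#' @export
degrade_to_bin <- function(genome, completeness = 1, contamination = 0,
                           contaminant = NULL, n_contigs = 10L, seed = 1L,
                           bin_id = "bin1", sample_id = "s1",
                           country = "Korea", ...) {
  if (completeness <= 0 || completeness > 1) stop("completeness must be in (0, 1]")
  if (contamination < 0 || contamination > 0.2) {
    stop("contamination must be in [0, 0.2]")
  }
  if (contamination > 0 && is.null(contaminant)) {
    stop("contaminant genome required when contamination > 0")
  }
  glen <- nchar(genome)
  if (n_contigs < 1 || n_contigs > glen) stop("invalid n_contigs")
  with_seed(seed, {
    cuts <- if (n_contigs > 1) sort(sample.int(glen - 1L, n_contigs - 1L)) else integer(0)
    starts <- c(1L, cuts + 1L)
    ends <- c(cuts, glen)
    frags <- substring(genome, starts, ends)
    target <- completeness * glen
    ord <- sample.int(length(frags))
    keep <- character(0)
    got <- 0
    for (i in ord) {
      if (got >= target) break
      frag <- frags[i]
      room <- target - got
      if (nchar(frag) > room) frag <- substr(frag, 1L, max(1L, round(room)))
      keep <- c(keep, frag)
      got <- got + nchar(frag)
    }
    realized_comp <- sum(nchar(keep)) / glen
    cont_frags <- character(0)
    if (contamination > 0) {
      clen_target <- contamination * sum(nchar(keep))
      nfrag <- max(1L, round(clen_target / 20000))
      per <- max(1L, round(clen_target / nfrag))
      maxstart <- max(1L, nchar(contaminant) - per)
      starts_c <- sample.int(maxstart, nfrag, replace = TRUE)
      cont_frags <- substring(contaminant, starts_c,
                              pmin(nchar(contaminant), starts_c + per - 1L))
    }
    realized_cont <- sum(nchar(cont_frags)) / max(1, sum(nchar(keep)))
    contigs <- c(keep, cont_frags)
    names(contigs) <- paste0(bin_id, "_c", seq_along(contigs))
    genome_bin(bin_id, contigs,
               completeness = 100 * realized_comp,
               contamination = 100 * realized_cont,
               sample_id = sample_id, country = country, ...)
  })
}

#' Generate a random proteome with planted epitope occurrences
#'
#' Proteins are i.i.d. random sequences over the 20-letter amino-acid
#' alphabet; each planted epitope is inserted verbatim at a random offset in
#' its target gene, overwriting the residues there so gene lengths are
#' unchanged. The returned truth lists exactly the planted (gene, epitope)
#' pairs; random ≥5-residue epitope matches are vanishingly unlikely
#' (20^-5 per position), so planted truth equals epitope content.
#'
#' @param n_genes Number of genes.
#' @param gene_len_range Length range (residues), inclusive.
#' @param epitopes Named character vector of epitope peptides (names are
#'   epitope ids).
#' @param planted Data frame with columns `gene` (1-based gene index) and
#'   `epitope_id`, or `NULL`/empty for none.
#' @param seed Integer seed.
#' @return List with `proteins` (named character vector, names
#'   `gene_<i>`) and `truth` (data frame of planted pairs).
#' @export
generate_proteome <- function(n_genes, gene_len_range = c(100L, 400L),
                              epitopes = character(0), planted = NULL,
                              seed = 1L) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  if (length(epitopes) > 0) {
    bad <- vapply(strsplit(toupper(epitopes), ""), function(ch) any(!ch %in% aa),
                  logical(1))
    if (any(bad)) stop("epitope peptides must use the 20-letter alphabet")
  }
  if (!is.null(planted) && nrow(planted) > 0) {
    if (any(planted$gene < 1 | planted$gene > n_genes)) {
      stop("planted gene indices must be in [1, n_genes]")
    }
    if (any(!planted$epitope_id %in% names(epitopes))) {
      stop("planted epitope ids must exist in `epitopes`")
    }
  }
  with_seed(seed, {
    len_choices <- gene_len_range[1]:gene_len_range[2]
    lens <- len_choices[sample.int(length(len_choices), n_genes,
                                   replace = TRUE)]
    proteins <- vapply(lens, function(L) {
      paste(sample(aa, L, replace = TRUE), collapse = "")
    }, character(1))
    names(proteins) <- paste0("gene_", seq_len(n_genes))
    truth <- data.frame(gene = integer(0), epitope_id = character(0),
                        offset = integer(0), stringsAsFactors = FALSE)
    if (!is.null(planted) && nrow(planted) > 0) {
      for (i in seq_len(nrow(planted))) {
        g <- planted$gene[i]
        ep <- toupper(epitopes[[planted$epitope_id[i]]])
        L <- nchar(proteins[g]); el <- nchar(ep)
        if (el > L) stop("epitope longer than target gene ", g)
        off <- sample.int(L - el + 1L, 1L)
        substr(proteins[g], off, off + el - 1L) <- ep
        truth <- rbind(truth, data.frame(
          gene = g, epitope_id = planted$epitope_id[i], offset = off,
          stringsAsFactors = FALSE))
      }
    }
    list(proteins = proteins, truth = truth)
  })
}

#' Generate a synthetic taxon-disease annotation table
#'
#' Emulates a gutMDisorder-style table: taxa split into a high and a low
#' cross-reactivity group; each taxon is annotated for the disease with its
#' group's Bernoulli probability, and annotated taxa get an
#' increase/decrease direction with a group-specific probability. The true
#' 2x2 counts underlying the association odds ratio are returned alongside.
#'
#' @param n_high,n_low Taxa per group.
#' @param p_annot_high,p_annot_low Annotation probabilities per group.
#' @param p_increase_high,p_increase_low Probability that an annotated
#'   taxon's direction is "increase".
#' @param disease Disease label.
#' @param seed Integer seed.
#' @return List with `table` (taxon, disease, direction rows for annotated
#'   taxa), `high_taxa`, `low_taxa`, and `counts` (a 2x2 matrix
#'   group x annotated).
#' @export
generate_disease_table <- function(n_high, n_low, p_annot_high, p_annot_low,
                                   p_increase_high = 0.5,
                                   p_increase_low = 0.5,
                                   disease = "disease_1", seed = 1L) {
  probs <- c(p_annot_high, p_annot_low, p_increase_high, p_increase_low)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  with_seed(seed, {
    high <- paste0("hi_taxon_", seq_len(n_high))
    low <- paste0("lo_taxon_", seq_len(n_low))
    ann_h <- runif(n_high) < p_annot_high
    ann_l <- runif(n_low) < p_annot_low
    mk <- function(taxa, ann, p_inc) {
      taxa <- taxa[ann]
      if (length(taxa) == 0) return(NULL)
      data.frame(taxon = taxa, disease = disease,
                 direction = ifelse(runif(length(taxa)) < p_inc,
                                    "increase", "decrease"),
                 stringsAsFactors = FALSE)
    }
    tab <- rbind(mk(high, ann_h, p_increase_high), mk(low, ann_l, p_increase_low))
    if (is.null(tab)) {
      tab <- data.frame(taxon = character(0), disease = character(0),
                        direction = character(0), stringsAsFactors = FALSE)
    }
    counts <- matrix(c(sum(ann_h), sum(!ann_h), sum(ann_l), sum(!ann_l)),
                     nrow = 2, byrow = TRUE,
                     dimnames = list(c("high", "low"),
                                     c("annotated", "not_annotated")))
    list(table = tab, high_taxa = high, low_taxa = low, counts = counts)
  })
}

#' Draw a community count profile at a given sequencing depth
#'
#' One multinomial draw of `depth` classified reads over the taxa of a true
#' community composition.
#'
#' @param composition Named numeric vector of taxon probabilities summing
#'   to 1.
#' @param depth Total read count (>= 1).
#' @param seed Integer seed.
#' @return Named integer vector of counts summing to `depth`.
#' @export
generate_community_counts <- function(composition, depth, seed = 1L) {
  if (any(composition < 0)) stop("composition probabilities must be >= 0")
  if (abs(sum(composition) - 1) > 1e-12) stop("composition must sum to 1")
  if (depth < 1) stop("depth must be >= 1")
  with_seed(seed, {
    counts <- as.integer(rmultinom(1L, size = depth, prob = composition))
    setNames(counts, names(composition))
  })
}

#' Log-uniform synthetic community composition
#'
#' Taxon probabilities proportional to 10^U with U uniform on
#' `[log10(lo), log10(hi)]`, normalized to sum to 1; spans the
#' relative-abundance strata used by the depth-profiling analysis.
#'
#' @param n_taxa Number of taxa.
#' @param lo,hi Range of unnormalized abundances.
#' @param seed Integer seed.
#' @return Named numeric probability vector.
#' @export
random_composition <- function(n_taxa, lo = 1e-7, hi = 1e-1, seed = 1L) {
  with_seed(seed, {
    raw <- 10^runif(n_taxa, log10(lo), log10(hi))
    setNames(raw / sum(raw), paste0("taxon_", seq_len(n_taxa)))
  })
}
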