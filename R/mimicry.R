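#' Filter a raw epitope table
#'
#' Keeps linear epitopes usable for cross-reactivity scanning: peptides
#' shorter than five residues are dropped, rows requiring a
#' post-translational modification are dropped, rows with non-amino-acid
#' characters are rejected with a warning, and identical peptides are
#' deduplicated (first id kept).
#'
#' @param raw Data frame with columns `epitope_id`, `peptide`, and
#'   `requires_ptm` (logical).
#' @return Named character vector of unique peptides (names = epitope
#'   ids).
#' @export
filter_epitopes <- function(raw) {
  stopifnot(all(c("epitope_id", "peptide", "requires_ptm") %in% names(raw)))
  pep <- toupper(raw$peptide)
  aa_ok <- grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", pep)
  if (any(!aa_ok)) {
    warning(sum(!aa_ok), " epitope row(s) with non-amino-acid characters rejected")
  }
  keep <- aa_ok & nchar(pep) >= 5 & !raw$requires_ptm
  pep <- pep[keep]
  ids <- raw$epitope_id[keep]
  dup <- duplicated(pep)
  setNames(pep[!dup], ids[!dup])
}

#' Align an epitope to a protein and compute the Alignment Score
#'
#' Smith-Waterman local alignment under BLOSUM62 with gap open 11 /
#' extend 1 (BLASTP defaults). The Alignment Score is
#' `AS = (match_length - gap_length) / epitope_length`, where match
#' length counts identical aligned residue pairs and gap length counts
#' gap positions; under this reading `AS = 1` holds exactly when the
#' epitope occurs in the protein verbatim and full-length.
#'
#' @param epitope,protein Peptide strings (non-empty).
#' @return List with `AS` (`-Inf` when no positive-scoring local
#'   alignment exists), `match_length`, `gap_length`, and
#'   `epitope_length`.
#' @export
align_epitope <- function(epitope, protein) {
  if (nchar(epitope) == 0 || nchar(protein) == 0) {
    stop("epitope and protein must be non-empty")
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(epitope), Biostrings::AAString(protein),
    type = "local", substitutionMatrix = "BLOSUM62",
    gapOpening = 11, gapExtension = 1)
  if (Biostrings::score(aln) <= 0) {
    return(list(AS = -Inf, match_length = 0L, gap_length = 0L,
                epitope_length = nchar(epitope)))
  }
  match_len <- unname(Biostrings::nmatch(aln))
  gap_len <- unname(Biostrings::nindel(aln)@insertion[, "WidthSum"] +
                    Biostrings::nindel(aln)@deletion[, "WidthSum"])
  list(AS = (match_len - gap_len) / nchar(epitope),
       match_length = as.integer(match_len), gap_length = as.integer(gap_len),
       epitope_length = nchar(epitope))
}

#' Count epitope-containing genes (ECGs) in a species proteome
#'
#' A gene is an ECG when at least one epitope aligns to it with AS = 1
#' (full-length, gap-free, exact identity); a gene counts once however
#' many epitopes hit it. The ECG density is the ECG count divided by the
#' total gene count, removing the dependence of raw ECG counts on
#' proteome size.
#'
#' @param proteins Named character vector of protein sequences (names =
#'   gene ids).
#' @param epitopes Named character vector of epitope peptides.
#' @return List with `ecg_count`, `gene_count`, `density`, and `ecg_genes`.
#' @export
count_ecgs <- function(proteins, epitopes) {
  if (length(proteins) == 0) stop("empty proteome")
  is_ecg <- vapply(proteins, function(prot) {
    for (ep in epitopes) {
      if (nchar(ep) > nchar(prot)) next
      if (align_epitope(ep, prot)$AS == 1) return(TRUE)
    }
    FALSE
  }, logical(1))
  list(ecg_count = sum(is_ecg), gene_count = length(proteins),
       density = sum(is_ecg) / length(proteins),
       ecg_genes = names(proteins)[is_ecg])
}

#' ECG-density enrichment of a taxonomic clade
#'
#' Compares the ECG densities of a clade's species against the densities
#' of all species: fold change of medians and a two-sided Mann-Whitney U
#' p-value.
#'
#' @param densities Named numeric vector of per-species ECG densities
#'   (all species).
#' @param clade_members Character vector of species ids in the clade
#'   (>= 3).
#' @return List with `fold_change` (NA, flagged, when the all-species
#'   median is 0), `p`, and `n_clade`.
#' @export
clade_enrichment <- function(densities, clade_members) {
  clade_members <- intersect(clade_members, names(densities))
  if (length(clade_members) < 3) stop("clade must have at least 3 members")
  med_all <- stats::median(densities)
  med_clade <- stats::median(densities[clade_members])
  fold <- if (med_all == 0) NA_real_ else med_clade / med_all
  mw <- mann_whitney_u(unname(densities[clade_members]), unname(densities))
  list(fold_change = fold, p = mw$p, n_clade = length(clade_members))
}

#' Partition taxa into high and low cross-reactivity sets
#'
#' Clades enriched for ECG density (p below `p_cutoff` AND fold change
#' above 1 -- a depleted clade with a small p-value must not enter), plus
#' all their descendant taxa, form the high cross-reactivity set; every
#' other taxon is low cross-reactivity.
#'
#' @param enrichments Data frame with columns `taxon`, `fold_change`,
#'   `p`.
#' @param taxonomy Named list mapping a taxon to its child taxa
#'   (recursive descent collects all descendants).
#' @param all_taxa Character vector of every taxon to partition.
#' @param p_cutoff Enrichment significance threshold. Default 1e-5.
#' @return List with `high` and `low` character vectors.
#' @export
partition_cross_reactivity <- function(enrichments, taxonomy, all_taxa,
                                       p_cutoff = 1e-5) {
  seeds <- enrichments$taxon[!is.na(enrichments$fold_change) &
                             enrichments$fold_change > 1 &
                             enrichments$p < p_cutoff]
  descend <- function(taxon) {
    kids <- taxonomy[[taxon]]
    if (is.null(kids)) return(taxon)
    c(taxon, unlist(lapply(kids, descend), use.names = FALSE))
  }
  high <- unique(unlist(lapply(seeds, descend), use.names = FALSE))
  high <- intersect(all_taxa, high)
  list(high = high, low = setdiff(all_taxa, high))
}

#' Disease association of high cross-reactivity taxa
#'
#' For each disease annotated for more than `min_taxa` taxa, two odds
#' ratios with two-sided Fisher's exact tests: association (odds that a
#' high-CR taxon is annotated for the disease / odds that a low-CR taxon
#' is), and direction (odds of "increase" among annotated high-CR taxa /
#' among annotated low-CR taxa). Zero cells get the Haldane-corrected
#' point estimate via [fisher_exact()].
#'
#' @param annotations Data frame with columns `taxon`, `disease`,
#'   `direction` ("increase"/"decrease").
#' @param high Character vector of high cross-reactivity taxa.
#' @param all_taxa All taxa under consideration (annotated or not).
#' @param min_taxa Diseases with annotated-taxon count <= this are
#'   skipped. Default 40 (strictly more than 40 required).
#' @return Data frame: disease, n_annotated, or_assoc, p_assoc,
#'   or_direction, p_direction.
#' @export
disease_association <- function(annotations, high, all_taxa, min_taxa = 40L) {
  out <- NULL
  is_high <- setNames(all_taxa %in% high, all_taxa)
  for (dis in sort(unique(annotations$disease))) {
    ann <- annotations[annotations$disease == dis, , drop = FALSE]
    ann <- ann[ann$taxon %in% all_taxa, , drop = FALSE]
    n_ann <- length(unique(ann$taxon))
    if (n_ann <= min_taxa) next
    annotated <- setNames(all_taxa %in% ann$taxon, all_taxa)
    assoc <- fisher_exact(matrix(c(
      sum(is_high & annotated), sum(is_high & !annotated),
      sum(!is_high & annotated), sum(!is_high & !annotated)),
      nrow = 2, byrow = TRUE))
    inc_taxa <- unique(ann$taxon[ann$direction == "increase"])
    dec_taxa <- setdiff(unique(ann$taxon), inc_taxa)
    dir_test <- fisher_exact(matrix(c(
      sum(inc_taxa %in% high), sum(dec_taxa %in% high),
      sum(!inc_taxa %in% high), sum(!dec_taxa %in% high)),
      nrow = 2, byrow = TRUE))
    out <- rbind(out, data.frame(
      disease = dis, n_annotated = n_ann,
      or_assoc = assoc$odds_ratio, p_assoc = assoc$p,
      or_direction = dir_test$odds_ratio, p_direction = dir_test$p,
      stringsAsFactors = FALSE))
  }
  if (is.null(out)) {
    out <- data.frame(disease = character(0), n_annotated = integer(0),
                      or_assoc = numeric(0), p_assoc = numeric(0),
                      or_direction = numeric(0), p_direction = numeric(0),
                      stringsAsFactors = FALSE)
  }
  out
}

#' Find byte-identical duplicate proteins
#'
#' Groups of 100%-identical sequences (exact string equality); singletons
#' are omitted. The redundant count is the number of sequences that could
#' be removed without losing any distinct sequence, i.e.
#' `sum(group size - 1)`.
#'
#' @param proteins Named character vector of protein sequences.
#' @return List with `groups` (list of id vectors, size >= 2) and
#'   `redundant_count`.
#' @export
find_identical_proteins <- function(proteins) {
  by_seq <- split(names(proteins), unname(proteins))
  groups <- unname(by_seq[vapply(by_seq, length, integer(1)) >= 2])
  list(groups = groups,
       redundant_count = sum(vapply(groups, length, integer(1)) - 1L))
}
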