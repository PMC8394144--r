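#' Contig N50
#'
#' Smallest contig length L such that contigs of length >= L sum to at
#' least half the total assembly length.
#'
#' @param contigs Character vector of sequences, or numeric vector of
#'   contig lengths.
#' @return N50 in bp.
#' @export
compute_n50 <- function(contigs) {
  lens <- if (is.character(contigs)) nchar(contigs) else as.numeric(contigs)
  if (length(lens) == 0 || any(lens <= 0)) {
    stop("contigs must be a non-empty list of non-empty sequences")
  }
  lens <- sort(unname(lens), decreasing = TRUE)
  lens[which(cumsum(lens) >= sum(lens) / 2)[1]]
}

#' CheckM-style genome quality score
#'
#' `QS = completeness - 5 * contamination`, both in percentage points.
#' May be negative for heavily contaminated bins.
#'
#' @param completeness,contamination Percentages in `[0, 100]`.
#' @return Quality score in percentage points.
#' @export
quality_score <- function(completeness, contamination) {
  if (any(completeness < 0 | completeness > 100) ||
      any(contamination < 0 | contamination > 100)) {
    stop("completeness and contamination must be in [0, 100]")
  }
  completeness - 5 * contamination
}

#' Genome intactness score
#'
#' `S = completeness - 5 * contamination + 0.5 * log10(N50)`. Used to pick
#' the representative genome of a species cluster: among conspecific bins
#' the most complete, least contaminated, most contiguous one wins.
#'
#' @inheritParams quality_score
#' @param n50 Assembly N50 in bp (>= 1).
#' @return Intactness score S.
#' @export
intactness_score <- function(completeness, contamination, n50) {
  if (any(n50 < 1)) stop("n50 must be >= 1")
  quality_score(completeness, contamination) + 0.5 * log10(n50)
}

bin_intactness <- function(bin) {
  intactness_score(bin$completeness, bin$contamination,
                   compute_n50(bin$contigs))
}

#' Minimum-quality bin filter
#'
#' A bin is retained when completeness >= 50%, contamination <= 5%, and
#' quality score (completeness - 5 x contamination) >= 50. Boundaries are
#' inclusive.
#'
#' @param bin A `genome_bin`.
#' @return Logical.
#' @export
passes_bin_filter <- function(bin) {
  bin$completeness >= 50 && bin$contamination <= 5 &&
    quality_score(bin$completeness, bin$contamination) >= 50
}

#' Genome quality tier
#'
#' Tiers follow the usual MAG-catalog definitions: HQ requires all three
#' rRNAs (5S, 16S, 23S), >= 18 tRNAs, >= 90% completeness and < 5%
#' contamination; NC requires >= 90% completeness and < 5% contamination;
#' MQ requires completeness in `[50, 90)` and < 5% contamination; anything
#' else is FAIL.
#'
#' @param bin A `genome_bin`.
#' @return One of `"HQ"`, `"NC"`, `"MQ"`, `"FAIL"`.
#' @export
classify_tier <- function(bin) {
  comp <- bin$completeness; cont <- bin$contamination
  if (cont < 5 && comp >= 90) {
    if (bin$has_5S && bin$has_16S && bin$has_23S && bin$trna_count >= 18) {
      return("HQ")
    }
    return("NC")
  }
  if (cont < 5 && comp >= 50 && comp < 90) return("MQ")
  "FAIL"
}

#' Per-bin QC report
#'
#' @param bins List of `genome_bin` objects.
#' @return Data frame with bin_id, n50, qs, intactness, tier, and whether
#'   the bin passes the minimum-quality filter.
#' @export
qc_report <- function(bins) {
  do.call(rbind, lapply(bins, function(b) {
    n50 <- compute_n50(b$contigs)
    data.frame(bin_id = b$bin_id, n50 = n50,
               qs = quality_score(b$completeness, b$contamination),
               intactness = intactness_score(b$completeness,
                                             b$contamination, n50),
               tier = classify_tier(b),
               passes_filter = passes_bin_filter(b),
               stringsAsFactors = FALSE)
  }))
}
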