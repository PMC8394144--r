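#' Construct a genome bin
#'
#' A `genome_bin` bundles the contig sequences of one genome bin (an isolate
#' assembly or a MAG) with the QC metadata that the quality and dereplication
#' stages consume: CheckM-style completeness and contamination estimates,
#' rRNA presence flags, and a tRNA count. Completeness and contamination are
#' percentages in `[0, 100]`, as reported by CheckM.
#'
#' @param bin_id Unique bin identifier.
#' @param contigs Named character vector of DNA sequences (A/C/G/T; IUPAC
#'   ambiguity codes are tolerated but never enter k-mers). Names are contig
#'   ids; unnamed contigs are auto-named.
#' @param completeness,contamination Percentages in `[0, 100]`.
#' @param sample_id,country Sample provenance labels.
#' @param has_5S,has_16S,has_23S Logical rRNA presence flags.
#' @param trna_count Non-negative integer count of tRNA genes.
#' @param source `"MAG"` or `"isolate"`.
#' @return An object of class `genome_bin`.
#' @export
genome_bin <- function(bin_id, contigs, completeness, contamination,
                       sample_id = NA_character_, country = NA_character_,
                       has_5S = FALSE, has_16S = FALSE, has_23S = FALSE,
                       trna_count = 0L, source = "MAG") {
  if (length(contigs) < 1L) stop("a genome bin needs at least one contig")
  contigs <- toupper(as.character(contigs))
  if (any(nchar(contigs) == 0L)) stop("all contigs must be non-empty")
  if (is.null(names(contigs)) || any(!nzchar(names(contigs)))) {
    names(contigs) <- paste0(bin_id, "_c", seq_along(contigs))
  }
  stopifnot_scalar_number(completeness, "completeness")
  stopifnot_scalar_number(contamination, "contamination")
  if (completeness < 0 || completeness > 100) {
    stop("completeness must be in [0, 100]")
  }
  if (contamination < 0 || contamination > 100) {
    stop("contamination must be in [0, 100]")
  }
  structure(list(
    bin_id = as.character(bin_id), sample_id = as.character(sample_id),
    country = as.character(country), contigs = contigs,
    completeness = as.numeric(completeness),
    contamination = as.numeric(contamination),
    has_5S = isTRUE(has_5S), has_16S = isTRUE(has_16S),
    has_23S = isTRUE(has_23S), trna_count = as.integer(trna_count),
    source = match.arg(source, c("MAG", "isolate"))
  ), class = "genome_bin")
}

#' @export
print.genome_bin <- function(x, ...) {
  cat(sprintf(
    "<genome_bin> %s: %d contig(s), %s bp, comp %.1f%%, cont %.1f%% [%s]\n",
    x$bin_id, length(x$contigs),
    format(sum(nchar(x$contigs)), big.mark = ","),
    x$completeness, x$contamination, x$source))
  invisible(x)
}

genome_length <- function(bin) sum(nchar(bin$contigs))

#' Write genome bins as multi-FASTA files (one file per bin)
#'
#' @param bins List of `genome_bin` objects.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the written file paths.
#' @export
write_bins <- function(bins, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(bins, function(b) {
    path <- file.path(dir, paste0(b$bin_id, ".fa"))
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(b$contigs), path)
    path
  }, character(1))
  invisible(paths)
}

#' Write the bin-metadata table
#'
#' Columns: bin_id, sample_id, country, completeness_pct, contamination_pct,
#' has_5S, has_16S, has_23S, trna_count.
#'
#' @inheritParams write_bins
#' @param path Output TSV path.
#' @return Invisibly, the metadata data frame.
#' @export
write_bin_metadata <- function(bins, path) {
  meta <- do.call(rbind, lapply(bins, function(b) {
    data.frame(bin_id = b$bin_id, sample_id = b$sample_id,
               country = b$country, completeness_pct = b$completeness,
               contamination_pct = b$contamination, has_5S = b$has_5S,
               has_16S = b$has_16S, has_23S = b$has_23S,
               trna_count = b$trna_count, stringsAsFactors = FALSE)
  }))
  write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(meta)
}

#' Read genome bins from a directory of FASTA files plus a metadata table
#'
#' @param dir Directory of per-bin FASTA files named `<bin_id>.fa`.
#' @param meta_path Path to the metadata TSV written by [write_bin_metadata()].
#' @return List of `genome_bin` objects.
#' @export
read_bins <- function(dir, meta_path) {
  meta <- read.delim(meta_path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(meta)), function(i) {
    m <- meta[i, ]
    path <- file.path(dir, paste0(m$bin_id, ".fa"))
    if (!file.exists(path)) stop("missing FASTA for bin ", m$bin_id)
    seqs <- Biostrings::readDNAStringSet(path)
    genome_bin(m$bin_id, setNames(as.character(seqs), names(seqs)),
               completeness = m$completeness_pct,
               contamination = m$contamination_pct,
               sample_id = m$sample_id, country = m$country,
               has_5S = m$has_5S, has_16S = m$has_16S, has_23S = m$has_23S,
               trna_count = m$trna_count)
  })
}
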