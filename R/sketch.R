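#' Build a MinHash sketch of a genome bin
#'
#' Canonical k-mers (lexicographic minimum of a k-mer and its reverse
#' complement) are hashed with a seeded 64-bit mix (masked to 53 bits so
#' values are exact R doubles) and the bottom `s` distinct hash values are
#' retained, Mash-style. K-mers containing non-ACGT characters are skipped.
#'
#' @param bin A `genome_bin`, or a character vector of sequences.
#' @param k K-mer size, odd, in `[11, 31]`. Default 21 (the Mash default).
#' @param s Sketch size. Default 10000.
#' @param hash_seed Seed of the hash function; sketches are only comparable
#'   when built with the same `k` and `hash_seed`.
#' @return An object of class `kmer_sketch` with fields `k`, `s`,
#'   `hash_seed`, and the sorted `hashes`.
#' @export
build_sketch <- function(bin, k = 21L, s = 10000L, hash_seed = 42L) {
  if (k < 11 || k > 31 || k %% 2 == 0) stop("k must be odd and in [11, 31]")
  if (s < 1) stop("s must be >= 1")
  contigs <- if (inherits(bin, "genome_bin")) bin$contigs else as.character(bin)
  hashes <- cpp_minhash_sketch(contigs, as.integer(k), as.integer(s),
                               as.numeric(hash_seed))
  structure(list(k = as.integer(k), s = as.integer(s),
                 hash_seed = as.numeric(hash_seed), hashes = hashes),
            class = "kmer_sketch")
}

#' Exact canonical k-mer Jaccard between two genomes
#'
#' Computed from the full distinct canonical k-mer hash sets (no
#' sketching); the reference value that MinHash estimates.
#'
#' @inheritParams build_sketch
#' @param a,b Genome bins or character sequences.
#' @return Exact Jaccard index in `[0, 1]`.
#' @export
exact_kmer_jaccard <- function(a, b, k = 21L, hash_seed = 42L) {
  ca <- if (inherits(a, "genome_bin")) a$contigs else as.character(a)
  cb <- if (inherits(b, "genome_bin")) b$contigs else as.character(b)
  ha <- cpp_all_kmer_hashes(ca, as.integer(k), as.numeric(hash_seed))
  hb <- cpp_all_kmer_hashes(cb, as.integer(k), as.numeric(hash_seed))
  inter <- length(intersect(ha, hb))
  inter / (length(ha) + length(hb) - inter)
}

#' Mash distance between two sketches
#'
#' The Jaccard index is estimated from the bottom-`s` union sketch: among
#' the `s` smallest hashes of the merged hash sets, the fraction present in
#' both sketches. The distance is `-(1/k) * log(2j / (1 + j))`, clamped to
#' `[0, 1]`, with `j = 0` mapped to 1.
#'
#' @param a,b `kmer_sketch` objects with identical `k` and `hash_seed`.
#' @return List with `jaccard` and `dist`.
#' @export
mash_distance <- function(a, b) {
  if (!inherits(a, "kmer_sketch") || !inherits(b, "kmer_sketch")) {
    stop("arguments must be kmer_sketch objects")
  }
  if (a$k != b$k) stop("sketches built with different k")
  if (a$hash_seed != b$hash_seed) stop("sketches built with different hash seeds")
  s <- min(a$s, b$s)
  merged <- sort(unique(c(a$hashes, b$hashes)))
  bottom <- head(merged, s)
  shared <- sum(bottom %in% a$hashes & bottom %in% b$hashes)
  j <- shared / length(bottom)
  d <- if (j <= 0) 1 else min(1, max(0, -(1 / a$k) * log(2 * j / (1 + j))))
  list(jaccard = j, dist = d)
}

#' All-pairs Mash distance matrix
#'
#' @param bins List of `genome_bin` objects (>= 2) or a named list of
#'   precomputed `kmer_sketch` objects.
#' @inheritParams build_sketch
#' @return Symmetric matrix of Mash distances with zero diagonal, with bin
#'   ids as dimnames.
#' @export
distance_matrix <- function(bins, k = 21L, s = 10000L, hash_seed = 42L) {
  if (length(bins) < 2) stop("need at least 2 bins")
  if (inherits(bins[[1]], "kmer_sketch")) {
    sketches <- bins
    ids <- names(bins)
  } else {
    ids <- vapply(bins, function(b) b$bin_id, character(1))
    sketches <- lapply(bins, function(b) {
      tryCatch(build_sketch(b, k, s, hash_seed),
               error = function(e) stop("bin ", b$bin_id, ": ",
                                        conditionMessage(e), call. = FALSE))
    })
  }
  n <- length(sketches)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- mash_distance(sketches[[i]], sketches[[j]])$dist
      m[i, j] <- d
      m[j, i] <- d
    }
  }
  m
}
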