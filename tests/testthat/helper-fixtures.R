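# Shared synthetic fixtures, built once per test run and cached.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# two unrelated 50-kb ancestors
fix_ancestors <- function() {
  fixture("ancestors", function() generate_ancestors(2, 50000, seed = 101))
}

# default planted catalog: 6 species x 5 bins, intact single-sample genomes
fix_scenario <- function() {
  fixture("scenario", function() {
    simulate_catalog_scenario(n_species = 6, bins_per_species = 5,
                              genome_length = 100000, sub_rate = 0.02,
                              completeness = 1, n_contigs = 5, seed = 2024)
  })
}

# independent pure-R canonical k-mer set (oracle for hashing/Jaccard)
oracle_canonical_kmers <- function(seq, k) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < k) return(character(0))
  kmers <- substring(seq, 1:(n - k + 1), k:n)
  kmers <- kmers[!grepl("[^ACGT]", kmers)]
  rc <- chartr("ACGT", "TGCA", kmers)
  rc <- vapply(strsplit(rc, ""), function(x) paste(rev(x), collapse = ""),
               character(1))
  unique(pmin(kmers, rc))
}

oracle_jaccard <- function(a, b, k) {
  ka <- oracle_canonical_kmers(a, k)
  kb <- oracle_canonical_kmers(b, k)
  length(intersect(ka, kb)) / length(union(ka, kb))
}

# exhaustive substring scan: which genes contain any epitope verbatim
oracle_ecg_genes <- function(proteins, epitopes) {
  hits <- vapply(proteins, function(p) {
    any(vapply(epitopes, function(e) grepl(e, p, fixed = TRUE), logical(1)))
  }, logical(1))
  names(proteins)[hits]
}

# two-sided Fisher p by hypergeometric enumeration over fixed margins
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k1 <- a + c
  support <- max(0, k1 - n):min(m, k1)
  probs <- dhyper(support, m, n, k1)
  p_obs <- dhyper(a, m, n, k1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# two-sided Mann-Whitney p by enumeration over group assignments,
# written independently of the package's implementation
oracle_mwu_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  idx <- utils::combn(length(pooled), n1)
  ustat <- function(sel) {
    xs <- pooled[sel]; ys <- pooled[-sel]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  u_obs <- ustat(seq_len(n1))
  u_all <- apply(idx, 2, ustat)
  mu <- n1 * length(y) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}
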