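#' Subsample a taxonomic count profile to a target depth
#'
#' Either without replacement (multivariate hypergeometric, the model for
#' re-sampling reads from a fixed sequencing run; requires `depth` at
#' most the total reference count) or multinomially (sampling from the
#' underlying composition, any depth).
#'
#' @param reference_counts Named integer vector of reference read counts.
#' @param depth Target read count (> 0).
#' @param seed Integer seed.
#' @param mode `"without_replacement"` or `"multinomial"`.
#' @return Object of class `abundance_profile`: list with `counts`,
#'   `rel_abundance` (counts/depth), `depth`, and `seed`.
#' @export
subsample_profile <- function(reference_counts, depth, seed = 1L,
                              mode = c("without_replacement", "multinomial")) {
  mode <- match.arg(mode)
  if (depth <= 0) stop("depth must be > 0")
  total <- sum(reference_counts)
  counts <- with_seed(seed, {
    if (mode == "multinomial") {
      as.numeric(rmultinom(1L, depth, reference_counts / total))
    } else {
      if (depth > total) stop("depth exceeds total reference reads")
      # sequential multivariate hypergeometric draw
      remaining_draw <- depth
      remaining_pool <- total
      out <- numeric(length(reference_counts))
      for (i in seq_along(reference_counts)) {
        ki <- reference_counts[i]
        out[i] <- rhyper(1L, ki, remaining_pool - ki, remaining_draw)
        remaining_draw <- remaining_draw - out[i]
        remaining_pool <- remaining_pool - ki
      }
      out
    }
  })
  counts <- setNames(counts, names(reference_counts))
  structure(list(counts = counts, rel_abundance = counts / depth,
                 depth = depth, seed = seed), class = "abundance_profile")
}

#' Assign features to ten-fold relative-abundance strata
#'
#' Eight strata with upper bounds 1e-07, 1e-06, ..., 1e-01, 1. Intervals
#' are half-open `(lower, upper]`; a feature whose mean abundance is at
#' or below 1e-08 (below the lowest printed level) joins the 1e-07
#' stratum, whose lower edge is otherwise 1e-08.
#'
#' @param mean_abundance Named numeric vector of mean relative abundances
#'   in `[0, 1]`.
#' @return Named integer vector of stratum indices (1 = rarest, 8 = most
#'   abundant), with the strata upper bounds as attribute `"bounds"`.
#' @export
stratify_features <- function(mean_abundance) {
  if (any(mean_abundance > 1)) stop("relative abundances cannot exceed 1")
  if (any(mean_abundance < 0)) stop("relative abundances cannot be negative")
  bounds <- 10^seq(-7, 0)
  idx <- vapply(mean_abundance, function(m) {
    which(m <= bounds + 1e-15)[1]
  }, integer(1))
  structure(setNames(as.integer(idx), names(mean_abundance)),
            bounds = bounds)
}

#' Stratum-wise correlation between two abundance profiles
#'
#' Per relative-abundance stratum, the Pearson (PCC) and Spearman (SCC)
#' correlations of relative abundances between a shallower profile and
#' the reference profile, over that stratum's features. Strata with
#' fewer than 3 features are reported as NA.
#'
#' @param p_low,p_ref `abundance_profile` objects over a common taxon
#'   universe.
#' @param strata Stratum assignment from [stratify_features()], computed
#'   from the reference profile's mean abundances.
#' @return Data frame: stratum, upper_bound, n_features, pcc, scc.
#' @export
stratified_correlation <- function(p_low, p_ref, strata) {
  taxa <- intersect(names(p_low$counts), names(p_ref$counts))
  if (length(taxa) == 0) stop("profiles share no taxa")
  taxa <- intersect(taxa, names(strata))
  bounds <- attr(strata, "bounds")
  do.call(rbind, lapply(seq_along(bounds), function(k) {
    feats <- taxa[strata[taxa] == k]
    if (length(feats) < 3) {
      return(data.frame(stratum = k, upper_bound = bounds[k],
                        n_features = length(feats), pcc = NA_real_,
                        scc = NA_real_))
    }
    x <- p_low$rel_abundance[feats]
    y <- p_ref$rel_abundance[feats]
    pcc <- if (sd(x) == 0 || sd(y) == 0) NA_real_ else cor(x, y)
    scc <- if (sd(x) == 0 || sd(y) == 0) NA_real_
           else suppressWarnings(cor(x, y, method = "spearman"))
    data.frame(stratum = k, upper_bound = bounds[k],
               n_features = length(feats), pcc = pcc, scc = scc)
  }))
}

#' Depth curve: stratified profile fidelity across sequencing depths
#'
#' Subsamples a reference count profile to each requested depth and
#' computes stratum-wise correlations against the full reference,
#' emulating the rarefaction design used to ask how deep one must
#' sequence to profile rare taxa reliably.
#'
#' @param reference_counts Named integer vector (the deepest profile).
#' @param depths Numeric vector of target depths.
#' @param seed Integer seed (one subsample per depth, seeds derived).
#' @param mode Passed to [subsample_profile()].
#' @return Data frame: depth x stratum rows with pcc/scc.
#' @export
depth_curve <- function(reference_counts, depths, seed = 1L,
                        mode = "multinomial") {
  ref_profile <- structure(list(
    counts = reference_counts,
    rel_abundance = reference_counts / sum(reference_counts),
    depth = sum(reference_counts), seed = NA), class = "abundance_profile")
  strata <- stratify_features(ref_profile$rel_abundance)
  do.call(rbind, lapply(seq_along(depths), function(i) {
    prof <- subsample_profile(reference_counts, depths[i],
                              seed = derive_seed(seed, paste0("depth", i)),
                              mode = mode)
    sc <- stratified_correlation(prof, ref_profile, strata)
    sc$depth <- depths[i]
    sc
  }))
}
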