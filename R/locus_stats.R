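#' Allele frequencies at one locus
#'
#' Counts over the `2N` allele copies of the typed (non-missing)
#' individuals.
#'
#' @param gm A [genotype_matrix()].
#' @param locus Locus name.
#' @param subset Optional accession ids restricting the sample.
#' @return List with `locus`, `n_typed` and the named frequency vector
#'   `freqs` (sums to 1).
#' @export
allele_frequencies <- function(gm, locus, subset = NULL) {
  ids <- if (is.null(subset)) gm$accessions else subset
  a1 <- gm$a1[ids, locus]; a2 <- gm$a2[ids, locus]
  typed <- !is.na(a1)
  if (!any(typed)) stop("locus ", locus, ": no typed individuals")
  copies <- c(a1[typed], a2[typed])
  tab <- table(copies)
  freqs <- as.numeric(tab) / length(copies)
  names(freqs) <- names(tab)
  list(locus = locus, n_typed = sum(typed), freqs = freqs)
}

#' Unbiased expected heterozygosity from Nei's gene diversity
#'
#' `He = 2N * h / (2N - 1)` corrects Nei's gene diversity
#' `h = 1 - sum(p^2)` for sampling `2N` allele copies.
#'
#' @param nei Nei's gene diversity at the locus.
#' @param n_typed Number of typed diploid individuals `N`.
#' @return Unbiased `He`.
#' @export
unbiased_expected_heterozygosity <- function(nei, n_typed) {
  2 * n_typed * nei / (2 * n_typed - 1)
}

#' Per-locus diversity statistics
#'
#' For a codominant locus with allele frequencies `p_i` over `N` typed
#' diploids:
#' `Na` = observed allele count; `Ne = 1 / sum(p^2)` effective alleles;
#' `Ho` = observed heterozygote fraction; Nei's gene diversity
#' `h = 1 - sum(p^2)`; unbiased `He = 2N h / (2N - 1)`; Shannon's
#' information index `I = -sum(p ln p)`; polymorphism information content
#' `PIC = 1 - sum(p^2) - sum_{i<j} 2 p_i^2 p_j^2`.
#'
#' @inheritParams allele_frequencies
#' @return One-row data frame with columns `locus, n_typed, na, ne, ho,
#'   he, nei, shannon_i, pic`.
#' @export
locus_summary <- function(gm, locus, subset = NULL) {
  ids <- if (is.null(subset)) gm$accessions else subset
  af <- allele_frequencies(gm, locus, subset = ids)
  if (af$n_typed < 2L) stop("locus ", locus, ": need >= 2 typed individuals")
  p <- af$freqs
  sp2 <- sum(p^2)
  a1 <- gm$a1[ids, locus]; a2 <- gm$a2[ids, locus]
  typed <- !is.na(a1)
  ho <- mean(a1[typed] != a2[typed])
  nei <- 1 - sp2
  # sum_{i<j} 2 p_i^2 p_j^2 = (sum p^2)^2 - sum p^4
  pic <- 1 - sp2 - (sp2^2 - sum(p^4))
  data.frame(locus = locus, n_typed = af$n_typed, na = length(p),
             ne = 1 / sp2, ho = ho,
             he = unbiased_expected_heterozygosity(nei, af$n_typed),
             nei = nei, shannon_i = -sum(p * log(p)), pic = pic,
             stringsAsFactors = FALSE)
}

#' Diversity statistics for every locus
#'
#' @param gm A [genotype_matrix()].
#' @param subset Optional accession ids.
#' @return Data frame with one [locus_summary()] row per locus.
#' @export
summarize_loci <- function(gm, subset = NULL) {
  do.call(rbind, lapply(gm$loci, function(l) locus_summary(gm, l, subset)))
}

#' Column means, totals and the PIC > 0.5 count of a locus-statistics table
#'
#' Mirrors the customary Mean/Total closing rows of a marker diversity
#' table.
#'
#' @param stats Data frame with (at least) numeric columns among
#'   `na, ne, ho, he, nei, shannon_i, pic`.
#' @return List with `mean` and `total` named numeric vectors over the
#'   numeric columns present, and `n_pic_above_0.5`.
#' @export
locus_stats_summary <- function(stats) {
  num <- names(stats)[vapply(stats, is.numeric, logical(1))]
  num <- setdiff(num, "n_typed")
  m <- vapply(num, function(cn) mean(stats[[cn]]), numeric(1))
  s <- vapply(num, function(cn) sum(stats[[cn]]), numeric(1))
  list(mean = m, total = s,
       n_pic_above_0.5 = if ("pic" %in% num) sum(stats$pic > 0.5) else NA)
}

#' Chi-square test of Hardy-Weinberg equilibrium at a locus
#'
#' Observed genotype counts are compared with the Hardy-Weinberg
#' expectations `N p_i^2` (homozygotes) and `2 N p_i p_j` (heterozygotes)
#' computed from the sample allele frequencies.  Degrees of freedom are
#' `a(a-1)/2` for `a` observed alleles (genotype classes `a(a+1)/2` minus
#' `a - 1` estimated frequencies minus 1).  A seeded Monte-Carlo p-value
#' (permuting allele copies into new pairs) is available for sparse
#' tables.
#'
#' @inheritParams allele_frequencies
#' @param monte_carlo Also compute a permutation p-value.
#' @param n_perm Number of permutations (default 999).
#' @return One-row data frame `locus, group, chi2, df, p_value, p_mc,
#'   sig_05, sig_01`; a monomorphic subset yields `df = 0` and `NA`
#'   p-values.
#' @export
hwe_test <- function(gm, locus, subset = NULL, monte_carlo = FALSE,
                     n_perm = 999L) {
  ids <- if (is.null(subset)) gm$accessions else subset
  a1 <- gm$a1[ids, locus]; a2 <- gm$a2[ids, locus]
  typed <- !is.na(a1)
  a1 <- a1[typed]; a2 <- a2[typed]
  n <- length(a1)
  alleles <- sort(unique(c(a1, a2)))
  a <- length(alleles)
  grp <- if (is.null(subset)) "all" else "subset"
  if (a < 2L) {
    return(data.frame(locus = locus, group = grp, chi2 = 0, df = 0L,
                      p_value = NA_real_, p_mc = NA_real_,
                      sig_05 = FALSE, sig_01 = FALSE,
                      stringsAsFactors = FALSE))
  }
  chi2_stat <- function(x1, x2) {
    p <- tabulate(c(match(x1, alleles), match(x2, alleles)), a) / (2 * n)
    obs <- matrix(0, a, a)
    i1 <- match(x1, alleles); i2 <- match(x2, alleles)
    for (k in seq_len(n)) {
      lo <- min(i1[k], i2[k]); hi <- max(i1[k], i2[k])
      obs[lo, hi] <- obs[lo, hi] + 1
    }
    expd <- outer(p, p) * n
    expd <- expd + t(expd)        # 2 N p_i p_j off-diagonal
    diag(expd) <- n * p^2
    ut <- upper.tri(expd, diag = TRUE)
    keep <- ut & expd > 0
    sum((obs[keep] - expd[keep])^2 / expd[keep])
  }
  chi2 <- chi2_stat(a1, a2)
  df <- a * (a - 1L) / 2L
  p_value <- pchisq(chi2, df, lower.tail = FALSE)
  p_mc <- NA_real_
  if (monte_carlo) {
    copies <- c(a1, a2)
    hits <- 0L
    for (b in seq_len(n_perm)) {
      perm <- sample(copies)
      if (chi2_stat(perm[seq_len(n)], perm[n + seq_len(n)]) >=
          chi2 - 1e-12) hits <- hits + 1L
    }
    p_mc <- (hits + 1) / (n_perm + 1)
  }
  data.frame(locus = locus, group = grp, chi2 = chi2, df = df,
             p_value = p_value, p_mc = p_mc,
             sig_05 = !is.na(p_value) && p_value <= 0.05,
             sig_01 = !is.na(p_value) && p_value <= 0.01,
             stringsAsFactors = FALSE)
}

#' Hardy-Weinberg tests for all loci, optionally per group
#'
#' @param gm A [genotype_matrix()].
#' @param groups Optional named vector accession -> group label.
#' @param ... Passed to [hwe_test()].
#' @return Data frame of [hwe_test()] rows.
#' @export
hwe_all <- function(gm, groups = NULL, ...) {
  if (is.null(groups)) {
    return(do.call(rbind, lapply(gm$loci, function(l)
      hwe_test(gm, l, ...))))
  }
  stopifnot(all(gm$accessions %in% names(groups)))
  out <- list()
  for (g in unique(groups[gm$accessions])) {
    ids <- gm$accessions[groups[gm$accessions] == g]
    rows <- do.call(rbind, lapply(gm$loci, function(l)
      hwe_test(gm, l, subset = ids, ...)))
    rows$group <- g
    out[[g]] <- rows
  }
  do.call(rbind, out)
}
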