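#' Hierarchical analysis of molecular variance (AMOVA)
#'
#' Allele-level AMOVA for codominant diploid data with three strata:
#' among groups, among individuals within groups, and within individuals.
#' Each individual contributes two allele copies per locus; the squared
#' distance between two copies is 1 if the alleles differ and 0
#' otherwise.  Per-locus sums of squares are obtained from the
#' pairwise-difference identity `SS = (n/2) (1 - sum(p^2))` for a set of
#' `n` copies with allele frequencies `p`, and summed over loci.
#'
#' Degrees of freedom are `g - 1` (among groups), `N - g` (among
#' individuals) and `N` (within individuals), total `2N - 1`.  Variance
#' components follow the standard nested expectations:
#' `sigma2_w = MS_within`; `sigma2_a = max(0, (MS_among_ind - MS_within)/2)`;
#' `sigma2_g = max(0, (MS_among_groups - MS_among_ind) / (2 n0))` with
#' `n0 = (N - sum(n_i^2)/N) / (g - 1)`.  Negative components are
#' truncated at zero before percentages.  `Phi_ST` is the among-group
#' share of the total variance; an optional permutation p-value permutes
#' whole individuals across groups.
#'
#' @param gm A [genotype_matrix()].
#' @param groups Named vector accession id -> group label; every group
#'   needs >= 2 individuals.
#' @param n_perm Number of permutations for the Phi_ST p-value (0 = none).
#' @param seed Seed for the permutation test.
#' @return Object of class `amova_result`: data frame `table` (df, SS,
#'   MS per level), `variance_components`, `percentages`, `phi_st`, `nm`,
#'   `n0`, and `p_value` when permuted.
#' @export
amova <- function(gm, groups, n_perm = 0L, seed = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  miss <- setdiff(gm$accessions, names(groups))
  if (length(miss)) {
    stop("group label missing for: ", paste(miss, collapse = ", "))
  }
  g_of <- as.character(groups[gm$accessions])
  sizes <- table(g_of)
  if (any(sizes < 2L)) {
    stop("singleton group(s): ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  }
  res <- amova_components(gm, g_of)
  out <- res
  if (n_perm > 0L) {
    if (!is.null(seed)) set.seed(seed)
    hits <- 0L
    for (b in seq_len(n_perm)) {
      perm <- sample(g_of)
      if (amova_components(gm, perm, components_only = TRUE) >=
          res$phi_st - 1e-12) hits <- hits + 1L
    }
    out$p_value <- (hits + 1) / (n_perm + 1)
  }
  structure(out, class = "amova_result")
}

# Core SS partition; with components_only returns just phi_st (for perms).
amova_components <- function(gm, g_of, components_only = FALSE) {
  n_ind <- length(gm$accessions)
  gl <- unique(g_of)
  g <- length(gl)
  ss_wi <- ss_ag <- ss_ai <- 0
  for (l in gm$loci) {
    a1 <- gm$a1[, l]; a2 <- gm$a2[, l]
    typed <- !is.na(a1)
    # sum of squares of a copy set from its allele counts
    ss_of <- function(copies) {
      n <- length(copies)
      if (n == 0L) return(0)
      p2 <- sum((table(copies) / n)^2)
      n / 2 * (1 - p2)
    }
    copies_all <- c(a1[typed], a2[typed])
    ss_tot_l <- ss_of(copies_all)
    ss_wi_l <- sum(a1[typed] != a2[typed]) / 2
    ss_grp_l <- 0
    for (gg in gl) {
      sel <- typed & g_of == gg
      ss_grp_l <- ss_grp_l + ss_of(c(a1[sel], a2[sel]))
    }
    ss_wi <- ss_wi + ss_wi_l
    ss_ai <- ss_ai + (ss_grp_l - ss_wi_l)
    ss_ag <- ss_ag + (ss_tot_l - ss_grp_l)
  }
  sizes <- as.numeric(table(g_of))
  df_ag <- g - 1L
  df_ai <- n_ind - g
  df_wi <- n_ind
  ms_ag <- ss_ag / df_ag
  ms_ai <- ss_ai / df_ai
  ms_wi <- ss_wi / df_wi
  n0 <- (n_ind - sum(sizes^2) / n_ind) / (g - 1)
  s2_w <- ms_wi
  s2_a <- max(0, (ms_ai - ms_wi) / 2)
  s2_g <- max(0, (ms_ag - ms_ai) / (2 * n0))
  tot <- s2_g + s2_a + s2_w
  phi_st <- if (tot > 0) s2_g / tot else 0
  if (components_only) return(phi_st)
  tab <- data.frame(
    source = c("among_groups", "among_individuals", "within_individuals",
               "total"),
    df = c(df_ag, df_ai, df_wi, df_ag + df_ai + df_wi),
    SS = c(ss_ag, ss_ai, ss_wi, ss_ag + ss_ai + ss_wi),
    MS = c(ms_ag, ms_ai, ms_wi, NA),
    est_var = c(s2_g, s2_a, s2_w, tot),
    percent = 100 * c(s2_g, s2_a, s2_w, tot) / tot,
    stringsAsFactors = FALSE)
  list(table = tab,
       variance_components = c(among_groups = s2_g,
                               among_individuals = s2_a,
                               within_individuals = s2_w),
       percentages = 100 * c(among_groups = s2_g, among_individuals = s2_a,
                             within_individuals = s2_w) / tot,
       phi_st = phi_st,
       nm = if (phi_st > 0 && phi_st < 1) gene_flow(phi_st) else NA_real_,
       n0 = n0, p_value = NA_real_)
}

#' @export
print.amova_result <- function(x, ...) {
  cat("AMOVA\n")
  print(x$table, row.names = FALSE, digits = 6)
  cat(sprintf("Phi_ST = %.4f  Nm = %.4f\n", x$phi_st, x$nm))
  if (!is.na(x$p_value)) cat(sprintf("permutation p = %.4g\n", x$p_value))
  invisible(x)
}

#' Island-model gene flow from a fixation index
#'
#' `Nm = (1 - Fst) / (4 Fst)`, the effective number of migrants per
#' generation under Wright's island model.
#'
#' @param fst Fixation index strictly between 0 and 1.
#' @return Positive scalar.
#' @export
gene_flow <- function(fst) {
  if (!is.numeric(fst) || fst <= 0 || fst >= 1) {
    stop("fst must lie strictly between 0 and 1")
  }
  (1 - fst) / (4 * fst)
}
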