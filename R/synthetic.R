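#' Simulate a structured germplasm genotype panel
#'
#' Balding-Nichols model: each locus draws ancestral allele frequencies
#' from a symmetric Dirichlet; each latent group draws its own
#' frequencies from `Dirichlet(p * (1 - F) / F)` so that the expected
#' among-group differentiation equals `fst`; individuals are two
#' independent allele copies (Hardy-Weinberg within groups).  Clone
#' groups are planted by copying a source genotype bit-identically to
#' other members under new accession ids (synonyms); homonym groups
#' assign one shared variety name to genetically distinct accessions.
#' Missing cells are masked at `missing_rate`.
#'
#' Defaults mirror a 113-accession yam panel genotyped at 19 SSR loci
#' carrying 4-15 alleles each, with five groups of sizes 75/27/6/3/2 and
#' strong differentiation.
#'
#' @param group_sizes Integer vector of latent group sizes.
#' @param n_loci Number of loci.
#' @param alleles_per_locus Inclusive range of allele counts per locus.
#' @param fst Balding-Nichols differentiation, strictly in (0, 1).
#' @param clone_groups Integer vector: sizes of planted clone groups
#'   (each >= 2); `clone_pairs = n` is shorthand for `rep(2, n)`.
#' @param clone_pairs Convenience count of clone pairs.
#' @param homonym_groups Number of planted homonym groups (distinct
#'   genotypes sharing one variety name).
#' @param missing_rate Per-cell missing probability.
#' @param seed RNG seed.
#' @return List with `gm` (a [genotype_matrix()]), `groups` (named
#'   vector), `names` (accession -> variety name), and `truth`
#'   (`clone_groups`, `homonym_names`, `group_freqs`, `fst`).
#' @export
simulate_populations <- function(group_sizes = c(75L, 27L, 6L, 3L, 2L),
                                 n_loci = 19L,
                                 alleles_per_locus = c(4L, 15L),
                                 fst = 0.32,
                                 clone_groups = integer(0),
                                 clone_pairs = NULL,
                                 homonym_groups = 0L,
                                 missing_rate = 0,
                                 seed = 1L) {
  if (fst <= 0 || fst >= 1) stop("fst must lie strictly in (0, 1)")
  if (!is.null(clone_pairs)) clone_groups <- rep(2L, clone_pairs)
  if (length(clone_groups) && any(clone_groups < 2L)) {
    stop("clone groups need >= 2 members")
  }
  n <- sum(group_sizes)
  if (sum(pmax(clone_groups - 1L, 0L)) > n / 2) {
    stop("infeasible: too many clones for the panel size")
  }
  set.seed(seed)
  g <- length(group_sizes)
  acc <- sprintf("ACC%03d", seq_len(n))
  grp <- rep(paste0("G", seq_len(g)), group_sizes)
  names(grp) <- acc

  a1 <- a2 <- matrix(NA_integer_, n, n_loci)
  loci <- sprintf("SSR%02d", seq_len(n_loci))
  group_freqs <- vector("list", n_loci)
  for (l in seq_len(n_loci)) {
    na_l <- sample(alleles_per_locus[1L]:alleles_per_locus[2L], 1L)
    base <- sample(80:320, 1L)
    sizes_bp <- base + 2L * (seq_len(na_l) - 1L)
    anc <- rgamma(na_l, 1, 1)
    anc <- anc / sum(anc)
    pf <- matrix(0, g, na_l)
    conc <- anc * (1 - fst) / fst
    for (k in seq_len(g)) {
      x <- rgamma(na_l, conc, 1)
      while (sum(x) == 0) x <- rgamma(na_l, conc, 1)
      pf[k, ] <- x / sum(x)
    }
    group_freqs[[l]] <- list(alleles = sizes_bp, freqs = pf)
    for (k in seq_len(g)) {
      rows <- which(grp == paste0("G", k))
      a1[rows, l] <- sizes_bp[sample.int(na_l, length(rows),
                                         replace = TRUE, prob = pf[k, ])]
      a2[rows, l] <- sizes_bp[sample.int(na_l, length(rows),
                                         replace = TRUE, prob = pf[k, ])]
    }
  }

  clone_manifest <- list()
  if (length(clone_groups)) {
    # plant clones inside the largest groups so sources stay distinct
    pool <- order(-group_sizes)
    used <- logical(n)
    gi <- 1L
    for (ci in seq_along(clone_groups)) {
      size <- clone_groups[ci]
      repeat {
        rows <- which(grp == paste0("G", pool[gi]) & !used)
        if (length(rows) >= size) break
        gi <- gi %% g + 1L
      }
      members <- rows[seq_len(size)]
      used[members] <- TRUE
      src <- members[1L]
      for (mbr in members[-1L]) {
        a1[mbr, ] <- a1[src, ]
        a2[mbr, ] <- a2[src, ]
      }
      clone_manifest[[ci]] <- acc[members]
      gi <- gi %% g + 1L
    }
  }

  if (missing_rate > 0) {
    mask <- matrix(runif(n * n_loci) < missing_rate, n, n_loci)
    a1[mask] <- NA_integer_
    a2[mask] <- NA_integer_
  }

  vnames <- paste0("Variety_", seq_len(n))
  names(vnames) <- acc
  homonym_names <- list()
  if (homonym_groups > 0L) {
    cloned <- unlist(clone_manifest)
    free <- setdiff(acc, cloned)
    for (h in seq_len(homonym_groups)) {
      size <- 2L + (h %% 2L)          # alternate pairs and triples
      members <- free[seq_len(size)]
      free <- setdiff(free, members)
      shared <- paste0("Shared_", h)
      vnames[members] <- shared
      homonym_names[[h]] <- members
    }
  }

  dimnames(a1) <- dimnames(a2) <- list(acc, loci)
  list(gm = genotype_matrix(a1, a2), groups = grp, names = vnames,
       truth = list(clone_groups = clone_manifest,
                    homonym_names = homonym_names,
                    group_freqs = group_freqs, fst = fst))
}

#' Simulate a graded DUS trait table with low-rank structure
#'
#' Accessions receive scores on `n_factors` independent standard-normal
#' latent factors.  Each of the `n_core` core traits tracks one factor
#' almost directly (loading 1, small unique noise `core_uniqueness`);
#' each remaining informative trait is a satellite of one factor with
#' its loading solved so that the factor components of the trait
#' correlation matrix follow the decaying `target_spectrum` -- the
#' spiked, well-separated eigen-spectrum typical of correlated
#' morphology, which is what makes the individual components (and hence
#' the composite score built from them) estimable.  Satellites carry
#' unique noise `satellite_uniqueness`, always larger than the cores',
#' so each factor's single best marker is its core trait.
#' `n_invariant` traits are constant.  Replicate measurements add noise
#' with SD `noise_sd`, and each quantitative trait is graded through its
#' own LSD scheme before entering the code matrix, exactly as field
#' data would be.
#'
#' Defaults mirror the DUS design of a 113-accession panel: 50 traits of
#' which 10 show no variation, a 14-trait generative core, and 30
#' replicate plants per accession.
#'
#' @param n_accessions,n_traits,n_invariant,n_core,n_factors Panel shape.
#' @param replicate_count Replicate measurements per accession.
#' @param noise_sd Replicate noise SD (trait units; factor signal has
#'   SD 1).
#' @param core_uniqueness,satellite_uniqueness Unique variance of core
#'   and satellite traits (trait units).
#' @param target_spectrum Decreasing target eigenvalues of the factor
#'   components (length `n_factors`); the default spans 4.3 to 1.35.
#' @param n_grades Grades per trait (odd).
#' @param seed RNG seed.
#' @return List with `table` (a [trait_table()] including raw means and
#'   replicates) and `truth` (`core_traits`, `loadings`, `factors`).
#' @export
simulate_traits <- function(n_accessions = 113L, n_traits = 50L,
                            n_invariant = 10L, n_core = 14L,
                            n_factors = 14L, replicate_count = 30L,
                            noise_sd = 0.5,
                            core_uniqueness = 0.025,
                            satellite_uniqueness = 0.25,
                            target_spectrum = NULL,
                            n_grades = 5L, seed = 1L) {
  if (n_invariant >= n_traits) stop("n_invariant must be < n_traits")
  if (n_factors > n_traits) stop("n_factors must be <= n_traits")
  n_inform <- n_traits - n_invariant
  if (n_core > n_inform) stop("too many core traits")
  if (is.null(target_spectrum)) {
    target_spectrum <- if (n_factors == 14L) {
      c(4.30, 3.55, 3.22, 2.95, 2.70, 2.45, 2.22, 2.02,
        1.85, 1.73, 1.62, 1.52, 1.43, 1.35)
    } else {
      exp(seq(log(4.3), log(1.35), length.out = n_factors))
    }
  }
  stopifnot(length(target_spectrum) == n_factors,
            !is.unsorted(rev(target_spectrum)))
  set.seed(seed)
  acc <- sprintf("ACC%03d", seq_len(n_accessions))
  tid <- sprintf("T%d", seq_len(n_traits))
  Z <- matrix(rnorm(n_accessions * n_factors), n_accessions, n_factors)

  loadings <- matrix(0, n_traits, n_factors,
                     dimnames = list(tid, paste0("F", seq_len(n_factors))))
  uniq <- numeric(n_traits)
  inform <- seq_len(n_inform)              # first traits informative
  core <- inform[seq_len(n_core)]
  h_core <- 1 / (1 + core_uniqueness)
  for (i in seq_len(n_core)) {
    fct <- ((i - 1L) %% n_factors) + 1L
    loadings[core[i], fct] <- 1
    uniq[core[i]] <- core_uniqueness
  }
  noncore <- setdiff(inform, core)
  # allocate satellites so factor components approach target_spectrum:
  # start one per factor, then greedily feed the factor with the
  # largest unmet communality need
  need <- pmax(target_spectrum - h_core, 0.05)
  counts <- rep(1L, n_factors)
  if (length(noncore) < n_factors) {
    counts <- rep(0L, n_factors)
    counts[seq_along(noncore)] <- 1L
  }
  while (sum(counts) < length(noncore)) {
    i <- which.max(need / pmax(counts, 1))
    counts[i] <- counts[i] + 1L
  }
  slot <- rep(seq_len(n_factors), counts)
  for (i in seq_along(noncore)) {
    fct <- slot[i]
    h_each <- min(need[fct] / counts[fct], 0.9)
    loadings[noncore[i], fct] <-
      sqrt(h_each * satellite_uniqueness / (1 - h_each))
    uniq[noncore[i]] <- satellite_uniqueness
  }

  mu <- Z %*% t(loadings)                  # accession x trait signal
  mu <- mu + sapply(uniq, function(u)
    if (u > 0) rnorm(n_accessions, 0, sqrt(u)) else numeric(n_accessions))
  invariant <- setdiff(seq_len(n_traits), inform)
  mu[, invariant] <- 0

  reps <- vector("list", n_traits)
  raw <- matrix(NA_real_, n_accessions, n_traits,
                dimnames = list(acc, tid))
  codes <- matrix(NA_integer_, n_accessions, n_traits,
                  dimnames = list(acc, tid))
  descriptors <- vector("list", n_traits)
  for (t in seq_len(n_traits)) {
    vals <- rep(mu[, t], each = replicate_count) +
      rnorm(n_accessions * replicate_count, 0,
            if (t %in% invariant) 0 else noise_sd)
    df <- data.frame(
      accession_id = rep(acc, each = replicate_count),
      trait_id = tid[t],
      replicate = rep(seq_len(replicate_count), n_accessions),
      value = vals, stringsAsFactors = FALSE)
    reps[[t]] <- df
    raw[, t] <- tapply(df$value, factor(df$accession_id, levels = acc),
                       mean)
    scheme <- build_lsd_grading(df, n_grades = n_grades)
    codes[, t] <- apply_grading(raw[, t], scheme)
    descriptors[[t]] <- trait_descriptor(
      tid[t], kind = "quantitative",
      class_codes = sort(unique(scheme$codes)),
      is_core = t %in% core)
  }
  tab <- trait_table(codes, descriptors, raw = raw,
                     replicates = do.call(rbind, reps))
  list(table = tab,
       truth = list(core_traits = tid[core], loadings = loadings,
                    factors = Z, invariant_traits = tid[invariant]))
}

#' Full-scale synthetic study bundle
#'
#' One call producing a 113-accession panel: 19 SSR loci with five
#' latent groups sized 75/27/6/3/2, nine planted clone groups totalling
#' 19 redundant accessions (so 94 distinct genotypes), three homonym
#' groups, and a 50-trait DUS table with 10 invariant traits and a
#' 14-trait generative core — the shape of a complete two-arm
#' characterization study, for end-to-end pipeline tests.
#'
#' @param seed RNG seed; the same seed reproduces the identical bundle.
#' @return List with `gm`, `groups`, `names`, `traits` (a
#'   [trait_table()]), and `truth` from both generators.
#' @export
paper_scale_fixture <- function(seed = 1L) {
  pop <- simulate_populations(
    group_sizes = c(75L, 27L, 6L, 3L, 2L),
    n_loci = 19L, alleles_per_locus = c(4L, 15L), fst = 0.32,
    clone_groups = c(6L, 4L, 3L, 3L, 3L, 3L, 2L, 2L, 2L),
    homonym_groups = 3L, missing_rate = 0, seed = seed)
  tr <- simulate_traits(n_accessions = 113L, seed = seed + 1L)
  list(gm = pop$gm, groups = pop$groups, names = pop$names,
       traits = tr$table,
       truth = c(pop$truth, tr$truth))
}
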