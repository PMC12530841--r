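#' Bayesian model-based clustering of multilocus genotypes
#'
#' Gibbs sampler for assigning diploid multilocus genotypes to `K`
#' clusters with an uncorrelated allele-frequency prior
#' `Dirichlet(lambda)`.  Each sweep updates cluster allele frequencies
#' from their Dirichlet full conditional, the origin of every allele copy
#' given frequencies and memberships, and the membership vectors: under
#' the admixture model `q_i ~ Dirichlet(alpha + copy counts)` with a
#' random-walk Metropolis step on the common `alpha` (uniform prior on
#' `(0, alpha_max)`); under the no-admixture model each individual gets a
#' single cluster sampled from its likelihood.  Missing genotypes are
#' skipped as uninformative.  The marginal data probability is estimated
#' as `mean(lnL) - var(lnL)/2` over post-burn-in sweeps.
#'
#' @param gm A [genotype_matrix()] with at least one polymorphic locus.
#' @param k Number of clusters (`1 <= k <=` accessions).
#' @param model `"admixture"` (default) or `"no_admixture"`.
#' @param burn_in,iterations Burn-in sweeps and post-burn-in sweeps.
#'   Defaults (5000/20000) suit test-scale data; production runs
#'   typically use 100000/200000.
#' @param seed RNG seed; identical inputs and seed give bit-identical
#'   output.
#' @param lambda Dirichlet prior parameter for allele frequencies.
#' @param alpha_init,alpha_step,alpha_max Admixture `alpha` initial
#'   value, Metropolis step SD, and upper bound.
#' @param thin Record every `thin`-th sweep in the traces.
#' @return Object of class `structure_run`: `q` (posterior-mean
#'   membership matrix, rows sum to 1), `ln_prob_data`, `lnl_trace`,
#'   `alpha_trace`, and the run settings.
#' @export
run_structure <- function(gm, k, model = c("admixture", "no_admixture"),
                          burn_in = 5000L, iterations = 20000L,
                          seed = NULL, lambda = 1, alpha_init = 1,
                          alpha_step = 0.025, alpha_max = 10,
                          thin = 10L) {
  model <- match.arg(model)
  stopifnot(inherits(gm, "genotype_matrix"))
  if (k < 1L) stop("k must be >= 1")
  if (k > length(gm$accessions)) stop("k exceeds the number of accessions")
  n_all <- integer(length(gm$loci))
  a1 <- matrix(-1L, nrow(gm$a1), ncol(gm$a1))
  a2 <- a1
  poly <- FALSE
  for (j in seq_along(gm$loci)) {
    alleles <- sort(unique(c(gm$a1[, j], gm$a2[, j])))
    alleles <- alleles[!is.na(alleles)]
    if (length(alleles) == 0L) {
      stop("locus ", gm$loci[j], " is entirely missing")
    }
    if (length(alleles) > 1L) poly <- TRUE
    n_all[j] <- length(alleles)
    a1[, j] <- match(gm$a1[, j], alleles) - 1L
    a2[, j] <- match(gm$a2[, j], alleles) - 1L
  }
  if (!poly) stop("no polymorphic locus")
  a1[is.na(a1)] <- -1L; a2[is.na(a2)] <- -1L
  if (!is.null(seed)) set.seed(seed)
  res <- .structure_gibbs(a1, a2, n_all, as.integer(k),
                          model == "admixture", as.integer(burn_in),
                          as.integer(iterations), lambda, alpha_init,
                          alpha_step, alpha_max, as.integer(thin))
  q <- res$q
  dimnames(q) <- list(gm$accessions, paste0("K", seq_len(k)))
  lnl <- res$lnl_post
  structure(
    list(k = as.integer(k), model = model, seed = seed,
         burn_in = as.integer(burn_in), iterations = as.integer(iterations),
         q = q,
         ln_prob_data = mean(lnl) - var(lnl) / 2,
         lnl_trace = res$lnl_trace, alpha_trace = res$alpha_trace,
         alpha_accept_rate = res$alpha_accept_rate),
    class = "structure_run")
}

#' @export
print.structure_run <- function(x, ...) {
  cat(sprintf("structure_run: K=%d (%s), %d+%d sweeps, lnP(D)=%.2f\n",
              x$k, x$model, x$burn_in, x$iterations, x$ln_prob_data))
  invisible(x)
}

#' Sweep over K with replicate runs
#'
#' Runs [run_structure()] for every combination of `k_range` and
#' replicate, with per-run seeds derived deterministically from `seed`.
#'
#' @param gm A [genotype_matrix()].
#' @param k_range Contiguous increasing integer vector of K values.
#' @param replicates Replicate runs per K (>= 2 for delta-K).
#' @param seed Base seed; run `(k, r)` uses `seed + 1000*k + r`.
#' @param ... Passed to [run_structure()].
#' @return Object of class `structure_sweep`: data frame `table`
#'   (`k, replicate, seed, ln_prob_data`), per-K `summary`
#'   (`k, mean_l, sd_l`), and the list of `runs`.
#' @export
sweep_k <- function(gm, k_range, replicates = 3L, seed = 1L, ...) {
  k_range <- as.integer(k_range)
  if (length(k_range) > 1L && !all(diff(k_range) == 1L)) {
    stop("k_range must be contiguous")
  }
  runs <- list()
  rows <- list()
  for (k in k_range) {
    for (r in seq_len(replicates)) {
      s <- seed + 1000L * k + r
      run <- run_structure(gm, k, seed = s, ...)
      runs[[sprintf("K%d_rep%d", k, r)]] <- run
      rows[[length(rows) + 1L]] <- data.frame(
        k = k, replicate = r, seed = s,
        ln_prob_data = run$ln_prob_data)
    }
  }
  tab <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(tab, tab$k), function(df) {
    data.frame(k = df$k[1L], mean_l = mean(df$ln_prob_data),
               sd_l = if (nrow(df) > 1L) sd(df$ln_prob_data) else NA_real_)
  }))
  rownames(summ) <- NULL
  structure(list(table = tab, summary = summ, runs = runs,
                 replicates = replicates),
            class = "structure_sweep")
}

#' Evanno delta-K statistic
#'
#' `L'(K) = L(K) - L(K-1)`;
#' `deltaK = |L(K+1) - 2 L(K) + L(K-1)| / sd(L(K))`, defined for interior
#' K only and requiring >= 2 replicates with non-zero spread.  The best K
#' is the interior argmax of deltaK.
#'
#' @param sweep A [sweep_k()] result, or a data frame with columns
#'   `k, mean_l, sd_l`.
#' @return List with `table` (k, mean_l, sd_l, delta_k) and `best_k`.
#' @export
evanno_delta_k <- function(sweep) {
  summ <- if (inherits(sweep, "structure_sweep")) sweep$summary else sweep
  summ <- summ[order(summ$k), ]
  if (nrow(summ) < 3L) stop("need at least 3 consecutive K values")
  interior <- seq(2L, nrow(summ) - 1L)
  if (any(is.na(summ$sd_l[interior]))) {
    stop("delta-K needs >= 2 replicates per K")
  }
  if (any(summ$sd_l[interior] == 0)) {
    stop("zero sd of L(K) at interior K; use distinct replicate seeds")
  }
  dk <- rep(NA_real_, nrow(summ))
  for (i in interior) {
    dk[i] <- abs(summ$mean_l[i + 1L] - 2 * summ$mean_l[i] +
                   summ$mean_l[i - 1L]) / summ$sd_l[i]
  }
  summ$delta_k <- dk
  best <- summ$k[interior][which.max(dk[interior])]
  list(table = summ, best_k = best)
}

#' Align replicate membership matrices across label switching
#'
#' Cluster labels are arbitrary between runs; each run's columns are
#' permuted to best match the first run (maximizing the summed
#' column-wise dot products), exhaustively for `K <= 8` and greedily
#' beyond, then averaged element-wise.
#'
#' @param runs List of [run_structure()] results (or Q matrices) at the
#'   same K and accession order.
#' @return List with `aligned` (permuted Q matrices), `mean_q`, and the
#'   column `permutations` applied.
#' @export
align_runs <- function(runs) {
  qs <- lapply(runs, function(r) if (inherits(r, "structure_run")) r$q else r)
  K <- unique(vapply(qs, ncol, integer(1)))
  if (length(K) != 1L) stop("runs have mismatched K")
  ref <- qs[[1L]]
  perm_of <- function(q) {
    score <- crossprod(ref, q)          # K x K column dot products
    if (K <= 8L) {
      best <- NULL; best_s <- -Inf
      perms <- all_permutations(K)
      for (p in perms) {
        s <- sum(score[cbind(seq_len(K), p)])
        if (s > best_s) { best_s <- s; best <- p }
      }
      best
    } else {
      p <- integer(K)
      used <- logical(K)
      for (k in seq_len(K)) {
        cand <- which(!used)
        p[k] <- cand[which.max(score[k, cand])]
        used[p[k]] <- TRUE
      }
      p
    }
  }
  perms <- lapply(qs, perm_of)
  aligned <- Map(function(q, p) {
    out <- q[, p, drop = FALSE]
    colnames(out) <- colnames(ref)
    out
  }, qs, perms)
  mean_q <- Reduce(`+`, aligned) / length(aligned)
  list(aligned = aligned, mean_q = mean_q, permutations = perms)
}

# all permutations of 1..k (k small)
all_permutations <- function(k) {
  if (k == 1L) return(list(1L))
  out <- list()
  for (p in all_permutations(k - 1L)) {
    for (pos in seq_len(k)) {
      out[[length(out) + 1L]] <- append(p, k, after = pos - 1L)
    }
  }
  out
}
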