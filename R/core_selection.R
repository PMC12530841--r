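#' Standardize graded traits for multivariate analysis
#'
#' Drops zero-variance (invariant) traits, reports them, and centers and
#' scales the remaining columns to unit variance.  Missing codes are
#' mean-imputed with a warning (PCA needs a complete matrix).
#'
#' @param table A [trait_table()] or a numeric matrix.
#' @param use `"codes"` or `"raw"`.
#' @return Numeric matrix with attribute `"dropped"` listing the excluded
#'   invariant traits.
#' @export
standardize_traits <- function(table, use = c("codes", "raw")) {
  use <- match.arg(use)
  X <- if (inherits(table, "trait_table")) {
    if (use == "raw") {
      if (is.null(table$raw)) stop("trait table carries no raw values")
      table$raw
    } else table$codes
  } else as.matrix(table)
  storage.mode(X) <- "double"
  if (nrow(X) < 2L) stop("need at least 2 accessions")
  if (anyNA(X)) {
    warning("missing values mean-imputed before standardization")
    for (j in seq_len(ncol(X))) {
      X[is.na(X[, j]), j] <- mean(X[, j], na.rm = TRUE)
    }
  }
  v <- apply(X, 2L, var)
  dropped <- colnames(X)[v == 0 | is.na(v)]
  X <- X[, v > 0 & !is.na(v), drop = FALSE]
  if (ncol(X) == 0L) stop("all traits invariant")
  X <- scale(X)
  attr(X, "scaled:center") <- NULL
  attr(X, "scaled:scale") <- NULL
  attr(X, "dropped") <- dropped
  X
}

#' Principal component analysis of a standardized trait matrix
#'
#' Eigen-decomposition of the trait correlation matrix.  Components are
#' ordered by descending eigenvalue; `retained` counts components with
#' eigenvalue above 1 (Kaiser rule).  Scores are standardized to unit
#' variance, and each loading vector's largest-magnitude entry is made
#' positive so results are reproducible across eigensolvers.
#'
#' @param x Standardized matrix from [standardize_traits()].
#' @return Object of class `trait_pca` with `eigenvalues`, `loadings`,
#'   `scores`, `contribution`, `cumulative_contribution`, `retained`.
#' @export
trait_pca <- function(x) {
  if (nrow(x) < 2L || ncol(x) < 2L) stop("need >= 2 accessions and traits")
  C <- cor(x)
  eg <- eigen(C, symmetric = TRUE)
  lambda <- pmax(eg$values, 0)
  V <- eg$vectors
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  dimnames(V) <- list(colnames(x), paste0("PC", seq_len(ncol(V))))
  scores <- x %*% V
  pos <- lambda > 1e-12
  # raw score X v has sample variance lambda; divide to unit variance
  scores[, pos] <- sweep(scores[, pos, drop = FALSE], 2L,
                         sqrt(lambda[pos]), "/")
  scores[, !pos] <- 0
  rownames(scores) <- rownames(x)
  structure(
    list(eigenvalues = lambda, loadings = V, scores = scores,
         contribution = lambda / ncol(x),
         cumulative_contribution = cumsum(lambda / ncol(x)),
         retained = max(1L, sum(lambda > 1))),
    class = "trait_pca")
}

#' Eigenvalue-weighted comprehensive score
#'
#' The composite score `F` of each accession is the weighted sum of its
#' standardized scores on the retained components, with weights
#' `w_i = lambda_i / sum(lambda_retained)` -- each retained component
#' contributes in proportion to the variance it explains.
#'
#' @param pca A [trait_pca()] result.
#' @return Object of class `composite_score` with `weights` and
#'   `f_values`.
#' @export
composite_score <- function(pca) {
  stopifnot(inherits(pca, "trait_pca"))
  k <- pca$retained
  lam <- pca$eigenvalues[seq_len(k)]
  w <- lam / sum(lam)
  names(w) <- colnames(pca$scores)[seq_len(k)]
  f <- drop(pca$scores[, seq_len(k), drop = FALSE] %*% w)
  structure(list(weights = w, f_values = f), class = "composite_score")
}

#' Correlation of each trait with the composite score
#'
#' Pearson r of every analyzed trait with `F`, starred at two significance
#' levels (`*` and `**`), the conventional core-trait screening table.
#'
#' @param table A [trait_table()] or standardized matrix.
#' @param score A [composite_score()].
#' @param alpha_levels Two significance levels, default `c(0.05, 0.01)`.
#' @return Data frame with columns `trait_id`, `r`, `p`, `sig`.
#' @export
trait_f_correlation <- function(table, score, alpha_levels = c(0.05, 0.01)) {
  X <- if (inherits(table, "trait_table")) {
    standardize_traits(table)
  } else as.matrix(table)
  f <- score$f_values
  stopifnot(nrow(X) == length(f))
  n <- nrow(X)
  r <- as.numeric(cor(X, f))
  tstat <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, 1e-300))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  sig <- ifelse(p <= min(alpha_levels), "**",
                ifelse(p <= max(alpha_levels), "*", ""))
  data.frame(trait_id = colnames(X), r = r, p = p, sig = sig,
             stringsAsFactors = FALSE)
}

#' Stepwise selection of a core trait set
#'
#' Forward stepwise ordinary least squares of the composite score `F` on
#' the candidate traits (those significantly correlated with `F` at
#' `p_enter`), with entry/removal tests at `p_enter`/`p_remove`.  Entry
#' ties are broken by larger absolute correlation with `F`, then by trait
#' id order.  The fitted equation approximates `F` from a small trait
#' subset, which is what makes a reduced field-evaluation set defensible.
#'
#' @param table A [trait_table()] or standardized matrix.
#' @param score A [composite_score()].
#' @param p_enter Entry p-value threshold (default 0.05).
#' @param p_remove Removal p-value threshold (default 0.10); must exceed
#'   `p_enter` to prevent cycling.
#' @return Object of class `core_trait_set` with `selected_traits`,
#'   `coefficients`, `r_squared`, `correlation_table`, `path`.
#' @export
stepwise_select <- function(table, score, p_enter = 0.05, p_remove = 0.10) {
  if (p_enter >= p_remove) stop("p_enter must be smaller than p_remove")
  X <- if (inherits(table, "trait_table")) {
    standardize_traits(table)
  } else as.matrix(table)
  f <- score$f_values
  stopifnot(nrow(X) == length(f))
  ct <- trait_f_correlation(X, score, alpha_levels = c(p_enter, p_enter))
  cand <- ct$trait_id[ct$p <= p_enter]
  absr <- abs(ct$r); names(absr) <- ct$trait_id
  if (length(cand) == 0L) {
    warning("no candidate trait passes the entry threshold")
    return(structure(list(selected_traits = character(0),
                          coefficients = numeric(0), r_squared = 0,
                          correlation_table = ct, path = NULL),
                     class = "core_trait_set"))
  }
  sel <- character(0)
  path <- list()
  n <- length(f)
  sst <- sum((f - mean(f))^2)
  # fit of f on the selected columns (plus intercept); returns the
  # marginal t-test p per term and R^2 -- the classical stepwise tests
  fit_sel <- function(vars) {
    M <- cbind(`(Intercept)` = 1, X[, vars, drop = FALSE])
    fit <- stats::lm.fit(M, f)
    rdf <- n - ncol(M)
    s2 <- sum(fit$residuals^2) / rdf
    xtxinv <- chol2inv(qr.R(fit$qr))
    se <- sqrt(diag(xtxinv) * s2)
    tval <- fit$coefficients / se
    p <- 2 * pt(-abs(tval), df = rdf)
    list(coefficients = fit$coefficients, p = p[-1L],
         r2 = 1 - sum(fit$residuals^2) / sst, qr = fit$qr)
  }
  # entry p-values for every remaining candidate at once: partial
  # correlation of f with each candidate given the current model,
  # equivalent to the added-term t-test
  entry_scan <- function(vars, remaining) {
    M <- cbind(1, X[, vars, drop = FALSE])
    qrM <- qr(M)
    rf <- qr.resid(qrM, f)
    rx <- qr.resid(qrM, X[, remaining, drop = FALSE])
    num <- drop(crossprod(rx, rf))
    den <- sqrt(colSums(rx^2) * sum(rf^2))
    r <- ifelse(den > 0, num / den, 0)
    rdf <- n - ncol(M) - 1L
    tval <- r * sqrt(rdf) / sqrt(pmax(1 - r^2, 1e-300))
    p <- 2 * pt(-abs(tval), df = rdf)
    names(p) <- remaining
    p
  }
  repeat {
    remaining <- setdiff(cand, sel)
    if (length(remaining) == 0L) break
    entry <- entry_scan(sel, remaining)
    best_p <- min(entry)
    if (best_p > p_enter) break
    tied <- remaining[entry <= best_p + 1e-12]
    if (length(tied) > 1L) {
      tied <- tied[order(-absr[tied], match(tied, cand))]
    }
    add <- tied[1L]
    sel <- c(sel, add)
    res <- fit_sel(sel)
    path[[length(path) + 1L]] <- data.frame(
      step = length(path) + 1L, action = "add", trait_id = add,
      p = best_p, r_squared = res$r2, stringsAsFactors = FALSE)
    # backward pass
    repeat {
      if (length(sel) < 2L) break
      res <- fit_sel(sel)
      worst <- which.max(res$p)
      if (res$p[worst] < p_remove) break
      drop_id <- sel[worst]
      sel <- setdiff(sel, drop_id)
      path[[length(path) + 1L]] <- data.frame(
        step = length(path) + 1L, action = "remove", trait_id = drop_id,
        p = res$p[[worst]], r_squared = fit_sel(sel)$r2,
        stringsAsFactors = FALSE)
    }
  }
  final <- fit_sel(sel)
  cf <- final$coefficients
  names(cf) <- c("(Intercept)", sel)
  structure(
    list(selected_traits = sel, coefficients = cf,
         r_squared = final$r2, correlation_table = ct,
         path = do.call(rbind, path)),
    class = "core_trait_set")
}

#' @export
print.core_trait_set <- function(x, ...) {
  cat("core_trait_set:", length(x$selected_traits), "traits, R^2 =",
      signif(x$r_squared, 4), "\n")
  cat("  ", paste(x$selected_traits, collapse = ", "), "\n")
  invisible(x)
}
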