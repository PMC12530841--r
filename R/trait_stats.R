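#' Descriptive statistics for one trait
#'
#' Maximum, minimum, range, mean, standard deviation and coefficient of
#' variation over the non-missing values of a trait, plus the class
#' frequency distribution and Shannon-Weaver index of the grade codes.
#' The SD uses the population (divide-by-n) convention; `CV% = 100*SD/mean`
#' and is reported as missing for a zero-mean trait.
#'
#' @param table A [trait_table()].
#' @param trait_id Trait to summarize.
#' @param use `"codes"` (default) or `"raw"` for the max/min/mean/SD/CV
#'   block; class frequencies and H' always use the codes.
#' @return An object of class `trait_stats`.
#' @export
descriptive_stats <- function(table, trait_id, use = c("codes", "raw")) {
  use <- match.arg(use)
  stopifnot(inherits(table, "trait_table"))
  codes <- table$codes[, trait_id]
  x <- if (use == "raw") {
    if (is.null(table$raw)) stop("trait table carries no raw values")
    table$raw[, trait_id]
  } else {
    as.numeric(codes)
  }
  x <- x[!is.na(x)]
  if (length(x) == 0L) stop("trait ", trait_id, ": all values missing")
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  cv <- if (m == 0) NA_real_ else 100 * s / m
  obs <- codes[!is.na(codes)]
  freq <- as.numeric(table(obs)) / length(obs)
  names(freq) <- names(table(obs))
  structure(
    list(trait_id = trait_id, max = max(x), min = min(x),
         range = max(x) - min(x), mean = m, sd = s, cv_percent = cv,
         shannon_h = shannon_weaver(table, trait_id),
         class_frequencies = freq, n = length(x)),
    class = "trait_stats")
}

#' @export
print.trait_stats <- function(x, ...) {
  cat(sprintf("%s: n=%d mean=%.4g sd=%.4g cv=%.4g%% H'=%.4g\n",
              x$trait_id, x$n, x$mean, x$sd, x$cv_percent, x$shannon_h))
  invisible(x)
}

#' Shannon-Weaver diversity index of a trait
#'
#' `H' = -sum_i P_i ln P_i` over the relative frequencies of the observed
#' grade classes; 0 for a monomorphic trait.
#'
#' @param table A [trait_table()] (or a vector of codes).
#' @param trait_id Trait to evaluate (ignored when `table` is a vector).
#' @return Non-negative scalar.
#' @export
shannon_weaver <- function(table, trait_id = NULL) {
  x <- if (inherits(table, "trait_table")) table$codes[, trait_id] else table
  x <- x[!is.na(x)]
  if (length(x) == 0L) stop("no non-missing values")
  p <- as.numeric(table(x)) / length(x)
  -sum(p * log(p))
}

#' Per-trait descriptive statistics table
#'
#' One row per trait with max, min, range, mean, SD, CV% and H',
#' mirroring a standard DUS diversity summary table.
#'
#' @param table A [trait_table()].
#' @param use Passed to [descriptive_stats()].
#' @return Data frame with one row per trait.
#' @export
trait_stats_table <- function(table, use = c("codes", "raw")) {
  use <- match.arg(use)
  rows <- lapply(names(table$traits), function(id) {
    s <- descriptive_stats(table, id, use = use)
    data.frame(trait_id = id, max = s$max, min = s$min, range = s$range,
               mean = s$mean, sd = s$sd, cv_percent = s$cv_percent,
               shannon_h = s$shannon_h, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pairwise trait correlation matrix
#'
#' Pearson correlations between graded trait codes with two-sided t-test
#' p-values and a significance flag.  Missing codes are excluded pairwise;
#' zero-variance traits are excluded with a warning and their rows/columns
#' set to `NA`.
#'
#' @param table A [trait_table()].
#' @param alpha Significance level for the flag (default 0.01).
#' @return List with matrices `r`, `p`, `significant` and the character
#'   vector `excluded`.
#' @export
trait_correlation_matrix <- function(table, alpha = 0.01) {
  stopifnot(inherits(table, "trait_table"))
  X <- table$codes
  storage.mode(X) <- "double"
  if (nrow(X) < 3L) stop("need at least 3 accessions")
  v <- apply(X, 2L, function(col) var(col, na.rm = TRUE))
  excluded <- colnames(X)[is.na(v) | v == 0]
  if (length(excluded)) {
    warning("zero-variance traits excluded: ",
            paste(excluded, collapse = ", "))
  }
  keep <- setdiff(colnames(X), excluded)
  p <- r <- matrix(NA_real_, ncol(X), ncol(X),
                   dimnames = list(colnames(X), colnames(X)))
  Xk <- X[, keep, drop = FALSE]
  rk <- cor(Xk, use = "pairwise.complete.obs")
  nk <- crossprod(!is.na(Xk))          # pairwise complete counts
  tstat <- rk * sqrt(pmax(nk - 2, 0)) / sqrt(pmax(1 - rk^2, 0))
  pk <- 2 * pt(-abs(tstat), df = pmax(nk - 2, 1))
  pk[which(abs(rk) >= 1 - 1e-15)] <- 0
  diag(rk) <- 1; diag(pk) <- 0
  r[keep, keep] <- rk
  p[keep, keep] <- pk
  list(r = r, p = p, significant = p <= alpha, excluded = excluded)
}
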