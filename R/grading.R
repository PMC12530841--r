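#' Build an LSD-based grading scheme for a quantitative trait
#'
#' Quantitative DUS traits are binned into an odd number of grades whose
#' class width exceeds twice the least significant difference (LSD) of a
#' one-way ANOVA of the replicate measurements on accession, so that two
#' accessions one grade apart differ by more than experimental noise.
#' The grand mean of the trait is placed at the midpoint of the central
#' grade and boundaries extend symmetrically.
#'
#' `LSD_alpha = t(1 - alpha/2, df_error) * sqrt(2 * MSE / r)` where `MSE`
#' is the ANOVA error mean square and `r` the harmonic-mean replicate
#' count.  The class width is the smallest value exceeding `2 * LSD` that
#' still spans the observed range of accession means within `n_grades`
#' classes.
#'
#' @param replicates Data frame with columns `accession_id` and `value`
#'   (a `trait_id` column, if present, must be constant).
#' @param alpha Significance level of the LSD (default 0.05).
#' @param n_grades Odd number of grades (3, 5 or 7 in DUS practice).
#' @param codes Integer codes for the grades; defaults to the odd numbers
#'   `1, 3, 5, ...`.
#' @return An object of class `grading_scheme` with fields `trait_id`,
#'   `boundaries`, `codes`, `center`, `class_width`, `lsd_alpha`,
#'   `lsd_value`.
#' @export
build_lsd_grading <- function(replicates, alpha = 0.05, n_grades = 5L,
                              codes = NULL) {
  if (n_grades %% 2L != 1L) stop("n_grades must be odd")
  if (!is.null(replicates$trait_id)) {
    tid <- unique(as.character(replicates$trait_id))
    if (length(tid) > 1L) stop("replicates span more than one trait")
  } else {
    tid <- NA_character_
  }
  if (is.null(codes)) codes <- seq(1L, by = 2L, length.out = n_grades)
  codes <- as.integer(codes)
  if (length(codes) != n_grades) stop("need exactly n_grades codes")

  acc <- as.character(replicates$accession_id)
  val <- as.numeric(replicates$value)
  reps <- table(acc)
  if (length(reps) < 2L) stop("need at least 2 accessions")
  if (any(reps < 2L)) {
    stop("insufficient replication: accessions with < 2 replicates: ",
         paste(names(reps)[reps < 2L], collapse = ", "))
  }

  means <- tapply(val, acc, mean)
  center <- mean(val)
  rng <- max(means) - min(means)

  if (all(val == val[1L])) {
    return(structure(
      list(trait_id = tid, boundaries = numeric(0), codes = codes[1L],
           center = center, class_width = 0, lsd_alpha = alpha,
           lsd_value = 0),
      class = "grading_scheme"))
  }

  # one-way ANOVA error mean square, computed from within-group sums
  # of squares directly
  ss_within <- sum((val - ave(val, acc))^2)
  df_err <- length(val) - length(reps)
  mse <- ss_within / df_err
  r_h <- length(reps) / sum(1 / as.numeric(reps))
  lsd <- qt(1 - alpha / 2, df_err) * sqrt(2 * mse / r_h)

  w_span <- rng / n_grades
  width <- if (w_span > 2 * lsd) w_span else 2 * lsd * (1 + 1e-9)
  if (width == 0) {
    # replicate noise zero and all accession means equal
    return(structure(
      list(trait_id = tid, boundaries = numeric(0), codes = codes[1L],
           center = center, class_width = 0, lsd_alpha = alpha,
           lsd_value = lsd),
      class = "grading_scheme"))
  }
  boundaries <- center + width * (seq_len(n_grades - 1L) - n_grades / 2)
  structure(
    list(trait_id = tid, boundaries = boundaries, codes = codes,
         center = center, class_width = width, lsd_alpha = alpha,
         lsd_value = lsd),
    class = "grading_scheme")
}

#' @export
print.grading_scheme <- function(x, ...) {
  cat("grading_scheme", if (!is.na(x$trait_id)) x$trait_id else "", "\n")
  cat("  codes:", paste(x$codes, collapse = " "), "\n")
  cat("  boundaries:", paste(signif(x$boundaries, 6), collapse = " "), "\n")
  cat("  center:", signif(x$center, 6), " width:", signif(x$class_width, 6),
      " LSD:", signif(x$lsd_value, 6), "\n")
  invisible(x)
}

#' Map raw trait values to grade codes
#'
#' Grades are half-open intervals `[b_i, b_{i+1})`; values below the first
#' boundary take the lowest code and values at or above the last boundary
#' take the highest (extreme grades are unbounded).  Missing values stay
#' missing.
#'
#' @param values Numeric vector of per-accession trait values.
#' @param scheme A [build_lsd_grading()] scheme.
#' @return Integer codes, same length and names as `values`.
#' @export
apply_grading <- function(values, scheme) {
  stopifnot(inherits(scheme, "grading_scheme"))
  if (length(scheme$boundaries) == 0L) {
    out <- rep(scheme$codes[1L], length(values))
  } else {
    out <- scheme$codes[findInterval(values, scheme$boundaries) + 1L]
  }
  out[is.na(values)] <- NA_integer_
  names(out) <- names(values)
  as.integer(out)
}
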