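#' Describe a single DUS trait
#'
#' A trait descriptor names a graded DUS (distinctness, uniformity,
#' stability) trait and fixes the legal set of integer grade codes, e.g.
#' `0 = absent, 1 = present` for bulbil presence or `3/5/7` for a
#' three-grade quantitative trait.
#'
#' @param trait_id Short label, e.g. `"T22"`.
#' @param name Human-readable trait name.
#' @param kind `"qualitative"` or `"quantitative"`.
#' @param class_codes Strictly increasing integer vector of legal codes.
#' @param is_core Whether the trait belongs to the core evaluation set.
#' @return An object of class `trait_descriptor`.
#' @export
trait_descriptor <- function(trait_id, name = trait_id,
                             kind = c("qualitative", "quantitative"),
                             class_codes, is_core = FALSE) {
  kind <- match.arg(kind)
  class_codes <- as.integer(class_codes)
  if (length(class_codes) == 0L) {
    stop("trait ", trait_id, ": class_codes must be non-empty")
  }
  if (is.unsorted(class_codes, strictly = TRUE)) {
    stop("trait ", trait_id, ": class_codes must be strictly increasing")
  }
  structure(
    list(trait_id = as.character(trait_id), name = as.character(name),
         kind = kind, class_codes = class_codes, is_core = isTRUE(is_core)),
    class = "trait_descriptor")
}

#' Assemble a validated DUS trait table
#'
#' Holds the accession-by-trait matrix of integer grade codes, plus
#' optional per-accession raw trait means and replicate-level raw
#' measurements.  Every non-missing code must belong to its trait's
#' `class_codes`; offenders are reported with accession and trait names.
#'
#' @param codes Integer matrix (accessions x traits) with accession ids as
#'   row names; `NA` marks missing.
#' @param descriptors List of [trait_descriptor()] objects, one per column.
#' @param raw Optional numeric matrix of per-accession trait means with the
#'   same dimensions as `codes`.
#' @param replicates Optional long data frame with columns
#'   `accession_id, trait_id, replicate, value`.
#' @return An object of class `trait_table`.
#' @export
trait_table <- function(codes, descriptors, raw = NULL, replicates = NULL) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  ids <- unname(vapply(descriptors, function(d) d$trait_id, character(1)))
  if (is.null(colnames(codes))) colnames(codes) <- ids
  if (!identical(colnames(codes), ids)) {
    stop("code matrix columns do not match descriptor trait ids")
  }
  if (is.null(rownames(codes))) {
    stop("code matrix must carry accession ids as row names")
  }
  names(descriptors) <- ids
  bad <- character(0)
  for (j in seq_along(ids)) {
    legal <- descriptors[[j]]$class_codes
    off <- which(!is.na(codes[, j]) & !(codes[, j] %in% legal))
    if (length(off)) {
      bad <- c(bad, paste0(ids[j], ": accession ",
                           rownames(codes)[off], " code ", codes[off, j]))
    }
  }
  if (length(bad)) {
    stop("codes outside the trait's class_codes:\n  ",
         paste(bad, collapse = "\n  "))
  }
  if (!is.null(raw)) {
    raw <- as.matrix(raw)
    if (!all(dim(raw) == dim(codes))) {
      stop("raw matrix dimensions differ from the code matrix")
    }
  }
  if (!is.null(replicates)) {
    need <- c("accession_id", "trait_id", "replicate", "value")
    if (!all(need %in% names(replicates))) {
      stop("replicates must have columns ", paste(need, collapse = ", "))
    }
  }
  structure(
    list(accessions = rownames(codes), traits = descriptors,
         codes = codes, raw = raw, replicates = replicates),
    class = "trait_table")
}

#' @export
print.trait_table <- function(x, ...) {
  cat("trait_table:", length(x$accessions), "accessions x",
      length(x$traits), "traits\n")
  cat("  missing codes:", sum(is.na(x$codes)), "\n")
  if (!is.null(x$replicates)) {
    cat("  replicate records:", nrow(x$replicates), "\n")
  }
  invisible(x)
}

#' Read a wide CSV of graded trait codes
#'
#' Expects a header row with an accession-id column first, then one column
#' per trait (matched to `descriptors` by name).  `NA` cells are preserved
#' as missing; any code outside a trait's legal set raises a validation
#' error naming trait and accession.
#'
#' @param path CSV file path.
#' @param descriptors List of [trait_descriptor()] objects for the trait
#'   columns present in the file.
#' @return A [trait_table()].
#' @export
read_trait_table <- function(path, descriptors) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("malformed CSV: need accession column plus traits")
  ids <- unname(vapply(descriptors, function(d) d$trait_id, character(1)))
  missing_cols <- setdiff(ids, names(df)[-1])
  if (length(missing_cols)) {
    stop("trait columns absent from ", path, ": ",
         paste(missing_cols, collapse = ", "))
  }
  codes <- as.matrix(df[, ids, drop = FALSE])
  suppressWarnings(storage.mode(codes) <- "integer")
  rownames(codes) <- as.character(df[[1]])
  trait_table(codes, descriptors)
}

#' Read replicate-level raw trait measurements
#'
#' Long CSV with columns `accession_id, trait_id, replicate, value`.
#'
#' @param path CSV file path.
#' @return A data frame.
#' @export
read_replicates <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("accession_id", "trait_id", "replicate", "value")
  if (!all(need %in% names(df))) {
    stop("replicate CSV must have columns ", paste(need, collapse = ", "))
  }
  df$value <- as.numeric(df$value)
  df
}
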