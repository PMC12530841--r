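#' Construct a codominant diploid genotype matrix
#'
#' Allele calls are unordered pairs of integer fragment sizes (bp); a
#' single detected allele is stored as a homozygous pair, and pairs are
#' stored sorted so `(182, 178)` and `(178, 182)` are the same genotype.
#' Missing is per cell (both copies).
#'
#' @param allele1,allele2 Integer matrices (accessions x loci); `NA` in
#'   either marks the cell missing.
#' @param accessions Accession ids (row names).
#' @param loci Locus names (column names).
#' @return Object of class `genotype_matrix` with sorted pair matrices
#'   `a1 <= a2`.
#' @export
genotype_matrix <- function(allele1, allele2, accessions = rownames(allele1),
                            loci = colnames(allele1)) {
  a1 <- as.matrix(allele1); a2 <- as.matrix(allele2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  if (!all(dim(a1) == dim(a2))) stop("allele matrices differ in shape")
  if (is.null(accessions) || is.null(loci)) {
    stop("accession ids and locus names are required")
  }
  bad <- which(!is.na(a1) & a1 <= 0L | !is.na(a2) & a2 <= 0L)
  if (length(bad)) stop("allele sizes must be positive integers")
  miss <- is.na(a1) | is.na(a2)
  a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
  swap <- !miss & a1 > a2
  tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  dimnames(a1) <- dimnames(a2) <- list(accessions, loci)
  structure(list(accessions = accessions, loci = loci, a1 = a1, a2 = a2,
                 ploidy = 2L),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$accessions), "accessions x",
      length(x$loci), "loci (diploid)\n")
  cat("  missing cells:", sum(is.na(x$a1)), "\n")
  invisible(x)
}

#' Read SSR genotypes from CSV
#'
#' Auto-detects the dialect from the header: long format
#' (`accession_id,locus,allele1,allele2`; blank `allele2` records a
#' single-peak call as homozygous) or wide format (first column
#' `accession_id`, then two columns `<locus>_1,<locus>_2` per locus).
#'
#' @param path CSV file path.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  hdr <- names(df)
  if (identical(hdr[seq_len(2L)], c("accession_id", "locus")) &&
      all(c("allele1", "allele2") %in% hdr)) {
    acc <- unique(as.character(df$accession_id))
    loci <- unique(as.character(df$locus))
    key <- paste(df$accession_id, df$locus, sep = "\r")
    if (anyDuplicated(key)) {
      d <- df[duplicated(key), , drop = FALSE]
      stop("duplicate (accession, locus) rows: ",
           paste(unique(paste(d$accession_id, d$locus)), collapse = ", "))
    }
    parse_allele <- function(x) {
      x <- trimws(as.character(x))
      x[x == ""] <- NA
      num <- suppressWarnings(as.numeric(x))
      if (any(!is.na(x) & (is.na(num) | num != round(num)))) {
        stop("non-integer allele size in ", path)
      }
      as.integer(num)
    }
    v1 <- parse_allele(df$allele1)
    v2 <- parse_allele(df$allele2)
    v2[is.na(v2) & !is.na(v1)] <- v1[is.na(v2) & !is.na(v1)]  # single peak
    a1 <- matrix(NA_integer_, length(acc), length(loci),
                 dimnames = list(acc, loci))
    a2 <- a1
    i <- cbind(match(df$accession_id, acc), match(df$locus, loci))
    a1[i] <- v1; a2[i] <- v2
    return(genotype_matrix(a1, a2))
  }
  if (hdr[1L] == "accession_id" &&
      length(hdr) > 1L && all(grepl("_[12]$", hdr[-1L]))) {
    loci <- unique(sub("_[12]$", "", hdr[-1L]))
    c1 <- paste0(loci, "_1"); c2 <- paste0(loci, "_2")
    if (!all(c(c1, c2) %in% hdr)) stop("wide dialect: unpaired locus columns")
    acc <- as.character(df$accession_id)
    if (anyDuplicated(acc)) stop("duplicate accession rows")
    a1 <- as.matrix(df[, c1, drop = FALSE])
    a2 <- as.matrix(df[, c2, drop = FALSE])
    suppressWarnings({storage.mode(a1) <- "integer"
                      storage.mode(a2) <- "integer"})
    single <- is.na(a2) & !is.na(a1)
    a2[single] <- a1[single]
    dimnames(a1) <- dimnames(a2) <- list(acc, loci)
    return(genotype_matrix(a1, a2))
  }
  stop("unknown genotype CSV dialect (header: ",
       paste(head(hdr, 5), collapse = ","), " ...)")
}

#' Write SSR genotypes to CSV
#'
#' @param gm A [genotype_matrix()].
#' @param path Output file.
#' @param format `"long"`, `"wide"`, or `"structure"` (two rows per
#'   individual, one allele copy per row-entry, `-9` for missing).
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gm, path, format = c("long", "wide",
                                                 "structure")) {
  format <- match.arg(format)
  if (format == "long") {
    idx <- expand.grid(a = seq_along(gm$accessions),
                       l = seq_along(gm$loci))
    df <- data.frame(accession_id = gm$accessions[idx$a],
                     locus = gm$loci[idx$l],
                     allele1 = gm$a1[cbind(idx$a, idx$l)],
                     allele2 = gm$a2[cbind(idx$a, idx$l)])
    df <- df[order(match(df$accession_id, gm$accessions),
                   match(df$locus, gm$loci)), ]
    write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  } else if (format == "wide") {
    out <- data.frame(accession_id = gm$accessions)
    for (l in gm$loci) {
      out[[paste0(l, "_1")]] <- gm$a1[, l]
      out[[paste0(l, "_2")]] <- gm$a2[, l]
    }
    write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NA")
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(c("accession_id", gm$loci), collapse = "\t"), con)
    for (i in seq_along(gm$accessions)) {
      r1 <- gm$a1[i, ]; r2 <- gm$a2[i, ]
      r1[is.na(r1)] <- -9L; r2[is.na(r2)] <- -9L
      writeLines(paste(c(gm$accessions[i], r1), collapse = "\t"), con)
      writeLines(paste(c(gm$accessions[i], r2), collapse = "\t"), con)
    }
  }
  invisible(path)
}

#' Subset a genotype matrix by accessions
#'
#' @param gm A [genotype_matrix()].
#' @param ids Accession ids to keep, in the given order.
#' @return A [genotype_matrix()].
#' @export
subset_genotypes <- function(gm, ids) {
  stopifnot(all(ids %in% gm$accessions))
  genotype_matrix(gm$a1[ids, , drop = FALSE], gm$a2[ids, , drop = FALSE])
}
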